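# Co-occurrence network construction, topology, modules, Zi-Pi node roles
# and keystone taxon comparison.
#
# Networks are built per condition group from prevalence-filtered relative
# abundances: edges are Spearman correlations with |rho| > 0.6 and
# two-sided p < 0.05 (t-approximation); module detection maximizes
# Newman-Girvan modularity on the unweighted, unsigned graph; node roles
# follow the degree-based within-module z-score / participation
# coefficient scheme with thresholds Zi = 2.5 and Pi = 0.62.

#' Prevalence filter
#'
#' Keeps OTUs present (nonzero) in strictly more than `min_prevalence`
#' of the samples; e.g. at 0.5, 23/44 samples is kept and 22/44 dropped.
#'
#' @param counts samples x OTUs matrix.
#' @param min_prevalence fraction in (0, 1].
#' @return filtered matrix.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.5) {
  if (min_prevalence <= 0 || min_prevalence > 1)
    fail("min_prevalence must be in (0, 1]")
  prev <- colMeans(counts > 0)
  keep <- prev > min_prevalence
  if (!any(keep))
    fail("no OTU exceeds prevalence ", min_prevalence,
         " (max observed ", signif(max(prev), 3), ")")
  counts[, keep, drop = FALSE]
}

#' All-pairs Spearman correlation edges
#'
#' Spearman rho with average ranks on ties, two-sided p from the
#' t-approximation; pairs with |rho| > `rho_min` and p < `p_max` are
#' retained, preserving the sign of rho.  Zero-variance OTUs have
#' undefined correlations; their pairs are excluded with a warning.
#'
#' @param x samples x OTUs matrix (relative abundances of the rarefied
#'   table by default in the pipeline).
#' @param rho_min absolute-correlation threshold (default 0.6).
#' @param p_max significance threshold on the raw p (default 0.05); set
#'   `adjust = "BH"` to threshold Benjamini-Hochberg adjusted p instead.
#' @param adjust `"none"` (default, the raw-p convention) or `"BH"`.
#' @return data.frame with columns from, to, rho, p.
#' @export
correlation_edges <- function(x, rho_min = 0.6, p_max = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  n <- nrow(x)
  if (n < 4) fail("need >= 4 samples for correlation edges")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " zero-variance OTU(s) excluded (",
            sum(const) * (ncol(x) - 1) - choose(sum(const), 2),
            " pairs dropped)")
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) return(data.frame(from = character(0), to = character(0),
                                     rho = numeric(0), p = numeric(0)))
  rk <- apply(x, 2, rank)
  C <- stats::cor(rk)
  iu <- which(upper.tri(C), arr.ind = TRUE)
  rho <- C[upper.tri(C)]
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  keep <- abs(rho) > rho_min & padj < p_max
  data.frame(from = colnames(x)[iu[keep, 1]],
             to = colnames(x)[iu[keep, 2]],
             rho = rho[keep], p = p[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble an igraph co-occurrence network from an edge list
#'
#' Nodes are the OTUs incident to at least one retained edge; each node
#' carries its mean relative abundance and phylum, each edge its signed
#' rho, |rho| as weight, and a positive/negative label.
#'
#' @param edges data.frame from [correlation_edges()].
#' @param x the samples x OTUs relative-abundance matrix the edges came from.
#' @param tax taxonomy data.frame (optional, for phylum attributes).
#' @param group optional label of the source sample group.
#' @return igraph object.
#' @export
build_cooccurrence_network <- function(edges, x, tax = NULL, group = NA_character_) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (length(nodes)) {
    vert$abundance <- colMeans(x[, nodes, drop = FALSE] / rowSums(x))
    if (!is.null(tax)) {
      ph <- tax$phylum[match(nodes, tax$otu_id)]
      vert$phylum <- ifelse(is.na(ph), "unclassified", ph)
    }
  }
  if (nrow(edges)) {
    edges$weight <- abs(edges$rho)
    edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  igraph::graph_attr(g, "group") <- group
  g
}

#' Detect modules by modularity maximization
#'
#' Louvain-style greedy maximization of Newman-Girvan modularity
#' Q = sum_m (e_m/E - (d_m/2E)^2) on the unweighted, unsigned graph,
#' seeded for determinism.  An edgeless graph puts every node in its own
#' module with Q = 0.
#'
#' @param net igraph object.
#' @param seed integer seed.
#' @return list with `membership` (named integer vector), `modularity`,
#'   `n_modules`.
#' @export
detect_modules <- function(net, seed = 1L) {
  n <- igraph::vcount(net)
  if (igraph::ecount(net) == 0) {
    memb <- seq_len(n)
    names(memb) <- igraph::V(net)$name
    return(list(membership = memb, modularity = 0, n_modules = n))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(net, weights = NA)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(net, memb, weights = rep(1, igraph::ecount(net)))
  list(membership = memb, modularity = q,
       n_modules = length(unique(memb)))
}

#' Within-module degree z-score and participation coefficient
#'
#' For node i in module s, with k_js = number of links of node j into
#' module s:  Zi = (k_is - mean_(j in s) k_js) / sd_(j in s) k_js
#' (population sd by default; Zi = 0 when the sd is 0), and
#' Pi = 1 - sum_t (k_it / k_i)^2 over all modules t.  Roles at the
#' thresholds Zi = 2.5, Pi = 0.62: peripheral (both low), connector
#' (Pi high only), provincial hub (Zi high only), kinless hub (both
#' high); exact-equality cases fall to the lower category.  Degrees are
#' unweighted.
#'
#' @param net igraph object.
#' @param membership module assignment (named, in vertex order).
#' @param zi_threshold,pi_threshold role thresholds (defaults 2.5, 0.62).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return data.frame with otu_id, module, degree, zi, pi, role.
#' @export
zi_pi <- function(net, membership, zi_threshold = 2.5, pi_threshold = 0.62,
                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- igraph::vcount(net)
  memb <- as.integer(membership)
  mods <- sort(unique(memb))
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  A <- (A > 0) + 0
  # k_links[i, t] = links of node i into module t
  ind <- outer(memb, mods, `==`) + 0
  k_links <- A %*% ind
  k <- rowSums(A)
  own <- k_links[cbind(seq_len(n), match(memb, mods))]
  zi <- numeric(n)
  for (s in seq_along(mods)) {
    in_s <- memb == mods[s]
    ks <- k_links[in_s, s]
    sdv <- if (sd_type == "population") sd_pop(ks) else stats::sd(ks)
    zi[in_s] <- if (is.na(sdv) || sdv == 0) 0 else (ks - mean(ks)) / sdv
  }
  pi_ <- ifelse(k > 0, 1 - rowSums((k_links / pmax(k, 1))^2), 0)
  hub <- zi > zi_threshold
  conn <- pi_ > pi_threshold
  role <- ifelse(hub & conn, "kinless_hub",
          ifelse(hub, "provincial_hub",
          ifelse(conn, "connector", "peripheral")))
  data.frame(otu_id = igraph::V(net)$name, module = memb,
             degree = as.integer(k), zi = zi, pi = pi_, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Keystone taxon report
#'
#' Keystones are the non-peripheral nodes (connectors, provincial hubs,
#' kinless hubs).  Reports each keystone's genus and relative-abundance
#' range (percent, across the given samples) and the keystone set's share
#' of total reads.
#'
#' @param roles data.frame from [zi_pi()].
#' @param tax taxonomy data.frame.
#' @param counts samples x OTUs matrix the share is computed against.
#' @return list with `taxa` (data.frame) and `share` (fraction of reads).
#' @export
keystone_taxa <- function(roles, tax, counts) {
  key <- roles[roles$role != "peripheral", , drop = FALSE]
  rel <- counts / rowSums(counts)
  if (nrow(key)) {
    present <- key$otu_id %in% colnames(counts)
    if (!all(present)) {
      warning("keystone OTU(s) absent from table: ",
              paste(key$otu_id[!present], collapse = ", "))
      key <- key[present, , drop = FALSE]
    }
  }
  taxa <- if (nrow(key)) {
    ra <- rel[, key$otu_id, drop = FALSE]
    data.frame(otu_id = key$otu_id, role = key$role,
               genus = tax$genus[match(key$otu_id, tax$otu_id)],
               mean_pct = 100 * colMeans(ra),
               min_pct = 100 * apply(ra, 2, min),
               max_pct = 100 * apply(ra, 2, max),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(otu_id = character(0), role = character(0),
               genus = character(0), mean_pct = numeric(0),
               min_pct = numeric(0), max_pct = numeric(0))
  }
  share <- if (nrow(key)) sum(counts[, key$otu_id]) / sum(counts) else 0
  list(taxa = taxa, share = share)
}

#' Compare keystone taxa between the two condition groups
#'
#' For every OTU that is a keystone in either group, a two-sided Wilcoxon
#' rank-sum test of relative abundance between groups, BH-adjusted.
#'
#' @param report_a,report_b keystone reports ([keystone_taxa()]) for the
#'   two groups.
#' @param counts full samples x OTUs matrix (both groups).
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame with otu_id, keystone_in, p, p_adj, higher_group,
#'   significant.
#' @export
compare_keystones <- function(report_a, report_b, counts, metadata,
                              alpha = 0.05) {
  otus <- union(report_a$taxa$otu_id, report_b$taxa$otu_id)
  miss <- setdiff(otus, colnames(counts))
  if (length(miss)) {
    warning("keystone OTU(s) absent from table, skipped: ",
            paste(miss, collapse = ", "))
    otus <- setdiff(otus, miss)
  }
  groups <- metadata$group[match(rownames(counts), metadata$sample_id)]
  lev <- unique(groups)
  rel <- counts / rowSums(counts)
  rows <- lapply(otus, function(o) {
    v <- rel[, o]
    a <- v[groups == lev[1]]; b <- v[groups == lev[2]]
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    data.frame(otu_id = o,
               keystone_in = paste(c(
                 if (o %in% report_a$taxa$otu_id) "A",
                 if (o %in% report_b$taxa$otu_id) "B"), collapse = "+"),
               p = p,
               higher_group = if (mean(a) >= mean(b)) lev[1] else lev[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(otu_id = character(0), keystone_in = character(0),
                      p = numeric(0), p_adj = numeric(0),
                      higher_group = character(0), significant = logical(0)))
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p_adj < alpha
  out[, c("otu_id", "keystone_in", "p", "p_adj", "higher_group", "significant")]
}

#' Topological summary of a network
#'
#' Average clustering is the mean of per-node local clustering
#' coefficients (0 for nodes of degree < 2); average path length is the
#' mean shortest-path length over connected pairs of the largest
#' connected component.
#'
#' @param net igraph object.
#' @param modules optional result of [detect_modules()] to fill the
#'   modularity fields.
#' @return one-row data.frame of summary statistics.
#' @export
topology_summary <- function(net, modules = NULL) {
  n <- igraph::vcount(net); e <- igraph::ecount(net)
  if (n == 0) {
    warning("empty network")
    return(data.frame(node_count = 0, edge_count = 0,
                      positive_edge_fraction = NA_real_, average_degree = 0,
                      average_clustering_coefficient = 0,
                      average_path_length = 0,
                      modularity = NA_real_, module_count = NA_integer_))
  }
  pos_frac <- if (e > 0 && "sign" %in% igraph::edge_attr_names(net))
    mean(igraph::E(net)$sign == "positive") else NA_real_
  local_cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(net, which(comp$membership ==
                                                 which.max(comp$csize)))
  apl <- if (igraph::vcount(giant) > 1)
    igraph::mean_distance(giant, directed = FALSE) else 0
  data.frame(node_count = n, edge_count = e,
             positive_edge_fraction = pos_frac,
             average_degree = 2 * e / n,
             average_clustering_coefficient = mean(local_cc),
             average_path_length = apl,
             modularity = if (!is.null(modules)) modules$modularity else NA_real_,
             module_count = if (!is.null(modules)) modules$n_modules else NA_integer_)
}

#' Build, modularize and classify a group's network in one call
#'
#' Convenience wrapper: prevalence filter, relative abundance, correlation
#' edges, graph assembly, module detection, Zi-Pi roles, keystone report
#' and topology summary for the samples of one group.
#'
#' @param counts samples x OTUs matrix (one group's samples).
#' @param tax taxonomy data.frame.
#' @param group group label recorded on the graph.
#' @param rho_min,p_max,prevalence thresholds (defaults 0.6, 0.05, 0.5).
#' @param seed integer seed for module detection.
#' @return list: net, modules, roles, keystones, topology, filtered table.
#' @export
group_network <- function(counts, tax, group = NA_character_,
                          rho_min = 0.6, p_max = 0.05, prevalence = 0.5,
                          seed = 1L) {
  filt <- prevalence_filter(counts, prevalence)
  rel <- filt / rowSums(filt)
  edges <- correlation_edges(rel, rho_min = rho_min, p_max = p_max)
  net <- build_cooccurrence_network(edges, rel, tax, group = group)
  mods <- detect_modules(net, seed = seed)
  roles <- zi_pi(net, mods$membership)
  keys <- keystone_taxa(roles, tax, counts)
  topo <- topology_summary(net, mods)
  list(net = net, modules = mods, roles = roles, keystones = keys,
       topology = topo, filtered = filt)
}
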