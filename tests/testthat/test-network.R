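# Network construction, modules, Zi-Pi roles, keystones and topology.

test_that("prevalence filter applies a strict boundary", {
  n <- 44
  x <- matrix(0, n, 3, dimnames = list(paste0("S", 1:n), c("keep", "drop", "all")))
  x[1:23, "keep"] <- 1
  x[1:22, "drop"] <- 1
  x[, "all"] <- 2
  out <- prevalence_filter(x, 0.5)
  expect_setequal(colnames(out), c("keep", "all"))
  expect_equal(prevalence_filter(x[, "all", drop = FALSE], 0.5),
               x[, "all", drop = FALSE])
  empty <- matrix(c(1, rep(0, 9)), 10, 1, dimnames = list(paste0("S", 1:10), "rare"))
  expect_error(prevalence_filter(empty, 0.5), "0.1")
})

test_that("perfect monotone relations give unit correlations with signs", {
  x <- cbind(a = 1:10, b = (1:10)^2, c = -(1:10), d = rnorm(10, 100))
  rownames(x) <- paste0("S", 1:10)
  e <- correlation_edges(x, rho_min = 0.6, p_max = 0.05)
  ab <- e[e$from == "a" & e$to == "b", ]
  expect_equal(ab$rho, 1)
  ac <- e[e$from == "a" & e$to == "c", ]
  expect_equal(ac$rho, -1)
  expect_true(all(e$p < 0.05))
})

test_that("Spearman rho and p match independent oracles on random vectors", {
  set.seed(55)
  for (i in 1:200) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- sample(1:5, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    m <- cbind(a = x, b = y, c = rnorm(8))
    rownames(m) <- paste0("S", 1:8)
    e <- correlation_edges(m, rho_min = 0, p_max = 1.0000001)
    got <- e[e$from == "a" & e$to == "b", ]
    expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("zero-variance OTUs are excluded with a warning", {
  x <- cbind(a = 1:10, b = c(2:10, 1), flat = rep(5, 10))
  rownames(x) <- paste0("S", 1:10)
  expect_warning(e <- correlation_edges(x), "zero-variance")
  expect_false("flat" %in% c(e$from, e$to))
})

test_that("edge retention is monotone in the correlation threshold", {
  set.seed(8)
  x <- matrix(rpois(200, 20), 10)
  x <- x + outer(rnorm(10), rep(1, 20)) * 5  # shared gradient -> correlations
  dimnames(x) <- list(paste0("S", 1:10), paste0("O", 1:20))
  loose <- correlation_edges(x, rho_min = 0.4, p_max = 0.2)
  tight <- correlation_edges(x, rho_min = 0.7, p_max = 0.2)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(tight) %in% key(loose)))
  # invariance to sample permutation and monotone transforms
  perm <- sample(10)
  e1 <- correlation_edges(x, 0.5, 0.1)
  e2 <- correlation_edges(x[perm, ], 0.5, 0.1)
  expect_equal(e1, e2)
  e3 <- correlation_edges(x^3, 0.5, 0.1)
  expect_equal(e1$rho, e3$rho, tolerance = 1e-12)
})

test_that("two disjoint cliques are split exactly with Q = 0.5", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- paste0("O", 1:10)
  mods <- detect_modules(g, seed = 1)
  expect_equal(mods$n_modules, 2L)
  expect_equal(mods$modularity, 0.5, tolerance = 1e-12)
  expect_equal(oracle_ari(mods$membership, rep(1:2, each = 5)), 1)
  single <- igraph::make_full_graph(5)
  igraph::V(single)$name <- paste0("O", 1:5)
  m1 <- detect_modules(single, seed = 1)
  expect_equal(m1$n_modules, 1L)
  expect_equal(m1$modularity, 0)
})

test_that("edgeless graphs degrade to singleton modules", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- paste0("O", 1:4)
  mods <- detect_modules(g, seed = 1)
  expect_equal(mods$n_modules, 4L)
  expect_equal(mods$modularity, 0)
})

test_that("planted three-block graphs are recovered with high ARI", {
  aris <- vapply(1:20, function(s) {
    set.seed(s)
    blocks <- rep(1:3, each = 20)
    n <- 60
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (blocks[i] == blocks[j]) 0.6 else 0.02
      adj[i, j] <- rbinom(1, 1, p)
    }
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- paste0("O", 1:n)
    mods <- detect_modules(g, seed = s)
    oracle_ari(mods$membership, blocks)
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.95)
})

test_that("Zi and Pi match closed forms on hand-built graphs", {
  # path A-B, C-D in module 1/1 and 2/2: all links internal -> Pi = 0
  g <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("C", "D")),
                                   directed = FALSE)
  memb <- c(A = 1, B = 1, C = 2, D = 2)[igraph::V(g)$name]
  r <- zi_pi(g, memb)
  expect_true(all(r$pi == 0))
  expect_true(all(r$zi == 0))          # sd of degrees within module is 0
  # hub with degree 4 split 2/2 across two modules -> Pi = 0.5
  g2 <- igraph::graph_from_edgelist(
    rbind(c("H", "a1"), c("H", "a2"), c("H", "b1"), c("H", "b2"), c("a1", "a2")),
    directed = FALSE)
  memb2 <- c(H = 1, a1 = 1, a2 = 1, b1 = 2, b2 = 2)[igraph::V(g2)$name]
  r2 <- zi_pi(g2, memb2)
  expect_equal(r2$pi[r2$otu_id == "H"], 0.5)
  expect_true(all(table(r2$role) >= 0))
  expect_equal(nrow(r2), 5L)
  expect_true(all(r2$role %in% c("peripheral", "connector",
                                 "provincial_hub", "kinless_hub")))
})

test_that("Zi and Pi match a brute-force recount on random graphs", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    adj <- random_graph_adj(n, p = runif(1, 0.1, 0.4))
    memb <- sample(1:3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- paste0("O", 1:n)
    r <- zi_pi(g, memb)
    oracle <- oracle_zi_pi(adj, memb)
    expect_equal(r$zi, oracle$zi, tolerance = 1e-12)
    expect_equal(r$pi, oracle$pi, tolerance = 1e-12)
    expect_equal(sum(r$role %in% c("peripheral", "connector",
                                   "provincial_hub", "kinless_hub")), n)
  }
})

test_that("keystone share is conserved and empty sets are allowed", {
  counts <- matrix(rpois(40, 30), 4, dimnames = list(paste0("S", 1:4),
                                                     paste0("O", 1:10)))
  tax <- parse_lineage_strings(paste0("O", 1:10),
                               rep("k__Fungi; p__Ascomycota; c__; o__; f__; g__Genus01", 10))
  roles <- data.frame(otu_id = paste0("O", 1:10), module = 1, degree = 1,
                      zi = 0, pi = 0, role = "peripheral",
                      stringsAsFactors = FALSE)
  ks <- keystone_taxa(roles, tax, counts)
  expect_equal(nrow(ks$taxa), 0L)
  expect_equal(ks$share, 0)
  roles$role[c(2, 5)] <- c("connector", "provincial_hub")
  ks2 <- keystone_taxa(roles, tax, counts)
  expect_equal(ks2$share, sum(counts[, c(2, 5)]) / sum(counts))
  expect_setequal(ks2$taxa$otu_id, c("O2", "O5"))
})

test_that("keystone comparison flags planted differences and respects BH", {
  set.seed(12)
  n <- 20
  counts <- matrix(rpois(n * 6, 50), n,
                   dimnames = list(paste0("S", 1:n), paste0("O", 1:6)))
  counts[1:10, "O1"] <- rpois(10, 400)     # enriched in group a
  meta <- data.frame(sample_id = paste0("S", 1:n),
                     group = rep(c("a", "b"), each = 10), site = "x")
  mk_report <- function(otus) list(taxa = data.frame(otu_id = otus))
  cmp <- compare_keystones(mk_report(c("O1", "O2")), mk_report("O3"),
                           counts, meta)
  expect_true(all(cmp$p_adj >= cmp$p))
  expect_true(cmp$significant[cmp$otu_id == "O1"])
  expect_equal(cmp$higher_group[cmp$otu_id == "O1"], "a")
  same <- counts; same[, "O1"] <- 50
  cmp2 <- compare_keystones(mk_report("O1"), mk_report("O1"), same, meta)
  expect_false(any(cmp2$significant))
  expect_warning(compare_keystones(mk_report("O99"), mk_report("O3"),
                                   counts, meta), "absent")
})

test_that("topology summary matches hand computations", {
  path3 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                       directed = FALSE)
  t1 <- topology_summary(path3)
  expect_equal(t1$average_degree, 4 / 3)
  expect_equal(t1$average_clustering_coefficient, 0)
  expect_equal(t1$average_path_length, 4 / 3)
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  t2 <- topology_summary(tri)
  expect_equal(t2$average_clustering_coefficient, 1)
  expect_equal(t2$average_path_length, 1)
  star <- igraph::graph_from_edgelist(rbind(c("h", "a"), c("h", "b"), c("h", "c")),
                                      directed = FALSE)
  expect_equal(topology_summary(star)$average_degree, 1.5)
})

test_that("positive and negative edge fractions sum to one", {
  x <- cbind(a = 1:12, b = c(1:11, 13), c = -(1:12) + rnorm(12, sd = 0.01),
              d = rnorm(12, 50))
  rownames(x) <- paste0("S", 1:12)
  e <- correlation_edges(x, 0.6, 0.05)
  net <- build_cooccurrence_network(e, abs(x) + 1, group = "g")
  topo <- topology_summary(net)
  neg_frac <- mean(igraph::E(net)$sign == "negative")
  expect_equal(topo$positive_edge_fraction + neg_frac, 1)
})

test_that("planted hub OTUs are recovered as connectors or hubs", {
  majority <- vapply(1:20, function(s) {
    dat <- synth_generate(synth_preset44(seed = 6000 + s))
    rare <- suppressWarnings(rarefy(dat$counts, 30815, seed = s))
    grp <- dat$samples$group[match(rownames(rare), dat$samples$sample_id)]
    hits <- 0; tries <- 0
    for (g in unique(grp)) {
      gn <- suppressWarnings(group_network(rare[grp == g, , drop = FALSE],
                                           dat$taxonomy, group = g, seed = s))
      r <- gn$roles
      for (h in dat$truth$hubs) {
        tries <- tries + 1
        if (h %in% r$otu_id && r$role[r$otu_id == h] != "peripheral")
          hits <- hits + 1
      }
    }
    hits / tries
  }, numeric(1))
  expect_gte(mean(majority >= 0.5), 0.8)
})
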