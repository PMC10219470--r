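# Rarefaction, alpha diversity, Bray-Curtis distances, principal
# coordinate analysis and the ANOSIM permutation test.

#' Rarefy a count table to even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (hypergeometric draw, via [vegan::rrarefy()]).  Samples whose total is
#' below `depth` are dropped with a warning listing them.
#'
#' @param counts samples x OTUs matrix.
#' @param depth target depth (default 30815 reads).
#' @param seed integer seed for the single subsampling draw.
#' @return rarefied matrix; every row sums to `depth`.
#' @export
rarefy <- function(counts, depth = 30815, seed = 1L) {
  validate_count_table(counts)
  if (depth < 1) fail("rarefaction depth must be >= 1")
  totals <- rowSums(counts)
  low <- totals < depth
  if (all(low))
    fail("all samples are below the rarefaction depth ", depth,
         " (max total ", max(totals), ")")
  if (any(low))
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[low], collapse = ", "))
  kept <- counts[!low, , drop = FALSE]
  set.seed(seed)
  # inputs are validated integer counts; vegan's advisory about
  # "observed counts" is spurious here
  out <- withCallingHandlers(
    vegan::rrarefy(kept, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "double"
  out
}

#' Per-sample richness and Shannon diversity
#'
#' Richness is the number of taxa with nonzero count; Shannon is
#' H = -sum p_i log p_i over nonzero proportions, natural log.
#'
#' @param counts samples x OTUs matrix.
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  validate_count_table(counts)
  zero <- rowSums(counts) == 0
  if (any(zero))
    fail("all-zero sample(s): ", paste(rownames(counts)[zero], collapse = ", "))
  data.frame(sample_id = rownames(counts),
             richness = as.integer(rowSums(counts > 0)),
             shannon = as.numeric(vegan::diversity(counts, index = "shannon")),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(j, k) = sum |x_j - x_k| / sum (x_j + x_k), entries in [0, 1].
#'
#' @param counts samples x OTUs matrix (counts or relative abundances).
#' @return a `dist` object.
#' @export
bray_curtis <- function(counts) {
  if (nrow(counts) < 2) fail("need at least 2 samples")
  zero <- rowSums(counts) == 0
  if (any(zero))
    fail("Bray-Curtis undefined for all-zero sample(s): ",
         paste(rownames(counts)[zero], collapse = ", "))
  vegan::vegdist(counts, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric MDS: Gower double-centering of -d^2/2 followed by
#' eigendecomposition.  Axes are ordered by eigenvalue; the explained
#' fraction of axis i is lambda_i over the sum of positive eigenvalues.
#' Negative eigenvalues are reported but excluded from that denominator
#' and no Lingoes/Cailliez correction is applied by default.
#'
#' @param d a `dist` object or symmetric matrix.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return list with `coordinates` (samples x positive axes),
#'   `eigenvalues` (all), `explained` (fraction per positive axis).
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) fail("distance matrix must be symmetric")
  n <- nrow(m)
  fit <- stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE,
                         add = (correction == "cailliez"))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig,
       explained = eig[pos] / sum(eig[pos]))
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones.  With ranks over all n(n-1)/2 pairwise
#' distances (average ranks on ties),
#' R = (mean between-group rank - mean within-group rank) / (M/2),
#' M = n(n-1)/2.  The p-value counts ties as exceedances:
#' p = (1 + #\{permuted R >= observed\}) / (1 + n_permutations).
#'
#' @param d `dist` object or symmetric matrix.
#' @param groups group label per sample (2+ groups, each with >= 2 samples).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with `statistic`, `p_value`, `n_permutations`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = 1L) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n) fail("groups length must match the distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) fail("need at least two groups")
  if (any(tab < 2))
    fail("every group needs >= 2 samples (offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  # pairs in lower-triangle order matching dist vectors
  pi_ <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  pj_ <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  dv <- m[cbind(pj_, pi_)]
  rk <- rank(dv)
  M <- length(rk)
  stat_for <- function(g) {
    btw <- g[pi_] != g[pj_]
    (mean(rk[btw]) - mean(rk[!btw])) / (M / 2)
  }
  observed <- stat_for(groups)
  set.seed(seed)
  B <- n_permutations
  perm_labels <- matrix(NA_character_, B, n)
  for (b in seq_len(B)) perm_labels[b, ] <- sample(groups)
  btw_mat <- perm_labels[, pi_, drop = FALSE] != perm_labels[, pj_, drop = FALSE]
  sum_b <- as.numeric(btw_mat %*% rk)
  n_b <- rowSums(btw_mat)
  total <- sum(rk)
  r_perm <- (sum_b / n_b - (total - sum_b) / (M - n_b)) / (M / 2)
  p <- (1 + sum(r_perm >= observed - 1e-12)) / (1 + B)
  list(statistic = observed, p_value = p, n_permutations = B,
       permuted = r_perm)
}
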