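# Independent oracle implementations used by the tests.  These are kept
# deliberately naive (brute-force loops, closed forms) and share no code
# with the package internals they check.

# Spearman rho by explicit rank-and-Pearson computation
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Kruskal-Wallis H with tie correction from the textbook formula
oracle_kruskal_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# ANOSIM R for a given labelling, straight from the definition
oracle_anosim_r <- function(dmat, labels) {
  n <- nrow(dmat)
  dv <- dmat[lower.tri(dmat)]
  rk <- rank(dv)
  btw <- outer(labels, labels, "!=")[lower.tri(dmat)]
  (mean(rk[btw]) - mean(rk[!btw])) / (length(rk) / 2)
}

# exhaustive ANOSIM over all distinct label assignments (small n only)
oracle_anosim_exhaustive <- function(dmat, labels) {
  n <- length(labels)
  k <- sum(labels == labels[1])
  combos <- utils::combn(n, k)
  rs <- apply(combos, 2, function(idx) {
    lab <- rep("b", n); lab[idx] <- "a"
    oracle_anosim_r(dmat, lab)
  })
  obs <- oracle_anosim_r(dmat, labels)
  list(R = obs, p_exact = mean(rs >= obs - 1e-12), all_r = rs)
}

# per-node Zi / Pi recount from the adjacency matrix, one node at a time
oracle_zi_pi <- function(adj, membership) {
  n <- nrow(adj)
  mods <- sort(unique(membership))
  zi <- pi_ <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(adj[i, ])
    kis <- sum(adj[i, membership == membership[i]])
    peers <- which(membership == membership[i])
    peer_k <- vapply(peers, function(j) sum(adj[j, membership == membership[i]]),
                     numeric(1))
    mu <- mean(peer_k)
    sdv <- sqrt(mean((peer_k - mu)^2))
    zi[i] <- if (sdv == 0) 0 else (kis - mu) / sdv
    pi_[i] <- if (ki == 0) 0 else
      1 - sum(vapply(mods, function(t)
        (sum(adj[i, membership == t]) / ki)^2, numeric(1)))
  }
  list(zi = zi, pi = pi_)
}

# adjusted Rand index between two partitions
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Procrustes error between two configurations (translation/rotation/
# reflection/scale removed); near zero when shapes match
oracle_procrustes_error <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  X <- X / sqrt(sum(X^2)); Y <- Y / sqrt(sum(Y^2))
  s <- svd(crossprod(Y, X))
  1 - sum(s$d)^2
}

# random small graph as an adjacency matrix
random_graph_adj <- function(n, p = 0.2) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

# fast LEfSe-scale dataset for unit tests (small community)
small_synth <- function(seed, ...) {
  synth_config(n_sites = 11L, n_otus = 60L,
               modules = list(list(size = 15L, loading = 0.6,
                                   hub_loading = 1.0,
                                   hub_cross_loading = 0.1,
                                   hub_noise_scale = 0.1)),
               seed = seed, ...)
}
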