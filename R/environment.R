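# Environment-community association: VIF screening, canonical
# correspondence analysis with per-term Monte Carlo tests, phylum-soil
# Spearman correlation matrices, and LMG relative-importance
# decomposition of a linear model's R^2.

#' Iterative VIF screening of environmental variables
#'
#' VIF_j = 1/(1 - R^2_j) from regressing variable j on the others.  The
#' variable with the largest VIF is dropped (ties broken toward the
#' larger column index) until all VIFs are at or below `threshold`.
#' Perfectly collinear variables have unbounded VIF and go first.
#'
#' @param X data.frame or matrix of environmental variables (n > columns).
#' @param threshold maximum tolerated VIF (default 10).
#' @return list with `retained` (column names), `dropped`
#'   (data.frame variable/vif in drop order) and `vif` (final VIFs).
#' @export
vif_screen <- function(X, threshold = 10) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) fail("need >= 2 variables")
  if (nrow(X) <= ncol(X)) fail("need more observations than variables")
  vif_of <- function(df) {
    vapply(seq_along(df), function(j) {
      r2 <- summary(stats::lm(df[[j]] ~ ., data = df[-j]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- data.frame(variable = character(0), vif = numeric(0))
  repeat {
    if (ncol(X) < 2) break
    v <- vif_of(X)
    if (all(v <= threshold)) break
    worst <- max(which(v == max(v)))        # tie -> larger index dropped
    dropped <- rbind(dropped,
                     data.frame(variable = colnames(X)[worst], vif = v[worst]))
    X <- X[, -worst, drop = FALSE]
  }
  list(retained = colnames(X), dropped = dropped,
       vif = if (ncol(X) >= 2) stats::setNames(vif_of(X), colnames(X))
             else stats::setNames(1, colnames(X)))
}

#' Canonical correspondence analysis
#'
#' Constrained ordination of the chi-square-standardized community table
#' on standardized environmental variables (via [vegan::cca()], scaling
#' type 2 for reported scores).  Axis percentages are eigenvalue over
#' total inertia.
#'
#' @param Y samples x taxa community matrix (no all-zero rows/columns).
#' @param X data.frame of (VIF-screened) environmental variables.
#' @return list with `eigenvalues` (constrained), `total_inertia`,
#'   `constrained_inertia`, `axis_pct` (percent of total inertia per
#'   constrained axis), `site_scores`, `species_scores`, `biplot` arrows
#'   and the underlying vegan fit.
#' @export
cca_ordination <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  if (any(rowSums(Y) == 0) || any(colSums(Y) == 0))
    fail("community matrix has all-zero row(s) or column(s)")
  if (ncol(X) > nrow(Y) - 1) fail("more constraints than samples - 1")
  fit <- vegan::cca(Y ~ ., data = X)
  eig <- fit$CCA$eig
  tot <- fit$tot.chi
  sc <- vegan::scores(fit, display = c("wa", "sp", "bp"), scaling = 2)
  list(eigenvalues = eig, total_inertia = tot,
       constrained_inertia = sum(eig),
       axis_pct = 100 * eig / tot,
       site_scores = sc$sites, species_scores = sc$species,
       biplot = sc$biplot, fit = fit)
}

# chi-square standardized residual matrix Q and row weights r of a
# community table; sum(Q^2) is the total inertia.
chi_square_Q <- function(Y) {
  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  list(Q = (P - E) / sqrt(E), r = r)
}

# constrained inertia of Q on row-weighted, centered constraints X
constrained_inertia <- function(Q, r, X) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(0)
  Xc <- sweep(X, 2, colSums(X * r) / sum(r))
  Z <- Xc * sqrt(r)
  qr_z <- qr(Z)
  sum(qr.fitted(qr_z, Q)^2)
}

#' Per-variable Monte Carlo (permutation) tests for CCA
#'
#' Marginal test of each retained variable: its constrained inertia is
#' the drop from the full model to the model without it;
#' F = (that inertia / 1) / (residual inertia / residual df).  The
#' community rows are permuted freely; p = (1 + exceedances) /
#' (1 + n_permutations), so 999 permutations give a minimum p of 0.001.
#'
#' @param Y community matrix.
#' @param X data.frame of retained environmental variables.
#' @param n_permutations default 999.
#' @param seed integer seed.
#' @return data.frame with variable, F, p.
#' @export
cca_term_tests <- function(Y, X, n_permutations = 999, seed = 1L) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  n <- nrow(Y); q <- ncol(X)
  resid_df <- n - 1 - q
  if (resid_df < 1) fail("not enough residual degrees of freedom")
  f_stats <- function(Ym) {
    qq <- chi_square_Q(Ym)
    total <- sum(qq$Q^2)
    full <- constrained_inertia(qq$Q, qq$r, X)
    resid_ms <- (total - full) / resid_df
    vapply(seq_len(q), function(j) {
      red <- constrained_inertia(qq$Q, qq$r, X[, -j, drop = FALSE])
      (full - red) / resid_ms
    }, numeric(1))
  }
  obs <- f_stats(Y)
  set.seed(seed)
  exceed <- numeric(q)
  for (b in seq_len(n_permutations)) {
    fp <- f_stats(Y[sample(n), , drop = FALSE])
    exceed <- exceed + (fp >= obs - 1e-12)
  }
  data.frame(variable = colnames(X), F = obs,
             p = (1 + exceed) / (1 + n_permutations),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Phylum-by-soil Spearman correlation matrix
#'
#' Pairwise Spearman rho and two-sided p for every (phylum, soil
#' variable) pair on phylum relative abundances; pairs with p < 0.05 are
#' marked significant.  Constant variables are skipped with a warning.
#'
#' @param counts samples x OTUs matrix.
#' @param tax taxonomy data.frame.
#' @param soil data.frame of soil variables (rows in sample order).
#' @param min_mean_abundance keep phyla whose mean relative abundance
#'   exceeds this (default 0.01, "predominant" phyla).
#' @return list of matrices `rho`, `p`, `significant`.
#' @export
phylum_soil_correlations <- function(counts, tax, soil,
                                     min_mean_abundance = 0.01) {
  phy <- aggregate_to_rank(counts, tax, "phylum")
  rel <- phy / rowSums(phy)
  rel <- rel[, colMeans(rel) > min_mean_abundance, drop = FALSE]
  soil <- as.data.frame(soil)
  rho <- p <- matrix(NA_real_, ncol(rel), ncol(soil),
                     dimnames = list(colnames(rel), colnames(soil)))
  for (i in seq_len(ncol(rel))) for (j in seq_len(ncol(soil))) {
    x <- rel[, i]; y <- soil[[j]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant variable in pair (", colnames(rel)[i], ", ",
              colnames(soil)[j], "), skipped")
      next
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p, significant = !is.na(p) & p < 0.05)
}

#' LMG relative-importance decomposition
#'
#' Decomposes the R^2 of `lm(y ~ X)` into non-negative per-predictor
#' shares: the LMG share of predictor j is the average, over all
#' orderings of the predictors, of the R^2 increment when j enters.
#' Computed by exact subset enumeration (2^p regressions), limited to
#' p <= 10 predictors.  Shares sum exactly to the full-model R^2.
#'
#' @param y response vector (e.g. per-sample summed keystone relative
#'   abundance).
#' @param X data.frame or matrix of predictors.
#' @return list with `shares` (named) and `r_squared`.
#' @export
lmg_importance <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p > 10) fail("LMG enumeration limited to 10 predictors")
  if (length(y) <= p) fail("need more observations than predictors")
  Xm <- as.matrix(X)
  r2_of <- function(idx) {
    if (!length(idx)) return(0)
    f <- stats::lm.fit(cbind(1, Xm[, idx, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  n_sub <- 2^p
  r2 <- numeric(n_sub)
  members <- vector("list", n_sub)
  for (s in seq_len(n_sub) - 1L) {
    idx <- which(bitwAnd(s, 2^(seq_len(p) - 1L)) > 0)
    members[[s + 1L]] <- idx
    r2[s + 1L] <- r2_of(idx)
  }
  shares <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (s in seq_len(n_sub) - 1L) {
      idx <- members[[s + 1L]]
      if (j %in% idx) next
      k <- length(idx)
      wt <- factorial(k) * factorial(p - k - 1) / factorial(p)
      acc <- acc + wt * (r2[s + 1L + 2^(j - 1L)] - r2[s + 1L])
    }
    shares[j] <- acc
  }
  names(shares) <- colnames(X)
  list(shares = shares, r_squared = r2[n_sub])
}

#' Random-forest permutation importance (cross-check)
#'
#' Optional companion to [lmg_importance()]: fits a random forest of the
#' response on the predictors and reports permutation importance
#' (mean decrease in accuracy/MSE).  Requires the randomForest package.
#'
#' @param y response vector.
#' @param X data.frame of predictors.
#' @param seed integer seed.
#' @param n_trees forest size (default 500).
#' @return named numeric vector of importance scores.
#' @export
rf_importance <- function(y, X, seed = 1L, n_trees = 500) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    fail("rf_importance needs the randomForest package")
  set.seed(seed)
  fit <- randomForest::randomForest(as.data.frame(X), y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)
  stats::setNames(imp[, 1], rownames(imp))
}
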