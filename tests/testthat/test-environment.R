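# VIF screening, CCA, permutation term tests, phylum-soil correlations
# and LMG importance.

test_that("VIF screening drops collinear variables first", {
  set.seed(2)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  X$c <- X$a                                  # perfect copy
  out <- vif_screen(X, 10)
  expect_equal(out$dropped$variable, "c")     # tie broken to larger index
  expect_setequal(out$retained, c("a", "b"))
  ortho <- data.frame(a = rep(c(-1, 1), 15), b = rep(c(-1, -1, 1, 1), length.out = 30))
  o <- vif_screen(ortho, 10)
  expect_equal(nrow(o$dropped), 0L)
  expect_true(all(abs(o$vif - 1) < 0.2))
})

test_that("VIFs match the closed form from pairwise correlations", {
  set.seed(6)
  z <- matrix(rnorm(90), 30, 3)
  X <- data.frame(x1 = z[, 1], x2 = 0.6 * z[, 1] + 0.8 * z[, 2],
                  x3 = 0.3 * z[, 1] + 0.5 * z[, 2] + z[, 3])
  out <- vif_screen(X, threshold = 1e9)       # no drops, inspect VIFs
  r12 <- cor(X$x1, X$x2); r13 <- cor(X$x1, X$x3); r23 <- cor(X$x2, X$x3)
  r2_1 <- (r12^2 + r13^2 - 2 * r12 * r13 * r23) / (1 - r23^2)
  expect_equal(unname(out$vif["x1"]), 1 / (1 - r2_1), tolerance = 1e-10)
})

test_that("CCA eigenvalues match a direct eigen oracle on a small fixture", {
  set.seed(10)
  Y <- matrix(rpois(30, 12) + 1, 6, 5,
              dimnames = list(paste0("S", 1:6), paste0("t", 1:5)))
  X <- data.frame(v1 = rnorm(6), v2 = rnorm(6))
  fit <- cca_ordination(Y, X)
  # oracle: chi-square residuals projected on weighted constraints
  P <- Y / sum(Y); r <- rowSums(P); cc <- colSums(P)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  Xc <- sweep(as.matrix(X), 2, colSums(as.matrix(X) * r) / sum(r))
  Z <- Xc * sqrt(r)
  H <- Z %*% solve(crossprod(Z)) %*% t(Z)
  lam <- sort(eigen(crossprod(H %*% Q), symmetric = TRUE)$values,
              decreasing = TRUE)[1:2]
  expect_equal(unname(fit$eigenvalues), lam, tolerance = 1e-8)
  # total inertia is the chi-square statistic over the grand total
  expect_equal(fit$total_inertia, unname(
    suppressWarnings(chisq.test(Y)$statistic) / sum(Y)), tolerance = 1e-10)
  expect_equal(fit$constrained_inertia, sum(fit$eigenvalues), tolerance = 1e-12)
})

test_that("a single planted gradient dominates the constrained inertia", {
  set.seed(20)
  n <- 24
  grad <- seq(-2, 2, length.out = n)
  Y <- sapply(1:12, function(j) rpois(n, exp(2 + grad * (j - 6) / 4)))
  dimnames(Y) <- list(paste0("S", 1:n), paste0("t", 1:12))
  X <- data.frame(g = grad, noise = rnorm(n))
  fit <- cca_ordination(Y, X)
  expect_gt(fit$eigenvalues[1] / fit$constrained_inertia, 0.9)
  tt <- cca_term_tests(Y, X, n_permutations = 199, seed = 4)
  expect_lt(tt$p[tt$variable == "g"], 0.01)
  expect_equal(min(cca_term_tests(Y, X, n_permutations = 999, seed = 1)$p) >=
                 1 / 1000, TRUE)
})

test_that("degenerate CCA inputs are rejected", {
  Y <- matrix(rpois(20, 5) + 1, 4, 5,
              dimnames = list(paste0("S", 1:4), paste0("t", 1:5)))
  expect_error(cca_ordination(Y, data.frame(a = rnorm(4), b = rnorm(4),
                                            c = rnorm(4), d = rnorm(4))),
               "constraints")
  Y0 <- Y; Y0[1, ] <- 0
  expect_error(cca_ordination(Y0, data.frame(a = rnorm(4))), "all-zero")
})

test_that("phylum-soil correlation matrix marks a planted monotone coupling", {
  set.seed(30)
  n <- 20
  counts <- matrix(rpois(n * 6, 40), n,
                   dimnames = list(paste0("S", 1:n), paste0("O", 1:6)))
  counts[, 1] <- round(seq(20, 400, length.out = n))   # phylum A tracks TC
  tax <- parse_lineage_strings(
    paste0("O", 1:6),
    paste0("k__Fungi; p__", rep(c("PhyA", "PhyB"), each = 3)))
  phyA_rel <- rowSums(counts[, 1:3]) / rowSums(counts)
  soil <- data.frame(TC = rank(phyA_rel),    # strictly monotone in phylum A
                     pH = rnorm(n), TN = rnorm(n), TP = rnorm(n),
                     AN = rnorm(n), NN = rnorm(n), AP = rnorm(n))
  hm <- phylum_soil_correlations(counts, tax, soil, min_mean_abundance = 0)
  expect_equal(dim(hm$rho), c(2L, 7L))
  expect_equal(hm$rho["PhyA", "TC"], 1)
  expect_true(hm$significant["PhyA", "TC"])
  soil$flat <- 1
  expect_warning(phylum_soil_correlations(counts, tax, soil,
                                          min_mean_abundance = 0), "constant")
})

test_that("LMG shares decompose R-squared exactly", {
  set.seed(40)
  n <- 50
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 1 + 2 * X$a + 1 * X$b + rnorm(n)
  out <- lmg_importance(y, X)
  expect_equal(sum(out$shares), out$r_squared, tolerance = 1e-10)
  expect_true(all(out$shares > -1e-12))
  # explicit enumeration over all 6 orderings of three predictors
  r2 <- function(vars) {
    if (!length(vars)) return(0)
    summary(lm(y ~ ., data = X[vars]))$r.squared
  }
  orders <- list(c("a","b","c"), c("a","c","b"), c("b","a","c"),
                 c("b","c","a"), c("c","a","b"), c("c","b","a"))
  manual <- sapply(c("a", "b", "c"), function(v) {
    mean(sapply(orders, function(o) {
      pos <- match(v, o)
      r2(o[1:pos]) - r2(o[seq_len(pos - 1)])
    }))
  })
  expect_equal(out$shares, manual, tolerance = 1e-10)
})

test_that("LMG edge cases: single predictor and orthogonal predictors", {
  set.seed(41)
  n <- 40
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), length.out = n)   # orthogonal to x1
  y <- 2 * x1 + x2 + rnorm(n)
  single <- lmg_importance(y, data.frame(x1 = x1))
  expect_equal(unname(single$shares["x1"]),
               summary(lm(y ~ x1))$r.squared, tolerance = 1e-12)
  both <- lmg_importance(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(unname(both$shares["x1"]),
               summary(lm(y ~ x1))$r.squared, tolerance = 1e-12)
  expect_equal(unname(both$shares["x2"]),
               summary(lm(y ~ x2))$r.squared, tolerance = 1e-12)
  expect_error(lmg_importance(y, as.data.frame(matrix(rnorm(n * 11), n))),
               "10 predictors")
})
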