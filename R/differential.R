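# Two-class biomarker discovery per taxonomic rank: Kruskal-Wallis
# screening followed by a bootstrap linear-discriminant effect size.
#
# The effect-size definition used here is fixed by this package: over
# n_boot bootstrap resamples (2/3 of each class, with replacement) a
# two-class linear discriminant with pooled ridge-regularized covariance
# is fit on the normalized features; for feature j with class-mean
# difference d_j and unit-norm discriminant weight w_j,
#   effect_j = mean over bootstraps of 0.5 * (|w_j * d_j| + |d_j|)
#   score_j  = log10(1 + effect_j).
# Screening and thresholding follow the usual LEfSe convention
# (Kruskal-Wallis alpha = 0.05, LDA score >= 3.0 on TSS-normalized
# abundances scaled to 1e6).

#' Total-sum scaling normalization
#'
#' Divides each sample by its total and multiplies by `scale`
#' (default 1e6, the LEfSe convention).
#'
#' @param counts samples x features matrix.
#' @param scale target row sum.
#' @return normalized matrix with all row sums equal to `scale`.
#' @export
normalize_tss <- function(counts, scale = 1e6) {
  totals <- rowSums(counts)
  zero <- totals == 0
  if (any(zero))
    fail("all-zero sample(s): ", paste(rownames(counts)[zero], collapse = ", "))
  counts / totals * scale
}

#' Kruskal-Wallis screen for one feature
#'
#' Kruskal-Wallis H with tie correction, chi-square p with
#' df = groups - 1.  All-identical values give p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value (two groups, each >= 2 samples).
#' @return list with `statistic` (H) and `p_value`.
#' @export
kruskal_screen <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) fail("each group needs >= 2 samples")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Bootstrap LDA effect size
#'
#' @param x normalized samples x features matrix (screened features).
#' @param groups two-class label per sample.
#' @param n_boot bootstrap resamples (default 30).
#' @param seed integer seed.
#' @param ridge diagonal regularization, relative to the mean diagonal of
#'   the pooled covariance (handles features >> samples).
#' @return named numeric vector of log10 effect-size scores (>= 0).
#' @export
lda_effect_size <- function(x, groups, n_boot = 30, seed = 1L, ridge = 1e-6) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) fail("exactly two classes required")
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  # canonical order so results do not depend on how samples were arranged
  if (!is.null(rownames(x))) {
    i1 <- i1[order(rownames(x)[i1])]
    i2 <- i2[order(rownames(x)[i2])]
  }
  n1 <- max(2L, ceiling(2 / 3 * length(i1)))
  n2 <- max(2L, ceiling(2 / 3 * length(i2)))
  p <- ncol(x)
  set.seed(seed)
  eff <- matrix(NA_real_, n_boot, p)
  for (b in seq_len(n_boot)) {
    s1 <- x[sample(i1, n1, replace = TRUE), , drop = FALSE]
    s2 <- x[sample(i2, n2, replace = TRUE), , drop = FALSE]
    m1 <- colMeans(s1); m2 <- colMeans(s2)
    d <- m1 - m2
    S <- ((n1 - 1) * stats::cov(s1) + (n2 - 1) * stats::cov(s2)) / (n1 + n2 - 2)
    lam <- ridge * max(mean(diag(S)), 1)   # regularization relative to scale
    w <- NULL
    repeat {
      w <- tryCatch({
        R <- chol(S + diag(lam, p))
        backsolve(R, forwardsolve(t(R), d))
      }, error = function(e) NULL)
      if (!is.null(w) && all(is.finite(w))) break
      lam <- lam * 1e3
      if (lam > 1e12 * max(abs(S), 1)) { w <- d; break }
    }
    nw <- sqrt(sum(w^2))
    if (nw > 0) w <- w / nw
    eff[b, ] <- 0.5 * (abs(w * d) + abs(d))
  }
  scores <- log10(1 + colMeans(eff))
  names(scores) <- colnames(x)
  scores
}

#' Run the full biomarker discovery stage per taxonomic rank
#'
#' Per rank: aggregate the count table, TSS-normalize, screen every taxon
#' by Kruskal-Wallis, compute bootstrap LDA scores for the screened taxa,
#' and assign the enriched group by larger class mean.  A taxon passes
#' when kw_p < alpha and lda_score >= lda_threshold.
#'
#' @param counts samples x OTUs matrix (typically rarefied).
#' @param tax taxonomy data.frame.
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param ranks taxonomic ranks to analyse.
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param lda_threshold minimum LDA score (default 3.0).
#' @param n_boot,seed passed to [lda_effect_size()].
#' @return data.frame with columns taxon, rank, enriched_group, kw_p,
#'   lda_score, passes.
#' @export
run_lefse <- function(counts, tax, metadata,
                      ranks = c("phylum", "family", "genus"),
                      alpha = 0.05, lda_threshold = 3.0,
                      n_boot = 30, seed = 1L) {
  bad <- setdiff(ranks, RANKS)
  if (length(bad)) fail("unknown rank(s): ", paste(bad, collapse = ", "))
  groups <- metadata$group[match(rownames(counts), metadata$sample_id)]
  if (any(is.na(groups))) fail("metadata missing for some samples")
  out <- list()
  for (rk in ranks) {
    agg <- aggregate_to_rank(counts, tax, rk)
    norm <- normalize_tss(agg)
    kw <- apply(norm, 2, function(v) kruskal_screen(v, groups)$p_value)
    screened <- names(kw)[kw < alpha]
    scores <- rep(NA_real_, ncol(norm))
    names(scores) <- colnames(norm)
    if (length(screened) >= 1) {
      scores[screened] <- lda_effect_size(norm[, screened, drop = FALSE],
                                          groups, n_boot = n_boot, seed = seed)
    }
    lev <- unique(groups)
    m1 <- colMeans(norm[groups == lev[1], , drop = FALSE])
    m2 <- colMeans(norm[groups == lev[2], , drop = FALSE])
    enriched <- ifelse(m1 >= m2, lev[1], lev[2])
    out[[rk]] <- data.frame(taxon = colnames(norm), rank = rk,
                            enriched_group = enriched, kw_p = unname(kw),
                            lda_score = unname(scores),
                            passes = !is.na(scores) & kw < alpha &
                              scores >= lda_threshold,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
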