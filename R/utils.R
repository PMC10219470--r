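# Internal helpers shared across modules.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
RANK_LETTERS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                  family = "f", genus = "g")

#' Derive a stage-specific child seed from a master seed
#'
#' Counter-based derivation: each pipeline stage gets an independent seed so
#' that adding a stage never perturbs the random draws of earlier stages.
#' The result always fits in a 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param index stage counter (small non-negative integer).
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 20000L) * 100000 + index)
}

# Stop with a consistent prefix; all user-facing validation errors go
# through here so tests can match on message content.
fail <- function(...) stop(..., call. = FALSE)

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# population standard deviation (divides by n, not n-1)
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
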