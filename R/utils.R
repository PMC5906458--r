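#' @keywords internal
"_PACKAGE"

#' @importFrom stats wilcox.test kruskal.test fisher.test cor.test binom.test
#'   plogis rpois runif rnorm rbinom optim approx sd median qnorm pnorm
#' @importFrom utils write.csv read.csv
NULL

# Deterministic substream seed: all randomness in a session bundle flows from
# one master seed; each component (behavior, each unit, pose) gets its own
# substream so it can be regenerated independently.  Kept below 2^31.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(as.character(name))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("parameter `%s` must be a single finite number in [%g, %g]", name, lower, upper)
  invisible(x)
}

# Tie-corrected standardized Wilcoxon rank-sum statistic.  z > 0 means `x`
# tends to exceed `y`.  No continuity correction: this is the raw test
# statistic used by the binned responsiveness criterion.
ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stopf("ranksum_z needs non-empty groups")
  n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  (W - mu) / sqrt(sigma2)
}

# Two-sided rank-sum p-value.  Exact where stats::wilcox.test supports it
# (small samples, no ties), normal approximation with continuity and tie
# corrections otherwise.
ranksum_p <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

# One-sample signed-rank p-value against zero; all-zero input gives p = 1 by
# convention (no evidence of shift).
signedrank_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L || all(x == 0)) return(1)
  suppressWarnings(stats::wilcox.test(x, mu = 0)$p.value)
}

#' Construct a modulation result
#'
#' Container for a normalized rate-difference index of the form
#' \eqn{(A - B)/(A + B)} together with its rank-sum test.  The index lies in
#' \eqn{[-1, 1]} when defined and is `NA` when both mean rates are zero
#' (silent unit); such units are excluded from population fractions and
#' counted separately.
#'
#' @param index numeric index in \eqn{[-1,1]}, or `NA` if undefined.
#' @param n_a,n_b group sizes.
#' @param p_value two-sided rank-sum p-value.
#' @param alpha significance level (default 0.05).
#' @param kind label describing which analysis produced the result.
#' @return An object of class `modulation_result`: a list with fields
#'   `index`, `n_a`, `n_b`, `p_value`, `significant`, `kind`.
#' @export
modulation_result <- function(index, n_a, n_b, p_value, alpha = 0.05,
                              kind = "modulation") {
  if (!is.na(index) && (index < -1 - 1e-12 || index > 1 + 1e-12))
    stopf("modulation index %g outside [-1, 1]", index)
  structure(
    list(index = unname(index), n_a = as.integer(n_a), n_b = as.integer(n_b),
         p_value = unname(p_value),
         significant = isTRUE(!is.na(p_value) && p_value < alpha),
         kind = kind),
    class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<%s> index = %s, n = (%d, %d), p = %s%s\n",
              x$kind,
              if (is.na(x$index)) "undefined" else sprintf("%.3f", x$index),
              x$n_a, x$n_b,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
              if (x$significant) " *" else ""))
  invisible(x)
}

# Shared core: index from mean counts of two groups + rank-sum test.
index_from_counts <- function(a, b, kind, alpha = 0.05) {
  ma <- mean(a); mb <- mean(b)
  idx <- if (ma + mb == 0) NA_real_ else (ma - mb) / (ma + mb)
  modulation_result(idx, length(a), length(b), ranksum_p(a, b),
                    alpha = alpha, kind = kind)
}
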