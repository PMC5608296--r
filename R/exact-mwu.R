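# Exact two-sided Mann-Whitney U test for small groups.
#
# The null distribution of the rank sum is computed exactly on the observed
# (possibly tied) mid-rank configuration by dynamic programming over doubled
# ranks, which is equivalent to enumerating all choose(n1+n2, n1) group
# assignments but polynomial in n. Distributions are memoised per tie pattern
# so genome-wide scans at fixed group sizes pay the cost once.

.mwu_cache <- new.env(parent = emptyenv())

# Subset-sum counts: number of size-n1 subsets of the doubled mid-ranks `d`
# attaining each doubled rank-sum s = 0..sum(d). Counts stay below 2^53 for
# n <= 30, so doubles are exact.
.ranksum_counts <- function(d, n1) {
  smax <- sum(d)
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (i in seq_along(d)) {
    di <- d[i]
    for (k in seq(min(n1, i), 1L)) {
      f[k + 1L, (di + 1L):(smax + 1L)] <-
        f[k + 1L, (di + 1L):(smax + 1L)] + f[k, 1L:(smax + 1L - di)]
    }
  }
  f[n1 + 1L, ]
}

#' Exact two-sided Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic from mid-ranks and an exact two-sided
#' p-value from the permutation distribution of the rank sum over all
#' \eqn{\binom{n_1+n_2}{n_1}} assignments of the pooled (tied) values to the
#' two groups. The two-sided p-value doubles the smaller one-sided tail
#' probability, capped at 1 -- the convention under which complete separation
#' of two groups of four yields \eqn{p = 2/70 \approx 0.0286}.
#'
#' For combined sample sizes above `max_exact_n` the test falls back to the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors of signals for the two groups (non-empty, finite).
#' @param max_exact_n Largest combined sample size for which the exact
#'   permutation distribution is computed (default 30).
#' @return A list with elements `u_stat` (U for group `x`), `p_two_sided`,
#'   `method` (`"exact"`, `"normal_approx"` or `"degenerate"`), and
#'   `degenerate` (`TRUE` when all pooled values are identical, in which case
#'   `p_two_sided` is 1).
#' @examples
#' exact_mwu(c(5, 6, 7, 8), c(1, 2, 3, 4))$p_two_sided # 2/70
#' @export
exact_mwu <- function(x, y, max_exact_n = 30L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y) ||
      any(!is.finite(c(x, y))))
    stop("inputs must be finite numeric vectors")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(u_stat = n1 * n2 / 2, p_two_sided = 1,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2

  if (n <= max_exact_n) {
    d <- as.integer(round(2 * r))
    key <- paste0(n1, "|", paste(sort(d), collapse = ","))
    entry <- .mwu_cache[[key]]
    if (is.null(entry)) {
      counts <- .ranksum_counts(sort(d), n1)
      entry <- list(cum = cumsum(counts), total = choose(n, n1))
      .mwu_cache[[key]] <- entry
    }
    s_obs <- as.integer(round(2 * w)) # doubled rank sum, exact integer
    # P(2W <= s_obs) and P(2W >= s_obs); index i of cum holds sum s = i - 1
    p_lo <- entry$cum[s_obs + 1L] / entry$total
    p_hi <- (entry$total - if (s_obs >= 1L) entry$cum[s_obs] else 0) /
      entry$total
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(u_stat = u, p_two_sided = p, method = "exact",
                degenerate = FALSE))
  }

  # normal approximation with tie correction
  tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(u_stat = u, p_two_sided = 1, method = "degenerate",
                degenerate = TRUE))
  }
  z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(u_stat = u, p_two_sided = p, method = "normal_approx",
       degenerate = FALSE)
}

#' Truncate a p-value for human-readable display
#'
#' Truncates (never rounds) to a fixed number of decimals, the convention used
#' in the reported tables (2/70 = 0.02857... prints as 0.028). Machine output
#' keeps full precision.
#'
#' @param p Numeric vector of p-values.
#' @param digits Decimals kept (default 3).
#' @return Character vector.
#' @export
format_p_truncated <- function(p, digits = 3L) {
  sprintf(paste0("%.", digits, "f"), floor(p * 10^digits) / 10^digits)
}
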