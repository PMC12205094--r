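# Paired Wilcoxon signed-rank test with an exact small-sample null
# distribution. The exact distribution is computed by dynamic-programming
# convolution over the (mid)ranks of |differences|, which equals full
# enumeration of the 2^n sign assignments and, unlike stats::wilcox.test,
# stays exact in the presence of tied ranks.

#' Exact paired Wilcoxon signed-rank test
#'
#' Tests the symmetry about zero of paired differences `post - pre`. The
#' statistic is `V`, the sum of the ranks of the positive differences
#' (midranks under ties). For `n <= exact_limit` non-zero pairs the
#' two-sided p-value is exact — the null distribution of `V` is obtained by
#' convolution over sign assignments, conditional on the observed absolute
#' differences — otherwise a normal approximation with continuity
#' correction and tie-corrected variance is used.
#'
#' Zero differences are dropped before ranking (the classical Wilcoxon
#' convention); `zero_method = "pratt"` keeps them in the ranking and drops
#' them from the statistic. When every difference is zero the test is
#' degenerate and `p_value = 1` is returned with `degenerate = TRUE`.
#'
#' @param pre,post Equal-length numeric vectors of paired measurements.
#' @param exact_limit Largest number of non-zero pairs for which the exact
#'   distribution is used, default 25.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @return List with `statistic` (V), `p_value` (two-sided), `n_pairs`
#'   (input pairs), `n_used` (non-zero pairs), `exact`, `degenerate`.
#' @examples
#' paired_wilcoxon(c(1, 2, 3, 4, 5, 6, 7), c(3, 4, 6, 7, 9, 10, 12))
#' @export
paired_wilcoxon <- function(pre, post, exact_limit = 25,
                            zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(pre) == length(post), length(pre) >= 1,
            all(is.finite(pre)), all(is.finite(post)))
  d <- post - pre
  n_pairs <- length(d)
  nonzero <- d != 0
  if (!any(nonzero)) {
    return(list(statistic = 0, p_value = 1, n_pairs = n_pairs, n_used = 0L,
                exact = TRUE, degenerate = TRUE))
  }
  if (zero_method == "wilcox") {
    dd <- d[nonzero]
    ranks <- rank(abs(dd))
  } else {
    # Pratt: rank |d| including zeros, then discard the zeros' ranks
    ranks_all <- rank(abs(d))
    dd <- d[nonzero]
    ranks <- ranks_all[nonzero]
  }
  n <- length(dd)
  v <- sum(ranks[dd > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(v, ranks)
    exact <- TRUE
  } else {
    mu <- sum(ranks) / 2
    sigma2 <- sum(ranks^2) / 4
    # continuity correction toward the mean
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = v, p_value = p, n_pairs = n_pairs, n_used = n,
       exact = exact, degenerate = FALSE)
}

# Exact two-sided p-value of the signed-rank statistic by convolution.
# Ranks (possibly midranks, i.e. multiples of 0.5) are doubled to integers;
# the DP table holds the number of the 2^n sign assignments reaching each
# achievable doubled rank-sum. Two-sided p = 2 * min(P(V <= v), P(V >= v)),
# capped at 1 (the wilcox.test convention).
signed_rank_exact_p <- function(v, ranks) {
  w <- as.integer(round(2 * ranks))
  total <- sum(w)
  counts <- numeric(total + 1)  # index s+1 holds count of assignments with sum s
  counts[1] <- 1
  for (wi in w) {
    shifted <- c(rep(0, wi), counts[seq_len(total + 1 - wi)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(w)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(counts[seq_len(v2 + 1)])
  p_ge <- sum(counts[seq.int(v2 + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}
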