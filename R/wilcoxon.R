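#' One-sided Wilcoxon rank-sum p-value (greater)
#'
#' P-value for the alternative that `x` is stochastically greater than `y`,
#' the per-window test at the heart of the peak caller. Ties are handled with
#' midranks throughout. For fewer than 10 values per side the permutation
#' null is evaluated exactly (a count of all rank partitions, computed by
#' dynamic programming over the tied-rank multiset); otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used, matching `stats::wilcox.test(..., exact = FALSE, correct = TRUE)`.
#'
#' The exact p is the conservative tail probability `P(W >= W_obs)`; when
#' every pooled value is tied the statistic is degenerate and the p-value is
#' 1 (no evidence), not an error.
#'
#' @param x,y Numeric vectors (ChIP and control window values), length >= 2
#'   each; the windowed use case has equal lengths but unequal are allowed.
#' @return p-value in (0, 1].
#' @export
wilcoxon_greater <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per side")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (min(n1, n2) < 10L) {
    wilcoxon_exact_tail(r, n1, W)
  } else {
    wilcoxon_normal_tail(r, n1, n2, W)
  }
}

# Exact P(W >= W_obs) by counting size-n1 subsets of the midrank multiset
# with each achievable rank sum. Midranks are multiples of 1/2, so doubling
# gives an integer knapsack: cnt[k+1, s+1] = number of size-k subsets with
# doubled-rank sum s.
wilcoxon_exact_tail <- function(r, n1, W) {
  r2 <- as.integer(round(2 * r))
  N <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  cnt <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  cnt[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      nz <- which(cnt[k, ] > 0)
      if (length(nz)) {
        dest <- nz + v
        dest_ok <- dest <= smax + 1L
        cnt[k + 1L, dest[dest_ok]] <- cnt[k + 1L, dest[dest_ok]] + cnt[k, nz[dest_ok]]
      }
    }
  }
  tail_counts <- cnt[n1 + 1L, ]
  total <- sum(tail_counts)
  thresh <- as.integer(round(2 * W))
  p <- sum(tail_counts[(thresh + 1L):(smax + 1L)]) / total
  min(max(p, .Machine$double.xmin), 1)
}

# Normal approximation with midrank tie correction and continuity correction
wilcoxon_normal_tail <- function(r, n1, n2, W) {
  N <- n1 + n2
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)               # all values tied
  z <- (U - mu - 0.5) / sqrt(sigma2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}
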