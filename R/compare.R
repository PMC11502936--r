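#' Mann-Whitney rank-sum comparison of per-transect densities
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test on two samples of
#' per-transect cone densities. The exact null distribution is used when
#' `n1 * n2 <= 400` and the pooled sample is tie-free; otherwise the normal
#' approximation with tie and continuity corrections is used. The reported
#' statistic is the smaller of the two one-sided U statistics (which always
#' satisfy `U + U' = n1 * n2`).
#'
#' The test's sampling units are individual transects, not pooled densities:
#' comparing two survey years with 31 and 33 transects gives n = 64.
#'
#' @param x,y Numeric vectors of per-transect densities (non-empty).
#' @return An object of class `rank_sum_result`: list with `u_statistic`,
#'   `n1`, `n2`, `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    cc_abort("Both samples must be non-empty.", class = "conecap_validation_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 * n2 <= 400) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  u_x <- unname(wt$statistic)   # U for x relative to y
  structure(
    list(u_statistic = min(u_x, n1 * n2 - u_x),
         n1 = n1, n2 = n2,
         p_value = unname(wt$p.value),
         method = if (exact) "exact" else "normal_approx"),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Fold change between two survey values
#'
#' @param before Baseline value (> 0).
#' @param after Later value.
#' @return `after / before` (e.g. 8.375 for an "eightfold" increase, 0.17
#'   for an 83% decline).
#' @export
#' @examples
#' fold_change(0.48, 4.02)
fold_change <- function(before, after) {
  assert_positive(before, "before")
  if (!is.numeric(after) || any(!is.finite(after))) {
    cc_abort("`after` must be finite.", class = "conecap_domain_error")
  }
  after / before
}

#' Decline range across two capacity intervals
#'
#' Compares a before interval (low, high) with an after interval by
#' cross-pairing every before bound with every after bound and computing
#' `100 * (1 - after / before)` for all four pairings; the minimum and
#' maximum of those four are the decline range. (Pairing low-with-low and
#' high-with-high would instead give a single percentage when the interval
#' ratio is constant.)
#'
#' @param before_interval,after_interval Numeric length-2 vectors
#'   `c(low, high)` with positive bounds, low <= high.
#' @return A list of class `decline_range`: `min_percent`, `max_percent`
#'   (unrounded; round for display).
#' @export
#' @examples
#' decline_range(c(241, 421), c(82, 143))
decline_range <- function(before_interval, after_interval) {
  for (iv in list(before = before_interval, after = after_interval)) {
    if (length(iv) != 2 || any(!is.finite(iv)) || any(iv <= 0)) {
      cc_abort("Intervals must be length-2 positive numeric vectors.",
               class = "conecap_domain_error")
    }
    if (iv[1] > iv[2]) {
      cc_abort("Interval low bound exceeds high bound.",
               class = "conecap_domain_error")
    }
  }
  pairs <- expand.grid(b = before_interval, a = after_interval)
  pct <- 100 * (1 - pairs$a / pairs$b)
  structure(list(min_percent = min(pct), max_percent = max(pct)),
            class = "decline_range")
}

#' @export
print.decline_range <- function(x, ...) {
  cat(sprintf("Decline range: %g%% - %g%%\n",
              round_half_up(x$min_percent), round_half_up(x$max_percent)))
  invisible(x)
}
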