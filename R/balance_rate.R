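#' Balance rate
#'
#' Composite evaluation metric
#' `BR = (2 - (sensitivity + specificity)) + |sensitivity - specificity|`.
#' The first term penalises low overall performance, the second penalises
#' imbalance between the two class-wise rates, so a classifier that buys
#' total accuracy by sacrificing one class scores badly. BR is symmetric in
#' its arguments, 0 for a perfect balanced classifier and 2 at the
#' degenerate corners (always-one-class predictions).
#'
#' @param sensitivity,specificity Class-wise rates in `[0, 1]`; vectors are
#'   recycled.
#' @return Numeric balance rate(s) in `[0, 2]`; lower is better.
#' @examples
#' balance_rate(1, 1)             # 0
#' balance_rate(0.6738, 0.7552)   # 0.6524
#' @export
balance_rate <- function(sensitivity, specificity) {
  if (anyNA(sensitivity) || anyNA(specificity) ||
      any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must be in [0, 1]", call. = FALSE)
  }
  (2 - (sensitivity + specificity)) + abs(sensitivity - specificity)
}
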