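#' Z-score standardization fitted on training data
#'
#' Learns per-feature mean and population standard deviation from training
#' feature vectors and applies `(x - mu) / sigma` to any vector or matrix of
#' features. Standardization puts magnitude- and phase-derived statistics on
#' a common scale so neither dominates a distance-based classifier.
#' Constant features (sigma = 0) map to 0 and are flagged.
#'
#' @param train_features A numeric matrix or data frame of training feature
#'   vectors (rows = samples), or a list of named numeric vectors.
#' @return An object of class `standardizer` with fields `mean`, `sd`
#'   (population), and `constant` (logical flags).
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' z <- apply_standardizer(fit_standardizer(x), x)
#' colMeans(z)  # ~0
#' @export
fit_standardizer <- function(train_features) {
  x <- as_feature_matrix(train_features)
  if (nrow(x) < 2) stop("need at least 2 training vectors", call. = FALSE)
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2, mu)^2))
  structure(list(mean = mu, sd = sd, constant = sd == 0),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params A fitted `standardizer`.
#' @param features A numeric vector, matrix or data frame of features with
#'   the same columns the standardizer was fitted on.
#' @export
apply_standardizer <- function(params, features) {
  stopifnot(inherits(params, "standardizer"))
  single <- is.null(dim(features))
  x <- as_feature_matrix(if (single) t(features) else features)
  if (ncol(x) != length(params$mean)) {
    stop("feature count mismatch: standardizer has ", length(params$mean),
         ", input has ", ncol(x), call. = FALSE)
  }
  sd_safe <- ifelse(params$constant, 1, params$sd)
  z <- sweep(sweep(x, 2, params$mean), 2, sd_safe, "/")
  z[, params$constant] <- 0
  if (single) z[1, ] else z
}

as_feature_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
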