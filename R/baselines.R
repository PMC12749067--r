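#' Statistical-feature (SF) baseline for one transmitter block
#'
#' Seven summary statistics of the flattened `|S21|` magnitudes of a block:
#' mean, population standard deviation, minimum, maximum, median, range and
#' the Shannon index `H = -sum(p_i log p_i)` with `p_i = x_i / sum(x)`
#' (zero magnitudes contribute 0; an all-zero block has `H = 0`).
#'
#' @param block A `tx_block`.
#' @return A named numeric vector of length 7.
#' @export
sf_features <- function(block) {
  stopifnot(inherits(block, "tx_block"))
  x <- as.vector(Mod(block$values))
  if (length(x) == 0) stop("empty block", call. = FALSE)
  total <- sum(x)
  shannon <- if (total == 0) 0 else {
    p <- x / total
    p <- p[p > 0]
    -sum(p * log(p))
  }
  c(mean = mean(x), sd = pop_sd(x), min = min(x), max = max(x),
    median = stats::median(x), range = max(x) - min(x), shannon = shannon)
}

#' PCA baseline features per transmitter block
#'
#' Fits, for each transmitter position, a principal component analysis on
#' the flattened `|S21|` vectors of the training scans, keeps the top
#' `n_pcs` components, and projects both training and test scans with the
#' training loadings. Scores are concatenated across the transmitter
#' positions.
#'
#' @param train_scans,test_scans Lists of [s21_scan()] objects.
#' @param n_pcs Number of principal components per block (10 or 40 in the
#'   standard configurations; any count up to the training rank works).
#' @return A list with tibbles `train` and `test` whose columns are
#'   `tx<t>_pc<k>` scores, preceded by `sample_id`, `density`, `health`.
#' @export
pca_features <- function(train_scans, test_scans = list(), n_pcs = 10L) {
  stopifnot(length(train_scans) >= 2)
  n_pcs <- as.integer(n_pcs)
  n_tx <- train_scans[[1]]$geometry$n_tx
  flatten <- function(scans, t) {
    do.call(rbind, lapply(scans, function(s) {
      as.vector(Mod(split_by_transmitter(s)[[t]]$values))
    }))
  }
  tr_list <- list(); te_list <- list()
  for (t in seq_len(n_tx)) {
    xtr <- flatten(train_scans, t)
    pr <- stats::prcomp(xtr, center = TRUE, scale. = FALSE, rank. = n_pcs)
    rank_avail <- sum(pr$sdev > pr$sdev[1] * 1e-10)
    if (n_pcs > rank_avail) {
      stop("n_pcs = ", n_pcs, " exceeds training rank (", rank_avail, ")",
           call. = FALSE)
    }
    nm <- paste0("tx", t, "_pc", seq_len(n_pcs))
    tr <- pr$x[, seq_len(n_pcs), drop = FALSE]
    colnames(tr) <- nm
    tr_list[[t]] <- tr
    if (length(test_scans)) {
      xte <- flatten(test_scans, t)
      te <- sweep(xte, 2, pr$center) %*% pr$rotation[, seq_len(n_pcs), drop = FALSE]
      colnames(te) <- nm
      te_list[[t]] <- te
    }
  }
  meta <- function(scans) tibble::tibble(
    sample_id = vapply(scans, function(s) s$sample_id, character(1)),
    density = vapply(scans, function(s) s$density_label, character(1)),
    health = vapply(scans, function(s) s$health_label, character(1))
  )
  out <- list(train = dplyr::bind_cols(meta(train_scans),
                                       tibble::as_tibble(do.call(cbind, tr_list))))
  out$test <- if (length(test_scans)) {
    dplyr::bind_cols(meta(test_scans), tibble::as_tibble(do.call(cbind, te_list)))
  } else {
    tibble::tibble()
  }
  out
}
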