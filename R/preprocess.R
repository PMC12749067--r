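#' Remove per-receiver DC bias
#'
#' Subtracts from each row of a transmitter block its complex mean across the
#' frequency columns, so every receiver trace has zero mean over frequency.
#' This suppresses the k = 0 (DC) coefficient of the subsequent spectral
#' transform, which otherwise carries uninformative background signal and
#' system bias.
#'
#' @param block A `tx_block`.
#' @return The block with row means removed; shape unchanged.
#' @export
remove_dc_bias <- function(block) {
  stopifnot(inherits(block, "tx_block"))
  if (ncol(block$values) < 2) {
    stop("cannot remove DC bias from a single-column block", call. = FALSE)
  }
  block$values <- block$values - rowMeans(block$values)
  block
}

#' Sub-band masks
#'
#' The 1-9 GHz sweep divides into eight contiguous 1 GHz sub-bands SB1-SB8.
#' A mask selects a subset of them, written as eight bits with an optional
#' space after the fourth, e.g. `"1011 1100"` (SB1, SB3-SB6). Band `b`
#' covers `[b, b+1)` GHz, i.e. 0-based columns `200*(b-1) ... 200*b - 1`;
#' band 8 additionally includes the 9 GHz endpoint column (201 columns).
#'
#' @param bits A mask string (`"1011 1100"` or `"10111100"`), or a logical
#'   vector of length 8.
#' @return An object of class `subband_mask` (logical vector of 8 with a
#'   canonical print form).
#' @examples
#' subband_mask("1011 1100")
#' subband_bands(subband_mask("1000 0001"))
#' @export
subband_mask <- function(bits) {
  if (inherits(bits, "subband_mask")) return(bits)
  if (is.character(bits)) {
    stopifnot(length(bits) == 1)
    s <- gsub(" ", "", bits)
    if (nchar(s) != 8 || grepl("[^01]", s)) {
      stop("mask must be 8 bits of 0/1, e.g. \"1011 1100\"", call. = FALSE)
    }
    bits <- strsplit(s, "")[[1]] == "1"
  }
  bits <- as.logical(bits)
  if (length(bits) != 8 || anyNA(bits)) {
    stop("mask must have exactly 8 logical bits", call. = FALSE)
  }
  structure(bits, class = "subband_mask")
}

#' @rdname subband_mask
#' @param mask A `subband_mask`.
#' @return `format.subband_mask()` gives the canonical `"1011 1100"` string;
#'   `subband_bands()` the integer band numbers selected.
#' @export
subband_bands <- function(mask) which(unclass(subband_mask(mask)))

#' @export
format.subband_mask <- function(x, ...) {
  s <- paste(ifelse(unclass(x), "1", "0"), collapse = "")
  paste(substr(s, 1, 4), substr(s, 5, 8))
}

#' @export
print.subband_mask <- function(x, ...) {
  cat("<subband_mask> ", format(x), " (bands ",
      paste(subband_bands(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# 1-based column indices of sub-band b on the full 1601-point grid
subband_cols <- function(b, geometry = scan_geometry()) {
  cols_per_band <- 1e9 / geometry$f_step_hz  # 200 on the default grid
  start <- (b - 1) * cols_per_band + 1
  end <- b * cols_per_band
  if (b == 8) end <- end + 1  # 9 GHz endpoint assigned to SB8
  as.integer(start:end)
}

#' Slice a transmitter block into selected sub-bands
#'
#' @param block A `tx_block` covering the full frequency grid.
#' @param mask A [subband_mask()] (or mask string) with at least one band set.
#' @param geometry The scan geometry of the full grid.
#' @return A list of `tx_block` objects, one per selected band in ascending
#'   band order.
#' @export
subband_slice <- function(block, mask, geometry = scan_geometry()) {
  stopifnot(inherits(block, "tx_block"))
  mask <- subband_mask(mask)
  bands <- subband_bands(mask)
  if (length(bands) == 0) stop("empty sub-band mask", call. = FALSE)
  full <- freq_grid(geometry)
  if (ncol(block$values) != geometry$n_freq ||
      max(abs(block$column_freqs_hz - full)) > 1e-3) {
    stop("block must cover the full ", geometry$n_freq, "-point grid",
         call. = FALSE)
  }
  lapply(bands, function(b) {
    cols <- subband_cols(b, geometry)
    tx_block(block$values[, cols, drop = FALSE], block$tx_index,
             block$column_freqs_hz[cols])
  })
}
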