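#' Construct an S21 scan object
#'
#' An `s21_scan` bundles the complex transmission matrix of one breast scan
#' with its geometry and labels. Rows are ordered transmitter-major: rows
#' `(t-1)*n_rx + 1 ... t*n_rx` hold the `n_rx` receiver positions of
#' transmitter `t`. Columns are ascending frequency.
#'
#' @param matrix Complex matrix with `n_tx * n_rx` rows and `n_freq` columns.
#' @param geometry A [scan_geometry()].
#' @param sample_id Identifier string.
#' @param density_label One of `"LD"`, `"HD"`, `"unknown"`.
#' @param health_label One of `"healthy"`, `"non-healthy"`, `"unknown"`.
#' @return An object of class `s21_scan`.
#' @export
s21_scan <- function(matrix, geometry = scan_geometry(), sample_id = "scan",
                     density_label = "unknown", health_label = "unknown") {
  density_label <- match.arg(density_label, c("LD", "HD", "unknown"))
  health_label <- match.arg(health_label, c("healthy", "non-healthy", "unknown"))
  if (!is.matrix(matrix)) stop("matrix must be a matrix", call. = FALSE)
  if (!is.complex(matrix)) storage.mode(matrix) <- "complex"
  validate_geometry(geometry)
  if (nrow(matrix) != geometry$n_tx * geometry$n_rx ||
      ncol(matrix) != geometry$n_freq) {
    stop("geometry error: matrix is ", nrow(matrix), "x", ncol(matrix),
         " but geometry implies ", geometry$n_tx * geometry$n_rx, "x",
         geometry$n_freq, call. = FALSE)
  }
  if (any(!is.finite(Re(matrix))) || any(!is.finite(Im(matrix)))) {
    stop("scan matrix contains non-finite entries", call. = FALSE)
  }
  structure(
    list(matrix = matrix, geometry = geometry, sample_id = as.character(sample_id),
         density_label = density_label, health_label = health_label),
    class = "s21_scan"
  )
}

#' @export
print.s21_scan <- function(x, ...) {
  cat("<s21_scan> ", x$sample_id, ": ", nrow(x$matrix), "x", ncol(x$matrix),
      " complex, density=", x$density_label, ", health=", x$health_label,
      "\n", sep = "")
  invisible(x)
}

# One transmitter's sub-matrix: n_rx rows x selected frequency columns.
tx_block <- function(values, tx_index, column_freqs_hz) {
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (ncol(values) != length(column_freqs_hz)) {
    stop("column_freqs_hz must match the number of columns", call. = FALSE)
  }
  if (length(column_freqs_hz) > 1 &&
      any(diff(column_freqs_hz) <= 0)) {
    stop("column frequencies must be strictly increasing", call. = FALSE)
  }
  structure(
    list(values = values, tx_index = as.integer(tx_index),
         column_freqs_hz = as.numeric(column_freqs_hz)),
    class = "tx_block"
  )
}

#' Split a scan into per-transmitter blocks
#'
#' Restructures the full `n_tx*n_rx x n_freq` matrix into `n_tx` blocks of
#' `n_rx` rows each; block `t` holds rows `(t-1)*n_rx + 1 ... t*n_rx`, so
#' concatenating the blocks in order reproduces the scan matrix exactly.
#'
#' @param scan An [s21_scan()].
#' @return A list of `n_tx` `tx_block` objects, in transmitter order.
#' @examples
#' scan <- generate_scan("LD", seed = 1)
#' blocks <- split_by_transmitter(scan)
#' length(blocks)           # 10
#' dim(blocks[[1]]$values)  # 80 x 1601
#' @export
split_by_transmitter <- function(scan) {
  stopifnot(inherits(scan, "s21_scan"))
  g <- scan$geometry
  if (nrow(scan$matrix) %% g$n_rx != 0) {
    stop("geometry error: row count not divisible by n_rx", call. = FALSE)
  }
  freqs <- freq_grid(g)
  lapply(seq_len(g$n_tx), function(t) {
    rows <- ((t - 1) * g$n_rx + 1):(t * g$n_rx)
    tx_block(scan$matrix[rows, , drop = FALSE], t, freqs)
  })
}
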