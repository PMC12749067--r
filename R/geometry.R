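#' Multistatic scan geometry
#'
#' Describes the antenna geometry and frequency grid of a multistatic
#' microwave breast scan: `n_tx` transmitter stops, `n_rx` receiver stops
#' spaced `rx_step_deg` degrees apart over a full rotation, and an evenly
#' spaced frequency sweep from `f_start_hz` in steps of `f_step_hz` over
#' `n_freq` points. The default is the acquisition geometry this package
#' targets: 10 transmitters at five 72-degree-spaced pairs (9 degrees within
#' a pair), 80 receivers every 4.5 degrees, and 1601 frequencies covering
#' 1-9 GHz at a 5 MHz step.
#'
#' @param n_tx Number of transmitter positions.
#' @param n_rx Number of receiver positions per transmitter.
#' @param rx_step_deg Receiver angular step in degrees.
#' @param tx_angles_deg Transmitter angles in degrees, sorted, unique,
#'   in `[0, 360)`.
#' @param f_start_hz First frequency of the sweep in Hz.
#' @param f_step_hz Frequency step in Hz.
#' @param n_freq Number of frequency points.
#'
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()
#' g$n_tx * g$n_rx      # 800 Tx/Rx pairs
#' tail(freq_grid(g), 1) # 9 GHz endpoint
#' @export
scan_geometry <- function(n_tx = 10L,
                          n_rx = 80L,
                          rx_step_deg = 4.5,
                          tx_angles_deg = c(0, 9, 72, 81, 144, 153, 216, 225, 288, 297),
                          f_start_hz = 1e9,
                          f_step_hz = 5e6,
                          n_freq = 1601L) {
  g <- structure(
    list(
      n_tx = as.integer(n_tx),
      n_rx = as.integer(n_rx),
      rx_step_deg = as.numeric(rx_step_deg),
      tx_angles_deg = as.numeric(tx_angles_deg),
      f_start_hz = as.numeric(f_start_hz),
      f_step_hz = as.numeric(f_step_hz),
      n_freq = as.integer(n_freq)
    ),
    class = "scan_geometry"
  )
  validate_geometry(g)
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  if (length(g$tx_angles_deg) != g$n_tx) {
    stop("geometry error: tx_angles_deg must have length n_tx (", g$n_tx, ")",
         call. = FALSE)
  }
  if (is.unsorted(g$tx_angles_deg, strictly = TRUE) ||
      any(g$tx_angles_deg < 0) || any(g$tx_angles_deg >= 360)) {
    stop("geometry error: tx angles must be sorted, unique, in [0, 360)",
         call. = FALSE)
  }
  if (abs(g$rx_step_deg * g$n_rx - 360) > 1e-9) {
    stop("geometry error: rx_step_deg * n_rx must equal 360", call. = FALSE)
  }
  if (g$n_freq < 2 || g$f_step_hz <= 0) {
    stop("geometry error: need an increasing frequency grid", call. = FALSE)
  }
  g
}

#' @describeIn scan_geometry Frequency grid (Hz) implied by a geometry;
#'   column `i` (1-based) maps to `f_start_hz + (i - 1) * f_step_hz`.
#' @param geometry A `scan_geometry`.
#' @export
freq_grid <- function(geometry = scan_geometry()) {
  geometry$f_start_hz + (seq_len(geometry$n_freq) - 1) * geometry$f_step_hz
}

#' @describeIn scan_geometry Receiver angles in degrees (length `n_rx`).
#' @export
rx_angles <- function(geometry = scan_geometry()) {
  (seq_len(geometry$n_rx) - 1) * geometry$rx_step_deg
}

# 1-based column index of a frequency that must lie on the grid
freq_col_index <- function(f_hz, geometry) {
  idx <- (f_hz - geometry$f_start_hz) / geometry$f_step_hz
  if (length(idx) != 1 || is.na(idx) || abs(idx - round(idx)) > 1e-6 ||
      round(idx) < 0 || round(idx) >= geometry$n_freq) {
    stop("frequency ", format(f_hz), " Hz is not on the scan grid", call. = FALSE)
  }
  as.integer(round(idx)) + 1L
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry> ", x$n_tx, " Tx x ", x$n_rx, " Rx (", x$rx_step_deg,
      " deg step), ", x$n_freq, " freqs ",
      format(x$f_start_hz / 1e9), "-",
      format((x$f_start_hz + (x$n_freq - 1) * x$f_step_hz) / 1e9),
      " GHz\n", sep = "")
  invisible(x)
}
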