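#' Dual-domain discrete Fourier transform of a transmitter block
#'
#' Applies the unnormalized forward DFT (kernel `exp(-j 2 pi k n / N)`) to a
#' transmitter block along one of its two axes. `"rf_spectral"` transforms
#' each receiver's trace across the frequency columns (`N` = column count),
#' describing how oscillatory the spectral response is; `"spatial"`
#' transforms each frequency column across the receiver rows (`N` = 80),
#' describing angular heterogeneity around the breast. Component order is
#' `k = 0, 1, ..., N-1` along the transform axis.
#'
#' @param block A `tx_block`.
#' @param domain `"rf_spectral"` or `"spatial"`.
#' @return A `coefficient_block`: list with complex `values` (same shape as
#'   the input), the `domain`, and `n_components_available` along the
#'   transform axis.
#' @export
fft_along <- function(block, domain = c("rf_spectral", "spatial")) {
  stopifnot(inherits(block, "tx_block"))
  domain <- match.arg(domain)
  v <- block$values
  if (length(v) == 0) stop("empty block", call. = FALSE)
  if (domain == "rf_spectral") {
    out <- t(stats::mvfft(t(v)))
    n_avail <- ncol(v)
  } else {
    out <- stats::mvfft(v)
    n_avail <- nrow(v)
  }
  structure(list(values = out, domain = domain,
                 n_components_available = n_avail),
            class = "coefficient_block")
}

#' Magnitude and phase of truncated Fourier coefficients
#'
#' Keeps components `k = 0 ... K-1` along the transform axis and returns the
#' elementwise modulus and principal-value phase (two-argument arctangent,
#' in `(-pi, pi]`). The phase of an exactly-zero coefficient is 0.
#'
#' @param coeffs A `coefficient_block` from [fft_along()].
#' @param K Number of leading components to keep.
#' @return A `polar_block`: list with `magnitude` and `phase` matrices.
#' @export
polar_decompose <- function(coeffs, K) {
  stopifnot(inherits(coeffs, "coefficient_block"))
  K <- as.integer(K)
  if (K < 1 || K > coeffs$n_components_available) {
    stop("K must be in 1..", coeffs$n_components_available, call. = FALSE)
  }
  v <- if (coeffs$domain == "rf_spectral") {
    coeffs$values[, seq_len(K), drop = FALSE]
  } else {
    coeffs$values[seq_len(K), , drop = FALSE]
  }
  polar_block(v)
}

# Numerically-zero coefficients (e.g. the DC term after mean removal) have
# an arbitrary phase branch; the zero-coefficient convention (phase = 0) is
# applied below a relative magnitude threshold to keep phase statistics
# stable across algebraically equivalent computation orders.
polar_block <- function(v, zero_tol = 1e-12) {
  magnitude <- Mod(v)
  phase <- Arg(v)
  mx <- max(magnitude)
  if (mx > 0) phase[magnitude < zero_tol * mx] <- 0
  structure(list(magnitude = magnitude, phase = phase), class = "polar_block")
}

#' Feature-extraction configuration
#'
#' @param n_components Number of leading FFT components `K` retained in each
#'   domain (default 40; must not exceed 80 for the spatial domain).
#' @param use_magnitude,use_phase Which polar quantities contribute
#'   statistics; at least one must be `TRUE`.
#' @param mask A [subband_mask()] used when `mode = "per_band"`.
#' @param mode `"whole_band"` (one feature block per transmitter over the
#'   full sweep) or `"per_band"` (independent feature blocks per selected
#'   sub-band).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_components = 40L,
                           use_magnitude = TRUE,
                           use_phase = TRUE,
                           mask = subband_mask("1111 1111"),
                           mode = c("whole_band", "per_band")) {
  mode <- match.arg(mode)
  n_components <- as.integer(n_components)
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  if (n_components > 80) {
    stop("n_components must be <= 80 (spatial domain has 80 components)",
         call. = FALSE)
  }
  if (!use_magnitude && !use_phase) {
    stop("at least one of use_magnitude/use_phase must be TRUE", call. = FALSE)
  }
  structure(list(n_components = n_components, use_magnitude = use_magnitude,
                 use_phase = use_phase, mask = subband_mask(mask), mode = mode),
            class = "feature_config")
}

# Leading K spectral DFT coefficients by direct kernel multiplication,
# S %*% exp(-j 2 pi k n / N). Equals the full transform truncated to
# k = 0..K-1 but costs O(R N K); much cheaper than a length-1601 (prime)
# FFT when K is small. Kernel matrices are memoised per (N, K).
.dft_kernel_cache <- new.env(parent = emptyenv())

truncated_spectral_dft <- function(values, K) {
  N <- ncol(values)
  key <- paste(N, K)
  W <- .dft_kernel_cache[[key]]
  if (is.null(W)) {
    W <- exp(-2i * pi * outer(0:(N - 1), 0:(K - 1)) / N)
    .dft_kernel_cache[[key]] <- W
  }
  values %*% W
}

# statistic names for one block, in the fixed concatenation order:
# spectral mag (mu, sd), spectral phase (mu, sd), spatial mag, spatial phase
block_stat_names <- function(config) {
  quantities <- c(if (config$use_magnitude) "mag",
                  if (config$use_phase) "phase")
  unlist(lapply(c("spec", "spat"), function(d)
    unlist(lapply(quantities, function(q)
      paste(d, q, c("mu", "sd"), sep = "_")))))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Eight summary statistics of one (DC-removed) transmitter block
#'
#' For each domain (spectral, spatial) the block is Fourier transformed,
#' truncated to the first `K` components, decomposed into magnitude and
#' phase, and each retained matrix is pooled into a mean and a population
#' standard deviation over all of its entries. With both magnitude and phase
#' enabled this yields eight numbers per block, in the fixed order:
#' spectral-magnitude mean/sd, spectral-phase mean/sd, spatial-magnitude
#' mean/sd, spatial-phase mean/sd.
#'
#' @param block A `tx_block` with DC bias already removed.
#' @param config A [feature_config()].
#' @return A named numeric vector (length 8, or 4 if only one quantity is
#'   enabled).
#' @export
block_features <- function(block, config = feature_config()) {
  stopifnot(inherits(block, "tx_block"), inherits(config, "feature_config"))
  out <- numeric(0)
  K <- config$n_components
  for (domain in c("rf_spectral", "spatial")) {
    polar <- if (domain == "rf_spectral" && K <= ncol(block$values) %/% 4) {
      polar_block(truncated_spectral_dft(block$values, K))
    } else {
      polar_decompose(fft_along(block, domain), K)
    }
    if (config$use_magnitude) {
      out <- c(out, mean(polar$magnitude), pop_sd(polar$magnitude))
    }
    if (config$use_phase) {
      out <- c(out, mean(polar$phase), pop_sd(polar$phase))
    }
  }
  stats::setNames(out, block_stat_names(config))
}

#' Extract the dual-domain FFT feature vector of a scan
#'
#' Splits the scan into its per-transmitter blocks and computes
#' [block_features()] for each. In `"whole_band"` mode the DC bias is removed
#' over the full sweep and one statistics block is produced per transmitter;
#' in `"per_band"` mode each selected 1 GHz sub-band is sliced first, DC is
#' removed within the band, and the band contributes its own statistics
#' block. Blocks are concatenated in (transmitter, band) lexicographic
#' order, so the whole-band vector with both quantities enabled has length
#' `8 * 10 = 80` and a per-band vector `8 * 10 * n_bands`.
#'
#' @param scan An [s21_scan()].
#' @param config A [feature_config()].
#' @return A named numeric feature vector; names are
#'   `tx<t>_<band>_<domain>_<quantity>_<stat>` with band `full` or `sb<b>`.
#' @examples
#' scan <- generate_scan("HD", seed = 7)
#' length(extract_features(scan))                               # 80
#' cfg <- feature_config(mask = "1011 1100", mode = "per_band")
#' length(extract_features(scan, cfg))                          # 400
#' @export
extract_features <- function(scan, config = feature_config()) {
  stopifnot(inherits(scan, "s21_scan"))
  blocks <- split_by_transmitter(scan)
  g <- scan$geometry
  pieces <- lapply(blocks, function(bl) {
    if (config$mode == "whole_band") {
      v <- block_features(remove_dc_bias(bl), config)
      stats::setNames(v, paste0("tx", bl$tx_index, "_full_", names(v)))
    } else {
      bands <- subband_bands(config$mask)
      slices <- subband_slice(bl, config$mask, g)
      unlist(lapply(seq_along(slices), function(i) {
        v <- block_features(remove_dc_bias(slices[[i]]), config)
        stats::setNames(v, paste0("tx", bl$tx_index, "_sb", bands[i], "_",
                                  names(v)))
      }))
    }
  })
  unlist(pieces)
}

#' @describeIn extract_features Length the feature vector will have under a
#'   configuration, without extracting anything.
#' @param geometry The scan geometry.
#' @export
feature_length <- function(config = feature_config(),
                           geometry = scan_geometry()) {
  per_block <- 4L * (config$use_magnitude + config$use_phase)
  n_bands <- if (config$mode == "whole_band") 1L else
    length(subband_bands(config$mask))
  per_block * geometry$n_tx * n_bands
}

#' Feature table for a set of scans
#'
#' Applies [extract_features()] to every scan and assembles a tibble with
#' one row per scan: `sample_id`, `density`, `health`, then the feature
#' columns.
#'
#' @param scans A list of [s21_scan()] objects.
#' @param config A [feature_config()].
#' @return A tibble.
#' @export
feature_table <- function(scans, config = feature_config()) {
  stopifnot(length(scans) > 0)
  feats <- lapply(scans, extract_features, config = config)
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = vapply(scans, function(s) s$sample_id, character(1)),
      density = vapply(scans, function(s) s$density_label, character(1)),
      health = vapply(scans, function(s) s$health_label, character(1))
    ),
    tibble::as_tibble(mat)
  )
}
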