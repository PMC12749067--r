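# Fixtures built in code: small random blocks, full-geometry random scans,
# and independent oracles used across test files.

# A tx_block with random complex entries (not tied to the scan geometry).
random_block <- function(n_rx = 4, n_col = 8, tx = 1, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(complex(real = rnorm(n_rx * n_col),
                        imaginary = rnorm(n_rx * n_col)), n_rx, n_col)
    mwdensity:::tx_block(v, tx, seq_len(n_col) * 1e6)
  })
}

# A full 800x1601 scan with iid complex Gaussian entries.
random_scan <- function(seed = 1, sample_id = paste0("rand", seed),
                        density = "unknown", health = "unknown") {
  g <- scan_geometry()
  withr::with_seed(seed, {
    m <- matrix(complex(real = rnorm(800 * 1601), imaginary = rnorm(800 * 1601)),
                800, 1601)
    s21_scan(m, g, sample_id, density, health)
  })
}

# Brute-force DFT oracle: the defining double sum, evaluated through an
# explicitly constructed kernel matrix -- no FFT routine involved.
dft_oracle <- function(x, along = c("cols", "rows")) {
  along <- match.arg(along)
  if (along == "cols") {           # transform each row across its columns
    N <- ncol(x)
    W <- outer(0:(N - 1), 0:(N - 1), function(k, n) exp(-2i * pi * k * n / N))
    x %*% t(W)
  } else {                          # transform each column across its rows
    N <- nrow(x)
    W <- outer(0:(N - 1), 0:(N - 1), function(k, n) exp(-2i * pi * k * n / N))
    W %*% x
  }
}

# Independent recomputation of block_features: separate code path built on
# the brute-force oracle, same phase convention for numerically-zero
# coefficients.
block_features_oracle <- function(block, K) {
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  polar_of <- function(v) {
    mag <- Mod(v)
    ph <- Arg(v)
    ph[mag < 1e-12 * max(mag)] <- 0
    list(mag = mag, ph = ph)
  }
  spec <- polar_of(dft_oracle(block$values, "cols")[, 1:K, drop = FALSE])
  spat <- polar_of(dft_oracle(block$values, "rows")[1:K, , drop = FALSE])
  c(mean(spec$mag), psd(spec$mag), mean(spec$ph), psd(spec$ph),
    mean(spat$mag), psd(spat$mag), mean(spat$ph), psd(spat$ph))
}

# Shared small synthetic dataset, generated once per test session.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(n_per_cell = 4, seed = 11)
    cache
  }
})
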