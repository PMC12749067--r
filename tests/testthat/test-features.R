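test_that("fft_along matches impulse/constant signals and the DFT oracle", {
  one_row <- function(x) mwdensity:::tx_block(matrix(x, 1), 1,
                                              seq_along(x) * 1e6)
  const <- fft_along(one_row(c(1, 1, 1, 1) + 0i), "rf_spectral")
  expect_equal(as.vector(const$values), c(4, 0, 0, 0) + 0i, tolerance = 1e-12)
  impulse <- fft_along(one_row(c(1, 0, 0, 0) + 0i), "rf_spectral")
  expect_equal(as.vector(impulse$values), rep(1 + 0i, 4), tolerance = 1e-12)

  for (seed in 1:10) {
    bl <- random_block(4, 8, seed = seed)
    expect_lt(max(Mod(fft_along(bl, "rf_spectral")$values -
                        dft_oracle(bl$values, "cols"))), 1e-9)
    expect_lt(max(Mod(fft_along(bl, "spatial")$values -
                        dft_oracle(bl$values, "rows"))), 1e-9)
  }
})

test_that("polar decomposition follows the magnitude/phase conventions", {
  v <- matrix(c(3 + 4i, -1 + 0i, 0 + 0i, 1i), 1, 4)
  cb <- structure(list(values = v, domain = "rf_spectral",
                       n_components_available = 4),
                  class = "coefficient_block")
  p <- polar_decompose(cb, 4)
  expect_equal(p$magnitude[1, ], c(5, 1, 0, 1))
  expect_equal(p$phase[1, ], c(atan2(4, 3), pi, 0, pi / 2))
  expect_error(polar_decompose(cb, 5), "K must be")

  # truncation keeps the leading components along the transform axis
  p2 <- polar_decompose(cb, 2)
  expect_equal(dim(p2$magnitude), c(1L, 2L))
})

test_that("block_features matches an independent oracle recomputation", {
  cfg <- feature_config(n_components = 5)
  for (seed in 1:5) {
    bl <- remove_dc_bias(random_block(8, 20, seed = 100 + seed))
    got <- unname(block_features(bl, cfg))
    want <- block_features_oracle(bl, 5)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # realistic block size, K = 40
  bl <- remove_dc_bias(random_block(80, 200, seed = 7))
  got <- unname(block_features(bl, feature_config(n_components = 40)))
  want <- block_features_oracle(bl, 40)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("block_features has the fixed eight-statistic layout", {
  bl <- remove_dc_bias(random_block(8, 20, seed = 3))
  v <- block_features(bl, feature_config(n_components = 4))
  expect_named(v, c("spec_mag_mu", "spec_mag_sd", "spec_phase_mu",
                    "spec_phase_sd", "spat_mag_mu", "spat_mag_sd",
                    "spat_phase_mu", "spat_phase_sd"))
  zero <- mwdensity:::tx_block(matrix(0i, 8, 20), 1, seq_len(20) * 1e6)
  expect_equal(unname(block_features(zero, feature_config(n_components = 4))),
               rep(0, 8))
  mag_only <- block_features(bl, feature_config(n_components = 4,
                                                use_phase = FALSE))
  expect_named(mag_only, c("spec_mag_mu", "spec_mag_sd",
                           "spat_mag_mu", "spat_mag_sd"))
})

test_that("feature vectors have the documented length and ordering", {
  scan <- random_scan(seed = 5)
  whole <- extract_features(scan)
  expect_length(whole, 80)
  expect_match(names(whole)[1], "^tx1_full_spec_mag_mu$")

  cfg5 <- feature_config(mask = "1011 1100", mode = "per_band")
  per5 <- extract_features(scan, cfg5)
  expect_length(per5, 400)
  # (tx, band) lexicographic order
  expect_match(names(per5)[1], "^tx1_sb1_")
  expect_match(names(per5)[9], "^tx1_sb3_")
  expect_match(names(per5)[41], "^tx2_sb1_")

  # the length formula holds for every mask and both modes
  g <- scan_geometry()
  for (bits in 1:255) {
    mask <- subband_mask(as.logical(intToBits(bits)[1:8]))
    n_bands <- length(subband_bands(mask))
    cfg <- feature_config(mask = mask, mode = "per_band")
    expect_identical(feature_length(cfg, g), 8L * 10L * n_bands)
    cfg_m <- feature_config(mask = mask, mode = "per_band", use_phase = FALSE)
    expect_identical(feature_length(cfg_m, g), 4L * 10L * n_bands)
  }
  expect_identical(feature_length(feature_config(), g), 80L)

  # extraction matches the formula on a sample of masks
  for (m in c("0100 0000", "1000 0001", "0111 0110")) {
    cfg <- feature_config(mask = m, mode = "per_band")
    expect_length(extract_features(scan, cfg), feature_length(cfg, g))
  }
})

test_that("feature extraction is deterministic and scale-aware", {
  scan <- random_scan(seed = 6)
  expect_identical(extract_features(scan), extract_features(scan))

  # a global complex scale e^{j theta} leaves FFT magnitudes scaled and
  # phase means shifted by at most the wrapped constant
  theta <- 0.37
  scaled <- s21_scan(scan$matrix * exp(1i * theta), scan$geometry,
                     "scaled", scan$density_label, scan$health_label)
  f0 <- extract_features(scan)
  f1 <- extract_features(scaled)
  mag_idx <- grep("_mag_", names(f0))
  expect_equal(unname(f1[mag_idx]), unname(f0[mag_idx]), tolerance = 1e-9)
  mu_idx <- grep("_phase_mu", names(f0))
  expect_lte(max(abs(f1[mu_idx] - f0[mu_idx])), 2 * pi)
})

test_that("per-scan features standardize to zero mean unit variance", {
  feats <- lapply(1:6, function(i) extract_features(random_scan(seed = 30 + i)))
  std <- fit_standardizer(feats)
  z <- apply_standardizer(std, do.call(rbind, feats))
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, function(x) sqrt(mean((x - mean(x))^2)))),
               rep(1, ncol(z)), tolerance = 1e-9)

  # a held-out vector equal to the training mean standardizes to zero
  expect_equal(unname(apply_standardizer(std, std$mean)),
               rep(0, length(std$mean)))

  # constant features are flagged and map to zero
  x <- cbind(a = rep(2, 5), b = rnorm(5))
  std2 <- fit_standardizer(x)
  expect_true(std2$constant[["a"]])
  expect_equal(unname(apply_standardizer(std2, x)[, "a"]), rep(0, 5))

  expect_error(fit_standardizer(x[1, , drop = FALSE]), "at least 2")
})
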