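test_that("calibration derives the documented class levels and ratios", {
  cal <- calibrate_generator(generator_config())
  i4 <- which(freq_grid() == 4e9)
  i6 <- which(freq_grid() == 6e9)
  expect_equal(cal$HD$mu_nom[i4], 5.73e-5 / 0.46, tolerance = 1e-12)
  expect_equal(cal$LD$mu_nom[i4], 4.66e-5 / 0.53, tolerance = 1e-12)
  # ~23% HD std excess at 4 GHz, exactly 14% at 6 GHz by construction
  expect_equal(cal$HD$sigma_nom[i4] / cal$LD$sigma_nom[i4], 5.73 / 4.66,
               tolerance = 1e-12)
  expect_equal(cal$HD$sigma_nom[i6] / cal$LD$sigma_nom[i6], 1.14,
               tolerance = 1e-12)
  # CV curves hit the anchors and clamp outside them
  expect_equal(cal$HD$cv[i4], 0.46)
  expect_equal(cal$HD$cv[i6], 0.62)
  expect_equal(cal$HD$cv[1], 0.46)
  expect_equal(cal$HD$cv[1601], 0.62)

  # attenuation 1 keeps the LD mean level flat between the anchors
  cal1 <- calibrate_generator(generator_config(attenuation = 1))
  expect_equal(cal1$LD$mu_nom[i6], cal1$LD$mu_nom[i4], tolerance = 1e-12)

  expect_error(generator_config(attenuation = -1), "attenuation")
  expect_error(generator_config(m_harmonics = c(LD = 12L, HD = 4L)),
               "HD >= LD")
})

test_that("degenerate field gives a constant magnitude at the model level", {
  cfg <- generator_config(noise_frac = 0)
  cal <- calibrate_generator(cfg)
  M <- cfg$m_harmonics[["HD"]]
  harm <- list(mag = rep(0, 2 * M), ripple = rep(0, 2 * M))
  f <- c(4e9, 6e9)
  out <- signal_model("HD", 0, harm, cfg, cal, f_hz = f, add_noise = FALSE)
  cols <- match(f, freq_grid())
  for (j in seq_along(f)) {
    expected <- cal$HD$mu_eff[cols[j]] * exp(-cal$HD$s_eff[cols[j]]^2 / 2)
    expect_equal(Mod(out[, j]), rep(expected, 80), tolerance = 1e-12)
  }
  expect_error(signal_model("HD", 0, harm, cfg, cal, f_hz = 4.0001e9),
               "not on the scan grid")
})

test_that("spatial moments recover a single-harmonic field exactly", {
  # m(theta) = A (1 + b cos theta): population std over the 80 uniform
  # angles is A b / sqrt(2) by discrete orthogonality
  g <- scan_geometry()
  A <- 3e-5
  b <- 0.3
  th <- rx_angles(g) * pi / 180
  row <- A * (1 + b * cos(th))
  m <- matrix(rep(rep(row, 10), 1601), 800, 1601)
  scan <- s21_scan(m + 0i, g, "harm", "unknown", "unknown")
  mom <- estimate_spatial_moments(scan, 4e9)
  expect_equal(mom$std, A * b / sqrt(2), tolerance = 1e-12)
  expect_equal(mom$mean, A, tolerance = 1e-12)

  const <- s21_scan(matrix(2e-5 + 0i, 800, 1601), g, "const")
  momc <- estimate_spatial_moments(const, 5e9)
  expect_equal(momc$std, 0)
  expect_equal(momc$cv, 0)
  expect_error(estimate_spatial_moments(const, 4.0021e9), "not on the scan grid")
})

test_that("generation is deterministic and respects the geometry", {
  cfg <- generator_config()
  cal <- calibrate_generator(cfg)
  a <- generate_scan("LD", "non-healthy", seed = 77, cfg, cal)
  b <- generate_scan("LD", "non-healthy", seed = 77, cfg, cal)
  expect_identical(a$matrix, b$matrix)
  expect_equal(dim(a$matrix), c(800L, 1601L))
  expect_identical(a$density_label, "LD")
  expect_identical(a$health_label, "non-healthy")
  c <- generate_scan("LD", "non-healthy", seed = 78, cfg, cal)
  expect_false(identical(a$matrix, c$matrix))
})

test_that("datasets cover the density-by-health design with unique seeds", {
  ds <- tiny_dataset()  # n_per_cell = 4
  expect_length(ds$scans, 16)
  expect_equal(sum(ds$labels$density == "LD"), 8)
  expect_equal(sum(ds$labels$density == "HD"), 8)
  expect_equal(sum(ds$labels$health == "healthy"), 8)
  expect_false(anyDuplicated(ds$labels$sample_id) > 0)
  mats <- lapply(ds$scans[1:4], function(s) s$matrix[1, 1])
  expect_length(unique(unlist(mats)), 4)
})

test_that("streaming feature generation matches the materialised path", {
  ds <- tiny_dataset()
  direct <- feature_table(ds$scans[1:4])
  streamed <- generate_feature_table(n_per_cell = 1, seed = 11)
  # first cell (LD healthy) shares seeds with the first dataset scan
  expect_equal(streamed[streamed$sample_id == "LD_healthy_001", ],
               direct[direct$sample_id == "LD_healthy_001", ])
})

test_that("ensemble spatial moments land near the calibration anchors", {
  cfg <- generator_config()
  cal <- calibrate_generator(cfg)
  res <- sapply(1:30, function(i) {
    s <- generate_scan("HD", seed = 500 + i, config = cfg, calibration = cal)
    m <- estimate_spatial_moments(s, 4e9)
    c(m$std, m$cv)
  })
  # 30 scans: sampling error well inside 10%
  expect_equal(mean(res[1, ]), 5.73e-5, tolerance = 0.1)
  expect_equal(mean(res[2, ]), 0.46, tolerance = 0.1)
})

test_that("HD fields carry more high-order angular energy than LD", {
  cfg <- generator_config(noise_frac = 0)
  cal <- calibrate_generator(cfg)
  high_energy <- function(cls, seed) {
    s <- generate_scan(cls, seed = seed, config = cfg, calibration = cal)
    cols <- match(c(1e9, 4e9, 6e9, 9e9), freq_grid())
    blocks <- split_by_transmitter(s)
    per_block <- sapply(blocks, function(bl) {
      # spatial spectrum of the magnitude field: the richness contract is
      # about angular oscillations of |S21|, not the delay-driven phase
      X <- stats::mvfft(Mod(bl$values[, cols]) + 0i)
      colSums(Mod(X[6:76, , drop = FALSE])^2)
    })
    rowMeans(per_block)
  }
  hd <- rowMeans(sapply(1:4, function(i) high_energy("HD", 900 + i)))
  ld <- rowMeans(sapply(1:4, function(i) high_energy("LD", 950 + i)))
  expect_true(all(hd > ld))
})
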