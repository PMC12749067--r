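#' Class moment anchors for the synthetic generator
#'
#' Published spatial-magnitude statistics that the generator is calibrated
#' to reproduce: the class-wise population standard deviation of `|S21|`
#' across the 80 receiver positions at 4 GHz, the coefficients of variation
#' (CV = std/mean) at 4 and 6 GHz, and the relative excess of the HD over
#' the LD standard deviation at 6 GHz. Mean levels derive from them as
#' `mu = sigma / cv`.
#'
#' @param sigma4 Named (LD, HD) spatial std of `|S21|` at 4 GHz.
#' @param cv4,cv6 Named (LD, HD) CVs at 4 and 6 GHz.
#' @param hd_excess_6ghz HD-over-LD std excess at 6 GHz (0.14 = 14%).
#' @return An object of class `moment_anchors`.
#' @export
moment_anchors <- function(sigma4 = c(LD = 4.66e-5, HD = 5.73e-5),
                           cv4 = c(LD = 0.53, HD = 0.46),
                           cv6 = c(LD = 0.68, HD = 0.62),
                           hd_excess_6ghz = 0.14) {
  for (v in list(sigma4, cv4, cv6)) {
    stopifnot(all(c("LD", "HD") %in% names(v)), all(v > 0))
  }
  if (any(c(cv4, cv6) >= 2)) stop("CV anchors must be in (0, 2)", call. = FALSE)
  structure(list(sigma4 = sigma4, cv4 = cv4, cv6 = cv6,
                 hd_excess_6ghz = hd_excess_6ghz),
            class = "moment_anchors")
}

#' Synthetic scan generator configuration
#'
#' Parameters of the phantom scan model. Each class's `|S21|` magnitude over
#' receiver angle is a lognormal angular field built from `m_harmonics`
#' random Fourier harmonics (the HD class uses more harmonics, giving it
#' richer high-angular-frequency content); its level and spread follow the
#' calibrated [moment_anchors()] curves. The phase follows a propagation
#' delay `tau0 * (1 + depth * cos(theta - tx))` plus a class-scaled angular
#' ripple. Tumour scans multiply the magnitude by a localized angular
#' Gaussian bump and add a local delay bump.
#'
#' @param anchors A [moment_anchors()].
#' @param m_harmonics Named (LD, HD) harmonic orders; HD must be >= LD.
#' @param attenuation Ratio `mu_LD(6 GHz) / mu_LD(4 GHz)` closing the mean
#'   level at 6 GHz, which the anchors alone leave undetermined.
#' @param tau0_s Base propagation delay in seconds.
#' @param delay_mod_depth Relative cosine modulation of the delay with
#'   angle from the active transmitter.
#' @param phase_ripple Named (LD, HD) phase-ripple scale in radians.
#' @param noise_frac Additive complex noise std as a fraction of the class
#'   mean magnitude.
#' @param tumour_amp Peak relative magnitude bump of a tumour.
#' @param tumour_width_deg Angular s.d. of the tumour bump in degrees.
#' @param tumour_delay_s Peak local delay bump of a tumour in seconds.
#' @param geometry A [scan_geometry()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(anchors = moment_anchors(),
                             m_harmonics = c(LD = 4L, HD = 12L),
                             attenuation = 0.5,
                             tau0_s = 1.5e-9,
                             delay_mod_depth = 0.2,
                             phase_ripple = c(LD = 0.1, HD = 0.3),
                             noise_frac = 0.02,
                             tumour_amp = 0.15,
                             tumour_width_deg = 15,
                             tumour_delay_s = 1e-10,
                             geometry = scan_geometry()) {
  stopifnot(inherits(anchors, "moment_anchors"))
  m_harmonics <- vapply(m_harmonics, as.integer, integer(1))
  if (any(m_harmonics < 1) || m_harmonics[["HD"]] < m_harmonics[["LD"]]) {
    stop("m_harmonics must be positive with HD >= LD", call. = FALSE)
  }
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  if (attenuation <= 0) stop("attenuation must be > 0", call. = FALSE)
  structure(list(anchors = anchors, m_harmonics = m_harmonics,
                 attenuation = attenuation, tau0_s = tau0_s,
                 delay_mod_depth = delay_mod_depth,
                 phase_ripple = phase_ripple, noise_frac = noise_frac,
                 tumour_amp = tumour_amp,
                 tumour_width_deg = tumour_width_deg,
                 tumour_delay_s = tumour_delay_s,
                 geometry = validate_geometry(geometry)),
            class = "generator_config")
}

# ---- calibration -----------------------------------------------------------

# Internal Monte-Carlo model of the unit angular field: expected spatial
# population std and CV of g = exp(s*u - s^2/2) over the n_rx uniform
# angles, where u is a unit-variance field of M equal-weight harmonics.
# Common random numbers (fixed internal seed) make the curves smooth and
# the calibration deterministic.
field_moment_model <- function(M, geometry, n_rep = 4000L, seed = 424243L) {
  th <- rx_angles(geometry) * pi / 180
  basis <- cbind(sapply(seq_len(M), function(m) cos(m * th)),
                 sapply(seq_len(M), function(m) sin(m * th)))
  U <- withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(2 * M * n_rep, sd = sqrt(1 / M)), 2 * M, n_rep)
    basis %*% Z
  })
  function(s) {
    g <- exp(s * U - s^2 / 2)
    mu <- colMeans(g)
    sd <- sqrt(pmax(colMeans(g^2) - mu^2, 0))
    c(E_std = mean(sd), E_cv = mean(sd / mu))
  }
}

# Solve for the field scale whose expected spatial CV equals cv_target.
solve_field_scale <- function(model, cv_target) {
  s_nom <- sqrt(log(1 + cv_target^2))
  stats::uniroot(function(s) model(s)[["E_cv"]] - cv_target,
                 interval = c(0.3 * s_nom, 3 * s_nom), tol = 1e-5)$root
}

#' Calibrate the generator to its moment anchors
#'
#' Derives, per class, the nominal mean-magnitude and CV curves over the
#' frequency grid (mean levels `mu = sigma/cv` at 4 GHz; the 6 GHz LD level
#' closed by the attenuation ratio and the HD level by the required 14%
#' std excess; CV linear in frequency between the anchors and clamped
#' outside; mean log-linear through the anchors), and then the effective
#' sampling parameters actually used by the field model. Because the
#' angular field has finitely many harmonics, the raw lognormal scale
#' `s = sqrt(log(1 + cv^2))` would under-produce the per-scan spatial
#' statistics; the calibration therefore root-finds an effective scale
#' whose expected spatial CV matches the target and rescales the mean so
#' the expected spatial std matches the target std.
#'
#' @param config A [generator_config()].
#' @return An object of class `generator_calibration`: per class, vectors
#'   over the frequency grid of nominal mean (`mu_nom`), CV (`cv`), nominal
#'   std (`sigma_nom`), effective field scale (`s_eff`) and effective mean
#'   (`mu_eff`).
#' @examples
#' cal <- calibrate_generator(generator_config())
#' at4 <- which(freq_grid() == 4e9)
#' cal$HD$mu_nom[at4]                       # ~1.2457e-4
#' cal$HD$sigma_nom[at4] / cal$LD$sigma_nom[at4]  # ~1.2296
#' @export
calibrate_generator <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  a <- config$anchors
  g <- config$geometry
  f <- freq_grid(g)
  mu4 <- a$sigma4 / a$cv4
  mu6 <- c(LD = unname(mu4[["LD"]] * config$attenuation))
  # sigma_HD6 / sigma_LD6 = 1 + hd_excess, with sigma = mu * cv
  mu6[["HD"]] <- mu6[["LD"]] * (1 + a$hd_excess_6ghz) *
    a$cv6[["LD"]] / a$cv6[["HD"]]
  if (any(mu6 <= 0) || any(mu4 <= 0)) {
    stop("inconsistent anchors: non-positive derived mean level", call. = FALSE)
  }
  out <- list()
  for (cls in c("LD", "HD")) {
    cv <- a$cv4[[cls]] + (a$cv6[[cls]] - a$cv4[[cls]]) *
      pmin(pmax((f - 4e9) / 2e9, 0), 1)
    log_mu <- log(mu4[[cls]]) + (log(mu6[[cls]]) - log(mu4[[cls]])) *
      (f - 4e9) / 2e9
    mu_nom <- exp(log_mu)
    model <- field_moment_model(config$m_harmonics[[cls]], g)
    cv_grid <- seq(min(a$cv4[[cls]], a$cv6[[cls]]),
                   max(a$cv4[[cls]], a$cv6[[cls]]), length.out = 3)
    s_grid <- vapply(cv_grid, function(ct) solve_field_scale(model, ct),
                     numeric(1))
    estd_grid <- vapply(s_grid, function(s) model(s)[["E_std"]], numeric(1))
    s_eff <- stats::approx(cv_grid, s_grid, xout = cv, rule = 2)$y
    e_std <- stats::approx(cv_grid, estd_grid, xout = cv, rule = 2)$y
    mu_eff <- mu_nom * cv / e_std
    out[[cls]] <- list(f_hz = f, mu_nom = mu_nom, cv = cv,
                       sigma_nom = mu_nom * cv, s_eff = s_eff,
                       mu_eff = mu_eff)
  }
  out$anchors <- a
  class(out) <- "generator_calibration"
  out
}

# ---- the signal model ------------------------------------------------------

# wrapped angular difference in degrees, in [-180, 180)
ang_diff_deg <- function(a, b) ((a - b + 180) %% 360) - 180

#' Synthetic S21 block for one transmitter
#'
#' Evaluates the phantom signal model on a grid of receiver angles and
#' frequencies for one transmitter position: magnitude
#' `m(theta, f) = mu_c(f) * exp(s_c(f) * u(theta) - s_c(f)^2 / 2)` with `u`
#' a unit-variance angular harmonic field given by `harmonics`; phase
#' `-2 pi f tau(theta) + ripple`, with delay
#' `tau(theta) = tau0 (1 + depth cos(theta - tx_angle))`; optional additive
#' complex Gaussian noise of std `noise_frac * mu_c(f)` (drawn from the
#' current RNG state); and, for non-healthy samples, a localized angular
#' magnitude bump `1 + amp * G(theta; theta0, width)` plus a local delay
#' bump.
#'
#' @param class `"LD"` or `"HD"`.
#' @param tx_angle_deg Transmitter angle in degrees.
#' @param harmonics List with standard-normal coefficient vectors `mag` and
#'   `ripple`, each of length `2 * m_harmonics[class]` (cos terms then sin
#'   terms); zero vectors give a degenerate constant-magnitude field.
#' @param config A [generator_config()].
#' @param calibration A [calibrate_generator()] result for `config`.
#' @param health `"healthy"` or `"non-healthy"`.
#' @param tumour_angle_deg Tumour centre angle (non-healthy only).
#' @param f_hz Frequencies to evaluate (must lie on the scan grid).
#' @param add_noise Draw the additive noise term?
#' @return A complex matrix, receivers x frequencies.
#' @export
signal_model <- function(class, tx_angle_deg, harmonics,
                         config = generator_config(),
                         calibration = calibrate_generator(config),
                         health = "healthy", tumour_angle_deg = 0,
                         f_hz = freq_grid(config$geometry),
                         add_noise = TRUE) {
  class <- match.arg(class, c("LD", "HD"))
  g <- config$geometry
  cols <- vapply(f_hz, freq_col_index, integer(1), geometry = g)
  cal <- calibration[[class]]
  mu <- cal$mu_eff[cols]
  s <- cal$s_eff[cols]
  th_deg <- rx_angles(g)
  th <- th_deg * pi / 180
  M <- config$m_harmonics[[class]]
  basis <- cbind(sapply(seq_len(M), function(m) cos(m * th)),
                 sapply(seq_len(M), function(m) sin(m * th)))
  u_mag <- as.vector(basis %*% (harmonics$mag / sqrt(M)))
  u_rip <- as.vector(basis %*% (harmonics$ripple / sqrt(M)))
  # magnitude: lognormal angular field around the calibrated mean level
  logm <- outer(u_mag, s) +
    matrix(log(mu) - s^2 / 2, length(th), length(cols), byrow = TRUE)
  m <- exp(logm)
  tau <- config$tau0_s *
    (1 + config$delay_mod_depth * cos(th - tx_angle_deg * pi / 180))
  if (health == "non-healthy") {
    bump <- exp(-0.5 * (ang_diff_deg(th_deg, tumour_angle_deg) /
                          config$tumour_width_deg)^2)
    m <- m * (1 + config$tumour_amp * bump)
    tau <- tau + config$tumour_delay_s * bump
  }
  phase <- -2 * pi * outer(tau, f_hz) + config$phase_ripple[[class]] * u_rip
  out <- m * exp(1i * phase)
  if (add_noise && config$noise_frac > 0) {
    n <- length(out)
    sd_n <- config$noise_frac *
      matrix(mu, length(th), length(cols), byrow = TRUE) / sqrt(2)
    out <- out + complex(real = stats::rnorm(n, sd = sd_n),
                         imaginary = stats::rnorm(n, sd = sd_n))
  }
  out
}

#' Generate a synthetic S21 scan
#'
#' Assembles a full scan (all transmitter blocks over the complete
#' frequency grid) from [signal_model()], with independent harmonic fields
#' per transmitter block and, for non-healthy samples, one tumour location
#' per scan. Deterministic given `(class, health, seed, config)`.
#'
#' @param class `"LD"` or `"HD"`.
#' @param health `"healthy"` or `"non-healthy"`.
#' @param seed Integer seed.
#' @param config A [generator_config()].
#' @param calibration Optional precomputed [calibrate_generator()] result
#'   (computed on the fly if missing; pass it when generating many scans).
#' @param sample_id Identifier; defaults to a class/health/seed string.
#' @return An [s21_scan()].
#' @examples
#' scan <- generate_scan("HD", seed = 1)
#' dim(scan$matrix)  # 800 x 1601
#' @export
generate_scan <- function(class, health = "healthy", seed = 1L,
                          config = generator_config(),
                          calibration = NULL,
                          sample_id = NULL) {
  class <- match.arg(class, c("LD", "HD"))
  health <- match.arg(health, c("healthy", "non-healthy"))
  if (is.null(calibration)) calibration <- calibrate_generator(config)
  g <- config$geometry
  M <- config$m_harmonics[[class]]
  if (is.null(sample_id)) sample_id <- paste(class, health, seed, sep = "_")
  withr::with_seed(as.integer(seed), {
    tumour_angle <- if (health == "non-healthy") stats::runif(1, 0, 360) else 0
    blocks <- lapply(seq_len(g$n_tx), function(t) {
      harmonics <- list(mag = stats::rnorm(2 * M), ripple = stats::rnorm(2 * M))
      signal_model(class, g$tx_angles_deg[t], harmonics, config, calibration,
                   health = health, tumour_angle_deg = tumour_angle)
    })
    s21_scan(do.call(rbind, blocks), g, sample_id, class, health)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Covers the 2 x 2 (density x health) design with `n_per_cell` scans per
#' cell, each generated with an independent seed derived from the master
#' seed.
#'
#' @param n_per_cell Scans per (density, health) cell.
#' @param seed Master seed.
#' @param config A [generator_config()].
#' @return A list with `scans` (list of [s21_scan()]) and `labels`
#'   (a tibble `sample_id, density, health`).
#' @export
generate_dataset <- function(n_per_cell, seed = 1L,
                             config = generator_config()) {
  calibration <- calibrate_generator(config)
  cells <- expand.grid(density = c("LD", "HD"),
                       health = c("healthy", "non-healthy"),
                       stringsAsFactors = FALSE)
  scans <- list()
  i <- 0L
  for (r in seq_len(nrow(cells))) {
    for (j in seq_len(n_per_cell)) {
      i <- i + 1L
      scan_seed <- as.integer((abs(as.double(seed)) + i * 2654435) %% 2147483629)
      scans[[i]] <- generate_scan(cells$density[r], cells$health[r],
                                  seed = scan_seed, config = config,
                                  calibration = calibration,
                                  sample_id = sprintf("%s_%s_%03d",
                                                      cells$density[r],
                                                      cells$health[r], j))
    }
  }
  labels <- tibble::tibble(
    sample_id = vapply(scans, function(s) s$sample_id, character(1)),
    density = vapply(scans, function(s) s$density_label, character(1)),
    health = vapply(scans, function(s) s$health_label, character(1))
  )
  list(scans = scans, labels = labels)
}

#' Generate a synthetic dataset directly as a feature table
#'
#' Streaming variant of [generate_dataset()] + [feature_table()]: each scan
#' is generated, its features extracted, and the 20 MB matrix discarded
#' before the next one, so datasets of hundreds of scans fit comfortably in
#' memory.
#'
#' @inheritParams generate_dataset
#' @param feature_cfg A [feature_config()].
#' @return A tibble as produced by [feature_table()].
#' @export
generate_feature_table <- function(n_per_cell, seed = 1L,
                                   config = generator_config(),
                                   feature_cfg = feature_config()) {
  calibration <- calibrate_generator(config)
  cells <- expand.grid(density = c("LD", "HD"),
                       health = c("healthy", "non-healthy"),
                       stringsAsFactors = FALSE)
  rows <- list()
  i <- 0L
  for (r in seq_len(nrow(cells))) {
    for (j in seq_len(n_per_cell)) {
      i <- i + 1L
      scan_seed <- as.integer((abs(as.double(seed)) + i * 2654435) %% 2147483629)
      scan <- generate_scan(cells$density[r], cells$health[r],
                            seed = scan_seed, config = config,
                            calibration = calibration,
                            sample_id = sprintf("%s_%s_%03d", cells$density[r],
                                                cells$health[r], j))
      rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = scan$sample_id, density = scan$density_label,
                       health = scan$health_label),
        tibble::as_tibble(as.list(extract_features(scan, feature_cfg))))
    }
  }
  dplyr::bind_rows(rows)
}

#' Spatial magnitude moments of a scan at one frequency
#'
#' For each transmitter block, computes the mean, population standard
#' deviation and CV of `|S21|` across the 80 receiver positions at the
#' requested frequency column, then averages the three statistics over the
#' transmitter blocks.
#'
#' @param scan An [s21_scan()].
#' @param f_hz A frequency on the scan grid.
#' @return A one-row tibble with columns `f_hz`, `mean`, `std`, `cv`.
#' @export
estimate_spatial_moments <- function(scan, f_hz) {
  stopifnot(inherits(scan, "s21_scan"))
  g <- scan$geometry
  col <- freq_col_index(f_hz, g)
  x <- Mod(scan$matrix[, col])
  per_block <- vapply(seq_len(g$n_tx), function(t) {
    v <- x[((t - 1) * g$n_rx + 1):(t * g$n_rx)]
    mu <- mean(v)
    sd <- pop_sd(v)
    c(mean = mu, std = sd, cv = if (mu == 0) 0 else sd / mu)
  }, numeric(3))
  tibble::tibble(f_hz = f_hz, mean = mean(per_block["mean", ]),
                 std = mean(per_block["std", ]), cv = mean(per_block["cv", ]))
}
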