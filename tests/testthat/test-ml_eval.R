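# feature tibble with two Gaussian classes separated by `sep` sd units
cluster_data <- function(n_per_class = 40, sep = 0, p = 4, seed = 1,
                         labels = c("LD", "HD")) {
  withr::with_seed(seed, {
    shift <- rep(c(0, sep), each = n_per_class)
    X <- matrix(rnorm(2 * n_per_class * p), ncol = p) + shift
    colnames(X) <- paste0("f", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(density = rep(labels, each = n_per_class)),
      tibble::as_tibble(X))
  })
}

test_that("balance rate matches its defining identities and printed values", {
  expect_equal(balance_rate(1, 1), 0)
  expect_equal(balance_rate(1, 0), 2)
  expect_equal(balance_rate(0, 1), 2)
  expect_equal(balance_rate(0, 0), 2)

  # symmetry over a grid
  s <- seq(0, 1, by = 0.1)
  grid <- expand.grid(s = s, p = s)
  expect_equal(balance_rate(grid$s, grid$p), balance_rate(grid$p, grid$s))
  expect_true(all(balance_rate(grid$s, grid$p) >= 0 &
                    balance_rate(grid$s, grid$p) <= 2))
  # zero only at the perfect corner
  expect_true(all(balance_rate(grid$s, grid$p)[!(grid$s == 1 & grid$p == 1)] > 0))

  # published class-accuracy pairs recompute to the printed values (2 d.p.)
  expect_equal(round(balance_rate(0.6738, 0.7552), 2), 0.65)
  expect_equal(round(balance_rate(0.7221, 0.6983), 2), 0.60)
  expect_equal(round(balance_rate(0.6067, 0.7017), 2), 0.79)

  expect_error(balance_rate(1.2, 0.5), "must be in")
  expect_error(balance_rate(0.5, -0.1), "must be in")
})

test_that("perfectly separable classes evaluate to perfect scores", {
  data <- cluster_data(n_per_class = 30, sep = 12, seed = 2)
  for (family in c("knn", "svm_rbf", "decision_tree")) {
    rep <- evaluate_classifier(data, "density", classifier_spec(family),
                               split_plan(n_monte_carlo = 2, seed = 5))
    agg <- summary_eval(rep)
    expect_equal(agg$total_accuracy_mean, c(1, 1))
    expect_equal(agg$balance_rate_mean, c(0, 0))
  }
})

test_that("random labels evaluate near chance", {
  data <- cluster_data(n_per_class = 200, sep = 0, seed = 3)
  rep <- evaluate_classifier(data, "density", classifier_spec("knn"),
                             split_plan(n_monte_carlo = 5, seed = 7))
  test_acc <- summary_eval(rep) |> dplyr::filter(phase == "test")
  # 3-sigma binomial band around 0.5 for 80-sample test sets x 5 runs
  expect_lt(abs(test_acc$total_accuracy_mean - 0.5), 0.075)
})

test_that("a majority-class predictor lands at the degenerate BR corner", {
  data <- cluster_data(n_per_class = 20, sep = 5, seed = 4)
  data$density[1] <- data$density[2]  # break the tie so a majority exists
  rep <- evaluate_classifier(data, "density", classifier_spec("majority"),
                             split_plan(n_monte_carlo = 2, seed = 9))
  runs <- tidy(rep)
  expect_true(all(runs$balance_rate == 2))
  expect_true(all(runs$sensitivity + runs$specificity == 1))
})

test_that("evaluation is reproducible from the plan seed", {
  data <- cluster_data(n_per_class = 25, sep = 1, seed = 6)
  plan <- split_plan(n_monte_carlo = 3, seed = 42)
  r1 <- evaluate_classifier(data, "density", classifier_spec("random_forest"),
                            plan)
  r2 <- evaluate_classifier(data, "density", classifier_spec("random_forest"),
                            plan)
  expect_identical(tidy(r1), tidy(r2))
  sp1 <- mwdensity:::draw_split(factor(data$density), plan, 2)
  sp2 <- mwdensity:::draw_split(factor(data$density), plan, 2)
  expect_identical(sp1, sp2)
})

test_that("every classifier family fits and predicts on easy data", {
  data <- cluster_data(n_per_class = 25, sep = 8, seed = 8)
  plan <- split_plan(n_monte_carlo = 1, seed = 1)
  for (family in c("knn", "naive_bayes", "svm_rbf", "svm_linear",
                   "decision_tree", "random_forest", "adaboost", "xgboost")) {
    rep <- evaluate_classifier(data, "density", classifier_spec(family), plan)
    acc <- (summary_eval(rep) |> dplyr::filter(phase == "test"))$total_accuracy_mean
    expect_gte(acc, 0.9)
  }
})

test_that("subband_search ranks the band carrying the class signal first", {
  # craft scans whose classes differ only inside SB3 (4.5 GHz region)
  g <- scan_geometry()
  f <- freq_grid(g)
  sb3 <- f >= 3e9 & f < 4e9
  make <- function(cls, seed) {
    withr::with_seed(seed, {
      m <- matrix(complex(real = rnorm(800 * 1601, sd = 0.1),
                          imaginary = rnorm(800 * 1601, sd = 0.1)), 800, 1601)
      if (cls == "HD") {
        # angular oscillation whose amplitude ramps across the band, so it
        # survives the within-band DC removal
        bump <- matrix(rep(sin(2 * pi * (1:80) / 8), 10), ncol = 1)
        ramp <- seq(0, 2, length.out = sum(sb3))
        m[, sb3] <- m[, sb3] + bump %*% t(ramp)
      }
      s21_scan(m, g, paste0(cls, seed), cls, "unknown")
    })
  }
  scans <- c(lapply(1:8, function(i) make("LD", i)),
             lapply(1:8, function(i) make("HD", 100 + i)))
  masks <- c("1000 0000", "0010 0000", "0000 0010")
  tab <- subband_search(scans, masks, classifier = classifier_spec("knn"),
                        plan = split_plan(n_monte_carlo = 2, n_folds = 2,
                                          seed = 3))
  test_rows <- tab |> dplyr::filter(phase == "test")
  expect_equal(test_rows$mask[1], "0010 0000")
  expect_equal(nrow(test_rows), 3)
  expect_true(all(c("balance_rate_mean", "balance_rate_sd",
                    "total_accuracy_mean") %in% names(tab)))

  expect_warning(
    subband_search(scans[c(1:3, 9:11)], c("1000 0000", "1000 0000"),
                   classifier = classifier_spec("knn"),
                   plan = split_plan(n_monte_carlo = 1, n_folds = 2, seed = 1)),
    "duplicate")
})

test_that("density-stratified detection beats pooling when effects oppose", {
  # the tumour level in one stratum coincides with the healthy level of the
  # other, so the signal is separable only within a stratum; pooled models
  # see an uninformative mixture
  withr::with_seed(10, {
    n <- 60
    make_stratum <- function(density, healthy_mu, tumour_mu) {
      tibble::tibble(
        density = density,
        health = rep(c("healthy", "non-healthy"), each = n),
        f1 = rnorm(2 * n, sd = 0.4) + rep(c(healthy_mu, tumour_mu), each = n),
        f2 = rnorm(2 * n))
    }
    data <- dplyr::bind_rows(make_stratum("LD", 0, 2),
                             make_stratum("HD", 2, 0))
  })
  plan <- split_plan(n_monte_carlo = 3, seed = 11)
  with_prior <- density_stratified_detection(
    data, classifier_spec("knn"), plan, use_density_prior = TRUE)
  without <- density_stratified_detection(
    data, classifier_spec("knn"), plan, use_density_prior = FALSE)
  sp <- summary_detection(with_prior)
  sn <- summary_detection(without)
  expect_true(all(sp$sensitivity_mean > sn$sensitivity_mean))
  expect_true(all(sp$specificity_mean > sn$specificity_mean))

  # report structure: (sensitivity, specificity) x (LD, HD)
  expect_setequal(sp$stratum, c("LD", "HD"))
  expect_true(all(c("sensitivity_mean", "specificity_mean") %in% names(sp)))
  g <- glance(with_prior)
  expect_equal(ncol(g), 5)  # prior flag + 2 metrics x 2 strata
})

test_that("identically distributed strata make the prior immaterial", {
  withr::with_seed(12, {
    n <- 50
    data <- tibble::tibble(
      density = rep(c("LD", "HD"), each = 2 * n),
      health = rep(rep(c("healthy", "non-healthy"), each = n), 2),
      f1 = rnorm(4 * n) + rep(rep(c(0, 2), each = n), 2),
      f2 = rnorm(4 * n))
  })
  plan <- split_plan(n_monte_carlo = 3, seed = 13)
  a <- summary_detection(density_stratified_detection(
    data, classifier_spec("svm_linear"), plan, TRUE))
  b <- summary_detection(density_stratified_detection(
    data, classifier_spec("svm_linear"), plan, FALSE))
  expect_lt(max(abs(a$sensitivity_mean - b$sensitivity_mean)), 0.15)
  expect_lt(max(abs(a$specificity_mean - b$specificity_mean)), 0.15)
})

test_that("a stratum without both health classes is skipped with a warning", {
  withr::with_seed(14, {
    data <- tibble::tibble(
      density = rep(c("LD", "HD"), each = 20),
      health = c(rep(c("healthy", "non-healthy"), 10), rep("healthy", 20)),
      f1 = rnorm(40))
  })
  expect_warning(
    rep <- density_stratified_detection(data, classifier_spec("knn"),
                                        split_plan(n_monte_carlo = 1, seed = 2)),
    "skipped")
  expect_equal(unique(tidy(rep)$stratum), "LD")
})
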