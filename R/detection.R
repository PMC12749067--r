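#' Density-stratified cancer detection
#'
#' Evaluates healthy vs non-healthy detection either with prior knowledge of
#' the density label (`use_density_prior = TRUE`: one detector trained per
#' density stratum on the training data, each test sample routed to the
#' model matching its density label) or without (`FALSE`: a single pooled
#' detector, with metrics still reported per density stratum). Splits are
#' stratified on the density-by-health cells and derive from the plan seed
#' only, so the two settings are compared on identical test samples.
#' Sensitivity is the non-healthy recall, specificity the healthy recall.
#'
#' @param data A feature table with `density` and `health` label columns
#'   plus numeric feature columns.
#' @param classifier A [classifier_spec()].
#' @param plan A [split_plan()]; the inner fold count is not used here
#'   (detection reports held-out test metrics per run).
#' @param use_density_prior Route test samples through per-stratum models?
#' @return An object of class `mw_detection` with per-run, per-stratum test
#'   metrics; `summary_detection()` / [glance.mw_detection()] aggregate to
#'   the four numbers (sensitivity, specificity) x (LD, HD).
#' @export
density_stratified_detection <- function(data,
                                         classifier = classifier_spec("naive_bayes"),
                                         plan = split_plan(),
                                         use_density_prior = TRUE) {
  stopifnot(all(c("density", "health") %in% names(data)))
  health <- factor(data$health, levels = c("healthy", "non-healthy"))
  density <- factor(data$density)
  if (anyNA(health) || nlevels(droplevels(health)) < 2) {
    stop("need both healthy and non-healthy samples", call. = FALSE)
  }
  X <- feature_columns(data, "health")
  strata <- levels(density)
  usable <- character(0)
  for (s in strata) {
    counts <- table(health[density == s])
    if (any(counts < 2)) {
      warning("stratum ", s, " skipped: fewer than 2 samples of a health class")
    } else {
      usable <- c(usable, s)
    }
  }
  if (length(usable) == 0) stop("no usable density stratum", call. = FALSE)
  cell <- factor(paste(density, health, sep = "."))
  runs <- list()
  for (r in seq_len(plan$n_monte_carlo)) {
    sp <- draw_split(cell, plan, r)
    withr::with_seed(run_seed(plan, r) + 13L, {
      for (s in usable) {
        te <- sp$test[density[sp$test] == s]
        tr <- if (use_density_prior) sp$train[density[sp$train] == s] else sp$train
        m <- fit_score(X, health, tr, te, classifier, "non-healthy")
        runs[[length(runs) + 1]] <- dplyr::bind_cols(
          tibble::tibble(run = r, stratum = s, n_test = length(te)),
          m[c("sensitivity", "specificity", "balance_rate", "total_accuracy")])
      }
    })
  }
  structure(list(runs = dplyr::bind_rows(runs), classifier = classifier,
                 plan = plan, use_density_prior = use_density_prior,
                 strata = usable),
            class = "mw_detection")
}

#' @rdname density_stratified_detection
#' @param report An `mw_detection` object.
#' @export
summary_detection <- function(report) {
  stopifnot(inherits(report, "mw_detection"))
  report$runs |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(dplyr::across(c("sensitivity", "specificity",
                                     "balance_rate", "total_accuracy"),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop")
}

#' @export
print.mw_detection <- function(x, ...) {
  cat("<mw_detection> ", x$classifier$family,
      if (x$use_density_prior) " with " else " without ",
      "density prior, ", x$plan$n_monte_carlo, " runs\n", sep = "")
  print(summary_detection(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mw_detection <- function(x, ...) x$runs

#' Glance at a detection report
#'
#' @param x An `mw_detection` object.
#' @param ... Unused.
#' @return A one-row tibble per stratum folded wide: sensitivity and
#'   specificity means for each density stratum.
#' @exportS3Method generics::glance
glance.mw_detection <- function(x, ...) {
  summary_detection(x) |>
    dplyr::select("stratum", "sensitivity_mean", "specificity_mean") |>
    tidyr::pivot_wider(names_from = "stratum",
                       values_from = c("sensitivity_mean", "specificity_mean")) |>
    dplyr::mutate(use_density_prior = x$use_density_prior, .before = 1)
}
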