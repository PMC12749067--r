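#' Monte-Carlo + k-fold split plan
#'
#' The evaluation protocol: in each of `n_monte_carlo` runs a stratified
#' `test_fraction` of the samples is held out as test data; the remaining
#' samples are assessed with stratified `n_folds`-fold cross-validation and
#' the model is then refitted on the full training portion and scored on the
#' held-out test samples. All randomness derives from `seed`, so two plans
#' with the same seed yield bit-identical split memberships.
#'
#' @param n_monte_carlo Number of Monte-Carlo runs (default 5).
#' @param test_fraction Held-out fraction per run (default 0.2).
#' @param n_folds Number of inner cross-validation folds (default 4).
#' @param seed Integer seed for the split stream.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(n_monte_carlo = 5L, test_fraction = 0.2,
                       n_folds = 4L, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  structure(list(n_monte_carlo = as.integer(n_monte_carlo),
                 test_fraction = test_fraction,
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

run_seed <- function(plan, run) {
  as.integer((abs(as.double(plan$seed)) + run * 131071) %% 2147483629)
}

# Stratified test/train membership and fold assignment for one run.
# Returns list(test = int idx, folds = int vector over the train idx).
draw_split <- function(y, plan, run) {
  withr::with_seed(run_seed(plan, run), {
    test <- integer(0)
    for (lev in levels(y)) {
      idx <- which(y == lev)
      n_test <- max(1L, round(length(idx) * plan$test_fraction))
      test <- c(test, sample(idx, n_test))
    }
    train <- setdiff(seq_along(y), test)
    folds <- integer(length(train))
    for (lev in levels(y)) {
      pos <- which(y[train] == lev)
      folds[sample(pos)] <- rep_len(seq_len(plan$n_folds), length(pos))
    }
    list(test = sort(test), train = train, folds = folds)
  })
}

classification_metrics <- function(truth, pred, positive) {
  levels <- levels(truth)
  acc <- vapply(levels, function(lev) {
    n <- sum(truth == lev)
    if (n == 0) NA_real_ else sum(pred == lev & truth == lev) / n
  }, numeric(1))
  negative <- setdiff(levels, positive)[1]
  sens <- acc[[positive]]
  spec <- acc[[negative]]
  out <- tibble::tibble(total_accuracy = mean(pred == truth),
                        sensitivity = sens, specificity = spec,
                        balance_rate = balance_rate(sens, spec))
  for (lev in levels) out[[paste0("acc_", lev)]] <- acc[[lev]]
  out
}

# Standardize on the fit rows, fit, predict the score rows, return metrics.
fit_score <- function(X, y, fit_idx, score_idx, spec, positive) {
  std <- fit_standardizer(X[fit_idx, , drop = FALSE])
  model <- fit_classifier(spec, apply_standardizer(std, X[fit_idx, , drop = FALSE]),
                          y[fit_idx])
  pred <- predict_classifier(model, apply_standardizer(std, X[score_idx, , drop = FALSE]))
  classification_metrics(y[score_idx], pred, positive)
}

#' Evaluate a classifier with the Monte-Carlo + k-fold harness
#'
#' Runs the full evaluation protocol on a feature table: per Monte-Carlo run
#' a stratified 80/20 split, inner stratified k-fold cross-validation on the
#' training portion (features standardized on each fold's fit rows only),
#' then a refit on the whole training portion scored on the held-out test
#' samples. Reported metrics are total accuracy, per-class accuracy,
#' sensitivity/specificity with respect to `positive`, and the
#' [balance_rate()].
#'
#' @param data A data frame with the response column plus numeric feature
#'   columns (non-numeric columns and `sample_id`/`density`/`health` other
#'   than the response are ignored as features).
#' @param response Name of the label column (default `"density"`).
#' @param classifier A [classifier_spec()].
#' @param plan A [split_plan()].
#' @param positive Level treated as "sensitivity"; defaults to `"LD"` for a
#'   density response, `"non-healthy"` for a health response, else the first
#'   level. The balance rate is symmetric, so this only names the slots.
#' @return An object of class `mw_eval`; see [tidy.mw_eval()] /
#'   [glance.mw_eval()].
#' @examples
#' \donttest{
#' scans <- generate_dataset(n_per_cell = 5, seed = 42)$scans
#' feats <- feature_table(scans)
#' rep <- evaluate_classifier(feats, "density", classifier_spec("knn"))
#' glance(rep)
#' }
#' @export
evaluate_classifier <- function(data, response = "density",
                                classifier = classifier_spec("svm_rbf"),
                                plan = split_plan(),
                                positive = NULL) {
  y <- factor(data[[response]])
  if (nlevels(y) < 2) stop("need at least 2 classes in '", response, "'",
                           call. = FALSE)
  X <- feature_columns(data, response)
  if (is.null(positive)) {
    positive <- if ("LD" %in% levels(y)) "LD"
    else if ("non-healthy" %in% levels(y)) "non-healthy"
    else levels(y)[1]
  }
  runs <- list()
  for (r in seq_len(plan$n_monte_carlo)) {
    sp <- draw_split(y, plan, r)
    withr::with_seed(run_seed(plan, r) + 7L, {
      for (k in seq_len(plan$n_folds)) {
        fit_idx <- sp$train[sp$folds != k]
        val_idx <- sp$train[sp$folds == k]
        m <- fit_score(X, y, fit_idx, val_idx, classifier, positive)
        runs[[length(runs) + 1]] <-
          dplyr::bind_cols(tibble::tibble(run = r, phase = "validation",
                                          fold = k), m)
      }
      m <- fit_score(X, y, sp$train, sp$test, classifier, positive)
      runs[[length(runs) + 1]] <-
        dplyr::bind_cols(tibble::tibble(run = r, phase = "test",
                                        fold = NA_integer_), m)
    })
  }
  structure(list(runs = dplyr::bind_rows(runs), classifier = classifier,
                 plan = plan, response = response, positive = positive,
                 levels = levels(y)),
            class = "mw_eval")
}

feature_columns <- function(data, response) {
  drop <- unique(c("sample_id", "density", "health", response))
  keep <- setdiff(names(data), drop)
  keep <- keep[vapply(data[keep], is.numeric, logical(1))]
  if (length(keep) == 0) stop("no numeric feature columns found", call. = FALSE)
  as.matrix(data[keep])
}

#' @export
print.mw_eval <- function(x, ...) {
  cat("<mw_eval> ", x$classifier$family, " on '", x$response, "', ",
      x$plan$n_monte_carlo, " MC runs x ", x$plan$n_folds, " folds\n",
      sep = "")
  print(summary_eval(x))
  invisible(x)
}

#' Aggregate an evaluation report
#'
#' Mean and standard deviation of every metric across the Monte-Carlo runs
#' (validation rows are first averaged within a run across folds), one row
#' per phase.
#'
#' @param report An `mw_eval` object.
#' @return A tibble with columns `<metric>_mean` and `<metric>_sd`.
#' @export
summary_eval <- function(report) {
  stopifnot(inherits(report, "mw_eval"))
  metric_cols <- setdiff(names(report$runs), c("run", "phase", "fold"))
  per_run <- report$runs |>
    dplyr::group_by(.data$phase, .data$run) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop")
  per_run |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$phase))
}

#' Tidy an evaluation report
#'
#' @param x An `mw_eval` object.
#' @param ... Unused.
#' @return Per-run, per-fold metric rows as a tibble.
#' @exportS3Method generics::tidy
tidy.mw_eval <- function(x, ...) x$runs

#' Glance at an evaluation report
#'
#' @param x An `mw_eval` object.
#' @param ... Unused.
#' @return A one-row tibble of held-out test aggregates (mean and sd across
#'   Monte-Carlo runs), plus the classifier family.
#' @exportS3Method generics::glance
glance.mw_eval <- function(x, ...) {
  out <- summary_eval(x) |> dplyr::filter(.data$phase == "test")
  dplyr::bind_cols(tibble::tibble(classifier = x$classifier$family), out)
}
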