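#' One-vs-rest confusion counts
#'
#' Tallies true/false positives and negatives of a prediction vector against
#' the truth, treating `positive_class` as positive and everything else as
#' negative.
#'
#' @param predicted Character vector of predicted class labels.
#' @param truth Character vector of true class labels (same length).
#' @param positive_class The label counted as positive.
#' @return An object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn` and `positive_class`.
#' @export
confusion_counts <- function(predicted, truth, positive_class) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth) || length(truth) < 1L) {
    stop("'predicted' and 'truth' must have equal length >= 1")
  }
  if (!(positive_class %in% predicted) && !(positive_class %in% truth)) {
    warning("positive class '", positive_class,
            "' absent from both vectors; positive counts are zero")
  }
  pp <- predicted == positive_class
  tp_ <- truth == positive_class
  structure(list(tp = sum(pp & tp_), tn = sum(!pp & !tp_),
                 fp = sum(pp & !tp_), fn = sum(!pp & tp_),
                 positive_class = as.character(positive_class)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes the five standard confusion-based metrics:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, specificity `TN/(TN+FP)`, sensitivity
#' `TP/(TP+FN)`, precision `TP/(TP+FP)` and the F1 score
#' `2TP/(2TP+FP+FN)` (the harmonic mean of sensitivity and precision).
#' A zero denominator yields `NA` (undefined), never an error.
#'
#' @param counts A [confusion_counts()] object, or a list/vector with
#'   elements `tp`, `tn`, `fp`, `fn` (counts may be real-valued to permit
#'   membership-weighted counting).
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `specificity`, `sensitivity`, `precision`, `f1`, the `counts` and the
#'   `positive_class`.
#' @examples
#' compute_metrics(list(tp = 3, tn = 5, fp = 1, fn = 1))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total <= 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(accuracy = (tp + tn) / total,
                 specificity = ratio(tn, tn + fp),
                 sensitivity = ratio(tp, tp + fn),
                 precision = ratio(tp, tp + fp),
                 f1 = ratio(2 * tp, 2 * tp + fp + fn),
                 counts = counts,
                 positive_class = counts$positive_class %||% NA_character_),
            class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("Accuracy %s | Specificity %s | Sensitivity %s | Precision %s | F1 %s\n",
              fmt(x$accuracy), fmt(x$specificity), fmt(x$sensitivity),
              fmt(x$precision), fmt(x$f1)))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(positive_class = x$positive_class,
             accuracy = x$accuracy, specificity = x$specificity,
             sensitivity = x$sensitivity, precision = x$precision,
             f1 = x$f1)
}

#' Multi-class report: one-vs-rest metrics per class plus macro average
#'
#' @param predicted,truth Character vectors of class labels.
#' @param classes Classes to report (default: union of observed labels).
#' @return A `data.frame` with one row per class and a final `"macro"` row
#'   averaging each metric over classes (undefined values excluded).
#' @export
classification_report <- function(predicted, truth,
                                  classes = sort(unique(c(predicted, truth)))) {
  rows <- lapply(classes, function(cl) {
    as.data.frame(compute_metrics(confusion_counts(predicted, truth, cl)))
  })
  rep_df <- do.call(rbind, rows)
  macro <- data.frame(
    positive_class = "macro",
    accuracy = mean(rep_df$accuracy, na.rm = TRUE),
    specificity = mean(rep_df$specificity, na.rm = TRUE),
    sensitivity = mean(rep_df$sensitivity, na.rm = TRUE),
    precision = mean(rep_df$precision, na.rm = TRUE),
    f1 = mean(rep_df$f1, na.rm = TRUE))
  rbind(rep_df, macro)
}

holdout_labels <- function(x, class_col = "class") {
  if (inherits(x, "fuzzy_dataset")) crisp_classes(x)
  else if (inherits(x, "feature_set")) x$labels
  else if (is.data.frame(x)) as.character(x[[class_col]])
  else stop("unsupported data container")
}

#' Hold-out split of a dataset
#'
#' Splits a dataset into disjoint, exhaustive train and test parts with a
#' seeded shuffle. The train size is `round(train_fraction * K)` (half-up).
#' With `stratified = TRUE` the per-class train quotas follow
#' largest-remainder rounding so class proportions are preserved; classes
#' with fewer than 2 samples fall back to the unstratified pool with a
#' warning.
#'
#' @param x A [fuzzy_dataset()], [feature_set()] or `data.frame`.
#' @param train_fraction Fraction of samples in the training part, in (0, 1).
#'   Default 0.7, the common 70:30 protocol.
#' @param stratified Preserve class proportions. Default `FALSE`.
#' @param seed Integer seed for the shuffle.
#' @param class_col Class column name when `x` is a `data.frame`.
#' @return List with `train`, `test` (same container as `x`), `train_idx`,
#'   `test_idx`.
#' @export
holdout_split <- function(x, train_fraction = 0.7, stratified = FALSE,
                          seed = 1, class_col = "class") {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie strictly between 0 and 1")
  }
  labels <- holdout_labels(x, class_col)
  K <- length(labels)
  if (K < 2L) stop("need at least 2 samples to split")
  n_train <- floor(train_fraction * K + 0.5)
  n_train <- max(1L, min(K - 1L, n_train))
  set.seed(seed)
  if (!stratified) {
    perm <- sample.int(K)
    train_idx <- sort(perm[seq_len(n_train)])
  } else {
    tab <- table(labels)
    small <- names(tab)[tab < 2L]
    if (length(small) > 0L) {
      warning("class(es) with < 2 samples fall back to unstratified: ",
              paste(small, collapse = ", "))
    }
    strat_classes <- names(tab)[tab >= 2L]
    quota <- train_fraction * as.numeric(tab[strat_classes])
    base <- floor(quota)
    # largest remainder against the overall train size for stratified samples
    n_strat <- sum(tab[strat_classes])
    target <- floor(train_fraction * n_strat + 0.5)
    rem <- target - sum(base)
    if (rem > 0) {
      order_rem <- order(quota - base, decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
    }
    train_idx <- integer(0)
    for (ci in seq_along(strat_classes)) {
      idx <- which(labels == strat_classes[ci])
      take <- min(max(base[ci], 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, take))
    }
    pool <- which(labels %in% small)
    if (length(pool) > 0L) {
      extra <- max(0L, min(length(pool), n_train - length(train_idx)))
      if (extra > 0L) train_idx <- c(train_idx, sample(pool, extra))
    }
    train_idx <- sort(train_idx)
  }
  test_idx <- setdiff(seq_len(K), train_idx)
  subset_of <- function(obj, idx) {
    if (is.data.frame(obj)) obj[idx, , drop = FALSE] else obj[idx]
  }
  list(train = subset_of(x, train_idx), test = subset_of(x, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Repeated random-subsampling evaluation of a fuzzy classifier
#'
#' Runs `reps` independent seeded hold-out rounds: split, fit the classifier
#' on the training part, classify the test part, and tally the confusion
#' metrics. Round seeds are derived deterministically from the master seed
#' (`seed + rep`).
#'
#' @param ds A [fuzzy_dataset()].
#' @param classifier `"fdt"` (default) or `"fnb"`.
#' @param reps Number of hold-out rounds, >= 1.
#' @param train_fraction Passed to [holdout_split()]. Default 0.7.
#' @param seed Master integer seed.
#' @param positive_class Label treated as positive (default: the first class
#'   term of the dataset).
#' @param stratified Stratify the splits. Default `TRUE`.
#' @param ... Passed to the classifier constructor ([fdt()] or [fnb()]),
#'   e.g. `alpha`, `beta`, `smoothing`.
#' @return An object of class `subsample_eval`: list with `per_rep` (a
#'   `data.frame` of metrics per round), `summary` (mean and sd per metric)
#'   and the call parameters.
#' @export
subsample_eval <- function(ds, classifier = c("fdt", "fnb"), reps = 10,
                           train_fraction = 0.7, seed = 1,
                           positive_class = NULL, stratified = TRUE, ...) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(ds, "fuzzy_dataset"))
  if (!is.numeric(reps) || reps < 1L) stop("'reps' must be >= 1")
  if (is.null(positive_class)) {
    positive_class <- ds$attributes[[ds$output_index]]$terms[1L]
  }
  fit_fun <- if (classifier == "fdt") fdt else fnb
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      sp <- holdout_split(ds, train_fraction, stratified, seed = seed + r)
      model <- fit_fun(sp$train, ...)
      pred <- predict(model, sp$test, type = "class")
      truth <- crisp_classes(sp$test)
      m <- compute_metrics(confusion_counts(pred, truth, positive_class))
      cbind(rep = r, rep_seed = seed + r, as.data.frame(m))
    }, error = function(e) {
      stop("rep ", r, ": ", conditionMessage(e), call. = FALSE)
    })
    rows[[r]] <- res
  }
  per_rep <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "specificity", "sensitivity", "precision", "f1")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cn) mean(per_rep[[cn]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols,
                function(cn) stats::sd(per_rep[[cn]][!is.na(per_rep[[cn]])]),
                numeric(1)))
  structure(list(per_rep = per_rep, summary = summ, classifier = classifier,
                 reps = reps, train_fraction = train_fraction, seed = seed,
                 positive_class = positive_class),
            class = "subsample_eval")
}

#' @export
print.subsample_eval <- function(x, ...) {
  cat(sprintf("Random subsampling: %d x %.0f:%.0f hold-out, classifier %s, positive '%s'\n",
              x$reps, 100 * x$train_fraction, 100 * (1 - x$train_fraction),
              x$classifier, x$positive_class))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
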