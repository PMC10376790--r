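#' Configure an end-to-end classification pipeline
#'
#' The stage chain is fixed by the data type:
#' * `"signal"`: segmentation -> FFT features -> PCA -> FCM fuzzification ->
#'   classifier;
#' * `"large_dimensional"`: PCA -> FCM fuzzification -> classifier;
#' * `"numeric"`: FCM / one-hot fuzzification only -> classifier;
#' * `"expert"`: no pre-processing, the fuzzy data are classified directly.
#'
#' Supplying a stage parameter that the data type does not use (for example
#' `segment_seconds` for tabular data, or any pre-processing parameter for
#' expert data) is a configuration error reported before execution.
#'
#' @param data_type One of `"signal"`, `"large_dimensional"`, `"numeric"`,
#'   `"expert"`.
#' @param segment_seconds Segment duration for signal data. Default 2.95.
#' @param n_components Number of principal components (signal default 8,
#'   large-dimensional default 5).
#' @param terms Linguistic terms per fuzzified numeric attribute. Default 3.
#' @param q FCM fuzzifier exponent. Default 2.
#' @param classifier `"fdt"` or `"fnb"`.
#' @param alpha,beta FDT pruning parameters (see [fdt()]).
#' @param smoothing FNB smoothing (see [fnb()]).
#' @param train_fraction Hold-out training fraction. Default 0.7.
#' @param reps Number of random-subsampling rounds. Default 1 (single
#'   hold-out).
#' @param positive_class Label reported as positive; default the first class.
#' @param stratified Stratify hold-out splits. Default TRUE.
#' @param seed Master seed for splitting.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_type = c("signal", "large_dimensional",
                                          "numeric", "expert"),
                            segment_seconds = NULL, n_components = NULL,
                            terms = 3, q = 2,
                            classifier = c("fdt", "fnb"),
                            alpha = 0.05, beta = 0.95, smoothing = 1,
                            train_fraction = 0.7, reps = 1,
                            positive_class = NULL, stratified = TRUE,
                            seed = 1) {
  data_type <- match.arg(data_type)
  classifier <- match.arg(classifier)
  if (data_type != "signal" && !is.null(segment_seconds)) {
    stop("'segment_seconds' only applies to data_type = 'signal'")
  }
  if (data_type %in% c("numeric", "expert") && !is.null(n_components)) {
    stop("'n_components' does not apply to data_type = '", data_type, "'")
  }
  if (data_type == "expert" && !missing(terms)) {
    stop("'terms' does not apply to expert data (already fuzzy)")
  }
  if (data_type == "signal" && is.null(segment_seconds)) segment_seconds <- 2.95
  if (is.null(n_components)) {
    n_components <- switch(data_type, signal = 8L, large_dimensional = 5L,
                           NULL)
  }
  structure(list(data_type = data_type, segment_seconds = segment_seconds,
                 n_components = n_components, terms = terms, q = q,
                 classifier = classifier, alpha = alpha, beta = beta,
                 smoothing = smoothing, train_fraction = train_fraction,
                 reps = reps, positive_class = positive_class,
                 stratified = stratified, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  args <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, args)
}

#' Run a full classification pipeline
#'
#' Applies the pre-processing chain prescribed by the configured data type
#' (see [pipeline_config()]), producing a [fuzzy_dataset()], then evaluates
#' the configured classifier by seeded hold-out (or repeated random
#' subsampling when `reps > 1`) and finally fits a model on all samples for
#' deployment/inspection. Pre-processing (PCA, FCM) is fitted on the full
#' dataset before splitting, matching the protocol in which the dataset is
#' divided after its transformation into fuzzy attributes.
#'
#' @param cfg A [pipeline_config()] (or path to a YAML config).
#' @param data The input matching the data type: a `signal_set` (or list of
#'   [signal_record()]s) for `"signal"`; a `data.frame` with a `class`
#'   column for `"large_dimensional"` / `"numeric"`; a [fuzzy_dataset()] for
#'   `"expert"`.
#' @param class_col Class column name for tabular input. Default `"class"`.
#' @param out_dir Optional directory; when given, intermediate artifacts
#'   (fuzzy dataset, fitted model, metrics CSV) are persisted there.
#' @return A list of class `pipeline_result`: `evaluation` (a
#'   [subsample_eval()] object), `metrics` (the metrics of the first round),
#'   `model` (classifier refitted on all samples), `dataset` (the fuzzified
#'   data), plus fitted pre-processing models where applicable (`pca`,
#'   `fuzzifier`) and stage timings.
#' @export
run_pipeline <- function(cfg, data, class_col = "class", out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  timings <- c()
  clock <- function(tag, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[tag] <<- proc.time()[["elapsed"]] - t0
    val
  }
  pca_model <- NULL
  fz <- NULL

  if (cfg$data_type == "signal") {
    records <- if (inherits(data, "signal_set")) data$records else data
    if (!all(vapply(records, inherits, logical(1), "signal_record"))) {
      stop("signal pipeline expects signal_record inputs")
    }
    segments <- clock("segment", segment_signals(records, cfg$segment_seconds))
    features <- clock("fft", fft_features(segments))
    red <- clock("pca", pca_reduce(features, cfg$n_components))
    pca_model <- red$model
    fz <- clock("fuzzify", fuzzify(red$features, terms = cfg$terms, q = cfg$q,
                                   provenance = "signal pipeline"))
    ds <- fz$dataset
  } else if (cfg$data_type == "large_dimensional") {
    if (!is.data.frame(data)) stop("tabular pipeline expects a data.frame")
    num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        class_col)
    fs <- feature_set(as.matrix(data[num_cols]), num_cols,
                      as.character(data[[class_col]]))
    red <- clock("pca", pca_reduce(fs, cfg$n_components))
    pca_model <- red$model
    fz <- clock("fuzzify", fuzzify(red$features, terms = cfg$terms, q = cfg$q,
                                   provenance = "large-dimensional pipeline"))
    ds <- fz$dataset
  } else if (cfg$data_type == "numeric") {
    if (!is.data.frame(data)) stop("tabular pipeline expects a data.frame")
    fz <- clock("fuzzify", fuzzify(data, class_col = class_col,
                                   terms = cfg$terms, q = cfg$q,
                                   provenance = "numeric pipeline"))
    ds <- fz$dataset
  } else {  # expert
    if (!inherits(data, "fuzzy_dataset")) {
      stop("expert pipeline expects an already-fuzzy dataset")
    }
    ds <- data
  }

  cls_args <- if (cfg$classifier == "fdt") {
    list(alpha = cfg$alpha, beta = cfg$beta)
  } else {
    list(smoothing = cfg$smoothing)
  }
  evaluation <- clock("evaluate", do.call(subsample_eval, c(
    list(ds = ds, classifier = cfg$classifier, reps = cfg$reps,
         train_fraction = cfg$train_fraction, seed = cfg$seed,
         positive_class = cfg$positive_class,
         stratified = cfg$stratified),
    cls_args)))
  model <- clock("fit_full", do.call(
    if (cfg$classifier == "fdt") fdt else fnb, c(list(ds), cls_args)))

  first <- evaluation$per_rep[1L, ]
  metrics <- structure(list(accuracy = first$accuracy,
                            specificity = first$specificity,
                            sensitivity = first$sensitivity,
                            precision = first$precision, f1 = first$f1,
                            counts = NULL,
                            positive_class = evaluation$positive_class),
                       class = "metrics_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fuzzy_dataset(ds, file.path(out_dir, "fuzzy_dataset.csv"))
    write_model(model, file.path(out_dir, paste0(cfg$classifier, ".json")))
    if (!is.null(pca_model)) write_model(pca_model,
                                         file.path(out_dir, "pca.json"))
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"),
                      algorithm = toupper(cfg$classifier))
  }

  structure(list(config = cfg, evaluation = evaluation, metrics = metrics,
                 model = model, dataset = ds, pca = pca_model,
                 fuzzifier = fz, timings = timings),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result (%s data, %s classifier)\n",
              x$config$data_type, x$config$classifier))
  print(x$evaluation)
  invisible(x)
}
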