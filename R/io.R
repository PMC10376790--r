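#' Read a crisp table with a declared schema
#'
#' Reads a CSV with a header, checks the class column, and coerces columns to
#' the declared kinds. Unparseable numeric cells raise an error naming the
#' row and column; genuinely missing cells are kept as `NA` (flagged, not
#' dropped) for downstream uniform-membership fuzzification.
#'
#' @param path CSV file path.
#' @param class_col Name of the class column (must exist).
#' @param numeric_cols,categorical_cols Optional character vectors declaring
#'   column kinds; undeclared columns keep their parsed type.
#' @return A `data.frame`.
#' @export
load_crisp_table <- function(path, class_col = "class",
                             numeric_cols = NULL, categorical_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) < 1L || ncol(df) < 1L) stop("empty table: ", path)
  if (!(class_col %in% names(df))) {
    stop("missing class column '", class_col, "' in ", path)
  }
  for (col in numeric_cols %||% character(0)) {
    if (!(col %in% names(df))) stop("declared numeric column '", col, "' absent")
    raw <- as.character(df[[col]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & nzchar(trimws(raw)))
    if (length(bad) > 0L) {
      stop("unparseable numeric value '", raw[bad[1L]], "' at row ", bad[1L],
           ", column '", col, "'")
    }
    df[[col]] <- num
  }
  for (col in categorical_cols %||% character(0)) {
    if (!(col %in% names(df))) stop("declared categorical column '", col, "' absent")
    df[[col]] <- as.character(df[[col]])
  }
  df
}

#' Write / read a fuzzy dataset as CSV plus a JSON side-car
#'
#' The CSV has one `attribute:term` column per membership degree; degrees are
#' written with 17 significant digits so the round-trip is bit-exact. The
#' side-car (`<path>.json`) records the attribute structure, roles and the
#' provenance tag.
#'
#' @param ds A [fuzzy_dataset()].
#' @param path CSV destination; the side-car goes to `paste0(path, ".json")`.
#' @return `write_fuzzy_dataset()` returns `path` invisibly;
#'   `read_fuzzy_dataset()` returns the reconstructed [fuzzy_dataset()].
#' @export
write_fuzzy_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "fuzzy_dataset"))
  cols <- list()
  for (i in seq_along(ds$attributes)) {
    at <- ds$attributes[[i]]
    m <- ds$memberships[[i]]
    for (j in seq_along(at$terms)) {
      cols[[paste0(at$name, ":", at$terms[j])]] <- sprintf("%.17g", m[, j])
    }
  }
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  meta <- list(
    format = "fuzzytree.fuzzy_dataset", version = 1L,
    provenance = ds$provenance,
    output = ds$attributes[[ds$output_index]]$name,
    attributes = lapply(ds$attributes, function(a) {
      list(name = a$name, terms = a$terms, role = a$role)
    }))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fuzzy_dataset
#' @export
read_fuzzy_dataset <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stop("dataset files not found: ", path, " (+ .json side-car)")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (!identical(meta$format, "fuzzytree.fuzzy_dataset")) {
    stop("not a fuzzy dataset file: ", path)
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  attrs <- lapply(meta$attributes, function(a) {
    fuzzy_attribute(a$name, unlist(a$terms), a$role)
  })
  mems <- lapply(attrs, function(a) {
    cn <- paste0(a$name, ":", a$terms)
    missing <- setdiff(cn, names(df))
    if (length(missing) > 0L) stop("missing column(s): ",
                                   paste(missing, collapse = ", "))
    m <- vapply(cn, function(x) as.numeric(df[[x]]), numeric(nrow(df)))
    matrix(m, nrow = nrow(df), dimnames = list(NULL, a$terms))
  })
  fuzzy_dataset(attrs, mems, meta$provenance %||% "")
}

model_schema <- c(fdt = "fuzzytree.fdt.v1",
                  fnb = "fuzzytree.fnb.v1",
                  fcm_model = "fuzzytree.fcm.v1",
                  pca_reduction = "fuzzytree.pca.v1",
                  fuzzifier = "fuzzytree.fuzzifier.v1")

mat_to_list <- function(m) list(data = as.numeric(m), nrow = nrow(m),
                                dimnames = dimnames(m))
list_to_mat <- function(l) {
  m <- matrix(unlist(l$data), nrow = l$nrow)
  if (!is.null(l$dimnames)) {
    dimnames(m) <- lapply(l$dimnames, function(d) if (length(d)) unlist(d))
  }
  m
}

attrs_to_list <- function(attrs) lapply(attrs, unclass)
attrs_from_list <- function(l) lapply(l, function(a) {
  fuzzy_attribute(a$name, unlist(a$terms), a$role)
})

#' Serialize a fitted model to JSON
#'
#' Supports [fdt()], [fnb()], [fit_fcm()], [fit_pca()] and [fuzzify()]
#' models. Numbers are written at full precision, so reloaded models give
#' predictions identical to the original (bit-level crisp decisions,
#' confidences to well below 1e-12). Each file carries a schema tag;
#' [read_model()] refuses files with an unknown or mismatching schema
#' version.
#'
#' @param model A supported fitted model object.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1L]
  if (!(cls %in% names(model_schema))) {
    stop("unsupported model class: ", cls)
  }
  payload <- switch(cls,
    fdt = list(alpha = model$alpha, beta = model$beta, tnorm = model$tnorm,
               attributes = attrs_to_list(model$attributes),
               output_index = model$output_index,
               root = model$root),
    fnb = list(priors = as.numeric(model$priors),
               smoothing = model$smoothing,
               conditionals = lapply(model$conditionals, mat_to_list),
               attributes = attrs_to_list(model$attributes),
               output_index = model$output_index),
    fcm_model = list(centers = model$centers, q = model$q,
                     terms = model$terms, name = model$name,
                     objective = model$objective,
                     iterations = model$iterations),
    pca_reduction = list(center = as.list(model$center),
                         scale = as.list(model$scale),
                         rotation = mat_to_list(model$rotation),
                         variances = model$variances,
                         kept = model$kept,
                         n_components = model$n_components),
    fuzzifier = list(class_col = model$class_col,
                     class_levels = model$class_levels,
                     q = model$q,
                     models = lapply(model$models, function(m) {
                       if (inherits(m, "fcm_model")) {
                         c(list(kind = "fcm"), unclass(m))
                       } else {
                         list(kind = "categorical", levels = m$levels)
                       }
                     }),
                     attributes = attrs_to_list(model$dataset$attributes)))
  obj <- list(schema = unname(model_schema[cls]), payload = payload)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Reload a model serialized by [write_model()]
#'
#' @param path JSON file written by [write_model()].
#' @return The reconstructed model object. Note that a reloaded `fuzzifier`
#'   carries no training dataset (only the fitted transformation), so it
#'   supports [predict.fuzzifier()] but not re-inspection of training rows.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- obj$schema %||% "(none)"
  cls <- names(model_schema)[match(schema, model_schema)]
  if (is.na(cls)) {
    stop("unknown or mismatching model schema '", schema, "' in ", path)
  }
  p <- obj$payload
  num <- function(x) as.numeric(unlist(x))
  switch(cls,
    fdt = {
      rebuild <- function(node) {
        if (identical(node$type, "leaf")) {
          list(type = "leaf", confidence = num(node$confidence),
               mass = num(node$mass))
        } else {
          list(type = "split", attribute = as.integer(node$attribute),
               score = num(node$score), mass = num(node$mass),
               confidence = num(node$confidence),
               children = lapply(node$children, rebuild))
        }
      }
      attrs <- attrs_from_list(p$attributes)
      oi <- as.integer(p$output_index)
      structure(list(root = rebuild(p$root), alpha = num(p$alpha),
                     beta = num(p$beta), tnorm = p$tnorm,
                     attributes = attrs, output_index = oi,
                     class_terms = attrs[[oi]]$terms,
                     log = data.frame()),
                class = "fdt")
    },
    fnb = {
      attrs <- attrs_from_list(p$attributes)
      oi <- as.integer(p$output_index)
      conds <- lapply(p$conditionals, list_to_mat)
      structure(list(priors = stats::setNames(num(p$priors),
                                              attrs[[oi]]$terms),
                     conditionals = conds, smoothing = num(p$smoothing),
                     attributes = attrs, output_index = oi,
                     class_terms = attrs[[oi]]$terms),
                class = "fnb")
    },
    fcm_model = structure(list(centers = num(p$centers), q = num(p$q),
                               terms = unlist(p$terms), name = p$name,
                               objective = num(p$objective),
                               iterations = as.integer(p$iterations)),
                          class = "fcm_model"),
    pca_reduction = structure(
      list(center = stats::setNames(num(p$center), names(p$center)),
           scale = stats::setNames(num(p$scale), names(p$scale)),
           rotation = list_to_mat(p$rotation),
           variances = num(p$variances), kept = unlist(p$kept),
           n_components = as.integer(p$n_components)),
      class = "pca_reduction"),
    fuzzifier = {
      attrs <- attrs_from_list(p$attributes)
      models <- lapply(p$models, function(m) {
        if (identical(m$kind, "fcm")) {
          structure(list(centers = num(m$centers), q = num(m$q),
                         terms = unlist(m$terms), name = m$name,
                         objective = num(m$objective),
                         iterations = as.integer(m$iterations)),
                    class = "fcm_model")
        } else {
          list(levels = unlist(m$levels))
        }
      })
      names(models) <- names(p$models)
      roles <- vapply(attrs, `[[`, character(1), "role")
      skel <- list(attributes = attrs,
                   output_index = which(roles == "output"),
                   provenance = "reloaded fuzzifier")
      structure(list(models = models,
                     dataset = structure(skel, class = "fuzzy_dataset_meta"),
                     class_col = p$class_col,
                     class_levels = unlist(p$class_levels),
                     terms = NA, q = num(p$q)),
                class = "fuzzifier")
    })
}

#' Write a metrics report (or multi-class report) to CSV
#'
#' Columns mirror the standard comparison-table layout: Algorithm, Type,
#' Accuracy, Specificity, Sensitivity, Precision, F1 Score.
#'
#' @param report A `metrics_report`, `subsample_eval` summary, or the
#'   `data.frame` from [classification_report()].
#' @param path CSV destination.
#' @param algorithm,type Labels for the first two columns.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path, algorithm = "FDT",
                              type = "Fuzzy") {
  df <- if (inherits(report, "metrics_report")) as.data.frame(report)
        else as.data.frame(report)
  out <- data.frame(Algorithm = algorithm, Type = type,
                    Accuracy = df$accuracy, Specificity = df$specificity,
                    Sensitivity = df$sensitivity, Precision = df$precision,
                    `F1 Score` = df$f1, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a signal record as plain text CSV
#'
#' Format: a header line `rate_hz,<rate>`, a line `label,<label>`, a line
#' `record_id,<id>`, then one sample value per line under a `sample` header.
#'
#' @param rec A [signal_record()].
#' @param path Destination file.
#' @return `write_signal_csv()` returns `path` invisibly;
#'   `read_signal_csv()` the reconstructed [signal_record()].
#' @export
write_signal_csv <- function(rec, path) {
  stopifnot(inherits(rec, "signal_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("rate_hz,%.17g", rec$sampling_rate),
               sprintf("label,%s", rec$label),
               sprintf("record_id,%s", rec$record_id),
               "sample",
               sprintf("%.17g", rec$samples)), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L || !startsWith(lines[1L], "rate_hz,")) {
    stop("not a signal CSV: ", path)
  }
  rate <- as.numeric(sub("^rate_hz,", "", lines[1L]))
  label <- sub("^label,", "", lines[2L])
  id <- sub("^record_id,", "", lines[3L])
  samples <- as.numeric(lines[-(1:4)])
  signal_record(samples, rate, label, id)
}
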