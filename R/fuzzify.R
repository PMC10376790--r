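#' Fuzzify a crisp table into a fuzzy dataset
#'
#' Converts every numeric column into a fuzzy attribute via a per-column
#' fuzzy C-means model ([fit_fcm()]), every categorical (character/factor)
#' column into a degenerate crisp fuzzy attribute (one term per observed
#' category, one-hot memberships), and the class column into a crisp output
#' attribute. Missing numeric values and (at prediction time) unseen
#' categories receive uniform memberships with a warning: maximal ignorance.
#'
#' @param x A `data.frame` with a class column, or a [feature_set()].
#' @param ... Passed on to methods.
#' @return An object of class `fuzzifier`: list with `models` (named list of
#'   [fit_fcm()] models / categorical level sets), `dataset` (the fuzzified
#'   [fuzzy_dataset()] of the training table), `class_col`, `terms`, `q`.
#' @seealso [predict.fuzzifier()] to fuzzify new rows with the fitted models.
#' @export
fuzzify <- function(x, ...) UseMethod("fuzzify")

#' @rdname fuzzify
#' @param class_col Name of the class column (for data frames).
#' @param terms Number of linguistic terms per numeric column: a single
#'   integer or a named vector covering all numeric columns. Default 3.
#' @param q Fuzzifier exponent for FCM. Default 2.
#' @param provenance Provenance tag for the resulting dataset.
#' @export
fuzzify.data.frame <- function(x, class_col = "class", terms = 3, q = 2,
                               provenance = "crisp table", ...) {
  if (!(class_col %in% names(x))) {
    stop("class column '", class_col, "' not found")
  }
  inputs <- setdiff(names(x), class_col)
  if (length(inputs) < 1L) stop("no input columns")
  term_of <- function(col) {
    if (length(terms) == 1L && is.null(names(terms))) return(as.integer(terms))
    if (!(col %in% names(terms))) {
      stop("'terms' does not cover numeric column '", col, "'")
    }
    as.integer(terms[[col]])
  }

  models <- list()
  attrs <- list()
  mems <- list()
  K <- nrow(x)
  for (col in inputs) {
    v <- x[[col]]
    if (is.numeric(v)) {
      m <- term_of(col)
      ok <- !is.na(v)
      fm <- fit_fcm(v[ok], m_terms = m, q = q, name = col)
      U <- matrix(1 / m, K, m)
      if (any(!ok)) {
        warning("column '", col, "': ", sum(!ok),
                " missing value(s) fuzzified as uniform membership")
      }
      U[ok, ] <- predict(fm, v[ok])
      models[[col]] <- fm
      attrs[[col]] <- fuzzy_attribute(col, fm$terms, "input")
      mems[[col]] <- U
    } else {
      lv <- sort(unique(as.character(v[!is.na(v)])))
      if (length(lv) < 2L) {
        stop("categorical column '", col, "' has fewer than 2 observed levels")
      }
      U <- matrix(0, K, length(lv))
      idx <- match(as.character(v), lv)
      ok <- !is.na(idx)
      U[cbind(which(ok), idx[ok])] <- 1
      if (any(!ok)) {
        warning("column '", col, "': ", sum(!ok),
                " missing value(s) fuzzified as uniform membership")
        U[!ok, ] <- 1 / length(lv)
      }
      models[[col]] <- list(levels = lv)
      attrs[[col]] <- fuzzy_attribute(col, lv, "input")
      mems[[col]] <- U
    }
  }

  cl <- as.character(x[[class_col]])
  if (anyNA(cl)) stop("class column contains missing values")
  lv <- sort(unique(cl))
  if (length(lv) < 2L) stop("class column must have at least 2 classes")
  B <- matrix(0, K, length(lv))
  B[cbind(seq_len(K), match(cl, lv))] <- 1
  attrs[[class_col]] <- fuzzy_attribute(class_col, lv, "output")
  mems[[class_col]] <- B

  structure(list(models = models,
                 dataset = fuzzy_dataset(attrs, mems, provenance),
                 class_col = class_col, terms = terms, q = q,
                 class_levels = lv),
            class = "fuzzifier")
}

#' @rdname fuzzify
#' @export
fuzzify.feature_set <- function(x, terms = 3, q = 2,
                                provenance = "feature set", ...) {
  df <- as.data.frame(x$values)
  df$class <- x$labels
  fuzzify.data.frame(df, class_col = "class", terms = terms, q = q,
                     provenance = provenance, ...)
}

#' Fuzzify new crisp rows with a fitted fuzzifier
#'
#' @param object A `fuzzifier` from [fuzzify()].
#' @param newdata A `data.frame` with the fitted input columns; the class
#'   column is optional (absent classes are recorded as the first class with
#'   zero information content only when `require_class = FALSE`).
#' @param require_class Require the class column to be present (default TRUE).
#' @param ... Unused.
#' @return A [fuzzy_dataset()] aligned to the training attributes.
#' @export
predict.fuzzifier <- function(object, newdata, require_class = TRUE, ...) {
  tr <- object$dataset
  K <- nrow(newdata)
  mems <- list()
  for (i in seq_along(tr$attributes)) {
    at <- tr$attributes[[i]]
    if (i == tr$output_index) {
      B <- matrix(0, K, length(at$terms))
      if (at$name %in% names(newdata)) {
        cl <- as.character(newdata[[at$name]])
        idx <- match(cl, at$terms)
        if (anyNA(idx)) stop("unseen class label in newdata")
        B[cbind(seq_len(K), idx)] <- 1
      } else if (require_class) {
        stop("class column '", at$name, "' missing from newdata")
      } else {
        B[, 1L] <- 1
      }
      mems[[at$name]] <- B
      next
    }
    if (!(at$name %in% names(newdata))) {
      stop("input column '", at$name, "' missing from newdata")
    }
    v <- newdata[[at$name]]
    mdl <- object$models[[at$name]]
    if (inherits(mdl, "fcm_model")) {
      U <- matrix(1 / length(at$terms), K, length(at$terms))
      ok <- !is.na(v)
      if (any(!ok)) {
        warning("column '", at$name, "': missing value(s) get uniform membership")
      }
      U[ok, ] <- predict(mdl, as.numeric(v[ok]))
    } else {
      lv <- mdl$levels
      U <- matrix(0, K, length(lv))
      idx <- match(as.character(v), lv)
      ok <- !is.na(idx)
      if (any(!ok)) {
        warning("column '", at$name,
                "': unseen or missing categor(ies) get uniform membership")
        U[!ok, ] <- 1 / length(lv)
      }
      U[cbind(which(ok), idx[ok])] <- 1
    }
    mems[[at$name]] <- U
  }
  fuzzy_dataset(tr$attributes, mems, paste0(tr$provenance, " (transformed)"))
}

#' @export
print.fuzzifier <- function(x, ...) {
  n_fcm <- sum(vapply(x$models, inherits, logical(1), "fcm_model"))
  cat(sprintf("Fuzzifier: %d FCM attribute(s), %d categorical attribute(s), classes: %s\n",
              n_fcm, length(x$models) - n_fcm,
              paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

#' Validate and wrap an expert pre-fuzzified table
#'
#' Expert data arrive already fuzzified: one block of per-term membership
#' degrees per attribute. This helper validates the degrees and assembles a
#' [fuzzy_dataset()] without any fitting. Input membership blocks are passed
#' through untouched.
#'
#' @param blocks Named list of numeric membership matrices (`K x m_i`), one
#'   per attribute, degrees in `[0, 1]`.
#' @param output Name of the output attribute block.
#' @param provenance Provenance tag.
#' @return A [fuzzy_dataset()].
#' @export
expert_dataset <- function(blocks, output, provenance = "expert") {
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    stop("'blocks' must be a named list")
  }
  if (!(output %in% names(blocks))) stop("output block '", output, "' missing")
  attrs <- lapply(names(blocks), function(nm) {
    m <- as.matrix(blocks[[nm]])
    tl <- colnames(m)
    if (is.null(tl)) tl <- paste0(nm, "_", seq_len(ncol(m)) - 1L)
    fuzzy_attribute(nm, tl, if (nm == output) "output" else "input")
  })
  fuzzy_dataset(attrs, blocks, provenance)
}
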