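#' Define a fuzzy attribute
#'
#' A fuzzy attribute is a named collection of linguistic terms ("low", "high",
#' ...), each term being a fuzzy set over the attribute's universe. A
#' [fuzzy_dataset()] holds one membership vector over these terms per sample.
#'
#' @param name Attribute name (single string).
#' @param terms Character vector of at least two unique linguistic term labels.
#' @param role Either `"input"` or `"output"`. Every dataset has exactly one
#'   output attribute, whose terms are the class labels.
#' @return An object of class `fuzzy_attribute`.
#' @examples
#' fuzzy_attribute("pc1", c("low", "medium", "high"))
#' @export
fuzzy_attribute <- function(name, terms, role = c("input", "output")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a single non-empty string")
  }
  terms <- as.character(terms)
  if (length(terms) < 2L) {
    stop("attribute '", name, "' must have at least 2 linguistic terms")
  }
  if (anyDuplicated(terms)) {
    stop("attribute '", name, "' has duplicated term labels")
  }
  structure(list(name = name, terms = terms, role = role),
            class = "fuzzy_attribute")
}

#' @export
print.fuzzy_attribute <- function(x, ...) {
  cat(sprintf("Fuzzy %s attribute '%s' with %d terms: %s\n",
              x$role, x$name, length(x$terms),
              paste(x$terms, collapse = ", ")))
  invisible(x)
}

#' Assemble a fuzzy dataset
#'
#' A fuzzy dataset holds `K` samples over `n` input fuzzy attributes and one
#' output fuzzy attribute. Each sample carries one membership vector per
#' attribute: the degree, in `[0, 1]`, to which the sample belongs to each of
#' the attribute's linguistic terms. Crisp data are the special case where each
#' vector is one-hot.
#'
#' @param attributes List of [fuzzy_attribute()] objects, exactly one of which
#'   has role `"output"`.
#' @param memberships List of numeric matrices, one per attribute, each
#'   `K x m_i` (samples by terms) with entries in `[0, 1]`.
#' @param provenance Free-text origin tag recorded alongside the data.
#' @return An object of class `fuzzy_dataset` with elements `attributes`,
#'   `memberships`, `output_index` and `provenance`.
#' @seealso [fuzzify()] to build one from a crisp table,
#'   [gen_expert_dataset()] for a synthetic example.
#' @export
fuzzy_dataset <- function(attributes, memberships, provenance = "") {
  if (!is.list(attributes) || length(attributes) < 2L) {
    stop("need at least one input and one output attribute")
  }
  ok <- vapply(attributes, inherits, logical(1), "fuzzy_attribute")
  if (!all(ok)) stop("'attributes' must be a list of fuzzy_attribute objects")
  roles <- vapply(attributes, `[[`, character(1), "role")
  if (sum(roles == "output") != 1L) {
    stop("exactly one attribute must have role 'output'")
  }
  if (length(memberships) != length(attributes)) {
    stop("'memberships' must have one matrix per attribute")
  }
  memberships <- lapply(memberships, as.matrix)
  K <- nrow(memberships[[1L]])
  if (K < 1L) stop("dataset must contain at least one sample")
  for (i in seq_along(attributes)) {
    m <- memberships[[i]]
    at <- attributes[[i]]
    if (nrow(m) != K) {
      stop("attribute '", at$name, "': expected ", K, " rows, got ", nrow(m))
    }
    if (ncol(m) != length(at$terms)) {
      stop("attribute '", at$name, "': expected ", length(at$terms),
           " term columns, got ", ncol(m))
    }
    if (anyNA(m) || any(m < 0) || any(m > 1)) {
      stop("attribute '", at$name, "': membership degrees must lie in [0, 1]")
    }
    colnames(memberships[[i]]) <- at$terms
  }
  names(memberships) <- vapply(attributes, `[[`, character(1), "name")
  structure(list(attributes = attributes,
                 memberships = memberships,
                 output_index = which(roles == "output"),
                 provenance = as.character(provenance)[1L]),
            class = "fuzzy_dataset")
}

#' Number of samples in a fuzzy dataset
#' @param ds A [fuzzy_dataset()].
#' @return Integer sample count `K`.
#' @export
n_samples <- function(ds) {
  stopifnot(inherits(ds, "fuzzy_dataset"))
  nrow(ds$memberships[[1L]])
}

input_indices <- function(ds) {
  setdiff(seq_along(ds$attributes), ds$output_index)
}

output_memberships <- function(ds) ds$memberships[[ds$output_index]]

#' Crisp class labels of a fuzzy dataset
#'
#' Defuzzifies the output attribute by maximum membership (ties resolved
#' toward the lowest term index).
#' @param ds A [fuzzy_dataset()].
#' @return Character vector of `K` class term labels.
#' @export
crisp_classes <- function(ds) {
  B <- output_memberships(ds)
  terms <- ds$attributes[[ds$output_index]]$terms
  terms[max.col(B, ties.method = "first")]
}

#' @export
print.fuzzy_dataset <- function(x, ...) {
  n_in <- length(input_indices(x))
  out <- x$attributes[[x$output_index]]
  cat(sprintf("Fuzzy dataset: %d samples, %d input attributes, output '%s' (%d classes)\n",
              n_samples(x), n_in, out$name, length(out$terms)))
  for (i in input_indices(x)) {
    a <- x$attributes[[i]]
    cat(sprintf("  %s: %s\n", a$name, paste(a$terms, collapse = "/")))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Subset a fuzzy dataset by sample
#'
#' @param x A [fuzzy_dataset()].
#' @param i Row (sample) index vector.
#' @param ... Unused.
#' @return A `fuzzy_dataset` holding the selected samples.
#' @export
`[.fuzzy_dataset` <- function(x, i, ...) {
  mem <- lapply(x$memberships, function(m) m[i, , drop = FALSE])
  fuzzy_dataset(x$attributes, mem, x$provenance)
}

#' Cardinality of a fuzzy set
#'
#' The cardinality `M(A)` of a fuzzy set is the sum of its membership degrees,
#' a measure of the set's size that reduces to the ordinary count for crisp
#' sets.
#'
#' @param degrees Numeric vector of membership degrees in `[0, 1]`.
#' @return The sum of the degrees.
#' @examples
#' cardinality(c(0.2, 0.5, 0.3))  # 1
#' cardinality(c(1, 1, 1, 1))     # 4, a crisp set of 4 elements
#' @export
cardinality <- function(degrees) {
  degrees <- as.numeric(degrees)
  bad <- which(is.na(degrees) | degrees < 0 | degrees > 1)
  if (length(bad) > 0L) {
    stop("membership degree outside [0, 1] at index ", bad[1L])
  }
  sum(degrees)
}

# t-norm combination of two degree vectors; the configurable conjunction used
# for joint membership mass throughout the package.
tnorm_apply <- function(a, b, tnorm = c("product", "min")) {
  tnorm <- match.arg(tnorm)
  if (tnorm == "product") a * b else pmin(a, b)
}
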