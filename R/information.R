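#' Fuzzy frequency table of an input attribute against the output
#'
#' Accumulates, over all samples, the joint membership mass of each (input
#' term, output class) pair under a t-norm conjunction. With crisp one-hot
#' memberships and unit weights this is the classical contingency table. The
#' table is the sufficient statistic for the information score that drives
#' fuzzy decision tree induction.
#'
#' @param ds A [fuzzy_dataset()].
#' @param input_index Index (into `ds$attributes`) of an input attribute.
#' @param weights Optional per-sample nonnegative weights (node membership
#'   masses during tree induction). Default: all 1.
#' @param tnorm Conjunction used for joint mass: `"product"` (default) or
#'   `"min"`.
#' @return An object of class `fuzzy_freq_table`: list with `cells`
#'   (`m_i x m_B` matrix), `row_marginals`, `col_marginals`, `total`.
#' @export
fuzzy_frequency_table <- function(ds, input_index,
                                  weights = NULL,
                                  tnorm = c("product", "min")) {
  stopifnot(inherits(ds, "fuzzy_dataset"))
  tnorm <- match.arg(tnorm)
  if (!(input_index %in% input_indices(ds))) {
    stop("'input_index' must address an input attribute")
  }
  K <- n_samples(ds)
  if (K < 1L) stop("empty dataset")
  A <- ds$memberships[[input_index]]
  B <- output_memberships(ds)
  if (is.null(weights)) weights <- rep(1, K)
  stopifnot(length(weights) == K, all(weights >= 0))

  mi <- ncol(A)
  mb <- ncol(B)
  cells <- matrix(0, mi, mb, dimnames = list(colnames(A), colnames(B)))
  if (tnorm == "product") {
    cells[] <- crossprod(A * weights, B)
  } else {
    for (j in seq_len(mi)) {
      for (k in seq_len(mb)) {
        cells[j, k] <- sum(weights * pmin(A[, j], B[, k]))
      }
    }
  }
  structure(list(cells = cells,
                 row_marginals = rowSums(cells),
                 col_marginals = colSums(cells),
                 total = sum(cells)),
            class = "fuzzy_freq_table")
}

#' @export
print.fuzzy_freq_table <- function(x, ...) {
  cat("Fuzzy frequency table (total mass ", format(x$total), "):\n", sep = "")
  print(x$cells)
  invisible(x)
}

#' Fuzzy mutual information of a frequency table
#'
#' Normalizes the joint membership masses of a [fuzzy_frequency_table()] to a
#' joint distribution and returns the Shannon mutual information
#' \deqn{I(A;B) = \sum_{j,k} p(j,k) \log_2 \frac{p(j,k)}{p(j)\,p(k)}}
#' with the conventions `0 log 0 = 0` and masses below `1e-12` treated as
#' zero. This score quantifies the degree of influence of an input attribute
#' on the output attribute and is the split criterion of [fdt()].
#'
#' @param ft A `fuzzy_freq_table`, or a plain nonnegative matrix of joint
#'   masses.
#' @return The mutual information in bits, with attributes `H_input` and
#'   `H_output` carrying the marginal entropies `H(A)` and `H(B)`.
#' @export
fuzzy_mutual_information <- function(ft) {
  cells <- if (inherits(ft, "fuzzy_freq_table")) ft$cells else as.matrix(ft)
  if (anyNA(cells) || any(cells < 0)) stop("cell masses must be nonnegative")
  total <- sum(cells)
  if (total <= 0) stop("zero total mass: mutual information undefined")
  p <- cells / total
  p[p < 1e-12] <- 0
  pr <- rowSums(p)
  pc <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  pj <- p[nz]
  mi <- sum(pj * log2(pj / (pr[nz[, 1L]] * pc[nz[, 2L]])))
  entropy <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  structure(mi, H_input = entropy(pr), H_output = entropy(pc))
}
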