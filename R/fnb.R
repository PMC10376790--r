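#' Fit a fuzzy naive Bayes classifier
#'
#' Baseline fuzzy classifier. Class priors are the normalized class
#' membership masses; per-attribute conditionals are the (attribute term x
#' class) joint membership masses with additive (Laplace) smoothing,
#' normalized over terms within each class.
#'
#' @param ds A [fuzzy_dataset()].
#' @param smoothing Additive smoothing constant, >= 0. Default 1 (Laplace).
#' @return An object of class `fnb` with `priors`, `conditionals` (one
#'   `m_i x classes` matrix per input attribute), attribute metadata and the
#'   smoothing constant.
#' @seealso [predict.fnb()]
#' @export
fnb <- function(ds, smoothing = 1) {
  stopifnot(inherits(ds, "fuzzy_dataset"))
  if (!is.numeric(smoothing) || smoothing < 0) stop("'smoothing' must be >= 0")
  K <- n_samples(ds)
  if (K < 1L) stop("empty dataset")
  B <- output_memberships(ds)
  class_mass <- colSums(B)
  priors <- class_mass / sum(class_mass)
  in_idx <- input_indices(ds)
  conditionals <- lapply(in_idx, function(i) {
    M <- crossprod(ds$memberships[[i]], B) + smoothing
    cs <- colSums(M)
    cs[cs == 0] <- 1  # zero-mass class (possible with smoothing 0)
    sweep(M, 2L, cs, "/")
  })
  names(conditionals) <- vapply(ds$attributes[in_idx], `[[`,
                                character(1), "name")
  structure(list(priors = priors,
                 conditionals = conditionals,
                 smoothing = smoothing,
                 attributes = ds$attributes,
                 output_index = ds$output_index,
                 class_terms = ds$attributes[[ds$output_index]]$terms),
            class = "fnb")
}

#' Classify instances with a fuzzy naive Bayes model
#'
#' The posterior for class `k` is proportional to
#' `prior(k) * prod_i sum_j mu_ij(x) * cond(i, j, k)`: each attribute's
#' contribution is the membership-weighted expectation of its conditional.
#' Crisp one-hot instances reduce to the ordinary counting posterior.
#'
#' @param object An [fnb()] model.
#' @param newdata A [fuzzy_dataset()] carrying the model's input attributes.
#' @param type `"confidence"` (default) or `"class"` (argmax, ties to the
#'   lowest class index).
#' @param ... Unused.
#' @return Posterior confidence matrix or crisp class labels.
#' @export
predict.fnb <- function(object, newdata, type = c("confidence", "class"), ...) {
  type <- match.arg(type)
  mems <- align_inputs(object, newdata)
  K <- nrow(mems[[which(!vapply(mems, is.null, logical(1)))[1L]]])
  nc <- length(object$class_terms)
  logpost <- matrix(rep(log(pmax(object$priors, 1e-300)), each = K), K, nc)
  in_idx <- setdiff(seq_along(object$attributes), object$output_index)
  for (i in in_idx) {
    nm <- object$attributes[[i]]$name
    lik <- mems[[i]] %*% object$conditionals[[nm]]   # K x classes
    logpost <- logpost + log(pmax(lik, 1e-300))
  }
  logpost <- logpost - apply(logpost, 1L, max)
  post <- exp(logpost)
  post <- post / rowSums(post)
  colnames(post) <- object$class_terms
  if (type == "class") {
    object$class_terms[max.col(post, ties.method = "first")]
  } else {
    post
  }
}

#' @export
print.fnb <- function(x, ...) {
  cat(sprintf("Fuzzy naive Bayes: %d input attributes, smoothing %g\n",
              length(x$conditionals), x$smoothing))
  cat("Priors:", paste(sprintf("%s=%.3f", x$class_terms, x$priors),
                       collapse = ", "), "\n")
  invisible(x)
}
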