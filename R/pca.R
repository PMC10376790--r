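#' Fit a principal-component reduction of a feature set
#'
#' Standardizes every feature to zero mean and unit variance (zero-variance
#' features are dropped with a warning), then computes the variance-ranked
#' principal components. Loadings are column-orthonormal; each loading column
#' is oriented so that its largest-magnitude entry is positive, making the
#' decomposition deterministic. The component variances are the eigenvalues of
#' the standardized covariance matrix, in non-increasing order.
#'
#' @param fs A [feature_set()] (or plain numeric matrix).
#' @param n_components Number of components to keep;
#'   `1 <= n_components <= min(K - 1, s)`.
#' @return An object of class `pca_reduction` with elements `center`, `scale`,
#'   `rotation` (`s x n_components` loadings), `variances` (all component
#'   variances, non-increasing), `kept` (names of retained input features) and
#'   `n_components`.
#' @seealso [predict.pca_reduction()], [pca_reduce()]
#' @export
fit_pca <- function(fs, n_components) {
  X <- if (inherits(fs, "feature_set")) fs$values else as.matrix(fs)
  K <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zero_var <- scl < 1e-12
  if (any(zero_var)) {
    warning("dropping ", sum(zero_var), " zero-variance feature(s): ",
            paste(utils::head(colnames(X)[zero_var], 5L), collapse = ", "))
    X <- X[, !zero_var, drop = FALSE]
    ctr <- ctr[!zero_var]
    scl <- scl[!zero_var]
  }
  s <- ncol(X)
  if (s < 1L) stop("no features with nonzero variance")
  max_nc <- min(K - 1L, s)
  if (!is.numeric(n_components) || n_components < 1L || n_components > max_nc) {
    stop("'n_components' must lie in [1, ", max_nc, "]")
  }
  n_components <- as.integer(n_components)
  Z <- scale(X, center = ctr, scale = scl)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(ncol(rot))) {
    piv <- which.max(abs(rot[, j]))
    if (rot[piv, j] < 0) rot[, j] <- -rot[, j]
  }
  colnames(rot) <- paste0("PC", seq_len(n_components))
  structure(list(center = ctr, scale = scl, rotation = rot,
                 variances = pc$sdev^2, kept = colnames(X),
                 n_components = n_components),
            class = "pca_reduction")
}

#' Project new data onto a fitted principal-component reduction
#'
#' @param object A `pca_reduction` from [fit_pca()].
#' @param newdata A [feature_set()] or numeric matrix whose columns include
#'   the features the model was fitted on.
#' @param ... Unused.
#' @return A [feature_set()] of component scores (`K x n_components`).
#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  labels <- if (inherits(newdata, "feature_set")) newdata$labels else
    rep(NA_character_, nrow(as.matrix(newdata)))
  X <- if (inherits(newdata, "feature_set")) newdata$values else as.matrix(newdata)
  miss <- setdiff(object$kept, colnames(X))
  if (length(miss) > 0L) {
    stop("newdata lacks fitted feature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  Z <- scale(X[, object$kept, drop = FALSE],
             center = object$center, scale = object$scale)
  scores <- Z %*% object$rotation
  feature_set(scores, colnames(object$rotation), labels)
}

#' Fit-and-transform convenience wrapper around [fit_pca()]
#'
#' @inheritParams fit_pca
#' @return List with `model` (the `pca_reduction`) and `features` (the score
#'   [feature_set()], `K x n_components`).
#' @export
pca_reduce <- function(fs, n_components) {
  model <- fit_pca(fs, n_components)
  list(model = model, features = predict(model, fs))
}

#' @export
print.pca_reduction <- function(x, ...) {
  tot <- sum(x$variances)
  kept <- sum(x$variances[seq_len(x$n_components)])
  cat(sprintf("PCA reduction: %d of %d components, %.1f%% of variance\n",
              x$n_components, length(x$variances), 100 * kept / tot))
  invisible(x)
}

#' Scree plot of a principal-component reduction
#' @param x A `pca_reduction`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pca_reduction <- function(x, ...) {
  graphics::plot(seq_along(x$variances), x$variances, type = "b",
                 xlab = "component", ylab = "variance", ...)
  graphics::abline(v = x$n_components + 0.5, lty = 2)
  invisible(x)
}
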