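#' Fit a one-dimensional fuzzy C-means model for an attribute
#'
#' Standard fuzzy C-means alternating optimization on a single numeric
#' column: memberships proportional to `distance^(-2/(q-1))`, centers the
#' membership-weighted means. Centers are initialized at the `m_terms`
#' equally spaced quantiles of the data, which makes the fit deterministic;
#' optional seeded random restarts can be requested and the run with the
#' lowest within-cluster objective wins. Centers are returned in ascending
#' order so that linguistic terms ("low" ... "high") have a reproducible
#' meaning.
#'
#' @param values Numeric vector with at least `m_terms` distinct values.
#' @param m_terms Number of linguistic terms (clusters), at least 2.
#' @param q Fuzzifier exponent, > 1. Default 2.
#' @param tol Convergence tolerance on the maximum center shift. Default 1e-6.
#' @param max_iter Iteration cap. Default 300.
#' @param restarts Number of additional seeded random-initialization runs.
#'   Default 0 (quantile initialization only).
#' @param seed Seed used for the random restarts (ignored when
#'   `restarts = 0`).
#' @param name Source column name stored in the model.
#' @return An object of class `fcm_model`: `centers` (strictly increasing),
#'   `q`, `terms` (autogenerated labels), `name`, `objective`, `iterations`.
#' @examples
#' m <- fit_fcm(c(rep(0, 10), rep(10, 10)), m_terms = 2)
#' m$centers  # close to 0 and 10
#' @export
fit_fcm <- function(values, m_terms, q = 2, tol = 1e-6, max_iter = 300,
                    restarts = 0, seed = 1, name = "x") {
  x <- as.numeric(values)
  if (anyNA(x)) stop("'values' must not contain NA")
  if (!is.numeric(m_terms) || m_terms < 2L) stop("'m_terms' must be >= 2")
  m_terms <- as.integer(m_terms)
  if (q <= 1) stop("fuzzifier 'q' must be > 1")
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    stop("column '", name, "' is constant; encode it as a categorical attribute")
  }
  if (length(ux) < m_terms) {
    stop("column '", name, "' has ", length(ux),
         " distinct values, fewer than m_terms = ", m_terms)
  }

  run <- function(centers) {
    it <- 0L
    repeat {
      it <- it + 1L
      U <- fcm_u(x, centers, q)
      Uq <- U^q
      new_centers <- as.numeric(crossprod(Uq, x) / colSums(Uq))
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol || it >= max_iter) break
    }
    D2 <- (outer(x, centers, "-"))^2
    list(centers = centers, objective = sum((fcm_u(x, centers, q)^q) * D2),
         iterations = it)
  }

  # deterministic init: m equally spaced quantiles (through distinct values)
  init <- ux[round(seq(1, length(ux), length.out = m_terms))]
  best <- run(init)
  if (restarts > 0) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      cand <- run(sort(stats::runif(m_terms, min(x), max(x))))
      if (cand$objective < best$objective) best <- cand
    }
  }
  centers <- sort(best$centers)
  if (any(diff(centers) < 1e-10)) {
    stop("degenerate FCM fit for '", name, "': coinciding cluster centers")
  }
  structure(list(centers = centers, q = q, terms = term_labels(m_terms),
                 name = name, objective = best$objective,
                 iterations = best$iterations),
            class = "fcm_model")
}

# FCM membership matrix for values x against centers (ascending not required)
fcm_u <- function(x, centers, q) {
  D <- abs(outer(x, centers, "-"))
  e <- 2 / (q - 1)
  U <- matrix(0, length(x), length(centers))
  zero <- D < 1e-12
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    # exact center: full member of that term (first on the vanishing tie)
    first0 <- apply(zero[hit, , drop = FALSE], 1L, which.max)
    U[cbind(which(hit), first0)] <- 1
  }
  if (any(!hit)) {
    Dinv <- D[!hit, , drop = FALSE]^(-e)
    U[!hit, ] <- Dinv / rowSums(Dinv)
  }
  U
}

term_labels <- function(m) {
  if (m == 2L) c("low", "high")
  else if (m == 3L) c("low", "medium", "high")
  else c("low", paste0("mid", seq_len(m - 2L)), "high")
}

#' Membership degrees of values under a fitted FCM model
#'
#' Evaluates the fuzzy C-means membership function
#' \eqn{\mu_j(x) = 1 / \sum_l (d_j/d_l)^{2/(q-1)}} with `d_j = |x - c_j|`.
#' Degrees sum to 1 for every value; a value exactly at a center is a full
#' member of that term. Extrapolation beyond the fitted range is allowed.
#'
#' @param object An `fcm_model` from [fit_fcm()].
#' @param newdata Numeric vector of crisp values.
#' @param ... Unused.
#' @return Numeric `length(newdata) x m_terms` membership matrix with term
#'   labels as column names.
#' @export
predict.fcm_model <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  U <- fcm_u(x, object$centers, object$q)
  colnames(U) <- object$terms
  U
}

#' @export
print.fcm_model <- function(x, ...) {
  cat(sprintf("FCM model for '%s' (q = %g): ", x$name, x$q))
  cat(paste(sprintf("%s=%.4g", x$terms, x$centers), collapse = ", "), "\n")
  invisible(x)
}
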