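#' Configurations for the synthetic data generators
#'
#' Each generator emulates the schema and marginal structure of one of four
#' biomedical data archetypes; none of them claims physiological realism.
#' All randomness flows from the mandatory `seed`, so a given configuration
#' reproduces its dataset exactly.
#'
#' * `signal_config()`: two-class single-channel signal records. The
#'   background class is a 10 Hz oscillation with Gaussian noise; the
#'   seizure-like class is an amplitude-modulated 3 Hz oscillation whose
#'   amplitude is `effect_size` times the background amplitude. Defaults:
#'   400 background + 100 seizure-like records of 23.6 s at 200 Hz.
#' * `wide_config()`: a wide laboratory table (more columns than rows):
#'   78 rows x 186 standard-normal columns, two balanced classes,
#'   `n_informative` columns shifted by `+/- effect_size / 2`.
#' * `clinical_config()`: a mixed clinical table: 177 rows, 29 input
#'   attributes (11 binary comorbidity-style flags, 18 numeric of which 16
#'   are log-normal biomarker-like), binary survival-style outcome with
#'   class-dependent shifts scaled by `effect_size`.
#' * `expert_config()`: a tiny expert-evaluated fuzzy table: 10 samples over
#'   inputs with 2/2/4 linguistic terms and a 3-class output generated from
#'   a monotone ground-truth structure function; membership degrees are
#'   Dirichlet draws sharpened toward the true term by `certainty`
#'   (`Inf` gives crisp one-hot data). With 10 of the 16 possible crisp
#'   situations covered, the table is incompletely specified.
#'
#' @param n_background,n_seizure Records per signal class.
#' @param duration_s Record duration in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @param effect_size Between-class effect size (amplitude ratio for
#'   signals, mean shift for tables); 0 makes the classes identical.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_samples,n_features,n_informative Table dimensions.
#' @param class_balance Probability of the majority class where classes are
#'   imbalanced.
#' @param certainty Dirichlet sharpening of expert memberships (>= 0, or
#'   `Inf` for crisp).
#' @param seed Mandatory integer seed.
#' @return A configuration list of the corresponding class.
#' @name synth_config
NULL

#' @rdname synth_config
#' @export
signal_config <- function(n_background = 400, n_seizure = 100,
                          duration_s = 23.6, rate_hz = 200,
                          effect_size = 3, noise_sd = 1, seed = 1) {
  stopifnot(n_background >= 1, n_seizure >= 1, duration_s > 0, rate_hz > 0,
            effect_size >= 0, noise_sd >= 0)
  if (duration_s * rate_hz < 2) stop("duration * rate must be at least 2 samples")
  structure(list(n_background = n_background, n_seizure = n_seizure,
                 duration_s = duration_s, rate_hz = rate_hz,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "signal_config")
}

#' Generate a two-class synthetic signal dataset
#'
#' @param cfg A [signal_config()].
#' @return List of class `signal_set`: `records` (list of [signal_record()]),
#'   `config` (the generating configuration, i.e. the dataset manifest).
#' @export
gen_signal_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "signal_config"))
  set.seed(cfg$seed)
  n <- floor(cfg$duration_s * cfg$rate_hz)
  t <- (seq_len(n) - 1L) / cfg$rate_hz
  make <- function(label, i) {
    phase <- stats::runif(1, 0, 2 * pi)
    base <- sin(2 * pi * 10 * t + phase)
    if (label == "seizure") {
      # seizure-like: an added low-frequency oscillation with a slow
      # amplitude envelope (bursting); its amplitude relative to the
      # shared background rhythm is the effect size, so effect 0 makes
      # the classes identical
      phase2 <- stats::runif(1, 0, 2 * pi)
      base <- base + cfg$effect_size *
        (0.5 + 0.5 * sin(2 * pi * 0.5 * t)) * sin(2 * pi * 3 * t + phase2)
    }
    signal_record(base + stats::rnorm(n, sd = cfg$noise_sd), cfg$rate_hz,
                  label, sprintf("%s%04d", substr(label, 1, 1), i))
  }
  records <- c(lapply(seq_len(cfg$n_background), make, label = "background"),
               lapply(seq_len(cfg$n_seizure), make, label = "seizure"))
  structure(list(records = records, config = cfg), class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  labs <- table(vapply(x$records, `[[`, character(1), "label"))
  cat(sprintf("Signal set: %d records (%s), %.1f s @ %g Hz\n",
              length(x$records),
              paste(sprintf("%s=%d", names(labs), labs), collapse = ", "),
              x$config$duration_s, x$config$rate_hz))
  invisible(x)
}

#' @rdname synth_config
#' @export
wide_config <- function(n_samples = 78, n_features = 186, n_informative = 20,
                        effect_size = 2, seed = 1) {
  stopifnot(n_samples >= 2, n_features >= 1,
            n_informative >= 0, n_informative <= n_features,
            effect_size >= 0)
  if (n_features <= n_samples) {
    stop("wide archetype requires more columns than rows")
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_informative = n_informative, effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "wide_config")
}

#' Generate a wide (columns > rows) two-class laboratory-style table
#'
#' @param cfg A [wide_config()].
#' @return A `data.frame` of `n_samples` rows: `n_features` numeric columns
#'   `V1..` plus a `class` column (`control` / `tumor`, balanced), with the
#'   generating configuration attached as attribute `"manifest"`.
#' @export
gen_wide_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "wide_config"))
  set.seed(cfg$seed)
  K <- cfg$n_samples
  cls <- rep(c("control", "tumor"), length.out = K)
  X <- matrix(stats::rnorm(K * cfg$n_features), K, cfg$n_features)
  if (cfg$n_informative > 0) {
    shift <- ifelse(cls == "tumor", cfg$effect_size / 2, -cfg$effect_size / 2)
    X[, seq_len(cfg$n_informative)] <-
      X[, seq_len(cfg$n_informative), drop = FALSE] + shift
  }
  colnames(X) <- paste0("V", seq_len(cfg$n_features))
  df <- as.data.frame(X)
  df$class <- cls
  attr(df, "manifest") <- cfg
  df
}

#' @rdname synth_config
#' @export
clinical_config <- function(n_samples = 177, class_balance = 0.7,
                            effect_size = 1.5, seed = 1) {
  stopifnot(n_samples >= 2, class_balance > 0, class_balance < 1,
            effect_size >= 0)
  structure(list(n_samples = n_samples, class_balance = class_balance,
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "clinical_config")
}

#' Generate a mixed numeric/categorical clinical-style table
#'
#' 29 input attributes: 11 binary flags (comorbidity-style categorical
#' attributes whose prevalence shifts with the outcome), 2 plain numeric
#' baseline attributes (age-like, BMI-like) and 16 log-normal biomarker-like
#' attributes whose log-means shift with the outcome. The binary outcome
#' `survived`/`died` has `P(survived) = class_balance`.
#'
#' @param cfg A [clinical_config()].
#' @return A `data.frame` with 29 input columns plus `class`; configuration
#'   attached as attribute `"manifest"`.
#' @export
gen_clinical_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "clinical_config"))
  set.seed(cfg$seed)
  K <- cfg$n_samples
  es <- cfg$effect_size
  cls <- ifelse(stats::runif(K) < cfg$class_balance, "survived", "died")
  died <- cls == "died"
  df <- data.frame(row.names = seq_len(K))
  base_prev <- 0.25
  for (i in seq_len(11)) {
    p <- ifelse(died, min(0.95, base_prev + 0.1 * es), base_prev)
    df[[sprintf("flag%02d", i)]] <-
      ifelse(stats::runif(K) < p, "yes", "no")
  }
  df$age <- stats::rnorm(K, mean = 58 + ifelse(died, 4 * es, 0), sd = 12)
  df$bmi <- stats::rnorm(K, mean = 28, sd = 5)
  for (i in seq_len(16)) {
    mu <- ifelse(died, 0.4 * es, 0)
    df[[sprintf("marker%02d", i)]] <- exp(stats::rnorm(K, mean = mu, sd = 1))
  }
  df$class <- cls
  attr(df, "manifest") <- cfg
  df
}

#' @rdname synth_config
#' @export
expert_config <- function(n_samples = 10, certainty = 8, seed = 1) {
  stopifnot(n_samples >= 1, n_samples <= 16, certainty >= 0)
  structure(list(n_samples = n_samples, certainty = certainty,
                 seed = as.integer(seed)),
            class = "expert_config")
}

# monotone ground-truth structure function over (a1, a2, a3) with
# a1, a2 in {0,1}, a3 in {0..3}: team-performance score mapped to 3 classes
expert_structure_function <- function(a1, a2, a3) {
  s <- a1 + a2 + a3
  ifelse(s <= 1, 0L, ifelse(s <= 3, 1L, 2L))
}

#' Generate a tiny expert-style fuzzy dataset
#'
#' Emulates expert evaluations of a three-member team (two binary
#' performance attributes, one four-level attribute) against a three-class
#' outcome given by a monotone structure function of the crisp states. Each
#' sampled crisp situation is expressed as fuzzy membership degrees: a
#' Dirichlet draw sharpened toward the true term with concentration
#' `certainty` (the crisp limit `certainty = Inf` reproduces one-hot data).
#' Sampling `n_samples < 16` distinct situations leaves the dataset
#' incompletely specified.
#'
#' @param cfg An [expert_config()].
#' @return A [fuzzy_dataset()] with attributes `A1` (2 terms), `A2`
#'   (2 terms), `A3` (4 terms) and output `B` (3 classes). The sampled crisp
#'   situations and their true classes are attached as attribute `"truth"`.
#' @export
gen_expert_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "expert_config"))
  set.seed(cfg$seed)
  grid <- expand.grid(a1 = 0:1, a2 = 0:1, a3 = 0:3)
  pick <- sort(sample.int(nrow(grid), cfg$n_samples))
  situations <- grid[pick, , drop = FALSE]
  situations$b <- expert_structure_function(situations$a1, situations$a2,
                                            situations$a3)
  sharpen <- function(true_idx, m) {
    if (!is.finite(cfg$certainty)) {
      v <- numeric(m); v[true_idx] <- 1
      return(v)
    }
    g <- stats::rgamma(m, shape = 1 + cfg$certainty *
                         (seq_len(m) == true_idx))
    g / sum(g)
  }
  K <- nrow(situations)
  block <- function(states, m, prefix) {
    U <- t(vapply(states + 1L, sharpen, numeric(m), m = m))
    colnames(U) <- paste0(prefix, seq_len(m) - 1L)
    U
  }
  blocks <- list(A1 = block(situations$a1, 2L, "A1_"),
                 A2 = block(situations$a2, 2L, "A2_"),
                 A3 = block(situations$a3, 4L, "A3_"),
                 B  = block(situations$b, 3L, "B"))
  ds <- expert_dataset(blocks, output = "B",
                       provenance = sprintf("synthetic expert table (seed %d)",
                                            cfg$seed))
  attr(ds, "truth") <- situations
  ds
}
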