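test_that("signal generator honors its configuration and seed", {
  cfg <- signal_config(n_background = 6, n_seizure = 3, duration_s = 2,
                       rate_hz = 100, seed = 5)
  ss <- gen_signal_dataset(cfg)
  expect_length(ss$records, 9)
  labs <- vapply(ss$records, `[[`, character(1), "label")
  expect_equal(sum(labs == "background"), 6)
  expect_equal(sum(labs == "seizure"), 3)
  expect_length(ss$records[[1]]$samples, 200)

  ss2 <- gen_signal_dataset(cfg)
  expect_identical(lapply(ss$records, `[[`, "samples"),
                   lapply(ss2$records, `[[`, "samples"))
  expect_error(signal_config(duration_s = 0.001, rate_hz = 100), "at least 2")
})

test_that("signal mean power matches the closed-form generator expectation", {
  # E[x^2] = (tone amplitude^2)/2 + sigma^2 for background;
  # + effect^2 * mean(envelope^2)/2 for seizure, envelope = 0.5 + 0.5 sin
  cfg <- signal_config(n_background = 80, n_seizure = 80, duration_s = 10,
                       rate_hz = 100, effect_size = 2, noise_sd = 1, seed = 7)
  ss <- gen_signal_dataset(cfg)
  labs <- vapply(ss$records, `[[`, character(1), "label")
  pw <- vapply(ss$records, function(r) mean(r$samples^2), numeric(1))
  exp_bg <- 0.5 + 1
  env2 <- mean((0.5 + 0.5 * sin(2 * pi * 0.5 * (0:999) / 100))^2)
  exp_sz <- exp_bg + cfg$effect_size^2 * env2 / 2
  expect_equal(mean(pw[labs == "background"]), exp_bg, tolerance = 0.05)
  expect_equal(mean(pw[labs == "seizure"]), exp_sz, tolerance = 0.05)
})

test_that("noise-free tones are perfectly separated by their spectra", {
  cfg <- signal_config(n_background = 10, n_seizure = 10, duration_s = 4,
                       rate_hz = 100, effect_size = 3, noise_sd = 0, seed = 3)
  ss <- gen_signal_dataset(cfg)
  fm <- fft_features(segment_signals(ss$records, 2))
  # energy below 5 Hz separates the classes exactly
  low <- rowSums(fm$values[, 2:11])
  lo_rng <- range(low[fm$labels == "seizure"])
  hi_rng <- range(low[fm$labels == "background"])
  expect_gt(lo_rng[1], hi_rng[2])
})

test_that("wide generator produces the declared shape and mean shifts", {
  df <- gen_wide_dataset(wide_config(seed = 1))
  expect_equal(dim(df), c(78, 187))
  expect_equal(sum(df$class == "tumor"), 39)
  expect_gt(ncol(df) - 1, nrow(df))  # columns exceed rows

  # informative column means sit near +/- delta/2 (law of large numbers)
  big <- gen_wide_dataset(wide_config(n_samples = 400, n_features = 401,
                                      n_informative = 5, effect_size = 2,
                                      seed = 4))
  m_t <- mean(big$V1[big$class == "tumor"])
  m_c <- mean(big$V1[big$class == "control"])
  expect_equal(m_t, 1, tolerance = 0.2)
  expect_equal(m_c, -1, tolerance = 0.2)
  # null: no informative signal
  nul <- gen_wide_dataset(wide_config(effect_size = 0, seed = 4))
  expect_equal(mean(as.matrix(nul[, 1:186])), 0, tolerance = 0.05)
})

test_that("clinical generator mixes flags and markers with configured prevalence", {
  df <- gen_clinical_dataset(clinical_config(seed = 6))
  expect_equal(dim(df), c(177, 30))
  expect_equal(sum(vapply(df, is.character, logical(1))), 12)  # 11 flags + class

  big <- gen_clinical_dataset(clinical_config(n_samples = 4000,
                                              effect_size = 0, seed = 8))
  # with zero effect the flag prevalence equals its base rate
  p_hat <- mean(big$flag01 == "yes")
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  expect_equal(mean(big$class == "survived"), 0.7, tolerance = 0.03)
})

test_that("expert generator covers 10 of 16 situations and sharpens to crisp", {
  ds <- gen_expert_dataset(expert_config(seed = 9))
  expect_equal(n_samples(ds), 10)
  expect_equal(vapply(ds$attributes, function(a) length(a$terms), integer(1)),
               c(A1 = 2L, A2 = 2L, A3 = 4L, B = 3L), ignore_attr = TRUE)
  truth <- attr(ds, "truth")
  expect_equal(nrow(unique(truth[, 1:3])), 10)
  # memberships normalized
  for (m in ds$memberships) expect_equal(rowSums(m), rep(1, 10),
                                         tolerance = 1e-9)

  # crisp limit reproduces the structure function exactly
  crisp <- gen_expert_dataset(expert_config(seed = 9, certainty = Inf))
  tt <- attr(crisp, "truth")
  expect_true(all(crisp$memberships[["B"]][cbind(1:10, tt$b + 1)] == 1))
  expect_true(all(crisp$memberships[["A3"]][cbind(1:10, tt$a3 + 1)] == 1))
})

test_that("an fdt trained on fully covered sharp expert data recovers the structure function", {
  ds <- gen_expert_dataset(expert_config(n_samples = 16, certainty = 60,
                                         seed = 12))
  m <- fdt(ds, alpha = 0, beta = 1)
  dt <- decision_table(m)
  a1 <- as.integer(sub("A1_", "", dt$A1))
  a2 <- as.integer(sub("A2_", "", dt$A2))
  a3 <- as.integer(sub("A3_", "", dt$A3))
  want <- ifelse(a1 + a2 + a3 <= 1, "B0",
                 ifelse(a1 + a2 + a3 <= 3, "B1", "B2"))
  expect_equal(dt$class, want)
})

test_that("generators are deterministic given the seed", {
  expect_identical(gen_wide_dataset(wide_config(seed = 42)),
                   gen_wide_dataset(wide_config(seed = 42)))
  expect_identical(gen_clinical_dataset(clinical_config(seed = 42)),
                   gen_clinical_dataset(clinical_config(seed = 42)))
  e1 <- gen_expert_dataset(expert_config(seed = 42))
  e2 <- gen_expert_dataset(expert_config(seed = 42))
  expect_identical(e1$memberships, e2$memberships)
})
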