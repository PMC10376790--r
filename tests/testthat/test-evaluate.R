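test_that("confusion counts match manual tallies", {
  p <- rep("pos", 5); t <- rep("pos", 5)
  cc <- confusion_counts(p, t, "pos")
  expect_equal(cc[c("tp", "tn", "fp", "fn")],
               list(tp = 5, tn = 0, fp = 0, fn = 0))

  # complement of the truth: no correct decisions
  cc2 <- confusion_counts(c("a", "b", "a"), c("b", "a", "b"), "a")
  expect_equal(cc2$tp + cc2$tn, 0)

  set.seed(53)
  for (rep in 1:10) {
    pred <- sample(c("x", "y"), 10, TRUE)
    truth <- sample(c("x", "y"), 10, TRUE)
    cc3 <- confusion_counts(pred, truth, "x")
    expect_equal(cc3[c("tp", "tn", "fp", "fn")],
                 oracle_confusion(pred, truth, "x"))
  }
  expect_warning(confusion_counts(c("a", "a"), c("a", "a"), "zzz"), "absent")
  expect_error(confusion_counts("a", c("a", "b")), "equal length")
})

test_that("metrics follow their defining ratios", {
  m <- compute_metrics(list(tp = 3, tn = 5, fp = 1, fn = 1))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)

  # all-positive: specificity undefined, everything else 1
  m2 <- compute_metrics(list(tp = 7, tn = 0, fp = 0, fn = 0))
  expect_equal(m2$accuracy, 1)
  expect_true(is.na(m2$specificity))
  expect_equal(m2$f1, 1)

  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
})

test_that("f1 equals the harmonic mean of precision and sensitivity", {
  set.seed(59)
  for (rep in 1:50) {
    cts <- as.list(stats::setNames(sample(0:20, 4, TRUE),
                                   c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cts)) == 0) next
    m <- compute_metrics(cts)
    if (!is.na(m$precision) && !is.na(m$sensitivity) &&
        (m$precision + m$sensitivity) > 0) {
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity), tolerance = 1e-12)
    }
  }
})

test_that("accuracy is invariant to swapping the positive class", {
  set.seed(61)
  pred <- sample(c("a", "b"), 30, TRUE)
  truth <- sample(c("a", "b"), 30, TRUE)
  ma <- compute_metrics(confusion_counts(pred, truth, "a"))
  mb <- compute_metrics(confusion_counts(pred, truth, "b"))
  expect_equal(ma$accuracy, mb$accuracy)
  expect_equal(ma$sensitivity, mb$specificity)
  expect_equal(ma$specificity, mb$sensitivity)
})

test_that("multi-class reports carry per-class rows and a macro average", {
  pred <- c("a", "b", "c", "a", "b", "c", "a")
  truth <- c("a", "b", "c", "b", "b", "a", "a")
  rep_df <- classification_report(pred, truth)
  expect_equal(rep_df$positive_class, c("a", "b", "c", "macro"))
  for (i in 1:3) {
    r <- rep_df[i, ]
    if (!is.na(r$precision) && !is.na(r$sensitivity) &&
        r$precision + r$sensitivity > 0) {
      expect_equal(r$f1, 2 * r$precision * r$sensitivity /
                     (r$precision + r$sensitivity), tolerance = 1e-12)
    }
  }
  expect_equal(rep_df$accuracy[4], mean(rep_df$accuracy[1:3]))
})

test_that("hold-out splits are exhaustive, sized by half-up rounding, reproducible", {
  df <- gen_wide_dataset(wide_config(n_samples = 100, n_features = 101,
                                     seed = 2))
  sp <- holdout_split(df, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:100)

  sp2 <- holdout_split(df, 0.7, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)

  # boundary: train = K - 1
  sp3 <- holdout_split(df[1:10, ], 0.95, seed = 1)
  expect_equal(length(sp3$test_idx), 1)

  expect_error(holdout_split(df, 1.2), "train_fraction")
})

test_that("stratified splits preserve class proportions", {
  df <- data.frame(x = rnorm(60), class = rep(c("a", "b", "c"), c(30, 20, 10)))
  sp <- holdout_split(df, 0.7, stratified = TRUE, seed = 11)
  tr <- table(sp$train$class)
  expect_equal(as.numeric(tr), c(21, 14, 7))
  # a singleton class falls back with a warning
  df2 <- rbind(df, data.frame(x = 0, class = "rare"))
  expect_warning(holdout_split(df2, 0.7, stratified = TRUE, seed = 1),
                 "rare")
})

test_that("random subsampling composes split, fit and metrics", {
  df <- gen_clinical_dataset(clinical_config(n_samples = 70, seed = 13))
  ds <- fuzzify(df, class_col = "class")$dataset
  # reps = 1 equals a manual hold-out round (same derived seed)
  ev <- subsample_eval(ds, "fnb", reps = 1, seed = 100,
                       positive_class = "died")
  sp <- holdout_split(ds, 0.7, stratified = TRUE, seed = 101)
  model <- fnb(sp$train)
  pred <- predict(model, sp$test, type = "class")
  m <- compute_metrics(confusion_counts(pred, crisp_classes(sp$test), "died"))
  expect_equal(ev$per_rep$accuracy[1], m$accuracy)
  expect_equal(ev$per_rep$f1[1], m$f1)

  # determinism across runs
  ev2 <- subsample_eval(ds, "fnb", reps = 5, seed = 100,
                        positive_class = "died")
  ev3 <- subsample_eval(ds, "fnb", reps = 5, seed = 100,
                        positive_class = "died")
  expect_identical(ev2$per_rep, ev3$per_rep)
  expect_equal(ev2$summary$mean[1], mean(ev2$per_rep$accuracy))
})

test_that("perfectly separable data give mean accuracy 1 and sd 0", {
  df <- data.frame(x = c(rnorm(30, -10), rnorm(30, 10)),
                   class = rep(c("lo", "hi"), each = 30))
  ds <- fuzzify(df, class_col = "class", terms = 2)$dataset
  ev <- subsample_eval(ds, "fdt", reps = 4, seed = 9, positive_class = "hi",
                       alpha = 0.05, beta = 0.95)
  expect_equal(ev$summary$mean[ev$summary$metric == "accuracy"], 1)
  expect_equal(ev$summary$sd[ev$summary$metric == "accuracy"], 0)
})
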