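boolean_ds <- function(y) {
  # 4-row truth table over two binary attributes with outputs y (chars)
  df <- data.frame(x1 = c("0", "0", "1", "1"), x2 = c("0", "1", "0", "1"),
                   class = y)
  make_crisp_ds(df, "class",
                list(x1 = c("0", "1"), x2 = c("0", "1"),
                     class = c("0", "1")))
}

test_that("degenerate inductions produce single leaves", {
  ds <- boolean_ds(c("1", "1", "1", "1"))   # single observed class
  m <- fdt(ds, alpha = 0, beta = 1)
  expect_equal(fdt_size(m)[["nodes"]], 1)
  expect_equal(unname(predict(m, ds)[1, ]), c(0, 1))

  # alpha = 1: no split can retain full mass fraction below the root
  m2 <- fdt(boolean_ds(c("0", "1", "1", "0")), alpha = 1, beta = 1)
  expect_equal(fdt_size(m2)[["nodes"]], 1)

  # single sample is a single-leaf tree, not an error
  one <- make_crisp_ds(data.frame(x1 = "0", class = "1"), "class",
                       list(x1 = c("0", "1"), class = c("0", "1")))
  expect_equal(fdt_size(fdt(one))[["nodes"]], 1)

  expect_error(fdt(ds, alpha = -0.1), "alpha")
  expect_error(fdt(ds, beta = 1.1), "beta")
})

test_that("AND function induces the depth-2 tree chosen by the gain oracle", {
  ds <- boolean_ds(c("0", "0", "0", "1"))
  m <- fdt(ds, alpha = 0.01, beta = 0.99)
  tree <- oracle_id3(data.frame(x1 = c("0", "0", "1", "1"),
                                x2 = c("0", "1", "0", "1"),
                                class = c("0", "0", "0", "1")),
                     c("x1", "x2"), "class", c("0", "1"))
  expect_equal(fdt_structure(m), tree)
  expect_equal(fdt_size(m)[["depth"]], 2)
  expect_equal(predict(m, ds, type = "class"), c("0", "0", "0", "1"))
})

test_that("crisp induction equals classical information-gain trees on all Boolean functions", {
  grid <- expand.grid(a = c("0", "1"), b = c("0", "1"), c = c("0", "1"),
                      d = c("0", "1"), stringsAsFactors = FALSE)
  for (f in seq_len(nrow(grid))) {
    y <- unlist(grid[f, ])
    ds <- boolean_ds(y)
    m <- fdt(ds, alpha = 0, beta = 1)
    df <- data.frame(x1 = c("0", "0", "1", "1"), x2 = c("0", "1", "0", "1"),
                     class = y, stringsAsFactors = FALSE)
    tree <- oracle_id3(df, c("x1", "x2"), "class", c("0", "1"))
    expect_equal(fdt_structure(m), tree, label = paste("function", f))
    pred <- predict(m, ds, type = "class")
    oracle_pred <- vapply(1:4, function(i) oracle_id3_predict(tree, df[i, ]),
                          character(1))
    expect_equal(pred, unname(oracle_pred), label = paste("function", f))
    # consistent crisp data at alpha=0, beta=1 is separated perfectly
    expect_equal(mean(pred == y), 1)
  }
})

test_that("fuzzy inference aggregates path masses", {
  # depth-1 tree: mixed instance blends the two leaf confidences
  attrs <- list(fuzzy_attribute("A", c("lo", "hi"), "input"),
                fuzzy_attribute("B", c("c0", "c1"), "output"))
  train <- fuzzy_dataset(attrs, list(rbind(c(1, 0), c(0, 1)),
                                     rbind(c(1, 0), c(0, 1))))
  m <- fdt(train, alpha = 0, beta = 1)
  expect_equal(fdt_size(m)[["depth"]], 1)
  inst <- fuzzy_dataset(attrs, list(matrix(c(0.4, 0.6), 1),
                                    matrix(c(1, 0), 1)))
  leaf0 <- c(1, 0); leaf1 <- c(0, 1)
  expect_equal(unname(predict(m, inst)[1, ]),
               0.4 * leaf0 + 0.6 * leaf1, tolerance = 1e-12)
  # wrong membership arity is rejected
  bad_attrs <- list(fuzzy_attribute("A", c("a", "b", "c"), "input"),
                    fuzzy_attribute("B", c("c0", "c1"), "output"))
  bad <- fuzzy_dataset(bad_attrs, list(matrix(c(0.2, 0.3, 0.5), 1),
                                       matrix(c(1, 0), 1)))
  expect_error(predict(m, bad), "membership degrees")
})

test_that("prediction confidences are conserved and tie-breaks are stable", {
  set.seed(43)
  ds <- random_fuzzy_ds(40, m_in = c(2, 3, 2), m_out = 3)
  m <- fdt(ds, alpha = 0.05, beta = 0.9)
  conf <- predict(m, ds)
  expect_equal(rowSums(conf), rep(1, 40), tolerance = 1e-9)
  cls <- predict(m, ds, type = "class")
  expect_equal(cls, m$class_terms[max.col(conf, ties.method = "first")])
})

test_that("decision tables enumerate the Cartesian product of terms", {
  ds <- gen_expert_dataset(expert_config(seed = 5, certainty = Inf,
                                         n_samples = 16))
  m <- fdt(ds, alpha = 0, beta = 1)
  dt <- decision_table(m)
  expect_equal(nrow(dt), 16)  # 2 * 2 * 4 input-term combinations
  expect_equal(ncol(dt), 3 + 1 + 3)

  # binary single attribute -> 2 rows
  attrs <- list(fuzzy_attribute("A", c("lo", "hi"), "input"),
                fuzzy_attribute("B", c("c0", "c1"), "output"))
  small <- fuzzy_dataset(attrs, list(rbind(c(1, 0), c(0, 1)),
                                     rbind(c(1, 0), c(0, 1))))
  expect_equal(nrow(decision_table(fdt(small))), 2)

  # decision-table rows agree with re-classification of crisp instances
  redo <- decision_table(m)
  mems <- list()
  for (nm in c("A1", "A2", "A3")) {
    at <- m$attributes[[which(vapply(m$attributes, `[[`, character(1),
                                     "name") == nm)]]
    U <- matrix(0, nrow(redo), length(at$terms))
    U[cbind(seq_len(nrow(redo)), match(redo[[nm]], at$terms))] <- 1
    mems[[nm]] <- U
  }
  mems[["B"]] <- matrix(rep(c(1, 0, 0), each = nrow(redo)), nrow(redo))
  grid_ds <- fuzzy_dataset(m$attributes, mems)
  expect_equal(predict(m, grid_ds, type = "class"), redo$class)
})

test_that("tree size is monotone in the pruning parameters", {
  df <- gen_clinical_dataset(clinical_config(n_samples = 80, seed = 33))
  ds <- fuzzify(df, class_col = "class")$dataset
  sizes_a <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.6), function(a) {
    fdt_size(fdt(ds, alpha = a, beta = 0.95))[["nodes"]]
  }, numeric(1))
  expect_true(all(diff(sizes_a) <= 0))
  sizes_b <- vapply(c(0.5, 0.7, 0.85, 0.95, 1), function(b) {
    fdt_size(fdt(ds, alpha = 0.05, beta = b))[["nodes"]]
  }, numeric(1))
  expect_true(all(diff(sizes_b) >= 0))
})

test_that("rule and dot exports reflect the tree", {
  ds <- boolean_ds(c("0", "0", "0", "1"))
  m <- fdt(ds, alpha = 0, beta = 1)
  rules <- fdt_rules(m)
  expect_equal(length(rules), fdt_size(m)[["leaves"]])
  expect_true(any(grepl("THEN class 1", rules)))
  dot <- fdt_dot(m)
  expect_match(dot, "^digraph fdt \\{")
  expect_match(dot, "x1|x2")
})

test_that("fuzzy naive Bayes matches hand-computed posteriors", {
  # one crisp sample, smoothing 0: predicts its own class with confidence 1
  one <- make_crisp_ds(data.frame(x1 = "0", class = "1"), "class",
                       list(x1 = c("0", "1"), class = c("0", "1")))
  m1 <- fnb(one, smoothing = 0)
  expect_equal(unname(predict(m1, one)[1, ]), c(0, 1))

  # attribute identical across classes: posterior = prior
  df <- data.frame(x1 = c("0", "0", "0", "0"), class = c("0", "0", "0", "1"))
  ds <- make_crisp_ds(df, "class", list(x1 = c("0", "1"),
                                        class = c("0", "1")))
  m2 <- fnb(ds, smoothing = 0)
  expect_equal(unname(predict(m2, ds)[1, ]), c(0.75, 0.25), tolerance = 1e-9)

  # 4-row crisp toy set against the product rule by hand
  df3 <- data.frame(x1 = c("0", "0", "1", "1"), x2 = c("0", "1", "0", "1"),
                    class = c("0", "0", "1", "1"))
  ds3 <- make_crisp_ds(df3, "class",
                       list(x1 = c("0", "1"), x2 = c("0", "1"),
                            class = c("0", "1")))
  m3 <- fnb(ds3, smoothing = 0)
  # instance (x1=0, x2=0): P(0)*P(x1=0|0)*P(x2=0|0) = .5*1*.5 = .25
  #                        P(1)*P(x1=0|1)*P(x2=0|1) = .5*0*.5 = 0
  inst <- ds3[1]
  expect_equal(unname(predict(m3, inst)[1, ]), c(1, 0), tolerance = 1e-9)
  expect_equal(predict(m3, ds3, type = "class"), df3$class)
})

test_that("fuzzy naive Bayes posterior equals direct formula evaluation", {
  set.seed(47)
  ds <- random_fuzzy_ds(25, m_in = c(2, 3), m_out = 2)
  m <- fnb(ds, smoothing = 1)
  conf <- predict(m, ds)
  # direct evaluation for a handful of samples
  for (s in c(1, 7, 25)) {
    post <- m$priors
    for (nm in c("A1", "A2")) {
      mu <- ds$memberships[[nm]][s, ]
      post <- post * as.numeric(mu %*% m$conditionals[[nm]])
    }
    post <- post / sum(post)
    expect_equal(unname(conf[s, ]), unname(post), tolerance = 1e-9)
  }
  expect_equal(rowSums(conf), rep(1, 25), tolerance = 1e-9)
})

test_that("uniform fuzzy naive Bayes models give uniform posteriors", {
  attrs <- list(fuzzy_attribute("A", c("lo", "hi"), "input"),
                fuzzy_attribute("B", c("c0", "c1"), "output"))
  ds <- fuzzy_dataset(attrs, list(rbind(c(0.5, 0.5), c(0.5, 0.5)),
                                  rbind(c(1, 0), c(0, 1))))
  m <- fnb(ds, smoothing = 1)
  expect_equal(unname(predict(m, ds)[1, ]), c(0.5, 0.5), tolerance = 1e-9)
})
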