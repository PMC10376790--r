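# Independent oracles: deliberately naive re-implementations (explicit loops,
# no shared code with the package) used to cross-check the fast paths.

# direct-summation mutual information over a joint mass matrix, in bits
oracle_mi <- function(cells) {
  total <- 0
  for (j in seq_len(nrow(cells))) for (k in seq_len(ncol(cells))) {
    total <- total + cells[j, k]
  }
  p <- cells / total
  rowm <- numeric(nrow(p)); colm <- numeric(ncol(p))
  for (j in seq_len(nrow(p))) for (k in seq_len(ncol(p))) {
    rowm[j] <- rowm[j] + p[j, k]
    colm[k] <- colm[k] + p[j, k]
  }
  mi <- 0
  for (j in seq_len(nrow(p))) for (k in seq_len(ncol(p))) {
    if (p[j, k] > 1e-12) {
      mi <- mi + p[j, k] * log(p[j, k] / (rowm[j] * colm[k])) / log(2)
    }
  }
  mi
}

oracle_entropy <- function(q) {
  h <- 0
  for (v in q) if (v > 0) h <- h - v * log(v) / log(2)
  h
}

# textbook FCM alternating optimization on one dimension, same deterministic
# quantile initialization contract as the package
oracle_fcm <- function(x, m, q = 2, tol = 1e-6, max_iter = 300) {
  ux <- sort(unique(x))
  centers <- ux[round(seq(1, length(ux), length.out = m))]
  for (it in seq_len(max_iter)) {
    U <- matrix(0, length(x), m)
    for (i in seq_along(x)) {
      d <- abs(x[i] - centers)
      if (any(d < 1e-12)) {
        U[i, which(d < 1e-12)[1]] <- 1
      } else {
        for (j in seq_len(m)) {
          U[i, j] <- 1 / sum((d[j] / d)^(2 / (q - 1)))
        }
      }
    }
    newc <- numeric(m)
    for (j in seq_len(m)) {
      newc[j] <- sum(U[, j]^q * x) / sum(U[, j]^q)
    }
    shift <- max(abs(newc - centers))
    centers <- newc
    if (shift < tol) break
  }
  sort(centers)
}

# brute-force tally of one-vs-rest confusion counts
oracle_confusion <- function(pred, truth, pos) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == pos && truth[i] == pos) tp <- tp + 1
    else if (pred[i] != pos && truth[i] != pos) tn <- tn + 1
    else if (pred[i] == pos && truth[i] != pos) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# classical ID3 with information gain on a crisp data.frame; returns a
# comparable nested structure (split attribute names, leaf class labels).
# Tie-breaks: lowest attribute index, lowest class index.
oracle_id3 <- function(df, attrs, class_col, class_levels,
                       parent_majority = NULL) {
  y <- as.character(df[[class_col]])
  if (nrow(df) == 0) {
    return(list(leaf = parent_majority))
  }
  counts <- vapply(class_levels, function(cl) sum(y == cl), numeric(1))
  majority <- class_levels[which.max(counts)]
  if (length(unique(y)) == 1) return(list(leaf = y[1]))
  if (length(attrs) == 0) return(list(leaf = majority))
  h <- function(labels) {
    if (length(labels) == 0) return(0)
    p <- table(labels) / length(labels)
    oracle_entropy(as.numeric(p))
  }
  gains <- vapply(attrs, function(a) {
    g <- h(y)
    for (v in sort(unique(as.character(df[[a]])))) {
      sub <- y[df[[a]] == v]
      g <- g - length(sub) / length(y) * h(sub)
    }
    g
  }, numeric(1))
  best <- attrs[which(gains >= max(gains) - 1e-12)[1]]
  vals <- sort(unique(as.character(df[[best]])))
  kids <- lapply(vals, function(v) {
    oracle_id3(df[df[[best]] == v, , drop = FALSE], setdiff(attrs, best),
               class_col, class_levels, majority)
  })
  names(kids) <- vals
  list(split = best, children = kids)
}

oracle_id3_predict <- function(tree, row) {
  while (is.null(tree$leaf)) {
    tree <- tree$children[[as.character(row[[tree$split]])]]
  }
  tree$leaf
}

# build a crisp fuzzy_dataset from a data.frame of character columns, with
# explicitly declared term levels (so unobserved classes stay representable)
make_crisp_ds <- function(df, class_col, levels_list) {
  attrs <- list(); mems <- list()
  for (nm in names(levels_list)) {
    lv <- levels_list[[nm]]
    role <- if (nm == class_col) "output" else "input"
    attrs[[nm]] <- fuzzy_attribute(nm, lv, role)
    U <- matrix(0, nrow(df), length(lv))
    U[cbind(seq_len(nrow(df)), match(as.character(df[[nm]]), lv))] <- 1
    colnames(U) <- lv
    mems[[nm]] <- U
  }
  fuzzy_dataset(attrs, mems, "crisp test data")
}

# comparable structure of an fdt on crisp data: splits by attribute name,
# leaves by argmax class
fdt_structure <- function(model) {
  strip <- function(node) {
    if (node$type == "leaf") {
      return(list(leaf = model$class_terms[which.max(node$confidence)]))
    }
    at <- model$attributes[[node$attribute]]
    kids <- lapply(node$children, strip)
    names(kids) <- at$terms
    list(split = at$name, children = kids)
  }
  strip(model$root)
}

# random small fuzzy dataset (normalized memberships) for property tests
random_fuzzy_ds <- function(K, m_in = c(2, 3), m_out = 2) {
  rdirich <- function(n, m) {
    g <- matrix(stats::rgamma(n * m, shape = 1), n, m)
    g / rowSums(g)
  }
  attrs <- list(); mems <- list()
  for (i in seq_along(m_in)) {
    nm <- paste0("A", i)
    attrs[[nm]] <- fuzzy_attribute(nm, paste0("t", seq_len(m_in[i])), "input")
    mems[[nm]] <- rdirich(K, m_in[i])
  }
  attrs[["B"]] <- fuzzy_attribute("B", paste0("c", seq_len(m_out)), "output")
  mems[["B"]] <- rdirich(K, m_out)
  fuzzy_dataset(attrs, mems, "random fuzzy")
}
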