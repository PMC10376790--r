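#' Induct a fuzzy decision tree
#'
#' Recursive top-down induction of a fuzzy decision tree (FDT). Each sample
#' enters the root with unit membership mass; a split on attribute `A_i`
#' sends t-norm-combined mass down one branch per linguistic term. At every
#' node the candidate split is the unused input attribute with the largest
#' [fuzzy_mutual_information()] against the output on the node-restricted
#' frequency table (ties go to the lowest attribute index).
#'
#' A node becomes a leaf when any of these holds:
#' * its dominant-class confidence reaches `beta`;
#' * its membership mass fraction `M_node / M_total` does not exceed `alpha`
#'   (so `alpha = 1` keeps even the root from expanding);
#' * no unused attribute remains.
#'
#' Hence decreasing `alpha` or increasing `beta` grows the tree, and the
#' converse shrinks it. Leaf confidence is the normalized class membership
#' mass reaching the leaf; a zero-mass branch becomes a leaf inheriting its
#' parent's confidence. Attributes are never reused along a path.
#'
#' @param ds A [fuzzy_dataset()].
#' @param alpha Minimum node mass fraction required to keep expanding, in
#'   `[0, 1]`. Default 0.05.
#' @param beta Dominant-confidence threshold at which a node becomes a leaf,
#'   in `[0, 1]`. Default 0.95.
#' @param tnorm Conjunction for joint masses and branch accumulation:
#'   `"product"` (default) or `"min"`.
#' @return An object of class `fdt` with the tree in `$root`, the pruning
#'   parameters, attribute metadata and an induction log (one row per split:
#'   node id, depth, attribute, information score, node mass).
#' @seealso [predict.fdt()], [decision_table()], [fdt_rules()], [fdt_size()]
#' @examples
#' ds <- gen_expert_dataset(expert_config(seed = 7, certainty = Inf,
#'                                        n_samples = 16))
#' model <- fdt(ds, alpha = 0, beta = 1)
#' model
#' @export
fdt <- function(ds, alpha = 0.05, beta = 0.95,
                tnorm = c("product", "min")) {
  stopifnot(inherits(ds, "fuzzy_dataset"))
  tnorm <- match.arg(tnorm)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  if (!is.numeric(beta) || beta < 0 || beta > 1) stop("'beta' must be in [0, 1]")

  B <- output_memberships(ds)
  in_idx <- input_indices(ds)
  K <- n_samples(ds)
  M_total <- K
  log_rows <- list()
  node_id <- 0L

  build <- function(w, unused, parent_conf, depth) {
    node_id <<- node_id + 1L
    this_id <- node_id
    mass <- sum(w)
    if (mass < 1e-12) {
      return(list(type = "leaf", confidence = parent_conf, mass = 0))
    }
    class_mass <- as.numeric(crossprod(B, w))
    conf <- class_mass / sum(class_mass)
    leaf <- list(type = "leaf", confidence = conf, mass = mass)
    if (max(conf) >= beta - 1e-9) return(leaf)
    if (mass / M_total <= alpha) return(leaf)  # expand only above alpha
    if (length(unused) == 0L) return(leaf)

    scores <- vapply(unused, function(i) {
      ft <- fuzzy_frequency_table(ds, i, weights = w, tnorm = tnorm)
      if (ft$total <= 0) return(-Inf)
      as.numeric(fuzzy_mutual_information(ft))
    }, numeric(1))
    if (all(!is.finite(scores))) return(leaf)
    best <- unused[which(scores >= max(scores) - 1e-12)[1L]]
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      node = this_id, depth = depth,
      attribute = ds$attributes[[best]]$name,
      score = max(scores), mass = mass)

    A <- ds$memberships[[best]]
    children <- lapply(seq_len(ncol(A)), function(j) {
      build(tnorm_apply(w, A[, j], tnorm), setdiff(unused, best), conf,
            depth + 1L)
    })
    names(children) <- ds$attributes[[best]]$terms
    list(type = "split", attribute = best, score = max(scores),
         mass = mass, confidence = conf, children = children)
  }

  root_conf <- {
    cm <- colSums(B)
    cm / sum(cm)
  }
  root <- build(rep(1, K), in_idx, root_conf, 0L)
  structure(list(root = root, alpha = alpha, beta = beta, tnorm = tnorm,
                 attributes = ds$attributes,
                 output_index = ds$output_index,
                 class_terms = ds$attributes[[ds$output_index]]$terms,
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame(node = integer(), depth = integer(),
                                       attribute = character(),
                                       score = numeric(), mass = numeric())),
            class = "fdt")
}

walk_tree <- function(node, f_leaf, f_split, path = list()) {
  if (node$type == "leaf") return(list(f_leaf(node, path)))
  out <- list()
  for (j in seq_along(node$children)) {
    out <- c(out, walk_tree(node$children[[j]], f_leaf, f_split,
                            c(path, list(list(attr = node$attribute, term = j)))))
  }
  out
}

#' Size of a fuzzy decision tree
#'
#' @param model An [fdt()] model.
#' @return Named numeric vector: `nodes` (total), `leaves`, `depth`.
#' @export
fdt_size <- function(model) {
  stopifnot(inherits(model, "fdt"))
  count <- function(node, d) {
    if (node$type == "leaf") return(c(nodes = 1, leaves = 1, depth = d))
    kid <- vapply(node$children, count, numeric(3), d = d + 1)
    c(nodes = 1 + sum(kid["nodes", ]), leaves = sum(kid["leaves", ]),
      depth = max(kid["depth", ]))
  }
  count(model$root, 0)
}

#' Classify instances with a fuzzy decision tree
#'
#' Inference aggregates over every root-to-leaf path: the instance's branch
#' memberships are combined with the model's t-norm along the path, the leaf
#' confidence is weighted by the resulting path mass, and the contributions
#' are summed and renormalized to a class-confidence vector. A crisp instance
#' follows exactly one path.
#'
#' @param object An [fdt()] model.
#' @param newdata A [fuzzy_dataset()] with the model's input attributes
#'   (term counts must match; the output attribute, if present, is ignored).
#' @param type `"confidence"` (default) for the `K x classes` confidence
#'   matrix, `"class"` for the crisp argmax labels (ties to the lowest class
#'   index).
#' @param ... Unused.
#' @return A confidence matrix or a character vector of class labels.
#' @export
predict.fdt <- function(object, newdata, type = c("confidence", "class"), ...) {
  type <- match.arg(type)
  mems <- align_inputs(object, newdata)
  K <- nrow(mems[[1L]])
  nc <- length(object$class_terms)
  acc <- matrix(0, K, nc, dimnames = list(NULL, object$class_terms))
  traverse <- function(node, w) {
    if (node$type == "leaf") {
      acc <<- acc + w %o% node$confidence
      return(invisible(NULL))
    }
    A <- mems[[node$attribute]]
    for (j in seq_len(ncol(A))) {
      wj <- tnorm_apply(w, A[, j], object$tnorm)
      if (any(wj > 0)) traverse(node$children[[j]], wj)
    }
  }
  traverse(object$root, rep(1, K))
  rs <- rowSums(acc)
  zero <- rs < 1e-300
  if (any(zero)) acc[zero, ] <- 1 / nc
  acc <- acc / rowSums(acc)
  if (type == "class") {
    object$class_terms[max.col(acc, ties.method = "first")]
  } else {
    acc
  }
}

# Align a fuzzy_dataset's input memberships to a model's attribute slots,
# matching by attribute name and validating term counts.
align_inputs <- function(model, newdata) {
  stopifnot(inherits(newdata, "fuzzy_dataset"))
  in_idx <- setdiff(seq_along(model$attributes), model$output_index)
  mems <- vector("list", length(model$attributes))
  for (i in in_idx) {
    at <- model$attributes[[i]]
    m <- newdata$memberships[[at$name]]
    if (is.null(m)) stop("newdata lacks input attribute '", at$name, "'")
    if (ncol(m) != length(at$terms)) {
      stop("attribute '", at$name, "': expected ", length(at$terms),
           " membership degrees, got ", ncol(m))
    }
    mems[[i]] <- m
  }
  mems
}

#' Exhaustive decision table of a fuzzy decision tree
#'
#' Enumerates every combination of crisp input terms (the Cartesian product
#' of the model's linguistic terms), classifies each combination as a crisp
#' instance, and reports the predicted class and class confidences. A model
#' over attributes with 2, 2 and 4 terms yields 16 rows. The decision table
#' is the complete knowledge representation the classifier induces from an
#' (often incompletely specified) training table.
#'
#' @param model An [fdt()] model.
#' @return A `data.frame` with one term column per input attribute, the
#'   predicted `class`, and one `conf_<class>` column per class.
#' @export
decision_table <- function(model) {
  stopifnot(inherits(model, "fdt"))
  in_idx <- setdiff(seq_along(model$attributes), model$output_index)
  term_lists <- lapply(model$attributes[in_idx], `[[`, "terms")
  names(term_lists) <- vapply(model$attributes[in_idx], `[[`, character(1), "name")
  grid <- expand.grid(term_lists, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  K <- nrow(grid)
  mems <- list()
  for (nm in names(term_lists)) {
    tl <- term_lists[[nm]]
    U <- matrix(0, K, length(tl), dimnames = list(NULL, tl))
    U[cbind(seq_len(K), match(grid[[nm]], tl))] <- 1
    mems[[nm]] <- U
  }
  attrs <- c(model$attributes[in_idx],
             list(model$attributes[[model$output_index]]))
  B <- matrix(0, K, length(model$class_terms))
  B[, 1L] <- 1  # placeholder output, ignored by predict
  mems[[model$attributes[[model$output_index]]$name]] <- B
  ds <- fuzzy_dataset(attrs, mems, "decision table grid")
  conf <- predict(model, ds)
  grid$class <- model$class_terms[max.col(conf, ties.method = "first")]
  conf_df <- as.data.frame(conf)
  names(conf_df) <- paste0("conf_", model$class_terms)
  cbind(grid, conf_df)
}

#' Export a fuzzy decision tree as human-readable rules
#'
#' @param model An [fdt()] model.
#' @return Character vector, one `IF ... THEN class ... [confidence]` rule
#'   per leaf.
#' @export
fdt_rules <- function(model) {
  stopifnot(inherits(model, "fdt"))
  rules <- walk_tree(model$root, function(leaf, path) {
    cond <- if (length(path) == 0L) "TRUE" else {
      paste(vapply(path, function(p) {
        at <- model$attributes[[p$attr]]
        sprintf("%s is %s", at$name, at$terms[p$term])
      }, character(1)), collapse = " AND ")
    }
    k <- which.max(leaf$confidence)
    sprintf("IF %s THEN class %s [%.2f]", cond, model$class_terms[k],
            leaf$confidence[k])
  })
  unlist(rules)
}

#' DOT (Graphviz) export of a fuzzy decision tree
#'
#' @param model An [fdt()] model.
#' @return A single string with the DOT source of the tree.
#' @export
fdt_dot <- function(model) {
  stopifnot(inherits(model, "fdt"))
  lines <- c("digraph fdt {", "  node [shape=box];")
  counter <- 0L
  emit <- function(node) {
    counter <<- counter + 1L
    id <- sprintf("n%d", counter)
    if (node$type == "leaf") {
      k <- which.max(node$confidence)
      lines <<- c(lines, sprintf(
        "  %s [label=\"%s\\n%.2f\", shape=ellipse];",
        id, model$class_terms[k], node$confidence[k]))
      return(id)
    }
    at <- model$attributes[[node$attribute]]
    lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, at$name))
    for (j in seq_along(node$children)) {
      cid <- emit(node$children[[j]])
      lines <<- c(lines, sprintf("  %s -> %s [label=\"%s\"];",
                                 id, cid, at$terms[j]))
    }
    id
  }
  emit(model$root)
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.fdt <- function(x, ...) {
  sz <- fdt_size(x)
  cat(sprintf("Fuzzy decision tree (alpha = %g, beta = %g, %s t-norm)\n",
              x$alpha, x$beta, x$tnorm))
  cat(sprintf("  %d nodes, %d leaves, depth %d; classes: %s\n",
              sz["nodes"], sz["leaves"], sz["depth"],
              paste(x$class_terms, collapse = ", ")))
  invisible(x)
}

#' @export
summary.fdt <- function(object, ...) {
  sz <- fdt_size(object)
  cat(sprintf("Fuzzy decision tree: %d nodes (%d leaves), depth %d\n",
              sz["nodes"], sz["leaves"], sz["depth"]))
  cat(sprintf("Pruning: alpha = %g, beta = %g; t-norm: %s\n",
              object$alpha, object$beta, object$tnorm))
  if (nrow(object$log) > 0L) {
    cat("Splits (information score per node):\n")
    print(object$log, row.names = FALSE)
  } else {
    cat("No splits: single-leaf tree\n")
  }
  invisible(object)
}

#' Plot a fuzzy decision tree
#'
#' Draws the tree with base graphics: internal nodes labeled by split
#' attribute, edges by linguistic term, leaves by dominant class and
#' confidence.
#'
#' @param x An [fdt()] model.
#' @param ... Unused.
#' @export
plot.fdt <- function(x, ...) {
  # assign leaf x-positions left-to-right, internal nodes centered over kids
  pos <- list()
  leaf_x <- 0
  layout_node <- function(node, depth) {
    if (node$type == "leaf") {
      leaf_x <<- leaf_x + 1
      k <- which.max(node$confidence)
      return(list(x = leaf_x, y = -depth,
                  label = sprintf("%s\n%.2f", x$class_terms[k],
                                  node$confidence[k]),
                  leaf = TRUE, edges = list()))
    }
    kids <- lapply(node$children, layout_node, depth = depth + 1)
    at <- x$attributes[[node$attribute]]
    me <- list(x = mean(vapply(kids, `[[`, numeric(1), "x")), y = -depth,
               label = at$name, leaf = FALSE,
               edges = lapply(seq_along(kids), function(j) {
                 list(to = kids[[j]], term = at$terms[j])
               }))
    me
  }
  root <- layout_node(x$root, 0)
  xs <- c(); ys <- c()
  collect <- function(n) {
    xs <<- c(xs, n$x); ys <<- c(ys, n$y)
    for (e in n$edges) collect(e$to)
  }
  collect(root)
  graphics::plot(NA, xlim = range(xs) + c(-0.5, 0.5),
                 ylim = range(ys) + c(-0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", ...)
  draw <- function(n) {
    for (e in n$edges) {
      graphics::segments(n$x, n$y, e$to$x, e$to$y, col = "grey50")
      graphics::text((n$x + e$to$x) / 2, (n$y + e$to$y) / 2, e$term,
                     cex = 0.7, col = "grey30")
      draw(e$to)
    }
    graphics::text(n$x, n$y, n$label, cex = 0.8,
                   font = if (n$leaf) 1 else 2)
  }
  draw(root)
  invisible(x)
}
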