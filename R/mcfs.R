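#' Parameters for a Monte Carlo feature-selection run
#'
#' Bundles every tunable of the MCFS-ID procedure. The defaults follow the
#' conventional settings of Monte Carlo feature selection on wide omics
#' tables: feature projections of size `m = 200`, disjoint-block projection
#' sampling (`mode = 2`) so that every feature is evaluated equally often,
#' `t = 5` train/test splits per projection with a 0.66 train fraction,
#' relative-importance exponents `u = v = 1`, and a permutation cutoff built
#' from 20 label-permuted runs.
#'
#' @param m features per projection ("splitSetSize"); clamped to the number
#'   of available features at run time.
#' @param s total number of projections. `NULL` (default) chooses `s` so that
#'   each feature is evaluated in at least `projections_per_feature`
#'   projections.
#' @param t train/test splits per projection.
#' @param train_fraction fraction of samples used to grow each tree; the
#'   remainder scores the tree's predictive quality.
#' @param u,v exponents weighting tree quality and node sample fraction in
#'   the relative-importance score.
#' @param n_perm number of label permutations for the significance cutoff.
#' @param mode projection sampling: `2` partitions the features into disjoint
#'   random blocks of size `m` per sweep; `1` draws `m` features uniformly
#'   and independently for every projection.
#' @param task `"classification"` or `"regression"`.
#' @param projections_per_feature target evaluation count per feature used
#'   when `s` is `NULL`.
#' @param cutoff_quantile quantile of the permuted max-RI values used as the
#'   significance cutoff.
#' @param cutoff_method `"max_percentile"` (default; quantile of permuted
#'   maxima, controls family-wise error) or `"mean_t"` (mean plus one-sided
#'   t-interval of the permuted maxima).
#' @param min_split minimum node size eligible for splitting.
#' @param seed integer seed making the whole run reproducible.
#' @return A list of class `mcfs_params`.
#' @export
mcfs_params <- function(m = 200L, s = NULL, t = 5L, train_fraction = 0.66,
                        u = 1, v = 1, n_perm = 20L, mode = 2L,
                        task = c("classification", "regression"),
                        projections_per_feature = 30L,
                        cutoff_quantile = 0.95,
                        cutoff_method = c("max_percentile", "mean_t"),
                        min_split = 5L, seed = 123L) {
  task <- match.arg(task)
  cutoff_method <- match.arg(cutoff_method)
  if (m < 2) stop_input("m (features per projection) must be >= 2")
  if (!is.null(s) && s < 1) stop_input("s must be >= 1")
  if (t < 1) stop_input("t must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_input("train_fraction must be in (0, 1)")
  }
  if (u < 0 || v < 0) stop_input("u and v must be >= 0")
  if (n_perm < 1) stop_input("n_perm must be >= 1")
  if (!mode %in% c(1L, 2L)) stop_input("mode must be 1 or 2")
  structure(list(
    m = as.integer(m), s = if (is.null(s)) NULL else as.integer(s),
    t = as.integer(t), train_fraction = train_fraction, u = u, v = v,
    n_perm = as.integer(n_perm), mode = as.integer(mode), task = task,
    projections_per_feature = as.integer(projections_per_feature),
    cutoff_quantile = cutoff_quantile, cutoff_method = cutoff_method,
    min_split = as.integer(min_split), seed = as.integer(seed)
  ), class = "mcfs_params")
}

#' Shannon entropy of class counts, in bits
#'
#' @param counts nonnegative class counts with positive sum.
#' @return Entropy in bits, between 0 and `log2(length(counts))`.
#' @examples
#' entropy(c(5, 5)) # 1 bit
#' @export
entropy <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    stop_input("counts must be nonnegative with positive sum")
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a binary split, in bits
#'
#' `IG = H(parent) - sum_c (n_c / n_p) H(child_c)`.
#'
#' @param parent,left,right class label vectors of the parent node and its
#'   two children (`left` and `right` together must partition `parent`).
#' @return Information gain in bits (nonnegative up to rounding).
#' @export
information_gain <- function(parent, left, right) {
  if (length(left) + length(right) != length(parent)) {
    stop_input("children must partition the parent samples")
  }
  lv <- unique(parent)
  h <- function(x) {
    if (length(x) == 0) return(0)
    entropy(tabulate(match(x, lv), nbins = length(lv)))
  }
  n <- length(parent)
  h(parent) - length(left) / n * h(left) - length(right) / n * h(right)
}

#' Variance reduction of a binary split (regression analogue)
#'
#' Population-variance convention:
#' `VR = Var(parent) - sum_c (n_c / n_p) Var(child_c)`.
#'
#' @param parent numeric values at the parent node.
#' @param children list of numeric vectors partitioning `parent`.
#' @return Variance reduction in squared value units.
#' @export
variance_reduction <- function(parent, children) {
  if (sum(lengths(children)) != length(parent)) {
    stop_input("children must partition the parent samples")
  }
  pvar <- function(x) if (length(x) == 0) 0 else mean((x - mean(x))^2)
  n <- length(parent)
  pvar(parent) - sum(vapply(
    children,
    function(ch) length(ch) / n * pvar(ch), numeric(1)
  ))
}

#' Weighted (class-balanced) accuracy
#'
#' Mean of the per-class accuracies over the classes present in `y_true`;
#' insensitive to class imbalance.
#'
#' @param y_true,y_pred observed and predicted labels.
#' @return wAcc in `[0, 1]`.
#' @export
weighted_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_input("length mismatch")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  cls <- unique(y_true)
  mean(vapply(cls, function(c) {
    mean(y_pred[y_true == c] == c)
  }, numeric(1)))
}

#' Grow a single decision or regression tree
#'
#' Greedy binary CART-style induction: each node takes the
#' (feature, threshold) split maximising information gain (classification,
#' bits) or population-variance reduction (regression); thresholds are
#' midpoints of consecutive distinct sorted values; growth stops at pure
#' nodes, nodes below `min_split`, or when no split has positive gain.
#' Ties between equal-gain splits go to the feature earlier in column order
#' and then to the smaller threshold, making the tree fully deterministic.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param y factor (classification) or numeric vector (regression).
#' @param task `"classification"` or `"regression"`.
#' @param min_split minimum node size eligible for splitting.
#' @return An object of class `mcfs_tree`: a list with a `nodes` data frame
#'   (`feature`, `threshold`, `ig`, `n`, `left`, `right`, `parent`, `pred`),
#'   the `task`, and factor `classes` when classifying.
#' @export
build_tree <- function(x, y, task = c("classification", "regression"),
                       min_split = 5L) {
  task <- match.arg(task)
  x <- as_values(x)
  if (nrow(x) < 2) stop_input("need at least 2 samples")
  if (ncol(x) < 1) stop_input("need at least 1 feature")
  if (length(y) != nrow(x)) stop_input("y length must match nrow(x)")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  classes <- NULL
  if (task == "classification") {
    y <- factor(y)
    classes <- levels(y)
    yc <- as.numeric(y) - 1
    raw <- .cpp_build_tree(x, yc, TRUE, length(classes), as.integer(min_split))
  } else {
    y <- as.numeric(y)
    if (anyNA(y)) stop_input("y must not contain NA")
    raw <- .cpp_build_tree(x, y, FALSE, 0L, as.integer(min_split))
  }
  nodes <- data.frame(
    feature = ifelse(raw$feature > 0, colnames(x)[pmax(raw$feature, 1L)], NA),
    threshold = raw$threshold, ig = raw$ig, n = raw$n,
    left = raw$left, right = raw$right, parent = 0L, pred = raw$pred,
    stringsAsFactors = FALSE
  )
  nodes$feature[raw$feature == 0] <- NA_character_
  kids <- c(nodes$left, nodes$right)
  par <- rep(seq_len(nrow(nodes)), 2L)
  nodes$parent[kids[kids > 0]] <- par[kids > 0]
  structure(list(nodes = nodes, task = task, classes = classes),
    class = "mcfs_tree"
  )
}

#' @export
predict.mcfs_tree <- function(object, newdata, ...) {
  x <- as_values(newdata)
  nd <- object$nodes
  feat_idx <- match(nd$feature, colnames(x))
  if (any(is.na(feat_idx) & !is.na(nd$feature))) {
    stop_input("newdata is missing features used by the tree")
  }
  feat_idx[is.na(feat_idx)] <- 0L
  p <- .cpp_predict_tree(
    as.integer(feat_idx), nd$threshold, as.integer(nd$left),
    as.integer(nd$right), nd$pred, x
  )
  if (object$task == "classification") {
    factor(object$classes[p], levels = object$classes)
  } else {
    p
  }
}

# Held-out quality of a fitted tree: wAcc for classification, max(0, Pearson
# correlation between predictions and truth) for regression.
tree_quality <- function(tree, x_test, y_test) {
  pred <- predict(tree, x_test)
  if (tree$task == "classification") {
    weighted_accuracy(y_test, pred)
  } else {
    if (stats::sd(pred) == 0 || stats::sd(y_test) == 0) return(0)
    max(0, stats::cor(pred, y_test))
  }
}

#' Relative-importance contributions of one fitted tree
#'
#' For a tree with held-out quality `q`, each node splitting on feature `g`
#' contributes `q^u * IG(node) * (n(node) / n(root))^v` to `RI(g)`.
#'
#' @param nodes a tree's `nodes` data frame (see [build_tree()]), or an
#'   `mcfs_tree`.
#' @param q held-out tree quality in `[0, 1]`.
#' @param u,v RI exponents.
#' @return Named numeric vector of per-feature RI contributions.
#' @export
accumulate_ri <- function(nodes, q, u = 1, v = 1) {
  if (inherits(nodes, "mcfs_tree")) nodes <- nodes$nodes
  internal <- !is.na(nodes$feature)
  if (!any(internal)) return(stats::setNames(numeric(0), character(0)))
  contrib <- q^u * nodes$ig[internal] *
    (nodes$n[internal] / nodes$n[1])^v
  rowsum(contrib, nodes$feature[internal])[, 1]
}

#' Interdependency (ID) edges of one fitted tree
#'
#' Every directly nested pair of split nodes (parent node on feature `a`,
#' child node on feature `b`) contributes
#' `IG(child) * n(child) / n(parent)` to the directed edge `a -> b`.
#'
#' @inheritParams accumulate_ri
#' @return Data frame with columns `parent`, `child`, `weight`.
#' @export
id_edges <- function(nodes) {
  if (inherits(nodes, "mcfs_tree")) nodes <- nodes$nodes
  internal <- which(!is.na(nodes$feature))
  keep <- internal[nodes$parent[internal] > 0]
  keep <- keep[!is.na(nodes$feature[nodes$parent[keep]])]
  if (length(keep) == 0) {
    return(data.frame(
      parent = character(0), child = character(0),
      weight = numeric(0), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    parent = nodes$feature[nodes$parent[keep]],
    child = nodes$feature[keep],
    weight = nodes$ig[keep] * nodes$n[keep] / nodes$n[nodes$parent[keep]],
    stringsAsFactors = FALSE
  )
}

#' Accumulate an ID-graph over a forest
#'
#' @param trees list of `mcfs_tree` objects (or node data frames).
#' @return Data frame (`parent`, `child`, `weight`) with weights summed over
#'   all trees, sorted by decreasing weight (ties by endpoints).
#' @export
compute_id_graph <- function(trees) {
  parts <- lapply(trees, id_edges)
  aggregate_id_edges(do.call(rbind, parts))
}

aggregate_id_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) {
    return(data.frame(
      parent = character(0), child = character(0),
      weight = numeric(0), stringsAsFactors = FALSE
    ))
  }
  key <- paste(edges$parent, edges$child, sep = "\r")
  w <- rowsum(edges$weight, key)
  parts <- strsplit(rownames(w), "\r", fixed = TRUE)
  out <- data.frame(
    parent = vapply(parts, `[`, character(1), 1L),
    child = vapply(parts, `[`, character(1), 2L),
    weight = w[, 1], stringsAsFactors = FALSE
  )
  out <- out[order(-out$weight, out$parent, out$child), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the Monte Carlo feature-selection and interdependency procedure
#'
#' Grows `s * t` decision (or regression) trees on random feature
#' projections, accumulates per-feature relative importance
#' `RI(g) = sum_trees q^u * sum_nodes IG * (n_node / n_root)^v`,
#' builds the directed feature-interdependency graph, and (optionally)
#' computes a permutation significance cutoff by rerunning the whole
#' procedure `n_perm` times on permuted targets and taking a quantile of the
#' permuted max-RI values.
#'
#' @param x numeric matrix (samples x features) with unique column names and
#'   no missing values.
#' @param y target: factor/character for classification, numeric for
#'   regression (length `nrow(x)`).
#' @param params an [mcfs_params()] object.
#' @param compute_cutoff compute the permutation cutoff (default `TRUE`).
#' @return A list of class `mcfs_result`: `ranking` (data frame `feature`,
#'   `ri`, `rank`, `significant`), `cutoff`, `id_graph`, `mean_quality`,
#'   `n_trees`, and the `params` used.
#' @export
run_mcfs <- function(x, y, params = mcfs_params(), compute_cutoff = TRUE) {
  x <- as_values(x)
  if (anyNA(x)) stop_input("x must not contain missing values")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop_input("x must have unique column names")
  }
  if (length(y) != nrow(x)) stop_input("target length must equal sample count")
  classification <- params$task == "classification"
  if (classification) {
    y <- factor(y)
    if (nlevels(y) < 2) stop_input("classification needs >= 2 classes")
  } else {
    y <- as.numeric(y)
  }
  p <- ncol(x)
  m <- params$m
  if (m > p) {
    warning(sprintf("m = %d exceeds %d available features; clamped", m, p))
    m <- p
  }

  fit <- with_seed(params$seed, mcfs_forest_pass(x, y, params, m))

  ri <- fit$ri
  ord <- order(-ri, names(ri))
  ranking <- data.frame(
    feature = names(ri)[ord], ri = unname(ri[ord]),
    rank = seq_along(ri), stringsAsFactors = FALSE
  )
  cutoff <- NA_real_
  if (compute_cutoff) {
    cutoff <- permutation_cutoff(x, y, params)
  }
  ranking$significant <- !is.na(cutoff) & ranking$ri > cutoff
  structure(list(
    ranking = ranking, cutoff = cutoff, id_graph = fit$id_graph,
    mean_quality = fit$mean_quality, n_trees = fit$n_trees, params = params
  ), class = "mcfs_result")
}

# One full projection/tree pass; assumes the RNG is already seeded. Works
# on raw integer node vectors from the compiled tree builder to keep the
# per-tree overhead low over tens of thousands of trees.
mcfs_forest_pass <- function(x, y, params, m) {
  p <- ncol(x)
  n <- nrow(x)
  classification <- params$task == "classification"
  n_blocks <- as.integer(ceiling(p / m))
  s <- params$s %||% (params$projections_per_feature * n_blocks)

  projections <- list()
  if (params$mode == 2L) {
    n_sweeps <- ceiling(s / n_blocks)
    for (sw in seq_len(n_sweeps)) {
      perm <- sample.int(p)
      blocks <- split(perm, ceiling(seq_along(perm) / m))
      if (length(blocks) > 1 && length(blocks[[length(blocks)]]) < 2) {
        blocks[[length(blocks) - 1]] <-
          c(blocks[[length(blocks) - 1]], blocks[[length(blocks)]])
        blocks[[length(blocks)]] <- NULL
      }
      projections <- c(projections, blocks)
    }
    projections <- projections[seq_len(min(s, length(projections)))]
  } else {
    projections <- lapply(seq_len(s), function(i) sample.int(p, m))
  }

  if (classification) {
    yf <- factor(y)
    ycode <- as.numeric(yf) - 1
    nclass <- nlevels(yf)
  }
  yn <- if (classification) ycode else as.numeric(y)

  ri <- stats::setNames(numeric(p), colnames(x))
  edge_pf <- vector("list", length(projections) * params$t)
  edge_cf <- edge_pf
  edge_w <- edge_pf
  q_sum <- 0
  n_trees <- 0L
  n_train <- max(2L, round(params$train_fraction * n))
  if (n_train >= n) n_train <- n - 1L
  cn <- colnames(x)

  for (proj in projections) {
    cols <- proj[order(cn[proj])] # lexicographic tie-break order
    xs <- x[, cols, drop = FALSE]
    for (split_i in seq_len(params$t)) {
      train <- sample.int(n, n_train)
      if (classification) {
        tries <- 0L
        while (length(unique(yn[train])) < 2 && tries < 25L) {
          train <- sample.int(n, n_train)
          tries <- tries + 1L
        }
        if (length(unique(yn[train])) < 2) {
          warning("could not draw a training split with 2 classes; skipped")
          next
        }
      }
      test <- which(!seq_len(n) %in% train)
      raw <- .cpp_build_tree(
        xs[train, , drop = FALSE],
        if (classification) yn[train] else yn[train],
        classification, if (classification) nclass else 0L,
        params$min_split
      )
      pred <- .cpp_predict_tree(
        raw$feature, raw$threshold, raw$left, raw$right, raw$pred,
        xs[test, , drop = FALSE]
      )
      yt <- yn[test]
      if (classification) {
        predc <- pred - 1
        present <- unique(yt)
        q <- mean(vapply(
          present,
          function(cc) mean(predc[yt == cc] == cc), numeric(1)
        ))
      } else {
        q <- if (stats::sd(pred) == 0 || stats::sd(yt) == 0) {
          0
        } else {
          max(0, stats::cor(pred, yt))
        }
      }
      internal <- which(raw$feature > 0)
      if (length(internal)) {
        gidx <- cols[raw$feature[internal]]
        contrib <- q^params$u * raw$ig[internal] *
          (raw$n[internal] / raw$n[1])^params$v
        for (k in seq_along(internal)) {
          ri[gidx[k]] <- ri[gidx[k]] + contrib[k]
        }
      }
      n_trees <- n_trees + 1L
      q_sum <- q_sum + q
      # direct parent/child split-node pairs -> ID edges
      if (length(internal) > 1) {
        parent <- integer(length(raw$feature))
        kids <- c(raw$left, raw$right)
        who <- rep(seq_along(raw$feature), 2L)
        parent[kids[kids > 0]] <- who[kids > 0]
        keep <- internal[parent[internal] > 0]
        keep <- keep[raw$feature[parent[keep]] > 0]
        if (length(keep)) {
          edge_pf[[n_trees]] <- cols[raw$feature[parent[keep]]]
          edge_cf[[n_trees]] <- cols[raw$feature[keep]]
          edge_w[[n_trees]] <- raw$ig[keep] * raw$n[keep] /
            raw$n[parent[keep]]
        }
      }
    }
  }

  pf <- unlist(edge_pf)
  graph <- if (length(pf)) {
    cf <- unlist(edge_cf)
    w <- rowsum(unlist(edge_w), pf * (p + 1) + cf)
    key <- as.numeric(rownames(w))
    aggregate_id_edges(data.frame(
      parent = cn[key %/% (p + 1)], child = cn[key %% (p + 1)],
      weight = w[, 1], stringsAsFactors = FALSE
    ))
  } else {
    aggregate_id_edges(NULL)
  }
  list(
    ri = ri,
    id_graph = graph,
    mean_quality = if (n_trees > 0) q_sum / n_trees else NA_real_,
    n_trees = n_trees
  )
}

#' Permutation-based significance cutoff for RI scores
#'
#' Reruns the full projection/tree procedure `n_perm` times on uniformly
#' permuted targets, records the maximum RI of each permuted run, and
#' returns a cutoff statistic of those maxima: by default their
#' `cutoff_quantile` (95th percentile) — a max-statistic that controls the
#' family-wise chance of flagging a random feature — or, with
#' `cutoff_method = "mean_t"`, their mean plus a one-sided t-interval.
#'
#' @inheritParams run_mcfs
#' @return The cutoff value; features with `RI > cutoff` are significant.
#' @export
permutation_cutoff <- function(x, y, params = mcfs_params()) {
  if (params$n_perm < 1) stop_input("n_perm must be >= 1")
  x <- as_values(x)
  m <- min(params$m, ncol(x))
  maxima <- vapply(seq_len(params$n_perm), function(i) {
    seed_i <- derive_seed(params$seed, i)
    with_seed(seed_i, {
      y_perm <- sample(y)
      fit <- mcfs_forest_pass(x, y_perm, params, m)
      max(fit$ri)
    })
  }, numeric(1))
  if (params$cutoff_method == "max_percentile" || params$n_perm < 2) {
    unname(stats::quantile(maxima, params$cutoff_quantile, type = 7))
  } else {
    mean(maxima) + stats::qt(params$cutoff_quantile, params$n_perm - 1) *
      stats::sd(maxima) / sqrt(params$n_perm)
  }
}

#' Restrict an ID-graph to its strongest nodes and edges
#'
#' Keeps the `top_nodes` features by RI, then the `top_edges` heaviest edges
#' among them (ties broken lexicographically by endpoints).
#'
#' @param graph ID-graph edge data frame (`parent`, `child`, `weight`).
#' @param ranking ranking data frame with `feature` and `ri` columns.
#' @param top_nodes,top_edges how many nodes/edges to keep.
#' @return Filtered edge data frame.
#' @export
idgraph_view <- function(graph, ranking, top_nodes = 50L, top_edges = 50L) {
  keep_nodes <- utils::head(
    ranking$feature[order(-ranking$ri, ranking$feature)], top_nodes
  )
  g <- graph[graph$parent %in% keep_nodes & graph$child %in% keep_nodes, ,
    drop = FALSE
  ]
  g <- g[order(-g$weight, g$parent, g$child), , drop = FALSE]
  g <- utils::head(g, top_edges)
  rownames(g) <- NULL
  g
}

#' @export
print.mcfs_result <- function(x, ...) {
  cat(sprintf(
    "MCFS-ID %s run: %d features, %d trees, mean tree quality %.3f\n",
    x$params$task, nrow(x$ranking), x$n_trees, x$mean_quality
  ))
  cat(sprintf(
    "cutoff %.4g; %d significant features\n", x$cutoff,
    sum(x$ranking$significant)
  ))
  invisible(x)
}
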