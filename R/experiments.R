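# The two experiment designs built on the MCFS-ID core: the four-run main
# feature-selection experiment with held-out classification validation, and
# the mass per-mRNA regression experiments with cross-ranking aggregation.

#' Random forest from the package's own trees (bagging)
#'
#' Each tree is grown on a bootstrap sample of the rows and a random
#' subspace of `mtry` features; prediction is the majority vote.
#'
#' @param x samples-by-features numeric matrix.
#' @param y factor of class labels.
#' @param n_tree number of bagged trees.
#' @param mtry features per tree (default `floor(sqrt(p))`).
#' @param seed integer seed.
#' @return An object of class `mcfs_rf`.
#' @export
rf_train <- function(x, y, n_tree = 300L, mtry = NULL, seed = 1L) {
  x <- as_values(x)
  y <- factor(y)
  p <- ncol(x)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  with_seed(seed, {
    trees <- lapply(seq_len(n_tree), function(i) {
      rows <- sample.int(nrow(x), replace = TRUE)
      tries <- 0L
      while (length(unique(y[rows])) < 2 && tries < 25L) {
        rows <- sample.int(nrow(x), replace = TRUE)
        tries <- tries + 1L
      }
      cols <- sort(sample.int(p, min(mtry, p)))
      build_tree(x[rows, cols, drop = FALSE], y[rows],
        task = "classification"
      )
    })
    structure(list(trees = trees, classes = levels(y)), class = "mcfs_rf")
  })
}

#' @export
predict.mcfs_rf <- function(object, newdata, ...) {
  newdata <- as_values(newdata)
  votes <- matrix(0L, nrow(newdata), length(object$classes))
  for (tr in object$trees) {
    p <- as.integer(predict(tr, newdata))
    votes[cbind(seq_len(nrow(newdata)), p)] <-
      votes[cbind(seq_len(nrow(newdata)), p)] + 1L
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
    levels = object$classes
  )
}

#' Held-out validation of a selected feature set
#'
#' Trains a classifier on the training samples restricted to the selected
#' features and reports weighted accuracy on the held-out samples only.
#' `"rf"` uses this package's own bagged trees; `"svm"` delegates to a
#' standard support-vector machine (radial kernel, default
#' hyperparameters).
#'
#' @param x_train,y_train,x_test,y_test training and held-out data.
#' @param selected nonempty character vector of feature IDs.
#' @param classifier `"rf"` or `"svm"`.
#' @param seed integer seed (RF bootstrap).
#' @return Held-out weighted accuracy.
#' @export
validate_selection <- function(x_train, y_train, x_test, y_test, selected,
                               classifier = c("rf", "svm"), seed = 1L) {
  classifier <- match.arg(classifier)
  if (length(selected) < 1) {
    stop_input("validation requires at least 1 selected feature")
  }
  x_train <- as_values(x_train)[, selected, drop = FALSE]
  x_test <- as_values(x_test)[, selected, drop = FALSE]
  y_train <- factor(y_train)
  if (classifier == "rf") {
    fit <- rf_train(x_train, y_train, seed = seed)
    pred <- predict(fit, x_test)
  } else {
    fit <- e1071::svm(x_train, y_train)
    pred <- predict(fit, x_test)
  }
  weighted_accuracy(y_test, pred)
}

#' The main four-run feature-selection experiment
#'
#' Runs MCFS-ID on the joined multi-omics table restricted to complete
#' samples (capturing cross-omics feature interactions), then once per omic
#' on all samples carrying that omic. Per omic it reports the joined-run
#' significant set, the individual-run significant set, their intersection
#' and union, and (optionally) held-out weighted accuracy of RF and SVM
#' classifiers trained on complete samples with the union set and tested on
#' that omic's held-out (incomplete) samples.
#'
#' @param mrna,mirna,meth [omics_matrix()] objects (samples that carry the
#'   layer).
#' @param meta cohort metadata (see [generate_cohort()]).
#' @param params an [mcfs_params()] (classification task).
#' @param include_joined run the joined selection (default `TRUE`).
#' @param validate train/test RF and SVM validation models.
#' @return A list of class `main_experiment`: per-omic element with
#'   `joined_set`, `individual_set`, `intersection`, `union`, `rf_wacc`,
#'   `svm_wacc`, plus `joined` and per-omic `mcfs_result` objects and a
#'   Table-style `summary` data frame.
#' @export
main_experiment <- function(mrna, mirna, meth, meta, params = mcfs_params(),
                            include_joined = TRUE, validate = TRUE) {
  omics <- list(mrna = mrna, mirna = mirna, meth = meth)
  groups <- stats::setNames(as.character(meta$group), meta$sample)
  complete <- meta$sample[meta$complete]
  if (length(complete) == 0) stop_input("no complete samples")

  joined_fit <- NULL
  sig_joined <- character(0)
  if (include_joined) {
    joined <- do.call(cbind, lapply(omics, function(o) {
      as_values(o)[complete, , drop = FALSE]
    }))
    jp <- params
    jp$seed <- derive_seed(params$seed, 101L)
    joined_fit <- run_mcfs(joined, groups[complete], jp)
    sig_joined <- joined_fit$ranking$feature[joined_fit$ranking$significant]
  }

  results <- list()
  fits <- list()
  for (k in seq_along(omics)) {
    nm <- names(omics)[k]
    x <- as_values(omics[[nm]])
    y <- groups[rownames(x)]
    if (length(unique(y)) < 2) {
      warning(sprintf("omic '%s' has < 2 classes; skipped", nm))
      next
    }
    op <- params
    op$seed <- derive_seed(params$seed, 200L + k)
    fit <- run_mcfs(x, y, op)
    fits[[nm]] <- fit
    sig_ind <- fit$ranking$feature[fit$ranking$significant]
    sig_j <- intersect(sig_joined, colnames(x))
    res <- list(
      joined_set = sig_j, individual_set = sig_ind,
      intersection = intersect(sig_j, sig_ind),
      union = sort(union(sig_j, sig_ind)),
      rf_wacc = NA_real_, svm_wacc = NA_real_
    )
    if (validate && length(res$union) > 0) {
      train_ids <- intersect(complete, rownames(x))
      test_ids <- setdiff(rownames(x), complete)
      if (length(test_ids) > 0 && length(unique(y[train_ids])) == 2) {
        res$rf_wacc <- validate_selection(
          x[train_ids, , drop = FALSE], y[train_ids],
          x[test_ids, , drop = FALSE], y[test_ids],
          res$union, "rf",
          seed = derive_seed(params$seed, 300L + k)
        )
        res$svm_wacc <- validate_selection(
          x[train_ids, , drop = FALSE], y[train_ids],
          x[test_ids, , drop = FALSE], y[test_ids],
          res$union, "svm"
        )
      }
    }
    results[[nm]] <- res
  }

  summary <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(
      omic = nm, joined_set = length(r$joined_set),
      individual_set = length(r$individual_set),
      intersection = length(r$intersection), union = length(r$union),
      rf_wacc = r$rf_wacc, svm_wacc = r$svm_wacc, stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      per_omic = results, joined = joined_fit, fits = fits,
      summary = summary
    ),
    class = "main_experiment"
  )
}

#' @export
print.main_experiment <- function(x, ...) {
  cat("Main MCFS-ID experiment\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# 5-fold cross-validated Pearson correlation of a regression tree fit on
# the selected features
cv_tree_pearson <- function(x, y, selected, k = 5L, seed = 1L,
                            min_split = 5L) {
  if (length(selected) == 0) return(NA_real_)
  x <- x[, selected, drop = FALSE]
  n <- length(y)
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), n))
    rs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      tree <- build_tree(x[tr, , drop = FALSE], y[tr],
        task = "regression", min_split = min_split
      )
      pred <- predict(tree, x[!tr, , drop = FALSE])
      if (stats::sd(pred) == 0 || stats::sd(y[!tr]) == 0) {
        return(0)
      }
      stats::cor(pred, y[!tr])
    }, numeric(1))
    mean(rs)
  })
}

#' Mass per-target regression experiments
#'
#' Runs one regression-mode MCFS-ID experiment per target feature (each
#' target's values as the continuous response, the predictor omic as
#' features), then scores each target's significant set by 5-fold
#' cross-validated Pearson correlation of a regression tree; targets at or
#' above `gate` are flagged well-predicted. When chromosome maps are given,
#' each target's candidate predictors are restricted to the target gene's
#' chromosome.
#'
#' @param targets samples-by-targets numeric matrix (or [omics_matrix()]).
#' @param predictors samples-by-predictors matrix; rows matched to
#'   `targets` by shared sample names.
#' @param params an [mcfs_params()]; forced to regression task.
#' @param target_chrom,predictor_chrom optional named chromosome vectors
#'   enabling the same-chromosome restriction.
#' @param gate well-predicted cross-validated Pearson threshold
#'   (default 0.8).
#' @param cv_folds cross-validation folds.
#' @return A list of class `mass_experiments`: per-target element with
#'   `ranking`, `significant`, `cutoff`, `cv_pearson`, `well_predicted`.
#' @export
mass_experiments <- function(targets, predictors, params = mcfs_params(),
                             target_chrom = NULL, predictor_chrom = NULL,
                             gate = 0.8, cv_folds = 5L) {
  targets <- as_values(targets)
  predictors <- as_values(predictors)
  shared <- intersect(rownames(targets), rownames(predictors))
  if (length(shared) < 10) stop_input("need >= 10 shared samples")
  targets <- targets[shared, , drop = FALSE]
  predictors <- predictors[shared, , drop = FALSE]
  params$task <- "regression"

  out <- list()
  for (ti in seq_len(ncol(targets))) {
    tg <- colnames(targets)[ti]
    y <- targets[, ti]
    if (stats::sd(y) == 0) {
      warning(sprintf("target '%s' has zero variance; skipped", tg))
      next
    }
    cand <- colnames(predictors)
    if (!is.null(target_chrom) && !is.null(predictor_chrom) &&
      tg %in% names(target_chrom)) {
      cand <- cand[predictor_chrom[cand] == target_chrom[[tg]]]
      cand <- cand[!is.na(cand)]
    }
    if (length(cand) < 2) {
      warning(sprintf("target '%s' has < 2 candidate predictors; skipped", tg))
      next
    }
    tp <- params
    tp$seed <- derive_seed(params$seed, 1000L + ti)
    fit <- run_mcfs(predictors[, cand, drop = FALSE], y, tp)
    sig <- fit$ranking$feature[fit$ranking$significant]
    cvp <- cv_tree_pearson(
      predictors, y, sig,
      k = cv_folds,
      seed = derive_seed(params$seed, 2000L + ti),
      min_split = params$min_split
    )
    out[[tg]] <- list(
      ranking = fit$ranking, significant = sig, cutoff = fit$cutoff,
      cv_pearson = cvp,
      well_predicted = !is.na(cvp) && cvp >= gate
    )
  }
  structure(out, class = "mass_experiments")
}

#' Aggregate the mass-experiment rankings across well-predicted targets
#'
#' For every predictor found significant for at least one well-predicted
#' target: `freq` = the number of such targets, `sum_ri` = total RI over
#' them, `mean_ri = sum_ri / freq` (exactly). Sorted by `sum_ri`
#' descending. Never-significant predictors are absent.
#'
#' @param results a [mass_experiments()] result.
#' @param main_ranking optional ranking data frame of the main experiment;
#'   adds each predictor's main-experiment rank.
#' @return Data frame with `feature`, `freq`, `sum_ri`, `mean_ri` and
#'   optionally `main_rank`.
#' @export
aggregate_mass <- function(results, main_ranking = NULL) {
  rows <- list()
  for (tg in names(results)) {
    r <- results[[tg]]
    if (!isTRUE(r$well_predicted) || length(r$significant) == 0) next
    sub <- r$ranking[r$ranking$feature %in% r$significant, c("feature", "ri")]
    rows[[tg]] <- sub
  }
  if (length(rows) == 0) {
    return(data.frame(
      feature = character(0), freq = integer(0), sum_ri = numeric(0),
      mean_ri = numeric(0), stringsAsFactors = FALSE
    ))
  }
  all <- do.call(rbind, rows)
  freq <- table(all$feature)
  sums <- rowsum(all$ri, all$feature)
  out <- data.frame(
    feature = rownames(sums), freq = as.integer(freq[rownames(sums)]),
    sum_ri = sums[, 1], stringsAsFactors = FALSE
  )
  out$mean_ri <- out$sum_ri / out$freq
  if (!is.null(main_ranking)) {
    out$main_rank <- main_ranking$rank[
      match(out$feature, main_ranking$feature)
    ]
  }
  out <- out[order(-out$sum_ri, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
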