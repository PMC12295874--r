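# Regulatory-model layer: miRNA filters and miRNA-mRNA correlation
# screening, the combined TF+DMS classification run, per-target linear
# models with tissue-type ablation, and the resulting edge tables.

#' Select miRNAs down-expressed in cancer
#'
#' Expression `log2FC = log2((mean cancer + eps) / (mean normal + eps))`;
#' miRNAs with `log2FC <= cutoff` (default -0.5) are returned.
#'
#' @param mirna samples-by-miRNA matrix (or [omics_matrix()]).
#' @param groups factor/character aligned to rows, with `"cancer"` and
#'   `"normal"`.
#' @param cutoff log2FC selection threshold.
#' @param eps pseudocount guarding zero group means.
#' @return Character vector of selected miRNA IDs.
#' @export
select_down_mirnas <- function(mirna, groups, cutoff = -0.5, eps = 1e-6) {
  lfc <- expression_log2fc(mirna, groups, eps)
  names(lfc)[lfc <= cutoff]
}

#' Negative-correlation screen over mapped miRNA-mRNA pairs
#'
#' Spearman correlation per mapped pair, BH-FDR across all tested pairs;
#' pairs with `rho <= rho_max` (default -0.2) and `q <= q_max` are flagged.
#' Unmapped pairs are never tested, and positively correlated pairs are
#' excluded regardless of q.
#'
#' @param mirna,mrna expression matrices; rows matched by shared sample
#'   names.
#' @param target_map data frame with columns `mirna`, `mrna` listing the
#'   candidate regulatory pairs.
#' @param rho_max,q_max significance thresholds.
#' @return Data frame of tested pairs (`mirna`, `mrna`, `rho`, `p`, `q`,
#'   `significant`).
#' @export
mirna_mrna_screen <- function(mirna, mrna, target_map, rho_max = -0.2,
                              q_max = 0.05) {
  mirna <- as_values(mirna)
  mrna <- as_values(mrna)
  shared <- intersect(rownames(mirna), rownames(mrna))
  if (length(shared) < 3) stop_input("need >= 3 shared samples")
  keep <- target_map$mirna %in% colnames(mirna) &
    target_map$mrna %in% colnames(mrna)
  tm <- target_map[keep, , drop = FALSE]
  if (nrow(tm) == 0) {
    return(data.frame(
      mirna = character(0), mrna = character(0), rho = numeric(0),
      p = numeric(0), q = numeric(0), significant = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  res <- lapply(seq_len(nrow(tm)), function(i) {
    ct <- suppressWarnings(stats::cor.test(
      mirna[shared, tm$mirna[i]], mrna[shared, tm$mrna[i]],
      method = "spearman", exact = FALSE
    ))
    data.frame(
      mirna = tm$mirna[i], mrna = tm$mrna[i],
      rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$rho <= rho_max & out$q <= q_max
  out
}

#' Combined TF-expression + DMS-methylation MCFS-ID run
#'
#' One classification-mode MCFS-ID run on the concatenated feature table of
#' transcription-factor gene expressions and DMS beta-values, restricted to
#' samples carrying both omics.
#'
#' @param tf_expr samples-by-TF expression matrix.
#' @param dms_beta samples-by-DMS beta matrix.
#' @param groups named group labels (names are sample IDs).
#' @param params an [mcfs_params()] (classification task).
#' @return An `mcfs_result` (see [run_mcfs()]).
#' @export
tf_dms_mcfs <- function(tf_expr, dms_beta, groups, params = mcfs_params()) {
  tf_expr <- as_values(tf_expr)
  dms_beta <- as_values(dms_beta)
  shared <- intersect(rownames(tf_expr), rownames(dms_beta))
  if (length(shared) == 0) {
    stop_input("the two omics share no samples")
  }
  x <- cbind(
    tf_expr[shared, , drop = FALSE],
    dms_beta[shared, , drop = FALSE]
  )
  run_mcfs(x, groups[shared], params)
}

#' Per-target linear regulatory models with tissue-type ablation
#'
#' Fits one ordinary-least-squares model per target gene from its predictor
#' set (TF expressions, DMS beta-values) plus a 0/1 tissue indicator
#' (normal = 0, cancer = 1). Model F-test p-values are BH-adjusted across
#' targets; a model is "best-fitted" iff adjusted `p <= 0.05` and
#' `R^2 > 0.5`. The ablation refits the model without the tissue column and
#' reports the Pearson correlation between fitted and observed expression
#' for both fits. Predictors collinear to machine precision are dropped
#' with a warning and the model refitted.
#'
#' @param targets samples-by-targets expression matrix.
#' @param predictor_sets named list (by target) of predictor feature IDs.
#' @param predictors samples-by-predictors numeric matrix holding every
#'   feature named in `predictor_sets`.
#' @param tissue named 0/1 numeric vector (or factor) per sample.
#' @param q_max,r2_min best-fitted thresholds.
#' @return Data frame of class `linear_model_report` with one row per
#'   target: `target`, `n_predictors`, `r2`, `p`, `q`, `best_fitted`,
#'   `pearson_with_tissue`, `pearson_without_tissue`, plus a `coef`
#'   attribute (named list of coefficient tables).
#' @export
fit_target_models <- function(targets, predictor_sets, predictors, tissue,
                              q_max = 0.05, r2_min = 0.5) {
  targets <- as_values(targets)
  predictors <- as_values(predictors)
  tissue <- if (is.factor(tissue) || is.character(tissue)) {
    stats::setNames(as.numeric(as.character(tissue) == "cancer"),
                    names(tissue))
  } else {
    tissue
  }
  samples <- intersect(rownames(targets), rownames(predictors))
  samples <- samples[samples %in% names(tissue)]
  rows <- list()
  coefs <- list()
  for (tg in names(predictor_sets)) {
    sel <- intersect(predictor_sets[[tg]], colnames(predictors))
    if (!tg %in% colnames(targets) || length(sel) == 0) next
    df <- data.frame(
      y = targets[samples, tg],
      predictors[samples, sel, drop = FALSE],
      tissue = tissue[samples], check.names = FALSE
    )
    fit <- stats::lm(y ~ ., data = df)
    if (anyNA(stats::coef(fit))) {
      drop <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      drop <- gsub("^`|`$", "", drop)
      warning(sprintf(
        "target '%s': dropped collinear predictor(s) %s", tg,
        paste(drop, collapse = ", ")
      ))
      sel <- setdiff(sel, drop)
      df <- df[, !(colnames(df) %in% drop), drop = FALSE]
      fit <- stats::lm(y ~ ., data = df)
    }
    sm <- summary(fit)
    fstat <- sm$fstatistic
    p <- if (is.null(fstat)) NA_real_ else {
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    }
    fit_ablate <- stats::lm(y ~ ., data = df[, colnames(df) != "tissue",
      drop = FALSE
    ])
    cor_safe <- function(f) {
      if (stats::sd(stats::fitted(f)) == 0) 0 else {
        stats::cor(stats::fitted(f), df$y)
      }
    }
    rows[[tg]] <- data.frame(
      target = tg, n_predictors = length(sel), r2 = sm$r.squared,
      p = unname(p), pearson_with_tissue = cor_safe(fit),
      pearson_without_tissue = cor_safe(fit_ablate),
      stringsAsFactors = FALSE
    )
    coefs[[tg]] <- sm$coefficients
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_input("no target could be modeled")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$best_fitted <- !is.na(out$q) & out$q <= q_max & out$r2 > r2_min
  rownames(out) <- NULL
  attr(out, "coef") <- coefs
  class(out) <- c("linear_model_report", class(out))
  out
}

#' Regulatory edge table from fitted models
#'
#' Emits, for every best-fitted model, TF -> DMS edges (each TF predictor
#' connected to each DMS predictor) and DMS -> target edges; miRNA ->
#' target edges are added from the miRNA screen hits touching model
#' targets. Duplicate edges are deduplicated with `weight` = multiplicity.
#'
#' @param reports a [fit_target_models()] report.
#' @param predictor_sets the named predictor lists used for the models.
#' @param is_tf function or character vector identifying TF features among
#'   the predictors (others are treated as DMSs).
#' @param mirna_hits optional [mirna_mrna_screen()] result.
#' @return Data frame with `from`, `to`, `type`, `weight`.
#' @export
model_edges <- function(reports, predictor_sets, is_tf = character(0),
                        mirna_hits = NULL) {
  tf_test <- if (is.function(is_tf)) is_tf else function(x) x %in% is_tf
  edges <- list()
  for (tg in reports$target[reports$best_fitted]) {
    sel <- predictor_sets[[tg]]
    tfs <- sel[tf_test(sel)]
    dms <- setdiff(sel, tfs)
    for (d in dms) {
      for (tf in tfs) {
        edges[[length(edges) + 1]] <- data.frame(
          from = tf, to = d, type = "tf_dms", stringsAsFactors = FALSE
        )
      }
      edges[[length(edges) + 1]] <- data.frame(
        from = d, to = tg, type = "dms_target", stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(mirna_hits)) {
    hit <- mirna_hits[mirna_hits$significant &
      mirna_hits$mrna %in% reports$target[reports$best_fitted], ,
    drop = FALSE
    ]
    for (i in seq_len(nrow(hit))) {
      edges[[length(edges) + 1]] <- data.frame(
        from = hit$mirna[i], to = hit$mrna[i], type = "mirna_target",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(edges) == 0) {
    return(data.frame(
      from = character(0), to = character(0), type = character(0),
      weight = integer(0), stringsAsFactors = FALSE
    ))
  }
  all <- do.call(rbind, edges)
  key <- paste(all$from, all$to, all$type, sep = "\r")
  cnt <- table(key)
  uniq <- all[!duplicated(key), , drop = FALSE]
  uniq$weight <- as.integer(cnt[paste(uniq$from, uniq$to, uniq$type,
    sep = "\r"
  )])
  rownames(uniq) <- NULL
  uniq
}
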