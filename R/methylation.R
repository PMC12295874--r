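# Genomic-context annotation, differential-methylation calling, enrichment
# against constructed nulls, cis correlation and survival screens.
#
# Sites are given as a data frame (site, chrom, pos) with 0-based positions;
# interval tracks are GRanges in the BED convention used across the package.

sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}

#' CpG context of methylation sites
#'
#' Classifies each site relative to CpG islands: `island` inside an island,
#' `shore` within 2000 bp of an island, `shelf` within the next 2000 bp
#' (2001-4000), `open_sea` beyond. When flanks of neighbouring islands
#' overlap, the closer class wins (island > shore > shelf > open sea);
#' flanks are implicitly clipped at chromosome bounds.
#'
#' @param sites data frame with `site`, `chrom`, `pos` (0-based).
#' @param cpgi `GRanges` of CpG islands.
#' @return Character vector (`island`, `shore`, `shelf`, `open_sea`),
#'   one per site.
#' @export
cpg_context <- function(sites, cpgi) {
  gr <- sites_to_granges(sites)
  ctx <- rep("open_sea", nrow(sites))
  cpgi_chr <- as.character(GenomeInfoDb::seqnames(cpgi))
  for (i in seq_len(nrow(sites))) {
    on_chr <- cpgi[cpgi_chr == sites$chrom[i]]
    if (length(on_chr) == 0) next
    s0 <- BiocGenerics::start(on_chr) - 1L # back to 0-based half-open
    e0 <- BiocGenerics::end(on_chr)
    p <- sites$pos[i]
    d <- ifelse(p >= s0 & p < e0, 0L, ifelse(p < s0, s0 - p, p - e0 + 1L))
    d <- min(d)
    ctx[i] <- if (d == 0) {
      "island"
    } else if (d <= 2000) {
      "shore"
    } else if (d <= 4000) {
      "shelf"
    } else {
      "open_sea"
    }
  }
  ctx
}

#' Gene context and target-gene pairing of methylation sites
#'
#' Promoters are TSS +/- 2000 bp, strand-aware (TSS = interval start on `+`,
#' interval end on `-`). Precedence: promoter > gene body > intergenic.
#' Promoter and intergenic sites pair with the gene of the nearest TSS;
#' distance ties break lexicographically by gene ID.
#'
#' @param sites data frame with `site`, `chrom`, `pos` (0-based).
#' @param genes `GRanges` of genes with `name` metadata and strand.
#' @return Data frame with `site`, `context`
#'   (`promoter`/`gene_body`/`intergenic`), `gene`, and `tss_distance`.
#' @export
gene_context <- function(sites, genes) {
  gname <- S4Vectors::mcols(genes)$name
  gchr <- as.character(GenomeInfoDb::seqnames(genes))
  gstrand <- as.character(BiocGenerics::strand(genes))
  s0 <- BiocGenerics::start(genes) - 1L
  e0 <- BiocGenerics::end(genes)
  tss <- ifelse(gstrand == "-", e0 - 1L, s0) # 0-based TSS position

  out <- data.frame(
    site = sites$site, context = "intergenic", gene = NA_character_,
    tss_distance = NA_integer_, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(sites))) {
    on_chr <- which(gchr == sites$chrom[i])
    if (length(on_chr) == 0) next
    p <- sites$pos[i]
    dtss <- abs(p - tss[on_chr])
    ord <- order(dtss, gname[on_chr])
    nearest <- on_chr[ord[1]]
    in_prom <- on_chr[dtss <= 2000]
    if (length(in_prom)) {
      pick <- in_prom[order(dtss[match(in_prom, on_chr)], gname[in_prom])][1]
      out$context[i] <- "promoter"
      out$gene[i] <- gname[pick]
      out$tss_distance[i] <- abs(p - tss[pick])
      next
    }
    in_body <- on_chr[p >= s0[on_chr] & p < e0[on_chr]]
    if (length(in_body)) {
      pick <- in_body[order(dtss[match(in_body, on_chr)], gname[in_body])][1]
      out$context[i] <- "gene_body"
      out$gene[i] <- gname[pick]
      out$tss_distance[i] <- abs(p - tss[pick])
      next
    }
    out$gene[i] <- gname[nearest]
    out$tss_distance[i] <- dtss[ord[1]]
  }
  out
}

#' Methylation log2 fold change and hyper/medium/hypo labels
#'
#' `log2FC = log2((mean beta normal + eps) / (mean beta cancer + eps))`, so
#' sites more methylated in cancer get negative values. Labels:
#' `hyper` (methylated in cancer) when `log2FC <= -1`, `hypo` when
#' `log2FC >= 1`, otherwise `medium`. Swapping the group labels negates the
#' log2FC and swaps hyper and hypo.
#'
#' @param beta samples-by-sites beta-value matrix (or [omics_matrix()]).
#' @param groups factor/character with levels containing `"cancer"` and
#'   `"normal"`, aligned with the rows of `beta`.
#' @param eps pseudocount guarding a zero group mean.
#' @return Data frame with `site`, `mean_cancer`, `mean_normal`, `log2fc`,
#'   `label`.
#' @export
methylation_log2fc <- function(beta, groups, eps = 1e-6) {
  beta <- as_values(beta)
  groups <- as.character(groups)
  mc <- colMeans(beta[groups == "cancer", , drop = FALSE])
  mn <- colMeans(beta[groups == "normal", , drop = FALSE])
  lfc <- log2((mn + eps) / (mc + eps))
  data.frame(
    site = colnames(beta), mean_cancer = unname(mc), mean_normal = unname(mn),
    log2fc = unname(lfc),
    label = ifelse(lfc <= -1, "hyper", ifelse(lfc >= 1, "hypo", "medium")),
    stringsAsFactors = FALSE
  )
}

#' Expression log2 fold change (cancer over normal)
#'
#' `log2FC = log2((mean cancer + eps) / (mean normal + eps))`: negative
#' values mean down-expression in cancer.
#'
#' @inheritParams methylation_log2fc
#' @param x samples-by-features expression matrix (or [omics_matrix()]).
#' @return Named numeric vector of per-feature log2FC.
#' @export
expression_log2fc <- function(x, groups, eps = 1e-6) {
  x <- as_values(x)
  groups <- as.character(groups)
  mc <- colMeans(x[groups == "cancer", , drop = FALSE])
  mn <- colMeans(x[groups == "normal", , drop = FALSE])
  log2((mc + eps) / (mn + eps))
}

#' Two-group differential test with normality gate and FDR
#'
#' Per feature, Shapiro-Wilk normality is assessed in each group (recorded,
#' and used to justify the nonparametric route); the two-sided Wilcoxon
#' rank-sum test compares the unpaired groups, and Benjamini-Hochberg FDR is
#' applied across all tested features. Features with fewer than 3 values in
#' a group are skipped with a warning.
#'
#' @param x samples-by-features numeric matrix (or [omics_matrix()]).
#' @param groups two-level factor/character aligned with rows of `x`.
#' @return Data frame with `feature`, `shapiro_p_min`, `p`, `q`.
#' @export
differential_test <- function(x, groups) {
  x <- as_values(x)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop_input("groups must have exactly 2 levels")
  a <- groups == lev[1]
  b <- groups == lev[2]
  res <- data.frame(
    feature = colnames(x), shapiro_p_min = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE
  )
  skipped <- 0L
  for (j in seq_len(ncol(x))) {
    va <- x[a, j]
    vb <- x[b, j]
    if (length(va) < 3 || length(vb) < 3) {
      skipped <- skipped + 1L
      next
    }
    sw <- function(v) {
      if (length(unique(v)) < 3 || length(v) > 5000) return(NA_real_)
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    }
    res$shapiro_p_min[j] <- suppressWarnings(min(sw(va), sw(vb), na.rm = TRUE))
    res$p[j] <- suppressWarnings(
      stats::wilcox.test(va, vb, exact = FALSE)$p.value
    )
  }
  if (skipped > 0) {
    warning(sprintf("%d feature(s) skipped (group size < 3)", skipped))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Region enrichment of DMS contexts against a background panel
#'
#' For each region class, a 2x2 chi-squared test compares in-region versus
#' out-of-region membership between the DMS set and the background panel;
#' Bonferroni correction is applied over the tested regions and the
#' direction is called from the odds ratio.
#'
#' @param observed character vector of region contexts of the DMS set.
#' @param background character vector of region contexts of the full panel.
#' @param regions region classes to test (default: all classes seen).
#' @return Data frame with `region`, counts, `odds_ratio`, `p`,
#'   `p_bonferroni`, `direction` (`enriched`/`depleted`/`none`).
#' @export
region_enrichment <- function(observed, background,
                              regions = sort(unique(c(observed, background)))) {
  res <- lapply(regions, function(r) {
    a <- sum(observed == r)
    b <- length(observed) - a
    c_ <- sum(background == r)
    d <- length(background) - c_
    if (a + c_ == 0) {
      warning(sprintf("region '%s' absent from both sets; skipped", r))
      return(NULL)
    }
    tab <- matrix(c(a, b, c_, d), 2)
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
    data.frame(
      region = r, dms_in = a, dms_out = b, panel_in = c_, panel_out = d,
      odds_ratio = or, p = p, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(res)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res$direction <- ifelse(
    res$p_bonferroni > 0.05, "none",
    ifelse(res$odds_ratio > 1, "enriched", "depleted")
  )
  res
}

# map each site to the single chromatin state covering it (states tile the
# genome, so membership is unique)
site_states <- function(sites, states) {
  hits <- GenomicRanges::findOverlaps(
    sites_to_granges(sites), states,
    select = "first"
  )
  S4Vectors::mcols(states)$name[hits]
}

#' Chromatin-state enrichment with a resampling null
#'
#' Computes, per chromatin state, the percentage of tested DMSs falling in
#' that state, compares it to `n_draws` size-matched random draws (without
#' replacement) from the background panel, and reports
#' `logFC = log2(observed %% / mean random %%)` with empirical p-values:
#' enrichment `p = (1 + #draws >= observed) / (1 + n_draws)`, depletion
#' mirrored, two-sided twice the smaller tail capped at 1. Empirical
#' p-values are therefore never 0.
#'
#' @param dms_sites data frame (`site`, `chrom`, `pos`) of tested DMSs.
#' @param states chromatin-state `GRanges` tiling the genome (`name` column).
#' @param panel_sites background panel data frame (same columns), typically
#'   the full methylation array.
#' @param n_draws number of random draws (must be >= 1).
#' @param seed integer seed.
#' @return Data frame with `state`, `observed_pct`, `mean_random_pct`,
#'   `logfc`, `p_enriched`, `p_depleted`, `p_two_sided`.
#' @export
chromatin_state_enrichment <- function(dms_sites, states, panel_sites,
                                       n_draws = 1000L, seed = 1L) {
  if (n_draws < 1) stop_input("n_draws must be >= 1")
  state_names <- sort(unique(S4Vectors::mcols(states)$name))
  obs_states <- site_states(dms_sites, states)
  panel_states <- site_states(panel_sites, states)
  k <- nrow(dms_sites)
  if (k > nrow(panel_sites)) {
    stop_input("DMS set larger than the background panel")
  }
  pct <- function(s) {
    100 * vapply(state_names, function(x) mean(s == x), numeric(1))
  }
  obs <- pct(obs_states)
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      pct(panel_states[sample.int(length(panel_states), k)])
    }, numeric(length(state_names)))
  })
  draws <- matrix(draws, nrow = length(state_names))
  mean_rand <- rowMeans(draws)
  eps <- 1e-9
  ge <- rowSums(draws >= matrix(obs, length(obs), n_draws) - eps)
  le <- rowSums(draws <= matrix(obs, length(obs), n_draws) + eps)
  p_enr <- (1 + ge) / (1 + n_draws)
  p_dep <- (1 + le) / (1 + n_draws)
  data.frame(
    state = state_names, observed_pct = unname(obs),
    mean_random_pct = mean_rand,
    logfc = log2((obs + eps) / (mean_rand + eps)),
    p_enriched = p_enr, p_depleted = p_dep,
    p_two_sided = pmin(1, 2 * pmin(p_enr, p_dep)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cis correlation screen between gene expression and DMS methylation
#'
#' Tests every (gene, site) pair on the same chromosome with the site within
#' `window` bp of the gene's TSS: Spearman correlation with BH-FDR across
#' all tested pairs; pairs with `|rho| >= rho_min` and `q <= q_max` are
#' flagged significant. Constant beta-value sites are skipped.
#'
#' @param expr samples-by-genes expression matrix (or [omics_matrix()]).
#' @param beta samples-by-sites beta matrix; rows are matched to `expr` by
#'   shared sample names.
#' @param genes `GRanges` of the genes (with `name` and strand).
#' @param sites data frame (`site`, `chrom`, `pos`).
#' @param window max distance (bp) from TSS (default 1 Mbp).
#' @param rho_min,q_max significance thresholds.
#' @return Data frame of tested pairs (`gene`, `site`, `distance`, `rho`,
#'   `p`, `q`, `significant`).
#' @export
cis_correlation <- function(expr, beta, genes, sites, window = 1e6,
                            rho_min = 0.6, q_max = 0.05) {
  expr <- as_values(expr)
  beta <- as_values(beta)
  shared <- intersect(rownames(expr), rownames(beta))
  if (length(shared) < 3) stop_input("need >= 3 shared samples")
  expr <- expr[shared, , drop = FALSE]
  beta <- beta[shared, , drop = FALSE]
  gname <- S4Vectors::mcols(genes)$name
  gchr <- as.character(GenomeInfoDb::seqnames(genes))
  gstrand <- as.character(BiocGenerics::strand(genes))
  tss <- ifelse(gstrand == "-", BiocGenerics::end(genes) - 1L,
    BiocGenerics::start(genes) - 1L
  )
  keep_g <- gname %in% colnames(expr)
  rows <- list()
  for (gi in which(keep_g)) {
    cand <- sites[sites$chrom == gchr[gi] &
      abs(sites$pos - tss[gi]) <= window &
      sites$site %in% colnames(beta), , drop = FALSE]
    if (nrow(cand) == 0) next
    for (si in seq_len(nrow(cand))) {
      b <- beta[, cand$site[si]]
      if (stats::sd(b) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(expr[, gname[gi]], b,
          method = "spearman", exact = FALSE
        )
      )
      rows[[length(rows) + 1]] <- data.frame(
        gene = gname[gi], site = cand$site[si],
        distance = abs(cand$pos[si] - tss[gi]),
        rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      gene = character(0), site = character(0), distance = integer(0),
      rho = numeric(0), p = numeric(0), q = numeric(0),
      significant = logical(0), stringsAsFactors = FALSE
    ))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- abs(out$rho) >= rho_min & out$q <= q_max
  out
}

#' Median-split log-rank survival screen over methylation sites
#'
#' For each site, samples are split into high/low methylation at the site's
#' median (values equal to the median go to the low group) and a two-group
#' log-rank test is computed. Sites whose split leaves a group empty are
#' skipped.
#'
#' @param beta samples-by-sites beta matrix (or [omics_matrix()]).
#' @param surv data frame with `sample`, `time`, `event` (1 = event).
#' @param alpha significance level used for the `significant` flag.
#' @return Data frame with `site`, `n_high`, `n_low`, `chisq`, `p`,
#'   `significant`.
#' @export
survival_screen <- function(beta, surv, alpha = 0.05) {
  beta <- as_values(beta)
  surv <- surv[!is.na(surv$time) & surv$sample %in% rownames(beta), ,
    drop = FALSE
  ]
  beta <- beta[surv$sample, , drop = FALSE]
  res <- lapply(colnames(beta), function(s) {
    v <- beta[, s]
    high <- v > stats::median(v)
    if (all(high) || !any(high)) return(NULL)
    sd <- survival::survdiff(
      survival::Surv(surv$time, surv$event) ~ high
    )
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    data.frame(
      site = s, n_high = sum(high), n_low = sum(!high),
      chisq = unname(sd$chisq), p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  out
}

#' Bootstrap null for the count of survival-associated sites
#'
#' Draws `n_rounds` random site sets of size `set_size` from the panel,
#' screens each with [survival_screen()], and records the number of sites
#' with `p < alpha` per round — the null distribution against which an
#' observed count is judged.
#'
#' @param panel_beta samples-by-sites beta matrix of the full panel.
#' @param surv survival data frame (`sample`, `time`, `event`).
#' @param set_size sites per random draw.
#' @param n_rounds number of bootstrap rounds.
#' @param alpha per-site significance level.
#' @param seed integer seed.
#' @return Integer vector (length `n_rounds`) of null significant counts.
#' @export
survival_bootstrap_null <- function(panel_beta, surv, set_size,
                                    n_rounds = 100L, alpha = 0.05,
                                    seed = 1L) {
  panel_beta <- as_values(panel_beta)
  if (set_size > ncol(panel_beta)) stop_input("set_size exceeds panel size")
  with_seed(seed, {
    vapply(seq_len(n_rounds), function(i) {
      pick <- sample.int(ncol(panel_beta), set_size)
      sc <- survival_screen(panel_beta[, pick, drop = FALSE], surv, alpha)
      sum(sc$significant)
    }, integer(1))
  })
}
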