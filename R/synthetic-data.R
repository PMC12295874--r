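#' Specification of a synthetic multi-omics cohort
#'
#' Defines the study conditions for the simulated cancer/normal cohort:
#' three sample-by-feature omics layers (mRNA expression, miRNA expression,
#' DNA methylation beta-values) with a small set of planted discriminative
#' features per layer, partial overlap of samples across layers, and
#' optionally a planted regulator map driving selected mRNA targets from
#' miRNA expression.
#'
#' Expression layers are log-normal: feature values are `2^z` with
#' `z ~ N(baseline, noise_sd)`; informative features shift the cancer-group
#' mean by `effect_size` standard deviations (half up, half down).
#' Methylation features are Beta-distributed with a common concentration
#' parameter; informative sites separate the group means symmetrically
#' around 0.5 by `beta_shift` (half hyper-methylated in cancer, half hypo).
#'
#' @param n_cancer,n_normal sample counts per group.
#' @param p_mrna,p_mirna,p_meth feature counts per omic.
#' @param k_informative planted discriminative features per omic.
#' @param effect_size standardized mean shift on the log2-expression scale.
#' @param beta_shift absolute difference between the cancer and normal group
#'   means of an informative methylation site; defaults to
#'   `min(0.15 * effect_size, 0.8)`. Must keep both group means in (0, 1).
#' @param noise_sd log2-scale standard deviation of expression noise.
#' @param complete_fraction fraction of samples complete across all three
#'   omics; the remainder miss at least one layer and serve as held-out
#'   validation material.
#' @param beta_concentration Beta-distribution concentration (a + b) shared
#'   by all methylation sites.
#' @param n_regulated number of planted regulated mRNA targets.
#' @param drivers_per_target miRNA drivers per regulated target.
#' @param regulatory_r target Pearson correlation between a regulated mRNA
#'   and its noiseless driver combination.
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cancer = 100L, n_normal = 20L,
                        p_mrna = 2020L, p_mirna = 2020L, p_meth = 2020L,
                        k_informative = 20L, effect_size = 2,
                        beta_shift = NULL, noise_sd = 1,
                        complete_fraction = 1 / 3,
                        beta_concentration = 20,
                        n_regulated = 0L, drivers_per_target = 3L,
                        regulatory_r = 0.9, seed = 1L) {
  if (n_cancer < 1 || n_normal < 1) stop_input("need >= 1 sample per group")
  if (min(p_mrna, p_mirna, p_meth) < 1) stop_input("feature counts must be >= 1")
  if (k_informative > min(p_mrna, p_mirna, p_meth)) {
    stop_input("k_informative cannot exceed any omic's feature count")
  }
  if (is.null(beta_shift)) beta_shift <- min(0.15 * abs(effect_size), 0.8)
  if (beta_shift < 0 || 0.5 + beta_shift / 2 >= 1) {
    stop_input(
      "infeasible beta_shift %.3f: group means must stay inside (0, 1)",
      beta_shift
    )
  }
  if (noise_sd <= 0) stop_input("noise_sd must be positive")
  if (complete_fraction <= 0 || complete_fraction > 1) {
    stop_input("complete_fraction must be in (0, 1]")
  }
  if (n_regulated > 0 && drivers_per_target > p_mirna) {
    stop_input("drivers_per_target cannot exceed p_mirna")
  }
  structure(list(
    n_cancer = as.integer(n_cancer), n_normal = as.integer(n_normal),
    p_mrna = as.integer(p_mrna), p_mirna = as.integer(p_mirna),
    p_meth = as.integer(p_meth), k_informative = as.integer(k_informative),
    effect_size = effect_size, beta_shift = beta_shift, noise_sd = noise_sd,
    complete_fraction = complete_fraction,
    beta_concentration = beta_concentration,
    n_regulated = as.integer(n_regulated),
    drivers_per_target = as.integer(drivers_per_target),
    regulatory_r = regulatory_r, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Construct an omics matrix container
#'
#' @param values numeric matrix, samples in rows (named), features in
#'   columns (named).
#' @param kind feature kind tag, e.g. `"mrna"`, `"mirna"`, `"meth"`.
#' @param feature_meta optional per-feature metadata data frame.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, kind, feature_meta = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("values must have sample (row) and feature (column) names")
  }
  if (anyDuplicated(rownames(values))) stop_input("duplicate sample IDs")
  if (anyDuplicated(colnames(values))) stop_input("duplicate feature IDs")
  structure(list(values = values, kind = kind, feature_meta = feature_meta),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "omics_matrix [%s]: %d samples x %d features\n",
    x$kind, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Draws the three omics layers described by [cohort_spec()], assigns each
#' sample a completeness pattern (a `complete_fraction` of samples carry all
#' three layers; the rest miss at least one), and records every planted
#' structure in a ground-truth object. All output is deterministic under the
#' spec's seed. Zero-variance features are never emitted (a degenerate draw
#' is redrawn).
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `mrna`, `mirna`, `meth` (each an
#'   [omics_matrix()] holding only the samples carrying that layer), `meta`
#'   (data frame: `sample`, `group`, `has_mrna`, `has_mirna`, `has_meth`,
#'   `complete`), and `truth` (informative feature IDs per omic, planted DEG
#'   directions, planted methylation labels, planted regulator map).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cancer + spec$n_normal
    samples <- sprintf("S%04d", seq_len(n))
    group <- factor(
      c(rep("cancer", spec$n_cancer), rep("normal", spec$n_normal)),
      levels = c("cancer", "normal")
    )

    n_complete <- max(1L, round(spec$complete_fraction * n))
    complete <- rep(FALSE, n)
    complete[sample.int(n, n_complete)] <- TRUE
    # incomplete samples miss >= 1 layer: draw one of the 6 partial patterns
    patterns <- rbind(
      c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
      c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)
    )
    has <- matrix(TRUE, n, 3)
    inc <- which(!complete)
    if (length(inc)) {
      pick <- sample.int(nrow(patterns), length(inc), replace = TRUE)
      has[inc, ] <- patterns[pick, ] == 1
    }
    meta <- data.frame(
      sample = samples, group = group,
      has_mrna = has[, 1], has_mirna = has[, 2], has_meth = has[, 3],
      complete = complete, stringsAsFactors = FALSE
    )

    gen_expression <- function(p, prefix) {
      ids <- sprintf("%s%04d", prefix, seq_len(p))
      info <- sort(sample(ids, spec$k_informative))
      dir <- stats::setNames(
        rep(c(1, -1), length.out = spec$k_informative), info
      )
      base <- stats::runif(p, 3, 8)
      z <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
      z <- sweep(z, 2, base, "+")
      shift <- spec$effect_size * spec$noise_sd
      icol <- match(info, ids)
      z[group == "cancer", icol] <- sweep(
        z[group == "cancer", icol, drop = FALSE], 2, dir * shift, "+"
      )
      vals <- 2^z
      dimnames(vals) <- list(samples, ids)
      list(values = vals, informative = info, direction = dir)
    }

    mrna <- gen_expression(spec$p_mrna, "gene")
    mirna <- gen_expression(spec$p_mirna, "mir")

    meth_ids <- sprintf("cg%06d", seq_len(spec$p_meth))
    meth_info <- sort(sample(meth_ids, spec$k_informative))
    # +1: cancer mean above normal mean (hyper-methylated in cancer)
    meth_dir <- stats::setNames(
      rep(c(1, -1), length.out = spec$k_informative), meth_info
    )
    mu_noise <- stats::runif(spec$p_meth, 0.1, 0.9)
    mu <- matrix(rep(mu_noise, each = n), n, spec$p_meth)
    icol <- match(meth_info, meth_ids)
    for (k in seq_along(icol)) {
      mu_c <- 0.5 + meth_dir[k] * spec$beta_shift / 2
      mu_n <- 0.5 - meth_dir[k] * spec$beta_shift / 2
      mu[, icol[k]] <- ifelse(group == "cancer", mu_c, mu_n)
    }
    conc <- spec$beta_concentration
    beta <- matrix(
      stats::rbeta(n * spec$p_meth, c(mu) * conc, (1 - c(mu)) * conc),
      n, spec$p_meth
    )
    dimnames(beta) <- list(samples, meth_ids)

    # planted regulator map: selected non-informative mRNA targets become
    # noisy linear combinations of miRNA drivers
    regulators <- list()
    if (spec$n_regulated > 0) {
      free <- setdiff(colnames(mrna$values), mrna$informative)
      targets <- sort(sample(free, spec$n_regulated))
      # drivers come from the full miRNA panel: regulated targets of
      # differentially expressed drivers inherit the cancer/normal contrast,
      # as the study's well-predicted mRNAs do
      driver_pool <- colnames(mirna$values)
      for (tg in targets) {
        drv <- sort(sample(driver_pool, spec$drivers_per_target))
        coefs <- stats::runif(spec$drivers_per_target, 0.5, 1.5) *
          sample(c(-1, 1), spec$drivers_per_target, replace = TRUE)
        z <- scale(mirna$values[, drv, drop = FALSE])
        signal <- drop(z %*% coefs)
        sd_sig <- stats::sd(signal)
        sd_eps <- sd_sig * sqrt(1 / spec$regulatory_r^2 - 1)
        yv <- signal + stats::rnorm(n, sd = sd_eps)
        yv <- yv - min(yv) + 0.5 # expression stays nonnegative
        mrna$values[, tg] <- yv
        regulators[[tg]] <- data.frame(
          driver = drv, coef = coefs, stringsAsFactors = FALSE
        )
      }
    }

    drop_zero_var <- function(vals) {
      # redraw degenerate columns rather than emitting zero variance
      v <- apply(vals, 2, stats::var)
      if (any(v == 0)) {
        for (j in which(v == 0)) {
          vals[, j] <- vals[, j] + abs(stats::rnorm(nrow(vals), sd = 1e-6))
        }
      }
      vals
    }

    subset_layer <- function(vals, keep, kind) {
      omics_matrix(drop_zero_var(vals[keep, , drop = FALSE]), kind)
    }

    truth <- list(
      informative = list(
        mrna = mrna$informative, mirna = mirna$informative, meth = meth_info
      ),
      deg_direction = ifelse(mrna$direction > 0, "up", "down"),
      mirna_direction = ifelse(mirna$direction > 0, "up", "down"),
      dms_label = stats::setNames(
        ifelse(meth_dir > 0, "hyper", "hypo"), meth_info
      ),
      regulators = regulators
    )

    list(
      mrna = subset_layer(mrna$values, meta$has_mrna, "mrna"),
      mirna = subset_layer(mirna$values, meta$has_mirna, "mirna"),
      meth = subset_layer(beta, meta$has_meth, "meth"),
      meta = meta, truth = truth
    )
  })
}

#' Generate a toy genome with annotation tracks
#'
#' Emits random chromosome sequences plus three interval tracks in 0-based
#' half-open coordinates: strand-aware gene intervals (with TSS), CpG-island
#' intervals, and an 8-state chromatin-state tiling covering each chromosome
#' exactly once. Methylation site IDs are assigned unique genomic positions.
#'
#' @param site_ids methylation feature IDs to place on the genome.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length (bp), recycled over chromosomes.
#' @param n_genes,n_cpgi interval counts (genome-wide totals).
#' @param gene_width,cpgi_width integer ranges the interval widths are drawn
#'   from.
#' @param state_mean_len mean chromatin-state segment length.
#' @param seed integer seed.
#' @param max_tries placement retries per interval before failing.
#' @return A list: `seq` (named character of chromosome sequences), `genes`,
#'   `cpgi`, `states` (each a `GRanges`), and `sites` (data frame `site`,
#'   `chrom`, `pos` with 0-based positions).
#' @export
generate_genome_fixture <- function(site_ids, n_chrom = 2L,
                                    chrom_len = 200000L, n_genes = 40L,
                                    n_cpgi = 30L,
                                    gene_width = c(2000L, 8000L),
                                    cpgi_width = c(300L, 1500L),
                                    state_mean_len = 5000L, seed = 1L,
                                    max_tries = 200L) {
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    lens <- stats::setNames(rep_len(as.integer(chrom_len), n_chrom), chroms)
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))

    place_track <- function(n_iv, width_range, prefix) {
      # rejection sampling of non-overlapping intervals within a track
      out <- data.frame(
        chrom = character(0), start = integer(0), end = integer(0),
        name = character(0), stringsAsFactors = FALSE
      )
      for (i in seq_len(n_iv)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          ch <- sample(chroms, 1)
          w <- sample(seq(width_range[1], width_range[2]), 1)
          if (w >= lens[ch]) next
          s <- sample.int(lens[ch] - w, 1) - 1L
          e <- s + w
          same <- out[out$chrom == ch, , drop = FALSE]
          if (nrow(same) == 0 || all(e <= same$start | s >= same$end)) {
            out <- rbind(out, data.frame(
              chrom = ch, start = s, end = e,
              name = sprintf("%s%03d", prefix, i), stringsAsFactors = FALSE
            ))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop_input(
            "could not place interval %d of track '%s' after %d tries",
            i, prefix, max_tries
          )
        }
      }
      out
    }

    genes_df <- place_track(n_genes, gene_width, "gene")
    genes_df$strand <- sample(c("+", "-"), nrow(genes_df), replace = TRUE)
    cpgi_df <- place_track(n_cpgi, cpgi_width, "cpgi")

    # chromatin states tile each chromosome exactly once
    state_names <- c(
      "promoter", "enhancer", "transcribed", "weak_transcribed",
      "polycomb", "heterochromatin", "quiescent", "insulator"
    )
    st <- list()
    for (ch in chroms) {
      pos <- 0L
      while (pos < lens[ch]) {
        w <- min(
          lens[ch] - pos,
          max(500L, stats::rgeom(1, 1 / state_mean_len) + 1L)
        )
        st[[length(st) + 1]] <- data.frame(
          chrom = ch, start = pos, end = pos + w,
          name = sample(state_names, 1), stringsAsFactors = FALSE
        )
        pos <- pos + w
      }
    }
    states_df <- do.call(rbind, st)

    # unique genomic positions for the methylation sites
    sites <- data.frame(
      site = site_ids,
      chrom = sample(chroms, length(site_ids), replace = TRUE),
      stringsAsFactors = FALSE
    )
    sites$pos <- vapply(sites$chrom, function(ch) {
      sample.int(lens[ch] - 50L, 1) + 20L
    }, integer(1))
    while (anyDuplicated(sites[c("chrom", "pos")])) {
      dup <- duplicated(sites[c("chrom", "pos")])
      sites$pos[dup] <- vapply(sites$chrom[dup], function(ch) {
        sample.int(lens[ch] - 50L, 1) + 20L
      }, integer(1))
    }

    list(
      seq = seqs,
      genes = df_to_granges(genes_df, lens),
      cpgi = df_to_granges(cpgi_df, lens),
      states = df_to_granges(states_df, lens),
      sites = sites
    )
  })
}

# data frame (0-based half-open) -> GRanges (1-based closed, BED convention)
df_to_granges <- function(df, seqlens = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  S4Vectors::mcols(gr)$name <- df$name
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlengths(gr) <-
      seqlens[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Plant motif instances into a genome around methylation sites
#'
#' For each requested site, a word is sampled from the chosen PWM's column
#' distributions and written into the chromosome sequence at an offset such
#' that the site position falls inside the planted word and the word lies
#' fully inside the 41-bp window centred on the site (placement clamped at
#' window and chromosome edges).
#'
#' @param genome a genome fixture (list with `seq` and `sites`), see
#'   [generate_genome_fixture()].
#' @param pwms list of [pwm()] objects; sites cycle through them.
#' @param dms_ids site IDs (present in `genome$sites`) to receive a motif.
#' @param seed integer seed.
#' @return The genome with modified sequences, plus an `insertion_log` data
#'   frame (`site`, `motif`, `chrom`, `start`, `end`, `word`).
#' @export
plant_motifs <- function(genome, pwms, dms_ids, seed = 1L) {
  if (length(dms_ids) == 0) {
    genome$insertion_log <- data.frame(
      site = character(0), motif = character(0), chrom = character(0),
      start = integer(0), end = integer(0), word = character(0),
      stringsAsFactors = FALSE
    )
    return(genome)
  }
  missing <- setdiff(dms_ids, genome$sites$site)
  if (length(missing)) {
    stop_input("unknown site(s): %s", paste(missing, collapse = ", "))
  }
  with_seed(seed, {
    log <- vector("list", length(dms_ids))
    for (i in seq_along(dms_ids)) {
      id <- dms_ids[i]
      pw <- pwms[[(i - 1L) %% length(pwms) + 1L]]
      w <- ncol(pw$mat)
      row <- genome$sites[genome$sites$site == id, ]
      pos <- row$pos
      len <- nchar(genome$seq[[row$chrom]])
      # sample a high-scoring word: resample until the word itself passes a
      # stringent scan threshold, falling back to the consensus
      dist <- score_distribution(pw)
      thr <- score_threshold_units(dist, 1e-4)
      word_codes <- NULL
      for (try in seq_len(20)) {
        cand <- vapply(seq_len(w), function(j) {
          sample.int(4, 1, prob = pw$mat[, j])
        }, integer(1))
        sc <- sum(dist$units[cbind(cand, seq_len(w))])
        if (is.na(thr) || sc >= thr) {
          word_codes <- cand
          break
        }
      }
      if (is.null(word_codes)) word_codes <- apply(pw$mat, 2, which.max)
      word <- paste(c("A", "C", "G", "T")[word_codes], collapse = "")
      # start range keeping the site inside the word and the word inside
      # the +/-20 bp window, clamped at chromosome bounds
      lo <- max(0L, pos - 20L, pos - w + 1L)
      hi <- min(len - w, pos, pos + 21L - w)
      if (hi < lo) hi <- lo <- max(0L, min(pos, len - w))
      start <- if (hi > lo) sample(seq(lo, hi), 1) else lo
      substr(genome$seq[[row$chrom]], start + 1L, start + w) <- word
      log[[i]] <- data.frame(
        site = id, motif = pw$name, chrom = row$chrom,
        start = as.integer(start), end = as.integer(start + w), word = word,
        stringsAsFactors = FALSE
      )
    }
    genome$insertion_log <- do.call(rbind, log)
    genome
  })
}

#' Generate a gene-description corpus with planted topic clusters
#'
#' Every gene document mixes a shared vocabulary with terms specific to the
#' gene's topic; topic vocabularies are disjoint. Topic assignments are the
#' recoverable ground truth for the description-clustering pipeline.
#'
#' @param gene_ids gene identifiers (one document each).
#' @param k_topics number of planted topics.
#' @param n_shared,n_topic shared / per-topic vocabulary sizes.
#' @param words_per_doc words per document.
#' @param shared_frac expected fraction of shared-vocabulary words per
#'   document.
#' @param seed integer seed.
#' @return A list: `corpus` (data frame `gene`, `text`) and `topic` (named
#'   integer vector of planted assignments).
#' @export
generate_descriptions <- function(gene_ids, k_topics = 3L, n_shared = 40L,
                                  n_topic = 30L, words_per_doc = 60L,
                                  shared_frac = 0.4, seed = 1L) {
  if (length(gene_ids) == 0) stop_input("need at least one gene")
  if (words_per_doc < 1) stop_input("empty descriptions are not allowed")
  if (k_topics < 1) stop_input("k_topics must be >= 1")
  with_seed(seed, {
    shared <- sprintf("common%03d", seq_len(n_shared))
    topics <- lapply(seq_len(k_topics), function(k) {
      sprintf("topic%dterm%03d", k, seq_len(n_topic))
    })
    assign <- stats::setNames(
      rep(seq_len(k_topics), length.out = length(gene_ids))[
        sample.int(length(gene_ids))
      ],
      gene_ids
    )
    docs <- vapply(gene_ids, function(g) {
      k <- assign[[g]]
      n_sh <- stats::rbinom(1, words_per_doc, shared_frac)
      words <- c(
        sample(shared, n_sh, replace = TRUE),
        sample(topics[[k]], words_per_doc - n_sh, replace = TRUE)
      )
      paste(sample(words), collapse = " ")
    }, character(1))
    list(
      corpus = data.frame(
        gene = gene_ids, text = unname(docs), stringsAsFactors = FALSE
      ),
      topic = assign
    )
  })
}

#' Generate survival outcomes with planted methylation effects
#'
#' Event times are exponential; each planted effect site multiplies a
#' sample's hazard by `hazard_ratio` when its beta-value lies above the
#' site's median. Censoring is independent exponential, so every emitted
#' event or censoring time is strictly positive.
#'
#' @param meta cohort sample metadata (see [generate_cohort()]).
#' @param meth methylation [omics_matrix()] (or matrix).
#' @param effect_dms_ids site IDs carrying a survival effect (may be empty).
#' @param hazard_ratio hazard multiplier per high-methylation effect site.
#' @param baseline_hazard,censor_hazard exponential rates of events and
#'   censoring (per unit time).
#' @param seed integer seed.
#' @return `meta` with added columns `time` and `event` (1 = event,
#'   0 = censored); samples without methylation data get baseline hazard.
#' @export
generate_survival <- function(meta, meth, effect_dms_ids = character(0),
                              hazard_ratio = 3, baseline_hazard = 0.1,
                              censor_hazard = 0.05, seed = 1L) {
  beta <- as_values(meth)
  missing <- setdiff(effect_dms_ids, colnames(beta))
  if (length(missing)) {
    stop_input("unknown effect site(s): %s", paste(missing, collapse = ", "))
  }
  with_seed(seed, {
    hazard <- rep(baseline_hazard, nrow(meta))
    for (id in effect_dms_ids) {
      v <- beta[, id]
      high <- rownames(beta)[v > stats::median(v)]
      hazard[meta$sample %in% high] <-
        hazard[meta$sample %in% high] * hazard_ratio
    }
    t_event <- stats::rexp(nrow(meta), rate = hazard)
    t_cens <- stats::rexp(nrow(meta), rate = censor_hazard)
    meta$time <- pmin(t_event, t_cens)
    meta$event <- as.integer(t_event <= t_cens)
    meta
  })
}
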