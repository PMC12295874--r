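#' Position weight matrix
#'
#' A PWM is a 4 x w column-stochastic probability matrix over A, C, G, T
#' with a background distribution. Probabilities are floored at `1e-4` (and
#' columns renormalized) before any log-odds computation so scores stay
#' finite.
#'
#' @param mat 4 x w numeric matrix; rows A, C, G, T; columns sum to 1
#'   within 1e-6.
#' @param name motif name.
#' @param background length-4 background distribution (default uniform).
#' @return An object of class `pwm`.
#' @export
pwm <- function(mat, name = "motif",
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop_input("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1) stop_input("PWM width must be >= 1")
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stop_input("PWM columns must sum to 1 (tolerance 1e-6)")
  }
  if (abs(sum(background) - 1) > 1e-6) {
    stop_input("background must sum to 1")
  }
  rownames(mat) <- c("A", "C", "G", "T")
  background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  structure(list(name = name, mat = mat, background = background),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (width %d)\n", x$name, ncol(x$mat)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Reverse complement of a PWM
#'
#' Columns reversed and rows complemented (A<->T, C<->G); the background is
#' complemented likewise.
#'
#' @param x a [pwm()].
#' @export
reverse_complement_pwm <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mat <- x$mat[comp, rev(seq_len(ncol(x$mat))), drop = FALSE]
  rownames(mat) <- c("A", "C", "G", "T")
  pwm(mat, name = x$name, background = unname(x$background[comp]))
}

# integer log-odds contributions on a fixed grid (units of `grid` bits)
pwm_units <- function(x, grid = 1e-3, floor_p = 1e-4) {
  mat <- pmax(x$mat, floor_p)
  mat <- sweep(mat, 2, colSums(mat), "/")
  lo <- log2(mat / x$background)
  matrix(as.integer(round(lo / grid)), 4, ncol(mat))
}

#' Exact score distribution of a PWM under its background
#'
#' Per-position log-odds contributions are discretized on a fixed grid
#' (default `1e-3` bits) and the distribution of the total score of a
#' random background word is built by position-wise convolution. Tail
#' probabilities are exact for the discretized scores; for small widths they
#' coincide with full enumeration over all `4^w` words.
#'
#' @param x a [pwm()].
#' @param grid score grid in bits.
#' @return An object of class `pwm_score_dist` with elements `grid`,
#'   `units` (discretized log-odds), `offset` (minimum total in grid units)
#'   and `probs` (probability of each achievable total).
#' @export
score_distribution <- function(x, grid = 1e-3) {
  units <- pwm_units(x, grid)
  bg <- x$background
  probs <- 1
  offset <- 0L
  for (j in seq_len(ncol(units))) {
    u <- units[, j]
    lo <- min(u)
    span <- max(u) - lo
    new <- numeric(length(probs) + span)
    for (b in 1:4) {
      k <- u[b] - lo
      idx <- seq.int(1 + k, length(probs) + k)
      new[idx] <- new[idx] + probs * bg[b]
    }
    probs <- new
    offset <- offset + lo
  }
  structure(
    list(grid = grid, units = units, offset = offset, probs = probs,
         tail = rev(cumsum(rev(probs)))),
    class = "pwm_score_dist"
  )
}

#' Tail probability of a PWM score
#'
#' `P(score >= s)` for a random background word, from the discretized exact
#' distribution. Monotone non-increasing in `s`.
#'
#' @param dist a [score_distribution()].
#' @param score score in bits.
#' @export
score_tail_p <- function(dist, score) {
  u <- as.integer(round(score / dist$grid))
  i <- u - dist$offset + 1L
  n <- length(dist$probs)
  vapply(i, function(ii) {
    if (ii <= 1) 1 else if (ii > n) 0 else dist$tail[ii]
  }, numeric(1))
}

# minimum grid-unit score whose tail probability is <= p
score_threshold_units <- function(dist, p) {
  ok <- which(dist$tail <= p)
  if (length(ok) == 0) return(NA_integer_)
  dist$offset + ok[1] - 1L
}

code_sequence <- function(s) {
  match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
}

# total discretized score at every offset of a coded sequence; NA where the
# window contains an unknown base
units_scores <- function(codes, units) {
  w <- ncol(units)
  L <- length(codes)
  if (L < w) return(integer(0))
  n_off <- L - w + 1L
  tot <- numeric(n_off)
  bad <- logical(n_off)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_off - 1L)]
    nas <- is.na(cj)
    bad <- bad | nas
    cj[nas] <- 1L
    tot <- tot + units[cbind(cj, j)]
  }
  tot[bad] <- NA
  as.integer(round(tot))
}

#' Scan sequences for PWM hits with exact p-values
#'
#' Scores every offset of every sequence on both strands with the
#' discretized log-odds and keeps hits whose exact background tail
#' probability is at most `p_threshold`. Sequences shorter than the motif
#' yield no hits (and no error). Windows containing unknown bases are
#' skipped.
#'
#' @param seqs named character vector of sequences.
#' @param x a [pwm()].
#' @param p_threshold significance threshold (default `1e-4`).
#' @param both_strands also scan the reverse complement (default `TRUE`).
#' @param grid score grid in bits.
#' @return Data frame of hits: `seq_id`, `offset` (0-based window start on
#'   the given sequence), `strand`, `width`, `score` (bits), `p`.
#' @export
scan_pwm <- function(seqs, x, p_threshold = 1e-4, both_strands = TRUE,
                     grid = 1e-3) {
  orients <- list(list(pwm = x, strand = "+"))
  if (both_strands) {
    orients <- c(orients, list(list(pwm = reverse_complement_pwm(x),
                                    strand = "-")))
  }
  rows <- list()
  for (o in orients) {
    dist <- score_distribution(o$pwm, grid)
    thr <- score_threshold_units(dist, p_threshold)
    if (is.na(thr)) next
    for (sid in names(seqs)) {
      codes <- code_sequence(seqs[[sid]])
      sc <- units_scores(codes, dist$units)
      hit <- which(!is.na(sc) & sc >= thr)
      if (length(hit) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = sid, offset = hit - 1L, strand = o$strand,
        width = ncol(x$mat), score = sc[hit] * grid,
        p = score_tail_p(dist, sc[hit] * grid),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      seq_id = character(0), offset = integer(0), strand = character(0),
      width = integer(0), score = numeric(0), p = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  out[order(out$seq_id, out$offset, out$strand), , drop = FALSE]
}

# best log-odds score (bits, both strands) per sequence; NA if shorter than w
best_scores <- function(seqs, x, grid = 1e-3) {
  u_f <- pwm_units(x, grid)
  u_r <- pwm_units(reverse_complement_pwm(x), grid)
  vapply(seqs, function(s) {
    codes <- code_sequence(s)
    sc <- c(units_scores(codes, u_f), units_scores(codes, u_r))
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0) NA_real_ else max(sc) * grid
  }, numeric(1))
}

#' Extract fixed windows around methylation sites
#'
#' The window of a site at position `pos` is `[pos - 20, pos + 21)` (41 bp
#' centred on the site), clipped at chromosome ends; clipped and N-containing
#' windows are flagged.
#'
#' @param dms_sites data frame (`site`, `chrom`, `pos`, 0-based positions).
#' @param genome named character vector of chromosome sequences (or a genome
#'   fixture list with a `seq` element).
#' @param flank half-window size in bp (default 20).
#' @return Data frame with `site`, `chrom`, `start`, `end` (genomic, 0-based
#'   half-open), `seq` (uppercase), `clipped`, `has_n`.
#' @export
extract_windows <- function(dms_sites, genome, flank = 20L) {
  if (is.list(genome) && !is.null(genome$seq)) genome <- genome$seq
  unknown <- setdiff(unique(dms_sites$chrom), names(genome))
  if (length(unknown)) {
    bad <- dms_sites$site[dms_sites$chrom %in% unknown][1]
    stop_input("site '%s' lies on unknown chromosome", bad)
  }
  res <- dms_sites[c("site", "chrom", "pos")]
  res$start <- pmax(0L, res$pos - flank)
  lens <- nchar(genome)[res$chrom]
  res$end <- pmin(lens, res$pos + flank + 1L)
  res$seq <- toupper(substr(genome[res$chrom], res$start + 1L, res$end))
  res$clipped <- (res$end - res$start) < (2L * flank + 1L)
  res$has_n <- grepl("[^ACGT]", res$seq)
  res$pos <- NULL
  res
}

#' PWM enrichment of foreground windows against background windows
#'
#' The group statistic of a PWM is the mean, over foreground sequences, of
#' the best per-sequence log-odds score (both strands). The null resamples
#' size-matched sets from the background windows (`n_resamples` times,
#' without replacement when the background is large enough) and the
#' empirical p-value is `(1 + #resamples >= observed) / (1 + n_resamples)`.
#'
#' @param foreground,background character vectors of window sequences.
#' @param pwms list of [pwm()] objects.
#' @param p_cutoff report PWMs with empirical p at or below this (default
#'   `1e-3` requires `n_resamples >= 999`).
#' @param n_resamples background resamples per PWM.
#' @param seed integer seed.
#' @return Data frame with `motif`, `statistic`, `null_mean`, `p`,
#'   `enriched`.
#' @export
motif_enrichment <- function(foreground, background, pwms, p_cutoff = 1e-3,
                             n_resamples = 1000L, seed = 1L) {
  if (length(foreground) == 0) stop_input("empty foreground")
  if (length(background) < 2) stop_input("background too small")
  n_f <- length(foreground)
  replace <- length(background) < n_f
  res <- lapply(pwms, function(pw) {
    fg <- best_scores(foreground, pw)
    bg <- best_scores(background, pw)
    fg <- fg[!is.na(fg)]
    bg_ok <- bg[!is.na(bg)]
    obs <- mean(fg)
    null <- with_seed(seed, {
      vapply(seq_len(n_resamples), function(i) {
        mean(sample(bg_ok, n_f, replace = replace || n_f > length(bg_ok)))
      }, numeric(1))
    })
    p <- (1 + sum(null >= obs - 1e-12)) / (1 + n_resamples)
    data.frame(
      motif = pw$name, statistic = obs, null_mean = mean(null), p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$enriched <- out$p <= p_cutoff
  out
}

#' Keep only motif hits covering a differentially methylated site
#'
#' A hit is retained iff some DMS genomic position lies within the hit's
#' genomic footprint `[start, start + width)`. The intersection uses
#' genomic, not window, coordinates, so clipped windows are handled
#' correctly.
#'
#' @param hits hit data frame from [scan_pwm()] whose `seq_id` values name
#'   rows of `windows`.
#' @param windows window data frame from [extract_windows()].
#' @param dms_sites data frame (`site`, `chrom`, `pos`).
#' @return The retained hits with added `chrom`, `gstart`, `gend`, `dms`.
#' @export
intersect_hits_with_dms <- function(hits, windows, dms_sites) {
  if (nrow(hits) == 0) {
    hits$chrom <- character(0)
    hits$gstart <- integer(0)
    hits$gend <- integer(0)
    hits$dms <- character(0)
    return(hits)
  }
  wi <- match(hits$seq_id, windows$site)
  if (anyNA(wi)) stop_input("hit seq_id not found among windows")
  hits$chrom <- windows$chrom[wi]
  hits$gstart <- windows$start[wi] + hits$offset
  hits$gend <- hits$gstart + hits$width
  hits$dms <- NA_character_
  for (i in seq_len(nrow(hits))) {
    inside <- dms_sites$chrom == hits$chrom[i] &
      dms_sites$pos >= hits$gstart[i] & dms_sites$pos < hits$gend[i]
    if (any(inside)) hits$dms[i] <- dms_sites$site[which(inside)[1]]
  }
  out <- hits[!is.na(hits$dms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sum of per-column Pearson correlations for one ungapped overlap
overlap_corr_sum <- function(ma, mb, off, len) {
  s <- 0
  for (k in seq_len(len)) {
    a <- ma[, off$a + k - 1L]
    b <- mb[, off$b + k - 1L]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    s <- s + stats::cor(a, b)
  }
  s
}

#' Best ungapped local alignment similarity of two PWMs
#'
#' Slides one matrix over the other in both orientations (forward and
#' reverse complement), scoring each ungapped overlap of at least
#' `min_overlap` columns by the sum of per-column Pearson correlations of
#' the base probabilities; the best-scoring alignment is reported with its
#' similarity normalized by overlap length. Ties prefer longer overlaps,
#' then smaller absolute offsets, then the forward orientation. Identical
#' PWMs score exactly 1 at offset 0.
#'
#' @param a,b [pwm()] objects.
#' @param min_overlap minimum aligned columns (default 4, reduced for very
#'   narrow motifs).
#' @return List with `similarity`, `offset` (columns of `b` shifted right
#'   relative to `a`), `orientation` (`"forward"`/`"reverse"`), `overlap`.
#' @export
pwm_similarity <- function(a, b, min_overlap = 4L) {
  wa <- ncol(a$mat)
  wb <- ncol(b$mat)
  minov <- max(1L, min(min_overlap, wa, wb))
  best <- NULL
  for (orient in c("forward", "reverse")) {
    mb <- if (orient == "forward") b$mat else reverse_complement_pwm(b)$mat
    for (off in seq(-(wb - minov), wa - minov)) {
      # columns of b start at position off+1 relative to a's first column
      a0 <- max(1L, off + 1L)
      b0 <- max(1L, 1L - off)
      len <- min(wa - a0 + 1L, wb - b0 + 1L)
      if (len < minov) next
      s <- overlap_corr_sum(a$mat, mb, list(a = a0, b = b0), len)
      cand <- list(
        sum = s, similarity = s / len, offset = off,
        orientation = orient, overlap = len
      )
      if (is.null(best) ||
        cand$sum > best$sum + 1e-12 ||
        (abs(cand$sum - best$sum) <= 1e-12 &&
          (cand$overlap > best$overlap ||
            (cand$overlap == best$overlap &&
              abs(cand$offset) < abs(best$offset))))) {
        best <- cand
      }
    }
  }
  best[c("similarity", "offset", "orientation", "overlap")]
}

#' Pairwise PWM distance matrix
#'
#' `distance = 1 - similarity` from [pwm_similarity()]; symmetric with zero
#' diagonal.
#'
#' @param pwms list of [pwm()] objects.
#' @param min_overlap passed to [pwm_similarity()].
#' @return Symmetric numeric matrix with motif names as dimnames.
#' @export
pwm_distance_matrix <- function(pwms, min_overlap = 4L) {
  n <- length(pwms)
  d <- matrix(0, n, n)
  nm <- vapply(pwms, function(p) p$name, character(1))
  dimnames(d) <- list(nm, nm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      s <- pwm_similarity(pwms[[i]], pwms[[j]], min_overlap)$similarity
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  d
}

#' UPGMA (average-linkage) agglomeration with deterministic tie-breaking
#'
#' Standard unweighted pair-group agglomeration: the closest pair of
#' clusters merges at height `d/2` (so leaves sit at height 0 and the tree
#' is ultrametric) and distances update as size-weighted averages. Ties are
#' broken lexicographically by each cluster's smallest member label, making
#' the tree fully deterministic. Merge heights are non-decreasing.
#'
#' @param d symmetric distance matrix with labels, or a `dist`.
#' @return An `hclust`-compatible object (class `c("upgma", "hclust")`) with
#'   `merge`, `height` (merge heights, `d/2`), `order`, and `labels`; usable
#'   with [stats::cutree()] and convertible via `ape::as.phylo()`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("L", seq_len(n))
  if (n == 1) {
    return(structure(
      list(
        merge = matrix(integer(0), 0, 2), height = numeric(0),
        order = 1L, labels = labels, method = "upgma"
      ),
      class = c("upgma", "hclust")
    ))
  }
  active <- seq_len(n)
  id <- -seq_len(n) # hclust convention: negatives are leaves
  size <- rep(1L, n)
  rep_label <- labels
  dm <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        dij <- dm[i, j]
        key <- sort(c(rep_label[i], rep_label[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
            (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i
    j <- best$j
    merge[step, ] <- c(id[i], id[j])[order(c(id[i], id[j]))]
    height[step] <- best$d / 2
    newd <- (size[i] * dm[i, ] + size[j] * dm[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(
      cbind(dm[keep, keep, drop = FALSE], newd[keep]),
      c(newd[keep], 0)
    )
    id <- c(id[keep], step)
    size <- c(size[keep], size[i] + size[j])
    rep_label <- c(rep_label[keep], min(rep_label[c(i, j)]))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    active <- seq_len(k - 1)
  }
  ord <- members[[length(members)]]
  structure(
    list(
      merge = merge, height = height, order = ord, labels = labels,
      method = "upgma"
    ),
    class = c("upgma", "hclust")
  )
}
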