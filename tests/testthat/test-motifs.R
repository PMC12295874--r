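test_that("window extraction is 41 bp, clipped and flagged at edges", {
  genome <- c(chr1 = random_sequence(5000, seed = 1))
  sites <- data.frame(
    site = c("mid", "edge"), chrom = "chr1", pos = c(1000, 5)
  )
  w <- extract_windows(sites, genome)
  expect_equal(nchar(w$seq[1]), 41)
  expect_equal(w$start[1], 980)
  expect_equal(w$end[1], 1021)
  expect_false(w$clipped[1])
  expect_equal(nchar(w$seq[2]), 26) # left-clipped at position 5
  expect_true(w$clipped[2])
  expect_error(
    extract_windows(
      data.frame(site = "ghost", chrom = "chrX", pos = 1), genome
    ),
    "ghost"
  )
})

test_that("a uniform PWM equal to background scores 0 with certainty", {
  u <- pwm(matrix(0.25, 4, 3), "uniform")
  d <- score_distribution(u)
  expect_equal(score_tail_p(d, 0), 1)
  expect_equal(score_tail_p(d, 0.01), 0)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
})

test_that("an all-A dinucleotide PWM puts 1/16 mass on its top score", {
  m <- matrix(0, 4, 2)
  m[1, ] <- 1
  pw <- pwm(m, "AA")
  d <- score_distribution(pw)
  top <- (d$offset + length(d$probs) - 1) * d$grid
  expect_equal(top, 4, tolerance = 0.01) # ~2 bits per position
  expect_equal(score_tail_p(d, top), 1 / 16, tolerance = 1e-12)
})

test_that("tail probabilities match exhaustive enumeration for small widths", {
  for (w in 3:6) {
    pw <- random_pwm(w, seed = w)
    d <- score_distribution(pw)
    units <- mcfsomics:::pwm_units(pw)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- words
    word_scores <- vapply(seq_len(nrow(words)), function(i) {
      sum(units[cbind(words[i, ], seq_len(w))])
    }, numeric(1))
    probs <- apply(words, 1, function(wd) prod(pw$background[wd]))
    thrs <- sort(unique(word_scores))
    thrs <- thrs[round(c(0.05, 0.5, 0.9, 1) * (length(thrs) - 1)) + 1]
    for (thr in thrs) {
      expect_equal(
        score_tail_p(d, thr * d$grid),
        sum(probs[word_scores >= thr]),
        tolerance = 1e-9
      )
    }
    # monotone non-increasing tails
    ts <- score_tail_p(d, seq(min(word_scores), max(word_scores)) * d$grid)
    expect_true(all(diff(ts) <= 1e-15))
  }
})

test_that("scanning recovers a planted consensus site on either strand", {
  pw <- consensus_pwm(8)
  consensus <- "ACGTACGT"
  seqs <- c(
    fwd = paste0(random_sequence(30, 2), consensus, random_sequence(30, 3))
  )
  h <- scan_pwm(seqs, pw, p_threshold = 1e-4)
  expect_true(30 %in% h$offset[h$seq_id == "fwd"])
  # strand symmetry: the reverse complement yields mirrored hits with
  # identical scores and p-values
  rc <- c(fwd = revcomp_chr(seqs[["fwd"]]))
  h2 <- scan_pwm(rc, pw, p_threshold = 1e-4)
  expect_equal(nrow(h), nrow(h2))
  L <- nchar(seqs[["fwd"]])
  mirrored <- sort(L - 8 - h2$offset)
  expect_equal(sort(h$offset), mirrored)
  expect_equal(sort(h$score), sort(h2$score))
  expect_equal(sort(h$p), sort(h2$p))
  # shorter than the motif: no hits, no error
  expect_equal(nrow(scan_pwm(c(s = "ACGT"), pw)), 0)
})

test_that("background hit counts sit at the Poisson scale of the p cutoff", {
  pw <- consensus_pwm(8)
  hits <- vapply(1:10, function(s) {
    nrow(scan_pwm(c(x = random_sequence(10000, s + 100)), pw,
      p_threshold = 1e-3
    ))
  }, numeric(1))
  expected <- 2 * (10000 - 8 + 1) * 1e-3
  expect_lt(abs(mean(hits) - expected), 3 * sqrt(expected))
})

test_that("motif enrichment flags a planted motif and not a null set", {
  pw <- consensus_pwm(8)
  set.seed(9)
  bg <- vapply(1:120, function(i) random_sequence(41, i + 500), character(1))
  fg_null <- bg[1:40]
  fg_planted <- vapply(41:80, function(i) {
    s <- bg[i]
    if (i %% 2 == 0) s <- paste0(substr(s, 1, 16), "ACGTACGT", substr(s, 25, 41))
    s
  }, character(1))
  r0 <- motif_enrichment(fg_null, bg[41:120], list(pw), n_resamples = 499)
  expect_false(any(r0$enriched))
  r1 <- motif_enrichment(fg_planted, bg[c(1:40, 81:120)], list(pw),
    n_resamples = 1999, seed = 2
  )
  expect_true(all(r1$enriched))
  expect_lte(r1$p, 1e-3)
  expect_error(motif_enrichment(character(0), bg, list(pw)), "empty")
})

test_that("hit-DMS intersection uses genomic coordinates", {
  windows <- data.frame(
    site = "s1", chrom = "chr1", start = 980, end = 1021,
    seq = NA, clipped = FALSE, has_n = FALSE, stringsAsFactors = FALSE
  )
  sites <- data.frame(site = "s1", chrom = "chr1", pos = 1000)
  hits <- data.frame(
    seq_id = "s1", offset = c(16, 2), strand = "+", width = 8,
    score = 10, p = 1e-5, stringsAsFactors = FALSE
  )
  kept <- intersect_hits_with_dms(hits, windows, sites)
  # offset 16 -> genomic [996, 1004) spans the centre base; offset 2 does not
  expect_equal(kept$offset, 16)
  expect_equal(kept$gstart, 996)
  expect_equal(kept$dms, "s1")
  # clipped window: genomic offsets shift with the clipped start
  wclip <- data.frame(
    site = "s2", chrom = "chr1", start = 0, end = 26,
    seq = NA, clipped = TRUE, has_n = FALSE, stringsAsFactors = FALSE
  )
  sclip <- data.frame(site = "s2", chrom = "chr1", pos = 5)
  hclip <- data.frame(
    seq_id = "s2", offset = c(0, 10), strand = "+", width = 8,
    score = 10, p = 1e-5, stringsAsFactors = FALSE
  )
  kept2 <- intersect_hits_with_dms(hclip, wclip, sclip)
  expect_equal(kept2$offset, 0) # [0, 8) covers pos 5; [10, 18) does not
})

test_that("PWM similarity is exact for identity and reverse complement", {
  a <- random_pwm(8, "A", seed = 11)
  s <- pwm_similarity(a, a)
  expect_equal(s$similarity, 1, tolerance = 1e-12)
  expect_equal(s$offset, 0)
  expect_equal(s$orientation, "forward")
  rc <- reverse_complement_pwm(a)
  s2 <- pwm_similarity(a, rc)
  expect_equal(s2$similarity, 1, tolerance = 1e-12)
  expect_equal(s2$orientation, "reverse")
  # symmetry of the distance matrix
  b <- random_pwm(6, "B", seed = 12)
  expect_equal(
    pwm_similarity(a, b)$similarity, pwm_similarity(b, a)$similarity,
    tolerance = 1e-12
  )
})

test_that("PWM similarity matches a brute-force alignment search", {
  for (seeds in list(c(21, 22), c(23, 24), c(25, 26))) {
    a <- random_pwm(8, "A", seed = seeds[1])
    b <- random_pwm(8, "B", seed = seeds[2])
    brute_sum <- -Inf
    for (orient in 1:2) {
      mb <- if (orient == 1) b$mat else reverse_complement_pwm(b)$mat
      for (off in -4:4) {
        cols_a <- max(1, off + 1):min(8, 8 + off)
        cols_b <- cols_a - off
        if (length(cols_a) < 4) next
        s <- sum(vapply(seq_along(cols_a), function(k) {
          ca <- a$mat[, cols_a[k]]
          cb <- mb[, cols_b[k]]
          if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
            0
          } else {
            stats::cor(ca, cb)
          }
        }, numeric(1)))
        if (s > brute_sum) brute_sum <- s
      }
    }
    got <- pwm_similarity(a, b)
    expect_equal(got$similarity * got$overlap, brute_sum, tolerance = 1e-9)
  }
  a <- random_pwm(8, "A", seed = 21)
  b <- random_pwm(8, "B", seed = 22)
  got <- pwm_similarity(a, b)
  d <- pwm_distance_matrix(list(a, b))
  expect_equal(d["A", "B"], 1 - got$similarity, tolerance = 1e-12)
  expect_equal(d, t(d))
})

test_that("UPGMA reproduces hand arithmetic and matches hclust heights", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  hc <- upgma(d)
  expect_equal(hc$height, c(1, 3)) # merge (A,B) at 1, then C at 3
  expect_equal(hc$merge[1, ], c(-2, -1))
  # equal distances: all merges at the same height, resolved by tie rule
  de <- matrix(1, 4, 4) - diag(4)
  dimnames(de) <- list(letters[1:4], letters[1:4])
  he <- upgma(de)
  expect_equal(he$height, rep(0.5, 3))
  # single leaf
  h1 <- upgma(matrix(0, 1, 1, dimnames = list("A", "A")))
  expect_equal(h1$labels, "A")
  expect_equal(length(h1$height), 0)
  # cross-check against average-linkage hclust on a random matrix
  set.seed(30)
  x <- matrix(rnorm(60), 12, 5)
  dm <- as.matrix(stats::dist(x))
  dimnames(dm) <- list(paste0("L", 1:12), paste0("L", 1:12))
  ours <- upgma(dm)
  ref <- stats::hclust(stats::as.dist(dm), method = "average")
  expect_equal(sort(ours$height * 2), sort(ref$height), tolerance = 1e-9)
  expect_true(all(diff(ours$height) >= -1e-12)) # non-decreasing merges
  for (k in c(2, 4, 6)) {
    t1 <- stats::cutree(ours, k)
    t2 <- stats::cutree(ref, k)
    expect_equal(
      mclust::adjustedRandIndex(t1, t2), 1
    )
  }
})
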