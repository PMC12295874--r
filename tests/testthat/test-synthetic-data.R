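test_that("cohort generation is deterministic and respects invariants", {
  co <- small_cohort()
  co2 <- generate_cohort(cohort_spec(
    n_cancer = 30, n_normal = 10, p_mrna = 60, p_mirna = 50,
    p_meth = 70, k_informative = 5, effect_size = 2, seed = 42
  ))
  expect_identical(co, co2)
  expect_true(all(co$meth$values >= 0 & co$meth$values <= 1))
  expect_true(all(co$mrna$values >= 0))
  expect_true(all(apply(co$mrna$values, 2, stats::var) > 0))
  expect_true(all(apply(co$meth$values, 2, stats::var) > 0))
  # layer matrices hold exactly the samples carrying that layer
  expect_setequal(rownames(co$mrna$values), co$meta$sample[co$meta$has_mrna])
  # incomplete samples miss at least one layer
  inc <- !co$meta$complete
  expect_true(all(rowSums(co$meta[inc, c("has_mrna", "has_mirna", "has_meth")]) < 3))
  # planted IDs exist in the matrices
  expect_true(all(co$truth$informative$meth %in% colnames(co$meth$values)))
  expect_true(all(co$truth$informative$mrna %in% colnames(co$mrna$values)))
})

test_that("zero effect size leaves planted features indistinguishable", {
  co <- generate_cohort(cohort_spec(
    n_cancer = 60, n_normal = 60, p_mrna = 40, p_mirna = 10, p_meth = 10,
    k_informative = 10, effect_size = 0, seed = 5, complete_fraction = 1
  ))
  g <- co$meta$group
  ps <- vapply(co$truth$informative$mrna, function(f) {
    stats::wilcox.test(
      co$mrna$values[g == "cancer", f], co$mrna$values[g == "normal", f],
      exact = FALSE
    )$p.value
  }, numeric(1))
  expect_true(all(ps > 1e-3)) # no planted signal at effect 0
})

test_that("a strong planted beta shift is detected by a rank-sum test", {
  # cancer-group mean 0.8 vs normal 0.2 at an informative site
  co <- generate_cohort(cohort_spec(
    n_cancer = 100, n_normal = 20, p_mrna = 5, p_mirna = 5, p_meth = 50,
    k_informative = 4, beta_shift = 0.6, seed = 8, complete_fraction = 1
  ))
  g <- co$meta$group
  hyper <- names(co$truth$dms_label)[co$truth$dms_label == "hyper"][1]
  v <- co$meth$values[, hyper]
  expect_gt(mean(v[g == "cancer"]), mean(v[g == "normal"]))
  p <- stats::wilcox.test(
    v[g == "cancer"], v[g == "normal"], exact = FALSE
  )$p.value
  expect_lt(p, 1e-6)
  # planted labels agree with the methylation log2FC convention
  lab <- methylation_log2fc(co$meth$values, g)
  expect_equal(
    lab$label[match(names(co$truth$dms_label), lab$site)],
    unname(co$truth$dms_label)
  )
})

test_that("infeasible beta shifts are rejected", {
  expect_error(
    cohort_spec(beta_shift = 1.1), "infeasible"
  )
  expect_error(cohort_spec(k_informative = 50, p_mirna = 10), "k_informative")
})

test_that("genome fixture tiles chromatin states and places sites uniquely", {
  co <- small_cohort()
  g <- generate_genome_fixture(colnames(co$meth$values),
    n_chrom = 2, chrom_len = 60000, n_genes = 12, n_cpgi = 10, seed = 3
  )
  for (ch in c("chr1", "chr2")) {
    st <- g$states[as.character(GenomeInfoDb::seqnames(g$states)) == ch]
    st <- st[order(BiocGenerics::start(st))]
    expect_equal(sum(BiocGenerics::width(st)), 60000) # full cover
    expect_equal(BiocGenerics::start(st)[1], 1)
    expect_true(all(
      BiocGenerics::start(st)[-1] == utils::head(BiocGenerics::end(st), -1) + 1
    )) # no overlap, no gap
  }
  # bijection: every site id has exactly one (chrom, pos)
  expect_setequal(g$sites$site, colnames(co$meth$values))
  expect_false(anyDuplicated(g$sites$site) > 0)
  expect_false(anyDuplicated(g$sites[c("chrom", "pos")]) > 0)
  # BED round trip of a planted interval is verbatim
  tmp <- tempfile(fileext = ".bed")
  write_bed(g$cpgi, tmp)
  back <- read_bed(tmp)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(g$cpgi))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(g$cpgi))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(g$cpgi)$name)
})

test_that("planted motifs are rediscovered by scanning the 41-bp window", {
  co <- small_cohort()
  g <- generate_genome_fixture(colnames(co$meth$values),
    n_chrom = 2, chrom_len = 60000, n_genes = 5, n_cpgi = 5, seed = 3
  )
  pw <- consensus_pwm(8)
  ids <- g$sites$site[1:6]
  g2 <- plant_motifs(g, list(pw), ids, seed = 11)
  expect_equal(nrow(g2$insertion_log), 6)
  w <- extract_windows(g$sites[g$sites$site %in% ids, ], g2)
  hits <- scan_pwm(stats::setNames(w$seq, w$site), pw, p_threshold = 1e-4)
  for (id in ids) {
    h <- hits[hits$seq_id == id, ]
    expect_gt(nrow(h), 0)
    # a hit overlaps the site (window centre), in genomic coordinates
    ih <- intersect_hits_with_dms(h, w, g$sites)
    expect_gt(nrow(ih), 0)
    expect_true(all(ih$p <= 1e-4))
  }
  # planted words stay inside the window even at chromosome edges
  log <- g2$insertion_log
  pos <- g$sites$pos[match(log$site, g$sites$site)]
  expect_true(all(log$start >= pmax(0, pos - 20)))
  expect_true(all(log$end <= pos + 21))
  # no planting requested -> genome unchanged
  g3 <- plant_motifs(g, list(pw), character(0))
  expect_identical(g3$seq, g$seq)
})

test_that("description corpus carries recoverable planted topics", {
  d <- generate_descriptions(sprintf("g%02d", 1:12), k_topics = 3, seed = 2)
  expect_equal(nrow(d$corpus), 12)
  expect_true(all(nchar(d$corpus$text) > 0))
  expect_setequal(unique(d$topic), 1:3)
  expect_error(
    generate_descriptions(sprintf("g%02d", 1:5), words_per_doc = 0), "empty"
  )
})

test_that("survival times are positive and effects are planted reproducibly", {
  co <- small_cohort()
  id <- colnames(co$meth$values)[1]
  m1 <- generate_survival(co$meta, co$meth, id, hazard_ratio = 3, seed = 4)
  m2 <- generate_survival(co$meta, co$meth, id, hazard_ratio = 3, seed = 4)
  expect_identical(m1, m2)
  expect_true(all(m1$time > 0))
  expect_true(all(m1$event %in% c(0, 1)))
  expect_error(
    generate_survival(co$meta, co$meth, "nope", seed = 1), "unknown effect"
  )
})
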