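make_cpgi <- function(starts, ends, chrom = "chr1") {
  mcfsomics:::df_to_granges(data.frame(
    chrom = chrom, start = starts, end = ends,
    name = paste0("cpgi", seq_along(starts)), stringsAsFactors = FALSE
  ))
}

make_genes <- function(starts, ends, strands, names, chrom = "chr1") {
  mcfsomics:::df_to_granges(data.frame(
    chrom = chrom, start = starts, end = ends, name = names,
    strand = strands, stringsAsFactors = FALSE
  ))
}

test_that("CpG context follows island/shore/shelf/open-sea distances", {
  cpgi <- make_cpgi(10000, 10500)
  sites <- data.frame(
    site = paste0("s", 1:5), chrom = "chr1",
    pos = c(10250, 9000, 7000, 5000, 9999)
  )
  expect_equal(
    cpg_context(sites, cpgi),
    c("island", "shore", "shelf", "open_sea", "shore")
  )
  # two islands 1000 bp apart: the gap is entirely shore
  cpgi2 <- make_cpgi(c(10000, 11500), c(10500, 12000))
  gap <- data.frame(
    site = paste0("g", 1:3), chrom = "chr1", pos = c(10501, 11000, 11499)
  )
  expect_equal(cpg_context(gap, cpgi2), rep("shore", 3))
  # unknown chromosome falls through to open sea
  off <- data.frame(site = "x", chrom = "chr9", pos = 100)
  expect_equal(cpg_context(off, cpgi), "open_sea")
})

test_that("gene context applies promoter > gene body > intergenic precedence", {
  genes <- make_genes(
    starts = c(50000, 80000), ends = c(60000, 90000),
    strands = c("+", "-"), names = c("geneA", "geneB")
  )
  sites <- data.frame(
    site = paste0("s", 1:4), chrom = "chr1",
    pos = c(48500, 55000, 65000, 89000)
  )
  ctx <- gene_context(sites, genes)
  expect_equal(ctx$context, c("promoter", "gene_body", "intergenic", "promoter"))
  expect_equal(ctx$gene, c("geneA", "geneA", "geneA", "geneB"))
  # minus-strand TSS is the interval end: site at 89000 is within 2000 of
  # geneB's TSS at 89999
  expect_equal(ctx$tss_distance[4], 999)

  # a site inside one gene's body but within another promoter -> promoter wins
  genes2 <- make_genes(
    starts = c(1000, 12000), ends = c(11000, 20000),
    strands = c("+", "+"), names = c("host", "nextdoor")
  )
  s <- data.frame(site = "x", chrom = "chr1", pos = 10500)
  ctx2 <- gene_context(s, genes2)
  expect_equal(ctx2$context, "promoter")
  expect_equal(ctx2$gene, "nextdoor")

  # equidistant TSSs break ties lexicographically
  genes3 <- make_genes(
    starts = c(1000, 3000), ends = c(1500, 3500),
    strands = c("+", "+"), names = c("alpha", "beta")
  )
  s3 <- data.frame(site = "x", chrom = "chr1", pos = 2000)
  expect_equal(gene_context(s3, genes3)$gene, "alpha")
})

test_that("methylation log2FC labels follow the declared convention", {
  beta <- cbind(
    hyper_site = c(rep(0.8, 5), rep(0.2, 5)),
    flat_site = rep(0.5, 10),
    hypo_site = c(rep(0.2, 5), rep(0.8, 5))
  )
  rownames(beta) <- paste0("s", 1:10)
  groups <- rep(c("cancer", "normal"), each = 5)
  r <- methylation_log2fc(beta, groups)
  expect_equal(r$log2fc, c(-2, 0, 2), tolerance = 1e-4)
  expect_equal(r$label, c("hyper", "medium", "hypo"))
  # antisymmetry under swapping group labels
  r2 <- methylation_log2fc(beta, rev(groups))
  expect_equal(r2$log2fc, -r$log2fc, tolerance = 1e-12)
  expect_equal(r2$label, c("hypo", "medium", "hyper"))
})

test_that("expression log2FC uses the cancer-over-normal orientation", {
  x <- cbind(down = c(rep(1, 4), rep(2, 4)), up = c(rep(4, 4), rep(1, 4)))
  rownames(x) <- paste0("s", 1:8)
  groups <- rep(c("cancer", "normal"), each = 4)
  lfc <- expression_log2fc(x, groups)
  expect_equal(unname(lfc), c(-1, 2), tolerance = 1e-5)
})

test_that("differential test flags a planted shift and skips tiny groups", {
  set.seed(1)
  x <- matrix(rnorm(120 * 20), 120, 20,
    dimnames = list(paste0("s", 1:120), paste0("f", 1:20))
  )
  g <- rep(c("cancer", "normal"), each = 60)
  x[g == "cancer", 1] <- x[g == "cancer", 1] + 2 # 2 pooled SDs
  r <- differential_test(x, g)
  expect_lt(r$q[1], 0.05)
  expect_gt(min(r$p, na.rm = TRUE), 0) # p-values well-defined
  g2 <- c(rep("cancer", 2), rep("normal", 118))
  expect_warning(r2 <- differential_test(x, g2), "skipped")
  expect_true(all(is.na(r2$p)))
})

test_that("region enrichment calls a planted island excess and nothing null", {
  set.seed(2)
  regions <- c("island", "shore", "shelf", "open_sea")
  background <- sample(regions, 4000, replace = TRUE,
    prob = c(0.25, 0.25, 0.25, 0.25)
  )
  null_obs <- sample(regions, 2000, replace = TRUE,
    prob = c(0.25, 0.25, 0.25, 0.25)
  )
  r0 <- region_enrichment(null_obs, background)
  expect_true(all(r0$direction == "none"))
  planted <- sample(regions, 2000, replace = TRUE,
    prob = c(0.5, 1 / 6, 1 / 6, 1 / 6)
  )
  r1 <- region_enrichment(planted, background)
  isl <- r1[r1$region == "island", ]
  expect_lt(isl$p_bonferroni, 0.05)
  expect_equal(isl$direction, "enriched")
  expect_warning(
    region_enrichment(c("a"), c("a"), regions = c("a", "b")), "absent"
  )
})

test_that("chromatin-state resampling null attains its extreme p exactly", {
  co <- small_cohort()
  g <- generate_genome_fixture(colnames(co$meth$values),
    n_chrom = 2, chrom_len = 60000, n_genes = 5, n_cpgi = 5, seed = 3
  )
  # plant: every tested DMS inside one chosen state
  st <- mcfsomics:::site_states(g$sites, g$states)
  target <- names(sort(table(st), decreasing = TRUE))[1]
  dms <- g$sites[st == target, ][1:10, ]
  r <- chromatin_state_enrichment(dms, g$states, g$sites,
    n_draws = 200, seed = 5
  )
  expect_equal(r$p_enriched[r$state == target], 1 / 201)
  expect_true(all(r$p_enriched > 0 & r$p_enriched <= 1))
  expect_true(all(r$p_enriched + r$p_depleted >= 1))
  expect_true(all(r$p_two_sided <= 1))
  expect_error(
    chromatin_state_enrichment(dms, g$states, g$sites, n_draws = 0), "n_draws"
  )
})

test_that("cis correlation respects the window and finds a planted pair", {
  set.seed(4)
  n <- 60
  genes <- make_genes(50000, 60000, "+", "geneA")
  sites <- data.frame(
    site = c("near", "far", "flat"), chrom = "chr1",
    pos = c(100000, 2050000, 120000)
  )
  expr <- matrix(rnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "geneA"))
  beta <- cbind(
    near = drop(1 / (1 + exp(-scale(expr[, 1])))) + rnorm(n, sd = 0.01),
    far = runif(n), flat = rep(0.4, n)
  )
  rownames(beta) <- rownames(expr)
  r <- cis_correlation(expr, beta, genes, sites)
  expect_false("far" %in% r$site) # 2 Mbp away: never tested
  expect_false("flat" %in% r$site) # constant beta: skipped
  hit <- r[r$site == "near", ]
  expect_true(hit$significant)
  expect_gte(abs(hit$rho), 0.6)
})

test_that("survival screen detects a planted hazard and skips constant sites", {
  set.seed(6)
  n <- 200
  beta <- cbind(
    effect = runif(n), flat = rep(0.3, n), noise = runif(n)
  )
  rownames(beta) <- paste0("s", 1:n)
  meta <- data.frame(sample = rownames(beta), stringsAsFactors = FALSE)
  surv <- generate_survival(meta, beta, "effect", hazard_ratio = 3, seed = 7)
  r <- survival_screen(beta, surv)
  expect_false("flat" %in% r$site)
  expect_lt(r$p[r$site == "effect"], 0.01)
  # ties at the median go to the low group
  expect_equal(r$n_high[r$site == "effect"], n / 2)
  nulls <- survival_bootstrap_null(beta[, c("effect", "noise")], surv,
    set_size = 1, n_rounds = 10, seed = 2
  )
  expect_length(nulls, 10)
  expect_true(all(nulls %in% 0:1))
})
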