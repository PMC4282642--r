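test_that("percent editing pools read-bases over union positions", {
  sheet <- data.frame(sample_id = c("wt_rep1", "mut_rep1"),
                      genotype = c("wt", "mut"), replicate = 1L,
                      role = "test")
  mk_sites <- function(edited_wt, cov_wt, edited_mut, cov_mut) {
    k <- length(edited_wt)
    rbind(
      data.frame(region_id = "region0001", chrom = "c1",
                 pos = 100L + seq_len(k) * 10L, strand = "+",
                 gene_id = "g", sample_id = "wt_rep1",
                 edited = edited_wt, coverage = cov_wt,
                 candidate = edited_wt > 0, untestable = FALSE),
      data.frame(region_id = "region0001", chrom = "c1",
                 pos = 100L + seq_len(k) * 10L, strand = "+",
                 gene_id = "g", sample_id = "mut_rep1",
                 edited = edited_mut, coverage = cov_mut,
                 candidate = edited_mut > 0, untestable = FALSE))
  }
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(110, 130),
                               strand = "+")
  S4Vectors::mcols(gr)$region_id <- "region0001"
  S4Vectors::mcols(gr)$gene_id <- "g"
  S4Vectors::mcols(gr)$n_sites <- 2L
  # one position, 8 of 20 reads
  er <- new("EditedRegions", regions = gr,
            sites = mk_sites(8L, 20L, 1L, 20L),
            samples = sheet)
  expect_equal(unname(regionPercentEditing(er, "wt")), 0.4)
  # two positions 3/10 and 1/10 pool to 4/20
  er2 <- new("EditedRegions", regions = gr,
             sites = mk_sites(c(3L, 1L), c(10L, 10L), c(2L, 2L),
                              c(10L, 10L)),
             samples = sheet)
  expect_equal(unname(regionPercentEditing(er2, "wt")), 0.2)
  # all-reference genotype at union positions gives exactly zero
  er3 <- new("EditedRegions", regions = gr,
             sites = mk_sites(c(0L, 0L), c(30L, 30L), c(5L, 5L),
                              c(30L, 30L)),
             samples = sheet)
  expect_equal(unname(regionPercentEditing(er3, "wt")), 0)
})

test_that("region comparison reproduces the pooled z-test arithmetic", {
  er <- regionsFromCounts(k1 = c(20L, 30L, 10L), n1 = c(100L, 107L, 100L),
                         k2 = c(20L, 0L, 14L), n2 = c(100L, 122L, 100L))
  cmp <- compareRegions(er, "wt", "mut")
  # equal proportions: z = 0, p = 1
  expect_equal(cmp$z[1], 0)
  expect_equal(cmp$p[1], 1)
  # 30/107 vs 0/122 matches the pooled formula and is overwhelming
  zt <- twoProportionZTest(0, 122, 30, 107)
  expect_equal(cmp$z[2], zt$z)
  expect_lt(cmp$p[2], 1e-9)
  # 0.10 vs 0.14 is a 1.4-fold increase
  expect_equal(cmp$fold_change[3], 1.4)
  expect_true(all(cmp$well_represented))
})

test_that("regions below the read threshold are flagged, not tested", {
  er <- regionsFromCounts(k1 = c(5L, 5L), n1 = c(15L, 50L),
                         k2 = c(8L, 8L), n2 = c(15L, 50L))
  cmp <- compareRegions(er, "wt", "mut", min_reads = 20L)
  expect_false(cmp$well_represented[1])
  expect_true(is.na(cmp$z[1]))
  expect_false(cmp$significant[1])
  expect_true(cmp$well_represented[2])
  expect_false(is.na(cmp$z[2]))
  # the threshold is strict: exactly 20 reads is not well represented
  er20 <- regionsFromCounts(4L, 20L, 5L, 21L)
  expect_false(compareRegions(er20, "wt", "mut")$well_represented[1])
})

test_that("percent editing is invariant to region partitioning", {
  # same sites split into one or two regions: pooled totals agree
  sheet <- data.frame(sample_id = "wt_rep1", genotype = "wt",
                      replicate = 1L, role = "test")
  st <- data.frame(chrom = "c1", pos = c(100L, 150L, 600L), strand = "+",
                   gene_id = "g", ref = "A", sample_id = "wt_rep1",
                   genotype = "wt", role = "test",
                   edited = c(3L, 4L, 5L), coverage = c(10L, 10L, 20L),
                   candidate = TRUE, untestable = FALSE)
  one <- mergeRegions(st, sheet, max_gap = 1000L)
  two <- mergeRegions(st, sheet, max_gap = 100L)
  expect_equal(length(regionRanges(one)), 1L)
  expect_equal(length(regionRanges(two)), 2L)
  p1 <- regionPercentEditing(one, "wt", union_over = "wt")
  p2 <- regionPercentEditing(two, "wt", union_over = "wt")
  tot1 <- p1 * 40
  tot2 <- sum(p2 * c(20, 20))
  expect_equal(unname(tot1), tot2)   # pooled edited reads conserved
})

test_that("null regions are called at close to the nominal rate", {
  set.seed(42)
  n <- 400L
  k1 <- rbinom(n, 100, 0.2)
  k2 <- rbinom(n, 100, 0.2)
  er <- regionsFromCounts(k1, rep(100L, n), k2, rep(100L, n))
  cmp <- compareRegions(er, "wt", "mut", alpha = 0.05)
  frac <- mean(cmp$significant)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("power against a 1.4-fold shift matches the analytic value", {
  set.seed(43)
  n <- 400L
  cov <- 500L
  k1 <- rbinom(n, cov, 0.10)
  k2 <- rbinom(n, cov, 0.14)
  er <- regionsFromCounts(k1, rep(cov, n), k2, rep(cov, n))
  cmp <- compareRegions(er, "wt", "mut", alpha = 0.05)
  # analytic power of the pooled two-proportion z-test
  pbar <- 0.12
  se0 <- sqrt(2 * pbar * (1 - pbar) / cov)
  se1 <- sqrt((0.1 * 0.9 + 0.14 * 0.86) / cov)
  pow <- pnorm((0.04 - qnorm(0.975) * se0) / se1) +
    pnorm((-0.04 - qnorm(0.975) * se0) / se1)
  expect_lt(abs(mean(cmp$significant) - pow),
            3 * sqrt(pow * (1 - pow) / n) + 0.02)
  # unshifted regions stay near the nominal level
  k2n <- rbinom(n, cov, 0.10)
  ern <- regionsFromCounts(k1, rep(cov, n), k2n, rep(cov, n))
  expect_lt(mean(compareRegions(ern, "wt", "mut")$significant), 0.1)
})

test_that("the editing summary degrades gracefully and counts correctly", {
  empty <- summarizeEditing(compareRegions(
    regionsFromCounts(integer(), integer(), integer(), integer()),
    "wt", "mut"))
  expect_equal(empty$n_regions, 0L)
  expect_true(is.na(empty$frac_significant))
  er <- regionsFromCounts(k1 = c(10L, 10L, 40L), n1 = rep(200L, 3),
                         k2 = c(60L, 10L, 5L), n2 = rep(200L, 3))
  s <- summarizeEditing(compareRegions(er, "wt", "mut"))
  expect_equal(s$n_well_represented, 3L)
  expect_equal(s$n_significant, 2L)
  expect_equal(s$n_increased, 1L)
  expect_equal(s$n_decreased, 1L)
  expect_equal(s$frac_increased_among_significant, 0.5)
  expect_equal(s$mean_fold_increase, 6)
})

test_that("the per-site-averaged alternative is exposed and differs", {
  sheet <- data.frame(sample_id = c("wt_rep1", "mut_rep1"),
                      genotype = c("wt", "mut"), replicate = 1L,
                      role = "test")
  st <- rbind(
    data.frame(region_id = "region0001", chrom = "c1", pos = c(110L, 120L),
               strand = "+", gene_id = "g", sample_id = "wt_rep1",
               edited = c(9L, 1L), coverage = c(10L, 90L),
               candidate = TRUE, untestable = FALSE),
    data.frame(region_id = "region0001", chrom = "c1", pos = c(110L, 120L),
               strand = "+", gene_id = "g", sample_id = "mut_rep1",
               edited = c(5L, 5L), coverage = c(10L, 90L),
               candidate = TRUE, untestable = FALSE))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(110, 120),
                               strand = "+")
  S4Vectors::mcols(gr)$region_id <- "region0001"
  S4Vectors::mcols(gr)$gene_id <- "g"
  S4Vectors::mcols(gr)$n_sites <- 2L
  er <- new("EditedRegions", regions = gr, sites = st, samples = sheet)
  pooled <- compareRegions(er, "wt", "mut")
  averaged <- compareRegions(er, "wt", "mut", per_site_average = TRUE)
  expect_equal(pooled$percent_wt, 0.1)            # 10 of 100 read-bases
  expect_equal(averaged$percent_wt, (0.9 + 1 / 90) / 2)
})
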