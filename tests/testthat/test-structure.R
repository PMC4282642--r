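test_that("antisense pairs require opposite strands and enough overlap", {
  mk <- function(sa, sb, a_start = 101L, a_end = 500L, b_start = 401L,
                 b_end = 700L) {
    GeneModels(c("ga", "gb"), list(
      GenomicRanges::GRanges("c1", IRanges::IRanges(a_start, a_end),
                             strand = sa),
      GenomicRanges::GRanges("c1", IRanges::IRanges(b_start, b_end),
                             strand = sb)))
  }
  p <- findAntisensePairs(mk("+", "-"), min_overlap = 40L)
  expect_equal(nrow(p), 1L)
  expect_equal(p$overlap_bp, 100L)
  expect_equal(p$gene_a, "ga")
  # same strand: no pair
  expect_equal(nrow(findAntisensePairs(mk("+", "+"))), 0L)
  # overlap of 10 below the threshold
  expect_equal(nrow(findAntisensePairs(
    mk("+", "-", b_start = 491L, b_end = 800L), min_overlap = 40L)), 0L)
})

test_that("antisense pairing is symmetric and strand-flip covariant", {
  cfg <- smallConfig(rng_seed = 30L)
  sim <- simulateReference(cfg)
  p <- findAntisensePairs(sim$models)
  expect_true(all(p$gene_a < p$gene_b))
  # flipping every strand leaves the pair set unchanged
  flipped <- GeneModels(geneIds(sim$models),
    lapply(seq_along(geneIds(sim$models)), function(i) {
      ex <- exonsByGene(sim$models)[[i]]
      GenomicRanges::GRanges(
        GenomicRanges::seqnames(ex), IRanges::ranges(ex),
        strand = ifelse(as.character(strand(ex)) == "+", "-", "+"))
    }))
  p2 <- findAntisensePairs(flipped)
  expect_equal(p, p2)
  # planted pairs are all found
  tp <- sim$truth@antisensePairs
  key <- paste(pmin(tp$gene_a, tp$gene_b), pmax(tp$gene_a, tp$gene_b))
  expect_true(all(key %in% paste(p$gene_a, p$gene_b)))
})

test_that("inverted repeats are found exactly where constructed", {
  set.seed(55)
  arm <- "ACGTACGTACGTACGTACGT"
  # AAAA flanks cannot pair with themselves, pinning the arm boundaries
  seqv <- paste0(randDNA(96), "AAAA", arm, "TTTTT", revComp(arm), "AAAA",
                 randDNA(96))
  ir <- findInvertedRepeats(seqv, min_arm = 20L, min_loop = 3L)
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$loop_length, 5L)
  expect_equal(ir$identity, 1)
  expect_equal(ir$arm_a_start, 101L)
  expect_equal(ir$arm_b_end, 145L)
  # homopolymers cannot pair with their own reverse complement
  expect_equal(nrow(findInvertedRepeats(strrep("A", 500))), 0L)
  # arms below the seed size are refused
  expect_error(findInvertedRepeats(seqv, min_arm = 8L), "seed")
})

test_that("a bridged mismatch is tolerated within the identity bound", {
  set.seed(56)
  host <- randDNA(600)
  s <- plantIR(host, arm_len = 30L, loop_len = 40L, at = 200L,
               n_mismatch = 1L)
  ir <- findInvertedRepeats(s, min_arm = 25L, min_identity = 0.9)
  expect_equal(nrow(ir), 1L)
  # the arm may be extended by chance flank matches, never truncated
  expect_gte(ir$arm_length, 30L)
  expect_gte(ir$identity, 0.9)
  expect_lt(ir$identity, 1)
  # with perfect identity demanded the bridged chain is rejected
  expect_equal(nrow(findInvertedRepeats(s, min_arm = 25L,
                                        min_identity = 1)), 0L)
})

test_that("the seed-and-extend finder equals the brute-force oracle", {
  set.seed(57)
  settings <- list(list(min_arm = 20L, max_loop = 2000L,
                        min_identity = 0.85),
                   list(min_arm = 12L, max_loop = 500L,
                        min_identity = 1.0),
                   list(min_arm = 25L, max_loop = 100L,
                        min_identity = 0.9))
  for (i in 1:8) {
    host <- randDNA(1200)
    s <- switch(1L + (i %% 4),
                host,
                plantIR(host, 30L, 50L, 300L, n_mismatch = 0L),
                plantIR(host, 40L, 80L, 500L, n_mismatch = 2L),
                plantIR(plantIR(host, 25L, 30L, 200L), 20L, 400L, 700L))
    chains <- oracleIRChains(s)
    for (st in settings) {
      want <- oracleIRFilter(chains, st$min_arm, st$max_loop,
                             st$min_identity)
      got <- findInvertedRepeats(s, min_arm = st$min_arm,
                                 max_loop = st$max_loop,
                                 min_identity = st$min_identity)
      got <- got[, c("arm_a_start", "arm_a_end", "arm_b_start",
                     "arm_b_end")]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("UG-repeat tracts are strand-aware maximal runs", {
  genome <- Biostrings::DNAStringSet(c(
    c1 = "AATGTGTGTGTGTGAA",          # TG x 6
    c2 = paste0("AA", strrep("TG", 5), "AA"),  # TG x 5: below threshold
    c3 = "CACACACACACA"))             # CA x 6: UG on the minus strand
  ug <- findUGRepeats(genome, min_units = 6L)
  expect_equal(length(ug), 2L)
  on1 <- ug[as.character(GenomicRanges::seqnames(ug)) == "c1"]
  expect_equal(start(on1), 3L)
  expect_equal(end(on1), 14L)
  expect_equal(as.character(strand(on1)), "+")
  on3 <- ug[as.character(GenomicRanges::seqnames(ug)) == "c3"]
  expect_equal(as.character(strand(on3)), "-")
  expect_equal(S4Vectors::mcols(on3)$n_units, 6L)
  expect_error(findUGRepeats(genome, min_units = 1L), ">= 2")
})

test_that("overlap statistics reproduce printed-ratio formatting", {
  # 2,061 of 5,587 queries overlapping rounds to 37%
  q <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(seq_len(5587) * 10L, width = 5L))
  s <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(1L, 2061L * 10L + 5L))
  st <- intervalOverlapStats(q, s)
  expect_equal(st$n_overlapping, 2061L)
  expect_equal(round(100 * st$fraction), 37)
  # disjoint and identical sets
  expect_equal(intervalOverlapStats(q[1:5], GenomicRanges::shift(
    q[1:5], 10000L))$fraction, 0)
  expect_equal(intervalOverlapStats(q, q)$fraction, 1)
  expect_warning(st0 <- intervalOverlapStats(q[0], s), "empty")
  expect_true(is.na(st0$fraction))
})

test_that("gene classification recovers the generator's truth exactly", {
  cfg <- smallConfig(rng_seed = 31L)
  sim <- simulateReference(cfg)
  cls <- classifyGenes(sim$models, sim$genome, sim$truth@repeats)
  truth <- sim$truth
  want_as <- sort(unique(c(truth@antisensePairs$gene_a,
                           truth@antisensePairs$gene_b)))
  expect_equal(sort(cls$gene_id[cls$has_antisense_overlap]), want_as)
  expect_equal(sort(cls$gene_id[cls$n_intronic_irs > 0]),
               sort(truth@invertedRepeats$gene_id))
  want_rep <- geneIds(sim$models)[GenomicRanges::countOverlaps(
    geneRanges(sim$models), truth@repeats, ignore.strand = TRUE) > 0]
  expect_equal(cls$gene_id[cls$overlaps_repeat_annotation], want_rep)
  want_struct <- sort(
    truth@enrichedFeatures$feature_id[truth@enrichedFeatures$structured])
  expect_true(all(want_struct %in% cls$gene_id[cls$dsrna_structured]))
})

test_that("the long-intron restriction excludes short-intron repeats", {
  set.seed(58)
  # gene with an 800 bp intron carrying a perfect inverted repeat
  intron <- plantIR(randDNA(800), 25L, 40L, 300L)
  chrom <- paste0(randDNA(150), intron, randDNA(150))
  genome <- Biostrings::DNAStringSet(c(c1 = chrom))
  m <- GeneModels("g1", list(
    GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 951),
                                                  c(150, 1100)),
                           strand = "+")))
  cls <- classifyGenes(m, genome, GenomicRanges::GRanges())
  expect_equal(cls$n_intronic_irs, 0L)
  expect_gte(cls$n_irs_any_intron, 1L)
  expect_false(cls$multi_ir_or_repeat)
})
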