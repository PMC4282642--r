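test_that("candidate calling follows the strand-aware A-to-I signature", {
  m <- tinyModels()
  pu <- rbind(
    pileupRow("c1", 150L, "A", A = 12L, G = 8L),          # + gene: call
    pileupRow("c1", 160L, "C", C = 5L, T = 5L),           # wrong class
    pileupRow("c1", 170L, "A", A = 50L, G = 1L),          # below min reads
    pileupRow("c1", 180L, "A", A = 98L, G = 2L),          # below min frac
    pileupRow("c1", 1050L, "T", T = 9L, C = 3L),          # - gene: call
    pileupRow("c1", 1060L, "A", A = 5L, G = 5L),          # A->G on - gene
    pileupRow("c1", 5000L, "A", A = 5L, G = 5L))          # intergenic
  sites <- callCandidateSites(pu, m, min_edited_reads = 2L,
                              min_fraction = 0.05)
  called <- sites[sites$candidate, ]
  expect_equal(sort(called$pos), c(150L, 1050L))
  expect_equal(called$strand[called$pos == 150L], "+")
  expect_equal(called$strand[called$pos == 1050L], "-")
  expect_equal(called$edited[called$pos == 150L] /
                 called$coverage[called$pos == 150L], 0.4)
  expect_equal(called$gene_id[called$pos == 1050L], "gminus")
})

test_that("positions under genes on both strands are ambiguous", {
  m <- GeneModels(c("fwd", "rev"), list(
    GenomicRanges::GRanges("c1", IRanges::IRanges(100, 500), strand = "+"),
    GenomicRanges::GRanges("c1", IRanges::IRanges(400, 800), strand = "-")))
  pu <- rbind(pileupRow("c1", 450L, "A", A = 10L, G = 10L),
              pileupRow("c1", 150L, "A", A = 10L, G = 10L))
  expect_message(sites <- callCandidateSites(pu, m), "both strands")
  expect_equal(sites$pos[sites$candidate], 150L)
  # unanchored mode calls both orientations with strand "."
  un <- callCandidateSites(pu, m, unanchored = TRUE)
  expect_setequal(un$pos[un$candidate], c(150L, 450L))
  expect_true(all(un$strand == "."))
})

test_that("replicate-consistency and control subtraction filter sites", {
  sheet <- data.frame(
    sample_id = c("wt_rep1", "wt_rep2", "wt_rep3", "adr2_rep1"),
    genotype = c("wt", "wt", "wt", "adr2"),
    replicate = c(1L, 2L, 3L, 1L),
    role = c("test", "test", "test", "control"))
  m <- tinyModels()
  mk <- function(pos, gcounts, ctrl_g = 0L, ctrl_cov = 30L) {
    rbind(
      pileupRow("c1", pos, "A", A = 20L, G = gcounts[1], sample = "wt_rep1"),
      pileupRow("c1", pos, "A", A = 20L, G = gcounts[2], sample = "wt_rep2"),
      pileupRow("c1", pos, "A", A = 20L, G = gcounts[3], sample = "wt_rep3"),
      pileupRow("c1", pos, "A", A = ctrl_cov, G = ctrl_g,
                sample = "adr2_rep1"))
  }
  pu <- rbind(mk(110L, c(5L, 6L, 7L)),            # kept
              mk(120L, c(5L, 6L, 0L)),            # fails one replicate
              mk(130L, c(5L, 6L, 7L), ctrl_g = 4L),   # control candidate
              mk(140L, c(5L, 6L, 7L), ctrl_cov = 3L)) # untestable control
  sites <- callCandidateSites(pu, m)
  kept <- filterCandidates(sites, sheet, min_control_coverage = 10L)
  expect_setequal(unique(kept$pos), c(110L, 140L))
  expect_false(any(kept$untestable[kept$pos == 110L]))
  expect_true(all(kept$untestable[kept$pos == 140L]))
  expect_error(filterCandidates(sites, within(sheet, role <- "test")),
               "control")
})

test_that("sites merge into regions by gap and gene, conserving counts", {
  sheet <- data.frame(sample_id = c("wt_rep1", "adr2_rep1"),
                      genotype = c("wt", "adr2"), replicate = 1L,
                      role = c("test", "control"))
  st <- data.frame(chrom = "c1", pos = c(100L, 150L, 400L),
                   strand = "+", gene_id = "g", ref = "A",
                   sample_id = "wt_rep1", genotype = "wt", role = "test",
                   edited = c(3L, 4L, 5L), coverage = c(10L, 11L, 12L),
                   candidate = TRUE, untestable = FALSE)
  er <- mergeRegions(st, sheet, max_gap = 100L)
  reg <- regionRanges(er)
  expect_equal(length(reg), 2L)
  expect_equal(start(reg), c(100L, 400L))
  expect_equal(end(reg), c(150L, 400L))
  expect_equal(S4Vectors::mcols(reg)$n_sites, c(2L, 1L))
  # pooled counts equal the sums over member sites
  pct <- regionPercentEditing(er, "wt", union_over = "wt")
  expect_equal(unname(pct), c((3 + 4) / (10 + 11), 5 / 12))
  # a single site forms its own region
  er1 <- mergeRegions(st[1, ], sheet, max_gap = 100L)
  expect_equal(length(regionRanges(er1)), 1L)
  # sites on different genes never merge
  st2 <- st
  st2$gene_id <- c("g", "h", "h")
  er2 <- mergeRegions(st2, sheet, max_gap = 500L)
  expect_equal(length(regionRanges(er2)), 2L)
})

test_that("SAM and pileup-TSV routes produce identical columns", {
  set.seed(1234)
  genome <- Biostrings::DNAStringSet(c(c1 = randDNA(3000)))
  reads <- simulateReads(genome, "c1", start = 500L, end = 1500L,
                         n_reads = 300L, edit_pos = c(700L, 900L),
                         edit_frac = c(0.5, 0.3))
  sam <- tempfile(fileext = ".sam")
  writeSAM(reads, genome, sam)
  via_sam <- buildPileup(sam, genome = genome, sample_id = "s1")
  via_reads <- pileupFromReads(reads, genome, sample_id = "s1")
  tsv <- tempfile(fileext = ".tsv")
  writePileupTable(via_reads, tsv)
  via_tsv <- buildPileup(tsv)
  for (col in c("chrom", "pos", "ref", "A", "C", "G", "T", "N"))
    expect_equal(via_sam[[col]], via_tsv[[col]], label = col)
})

test_that("unsorted pileup TSVs are rejected", {
  pu <- rbind(pileupRow("c1", 200L, "A", A = 5L),
              pileupRow("c1", 100L, "A", A = 5L))
  tsv <- tempfile(fileext = ".tsv")
  writePileupTable(pu, tsv)
  expect_error(buildPileup(tsv), "sorted")
})

test_that("planted regions are recovered and the ADAR-null stays silent", {
  cfg <- smallConfig(rng_seed = 20L, coverage_mean = 50,
                     per_site_edit_fraction = c(wt = 0.3, tdp1 = 0.3,
                                                adr2 = 0),
                     frac_regions_altered = 0)
  sim <- simulateReference(cfg)
  pl <- simulateEditingPileups(sim$genome, sim$models, sim$truth, cfg)
  sites <- callCandidateSites(pl$pileup, sim$models)
  kept <- filterCandidates(sites, pl$samples)
  er <- mergeRegions(kept, pl$samples)
  truth_key <- paste(
    as.character(GenomicRanges::seqnames(sim$truth@editedSites)),
    start(sim$truth@editedSites))
  called_key <- unique(paste(regionSites(er)$chrom, regionSites(er)$pos))
  recall <- mean(truth_key %in% called_key)
  fdr <- if (length(called_key)) mean(!(called_key %in% truth_key)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.05)
  expect_equal(length(regionRanges(er)), 8L)
  # region-level truth recovery with >= 80% site overlap per region
  ov <- GenomicRanges::countOverlaps(regionRanges(er),
                                     sim$truth@editedSites,
                                     ignore.strand = TRUE)
  expect_true(all(ov / cfg$sites_per_region >= 0.8))
  # the ADAR-null genotype itself yields no replicate-consistent calls
  ctrl_ids <- pl$samples$sample_id[pl$samples$genotype == "adr2"]
  ctrl <- sites[sites$sample_id %in% ctrl_ids & sites$candidate, ]
  consistent <- table(paste(ctrl$chrom, ctrl$pos))
  expect_equal(sum(consistent == length(ctrl_ids)), 0L)
})

test_that("region calls are covariant under genome reverse-complement", {
  # one plus-strand gene with two editing sites; flip the world and the
  # same regions must appear at mirrored coordinates
  L <- 2000L
  set.seed(77)
  base <- strsplit(randDNA(L), "")[[1]]
  base[c(500, 520)] <- "A"
  genome <- Biostrings::DNAStringSet(c(c1 = paste(base, collapse = "")))
  m <- GeneModels("g1", list(
    GenomicRanges::GRanges("c1", IRanges::IRanges(c(200, 900),
                                                  c(600, 1200)),
                           strand = "+")))
  sheet <- data.frame(sample_id = c("wt_rep1", "adr2_rep1"),
                      genotype = c("wt", "adr2"), replicate = 1L,
                      role = c("test", "control"))
  pu <- rbind(
    pileupRow("c1", 500L, "A", A = 10L, G = 10L, sample = "wt_rep1"),
    pileupRow("c1", 520L, "A", A = 12L, G = 8L, sample = "wt_rep1"),
    pileupRow("c1", 500L, "A", A = 20L, sample = "adr2_rep1"),
    pileupRow("c1", 520L, "A", A = 20L, sample = "adr2_rep1"))
  er <- mergeRegions(filterCandidates(
    callCandidateSites(pu, m), sheet), sheet)
  # mirrored dataset
  flip <- function(p) L - p + 1L
  mg <- GeneModels("g1", list(
    GenomicRanges::GRanges("c1", IRanges::IRanges(flip(c(1200, 600)),
                                                  flip(c(900, 200))),
                           strand = "-")))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pu2 <- pu
  pu2$pos <- flip(pu$pos)
  pu2$ref <- unname(comp[pu$ref])
  tmp <- pu2$A; pu2$A <- pu2$T; pu2$T <- tmp
  tmp <- pu2$C; pu2$C <- pu2$G; pu2$G <- tmp
  er2 <- mergeRegions(filterCandidates(
    callCandidateSites(pu2, mg), sheet), sheet)
  r1 <- regionRanges(er)
  r2 <- regionRanges(er2)
  expect_equal(length(r1), length(r2))
  expect_equal(sort(flip(end(r1))), sort(start(r2)))
  expect_equal(sort(flip(start(r1))), sort(end(r2)))
})
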