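# shared fixtures, built in code at test time

# a compact simulation configuration for unit tests
smallConfig <- function(...) {
  base <- list(n_chroms = 2L, chrom_length = 60000L, n_genes = 30L,
               n_ir_introns = 2L, n_edited_regions = 8L,
               sites_per_region = 10L, fraction_antisense_pairs = 0.2,
               n_repeats = 6L, n_peaks = 10L, n_enriched = 8L,
               n_diff = 4L)
  do.call(simConfig, utils::modifyList(base, list(...)))
}

# hand-built two-gene models: one gene per strand, non-overlapping
tinyModels <- function() {
  GeneModels(
    geneIds = c("gplus", "gminus"),
    exons = list(
      GenomicRanges::GRanges("c1", IRanges::IRanges(c(101, 301),
                                                    c(200, 400)),
                             strand = "+"),
      GenomicRanges::GRanges("c1", IRanges::IRanges(c(1001, 1201),
                                                    c(1100, 1300)),
                             strand = "-")))
}

# one pileup row in the internal (1-based) layout
pileupRow <- function(chrom, pos, ref, A = 0L, C = 0L, G = 0L, T = 0L,
                      N = 0L, sample = "s1") {
  data.table::data.table(chrom = chrom, pos = pos, ref = ref, A = A,
                         C = C, G = G, T = T, N = N, sample = sample)
}

# minimal truth object carrying only IP enrichment information
ipTruth <- function(feature_ids, enriched = character(),
                    ip_fold = 4, diff = character(), diff_fold = 2.5) {
  ef <- data.frame(feature_id = feature_ids,
                   ip_fold = ifelse(feature_ids %in% enriched, ip_fold, 1),
                   diff_fold = ifelse(feature_ids %in% diff, diff_fold, 1),
                   structured = FALSE, stringsAsFactors = FALSE)
  new("SyntheticTruth",
      editedSites = GenomicRanges::GRanges(),
      antisensePairs = data.frame(),
      invertedRepeats = data.frame(),
      repeats = GenomicRanges::GRanges(),
      peaks = GenomicRanges::GRanges(),
      enrichedFeatures = ef)
}

# an EditedRegions object built directly from per-region 2x2 counts,
# one site and one sample per genotype (for the z-test layers)
regionsFromCounts <- function(k1, n1, k2, n2,
                              genotypes = c("wt", "mut")) {
  nr <- length(k1)
  rid <- sprintf("region%04d", seq_len(nr))
  samples <- data.frame(sample_id = paste0(genotypes, "_rep1"),
                        genotype = genotypes, replicate = 1L,
                        role = "test", stringsAsFactors = FALSE)
  sites <- rbind(
    data.frame(region_id = rid, chrom = rep("c1", nr),
               pos = seq_len(nr) * 10L,
               strand = rep("+", nr), gene_id = rid,
               sample_id = rep(paste0(genotypes[1], "_rep1"), nr),
               edited = k1, coverage = n1,
               candidate = rep(TRUE, nr), untestable = rep(FALSE, nr)),
    data.frame(region_id = rid, chrom = rep("c1", nr),
               pos = seq_len(nr) * 10L,
               strand = rep("+", nr), gene_id = rid,
               sample_id = rep(paste0(genotypes[2], "_rep1"), nr),
               edited = k2, coverage = n2,
               candidate = rep(TRUE, nr), untestable = rep(FALSE, nr)))
  regions <- if (nr) {
    GenomicRanges::GRanges("c1",
      IRanges::IRanges(seq_len(nr) * 10L, seq_len(nr) * 10L),
      strand = "+")
  } else GenomicRanges::GRanges()
  S4Vectors::mcols(regions)$region_id <- rid
  S4Vectors::mcols(regions)$gene_id <- rid
  S4Vectors::mcols(regions)$n_sites <- rep(1L, nr)
  new("EditedRegions", regions = regions, sites = sites,
      samples = samples)
}

# random DNA string
randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
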