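#' Run the complete dsRNA analysis pipeline on a synthetic dataset
#'
#' Orchestrates simulate, editing calling, region comparison, structural
#' annotation, IP enrichment and differential IP into one reproducible run.
#' Every stage reads its inputs from the files the previous stage wrote.
#' All thresholds, the seed and md5 checksums of every output are recorded
#' in a JSON manifest, so a rerun with an identical configuration is
#' byte-identical.
#'
#' @param config A \code{\link{simConfig}}.
#' @param outdir Run directory (created; existing files overwritten).
#' @param thresholds Named list overriding any of the default analysis
#'   thresholds: min_edited_reads, min_fraction, min_control_coverage,
#'   max_gap, alpha, min_region_reads, min_overlap, min_arm, max_loop,
#'   min_identity, min_ir_intron, ug_min_units, min_fold, fdr, min_count,
#'   min_intron_length.
#' @return Invisibly, a list with the run summaries and output paths.
#' @export
runPipeline <- function(config, outdir, thresholds = list()) {
  th <- utils::modifyList(list(
    min_edited_reads = 2L, min_fraction = 0.05, min_control_coverage = 10L,
    max_gap = 100L, alpha = 0.05, min_region_reads = 20L,
    min_overlap = 40L, min_arm = 20L, max_loop = 2000L,
    min_identity = 0.85, min_ir_intron = 1000L, ug_min_units = 6L,
    min_fold = 1.5, fdr = 0.1, min_count = 10L,
    min_intron_length = 250L), thresholds)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: simulation, written to disk
  simdir <- file.path(outdir, "sim")
  paths <- writeSimulation(config, simdir)

  # stage 2: editing calling from the written files
  genome <- readGenome(paths$genome)
  models <- readAnnotation(paths$annotation)
  pileup <- readPileupTable(paths$pileup)
  psheet <- utils::read.delim(paths$pileup_samples)
  sites <- callCandidateSites(pileup, models,
                              min_edited_reads = th$min_edited_reads,
                              min_fraction = th$min_fraction)
  filt <- filterCandidates(sites, psheet,
                           min_control_coverage = th$min_control_coverage)
  er <- mergeRegions(filt, psheet, max_gap = th$max_gap)
  out_sites <- file.path(outdir, "sites.tsv")
  out_regions <- file.path(outdir, "regions.tsv")
  out_bed <- file.path(outdir, "regions.bed")
  utils::write.table(regionSites(er), out_sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  reg <- regionRanges(er)
  utils::write.table(data.frame(
    region_id = mcols(reg)$region_id, gene_id = mcols(reg)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(reg)),
    start = start(reg), end = end(reg),
    strand = as.character(strand(reg)), n_sites = mcols(reg)$n_sites),
    out_regions, sep = "\t", quote = FALSE, row.names = FALSE)
  regbed <- reg
  mcols(regbed)$name <- mcols(reg)$region_id
  writeBed(regbed, out_bed)

  # stage 3: editing comparison between the two test genotypes
  test_g <- unique(psheet$genotype[psheet$role == "test"])
  cmp <- compareRegions(er, test_g[1], test_g[2], alpha = th$alpha,
                        min_reads = th$min_region_reads)
  out_cmp <- file.path(outdir, "editing_comparison.tsv")
  utils::write.table(cmp, out_cmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  esum <- summarizeEditing(cmp)

  # stage 4: structural annotation
  repeats <- readBed(paths$repeats)
  peaks <- readBed(paths$peaks)
  pairs <- findAntisensePairs(models, min_overlap = th$min_overlap)
  cls <- classifyGenes(models, genome, repeats, pairs = pairs,
                       min_ir_intron = th$min_ir_intron,
                       min_arm = th$min_arm, max_loop = th$max_loop,
                       min_identity = th$min_identity)
  ug <- findUGRepeats(genome, min_units = th$ug_min_units)
  ovst <- intervalOverlapStats(peaks, repeats)
  out_pairs <- file.path(outdir, "antisense_pairs.tsv")
  out_cls <- file.path(outdir, "gene_structure.tsv")
  out_ug <- file.path(outdir, "ug_repeats.bed")
  out_ov <- file.path(outdir, "overlap_stats.tsv")
  utils::write.table(pairs, out_pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cls, out_cls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ugbed <- ug
  if (length(ugbed)) mcols(ugbed)$name <- sprintf("ug%04d",
                                                  seq_along(ugbed))
  writeBed(ugbed, out_ug)
  utils::write.table(data.frame(query = "peaks", subject = "repeats",
                                n_overlapping = ovst$n_overlapping,
                                n_total = ovst$n_total,
                                fraction = ovst$fraction),
                     out_ov, sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 5: IP enrichment and differential IP from the written counts
  ctab <- utils::read.delim(paths$counts, check.names = FALSE)
  csheet <- utils::read.delim(paths$count_samples)
  cntm <- as.matrix(ctab[, -1, drop = FALSE])
  rownames(cntm) <- ctab$feature_id
  flen <- width(geneRanges(models))[match(ctab$feature_id,
                                          geneIds(models))]
  ipx <- IPExperiment(cntm, lengths = flen, samples = csheet)
  ip_g <- unique(csheet$genotype)
  enr <- lapply(ip_g, function(g)
    suppressMessages(callEnriched(ipx, g, min_fold = th$min_fold,
                                  alpha = th$alpha,
                                  min_count = th$min_count)))
  names(enr) <- ip_g
  out_enr <- file.path(outdir, sprintf("ip_enrichment_%s.tsv", ip_g))
  for (i in seq_along(ip_g))
    utils::write.table(enr[[i]], out_enr[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  diff <- suppressMessages(
    differentialIP(ipx, ip_g[1], ip_g[2], alpha = th$alpha, fdr = th$fdr,
                   min_count = th$min_count))
  out_diff <- file.path(outdir, "ip_differential.tsv")
  utils::write.table(diff, out_diff, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # stage 6: category enrichment of IP-enriched genes among structured
  universe <- cls$gene_id
  enr_genes <- enr[[1]]$feature_id[enr[[1]]$enriched]
  cat_enr <- categoryEnrichment(enr_genes,
                                cls$gene_id[cls$dsrna_structured],
                                universe)
  out_cat <- file.path(outdir, "category_enrichment.tsv")
  utils::write.table(cat_enr, out_cat, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  outputs <- c(unlist(paths), sites = out_sites, regions = out_regions,
               regions_bed = out_bed, editing_comparison = out_cmp,
               antisense_pairs = out_pairs, gene_structure = out_cls,
               ug_repeats = out_ug, overlap_stats = out_ov,
               stats::setNames(out_enr, sprintf("ip_enrichment_%s", ip_g)),
               ip_differential = out_diff, category_enrichment = out_cat)
  manifest <- list(
    tool = "dsRNAtools",
    version = as.character(utils::packageVersion("dsRNAtools")),
    seed = config$rng_seed,
    config = config[setdiff(names(config), character(0))],
    thresholds = th,
    checksums = as.list(tools::md5sum(unname(outputs))))
  names(manifest$checksums) <- names(outputs)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report_path <- writeReport(outdir)
  invisible(list(outdir = outdir, outputs = outputs,
                 manifest = manifest_path, report = report_path,
                 editing_summary = esum, comparisons = cmp,
                 enrichment = enr, differential = diff,
                 classification = cls, overlap_stats = ovst,
                 regions = er))
}

.reportSection <- function(lines, title) c(lines, "", title,
                                           strrep("-", nchar(title)))

#' Write a plain-text summary report for a pipeline run
#'
#' Reads only the TSV outputs under the run directory; sections whose input
#' files are missing are marked as missing rather than failing. Regenerating
#' the report is idempotent.
#'
#' @param run_dir A directory produced by \code{\link{runPipeline}}.
#' @return Invisibly, the report path.
#' @export
writeReport <- function(run_dir) {
  L <- c("dsRNAtools run report", strrep("=", 21))
  f <- function(name) file.path(run_dir, name)

  L <- .reportSection(L, "Edited regions")
  if (file.exists(f("regions.tsv"))) {
    reg <- utils::read.delim(f("regions.tsv"))
    L <- c(L, sprintf("regions called: %d", nrow(reg)),
           sprintf("mean sites per region: %.1f",
                   if (nrow(reg)) mean(reg$n_sites) else 0))
  } else L <- c(L, "[missing]")

  L <- .reportSection(L, "Region editing comparison")
  if (file.exists(f("editing_comparison.tsv"))) {
    cmp <- utils::read.delim(f("editing_comparison.tsv"))
    s <- summarizeEditing(cmp)
    L <- c(L,
      sprintf("well represented: %d of %d", s$n_well_represented,
              s$n_regions),
      sprintf("significantly altered: %d (%.0f%% of well represented)",
              s$n_significant, 100 * ifelse(is.na(s$frac_significant), 0,
                                            s$frac_significant)),
      sprintf("increased among significant: %d (%.0f%%)", s$n_increased,
              100 * ifelse(is.na(s$frac_increased_among_significant), 0,
                           s$frac_increased_among_significant)),
      sprintf("mean fold change among increased: %.2f",
              ifelse(is.na(s$mean_fold_increase), 0,
                     s$mean_fold_increase)))
  } else L <- c(L, "[missing]")

  L <- .reportSection(L, "Structural annotation")
  if (file.exists(f("gene_structure.tsv"))) {
    cls <- utils::read.delim(f("gene_structure.tsv"))
    L <- c(L,
      sprintf("genes: %d", nrow(cls)),
      sprintf("antisense overlap: %d", sum(cls$has_antisense_overlap)),
      sprintf("long-intron inverted repeats: %d genes",
              sum(cls$n_intronic_irs > 0)),
      sprintf("repeat overlap: %d", sum(cls$overlaps_repeat_annotation)),
      sprintf("dsRNA-structured: %d", sum(cls$dsrna_structured)))
  } else L <- c(L, "[missing]")

  L <- .reportSection(L, "Interval overlap")
  if (file.exists(f("overlap_stats.tsv"))) {
    ov <- utils::read.delim(f("overlap_stats.tsv"))
    L <- c(L, sprintf("%s vs %s: %d/%d (%.0f%%)", ov$query, ov$subject,
                      ov$n_overlapping, ov$n_total, 100 * ov$fraction))
  } else L <- c(L, "[missing]")

  L <- .reportSection(L, "IP enrichment")
  enr_files <- list.files(run_dir, pattern = "^ip_enrichment_.*\\.tsv$",
                          full.names = TRUE)
  if (length(enr_files)) {
    for (ef in sort(enr_files)) {
      e <- utils::read.delim(ef)
      L <- c(L, sprintf("%s: %d of %d features enriched",
                        sub("^ip_enrichment_(.*)\\.tsv$", "\\1",
                            basename(ef)), sum(e$enriched), nrow(e)))
    }
  } else L <- c(L, "[missing]")

  L <- .reportSection(L, "Differential IP")
  if (file.exists(f("ip_differential.tsv"))) {
    d <- utils::read.delim(f("ip_differential.tsv"))
    L <- c(L, sprintf("tested: %d; significant: %d (up %d, down %d)",
                      nrow(d), sum(d$significant),
                      sum(d$significant & d$direction == "up"),
                      sum(d$significant & d$direction == "down")))
  } else L <- c(L, "[missing]")

  L <- .reportSection(L, "Category enrichment")
  if (file.exists(f("category_enrichment.tsv"))) {
    ce <- utils::read.delim(f("category_enrichment.tsv"))
    L <- c(L, sprintf(
      "structured among IP-enriched: %d/%d (expected %.1f), p = %.3g",
      ce$overlap, ce$set_size, ce$expected, ce$p))
  } else L <- c(L, "[missing]")

  path <- file.path(run_dir, "report.txt")
  writeLines(L, path)
  invisible(path)
}
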