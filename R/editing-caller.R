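#' Build per-position pileup columns from alignments or a pileup TSV
#'
#' Two input routes produce identical columns: a SAM/BAM file (parsed via
#' Rsamtools; SAM is converted and coordinate-sorted first) or a pileup TSV
#' (see \code{\link{readPileupTable}}) that bypasses alignment parsing.
#' One column is emitted per covered position per sample; deletions and
#' clipped bases are excluded; zero-coverage positions are not emitted.
#'
#' @param input Path to a \code{.sam}/\code{.bam} file or a pileup TSV.
#' @param genome Optional \link[Biostrings]{DNAStringSet}; required for the
#'   SAM route (reference bases), and used to check that reference sequence
#'   names match.
#' @param sample_id Sample label for the SAM route.
#' @return A data.table with columns chrom, pos (1-based), ref, A, C, G, T,
#'   N, sample.
#' @export
buildPileup <- function(input, genome = NULL, sample_id = NULL) {
  if (grepl("\\.(sam|bam)$", input, ignore.case = TRUE)) {
    if (is.null(genome))
      stop("the SAM/BAM route requires 'genome' for reference bases")
    if (is.null(sample_id)) sample_id <- sub("\\.(sam|bam)$", "",
                                             basename(input))
    bam <- if (grepl("\\.sam$", input, ignore.case = TRUE)) {
      Rsamtools::asBam(input, tempfile(), overwrite = TRUE,
                       indexDestination = TRUE)
    } else input
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (!all(names(hdr) %in% names(genome)))
      stop("alignment reference names not present in genome: ",
           paste(setdiff(names(hdr), names(genome)), collapse = ", "))
    pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                                 min_mapq = 0L, min_nucleotide_depth = 1L,
                                 distinguish_strands = FALSE,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    res <- Rsamtools::pileup(bam, pileupParam = pp)
    dt <- data.table::as.data.table(res)
    dt <- dt[dt$nucleotide %in% c("A", "C", "G", "T", "N")]
    wide <- data.table::dcast(dt, seqnames + pos ~ nucleotide,
                              value.var = "count", fill = 0L)
    for (b in c("A", "C", "G", "T", "N"))
      if (is.null(wide[[b]])) wide[, (b) := 0L]
    data.table::setnames(wide, "seqnames", "chrom")
    wide[, "chrom" := as.character(wide$chrom)]
    refs <- vapply(seq_len(nrow(wide)), function(i)
      substr(as.character(genome[[wide$chrom[i]]]), wide$pos[i],
             wide$pos[i]), "")
    wide[, "ref" := refs]
    wide[, "sample" := sample_id]
    data.table::setcolorder(wide, c("chrom", "pos", "ref",
                                    "A", "C", "G", "T", "N", "sample"))
    data.table::setorderv(wide, c("chrom", "pos"))
    return(wide[])
  }
  pu <- readPileupTable(input)
  if (!is.null(genome) && !all(unique(pu$chrom) %in% names(genome)))
    stop("pileup reference names not present in genome: ",
         paste(setdiff(unique(pu$chrom), names(genome)), collapse = ", "))
  # positions must be sorted within each sample and chromosome
  unsorted <- pu[, list(bad = is.unsorted(pos)),
                 by = c("sample", "chrom")]
  if (any(unsorted$bad))
    stop("pileup TSV is not position-sorted within sample/chromosome")
  pu
}

#' Call candidate A-to-I editing sites from pileup columns
#'
#' A site is a candidate in a sample iff the mismatch is consistent with
#' A-to-I editing on the transcribed strand: reference A with at least
#' \code{min_edited_reads} G reads under a plus-strand gene, or reference T
#' with at least \code{min_edited_reads} C reads under a minus-strand gene,
#' with edited fraction at least \code{min_fraction}. Other mismatch classes
#' are never called. Positions overlapping genes on both strands are
#' ambiguous and excluded (counted in a message), unless
#' \code{unanchored = TRUE}, in which case both orientations are called and
#' the strand reported as ".".
#'
#' @param pileup A pileup data.table (possibly multi-sample).
#' @param models A \linkS4class{GeneModels}; calling is restricted to
#'   positions inside annotated gene spans.
#' @param min_edited_reads Minimum edited-read count per sample (default 2).
#' @param min_fraction Minimum edited fraction per sample (default 0.05).
#' @param unanchored Call outside strand anchoring (default FALSE).
#' @return A data.table of site x sample rows (chrom, pos, strand, gene_id,
#'   sample_id, ref, edited, coverage, candidate) restricted to positions
#'   where at least one sample is a candidate.
#' @export
callCandidateSites <- function(pileup, models, min_edited_reads = 2L,
                               min_fraction = 0.05, unanchored = FALSE) {
  pu <- data.table::as.data.table(pileup)
  upos <- unique(pu[, c("chrom", "pos")])
  gr <- GenomicRanges::GRanges(upos$chrom, IRanges::IRanges(upos$pos,
                                                            upos$pos))
  genes <- geneRanges(models)
  ov <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  gstr <- as.character(strand(genes))[S4Vectors::subjectHits(ov)]
  gid <- geneIds(models)[S4Vectors::subjectHits(ov)]
  qh <- S4Vectors::queryHits(ov)
  # per position: set of gene strands; both strands -> ambiguous
  ann <- data.table::data.table(q = qh, strand = gstr, gene_id = gid)
  ann <- ann[order(ann$q, ann$gene_id)]
  ann <- ann[, list(strand = if (length(unique(strand)) > 1L) "ambiguous"
                    else strand[1L],
                    gene_id = gene_id[1L]), by = "q"]
  upos[, "strand" := NA_character_]
  upos[, "gene_id" := NA_character_]
  data.table::set(upos, ann$q, "strand", ann$strand)
  data.table::set(upos, ann$q, "gene_id", ann$gene_id)
  n_amb <- sum(upos$strand == "ambiguous", na.rm = TRUE)
  if (n_amb > 0 && !unanchored)
    message(sprintf("%d position(s) overlap genes on both strands: excluded",
                    n_amb))
  pu <- merge(pu, upos, by = c("chrom", "pos"))
  if (unanchored) {
    plus <- pu$ref == "A"
    minus <- pu$ref == "T"
    pu[, "strand" := ifelse(plus | minus, ".", NA_character_)]
  } else {
    pu <- pu[!is.na(pu$strand) & pu$strand != "ambiguous"]
    plus <- pu$strand == "+" & pu$ref == "A"
    minus <- pu$strand == "-" & pu$ref == "T"
  }
  pu[, "coverage" := pu$A + pu$C + pu$G + pu$T]
  pu[, "edited" := ifelse(plus, pu$G, ifelse(minus, pu$C, NA_integer_))]
  pu <- pu[!is.na(pu$edited)]
  pu[, "candidate" := pu$edited >= min_edited_reads & pu$coverage > 0 &
       pu$edited / pu$coverage >= min_fraction]
  keyed <- paste(pu$chrom, pu$pos)
  keep_keys <- unique(keyed[pu$candidate])
  out <- pu[keyed %in% keep_keys,
            c("chrom", "pos", "strand", "gene_id", "sample", "ref",
              "edited", "coverage", "candidate")]
  data.table::setnames(out, "sample", "sample_id")
  data.table::setorderv(out, c("chrom", "pos", "sample_id"))
  out[]
}

#' Filter candidate sites by replicate consistency and the ADAR-null control
#'
#' A site is retained iff it is a candidate in every replicate of at least
#' one test genotype AND is not a candidate in any control sample. Sites
#' whose control coverage is below \code{min_control_coverage} in every
#' control sample are retained but flagged \code{untestable}. Samples with
#' no pileup column at a site contribute zero coverage (and are therefore
#' not candidates there).
#'
#' @param sites Output of \code{\link{callCandidateSites}}.
#' @param samples Sample sheet data.frame (sample_id, genotype, replicate,
#'   role), role in {test, control}.
#' @param min_control_coverage Minimum control coverage for a site to be
#'   testable against the control (default 10).
#' @return A data.table like \code{sites}, restricted to retained sites,
#'   with all samples' rows completed and an \code{untestable} column.
#' @export
filterCandidates <- function(sites, samples, min_control_coverage = 10L) {
  ctrl <- samples$sample_id[samples$role == "control"]
  if (length(ctrl) == 0L)
    stop("control-group subtraction is mandatory: no control samples")
  st <- data.table::as.data.table(sites)
  # complete the site x sample grid with zero-coverage rows
  key <- unique(st[, c("chrom", "pos", "strand", "gene_id", "ref")])
  grid <- key[rep(seq_len(nrow(key)), each = nrow(samples))]
  grid[, "sample_id" := rep(samples$sample_id, nrow(key))]
  st <- merge(grid, st,
              by = c("chrom", "pos", "strand", "gene_id", "ref",
                     "sample_id"),
              all.x = TRUE)
  for (cc in c("edited", "coverage"))
    data.table::set(st, which(is.na(st[[cc]])), cc, 0L)
  data.table::set(st, which(is.na(st$candidate)), "candidate", FALSE)
  st <- merge(st, data.table::as.data.table(
    samples[, c("sample_id", "genotype", "role")]), by = "sample_id")
  genotype <- role <- candidate <- coverage <- NULL
  byc <- c("chrom", "pos")
  test_ok <- st[role == "test",
                list(ok = any(tapply(candidate, genotype, all))), by = byc]
  ctrl_st <- st[role == "control",
                list(ctrl_cand = any(candidate),
                     ctrl_testable = any(coverage >= min_control_coverage)),
                by = byc]
  dec <- merge(test_ok, ctrl_st, by = byc)
  dec <- dec[dec$ok & !dec$ctrl_cand]
  dec[, "untestable" := !dec$ctrl_testable]
  out <- merge(st, dec[, c("chrom", "pos", "untestable")], by = byc)
  out <- out[, c("chrom", "pos", "strand", "gene_id", "ref", "sample_id",
                 "genotype", "role", "edited", "coverage", "candidate",
                 "untestable")]
  data.table::setorderv(out, c("chrom", "pos", "sample_id"))
  out[]
}

#' Merge filtered sites into edited regions
#'
#' Single-linkage merge of same-gene sites separated by at most
#' \code{max_gap} bases. Returns an \linkS4class{EditedRegions} object whose
#' pooled per-genotype counts are derived from the member sites.
#'
#' @param sites Output of \code{\link{filterCandidates}}.
#' @param samples Sample sheet data.frame.
#' @param max_gap Maximum gap between consecutive sites of one region
#'   (default 100).
#' @return An \linkS4class{EditedRegions}.
#' @export
mergeRegions <- function(sites, samples, max_gap = 100L) {
  st <- data.table::as.data.table(sites)
  if (nrow(st) == 0L) {
    return(new("EditedRegions",
               regions = GenomicRanges::GRanges(),
               sites = data.frame(region_id = character(),
                                  chrom = character(), pos = integer(),
                                  strand = character(),
                                  gene_id = character(),
                                  sample_id = character(),
                                  edited = integer(), coverage = integer(),
                                  candidate = logical(),
                                  untestable = logical()),
               samples = samples))
  }
  upos <- unique(st[, c("chrom", "pos", "strand", "gene_id")])
  data.table::setorderv(upos, c("gene_id", "chrom", "pos"))
  pos <- gene_id <- chrom <- strand <- NULL
  # regions restart at gene boundaries and at gaps > max_gap
  upos[, "newreg" := c(TRUE, diff(pos) > max_gap), by = "gene_id"]
  upos[, "regnum" := cumsum(upos$newreg)]
  upos[, "region_id" := sprintf("region%04d", upos$regnum)]
  reg <- upos[, list(chrom = chrom[1L], start = min(pos), end = max(pos),
                     strand = strand[1L], gene_id = gene_id[1L],
                     n_sites = .N),
              by = "region_id"]
  regions <- GenomicRanges::GRanges(reg$chrom,
    IRanges::IRanges(reg$start, reg$end),
    strand = ifelse(reg$strand == ".", "*", reg$strand))
  mcols(regions)$region_id <- reg$region_id
  mcols(regions)$gene_id <- reg$gene_id
  mcols(regions)$n_sites <- reg$n_sites
  st <- merge(st, upos[, c("chrom", "pos", "region_id")],
              by = c("chrom", "pos"))
  sites_df <- as.data.frame(st[, c("region_id", "chrom", "pos", "strand",
                                   "gene_id", "sample_id", "edited",
                                   "coverage", "candidate", "untestable")])
  new("EditedRegions", regions = regions, sites = sites_df,
      samples = samples)
}
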