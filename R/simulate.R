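#' Configuration for the synthetic dsRNA transcriptome generator
#'
#' Returns a validated configuration list describing the simulated study:
#' a toy genome with strand-alternating genes, a designated ADAR-null
#' genotype with zero editing, three biological replicates per genotype,
#' region-clustered A-to-I editing with a 1.4-fold editing increase in the
#' mutant for half of the regions, antisense-overlapping gene pairs, long
#' introns carrying exact inverted repeats, transposon-like repeat
#' intervals, ChIP-style peaks, and IP/input count tables with planted
#' fold-enrichments. All defaults are the package's reference study
#' conditions; see the package vignette for the rationale behind each value.
#'
#' @param rng_seed Integer seed driving all randomness.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Number of genes.
#' @param exon_length,intron_length Exon and standard intron sizes (bp);
#'   every gene is exon-intron-exon.
#' @param fraction_antisense_pairs Fraction of genes arranged in
#'   antisense-overlapping pairs (span overlap 300 bp).
#' @param n_ir_introns Number of genes whose (long, > 1 kb) intron carries an
#'   exact inverted repeat.
#' @param ir_arm_length,ir_loop_length,ir_intron_length Arm/loop sizes of
#'   planted inverted repeats and the length of their host introns.
#' @param n_edited_regions,sites_per_region,site_spacing Editing truth:
#'   number of edited regions (one per host gene), A-to-I sites per region
#'   and their spacing in bp.
#' @param genotypes Character vector of genotype names; the last one is the
#'   ADAR-null control and always edits at fraction 0.
#' @param control_genotype Name of the ADAR-null genotype.
#' @param per_site_edit_fraction Named baseline per-site editing fraction per
#'   genotype (control forced to 0).
#' @param frac_regions_altered Fraction of regions whose editing level
#'   differs between the two test genotypes.
#' @param alteration_fold Fold change applied to altered regions.
#' @param frac_increase_among_altered Fraction of altered regions in which
#'   editing increases (rest decrease).
#' @param coverage_mean Mean per-position read coverage (Poisson).
#' @param n_replicates Biological replicates per genotype.
#' @param error_rate Per-base sequencing error rate (uniform over the three
#'   non-reference bases).
#' @param n_repeats,repeat_length Transposon-like repeat intervals.
#' @param n_peaks,peak_length,frac_peaks_on_repeats ChIP-style peak
#'   intervals and the fraction placed on repeats.
#' @param n_enriched,ip_fold IP truth: number of IP-enriched features and
#'   their fold over input.
#' @param frac_enriched_structured Fraction of IP-enriched features drawn
#'   from structurally dsRNA-capable genes (antisense, inverted repeat or
#'   repeat overlap).
#' @param n_diff,diff_fold Number of enriched features with an additional
#'   genotype-specific IP fold increase in the mutant.
#' @param nb_dispersion Negative-binomial dispersion of counts (shared
#'   biological latent between the IP and input library of one replicate).
#' @param lib_size Library size (total mapped reads normalisation constant)
#'   per sample.
#' @param expr_sdlog Log-sd of the lognormal per-feature expression levels.
#' @return A list of class \code{simConfig}.
#' @export
simConfig <- function(rng_seed = 1L,
                      n_chroms = 2L, chrom_length = 200000L,
                      n_genes = 150L,
                      exon_length = 150L, intron_length = 800L,
                      fraction_antisense_pairs = 0.2,
                      n_ir_introns = 5L, ir_arm_length = 30L,
                      ir_loop_length = 50L, ir_intron_length = 1500L,
                      n_edited_regions = 50L, sites_per_region = 20L,
                      site_spacing = 15L,
                      genotypes = c("wt", "tdp1", "adr2"),
                      control_genotype = "adr2",
                      per_site_edit_fraction = c(wt = 0.15, tdp1 = 0.15,
                                                 adr2 = 0),
                      frac_regions_altered = 0.5,
                      alteration_fold = 1.4,
                      frac_increase_among_altered = 0.9,
                      coverage_mean = 50,
                      n_replicates = 3L,
                      error_rate = 0.001,
                      n_repeats = 30L, repeat_length = 500L,
                      n_peaks = 60L, peak_length = 300L,
                      frac_peaks_on_repeats = 0.37,
                      n_enriched = 40L, ip_fold = 4,
                      frac_enriched_structured = 0.73,
                      n_diff = 20L, diff_fold = 2.5,
                      nb_dispersion = 0.1,
                      lib_size = 1e6,
                      expr_sdlog = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  props <- c("fraction_antisense_pairs", "frac_regions_altered",
             "frac_increase_among_altered", "frac_peaks_on_repeats",
             "frac_enriched_structured", "error_rate")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", p))
  if (any(cfg$per_site_edit_fraction < 0 | cfg$per_site_edit_fraction > 1))
    stop("editing fractions must lie in [0, 1]")
  if (cfg$coverage_mean <= 0) stop("'coverage_mean' must be positive")
  if (cfg$ir_arm_length < 10) stop("'ir_arm_length' must be >= 10")
  if (!cfg$control_genotype %in% cfg$genotypes)
    stop("'control_genotype' must be one of 'genotypes'")
  if (!all(cfg$genotypes %in% names(cfg$per_site_edit_fraction)))
    stop("'per_site_edit_fraction' must name every genotype")
  if (cfg$per_site_edit_fraction[[cfg$control_genotype]] != 0)
    stop("the ADAR-null control genotype must edit at fraction 0")
  if (cfg$n_diff > cfg$n_enriched)
    stop("'n_diff' must not exceed 'n_enriched'")
  invisible(TRUE)
}

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome, annotation and truth table
#'
#' Places strand-alternating exon-intron-exon genes on random chromosomes.
#' The first \code{n_ir_introns} genes receive a long (> 1 kb) intron with an
#' exact planted inverted repeat; the following \code{n_edited_regions}
#' genes host one edited region each in their intron; the next block of
#' genes is arranged in antisense-overlapping pairs (span overlap 300 bp on
#' opposite strands). Repeat intervals and ChIP-style peaks are added, and
#' everything planted is recorded in the returned truth table. Identical
#' seeds give identical output.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list with elements \code{genome}
#'   (\link[Biostrings]{DNAStringSet}), \code{models}
#'   (\linkS4class{GeneModels}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @export
simulateReference <- function(config) {
  .validateSimConfig(config)
  set.seed(config$rng_seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  seqs <- vapply(chroms, function(ch) .randSeq(config$chrom_length), "")

  n_pairs <- floor(config$n_genes * config$fraction_antisense_pairs / 2)
  need <- config$n_ir_introns + config$n_edited_regions + 2L * n_pairs
  if (need > config$n_genes)
    stop(sprintf("n_genes too small: %d special genes requested, %d genes",
                 need, config$n_genes))
  role <- rep("plain", config$n_genes)
  role[seq_len(config$n_ir_introns)] <- "ir"
  role[config$n_ir_introns + seq_len(config$n_edited_regions)] <- "edited"
  if (n_pairs > 0)
    role[config$n_ir_introns + config$n_edited_regions +
           seq_len(2L * n_pairs)] <- rep(c("pair_a", "pair_b"), n_pairs)

  exl <- config$exon_length
  gap <- 700L  # wide enough to host intergenic repeat/peak intervals
  ids <- sprintf("gene%03d", seq_len(config$n_genes))
  chrom_i <- 1L
  cursor <- 101L
  rows <- vector("list", config$n_genes)
  i <- 1L
  while (i <= config$n_genes) {
    intr <- if (role[i] == "ir") config$ir_intron_length else
      config$intron_length
    span <- 2L * exl + intr
    is_pair <- role[i] == "pair_a"
    extent <- if (is_pair) span + span - 300L else span
    if (cursor + extent + gap > config$chrom_length) {
      chrom_i <- chrom_i + 1L
      cursor <- 101L
      if (chrom_i > config$n_chroms)
        stop(sprintf(paste0("genome too small to place requested features: ",
                            "%d bp still needed"),
                     sum(vapply(i:config$n_genes, function(j) {
                       2L * exl + (if (role[j] == "ir")
                         config$ir_intron_length else config$intron_length) +
                         gap
                     }, 0L))))
      next
    }
    strand_i <- if (i %% 2L == 1L) "+" else "-"
    rows[[i]] <- data.frame(gene_id = ids[i], chrom = chroms[chrom_i],
                            start = cursor, intron_len = intr,
                            strand = strand_i, role = role[i])
    if (is_pair) {
      # partner on the opposite strand, span overlap exactly 300 bp
      p_start <- cursor + span - 300L
      rows[[i + 1L]] <- data.frame(gene_id = ids[i + 1L],
                                   chrom = chroms[chrom_i], start = p_start,
                                   intron_len = config$intron_length,
                                   strand = if (strand_i == "+") "-" else "+",
                                   role = "pair_b")
      cursor <- p_start + span + gap
      i <- i + 2L
    } else {
      cursor <- cursor + span + gap
      i <- i + 1L
    }
  }
  gtab <- do.call(rbind, rows)
  gtab$end <- gtab$start + 2L * exl + gtab$intron_len - 1L

  exon_list <- lapply(seq_len(nrow(gtab)), function(j) {
    s <- gtab$start[j]
    e <- gtab$end[j]
    GenomicRanges::GRanges(gtab$chrom[j],
      IRanges::IRanges(start = c(s, e - exl + 1L),
                       end = c(s + exl - 1L, e)),
      strand = gtab$strand[j])
  })
  models <- GeneModels(geneIds = gtab$gene_id, exons = exon_list)

  seq_env <- new.env()
  for (ch in chroms) assign(ch, strsplit(seqs[[ch]], "")[[1]], envir = seq_env)

  # plant inverted repeats inside the long introns
  ir_rows <- list()
  for (j in which(gtab$role == "ir")) {
    intron_start <- gtab$start[j] + exl
    arm <- .randSeq(config$ir_arm_length)
    a_start <- intron_start + 100L
    a_end <- a_start + config$ir_arm_length - 1L
    b_start <- a_end + config$ir_loop_length + 1L
    b_end <- b_start + config$ir_arm_length - 1L
    v <- get(gtab$chrom[j], envir = seq_env)
    v[a_start:a_end] <- strsplit(arm, "")[[1]]
    v[b_start:b_end] <- strsplit(revComp(arm), "")[[1]]
    assign(gtab$chrom[j], v, envir = seq_env)
    ir_rows[[length(ir_rows) + 1L]] <- data.frame(
      gene_id = gtab$gene_id[j], chrom = gtab$chrom[j],
      intron_start = intron_start + 1L,
      intron_end = intron_start + gtab$intron_len[j],
      arm_a_start = a_start, arm_a_end = a_end,
      arm_b_start = b_start, arm_b_end = b_end,
      arm_length = config$ir_arm_length,
      loop_length = config$ir_loop_length)
  }
  ir_df <- if (length(ir_rows)) do.call(rbind, ir_rows) else
    data.frame(gene_id = character(), chrom = character(),
               intron_start = integer(), intron_end = integer(),
               arm_a_start = integer(), arm_a_end = integer(),
               arm_b_start = integer(), arm_b_end = integer(),
               arm_length = integer(), loop_length = integer())

  # plant edited sites: ref A on plus-strand genes, ref T on minus-strand
  edited_idx <- which(gtab$role == "edited")
  n_alt <- round(config$frac_regions_altered * length(edited_idx))
  alt_regions <- sort(sample(seq_along(edited_idx), n_alt))
  n_up <- round(config$frac_increase_among_altered * n_alt)
  up_regions <- if (n_alt > 0) sort(sample(alt_regions, n_up)) else integer()
  test_genos <- setdiff(config$genotypes, config$control_genotype)
  base_fr <- config$per_site_edit_fraction
  site_rows <- list()
  for (r in seq_along(edited_idx)) {
    j <- edited_idx[r]
    intron_start <- gtab$start[j] + exl
    pos <- intron_start + 50L + (seq_len(config$sites_per_region) - 1L) *
      config$site_spacing
    ref <- if (gtab$strand[j] == "+") "A" else "T"
    v <- get(gtab$chrom[j], envir = seq_env)
    v[pos] <- ref
    assign(gtab$chrom[j], v, envir = seq_env)
    fr <- base_fr
    if (r %in% alt_regions && length(test_genos) >= 2) {
      mut <- test_genos[2]
      fr[[mut]] <- if (r %in% up_regions)
        min(0.95, fr[[mut]] * config$alteration_fold)
      else fr[[mut]] / config$alteration_fold
    }
    df <- data.frame(chrom = gtab$chrom[j], pos = pos,
                     strand = gtab$strand[j], gene_id = gtab$gene_id[j],
                     region_id = sprintf("tregion%03d", r))
    for (g in config$genotypes) df[[paste0("frac_", g)]] <- fr[[g]]
    site_rows[[r]] <- df
  }
  site_df <- do.call(rbind, site_rows)
  editedSites <- GenomicRanges::GRanges(site_df$chrom,
    IRanges::IRanges(site_df$pos, site_df$pos), strand = site_df$strand)
  mcols(editedSites) <- DataFrame(
    site_df[, setdiff(names(site_df), c("chrom", "pos", "strand")),
            drop = FALSE])

  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(get(ch, envir = seq_env), collapse = ""), ""))
  names(genome) <- chroms

  pairs_df <- data.frame(
    gene_a = gtab$gene_id[gtab$role == "pair_a"],
    gene_b = gtab$gene_id[gtab$role == "pair_b"],
    stringsAsFactors = FALSE)

  gr_genes <- geneRanges(models)

  # repeat intervals: half inside plain-gene introns, half intergenic
  n_genic <- floor(config$n_repeats / 2)
  plain_idx <- which(gtab$role == "plain")
  if (length(plain_idx) < n_genic)
    stop("not enough plain genes to host genic repeat intervals")
  host <- sample(plain_idx, n_genic)
  rep_rows <- lapply(host, function(j) {
    s <- gtab$start[j] + exl + 50L
    data.frame(chrom = gtab$chrom[j], start = s,
               end = min(s + config$repeat_length - 1L, gtab$end[j] - exl))
  })
  # intergenic placements: scan gaps between genes
  occupied <- GenomicRanges::reduce(gr_genes, ignore.strand = TRUE)
  free <- GenomicRanges::gaps(occupied)
  free <- free[strand(free) == "*" & width(free) >
                 config$repeat_length + 100L]
  n_inter <- config$n_repeats - n_genic
  if (length(free) < n_inter)
    stop("not enough intergenic space for repeat intervals")
  pick <- sample(seq_along(free), n_inter)
  rep_rows2 <- lapply(pick, function(j) {
    s <- start(free)[j] + 50L
    data.frame(chrom = as.character(GenomicRanges::seqnames(free)[j]),
               start = s, end = s + config$repeat_length - 1L)
  })
  rep_df <- do.call(rbind, c(rep_rows, rep_rows2))
  repeats <- GenomicRanges::GRanges(rep_df$chrom,
    IRanges::IRanges(rep_df$start, rep_df$end), strand = "*")
  mcols(repeats)$name <- sprintf("repeat%03d", seq_along(repeats))

  # ChIP-style peaks, a configured fraction centred on repeats
  n_on <- round(config$frac_peaks_on_repeats * config$n_peaks)
  if (n_on > length(repeats)) {
    on_idx <- c(rep(seq_along(repeats),
                    length.out = n_on))
  } else on_idx <- sample(seq_along(repeats), n_on)
  half <- floor(config$peak_length / 2)
  peak_rows <- lapply(on_idx, function(j) {
    mid <- (start(repeats)[j] + end(repeats)[j]) %/% 2L
    data.frame(chrom = as.character(GenomicRanges::seqnames(repeats)[j]),
               start = mid - half, end = mid + half)
  })
  n_off <- config$n_peaks - n_on
  free2 <- GenomicRanges::gaps(GenomicRanges::reduce(
    c(GenomicRanges::granges(occupied), GenomicRanges::granges(repeats)),
    ignore.strand = TRUE))
  free2 <- free2[strand(free2) == "*" & width(free2) >
                   config$peak_length + 100L]
  if (length(free2) < 1L && n_off > 0L)
    stop("not enough free space for off-repeat peaks")
  pick2 <- sample(rep(seq_along(free2), length.out = max(n_off, 1L)), n_off)
  peak_rows2 <- lapply(pick2, function(j) {
    s <- start(free2)[j] + 20L
    data.frame(chrom = as.character(GenomicRanges::seqnames(free2)[j]),
               start = s, end = s + config$peak_length - 1L)
  })
  peak_df <- do.call(rbind, c(peak_rows, peak_rows2))
  peaks <- GenomicRanges::GRanges(peak_df$chrom,
    IRanges::IRanges(peak_df$start, peak_df$end), strand = "*")
  mcols(peaks)$name <- sprintf("peak%03d", seq_along(peaks))

  # IP truth: enriched features preferentially from structured genes
  structured <- unique(c(pairs_df$gene_a, pairs_df$gene_b, ir_df$gene_id,
                         gtab$gene_id[.overlapsAny(gr_genes, repeats)]))
  n_struct <- min(round(config$frac_enriched_structured * config$n_enriched),
                  length(structured))
  pool_rest <- setdiff(gtab$gene_id, structured)
  enr <- c(sample(structured, n_struct),
           sample(pool_rest, config$n_enriched - n_struct))
  diff_feats <- sample(enr, config$n_diff)
  enr_df <- data.frame(feature_id = gtab$gene_id,
                       ip_fold = ifelse(gtab$gene_id %in% enr,
                                        config$ip_fold, 1),
                       diff_fold = ifelse(gtab$gene_id %in% diff_feats,
                                          config$diff_fold, 1),
                       structured = gtab$gene_id %in% structured,
                       stringsAsFactors = FALSE)

  truth <- new("SyntheticTruth", editedSites = editedSites,
               antisensePairs = pairs_df, invertedRepeats = ir_df,
               repeats = repeats, peaks = peaks, enrichedFeatures = enr_df)
  list(genome = genome, models = models, truth = truth)
}

.overlapsAny <- function(query, subject) {
  GenomicRanges::countOverlaps(query, subject, ignore.strand = TRUE) > 0
}

#' Simulate per-replicate editing pileups
#'
#' At every transcribed position (union of gene spans) each sample draws a
#' Poisson coverage; at truth editing sites a binomial number of reads carry
#' the edited base (G over a reference A on plus-strand genes, appearing as
#' C over a reference T for minus-strand genes); sequencing error adds
#' uniform mismatches at \code{error_rate}. The ADAR-null genotype always
#' edits at fraction 0. Zero-coverage positions are not emitted.
#'
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param models A \linkS4class{GeneModels}.
#' @param truth A \linkS4class{SyntheticTruth}.
#' @param config A \code{\link{simConfig}}.
#' @return A list with \code{pileup} (data.table: chrom, pos, ref, A, C, G,
#'   T, N, sample) and \code{samples} (the sample sheet).
#' @export
simulateEditingPileups <- function(genome, models, truth, config) {
  set.seed(config$rng_seed + 1L)
  gr <- geneRanges(models)
  ts <- truth@editedSites
  hit <- GenomicRanges::countOverlaps(ts, gr, ignore.strand = TRUE)
  if (any(hit == 0L))
    stop("truth editing site outside any gene: ",
         paste(utils::head(which(hit == 0L)), collapse = ","))
  tx <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  pos_dt <- data.table::rbindlist(lapply(seq_along(tx), function(j) {
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(tx)[j]),
      pos = start(tx)[j]:end(tx)[j])
  }))
  # extract reference bases chromosome-wise (vectorised)
  pos_dt[, "ref" := NA_character_]
  for (ch in names(genome)) {
    sel <- pos_dt$chrom == ch
    if (!any(sel)) next
    v <- strsplit(as.character(genome[[ch]]), "")[[1]]
    data.table::set(pos_dt, which(sel), "ref", v[pos_dt$pos[sel]])
  }
  # N reference positions are never emitted (not callable downstream)
  pos_dt <- pos_dt[pos_dt$ref %in% c("A", "C", "G", "T")]
  # editing fractions per genotype at truth sites
  key <- paste(pos_dt$chrom, pos_dt$pos)
  tkey <- paste(as.character(GenomicRanges::seqnames(ts)), start(ts))
  site_ix <- match(key, tkey)
  genos <- config$genotypes
  sheet <- expand.grid(replicate = seq_len(config$n_replicates),
                       genotype = genos, stringsAsFactors = FALSE)
  sheet$sample_id <- sprintf("%s_rep%d", sheet$genotype, sheet$replicate)
  sheet$role <- ifelse(sheet$genotype == config$control_genotype,
                       "control", "test")
  sheet <- sheet[, c("sample_id", "genotype", "replicate", "role")]

  bases <- c("A", "C", "G", "T")
  npos <- nrow(pos_dt)
  ref_i <- match(pos_dt$ref, bases)
  # non-reference bases per position (fixed order), and the edited base:
  # G over ref A (plus strand), C over ref T (minus strand)
  altmap <- rbind(A = c(2L, 3L, 4L), C = c(1L, 3L, 4L),
                  G = c(1L, 2L, 4L), T = c(1L, 2L, 3L))
  alt <- altmap[ref_i, , drop = FALSE]
  ed_base <- ifelse(pos_dt$ref == "A", 3L, 2L)
  out <- vector("list", nrow(sheet))
  for (s in seq_len(nrow(sheet))) {
    g <- sheet$genotype[s]
    frcol <- paste0("frac_", g)
    frac <- rep(0, npos)
    has <- !is.na(site_ix)
    frac[has] <- mcols(ts)[[frcol]][site_ix[has]]
    cov <- stats::rpois(npos, config$coverage_mean)
    edited <- integer(npos)
    ed_sel <- which(frac > 0 & cov > 0)
    edited[ed_sel] <- stats::rbinom(length(ed_sel), cov[ed_sel],
                                    frac[ed_sel])
    nerr <- stats::rbinom(npos, cov - edited, config$error_rate)
    e1 <- stats::rbinom(npos, nerr, 1 / 3)
    e2 <- stats::rbinom(npos, nerr - e1, 1 / 2)
    e3 <- nerr - e1 - e2
    cnt <- matrix(0L, nrow = npos, ncol = 4L,
                  dimnames = list(NULL, bases))
    cnt[cbind(seq_len(npos), ref_i)] <- cov - edited - nerr
    # distribute errors over the three non-reference bases in fixed order
    cnt[cbind(seq_len(npos), alt[, 1])] <-
      cnt[cbind(seq_len(npos), alt[, 1])] + e1
    cnt[cbind(seq_len(npos), alt[, 2])] <-
      cnt[cbind(seq_len(npos), alt[, 2])] + e2
    cnt[cbind(seq_len(npos), alt[, 3])] <-
      cnt[cbind(seq_len(npos), alt[, 3])] + e3
    cnt[cbind(seq_len(npos), ed_base)] <-
      cnt[cbind(seq_len(npos), ed_base)] + edited
    keep <- cov > 0L
    out[[s]] <- data.table::data.table(
      chrom = pos_dt$chrom[keep], pos = pos_dt$pos[keep],
      ref = pos_dt$ref[keep],
      A = cnt[keep, 1], C = cnt[keep, 2], G = cnt[keep, 3],
      T = cnt[keep, 4], N = 0L, sample = sheet$sample_id[s])
  }
  list(pileup = data.table::rbindlist(out), samples = sheet)
}

#' Simulate a dsRNA-IP count experiment
#'
#' Input counts are negative-binomial with mean proportional to feature
#' length times a lognormal expression level, scaled to the configured
#' library size. The IP library of each replicate shares that replicate's
#' biological expression latent (the two libraries come from the same
#' lysate), multiplies the mean by the planted fold for enriched features
#' (times the genotype-specific differential fold in the mutant), and is
#' scaled so that an unenriched feature has equal RPKM in IP and input.
#' Marginally every count is NB with dispersion \code{nb_dispersion}.
#'
#' @param features A data.frame with columns \code{feature_id} and
#'   \code{length}; defaults to the truth's feature set must be supplied by
#'   the caller (gene spans in the pipeline).
#' @param truth A \linkS4class{SyntheticTruth} (its \code{enrichedFeatures}
#'   must cover all features).
#' @param config A \code{\link{simConfig}}.
#' @return An \linkS4class{IPExperiment} with genotypes x roles x
#'   replicates columns.
#' @export
simulateIPCounts <- function(features, truth, config) {
  set.seed(config$rng_seed + 2L)
  ef <- truth@enrichedFeatures
  if (!all(ef$feature_id[ef$ip_fold > 1] %in% features$feature_id))
    stop("enriched truth features missing from the feature table")
  m <- match(features$feature_id, ef$feature_id)
  ip_fold <- ifelse(is.na(m), 1, ef$ip_fold[m])
  diff_fold <- ifelse(is.na(m), 1, ef$diff_fold[m])
  nf <- nrow(features)
  expr <- stats::rlnorm(nf, meanlog = 0, sdlog = config$expr_sdlog)
  base <- expr * features$length / 1000
  mu_in <- base / sum(base) * config$lib_size
  genos <- utils::head(setdiff(config$genotypes, config$control_genotype), 2)
  phi <- config$nb_dispersion
  cols <- list()
  sheet <- list()
  for (g in genos) {
    fold <- ip_fold * (if (g == genos[2]) diff_fold else 1)
    for (r in seq_len(config$n_replicates)) {
      lat <- if (phi > 0)
        stats::rgamma(nf, shape = 1 / phi, scale = phi) else rep(1, nf)
      cin <- stats::rpois(nf, mu_in * lat)
      cip <- stats::rpois(nf, mu_in * lat * fold)
      id_in <- sprintf("%s_input_rep%d", g, r)
      id_ip <- sprintf("%s_IP_rep%d", g, r)
      cols[[id_in]] <- cin
      cols[[id_ip]] <- cip
      sheet[[id_in]] <- data.frame(sample_id = id_in, genotype = g,
                                   role = "input", replicate = r,
                                   lib_size = config$lib_size)
      sheet[[id_ip]] <- data.frame(sample_id = id_ip, genotype = g,
                                   role = "IP", replicate = r,
                                   lib_size = config$lib_size)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- features$feature_id
  IPExperiment(counts = counts, lengths = features$length,
               samples = do.call(rbind, sheet))
}

#' Simulate single-end reads over a region and write them as SAM
#'
#' A small read-level emitter used for IO testing: 50 nt single-end reads
#' drawn uniformly over a region, each base carrying an independent
#' error at \code{error_rate}; reads overlapping an edited site carry the
#' edited base with the site's probability. Reads are reported in reference
#' orientation (as in SAM).
#'
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param chrom,start,end Region to cover.
#' @param n_reads Number of reads.
#' @param read_len Read length.
#' @param edit_pos,edit_frac Optional vectors of edited positions (must be
#'   reference A) and per-site editing fractions.
#' @param error_rate Per-base error rate.
#' @return A data.frame with columns qname, flag, chrom, pos, seq.
#' @export
simulateReads <- function(genome, chrom, start, end, n_reads,
                          read_len = 50L, edit_pos = integer(),
                          edit_frac = numeric(), error_rate = 0.001) {
  template <- strsplit(as.character(genome[[chrom]]), "")[[1]]
  maxs <- end - read_len + 1L
  starts <- sample(start:maxs, n_reads, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  reads <- lapply(seq_len(n_reads), function(i) {
    s <- starts[i]
    v <- template[s:(s + read_len - 1L)]
    if (length(edit_pos)) {
      inside <- which(edit_pos >= s & edit_pos <= s + read_len - 1L)
      for (k in inside) {
        if (stats::runif(1) < edit_frac[k])
          v[edit_pos[k] - s + 1L] <- "G"
      }
    }
    err <- which(stats::runif(read_len) < error_rate)
    for (k in err) v[k] <- sample(setdiff(bases, v[k]), 1)
    paste(v, collapse = "")
  })
  data.frame(qname = sprintf("read%05d", seq_len(n_reads)), flag = 0L,
             chrom = chrom, pos = starts,
             seq = unlist(reads), stringsAsFactors = FALSE)
}

#' Write simulated reads to a SAM file
#' @param reads A data.frame from \code{\link{simulateReads}}.
#' @param genome The genome the reads were drawn from (for the header).
#' @param path Output SAM path.
#' @return Invisibly, \code{path}.
#' @export
writeSAM <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, length(genome[[ch]])), con)
  reads <- reads[order(reads$chrom, reads$pos), ]
  writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                     reads$qname, reads$flag, reads$chrom, reads$pos,
                     nchar(reads$seq), reads$seq,
                     strrep("I", nchar(reads$seq[1]))), con)
  invisible(path)
}

#' Per-base pileup of simulated reads (read-counting path)
#'
#' Independent of the SAM/BAM machinery: counts each read base at its
#' reference position directly. Used as the second route in cross-path
#' equivalence tests of \code{\link{buildPileup}}.
#'
#' @param reads A data.frame from \code{\link{simulateReads}}.
#' @param genome The source genome (for reference bases).
#' @param sample_id Sample label for the emitted columns.
#' @return A pileup data.table (chrom, pos, ref, A, C, G, T, N, sample).
#' @export
pileupFromReads <- function(reads, genome, sample_id = "sample1") {
  dt <- data.table::rbindlist(lapply(seq_len(nrow(reads)), function(i) {
    v <- strsplit(reads$seq[i], "")[[1]]
    data.table::data.table(chrom = reads$chrom[i],
                           pos = reads$pos[i] + seq_along(v) - 1L,
                           base = v)
  }))
  base <- NULL  # appease R CMD check
  tab <- dt[, list(
    A = sum(base == "A"), C = sum(base == "C"),
    G = sum(base == "G"), T = sum(base == "T"), N = sum(base == "N")),
    by = c("chrom", "pos")]
  data.table::setorderv(tab, c("chrom", "pos"))
  refs <- vapply(seq_len(nrow(tab)), function(i)
    substr(as.character(genome[[tab$chrom[i]]]), tab$pos[i], tab$pos[i]), "")
  tab[, "ref" := refs]
  tab[, "sample" := sample_id]
  data.table::setcolorder(tab, c("chrom", "pos", "ref",
                                 "A", "C", "G", "T", "N", "sample"))
  tab[]
}

.truthToList <- function(truth) {
  es <- truth@editedSites
  list(
    edited_sites = cbind(
      data.frame(chrom = as.character(GenomicRanges::seqnames(es)),
                 pos = start(es),
                 strand = as.character(strand(es))),
      as.data.frame(mcols(es))),
    antisense_pairs = truth@antisensePairs,
    inverted_repeats = truth@invertedRepeats,
    repeats = data.frame(
      chrom = as.character(GenomicRanges::seqnames(truth@repeats)),
      start = start(truth@repeats), end = end(truth@repeats),
      name = mcols(truth@repeats)$name),
    peaks = data.frame(
      chrom = as.character(GenomicRanges::seqnames(truth@peaks)),
      start = start(truth@peaks), end = end(truth@peaks),
      name = mcols(truth@peaks)$name),
    enriched_features = truth@enrichedFeatures)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the genome (FASTA), annotation (GFF3), repeat and peak intervals
#' (BED6), per-sample pileups (TSV), IP/input counts plus sample sheets
#' (TSV) and the truth table (JSON) under \code{outdir}. Identical
#' configurations produce byte-identical files.
#'
#' @param config A \code{\link{simConfig}}.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
writeSimulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateReference(config)
  pl <- simulateEditingPileups(sim$genome, sim$models, sim$truth, config)
  feats <- data.frame(feature_id = geneIds(sim$models),
                      length = width(geneRanges(sim$models)))
  ipx <- simulateIPCounts(feats, sim$truth, config)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.gff3"),
    repeats = file.path(outdir, "repeats.bed"),
    peaks = file.path(outdir, "peaks.bed"),
    pileup = file.path(outdir, "pileup.tsv"),
    pileup_samples = file.path(outdir, "pileup_samples.tsv"),
    counts = file.path(outdir, "counts.tsv"),
    count_samples = file.path(outdir, "count_samples.tsv"),
    truth = file.path(outdir, "truth.json"))
  writeGenome(sim$genome, paths$genome)
  writeAnnotation(sim$models, paths$annotation)
  writeBed(sim$truth@repeats, paths$repeats)
  writeBed(sim$truth@peaks, paths$peaks)
  writePileupTable(pl$pileup, paths$pileup)
  utils::write.table(pl$samples, paths$pileup_samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cnt <- SummarizedExperiment::assay(ipx, "counts")
  utils::write.table(data.frame(feature_id = rownames(cnt), cnt,
                                check.names = FALSE),
                     paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sampleSheet(ipx), paths$count_samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(.truthToList(sim$truth), paths$truth,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
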