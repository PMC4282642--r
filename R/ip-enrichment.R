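#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count / (length_kb * lib_size_millions)}. Doubling both the
#' count and the library size leaves the value unchanged.
#'
#' @param counts Numeric matrix (features x samples) or vector.
#' @param lengths Feature lengths in bases.
#' @param lib_sizes Library sizes (total mapped reads), one per sample.
#' @return Matrix (or vector) of RPKM values.
#' @export
computeRPKM <- function(counts, lengths, lib_sizes) {
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (is.matrix(counts)) {
    if (length(lib_sizes) != ncol(counts))
      stop("one library size per sample is required")
    sweep(counts / (lengths / 1000), 2, lib_sizes / 1e6, "/")
  } else {
    counts / (lengths / 1000) / (lib_sizes / 1e6)
  }
}

#' Intronic features for region-level counting
#'
#' All introns strictly longer than \code{min_length} bases, with stable
#' identifiers \code{<gene_id>.intron<k>} (k in transcript order).
#' Single-exon genes contribute nothing.
#'
#' @param models A \linkS4class{GeneModels}.
#' @param min_length Strict minimum intron length (default 250).
#' @return A \link[GenomicRanges]{GRanges} with feature_id, gene_id and
#'   length metadata columns.
#' @export
extractIntronFeatures <- function(models, min_length = 250L) {
  introns <- intronsByGene(models)
  ids <- geneIds(models)
  res <- list()
  for (i in seq_along(ids)) {
    intr <- introns[[i]]
    if (length(intr) == 0L) next
    keep <- width(intr) > min_length
    if (!any(keep)) next
    intr <- intr[keep]
    mcols(intr)$feature_id <- sprintf("%s.intron%d", ids[i],
                                      which(keep))
    mcols(intr)$gene_id <- ids[i]
    mcols(intr)$length <- width(intr)
    res[[length(res) + 1L]] <- intr
  }
  if (length(res) == 0L) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$feature_id <- character(0)
    mcols(gr)$gene_id <- character(0)
    mcols(gr)$length <- integer(0)
    return(gr)
  }
  # genes from different chromosomes carry disjoint seqlevels
  sort(suppressWarnings(do.call(c, res)), ignore.strand = TRUE)
}

# per-replicate input-normalised log-ratios and their delta-method count
# variances for one genotype; replicates are paired (IP and input libraries
# of one replicate come from the same lysate)
.ipLogRatios <- function(ipx, genotype, pseudocount = 0.5) {
  cd <- sampleSheet(ipx)
  cnt <- SummarizedExperiment::assay(ipx, "counts")
  sel_ip <- cd$genotype == genotype & cd$role == "IP"
  sel_in <- cd$genotype == genotype & cd$role == "input"
  if (!any(sel_ip) || !any(sel_in))
    stop(sprintf("genotype '%s' needs at least one IP and one input sample",
                 genotype))
  reps <- intersect(cd$replicate[sel_ip], cd$replicate[sel_in])
  if (length(reps) == 0L) stop("no paired IP/input replicates")
  lam <- v <- matrix(NA_real_, nrow(cnt), length(reps))
  for (k in seq_along(reps)) {
    iip <- which(sel_ip & cd$replicate == reps[k])[1]
    iin <- which(sel_in & cd$replicate == reps[k])[1]
    ip <- cnt[, iip] + pseudocount
    inp <- cnt[, iin] + pseudocount
    lam[, k] <- log(ip / cd$lib_size[iip]) - log(inp / cd$lib_size[iin])
    v[, k] <- 1 / ip + 1 / inp
  }
  list(lambda = lam, var = v, n = length(reps))
}

# pooled method-of-moments extra-dispersion: excess of the observed
# between-replicate variance of the log-ratios over the count-level variance
.pooledTau2 <- function(lam, v) {
  if (ncol(lam) < 2L) return(0)
  s2 <- apply(lam, 1, stats::var)
  mv <- rowMeans(v)
  stats::median(pmax(0, s2 - mv))
}

#' Call features enriched by dsRNA immunoprecipitation over input
#'
#' For one genotype, compares IP with input libraries on per-replicate
#' input-normalised log-ratios. The fold over input is the ratio of mean IP
#' RPKM to mean input RPKM (pseudocount added to counts first); the p-value
#' comes from a z-test on the mean log-ratio with delta-method count
#' variance plus a pooled method-of-moments extra-dispersion term, and is
#' BH-adjusted across tested features. A feature is enriched iff its fold
#' over input exceeds \code{min_fold} and its adjusted p is below
#' \code{alpha}. Filtering order is fixed: low-count filter, then test,
#' then BH (attrition reported via a message).
#'
#' @param ipx An \linkS4class{IPExperiment}.
#' @param genotype Genotype to analyse.
#' @param min_fold Fold-over-input threshold (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_count Features whose summed count over this genotype's
#'   samples is below this are excluded (default 10).
#' @param pseudocount Added to all counts before ratios (default 0.5).
#' @return A data.frame: feature_id, mean_input_rpkm, mean_ip_rpkm,
#'   fold_over_input, log2_ratio, z, p, p_adj, enriched.
#' @export
callEnriched <- function(ipx, genotype, min_fold = 1.5, alpha = 0.05,
                         min_count = 10L, pseudocount = 0.5) {
  cd <- sampleSheet(ipx)
  sel <- cd$genotype == genotype
  cnt <- SummarizedExperiment::assay(ipx, "counts")
  keep <- rowSums(cnt[, sel, drop = FALSE]) >= min_count
  message(sprintf("low-count filter: %d of %d features kept",
                  sum(keep), length(keep)))
  sub <- ipx[keep, ]
  lr <- .ipLogRatios(sub, genotype, pseudocount)
  tau2 <- .pooledTau2(lr$lambda, lr$var)
  se <- sqrt((rowMeans(lr$var) + tau2) / lr$n)
  z <- rowMeans(lr$lambda) / se
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- bhFDR(p)
  cdx <- sampleSheet(sub)
  rp <- computeRPKM(SummarizedExperiment::assay(sub, "counts") + pseudocount,
                    featureLengths(sub), librarySizes(sub))
  m_in <- rowMeans(rp[, cdx$genotype == genotype & cdx$role == "input",
                      drop = FALSE])
  m_ip <- rowMeans(rp[, cdx$genotype == genotype & cdx$role == "IP",
                      drop = FALSE])
  fold <- m_ip / m_in
  data.frame(feature_id = rownames(sub),
             mean_input_rpkm = m_in, mean_ip_rpkm = m_ip,
             fold_over_input = fold,
             log2_ratio = rowMeans(lr$lambda) / log(2),
             z = z, p = p, p_adj = p_adj,
             enriched = fold > min_fold & p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential dsRNA-IP between two genotypes
#'
#' Compares the input-normalised IP enrichment (ratio of ratios) between
#' two genotypes. Filtering order is fixed and logged: low-count filter,
#' then IP-selection filter (features must be IP-enriched over input in at
#' least one genotype), then the test, then BH. The statistic is the
#' difference of mean per-replicate log-ratios with delta-method count
#' variance plus a pooled extra-dispersion term shared by both genotypes;
#' swapping the genotypes negates every log fold change and preserves the
#' p-values exactly.
#'
#' @param ipx An \linkS4class{IPExperiment} containing both genotypes.
#' @param genotype_a,genotype_b Genotypes to compare (log fold changes are
#'   b over a).
#' @param alpha Raw-p threshold (default 0.05).
#' @param fdr BH-adjusted threshold (default 0.1).
#' @param min_count Low-count filter on summed counts across both
#'   genotypes (default 10).
#' @param pseudocount Added to counts before ratios (default 0.5).
#' @param enrich_alpha,enrich_min_fold Thresholds used for the IP-selection
#'   filter (defaults 0.05 and 1.5).
#' @return A data.frame: feature_id, log2fc (IP/input ratio, b over a), z,
#'   p, p_adj, direction, significant.
#' @export
differentialIP <- function(ipx, genotype_a, genotype_b, alpha = 0.05,
                           fdr = 0.1, min_count = 10L, pseudocount = 0.5,
                           enrich_alpha = 0.05, enrich_min_fold = 1.5) {
  cd <- sampleSheet(ipx)
  for (g in c(genotype_a, genotype_b)) {
    nr <- length(intersect(
      cd$replicate[cd$genotype == g & cd$role == "IP"],
      cd$replicate[cd$genotype == g & cd$role == "input"]))
    if (nr < 2L)
      stop(sprintf(
        "genotype '%s' has %d paired replicate(s); at least 2 are needed",
        g, nr))
  }
  sel <- cd$genotype %in% c(genotype_a, genotype_b)
  cnt <- SummarizedExperiment::assay(ipx, "counts")
  keep <- rowSums(cnt[, sel, drop = FALSE]) >= min_count
  message(sprintf("low-count filter: %d of %d features kept",
                  sum(keep), length(keep)))
  sub <- ipx[keep, ]
  enr_a <- suppressMessages(
    callEnriched(sub, genotype_a, min_fold = enrich_min_fold,
                 alpha = enrich_alpha, min_count = 0L,
                 pseudocount = pseudocount))
  enr_b <- suppressMessages(
    callEnriched(sub, genotype_b, min_fold = enrich_min_fold,
                 alpha = enrich_alpha, min_count = 0L,
                 pseudocount = pseudocount))
  selected <- enr_a$enriched | enr_b$enriched
  message(sprintf("IP-selection filter: %d of %d features kept",
                  sum(selected), length(selected)))
  sub <- sub[selected, ]
  if (nrow(sub) == 0L)
    return(data.frame(feature_id = character(), log2fc = numeric(),
                      z = numeric(), p = numeric(), p_adj = numeric(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE))
  la <- .ipLogRatios(sub, genotype_a, pseudocount)
  lb <- .ipLogRatios(sub, genotype_b, pseudocount)
  tau2 <- stats::median(c(
    pmax(0, apply(la$lambda, 1, stats::var) - rowMeans(la$var)),
    pmax(0, apply(lb$lambda, 1, stats::var) - rowMeans(lb$var))))
  dlam <- rowMeans(lb$lambda) - rowMeans(la$lambda)
  se <- sqrt((rowMeans(la$var) + tau2) / la$n +
             (rowMeans(lb$var) + tau2) / lb$n)
  z <- dlam / se
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- bhFDR(p)
  data.frame(feature_id = rownames(sub),
             log2fc = dlam / log(2), z = z, p = p, p_adj = p_adj,
             direction = ifelse(dlam > 0, "up", ifelse(dlam < 0, "down",
                                                       "none")),
             significant = p < alpha & p_adj < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}
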