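#' Pooled per-genotype counts over the potentially edited positions
#'
#' The potentially edited positions of a region, for a pair (or set) of
#' genotypes, are the positions with evidence of editing (a per-sample
#' candidate call) in at least one sample of any of those genotypes. Counts
#' are pooled read-bases: the sum of edited reads and of covering reads over
#' those positions and all replicates of each genotype.
#'
#' @param er An \linkS4class{EditedRegions}.
#' @param genotypes Character vector of genotypes to pool over.
#' @return A data.table with region_id, genotype, edited, coverage,
#'   n_union_sites.
#' @keywords internal
.pooledRegionCounts <- function(er, genotypes) {
  st <- data.table::as.data.table(regionSites(er))
  sheet <- sampleSheet(er)
  st <- merge(st, data.table::as.data.table(
    sheet[, c("sample_id", "genotype")]), by = "sample_id")
  st <- st[st$genotype %in% genotypes]
  candidate <- NULL
  un <- st[, list(in_union = any(candidate)),
           by = c("region_id", "chrom", "pos")]
  un <- un[un$in_union]
  st <- merge(st, un[, c("region_id", "chrom", "pos")],
              by = c("region_id", "chrom", "pos"))
  edited <- coverage <- pos <- NULL
  st[, list(edited = sum(edited), coverage = sum(coverage),
            n_union_sites = length(unique(pos))),
     by = c("region_id", "genotype")]
}

#' Region-level percent editing for one genotype
#'
#' Total edited read-bases divided by total covering read-bases over the
#' region's potentially edited positions (union of per-sample candidate
#' positions across the genotypes named in \code{union_over}), pooled across
#' the genotype's replicates. Regions with zero covering reads are returned
#' as NA.
#'
#' @param er An \linkS4class{EditedRegions}.
#' @param genotype Genotype to quantify.
#' @param union_over Genotypes defining the potentially edited positions
#'   (default: all test genotypes in the sample sheet).
#' @return Named numeric vector of proportions, one per region.
#' @export
regionPercentEditing <- function(er, genotype, union_over = NULL) {
  sheet <- sampleSheet(er)
  if (is.null(union_over))
    union_over <- unique(sheet$genotype[sheet$role == "test"])
  pc <- .pooledRegionCounts(er, union_over)
  pc <- pc[pc$genotype == genotype]
  ids <- mcols(regionRanges(er))$region_id
  res <- stats::setNames(rep(NA_real_, length(ids)), ids)
  res[pc$region_id] <- ifelse(pc$coverage > 0, pc$edited / pc$coverage,
                              NA_real_)
  res
}

#' Compare region-level editing between two genotypes
#'
#' For every region, pools edited and covering read-bases over the
#' potentially edited positions (union of candidate positions across the two
#' genotypes), computes percent editing in each genotype, their fold change
#' (genotype_b over genotype_a), and a pooled-variance two-proportion z-test
#' with a two-sided p-value. A region is well represented when its pooled
#' covering reads exceed \code{min_reads} in both genotypes; regions that
#' are not well represented are emitted with NA statistics. A
#' Benjamini-Hochberg adjusted column is included alongside the raw p
#' (significance is assessed on the raw p at \code{alpha}, the adjusted
#' column is informational).
#'
#' @param er An \linkS4class{EditedRegions}.
#' @param genotype_a Reference genotype (e.g. wild type).
#' @param genotype_b Test genotype.
#' @param alpha Significance level on the raw two-sided p (default 0.05).
#' @param min_reads Well-represented threshold on pooled covering reads,
#'   strict inequality (default 20).
#' @param per_site_average If TRUE, percent editing is the mean of per-site
#'   pooled fractions instead of the pooled read-base proportion
#'   (sensitivity analysis; the z-test still uses pooled read counts).
#' @return A data.frame with one row per region: region_id, gene_id,
#'   n_union_sites, edited/coverage and percent per genotype, fold_change,
#'   z, p, p_adj, well_represented, significant.
#' @export
compareRegions <- function(er, genotype_a, genotype_b, alpha = 0.05,
                           min_reads = 20L, per_site_average = FALSE) {
  genos <- c(genotype_a, genotype_b)
  pc <- .pooledRegionCounts(er, genos)
  if (nrow(pc) == 0L) {
    out <- data.frame(region_id = character(), gene_id = character(),
                      n_union_sites = integer(), fold_change = numeric(),
                      z = numeric(), p = numeric(), p_adj = numeric(),
                      well_represented = logical(),
                      significant = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  wide <- data.table::dcast(pc, region_id ~ genotype,
                            value.var = c("edited", "coverage"),
                            fill = 0L)
  for (cc in c(paste0("edited_", genos), paste0("coverage_", genos)))
    if (is.null(wide[[cc]])) wide[, (cc) := 0L]
  reg <- regionRanges(er)
  m <- match(wide$region_id, mcols(reg)$region_id)
  ka <- wide[[paste0("edited_", genotype_a)]]
  na <- wide[[paste0("coverage_", genotype_a)]]
  kb <- wide[[paste0("edited_", genotype_b)]]
  nb <- wide[[paste0("coverage_", genotype_b)]]
  pa <- ifelse(na > 0, ka / na, NA_real_)
  pb <- ifelse(nb > 0, kb / nb, NA_real_)
  if (per_site_average) {
    ps <- .perSiteAverage(er, genos)
    pa <- ps[[genotype_a]][match(wide$region_id, ps$region_id)]
    pb <- ps[[genotype_b]][match(wide$region_id, ps$region_id)]
  }
  well <- na > min_reads & nb > min_reads
  z <- p <- rep(NA_real_, nrow(wide))
  ok <- which(well & na > 0 & nb > 0)
  if (length(ok)) {
    zt <- twoProportionZTest(kb[ok], nb[ok], ka[ok], na[ok])
    z[ok] <- zt$z
    p[ok] <- zt$p
  }
  n_union_sites <- NULL
  nsu <- pc[, list(n_union_sites = max(n_union_sites)), by = "region_id"]
  out <- data.frame(
    region_id = wide$region_id,
    gene_id = mcols(reg)$gene_id[m],
    n_union_sites = nsu$n_union_sites[match(wide$region_id,
                                            nsu$region_id)],
    edited_a = ka, coverage_a = na, percent_a = pa,
    edited_b = kb, coverage_b = nb, percent_b = pb,
    fold_change = ifelse(!is.na(pa) & !is.na(pb) & pa > 0 & pb > 0,
                         pb / pa, NA_real_),
    z = z, p = p, p_adj = NA_real_,
    well_represented = well,
    stringsAsFactors = FALSE)
  out$p_adj[!is.na(out$p)] <- bhFDR(out$p[!is.na(out$p)])
  out$significant <- !is.na(out$p) & out$p < alpha
  names(out)[names(out) == "edited_a"] <-
    paste0("edited_", genotype_a)
  names(out)[names(out) == "coverage_a"] <-
    paste0("coverage_", genotype_a)
  names(out)[names(out) == "percent_a"] <-
    paste0("percent_", genotype_a)
  names(out)[names(out) == "edited_b"] <-
    paste0("edited_", genotype_b)
  names(out)[names(out) == "coverage_b"] <-
    paste0("coverage_", genotype_b)
  names(out)[names(out) == "percent_b"] <-
    paste0("percent_", genotype_b)
  attr(out, "genotype_a") <- genotype_a
  attr(out, "genotype_b") <- genotype_b
  out[order(out$region_id), ]
}

.perSiteAverage <- function(er, genos) {
  st <- data.table::as.data.table(regionSites(er))
  sheet <- sampleSheet(er)
  st <- merge(st, data.table::as.data.table(
    sheet[, c("sample_id", "genotype")]), by = "sample_id")
  st <- st[st$genotype %in% genos]
  candidate <- edited <- coverage <- NULL
  un <- st[, list(in_union = any(candidate)),
           by = c("region_id", "chrom", "pos")]
  st <- merge(st, un[un$in_union, c("region_id", "chrom", "pos")],
              by = c("region_id", "chrom", "pos"))
  persite <- st[, list(frac = sum(edited) / max(1L, sum(coverage))),
                by = c("region_id", "chrom", "pos", "genotype")]
  frac <- NULL
  avg <- persite[, list(mean_frac = mean(frac)),
                 by = c("region_id", "genotype")]
  data.table::dcast(avg, region_id ~ genotype, value.var = "mean_frac")
}

#' Summarise a table of region editing comparisons
#'
#' Counts and fractions mirroring the region-level editing narrative:
#' how many well-represented regions changed significantly, how many of the
#' significant changes are increases, and the mean fold change among the
#' increased regions.
#'
#' @param cmp Output of \code{\link{compareRegions}}.
#' @return A one-row data.frame: n_regions, n_well_represented,
#'   n_significant, frac_significant, n_increased, n_decreased,
#'   frac_increased_among_significant, mean_fold_increase.
#' @export
summarizeEditing <- function(cmp) {
  if (nrow(cmp) == 0L)
    return(data.frame(n_regions = 0L, n_well_represented = 0L,
                      n_significant = 0L, frac_significant = NA_real_,
                      n_increased = 0L, n_decreased = 0L,
                      frac_increased_among_significant = NA_real_,
                      mean_fold_increase = NA_real_))
  wr <- cmp[cmp$well_represented & !is.na(cmp$p), ]
  sig <- wr[wr$significant, ]
  up <- sig[!is.na(sig$fold_change) & sig$fold_change > 1, ]
  down <- sig[!is.na(sig$fold_change) & sig$fold_change < 1, ]
  data.frame(
    n_regions = nrow(cmp),
    n_well_represented = nrow(wr),
    n_significant = nrow(sig),
    frac_significant = if (nrow(wr)) nrow(sig) / nrow(wr) else NA_real_,
    n_increased = nrow(up),
    n_decreased = nrow(down),
    frac_increased_among_significant =
      if (nrow(sig)) nrow(up) / nrow(sig) else NA_real_,
    mean_fold_increase = if (nrow(up)) mean(up$fold_change) else NA_real_)
}
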