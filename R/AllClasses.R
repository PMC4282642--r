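#' Strand-aware gene models with derived introns
#'
#' Container for a set of gene models in one coordinate convention
#' (1-based, closed intervals, as throughout Bioconductor). Exons of each
#' gene must be non-overlapping, sorted, and share the gene's chromosome and
#' strand; introns are derived as the gaps between consecutive exons within
#' the gene span and are stored rather than recomputed.
#'
#' @slot genes A \link[GenomicRanges]{GRanges} with one range per gene and a
#'   \code{gene_id} metadata column; sorted by (chrom, start, gene_id).
#' @slot exons A \link[GenomicRanges]{GRangesList} named by gene_id.
#' @slot introns A \link[GenomicRanges]{GRangesList} named by gene_id
#'   (possibly empty per gene).
#' @export
setClass("GeneModels",
  slots = c(genes = "GRanges", exons = "GRangesList", introns = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  ids <- mcols(g)$gene_id
  if (is.null(ids)) return("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(ids)) return("duplicated gene_id")
  if (!identical(names(object@exons), ids) ||
      !identical(names(object@introns), ids))
    return("exons/introns must be named by gene_id in gene order")
  for (i in seq_along(g)) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L) return("every gene needs at least one exon")
    if (!all(as.character(GenomicRanges::seqnames(ex)) ==
             as.character(GenomicRanges::seqnames(g)[i])) ||
        !all(as.character(strand(ex)) == as.character(strand(g)[i])))
      return(sprintf("gene %s: exon chrom/strand mismatch", ids[i]))
    if (is.unsorted(start(ex))) return(sprintf("gene %s: exons unsorted", ids[i]))
    if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      return(sprintf("gene %s: overlapping exons", ids[i]))
    if (min(start(ex)) != start(g)[i] || max(end(ex)) != end(g)[i])
      return(sprintf("gene %s: span does not match exon extent", ids[i]))
    # introns must be exactly the within-span complement of the exons
    expect <- .intronGaps(ex)
    got <- object@introns[[i]]
    if (length(expect) != length(got) ||
        (length(got) && (!all(start(got) == start(expect)) ||
                         !all(end(got) == end(expect)))))
      return(sprintf("gene %s: introns are not the exon complement", ids[i]))
  }
  TRUE
})

# gaps between consecutive exons, inheriting chrom and strand
.intronGaps <- function(ex) {
  if (length(ex) < 2L) return(ex[0])
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ex)[-1L],
    ranges = IRanges::IRanges(start = end(ex)[-length(ex)] + 1L,
                              end = start(ex)[-1L] - 1L),
    strand = strand(ex)[-1L])
}

#' Construct a GeneModels object
#'
#' @param geneIds Character vector of gene identifiers.
#' @param exons A \link[GenomicRanges]{GRangesList} of exons, one element per
#'   gene, in the same order as \code{geneIds}.
#' @return A \linkS4class{GeneModels} object sorted by (chrom, start,
#'   gene_id).
#' @export
GeneModels <- function(geneIds, exons) {
  stopifnot(length(geneIds) == length(exons))
  exons <- GenomicRanges::GRangesList(lapply(seq_along(exons),
                                             function(i) {
    ex <- GenomicRanges::sort.GenomicRanges(exons[[i]],
                                            ignore.strand = TRUE)
    if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      stop("overlapping exons in gene ", geneIds[i])
    mcols(ex) <- NULL
    ex
  }))
  genes <- unlist(GenomicRanges::GRangesList(lapply(exons, range)),
                  use.names = FALSE)
  mcols(genes)$gene_id <- geneIds
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               start(genes), geneIds)
  genes <- genes[ord]
  exons <- exons[ord]
  names(exons) <- mcols(genes)$gene_id
  introns <- GenomicRanges::GRangesList(lapply(exons, .intronGaps))
  names(introns) <- mcols(genes)$gene_id
  new("GeneModels", genes = genes, exons = exons, introns = introns)
}

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneModels", function(x) mcols(x@genes)$gene_id)

#' @rdname geneRanges
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @rdname exonsByGene
#' @export
setMethod("exonsByGene", "GeneModels", function(x) x@exons)

#' @rdname intronsByGene
#' @export
setMethod("intronsByGene", "GeneModels", function(x) x@introns)

setMethod("length", "GeneModels", function(x) length(x@genes))

setMethod("show", "GeneModels", function(object) {
  n <- length(object)
  nex <- sum(lengths(object@exons))
  cat(sprintf("GeneModels with %d genes (%d exons, %d introns) on %d sequences\n",
              n, nex, sum(lengths(object@introns)),
              length(unique(as.character(GenomicRanges::seqnames(object@genes))))))
})

#' Merged A-to-I edited regions with per-site, per-sample counts
#'
#' A set of candidate editing sites merged into regions, together with the
#' per-sample edited-read and covering-read tallies at every member site, and
#' the sample sheet mapping samples to genotypes and roles.
#'
#' @slot regions A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{region_id}, \code{gene_id} and \code{n_sites}.
#' @slot sites A data.frame in long format with columns \code{region_id},
#'   \code{chrom}, \code{pos}, \code{strand}, \code{gene_id},
#'   \code{sample_id}, \code{edited}, \code{coverage}, \code{candidate},
#'   \code{untestable}.
#' @slot samples A data.frame with columns \code{sample_id},
#'   \code{genotype}, \code{replicate}, \code{role}.
#' @export
setClass("EditedRegions",
  slots = c(regions = "GRanges", sites = "data.frame", samples = "data.frame"))

setValidity("EditedRegions", function(object) {
  need <- c("region_id", "chrom", "pos", "strand", "gene_id", "sample_id",
            "edited", "coverage", "candidate", "untestable")
  if (!all(need %in% names(object@sites)))
    return("sites is missing required columns")
  if (any(object@sites$edited > object@sites$coverage))
    return("edited counts exceed coverage")
  if (any(object@sites$edited < 0) || any(object@sites$coverage < 0))
    return("negative counts")
  if (!all(object@sites$region_id %in% mcols(object@regions)$region_id))
    return("sites refer to unknown regions")
  if (!all(c("sample_id", "genotype", "replicate", "role") %in%
           names(object@samples)))
    return("samples sheet is missing required columns")
  TRUE
})

#' @rdname regionRanges
#' @export
setMethod("regionRanges", "EditedRegions", function(x) x@regions)

#' @rdname regionSites
#' @export
setMethod("regionSites", "EditedRegions", function(x) x@sites)

#' @rdname sampleSheet
#' @export
setMethod("sampleSheet", "EditedRegions", function(x) x@samples)

setMethod("length", "EditedRegions", function(x) length(x@regions))

setMethod("show", "EditedRegions", function(object) {
  cat(sprintf("EditedRegions: %d regions, %d sites, %d samples\n",
              length(object@regions),
              length(unique(paste(object@sites$chrom, object@sites$pos))),
              nrow(object@samples)))
})

#' dsRNA-IP count experiment
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding a counts
#' assay for IP and input libraries. Row data carry feature lengths; column
#' data carry \code{sample_id}, \code{genotype}, \code{role} (one of
#' "input"/"IP"), \code{replicate} and \code{lib_size}.
#'
#' @export
setClass("IPExperiment", contains = "SummarizedExperiment")

setValidity("IPExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "genotype", "role", "replicate", "lib_size")
  if (!all(need %in% names(cd))) return("colData is missing required columns")
  if (!all(cd$role %in% c("input", "IP")))
    return("role must be 'input' or 'IP'")
  if (any(cd$lib_size <= 0)) return("library sizes must be positive")
  if (!"length" %in% names(SummarizedExperiment::rowData(object)))
    return("rowData must carry feature 'length'")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be non-negative integers")
  TRUE
})

#' Construct an IPExperiment
#'
#' @param counts Integer matrix, features x samples.
#' @param lengths Numeric vector of feature lengths (bases), one per row.
#' @param samples A data.frame with columns \code{sample_id},
#'   \code{genotype}, \code{role}, \code{replicate} and optionally
#'   \code{lib_size} (defaults to the column sums).
#' @return An \linkS4class{IPExperiment}.
#' @export
IPExperiment <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(lengths),
            ncol(counts) == nrow(samples))
  if (is.null(samples$lib_size)) samples$lib_size <- colSums(counts)
  colnames(counts) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(length = lengths, row.names = rownames(counts)),
    colData = DataFrame(samples, row.names = samples$sample_id))
  new("IPExperiment", se)
}

#' @rdname featureLengths
#' @export
setMethod("featureLengths", "IPExperiment", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$length, rownames(x))
})

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "IPExperiment", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$lib_size, colnames(x))
})

#' @rdname sampleSheet
#' @export
setMethod("sampleSheet", "IPExperiment", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Truth table of a synthetic simulation
#'
#' Records everything the generator planted so downstream stages can be
#' scored against known truth: edited sites with per-genotype editing
#' fractions, antisense gene pairs, inverted repeats placed in long introns,
#' repeat intervals, synthetic ChIP-style peaks and IP-enriched /
#' differential features.
#'
#' @slot editedSites GRanges with \code{gene_id}, \code{region_id} and one
#'   \code{frac_<genotype>} column per genotype.
#' @slot antisensePairs data.frame with columns \code{gene_a}, \code{gene_b}.
#' @slot invertedRepeats data.frame describing planted IRs (gene, intron
#'   coordinates, arm coordinates, arm/loop lengths).
#' @slot repeats GRanges of transposon-like repeat intervals.
#' @slot peaks GRanges of synthetic ChIP-style peaks.
#' @slot enrichedFeatures data.frame with \code{feature_id}, \code{ip_fold},
#'   \code{diff_fold}.
#' @export
setClass("SyntheticTruth",
  slots = c(editedSites = "GRanges", antisensePairs = "data.frame",
            invertedRepeats = "data.frame", repeats = "GRanges",
            peaks = "GRanges", enrichedFeatures = "data.frame"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d edited sites in %d regions, ",
                     "%d antisense pairs, %d inverted repeats, %d repeats, ",
                     "%d peaks, %d enriched features\n"),
              length(object@editedSites),
              length(unique(mcols(object@editedSites)$region_id)),
              nrow(object@antisensePairs), nrow(object@invertedRepeats),
              length(object@repeats), length(object@peaks),
              sum(object@enrichedFeatures$ip_fold > 1)))
})
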