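#' @import methods
#' @importFrom BiocGenerics strand start end width
#' @importFrom S4Vectors DataFrame metadata mcols mcols<-
NULL

#' Gene identifiers of an object
#' @param x An object holding gene models.
#' @return Character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Gene span ranges
#' @param x An object holding gene models.
#' @return A \link[GenomicRanges]{GRanges} of gene spans.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' Exons grouped by gene
#' @param x An object holding gene models.
#' @return A \link[GenomicRanges]{GRangesList} named by gene.
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' Introns grouped by gene
#' @param x An object holding gene models.
#' @return A \link[GenomicRanges]{GRangesList} named by gene.
#' @export
setGeneric("intronsByGene", function(x) standardGeneric("intronsByGene"))

#' Region ranges of a set of edited regions
#' @param x An \linkS4class{EditedRegions} object.
#' @return A \link[GenomicRanges]{GRanges} of merged regions.
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' Per-site, per-sample counts of a set of edited regions
#' @param x An \linkS4class{EditedRegions} object.
#' @return A data.frame in long format (one row per site and sample).
#' @export
setGeneric("regionSites", function(x) standardGeneric("regionSites"))

#' Sample sheet of an experiment container
#' @param x An object holding per-sample metadata.
#' @return A data.frame with one row per sample.
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' Feature lengths in bases
#' @param x An \linkS4class{IPExperiment}.
#' @return Named numeric vector of feature lengths.
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))

#' Library sizes (total mapped reads) per sample
#' @param x An \linkS4class{IPExperiment}.
#' @return Named numeric vector of library sizes.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))
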