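#' Reverse complement of a nucleotide string
#'
#' Standard complement over the alphabet {A, C, G, T, N}, reversed. An
#' involution: \code{revComp(revComp(s)) == s}.
#'
#' @param seq A single character string.
#' @return The reverse-complemented string.
#' @examples revComp("GAAT")  # "ATTC"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("non-IUPAC character '%s' at offset %d",
                 substr(seq, bad, bad), as.integer(bad)))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read gene models from a GFF3 file
#'
#' Expects a gene/mRNA/exon hierarchy with one transcript per gene.
#' Coordinates on disk are 1-based inclusive (GFF3 convention) and are kept
#' in that convention internally (GRanges). Introns are derived as the gaps
#' between consecutive exons. Genes are returned in deterministic order
#' (chrom, start, gene_id).
#'
#' @param path Path to a GFF3 file.
#' @return A \linkS4class{GeneModels} object.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  mrnas <- gff[gff$type == "mRNA"]
  exons <- gff[gff$type == "exon"]
  if (length(genes) == 0L) stop("no gene records in ", path)
  mparent <- as.character(unlist(mrnas$Parent))
  if (length(mparent) != length(mrnas) || !all(mparent %in% genes$ID))
    stop("malformed hierarchy: mRNA without gene parent in ", path)
  eparent <- as.character(unlist(exons$Parent))
  if (length(eparent) != length(exons)) {
    .orphanLine(path, "exon")
  }
  orphan <- !(eparent %in% mrnas$ID)
  if (any(orphan)) .orphanLine(path, "exon", eparent[orphan][1])
  if (anyDuplicated(mparent))
    stop("more than one transcript per gene is not supported: ",
         mparent[duplicated(mparent)][1])
  gene_of_mrna <- stats::setNames(mparent, mrnas$ID)
  egene <- unname(gene_of_mrna[eparent])
  ids <- genes$ID
  exl <- lapply(ids, function(gid) {
    ex <- exons[egene == gid]
    if (length(ex) == 0L) stop("gene without exons: ", gid)
    ex <- GenomicRanges::sort.GenomicRanges(ex, ignore.strand = TRUE)
    if (length(ex) > 1L &&
        any(GenomicRanges::start(ex)[-1L] <=
            GenomicRanges::end(ex)[-length(ex)]))
      stop("overlapping exons in transcript of gene ", gid)
    GenomicRanges::granges(ex)
  })
  GeneModels(geneIds = ids, exons = exl)
}

# report the first line number mentioning an orphaned record
.orphanLine <- function(path, type, parent = NULL) {
  lines <- readLines(path)
  pat <- if (is.null(parent)) sprintf("\t%s\t", type)
         else sprintf("Parent=%s\\b", parent)
  hit <- grep(pat, lines)[1]
  stop(sprintf("malformed hierarchy in %s: %s without parent (line %s)",
               path, type, ifelse(is.na(hit), "?", hit)))
}

#' Write gene models to a GFF3 file
#'
#' Emits the gene/mRNA/exon hierarchy (one transcript per gene) with 1-based
#' inclusive coordinates; a round trip through
#' \code{\link{readAnnotation}} reproduces identical models.
#'
#' @param models A \linkS4class{GeneModels} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotation <- function(models, path) {
  g <- geneRanges(models)
  ids <- geneIds(models)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- "%s\tdsRNAtools\t%s\t%d\t%d\t.\t%s\t.\t%s"
  for (i in seq_along(g)) {
    chrom <- as.character(GenomicRanges::seqnames(g)[i])
    str <- as.character(strand(g)[i])
    writeLines(sprintf(fmt, chrom, "gene", start(g)[i], end(g)[i], str,
                       sprintf("ID=%s", ids[i])), con)
    tid <- sprintf("%s.t1", ids[i])
    writeLines(sprintf(fmt, chrom, "mRNA", start(g)[i], end(g)[i], str,
                       sprintf("ID=%s;Parent=%s", tid, ids[i])), con)
    ex <- exonsByGene(models)[[i]]
    for (j in seq_along(ex)) {
      writeLines(sprintf(fmt, chrom, "exon", start(ex)[j], end(ex)[j], str,
                         sprintf("ID=%s.e%d;Parent=%s", ids[i], j, tid)), con)
    }
  }
  invisible(path)
}

#' Read a genome from a FASTA file
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet} named by sequence.
#' @export
readGenome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome to a FASTA file
#' @param genome A named \link[Biostrings]{DNAStringSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' BED is 0-based half-open on disk; the returned GRanges is 1-based closed
#' (conversion handled by rtracklayer, losslessly).
#'
#' @param path Path to a BED/BED6 file.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")

#' Write intervals to a BED6 file
#' @param gr A \link[GenomicRanges]{GRanges}; a \code{name} metadata column
#'   is used for the BED name field when present.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
  nm <- mcols(gr)$name
  if (is.null(nm)) nm <- sprintf("iv%05d", seq_along(gr))
  dt <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start0 = start(gr) - 1L, end = end(gr), name = nm,
                   score = rep(0L, length(gr)),
                   strand = as.character(strand(gr)))
  dt$strand[dt$strand == "*"] <- "."
  utils::write.table(dt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-position pileup table
#'
#' The on-disk format is a TSV with header columns \code{chrom},
#' \code{pos0} (0-based), \code{ref}, \code{A}, \code{C}, \code{G},
#' \code{T}, \code{N}, \code{sample}. Internally positions are 1-based
#' (column \code{pos}).
#'
#' @param path Path to a pileup TSV.
#' @return A data.table with 1-based \code{pos}.
#' @export
readPileupTable <- function(path) {
  pu <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "pos0", "ref", "A", "C", "G", "T", "N", "sample")
  if (!all(need %in% names(pu)))
    stop("pileup TSV is missing columns: ",
         paste(setdiff(need, names(pu)), collapse = ", "))
  pu[, "pos" := pu$pos0 + 1L]
  pu[, "pos0" := NULL]
  data.table::setcolorder(pu, c("chrom", "pos", "ref",
                                "A", "C", "G", "T", "N", "sample"))
  pu[]
}

#' Write a per-position pileup table
#' @param pileup A data.table as returned by \code{\link{buildPileup}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePileupTable <- function(pileup, path) {
  out <- data.table::copy(data.table::as.data.table(pileup))
  out[, "pos0" := out$pos - 1L]
  out[, "pos" := NULL]
  data.table::setcolorder(out, c("chrom", "pos0", "ref",
                                 "A", "C", "G", "T", "N", "sample"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
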