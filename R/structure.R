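#' Find antisense-overlapping gene pairs
#'
#' Unordered pairs of genes on opposite strands whose spans overlap by at
#' least \code{min_overlap} bases. The default of 40 bp is the minimum
#' duplex length recognised by the J2 anti-dsRNA antibody, so shorter
#' overlaps cannot form a detectable duplex.
#'
#' @param models A \linkS4class{GeneModels}.
#' @param min_overlap Minimum span overlap in bases (default 40).
#' @return A data.frame with columns gene_a, gene_b (gene_a < gene_b
#'   lexicographically) and overlap_bp, sorted by (gene_a, gene_b).
#' @export
findAntisensePairs <- function(models, min_overlap = 40L) {
  g <- geneRanges(models)
  ids <- geneIds(models)
  ov <- GenomicRanges::findOverlaps(g, minoverlap = min_overlap,
                                    ignore.strand = TRUE,
                                    drop.self = TRUE, drop.redundant = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  opp <- as.character(strand(g)[qh]) != as.character(strand(g)[sh])
  qh <- qh[opp]
  sh <- sh[opp]
  if (length(qh) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE))
  wd <- width(IRanges::pintersect(IRanges::ranges(g)[qh],
                                  IRanges::ranges(g)[sh]))
  a <- pmin(ids[qh], ids[sh])
  b <- pmax(ids[qh], ids[sh])
  out <- data.frame(gene_a = a, gene_b = b, overlap_bp = wd,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

.compMap <- c(A = "T", C = "G", G = "C", T = "A", N = "?")

# arms on one anti-diagonal c (pair sum, 1-based): maximal chains of
# exact-match runs, bridging single mismatches flanked by runs of >= 4
# matches on both sides; a reported arm must contain a run >= seed_len
.diagonalArms <- function(sv, cv, c, n, seed_len, min_arm, min_loop,
                          max_loop, min_identity) {
  pmin_ <- max(1L, c - n)
  pmax_ <- (c - 1L) %/% 2L
  if (pmax_ - pmin_ + 1L < min_arm) return(NULL)
  pidx <- pmin_:pmax_
  m <- sv[pidx] == cv[c - pidx]
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) return(NULL)
  # chain runs: join consecutive match runs across a single-mismatch gap
  # when both flanks have length >= 4
  chain_id <- integer(length(runs))
  cur <- 1L
  chain_id[1L] <- cur
  if (length(runs) > 1L) {
    for (i in 2L:length(runs)) {
      prev <- runs[i - 1L]
      gap_len <- starts[runs[i]] - (ends[prev] + 1L)
      join <- gap_len == 1L && r$lengths[prev] >= 4L &&
        r$lengths[runs[i]] >= 4L
      if (!join) cur <- cur + 1L
      chain_id[i] <- cur
    }
  }
  out <- NULL
  for (ch in unique(chain_id)) {
    rr <- runs[chain_id == ch]
    if (max(r$lengths[rr]) < seed_len) next
    p1 <- pidx[starts[rr[1L]]]
    p2 <- pidx[ends[rr[length(rr)]]]
    L <- p2 - p1 + 1L
    if (L < min_arm) next
    nmatch <- sum(r$lengths[rr])
    identity <- nmatch / L
    if (identity < min_identity) next
    loop <- c - 2L * p2 - 1L
    if (loop < min_loop || loop > max_loop) next
    out <- rbind(out, data.frame(
      arm_a_start = p1, arm_a_end = p2,
      arm_b_start = c - p2, arm_b_end = c - p1,
      arm_length = L, loop_length = loop, identity = identity,
      n_matches = nmatch))
  }
  out
}

#' Find inverted repeats in a nucleotide sequence
#'
#' Seed-and-extend search for ungapped inverted repeats: exact
#' \code{seed_len}-mers of the sequence are matched against the reverse
#' complement; every seeded anti-diagonal is then scanned for arms, defined
#' as maximal chains of exact-match runs in which single mismatches are
#' bridged when flanked by at least 4 matches on both sides. A reported
#' inverted repeat must contain an exact run of at least \code{seed_len}
#' matches, have arm length >= \code{min_arm}, arm identity >=
#' \code{min_identity}, and a loop (gap between the arms) between
#' \code{min_loop} and \code{max_loop}. N bases never match and therefore
#' never extend an arm. The result is the maximal non-redundant hit set
#' (one maximal arm per chain per diagonal, duplicates removed).
#'
#' @param seq A nucleotide string over {A,C,G,T,N}.
#' @param min_arm Minimum arm length (default 20; must be >= seed_len).
#' @param max_loop Maximum loop length (default 2000).
#' @param min_identity Minimum arm identity (default 0.85).
#' @param seed_len Exact seed length (default 12).
#' @param min_loop Minimum loop length (default 3, the shortest hairpin
#'   loop).
#' @return A data.frame with 1-based inclusive coordinates arm_a_start,
#'   arm_a_end, arm_b_start, arm_b_end, arm_length, loop_length, identity,
#'   n_matches, sorted by (arm_a_start, arm_b_start).
#' @export
findInvertedRepeats <- function(seq, min_arm = 20L, max_loop = 2000L,
                                min_identity = 0.85, seed_len = 12L,
                                min_loop = 3L) {
  if (min_arm < seed_len)
    stop(sprintf("'min_arm' (%d) is below the seed size (%d)",
                 min_arm, seed_len))
  n <- nchar(seq)
  empty <- data.frame(arm_a_start = integer(), arm_a_end = integer(),
                      arm_b_start = integer(), arm_b_end = integer(),
                      arm_length = integer(), loop_length = integer(),
                      identity = numeric(), n_matches = integer())
  if (n < 2L * min_arm + min_loop) return(empty)
  sv <- strsplit(seq, "")[[1]]
  cv <- unname(.compMap[sv])
  cv[is.na(cv)] <- "?"
  # seed stage: k-mers of seq matched against k-mers of its reverse
  # complement; a hit at (i, j') corresponds to anti-diagonal i - j' + n + 1
  starts <- seq_len(n - seed_len + 1L)
  km <- substring(seq, starts, starts + seed_len - 1L)
  rc <- revComp(seq)
  kmr <- substring(rc, starts, starts + seed_len - 1L)
  common <- intersect(km, kmr)
  common <- common[!grepl("N", common)]
  if (length(common) == 0L) return(empty)
  ik <- which(km %in% common)
  jk <- which(kmr %in% common)
  map <- split(jk, kmr[jk])
  diags <- unlist(lapply(ik, function(i) {
    js <- map[[km[i]]]
    i - js + n + 1L
  }), use.names = FALSE)
  diags <- sort(unique(diags))
  out <- lapply(diags, function(c)
    .diagonalArms(sv, cv, c, n, seed_len, min_arm, min_loop, max_loop,
                  min_identity))
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- unique(out)
  out[order(out$arm_a_start, out$arm_b_start), , drop = FALSE]
}

#' Find UG-repeat tracts in a genome
#'
#' Maximal runs of the TG dinucleotide on the plus strand (transcribed as UG
#' from plus-strand genes) and of CA on the plus strand (transcribed as UG
#' from minus-strand genes) with at least \code{min_units} units.
#'
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param min_units Minimum number of dinucleotide units (default 6,
#'   >= 2 required).
#' @return A \link[GenomicRanges]{GRanges} with strand and an
#'   \code{n_units} metadata column.
#' @export
findUGRepeats <- function(genome, min_units = 6L) {
  if (min_units < 2L) stop("'min_units' must be >= 2")
  hits <- list()
  for (ch in names(genome)) {
    s <- as.character(genome[[ch]])
    for (spec in list(list(pat = "(?:TG)+", strand = "+"),
                      list(pat = "(?:CA)+", strand = "-"))) {
      m <- gregexpr(spec$pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      keep <- len >= 2L * min_units
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(as.integer(m[keep]),
                             width = len[keep]),
        strand = spec$strand,
        n_units = len[keep] %/% 2L)
    }
  }
  if (length(hits) == 0L) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$n_units <- integer(0)
    return(gr)
  }
  # hits from different chromosomes have disjoint seqlevels by design
  sort(suppressWarnings(do.call(c, hits)), ignore.strand = TRUE)
}

#' Overlap statistics between two interval sets
#'
#' A query interval counts as overlapping iff it shares at least one base
#' with any subject interval (strand-blind).
#'
#' @param query,subject \link[GenomicRanges]{GRanges} objects.
#' @return A list with n_overlapping, n_total and fraction (NA with a
#'   warning when the query set is empty).
#' @export
intervalOverlapStats <- function(query, subject) {
  n_total <- length(query)
  if (n_total == 0L) {
    warning("empty query set: overlap fraction is undefined")
    return(list(n_overlapping = 0L, n_total = 0L, fraction = NA_real_))
  }
  n_ov <- sum(GenomicRanges::countOverlaps(query, subject,
                                           ignore.strand = TRUE) > 0L)
  list(n_overlapping = n_ov, n_total = n_total,
       fraction = n_ov / n_total)
}

#' Classify genes by dsRNA-forming potential
#'
#' Per-gene structural annotation: antisense overlap with another gene,
#' inverted repeats within introns (counted separately for long introns
#' above \code{min_ir_intron} and for all introns), and overlap with
#' annotated repeat elements. A gene satisfies the structured-dsRNA
#' criterion when it has an antisense partner, at least one inverted repeat
#' in a long intron, or overlaps a repeat element.
#'
#' @param models A \linkS4class{GeneModels}.
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param repeats A \link[GenomicRanges]{GRanges} of repeat elements
#'   (may be empty).
#' @param pairs Optional precomputed output of
#'   \code{\link{findAntisensePairs}}.
#' @param min_ir_intron Minimum intron length for the long-intron inverted
#'   repeat census (default 1000, strict inequality).
#' @param min_overlap Antisense-overlap threshold passed on (default 40).
#' @param ... Further arguments passed to
#'   \code{\link{findInvertedRepeats}}.
#' @return A data.frame with one row per gene: gene_id,
#'   has_antisense_overlap, n_intronic_irs (long introns),
#'   n_irs_any_intron, overlaps_repeat_annotation, multi_ir_or_repeat
#'   (two or more long-intron IRs and/or repeat overlap), dsrna_structured.
#' @export
classifyGenes <- function(models, genome, repeats = GenomicRanges::GRanges(),
                          pairs = NULL, min_ir_intron = 1000L,
                          min_overlap = 40L, ...) {
  if (is.null(pairs)) pairs <- findAntisensePairs(models, min_overlap)
  ids <- geneIds(models)
  as_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  introns <- intronsByGene(models)
  ir_long <- integer(length(ids))
  ir_any <- integer(length(ids))
  for (i in seq_along(ids)) {
    intr <- introns[[i]]
    if (length(intr) == 0L) next
    for (j in seq_along(intr)) {
      ch <- as.character(GenomicRanges::seqnames(intr)[j])
      s <- as.character(Biostrings::subseq(genome[[ch]], start(intr)[j],
                                           end(intr)[j]))
      n_ir <- nrow(findInvertedRepeats(s, ...))
      ir_any[i] <- ir_any[i] + n_ir
      if (width(intr)[j] > min_ir_intron) ir_long[i] <- ir_long[i] + n_ir
    }
  }
  rep_ov <- if (length(repeats))
    GenomicRanges::countOverlaps(geneRanges(models), repeats,
                                 ignore.strand = TRUE) > 0L
  else rep(FALSE, length(ids))
  data.frame(
    gene_id = ids,
    has_antisense_overlap = ids %in% as_genes,
    n_intronic_irs = ir_long,
    n_irs_any_intron = ir_any,
    overlaps_repeat_annotation = rep_ov,
    multi_ir_or_repeat = ir_long >= 2L | rep_ov,
    dsrna_structured = ids %in% as_genes | ir_long >= 1L | rep_ov,
    stringsAsFactors = FALSE)
}
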