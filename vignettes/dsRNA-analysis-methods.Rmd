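---
title: "Detecting double-stranded RNA signatures in transcriptome data"
author: "dsRNAtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting double-stranded RNA signatures in transcriptome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Double-stranded RNA (dsRNA) arises in a transcriptome in two ways:
intramolecularly, when a transcript folds back on itself because it carries
an inverted repeat (typically in a long intron), and intermolecularly, when
two genes are transcribed antisense to one another and their transcripts
hybridise. dsRNA leaves several measurable footprints in ordinary RNA-seq
and immunoprecipitation experiments:

* **A-to-I RNA editing.** ADAR enzymes deaminate adenosines within long
  duplexes; inosine is read as guanosine by sequencers, so editing appears
  as A→G mismatches on the transcribed strand (equivalently T→C in
  reference coordinates for minus-strand genes). Promiscuous editing
  targets many adenosines per duplex, so genuine editing clusters into
  regions.
* **Recovery by a dsRNA-specific antibody.** The J2 monoclonal antibody
  binds duplexes of roughly 40 bp and longer regardless of sequence, so
  sequencing a J2 immunoprecipitate (J2-IP) against its input library
  identifies transcripts that actually contain duplex RNA in vivo.
* **Structural features in the annotation itself**: antisense gene
  overlap, intronic inverted repeats, overlap with transposons and tandem
  repeats, and UG-repeat tracts (the preferred binding sequence of
  TDP-43-family RNA-binding proteins).

dsRNAtools implements all three layers as a tested pipeline: an editing
caller with replicate-consistency and ADAR-null control filtering,
region-level editing statistics, a structural annotator, a dsRNA-IP
enrichment and differential-IP analysis, and a shared statistical kernel.
A deterministic synthetic-data generator with a machine-readable truth
table makes every stage testable by parameter recovery without any
external download.

## The editing caller

Input is a per-position pileup (from a SAM/BAM file via `Rsamtools`, or a
documented pileup TSV that bypasses alignment parsing; both routes produce
identical columns). Calling proceeds in three stages:

1. **Candidate sites** (`callCandidateSites`). A position is a candidate
   in one sample iff the mismatch matches the A-to-I signature on the
   transcribed strand: reference A with at least `min_edited_reads` G
   reads under a plus-strand gene, or reference T with at least that many
   C reads under a minus-strand gene, with edited fraction at least
   `min_fraction`. Other mismatch classes are never called; a C→T
   mismatch on the transcribed strand is not an A-to-I signature, and the
   two transition classes quoted for this assay are interpreted as the
   two reference-coordinate appearances of A→G editing on opposite
   strands. Positions under genes on both strands are ambiguous and
   excluded (an `unanchored` mode calls both orientations with strand
   "."). Defaults are `min_edited_reads = 2` and `min_fraction = 0.05`
   per sample — deliberately permissive per-sample thresholds, because
   the real specificity comes from the next stage.
2. **Replicate and control filtering** (`filterCandidates`). A site is
   kept only if it is a candidate in *every* replicate of at least one
   test genotype and in *no* sample of the ADAR-null control genotype.
   Control subtraction is mandatory; sites whose control coverage is
   below `min_control_coverage` (default 10) cannot be tested against
   the control and are retained but flagged `untestable`.
3. **Region merging** (`mergeRegions`). Promiscuous editing clusters
   densely, so same-gene sites within `max_gap = 100` bases are merged by
   single linkage. The default keeps simulated clusters (sites every
   ~15 bp) intact while never joining sites across genes.

Thresholds are configuration, not biology: the assay this package models
annotated its regions by hand, so no published per-site threshold exists
to reproduce. Region counts from that kind of manual annotation are
therefore not recovery targets; the caller is validated against the
synthetic truth table instead (recall ≥ 0.9 and false discovery ≤ 0.05 at
coverage 50 and editing fraction 0.3, and exactly zero replicate-consistent
calls in the ADAR-null genotype).

## Region-level editing statistics

For a pair of genotypes, the *potentially edited positions* of a region
are the positions with a candidate call in at least one sample of either
genotype. Percent editing of a genotype is the pooled read-base
proportion: total edited reads divided by total covering reads over those
positions, pooled across replicates (`regionPercentEditing`). The pooled
reading is the one under which a two-proportion z-test with read-count
denominators is well-posed; a per-site-averaged alternative is available
behind `per_site_average = TRUE` for sensitivity analysis, and the two
can differ markedly when coverage is very uneven across sites.

`compareRegions` tests each region with the pooled-variance two-proportion
z statistic, two-sided, no continuity correction. A region is *well
represented* when both genotypes have strictly more than 20 pooled
covering reads; other regions are reported but carry NA statistics.
Significance is assessed on the raw p at `alpha = 0.05` — matching the
analysis this package models, which applied no multiple-testing correction
to region comparisons — and a BH-adjusted column is emitted alongside for
the user. `summarizeEditing` then reports the quantities that make up the
headline narrative: the fraction of well-represented regions with
significantly altered editing, the fraction of increases among them, and
the mean fold change among increases.

The z-test is validated three ways: algebraically (z² equals the Pearson
chi-square statistic on the same 2×2 table to 1e-9), by calibration
(significant fraction of 1,000 null regions at coverage 100 lies in
[0.03, 0.07] at α = 0.05), and against its own analytic power function.
At pooled coverage 500 per genotype, a 0.10 → 0.14 shift (1.4-fold) has
analytic power near 0.5 — worth knowing when interpreting "fraction of
regions altered" on real data, since that fraction confounds effect size
and coverage.

## The structural annotator

**Antisense pairs** (`findAntisensePairs`) are opposite-strand genes whose
spans overlap by at least `min_overlap = 40` bp. The default is the
shortest duplex the J2 antibody recognises: a shorter sense–antisense
overlap could not be seen by the IP layer. Span overlap (not exon-only)
is used because pre-mRNA hybridisation is the proposed mechanism; the
overlap is computed on whole gene extents.

**Inverted repeats** (`findInvertedRepeats`) are found by seed-and-extend:
exact 12-mers of the sequence are hashed against its reverse complement;
every seeded anti-diagonal is then scanned for *arms*, defined as maximal
chains of exact-match runs in which a single mismatch is bridged when
flanked by at least 4 matches on both sides. A reported repeat must
contain an exact run at least as long as the seed, have arm length ≥
`min_arm = 20`, identity ≥ `min_identity = 0.85`, and a loop between 3
(the shortest hairpin) and `max_loop = 2000` bases. This definition is
deliberately exact and deterministic, so that an exhaustive per-diagonal
oracle can assert set equality in the tests — ambiguity about what
"maximal arm under an identity threshold" means is resolved by the
bridging rule rather than by a scoring heuristic. The census feeding
gene classification is restricted to introns longer than 1 kb (with an
all-introns count retained), because short introns are spliced too
quickly to present long duplexes and the editing data show intronic
duplexes concentrated in long introns. N bases never match and never
extend an arm. No thermodynamic folding is attempted; arm/loop geometry
is a proxy for duplex-forming potential, not a structure prediction.

**UG repeats** (`findUGRepeats`) are maximal TG-dinucleotide runs (CA on
the opposite strand) of at least 6 units, strand-annotated.

**Classification** (`classifyGenes`) combines the layers per gene:
antisense partner, long-intron inverted repeats, repeat-element overlap,
and the derived flags used by enrichment analyses (`dsrna_structured`:
any of the three; `multi_ir_or_repeat`: two or more long-intron IRs
and/or repeat overlap).

## dsRNA-IP enrichment

Counts live in an `IPExperiment` (a `SummarizedExperiment` with feature
lengths in the row data and sample genotype/role/replicate/library size in
the column data). Abundances are RPKM; the enrichment decision rule is
fold over input > 1.5 with BH-adjusted p < 0.05, and the differential
rule between genotypes is raw p < 0.05 with BH-adjusted p < 0.1 — both
rules preserved exactly from the assay this package models.

The test itself is a stand-in for a full count-model fit, built around
the design of the experiment: the IP and input libraries of one replicate
come from the *same lysate*, so their shared biological variation cancels
in the per-replicate input-normalised log-ratio. The statistic is the
mean (or between-genotype difference of means) of those log-ratios over a
standard error combining the delta-method count-level variance
(1/(count+0.5) terms) with a pooled method-of-moments extra-dispersion
term estimated from the excess of the observed between-replicate variance
over the count-level expectation, with a two-sided normal reference.
An unpaired negative-binomial test was rejected during design: with
dispersion 0.1 and three replicates its biological-variance floor makes a
2.5-fold genotype difference undetectable at useful power, whereas the
paired ratio cancels that term. Pseudocount 0.5 is added to all counts
before ratios so zero-input features have finite folds. Filtering order
is fixed and logged: low-count filter (summed count < 10), then — for the
differential analysis — the IP-selection filter (a feature must be
IP-enriched over input in at least one genotype), then the test, then BH.
Swapping the genotypes negates every log fold change and preserves every
p-value exactly.

Intron-level analysis uses `extractIntronFeatures`: all introns strictly
longer than 250 bp become countable features named `<gene>.intron<k>`.

The shared kernel computes hypergeometric tails in log space
(`hypergeomSF`), so category-enrichment p-values far below 1e-300 remain
representable on the log scale; enrichment tests are upper-tailed by
default with an explicit lower tail for depletion claims; `bhFDR` is the
Benjamini–Hochberg step-up (the FDR procedure is a package choice — only
the control level, not the procedure, is inherited from the modelled
analysis).

## The synthetic study and what it does (not) show

`simConfig()` defaults define the reference study conditions emulated by
the generator:

* two 200 kb chromosomes carrying 150 strand-alternating
  exon–intron–exon genes; 15 antisense pairs (span overlap 300 bp ≥ the
  200 bp planting guarantee), 5 genes with a 1.5 kb intron containing an
  exact 30 bp inverted repeat with a 50 bp loop, 30 transposon-like
  repeat intervals and 60 ChIP-style peaks of which 37% sit on repeats
  (the observed peak–repeat overlap rate in the modelled assay);
* three biological replicates per genotype, two test genotypes plus an
  ADAR-null control that always edits at fraction 0; mean coverage 50
  (Poisson), sequencing error 0.1% uniform over the non-reference bases;
* 50 edited regions of 20 sites each, baseline per-site editing fraction
  0.15; half the regions are altered 1.4-fold in the second test
  genotype, 90% of alterations being increases — reproducing the
  "roughly half of regions altered, almost all increased, mean fold
  ~1.4" regime of the modelled study;
* IP/input count tables for 150 gene features with 40 planted enrichments
  at fold 4 (73% of them drawn from structurally dsRNA-capable genes)
  and 20 with an additional 2.5-fold genotype-specific increase; counts
  are marginally negative binomial with dispersion 0.1, generated as a
  Gamma replicate latent shared between the paired IP and input library
  and Poisson sampling on top; library sizes 1e6, lognormal expression
  (sdlog 1). The IP library is scaled so an unenriched feature has equal
  RPKM in IP and input, i.e. normalisation is to the non-enriched
  background, which is what "normalised to input" means operationally.

Simulation operates at the pileup level (per-position base counts), not
the read level, because every downstream computation consumes positional
or feature counts; a small single-end 50 nt SAM emitter
(`simulateReads`/`writeSAM`) exists to test the alignment-input route
against the read-counting route. One seed drives all randomness and
identical configurations yield byte-identical files.

What passing recovery tests on these data shows: the decision rules,
strand conventions, filters and statistics are implemented correctly and
are calibrated under the stated noise models. What it does not show:
robustness to alignment artefacts, position-dependent error profiles,
SNP contamination (a user-supplied exclusion BED is the intended remedy;
no variant catalogue is consulted), mapping bias in repeats, or
overdispersion structure beyond a single NB dispersion. Headline counts
of the modelled study (numbers of altered transcripts, hand-annotated
regions, IP-selected genes) depend on the full deposited data and manual
annotation and are not reproduction targets at this scale.

## Numerical and design choices

* Coordinates are 1-based closed in every container (the Bioconductor
  convention, GRanges/IRanges); GFF3 (1-based) and BED (0-based
  half-open) conversion happens only at the IO boundary, through
  rtracklayer, and round-trips losslessly. The pileup TSV keeps an
  explicit 0-based `pos0` column on disk.
* Deterministic ordering everywhere: genes by (chrom, start, gene_id),
  ties by identifier; region identifiers assigned in that order; all
  tabular output written with fixed formatting so reruns are
  byte-identical and manifest checksums comparable.
* Degenerate inputs are defined, not crashed on: zero-coverage regions
  are flagged rather than divided by; fold change is NA unless both
  percents are positive; an empty comparison table summarises to zeros;
  an empty overlap query yields an NA fraction with a warning; the
  two-proportion z-test returns (z = 0, p = 1) when the pooled
  proportion is 0 or 1.
* `runPipeline` writes every stage's output to files and each stage reads
  its inputs back from the previous stage's files; a JSON manifest
  records the seed, every threshold, the package version and md5
  checksums of every output. The plain-text report marks missing
  sections instead of failing on partial runs.
* Problem sizes in the test-suite recovery studies (default genome,
  50-region editing recovery at coverage 50; 200–300-feature IP studies
  over 10 seeds; 50 random 2 kb sequences for the inverted-repeat oracle;
  1,000 regions for z-calibration) were chosen as the smallest designs
  whose pass/fail criteria are statistically stable across seeds.

## Known limitations

* The caller is transcript-anchored: intergenic editing is invisible
  unless `unanchored` mode is used, and antisense-overlap regions are
  excluded as strand-ambiguous — exactly the regions where dsRNA is
  expected. This mirrors the modelled analysis but is a real blind spot.
* The IP stand-in test assumes paired IP/input replicates; unpaired
  designs are rejected rather than approximated.
* The inverted-repeat definition is ungapped; bulged or gapped stems are
  not found.
* No isoform-level quantification; features are gene spans, introns and
  user-supplied intervals.
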