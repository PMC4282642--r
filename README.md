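# dsRNAtools

Tools for characterising **double-stranded RNA (dsRNA)** in bulk
transcriptome sequencing. Written for RNA biologists studying dsRNA-binding
proteins, ADAR editing or sense–antisense transcription who need the three
classic dsRNA footprints quantified from standard files (FASTA, GFF3, BED,
SAM/pileup, count tables):

1. **A-to-I RNA editing** — ADAR enzymes deaminate adenosines in long RNA
   duplexes; inosine reads as guanosine, so editing appears as A→G
   mismatches on the transcribed strand (T→C in reference coordinates for
   minus-strand genes). The caller demands the signature in **every**
   biological replicate of a test genotype and in **no** ADAR-null control
   sample, then merges clustered sites into edited regions.
2. **Region-level editing statistics** — percent editing per genotype is
   the pooled read-base proportion over a region's potentially edited
   positions, x/n = Σ edited reads / Σ covering reads; genotypes are
   compared with the pooled two-proportion z-test
   `z = (p̂₁ − p̂₂) / √(p̄(1−p̄)(1/n₁ + 1/n₂))`, two-sided, on
   well-represented regions (> 20 pooled reads in both genotypes).
3. **dsRNA-IP enrichment** — for immunoprecipitation with a dsRNA-specific
   antibody (J2-IP), features are called enriched when their RPKM fold over
   input exceeds 1.5 with BH-adjusted p < 0.05, and differentially
   structured between genotypes when the input-normalised IP ratio differs
   at p < 0.05, FDR < 0.1. The test works on per-replicate log(IP/input)
   ratios (IP and input come from the same lysate, so shared biological
   noise cancels) with delta-method count variance plus pooled
   method-of-moments extra-dispersion.

Around these sit a structural annotator (antisense-overlapping gene pairs,
intronic inverted repeats found by seed-and-extend against the reverse
complement, UG-repeat tracts, repeat/peak interval overlap statistics), a
statistical kernel (log-space hypergeometric tails, 2×2 chi-square,
two-proportion z, Benjamini–Hochberg FDR), and a fully deterministic
synthetic-data generator whose truth table drives parameter-recovery tests
for every stage.

## Worked example

The end-to-end pipeline on the default synthetic study (three replicates
per genotype, an ADAR-null control, 50 planted edited regions, planted IP
enrichments):

```r
library(dsRNAtools)
cfg <- simConfig(rng_seed = 1)
res <- runPipeline(cfg, "run1")
cat(readLines(res$report), sep = "\n")
```

```
dsRNAtools run report
=====================

Edited regions
--------------
regions called: 50
mean sites per region: 20.0

Region editing comparison
-------------------------
well represented: 50 of 50
significantly altered: 26 (52% of well represented)
increased among significant: 23 (88%)
mean fold change among increased: 1.39

Structural annotation
---------------------
genes: 150
antisense overlap: 30
long-intron inverted repeats: 5 genes
repeat overlap: 15
dsRNA-structured: 50

Interval overlap
----------------
peaks vs repeats: 22/60 (37%)

IP enrichment
-------------
tdp1: 40 of 150 features enriched
wt: 40 of 150 features enriched

Differential IP
---------------
tested: 40; significant: 20 (up 20, down 0)

Category enrichment
-------------------
structured among IP-enriched: 29/40 (expected 13.3), p = 2.36e-09
```

Reading it: all 50 planted edited regions are recovered with their 20
sites each; the generator plants a 1.4-fold editing increase in half the
regions, and the z-test layer reports 52% of regions significantly
altered, 88% of those increased, mean fold 1.39 — the alteration regime
the generator encodes. The structural annotator finds exactly the planted
15 antisense pairs (30 genes), 5 inverted-repeat introns and 15
repeat-overlapping genes; 22 of 60 synthetic ChIP peaks (37%) sit on
repeat elements. All 40 planted IP enrichments are called in both
genotypes, all 20 planted genotype-specific increases are recovered, and
IP-enriched genes are strongly enriched for structurally dsRNA-capable
genes (29/40 observed vs 13.3 expected, hypergeometric p = 2.4e-09).

Every number in the report is traceable to a TSV in the run directory,
and `manifest.json` records the seed, all thresholds and md5 checksums of
every output; rerunning with the same configuration is byte-identical.

Individual stages are plain functions — `callCandidateSites()`,
`filterCandidates()`, `mergeRegions()`, `compareRegions()`,
`findAntisensePairs()`, `findInvertedRepeats()`, `callEnriched()`,
`differentialIP()` — and accept standard files via `readGenome()`,
`readAnnotation()`, `readBed()`, `buildPileup()` (SAM/BAM or pileup TSV).
A thin command-line wrapper lives at `inst/scripts/dsrna-scan.R`.

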