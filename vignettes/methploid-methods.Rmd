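---
title: "Methods and design of the methploid pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the methploid pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methploid` analyses whole-genome bisulfite sequencing (WGBS) experiments
that compare two cytotypes of one genotype — a diploid (2x) and its
autotetraploid (4x). This vignette records the statistical model behind
each stage, the tunable parameters with their defaults and rationale,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where more than one reasonable choice existed.

## Coordinates and containers

Every interval held in memory is 0-based half-open and every cytosine
position is 0-based on the forward reference axis, whatever the on-disk
dialect: GFF3 (1-based inclusive) is shifted on read and write, BED
passes through, and the cytosine/TE TSV dialects are defined 0-based.
A single internal convention removes the classic off-by-one family of
bugs; `IRanges`/`GenomicRanges` machinery is used inside the interval
engine with the shift applied at the boundary. Tables are `data.table`
objects: per-cytosine data for a plant genome easily reaches millions of
rows, and grouped aggregation is the dominant operation in every stage.

## Methylcytosine calling

An unmethylated cytosine still yields "methylated" read evidence at rate
ε, the combined failed-conversion and sequencing error rate. Calling
tests each site's counts against that error floor:

* one-sided binomial p = P(X ≥ n_mC | n, ε), ε default 0.005
  (conversion > 99%); ε can be re-estimated from any user-designated
  unmethylated control sequence as mean n_mC/n.
* Benjamini–Hochberg correction **within each context**. Genome-wide
  mCHH sits an order of magnitude below mCG; a shared FDR pool would let
  the abundant high-signal CG tests drag CHH calls through, so each
  context pays for its own multiplicity.
* coverage below 4 reads leaves a site "uncalled" rather than "no" — a
  status, not evidence of absence. The floor of 4 is also the coverage
  rule the DMR caller applies to both groups.

Under a pure-error simulation (true p = ε everywhere) the fraction of
sites called methylated at α = 0.05 stays at or below 0.05; the test
suite checks this at 10^5 sites and the acceptance script reports the
realised rate.

Symmetric CG sites are kept as two per-strand records (methratio-style).
The literature is split on merging CG pairs; per-strand is the least
destructive default and a count-pooling merge can be layered on without
information loss.

## Weighted methylation levels

All levels are read-weighted: Σ n_mC / Σ n_total over the covered
cytosines of a context and region. A region with no covered cytosine has
an *undefined* level (`NA`), deliberately distinct from 0 — absence of
evidence versus evidence of absence. Read weighting (rather than
averaging per-site ratios) keeps deep and shallow sites on a common
footing and makes levels additive across region partitions, a property
the test suite asserts exactly.

Replicate QC computes these levels in fixed windows (default 10 kb) and
reports the pairwise Pearson matrix over windows covered in every
replicate, mirroring how replicate agreement is usually summarised for
WGBS.

## Metagene profiles

Bodies are divided into 20 equal-width (percentile) bins per feature and
the 2-kb flanks into fixed 100-bp bins; minus-strand features are
reversed so bin 1 is always 5'. Percentile body binning is the standard
metagene choice when feature lengths vary by an order of magnitude. The
per-bin statistic pools counts across features (Σ n_mC / Σ n_total within
the bin) — consistent with the package-wide level definition and robust
to shallow features; a mean-of-feature-means mode exists as an option.
Flanks truncate at chromosome edges (truncated bins simply pool whatever
sequence exists) and features shorter than the bin count are skipped and
counted, not errors.

Two profiles are compared by a paired two-sided t-test over per-bin
levels, dropping bins undefined in either profile. Whether such tests
should pair over bins or over features is genuinely ambiguous; bins were
chosen because a single p per context-and-panel is the reporting unit
this field uses, and the choice is recorded here as a limitation. An
exactly constant nonzero difference has zero variance — the result is
flagged `degenerate` with p reported below 1e-10 rather than erroring.

## DMR detection

Windows of 200 bp advanced in 100-bp steps tile each chromosome (both
exposed as configuration; the window geometry is a free choice and the
per-window site minima below are plausible for ~200 bp in a plant
genome). Within each window, per context:

1. replicates are pooled per cytotype; only positions with pooled
   coverage ≥ 4 in **both** groups enter, so coverage composition cannot
   masquerade as differential methylation;
2. the window must hold enough such cytosines: ≥ 20 for all-C runs,
   ≥ 5 for CG, ≥ 5 for CHG, ≥ 15 for CHH ("numbers in a window" is read
   as cytosines of the context under test);
3. the pooled 2×2 table [mC, non-mC] × cytotype is scored by two-sided
   Fisher's exact test; BH correction runs across all tested windows of
   the context (per-context rather than global correction, matching the
   per-context calling philosophy);
4. windows with |Δ| below 0.20 (all C) / 0.25 (single context) or
   q > 0.05 are discarded;
5. surviving windows of one direction that overlap or are book-ended
   merge into maximal regions — the step being smaller than the window
   would otherwise double-report every locus — with ratios recomputed
   over the merged interval and the minimum q retained.

Direction is the sign of Δ = level(4x) − level(2x): hyper means the
tetraploid is more methylated. Annotation assigns each DMR by
base-pair-majority overlap with PCG > lncRNA > TE precedence on ties,
with a flag for DMR midpoints within 4 kb of a gene. A per-replicate
sign-consistency filter exists but is off by default, since pooled
single-ratio comparisons are the reporting convention emulated here.

The caller is validated two ways: exact agreement of every tested
window's Δ, p and q with a brute-force hypergeometric-enumeration oracle
on toy inputs, and recovery of planted DMRs on generator output
(sensitivity ≥ 0.9, empirical FDR ≤ 0.1 under the default conditions).

## TE association

Distances are gap distances between half-open intervals: 0 for body
overlap *and* for book-ended intervals, else the number of intervening
bases — the "0 = overlapping" convention used when plotting expression
against TE distance. Nearest-TE ties break to the lower TE start, then
id, making outputs deterministic. Flank TE counts use the union of the
two 4-kb flanks, deduplicating TEs that span both and excluding TEs
confined to the body (whether such counts should deduplicate is
unstated in the conventions this mirrors; deduplication was chosen).
Flanks are measured from annotated boundaries ignoring strand, since the
analyses they feed are symmetric.

Expression grouping: features below 0.1 FPKM (configurable) form the
"none" class; the remaining features split into equal tertiles
low/middle/high, remainders to the lower groups. Four named groups where
one is "none" cannot be literal quartiles — the zero class has arbitrary
size — so threshold-plus-tertiles is the faithful construction.

TE methylation by anchor distance uses 500-bp bins to 8 kb (both
configurable; 500 bp matches the finest flanking-region granularity the
emulated analyses discuss) and pools cytosine counts within the TE
bodies of each bin.

Group tests are two-sided Welch t and Wilcoxon rank-sum. The Wilcoxon
path delegates to `stats::wilcox.test`, exact for small untied samples
(combined n ≤ 20) and tie-corrected normal approximation otherwise; the
test suite pins its exact small-sample behaviour to a full permutation
enumeration. A Welch test on two zero-variance samples is reported with
a `degenerate` flag instead of an error.

## The synthetic-data generator

The generator is the package's test bed: it produces genomes,
annotations, per-cytosine counts, expression tables and a truth record
under the conditions the analyses are meant to face.

**What it emulates.**

* Genome: random sequence at GC 0.36; TEs placed until their union
  covers 60% of the genome (the TE load of the emulated genome), orders
  drawn from a Gypsy-dominated mixture with class I ≈ 64% by weight;
  PCG/lncRNA densities (57 and 23 per Mb) scale the ~33k PCGs and
  ~13.5k lncRNAs of a ~580-Mb genome; 42% of lncRNAs are intergenic
  (lincRNAs) and placed outside genes. 40% of gene bodies are protected
  from TE insertion so TE-free genes exist for the proximity analyses.
* Methylation: per-stratum baselines (TE body by order > lncRNA body >
  PCG body; intergenic between) calibrated so the genome-wide weighted
  levels land near mCG 0.67 / mCHG 0.49 / mCHH 0.06; gene bodies carry a
  multiplicative metagene shape (CG peak 1.15, CHG/CHH dip 0.5 for PCGs;
  milder for lncRNAs) with 10%-of-body linear ramps. Only genome-wide
  levels and figure-level shapes constrain these numbers; the
  per-stratum values are qualitative choices, frozen here and
  user-overridable.
* Sequencing: negative-binomial depth (mean 30, size 5) so uncovered
  cytosines occur and the coverage-4 filter is exercised; observed
  counts are Binomial(depth, p(1−ε) + (1−p)ε) with a single symmetric
  ε = 0.005 folding failed conversion and sequencing error together.
* DMRs: by default 20 hyper CG regions of width 400 bp and Δ = +0.4 are
  planted in intergenic windows pre-screened to hold ≥ 10 CG sites, so
  every planted DMR is detectable in principle and the intergenic
  baseline keeps both group means inside [0, 1].
* Expression: log FPKM = intercept + 0.5·log10(1+d) − 0.10·n_TE + noise
  (sd 0.9) for PCGs, with the slopes' signs flipped (−0.5, +0.10) for
  lncRNAs — TE proximity and abundance suppress PCGs and activate
  lncRNAs. The configured "none" fraction (25% PCGs, 35% lncRNAs)
  silences the features with the *lowest* model mean, coupling silencing
  to TE burden the way the expression-group methylation analyses
  presuppose. Both cytotypes share one expression model: the generator
  plants no dosage response, so cytotype contrasts in expression are
  null by construction.

**Reproducibility.** One experiment seed expands into labelled
substreams per (stage, cytotype, replicate, chromosome), so any sample
can be regenerated in isolation and results do not depend on iteration
order. Identical config + seed gives byte-identical output files.

**What it does not emulate** — and therefore what passing tests do not
show about real data: pericentromeric clustering of TEs and methylation
(placement is uniform), sequence-composition biases of bisulfite
conversion, mapping artefacts and strand-coverage asymmetry, correlated
methylation of neighbouring cytosines (sites are independent given the
stratum), subcontext (e.g. CAA vs CAT) structure, allele- or
haplotype-specific methylation, and any true dosage response.

## Calibration targets and problem sizes

Two generator settings are tied to external anchor values rather than
free choices: the genome-wide context levels (defaults calibrated to
mCG ≈ 0.67, mCHG ≈ 0.49, mCHH ≈ 0.059 for the 2x cytotype) and the
conversion error (> 99% conversion → ε = 0.005). The calibration was
done once against the expected (noise-free) site probabilities and then
frozen.

The bundled checks run at desk scale: the default experiment uses two
1-Mb chromosomes (≈ 7 × 10^5 cytosine sites, six samples), the
estimator-calibration genome 1.6 Mb of intergenic sequence with ε = 0 so
the 3-standard-error comparison against the configured 0.67 baseline is
exact, and the TE-association run two 2-Mb chromosomes (~230 PCGs) so
the four expression groups hold ~57 genes each — enough for the planted
body-mCHG ordering (none > low > middle > high) to be stable across
seeds. Headline numbers from the full-scale study this emulates (DMR
counts in the hundreds, 33k-gene group tests) require the deposited
~100-M-read dataset and are out of desk-scale reach by design; the
pipeline applies unchanged to such data via the `real` input mode.

## Degenerate inputs and numerical corners

* empty cytosine tables and empty DMR sets round-trip through every
  writer (headers-only TSV, empty BED);
* `NA` context (sequence edge or N in the trinucleotide) excludes a site
  from every denominator;
* windows, bins or regions with zero coverage report `NA`, never 0;
* Fisher tests use exact hypergeometric tails however large the pooled
  counts; BH is applied to exactly the set of tested windows;
* ties in expression ranking break on feature id, nearest-TE ties on
  (start, id) — all outputs deterministic under a fixed seed.
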