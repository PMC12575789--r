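---
title: "Methods: repetitive-region genomics and epigenomics from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repetitive-region genomics and epigenomics from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`repeatscape` implements the downstream analysis of tumor/normal long-read
sequencing in repetitive genomic regions: consensus structural-variant (SV)
calling, mutational-signature refitting, binned coverage and CpG-methylation
profiling over centromeric satellite and transposable-element (TE)
annotations, and haplotype-resolved promoter (THOR) methylation
classification. This vignette explains the models, the tunable parameters,
the synthetic-data generator, and the numerical choices, in the package's
own terms.

## Coordinate conventions

All internal coordinates are 0-based half-open. BED-family inputs pass
through unchanged; VCF positions are shifted by −1 exactly once, in the
reader. Keeping a single convention internally removes an entire class of
off-by-one errors; the readers and writers are the only code that converts.

## Consensus SV calling

Each caller's somatic call set is reduced to breakpoint-pair records
(`chrom1, pos1, chrom2, pos2, svtype, svlen`). Two calls match when their
types are equal, their chromosome pairs agree, and each breakpoint differs
by at most `tol` bp (default **500 bp**, typical long-read caller jitter;
exposed because no single value suits every caller combination). Insertions
additionally require reciprocal length agreement
`min(svlen)/max(svlen) ≥ 0.5`, since their second coordinate is degenerate.
DUP and INS are deliberately *not* cross-matched: treating a duplication as
an insertion is caller-specific behavior and merging them is not
conservative.

Matches define a graph; consensus events are its connected components
(single-linkage). Components are deterministic and independent of caller
input order — calls are canonically sorted before the graph is built.
Single-linkage can chain-merge nearby events in principle; the tolerance
keeps chains local, and the simulator (below) spaces planted events so the
property tests can distinguish chaining bugs from expected behavior. The
retention rule for *simple SVs* is: support from at least `min_support = 2`
distinct callers and representative length at least `min_size = 50` bp.
Translocations carry no meaningful length and are exempt from the size
filter. Representative breakpoints are per-end **lower medians** of the
member calls (the lower of the two central values on even counts), which
keeps representatives at observed coordinates; for DEL/DUP/INV the
representative length is recomputed from the median breakpoints, for INS it
is the lower-median member length.

## Signature refitting

SBS96 catalogs key each SNV by pyrimidine-strand substitution ×
trinucleotide context; purine-reference records are reverse-complemented.
SV32 catalogs follow the COSMIC rearrangement scheme:
{clustered, non-clustered} × {del, tds, inv} × five size bins (1–10 kb,
10–100 kb, 100 kb–1 Mb, 1–10 Mb, > 10 Mb) plus two translocation channels;
events under 1 kb go to the smallest bin, and insertions have no channel
(skipped with a counted warning). The clustered flag uses a simple density
rule — an SV is clustered when ≥ 10 consensus breakpoints fall within 5 Mb
on its chromosome — because a full piecewise-constant-fit segmentation of
inter-breakpoint distances is out of scope; both knobs are arguments.

Exposures solve the non-negative least-squares problem
`e = argmin ‖c − S e‖₂, e ≥ 0` with the Lawson–Hanson active-set algorithm,
implemented in the package and cross-checked in the tests against an
independent solver (`pracma::lsqnonneg`) and against the KKT conditions
(gradient zero on the passive set, non-negative on the active set). All
signatures in the supplied matrix are fit, with no sparsity penalty or
forward selection — anything else would be a different method. Percent
contributions divide by total fitted exposure (not by total mutations) so
they always sum to 100; an all-zero catalog returns all-zero exposures with
percents defined as 0. Channels are aligned by label before solving, so row
order never matters.

## Binned coverage over repeat annotations

Annotated regions are tiled into `width = 1000` bp bins. The tiling dialect
for the final partial bin is configurable because published bin totals
depend on it: under `partial = "merge"` (default) a remainder of at most
`width/2` folds into the previous bin, longer remainders stand alone; under
`partial = "keep"` every remainder stands alone. Bin lengths always sum to
region lengths under both dialects.

Per-bin depth is the per-base **lower median** of overlapping depth
records (interval records are length-weighted, equivalent to expanding to
per-base values), normalized by the sample's genome-wide median per-base
depth. Genome-wide median of per-base depth — not the median of per-bin
medians — is used as the denominator, matching a "normalized to genome-wide
median coverage" reading. Bins with no overlapping data are missing (`NA`),
never zero: zero-imputation would fabricate hypo-coverage. A sample whose
genome-wide median is 0 is unusable and raises an error.

Full-length TE insertions are selected with strict length filters
(`>` not `≥`): L1HS > 6 kb, AluY > 300 bp, SVA > 1 kb, ERV > 1 kb. Depth is
summarised per 1-kb bin for L1HS/SVA/ERV and per insertion for AluY
(elements shorter than one bin).

Coverage dispersion between groups is compared with the classic **Levene
test** (one-way ANOVA F on absolute deviations from the group *mean*, df
(1, n₁+n₂−2)); median centering (Brown–Forsythe) is available via
`center = "median"`. Identical groups give W = 0, p = 1.

## Binned methylation, PCA, clustering

The per-bin 5mC level is the coverage-weighted pooled ratio
Σ n_mod / Σ n_valid over the CpG sites in the bin — the direct reading of
"methylated reads / total reads". An unweighted mean of per-site ratios is
available (`method = "mean_of_sites"`) because the two disagree when
coverage varies within a bin and the pooled choice, while natural, is a
judgment call. Bins with no covered sites are missing.

The bin × sample matrix is restricted to the requested region classes
(default active + inactive higher-order-repeat arrays, pooled into one
matrix with class labels kept for display) and filtered to complete cases;
the dropped-row count is reported. Imputation is deliberately avoided.
PCA treats samples as observations and bins as features, centered but not
scaled — ratios share a scale, and unit-variance scaling would inflate
near-constant bins. Component signs are fixed (largest-magnitude loading
positive) so coordinates are reproducible; a constant matrix yields all-zero
scores rather than an error. Ward clustering uses
`stats::hclust(method = "ward.D2")` — the Ward criterion on Euclidean
distances between sample profiles — cut at `k = 2`; `hclust`'s deterministic
lowest-index merge order breaks ties. Tumors are assigned to HRD groups at
`hrd_score ≥ 63` (a published optimal cutoff for HRD-positive HGSOC; scores
are consumed as inputs, never computed here). Group means are compared with
two-sided Student t-tests (equal-variance unpaired, or paired), with the
convention t = 0, p = 1 for two identical constant groups.

## Haplotype-resolved THOR classification

Phased bedMethyl records are split by haplotype within the locus; a CpG site
with fewer than 3 supporting reads on a haplotype is excluded *from that
haplotype only*, and unphased records are excluded. Each haplotype profile
is smoothed with a centered 100-bp sliding window evaluated **at CpG
positions** (matching per-site rendering; a fixed-step grid would
interpolate where there is no data), with windows shrinking at the edges.
Whether smoothing should be centered or trailing was an open choice;
centered is symmetric and is the default.

A haplotype is hypermethylated when its mean smoothed value over the THOR
span is ≥ `hyper_threshold` (default **0.6**); the call is biallelic when
both are, monoallelic when exactly one is *and* the other's mean is
≤ `hypo_threshold` (default **0.3**), and none otherwise — an intermediate
second allele is flagged indeterminate rather than forced into a class.
These thresholds are package defaults, not published constants: a
reproducible call needs numeric criteria where visual inspection was used
before, so every output records the thresholds applied. Fewer than 3
retained sites on a haplotype inside the span is an error, not a "none":
absence of evidence must not look like evidence of absence. Read
haplotagging itself is upstream; the module consumes tags.

## The synthetic cohort

Because patient-level data of this kind are controlled-access, the
generators produce every input with the statistical structure the analysis
assumes. They define the study conditions; they are not tuned per test.

* **Genome.** Two 600-kb chromosomes: one carrying satellite spans (200 kb
  active HOR, 50 kb inactive HOR, HSat2, beta, monomeric), one carrying TE
  insertions whose lengths straddle the full-length filters (L1HS around
  6 kb, AluY around 300 bp, SVA/ERV around 1 kb; 206 TE bins/insertions in
  total). Sequences are uniform random nucleotides — CpG density ~1/16 bp —
  which is unrealistic sequence-wise but irrelevant to binned statistics.
* **Depth** is gamma-Poisson (negative binomial), mean 30×, size 50
  (CV ≈ 0.23, typical of nanopore coverage), emitted as 100-bp windows
  (mosdepth-style per-interval records). In tumor samples the dispersion
  inside TE spans is multiplied by `tumor_variance_inflation` (default 4),
  planting the coverage-variance excess the Levene test should detect.
* **Methylomes** are beta-binomial: each CpG's methylation probability is
  beta-distributed (concentration 30) around a class/group mean, read counts
  Poisson (mean 15). Satellite means are 0.75 / 0.55 / 0.35 for normal /
  high-HRD tumor / low-HRD tumor — values chosen once for clear planted
  ordering and test power, not biological fidelity, since no quantitative
  group gaps are published. TE and background means plant milder tumor
  hypomethylation (global hypomethylation with a stronger repeat-specific
  component).
* **SV call sets.** 200 truth SVs per sample (mixed DEL/DUP/INV/INS/TRA,
  log-uniform sizes 30 bp–50 kb), detected by four callers with
  sensitivities 0.95/0.90/0.85/0.80, plus caller-private false positives.
  Breakpoint jitter is a truncated normal (sd 100 bp, clamped at 2.4 sd) and
  intra-chromosomal jitter shrinks with event size (sd ≤ svlen/20, as real
  callers localize small events precisely). Planted breakpoints are spaced
  ≥ 2 kb apart, and truth sizes avoid a guard band around the 50-bp
  threshold where the retention decision would depend on jitter. These
  three choices follow analytically from the matching tolerance: they
  guarantee two jittered copies of one event always match, distinct events
  never do, and no event's filter decision flips — which is exactly what
  makes the truth table an *exact* oracle for the consensus stage rather
  than an approximate one.
* **Catalogs** are multinomial draws from S·w for truth weights w;
  **phased loci** place CpGs on a jittered 20-bp grid with per-haplotype
  Poisson(6) read support, so some sites fall under the 3-read filter.
* **Determinism.** Every generator draws from a stream seeded by a stable
  hash of (master seed, operation, sample), so outputs are byte-identical
  under a fixed seed and adding a sample never reshuffles another's data.

What passing tests on this cohort do **not** show: robustness to reference
bias in real repeat arrays, to mappability artifacts, to tumor purity and
subclonality, to caller-specific VCF quirks beyond the dialects exercised,
or to tissue-of-origin methylation differences (blood controls vs tumor
tissue). The generator plants clean group structure; real cohorts will not
separate this cleanly.

## Problem sizes and runtime choices

The test suite and the acceptance script run the full synthetic conditions:
6 tumor/normal pairs on the 1.2-Mb mini genome (~75,000 CpGs per methylome,
~250 HOR bins in the matrix), 20 call-set seeds for consensus/truth
agreement, 200 replicate catalogs of 5,000 mutations for NNLS recovery,
100 seeds for Levene power and 1,000 replicates for its type-I error, and
100 seeds per THOR allele state. Unit tests use a smaller two-chromosome
spec (120 kb + 40 kb) where full size adds nothing.

## Known limitations

* Same-chromosome breakends are classified from bracket orientation only;
  callers that encode duplications as unorthodox BND pairs may be
  misclassified (they still merge by coordinates).
* The clustered/non-clustered SV rule is a density heuristic, not a
  segmentation; exposures on the two clustered/non-clustered halves of SV32
  should be read accordingly.
* Complete-case filtering of the methylation matrix biases toward
  well-covered bins; with very uneven coverage the PCA feature set shrinks.
* Levene's test with mean centering is sensitive to heavy tails; the
  Brown–Forsythe option is provided for that case.
* `run_pipeline()` orchestrates the synthetic demonstration cohort
  end-to-end; on real data the per-stage functions are the interface, fed
  from `read_*()` on caller outputs.
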