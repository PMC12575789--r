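# repeatscape

Tumor/normal long-read sequencing opens up the parts of the genome that
short reads never resolved: centromeric alpha-satellite arrays, pericentric
human-satellite families, and young transposable-element (TE) insertions.
`repeatscape` packages the downstream analysis of such data for cancer
cohorts — in particular high-grade serous ovarian carcinoma (HGSOC), where
homologous-recombination deficiency (HRD) stratifies patients — into tested,
composable R functions. Every function takes a data frame and returns a
tibble, so stages chain with the pipe.

The package covers four analysis arms plus a first-class synthetic-data
generator:

1. **Consensus somatic SV calling.** Calls from multiple SV callers
   (e.g. Severus, SAVANA, nanomonsv, DELLY) are matched per breakpoint pair
   (same type, each breakpoint within a tolerance `tol`, default 500 bp;
   insertions additionally require reciprocal length ≥ 0.5), merged by
   connected components, and retained as *simple SVs* when supported by at
   least 2 callers with length ≥ 50 bp (translocations exempt from the size
   rule). Representative breakpoints are per-end lower medians.
2. **Mutational-signature refitting.** SBS96 trinucleotide and SV32
   rearrangement catalogs are refit against a reference signature matrix *S*
   by non-negative least squares: *e* = argmin‖*c* − *S e*‖₂ s.t. *e* ≥ 0
   (Lawson–Hanson active set), with per-signature percent contributions.
3. **Binned coverage and CpG methylation over repeat annotations.** Depth is
   summarised as per-base medians per 1-kb bin, normalized to each sample's
   genome-wide median coverage; CpG methylation as the pooled 5mC ratio
   Σ n_mod / Σ n_valid per bin (per insertion for AluY). Full-length TEs are
   selected by strict length filters (L1HS > 6 kb, AluY > 300 bp,
   SVA > 1 kb, ERV > 1 kb). Group dispersion is compared with Levene's test;
   sample structure with PCA and Ward hierarchical clustering; HRD groups
   are assigned at a score cutoff of 63.
4. **Haplotype-resolved THOR methylation.** Phased per-CpG calls at the TERT
   promoter region are split by haplotype (sites with < 3 reads on a
   haplotype are excluded from that haplotype), smoothed with a centered
   100-bp sliding window, and classified as biallelic, monoallelic, or no
   hypermethylation from per-haplotype THOR means.

Patient-level inputs of this kind are controlled-access, so the
`simulate_*` generators produce every input format the pipeline reads —
bedMethyl (modkit dialects), mosdepth-style depth tracks, four-caller SV
VCFs with a truth table, mutation catalogs from known signature mixtures,
and phased CpG calls at a THOR-like locus — with planted effects and full
determinism under a seed.

## Worked example

```r
library(repeatscape)
cfg <- sim_config(seed = 42)           # 6 tumor/normal pairs, 1.2 Mb mini genome
ref <- make_mini_reference(cfg)

# four-caller SV call sets with a truth table, then consensus merging
sv <- simulate_sv_callsets(ref, cfg, sample_id = "T1")
consensus <- merge_callsets(sv$callsets, tol = 500, min_size = 50, min_support = 2)
consensus_summary(consensus)
#>   sample svtype     n
#> 1 T1     DEL       79
#> 2 T1     DUP       42
#> 3 T1     INV       27
#> 4 T1     INS       35
#> 5 T1     TRA       11
truth_consensus_count(sv$truth)        # independent oracle: 194 == nrow(consensus)

# refit a 5000-mutation catalog drawn from a 60/30/10 signature mixture
sigs <- simulate_signature_matrix(n_signatures = 3, seed = 42)
catalog <- simulate_mutation_catalog(sigs, c(0.6, 0.3, 0.1), size = 5000,
                                     seed = 42, sample_id = "T1")
tidy(nnls_fit(catalog, sigs))
#>   sample_id signature exposure percent
#> 1 T1        SynthSig1    2981.   59.7
#> 2 T1        SynthSig2    1562.   31.3
#> 3 T1        SynthSig3     447.    8.95

# haplotype-resolved THOR classification
locus <- simulate_phased_locus(seed = 42, hap_means = c(0.9, 0.1))
tracks <- lapply(site_methylation_by_haplotype(locus, "chrTHOR:0-4000"), smooth_track)
classify_thor(tracks, "chrTHOR:1000-2500", sample_id = "T1")
#>   sample_id mean_hap1 mean_hap2 call
#> 1 T1            0.911     0.110 monoallelic_hyper
```

The consensus count equals the truth table's count of events detected by
≥ 2 callers with size ≥ 50 bp; the fitted percents recover the planted
60/30/10 mixture to within multinomial noise; and the planted one-high /
one-low haplotype pair is called monoallelic.

`run_pipeline(pipeline_config(outdir = "run1", seed = 1))` executes all
stages end to end (simulate → sv_merge → signatures → coverage →
methylation → thor), writing TSV tables plus a `manifest.json` with the
config hash; a rerun with the same config is byte-identical. Result objects
have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` visualizations.

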