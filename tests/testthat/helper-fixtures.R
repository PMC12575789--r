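# Shared fixtures: a downscaled genome so unit tests stay fast, plus small
# builders used across files.

tiny_genome_spec <- function() {
  ann <- tibble::tibble(
    chrom = c("chrA", "chrA", "chrA", "chrB", "chrB", "chrB", "chrB"),
    start = c(5000L, 40000L, 60000L, 2000L, 12000L, 20000L, 26000L),
    end = c(35000L, 50000L, 68000L, 9000L, 15200L, 21500L, 26320L),
    label = c("active_hor", "inactive_hor", "hsat2", "L1HS", "L1HS", "SVA", "AluY")
  )
  list(
    chrom_lengths = tibble::tibble(chrom = c("chrA", "chrB"),
                                   length = c(80000L, 40000L)),
    annotation = ann
  )
}

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, genome_spec = tiny_genome_spec(), n_pairs = 2L,
                   n_truth_sv = 12L, fp_per_caller = 2L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# one-row SV record helper
sv_rec <- function(chrom1, pos1, chrom2, pos2, svtype, svlen,
                   caller = "c1", sample = "S") {
  tibble::tibble(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
                 svtype = svtype, svlen = svlen, caller = caller, sample = sample)
}

# bedMethyl record helper
bm_rec <- function(chrom, start, n_valid, n_mod, haplotype = NA_character_,
                   strand = "+") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + 2L), strand = strand,
                 n_valid = as.integer(n_valid), n_mod = as.integer(n_mod),
                 ratio = ifelse(n_valid > 0, n_mod / n_valid, NA_real_),
                 haplotype = haplotype)
}
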