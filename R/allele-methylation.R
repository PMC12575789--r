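# Haplotype-resolved CpG methylation profiling of a locus and classification
# of promoter-region (THOR) hypermethylation as biallelic / monoallelic /
# absent.

#' Per-haplotype CpG methylation within a region
#'
#' Splits haplotype-tagged bedMethyl records by haplotype and computes
#' per-site 5mC ratios inside `region`. Sites with fewer than `min_reads`
#' supporting reads on a haplotype are excluded from that haplotype only;
#' unphased records are excluded.
#'
#' @param records Haplotype-tagged bedMethyl tibble (`haplotype` in
#'   `"1"`, `"2"`, `"unphased"`).
#' @param region One-row interval tibble (`chrom`, `start`, `end`) or a
#'   `"chrom:start-end"` string (0-based half-open).
#' @param min_reads Minimum reads per site per haplotype (default 3).
#' @return Named list of two tibbles (`"1"`, `"2"`), each `chrom`, `start`,
#'   `end`, `pos` (site start), `n_valid`, `n_mod`, `ratio`.
#' @export
site_methylation_by_haplotype <- function(records, region, min_reads = 3L) {
  region <- parse_region(region)
  inside <- records$chrom == region$chrom & records$start >= region$start &
    records$start < region$end
  phased <- records[inside & records$haplotype %in% c("1", "2"), , drop = FALSE]
  if (nrow(phased) == 0L) {
    abort("no phased records in region: locus unphasable")
  }
  per_hap <- function(h) {
    x <- phased[phased$haplotype == h & phased$n_valid >= min_reads, , drop = FALSE]
    tibble(chrom = x$chrom, start = x$start, end = x$end, pos = x$start,
           n_valid = x$n_valid, n_mod = x$n_mod, ratio = x$n_mod / x$n_valid) |>
      arrange(.data$pos)
  }
  list(`1` = per_hap("1"), `2` = per_hap("2"))
}

parse_region <- function(region) {
  if (is.character(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) == 0L) abort("region string must be 'chrom:start-end'")
    return(list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L])))
  }
  list(chrom = region$chrom[1L], start = region$start[1L], end = region$end[1L])
}

#' Sliding-window smoothing of a per-site methylation track
#'
#' At each retained CpG position `p` the smoothed value is the unweighted
#' mean of site ratios at positions within `window/2` bp of `p` (a centered
#' `window`-bp sliding window evaluated at CpG positions); windows shrink at
#' the edges, with no padding.
#'
#' @param track Per-haplotype site tibble from
#'   [site_methylation_by_haplotype()] (needs `pos` and `ratio`).
#' @param window Window width in bp (default 100).
#' @return `track` with a `smoothed` column.
#' @export
smooth_track <- function(track, window = 100) {
  if (nrow(track) == 0L) abort("smooth_track: no retained sites")
  half <- window / 2
  track$smoothed <- vapply(track$pos, function(p) {
    mean(track$ratio[abs(track$pos - p) <= half])
  }, numeric(1))
  track
}

#' Classify THOR hypermethylation from two haplotype tracks
#'
#' A haplotype is hypermethylated when its mean smoothed value over
#' `thor_region` is at least `hyper_threshold`. The call is
#' `biallelic_hyper` when both haplotypes are hypermethylated;
#' `monoallelic_hyper` when exactly one is and the other's mean is at most
#' `hypo_threshold`; otherwise `none` (intermediate combinations are flagged
#' indeterminate). The thresholds used are recorded in the output.
#'
#' @param tracks Named list of two smoothed haplotype tracks (from
#'   [smooth_track()]).
#' @param thor_region Interval tibble or `"chrom:start-end"` string.
#' @param hyper_threshold Mean smoothed value calling a haplotype
#'   hypermethylated (default 0.6).
#' @param hypo_threshold Upper bound on the other haplotype's mean for a
#'   monoallelic call (default 0.3).
#' @param min_sites Minimum retained sites per haplotype inside the region
#'   (default 3); fewer is an error, not a `none` call.
#' @param sample_id Optional sample label.
#' @return One-row tibble of class `thor_call`: `sample_id`, `chrom`,
#'   `start`, `end`, `mean_hap1`, `mean_hap2`, `n_sites_hap1`,
#'   `n_sites_hap2`, `call`, `indeterminate`, `hyper_threshold`,
#'   `hypo_threshold`.
#' @export
classify_thor <- function(tracks, thor_region, hyper_threshold = 0.6,
                          hypo_threshold = 0.3, min_sites = 3L,
                          sample_id = NA_character_) {
  region <- parse_region(thor_region)
  in_region <- function(tr) {
    filter(tr, .data$chrom == region$chrom, .data$pos >= region$start,
           .data$pos < region$end)
  }
  t1 <- in_region(tracks[["1"]]); t2 <- in_region(tracks[["2"]])
  if (nrow(t1) < min_sites || nrow(t2) < min_sites) {
    abort(sprintf("insufficient retained sites in THOR region (hap1: %d, hap2: %d, need %d)",
                  nrow(t1), nrow(t2), min_sites))
  }
  m1 <- mean(t1$smoothed); m2 <- mean(t2$smoothed)
  hyper <- c(m1 >= hyper_threshold, m2 >= hyper_threshold)
  indeterminate <- FALSE
  call <- if (all(hyper)) {
    "biallelic_hyper"
  } else if (xor(hyper[1L], hyper[2L])) {
    other <- if (hyper[1L]) m2 else m1
    if (other <= hypo_threshold) "monoallelic_hyper" else { indeterminate <- TRUE; "none" }
  } else {
    "none"
  }
  out <- tibble(sample_id = sample_id, chrom = region$chrom,
                start = region$start, end = region$end,
                mean_hap1 = m1, mean_hap2 = m2,
                n_sites_hap1 = nrow(t1), n_sites_hap2 = nrow(t2),
                call = call, indeterminate = indeterminate,
                hyper_threshold = hyper_threshold, hypo_threshold = hypo_threshold)
  structure(out, class = c("thor_call", class(out)))
}
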