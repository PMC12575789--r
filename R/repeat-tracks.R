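# Binned, normalized read-coverage profiling over repeat annotations, plus
# the group variance comparison (Levene's test).

#' Tile annotated regions into fixed-width genomic bins
#'
#' Each region is tiled left to right with `width`-bp bins. Under the default
#' `partial = "merge"` dialect a final remainder of at most `width/2` is
#' merged into the previous bin (a region shorter than `width` stays a single
#' bin); remainders longer than `width/2` become their own bin. With
#' `partial = "keep"` every remainder is kept as its own bin.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`, optional `label`).
#' @param width Bin width in bp (default 1000, i.e. 1-kb bins).
#' @param partial Partial-bin dialect, `"merge"` (default) or `"keep"`.
#' @return Tibble `chrom`, `start`, `end`, `label`, `bin_id`; bin lengths sum
#'   to the region lengths.
#' @export
#' @examples
#' make_bins(tibble::tibble(chrom = "chr1", start = 0L, end = 3500L, label = "hor"))
make_bins <- function(regions, width = 1000L, partial = c("merge", "keep")) {
  partial <- match.arg(partial)
  stopifnot(width > 0)
  check_intervals(regions, "regions")
  if (!"label" %in% names(regions)) regions$label <- NA_character_
  one_region <- function(chrom, start, end, label) {
    len <- end - start
    n_full <- len %/% width
    rem <- len - n_full * width
    starts <- start + width * seq_len(n_full) - width
    ends <- starts + width
    if (rem > 0) {
      if (n_full == 0L) {
        starts <- start; ends <- end
      } else if (partial == "keep" || rem > width / 2) {
        starts <- c(starts, end - rem); ends <- c(ends, end)
      } else {
        ends[n_full] <- end  # merge short remainder into the previous bin
      }
    }
    tibble(chrom = chrom, start = as.integer(starts), end = as.integer(ends),
           label = label)
  }
  out <- purrr::pmap(
    list(regions$chrom, regions$start, regions$end, regions$label), one_region)
  out <- bind_rows(out)
  out$bin_id <- seq_len(nrow(out))
  out
}

#' Genome-wide median per-base depth
#'
#' Median of per-base depth over all covered positions; interval records are
#' weighted by their length so the result equals the median of the per-base
#' expansion. On even totals the lower median is returned.
#'
#' @param depth Depth tibble (`chrom`, `start`, `end`, `depth`).
#' @return Scalar median depth.
#' @export
genome_median_depth <- function(depth) {
  if (is.null(depth) || nrow(depth) == 0L) abort("genome_median_depth: empty depth track")
  weighted_median_lower(depth$depth, depth$end - depth$start)
}

#' Per-bin median depth
#'
#' Per-base median of depth within each bin; partial overlaps contribute only
#' their overlapping bases. Bins with no overlapping depth records are
#' reported as `NA` (missing), never zero.
#'
#' @param depth Depth tibble.
#' @param bins Bin tibble from [make_bins()].
#' @return `bins` with a `median_depth` column.
#' @export
bin_median_depth <- function(depth, bins) {
  out <- bins
  out$median_depth <- NA_real_
  if (nrow(depth) == 0L || nrow(bins) == 0L) return(out)
  ov <- overlap_pairs(bins, depth)
  if (nrow(ov) == 0L) return(out)
  med <- ov |>
    mutate(value = depth$depth[.data$subject_idx]) |>
    group_by(.data$query_idx) |>
    summarise(m = weighted_median_lower(.data$value, .data$overlap_bp),
              .groups = "drop")
  out$median_depth[med$query_idx] <- med$m
  out
}

#' Normalize per-bin depth by the genome-wide median
#'
#' @param bin_depth Tibble from [bin_median_depth()].
#' @param genome_median Genome-wide median depth for the sample (> 0).
#' @return `bin_depth` with a `norm_depth` column (`median_depth /
#'   genome_median`).
#' @export
normalize_depth <- function(bin_depth, genome_median) {
  if (is.na(genome_median) || genome_median <= 0) {
    abort("normalize_depth: genome-wide median depth must be > 0 (sample unusable)")
  }
  mutate(bin_depth, norm_depth = .data$median_depth / genome_median)
}

#' Select full-length transposable-element insertions by class and length
#'
#' Keeps annotated intervals of `te_class` strictly longer than `min_length`
#' bp; used to restrict to full-length elements (e.g. L1HS > 6 kb,
#' AluY > 300 bp, SVA > 1 kb, ERV > 1 kb).
#'
#' @param annotation Annotation tibble (`chrom`, `start`, `end`, `label`).
#' @param te_class Class label to select.
#' @param min_length Strict lower length bound in bp.
#' @return Filtered annotation tibble.
#' @export
filter_te_annotation <- function(annotation, te_class, min_length) {
  known <- unique(annotation$label)
  if (!te_class %in% known) {
    abort(sprintf("unknown TE class '%s'; annotation has: %s", te_class,
                  paste(sort(known), collapse = ", ")))
  }
  filter(annotation, .data$label == te_class,
         (.data$end - .data$start) > min_length)
}

#' Per-insertion normalized median depth
#'
#' Median depth across each whole insertion (used for AluY, where elements
#' are shorter than one bin), normalized by the genome-wide median.
#'
#' @param depth Depth tibble.
#' @param insertions Interval tibble of insertions.
#' @param genome_median Genome-wide median depth (> 0).
#' @return `insertions` with `median_depth` and `norm_depth` columns.
#' @export
per_insertion_depth <- function(depth, insertions, genome_median) {
  ins <- insertions
  ins$bin_id <- seq_len(nrow(ins))
  normalize_depth(bin_median_depth(depth, ins), genome_median)
}

#' Compare dispersion between two groups with Levene's test
#'
#' Classic Levene test: the one-way ANOVA F statistic on absolute deviations
#' from the group center, with `(1, n_a + n_b - 2)` degrees of freedom.
#' `center = "mean"` gives the classic test; `center = "median"` gives the
#' Brown-Forsythe variant. Two identical groups give `W = 0`, `p = 1`.
#'
#' @param values_a,values_b Numeric vectors (NAs dropped); each group needs
#'   at least 2 values.
#' @param center `"mean"` (default) or `"median"`.
#' @return Tibble with `statistic` (Levene W), `p_value`, `df1`, `df2`.
#' @export
compare_variance <- function(values_a, values_b, center = c("mean", "median")) {
  center <- match.arg(center)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("compare_variance: each group needs >= 2 non-missing values")
  }
  cfun <- if (center == "mean") mean else median
  za <- abs(a - cfun(a)); zb <- abs(b - cfun(b))
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  zbar <- (sum(za) + sum(zb)) / N
  between <- n_a * (mean(za) - zbar)^2 + n_b * (mean(zb) - zbar)^2
  within <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  W <- if (between == 0) 0 else (N - 2) * between / within
  tibble(statistic = W, p_value = pf(W, 1, N - 2, lower.tail = FALSE),
         df1 = 1L, df2 = N - 2L)
}
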