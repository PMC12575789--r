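# Binned CpG methylation quantification, the bin x sample matrix, PCA and
# Ward clustering of samples, HRD grouping, and group mean comparisons.

#' Average 5mC ratio per genomic bin
#'
#' Default is the coverage-weighted pooled ratio: sum of modified reads over
#' sum of valid reads across the CpG sites in each bin
#' (methylated reads / total reads). `method = "mean_of_sites"` instead
#' averages per-site ratios unweighted. Bins with no covered CpG sites are
#' `NA`. Passing insertion intervals as `bins` yields the per-insertion
#' variant used for AluY.
#'
#' @param records bedMethyl tibble (see [read_bedmethyl()]).
#' @param bins Bin tibble from [make_bins()] (or any interval tibble with a
#'   `bin_id` column; one is added if absent).
#' @param method `"pooled"` (default) or `"mean_of_sites"`.
#' @return `bins` with `n_sites`, `n_valid`, `n_mod` and `meth_ratio` columns.
#' @export
bin_methylation <- function(records, bins, method = c("pooled", "mean_of_sites")) {
  method <- match.arg(method)
  out <- bins
  if (!"bin_id" %in% names(out)) out$bin_id <- seq_len(nrow(out))
  out$n_sites <- 0L; out$n_valid <- 0L; out$n_mod <- 0L; out$meth_ratio <- NA_real_
  covered <- records[records$n_valid > 0, , drop = FALSE]
  if (nrow(covered) == 0L || nrow(bins) == 0L) return(out)
  ov <- overlap_pairs(out, covered)
  if (nrow(ov) == 0L) return(out)
  agg <- ov |>
    mutate(n_valid = covered$n_valid[.data$subject_idx],
           n_mod = covered$n_mod[.data$subject_idx]) |>
    group_by(.data$query_idx) |>
    summarise(ratio = if (method == "pooled") sum(.data$n_mod) / sum(.data$n_valid)
                      else mean(.data$n_mod / .data$n_valid),
              n_sites = n(), n_valid = sum(.data$n_valid), n_mod = sum(.data$n_mod),
              .groups = "drop")
  out$n_sites[agg$query_idx] <- agg$n_sites
  out$n_valid[agg$query_idx] <- agg$n_valid
  out$n_mod[agg$query_idx] <- agg$n_mod
  out$meth_ratio[agg$query_idx] <- agg$ratio
  out
}

#' Summary of genome-wide CpG site methylation
#'
#' Site-level 5mC ratios for sites with at least `min_valid` supporting
#' reads, summarised by mean and quartiles.
#'
#' @param records bedMethyl tibble.
#' @param min_valid Minimum valid read count per site (default 1).
#' @return One-row tibble: `n_sites`, `mean`, `q25`, `median`, `q75`.
#' @export
genome_cpg_summary <- function(records, min_valid = 1L) {
  if (nrow(records) == 0L) abort("genome_cpg_summary: no records")
  r <- records$n_mod[records$n_valid >= min_valid] /
    records$n_valid[records$n_valid >= min_valid]
  q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
  tibble(n_sites = length(r), mean = mean(r), q25 = q[1], median = q[2], q75 = q[3])
}

#' Assemble the bin x sample methylation matrix
#'
#' Binds per-sample binned methylation (as returned by [bin_methylation()]
#' over a shared bin set), restricts rows to the requested region classes,
#' and drops any bin missing in at least one sample (complete-case); the
#' number of dropped rows is recorded.
#'
#' @param per_sample Named list of per-sample binned-methylation tibbles, or
#'   one tibble with a `sample` column.
#' @param classes Region class labels to keep (default
#'   `c("active_hor", "inactive_hor")`).
#' @return Tibble of class `methylation_matrix`: `bin_id`, `chrom`, `start`,
#'   `end`, `label`, plus one numeric column per sample. Dropped-row count in
#'   `attr(x, "n_dropped")`.
#' @export
build_methylation_matrix <- function(per_sample,
                                     classes = c("active_hor", "inactive_hor")) {
  long <- if (is.data.frame(per_sample)) {
    stopifnot("sample" %in% names(per_sample))
    as_tibble(per_sample)
  } else {
    stopifnot(!is.null(names(per_sample)), length(per_sample) >= 2L)
    bind_rows(purrr::imap(per_sample, ~ mutate(.x, sample = .y)))
  }
  if (length(unique(long$sample)) < 2L) abort("need >= 2 samples")
  long <- filter(long, .data$label %in% classes)
  wide <- long |>
    select("bin_id", "chrom", "start", "end", "label", "sample", "meth_ratio") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "meth_ratio") |>
    arrange(.data$bin_id)
  sample_cols <- setdiff(names(wide), c("bin_id", "chrom", "start", "end", "label"))
  complete <- stats::complete.cases(wide[, sample_cols])
  n_dropped <- sum(!complete)
  out <- wide[complete, , drop = FALSE]
  if (nrow(out) == 0L) abort("no bins covered in every sample")
  if (n_dropped > 0L) {
    inform(sprintf("build_methylation_matrix: dropped %d incomplete bin(s)", n_dropped))
  }
  structure(out, class = c("methylation_matrix", class(out)),
            n_dropped = n_dropped, samples = sample_cols)
}

meth_matrix_samples <- function(matrix) {
  attr(matrix, "samples") %||%
    setdiff(names(matrix), c("bin_id", "chrom", "start", "end", "label"))
}

#' PCA of samples on bin-wise methylation
#'
#' Samples are the observations and bins the features; features are centered
#' but not scaled (ratios share a scale). Component signs are fixed so the
#' largest-magnitude loading of each component is positive. A constant matrix
#' yields all-zero coordinates with zero explained variance.
#'
#' @param matrix A `methylation_matrix` tibble.
#' @param n_components Number of components to return (default 2).
#' @return Object of class `meth_pca`: list with `scores` (tibble `sample`,
#'   `PC1`, ...), `var_explained`, `sdev`. [tidy()] returns the scores.
#' @export
run_pca <- function(matrix, n_components = 2L) {
  samples <- meth_matrix_samples(matrix)
  X <- t(as.matrix(as_tibble(matrix)[, samples]))  # samples x bins
  if (nrow(X) < 2L) abort("run_pca: need >= 2 samples")
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) {
    scores <- matrix(0, nrow(X), n_components)
    ve <- rep(0, n_components)
    sdev <- rep(0, n_components)
  } else {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    flip <- vapply(seq_len(k), function(j) {
      rot <- pc$rotation[, j]
      sign(rot[which.max(abs(rot))]) < 0
    }, logical(1))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    scores[, flip] <- -scores[, flip]
    tot <- sum(pc$sdev^2)
    ve <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
    sdev <- pc$sdev[seq_len(k)]
    n_components <- k
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    scores = dplyr::bind_cols(tibble(sample = rownames(X)), as_tibble(scores)),
    var_explained = ve,
    sdev = sdev
  ), class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat("Methylation PCA:", nrow(x$scores), "samples;",
      paste(sprintf("%s %.1f%%", names(x$scores)[-1], 100 * x$var_explained),
            collapse = ", "), "\n")
  print(x$scores)
  invisible(x)
}

#' @rdname run_pca
#' @param x A `meth_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.meth_pca <- function(x, ...) x$scores

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances between
#' sample methylation profiles (`stats::hclust(method = "ward.D2")`), cut at
#' `k` clusters.
#'
#' @param matrix A `methylation_matrix` tibble.
#' @param k Number of clusters (default 2).
#' @return Object of class `meth_ward`: list with `partition` (tibble
#'   `sample`, `cluster`), `hclust` (the merge tree), `k`.
#' @export
ward_cluster <- function(matrix, k = 2L) {
  samples <- meth_matrix_samples(matrix)
  if (k > length(samples)) abort("ward_cluster: k exceeds the number of samples")
  X <- t(as.matrix(as_tibble(matrix)[, samples]))
  rownames(X) <- samples
  hc <- hclust(dist(X, method = "euclidean"), method = "ward.D2")
  part <- cutree(hc, k = k)
  structure(list(
    partition = tibble(sample = names(part), cluster = unname(part)),
    hclust = hc, k = k
  ), class = "meth_ward")
}

#' @export
print.meth_ward <- function(x, ...) {
  cat("Ward clustering,", x$k, "clusters:\n")
  print(x$partition)
  invisible(x)
}

#' @rdname ward_cluster
#' @param x A `meth_ward` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.meth_ward <- function(x, ...) x$partition

#' Assign tumors to high/low HRD-score groups
#'
#' @param meta Sample-sheet tibble (see [read_sample_sheet()]); only tumor
#'   rows are classified.
#' @param cutoff HRD-score cutoff (default 63); `high` iff
#'   `hrd_score >= cutoff`.
#' @return Tibble `sample_id`, `score`, `group` (`high`/`low`).
#' @export
hrd_group <- function(meta, cutoff = 63) {
  tum <- filter(as_tibble(meta), .data$group == "tumor")
  if (any(is.na(tum$hrd_score))) {
    abort(sprintf("missing HRD score for sample(s): %s",
                  paste(tum$sample_id[is.na(tum$hrd_score)], collapse = ", ")))
  }
  tibble(sample_id = tum$sample_id, score = tum$hrd_score,
         group = ifelse(tum$hrd_score >= cutoff, "high", "low"))
}

#' Two-group comparison of means by t-test
#'
#' Two-sided Student t-test: equal-variance unpaired, or paired on matched
#' vectors. Two groups with zero variance and equal values give `t = 0`,
#' `p = 1` by convention.
#'
#' @param values_a,values_b Numeric vectors (NAs dropped pairwise for the
#'   paired test).
#' @param paired Paired test flag (default `FALSE`); requires equal lengths
#'   in matched order.
#' @return Tibble `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
group_mean_test <- function(values_a, values_b, paired = FALSE) {
  if (paired) {
    if (length(values_a) != length(values_b)) {
      abort("paired test requires equal-length, matched vectors")
    }
    keep <- !is.na(values_a) & !is.na(values_b)
    a <- values_a[keep]; b <- values_b[keep]
    if (length(a) < 2L) abort("need >= 2 pairs")
    d <- a - b
    if (sd(d) == 0) {
      if (all(d == 0)) {
        return(tibble(statistic = 0, p_value = 1, df = length(d) - 1L,
                      mean_a = mean(a), mean_b = mean(b)))
      }
      abort("paired differences are constant and nonzero; t undefined")
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
    if (length(a) < 2L || length(b) < 2L) abort("need >= 2 values per group")
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) {
        return(tibble(statistic = 0, p_value = 1, df = length(a) + length(b) - 2L,
                      mean_a = mean(a), mean_b = mean(b)))
      }
      abort("both groups constant with different means; t undefined")
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}
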