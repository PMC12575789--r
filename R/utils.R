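# Internal helpers shared across modules: deterministic seed streams,
# weighted medians, interval overlap plumbing.

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Every stochastic generator draws from its own seed stream derived from
#' `(seed, key)` so that adding a sample or reordering calls never reshuffles
#' another sample's data. The hash is a plain polynomial rolling hash over the
#' key's UTF-8 bytes, kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed Master integer seed.
#' @param ... Character/numeric components identifying the stream, e.g.
#'   `derive_seed(1, "depth", "T1")`.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "depth", "T1")
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  bytes <- as.integer(charToRaw(key))
  mod <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed %% mod)
  for (b in bytes) h <- (h * 131 + b) %% mod
  as.integer(h)
}

# Evaluate `expr` under a derived seed without touching the global RNG state.
with_stream <- function(seed, key, expr) {
  withr::with_seed(derive_seed(seed, key), expr)
}

#' Lower weighted median
#'
#' Median of the per-base expansion `rep(x, w)` without materializing it;
#' on even totals the lower of the two central values is returned.
#'
#' @param x Numeric values.
#' @param w Non-negative integer weights (e.g. interval lengths in bp).
#' @return The lower median as a scalar.
#' @keywords internal
weighted_median_lower <- function(x, w) {
  keep <- w > 0 & !is.na(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  ord <- order(x)
  x <- x[ord]; w <- as.numeric(w[ord])
  total <- sum(w)
  k <- ceiling(total / 2)          # position of the lower median
  x[which(cumsum(w) >= k)[1L]]
}

# Convert an interval tibble (chrom, start, end; 0-based half-open) to GRanges.
# IRanges is 1-based closed: start+1 .. end.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Overlap join between two 0-based interval tibbles; returns a tibble of
# (query_idx, subject_idx, overlap_bp).
overlap_pairs <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) - pmax(query$start[qi], subject$start[si])
  tibble(query_idx = qi, subject_idx = si, overlap_bp = ov)
}

# Validate a 0-based half-open interval tibble.
check_intervals <- function(df, what = "intervals") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end) | is.na(df$chrom) | df$chrom == "")
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid coordinates at row(s) %s (need 0 <= start < end, non-empty chrom)",
                  what, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(df)
}
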