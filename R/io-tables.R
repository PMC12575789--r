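# Tabular inputs: COSMIC-style signature matrices and the cohort sample sheet.

#' Read a COSMIC-style signature reference matrix
#'
#' First column: channel labels (e.g. the 96 trinucleotide substitution
#' classes); remaining columns: one signature each, holding per-channel
#' probabilities that must sum to 1.
#'
#' @param path Tab-separated file with a header row of signature names.
#' @param tol Allowed deviation of each column sum from 1 (default `1e-3`).
#' @return A tibble of class `signature_matrix`: column `channel` plus one
#'   numeric column per signature, channel order as in the file.
#' @export
read_signature_matrix <- function(path, tol = 1e-3) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(df)[1L] <- "channel"
  sig_cols <- names(df)[-1L]
  if (length(sig_cols) == 0L) abort("signature matrix has no signature columns")
  for (s in sig_cols) {
    v <- df[[s]]
    if (any(v < 0)) abort(sprintf("signature '%s' has negative entries", s))
    if (abs(sum(v) - 1) > tol) {
      abort(sprintf("signature '%s' column sums to %.6f, not 1", s, sum(v)))
    }
  }
  if (anyDuplicated(df$channel)) abort("duplicate channel labels in signature matrix")
  structure(as_tibble(df), class = c("signature_matrix", class(as_tibble(df))))
}

#' Write a signature matrix as TSV
#' @param signatures `signature_matrix` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(signatures, path) {
  readr::write_tsv(as_tibble(signatures), path)
  invisible(path)
}

#' Read the cohort sample sheet
#'
#' Required columns: `sample_id`, `group` (`tumor`/`normal`), `pair_id`.
#' Optional per-sample metadata: `hrd_score`, `lst`, `loh`, `tai`,
#' `brca1_germline`, `ccne1_amp`, `purity`, `ploidy`. When all three scar
#' components are present the HRD score is checked against their sum
#' (HRD = LST + LOH + TAI) with a warning on mismatch.
#'
#' @param path Tab-separated sample sheet with a header.
#' @return Tibble of per-sample metadata, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  df <- as_tibble(readr::read_tsv(path, col_types = readr::cols(), progress = FALSE))
  required <- c("sample_id", "group", "pair_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("sample sheet missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicate sample_id: %s",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  if (!all(df$group %in% c("tumor", "normal"))) {
    abort("group must be 'tumor' or 'normal'")
  }
  # each pair must have exactly one tumor and at most one normal
  tally <- df |>
    count(.data$pair_id, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n", values_fill = 0L)
  if (!"tumor" %in% names(tally)) tally$tumor <- 0L
  if (!"normal" %in% names(tally)) tally$normal <- 0L
  bad <- tally$pair_id[tally$tumor > 1L | tally$normal > 1L |
                         (tally$tumor == 0L & tally$normal == 0L)]
  if (length(bad) > 0L) {
    abort(sprintf("invalid tumor/normal pairing for pair_id: %s",
                  paste(bad, collapse = ", ")))
  }
  scar <- c("hrd_score", "lst", "loh", "tai")
  if (all(scar %in% names(df))) {
    full <- stats::complete.cases(df[, scar])
    mism <- full & (df$hrd_score != df$lst + df$loh + df$tai)
    if (any(mism)) {
      warn(sprintf("hrd_score != lst + loh + tai for sample(s): %s",
                   paste(df$sample_id[mism], collapse = ", ")))
    }
  }
  df
}
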