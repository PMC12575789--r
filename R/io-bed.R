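# Readers/writers for BED-family formats. Internal coordinates are 0-based
# half-open everywhere; BED is already 0-based half-open so values pass
# through unchanged.

#' Read a BED annotation with class labels
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @param class_column 1-based column index holding the class label
#'   (default 4, the BED name field). If the file has fewer columns, labels
#'   are `NA`.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`, in input
#'   order. Coordinates are 0-based half-open, exactly as in the file.
#' @export
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t1000\tactive_hor", p)
#' read_bed_annotation(p)
read_bed_annotation <- function(path, class_column = 4L) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  label = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d in '%s': fewer than 3 tab-separated fields",
                  bad[1L], path))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED line %d in '%s': non-numeric coordinates", bad[1L], path))
  }
  label <- if (all(nf >= class_column)) {
    vapply(fields, `[[`, "", class_column)
  } else {
    rep(NA_character_, length(fields))
  }
  out <- tibble(chrom = vapply(fields, `[[`, "", 1L), start = start, end = end,
                label = label)
  bad <- which(out$start >= out$end)
  if (length(bad) > 0L) {
    abort(sprintf("BED record at line %d has start >= end", bad[1L]))
  }
  out
}

#' Write an annotation tibble as BED4
#' @param annotation Tibble with `chrom`, `start`, `end`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_annotation <- function(annotation, path) {
  check_intervals(annotation, "annotation")
  readr::write_tsv(annotation[, c("chrom", "start", "end", "label")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a per-interval depth track (mosdepth-style BED4)
#'
#' @param path BED4 file: chrom, start, end, mean depth over the interval.
#' @return Tibble `chrom`, `start`, `end`, `depth` (0-based half-open).
#' @export
read_depth_bed <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                        col_types = "ciid", progress = FALSE)
  if (any(df$depth < 0, na.rm = TRUE)) abort("depth track contains negative depth")
  as_tibble(df)
}

#' Write a depth track as BED4
#' @param depth Tibble `chrom`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(depth, path) {
  readr::write_tsv(depth[, c("chrom", "start", "end", "depth")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a modkit-style bedMethyl file
#'
#' Accepts both modkit dialects: fully tab-separated BED9+ rows, and the
#' traditional dialect where fields beyond column 9 live in one
#' space-separated trailing field. The two count fields used downstream are
#' N_valid (field 10) and N_mod (field 12). An optional trailing `haplotype`
#' column (values `1`, `2`, `ungrouped`) is recognized; alternatively the
#' haplotype is inferred from modkit partitioned-output file naming
#' (`*_1.bed`, `*_2.bed`, `*_ungrouped.bed`) or passed explicitly.
#'
#' @param path bedMethyl file path.
#' @param haplotype Optional haplotype tag for the whole file
#'   (`"1"`, `"2"`, `"unphased"`); overrides filename inference.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `n_valid`, `n_mod`,
#'   `ratio` (`NA` when `n_valid == 0`) and `haplotype`. Records with
#'   `n_valid == 0` are retained.
#' @export
read_bedmethyl <- function(path, haplotype = NULL) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (is.null(haplotype)) {
    base <- sub("\\.(bed|bedmethyl|tsv)(\\.gz)?$", "", basename(path))
    haplotype <- if (grepl("_1$", base)) "1"
      else if (grepl("_2$", base)) "2"
      else if (grepl("_(ungrouped|unphased)$", base)) "unphased"
      else NA_character_
  }
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), n_valid = integer(), n_mod = integer(),
                  ratio = numeric(), haplotype = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, i) {
    if (length(f) < 10L) {
      abort(sprintf("bedMethyl line %d: expected BED9+ with trailing count fields", i))
    }
    trailing <- f[10:length(f)]
    # traditional dialect: fields 10+ space-separated inside one tab field
    if (length(trailing) == 1L && grepl(" ", trailing)) {
      trailing <- strsplit(trailing, " +")[[1L]]
    }
    hap <- NA_character_
    last <- trailing[length(trailing)]
    # a haplotype column sits after the 3 (minimal) or 9 (full modkit)
    # trailing count fields; never mistake a count field for a tag
    if (last %in% c("1", "2", "ungrouped", "unphased") &&
        length(trailing) %in% c(4L, 10L)) {
      hap <- if (last == "ungrouped") "unphased" else last
      trailing <- trailing[-length(trailing)]
    }
    c(f[1L], f[2L], f[3L], f[6L], trailing[1L], trailing[3L], hap)
  }
  m <- t(mapply(parse_row, fields, seq_along(fields)))
  out <- tibble(
    chrom = m[, 1L],
    start = as.integer(m[, 2L]),
    end = as.integer(m[, 3L]),
    strand = m[, 4L],
    n_valid = as.integer(m[, 5L]),
    n_mod = as.integer(m[, 6L]),
    haplotype = ifelse(is.na(m[, 7L]), haplotype, m[, 7L])
  )
  bad <- which(out$n_mod > out$n_valid)
  if (length(bad) > 0L) {
    abort(sprintf("bedMethyl line %d: N_mod exceeds N_valid", bad[1L]))
  }
  out$ratio <- ifelse(out$n_valid > 0, out$n_mod / out$n_valid, NA_real_)
  out[, c("chrom", "start", "end", "strand", "n_valid", "n_mod", "ratio", "haplotype")]
}

#' Write CpG methylation records as modkit-style bedMethyl
#'
#' Emits the fully tab-separated modkit dialect (BED9 + N_valid, percent,
#' N_mod) plus a trailing haplotype column when any record is haplotagged.
#'
#' @param records Tibble as returned by [read_bedmethyl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(records, path) {
  pct <- ifelse(records$n_valid > 0,
                formatC(100 * records$n_mod / records$n_valid, format = "f", digits = 2),
                "0.00")
  has_hap <- "haplotype" %in% names(records) && any(!is.na(records$haplotype))
  rows <- paste(records$chrom, records$start, records$end, "m", records$n_valid,
                records$strand, records$start, records$end, "255,0,0",
                records$n_valid, pct, records$n_mod, sep = "\t")
  if (has_hap) {
    hap <- ifelse(is.na(records$haplotype), "unphased", records$haplotype)
    rows <- paste(rows, hap, sep = "\t")
  }
  readr::write_lines(rows, path)
  invisible(path)
}
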