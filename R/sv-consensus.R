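# Multi-caller consensus SV merging: breakpoint-tolerant matching, connected
# components over the match graph, then the retention rule used for simple
# SVs: length >= 50 bp (translocations exempt) and support from >= 2 callers.

#' Decide whether two SV calls describe the same event
#'
#' Two calls match iff their types are equal, both breakpoint chromosome
#' pairs agree, and each breakpoint differs by at most `tol` bp. Insertions
#' additionally require a reciprocal length ratio
#' `min(svlen)/max(svlen) >= 0.5`. The predicate is symmetric.
#'
#' @param a,b Single-row SV tibbles (or lists) with `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `svtype`, `svlen`.
#' @param tol Per-breakpoint tolerance in bp (default 500).
#' @return `TRUE` or `FALSE`.
#' @export
match_sv_pair <- function(a, b, tol = 500) {
  if (a$svtype != b$svtype) return(FALSE)
  if (a$chrom1 != b$chrom1 || a$chrom2 != b$chrom2) return(FALSE)
  if (abs(a$pos1 - b$pos1) > tol || abs(a$pos2 - b$pos2) > tol) return(FALSE)
  if (a$svtype == "INS") {
    lo <- min(a$svlen, b$svlen); hi <- max(a$svlen, b$svlen)
    if (hi > 0 && lo / hi < 0.5) return(FALSE)
  }
  TRUE
}

# Vectorized pairwise match within one (svtype, chrom1, chrom2) block;
# returns an edge list (i, j) over block row indices.
match_edges_block <- function(blk, tol) {
  n <- nrow(blk)
  if (n < 2L) return(NULL)
  cmb <- utils::combn(n, 2L)
  i <- cmb[1L, ]; j <- cmb[2L, ]
  ok <- abs(blk$pos1[i] - blk$pos1[j]) <= tol &
    abs(blk$pos2[i] - blk$pos2[j]) <= tol
  if (blk$svtype[1L] == "INS") {
    lo <- pmin(blk$svlen[i], blk$svlen[j]); hi <- pmax(blk$svlen[i], blk$svlen[j])
    ok <- ok & (hi == 0 | lo / hi >= 0.5)
  }
  cbind(i[ok], j[ok])
}

# lower median: on even counts take the lower central value
median_lower <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Merge per-caller SV call sets into consensus SVs
#'
#' Builds a match graph over all calls (edges from [match_sv_pair()]), takes
#' connected components (single-linkage), and retains components supported by
#' at least `min_support` distinct callers whose representative length is at
#' least `min_size` bp; translocations are exempt from the size filter.
#' Representative breakpoints are per-end lower medians over the component's
#' members.
#'
#' @param callsets A list of per-caller SV tibbles (as from [read_sv_vcf()]),
#'   or one tibble with a `caller` column.
#' @param tol Breakpoint matching tolerance in bp (default 500).
#' @param min_size Minimum representative SV length in bp (default 50;
#'   variants shorter than this are excluded).
#' @param min_support Minimum number of distinct supporting callers
#'   (default 2).
#' @return Tibble of class `consensus_sv`, sorted by (`chrom1`, `pos1`):
#'   `chrom1`, `pos1`, `chrom2`, `pos2`, `svtype`, `svlen`, `support`,
#'   `callers` (comma-separated), `n_members`, `sample`. All merged
#'   components (including those failing the retention rule) are available
#'   via `attr(x, "all_components")`.
#' @export
merge_callsets <- function(callsets, tol = 500, min_size = 50, min_support = 2) {
  calls <- if (is.data.frame(callsets)) as_tibble(callsets) else bind_rows(callsets)
  if (nrow(calls) == 0L) {
    out <- tibble(chrom1 = character(), pos1 = integer(), chrom2 = character(),
                  pos2 = integer(), svtype = character(), svlen = numeric(),
                  support = integer(), callers = character(),
                  n_members = integer(), sample = character())
    return(structure(out, class = c("consensus_sv", class(out)),
                     all_components = out))
  }
  stopifnot("caller" %in% names(calls))
  if (!"sample" %in% names(calls)) calls$sample <- NA_character_
  # canonical deterministic order removes any dependence on caller input order
  calls <- arrange(calls, .data$svtype, .data$chrom1, .data$chrom2, .data$pos1,
                   .data$pos2, .data$svlen, .data$caller)
  calls$.row <- seq_len(nrow(calls))

  blocks <- split(calls, paste(calls$svtype, calls$chrom1, calls$chrom2, sep = "\r"))
  edges <- purrr::map(blocks, function(blk) {
    e <- match_edges_block(blk, tol)
    if (is.null(e) || nrow(e) == 0L) return(NULL)
    cbind(blk$.row[e[, 1L]], blk$.row[e[, 2L]])
  })
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])

  g <- igraph::make_empty_graph(n = nrow(calls), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership

  calls$component <- comp
  reps <- calls |>
    group_by(.data$component) |>
    summarise(
      chrom1 = .data$chrom1[1L],
      pos1 = median_lower(.data$pos1),
      chrom2 = .data$chrom2[1L],
      pos2 = median_lower(.data$pos2),
      svtype = .data$svtype[1L],
      svlen_member = median_lower(.data$svlen),
      support = dplyr::n_distinct(.data$caller),
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      n_members = n(),
      sample = .data$sample[1L],
      .groups = "drop"
    ) |>
    mutate(
      svlen = dplyr::case_when(
        .data$svtype %in% c("DEL", "DUP", "INV") ~ as.numeric(.data$pos2 - .data$pos1),
        .data$svtype == "TRA" ~ 0,
        TRUE ~ as.numeric(.data$svlen_member)
      )
    ) |>
    select("chrom1", "pos1", "chrom2", "pos2", "svtype", "svlen", "support",
           "callers", "n_members", "sample") |>
    arrange(.data$chrom1, .data$pos1, .data$chrom2, .data$pos2, .data$svtype)

  retained <- reps |>
    filter(.data$support >= min_support,
           .data$svtype == "TRA" | .data$svlen >= min_size)
  structure(retained, class = c("consensus_sv", class(retained)),
            all_components = reps,
            params = list(tol = tol, min_size = min_size, min_support = min_support))
}

#' Summarise consensus SV counts per type and sample
#'
#' @param consensus Tibble from [merge_callsets()].
#' @return Tibble `sample`, `svtype`, `n` with one row per type seen,
#'   zero-filled over the standard five types.
#' @export
consensus_summary <- function(consensus) {
  types <- c("DEL", "DUP", "INV", "INS", "TRA")
  as_tibble(consensus) |>
    count(.data$sample, .data$svtype) |>
    tidyr::complete(sample = unique(consensus$sample),
                    svtype = types, fill = list(n = 0L)) |>
    arrange(.data$sample, match(.data$svtype, types))
}
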