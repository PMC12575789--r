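# Mutation catalogs (SBS96 trinucleotide, SV32 rearrangement) and signature
# refitting by non-negative least squares.

#' Canonical SBS96 channel labels
#'
#' The 96 single-base-substitution classes: six pyrimidine-strand
#' substitutions x 16 trinucleotide contexts, in COSMIC order
#' (`A[C>A]A`, `A[C>A]C`, ...).
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(p, q) paste0(p, "[", s, "]", q))))
  }))
}

#' Canonical SV32 channel labels
#'
#' The 32 rearrangement classes: {clustered, non-clustered} x
#' {del, tds (tandem duplication), inv} x five size bins, plus
#' {clustered, non-clustered} translocation.
#'
#' @return Character vector of length 32.
#' @export
sv32_channels <- function() {
  bins <- c("1-10Kb", "10-100Kb", "100Kb-1Mb", "1Mb-10Mb", ">10Mb")
  unlist(lapply(c("clustered", "non-clustered"), function(cl) {
    c(as.vector(t(outer(c("del", "tds", "inv"), bins, function(t, b)
      paste(cl, t, b, sep = "_")))), paste(cl, "trans", sep = "_"))
  }))
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), ""))
}

#' Build an SBS96 trinucleotide mutation catalog
#'
#' Substitutions whose reference base is a purine are reverse-complemented to
#' the pyrimidine strand before channel assignment, so every SNV lands in one
#' of the 96 canonical classes.
#'
#' @param snvs Tibble with `chrom`, `pos` (0-based), `ref`, `alt` single-base
#'   alleles.
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file
#'   covering all SNV positions.
#' @param sample_id Sample label attached to the catalog.
#' @return Tibble of class `mutation_catalog` with `channel` (96 rows, COSMIC
#'   order) and `count`; counts sum to the number of SNVs.
#' @export
build_sbs96_catalog <- function(snvs, reference, sample_id = NA_character_) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  channels <- sbs96_channels()
  if (nrow(snvs) == 0L) {
    return(new_catalog(channels, rep(0L, 96L), sample_id, "SBS96"))
  }
  stopifnot(all(snvs$chrom %in% names(reference)))
  ctx <- character(nrow(snvs))
  for (ch in unique(snvs$chrom)) {
    idx <- which(snvs$chrom == ch)
    # internal 0-based pos p -> 1-based p+1; context spans p-1..p+1 0-based
    ctx[idx] <- as.character(Biostrings::extractAt(
      reference[[ch]], IRanges::IRanges(snvs$pos[idx], width = 3L)))
  }
  ref_base <- substr(ctx, 2L, 2L)
  bad <- which(ref_base != snvs$ref)
  if (length(bad) > 0L) {
    abort(sprintf("reference allele mismatch at %s",
                  paste(sprintf("%s:%d (%s vs %s)", snvs$chrom[bad], snvs$pos[bad],
                                snvs$ref[bad], ref_base[bad])[seq_len(min(5, length(bad)))],
                        collapse = ", ")))
  }
  alt <- snvs$alt
  purine <- ref_base %in% c("A", "G")
  ctx[purine] <- revcomp_chr(ctx[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  ref_c <- substr(ctx, 2L, 2L)
  label <- paste0(substr(ctx, 1L, 1L), "[", ref_c, ">", alt, "]", substr(ctx, 3L, 3L))
  counts <- table(factor(label, levels = channels))
  new_catalog(channels, as.integer(counts), sample_id, "SBS96")
}

# Flag consensus breakpoints as clustered: a breakpoint is clustered when at
# least `min_neighbors` consensus breakpoints (itself included) fall within
# `window` bp of it on its chromosome.
sv_clustered_flags <- function(consensus, window = 5e6, min_neighbors = 10L) {
  bp <- tibble(chrom = c(consensus$chrom1, consensus$chrom2),
               pos = c(consensus$pos1, consensus$pos2),
               sv = rep(seq_len(nrow(consensus)), 2L))
  counts <- vapply(seq_len(nrow(bp)), function(i) {
    sum(bp$chrom == bp$chrom[i] & abs(bp$pos - bp$pos[i]) <= window)
  }, integer(1))
  bp$clustered <- counts >= min_neighbors
  vapply(split(bp$clustered, bp$sv), any, logical(1))[as.character(seq_len(nrow(consensus)))]
}

#' Build an SV32 rearrangement catalog from consensus SVs
#'
#' Channels follow the COSMIC SV scheme: clustered vs non-clustered DEL /
#' tandem-duplication / INV in five size bins (1-10 kb, 10-100 kb,
#' 100 kb-1 Mb, 1-10 Mb, >10 Mb) plus clustered / non-clustered
#' translocation. Events shorter than 1 kb are assigned to the 1-10 kb bin.
#' A breakpoint-density rule assigns the clustered flag: an SV is clustered
#' when `cluster_min` or more consensus breakpoints fall within
#' `cluster_window` bp on its chromosome. Insertions have no channel in the
#' scheme and are skipped with a warning.
#'
#' @param consensus Consensus SV tibble for one sample.
#' @param cluster_window Clustering window in bp (default 5e6).
#' @param cluster_min Breakpoint count within the window that marks an SV as
#'   clustered (default 10).
#' @param sample_id Sample label; defaults to the consensus records' sample.
#' @return Tibble of class `mutation_catalog` with `channel` (32 rows) and
#'   `count`.
#' @export
build_sv32_catalog <- function(consensus, cluster_window = 5e6, cluster_min = 10L,
                               sample_id = NULL) {
  channels <- sv32_channels()
  sample_id <- sample_id %||%
    (if (nrow(consensus) > 0) consensus$sample[1L] else NA_character_)
  if (nrow(consensus) == 0L) {
    return(new_catalog(channels, rep(0L, 32L), sample_id, "SV32"))
  }
  n_ins <- sum(consensus$svtype == "INS")
  if (n_ins > 0L) {
    warn(sprintf("build_sv32_catalog: skipped %d insertion(s) (no SV32 channel)", n_ins))
  }
  sv <- filter(as_tibble(consensus), .data$svtype != "INS")
  if (nrow(sv) == 0L) return(new_catalog(channels, rep(0L, 32L), sample_id, "SV32"))
  clustered <- sv_clustered_flags(sv, cluster_window, cluster_min)
  cl <- ifelse(clustered, "clustered", "non-clustered")
  size_bin <- function(len) {
    cut(len, breaks = c(-Inf, 1e4, 1e5, 1e6, 1e7, Inf),
        labels = c("1-10Kb", "10-100Kb", "100Kb-1Mb", "1Mb-10Mb", ">10Mb"))
  }
  type_tag <- c(DEL = "del", DUP = "tds", INV = "inv")
  label <- ifelse(sv$svtype == "TRA",
                  paste(cl, "trans", sep = "_"),
                  paste(cl, type_tag[sv$svtype], as.character(size_bin(sv$svlen)),
                        sep = "_"))
  counts <- table(factor(label, levels = channels))
  new_catalog(channels, as.integer(counts), sample_id, "SV32")
}

new_catalog <- function(channels, counts, sample_id, scheme) {
  out <- tibble(channel = channels, count = counts)
  structure(out, class = c("mutation_catalog", class(out)),
            sample_id = sample_id, scheme = scheme)
}

# Lawson-Hanson active-set non-negative least squares:
# argmin ||A x - b||_2 s.t. x >= 0.
nnls_lawson_hanson <- function(A, b, tol = NULL, max_iter = NULL) {
  p <- ncol(A)
  tol <- tol %||% (10 * .Machine$double.eps * sum(abs(A)) * max(dim(A)))
  max_iter <- max_iter %||% (30L * p)
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) abort("nnls: iteration limit exceeded")
      z <- numeric(p)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & (z <= tol)
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & (x <= tol)] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Refit a mutation catalog against reference signatures by NNLS
#'
#' Solves `e = argmin || c - S e ||_2` subject to `e >= 0` with the
#' Lawson-Hanson active-set algorithm, where `c` is the catalog count vector
#' and `S` the reference signature matrix. Channels are aligned by label
#' before solving, so row order in the inputs does not matter.
#'
#' @param catalog A `mutation_catalog` tibble (`channel`, `count`).
#' @param signatures A `signature_matrix` tibble (see
#'   [read_signature_matrix()]).
#' @return An object of class `signature_fit`: list with `exposures` (named
#'   non-negative vector, mutation-count scale), `percent` (exposures as % of
#'   total fitted exposure; sums to 100, all 0 for an all-zero catalog),
#'   `residual_norm`, `sample_id`, `n_mutations`. Use [tidy()] / [glance()]
#'   for tabular access.
#' @export
nnls_fit <- function(catalog, signatures) {
  sig <- as_tibble(signatures)
  cat_df <- as_tibble(catalog)
  unmatched <- setdiff(cat_df$channel, sig$channel)
  if (length(unmatched) > 0L || nrow(sig) != nrow(cat_df)) {
    abort(sprintf("channel labels do not align between catalog and signatures: %s",
                  paste(head(c(unmatched, setdiff(sig$channel, cat_df$channel)), 8),
                        collapse = ", ")))
  }
  sig <- sig[match(cat_df$channel, sig$channel), , drop = FALSE]
  S <- as.matrix(sig[, -1L, drop = FALSE])
  cvec <- as.numeric(cat_df$count)
  if (all(cvec == 0)) {
    e <- setNames(numeric(ncol(S)), colnames(S))
    return(new_signature_fit(e, e, 0, attr(catalog, "sample_id"), 0))
  }
  e <- nnls_lawson_hanson(S, cvec)
  e <- setNames(e, colnames(S))
  total <- sum(e)
  pct <- if (total > 0) 100 * e / total else e * 0
  new_signature_fit(e, pct, sqrt(sum((cvec - drop(S %*% e))^2)),
                    attr(catalog, "sample_id"), sum(cvec))
}

new_signature_fit <- function(exposures, percent, residual_norm, sample_id, n_mut) {
  structure(list(exposures = exposures, percent = percent,
                 residual_norm = residual_norm,
                 sample_id = sample_id %||% NA_character_, n_mutations = n_mut),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("Signature NNLS fit for sample %s (%g mutations, residual %.4g)\n",
              x$sample_id, x$n_mutations, x$residual_norm))
  print(round(x$percent, 2))
  invisible(x)
}

#' Tidy a signature fit into one row per signature
#' @param x A `signature_fit` object.
#' @param ... Unused.
#' @return Tibble `sample_id`, `signature`, `exposure`, `percent`.
#' @exportS3Method generics::tidy
#' @export
tidy.signature_fit <- function(x, ...) {
  tibble(sample_id = x$sample_id, signature = names(x$exposures),
         exposure = unname(x$exposures), percent = unname(x$percent))
}

#' One-row summary of a signature fit
#' @param x A `signature_fit` object.
#' @param ... Unused.
#' @return Tibble `sample_id`, `n_mutations`, `total_exposure`,
#'   `residual_norm`, `n_active` (signatures with positive exposure).
#' @exportS3Method generics::glance
#' @export
glance.signature_fit <- function(x, ...) {
  tibble(sample_id = x$sample_id, n_mutations = x$n_mutations,
         total_exposure = sum(x$exposures), residual_norm = x$residual_norm,
         n_active = sum(x$exposures > 0))
}
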