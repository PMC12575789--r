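# SV VCF input/output. VCF positions are 1-based; conversion to the internal
# 0-based convention happens here and only here (pos_internal = pos_vcf - 1).

# Parse a BND ALT string like N[chr5:900[ or ]chr5:900]N.
# Returns list(chrom, pos (1-based), bracket, mate_first) or NULL.
parse_bnd_alt <- function(alt) {
  if (is.na(alt) || !grepl("[][]", alt)) return(NULL)
  m <- regmatches(alt, regexec("(\\[|\\])([^\\[\\]:]+):([0-9]+)(\\[|\\])", alt,
                               perl = TRUE))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(chrom = m[3L], pos = as.integer(m[4L]), bracket = m[2L],
       t_first = !startsWith(alt, m[2L]))
}

# Classify a same-chromosome breakend pair by bracket orientation:
# t[p[ deletion-like, ]p]t duplication-like, t]p] / [p[t inversion-like.
classify_bnd <- function(bracket, t_first) {
  if (bracket == "[" && t_first) "DEL"
  else if (bracket == "]" && !t_first) "DUP"
  else "INV"
}

#' Read somatic SV calls from a VCF
#'
#' Handles symbolic ALTs (`<DEL>`, `<DUP>`, `<INV>`, `<INS>`) with `END` /
#' `SVLEN` INFO fields, and BND breakend notation. BND mate pairs are
#' collapsed to a single record with the lexicographically smaller breakpoint
#' first; inter-chromosomal pairs become `TRA`, intra-chromosomal pairs are
#' classified by bracket orientation. Records with neither a usable `SVTYPE`
#' nor a BND ALT are skipped with a counted warning.
#'
#' @param path VCF file (symbolic and/or breakend records).
#' @param caller Caller identifier attached to every record.
#' @param sample Sample identifier attached to every record.
#' @return Tibble with `chrom1`, `pos1`, `chrom2`, `pos2` (0-based),
#'   `svtype` (`DEL`,`DUP`,`INV`,`INS`,`TRA`), `svlen`, `caller`, `sample`.
#'   The number of skipped records is available as `attr(x, "n_skipped")`.
#' @export
read_sv_vcf <- function(path, caller, sample = NA_character_) {
  stopifnot(file.exists(path))
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- tibble(chrom1 = character(), pos1 = integer(), chrom2 = character(),
                  pos2 = integer(), svtype = character(), svlen = numeric(),
                  caller = character(), sample = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  info_get <- function(key) {
    unname(suppressWarnings(vcfR::extract.info(vcf, element = key)))
  }
  svtype <- info_get("SVTYPE")
  endpos <- suppressWarnings(as.integer(info_get("END")))
  svlen <- suppressWarnings(as.numeric(info_get("SVLEN")))
  mateid <- info_get("MATEID")
  pos <- as.integer(fix$POS)

  simple <- list(); bnds <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    st <- svtype[i]
    alt <- fix$ALT[i]
    bnd <- parse_bnd_alt(alt)
    if (!is.null(bnd) || identical(st, "BND") || identical(st, "TRA")) {
      if (is.null(bnd)) { n_skipped <- n_skipped + 1L; next }
      bnds[[length(bnds) + 1L]] <- tibble(
        id = fix$ID[i], mate = if (!is.null(mateid)) mateid[i] else NA_character_,
        chrom = fix$CHROM[i], pos = pos[i] - 1L,
        mchrom = bnd$chrom, mpos = bnd$pos - 1L,
        bracket = bnd$bracket, t_first = bnd$t_first
      )
    } else if (!is.na(st) && st %in% c("DEL", "DUP", "INV", "INS")) {
      p1 <- pos[i] - 1L
      len <- abs(svlen[i])
      if (st == "INS") {
        p2 <- p1
        if (is.na(len)) { n_skipped <- n_skipped + 1L; next }
      } else {
        e <- endpos[i]
        if (is.na(e) && !is.na(len)) e <- pos[i] + len
        if (is.na(e)) { n_skipped <- n_skipped + 1L; next }
        p2 <- e - 1L
        if (is.na(len)) len <- abs(p2 - p1)
      }
      simple[[length(simple) + 1L]] <- tibble(
        chrom1 = fix$CHROM[i], pos1 = min(p1, p2), chrom2 = fix$CHROM[i],
        pos2 = max(p1, p2), svtype = st, svlen = len
      )
    } else {
      n_skipped <- n_skipped + 1L
    }
  }

  merged_bnd <- NULL
  if (length(bnds) > 0L) {
    b <- bind_rows(bnds)
    # canonical key: unordered breakpoint pair
    a_first <- b$chrom < b$mchrom | (b$chrom == b$mchrom & b$pos <= b$mpos)
    key <- ifelse(a_first,
                  paste(b$chrom, b$pos, b$mchrom, b$mpos),
                  paste(b$mchrom, b$mpos, b$chrom, b$pos))
    b <- b[!duplicated(key), , drop = FALSE]
    a_first <- a_first[!duplicated(key)]
    merged_bnd <- tibble(
      chrom1 = ifelse(a_first, b$chrom, b$mchrom),
      pos1 = ifelse(a_first, b$pos, b$mpos),
      chrom2 = ifelse(a_first, b$mchrom, b$chrom),
      pos2 = ifelse(a_first, b$mpos, b$pos),
      svtype = ifelse(b$chrom != b$mchrom, "TRA",
                      mapply(classify_bnd, b$bracket, b$t_first)),
      svlen = ifelse(b$chrom != b$mchrom, 0, abs(b$mpos - b$pos))
    )
  }

  out <- bind_rows(bind_rows(simple), merged_bnd)
  if (nrow(out) == 0L) {
    out <- tibble(chrom1 = character(), pos1 = integer(), chrom2 = character(),
                  pos2 = integer(), svtype = character(), svlen = numeric())
  }
  out$caller <- caller
  out$sample <- sample
  out <- arrange(out, .data$chrom1, .data$pos1)
  if (n_skipped > 0L) {
    warn(sprintf("read_sv_vcf: skipped %d unparseable record(s) in '%s'",
                 n_skipped, basename(path)))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

vcf_header <- function(source, contigs = NULL) {
  c("##fileformat=VCFv4.2",
    sprintf("##source=%s", source),
    if (!is.null(contigs)) sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Breakend mate\">",
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Supporting caller count\">",
    "##INFO=<ID=SUPP_CALLERS,Number=1,Type=String,Description=\"Supporting callers\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

# Format one internal SV record (0-based) as VCF body line(s); TRA becomes a
# BND mate pair.
sv_vcf_lines <- function(sv, id_prefix = "sv", extra_info = NULL) {
  lines <- character(0)
  for (i in seq_len(nrow(sv))) {
    r <- sv[i, ]
    info_extra <- if (is.null(extra_info)) "" else paste0(";", extra_info[i])
    if (r$svtype == "TRA") {
      id1 <- sprintf("%s%d_1", id_prefix, i); id2 <- sprintf("%s%d_2", id_prefix, i)
      lines <- c(lines,
        sprintf("%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s%s",
                r$chrom1, r$pos1 + 1L, id1, r$chrom2, r$pos2 + 1L, id2, info_extra),
        sprintf("%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s%s",
                r$chrom2, r$pos2 + 1L, id2, r$chrom1, r$pos1 + 1L, id1, info_extra))
    } else {
      lines <- c(lines,
        sprintf("%s\t%d\t%s%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d%s",
                r$chrom1, r$pos1 + 1L, id_prefix, i, r$svtype, r$svtype,
                r$pos2 + 1L, as.integer(round(r$svlen)), info_extra))
    }
  }
  lines
}

#' Write SV records as a VCF 4.2 file
#'
#' DEL/DUP/INV/INS become symbolic-ALT records with `END`/`SVLEN`;
#' TRA records become BND mate pairs.
#'
#' @param sv Tibble of SV records (internal 0-based coordinates).
#' @param path Output path.
#' @param source `##source` header value.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(sv, path, source = "repeatscape") {
  contigs <- sort(unique(c(sv$chrom1, sv$chrom2)))
  readr::write_lines(c(vcf_header(source, contigs), sv_vcf_lines(sv)), path)
  invisible(path)
}

#' Write consensus SVs as a VCF with support annotations
#'
#' Each record carries `SUPP` (distinct supporting callers) and
#' `SUPP_CALLERS` (comma-separated caller ids) in INFO.
#'
#' @param consensus Consensus tibble from [merge_callsets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, path) {
  extra <- sprintf("SUPP=%d;SUPP_CALLERS=%s", consensus$support,
                   gsub(",", "|", consensus$callers))
  contigs <- sort(unique(c(consensus$chrom1, consensus$chrom2)))
  readr::write_lines(
    c(vcf_header("repeatscape-consensus", contigs),
      sv_vcf_lines(consensus, id_prefix = "cons", extra_info = extra)),
    path)
  invisible(path)
}
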