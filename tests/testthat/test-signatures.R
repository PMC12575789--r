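# Mutation catalogs and NNLS signature refitting. pracma::lsqnonneg is the
# independent oracle for the active-set solver.

test_that("channel label sets have the canonical sizes and structure", {
  ch96 <- sbs96_channels()
  expect_length(ch96, 96L)
  expect_false(anyDuplicated(ch96) > 0)
  expect_true(all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", ch96)))
  ch32 <- sv32_channels()
  expect_length(ch32, 32L)
  expect_equal(sum(grepl("trans$", ch32)), 2L)
  expect_equal(sum(grepl("^clustered", ch32)), 16L)
})

test_that("purine-reference SNVs are reverse-complemented to pyrimidine channels", {
  # reference AGC at positions 0..2: G>T at pos 1 has context A[G>T]C,
  # canonicalized to G[C>A]T
  ref <- Biostrings::DNAStringSet(c(chrX = "AGCAA"))
  snvs <- tibble::tibble(chrom = "chrX", pos = 1L, ref = "G", alt = "T")
  cat1 <- build_sbs96_catalog(snvs, ref)
  expect_equal(cat1$count[cat1$channel == "G[C>A]T"], 1L)
  expect_equal(sum(cat1$count), 1L)
})

test_that("empty SNV lists give an all-zero catalog and mismatches error", {
  ref <- Biostrings::DNAStringSet(c(chrX = "AGCAA"))
  cat0 <- build_sbs96_catalog(tibble::tibble(chrom = character(), pos = integer(),
                                             ref = character(), alt = character()),
                              ref)
  expect_equal(sum(cat0$count), 0L)
  expect_error(
    build_sbs96_catalog(tibble::tibble(chrom = "chrX", pos = 1L, ref = "C", alt = "T"),
                        ref),
    "mismatch.*chrX:1")
})

test_that("a random SNV set tallies to its construction bookkeeping", {
  cfg <- tiny_config(seed = 41L)
  ref <- make_mini_reference(cfg)
  seqs <- ref$sequences
  withr::local_seed(41)
  n <- 1000L
  chrom <- sample(names(seqs), n, replace = TRUE)
  pos <- vapply(chrom, function(ch) sample(2:(Biostrings::width(seqs[ch]) - 2), 1L),
                integer(1))
  ref_base <- vapply(seq_len(n), function(i)
    as.character(Biostrings::subseq(seqs[[chrom[i]]], pos[i] + 1L, pos[i] + 1L)),
    character(1))
  alt <- vapply(ref_base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1))
  snvs <- tibble::tibble(chrom = chrom, pos = pos, ref = ref_base, alt = alt)
  catalog <- build_sbs96_catalog(snvs, seqs)
  expect_equal(sum(catalog$count), n)
  # independent per-record tally: canonicalize each SNV by hand
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  labels <- vapply(seq_len(n), function(i) {
    tri <- as.character(Biostrings::subseq(seqs[[chrom[i]]], pos[i], pos[i] + 2L))
    a <- alt[i]
    if (substr(tri, 2, 2) %in% c("A", "G")) {
      tri <- rc(tri); a <- chartr("ACGT", "TGCA", a)
    }
    paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", a, "]", substr(tri, 3, 3))
  }, character(1))
  tally <- table(factor(labels, levels = sbs96_channels()))
  expect_equal(catalog$count, as.integer(tally))
})

test_that("SV32 binning follows the COSMIC size and clustering scheme", {
  cons <- tibble::tibble(
    chrom1 = "chr1", pos1 = c(1e6, 3e7, 6e7), chrom2 = "chr1",
    pos2 = c(1e6 + 5e4, 3e7 + 500, 6e7 + 2e6),
    svtype = c("DEL", "DUP", "INV"), svlen = c(5e4, 500, 2e6),
    support = 2L, callers = "a,b", n_members = 2L, sample = "T1")
  cat32 <- build_sv32_catalog(cons)
  expect_equal(cat32$count[cat32$channel == "non-clustered_del_10-100Kb"], 1L)
  # sub-1 kb events fall into the smallest bin
  expect_equal(cat32$count[cat32$channel == "non-clustered_tds_1-10Kb"], 1L)
  expect_equal(cat32$count[cat32$channel == "non-clustered_inv_1Mb-10Mb"], 1L)

  tra <- tibble::tibble(chrom1 = "chr1", pos1 = 1e6, chrom2 = "chr2", pos2 = 2e6,
                        svtype = "TRA", svlen = 0, support = 3L, callers = "a,b,c",
                        n_members = 3L, sample = "T1")
  cat_tra <- build_sv32_catalog(tra)
  expect_equal(cat_tra$count[cat_tra$channel == "non-clustered_trans"], 1L)

  ins <- dplyr::mutate(tra, svtype = "INS", chrom2 = "chr1", svlen = 300)
  expect_warning(cat_ins <- build_sv32_catalog(ins), "insertion")
  expect_equal(sum(cat_ins$count), 0L)
})

test_that("a dense breakpoint cluster flips events to clustered channels", {
  # 12 DELs with breakpoints inside 5 Mb on one chromosome
  dense <- tibble::tibble(
    chrom1 = "chr1", pos1 = seq(1e6, by = 2e5, length.out = 12),
    chrom2 = "chr1", svtype = "DEL", support = 2L, callers = "a,b",
    n_members = 2L, sample = "T1") |>
    dplyr::mutate(pos2 = pos1 + 5e3, svlen = 5e3)
  cat32 <- build_sv32_catalog(dense)
  expect_equal(cat32$count[cat32$channel == "clustered_del_1-10Kb"], 12L)
  # one isolated event on another chromosome stays non-clustered
  lone <- dplyr::bind_rows(dense, tibble::tibble(
    chrom1 = "chr9", pos1 = 1e6, chrom2 = "chr9", pos2 = 1e6 + 5e3,
    svtype = "DEL", svlen = 5e3, support = 2L, callers = "a,b",
    n_members = 2L, sample = "T1"))
  cat2 <- build_sv32_catalog(lone)
  expect_equal(cat2$count[cat2$channel == "non-clustered_del_1-10Kb"], 1L)
})

test_that("a 20-SV fixture tallies to a hand enumeration", {
  withr::local_seed(7)
  types <- rep(c("DEL", "DUP", "INV", "TRA"), 5)
  sizes <- rep(c(2e3, 5e4, 5e5, 0), 5)
  cons <- tibble::tibble(
    chrom1 = paste0("chr", seq_len(20)),  # all isolated -> non-clustered
    pos1 = 1e6, svtype = types, svlen = sizes,
    support = 2L, callers = "a,b", n_members = 2L, sample = "T1") |>
    dplyr::mutate(chrom2 = ifelse(svtype == "TRA", "chrZ", chrom1),
                  pos2 = ifelse(svtype == "TRA", 5e6, pos1 + svlen))
  cat32 <- build_sv32_catalog(cons)
  expect_equal(sum(cat32$count), 20L)
  expect_equal(cat32$count[cat32$channel == "non-clustered_del_1-10Kb"], 5L)
  expect_equal(cat32$count[cat32$channel == "non-clustered_tds_10-100Kb"], 5L)
  expect_equal(cat32$count[cat32$channel == "non-clustered_inv_100Kb-1Mb"], 5L)
  expect_equal(cat32$count[cat32$channel == "non-clustered_trans"], 5L)
})

test_that("NNLS recovers exact representations with zero residual", {
  sig <- simulate_signature_matrix(n_signatures = 3L, seed = 51L)
  S <- as.matrix(sig[, -1])
  # catalog = 1000 x signature 2
  cat_pure <- structure(tibble::tibble(channel = sig$channel,
                                       count = 1000 * S[, 2]),
                        class = c("mutation_catalog", "tbl_df", "tbl", "data.frame"),
                        sample_id = "S1", scheme = "SBS96")
  fit <- nnls_fit(cat_pure, sig)
  expect_equal(unname(fit$exposures), c(0, 1000, 0), tolerance = 1e-8)
  expect_lt(fit$residual_norm, 1e-8)
  # exact 600/400 mixture
  cat_mix <- structure(tibble::tibble(channel = sig$channel,
                                      count = 600 * S[, 1] + 400 * S[, 3]),
                       class = class(cat_pure), sample_id = "S1", scheme = "SBS96")
  fit2 <- nnls_fit(cat_mix, sig)
  expect_equal(unname(fit2$percent), c(60, 0, 40), tolerance = 1e-6)
  expect_lt(fit2$residual_norm, 1e-8)
})

test_that("the active-set solver agrees with pracma::lsqnonneg on random problems", {
  skip_if_not_installed("pracma")
  sig <- simulate_signature_matrix(n_signatures = 6L, seed = 61L)
  S <- as.matrix(sig[, -1])
  withr::local_seed(61)
  for (i in 1:20) {
    cvec <- rpois(96, 30) * runif(96)
    catalog <- structure(tibble::tibble(channel = sig$channel, count = cvec),
                         class = c("mutation_catalog", "tbl_df", "tbl", "data.frame"),
                         sample_id = "S", scheme = "SBS96")
    fit <- nnls_fit(catalog, sig)
    oracle <- pracma::lsqnonneg(S, cvec)
    expect_equal(unname(fit$exposures), oracle$x, tolerance = 1e-6)
    # pracma reports the squared 2-norm of the residual
    expect_equal(fit$residual_norm, sqrt(oracle$resid.norm), tolerance = 1e-6)
  }
})

test_that("NNLS satisfies scale equivariance and the KKT conditions", {
  sig <- simulate_signature_matrix(n_signatures = 4L, seed = 71L)
  S <- as.matrix(sig[, -1])
  catalog <- simulate_mutation_catalog(sig, c(0.4, 0.3, 0.2, 0.1), 3000L, seed = 71L)
  fit <- nnls_fit(catalog, sig)
  scaled <- structure(tibble::tibble(channel = catalog$channel,
                                     count = catalog$count * 5),
                      class = class(catalog), sample_id = "S", scheme = "SBS96")
  fit5 <- nnls_fit(scaled, sig)
  expect_equal(fit5$exposures, 5 * fit$exposures, tolerance = 1e-8)
  expect_equal(fit5$percent, fit$percent, tolerance = 1e-8)
  # KKT: gradient of 0.5||c - Se||^2 is -S'(c - Se); zero for positive
  # exposures, nonnegative residual correlation never positive at zero coords
  grad <- -drop(crossprod(S, catalog$count - S %*% fit$exposures))
  active <- fit$exposures > 1e-10
  expect_true(all(abs(grad[active]) < 1e-6))
  expect_true(all(grad[!active] > -1e-6))
})

test_that("all-zero catalogs fit to all-zero exposures with percent 0", {
  sig <- simulate_signature_matrix(n_signatures = 3L, seed = 81L)
  cat0 <- structure(tibble::tibble(channel = sig$channel, count = 0L),
                    class = c("mutation_catalog", "tbl_df", "tbl", "data.frame"),
                    sample_id = "S0", scheme = "SBS96")
  fit <- nnls_fit(cat0, sig)
  expect_true(all(fit$exposures == 0))
  expect_true(all(fit$percent == 0))
  expect_equal(fit$residual_norm, 0)
})

test_that("channel mismatches between catalog and matrix are reported", {
  sig <- simulate_signature_matrix(n_signatures = 2L, seed = 91L)
  bad <- structure(tibble::tibble(channel = paste0("X", 1:96), count = 1L),
                   class = c("mutation_catalog", "tbl_df", "tbl", "data.frame"),
                   sample_id = "S", scheme = "SBS96")
  expect_error(nnls_fit(bad, sig), "do not align")
})

test_that("tidy and glance expose the fit as tibbles", {
  sig <- simulate_signature_matrix(n_signatures = 3L, seed = 15L)
  catalog <- simulate_mutation_catalog(sig, c(0.5, 0.3, 0.2), 2000L, seed = 15L,
                                       sample_id = "T9")
  fit <- nnls_fit(catalog, sig)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 3L)
  expect_equal(sum(td$percent), 100, tolerance = 1e-6)
  gl <- generics::glance(fit)
  expect_equal(gl$sample_id, "T9")
  expect_equal(gl$n_mutations, 2000)
})
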