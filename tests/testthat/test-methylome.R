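# Bin-wise methylation, the bin x sample matrix, PCA / Ward clustering of
# samples, HRD grouping, and the two-group t-test.

test_that("bin methylation pools reads: sum(n_mod) / sum(n_valid)", {
  bins <- make_bins(tibble::tibble(chrom = "chr1", start = 0L, end = 2000L))
  recs <- dplyr::bind_rows(bm_rec("chr1", 100, 10, 3), bm_rec("chr1", 200, 10, 7))
  bm <- bin_methylation(recs, bins)
  expect_equal(bm$meth_ratio, c(0.5, NA))  # (3+7)/(10+10); empty bin missing
  expect_equal(bm$n_sites, c(2L, 0L))
  # unweighted mean-of-sites alternative
  recs2 <- dplyr::bind_rows(bm_rec("chr1", 100, 100, 100), bm_rec("chr1", 200, 10, 0))
  expect_equal(bin_methylation(recs2, bins)$meth_ratio[1], 100 / 110)
  expect_equal(bin_methylation(recs2, bins, method = "mean_of_sites")$meth_ratio[1], 0.5)
})

test_that("pooled bin ratios match brute-force site expansion and stay in site range", {
  bins <- make_bins(tibble::tibble(chrom = "chr1", start = 0L, end = 5000L))
  withr::local_seed(50)
  n <- 300L
  nv <- rpois(n, 8)
  recs <- bm_rec("chr1", sort(sample.int(4990, n)), nv, rbinom(n, nv, runif(n)))
  bm <- bin_methylation(recs, bins)
  for (b in seq_len(nrow(bins))) {
    inb <- recs$start >= bins$start[b] & recs$start < bins$end[b] & recs$n_valid > 0
    if (!any(inb)) {
      expect_true(is.na(bm$meth_ratio[b]))
    } else {
      expect_equal(bm$meth_ratio[b], sum(recs$n_mod[inb]) / sum(recs$n_valid[inb]),
                   tolerance = 1e-12)
      expect_gte(bm$meth_ratio[b], min(recs$ratio[inb]))
      expect_lte(bm$meth_ratio[b], max(recs$ratio[inb]))
    }
  }
})

test_that("genome-wide CpG summary is order-invariant and recovers planted means", {
  full <- bm_rec("chr1", c(10, 20, 30), c(5, 8, 2), c(5, 8, 2))
  expect_equal(genome_cpg_summary(full)$mean, 1)
  shuf <- full[c(3, 1, 2), ]
  expect_equal(genome_cpg_summary(shuf), genome_cpg_summary(full))
  # planted global hypomethylation: tumor 0.55 vs normal 0.75
  eff_t <- c(normal = 0.75, tumor_highHRD = 0.55, tumor_lowHRD = 0.55)
  cfg <- tiny_config(seed = 61L, methylation_effects = eff_t,
                     te_methylation = eff_t, methylation_background = eff_t)
  ref <- make_mini_reference(cfg)
  m_n <- simulate_methylome(ref, cfg, "N1", group = "normal")
  m_t <- simulate_methylome(ref, cfg, "T1", group = "tumor_highHRD")
  expect_equal(genome_cpg_summary(m_n)$mean, 0.75, tolerance = 0.02)
  expect_equal(genome_cpg_summary(m_t)$mean, 0.55, tolerance = 0.02)
  # min_valid filter drops low-support sites
  expect_lte(genome_cpg_summary(m_n, min_valid = 10)$n_sites,
             genome_cpg_summary(m_n)$n_sites)
})

test_that("the methylation matrix is complete-case with class labels kept", {
  bins <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L, 2000L),
                         end = c(1000L, 2000L, 3000L),
                         label = c("active_hor", "active_hor", "inactive_hor"),
                         bin_id = 1:3)
  s1 <- dplyr::mutate(bins, meth_ratio = c(0.8, 0.7, 0.6))
  s2 <- dplyr::mutate(bins, meth_ratio = c(0.5, NA, 0.4))
  expect_message(
    mat <- build_methylation_matrix(list(A = s1, B = s2)),
    "dropped 1")
  expect_equal(nrow(mat), 2L)
  expect_equal(attr(mat, "n_dropped"), 1L)
  expect_equal(mat$A, c(0.8, 0.6))
  expect_true(all(c("label", "A", "B") %in% names(mat)))
  # full matrix passes through unchanged
  mat2 <- build_methylation_matrix(list(A = s1, B = dplyr::mutate(s2, meth_ratio = 0.5)))
  expect_equal(nrow(mat2), 3L)
  # restricting classes drops other rows
  s3 <- dplyr::mutate(bins, label = "hsat2", meth_ratio = 0.2)
  expect_error(build_methylation_matrix(list(A = s3, B = s3)),
               "no bins")
})

make_matrix_fixture <- function(offsets, n_bins = 60L, noise = 0.01, seed = 70L) {
  withr::with_seed(seed, {
    base <- runif(n_bins, 0.3, 0.9)
    cols <- purrr::imap(offsets, function(off, nm) {
      pmin(pmax(base + off + rnorm(n_bins, 0, noise), 0), 1)
    })
    bins <- tibble::tibble(chrom = "chr1", start = seq_len(n_bins) * 1000L - 1000L,
                           end = seq_len(n_bins) * 1000L,
                           label = "active_hor", bin_id = seq_len(n_bins))
    build_methylation_matrix(
      purrr::imap(cols, ~ dplyr::mutate(bins, meth_ratio = .x)))
  })
}

test_that("PCA places identical samples at the origin and bounds variance fractions", {
  mat <- make_matrix_fixture(list(A = 0, B = 0), noise = 0)
  pca <- run_pca(mat)
  expect_true(all(abs(as.matrix(pca$scores[, -1])) < 1e-10))
  expect_equal(sum(pca$var_explained), 0)
  mat2 <- make_matrix_fixture(list(A = 0, B = 0.1, C = -0.05, D = 0.2))
  pca2 <- run_pca(mat2)
  expect_lte(sum(pca2$var_explained), 1 + 1e-12)
})

test_that("PCA separates a planted two-group shift on PC1", {
  mat <- make_matrix_fixture(list(A = 0, B = 0.005, C = -0.005,
                                  D = 0.3, E = 0.3, F = 0.31),
                             n_bins = 500L)
  pca <- run_pca(mat)
  pc1 <- pca$scores$PC1
  g1 <- pc1[pca$scores$sample %in% c("A", "B", "C")]
  g2 <- pc1[pca$scores$sample %in% c("D", "E", "F")]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2))
  # margin: group gap exceeds within-group spread
  expect_gt(abs(mean(g1) - mean(g2)), 3 * (diff(range(g1)) + diff(range(g2))))
})

test_that("PCA coordinates are invariant to bin (row) ordering", {
  mat <- make_matrix_fixture(list(A = 0, B = 0.1, C = 0.2, D = -0.1))
  pca1 <- run_pca(mat)
  perm <- withr::with_seed(1, sample(nrow(mat)))
  mat_perm <- mat[perm, ]
  attr(mat_perm, "samples") <- attr(mat, "samples")
  pca2 <- run_pca(mat_perm)
  expect_equal(pca1$scores, pca2$scores, tolerance = 1e-9)
})

test_that("Ward clustering recovers planted groups and is order-invariant", {
  skip_if_not_installed("mclust")
  mat <- make_matrix_fixture(list(A = 0, B = 0.01, C = -0.01,
                                  D = 0.3, E = 0.31, F = 0.3),
                             n_bins = 300L)
  cl <- ward_cluster(mat, k = 2L)
  truth <- c(1, 1, 1, 2, 2, 2)
  expect_equal(mclust::adjustedRandIndex(cl$partition$cluster, truth), 1)
  # merge heights are non-decreasing (Ward monotonicity)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  # sample order invariance
  cols <- rev(attr(mat, "samples"))
  mat_rev <- mat[, c("bin_id", "chrom", "start", "end", "label", cols)]
  attr(mat_rev, "samples") <- cols
  cl2 <- ward_cluster(mat_rev, k = 2L)
  merged <- dplyr::inner_join(cl$partition, cl2$partition, by = "sample")
  expect_equal(mclust::adjustedRandIndex(merged$cluster.x, merged$cluster.y), 1)
})

test_that("k = n gives singletons and k > n errors", {
  mat <- make_matrix_fixture(list(A = 0, B = 0.1, C = 0.2))
  cl <- ward_cluster(mat, k = 3L)
  expect_equal(sort(cl$partition$cluster), 1:3)
  expect_error(ward_cluster(mat, k = 4L), "exceeds")
})

test_that("HRD grouping at cutoff 63 reproduces the printed worked example", {
  # printed cohort scores: T1 70, T2 65, T3 34, T4 88, T5 52, T6 26
  meta <- tibble::tibble(
    sample_id = paste0("T", 1:6), group = "tumor", pair_id = paste0("P", 1:6),
    hrd_score = c(70L, 65L, 34L, 88L, 52L, 26L))
  g <- hrd_group(meta, cutoff = 63)
  expect_equal(g$sample_id[g$group == "high"], c("T1", "T2", "T4"))
  expect_equal(g$sample_id[g$group == "low"], c("T3", "T5", "T6"))
  # boundary: exactly 63 is high (>= convention)
  expect_equal(hrd_group(dplyr::mutate(meta, hrd_score = 63L))$group,
               rep("high", 6))
  expect_error(hrd_group(dplyr::mutate(meta, hrd_score = NA_integer_)),
               "missing HRD score")
})

test_that("the t-test matches the textbook closed form", {
  a <- c(1.1, 2.3, 3.0)
  b <- c(2.0, 2.2, 4.1)
  res <- group_mean_test(a, b)
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / (3 + 3 - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_manual)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), 4))
  # paired variant on matched vectors
  resp <- group_mean_test(a, b, paired = TRUE)
  d <- a - b
  t_p <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(resp$statistic, t_p)
  expect_equal(resp$df, 2)
})

test_that("degenerate t-test inputs follow the stated conventions", {
  same <- group_mean_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_mean_test(c(1, 1), c(2, 2)), "t undefined")
  expect_error(group_mean_test(1, c(1, 2)), ">= 2")
  expect_error(group_mean_test(c(1, 2), c(1, 2, 3), paired = TRUE), "equal-length")
})

test_that("end-to-end: planted HRD methylation structure is recovered", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(seed = 77L, n_pairs = 4L, genome_spec = tiny_genome_spec())
  ref <- make_mini_reference(cfg)
  sheet <- simulate_sample_sheet(cfg)
  groups <- hrd_group(sheet)
  key <- setNames(ifelse(groups$group == "high", "tumor_highHRD", "tumor_lowHRD"),
                  groups$sample_id)
  bins <- make_bins(dplyr::filter(ref$annotation,
                                  label %in% c("active_hor", "inactive_hor")))
  per_sample <- purrr::map(setNames(sheet$sample_id, sheet$sample_id), function(sid) {
    grp <- if (startsWith(sid, "N")) "normal" else key[[sid]]
    bin_methylation(simulate_methylome(ref, cfg, sid, group = grp), bins)
  })
  mat <- build_methylation_matrix(per_sample)
  # (i) normals tightly clustered in PCA relative to tumor separation
  pca <- run_pca(mat)
  sc <- as.matrix(pca$scores[, -1])
  rownames(sc) <- pca$scores$sample
  normals <- sc[startsWith(rownames(sc), "N"), ]
  tumors <- sc[startsWith(rownames(sc), "T"), ]
  diam <- max(dist(normals))
  centroid_gap <- sqrt(sum((colMeans(normals) - colMeans(tumors))^2))
  expect_lt(diam, centroid_gap / 4)
  # (ii) Ward k=2 on tumors recovers the planted HRD split exactly
  tum_cols <- grep("^T", attr(mat, "samples"), value = TRUE)
  mat_t <- mat[, c("bin_id", "chrom", "start", "end", "label", tum_cols)]
  attr(mat_t, "samples") <- tum_cols
  cl <- ward_cluster(mat_t, k = 2L)
  planted <- as.integer(factor(groups$group[match(cl$partition$sample,
                                                  groups$sample_id)]))
  expect_equal(mclust::adjustedRandIndex(cl$partition$cluster, planted), 1)
  # (iii) satellite-class group difference is overwhelming
  long <- dplyr::bind_rows(purrr::imap(per_sample, ~ dplyr::mutate(.x, sample = .y)))
  sat <- dplyr::filter(long, label %in% c("active_hor", "inactive_hor"),
                       startsWith(sample, "T"), !is.na(meth_ratio))
  hi <- sat$meth_ratio[sat$sample %in% groups$sample_id[groups$group == "high"]]
  lo <- sat$meth_ratio[sat$sample %in% groups$sample_id[groups$group == "low"]]
  expect_lt(group_mean_test(hi, lo)$p_value, 1e-20)
})
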