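# Seeded synthetic-data generators. Every generator draws from its own seed
# stream derived from (config seed, operation, sample) so adding or reordering
# samples never reshuffles another sample's data, and outputs are
# byte-identical under a fixed seed.

SATELLITE_CLASSES <- c("active_hor", "inactive_hor", "monomeric", "divergent",
                       "hsat1a", "hsat1b", "hsat2", "hsat3", "beta", "gamma")
TE_CLASSES <- c("L1HS", "AluY", "SVA", "ERV")

#' Satellite and transposable-element class labels
#' @return Character vector of annotation class labels the generators and
#'   track operations recognize.
#' @export
repeat_classes <- function() c(SATELLITE_CLASSES, TE_CLASSES)

#' Default mini-genome specification
#'
#' Two synthetic chromosomes: `chrS` (600 kb) carrying centromeric satellite
#' spans (active HOR 200 kb, inactive HOR 50 kb, HSat2 40 kb, beta 20 kb,
#' monomeric 20 kb) and `chrT` (600 kb) carrying TE insertions whose lengths
#' straddle the full-length filters (L1HS around 6 kb, AluY around 300 bp,
#' SVA and ERV around 1 kb).
#'
#' @return List with `chrom_lengths` (tibble `chrom`, `length`) and
#'   `annotation` (tibble `chrom`, `start`, `end`, `label`).
#' @export
default_genome_spec <- function() {
  ann_s <- tibble(
    chrom = "chrS",
    start = as.integer(c(50000, 300000, 400000, 480000, 520000)),
    end = as.integer(c(250000, 350000, 440000, 500000, 540000)),
    label = c("active_hor", "inactive_hor", "hsat2", "beta", "monomeric")
  )
  te <- list(
    L1HS = c(rep(6500L, 20L), rep(3000L, 8L)),
    AluY = c(rep(320L, 30L), rep(280L, 10L)),
    SVA = c(rep(1500L, 7L), rep(800L, 3L)),
    ERV = c(rep(2500L, 10L), rep(900L, 2L))
  )
  lens <- unlist(te, use.names = FALSE)
  labels <- rep(names(te), lengths(te))
  gap <- 3000L
  starts <- 10000L + cumsum(c(0L, head(lens + gap, -1L)))
  ann_t <- tibble(chrom = "chrT", start = starts, end = starts + lens,
                  label = labels)
  list(
    chrom_lengths = tibble(chrom = c("chrS", "chrT"),
                           length = c(600000L, 600000L)),
    annotation = bind_rows(ann_s, ann_t)
  )
}

#' Simulation configuration
#'
#' Bundles the study conditions for the synthetic cohort; unknown arguments
#' are rejected. Defaults: 6 tumor/normal pairs, 30x mean depth with
#' negative-binomial dispersion (`nb_size` 50), 4x dispersion inflation in TE
#' spans of tumor samples, satellite methylation means 0.75 / 0.55 / 0.35 for
#' normal / high-HRD tumor / low-HRD tumor, four callers with sensitivities
#' 0.95 / 0.90 / 0.85 / 0.80, 100-bp breakpoint jitter, 200 truth SVs,
#' catalogs of 5000 mutations.
#'
#' @param seed Master seed (integer).
#' @param n_pairs Tumor/normal pair count.
#' @param genome_spec Genome specification (see [default_genome_spec()]).
#' @param depth_mean Genome-wide mean depth.
#' @param nb_size Negative-binomial size (inverse dispersion) of depth.
#' @param tumor_variance_inflation Dispersion multiplier in TE spans of
#'   tumor samples (1 disables the effect).
#' @param depth_window Depth-track window width in bp (mosdepth-style).
#' @param methylation_effects Named per-group mean 5mC in satellite classes
#'   (`normal`, `tumor_highHRD`, `tumor_lowHRD`).
#' @param te_methylation Named per-group mean 5mC in TE classes.
#' @param methylation_background Named per-group mean 5mC outside annotated
#'   repeats (the genome-wide background).
#' @param beta_concentration Beta-binomial concentration for site-to-site
#'   methylation heterogeneity.
#' @param cpg_read_lambda Poisson mean of per-CpG valid read counts.
#' @param caller_sensitivities Named per-caller detection probabilities.
#' @param breakpoint_jitter_sd Breakpoint jitter SD in bp; jitter is a
#'   truncated normal, clamped at `jitter_truncate` SDs, so two jittered
#'   copies of one breakpoint stay within the default matching tolerance.
#' @param jitter_truncate Truncation point of the jitter in SD units.
#' @param n_truth_sv Number of truth SVs per sample.
#' @param fp_per_caller Caller-private false positives per caller.
#' @param sv_min_separation Minimum spacing in bp between planted breakpoints
#'   (keeps distinct events from chain-merging, so the truth table is an
#'   exact consensus oracle).
#' @param catalog_size Mutations per simulated catalog.
#' @param exposure_truth Optional matrix/tibble of per-sample truth signature
#'   weights (rows sum to 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_pairs = 6L,
                       genome_spec = default_genome_spec(),
                       depth_mean = 30,
                       nb_size = 50,
                       tumor_variance_inflation = 4,
                       depth_window = 100L,
                       methylation_effects = c(normal = 0.75, tumor_highHRD = 0.55,
                                               tumor_lowHRD = 0.35),
                       te_methylation = c(normal = 0.85, tumor_highHRD = 0.70,
                                          tumor_lowHRD = 0.55),
                       methylation_background = c(normal = 0.75, tumor_highHRD = 0.65,
                                                  tumor_lowHRD = 0.60),
                       beta_concentration = 30,
                       cpg_read_lambda = 15,
                       caller_sensitivities = c(severus = 0.95, savana = 0.90,
                                                nanomonsv = 0.85, delly = 0.80),
                       breakpoint_jitter_sd = 100,
                       jitter_truncate = 2.4,
                       n_truth_sv = 200L,
                       fp_per_caller = 5L,
                       sv_min_separation = 2000L,
                       catalog_size = 5000L,
                       exposure_truth = NULL) {
  cfg <- as.list(environment())
  groups <- c("normal", "tumor_highHRD", "tumor_lowHRD")
  for (nm in c("methylation_effects", "te_methylation", "methylation_background")) {
    v <- cfg[[nm]]
    if (!all(groups %in% names(v)) || any(v < 0 | v > 1)) {
      abort(sprintf("%s must name groups %s with values in [0,1]",
                    nm, paste(groups, collapse = ", ")))
    }
  }
  if (any(cfg$caller_sensitivities < 0 | cfg$caller_sensitivities > 1)) {
    abort("caller_sensitivities must be probabilities in [0,1]")
  }
  if (any(cfg$genome_spec$chrom_lengths$length <= 0)) abort("chromosome lengths must be positive")
  if (sum(as.numeric(cfg$genome_spec$chrom_lengths$length)) > 1e7) {
    abort("genome_spec total length must be <= 10 Mb")
  }
  if (!is.null(cfg$exposure_truth)) {
    w <- as.matrix(cfg$exposure_truth)
    if (any(abs(rowSums(w) - 1) > 1e-8) || any(w < 0)) {
      abort("exposure_truth rows must be nonnegative and sum to 1")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Build the mini reference: FASTA sequences plus annotation
#'
#' Draws random chromosome sequences under the config seed, validates the
#' annotation (same-class spans must not overlap), and indexes all CpG sites.
#' Byte-identical outputs for a fixed seed.
#'
#' @param config A `sim_config`.
#' @param dir Optional directory; when given, writes `reference.fa` and
#'   `annotation.bed` there.
#' @return List of class `mini_reference`: `sequences`
#'   ([Biostrings::DNAStringSet]), `annotation`, `chrom_lengths`, `cpg_sites`
#'   (tibble `chrom`, `start`, `end`), and `paths` (when written).
#' @export
make_mini_reference <- function(config, dir = NULL) {
  spec <- config$genome_spec
  ann <- arrange(spec$annotation, .data$chrom, .data$start)
  check_intervals(ann, "annotation")
  for (lab in unique(ann$label)) {
    a <- filter(ann, .data$label == lab)
    for (ch in unique(a$chrom)) {
      x <- filter(a, .data$chrom == ch)
      if (nrow(x) > 1L && any(x$start[-1L] < head(x$end, -1L))) {
        abort(sprintf("overlapping '%s' annotation spans on %s", lab, ch))
      }
    }
  }
  seqs <- with_stream(config$seed, "reference", {
    setNames(Biostrings::DNAStringSet(vapply(
      seq_len(nrow(spec$chrom_lengths)),
      function(i) paste(sample(c("A", "C", "G", "T"),
                               spec$chrom_lengths$length[i], replace = TRUE),
                        collapse = ""),
      character(1))), spec$chrom_lengths$chrom)
  })
  cpg <- bind_rows(lapply(names(seqs), function(ch) {
    pos <- Biostrings::start(Biostrings::matchPattern("CG", seqs[[ch]]))
    tibble(chrom = ch, start = as.integer(pos - 1L), end = as.integer(pos + 1L))
  }))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "reference.fa")
    bed <- file.path(dir, "annotation.bed")
    Biostrings::writeXStringSet(seqs, fa)
    write_bed_annotation(ann, bed)
    paths <- list(fasta = fa, annotation = bed)
  }
  structure(list(sequences = seqs, annotation = ann,
                 chrom_lengths = spec$chrom_lengths, cpg_sites = cpg,
                 paths = paths),
            class = "mini_reference")
}

#' Simulated cohort sample sheet
#'
#' `n_pairs` tumor/normal pairs; the first half of the tumors is planted in
#' the high-HRD group (scores drawn in 63-95), the rest in the low group
#' (scores 15-62); scar components LST/LOH/TAI are drawn to sum to the HRD
#' score.
#'
#' @param config A `sim_config`.
#' @return Sample-sheet tibble (see [read_sample_sheet()] for columns).
#' @export
simulate_sample_sheet <- function(config) {
  n <- config$n_pairs
  n_high <- ceiling(n / 2)
  with_stream(config$seed, "sample_sheet", {
    hi <- sample(63:95, n_high, replace = TRUE)
    lo <- sample(15:62, n - n_high, replace = TRUE)
    score <- c(hi, lo)
    lst <- floor(score * runif(n, 0.25, 0.45))
    loh <- floor((score - lst) * runif(n, 0.3, 0.6))
    tai <- score - lst - loh
    tum <- tibble(
      sample_id = paste0("T", seq_len(n)), group = "tumor",
      pair_id = paste0("P", seq_len(n)),
      hrd_score = score, lst = lst, loh = loh, tai = tai,
      brca1_germline = ifelse(seq_len(n) <= min(2, n_high), "present", "absent"),
      ccne1_amp = ifelse(seq_len(n) > n_high, "present", "absent"),
      purity = round(runif(n, 0.35, 0.9), 2),
      ploidy = round(runif(n, 1.8, 4.6), 2)
    )
    nor <- tibble(
      sample_id = paste0("N", seq_len(n)), group = "normal",
      pair_id = paste0("P", seq_len(n)),
      hrd_score = NA_integer_, lst = NA_integer_, loh = NA_integer_,
      tai = NA_integer_, brca1_germline = tum$brca1_germline,
      ccne1_amp = "absent", purity = NA_real_, ploidy = 2
    )
    bind_rows(tum, nor)
  })
}

# planted methylation group key for a sample row
sample_group_key <- function(group, hrd_score, cutoff = 63) {
  if (group == "normal") "normal"
  else if (!is.na(hrd_score) && hrd_score >= cutoff) "tumor_highHRD"
  else "tumor_lowHRD"
}

#' Simulate a mosdepth-style depth track
#'
#' Depth per fixed-width window is negative-binomial (gamma-Poisson) with
#' mean `depth_mean` and size `nb_size`; in tumor samples the dispersion
#' inside TE spans is multiplied by `tumor_variance_inflation` (size divided
#' by it), emulating coverage-variance inflation of transposable elements in
#' unstable genomes.
#'
#' @param reference A `mini_reference`.
#' @param config A `sim_config`.
#' @param sample_id Sample label (also keys the seed stream).
#' @param group `"normal"` or one of the tumor group keys.
#' @return Depth tibble `chrom`, `start`, `end`, `depth`.
#' @export
simulate_depth_track <- function(reference, config, sample_id,
                                 group = "normal") {
  w <- config$depth_window
  wins <- bind_rows(lapply(seq_len(nrow(reference$chrom_lengths)), function(i) {
    len <- reference$chrom_lengths$length[i]
    starts <- seq(0L, len - 1L, by = w)
    tibble(chrom = reference$chrom_lengths$chrom[i], start = starts,
           end = pmin(starts + w, len))
  }))
  te_spans <- filter(reference$annotation, .data$label %in% TE_CLASSES)
  in_te <- rep(FALSE, nrow(wins))
  if (nrow(te_spans) > 0L) {
    in_te[unique(overlap_pairs(wins, te_spans)$query_idx)] <- TRUE
  }
  size <- rep(config$nb_size, nrow(wins))
  if (group != "normal") {
    size[in_te] <- config$nb_size / config$tumor_variance_inflation
  }
  wins$depth <- with_stream(config$seed, paste("depth", sample_id),
                            rnbinom(nrow(wins), mu = config$depth_mean, size = size))
  wins
}

#' Simulate a whole-genome CpG methylome
#'
#' Each CpG site gets a class-specific group mean (satellite classes from
#' `methylation_effects`, TE classes from `te_methylation`, background
#' elsewhere); the site-level methylation probability is beta-distributed
#' around that mean (concentration `beta_concentration`) and read counts are
#' binomial given a Poisson valid-read count, i.e. a beta-binomial methylome
#' with planted group ordering normal > high-HRD tumor > low-HRD tumor in
#' satellite classes.
#'
#' @param reference A `mini_reference`.
#' @param config A `sim_config`.
#' @param sample_id Sample label (keys the seed stream).
#' @param group `"normal"`, `"tumor_highHRD"` or `"tumor_lowHRD"`.
#' @return bedMethyl-shaped tibble (`chrom`, `start`, `end`, `strand`,
#'   `n_valid`, `n_mod`, `ratio`, `haplotype`); sites with `n_valid == 0` are
#'   retained with `ratio = NA`.
#' @export
simulate_methylome <- function(reference, config, sample_id,
                               group = c("normal", "tumor_highHRD", "tumor_lowHRD")) {
  group <- match.arg(group)
  sites <- reference$cpg_sites
  mu <- rep(unname(config$methylation_background[group]), nrow(sites))
  ov <- overlap_pairs(sites, reference$annotation)
  if (nrow(ov) > 0L) {
    ov <- ov[!duplicated(ov$query_idx), , drop = FALSE]
    lab <- reference$annotation$label[ov$subject_idx]
    mu[ov$query_idx] <- ifelse(
      lab %in% SATELLITE_CLASSES, config$methylation_effects[group],
      ifelse(lab %in% TE_CLASSES, config$te_methylation[group],
             config$methylation_background[group]))
  }
  conc <- config$beta_concentration
  out <- with_stream(config$seed, paste("methylome", sample_id), {
    p <- rbeta(nrow(sites), mu * conc, (1 - mu) * conc)
    n_valid <- rpois(nrow(sites), config$cpg_read_lambda)
    n_mod <- rbinom(nrow(sites), n_valid, p)
    tibble(chrom = sites$chrom, start = sites$start, end = sites$end,
           strand = "+", n_valid = n_valid, n_mod = n_mod,
           ratio = ifelse(n_valid > 0, n_mod / n_valid, NA_real_),
           haplotype = NA_character_)
  })
  out
}

# truncated-normal breakpoint jitter, clamped at k sd
jitter_bp <- function(n, sd, k) {
  if (sd <= 0) return(integer(n))
  as.integer(round(pmin(pmax(rnorm(n, 0, sd), -k * sd), k * sd)))
}

#' Simulate four-caller somatic SV call sets with a truth table
#'
#' Plants `n_truth_sv` truth SVs (mixed DEL/DUP/INV/INS/TRA, log-uniform
#' sizes 30 bp - 50 kb) at breakpoints spaced at least `sv_min_separation`
#' apart. Each caller reports each truth SV with its sensitivity, both
#' breakpoints jittered by a truncated normal, plus caller-private false
#' positives at separate spaced positions. Spacing plus jitter truncation
#' guarantees the truth table is an exact oracle for breakpoint-tolerance-500
#' consensus merging.
#'
#' @param reference A `mini_reference`.
#' @param config A `sim_config`.
#' @param sample_id Sample label (keys the seed stream).
#' @param dir Optional directory; when given, one VCF per caller plus a
#'   `truth.tsv` are written.
#' @return List with `truth` (tibble: coordinates, `svtype`, `svlen`,
#'   `detected_by`, `n_detected`), `callsets` (named list of SV tibbles) and
#'   `paths`.
#' @export
simulate_sv_callsets <- function(reference, config, sample_id, dir = NULL) {
  sens <- config$caller_sensitivities
  callers <- names(sens)
  lens <- setNames(reference$chrom_lengths$length, reference$chrom_lengths$chrom)
  res <- with_stream(config$seed, paste("sv", sample_id), {
    slots <- bind_rows(lapply(names(lens), function(ch) {
      # leave headroom for event extents; sizes are clipped to the chromosome
      margin <- max(2L * config$sv_min_separation,
                    min(60000L, floor(lens[[ch]] / 10)))
      tibble(chrom = ch,
             pos = seq(5000L, lens[[ch]] - margin, by = config$sv_min_separation))
    }))
    slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
    n <- config$n_truth_sv
    n_fp <- config$fp_per_caller * length(callers)
    if (nrow(slots) < n + n_fp) abort("genome too small for requested SV count")
    types <- sample(c("DEL", "DUP", "INV", "INS", "TRA"), n, replace = TRUE,
                    prob = c(0.35, 0.2, 0.15, 0.2, 0.1))
    if (length(lens) < 2L) types[types == "TRA"] <- "DEL"
    sizes <- round(10^runif(n, log10(30), log10(5e4)))
    # guard band around the 50-bp retention threshold: with length-scaled,
    # truncated jitter the representative length stays within 24% of truth,
    # so sizes in [40, 66) would make the retention decision jitter-dependent
    sizes <- ifelse(sizes >= 40 & sizes < 66, sizes + 30, sizes)
    truth <- tibble(sv_id = sprintf("truth%03d", seq_len(n)),
                    chrom1 = slots$chrom[seq_len(n)], pos1 = slots$pos[seq_len(n)],
                    svtype = types, svlen = as.numeric(sizes))
    used <- n
    chrom2 <- truth$chrom1; pos2 <- integer(n)
    for (i in seq_len(n)) {
      if (truth$svtype[i] == "TRA") {
        j <- used + 1L
        while (slots$chrom[j] == truth$chrom1[i]) j <- j + 1L
        chrom2[i] <- slots$chrom[j]; pos2[i] <- slots$pos[j]
        # consume the slot used for the second breakend
        slots <- slots[-j, , drop = FALSE]
        truth$svlen[i] <- 0
      } else if (truth$svtype[i] == "INS") {
        pos2[i] <- truth$pos1[i]
      } else {
        truth$svlen[i] <- min(truth$svlen[i], lens[[truth$chrom1[i]]] - truth$pos1[i] - 1000)
        pos2[i] <- truth$pos1[i] + truth$svlen[i]
      }
    }
    truth$chrom2 <- chrom2; truth$pos2 <- pos2
    # canonical breakpoint order for TRA
    swap <- truth$svtype == "TRA" & truth$chrom2 < truth$chrom1
    if (any(swap)) {
      tmp_c <- truth$chrom1[swap]; tmp_p <- truth$pos1[swap]
      truth$chrom1[swap] <- truth$chrom2[swap]; truth$pos1[swap] <- truth$pos2[swap]
      truth$chrom2[swap] <- tmp_c; truth$pos2[swap] <- tmp_p
    }
    detected <- matrix(FALSE, n, length(callers), dimnames = list(NULL, callers))
    callsets <- list()
    fp_slots <- slots[seq(used + 1L, used + n_fp), , drop = FALSE]
    for (ci in seq_along(callers)) {
      cal <- callers[ci]
      hit <- runif(n) < sens[[cal]]
      detected[, ci] <- hit
      m <- sum(hit)
      calls <- truth[hit, , drop = FALSE]
      # callers localize small events more precisely: jitter sd shrinks with
      # event size for intra-chromosomal SVs (full sd for TRA breakends)
      sd_ev <- ifelse(calls$svtype %in% c("DEL", "DUP", "INV"),
                      pmin(config$breakpoint_jitter_sd, calls$svlen / 20),
                      config$breakpoint_jitter_sd)
      k <- config$jitter_truncate
      j1 <- vapply(sd_ev, function(s) jitter_bp(1L, s, k), integer(1))
      j2 <- vapply(sd_ev, function(s) jitter_bp(1L, s, k), integer(1))
      calls$pos1 <- pmax(calls$pos1 + j1, 1L)
      calls$pos2 <- ifelse(calls$svtype == "INS", calls$pos1,
                           pmax(calls$pos2 + j2, calls$pos1 + 1L))
      calls$svlen <- ifelse(calls$svtype %in% c("DEL", "DUP", "INV"),
                            calls$pos2 - calls$pos1, calls$svlen)
      fp_idx <- seq((ci - 1L) * config$fp_per_caller, length.out = config$fp_per_caller) + 1L
      fps <- NULL
      if (config$fp_per_caller > 0L) {
        fp_type <- sample(c("DEL", "DUP", "INV", "INS"), config$fp_per_caller,
                          replace = TRUE)
        fp_size <- round(10^runif(config$fp_per_caller, log10(60), log10(2e4)))
        fps <- tibble(chrom1 = fp_slots$chrom[fp_idx], pos1 = fp_slots$pos[fp_idx],
                      svtype = fp_type, svlen = as.numeric(fp_size)) |>
          mutate(chrom2 = .data$chrom1,
                 pos2 = ifelse(.data$svtype == "INS", .data$pos1,
                               .data$pos1 + as.integer(.data$svlen)))
      }
      cs <- bind_rows(
        select(calls, "chrom1", "pos1", "chrom2", "pos2", "svtype", "svlen"),
        fps) |>
        mutate(caller = cal, sample = sample_id) |>
        arrange(.data$chrom1, .data$pos1)
      callsets[[cal]] <- cs
    }
    truth$detected_by <- apply(detected, 1L, function(r)
      paste(callers[r], collapse = ","))
    truth$n_detected <- rowSums(detected)
    list(truth = truth, callsets = callsets)
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(truth = file.path(dir, sprintf("%s_truth.tsv", sample_id)))
    readr::write_tsv(res$truth, paths$truth)
    for (cal in callers) {
      p <- file.path(dir, sprintf("%s_%s.vcf", sample_id, cal))
      write_sv_vcf(res$callsets[[cal]], p, source = cal)
      paths[[cal]] <- p
    }
  }
  res$paths <- paths
  res
}

#' Expected consensus count from a simulated truth table
#'
#' The independent oracle for consensus merging: the number of truth events
#' detected by at least `min_support` callers whose length is at least
#' `min_size` bp (translocations exempt from the size rule).
#'
#' @param truth Truth tibble from [simulate_sv_callsets()].
#' @param min_support Minimum caller support (default 2).
#' @param min_size Minimum size in bp (default 50).
#' @return Integer count.
#' @export
truth_consensus_count <- function(truth, min_support = 2L, min_size = 50) {
  sum(truth$n_detected >= min_support &
        (truth$svtype == "TRA" | truth$svlen >= min_size))
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws `size` mutations from `multinomial(size, S w)` for truth weights
#' `w`.
#'
#' @param signatures A `signature_matrix`.
#' @param weights Named or ordered nonnegative truth weights summing to 1
#'   (one per signature).
#' @param size Catalog size (mutation count).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A `mutation_catalog` tibble; truth weights in
#'   `attr(x, "weights_truth")`.
#' @export
simulate_mutation_catalog <- function(signatures, weights, size, seed = 1L,
                                      sample_id = NA_character_) {
  sig <- as_tibble(signatures)
  S <- as.matrix(sig[, -1L, drop = FALSE])
  if (length(weights) != ncol(S)) abort("need one weight per signature")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("weights must be nonnegative and sum to 1")
  }
  if (!is.null(names(weights))) weights <- weights[colnames(S)]
  p <- drop(S %*% weights)
  counts <- with_stream(seed, paste("catalog", sample_id),
                        as.integer(rmultinom(1L, size, p)))
  out <- new_catalog(sig$channel, counts, sample_id,
                     if (nrow(sig) == 96L) "SBS96" else "custom")
  attr(out, "weights_truth") <- weights
  out
}

#' Generate a synthetic reference signature matrix
#'
#' Column-stochastic signature profiles drawn from a symmetric Dirichlet;
#' a labelled synthetic stand-in for a COSMIC-style reference.
#'
#' @param channels Channel labels (default [sbs96_channels()]).
#' @param n_signatures Number of signatures (default 5).
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration (default 0.3; sparse, signature-like
#'   profiles).
#' @return A `signature_matrix` tibble with signatures `SynthSig1`, ...
#' @export
simulate_signature_matrix <- function(channels = sbs96_channels(),
                                      n_signatures = 5L, seed = 1L, alpha = 0.3) {
  m <- with_stream(seed, "signature_matrix", {
    g <- matrix(stats::rgamma(length(channels) * n_signatures, shape = alpha),
                nrow = length(channels))
    sweep(g, 2L, colSums(g), "/")
  })
  colnames(m) <- paste0("SynthSig", seq_len(n_signatures))
  out <- bind_cols(tibble(channel = channels), as_tibble(m))
  structure(out, class = c("signature_matrix", class(out)))
}

#' Simulate haplotype-tagged CpG calls at a THOR-like locus
#'
#' CpG sites are placed on a jittered grid across the promoter span; per
#' haplotype, each site's methylation probability is beta-distributed around
#' the haplotype mean inside the THOR span (`flank_mean` outside), and read
#' support is Poisson so some sites fall below the 3-read filter on one
#' haplotype. A small fraction of unphased records is included.
#'
#' @param seed Integer seed.
#' @param chrom Chromosome name of the locus.
#' @param region Length-2 vector: promoter span (0-based half-open).
#' @param thor Length-2 vector: THOR span within the region.
#' @param hap_means Length-2 vector: mean THOR methylation of haplotypes 1
#'   and 2.
#' @param flank_mean Mean methylation outside the THOR span (default 0.1).
#' @param cpg_spacing Approximate CpG spacing in bp (default 20).
#' @param read_lambda Poisson mean of per-site per-haplotype read counts
#'   (default 6).
#' @param beta_concentration Site heterogeneity concentration (default 20).
#' @param unphased_frac Fraction of additional unphased records (default
#'   0.05).
#' @return Haplotype-tagged bedMethyl tibble.
#' @export
simulate_phased_locus <- function(seed = 1L, chrom = "chrTHOR",
                                  region = c(0L, 4000L), thor = c(1000L, 2500L),
                                  hap_means = c(0.9, 0.1), flank_mean = 0.1,
                                  cpg_spacing = 20L, read_lambda = 6,
                                  beta_concentration = 20, unphased_frac = 0.05) {
  stopifnot(length(hap_means) == 2L, all(hap_means >= 0 & hap_means <= 1))
  with_stream(seed, "phased_locus", {
    pos <- seq(region[1L] + 5L, region[2L] - 5L, by = cpg_spacing) +
      sample(-5L:5L, length(seq(region[1L] + 5L, region[2L] - 5L, by = cpg_spacing)),
             replace = TRUE)
    pos <- sort(unique(pmax(pos, region[1L])))
    in_thor <- pos >= thor[1L] & pos < thor[2L]
    one_hap <- function(h) {
      mu <- ifelse(in_thor, hap_means[h], flank_mean)
      mu <- pmin(pmax(mu, 0.02), 0.98)
      p <- rbeta(length(pos), mu * beta_concentration, (1 - mu) * beta_concentration)
      n_valid <- rpois(length(pos), read_lambda)
      n_mod <- rbinom(length(pos), n_valid, p)
      tibble(chrom = chrom, start = pos, end = pos + 2L, strand = "+",
             n_valid = n_valid, n_mod = n_mod,
             ratio = ifelse(n_valid > 0, n_mod / n_valid, NA_real_),
             haplotype = as.character(h))
    }
    out <- bind_rows(one_hap(1L), one_hap(2L))
    n_un <- round(unphased_frac * length(pos))
    if (n_un > 0L) {
      idx <- sample(length(pos), n_un)
      mu <- pmin(pmax(ifelse(in_thor[idx], mean(hap_means), flank_mean), 0.02), 0.98)
      nv <- rpois(n_un, read_lambda)
      nm <- rbinom(n_un, nv, mu)
      out <- bind_rows(out, tibble(
        chrom = chrom, start = pos[idx], end = pos[idx] + 2L, strand = "+",
        n_valid = nv, n_mod = nm, ratio = ifelse(nv > 0, nm / nv, NA_real_),
        haplotype = "unphased"))
    }
    arrange(out, .data$start, .data$haplotype)
  })
}
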