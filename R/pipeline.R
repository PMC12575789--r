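# Staged pipeline orchestration: validated config, dependency-ordered stages,
# per-run manifest, deterministic outputs.

PIPELINE_STAGES <- c("simulate", "sv_merge", "signatures", "coverage",
                     "methylation", "thor")

#' Build and validate a pipeline configuration
#'
#' All tunables in one validated object; unknown keys are rejected. Values
#' may come from a YAML file (`pipeline_config_from_yaml()`), with arguments
#' overriding file values.
#'
#' @param outdir Output directory for tables and the manifest.
#' @param seed Master seed driving every stochastic stage.
#' @param stages Character vector of stages to run, in dependency order
#'   (subset of `simulate`, `sv_merge`, `signatures`, `coverage`,
#'   `methylation`, `thor`).
#' @param sim `sim_config()` arguments as a named list (used by the simulate
#'   stage).
#' @param sv_tol Breakpoint matching tolerance in bp.
#' @param sv_min_size Minimum consensus SV size in bp.
#' @param sv_min_support Minimum supporting callers.
#' @param bin_width Genomic bin width in bp.
#' @param bin_partial Partial-bin dialect (`"merge"` or `"keep"`).
#' @param hrd_cutoff HRD-score cutoff separating high/low groups.
#' @param thor_hyper,thor_hypo THOR classification thresholds.
#' @param n_signatures Reference signatures for the synthetic matrix.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("repeatscape_run_"),
                            seed = 1L,
                            stages = PIPELINE_STAGES,
                            sim = list(),
                            sv_tol = 500,
                            sv_min_size = 50,
                            sv_min_support = 2,
                            bin_width = 1000L,
                            bin_partial = "merge",
                            hrd_cutoff = 63,
                            thor_hyper = 0.6,
                            thor_hypo = 0.3,
                            n_signatures = 5L) {
  cfg <- as.list(environment())
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s (known: %s)",
                  paste(bad, collapse = ", "), paste(PIPELINE_STAGES, collapse = ", ")))
  }
  if (!cfg$bin_partial %in% c("merge", "keep")) abort("bin_partial must be 'merge' or 'keep'")
  if (!is.list(cfg$sim)) abort("sim must be a named list of sim_config() arguments")
  known_sim <- names(formals(sim_config))
  bad <- setdiff(names(cfg$sim), known_sim)
  if (length(bad) > 0L) {
    abort(sprintf("unknown sim key(s): %s", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   unknown keys are rejected.
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    abort(sprintf("unknown config key(s) in '%s': %s", path,
                  paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

write_stage_table <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  readr::write_tsv(as_tibble(x), path)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic cohort:
#' `simulate` (reference, sample sheet, methylomes, depth tracks, SV call
#' sets, catalogs) -> `sv_merge` (consensus SVs per tumor) -> `signatures`
#' (NNLS refitting) -> `coverage` (normalized binned depth over repeat
#' classes + variance tests) -> `methylation` (bin x sample matrix, PCA,
#' Ward clustering, HRD grouping, group tests) -> `thor` (haplotype-resolved
#' promoter classification). Every run writes a `manifest.json` recording the
#' config hash, seed, package version and output files; a rerun with an
#' identical config is byte-identical. A stage failure aborts with a message
#' naming the stage.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  files <- character(0)
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[repeatscape] stage %-11s %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  sheet <- simulate_sample_sheet(scfg)
  reference <- NULL

  if ("simulate" %in% config$stages) {
    results$simulate <- run_stage("simulate", function() {
      reference <<- make_mini_reference(scfg, dir = file.path(config$outdir, "reference"))
      files <<- c(files, write_stage_table(sheet, config$outdir, "sample_sheet.tsv"))
      list(reference = reference, sheet = sheet)
    })
  } else {
    reference <- make_mini_reference(scfg)
  }

  tumors <- filter(sheet, .data$group == "tumor")
  groups <- hrd_group(sheet, cutoff = config$hrd_cutoff)
  group_key <- setNames(ifelse(groups$group == "high", "tumor_highHRD", "tumor_lowHRD"),
                        groups$sample_id)

  if ("sv_merge" %in% config$stages) {
    results$sv_merge <- run_stage("sv_merge", function() {
      per_sample <- purrr::map(setNames(tumors$sample_id, tumors$sample_id), function(sid) {
        sim <- simulate_sv_callsets(reference, scfg, sid)
        cons <- merge_callsets(sim$callsets, tol = config$sv_tol,
                               min_size = config$sv_min_size,
                               min_support = config$sv_min_support)
        write_consensus_vcf(cons, file.path(config$outdir,
                                            sprintf("%s_consensus.vcf", sid)))
        list(consensus = cons, truth = sim$truth)
      })
      summary <- bind_rows(purrr::map(per_sample, ~ consensus_summary(.x$consensus)))
      files <<- c(files, write_stage_table(summary, config$outdir, "sv_consensus_summary.tsv"))
      per_sample
    })
  }

  if ("signatures" %in% config$stages) {
    results$signatures <- run_stage("signatures", function() {
      sigs <- simulate_signature_matrix(n_signatures = config$n_signatures,
                                        seed = derive_seed(config$seed, "sigmatrix"))
      w <- rep(1 / config$n_signatures, config$n_signatures)
      fits <- purrr::map(setNames(tumors$sample_id, tumors$sample_id), function(sid) {
        cat_i <- simulate_mutation_catalog(
          sigs, w, scfg$catalog_size,
          seed = derive_seed(config$seed, "catalog", sid), sample_id = sid)
        nnls_fit(cat_i, sigs)
      })
      tab <- bind_rows(purrr::map(fits, tidy))
      files <<- c(files, write_stage_table(tab, config$outdir, "signature_exposures.tsv"))
      list(signatures = sigs, fits = fits)
    })
  }

  if ("coverage" %in% config$stages) {
    results$coverage <- run_stage("coverage", function() {
      repeat_ann <- filter(reference$annotation, .data$label %in% repeat_classes())
      bins <- make_bins(repeat_ann, width = config$bin_width,
                        partial = config$bin_partial)
      tracks <- purrr::map(setNames(sheet$sample_id, sheet$sample_id), function(sid) {
        grp <- if (sheet$group[sheet$sample_id == sid] == "normal") "normal"
               else group_key[[sid]]
        depth <- simulate_depth_track(reference, scfg, sid, group = grp)
        normalize_depth(bin_median_depth(depth, bins), genome_median_depth(depth)) |>
          mutate(sample = sid)
      })
      long <- bind_rows(tracks)
      files <<- c(files, write_stage_table(long, config$outdir, "coverage_bins.tsv"))
      te_long <- filter(long, .data$label %in% TE_CLASSES)
      norm_ids <- sheet$sample_id[sheet$group == "normal"]
      vt <- purrr::map_dfr(TE_CLASSES, function(cl) {
        x <- filter(te_long, .data$label == cl)
        a <- x$norm_depth[x$sample %in% norm_ids]
        b <- x$norm_depth[!x$sample %in% norm_ids]
        if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) return(NULL)
        mutate(compare_variance(a, b), te_class = cl, .before = 1L)
      })
      files <<- c(files, write_stage_table(vt, config$outdir, "coverage_variance_tests.tsv"))
      list(bins = long, variance_tests = vt)
    })
  }

  if ("methylation" %in% config$stages) {
    results$methylation <- run_stage("methylation", function() {
      sat_ann <- filter(reference$annotation, .data$label %in% SATELLITE_CLASSES)
      bins <- make_bins(sat_ann, width = config$bin_width,
                        partial = config$bin_partial)
      per_sample <- purrr::map(setNames(sheet$sample_id, sheet$sample_id), function(sid) {
        grp <- if (sheet$group[sheet$sample_id == sid] == "normal") "normal"
               else group_key[[sid]]
        bin_methylation(simulate_methylome(reference, scfg, sid, group = grp), bins)
      })
      mat <- build_methylation_matrix(per_sample,
                                      classes = c("active_hor", "inactive_hor"))
      pca <- run_pca(mat)
      ward <- ward_cluster(mat, k = 2L)
      files <<- c(files,
                  write_stage_table(as_tibble(mat), config$outdir, "methylation_matrix.tsv"),
                  write_stage_table(tidy(pca), config$outdir, "methylation_pca.tsv"),
                  write_stage_table(tidy(ward), config$outdir, "methylation_clusters.tsv"),
                  write_stage_table(groups, config$outdir, "hrd_groups.tsv"))
      list(matrix = mat, pca = pca, ward = ward, hrd_groups = groups)
    })
  }

  if ("thor" %in% config$stages) {
    results$thor <- run_stage("thor", function() {
      # planted allele states: first tumor biallelic, second monoallelic,
      # the rest unmethylated on both alleles
      states <- list(c(0.9, 0.9), c(0.9, 0.1))
      calls <- purrr::map_dfr(seq_len(nrow(tumors)), function(i) {
        hm <- if (i <= length(states)) states[[i]] else c(0.05, 0.05)
        recs <- simulate_phased_locus(
          seed = derive_seed(config$seed, "thor", tumors$sample_id[i]),
          hap_means = hm)
        tracks <- site_methylation_by_haplotype(recs, "chrTHOR:0-4000")
        classify_thor(purrr::map(tracks, smooth_track), "chrTHOR:1000-2500",
                      hyper_threshold = config$thor_hyper,
                      hypo_threshold = config$thor_hypo,
                      sample_id = tumors$sample_id[i])
      })
      files <<- c(files, write_stage_table(calls, config$outdir, "thor_calls.tsv"))
      calls
    })
  }

  manifest <- list(
    package = "repeatscape",
    version = as.character(utils::packageVersion("repeatscape")),
    seed = config$seed,
    stages = config$stages,
    config_hash = rlang::hash(unclass(config)),
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
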