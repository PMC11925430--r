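#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file driving all stages. Unknown
#' top-level keys are rejected; missing keys fall back to documented
#' defaults. Schema (all optional unless noted):
#'
#' * `seed`: integer, master seed for all randomness.
#' * `out_dir` (required): output directory.
#' * `simulate$phantoms`: `n`, `outer_radii`, `thickness_mm`, `density_hu`,
#'   `spacing`, `blur_fwhm`, `noise_sd`.
#' * `simulate$cohort`: `n_per_group` (named), `noise_sd`
#'   (`thickness`/`density`).
#' * `quantify`: `hu_threshold`, `n_locations`, `resample` (logical),
#'   `target_spacing`, `max_inplane_mm`, `max_slice_mm`.
#' * `analyze`: `regions`, `classifier` (`lambda`, `nfolds`),
#'   `spec_target`.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  known <- c("seed", "out_dir", "simulate", "quantify", "analyze")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$out_dir))
    stop("config field `out_dir` is required", call. = FALSE)
  defaults <- list(
    seed = 1L,
    simulate = list(
      phantoms = list(n = 2L, outer_radii = c(57, 72, 60), thickness_mm = 3,
                      density_hu = 800, spacing = c(0.5, 0.5, 1.5),
                      blur_fwhm = 0.8, noise_sd = 15),
      cohort = list(n_per_group = NULL,
                    noise_sd = c(thickness = 0.3, density = 80))
    ),
    quantify = list(hu_threshold = 150, n_locations = 2562L, resample = TRUE,
                    target_spacing = c(0.5, 0.5, 1.5), max_inplane_mm = 0.5,
                    max_slice_mm = 1.5),
    analyze = list(regions = study_regions(),
                   classifier = list(lambda = 1e-4, nfolds = 10L),
                   spec_target = 0.95)
  )
  cfg <- utils::modifyList(defaults, cfg)
  check_num <- function(x, field, len = 1, positive = FALSE) {
    if (!is.numeric(x) || length(x) != len || any(!is.finite(x)) ||
        (positive && any(x <= 0)))
      stop("invalid config field `", field, "`", call. = FALSE)
  }
  check_num(cfg$seed, "seed")
  check_num(cfg$simulate$phantoms$n, "simulate$phantoms$n")
  check_num(cfg$simulate$phantoms$spacing, "simulate$phantoms$spacing",
            len = 3, positive = TRUE)
  check_num(cfg$quantify$hu_threshold, "quantify$hu_threshold")
  check_num(cfg$quantify$n_locations, "quantify$n_locations", positive = TRUE)
  check_num(cfg$quantify$target_spacing, "quantify$target_spacing",
            len = 3, positive = TRUE)
  structure(cfg, class = "pipeline_config")
}

# Write a machine-readable run manifest next to a stage's outputs.
#' @keywords internal
write_manifest <- function(out_dir, stage, files, cfg) {
  files <- sort(files)
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("calvarisk")),
    config_hash = unname(tools::md5sum(write_temp_json(unclass(cfg)))),
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @keywords internal
write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  f
}

#' Simulation stage: phantoms and cohort
#'
#' Writes `n` skull phantoms (NRRD, raw encoding) with per-phantom analytic
#' ground-truth CSVs, a simulated cohort CSV, and a manifest listing every
#' written file with its MD5. Groups configured with a zero count are
#' absent from the cohort (with a warning).
#'
#' @param config A `pipeline_config` or path to one.
#' @return Invisibly, the list of written files.
#' @export
run_simulate <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- cfg$simulate$phantoms
  files <- character(0)
  for (i in seq_len(ph$n)) {
    spec <- phantom_spec(outer_radii = ph$outer_radii,
                         thickness_field = ph$thickness_mm,
                         density_field = ph$density_hu,
                         spacing = ph$spacing, blur_fwhm = ph$blur_fwhm,
                         noise_sd = ph$noise_sd,
                         rng_seed = cfg$seed * 1000L + i)
    out <- generate_skull_phantom(spec,
                                  n_locations = cfg$quantify$n_locations)
    vf <- sprintf("phantom_%03d.nrrd", i)
    tf <- sprintf("phantom_%03d_truth.csv", i)
    write_volume(out$volume, file.path(cfg$out_dir, vf))
    write.csv(out$truth, file.path(cfg$out_dir, tf), row.names = FALSE)
    files <- c(files, vf, tf)
  }
  co <- cfg$simulate$cohort
  npg <- if (is.null(co$n_per_group)) NULL else unlist(co$n_per_group)
  des_args <- list(rng_seed = cfg$seed)
  if (!is.null(npg)) des_args$n_per_group <- npg
  if (!is.null(co$noise_sd)) des_args$noise_sd <- unlist(co$noise_sd)
  design <- do.call(cohort_design, des_args)
  zero <- names(design$n_per_group)[design$n_per_group == 0]
  if (length(zero))
    warning("group(s) with zero count absent from cohort: ",
            paste(zero, collapse = ", "))
  cohort <- simulate_cohort(design)
  write.csv(cohort, file.path(cfg$out_dir, "cohort.csv"), row.names = FALSE)
  files <- c(files, "cohort.csv")
  write_manifest(cfg$out_dir, "simulate", files, cfg)
  invisible(files)
}

#' Quantification stage: maps and summaries for every phantom volume
#'
#' Reads every `phantom_*.nrrd` / `.nii(.gz)` under the output directory,
#' applies the resolution filter (excluded volumes are logged, not
#' processed), optionally resamples to the uniform grid, and computes
#' per-location maps and per-bone summaries for each kept volume.
#'
#' @param config A `pipeline_config` or path to one.
#' @return Invisibly, the summary data frame.
#' @export
run_quantify <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  q <- cfg$quantify
  vol_files <- sort(list.files(cfg$out_dir,
                               pattern = "^phantom_[0-9]+\\.(nrrd|nii|nii\\.gz)$"))
  if (!length(vol_files)) stop("no phantom volumes found in ", cfg$out_dir,
                               call. = FALSE)
  vols <- list(); readable <- character(0)
  for (f in vol_files) {
    v <- tryCatch(read_volume(file.path(cfg$out_dir, f)),
                  error = function(e) {
                    message("skipping unreadable volume ", f, ": ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(v)) { vols[[length(vols) + 1L]] <- v
                       readable <- c(readable, f) }
  }
  flt <- filter_by_resolution(vols, max_inplane = q$max_inplane_mm,
                              max_slice = q$max_slice_mm)
  excl <- data.frame(file = readable[setdiff(seq_along(vols), flt$kept_idx)],
                     reason = "resolution exclusion rule")
  write.csv(excl, file.path(cfg$out_dir, "exclusions.csv"), row.names = FALSE)
  summaries <- list(); files <- c("exclusions.csv")
  for (j in seq_along(flt$kept_idx)) {
    f <- readable[flt$kept_idx[j]]
    vol <- flt$kept[[j]]
    orig_voxvol <- voxel_volume(vol)
    if (isTRUE(q$resample)) vol <- resample_volume(vol, q$target_spacing)
    res <- quantify_volume(vol, hu_threshold = q$hu_threshold,
                           n_locations = q$n_locations)
    mf <- sub("\\.(nrrd|nii|nii\\.gz)$", "_maps.csv", f)
    write.csv(res$maps, file.path(cfg$out_dir, mf), row.names = FALSE)
    files <- c(files, mf)
    s <- res$summary
    row <- data.frame(file = f, original_voxel_volume = orig_voxvol)
    for (r in seq_len(nrow(s))) {
      row[[paste0("thickness_", s$region[r])]] <- s$thickness_mm[r]
      row[[paste0("density_", s$region[r])]] <- s$density_hu[r]
    }
    summaries[[j]] <- row
  }
  summary_df <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame()
  write.csv(summary_df, file.path(cfg$out_dir, "summaries.csv"),
            row.names = FALSE)
  files <- c(files, "summaries.csv")
  write_manifest(cfg$out_dir, "quantify", files, cfg)
  invisible(summary_df)
}

#' Analysis stage: contrasts, risk model, prevalence, correlations
#'
#' Reads the cohort table, fits the per-region covariate model, writes the
#' group-contrast report, trains the IIP classifier on normative + IIP
#' adjusted densities, scores the craniosynostosis groups, and writes the
#' prevalence table (both operating thresholds), the pairwise
#' Mann-Whitney/Bonferroni comparisons and the risk-age Spearman
#' correlation. With a normative-only cohort the comparative outputs are
#' skipped with a message instead of failing.
#'
#' @param config A `pipeline_config` or path to one.
#' @return Invisibly, a list of the main result tables.
#' @export
run_analyze <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  cohort_path <- file.path(cfg$out_dir, "cohort.csv")
  if (!file.exists(cohort_path))
    stop("cohort.csv not found in ", cfg$out_dir,
         "; run the simulate stage first", call. = FALSE)
  cohort <- read.csv(cohort_path)
  cohort$group <- factor(cohort$group, levels = study_groups())
  present <- levels(droplevels(cohort$group))
  files <- character(0)
  results <- list()
  if (length(present) < 2) {
    message("cohort contains a single group (", present,
            "); group contrasts and risk analysis skipped")
    write_manifest(cfg$out_dir, "analyze", files, cfg)
    return(invisible(results))
  }
  contrasts <- contrast_table(cohort, regions = cfg$analyze$regions)
  write.csv(contrasts, file.path(cfg$out_dir, "contrasts.csv"),
            row.names = FALSE)
  files <- c(files, "contrasts.csv")
  results$contrasts <- contrasts
  if (all(c("normative", "IIP") %in% present)) {
    groups_ind <- intersect(study_groups()[-1], present)
    feats <- adjusted_density_features(cohort,
                                       regions = cfg$analyze$regions,
                                       groups = groups_ind)
    ab <- cohort$group %in% c("normative", "IIP")
    model <- fit_iip_classifier(feats$features[ab, , drop = FALSE],
                                as.numeric(cohort$group[ab] == "IIP"),
                                lambda = cfg$analyze$classifier$lambda,
                                nfolds = cfg$analyze$classifier$nfolds,
                                seed = cfg$seed,
                                spec_target = cfg$analyze$spec_target)
    jsonlite::write_json(
      list(feature_names = model$feature_names,
           coefficients = as.list(model$coefficients),
           lambda = model$lambda, cv = model$cv,
           yi_threshold = model$yi_threshold,
           spec95_threshold = model$spec95_threshold),
      file.path(cfg$out_dir, "risk_model.json"), auto_unbox = TRUE,
      digits = NA)
    files <- c(files, "risk_model.json")
    cs_groups <- intersect(c("MC", "SC", "UCC", "BCC", "AS"), present)
    scored <- score_subjects(model, feats$features,
                             group = as.character(cohort$group))
    scored_cs <- scored[scored$group %in% c(cs_groups, "normative", "IIP"), ]
    prev <- rbind(
      cbind(threshold = "youden",
            estimate_prevalence(scored_cs, model$yi_threshold)),
      cbind(threshold = "spec95",
            estimate_prevalence(scored_cs, model$spec95_threshold))
    )
    write.csv(prev, file.path(cfg$out_dir, "prevalence.csv"),
              row.names = FALSE)
    files <- c(files, "prevalence.csv")
    results$model <- model
    results$prevalence <- prev
    if (length(cs_groups)) {
      pairs <- lapply(cs_groups, function(g) c(g, "normative"))
      cmp <- compare_risk_distributions(scored, pairs = pairs)
      write.csv(cmp, file.path(cfg$out_dir, "risk_comparisons.csv"),
                row.names = FALSE)
      files <- c(files, "risk_comparisons.csv")
      results$comparisons <- cmp
      cs <- scored$group %in% cs_groups
      ra <- correlate_risk_age(scored$risk[cs], cohort$age[cs])
      jsonlite::write_json(ra, file.path(cfg$out_dir, "risk_age.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, "risk_age.json")
      results$risk_age <- ra
    }
  } else {
    message("normative and IIP groups are both required for the risk ",
            "classifier; risk analysis skipped")
  }
  write_manifest(cfg$out_dir, "analyze", files, cfg)
  invisible(results)
}

#' Run all pipeline stages
#' @param config A `pipeline_config` or path to one.
#' @return Invisibly, the analysis results.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  run_simulate(cfg)
  run_quantify(cfg)
  invisible(run_analyze(cfg))
}
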