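#' Right-hemisphere atlas
#'
#' The half-lattice (`x >= shape_x/2`) label volume on the hemisphere grid,
#' used for cluster composition and cell/fiber partitioning of hemisphere
#' statistics.
#'
#' @param atlas full-grid `label_volume`.
#' @return `label_volume` on the right-hemisphere grid.
#' @export
hemisphere_atlas <- function(atlas) {
  g <- atlas$grid
  nx <- g$shape[1]
  hx <- (nx %/% 2 + 1):nx
  hgrid <- voxel_grid(c(length(hx), g$shape[2], g$shape[3]), g$spacing,
                      g$origin + c((hx[1] - 1) * g$spacing[1], 0, 0),
                      g$axis_order)
  label_volume(atlas$labels[hx, , , drop = FALSE], hgrid, atlas$regions)
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]. Defaults mirror the analysis parameters the pipeline
#' models: rolling-ball radius 20 px, smoothing sigma 0.05 mm, 18,000
#' permutations, gating alpha 0.05, minimum cluster size 100 voxels, and a
#' q grid from 0.05 down to 5e-5.
#'
#' @param outdir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param atlas list(shape, spacing).
#' @param cohort arguments forwarded to [cohort_spec()] (its `seed` is
#'   derived from the master seed).
#' @param preprocess list(rolling_ball_radius, smooth_sigma_mm).
#' @param voxelwise list(n_perm, alpha).
#' @param fdr list(q_grid, min_cluster, connectivity).
#' @param validate list(method, quantile, min_size, alpha).
#' @param write_volumes write per-sample NIfTI volumes? Default FALSE.
#' @param resume reuse cached simulated/preprocessed data found in
#'   `outdir`? Default FALSE.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            atlas = list(), cohort = list(),
                            preprocess = list(), voxelwise = list(),
                            fdr = list(), validate = list(),
                            write_volumes = FALSE, resume = FALSE) {
  merge_with <- function(defaults, given, path) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad))
      stop("config error at ", path, ": unknown field(s) ",
           paste(bad, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    atlas = merge_with(list(shape = c(64, 48, 48), spacing = 50),
                       atlas, "atlas"),
    cohort = cohort,  # validated by cohort_spec itself
    preprocess = merge_with(list(rolling_ball_radius = 20L,
                                 smooth_sigma_mm = 0.05),
                            preprocess, "preprocess"),
    voxelwise = merge_with(list(n_perm = 18000L, alpha = 0.05),
                           voxelwise, "voxelwise"),
    fdr = merge_with(list(q_grid = c(0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4, 5e-5),
                          min_cluster = 100L, connectivity = 26L),
                     fdr, "fdr"),
    validate = merge_with(list(method = "otsu", cell_threshold = NULL,
                               quantile = 0.97, min_size = 2L, alpha = 0.05),
                          validate, "validate"),
    write_volumes = isTRUE(write_volumes), resume = isTRUE(resume))
  class(cfg) <- "pipeline_config"
  cfg
}

#' The bundled smoke configuration
#'
#' A desk-scale end-to-end run: 32^3 toy atlas, 3 lesioned + 3 vehicle
#' samples, 200 permutations.
#'
#' @param outdir output directory.
#' @param seed master seed (default 42).
#' @return a `pipeline_config`.
#' @export
smoke_config <- function(outdir, seed = 42L) {
  pipeline_config(outdir, seed = seed,
                  atlas = list(shape = c(32, 32, 32)),
                  cohort = list(n_lesion = 3L, n_vehicle = 3L),
                  voxelwise = list(n_perm = 200L))
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j)
}

.config_hash <- function(cfg) {
  # hash the analysis-relevant configuration: where outputs land (and
  # whether caches are reused) does not change what is computed
  core <- unclass(cfg)
  core$outdir <- NULL
  core$resume <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> voxelwise -> FDR/clustering ->
#' validation -> report on a synthetic cohort, writing CSV tables, a report
#' JSON and a provenance JSON (config hash, seeds, file hashes, package
#' version) to `config$outdir`. Re-running with the same config reproduces
#' byte-identical outputs.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress per-stage progress messages?
#' @return invisibly, a result bundle: atlas, cohort, observation set,
#'   ANOVA and post hoc stat maps, per-contrast FDR results, validation
#'   tables and the report list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$outdir, "pipeline.log")
  cat("", file = logfile)
  say <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  t0 <- proc.time()[["elapsed"]]

  # --- simulate -------------------------------------------------------
  aspec <- toy_atlas_spec(shape = cfg$atlas$shape, spacing = cfg$atlas$spacing,
                          seed = cfg$seed)
  atlas <- make_toy_atlas(aspec)
  cohort <- do.call(cohort_spec, utils::modifyList(cfg$cohort,
                                                   list(seed = cfg$seed)))
  cache <- file.path(cfg$outdir, "cohort_cache.rds")
  if (cfg$resume && file.exists(cache)) {
    say("simulate: reusing cached cohort")
    cohort_data <- readRDS(cache)
  } else {
    cohort_data <- make_cohort(atlas, cohort)
    saveRDS(cohort_data, cache)
  }
  samples <- cohort_data$samples
  .write_table(cohort_data$manifest, file.path(cfg$outdir, "manifest.csv"))
  truth_counts <- do.call(rbind, lapply(samples, function(s)
    cbind(sample_id = s$sample_id, s$truth$counts)))
  .write_table(truth_counts, file.path(cfg$outdir, "truth_counts.csv"))
  write_region_table(atlas$regions, file.path(cfg$outdir, "regions.csv"))
  if (cfg$write_volumes) {
    vdir <- file.path(cfg$outdir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    write_nifti(atlas, file.path(vdir, "atlas.nii"))
    for (s in samples)
      write_nifti(s$volume, file.path(vdir, paste0(s$sample_id, ".nii")))
  }
  say("simulate: %d samples on a %s lattice [%.1fs]",
      length(samples), paste(cfg$atlas$shape, collapse = "x"),
      proc.time()[["elapsed"]] - t0)

  # --- preprocess -----------------------------------------------------
  # background subtraction in tissue space, downsampling into atlas space,
  # then smoothing (mirrors: subtract -> warp to atlas -> smooth)
  pre <- lapply(samples, function(s) {
    v <- rolling_ball_subtract(s$volume, cfg$preprocess$rolling_ball_radius)
    v <- resample(v, cohort$tissue_factor, "mean")
    gaussian_smooth(v, cfg$preprocess$smooth_sigma_mm)
  })
  names(pre) <- vapply(samples, `[[`, "", "sample_id")
  treatments <- vapply(samples, `[[`, "", "treatment")
  obs <- hemisphere_observations(pre, treatments, atlas)
  say("preprocess: %d in-mask hemisphere voxels [%.1fs]",
      length(obs$idx), proc.time()[["elapsed"]] - t0)

  # --- voxelwise ------------------------------------------------------
  np <- cfg$voxelwise$n_perm
  anova_pmaps <- list(
    side = permutation_pmap(obs, "F_side", np, seed = cfg$seed + 11L),
    treatment = permutation_pmap(obs, "F_treatment", np, seed = cfg$seed + 12L),
    interaction = permutation_pmap(obs, "F_interaction", np,
                                   seed = cfg$seed + 13L))
  posthoc <- posthoc_contrasts(obs, anova_pmaps, alpha = cfg$voxelwise$alpha,
                               n_perm = np, seed = cfg$seed + 20L)
  say("voxelwise: %d/%d/%d voxels p<%.2f (side/treatment/interaction) [%.1fs]",
      sum(anova_pmaps$side$p < cfg$voxelwise$alpha),
      sum(anova_pmaps$treatment$p < cfg$voxelwise$alpha),
      sum(anova_pmaps$interaction$p < cfg$voxelwise$alpha),
      cfg$voxelwise$alpha, proc.time()[["elapsed"]] - t0)

  # --- FDR / clustering ----------------------------------------------
  hatlas <- hemisphere_atlas(atlas)
  fdr_results <- list(); cluster_rows <- list(); comp_rows <- list()
  for (nm in names(posthoc)) {
    fr <- select_q(posthoc[[nm]], cfg$fdr$q_grid, cfg$fdr$min_cluster,
                   cfg$fdr$connectivity)
    if (!fr$no_signal)
      fr$clusters <- split_by_direction(fr$clusters, posthoc[[nm]],
                                        cfg$fdr$min_cluster,
                                        cfg$fdr$connectivity)
    fdr_results[[nm]] <- fr
    if (nrow(fr$clusters$table)) {
      tb <- fr$clusters$table
      tb$contrast <- nm
      cluster_rows[[nm]] <- tb
      cp <- cluster_composition(fr$clusters, hatlas)
      if (nrow(cp)) { cp$contrast <- nm; comp_rows[[nm]] <- cp }
    }
    say("fdr[%s]: q=%s, %d cluster(s)", nm,
        if (fr$no_signal) "none" else format(fr$q), nrow(fr$clusters$table))
    if (cfg$write_volumes) {
      vdir <- file.path(cfg$outdir, "volumes")
      dir.create(vdir, showWarnings = FALSE)
      write_stat_map(posthoc[[nm]], file.path(vdir, nm))
      if (!fr$no_signal) {
        cl_vol <- scalar_volume(array(as.numeric(fr$clusters$labels),
                                      dim(fr$clusters$labels)),
                                fr$clusters$grid)
        write_nifti(cl_vol, file.path(vdir, paste0(nm, "_clusters.nii")))
      }
    }
  }
  cluster_table <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
    data.frame()
  .write_table(cluster_table, file.path(cfg$outdir, "clusters.csv"))
  .write_table(if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(), file.path(cfg$outdir, "composition.csv"))

  # --- validation -----------------------------------------------------
  # soma threshold: calibrated stand-in for trained-classifier output,
  # midway between the simulated soma and fiber amplitudes (analogous to
  # training the paper's classifier on annotated samples)
  cell_thr <- cfg$validate$cell_threshold
  if (is.null(cell_thr))
    cell_thr <- (cohort$cell_amplitude + cohort$fiber_amplitude) / 2
  seg_par <- list(method = cfg$validate$method,
                  cell_threshold = cell_thr,
                  quantile = cfg$validate$quantile,
                  min_size = cfg$validate$min_size)
  dens_all <- list(); val_all <- list()
  for (nm in names(fdr_results)) {
    fr <- fdr_results[[nm]]
    if (fr$no_signal || nrow(fr$clusters$table) == 0) next
    vres <- validate_clusters(fr$clusters, nm, samples, atlas,
                              segment_params = seg_par,
                              alpha = cfg$validate$alpha)
    if (!is.null(vres$densities)) dens_all[[nm]] <- vres$densities
    if (!is.null(vres$validation)) val_all[[nm]] <- vres$validation
  }
  densities <- if (length(dens_all)) do.call(rbind, dens_all) else data.frame()
  validation <- if (length(val_all)) do.call(rbind, val_all) else data.frame()
  rownames(densities) <- rownames(validation) <- NULL
  .write_table(densities, file.path(cfg$outdir, "densities.csv"))
  .write_table(validation, file.path(cfg$outdir, "validation.csv"))
  say("validate: %d cluster-measure test(s), %d valid [%.1fs]",
      nrow(validation), if (nrow(validation)) sum(validation$valid) else 0L,
      proc.time()[["elapsed"]] - t0)

  # --- report / provenance -------------------------------------------
  report <- list(
    n_mask_voxels = length(obs$idx),
    n_perm = np,
    contrasts = lapply(names(fdr_results), function(nm) {
      fr <- fdr_results[[nm]]
      list(contrast = nm, no_signal = fr$no_signal,
           q = if (fr$no_signal) NULL else fr$q,
           p_threshold = fr$threshold, m = fr$m,
           n_significant = fr$n_significant,
           n_clusters = nrow(fr$clusters$table),
           n_valid = if (nrow(validation))
             sum(validation$valid[validation$contrast == nm]) else 0L)
    }))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tables <- c("manifest.csv", "truth_counts.csv", "clusters.csv",
              "composition.csv", "densities.csv", "validation.csv",
              "report.json")
  hashes <- as.list(tools::md5sum(file.path(cfg$outdir, tables)))
  names(hashes) <- tables
  provenance <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                     package_version = as.character(
                       utils::packageVersion("lesionmap")),
                     output_hashes = hashes)
  jsonlite::write_json(provenance, file.path(cfg$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = cfg, atlas = atlas, cohort_spec = cohort,
                 samples = samples, observations = obs,
                 anova_pmaps = anova_pmaps, posthoc = posthoc,
                 fdr = fdr_results, clusters = cluster_table,
                 densities = densities, validation = validation,
                 report = report, provenance = provenance))
}
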