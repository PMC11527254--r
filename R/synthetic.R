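#' Toy atlas specification
#'
#' Describes a bilateral ellipsoidal "brain" with mirror-symmetric labelled
#' regions, emulating the structure of a reference atlas: catecholaminergic
#' cell-group nuclei (SNpc/VTA/LC analogues), projection regions that carry
#' fibers, a ventricle-like excluded region, and a root label for brain
#' tissue belonging to no named region. Geometry is stated on a 64x48x48
#' lattice and scaled to `shape`. x is the left-right axis; the right
#' hemisphere (`x >= shape[1]/2`, 0-based) is ipsilateral to the simulated
#' infusion.
#'
#' @param shape integer length-3 lattice shape (default `c(64, 48, 48)`).
#' @param spacing atlas voxel spacing in um (default 50).
#' @param regions optional data.frame with columns `label_id`, `name`,
#'   `cell_group`, `excluded`, `cx`, `cy`, `cz`, `rx`, `ry`, `rz`,
#'   `bilateral` (centres/radii in voxels of `shape`); defaults to the
#'   bundled region set.
#' @param seed integer seed recorded with the spec.
#' @return object of class `toy_atlas_spec`.
#' @export
toy_atlas_spec <- function(shape = c(64, 48, 48), spacing = 50,
                           regions = NULL, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(regions)) {
    base <- data.frame(
      label_id = c(10L, 11L, 12L, 20L, 21L, 22L, 90L),
      name = c("snpc", "vta", "lc", "striatum", "cortex", "sum", "ventricle"),
      cell_group = c("dopaminergic", "dopaminergic", "noradrenergic",
                     "none", "none", "none", "none"),
      excluded = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
      cx = c(46, 35, 40, 44, 34, 35, 34),
      cy = c(16, 14, 8, 32, 38, 22, 24),
      cz = c(18, 21, 26, 24, 30, 14, 30),
      rx = c(7, 3, 3, 7, 5, 3, 2),
      ry = c(5, 3, 3, 6, 4, 3, 2),
      rz = c(5, 3, 3, 6, 4, 3, 4),
      bilateral = TRUE,
      stringsAsFactors = FALSE)
    sc <- shape / c(64, 48, 48)
    base$cx <- base$cx * sc[1]; base$rx <- base$rx * sc[1]
    base$cy <- base$cy * sc[2]; base$ry <- base$ry * sc[2]
    base$cz <- base$cz * sc[3]; base$rz <- base$rz * sc[3]
    regions <- base
  }
  structure(list(shape = shape, spacing = rep(as.numeric(spacing), 3)[1:3],
                 regions = regions, seed = as.integer(seed)),
            class = "toy_atlas_spec")
}

# logical array of voxels whose centre lies inside an ellipsoid
# (centre/radii in 0-based voxel index units)
.ellipsoid_mask <- function(shape, centre, radii) {
  x <- (seq_len(shape[1]) - 1 - centre[1]) / radii[1]
  y <- (seq_len(shape[2]) - 1 - centre[2]) / radii[2]
  z <- (seq_len(shape[3]) - 1 - centre[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Build a toy bilateral atlas
#'
#' Renders the brain ellipsoid and every region of the spec. Bilateral
#' regions are rendered on the right side and mirrored across the
#' mid-sagittal plane (`x -> shape[1]-1-x`), so mirror symmetry is exact by
#' construction. Voxels inside the brain but in no named region get the root
#' label 1. Overlapping region ellipsoids are a specification error.
#'
#' @param spec a `toy_atlas_spec`.
#' @return a `label_volume` whose `regions` table includes the root label.
#' @export
make_toy_atlas <- function(spec) {
  sh <- spec$shape
  brain <- .ellipsoid_mask(sh, (sh - 1) / 2,
                           c(0.47 * sh[1], 0.45 * sh[2], 0.45 * sh[3]))
  labels <- array(0L, sh)
  labels[brain] <- 1L
  rg <- spec$regions
  collisions <- character(0)
  for (i in seq_len(nrow(rg))) {
    m <- .ellipsoid_mask(sh, c(rg$cx[i], rg$cy[i], rg$cz[i]),
                         c(rg$rx[i], rg$ry[i], rg$rz[i]))
    if (isTRUE(rg$bilateral[i])) {
      ml <- .ellipsoid_mask(sh, c(sh[1] - 1 - rg$cx[i], rg$cy[i], rg$cz[i]),
                            c(rg$rx[i], rg$ry[i], rg$rz[i]))
      m <- m | ml
    }
    if (any(m & !brain))
      stop("region ", rg$name[i], " extends outside the brain mask")
    hit <- labels[m]
    clash <- unique(hit[hit > 1L])
    if (length(clash))
      collisions <- c(collisions, paste0(rg$name[i], " overlaps label(s) ",
                                         paste(clash, collapse = ",")))
    labels[m] <- rg$label_id[i]
  }
  if (length(collisions))
    stop("overlapping region ellipsoids: ", paste(collisions, collapse = "; "))
  regions <- region_table(
    label_id = c(1L, rg$label_id),
    name = c("root", rg$name),
    parent_id = c(NA_integer_, rep(1L, nrow(rg))),
    cell_group = c("none", rg$cell_group),
    excluded = c(FALSE, rg$excluded))
  label_volume(labels, voxel_grid(sh, spec$spacing), regions)
}

#' Cohort specification for the synthetic 6-OHDA model
#'
#' States the simulated world: group sizes (default 10 lesioned vs 8
#' vehicle, matching the imaging cohort the pipeline targets), per-nucleus
#' TH+ soma densities and neuropil fills, per-projection-region fiber
#' fills, the unilateral lesion effect factors (cell loss concentrated in
#' the SNpc analogue ipsilaterally; bilateral fiber loss, stronger
#' ipsilaterally), a focal compensatory fiber increase, and imaging noise.
#' Samples are rendered in tissue space, `tissue_factor` times finer than
#' the atlas lattice (default 2x, i.e. 25 um for the default atlas), where
#' somata are compact bright blobs and fibers/neuropil are 1-voxel-wide
#' curvilinear paths. Defaults are chosen once for the toy world (see the
#' methods vignette) and are not tuned.
#'
#' @param n_lesion,n_vehicle samples per group (both >= 2).
#' @param cell_density named vector, somata/mm^3 per cell-group region.
#' @param neuropil_fill named vector in `[0,1]`: dendritic/axonal fill
#'   inside each cell-group region, scaled by that region's *cell* effect
#'   factor (neuropil tracks cell loss).
#' @param fiber_fill named vector in `[0,1]`, fraction of projection-region
#'   voxels carrying fibers.
#' @param projection_map named list: cell-group source region -> projection
#'   target region(s).
#' @param lesion_effects data.frame(region, side, measure, factor) of
#'   multiplicative lesion effects (side in "ipsi"/"contra", measure in
#'   "cell"/"fiber"); applied to lesion-treated samples only.
#' @param compensation_effects same shape; factors > 1 for focal fiber
#'   increases, applied after (overriding) `lesion_effects`.
#' @param cell_amplitude,fiber_amplitude rendered intensities (a.u.);
#'   somata are brighter than neuropil/fibers, as in TH immunofluorescence.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param background_amplitude smooth low-frequency background scale (a.u.).
#' @param cell_radius soma radius in um (default 22): somata are uniform
#'   bright spheres, so every soma owns at least one full-amplitude voxel
#'   on the default tissue lattice and detection does not depend on
#'   sub-voxel position.
#' @param tissue_factor integer upsampling of the atlas lattice for tissue
#'   space (default 2).
#' @param seed cohort seed; per-sample seeds derive from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lesion = 10L, n_vehicle = 8L,
                        cell_density = c(snpc = 350, vta = 350, lc = 300),
                        neuropil_fill = c(snpc = 0.5, vta = 0.5, lc = 0.5),
                        fiber_fill = c(striatum = 0.6, cortex = 0.35, sum = 0.3),
                        projection_map = list(snpc = "striatum", vta = "sum",
                                              lc = "cortex"),
                        lesion_effects = NULL,
                        compensation_effects = NULL,
                        cell_amplitude = 150, fiber_amplitude = 60,
                        noise_sd = 5, background_amplitude = 10,
                        cell_radius = 22, tissue_factor = 2L, seed = 1L) {
  if (is.null(lesion_effects)) {
    lesion_effects <- data.frame(
      region = c("snpc", "vta", "striatum", "striatum", "cortex", "cortex"),
      side = c("ipsi", "ipsi", "ipsi", "contra", "ipsi", "contra"),
      measure = c("cell", "cell", "fiber", "fiber", "fiber", "fiber"),
      factor = c(0.5, 0.8, 0.5, 0.8, 0.5, 0.8),
      stringsAsFactors = FALSE)
  }
  if (is.null(compensation_effects)) {
    compensation_effects <- data.frame(
      region = "sum", side = "ipsi", measure = "fiber", factor = 1.5,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(cell_density >= 0),
            all(neuropil_fill >= 0 & neuropil_fill <= 1),
            all(fiber_fill >= 0 & fiber_fill <= 1))
  if (nrow(lesion_effects) && any(lesion_effects$factor < 0))
    stop("effect factors must be >= 0")
  structure(list(n_lesion = as.integer(n_lesion),
                 n_vehicle = as.integer(n_vehicle),
                 cell_density = cell_density, neuropil_fill = neuropil_fill,
                 fiber_fill = fiber_fill,
                 projection_map = projection_map,
                 lesion_effects = lesion_effects,
                 compensation_effects = compensation_effects,
                 cell_amplitude = cell_amplitude,
                 fiber_amplitude = fiber_amplitude,
                 noise_sd = noise_sd,
                 background_amplitude = background_amplitude,
                 cell_radius = cell_radius,
                 tissue_factor = as.integer(tissue_factor),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# side of each voxel (x >= nx/2 is "ipsi" = right hemisphere)
.side_array <- function(shape) {
  x <- rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3])
  array(ifelse(x >= shape[1] / 2, "ipsi", "contra"), shape)
}

# resolved multiplicative effect for (region, side, measure)
.effect_factor <- function(cohort, treatment, region, side, measure) {
  if (treatment != "lesion") return(1)
  f <- 1
  le <- cohort$lesion_effects
  hit <- le$region == region & le$side == side & le$measure == measure
  if (any(hit)) f <- le$factor[which(hit)[1]]
  ce <- cohort$compensation_effects
  hit <- ce$region == region & ce$side == side & ce$measure == measure
  if (any(hit)) f <- ce$factor[which(hit)[1]]
  f
}

# paint a uniform sphere (soma) at a continuous 0-based index position:
# voxels whose centre lies within `radius` take at least `amplitude`
.render_soma <- function(vol, pos, radius, amplitude) {
  sh <- dim(vol)
  r <- ceiling(radius)
  lo <- pmax(floor(pos) - r, 0); hi <- pmin(ceiling(pos) + r, sh - 1)
  xi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; zi <- lo[3]:hi[3]
  d2 <- outer(outer((xi - pos[1])^2, (yi - pos[2])^2, `+`), (zi - pos[3])^2, `+`)
  inside <- d2 <= radius^2
  if (!any(inside)) {  # radius below half a voxel: mark the nearest voxel
    nv <- pmin(pmax(round(pos), 0), sh - 1)
    vol[nv[1] + 1, nv[2] + 1, nv[3] + 1] <-
      pmax(vol[nv[1] + 1, nv[2] + 1, nv[3] + 1], amplitude)
    return(vol)
  }
  sub <- vol[xi + 1, yi + 1, zi + 1]
  sub[inside] <- pmax(sub[inside], amplitude)
  vol[xi + 1, yi + 1, zi + 1] <- sub
  vol
}

# smooth low-frequency background: coarse N(0,1) lattice upsampled trilinearly
.render_background <- function(shape, amplitude) {
  if (amplitude == 0) return(array(0, shape))
  coarse_sh <- pmax(as.integer(ceiling(shape / 8)), 2L)
  coarse <- array(stats::rnorm(prod(coarse_sh)), coarse_sh)
  f <- (coarse_sh - 1) / pmax(shape - 1, 1)
  up <- affine_resample_cpp(as.numeric(coarse), coarse_sh,
                            as.numeric(diag(f)), c(0, 0, 0),
                            as.integer(shape), 0L)
  amplitude * array(up, shape)
}

# grow fibers inside `tgt_mask` from `src_idx` until round(fill * |tgt|)
# target voxels are marked; wrapper over the C++ walker
.grow_fibers <- function(fiber, src_idx, tgt_mask, brain, fill,
                         persistence = 0.8) {
  budget <- round(fill * sum(tgt_mask))
  if (budget <= 0 || length(src_idx) == 0) return(fiber)
  sh <- dim(fiber)
  tc <- colMeans(arrayInd(which(tgt_mask), sh))
  out <- fiber_walk_cpp(as.logical(fiber), sh, as.integer(src_idx),
                        as.logical(tgt_mask), as.logical(brain),
                        as.integer(budget), persistence, 6000L, 400L, tc)
  array(out, sh)
}

#' Simulate one TH-immunofluorescence sample
#'
#' Renders a synthetic whole-brain volume in tissue space (the atlas
#' lattice upsampled by `cohort$tissue_factor`): Poisson-placed TH+ somata
#' as compact bright Gaussian blobs inside cell-group nuclei, dense
#' neuropil grown inside each nucleus (its fill scaled by the nucleus's
#' cell effect factor), curvilinear fibers grown from each nucleus into its
#' projection regions up to a target fill, a smooth random background, and
#' additive Gaussian noise. Ground truth (cell centres, per region/side
#' counts, signal masks, applied factors) is recorded before noise.
#'
#' @param atlas a toy `label_volume`.
#' @param cohort a `cohort_spec`.
#' @param treatment `"lesion"` or `"vehicle"`.
#' @param sample_seed integer seed for this sample.
#' @return list with `volume` (`scalar_volume` in tissue space) and
#'   `truth` (cells, counts, fibers, cell_mask, fiber_mask, truth_mask,
#'   applied factors, warnings).
#' @export
simulate_sample <- function(atlas, cohort, treatment = c("lesion", "vehicle"),
                            sample_seed = 1L) {
  treatment <- match.arg(treatment)
  set.seed(sample_seed)
  f <- cohort$tissue_factor
  tg <- voxel_grid(atlas$grid$shape * f, atlas$grid$spacing / f,
                   atlas$grid$origin, atlas$grid$axis_order)
  tl <- if (f == 1L) atlas else
    apply_affine(atlas, affine_transform(from = "atlas", to = "atlas"),
                 tg, mode = "nearest")
  labels <- tl$labels
  sh <- dim(labels)
  brain <- labels > 0L
  side <- .side_array(sh)
  radius_vox <- max(cohort$cell_radius / tg$spacing[1], 0.875)
  vox_mm3 <- voxel_volume_mm3(tg)
  cellrender <- array(0, sh)
  cells <- list()
  counts <- list()
  warnings <- character(0)

  for (rn in names(cohort$cell_density)) {
    lid <- atlas$regions$label_id[match(rn, atlas$regions$name)]
    if (is.na(lid)) stop("cohort references unknown region: ", rn)
    for (sd_ in c("ipsi", "contra")) {
      idx <- which(labels == lid & side == sd_)
      vol_mm3 <- length(idx) * vox_mm3
      fac <- .effect_factor(cohort, treatment, rn, sd_, "cell")
      lambda <- cohort$cell_density[[rn]] * vol_mm3 * fac
      n <- stats::rpois(1, lambda)
      if (n > 0) {
        at <- arrayInd(sample(idx, n, replace = TRUE), sh)
        at <- at - 1 + matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
        for (k in seq_len(n))
          cellrender <- .render_soma(cellrender, at[k, ], radius_vox,
                                     cohort$cell_amplitude)
        cells[[length(cells) + 1]] <-
          data.frame(x = at[, 1], y = at[, 2], z = at[, 3],
                     region = rn, side = sd_)
      }
      counts[[length(counts) + 1]] <-
        data.frame(region = rn, side = sd_, measure = "cell",
                   true_count = n, factor = fac,
                   true_density = if (vol_mm3 > 0) n / vol_mm3 else 0)
    }
  }

  fibermask <- array(FALSE, sh)
  fiberfill <- list()
  render_fill <- function(src_name, tgt_name, base_fill, measure_factor_of) {
    src_lid <- atlas$regions$label_id[match(src_name, atlas$regions$name)]
    tgt_lid <- atlas$regions$label_id[match(tgt_name, atlas$regions$name)]
    if (is.na(src_lid) || is.na(tgt_lid))
      stop("fiber spec references unknown region")
    for (sd_ in c("ipsi", "contra")) {
      fac <- measure_factor_of(sd_)
      fill <- base_fill * fac
      if (fill > 1) {
        fill <- 1
        warnings <<- c(warnings,
                       paste0("fill clipped to 1 for ", tgt_name, "/", sd_))
      }
      tgt_mask <- labels == tgt_lid & side == sd_
      src_idx <- which(labels == src_lid & side == sd_)
      fibermask <<- .grow_fibers(fibermask, src_idx, tgt_mask, brain, fill)
      fiberfill[[length(fiberfill) + 1]] <<-
        data.frame(region = tgt_name, side = sd_, measure = "fiber",
                   target_fill = fill, factor = fac,
                   realized_fill = sum(fibermask & tgt_mask) /
                     max(sum(tgt_mask), 1))
    }
  }
  # neuropil inside each nucleus, tracking the cell effect factor
  for (rn in names(cohort$neuropil_fill))
    render_fill(rn, rn, cohort$neuropil_fill[[rn]],
                function(sd_) .effect_factor(cohort, treatment, rn, sd_, "cell"))
  # long-range fibers into projection regions
  for (src in names(cohort$projection_map))
    for (tgt in cohort$projection_map[[src]]) {
      base_fill <- cohort$fiber_fill[[tgt]]
      if (is.null(base_fill)) base_fill <- 0
      render_fill(src, tgt, base_fill,
                  function(sd_) .effect_factor(cohort, treatment, tgt, sd_,
                                               "fiber"))
    }

  # noiseless signal and its ground truth: fibers/neuropil at
  # fiber_amplitude, somata (brighter) on top; one threshold at half the
  # weakest rendered amplitude classifies a voxel as TH+ signal
  signal <- cellrender + cohort$fiber_amplitude * fibermask
  thr <- if (cohort$fiber_amplitude > 0) cohort$fiber_amplitude / 2 else
    cohort$cell_amplitude / 2
  cellmask <- cellrender >= cohort$cell_amplitude / 2
  truth_mask <- signal >= thr
  vol <- signal + .render_background(sh, cohort$background_amplitude) * brain
  vol <- vol + array(stats::rnorm(prod(sh), 0, cohort$noise_sd), sh) * brain

  truth <- list(
    cells = if (length(cells)) do.call(rbind, cells) else
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 region = character(0), side = character(0)),
    counts = do.call(rbind, counts),
    fibers = if (length(fiberfill)) do.call(rbind, fiberfill) else NULL,
    cell_mask = cellmask, fiber_mask = fibermask, truth_mask = truth_mask,
    treatment = treatment, sample_seed = sample_seed, warnings = warnings)
  list(volume = scalar_volume(vol, tg), truth = truth)
}

#' Simulate a full cohort
#'
#' Per-sample seeds are derived deterministically from the cohort seed, so
#' identical specs reproduce bit-identical cohorts.
#'
#' @param atlas a toy `label_volume`.
#' @param cohort a `cohort_spec` with `n_lesion, n_vehicle >= 2`.
#' @return list with `samples` (each: sample_id, treatment, seed, volume,
#'   truth) and a `manifest` data.frame (sample_id, treatment, seed).
#' @export
make_cohort <- function(atlas, cohort) {
  if (cohort$n_lesion < 2L || cohort$n_vehicle < 2L)
    stop("need at least 2 samples per group")
  treatments <- c(rep("lesion", cohort$n_lesion),
                  rep("vehicle", cohort$n_vehicle))
  samples <- vector("list", length(treatments))
  for (i in seq_along(treatments)) {
    seed_i <- as.integer((as.double(cohort$seed) + 104729 * i) %% 2147483647)
    s <- simulate_sample(atlas, cohort, treatments[i], seed_i)
    samples[[i]] <- list(sample_id = sprintf("%s_%02d", treatments[i], i),
                         treatment = treatments[i], seed = seed_i,
                         volume = s$volume, truth = s$truth)
  }
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    treatment = treatments,
    seed = vapply(samples, function(s) s$seed, 1L),
    stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest)
}
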