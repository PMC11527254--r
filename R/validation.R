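#' Partition a cluster into cell and fiber parts
#'
#' Cell densities are measured where the cluster overlaps regions carrying
#' dopaminergic or noradrenergic somata; fiber densities in the remainder.
#' The two parts are disjoint and cover the cluster.
#'
#' @param cluster_mask logical array.
#' @param cellgroup_mask logical array, union of cell-group regions.
#' @return list with logical arrays `cell` and `fiber`.
#' @export
partition_cluster <- function(cluster_mask, cellgroup_mask) {
  if (!identical(dim(cluster_mask), dim(cellgroup_mask)))
    stop("cluster and cell-group masks do not match")
  list(cell = cluster_mask & cellgroup_mask,
       fiber = cluster_mask & !cellgroup_mask)
}

#' Mask of all cell-group regions
#'
#' @param atlas a `label_volume`.
#' @return logical array, TRUE in regions flagged dopaminergic or
#'   noradrenergic.
#' @export
cellgroup_mask <- function(atlas) {
  ids <- atlas$regions$label_id[atlas$regions$cell_group %in%
                                  c("dopaminergic", "noradrenergic")]
  array(atlas$labels %in% ids, dim(atlas$labels))
}

#' Warp a cluster mask to tissue space
#'
#' Nearest-neighbour resampling of a binary atlas-space mask onto the
#' full-resolution tissue grid, where density measurements are made.
#'
#' @param cluster_mask logical array on `atlas_grid`.
#' @param atlas_grid the `voxel_grid` the mask lives on.
#' @param t an `affine_transform` from atlas space to tissue space.
#' @param tissue_grid the target `voxel_grid`.
#' @return list with `mask` (logical array on `tissue_grid`) and
#'   `volume_mm3`.
#' @export
warp_cluster <- function(cluster_mask, atlas_grid, t, tissue_grid) {
  vol <- scalar_volume(array(as.numeric(cluster_mask), dim(cluster_mask)),
                       atlas_grid)
  warped <- apply_affine(vol, t, tissue_grid, mode = "nearest")
  m <- warped$values != 0
  list(mask = m, volume_mm3 = sum(m) * voxel_volume_mm3(tissue_grid))
}

#' Segment TH+ signal
#'
#' Deterministic stand-in for interactive classifier output: global
#' quantile or Otsu thresholding followed by minimum-object-size speck
#' removal (26-connectivity). An `external_mask` path accepts classifier
#' output produced elsewhere.
#'
#' @param raw a `scalar_volume` (raw immunofluorescence).
#' @param method `"otsu"` (threshold between background and signal),
#'   `"otsu_upper"` (the upper level of a two-step Otsu, separating the
#'   brightest class - somata - from dimmer neuropil/fibers; unreliable
#'   when the bright class is a tiny fraction of the signal),
#'   `"absolute"` (a fixed intensity threshold, the calibrated stand-in
#'   for trained-classifier soma output), `"quantile_threshold"` or
#'   `"external_mask"`.
#' @param quantile for `quantile_threshold`: the intensity quantile (in
#'   (0,1)) computed over `roi` voxels; default 0.97.
#' @param roi optional logical array restricting the threshold estimation
#'   (e.g. the brain mask); the threshold is applied everywhere.
#' @param min_size objects smaller than this many voxels are removed.
#' @param external binary array for `external_mask`.
#' @return logical segmentation array.
#' @export
segment_signal <- function(raw, method = c("otsu", "otsu_upper", "absolute",
                                           "quantile_threshold",
                                           "external_mask"),
                           quantile = 0.97, threshold = NULL, roi = NULL,
                           min_size = 2L, external = NULL) {
  method <- match.arg(method)
  if (method == "external_mask") {
    if (is.null(external)) stop("external_mask requires `external`")
    seg <- array(as.logical(external), dim(raw$values))
  } else {
    vals <- if (is.null(roi)) as.vector(raw$values) else raw$values[roi]
    thr <- switch(method,
      quantile_threshold = {
        if (!(quantile > 0 && quantile < 1)) stop("quantile must be in (0, 1)")
        stats::quantile(vals, quantile, names = FALSE)
      },
      absolute = {
        if (is.null(threshold)) stop("absolute method requires `threshold`")
        threshold
      },
      otsu = .otsu_threshold(vals),
      otsu_upper = {
        t1 <- .otsu_threshold(vals)
        hi <- vals[vals > t1]
        if (length(hi) > 1 && diff(range(hi)) > 0) .otsu_threshold(hi) else t1
      })
    seg <- raw$values > thr
  }
  if (min_size > 1L && any(seg)) {
    cc <- label_clusters(seg, 26L)
    small <- which(cc$sizes < min_size)
    if (length(small)) seg[cc$labels %in% small] <- FALSE
  }
  seg
}

.otsu_threshold <- function(vals, n_bins = 256L) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  h <- as.numeric(tabulate(findInterval(vals, seq(rng[1], rng[2],
                                                  length.out = n_bins + 1L),
                                        all.inside = TRUE), n_bins))
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-1] - diff(rng) / (2 * n_bins)
  w <- cumsum(h); mu <- cumsum(h * mids)
  tot_w <- w[n_bins]; tot_mu <- mu[n_bins]
  between <- (tot_mu * w - tot_w * mu)^2 / (w * (tot_w - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Count cells inside a cluster
#'
#' Counts 26-connected components of the segmentation whose centroid lies
#' inside the cluster mask (centroid membership avoids double counting of
#' objects straddling the cell/fiber partition boundary), and converts to
#' cells/mm^3 using the cluster volume.
#'
#' @param segmentation logical array.
#' @param cluster_mask logical array on the same lattice (non-empty).
#' @param spacing voxel spacing in um (length 3).
#' @return list with `count` and `density` (cells/mm^3).
#' @export
count_cells <- function(segmentation, cluster_mask, spacing) {
  n_cluster <- sum(cluster_mask)
  if (n_cluster == 0) stop("undefined density: empty cluster mask")
  cc <- label_clusters(segmentation, 26L)
  count <- 0L
  k <- length(cc$sizes)
  if (k > 0L) {
    pos <- which(cc$labels > 0L)
    ind <- arrayInd(pos, dim(segmentation))
    lab <- cc$labels[pos]
    cx <- round(rowsum(ind[, 1], lab) / cc$sizes[sort(unique(lab))])
    cy <- round(rowsum(ind[, 2], lab) / cc$sizes[sort(unique(lab))])
    cz <- round(rowsum(ind[, 3], lab) / cc$sizes[sort(unique(lab))])
    sh <- dim(segmentation)
    cx <- pmin(pmax(cx, 1), sh[1]); cy <- pmin(pmax(cy, 1), sh[2])
    cz <- pmin(pmax(cz, 1), sh[3])
    inside <- cluster_mask[cbind(cx, cy, cz)]
    count <- sum(inside)
  }
  vol_mm3 <- n_cluster * prod(spacing) / 1e9
  list(count = as.integer(count), density = count / vol_mm3)
}

#' Fiber density within a cluster
#'
#' `100 * |segmentation AND cluster| / |cluster|`, in percent.
#'
#' @param segmentation logical array.
#' @param cluster_mask non-empty logical array on the same lattice.
#' @return percent of cluster voxels segmented as fibers.
#' @export
fiber_density <- function(segmentation, cluster_mask) {
  n <- sum(cluster_mask)
  if (n == 0) stop("undefined density: empty cluster mask")
  100 * sum(segmentation & cluster_mask) / n
}

#' Validate a cluster with an unpaired two-tailed t-test
#'
#' A cluster is valid if the per-sample density values differ between the
#' two comparison groups (hemispheres or treatments) at `alpha`,
#' two-tailed, using the pooled-variance t statistic with
#' `n_A + n_B - 2` degrees of freedom.
#'
#' @param values_A,values_B numeric density values (>= 2 each).
#' @param alpha significance level (default 0.05).
#' @return list: `t`, `df`, `p`, `valid`, `direction` ("+" if A > B),
#'   `n_A`, `n_B`.
#' @export
validate_cluster <- function(values_A, values_B, alpha = 0.05) {
  n1 <- length(values_A); n2 <- length(values_B)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group")
  m1 <- mean(values_A); m2 <- mean(values_B)
  df <- n1 + n2 - 2L
  sp2 <- (sum((values_A - m1)^2) + sum((values_B - m2)^2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se > 0) (m1 - m2) / se else if (m1 == m2) 0 else Inf * sign(m1 - m2)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, valid = is.finite(p) && p < alpha,
       direction = if (m1 >= m2) "+" else "-", n_A = n1, n_B = n2)
}

#' Region-wise 3D cell counting
#'
#' Counts segmented components per atlas region (component centroid rule)
#' and reports per-region volume and density, mirroring warping the atlas
#' to tissue space and multiplying it with the binary cell segmentation.
#'
#' @param atlas a `label_volume` in tissue space.
#' @param segmentation logical array on the atlas lattice.
#' @return data.frame: label_id, name, n_cells, volume_mm3, density.
#' @export
regionwise_densities <- function(atlas, segmentation) {
  sh <- dim(atlas$labels)
  if (!identical(sh, dim(segmentation))) stop("grids do not match")
  cc <- label_clusters(segmentation, 26L)
  region_count <- integer(nrow(atlas$regions))
  if (length(cc$sizes)) {
    pos <- which(cc$labels > 0L)
    ind <- arrayInd(pos, sh)
    lab <- cc$labels[pos]
    ids <- sort(unique(lab))
    cx <- pmin(pmax(round(rowsum(ind[, 1], lab) / cc$sizes[ids]), 1), sh[1])
    cy <- pmin(pmax(round(rowsum(ind[, 2], lab) / cc$sizes[ids]), 1), sh[2])
    cz <- pmin(pmax(round(rowsum(ind[, 3], lab) / cc$sizes[ids]), 1), sh[3])
    centroid_label <- atlas$labels[cbind(cx, cy, cz)]
    tb <- table(centroid_label)
    hit <- match(atlas$regions$label_id, as.integer(names(tb)))
    region_count <- ifelse(is.na(hit), 0L, as.integer(tb)[hit])
  }
  vols <- vapply(atlas$regions$label_id,
                 function(id) sum(atlas$labels == id), 1L) *
    voxel_volume_mm3(atlas$grid)
  data.frame(label_id = atlas$regions$label_id, name = atlas$regions$name,
             n_cells = region_count, volume_mm3 = vols,
             density = ifelse(vols > 0, region_count / vols, 0))
}

#' One-way ANOVA with Tukey HSD post-tests on region densities
#'
#' @param values numeric density values.
#' @param groups group labels (>= 2 groups, >= 2 samples each).
#' @return list: `F`, `p`, and `pairs` data.frame (group1, group2, diff,
#'   p_adj from the studentized-range distribution).
#' @export
region_anova_tukey <- function(values, groups) {
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  groups <- factor(groups)
  if (nlevels(groups) < 2L || min(table(groups)) < 2L)
    stop("need >= 2 groups with >= 2 samples each")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- data.frame(
    group1 = sub("-.*$", "", rownames(tk)),
    group2 = sub("^[^-]*-", "", rownames(tk)),
    diff = tk[, "diff"], p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], pairs = pairs)
}

#' Measure and validate every cluster of a contrast
#'
#' For each cluster: build ipsilateral and mirrored contralateral full-brain
#' masks from the hemisphere cluster, warp them to tissue space, partition
#' into cell and fiber parts, measure per-sample cell and fiber densities in
#' the raw volumes, and run the contrast's unpaired two-tailed t-test. A
#' cluster is valid if any of its parts shows a significant difference.
#'
#' @param clusters a `cluster_set` on the hemisphere grid.
#' @param contrast one of the four post hoc contrast names.
#' @param samples list of samples (`sample_id`, `treatment`, `volume`) with
#'   raw volumes on the full atlas grid.
#' @param atlas full-grid `label_volume`.
#' @param t_atlas_tissue affine transform atlas -> tissue space (identity
#'   for synthetic data).
#' @param tissue_grid `voxel_grid` for density measurements.
#' @param segment_params list: `method` (fiber/overall segmentation,
#'   default `"otsu"`), `cell_method` (soma segmentation, default
#'   `"otsu_upper"`), `quantile`, `min_size`; see [segment_signal()].
#' @param alpha validity level (default 0.05).
#' @return list with `densities` (per sample x cluster x measure records)
#'   and `validation` (per cluster x measure t-test results).
#' @export
validate_clusters <- function(clusters, contrast, samples, atlas,
                              t_atlas_tissue = NULL, tissue_grid = NULL,
                              segment_params = list(), alpha = 0.05) {
  g <- atlas$grid
  nx <- g$shape[1]
  hx0 <- nx %/% 2                       # 0-based first right-half index
  if (is.null(t_atlas_tissue))
    t_atlas_tissue <- affine_transform(from = "atlas", to = "tissue")
  if (is.null(tissue_grid)) tissue_grid <- samples[[1]]$volume$grid
  sp <- utils::modifyList(list(method = "otsu", cell_method = "otsu_upper",
                               cell_threshold = NULL, quantile = 0.97,
                               min_size = 2L),
                          segment_params)
  if (!is.null(sp$cell_threshold)) sp$cell_method <- "absolute"
  # atlas warped to tissue space: ROI for thresholding and the cell-group
  # partition mask
  atlas_t <- apply_affine(atlas, t_atlas_tissue, tissue_grid, "nearest")
  roi_t <- atlas_t$labels > 0L
  cg_t <- cellgroup_mask(atlas_t)

  # per-sample segmentations of the raw tissue-space volumes, cached across
  # clusters: an overall signal mask for fiber densities and a soma mask
  # whose component centroids are precomputed for counting
  seg_fiber <- lapply(samples, function(s)
    segment_signal(s$volume, sp$method, quantile = sp$quantile, roi = roi_t,
                   min_size = sp$min_size))
  cell_centroids <- lapply(samples, function(s) {
    seg <- segment_signal(s$volume, sp$cell_method, quantile = sp$quantile,
                          threshold = sp$cell_threshold, roi = roi_t,
                          min_size = 1L)
    cc <- label_clusters(seg, 26L)
    if (!length(cc$sizes)) return(matrix(0L, 0, 3))
    pos <- which(cc$labels > 0L)
    ind <- arrayInd(pos, dim(seg))
    lab <- cc$labels[pos]
    sizes <- cc$sizes[sort(unique(lab))]
    sh <- dim(seg)
    cbind(pmin(pmax(round(rowsum(ind[, 1], lab) / sizes), 1), sh[1]),
          pmin(pmax(round(rowsum(ind[, 2], lab) / sizes), 1), sh[2]),
          pmin(pmax(round(rowsum(ind[, 3], lab) / sizes), 1), sh[3]))
  })
  treatments <- vapply(samples, `[[`, "", "treatment")
  ids <- vapply(samples, `[[`, "", "sample_id")

  dens_rows <- list(); val_rows <- list()
  for (ci in seq_len(nrow(clusters$table))) {
    id <- clusters$table$cluster_id[ci]
    hm <- clusters$labels == id
    # embed hemisphere mask into the full grid (ipsi = right half) and
    # mirror it for the contralateral side
    ipsi_full <- array(FALSE, g$shape)
    ipsi_full[(hx0 + 1):nx, , ] <- hm
    contra_full <- ipsi_full[rev(seq_len(nx)), , , drop = FALSE]
    side_masks <- list(ipsi = ipsi_full, contra = contra_full)

    this_cluster <- list()
    for (sd_ in names(side_masks)) {
      w <- warp_cluster(side_masks[[sd_]], g, t_atlas_tissue, tissue_grid)
      part <- partition_cluster(w$mask, cg_t)
      vox_mm3 <- voxel_volume_mm3(tissue_grid)
      for (i in seq_along(samples)) {
        if (any(part$cell)) {
          cen <- cell_centroids[[i]]
          n_in <- if (nrow(cen)) sum(part$cell[cen]) else 0L
          this_cluster[[length(this_cluster) + 1]] <- data.frame(
            sample_id = ids[i], cluster_id = id, contrast = contrast,
            measure = "cell_density", side = sd_, treatment = treatments[i],
            value = n_in / (sum(part$cell) * vox_mm3),
            volume_mm3 = sum(part$cell) * vox_mm3)
        }
        if (any(part$fiber)) {
          fd <- fiber_density(seg_fiber[[i]], part$fiber)
          this_cluster[[length(this_cluster) + 1]] <- data.frame(
            sample_id = ids[i], cluster_id = id, contrast = contrast,
            measure = "fiber_density", side = sd_, treatment = treatments[i],
            value = fd,
            volume_mm3 = sum(part$fiber) * vox_mm3)
        }
      }
    }
    if (!length(this_cluster)) next
    dens <- do.call(rbind, this_cluster)
    dens_rows[[length(dens_rows) + 1]] <- dens
    for (meas in unique(dens$measure)) {
      dm <- dens[dens$measure == meas, ]
      grp <- .contrast_groups(dm, contrast)
      if (is.null(grp)) next
      vt <- validate_cluster(grp$A, grp$B, alpha)
      val_rows[[length(val_rows) + 1]] <- data.frame(
        cluster_id = id, contrast = contrast, measure = meas,
        t = vt$t, df = vt$df, p = vt$p, valid = vt$valid,
        direction = vt$direction, n_A = vt$n_A, n_B = vt$n_B)
    }
  }
  list(densities = if (length(dens_rows)) do.call(rbind, dens_rows) else NULL,
       validation = if (length(val_rows)) do.call(rbind, val_rows) else NULL)
}

# group A / group B density values for a contrast
.contrast_groups <- function(dm, contrast) {
  pick <- function(side, trt) dm$value[dm$side == side & dm$treatment == trt]
  out <- switch(contrast,
    ipsi_vs_contra_lesion = list(A = pick("ipsi", "lesion"),
                                 B = pick("contra", "lesion")),
    ipsi_vs_contra_vehicle = list(A = pick("ipsi", "vehicle"),
                                  B = pick("contra", "vehicle")),
    lesion_vs_vehicle_ipsi = list(A = pick("ipsi", "lesion"),
                                  B = pick("ipsi", "vehicle")),
    lesion_vs_vehicle_contra = list(A = pick("contra", "lesion"),
                                    B = pick("contra", "vehicle")),
    stop("unknown contrast: ", contrast))
  if (length(out$A) < 2L || length(out$B) < 2L) return(NULL)
  out
}
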