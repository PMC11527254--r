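#' Per-voxel observation set for the 2x2 (side x treatment) design
#'
#' Holds one row per observation (one hemisphere of one sample, in atlas
#' space after preprocessing and left-right flipping) and one column per
#' in-mask voxel. Every sample must contribute exactly one ipsilateral and
#' one contralateral observation; all volumes must share one grid.
#'
#' @param volumes list of `scalar_volume`s, one per observation.
#' @param sample_id character, sample of each observation.
#' @param side `"ipsi"` or `"contra"` per observation.
#' @param treatment `"lesion"` or `"vehicle"` per observation.
#' @param mask logical array on the shared grid; statistics are computed
#'   only where TRUE.
#' @return object of class `observation_set`.
#' @export
observation_set <- function(volumes, sample_id, side, treatment, mask) {
  n <- length(volumes)
  stopifnot(length(sample_id) == n, length(side) == n, length(treatment) == n)
  if (!all(side %in% c("ipsi", "contra")) ||
      !all(treatment %in% c("lesion", "vehicle")))
    stop("side must be ipsi/contra and treatment lesion/vehicle")
  grid <- volumes[[1]]$grid
  for (v in volumes) if (!same_grid(v$grid, grid))
    stop("all observation volumes must share one grid")
  if (!identical(dim(mask), as.integer(grid$shape)))
    stop("mask shape does not match volume grid")
  per <- table(sample_id, side)
  if (!all(per == 1L))
    stop("each sample must contribute exactly one ipsi and one contra observation")
  idx <- which(mask)
  Y <- matrix(0, n, length(idx))
  for (i in seq_len(n)) Y[i, ] <- volumes[[i]]$values[idx]
  structure(list(Y = Y,
                 info = data.frame(sample_id = sample_id, side = side,
                                   treatment = treatment,
                                   stringsAsFactors = FALSE),
                 grid = grid, mask = mask, idx = idx),
            class = "observation_set")
}

#' Split preprocessed whole-brain volumes into hemisphere observations
#'
#' The right hemisphere (`x >= shape_x/2`, ipsilateral to the infusion) is
#' the analysis domain; the contralateral observation is the mirrored left
#' hemisphere (via [flip_left_to_right()]). The analysis mask is the
#' intersection of the right-half exclusion mask with its mirrored
#' counterpart, so both observations of a sample are defined on every mask
#' voxel.
#'
#' @param volumes named list of preprocessed `scalar_volume`s (whole brain,
#'   atlas space), names = sample ids.
#' @param treatment treatment per volume (`"lesion"`/`"vehicle"`).
#' @param atlas a `label_volume` on the same grid.
#' @return an `observation_set` on the right-hemisphere grid.
#' @export
hemisphere_observations <- function(volumes, treatment, atlas) {
  g <- atlas$grid
  nx <- g$shape[1]
  hx <- (nx %/% 2 + 1):nx           # right half, 1-based
  hgrid <- voxel_grid(c(length(hx), g$shape[2], g$shape[3]), g$spacing,
                      g$origin + c((hx[1] - 1) * g$spacing[1], 0, 0),
                      g$axis_order)
  full_mask <- exclusion_mask(atlas)
  flip_mask <- full_mask[rev(seq_len(nx)), , , drop = FALSE]
  hmask <- full_mask[hx, , , drop = FALSE] & flip_mask[hx, , , drop = FALSE]
  obs_vols <- list(); sid <- sidev <- trt <- character(0)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    name <- if (!is.null(names(volumes))) names(volumes)[i] else paste0("s", i)
    ipsi <- scalar_volume(v$values[hx, , , drop = FALSE], hgrid)
    fl <- flip_left_to_right(v)
    contra <- scalar_volume(fl$values[hx, , , drop = FALSE], hgrid)
    obs_vols <- c(obs_vols, list(ipsi, contra))
    sid <- c(sid, name, name)
    sidev <- c(sidev, "ipsi", "contra")
    trt <- c(trt, treatment[i], treatment[i])
  }
  observation_set(obs_vols, sid, sidev, trt, hmask)
}

# cell index 1..4 from side/treatment: 1 ipsi-lesion, 2 ipsi-vehicle,
# 3 contra-lesion, 4 contra-vehicle
.cell_index <- function(side, treatment) {
  2L * (side == "contra") + (treatment == "vehicle") + 1L
}

# Type-III two-way ANOVA F statistics from the cell-means model, vectorised
# over voxels. Y: n x V, cell: 1..4 per row. Each Type-III hypothesis in a
# 2x2 design is a single-df contrast on cell means with coefficients
# (+-1/2); SS = L^2 / sum(c^2/n) with c = (1,1,-1,-1)/2 etc.
.f_core <- function(Y, cell) {
  n_c <- tabulate(cell, 4L)
  if (any(n_c == 0L)) {
    nm <- c("ipsi-lesion", "ipsi-vehicle", "contra-lesion", "contra-vehicle")
    stop("empty design cell: ", paste(nm[n_c == 0L], collapse = ", "))
  }
  N <- nrow(Y)
  S <- rowsum(Y, cell)                       # 4 x V cell sums (cells sorted 1..4)
  M <- S / n_c
  SSY <- .colSums(Y * Y, N, ncol(Y))
  SSE <- pmax(SSY - .colSums(M * S, 4, ncol(Y)), 0)
  denom <- sum(1 / n_c)
  Ls <- M[1, ] + M[2, ] - M[3, ] - M[4, ]    # side (ipsi - contra)
  Lt <- M[1, ] - M[2, ] + M[3, ] - M[4, ]    # treatment (lesion - vehicle)
  Li <- M[1, ] - M[2, ] - M[3, ] + M[4, ]    # interaction
  mse <- SSE / (N - 4L)
  eps <- 1e-10 * pmax(SSY, 1)
  f_of <- function(L) {
    SS <- L^2 / denom
    f <- ifelse(SSE <= eps, ifelse(SS <= eps, 0, Inf), SS / mse)
    f[!is.finite(f) & SS <= eps] <- 0
    f
  }
  list(side = f_of(Ls), treatment = f_of(Lt), interaction = f_of(Li))
}

# pooled-variance two-sample t per voxel; g is 1 (group A) or 2 (group B)
.t_core <- function(Y, g) {
  n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  S <- rowsum(Y, g)
  m1 <- S[1, ] / n1; m2 <- S[2, ] / n2
  SSY <- .colSums(Y * Y, nrow(Y), ncol(Y))
  SSE <- pmax(SSY - n1 * m1^2 - n2 * m2^2, 0)
  sp2 <- SSE / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  eps <- 1e-10 * pmax(SSY, 1)
  t <- ifelse(se > 0, d / se, ifelse(abs(d)^2 <= eps, 0, Inf * sign(d)))
  list(t = t, sign = sign(d))
}

#' Two-way ANOVA F maps for the 2x2 design
#'
#' Classical two-way ANOVA on the cell-means linear model with Type-III
#' style sums of squares (exact for both balanced and unbalanced cells).
#' Requires at least 2 observations per cell.
#'
#' @param obs an `observation_set`.
#' @return named list of three `scalar_volume`s (`side`, `treatment`,
#'   `interaction`); F is 0 outside the mask.
#' @export
fstats_2x2 <- function(obs) {
  cell <- .cell_index(obs$info$side, obs$info$treatment)
  if (any(tabulate(cell, 4L) < 2L)) stop("need >= 2 observations per design cell")
  f <- .f_core(obs$Y, cell)
  lapply(f, function(v) {
    a <- array(0, obs$grid$shape)
    a[obs$idx] <- v
    scalar_volume(a, obs$grid)
  })
}

#' Pooled-variance two-sample t map
#'
#' @param groupA,groupB lists of `scalar_volume`s on one grid (>= 2 each).
#' @param mask optional logical array; default everywhere.
#' @return list with `t` and `sign` `scalar_volume`s. Zero-variance voxels
#'   with equal means give t = 0.
#' @export
ttest_map <- function(groupA, groupB, mask = NULL) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need >= 2 volumes per group")
  grid <- groupA[[1]]$grid
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  vols <- c(groupA, groupB)
  obs_idx <- which(mask)
  Y <- matrix(0, length(vols), length(obs_idx))
  for (i in seq_along(vols)) Y[i, ] <- vols[[i]]$values[obs_idx]
  g <- rep(c(1L, 2L), c(length(groupA), length(groupB)))
  tc <- .t_core(Y, g)
  embed <- function(v) {
    a <- array(0, grid$shape)
    a[obs_idx] <- v
    scalar_volume(a, grid)
  }
  list(t = embed(tc$t), sign = embed(tc$sign))
}

# all distinct arrangements of a multiset of labels (columns = arrangements);
# only called when the count is small
.multiset_perms <- function(labels) {
  n <- length(labels)
  levs <- sort(unique(labels))
  rec <- function(slots, remaining) {
    if (length(remaining) == 0) {
      out <- matrix(labels[1], n, 1)
      return(out)
    }
    lev <- remaining[1]
    k <- sum(labels == lev)
    if (length(remaining) == 1) {
      out <- matrix(lev, n, 1)
      return(out)
    }
    picks <- utils::combn(length(slots), k)
    res <- list()
    for (j in seq_len(ncol(picks))) {
      chosen <- slots[picks[, j]]
      rest <- rec(setdiff(slots, chosen), remaining[-1])
      block <- matrix(NA, n, ncol(rest))
      block[chosen, ] <- lev
      free <- setdiff(slots, chosen)
      if (length(free)) block[free, ] <- rest[free, , drop = FALSE]
      res[[j]] <- block
    }
    do.call(cbind, res)
  }
  rec(seq_len(n), levs)
}

.n_multiset_perms <- function(labels) {
  counts <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1)))
}

#' Empirical permutation p-value map
#'
#' Recomputes the chosen statistic under label permutations and reports, per
#' voxel, `p = (1 + #permuted >= observed) / (1 + n_perm)` (so p is always
#' > 0). All observations are treated as exchangeable units. For the three
#' ANOVA statistics the joint (side, treatment) cell label vector is
#' shuffled as a unit (synchronized full-label, Manly-type unrestricted
#' permutation) - per-factor label shuffling can empty a design cell in
#' small cohorts, which leaves the cell-means F undefined. For `t_contrast`
#' the two-group label is shuffled and |t| is compared two-tailed. When the
#' number of distinct label arrangements is at most `n_perm`, exact
#' enumeration is used instead and the metadata records it.
#'
#' @param obs an `observation_set`.
#' @param statistic one of `"F_side"`, `"F_treatment"`, `"F_interaction"`,
#'   `"t_contrast"`.
#' @param n_perm number of random permutations (default 18000).
#' @param seed RNG seed for the permutation draw.
#' @param groups for `t_contrast`: vector with two levels defining the two
#'   groups, one entry per observation.
#' @param voxels optional integer subset (positions within the mask-voxel
#'   columns) restricting evaluation, used for post hoc gating.
#' @return object of class `stat_map` with fields `statistic`, `p`, `sign`
#'   (t maps), `grid`, `mask`, `voxel_idx` (full-array indices evaluated)
#'   and `meta`.
#' @export
permutation_pmap <- function(obs, statistic = c("F_side", "F_treatment",
                                                "F_interaction", "t_contrast"),
                             n_perm = 18000L, seed = 1L, groups = NULL,
                             voxels = NULL) {
  statistic <- match.arg(statistic)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  Y <- obs$Y
  if (!is.null(voxels)) Y <- Y[, voxels, drop = FALSE]
  info <- obs$info
  cell <- .cell_index(info$side, info$treatment)

  if (statistic == "t_contrast") {
    if (is.null(groups)) stop("t_contrast requires a groups vector")
    g <- if (is.factor(groups)) as.integer(groups) else
      as.integer(factor(groups))
    if (length(unique(g)) != 2L) stop("groups must have exactly two levels")
    if (min(tabulate(g)) < 2L) stop("need >= 2 observations per group")
    labels <- g
    stat_fn <- function(lab) abs(.t_core(Y, lab)$t)
    obs_ct <- .t_core(Y, g)
    observed <- abs(obs_ct$t)
    signed <- obs_ct$t
    sgn <- obs_ct$sign
  } else {
    if (any(tabulate(cell, 4L) < 2L))
      stop("need >= 2 observations per design cell")
    which_f <- c(F_side = "side", F_treatment = "treatment",
                 F_interaction = "interaction")[[statistic]]
    # synchronized full-label (Manly-type unrestricted) permutation: the
    # joint (side, treatment) cell label vector is shuffled as a unit, so
    # cell counts are invariant and no permutation empties a design cell
    labels <- cell
    stat_fn <- function(lab) .f_core(Y, lab)[[which_f]]
    observed <- stat_fn(labels)
    signed <- observed
    sgn <- NULL
  }

  tol <- 1e-8 * (1 + abs(observed))
  count <- numeric(length(observed))
  n_distinct <- .n_multiset_perms(labels)
  exact <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exact) {
    perms <- .multiset_perms(labels)
    for (j in seq_len(ncol(perms)))
      count <- count + (stat_fn(perms[, j]) >= observed - tol)
    p <- count / ncol(perms)
    meta_n <- ncol(perms)
  } else {
    set.seed(seed)
    for (j in seq_len(n_perm))
      count <- count + (stat_fn(sample(labels)) >= observed - tol)
    p <- (count + 1) / (n_perm + 1)
    meta_n <- n_perm
  }

  voxel_idx <- if (is.null(voxels)) obs$idx else obs$idx[voxels]
  structure(list(statistic = unname(signed), p = unname(p),
                 sign = if (!is.null(sgn)) unname(sgn),
                 grid = obs$grid, mask = obs$mask, voxel_idx = voxel_idx,
                 meta = list(statistic = statistic,
                             n_obs = nrow(Y),
                             n_perm = meta_n, seed = seed,
                             estimator = if (exact) "exact_enumeration"
                                         else "monte_carlo_with_replacement")),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s over %d voxels, %s (%d perms), min p = %.3g\n",
              x$meta$statistic, length(x$p), x$meta$estimator,
              x$meta$n_perm, min(x$p)))
  invisible(x)
}

#' Embed a stat_map field into a scalar volume
#'
#' @param sm a `stat_map`.
#' @param what `"p"`, `"statistic"` or `"sign"`.
#' @param fill value outside evaluated voxels (default 1 for p, 0 otherwise).
#' @return a `scalar_volume`.
#' @export
stat_volume <- function(sm, what = c("p", "statistic", "sign"), fill = NULL) {
  what <- match.arg(what)
  if (is.null(fill)) fill <- if (what == "p") 1 else 0
  a <- array(fill, sm$grid$shape)
  v <- sm[[what]]
  if (is.null(v)) stop("stat_map has no ", what, " field")
  a[sm$voxel_idx] <- v
  scalar_volume(a, sm$grid)
}

#' Write a stat_map as NIfTI volumes with a JSON sidecar
#'
#' Writes `<prefix>_stat.nii`, `<prefix>_p.nii` (p = 1 outside the
#' evaluated voxels) and, for t maps, `<prefix>_sign.nii`, plus
#' `<prefix>.json` with the contrast metadata (statistic, n, n_perm,
#' seed, estimator).
#'
#' @param sm a `stat_map`.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_stat_map <- function(sm, prefix) {
  write_nifti(stat_volume(sm, "statistic"), paste0(prefix, "_stat.nii"))
  write_nifti(stat_volume(sm, "p"), paste0(prefix, "_p.nii"))
  if (!is.null(sm$sign))
    write_nifti(stat_volume(sm, "sign"), paste0(prefix, "_sign.nii"))
  side <- paste0(prefix, ".json")
  jsonlite::write_json(sm$meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' Post hoc pairwise contrasts gated by the ANOVA maps
#'
#' Voxels reaching uncorrected significance (`p < alpha`) for the main
#' effect of side, the main effect of treatment, or their interaction (the
#' union, by default) are evaluated further with permutation t-tests for the
#' four pairwise comparisons: ipsilateral vs contralateral within each
#' treatment group, and lesion vs vehicle within each side.
#'
#' @param obs an `observation_set`.
#' @param anova_pmaps named list of `stat_map`s for `side`, `treatment`,
#'   `interaction` on the same grid/mask.
#' @param alpha gating threshold (default 0.05).
#' @param n_perm,seed passed to [permutation_pmap()].
#' @param gating `"union"` (default) or `"per_effect"` (gate each contrast
#'   on its most related effect: side contrasts on side+interaction,
#'   treatment contrasts on treatment+interaction).
#' @return named list of four `stat_map`s:
#'   `ipsi_vs_contra_lesion`, `ipsi_vs_contra_vehicle`,
#'   `lesion_vs_vehicle_ipsi`, `lesion_vs_vehicle_contra`.
#' @export
posthoc_contrasts <- function(obs, anova_pmaps, alpha = 0.05,
                              n_perm = 18000L, seed = 1L,
                              gating = c("union", "per_effect")) {
  gating <- match.arg(gating)
  for (nm in c("side", "treatment", "interaction"))
    if (!identical(anova_pmaps[[nm]]$voxel_idx, obs$idx))
      stop("anova p-map '", nm, "' is not on the observation mask/grid")
  sig <- lapply(anova_pmaps[c("side", "treatment", "interaction")],
                function(sm) sm$p < alpha)
  union_gate <- sig$side | sig$treatment | sig$interaction
  gate_for <- function(kind) {
    if (gating == "union") union_gate
    else if (kind == "side") sig$side | sig$interaction
    else sig$treatment | sig$interaction
  }
  info <- obs$info
  sub_map <- function(rows, groups, kind, seed_off) {
    gate <- which(gate_for(kind))
    sub <- structure(list(Y = obs$Y[rows, , drop = FALSE],
                          info = info[rows, , drop = FALSE],
                          grid = obs$grid, mask = obs$mask, idx = obs$idx),
                     class = "observation_set")
    permutation_pmap(sub, "t_contrast", n_perm = n_perm,
                     seed = seed + seed_off, groups = groups,
                     voxels = gate)
  }
  les <- info$treatment == "lesion"
  veh <- info$treatment == "vehicle"
  ips <- info$side == "ipsi"
  con <- info$side == "contra"
  side_f <- function(x) factor(x, levels = c("ipsi", "contra"))
  trt_f <- function(x) factor(x, levels = c("lesion", "vehicle"))
  out <- list(
    ipsi_vs_contra_lesion =
      sub_map(which(les), side_f(info$side[les]), "side", 1L),
    ipsi_vs_contra_vehicle =
      sub_map(which(veh), side_f(info$side[veh]), "side", 2L),
    lesion_vs_vehicle_ipsi =
      sub_map(which(ips), trt_f(info$treatment[ips]), "treatment", 3L),
    lesion_vs_vehicle_contra =
      sub_map(which(con), trt_f(info$treatment[con]), "treatment", 4L))
  for (nm in names(out)) out[[nm]]$meta$contrast <- nm
  out
}
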