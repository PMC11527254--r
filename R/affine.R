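#' Affine transform between spaces
#'
#' Maps world coordinates (um) of the `from` space to world coordinates of
#' the `to` space: `w_to = linear %*% w_from + offset`. Registration is out
#' of scope for this package; transforms are ingested (for synthetic data an
#' identity or scaling transform suffices).
#'
#' @param linear invertible 3x3 matrix.
#' @param offset numeric length-3 translation (um).
#' @param from,to free-text space tags (e.g. "tissue", "atlas").
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), offset = c(0, 0, 0),
                             from = "tissue", to = "atlas") {
  linear <- matrix(as.numeric(linear), 3, 3)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 3)
  d <- det(linear)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("invalid transform: linear part is singular")
  inv <- solve(linear)
  err <- max(abs(inv %*% linear - diag(3)))
  if (err > 1e-9) stop("invalid transform: inverse inaccurate")
  structure(list(linear = linear, offset = offset, from = from, to = to),
            class = "affine_transform")
}

#' @param t an `affine_transform`.
#' @rdname affine_transform
#' @export
invert_affine <- function(t) {
  inv <- solve(t$linear)
  affine_transform(inv, -inv %*% t$offset, from = t$to, to = t$from)
}

#' @param t2,t1 transforms; the composition applies `t1` first.
#' @rdname affine_transform
#' @export
compose_affine <- function(t2, t1) {
  affine_transform(t2$linear %*% t1$linear,
                   as.numeric(t2$linear %*% t1$offset) + t2$offset,
                   from = t1$from, to = t2$to)
}

#' Warp a volume onto a target grid through an affine transform
#'
#' Each target voxel samples the source volume at the inverse-mapped world
#' coordinate (pull-back resampling); out-of-bounds samples are 0. Label
#' volumes must use nearest-neighbour sampling so only source labels (or 0)
#' appear in the output.
#'
#' @param vol a `scalar_volume` or `label_volume` in the transform's `from`
#'   space.
#' @param t an `affine_transform` mapping `from` world coordinates to the
#'   target's world coordinates.
#' @param target the target `voxel_grid`.
#' @param mode `"nearest"` or `"trilinear"` (scalar volumes only).
#' @return a volume of the same kind on `target`.
#' @export
apply_affine <- function(vol, t, target, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  is_labels <- inherits(vol, "label_volume")
  if (is_labels && mode != "nearest")
    stop("label volumes require mode = \"nearest\"")
  src_grid <- vol$grid
  inv <- solve(t$linear)
  # 0-based target index -> continuous 0-based source index:
  #   w_t = o_t + (v + 0.5) s_t ;  w_s = inv (w_t - b) ;  i_s = w_s/s_s - 0.5 - o_s/s_s
  Ds <- diag(1 / src_grid$spacing)
  Dt <- diag(target$spacing)
  M <- Ds %*% inv %*% Dt
  off <- as.numeric(
    Ds %*% (inv %*% (target$origin + 0.5 * target$spacing - t$offset) -
              src_grid$origin)) - 0.5
  src <- if (is_labels) vol$labels else vol$values
  out <- affine_resample_cpp(as.numeric(src), dim(src), as.numeric(M),
                             off, target$shape,
                             as.integer(mode == "nearest"))
  out <- array(out, target$shape)
  if (is_labels) {
    storage.mode(out) <- "integer"
    label_volume(out, target, vol$regions)
  } else {
    scalar_volume(out, target)
  }
}

#' Block-resample a scalar volume by an integer factor
#'
#' Mirrors the paper-style "downsample by a factor of two" step. With
#' `reducer = "mean"` each `factor^3` block is averaged (edge blocks average
#' the voxels that exist); `"nearest"` keeps the first voxel of each block.
#' Output spacing is multiplied by `factor`; the origin is unchanged.
#'
#' @param vol a `scalar_volume`.
#' @param factor positive integer.
#' @param reducer `"mean"` or `"nearest"`.
#' @return resampled `scalar_volume`.
#' @export
resample <- function(vol, factor, reducer = c("mean", "nearest")) {
  reducer <- match.arg(reducer)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(vol)
  sh <- vol$grid$shape
  nsh <- as.integer(ceiling(sh / factor))
  g <- voxel_grid(nsh, vol$grid$spacing * factor, vol$grid$origin,
                  vol$grid$axis_order)
  if (reducer == "nearest") {
    out <- vol$values[seq(1, sh[1], by = factor),
                      seq(1, sh[2], by = factor),
                      seq(1, sh[3], by = factor), drop = FALSE]
    return(scalar_volume(array(out, nsh), g))
  }
  acc <- array(0, nsh)
  cnt <- array(0L, nsh)
  for (dz in seq_len(factor)) for (dy in seq_len(factor)) for (dx in seq_len(factor)) {
    xi <- seq(dx, sh[1], by = factor)
    yi <- seq(dy, sh[2], by = factor)
    zi <- seq(dz, sh[3], by = factor)
    block <- vol$values[xi, yi, zi, drop = FALSE]
    tx <- seq_along(xi); ty <- seq_along(yi); tz <- seq_along(zi)
    acc[tx, ty, tz] <- acc[tx, ty, tz] + block
    cnt[tx, ty, tz] <- cnt[tx, ty, tz] + 1L
  }
  scalar_volume(acc / cnt, g)
}

#' Rescale intensities to a display range
#'
#' Linearly maps `[lo, hi]` to `[0, 1]` and clamps, reproducing the
#' display-range zeroing used to suppress out-of-brain intensities before
#' registration.
#'
#' @param vol a `scalar_volume`.
#' @param lo,hi display range bounds, `hi > lo`.
#' @return rescaled `scalar_volume` with values in `[0, 1]`.
#' @export
rescale_display_range <- function(vol, lo, hi) {
  if (!(hi > lo)) stop("hi must be greater than lo")
  v <- (vol$values - lo) / (hi - lo)
  v[v < 0] <- 0
  v[v > 1] <- 1
  scalar_volume(v, vol$grid)
}
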