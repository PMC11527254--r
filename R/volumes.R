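#' Voxel grid geometry
#'
#' A `voxel_grid` fixes the lattice geometry shared by all volumes in one
#' space: shape (voxels per axis), isotropic-or-not spacing in micrometres,
#' world origin in micrometres, and the anatomical axis order. The world
#' coordinate of 0-based voxel index `v` is `origin + (v + 0.5) * spacing`
#' (voxel-centre convention). The default axis order is
#' x = left-to-right, y = posterior-to-anterior, z = inferior-to-superior;
#' all hemisphere operations assume x is the left-right axis.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric length 3 (or scalar), voxel edge length in um (> 0).
#' @param origin numeric length 3, world coordinate (um) of the lattice corner.
#' @param axis_order character tag; only `"LR-PA-IS"` is interpreted.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0),
                       axis_order = "LR-PA-IS") {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("grid shape must be >= 1 in all axes")
  if (any(spacing <= 0)) stop("grid spacing must be > 0 in all axes")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axis_order = axis_order),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s um spacing, origin (%s) um [%s]\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              x$axis_order))
  invisible(x)
}

#' @param a,b voxel grids.
#' @return TRUE if shape, spacing and origin agree.
#' @rdname voxel_grid
#' @export
same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

#' Voxel volume in cubic millimetres
#' @param grid a `voxel_grid`.
#' @return scalar, mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing) / 1e9

#' World coordinates of voxel centres
#'
#' @param grid a `voxel_grid`.
#' @param index 0-based integer voxel indices, an n x 3 matrix.
#' @return n x 3 matrix of world coordinates (um).
#' @export
voxel_to_world <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index + 0.5, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Scalar fluorescence / statistic volume
#'
#' Couples a numeric 3D array with its grid. Values must be finite.
#'
#' @param values numeric 3D array matching `grid$shape`.
#' @param grid a `voxel_grid`.
#' @return object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid) {
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("values array shape does not match grid shape")
  if (!all(is.finite(values))) stop("scalar_volume values must be finite")
  structure(list(values = values, grid = grid), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Region metadata table
#'
#' One row per atlas label: id, name, optional parent, catecholaminergic
#' cell-group class (`"dopaminergic"`, `"noradrenergic"` or `"none"`), and an
#' exclusion flag (ventricle-like / undefined regions excluded from
#' voxel-wise statistics). Label 0 (outside the brain) never appears.
#'
#' @param label_id positive integers, unique.
#' @param name character region names.
#' @param parent_id integer parent label or NA; parent links must be acyclic.
#' @param cell_group one of "dopaminergic", "noradrenergic", "none" per row.
#' @param excluded logical per row.
#' @return data.frame of class `region_table`.
#' @export
region_table <- function(label_id, name, parent_id = NA_integer_,
                         cell_group = "none", excluded = FALSE) {
  df <- data.frame(label_id = as.integer(label_id),
                   name = as.character(name),
                   parent_id = as.integer(parent_id),
                   cell_group = as.character(cell_group),
                   excluded = as.logical(excluded),
                   stringsAsFactors = FALSE)
  if (any(df$label_id <= 0L)) stop("label_id must be positive (0 is background)")
  if (anyDuplicated(df$label_id)) stop("label_id must be unique")
  if (!all(df$cell_group %in% c("dopaminergic", "noradrenergic", "none")))
    stop("cell_group must be dopaminergic, noradrenergic or none")
  # parent links acyclic: walk up from every node
  for (id in df$label_id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur) && cur != 0L) {
      if (cur %in% seen) stop("parent links form a cycle at label ", id)
      seen <- c(seen, cur)
      row <- match(cur, df$label_id)
      cur <- if (is.na(row)) NA_integer_ else df$parent_id[row]
    }
  }
  class(df) <- c("region_table", "data.frame")
  df
}

#' Integer-labelled atlas volume
#'
#' @param labels integer 3D array (0 = outside brain) matching `grid$shape`.
#' @param grid a `voxel_grid`.
#' @param regions a `region_table` covering every nonzero label.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, regions) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!identical(dim(labels), as.integer(grid$shape)))
    stop("labels array shape does not match grid shape")
  if (any(labels < 0L)) stop("labels must be non-negative")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, regions$label_id)
  if (length(missing))
    stop("labels missing from region table: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, grid = grid, regions = regions),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d regions, %d labelled voxels\n",
              paste(dim(x$labels), collapse = "x"),
              nrow(x$regions), sum(x$labels != 0L)))
  invisible(x)
}

#' Read / write region tables as CSV
#'
#' Columns: label_id,name,parent_id,cell_group,excluded.
#' @param path CSV file path.
#' @return `read_region_table` returns a `region_table`.
#' @export
read_region_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_table(df$label_id, df$name, df$parent_id, df$cell_group,
               as.logical(df$excluded))
}

#' @param regions a `region_table`.
#' @rdname read_region_table
#' @export
write_region_table <- function(regions, path) {
  utils::write.csv(as.data.frame(regions), path, row.names = FALSE)
  invisible(path)
}
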