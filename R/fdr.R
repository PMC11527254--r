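#' Benjamini-Hochberg step-up threshold
#'
#' Orders the p-values from smallest to largest and scans from the largest
#' down for the first (i.e. largest) `p_(i)` satisfying
#' `p_(i) <= (i/m) * q`; that p-value is the adjusted significance
#' threshold and every p at or below it is significant. `m` is the number
#' of comparisons (here: in-mask voxels for the contrast). If no p-value
#' satisfies the inequality the threshold is 0 and nothing is significant.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return list with `threshold`, `n_significant` and `m`.
#' @export
bh_threshold <- function(pvals, q) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- ps <= (seq_len(m) / m) * q
  if (!any(ok)) return(list(threshold = 0, n_significant = 0L, m = m))
  thr <- ps[max(which(ok))]
  list(threshold = thr, n_significant = sum(pvals <= thr), m = m)
}

#' Label connected clusters of a binary mask
#'
#' Maximal connected components under 6- (faces), 18- (faces+edges) or 26-
#' (faces+edges+corners) adjacency. Cluster ids are assigned in decreasing
#' size order; ties are broken by the lexicographically smallest voxel
#' index.
#'
#' @param mask logical 3D array (or `scalar_volume` of 0/1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list with `labels` (integer array, 0 background) and `sizes`
#'   (voxel count per cluster id).
#' @export
label_clusters <- function(mask, connectivity = 26L) {
  if (inherits(mask, "scalar_volume")) mask <- mask$values != 0
  raw <- cc_label_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  k <- max(raw, 0L)
  labels <- array(raw, dim(mask))
  if (k == 0L) return(list(labels = labels, sizes = integer(0)))
  sizes <- tabulate(raw[raw > 0L], k)
  first <- match(seq_len(k), raw[raw > 0L])  # flood fill emits ids in
  ord <- order(-sizes, first)                # first-found (lexicographic) order
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  list(labels = labels, sizes = sizes[ord])
}

#' Cluster-size-constrained FDR q selection
#'
#' Applies [bh_threshold()] at each candidate q and returns the result for
#' the smallest (most stringent) q whose suprathreshold mask still contains
#' at least one connected cluster of `min_cluster` voxels. Clusters smaller
#' than `min_cluster` are discarded from the final cluster set. If no q in
#' the grid qualifies, an empty result flagged `no_signal` is returned.
#'
#' @param pmap a `stat_map` (needs `p` and `voxel_idx`).
#' @param q_grid candidate q values; default covers 0.05 down to 5e-5.
#' @param min_cluster minimum surviving cluster size in voxels (default 100).
#' @param connectivity cluster adjacency (default 26).
#' @return object of class `fdr_result`: `q`, `threshold`, `m`,
#'   `n_significant`, `no_signal`, and `clusters` (a `cluster_set`:
#'   `labels` array, `table` with per-cluster id/size/centroid).
#' @export
select_q <- function(pmap, q_grid = c(0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4, 5e-5),
                     min_cluster = 100L, connectivity = 26L) {
  if (length(q_grid) == 0) stop("q_grid must be non-empty")
  if (min_cluster < 1L) stop("min_cluster must be >= 1")
  q_grid <- sort(q_grid)
  empty <- structure(list(q = NA_real_, threshold = 0,
                          m = length(pmap$p), n_significant = 0L,
                          no_signal = TRUE,
                          clusters = .empty_cluster_set(pmap$grid)),
                     class = "fdr_result")
  if (length(pmap$p) == 0) return(empty)
  for (q in q_grid) {
    bh <- bh_threshold(pmap$p, q)
    if (bh$n_significant == 0L) next
    supra <- array(FALSE, pmap$grid$shape)
    supra[pmap$voxel_idx[pmap$p <= bh$threshold]] <- TRUE
    cc <- label_clusters(supra, connectivity)
    if (length(cc$sizes) == 0L || max(cc$sizes) < min_cluster) next
    keep <- which(cc$sizes >= min_cluster)
    labels <- cc$labels
    labels[!(labels %in% keep)] <- 0L
    # keep ids contiguous 1..K (they are already size-ordered)
    tab <- .cluster_table(labels, pmap$grid)
    tab$q <- q
    tab$p_threshold <- bh$threshold
    return(structure(list(q = q, threshold = bh$threshold, m = bh$m,
                          n_significant = bh$n_significant,
                          no_signal = FALSE,
                          clusters = structure(list(labels = labels,
                                                    grid = pmap$grid,
                                                    table = tab),
                                               class = "cluster_set")),
                     class = "fdr_result"))
  }
  empty
}

.empty_cluster_set <- function(grid) {
  structure(list(labels = array(0L, grid$shape), grid = grid,
                 table = .cluster_table(array(0L, grid$shape), grid)),
            class = "cluster_set")
}

.cluster_table <- function(labels, grid) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0)
    return(data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      direction = character(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0)))
  rows <- lapply(ids, function(id) {
    ind <- arrayInd(which(labels == id), dim(labels)) - 1L
    data.frame(cluster_id = id, n_voxels = nrow(ind),
               direction = NA_character_,
               centroid_x = mean(ind[, 1]), centroid_y = mean(ind[, 2]),
               centroid_z = mean(ind[, 3]))
  })
  do.call(rbind, rows)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d voxels total\n",
              nrow(x$table), sum(x$table$n_voxels)))
  invisible(x)
}

#' Split clusters into direction-homogeneous components
#'
#' Re-labels each cluster into sign-homogeneous 26-connected components
#' using the t-map sign (+1 increase / -1 decrease), records the direction
#' per cluster, and re-applies the minimum-size filter. Voxels with sign 0
#' inside a cluster take the majority sign of their 26-neighbourhood; ties
#' are excluded from the cluster set.
#'
#' @param clusters a `cluster_set`.
#' @param sign_map a `stat_map` with a `sign` field, or a numeric array of
#'   -1/0/+1 on the same grid.
#' @param min_cluster minimum size after splitting (default 100).
#' @param connectivity adjacency for the re-labelling (default 26).
#' @return a new `cluster_set` with a `direction` column ("+" or "-").
#' @export
split_by_direction <- function(clusters, sign_map, min_cluster = 100L,
                               connectivity = 26L) {
  labels <- clusters$labels
  sh <- dim(labels)
  if (inherits(sign_map, "stat_map")) {
    sgn <- array(0, sh)
    sgn[sign_map$voxel_idx] <- sign_map$sign
  } else sgn <- array(as.numeric(sign_map), sh)
  inside <- labels > 0L
  # resolve sign-0 voxels by 26-neighbour majority
  zero_idx <- which(inside & sgn == 0)
  if (length(zero_idx)) {
    ind <- arrayInd(zero_idx, sh)
    for (r in seq_along(zero_idx)) {
      v <- ind[r, ]
      xs <- max(1, v[1] - 1):min(sh[1], v[1] + 1)
      ys <- max(1, v[2] - 1):min(sh[2], v[2] + 1)
      zs <- max(1, v[3] - 1):min(sh[3], v[3] + 1)
      nb <- sgn[xs, ys, zs]
      s <- sum(nb > 0) - sum(nb < 0)
      sgn[zero_idx[r]] <- sign(s)      # 0 on tie -> excluded below
    }
  }
  out <- array(0L, sh)
  tabs <- list()
  next_id <- 0L
  for (dir_sign in c(1, -1)) {
    cc <- label_clusters(inside & sgn == dir_sign, connectivity)
    keep <- which(cc$sizes >= min_cluster)
    for (id in keep) {
      next_id <- next_id + 1L
      sel <- cc$labels == id
      out[sel] <- next_id
      ind <- arrayInd(which(sel), sh) - 1L
      tabs[[next_id]] <- data.frame(
        cluster_id = next_id, n_voxels = sum(sel),
        direction = if (dir_sign > 0) "+" else "-",
        centroid_x = mean(ind[, 1]), centroid_y = mean(ind[, 2]),
        centroid_z = mean(ind[, 3]))
    }
  }
  tab <- if (length(tabs)) do.call(rbind, tabs) else
    .cluster_table(array(0L, sh), clusters$grid)
  # preserve q / p_threshold metadata if present
  for (cl in intersect(c("q", "p_threshold"), names(clusters$table)))
    tab[[cl]] <- if (nrow(clusters$table)) clusters$table[[cl]][1] else numeric(0)
  structure(list(labels = out, grid = clusters$grid, table = tab),
            class = "cluster_set")
}

#' Regional composition of clusters
#'
#' Per cluster, the voxel count and fraction contributed by each atlas
#' label; fractions sum to 1 within a cluster.
#'
#' @param clusters a `cluster_set`.
#' @param atlas a `label_volume` on the same grid (shape must match).
#' @return data.frame with cluster_id, label_id, name, n_voxels, fraction.
#' @export
cluster_composition <- function(clusters, atlas) {
  if (!identical(dim(clusters$labels), dim(atlas$labels)))
    stop("cluster and atlas grids do not match")
  ids <- clusters$table$cluster_id
  rows <- list()
  for (id in ids) {
    lab <- atlas$labels[clusters$labels == id]
    tb <- table(lab)
    df <- data.frame(cluster_id = id,
                     label_id = as.integer(names(tb)),
                     n_voxels = as.integer(tb))
    df$fraction <- df$n_voxels / sum(df$n_voxels)
    df$name <- atlas$regions$name[match(df$label_id, atlas$regions$label_id)]
    df$name[is.na(df$name)] <- "outside"
    rows[[length(rows) + 1]] <- df
  }
  if (!length(rows))
    return(data.frame(cluster_id = integer(0), label_id = integer(0),
                      n_voxels = integer(0), fraction = numeric(0),
                      name = character(0)))
  do.call(rbind, rows)
}
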