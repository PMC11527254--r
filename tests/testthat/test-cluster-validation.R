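test_that("partition_cluster is a disjoint cover", {
  m <- array(runif(6^3) < 0.4, c(6, 6, 6))
  cg <- array(runif(6^3) < 0.5, c(6, 6, 6))
  p <- partition_cluster(m, cg)
  expect_false(any(p$cell & p$fiber))
  expect_identical(p$cell | p$fiber, m)
  expect_equal(sum(p$cell) + sum(p$fiber), sum(m))
  # containment / disjointness
  expect_false(any(partition_cluster(cg, cg)$fiber))
  expect_false(any(partition_cluster(m & !cg, cg)$cell))
})

test_that("warp_cluster preserves masks under rigid and scaling maps", {
  g <- voxel_grid(c(16, 16, 16), 10)
  blob <- array(FALSE, c(16, 16, 16))
  for (z in 1:16) for (y in 1:16) for (x in 1:16)
    blob[x, y, z] <- sum((c(x, y, z) - 8.5)^2) <= 36  # radius 6 voxels
  idt <- affine_transform(from = "atlas", to = "tissue")
  w <- warp_cluster(blob, g, idt, g)
  expect_identical(w$mask, blob)
  expect_equal(w$volume_mm3, sum(blob) * voxel_volume_mm3(g))

  tr <- affine_transform(offset = c(20, 0, 0), from = "atlas", to = "tissue")
  wt <- warp_cluster(blob, g, tr, g)
  expect_equal(sum(wt$mask), sum(blob[1:14, , ]))  # 2-voxel shift, zero fill

  # isotropic x2 upsampling: ~8x the voxel count for a radius-6 blob
  fine <- voxel_grid(c(32, 32, 32), 5)
  wf <- warp_cluster(blob, g, idt, fine)
  ratio <- sum(wf$mask) / sum(blob)
  expect_lt(abs(ratio - 8) / 8, 0.05)
  expect_error(warp_cluster(blob, g, affine_transform(matrix(0, 3, 3)), g),
               "singular")
})

test_that("segment_signal thresholds deterministically and removes specks", {
  g <- voxel_grid(c(10, 10, 10), 10)
  cst <- scalar_volume(array(5, c(10, 10, 10)), g)
  expect_false(any(segment_signal(cst, "quantile_threshold",
                                  quantile = 0.9, min_size = 1)))
  expect_error(segment_signal(cst, "quantile_threshold", quantile = 1.2),
               "quantile")
  expect_error(segment_signal(cst, "absolute"), "threshold")

  a <- array(0, c(10, 10, 10))
  a[2, 2, 2] <- 10                       # single-voxel speck
  a[5:6, 5, 5] <- 10                     # two-voxel object
  v <- scalar_volume(a, g)
  seg <- segment_signal(v, "absolute", threshold = 5, min_size = 2)
  expect_false(seg[2, 2, 2])
  expect_true(all(seg[5:6, 5, 5]))
  ext <- segment_signal(v, "external_mask", external = a > 0, min_size = 1)
  expect_identical(ext, a > 0)
})

test_that("default segmentation recovers ground truth at default SNR", {
  atlas <- make_toy_atlas(toy_atlas_spec(shape = c(32, 32, 32)))
  co <- cohort_spec(seed = 2)
  s <- simulate_sample(atlas, co, "vehicle", 55L)
  tg <- s$volume$grid
  atlas_t <- apply_affine(atlas, affine_transform(from = "atlas", to = "atlas"),
                          tg, "nearest")
  seg <- segment_signal(s$volume, "otsu", roi = atlas_t$labels > 0L,
                        min_size = 2)
  truth <- s$truth$truth_mask
  dice <- 2 * sum(seg & truth) / (sum(seg) + sum(truth))
  expect_gte(dice, 0.8)
})

test_that("count_cells and fiber_density follow their definitions", {
  sp <- c(100, 100, 100)  # 1e-3 mm^3 per voxel
  seg <- array(FALSE, c(12, 12, 4))
  cl <- array(TRUE, c(12, 12, 4))
  r0 <- count_cells(seg, cl, sp)
  expect_equal(r0$count, 0L); expect_equal(r0$density, 0)
  seg[1:2, 1, 1] <- TRUE; seg[6, 6, 2] <- TRUE; seg[10:11, 10, 3] <- TRUE
  r3 <- count_cells(seg, cl, sp)
  expect_equal(r3$count, 3L)
  expect_equal(r3$density, 3 / (sum(cl) * 1e-3))
  # centroid rule: an object whose centroid is outside the cluster mask
  cl2 <- array(FALSE, c(12, 12, 4)); cl2[1:4, 1:4, 1:4] <- TRUE
  expect_equal(count_cells(seg, cl2, sp)$count, 1L)
  expect_error(count_cells(seg, array(FALSE, c(12, 12, 4)), sp), "empty")

  expect_equal(fiber_density(seg, cl), 100 * sum(seg) / sum(cl))
  cl3 <- array(FALSE, c(12, 12, 4)); cl3[1:10, 1, 1] <- TRUE
  seg3 <- array(FALSE, c(12, 12, 4)); seg3[1:2, 1, 1] <- TRUE  # and [6,6,2] off-cluster
  expect_equal(fiber_density(seg3, cl3), 20)
  expect_equal(fiber_density(array(TRUE, c(12, 12, 4)), cl), 100)
  expect_equal(fiber_density(array(FALSE, c(12, 12, 4)), cl), 0)
  expect_error(fiber_density(seg, array(FALSE, c(12, 12, 4))), "empty")
})

test_that("validate_cluster reproduces the closed-form t-test", {
  r <- validate_cluster(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742, tolerance = 1e-4)
  expect_equal(r$t, t_oracle(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(r$df, 4L)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), 4), tolerance = 1e-12)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)
  expect_true(r$valid)
  expect_equal(r$direction, "-")

  r0 <- validate_cluster(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r0$t, 0); expect_false(r0$valid)

  rs <- validate_cluster(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(rs$t, r$t, tolerance = 1e-12)
  expect_equal(rs$p, r$p, tolerance = 1e-12)
  expect_error(validate_cluster(1, c(1, 2)), ">= 2")
})

test_that("regionwise_densities counts by centroid region", {
  atlas <- tiny_atlas()
  seg <- array(FALSE, dim(atlas$labels))
  rd0 <- regionwise_densities(atlas, seg)
  expect_true(all(rd0$n_cells == 0))

  # plant 3 objects in snpc and 2 in striatum
  snpc_idx <- which(atlas$labels == 10L)
  str_idx <- which(atlas$labels == 20L)
  pick <- c(snpc_idx[c(1, 10, 25)], str_idx[c(3, 40)])
  seg[pick] <- TRUE
  rd <- regionwise_densities(atlas, seg)
  expect_equal(rd$n_cells[rd$name == "snpc"], 3L)
  expect_equal(rd$n_cells[rd$name == "striatum"], 2L)
  expect_equal(sum(rd$n_cells), 5L)
  vol_snpc <- sum(atlas$labels == 10L) * voxel_volume_mm3(atlas$grid)
  expect_equal(rd$density[rd$name == "snpc"], 3 / vol_snpc)
})

test_that("region_anova_tukey matches the studentized-range oracle", {
  r0 <- region_anova_tukey(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(r0$pairs$p_adj > 0.99))

  # two groups: Tukey p equals the pooled two-sample t-test p
  v <- c(1.2, 1.9, 2.4, 3.1, 3.8, 4.0)
  gp <- rep(c("a", "b"), each = 3)
  r2 <- region_anova_tukey(v, gp)
  pt2 <- stats::t.test(v[1:3], v[4:6], var.equal = TRUE)$p.value
  # agreement limited by ptukey's quadrature accuracy (~1e-5)
  expect_equal(r2$pairs$p_adj, pt2, tolerance = 1e-4)

  # hand dataset: pairs (1,2) and (2,3) significant, (1,3) not
  vals <- c(2, 3, 4, 6, 7, 8, 2, 3, 4)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  r3 <- region_anova_tukey(vals, grp)
  # independent oracle: q = |diff| / sqrt(MSE/n), p from ptukey
  mse <- sum(tapply(vals, grp, function(x) sum((x - mean(x))^2))) / 6
  pq <- function(m1, m2) 1 - stats::ptukey(abs(m1 - m2) / sqrt(mse / 3), 3, 6)
  want <- c(pq(3, 7), pq(3, 3), pq(7, 3))  # g2-g1, g3-g1, g3-g2
  expect_equal(r3$pairs$p_adj, want, tolerance = 1e-10)
  sig <- r3$pairs$p_adj < 0.05
  expect_equal(sig, c(TRUE, FALSE, TRUE))
  expect_error(region_anova_tukey(1:4, c("a", "a", "a", "b")), ">= 2")
})

test_that("validate_clusters measures a planted two-sided difference", {
  # small synthetic check of the orchestration: a cluster over the snpc
  # analogue on the hemisphere grid, raw volumes with fewer ipsi cells
  atlas <- make_toy_atlas(toy_atlas_spec(shape = c(32, 32, 32)))
  co <- cohort_spec(n_lesion = 3, n_vehicle = 3, seed = 31)
  cd <- make_cohort(atlas, co)
  hat <- hemisphere_atlas(atlas)
  labels <- array(0L, hat$grid$shape)
  labels[hat$labels == 10L] <- 1L
  cs <- structure(list(labels = labels, grid = hat$grid,
                       table = data.frame(cluster_id = 1L,
                                          n_voxels = sum(labels))),
                  class = "cluster_set")
  out <- validate_clusters(cs, "ipsi_vs_contra_lesion", cd$samples, atlas,
                           segment_params = list(cell_threshold = 105))
  expect_false(is.null(out$validation))
  vc <- out$validation[out$validation$measure == "cell_density", ]
  expect_equal(vc$n_A, 3L)
  expect_equal(vc$direction, "-")  # ipsi cell loss
  d <- out$densities
  expect_true(all(d$measure %in% c("cell_density", "fiber_density")))
  expect_true(all(d$value[d$measure == "fiber_density"] >= 0 &
                    d$value[d$measure == "fiber_density"] <= 100))
})
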