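# observation set on a tiny 1-voxel grid from per-observation values
obs1 <- function(values, side, treatment,
                 sample_id = paste0("s", ceiling(seq_along(values) / 2))) {
  g <- voxel_grid(c(1, 1, 1), 1)
  vols <- lapply(values, function(v) scalar_volume(array(v, c(1, 1, 1)), g))
  observation_set(vols, sample_id, side, treatment, array(TRUE, c(1, 1, 1)))
}

# balanced 2x2 helper: one value per observation, 2 samples per treatment
design22 <- function(il, iv, cl, cv) {
  n <- length(il)
  obs1(c(il, cl, iv, cv),
       side = rep(c("ipsi", "contra", "ipsi", "contra"), each = n),
       treatment = rep(c("lesion", "vehicle"), each = 2 * n),
       sample_id = c(paste0("L", 1:n), paste0("L", 1:n),
                     paste0("V", 1:n), paste0("V", 1:n)))
}

test_that("fstats_2x2 matches hand-computed sums of squares", {
  # all observations identical constants -> every F is 0
  oc <- design22(c(4, 4), c(4, 4), c(4, 4), c(4, 4))
  fc <- fstats_2x2(oc)
  expect_equal(fc$side$values[1, 1, 1], 0)
  expect_equal(fc$treatment$values[1, 1, 1], 0)
  expect_equal(fc$interaction$values[1, 1, 1], 0)

  # cells: ipsi {1,2} / contra {5,6} in both treatments
  ob <- design22(c(1, 2), c(1, 2), c(5, 6), c(5, 6))
  f <- fstats_2x2(ob)
  # explicit arithmetic: balanced n=2/cell, L_side = 1.5+1.5-5.5-5.5 = -8,
  # SS_side = n L^2 / 4 = 32, SSE = 4 cells * 0.5 = 2, MSE = 2/4 = 0.5
  expect_equal(f$side$values[1, 1, 1], 32 / 0.5)
  expect_equal(f$interaction$values[1, 1, 1], 0)
  expect_equal(f$treatment$values[1, 1, 1], 0)

  # cross-check against R's own ANOVA on the balanced design
  df <- data.frame(y = c(1, 2, 5, 6, 1, 2, 5, 6),
                   side = rep(c("i", "i", "c", "c"), 2),
                   trt = rep(c("l", "v"), each = 4))
  an <- anova(stats::lm(y ~ side * trt, df))
  expect_equal(f$side$values[1, 1, 1], an["side", "F value"])

  # unbalanced cells: compare against the Type-III contrast formula
  ou <- obs1(c(1, 2, 3, 7, 8, 4, 5, 9, 10, 11),
             side = c("ipsi", "ipsi", "ipsi", "contra", "contra",
                      "ipsi", "ipsi", "contra", "contra", "contra"),
             treatment = c(rep("lesion", 5), rep("vehicle", 5)),
             sample_id = c("a", "b", "c", "a", "b", "d", "e", "c", "d", "e"))
  fu <- fstats_2x2(ou)
  m <- c(mean(c(1, 2, 3)), mean(c(4, 5)), mean(c(7, 8)), mean(c(9, 10, 11)))
  n_c <- c(3, 2, 2, 3)
  sse <- sum((c(1, 2, 3) - m[1])^2) + sum((c(4, 5) - m[2])^2) +
    sum((c(7, 8) - m[3])^2) + sum((c(9, 10, 11) - m[4])^2)
  L <- m[1] + m[2] - m[3] - m[4]
  expect_equal(fu$side$values[1, 1, 1],
               (L^2 / sum(1 / n_c)) / (sse / 6))

  # swapping the treatment labels globally leaves the interaction F alone
  set.seed(20)
  y <- rnorm(8)
  o1 <- design22(y[1:2], y[3:4], y[5:6], y[7:8])
  o2 <- design22(y[3:4], y[1:2], y[7:8], y[5:6])
  expect_equal(fstats_2x2(o1)$interaction$values,
               fstats_2x2(o2)$interaction$values, tolerance = 1e-12)

  expect_error(fstats_2x2(obs1(c(1, 2, 3, 4),
                               side = c("ipsi", "contra", "ipsi", "contra"),
                               treatment = rep("lesion", 4))),
               "empty design cell|per design cell")
})

test_that("ttest_map reproduces the closed-form pooled t", {
  g <- voxel_grid(c(1, 1, 1), 1)
  mk <- function(v) scalar_volume(array(v, c(1, 1, 1)), g)
  A <- lapply(c(1, 2, 3), mk); B <- lapply(c(4, 5, 6), mk)
  tm <- ttest_map(A, B)
  expect_equal(tm$t$values[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tm$t$values[1, 1, 1],
               stats::t.test(c(1, 2, 3), c(4, 5, 6),
                             var.equal = TRUE)$statistic[[1]],
               tolerance = 1e-12)
  expect_equal(tm$sign$values[1, 1, 1], -1)

  # identical group means -> t = 0
  t0 <- ttest_map(lapply(c(1, 3), mk), lapply(c(2, 2), mk))
  expect_equal(t0$t$values[1, 1, 1], 0)
  # adding a constant changes nothing
  tc <- ttest_map(lapply(c(11, 12, 13), mk), lapply(c(14, 15, 16), mk))
  expect_equal(tc$t$values[1, 1, 1], tm$t$values[1, 1, 1], tolerance = 1e-12)
  expect_error(ttest_map(A[1], B), ">= 2")
})

test_that("permutation p-values agree with exact enumeration", {
  # 3 vs 3 on one voxel: all C(6,3)=20 assignments
  ob <- obs1(c(1, 2, 3, 7, 8, 9),
             side = rep("ipsi", 6),
             treatment = rep(c("lesion", "vehicle"), each = 3),
             sample_id = paste0("s", 1:6))
  pm <- permutation_pmap(ob, "t_contrast", n_perm = 18000, seed = 1,
                         groups = ob$info$treatment)
  expect_equal(pm$meta$estimator, "exact_enumeration")
  expect_equal(pm$meta$n_perm, 20)
  expect_equal(pm$p, exact_t_perm_oracle(c(1, 2, 3), c(7, 8, 9)))

  # identical multisets per group -> p = 1
  ob2 <- obs1(c(1, 2, 3, 1, 2, 3),
              side = rep("ipsi", 6),
              treatment = rep(c("lesion", "vehicle"), each = 3),
              sample_id = paste0("s", 1:6))
  pm2 <- permutation_pmap(ob2, "t_contrast", groups = ob2$info$treatment)
  expect_equal(pm2$p, 1)

  # F statistic: Monte Carlo with all-but-identity draws converges on the
  # exact enumeration (2 obs/cell -> 2520 distinct full-label shuffles)
  set.seed(30)
  ob3 <- design22(rnorm(2, 5), rnorm(2), rnorm(2), rnorm(2))
  ex <- permutation_pmap(ob3, "F_treatment", n_perm = 18000, seed = 2)
  expect_equal(ex$meta$estimator, "exact_enumeration")
  expect_equal(ex$meta$n_perm, 2520)
  mc <- permutation_pmap(ob3, "F_treatment", n_perm = 2519, seed = 3)
  expect_equal(mc$meta$estimator, "monte_carlo_with_replacement")
  expect_lt(abs(mc$p - ex$p), 0.05)

  # independent brute-force enumeration of all 8!/(2!^4) = 2520 cell-label
  # assignments, with F computed by explicit sums-of-squares arithmetic
  y <- ob3$Y[, 1]
  f_treat <- function(cells) {
    n_c <- tabulate(cells, 4)
    m <- tapply(y, factor(cells, levels = 1:4), mean)
    sse <- sum((y - m[cells])^2)
    L <- m[1] - m[2] + m[3] - m[4]
    (L^2 / sum(1 / n_c)) / (sse / 4)
  }
  base_cells <- lesionmap:::.cell_index(ob3$info$side, ob3$info$treatment)
  obs_f <- f_treat(base_cells)
  count <- 0; total <- 0
  for (c1 in utils::combn(8, 2, simplify = FALSE)) {
    rest1 <- setdiff(1:8, c1)
    for (c2 in utils::combn(rest1, 2, simplify = FALSE)) {
      rest2 <- setdiff(rest1, c2)
      for (c3 in utils::combn(rest2, 2, simplify = FALSE)) {
        cells <- integer(8)
        cells[c1] <- 1L; cells[c2] <- 2L; cells[c3] <- 3L
        cells[setdiff(rest2, c3)] <- 4L
        total <- total + 1
        if (f_treat(cells) >= obs_f - 1e-8 * (1 + obs_f)) count <- count + 1
      }
    }
  }
  expect_equal(total, 2520)
  expect_equal(ex$p, count / total)
})

test_that("extreme separation drives p to its floor", {
  # 10 vs 10 so a random redraw of the (unique-up-to-complement) extreme
  # split is vanishingly unlikely among 199 draws
  set.seed(31)
  ob <- obs1(c(rnorm(10), rnorm(10, 100)),
             side = rep("ipsi", 20),
             treatment = rep(c("lesion", "vehicle"), each = 10),
             sample_id = paste0("s", 1:20))
  pm <- permutation_pmap(ob, "t_contrast", n_perm = 199, seed = 4,
                         groups = ob$info$treatment)
  expect_equal(pm$p, 1 / 200)
})

test_that("permutation maps are deterministic in the seed", {
  set.seed(32)
  g <- voxel_grid(c(3, 3, 1), 1)
  vols <- lapply(1:8, function(i)
    scalar_volume(array(rnorm(9), c(3, 3, 1)), g))
  ob <- observation_set(vols, rep(paste0("s", 1:4), each = 2),
                        rep(c("ipsi", "contra"), 4),
                        rep(c("lesion", "vehicle"), each = 4),
                        array(TRUE, c(3, 3, 1)))
  p1 <- permutation_pmap(ob, "F_interaction", n_perm = 300, seed = 7)
  p2 <- permutation_pmap(ob, "F_interaction", n_perm = 300, seed = 7)
  expect_identical(p1$p, p2$p)
  p3 <- permutation_pmap(ob, "F_interaction", n_perm = 300, seed = 8)
  expect_false(identical(p3$p, p1$p))
})

test_that("post hoc contrasts are gated by the ANOVA maps", {
  set.seed(33)
  g <- voxel_grid(c(4, 3, 2), 1)
  mask <- array(TRUE, g$shape)
  # plant a treatment effect in voxel 1 only
  vols <- list()
  trt <- rep(c("lesion", "vehicle"), each = 8)
  for (i in 1:16) {
    a <- array(rnorm(24, sd = 0.5), g$shape)
    if (trt[i] == "lesion") a[1, 1, 1] <- a[1, 1, 1] + 50
    vols[[i]] <- scalar_volume(a, g)
  }
  ob <- observation_set(vols, rep(paste0("s", 1:8), each = 2),
                        rep(c("ipsi", "contra"), 8), trt, mask)
  an <- list(side = permutation_pmap(ob, "F_side", 99, seed = 1),
             treatment = permutation_pmap(ob, "F_treatment", 99, seed = 2),
             interaction = permutation_pmap(ob, "F_interaction", 99, seed = 3))
  ph <- posthoc_contrasts(ob, an, alpha = 0.05, n_perm = 99, seed = 9)
  expect_named(ph, c("ipsi_vs_contra_lesion", "ipsi_vs_contra_vehicle",
                     "lesion_vs_vehicle_ipsi", "lesion_vs_vehicle_contra"))
  gate <- an$side$p < 0.05 | an$treatment$p < 0.05 | an$interaction$p < 0.05
  for (nm in names(ph)) {
    # support is exactly the gated voxels (subset of ANOVA significance)
    expect_identical(ph[[nm]]$voxel_idx, ob$idx[which(gate)])
  }
  # the planted voxel is gated and detected in the treatment contrasts
  expect_true(ob$idx[1] %in% ph$lesion_vs_vehicle_ipsi$voxel_idx)
  i1 <- match(ob$idx[1], ph$lesion_vs_vehicle_ipsi$voxel_idx)
  expect_lt(ph$lesion_vs_vehicle_ipsi$p[i1], 0.05)
  expect_equal(ph$lesion_vs_vehicle_ipsi$sign[i1], 1)  # lesion > vehicle
})
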