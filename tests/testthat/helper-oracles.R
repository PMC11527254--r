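# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no cc_label_cpp, no bh_threshold).

# connected components by iterative label propagation over array shifts
flood_fill_oracle <- function(mask, connectivity = 26L) {
  sh <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  man <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- man > 0 & switch(as.character(connectivity),
                           "6" = man == 1, "18" = man <= 2, "26" = TRUE)
  offs <- offs[keep, ]
  lab <- array(0, sh)
  lab[mask] <- seq_len(sum(mask))
  shift_arr <- function(a, d) {
    out <- array(0, dim(a))
    sx <- seq_len(sh[1] - abs(d[1])); sy <- seq_len(sh[2] - abs(d[2]))
    sz <- seq_len(sh[3] - abs(d[3]))
    out[sx + max(d[1], 0), sy + max(d[2], 0), sz + max(d[3], 0)] <-
      a[sx + max(-d[1], 0), sy + max(-d[2], 0), sz + max(-d[3], 0)]
    out
  }
  repeat {
    new_lab <- lab
    for (k in seq_len(nrow(offs))) {
      nb <- shift_arr(lab, c(offs$dx[k], offs$dy[k], offs$dz[k]))
      upd <- mask & nb > 0 & (new_lab == 0 | nb < new_lab)
      new_lab[upd] <- nb[upd]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  ids <- sort(unique(lab[lab > 0]))
  sizes <- vapply(ids, function(i) sum(lab == i), 1L)
  list(labels = lab, sizes = sizes, n = length(ids))
}

# step-up FDR threshold by direct scan of the inequality p_(i) <= (i/m) q
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  thr <- 0
  for (i in m:1) {
    if (ps[i] <= (i / m) * q) { thr <- ps[i]; break }
  }
  list(threshold = thr, n_significant = sum(p <= thr))
}

# pooled two-sample t by the closed-form formula
t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# exact two-group permutation p for |t|, enumerating all C(n, n1) assignments
exact_t_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  obs <- abs(t_oracle(a, b))
  picks <- utils::combn(length(pooled), n1)
  stats <- apply(picks, 2, function(ix)
    abs(t_oracle(pooled[ix], pooled[-ix])))
  mean(stats >= obs - 1e-8 * (1 + obs))
}

# tiny helper: scalar volume from an array with unit spacing
vol3 <- function(a, spacing = 1) scalar_volume(a, voxel_grid(dim(a), spacing))

# a small two-region bilateral atlas for unit tests (atlas-lattice scale)
tiny_atlas <- function(shape = c(20, 16, 16)) {
  make_toy_atlas(toy_atlas_spec(shape = shape, spacing = 50))
}

# cohort spec with every lesion/compensation effect removed (true null)
null_cohort_spec <- function(..., seed = 1L) {
  no_eff <- data.frame(region = character(0), side = character(0),
                       measure = character(0), factor = numeric(0))
  cohort_spec(..., lesion_effects = no_eff, compensation_effects = no_eff,
              seed = seed)
}
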