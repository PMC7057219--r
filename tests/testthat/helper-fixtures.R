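# Shared fixtures and independent oracles used across the suite.

classic_dimer <- function(n_res = 28) {
  build_crick_coiled_coil(crick_params(n_res = n_res, order = 2))
}

# tiny decoy set with a known two-group structure
two_group_decoys <- function(n_each = 6, n_res = 20, sigma = 0.05, seed = 1) {
  withr::with_seed(seed, {
    a <- build_crick_coiled_coil(crick_params(n_res = n_res, order = 1,
                                              r0 = 3, pitch = -50), atoms = "CA")
    b <- build_crick_coiled_coil(crick_params(n_res = n_res, order = 1,
                                              r0 = 7, pitch = 60), atoms = "CA")
    perturb <- function(m) {
      xyz <- as.matrix(m[, c("x", "y", "z")])
      set_coords(m, xyz + matrix(rnorm(length(xyz), 0, sigma), ncol = 3L))
    }
    c(lapply(seq_len(n_each), function(i) perturb(a)),
      lapply(seq_len(n_each), function(i) perturb(b)))
  })
}

# independent oracle: RMSD-threshold partition as connected components of the
# pairwise-RMSD graph (exhaustive over all pairs; no greedy shortcuts)
partition_oracle <- function(coords, threshold) {
  n <- length(coords)
  pm <- ccmr:::pairwise_rmsd(coords)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (pm[i, j] <= threshold && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# independent oracle: best superposition RMSD by dense rotation-grid search
grid_rmsd_oracle <- function(p, q, step_deg = 6) {
  pc <- sweep(p, 2L, colMeans(p)); qc <- sweep(q, 2L, colMeans(q))
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  tilt <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a in ang) for (b in tilt) for (g in ang) {
    ca_ <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    R <- matrix(c(ca_ * cb * cg - sa * sg, -ca_ * cb * sg - sa * cg, ca_ * sb,
                  sa * cb * cg + ca_ * sg, -sa * cb * sg + ca_ * cg, sa * sb,
                  -sb * cg, sb * sg, cb), 3L, 3L, byrow = TRUE)
    r <- sqrt(mean(rowSums((qc %*% t(R) - pc)^2)))
    if (r < best) best <- r
  }
  best
}

# independent internal-to-Cartesian oracle for a planar all-trans chain:
# 2D walk with alternating turn sense
planar_zigzag_end_to_end <- function(n_res, bonds, angles) {
  # bonds/angles cycle: N->CA, CA->C, C->N(next) with interior angles at
  # CA (N-CA-C), C (CA-C-N) and N (C-N-CA)
  pos <- c(0, 0); heading <- 0; sense <- 1
  first <- pos
  n_bonds <- 3L * n_res - 1L
  for (k in seq_len(n_bonds)) {
    b <- bonds[((k - 1L) %% 3L) + 1L]
    pos <- pos + b * c(cos(heading), sin(heading))
    a <- angles[((k - 1L) %% 3L) + 1L]
    heading <- heading + sense * (pi - a * pi / 180)
    sense <- -sense
  }
  sqrt(sum((pos - first)^2))
}
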