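test_that("clustering matches the exhaustive threshold-partition oracle", {
  dec <- two_group_decoys(n_each = 6)
  cfg <- ensembler_config(cluster_threshold = 1.0)
  cls <- cluster_decoys(dec, cfg)
  oracle <- partition_oracle(lapply(dec, ca_coords), 1.0)
  expect_equal(length(cls), length(unique(oracle)))
  for (cl in cls) {
    expect_equal(length(unique(oracle[cl$ids])), 1L)   # members share a group
    expect_equal(sort(cl$ids), sort(which(oracle == oracle[cl$ids[1]])))
  }
})

test_that("clustering respects caps, ordering and degenerate inputs", {
  dec <- two_group_decoys(n_each = 8)
  cls <- cluster_decoys(dec, ensembler_config(cluster_cap = 5,
                                              cluster_threshold = 1.0))
  expect_true(all(vapply(cls, function(cl) length(cl$members), integer(1)) <= 5))
  # all-identical decoys give one cluster
  same <- rep(dec[1], 7)
  expect_equal(length(cluster_decoys(same)), 1L)
  expect_error(cluster_decoys(list()), "empty")
  # members are aligned onto the representative
  cl1 <- cluster_decoys(dec, ensembler_config(cluster_threshold = 1.0))[[1]]
  rep_m <- cl1$members[[1]]
  for (m in cl1$members)
    expect_lt(superpose(rep_m, m)$rmsd - ccmr:::pairwise_rmsd(
      list(ca_coords(rep_m), ca_coords(m)))[1, 2], 1e-9)
})

test_that("variance profile localizes the noisy residues", {
  base <- crick_params(n_res = 30, order = 1)
  spec <- decoy_noise_spec(sigma = 0.05, fray_len = 5, fray_sigma = 2,
                           n_conformers = 1, n_decoys = 20, seed = 6,
                           jitter_r0 = 0, jitter_pitch = 0, jitter_phase = 0)
  dec <- generate_decoys(base, spec)
  cl <- cluster_decoys(dec, ensembler_config(cluster_threshold = 20))[[1]]
  prof <- variance_profile(cl)
  expect_length(prof, 30)
  expect_true(all(prof >= 0))
  # the 10 frayed terminal residues dominate the variance ranking
  top10 <- order(prof, decreasing = TRUE)[1:10]
  expect_setequal(top10, c(1:5, 26:30))
  # identical members give an all-zero profile
  same <- list(members = rep(list(dec[[1]]), 4))
  expect_equal(variance_profile(same), rep(0, 30))
  expect_equal(variance_profile(list(members = dec[1])), rep(0, 30))
})

test_that("truncation produces nested, shrinking, deterministic subsets", {
  dec <- two_group_decoys(n_each = 10, n_res = 20)
  cl <- cluster_decoys(dec, ensembler_config(cluster_threshold = 1.0))[[1]]
  prof <- variance_profile(cl)
  levels <- truncate_cluster(cl, prof)
  # 20 residues at 20 levels: sizes 20, 19, ..., 1
  expect_equal(vapply(levels, function(l) length(l$residues), integer(1)),
               20:1)
  for (k in seq_len(length(levels) - 1))
    expect_true(all(levels[[k + 1]]$residues %in% levels[[k]]$residues))
  # flat profile: ties break to the lower residue index, nesting holds
  flat <- truncate_cluster(cl, rep(1, 20))
  expect_equal(flat[[2]]$residues, 1:19)
  expect_equal(flat[[20]]$residues, 1L)
})

test_that("subclustering matches the exhaustive partition on tight groups", {
  dec <- two_group_decoys(n_each = 3, sigma = 0.02)
  sub <- subcluster(dec, radius = 0.5)
  oracle <- partition_oracle(lapply(dec, ca_coords), 0.5)
  expect_equal(length(sub), length(unique(oracle)))
  expect_setequal(sub[[1]]$ids, which(oracle == oracle[sub[[1]]$ids[1]]))
  # radius -> infinity: one subcluster with every model
  expect_equal(length(subcluster(dec, radius = 1e6)), 1L)
  expect_length(subcluster(dec, radius = 1e6)[[1]]$ids, 6)
  # isolated models give singleton subclusters
  iso <- two_group_decoys(n_each = 1, sigma = 0)
  expect_equal(lengths(lapply(subcluster(iso, 0.1), `[[`, "ids")), c(1L, 1L))
  expect_error(subcluster(list(), 1), "empty")
})

test_that("polyalanine treatment strips side chains but not coordinates", {
  m <- build_alpha_helix(helix_build_spec(5))
  m$resid <- c(rep("LYS", 5), rep("GLY", 5), rep("ALA", 5), rep("TRP", 5),
               rep("GLU", 5))
  pa <- polyalanine(m)
  expect_true(all(pa$resid == "ALA"))
  expect_true(all(pa$atom %in% c("N", "CA", "C", "O", "CB")))
  expect_equal(as.matrix(pa[, c("x", "y", "z")]),
               as.matrix(m[m$atom %in% c("N", "CA", "C", "O", "CB"),
                           c("x", "y", "z")]))
  # no CB is fabricated for residues that lack one
  gly <- m[m$atom != "CB", ]
  class(gly) <- c("cc_model", "data.frame")
  expect_false("CB" %in% polyalanine(gly)$atom)
})

test_that("pipeline emits cluster x level x radius ensembles with provenance", {
  noise <- decoy_noise_spec(n_decoys = 60, n_conformers = 3, seed = 7)
  dec <- generate_decoys(crick_params(n_res = 48, order = 1), noise)
  ens <- generate_ensembles(dec)
  expect_equal(length(ens), 3 * 20 * 2)
  prov <- unique(data.frame(
    cluster = vapply(ens, `[[`, integer(1), "cluster"),
    level = vapply(ens, `[[`, integer(1), "level"),
    radius = vapply(ens, `[[`, numeric(1), "radius")))
  expect_equal(nrow(prov), length(ens))          # unique provenance
  expect_true(all(vapply(ens, function(e) length(e$models) >= 1, logical(1))))
  # polyalanine members restricted to the retained residue subset
  e1 <- ens[[37]]
  expect_equal(sort(unique(e1$models[[1]]$resno)), sort(e1$residues))
})

test_that("top-k score filter restricts which decoys are clustered", {
  dec <- two_group_decoys(n_each = 6)
  scores <- c(rep(1, 6), rep(100, 6))   # group 1 scores best
  cfg <- ensembler_config(cluster_threshold = 1.0, top_k_models = 6,
                          n_truncation_levels = 5)
  ens <- generate_ensembles(dec, cfg, scores = scores)
  expect_true(all(vapply(ens, `[[`, integer(1), "cluster") == 1L))
  expect_error(generate_ensembles(dec, cfg), "scores")
})

test_that("ensembles are written with a readable manifest", {
  noise <- decoy_noise_spec(n_decoys = 10, n_conformers = 1, seed = 1)
  dec <- generate_decoys(crick_params(n_res = 12, order = 1), noise)
  ens <- generate_ensembles(dec, ensembler_config(n_truncation_levels = 3))
  dir <- withr::local_tempdir()
  manifest <- write_ensembles(ens, dir)
  tb <- read.delim(manifest)
  expect_equal(nrow(tb), length(ens))
  expect_true(all(file.exists(file.path(dir, paste0(tb$ensemble[1], "_m01.pdb")))))
})
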