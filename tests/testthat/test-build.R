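test_that("dihedral-built helix has standard backbone geometry", {
  h <- build_alpha_helix(helix_build_spec(28))
  expect_equal(model_chains(h), "A")
  expect_equal(unname(model_nres(h)), 28L)
  # peptide bond between consecutive residues has the imposed length
  cn <- vapply(1:27, function(i) {
    c_i <- as.numeric(h[h$resno == i & h$atom == "C", c("x", "y", "z")])
    n_j <- as.numeric(h[h$resno == i + 1 & h$atom == "N", c("x", "y", "z")])
    sqrt(sum((c_i - n_j)^2))
  }, numeric(1))
  expect_equal(cn, rep(1.329, 27), tolerance = 1e-6)
  # minimal chain
  h2 <- build_alpha_helix(helix_build_spec(2))
  expect_equal(unname(model_nres(h2)), 2L)
  expect_error(build_alpha_helix(helix_build_spec(1)), "degenerate")
  expect_error(helix_build_spec(5, phi = -190), "dihedrals")
})

test_that("dihedrals, not hard-coding, drive the measured geometry", {
  # extended dihedrals give a beta-like chain with 2 residues/turn whose
  # end-to-end length matches an independent planar-zigzag conversion
  e <- build_alpha_helix(helix_build_spec(28, phi = 180, psi = 180))
  g <- measure_geometry(e)
  expect_equal(g$residues_per_turn, 2, tolerance = 1e-6)
  n1 <- as.numeric(e[e$resno == 1 & e$atom == "N", c("x", "y", "z")])
  cn <- as.numeric(e[e$resno == 28 & e$atom == "C", c("x", "y", "z")])
  oracle <- planar_zigzag_end_to_end(28, bonds = c(1.458, 1.525, 1.329),
                                     angles = c(110.0, 116.2, 120.0))
  expect_equal(sqrt(sum((cn - n1)^2)), oracle, tolerance = 1e-6)
})

test_that("Crick oligomers have exact Cn symmetry before noise", {
  for (m in 2:4) {
    cc <- build_crick_coiled_coil(crick_params(n_res = 21, order = m))
    a <- ca_coords(cc, "A")
    b <- ca_coords(cc, "B")
    rot <- ccmr:::rotz(-360 / m)   # inverse of the generator maps B back onto A
    expect_lt(sqrt(mean(rowSums((b %*% t(rot) - a)^2))), 1e-6)
  }
  expect_error(build_crick_coiled_coil(crick_params(n_res = 21, order = 5)),
               "unsupported")
})

test_that("zero superhelix radius gives straight, uncrossed helices", {
  cc <- build_crick_coiled_coil(crick_params(n_res = 28, order = 2, r0 = 0,
                                             phase_offsets = c(0, 180)))
  g <- measure_geometry(cc)
  expect_equal(g$crossing_angle, 0, tolerance = 1e-6)
  ax <- local_axes(ca_coords(cc, "A"))$axis
  expect_lt(ccmr:::line_deviation(ax), 1e-3)
})

test_that("decoy generation is seeded, reproducible and correctly scaled", {
  base <- crick_params(n_res = 20, order = 1)
  # no noise, one conformer: all decoys identical to the base build
  quiet <- decoy_noise_spec(sigma = 0, fray_len = 0, n_conformers = 1,
                            n_decoys = 5, seed = 3, jitter_r0 = 0,
                            jitter_pitch = 0, jitter_phase = 0)
  dq <- generate_decoys(base, quiet)
  ref <- build_crick_coiled_coil(base, atoms = "CA")
  for (d in dq) expect_equal(as.matrix(d[, c("x", "y", "z")]),
                             as.matrix(ref[, c("x", "y", "z")]))
  # same seed, same spec: bit-identical coordinate sets
  spec <- decoy_noise_spec(n_decoys = 8, n_conformers = 2, seed = 11)
  expect_identical(generate_decoys(base, spec), generate_decoys(base, spec))
  # mean per-atom displacement matches the isotropic 3-D Gaussian closed form
  model_base <- build_crick_coiled_coil(crick_params(n_res = 48, order = 1),
                                        atoms = "CA")
  noisy <- decoy_noise_spec(sigma = 1, fray_len = 0, n_conformers = 1,
                            n_decoys = 200, seed = 5)
  dn <- generate_decoys(model_base, noisy)
  ref_xyz <- as.matrix(model_base[, c("x", "y", "z")])
  disp <- unlist(lapply(dn, function(d)
    sqrt(rowSums((as.matrix(d[, c("x", "y", "z")]) - ref_xyz)^2))))
  expect_equal(mean(disp), 2 * sqrt(2 / pi), tolerance = 0.03)
  expect_error(decoy_noise_spec(sigma = -1), "sigma")
})

test_that("terminal fraying scatters only the chain ends", {
  base <- crick_params(n_res = 40, order = 1)
  spec <- decoy_noise_spec(sigma = 0, fray_len = 5, fray_sigma = 1,
                           n_conformers = 1, n_decoys = 50, seed = 2,
                           jitter_r0 = 0, jitter_pitch = 0, jitter_phase = 0)
  dec <- generate_decoys(base, spec)
  ref <- ca_coords(build_crick_coiled_coil(base, atoms = "CA"))
  disp <- Reduce(`+`, lapply(dec, function(d)
    sqrt(rowSums((ca_coords(d) - ref)^2)))) / length(dec)
  expect_true(all(disp[6:35] == 0))
  expect_true(all(disp[c(1:5, 36:40)] > 0))
})

test_that("models round-trip through PDB files", {
  cc <- build_crick_coiled_coil(crick_params(n_res = 10, order = 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(cc, f)
  back <- read_model_pdb(f)
  expect_equal(model_chains(back), c("A", "B"))
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(cc[, c("x", "y", "z")]), tolerance = 1e-3)
  expect_equal(back$atom, cc$atom)
})
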