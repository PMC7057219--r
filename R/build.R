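# Backbone internal-coordinate constants (Engh & Huber style ideal values).
# Bond lengths in Angstrom, angles in degrees.
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 110.0, a_ca_c_n = 116.2, a_c_n_ca = 120.0,
  a_ca_c_o = 120.5, a_c_ca_cb = 110.1, t_n_c_ca_cb = 122.6
)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Natural-extension placement: position atom D bonded to C given atoms A, B, C,
# the C-D bond length, the B-C-D angle and the A-B-C-D torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle); ph <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.numeric(c + cbind(bc, m, n) %*% d_local)
}

#' Helix build specification
#'
#' Bundles the residue count and backbone dihedrals used to grow a chain by
#' sequential internal-coordinate placement. The canonical alpha-helical
#' dihedrals are the default; the measured helical parameters (residues per
#' turn, rise, pitch) are emergent properties of the dihedrals, not inputs.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi,omega backbone dihedrals in degrees, in (-180, 180].
#' @return An object of class `helix_build_spec`.
#' @export
helix_build_spec <- function(n_res, phi = -57, psi = -47, omega = 180) {
  if (n_res < 2) stop("degenerate input: n_res must be >= 2")
  for (d in c(phi, psi, omega))
    if (!is.finite(d) || d <= -180 || d > 180)
      stop("dihedrals must lie in (-180, 180]")
  structure(list(n_res = as.integer(n_res), phi = phi, psi = psi, omega = omega),
            class = "helix_build_spec")
}

#' Build an alpha-helix (or any regular chain) from backbone dihedrals
#'
#' Grows a single polyalanine chain atom by atom from standard backbone bond
#' lengths and angles and the repeated (phi, psi, omega) dihedrals of `spec`.
#' With the canonical alpha-helical dihedrals (phi = -57, psi = -47) the
#' resulting chain measures ~3.6 residues per turn with a rise of ~1.5 A per
#' residue; with extended dihedrals it produces a beta-like chain with 2
#' residues per turn. Carbonyl O and CB atoms are added from ideal geometry.
#'
#' @param spec a [helix_build_spec()].
#' @param chain chain id for the output model.
#' @return A single-chain `cc_model` with N, CA, C, O, CB per residue.
#' @export
build_alpha_helix <- function(spec, chain = "A") {
  stopifnot(inherits(spec, "helix_build_spec"))
  n <- spec$n_res
  # seed residue: N at origin, CA along x, C in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(.bb$b_n_ca, 0, 0)
  a1 <- deg2rad(.bb$a_n_ca_c)
  C1 <- CA1 + .bb$b_ca_c * c(-cos(a1), sin(a1), 0)
  bb <- vector("list", n)
  bb[[1L]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n - 1L) + 1L) {
    p <- bb[[i - 1L]]
    Ni <- place_atom(p$N, p$CA, p$C, .bb$b_c_n, .bb$a_ca_c_n, spec$psi)
    CAi <- place_atom(p$CA, p$C, Ni, .bb$b_n_ca, .bb$a_c_n_ca, spec$omega)
    Ci <- place_atom(p$C, Ni, CAi, .bb$b_ca_c, .bb$a_n_ca_c, spec$phi)
    bb[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  rows <- list()
  for (i in seq_len(n)) {
    p <- bb[[i]]
    O <- place_atom(p$N, p$CA, p$C, .bb$b_c_o, .bb$a_ca_c_o,
                    spec$psi + 180)
    CB <- place_atom(p$N, p$C, p$CA, .bb$b_ca_cb, .bb$a_c_ca_cb,
                     -.bb$t_n_c_ca_cb)
    rows[[i]] <- list(
      atom = c("N", "CA", "C", "O", "CB"),
      xyz = rbind(p$N, p$CA, p$C, O, CB)
    )
  }
  n_at <- 5L
  cc_model(
    chain = rep(chain, n * n_at),
    resno = rep(seq_len(n), each = n_at),
    resid = rep("ALA", n * n_at),
    atom = unlist(lapply(rows, `[[`, "atom")),
    xyz = do.call(rbind, lapply(rows, `[[`, "xyz"))
  )
}

#' Crick coiled-coil parameters
#'
#' Parameter bundle for the Crick superhelix description of a parallel
#' coiled-coil: each chain is a minor alpha-helix of radius `r1` wound on a
#' superhelical path of radius `r0` and pitch `pitch`. The sign of `pitch`
#' encodes supercoil handedness: negative = left-handed (the classic
#' heptad-repeat coiled-coil), positive = right-handed. Defaults give the
#' classic left-handed parallel coiled-coil: a seven-residue repeat over two
#' local turns (3.5 residues per turn in the supercoil frame) and a rise of
#' 1.5 A per residue along the helix, which together place ~5.1 A of axial
#' translation per alpha-helical turn.
#'
#' @param n_res residues per chain.
#' @param order oligomer order m (1-4); chains are related by exact 360/m
#'   degree rotations about the supercoil (z) axis.
#' @param r0 superhelix radius, A (0 gives straight untwisted helices).
#' @param pitch superhelix pitch P0, A; sign encodes handedness (negative =
#'   left-handed).
#' @param r1 minor-helix radius (CA radius about the local axis), A.
#' @param residues_per_turn local (supercoil-frame) residues per minor-helix
#'   turn; 3.5 for the heptad repeat.
#' @param rise rise per residue along the helix, A.
#' @param minor_phase minor-helix phase of residue 1 in degrees; 0 points
#'   radially away from the supercoil axis. The default places heptad core
#'   (a/d-like) positions symmetrically about the inward direction.
#' @param phase_offsets optional per-chain supercoil phase offsets in degrees;
#'   defaults to 360 (k-1) / order.
#' @return An object of class `crick_params`.
#' @export
crick_params <- function(n_res = 28, order = 2, r0 = 4.9, pitch = -140,
                         r1 = 2.26, residues_per_turn = 3.5, rise = 1.5,
                         minor_phase = 180 + 360 / 14, phase_offsets = NULL) {
  if (!order %in% 1:4) stop("unsupported oligomer order: ", order)
  if (n_res < 2) stop("degenerate input: n_res must be >= 2")
  if (r0 < 0) stop("r0 must be >= 0")
  if (rise <= 0) stop("rise must be > 0")
  if (r0 > 0 && pitch == 0) stop("pitch must be nonzero when r0 > 0")
  if (is.null(phase_offsets)) phase_offsets <- 360 * (seq_len(order) - 1L) / order
  stopifnot(length(phase_offsets) == order)
  structure(list(n_res = as.integer(n_res), order = as.integer(order),
                 r0 = r0, pitch = pitch, r1 = r1,
                 residues_per_turn = residues_per_turn, rise = rise,
                 minor_phase = minor_phase, phase_offsets = phase_offsets,
                 orientation = "parallel"),
            class = "crick_params")
}

# CA trace of one chain from Crick parameters (matrix n_res x 3).
crick_ca_trace <- function(p, phase_offset = 0) {
  t <- seq_len(p$n_res) - 1L
  alpha <- if (p$r0 > 0) atan2(2 * pi * p$r0, abs(p$pitch)) else 0
  dz <- p$rise * cos(alpha)                     # axial rise per residue
  w0 <- if (p$r0 > 0) sign(p$pitch) * 2 * pi * dz / abs(p$pitch) else 0
  w1 <- 2 * pi / p$residues_per_turn
  th0 <- w0 * t + deg2rad(phase_offset)
  th1 <- w1 * t + deg2rad(p$minor_phase)
  path <- cbind(p$r0 * cos(th0), p$r0 * sin(th0), dz * t)
  out <- matrix(0, p$n_res, 3L)
  for (i in seq_len(p$n_res)) {
    R <- c(cos(th0[i]), sin(th0[i]), 0)          # radial-out unit vector
    Tg <- unitv(c(-p$r0 * w0 * sin(th0[i]), p$r0 * w0 * cos(th0[i]), dz))
    U <- cross3(Tg, R)                           # completes local frame
    out[i, ] <- path[i, ] + p$r1 * (cos(th1[i]) * R + sin(th1[i]) * U)
  }
  out
}

# Local-frame backbone offsets measured once from a canonical dihedral-built
# helix; used to decorate CA traces with N, C, O, CB.
backbone_template <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    h <- build_alpha_helix(helix_build_spec(12L))
    ca <- ca_coords(h)
    offs <- list()
    for (i in 2:11) {
      fr <- ca_frame(ca, i)
      for (at in c("N", "C", "O", "CB")) {
        v <- as.numeric(h[h$resno == i & h$atom == at, c("x", "y", "z")]) - ca[i, ]
        offs[[at]] <- rbind(offs[[at]], as.numeric(t(fr) %*% v))
      }
    }
    cache <<- lapply(offs, colMeans)
    cache
  }
})

# Orthonormal local frame at CA i from the (i-1, i, i+1) triplet.
ca_frame <- function(ca, i) {
  e1 <- unitv(ca[i + 1L, ] - ca[i - 1L, ])
  v <- (ca[i - 1L, ] - ca[i, ]) + (ca[i + 1L, ] - ca[i, ])
  e2 <- unitv(v - sum(v * e1) * e1)
  cbind(e1, e2, cross3(e1, e2))
}

# Decorate a CA trace (n x 3) with template backbone atoms. Terminal residues
# borrow the frame of their nearest interior neighbour.
decorate_ca_trace <- function(ca, chain = "A", resid = "ALA") {
  n <- nrow(ca)
  if (n < 3L) stop("need >= 3 residues to rebuild a backbone from CAs")
  tpl <- backbone_template()
  atoms <- c("N", "CA", "C", "O", "CB")
  xyz <- matrix(0, n * 5L, 3L)
  for (i in seq_len(n)) {
    j <- min(max(i, 2L), n - 1L)
    fr <- ca_frame(ca, j)
    base <- ca[i, ]
    xyz[(i - 1L) * 5L + 1L, ] <- base + as.numeric(fr %*% tpl$N)
    xyz[(i - 1L) * 5L + 2L, ] <- base
    xyz[(i - 1L) * 5L + 3L, ] <- base + as.numeric(fr %*% tpl$C)
    xyz[(i - 1L) * 5L + 4L, ] <- base + as.numeric(fr %*% tpl$O)
    xyz[(i - 1L) * 5L + 5L, ] <- base + as.numeric(fr %*% tpl$CB)
  }
  cc_model(chain = rep(chain, n * 5L), resno = rep(seq_len(n), each = 5L),
           resid = rep(resid, n * 5L), atom = rep(atoms, n), xyz = xyz)
}

rotz <- function(deg) {
  th <- deg2rad(deg)
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

#' Build a Cn-symmetric coiled-coil from Crick parameters
#'
#' Generates the CA trace of chain A from the Crick superhelix equations and
#' replicates it by exact rotations of 360/order degrees about the supercoil
#' (z) axis, so the Cn symmetry of the output is exact to numerical precision.
#' Backbone atoms (N, C, O, CB) are rebuilt around the CA trace from a
#' canonical helical template unless `atoms = "CA"`.
#'
#' @param params a [crick_params()].
#' @param atoms `"backbone"` (N, CA, C, O, CB) or `"CA"` (CA-only trace).
#' @return A `cc_model` with `params$order` chains named A, B, C, D.
#' @export
build_crick_coiled_coil <- function(params, atoms = c("backbone", "CA")) {
  stopifnot(inherits(params, "crick_params"))
  atoms <- match.arg(atoms)
  ca <- crick_ca_trace(params, phase_offset = params$phase_offsets[1L])
  chain_a <- if (atoms == "CA") {
    cc_model(chain = rep("A", nrow(ca)), resno = seq_len(nrow(ca)),
             resid = rep("ALA", nrow(ca)), atom = rep("CA", nrow(ca)), xyz = ca)
  } else decorate_ca_trace(ca, chain = "A")
  if (params$order == 1L) return(chain_a)
  parts <- vector("list", params$order)
  parts[[1L]] <- chain_a
  for (k in seq_len(params$order - 1L)) {
    rot <- rotz(params$phase_offsets[k + 1L] - params$phase_offsets[1L])
    m <- transform_model(chain_a, rot = rot)
    m$chain <- rep(LETTERS[k + 1L], nrow(m))
    parts[[k + 1L]] <- m
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("cc_model", "data.frame")
  out
}

#' Decoy noise specification
#'
#' Controls the synthetic decoy generator that emulates the output of ab
#' initio modelling: `n_conformers` distinct base conformers (stand-ins for
#' the basins of an ab initio decoy distribution) are derived from the base
#' Crick parameters by supercoil-parameter modulation, and each decoy is a
#' perturbed copy of one conformer with isotropic per-atom Gaussian noise
#' plus extra scatter on `fray_len` residues at either terminus (terminal
#' fraying). Generation is a pure function of (base, spec): the same seed
#' reproduces bit-identical coordinates.
#'
#' @param sigma isotropic per-atom Gaussian displacement sd, A.
#' @param fray_len number of residues at each terminus given extra scatter.
#' @param fray_sigma extra terminal scatter sd, A.
#' @param n_conformers number of distinct base conformers.
#' @param n_decoys total number of decoys.
#' @param seed integer RNG seed.
#' @param jitter_r0,jitter_pitch,jitter_phase per-decoy within-conformer
#'   jitter sds on superhelix radius (A), pitch (A) and minor phase (degrees).
#' @return An object of class `decoy_noise_spec`.
#' @export
decoy_noise_spec <- function(sigma = 0.3, fray_len = 5, fray_sigma = 0.5,
                             n_conformers = 10, n_decoys = 1000, seed = 1,
                             jitter_r0 = 0.1, jitter_pitch = 1,
                             jitter_phase = 2) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (fray_len < 0 || fray_sigma < 0) stop("fray parameters must be >= 0")
  if (n_decoys < 1) stop("n_decoys must be >= 1")
  if (n_conformers < 1) stop("n_conformers must be >= 1")
  structure(list(sigma = sigma, fray_len = as.integer(fray_len),
                 fray_sigma = fray_sigma, n_conformers = as.integer(n_conformers),
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 jitter_r0 = jitter_r0, jitter_pitch = jitter_pitch,
                 jitter_phase = jitter_phase),
            class = "decoy_noise_spec")
}

# Fixed layout of conformer basins in (r0, pitch) space. Basins are spaced so
# that their pairwise CA RMSD far exceeds the within-basin noise scale, which
# is the separation property the ensembler exploits.
conformer_basins <- function(k, base) {
  layout <- cbind(
    r0    = c(7.0, 2.5, 7.0, 5.5, 4.0, 2.5, 7.0, 2.5, 4.0, 4.0),
    pitch = c(40, -100, -40, 65, -40, 40, -65, 100, -65, 40)
  )
  idx <- ((seq_len(k) - 1L) %% nrow(layout)) + 1L
  out <- layout[idx, , drop = FALSE]
  # additional cycles (k > 10) shift r0 to stay distinguishable
  out[, "r0"] <- out[, "r0"] + 0.8 * ((seq_len(k) - 1L) %/% nrow(layout))
  if (k == 1L) out <- cbind(r0 = base$r0, pitch = base$pitch)
  out
}

#' Generate a seeded set of noisy decoy models
#'
#' Emulates an ab initio decoy set: each decoy is a perturbed copy of one of
#' `noise$n_conformers` base conformers. When `base` is a [crick_params()],
#' conformers are Crick builds whose (r0, pitch) are taken from a fixed
#' well-separated basin layout and each decoy additionally receives a small
#' within-conformer supercoil-parameter jitter; when `base` is a `cc_model`,
#' all conformers equal the base (no parametric jitter is available). Per-atom
#' isotropic Gaussian noise of sd `sigma` is added everywhere and the
#' `fray_len` terminal residues receive extra `fray_sigma` scatter at both
#' ends.
#'
#' @param base a [crick_params()] or a `cc_model`.
#' @param noise a [decoy_noise_spec()].
#' @param atoms atom selection passed to the builder (`"CA"` keeps decoy sets
#'   light; `"backbone"` builds full backbones).
#' @return A list of `cc_model` decoys with attribute `conformer` (integer
#'   assignment vector).
#' @export
generate_decoys <- function(base, noise, atoms = c("CA", "backbone")) {
  stopifnot(inherits(noise, "decoy_noise_spec"))
  atoms <- match.arg(atoms)
  with_local_seed(noise$seed, {
    parametric <- inherits(base, "crick_params")
    if (!parametric && !inherits(base, "cc_model"))
      stop("base must be crick_params or cc_model")
    basins <- if (parametric) conformer_basins(noise$n_conformers, base)
    assign_conf <- sample.int(noise$n_conformers, noise$n_decoys, replace = TRUE)
    decoys <- vector("list", noise$n_decoys)
    for (d in seq_len(noise$n_decoys)) {
      if (parametric) {
        p <- base
        p$r0 <- max(0, basins[assign_conf[d], "r0"] + rnorm(1L, 0, noise$jitter_r0))
        p$pitch <- basins[assign_conf[d], "pitch"] + rnorm(1L, 0, noise$jitter_pitch)
        p$minor_phase <- base$minor_phase + rnorm(1L, 0, noise$jitter_phase)
        m <- build_crick_coiled_coil(p, atoms = atoms)
      } else {
        m <- base
      }
      xyz <- as.matrix(m[, c("x", "y", "z")])
      if (noise$sigma > 0)
        xyz <- xyz + matrix(rnorm(length(xyz), 0, noise$sigma), ncol = 3L)
      if (noise$fray_len > 0 && noise$fray_sigma > 0) {
        nres <- max(m$resno)
        frayed <- m$resno <= noise$fray_len | m$resno > nres - noise$fray_len
        if (any(frayed))
          xyz[frayed, ] <- xyz[frayed, ] +
            matrix(rnorm(3L * sum(frayed), 0, noise$fray_sigma), ncol = 3L)
      }
      decoys[[d]] <- set_coords(m, xyz)
    }
    names(decoys) <- sprintf("decoy_%04d", seq_along(decoys))
    attr(decoys, "conformer") <- assign_conf
    decoys
  })
}
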