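# Coiled-coil geometry analysis: local helix axes by the Sugeta-Miyazawa
# sliding-window construction, per-chain helical parameters, and supercoil
# parameters (radius, handedness, axial pitch) from the axis polyline.

perp <- function(v, axis) v - sum(v * axis) * axis

signed_angle <- function(a, b, axis) {
  atan2(sum(cross3(a, b) * axis), sum(a * b))
}

#' Local helix axis from a CA trace
#'
#' Sliding four-residue-window construction of the local helix axis: for each
#' window the local rotation per residue, minor-helix radius and an axis point
#' under each of the two interior residues are derived from the difference
#' vectors of consecutive CA positions (exact for an ideal helix). Axis points
#' contributed by overlapping windows are averaged.
#'
#' @param ca numeric n x 3 matrix of CA positions (n >= 4).
#' @return A list with `axis` ((n-2) x 3 axis points under residues
#'   2..n-1), `omega` (mean local rotation per residue, degrees), `radius`
#'   (mean minor-helix radius, A) and `rise` (mean spacing of consecutive
#'   axis points, A).
#' @export
local_axes <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4L) stop("need >= 4 CA positions to construct a local axis")
  acc <- matrix(0, n, 3L); cnt <- numeric(n)
  omegas <- radii <- numeric(0)
  for (i in seq_len(n - 3L)) {
    p <- ca[i:(i + 3L), ]
    u <- p[1L, ] - 2 * p[2L, ] + p[3L, ]
    v <- p[2L, ] - 2 * p[3L, ] + p[4L, ]
    nu <- vnorm(u); nv <- vnorm(v)
    if (nu < 1e-9 || nv < 1e-9) next       # locally straight: no axis offset
    cw <- max(-1, min(1, sum(u * v) / (nu * nv)))
    omega <- acos(cw)
    omegas <- c(omegas, omega)
    r <- (nu + nv) / 2 / (2 * (1 - cos(omega)))
    radii <- c(radii, r)
    acc[i + 1L, ] <- acc[i + 1L, ] + p[2L, ] + r * u / nu
    acc[i + 2L, ] <- acc[i + 2L, ] + p[3L, ] + r * v / nv
    cnt[i + 1L] <- cnt[i + 1L] + 1; cnt[i + 2L] <- cnt[i + 2L] + 1
  }
  idx <- 2:(n - 1L)
  axis <- acc[idx, , drop = FALSE] / cnt[idx]
  if (any(cnt[idx] == 0)) {                # degenerate (e.g. fully extended)
    axis[cnt[idx] == 0, ] <- ca[idx, , drop = FALSE][cnt[idx] == 0, ]
  }
  list(axis = axis,
       omega = if (length(omegas)) rad2deg(mean(omegas)) else 180,
       radius = if (length(radii)) mean(radii) else 0,
       rise = mean(sqrt(rowSums(diff(axis)^2))))
}

# Global helix fit to a smooth polyline (the axis points of a supercoiled
# chain). For an ideal helix the second-difference vectors of consecutive
# points are perpendicular to the helix axis, so the axis direction is the
# smallest principal direction of the second-difference matrix; the radius
# and central path then follow from a circle fit in the normal plane.
fit_helix_axis <- function(O, smooth_window = 7L) {
  # the raw axis polyline carries a residual wobble at the local helical
  # periodicity; a boxcar over ~two local turns removes it before fitting
  k <- min(smooth_window, nrow(O) - 3L)
  Os <- if (k >= 2L) {
    apply(O, 2L, function(v) as.numeric(stats::filter(v, rep(1 / k, k))))
  } else O
  Os <- Os[stats::complete.cases(Os), , drop = FALSE]
  n <- nrow(Os)
  U <- Os[1:(n - 2L), , drop = FALSE] - 2 * Os[2:(n - 1L), , drop = FALSE] +
    Os[3:n, , drop = FALSE]
  dir <- svd(U)$v[, 3L]
  if (sum(dir * (Os[n, ] - Os[1L, ])) < 0) dir <- -dir
  ctr <- colMeans(Os)
  Q <- sweep(Os, 2L, ctr)
  e1 <- unitv(perp(if (abs(dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0), dir))
  e2 <- cross3(dir, e1)
  x <- as.numeric(Q %*% e1); y <- as.numeric(Q %*% e2)
  A <- cbind(x, y, 1)
  cf <- solve(crossprod(A), crossprod(A, -(x^2 + y^2)))
  p0 <- ctr + (-cf[1L] / 2) * e1 + (-cf[2L] / 2) * e2   # point on the axis
  project <- function(pts)
    matrix(rep(p0, each = nrow(pts)), ncol = 3L) +
      outer(as.numeric(sweep(pts, 2L, p0) %*% dir), dir)
  list(dir = dir, project = project)
}

# Straightness of a polyline: max deviation from the best-fit line through it.
line_deviation <- function(pts) {
  ctr <- colMeans(pts)
  d <- svd(sweep(pts, 2L, ctr))
  dir <- d$v[, 1L]
  resid <- sweep(pts, 2L, ctr)
  resid <- resid - outer(as.numeric(resid %*% dir), dir)
  max(sqrt(rowSums(resid^2)))
}

# Analyse one chain against a central supercoil path (common residue index
# range). Returns supercoil-frame quantities.
chain_supercoil <- function(ca, O, C, idx) {
  # idx: residue numbers covered by both O (axis) and C (central path) rows
  axis_dir <- unitv(C[nrow(C), ] - C[1L, ])
  rho <- O - C
  rho_p <- t(apply(rho, 1L, perp, axis = axis_dir))
  r0 <- mean(sqrt(rowSums(rho_p^2)))
  dz <- mean(as.numeric(diff(C) %*% axis_dir))
  steps <- numeric(nrow(O) - 1L)
  for (t in seq_len(nrow(O) - 1L))
    steps[t] <- signed_angle(unitv(rho_p[t, ]), unitv(rho_p[t + 1L, ]), axis_dir)
  # local minor-helix phase relative to the outward radial reference
  th1 <- numeric(nrow(O))
  for (t in seq_len(nrow(O))) {
    tl <- if (t == 1L) 1L else t - 1L
    tu <- if (t == nrow(O)) nrow(O) else t + 1L
    tau <- unitv(O[tu, ] - O[tl, ])
    a <- perp(ca[idx[t], ] - O[t, ], tau)
    ref <- perp(rho[t, ], tau)
    th1[t] <- signed_angle(unitv(ref), unitv(a), tau)
  }
  dth1 <- diff(th1)
  dth1 <- ifelse(dth1 > pi, dth1 - 2 * pi, ifelse(dth1 < -pi, dth1 + 2 * pi, dth1))
  list(r0 = r0, dz = dz, sc_steps = rad2deg(steps),
       omega1 = rad2deg(mean(abs(dth1))), axis_dir = axis_dir)
}

#' Measure coiled-coil geometry
#'
#' Computes per-chain helical parameters (rise per residue along the local
#' axis, residues per turn, helical pitch) and, where a supercoil is present,
#' the supercoil radius, handedness, interhelical crossing angle and the
#' axial translation per alpha-helical turn measured along the supercoil
#' axis. For oligomers with equal-length chains the supercoil central axis is
#' the per-residue mean of the chains' local axis points; for single chains
#' it is recovered from the curvature of the chain's own axis polyline.
#' Handedness is reported as `"L"`, `"R"`, `"mixed"` (sign changes along the
#' length) or `"none"` (no supercoil or non-helical chain), with
#' per-window labels retained in `sc_steps`.
#'
#' @param model a `cc_model` (CA-only is sufficient).
#' @param straight_r0 supercoil radii below this value (A) are treated as
#'   straight (no supercoil).
#' @return An object of class `cc_geometry`: a list with fields
#'   `rise_per_residue`, `residues_per_turn`, `helical_pitch`,
#'   `minor_radius`, `supercoil_radius`, `axial_rise`,
#'   `axial_pitch_per_turn`, `crossing_angle`, `handedness`, `helical`,
#'   `sc_steps`, `axes` (per-chain axis polylines) and `diagnostics`.
#' @export
measure_geometry <- function(model, straight_r0 = 0.25) {
  chains <- model_chains(model)
  cas <- lapply(chains, function(ch) ca_coords(model, ch))
  names(cas) <- chains
  sms <- lapply(cas, local_axes)
  diag_notes <- character(0)

  rise <- mean(vapply(sms, `[[`, numeric(1L), "rise"))
  omega_sm <- mean(vapply(sms, `[[`, numeric(1L), "omega"))
  minor_radius <- mean(vapply(sms, `[[`, numeric(1L), "radius"))

  nres <- vapply(cas, nrow, integer(1L))
  equal_len <- length(unique(nres)) == 1L
  sc <- NULL
  if (length(chains) >= 2L && equal_len) {
    O_all <- lapply(sms, `[[`, "axis")
    C <- Reduce(`+`, O_all) / length(O_all)
    idx <- 2:(nres[1L] - 1L)
    sc <- lapply(seq_along(chains), function(k)
      chain_supercoil(cas[[k]], O_all[[k]], C, idx))
  } else {
    # single chain (or ragged oligomer): supercoil path from the curvature of
    # each chain's own axis polyline
    sc <- lapply(seq_along(chains), function(k) {
      O <- sms[[k]]$axis
      if (nrow(O) < 10L || line_deviation(O) < 0.05) return(NULL)
      fit <- fit_helix_axis(O)
      chain_supercoil(cas[[k]], O, fit$project(O), 2:(nres[k] - 1L))
    })
    sc <- Filter(Negate(is.null), sc)
    if (length(sc) == 0L) sc <- NULL
  }

  r0 <- if (is.null(sc)) 0 else mean(vapply(sc, `[[`, numeric(1L), "r0"))
  supercoiled <- !is.null(sc) && r0 >= straight_r0

  if (supercoiled) {
    res_turn <- mean(vapply(sc, function(s) 360 / s$omega1, numeric(1L)))
    dz <- mean(vapply(sc, `[[`, numeric(1L), "dz"))
    steps <- unlist(lapply(sc, `[[`, "sc_steps"))
  } else {
    res_turn <- 360 / omega_sm
    dz <- rise
    steps <- numeric(0)
  }
  helical <- is.finite(res_turn) && res_turn > 3 && res_turn < 4.6 &&
    rise > 0.9 && rise < 2.2
  if (!helical)
    diag_notes <- c(diag_notes, sprintf(
      "non-helical chain geometry (residues/turn %.2f, rise %.2f A)",
      res_turn, rise))

  handedness <- "none"
  if (supercoiled && helical && length(steps)) {
    sig <- steps[abs(steps) > 0.2]
    if (length(sig)) {
      fr_neg <- mean(sig < 0)
      handedness <- if (fr_neg >= 0.8) "L" else if (fr_neg <= 0.2) "R" else "mixed"
    }
  }

  crossing <- 0
  if (length(chains) >= 2L && equal_len && supercoiled) {
    # per-residue angle between local axis tangents of adjacent chain pairs
    O_all <- lapply(sms, `[[`, "axis")
    angs <- c()
    for (k in seq_len(length(chains) - 1L)) {
      Oa <- O_all[[k]]; Ob <- O_all[[k + 1L]]
      for (t in 2:(nrow(Oa) - 1L)) {
        ta <- unitv(Oa[t + 1L, ] - Oa[t - 1L, ])
        tb <- unitv(Ob[t + 1L, ] - Ob[t - 1L, ])
        angs <- c(angs, acos(max(-1, min(1, sum(ta * tb)))))
      }
    }
    crossing <- rad2deg(mean(angs))
  }

  structure(list(
    rise_per_residue = rise,
    residues_per_turn = res_turn,
    helical_pitch = rise * res_turn,
    minor_radius = minor_radius,
    supercoil_radius = if (supercoiled) r0 else 0,
    axial_rise = dz,
    axial_pitch_per_turn = dz * res_turn,
    crossing_angle = crossing,
    handedness = handedness,
    helical = helical,
    sc_steps = steps,
    axes = lapply(sms, `[[`, "axis"),
    diagnostics = diag_notes
  ), class = "cc_geometry")
}

#' @export
print.cc_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("cc_geometry: rise %.3f A/res, %.3f res/turn, pitch %.3f A\n",
           "  supercoil: radius %.2f A, axial pitch %.3f A/turn, ",
           "crossing %.1f deg, handedness %s\n"),
    x$rise_per_residue, x$residues_per_turn, x$helical_pitch,
    x$supercoil_radius, x$axial_pitch_per_turn, x$crossing_angle,
    x$handedness))
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}
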