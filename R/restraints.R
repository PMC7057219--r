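# Distance-restraint and symmetry-definition generation for unbiased
# oligomeric coiled-coil modelling, plus molecular-replacement keyword
# emission (tNCS correction off).

#' Restraint configuration
#'
#' Defaults encode the unbiased coiled-coil restraint scheme: a long-range
#' N-to-C restraint centred at 1.5 A per residue (the alpha-helical rise)
#' and per-residue short-range restraints between symmetry-related CA copies
#' centred at 10 A with a +-5 A flat width and 3 A standard deviation, i.e.
#' no penalty between 5 and 15 A.
#'
#' @param elongation_coefficient A per residue for the long-range centre.
#' @param short_center short-range restraint centre, A.
#' @param short_tol flat half-width of the short-range restraint, A.
#' @param short_sd standard deviation outside the flat region, A.
#' @param long_tol,long_sd flat half-width and sd of the long-range restraint, A.
#' @param rg_reweight radius-of-gyration reweight recorded in the flags file
#'   (0 removes the globularity bias of the external modeller).
#' @return An object of class `restraint_config`.
#' @export
restraint_config <- function(elongation_coefficient = 1.5, short_center = 10,
                             short_tol = 5, short_sd = 3,
                             long_tol = 5, long_sd = 3, rg_reweight = 0) {
  stopifnot(elongation_coefficient > 0, short_center > 0, short_tol >= 0,
            short_sd > 0, long_tol >= 0, long_sd > 0, rg_reweight >= 0)
  structure(list(elongation_coefficient = elongation_coefficient,
                 short_center = short_center, short_tol = short_tol,
                 short_sd = short_sd, long_tol = long_tol, long_sd = long_sd,
                 rg_reweight = rg_reweight),
            class = "restraint_config")
}

new_constraint <- function(res_a, res_b, copy_a, copy_b, x0, sd, tol) {
  stopifnot(x0 > 0, sd > 0, tol >= 0)
  structure(list(atom = "CA", res_a = as.integer(res_a),
                 res_b = as.integer(res_b), copy_a = as.integer(copy_a),
                 copy_b = as.integer(copy_b), fun = "FLAT_HARMONIC",
                 x0 = x0, sd = sd, tol = tol),
            class = "constraint_record")
}

#' Flat-harmonic penalty
#'
#' Evaluates the flat-harmonic restraint penalty: zero for
#' `|x - x0| <= tol`, and `((|x - x0| - tol) / sd)^2` outside the flat
#' region, so the penalty is symmetric about the flat window and strictly
#' increasing away from it.
#'
#' @param x distance(s), A.
#' @param x0 centre, A.
#' @param sd standard deviation, A.
#' @param tol flat half-width, A.
#' @return Penalty value(s).
#' @export
flat_harmonic <- function(x, x0, sd, tol) {
  excess <- pmax(abs(x - x0) - tol, 0)
  (excess / sd)^2
}

#' Penalty of a constraint record at given distances
#' @param record a `constraint_record`.
#' @param x distance(s), A.
#' @return Penalty value(s).
#' @export
constraint_penalty <- function(record, x)
  flat_harmonic(x, record$x0, record$sd, record$tol)

#' Long-range elongation restraint
#'
#' A flat-harmonic restraint between the CA atoms of the first and last
#' residues with centre `elongation_coefficient * n_res` (1.5n by default,
#' the length of an ideal alpha-helix of n residues), forcing elongated
#' rather than globular builds.
#'
#' @param n_res number of residues (>= 2).
#' @param cfg a [restraint_config()].
#' @return A `constraint_record`.
#' @export
elongation_restraint <- function(n_res, cfg = restraint_config()) {
  if (n_res < 2) stop("degenerate input: n_res must be >= 2")
  new_constraint(1L, as.integer(n_res), 1L, 1L,
                 x0 = cfg$elongation_coefficient * n_res,
                 sd = cfg$long_sd, tol = cfg$long_tol)
}

#' Oligomeric coiled-coil constraint set
#'
#' One long-range elongation restraint (centre 1.5n) plus one short-range
#' restraint per residue between cyclically adjacent symmetry copies of that
#' residue's CA (centre 10 A, flat width +-5 A, sd 3 A), leaving inter-chain
#' distances unpenalized between 5 and 15 A.
#'
#' @param n_res residues per chain (>= 2).
#' @param order oligomer order, one of 2, 3, 4.
#' @param cfg a [restraint_config()].
#' @return An object of class `constraint_set`: list with `long_range` (one
#'   record), `short_range` (list of n_res records), `n_res`, `order`.
#' @export
oligomer_constraints <- function(n_res, order, cfg = restraint_config()) {
  if (!order %in% 2:4)
    stop("unsupported oligomer order: ", order, " (dimer|trimer|tetramer)")
  if (n_res < 2) stop("degenerate input: n_res must be >= 2")
  short <- lapply(seq_len(n_res), function(i)
    new_constraint(i, i, 1L, 2L, x0 = cfg$short_center, sd = cfg$short_sd,
                   tol = cfg$short_tol))
  structure(list(long_range = elongation_restraint(n_res, cfg),
                 short_range = short, n_res = as.integer(n_res),
                 order = as.integer(order)),
            class = "constraint_set")
}

# one text line per record; inter-copy residues are addressed by global
# numbering (copy k residue i -> (k-1) n + i)
format_constraint <- function(rec, n_res) {
  ga <- (rec$copy_a - 1L) * n_res + rec$res_a
  gb <- (rec$copy_b - 1L) * n_res + rec$res_b
  sprintf("AtomPair %s %d %s %d %s %g %g %g",
          rec$atom, ga, rec$atom, gb, rec$fun, rec$x0, rec$sd, rec$tol)
}

#' Write a constraint set as a constraints file
#'
#' One `AtomPair CA <i> CA <j> FLAT_HARMONIC <x0> <sd> <tol>` line per
#' record; symmetry copies are addressed by global residue numbering.
#'
#' @param cs a `constraint_set` (or a single `constraint_record`).
#' @param file output path.
#' @param n_res residue count per chain (taken from `cs` when present).
#' @return `file`, invisibly.
#' @export
write_constraints <- function(cs, file, n_res = cs$n_res) {
  recs <- if (inherits(cs, "constraint_record")) list(cs)
  else c(list(cs$long_range), cs$short_range)
  writeLines(vapply(recs, format_constraint, character(1L), n_res = n_res),
             file)
  invisible(file)
}

#' Parse a constraints file
#'
#' Inverse of [write_constraints()]: reads `AtomPair ... FLAT_HARMONIC`
#' lines into a data frame of records with global residue numbering.
#'
#' @param file path to a constraints file.
#' @return Data frame with columns atom_a, res_a, atom_b, res_b, fun, x0,
#'   sd, tol.
#' @export
read_constraints <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(trimws(ln))]
  parts <- strsplit(trimws(ln), "\\s+")
  bad <- vapply(parts, function(p) length(p) != 9L || p[1L] != "AtomPair",
                logical(1L))
  if (any(bad)) stop("unrecognized constraint line: ", ln[which(bad)[1L]])
  do.call(rbind, lapply(parts, function(p) data.frame(
    atom_a = p[2L], res_a = as.integer(p[3L]),
    atom_b = p[4L], res_b = as.integer(p[5L]),
    fun = p[6L], x0 = as.numeric(p[7L]), sd = as.numeric(p[8L]),
    tol = as.numeric(p[9L]))))
}

#' Cn symmetry definition
#'
#' A cyclic point group of the given order with its generator rotation of
#' 360/order degrees about z. Only C2, C3 and C4 (parallel dimers, trimers,
#' tetramers) are supported.
#'
#' @param order oligomer order, one of 2, 3, 4.
#' @return An object of class `symmetry_def`: list with `point_group`,
#'   `order`, `angle` (degrees) and `generator` (3x3 rotation matrix).
#' @export
symmetry_definition <- function(order) {
  if (!order %in% 2:4)
    stop("unsupported oligomer order: ", order, " (dimer|trimer|tetramer)")
  structure(list(point_group = paste0("C", order), order = as.integer(order),
                 angle = 360 / order, generator = rotz(360 / order)),
            class = "symmetry_def")
}

#' Write a symmetry definition file
#' @param sym a `symmetry_def`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_symmetry <- function(sym, file) {
  writeLines(c(
    sprintf("symmetry_name %s", tolower(sym$point_group)),
    sprintf("subunits %d", sym$order),
    "rotation_axis z",
    sprintf("angle %g", sym$angle)
  ), file)
  invisible(file)
}

#' Parse a symmetry definition file
#' @param file path written by [write_symmetry()].
#' @return A `symmetry_def`.
#' @export
read_symmetry <- function(file) {
  ln <- readLines(file)
  get <- function(key) sub(paste0("^", key, " "), "",
                           ln[startsWith(ln, paste0(key, " "))])
  symmetry_definition(as.integer(get("subunits")))
}

#' Molecular-replacement keyword block
#'
#' Emits the keyword text that disables translational-NCS correction in
#' molecular replacement. tNCS is frequently detected spuriously for
#' coiled-coils (their internal periodicity produces non-origin Patterson
#' peaks), and correcting for it can preclude solution, so coiled-coil runs
#' default to switching it off.
#'
#' @param tncs_off disable tNCS correction (default TRUE in coiled-coil mode).
#' @return Character vector of keyword lines (empty when nothing is set).
#' @export
mr_keywords <- function(tncs_off = TRUE) {
  if (isTRUE(tncs_off)) "PKEY TNCS USE OFF" else character(0)
}

#' Parse a molecular-replacement keyword block
#' @param lines character vector as returned by [mr_keywords()].
#' @return List with logical `tncs_off`.
#' @export
parse_mr_keywords <- function(lines) {
  list(tncs_off = any(grepl("TNCS USE OFF", lines, fixed = TRUE)))
}

#' Write the modelling flags file
#'
#' Records the option settings handed to the external ab initio modeller:
#' `-rg_reweight` (0 removes the globularity bias) and
#' `-domain_termini_distance` (1.5n, the elongation restraint centre), plus
#' the symmetry flags for oligomeric runs.
#'
#' @param n_res number of residues.
#' @param cfg a [restraint_config()].
#' @param order optional oligomer order for oligomeric modelling.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_flags <- function(n_res, cfg = restraint_config(), order = NULL, file) {
  ln <- c(sprintf("-rg_reweight %g", cfg$rg_reweight),
          sprintf("-domain_termini_distance %g",
                  cfg$elongation_coefficient * n_res))
  if (!is.null(order))
    ln <- c(ln, sprintf("-multimer_modelling %s",
                        c("2" = "dimer", "3" = "trimer",
                          "4" = "tetramer")[as.character(order)]))
  writeLines(ln, file)
  invisible(file)
}
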