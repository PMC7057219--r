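#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

#' Coordinate model container
#'
#' A `cc_model` is a light hierarchical coordinate set: a data frame of atom
#' records (one row per atom) carrying chain id, 1-based residue number,
#' 3-letter residue name, atom name, element and Cartesian coordinates in
#' Angstrom. It is the common currency of the builder, ensembler, oligomer
#' preparation and geometry modules.
#'
#' @param chain character vector of chain ids (e.g. "A").
#' @param resno integer vector of residue numbers (1-based, strictly
#'   increasing within a chain).
#' @param resid character vector of 3-letter residue names.
#' @param atom character vector of atom names (N, CA, C, O, CB, ...).
#' @param xyz numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @param element optional element symbols; derived from the atom name when
#'   omitted.
#' @return An object of class `cc_model`.
#' @export
cc_model <- function(chain, resno, resid, atom, xyz, element = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(atom))
  if (is.null(element)) element <- substr(atom, 1L, 1L)
  m <- data.frame(
    chain = as.character(chain),
    resno = as.integer(resno),
    resid = as.character(resid),
    atom = as.character(atom),
    element = as.character(element),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE
  )
  class(m) <- c("cc_model", "data.frame")
  validate_model(m)
  m
}

#' Validate a coordinate model
#'
#' Checks the structural invariants: finite coordinates, non-empty atom names,
#' unique chain ids with strictly increasing residue numbers, and a CA atom in
#' every residue. With `require_backbone = TRUE` each residue must additionally
#' carry N and C.
#'
#' @param model a `cc_model`.
#' @param require_backbone require N and C atoms in every residue.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model, require_backbone = FALSE) {
  stopifnot(inherits(model, "cc_model"))
  if (nrow(model) == 0L) stop("model has no atoms")
  if (!all(is.finite(as.matrix(model[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(!nzchar(model$atom))) stop("empty atom name")
  for (ch in unique(model$chain)) {
    rn <- unique(model$resno[model$chain == ch])
    if (any(diff(rn) <= 0L))
      stop("residue numbers not strictly increasing in chain ", ch)
    per <- split(model$atom[model$chain == ch], model$resno[model$chain == ch])
    need <- if (require_backbone) c("N", "CA", "C") else "CA"
    ok <- vapply(per, function(a) all(need %in% a), logical(1L))
    if (!all(ok))
      stop("chain ", ch, ": residue missing ", paste(need, collapse = "/"))
  }
  invisible(model)
}

#' @export
print.cc_model <- function(x, ...) {
  ch <- unique(x$chain)
  nres <- vapply(ch, function(c) length(unique(x$resno[x$chain == c])), integer(1L))
  cat("cc_model:", length(ch), "chain(s),",
      paste0(ch, "(", nres, ")", collapse = " "), "-", nrow(x), "atoms\n")
  invisible(x)
}

#' Chain ids of a model
#' @param model a `cc_model`.
#' @return Character vector of chain ids in order of first appearance.
#' @export
model_chains <- function(model) unique(model$chain)

#' Number of residues per chain
#' @param model a `cc_model`.
#' @param chain optional chain id; all chains when omitted.
#' @return Named integer vector of residue counts.
#' @export
model_nres <- function(model, chain = NULL) {
  ch <- if (is.null(chain)) model_chains(model) else chain
  setNames(vapply(ch, function(c) length(unique(model$resno[model$chain == c])),
                  integer(1L)), ch)
}

#' Extract CA coordinates
#'
#' @param model a `cc_model`.
#' @param chain optional chain id filter.
#' @return Numeric matrix (n x 3) of CA positions in chain/residue order.
#' @export
ca_coords <- function(model, chain = NULL) {
  sel <- model$atom == "CA"
  if (!is.null(chain)) sel <- sel & model$chain %in% chain
  as.matrix(model[sel, c("x", "y", "z"), drop = FALSE])
}

#' Replace coordinates of a model
#' @param model a `cc_model`.
#' @param xyz numeric matrix (n_atoms x 3).
#' @return The model with coordinates replaced.
#' @export
set_coords <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(model), ncol(xyz) == 3L)
  model$x <- xyz[, 1L]; model$y <- xyz[, 2L]; model$z <- xyz[, 3L]
  model
}

#' Apply a rigid-body transform
#' @param model a `cc_model`.
#' @param rot 3x3 rotation matrix.
#' @param trans length-3 translation, applied after rotation.
#' @return Transformed model.
#' @export
transform_model <- function(model, rot = diag(3), trans = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  set_coords(model, sweep(xyz %*% t(rot), 2L, -trans))
}

#' Write a model as a PDB file
#'
#' Serializes ATOM records through bio3d. Chains keep their ids; residue
#' numbering is written as stored.
#'
#' @param model a `cc_model`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_model_pdb <- function(model, file) {
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = file, xyz = xyz,
    resno = model$resno, resid = model$resid, chain = model$chain,
    elety = model$atom, elesy = model$element, eleno = seq_len(nrow(model))
  )
  invisible(file)
}

#' Read a model from a PDB file
#'
#' Reads ATOM records through bio3d and returns a `cc_model` (heteroatoms and
#' alternate locations other than the first are dropped).
#'
#' @param file path to a PDB file.
#' @return A `cc_model`.
#' @export
read_model_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", file)
  ch <- at$chain
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  cc_model(chain = ch, resno = at$resno, resid = at$resid,
           atom = at$elety, xyz = cbind(at$x, at$y, at$z),
           element = at$elesy)
}

#' Write sequences as FASTA
#' @param seqs named character vector of one-letter sequences.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = file, as.string = TRUE, nbchar = 60)
  invisible(file)
}

#' Read sequences from FASTA
#' @param file path to a FASTA file.
#' @return Named character vector of upper-case one-letter sequences.
#' @export
read_fasta <- function(file) {
  s <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE)
  setNames(toupper(vapply(s, as.character, character(1L))), names(s))
}

# internal: run expr with a local RNG seed, restoring global state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
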