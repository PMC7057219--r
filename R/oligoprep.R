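# Oligomer preparation for the crystallographic asymmetric unit: chain
# reduction and merge/renumber into a single consecutively numbered chain.

#' Asymmetric-unit specification
#'
#' @param nmasu number of chains in the asymmetric unit.
#' @param oligomer_order oligomer order of the modelled coiled-coil.
#' @return An object of class `asu_spec`.
#' @export
asu_spec <- function(nmasu, oligomer_order) {
  nmasu <- as.integer(nmasu); oligomer_order <- as.integer(oligomer_order)
  if (nmasu < 1L || nmasu > oligomer_order)
    stop("nmasu must satisfy 1 <= nmasu <= oligomer_order")
  structure(list(nmasu = nmasu, oligomer_order = oligomer_order),
            class = "asu_spec")
}

#' Reduce an oligomer to the asymmetric-unit chain count
#'
#' Retains the first `nmasu` chains in input order (chains A, B for a
#' tetramer with two chains in the asymmetric unit: a "half-tetramer").
#' Coordinates are untouched.
#'
#' @param model a `cc_model` whose chain count equals the oligomer order.
#' @param spec an [asu_spec()].
#' @return The reduced model.
#' @export
reduce_to_asu <- function(model, spec) {
  stopifnot(inherits(spec, "asu_spec"))
  chains <- model_chains(model)
  if (length(chains) != spec$oligomer_order)
    stop("model has ", length(chains), " chains; oligomer order is ",
         spec$oligomer_order)
  if (spec$nmasu > length(chains)) stop("nmasu exceeds chain count")
  out <- model[model$chain %in% chains[seq_len(spec$nmasu)], , drop = FALSE]
  class(out) <- c("cc_model", "data.frame")
  out
}

#' Merge chains into a single consecutively renumbered chain
#'
#' Reassigns every chain to chain A and renumbers residues consecutively
#' 1..sum(n_i) in original chain order, with no numbering gap between
#' merged copies. Atom records and coordinates are conserved.
#'
#' @param model a `cc_model` with >= 1 chain.
#' @return A single-chain `cc_model`.
#' @export
merge_renumber <- function(model) {
  chains <- model_chains(model)
  offset <- 0L
  pieces <- lapply(chains, function(ch) {
    part <- model[model$chain == ch, , drop = FALSE]
    old <- unique(part$resno)
    part$resno <- match(part$resno, old) + offset
    offset <<- offset + length(old)
    part$chain <- rep("A", nrow(part))
    part
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cc_model", "data.frame")
  out
}

#' Multiply a sequence for a merged oligomer
#'
#' Builds the sequence record matching a [merge_renumber()]ed model: the
#' input sequence repeated `copies` times as one record.
#'
#' @param seq one-letter sequence string.
#' @param copies number of copies (>= 1).
#' @return Named character vector of length 1 (a FASTA-ready record).
#' @export
multiplied_sequence <- function(seq, copies) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("seq must be a nonempty sequence string")
  if (copies < 1L) stop("copies must be >= 1")
  setNames(paste(rep(seq, copies), collapse = ""),
           sprintf("merged_%dx%d", copies, nchar(seq)))
}
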