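# Knobs-into-holes packing detection and the ideal-coiled-coil classifier.

# Side-chain centre proxy per residue: mean of side-chain atoms when present
# (CB only for alanine-level models), CA for glycine / CA-only residues.
residue_centers <- function(model) {
  side <- !model$atom %in% c("N", "CA", "C", "O")
  key <- paste(model$chain, model$resno)
  ukey <- unique(key)
  ctr <- matrix(0, length(ukey), 3L)
  for (i in seq_along(ukey)) {
    rows <- key == ukey[i] & side
    if (!any(rows)) rows <- key == ukey[i] & model$atom == "CA"
    ctr[i, ] <- colMeans(as.matrix(model[rows, c("x", "y", "z"), drop = FALSE]))
  }
  info <- model[!duplicated(key), c("chain", "resno")]
  list(chain = info$chain, resno = info$resno, xyz = ctr)
}

#' Detect knobs-into-holes packing
#'
#' A residue is a knob when its side-chain centre (CB for polyalanine;
#' CA where no side-chain atom exists) lies within `packing_cutoff` of the
#' side-chain centres of at least four residues of one partner chain; those
#' four nearest residues form the hole. Contiguous knob runs (gaps of up to
#' `max_gap` residues, spanning the 3/4 spacing of a heptad interface) on a
#' chain pair are merged into coiled-coil segments whose orientation is
#' assigned from the dot product of the two chains' axis directions.
#'
#' @param model a `cc_model` with at least 2 chains (single-chain input
#'   yields empty results).
#' @param packing_cutoff centre-centre distance cutoff, A.
#' @param max_gap largest gap (residues) bridged when merging knob runs.
#' @return A list with `knobs` (data frame: chain, resno, partner_chain, and
#'   hole residue numbers hole1..hole4) and `segments` (data frame: chains,
#'   per-chain residue ranges, orientation, coverage_fraction).
#' @export
detect_kih <- function(model, packing_cutoff = 7.5, max_gap = 4L) {
  chains <- model_chains(model)
  empty <- list(knobs = data.frame(), segments = data.frame())
  if (length(chains) < 2L) return(empty)
  ctr <- residue_centers(model)
  knobs <- NULL
  for (ci in chains) for (cj in setdiff(chains, ci)) {
    ii <- which(ctr$chain == ci); jj <- which(ctr$chain == cj)
    for (i in ii) {
      d <- sqrt(colSums((t(ctr$xyz[jj, , drop = FALSE]) - ctr$xyz[i, ])^2))
      if (sum(d <= packing_cutoff) >= 4L) {
        hole <- ctr$resno[jj][order(d)[1:4]]
        knobs <- rbind(knobs, data.frame(
          chain = ci, resno = ctr$resno[i], partner_chain = cj,
          hole1 = hole[1L], hole2 = hole[2L], hole3 = hole[3L],
          hole4 = hole[4L]))
      }
    }
  }
  if (is.null(knobs)) return(empty)

  axes_dir <- lapply(chains, function(ch) {
    ca <- ca_coords(model, ch)
    if (nrow(ca) < 4L) return(unitv(ca[nrow(ca), ] - ca[1L, ]))
    O <- local_axes(ca)$axis
    unitv(O[nrow(O), ] - O[1L, ])
  })
  names(axes_dir) <- chains

  total_res <- sum(model_nres(model))
  segments <- NULL
  pairs <- unique(t(apply(knobs[, c("chain", "partner_chain")], 1L, sort)))
  for (p in seq_len(nrow(pairs))) {
    ca_ <- pairs[p, 1L]; cb_ <- pairs[p, 2L]
    sel <- (knobs$chain == ca_ & knobs$partner_chain == cb_) |
      (knobs$chain == cb_ & knobs$partner_chain == ca_)
    # contiguous runs over the pooled knob positions of both chains
    for (run in split_runs(sort(unique(knobs$resno[sel])), max_gap)) {
      in_run <- sel & knobs$resno %in% run
      safe_range <- function(x) if (length(x)) range(x) else c(NA_integer_, NA_integer_)
      r_a <- safe_range(knobs$resno[in_run & knobs$chain == ca_])
      r_b <- safe_range(knobs$resno[in_run & knobs$chain == cb_])
      span <- function(r) if (anyNA(r)) 0L else r[2L] - r[1L] + 1L
      ori <- if (sum(axes_dir[[ca_]] * axes_dir[[cb_]]) >= 0)
        "parallel" else "antiparallel"
      segments <- rbind(segments, data.frame(
        chain_a = ca_, chain_b = cb_,
        from_a = r_a[1L], to_a = r_a[2L], from_b = r_b[1L], to_b = r_b[2L],
        orientation = ori,
        coverage_fraction = (span(r_a) + span(r_b)) / total_res))
    }
  }
  list(knobs = knobs, segments = segments)
}

split_runs <- function(x, max_gap) {
  if (length(x) == 0L) return(list())
  grp <- cumsum(c(1L, diff(x) > max_gap))
  split(x, grp)
}

#' Classify a model as an ideal coiled-coil target
#'
#' A model is an ideal coiled-coil target when knobs-into-holes detection
#' finds a single uninterrupted coiled-coil segment covering more than half
#' of the sequence. Overlapping segments between the same chain pair are
#' first merged; distinct chain pairs sharing a contiguous bundle (as in
#' Cn oligomers, where every adjacent chain pair packs) are counted as one
#' coiled-coil when their residue ranges agree.
#'
#' @param model a `cc_model`.
#' @param packing_cutoff,max_gap passed to [detect_kih()].
#' @param min_coverage minimum coverage fraction for ideality.
#' @return A list with `ideal` (logical), `coverage` (best single-segment
#'   coverage of the sequence), `n_segments` and `reasons` (character).
#' @export
classify_ideal <- function(model, packing_cutoff = 7.5, max_gap = 4L,
                           min_coverage = 0.5) {
  kih <- detect_kih(model, packing_cutoff = packing_cutoff, max_gap = max_gap)
  seg <- kih$segments
  if (is.null(seg) || nrow(seg) == 0L)
    return(list(ideal = FALSE, coverage = 0, n_segments = 0L,
                reasons = "no knobs-into-holes packing detected"))
  # merge segments of different chain pairs that span the same residue run:
  # a Cn bundle yields one segment per adjacent pair but one coiled-coil
  grp <- overlap_groups(seg)
  n_distinct <- length(unique(grp))
  total_res <- sum(model_nres(model))
  cov_by_grp <- vapply(unique(grp), function(g) {
    s <- seg[grp == g, , drop = FALSE]
    resid_cov <- 0L
    for (ch in unique(c(s$chain_a, s$chain_b))) {
      lo <- suppressWarnings(
        min(s$from_a[s$chain_a == ch], s$from_b[s$chain_b == ch], na.rm = TRUE))
      hi <- suppressWarnings(
        max(s$to_a[s$chain_a == ch], s$to_b[s$chain_b == ch], na.rm = TRUE))
      if (!is.finite(lo) || !is.finite(hi)) next
      resid_cov <- resid_cov + (hi - lo + 1L)
    }
    resid_cov / total_res
  }, numeric(1L))
  coverage <- max(cov_by_grp)
  reasons <- character(0)
  if (n_distinct > 1L)
    reasons <- c(reasons, sprintf("%d separate coiled-coil segments", n_distinct))
  if (coverage <= min_coverage)
    reasons <- c(reasons, sprintf("coverage %.2f <= %.2f", coverage, min_coverage))
  list(ideal = n_distinct == 1L && coverage > min_coverage,
       coverage = coverage, n_segments = n_distinct,
       reasons = if (length(reasons)) reasons else "single uninterrupted coiled-coil covering >50% of sequence")
}

# group segments whose residue spans overlap (across chain pairs)
overlap_groups <- function(seg) {
  n <- nrow(seg)
  lo <- pmin(seg$from_a, seg$from_b, na.rm = TRUE)
  hi <- pmax(seg$to_a, seg$to_b, na.rm = TRUE)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] != grp[j] && lo[i] <= hi[j] && lo[j] <= hi[i]) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}
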