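# Multi-metric triage of candidate crystallographic solutions. No single
# statistic is allowed to force acceptance: a solution is accepted only when
# the tracing correlation coefficient, R_free, the R - R_free gap and
# side-chain placement all pass, and any hard failure rejects it outright.

#' Solution statistics
#'
#' Per-solution crystallographic statistics used by the triage rules.
#' `r_gap` (R - R_free overfitting gap), `side_chains` and `map_cc` may be
#' `NA` when unknown; unknown values can prevent acceptance (borderline) but
#' never cause rejection.
#'
#' @param id solution identifier.
#' @param shelxe_cc tracing correlation coefficient, percent (>= 0).
#' @param r_free cross-validation R factor, in `[0, 1]`.
#' @param r_work optional working R factor; used to derive `r_gap` when that
#'   is not given directly.
#' @param r_gap optional R_free - R_work gap.
#' @param side_chains optional count of side chains placed during building.
#' @param map_cc optional map correlation against a reference structure.
#' @param llg,tfz optional molecular-replacement scores.
#' @return An object of class `solution_stats`.
#' @export
solution_stats <- function(id, shelxe_cc, r_free, r_work = NA_real_,
                           r_gap = NA_real_, side_chains = NA_integer_,
                           map_cc = NA_real_, llg = NA_real_, tfz = NA_real_) {
  if (is.na(shelxe_cc) || shelxe_cc < 0) stop("shelxe_cc must be >= 0")
  if (is.na(r_free) || r_free < 0 || r_free > 1)
    stop("r_free must lie in [0, 1]")
  if (is.na(r_gap) && !is.na(r_work)) r_gap <- r_free - r_work
  structure(list(id = as.character(id), shelxe_cc = shelxe_cc,
                 r_free = r_free, r_work = r_work, r_gap = r_gap,
                 side_chains = side_chains, map_cc = map_cc,
                 llg = llg, tfz = tfz),
            class = "solution_stats")
}

#' Triage thresholds
#'
#' Defaults follow the combined assessment heuristics for coiled-coil
#' molecular replacement: tracing CC > 30 with a demarcation of at least 5
#' over background, R_free < 0.45, R - R_free gap < 0.05, side chains
#' placed, and (when available) map correlation > 0.60 against a reference.
#' The legacy CC > 25 rule is kept as a hard floor.
#'
#' @param cc_min CC required for acceptance.
#' @param cc_demarcation_min minimum top-minus-background CC margin.
#' @param r_free_max maximum acceptable R_free.
#' @param r_gap_max maximum acceptable R - R_free gap.
#' @param map_cc_min minimum map correlation (when supplied).
#' @param legacy_cc_min hard CC floor below which solutions are rejected.
#' @param llg_min,tfz_min advisory molecular-replacement score floors.
#' @return An object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(cc_min = 30, cc_demarcation_min = 5,
                              r_free_max = 0.45, r_gap_max = 0.05,
                              map_cc_min = 0.60, legacy_cc_min = 25,
                              llg_min = 120, tfz_min = 8) {
  stopifnot(cc_min > 0, cc_demarcation_min > 0, r_free_max > 0,
            r_free_max < 1, r_gap_max > 0, map_cc_min > 0,
            legacy_cc_min > 0, llg_min > 0, tfz_min > 0)
  structure(list(cc_min = cc_min, cc_demarcation_min = cc_demarcation_min,
                 r_free_max = r_free_max, r_gap_max = r_gap_max,
                 map_cc_min = map_cc_min, legacy_cc_min = legacy_cc_min,
                 llg_min = llg_min, tfz_min = tfz_min),
            class = "triage_thresholds")
}

#' Assess one candidate solution
#'
#' Applies the combined-metric rules. Hard failures (any one rejects): CC at
#' or below the legacy floor, R_free at or above the maximum, R - R_free gap
#' above the maximum, zero side chains placed, or map correlation below the
#' minimum when supplied. Acceptance requires every acceptance rule to pass
#' (CC above `cc_min`, R_free below the maximum, gap within bounds,
#' side chains placed); anything else - including unknown gap or side-chain
#' information, or CC between the legacy floor and `cc_min` - is borderline.
#' No single passing metric can force acceptance.
#'
#' @param stats a [solution_stats()].
#' @param thresholds a [triage_thresholds()].
#' @return An object of class `triage_verdict`: list with `status`
#'   (`"accept"`, `"borderline"` or `"reject"`) and `reasons`.
#' @export
assess <- function(stats, thresholds = triage_thresholds()) {
  stopifnot(inherits(stats, "solution_stats"))
  th <- thresholds
  fail <- character(0)
  if (stats$shelxe_cc <= th$legacy_cc_min)
    fail <- c(fail, sprintf("CC %.1f <= legacy floor %.0f",
                            stats$shelxe_cc, th$legacy_cc_min))
  if (stats$r_free >= th$r_free_max)
    fail <- c(fail, sprintf("R_free %.2f >= %.2f", stats$r_free, th$r_free_max))
  if (!is.na(stats$r_gap) && stats$r_gap > th$r_gap_max)
    fail <- c(fail, sprintf("R-R_free gap %.2f > %.2f (overfitting)",
                            stats$r_gap, th$r_gap_max))
  if (!is.na(stats$side_chains) && stats$side_chains == 0L)
    fail <- c(fail, "no side chains placed during model building")
  if (!is.na(stats$map_cc) && stats$map_cc < th$map_cc_min)
    fail <- c(fail, sprintf("map CC %.2f < %.2f", stats$map_cc, th$map_cc_min))
  if (length(fail))
    return(structure(list(status = "reject", reasons = fail),
                     class = "triage_verdict"))
  soft <- character(0)
  if (stats$shelxe_cc <= th$cc_min)
    soft <- c(soft, sprintf("CC %.1f between legacy floor and %.0f",
                            stats$shelxe_cc, th$cc_min))
  if (is.na(stats$r_gap)) soft <- c(soft, "R-R_free gap unknown")
  if (is.na(stats$side_chains)) soft <- c(soft, "side-chain placement unknown")
  if (!is.na(stats$llg) && stats$llg < th$llg_min)
    soft <- c(soft, sprintf("LLG %.0f < %.0f", stats$llg, th$llg_min))
  if (!is.na(stats$tfz) && stats$tfz < th$tfz_min)
    soft <- c(soft, sprintf("TFZ %.1f < %.1f", stats$tfz, th$tfz_min))
  if (length(soft))
    return(structure(list(status = "borderline", reasons = soft),
                     class = "triage_verdict"))
  structure(list(status = "accept",
                 reasons = "all combined metrics pass"),
            class = "triage_verdict")
}

#' @export
print.triage_verdict <- function(x, ...) {
  cat("triage:", x$status, "\n")
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Top-versus-background demarcation
#'
#' Correct solutions tend to stand clearly above the case-specific
#' background. The top solution is the one with the highest tracing CC
#' (ties keep input order); the margin is its CC minus the background level
#' (median CC of the remaining solutions, or their mean with
#' `background = "mean"`). With a single solution the margin is undefined
#' and `demarcated` is `NA` (indeterminate).
#'
#' @param solutions list of [solution_stats()].
#' @param thresholds a [triage_thresholds()].
#' @param background `"median"` (default) or `"mean"`.
#' @return List with `top` (a `solution_stats`), `margin` and `demarcated`
#'   (logical, `NA` when indeterminate).
#' @export
demarcation <- function(solutions, thresholds = triage_thresholds(),
                        background = c("median", "mean")) {
  if (length(solutions) == 0L) stop("no solutions supplied")
  background <- match.arg(background)
  cc <- vapply(solutions, `[[`, numeric(1L), "shelxe_cc")
  top_i <- which.max(cc)
  if (length(solutions) == 1L)
    return(list(top = solutions[[1L]], margin = NA_real_, demarcated = NA))
  bg <- if (background == "median") median(cc[-top_i]) else mean(cc[-top_i])
  margin <- cc[top_i] - bg
  list(top = solutions[[top_i]], margin = margin,
       demarcated = margin >= thresholds$cc_demarcation_min)
}

#' Rank solutions by tracing correlation coefficient
#'
#' @param solutions list of [solution_stats()].
#' @return The list reordered by descending CC, stable for ties.
#' @export
rank_solutions <- function(solutions) {
  if (length(solutions) == 0L) stop("no solutions supplied")
  cc <- vapply(solutions, `[[`, numeric(1L), "shelxe_cc")
  solutions[order(-cc, seq_along(cc))]
}

#' Read solution statistics from a delimited table
#'
#' Expects columns `id`, `shelxe_cc`, `r_free` and optionally `r_work`,
#' `r_gap`, `side_chains`, `map_cc`, `llg`, `tfz` (tab- or comma-separated,
#' chosen from the file header).
#'
#' @param file path to a TSV/CSV file.
#' @return List of [solution_stats()].
#' @export
read_solution_stats <- function(file) {
  hdr <- readLines(file, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
  need <- c("id", "shelxe_cc", "r_free")
  if (!all(need %in% names(df)))
    stop("missing mandatory columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  opt <- function(col, i, cast = as.numeric)
    if (col %in% names(df)) cast(df[[col]][i]) else cast(NA)
  lapply(seq_len(nrow(df)), function(i) solution_stats(
    id = df$id[i], shelxe_cc = df$shelxe_cc[i], r_free = df$r_free[i],
    r_work = opt("r_work", i), r_gap = opt("r_gap", i),
    side_chains = opt("side_chains", i, as.integer),
    map_cc = opt("map_cc", i), llg = opt("llg", i), tfz = opt("tfz", i)))
}

#' Triage a table of solutions
#'
#' Ranks solutions by CC, assesses each with [assess()], and demotes an
#' accepted top solution to borderline when it does not demarcate from the
#' background.
#'
#' @param solutions list of [solution_stats()].
#' @param thresholds a [triage_thresholds()].
#' @return Data frame with one row per solution: id, shelxe_cc, status,
#'   reasons (collapsed), demarcated flag for the top solution.
#' @export
triage_solutions <- function(solutions, thresholds = triage_thresholds()) {
  ranked <- rank_solutions(solutions)
  dem <- demarcation(ranked, thresholds)
  rows <- lapply(seq_along(ranked), function(i) {
    v <- assess(ranked[[i]], thresholds)
    status <- v$status
    reasons <- v$reasons
    if (i == 1L && identical(status, "accept") && identical(dem$demarcated, FALSE)) {
      status <- "borderline"
      reasons <- c(reasons,
                   sprintf("top CC margin %.1f below demarcation %.0f",
                           dem$margin, thresholds$cc_demarcation_min))
    }
    data.frame(id = ranked[[i]]$id, shelxe_cc = ranked[[i]]$shelxe_cc,
               status = status, reasons = paste(reasons, collapse = "; "),
               is_top = i == 1L)
  })
  do.call(rbind, rows)
}
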