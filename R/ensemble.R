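# Decoy -> search-ensemble pipeline: RMSD-threshold clustering, per-residue
# variance scoring, fractional truncation, radius subclustering and
# polyalanine treatment.

#' Ensembler configuration
#'
#' Defaults reproduce the standard ensembling scheme: up to 10 aligned
#' clusters of up to 30 decoys each, truncated at 20 variance-ranked levels
#' and subclustered at radii of 1 and 3 A, for up to 400 search ensembles.
#'
#' @param max_clusters maximum number of clusters.
#' @param cluster_cap maximum decoys retained per cluster.
#' @param n_truncation_levels number of fractional truncation levels.
#' @param subcluster_radii subclustering radii in A, ascending.
#' @param cluster_threshold pairwise CA RMSD (A) for cluster membership.
#' @param top_k_models optional: keep only the `top_k_models` best-scored
#'   decoys (by an externally supplied model score) before clustering.
#' @return An object of class `ensembler_config`.
#' @export
ensembler_config <- function(max_clusters = 10, cluster_cap = 30,
                             n_truncation_levels = 20,
                             subcluster_radii = c(1, 3),
                             cluster_threshold = 1.5,
                             top_k_models = NULL) {
  stopifnot(max_clusters >= 1, cluster_cap >= 1, n_truncation_levels >= 1,
            all(subcluster_radii > 0), !is.unsorted(subcluster_radii),
            cluster_threshold > 0)
  if (!is.null(top_k_models)) stopifnot(top_k_models >= 1)
  structure(list(max_clusters = as.integer(max_clusters),
                 cluster_cap = as.integer(cluster_cap),
                 n_truncation_levels = as.integer(n_truncation_levels),
                 subcluster_radii = subcluster_radii,
                 cluster_threshold = cluster_threshold,
                 top_k_models = top_k_models),
            class = "ensembler_config")
}

#' Cluster decoys by pairwise CA RMSD
#'
#' Greedy representative-based clustering: the decoy with the most
#' neighbours within `cluster_threshold` becomes the next representative;
#' it and its neighbours (capped at `cluster_cap`, closest first) form a
#' cluster and are removed, until `max_clusters` clusters exist or no decoys
#' remain. Members are rigid-body aligned onto their representative. Ties
#' break to the earlier decoy index.
#'
#' @param decoys list of `cc_model`s of equal residue count.
#' @param cfg an [ensembler_config()].
#' @return List of clusters ordered by size; each a list with `members`
#'   (aligned models), `ids` (decoy indices), `representative` (decoy index)
#'   and `rmsd_to_rep`.
#' @export
cluster_decoys <- function(decoys, cfg = ensembler_config()) {
  if (length(decoys) == 0L) stop("empty decoy set")
  nres <- vapply(decoys, function(d) length(unique(d$resno)), integer(1L))
  if (length(unique(nres)) != 1L) stop("decoys differ in residue count")
  coords <- lapply(decoys, ca_coords)
  pm <- pairwise_rmsd(coords)
  avail <- rep(TRUE, length(decoys))
  clusters <- list()
  while (any(avail) && length(clusters) < cfg$max_clusters) {
    nb_count <- vapply(seq_along(decoys), function(i) {
      if (!avail[i]) return(-1L)
      sum(pm[i, avail] <= cfg$cluster_threshold)   # includes self
    }, integer(1L))
    rep_i <- which.max(nb_count)                   # ties -> earliest index
    nb <- which(avail & pm[rep_i, ] <= cfg$cluster_threshold)
    nb <- nb[order(pm[rep_i, nb], nb)]             # closest first, stable
    members_idx <- head(nb, cfg$cluster_cap)
    aligned <- lapply(members_idx, function(j) {
      fit <- superpose(coords[[rep_i]], coords[[j]])
      apply_superposition(decoys[[j]], fit)
    })
    clusters[[length(clusters) + 1L]] <- list(
      members = aligned, ids = members_idx, representative = rep_i,
      rmsd_to_rep = pm[rep_i, members_idx])
    avail[nb] <- FALSE                             # all neighbours consumed
  }
  clusters[order(-vapply(clusters, function(cl) length(cl$members), integer(1L)),
                 vapply(clusters, function(cl) cl$representative, integer(1L)))]
}

#' Per-residue positional variance of an aligned cluster
#'
#' Mean squared deviation of each residue's CA position about the member
#' mean, across the aligned members of a cluster. Identical members give an
#' all-zero profile, as does a singleton cluster.
#'
#' @param cluster a cluster from [cluster_decoys()] (or a bare list of
#'   aligned `cc_model`s).
#' @return Numeric vector of per-residue variances (A^2), one per residue.
#' @export
variance_profile <- function(cluster) {
  members <- if (!is.null(cluster$members)) cluster$members else cluster
  coords <- lapply(members, ca_coords)
  n <- nrow(coords[[1L]])
  if (length(members) < 2L) return(rep(0, n))
  arr <- simplify2array(coords)          # n x 3 x k
  ctr <- apply(arr, c(1L, 2L), mean)
  v <- numeric(n)
  for (k in seq_along(members)) v <- v + rowSums((arr[, , k] - ctr)^2)
  as.numeric(v / length(members))
}

#' Fractional variance-ranked truncation of a cluster
#'
#' Produces up to `n_truncation_levels` nested residue subsets: level 1
#' keeps the full chain and each further level removes the next 5% (for 20
#' levels) of highest-variance residues, so level k keeps the
#' (100 - 100(k-1)/n_levels)% lowest-variance residues. Ties in the variance
#' profile break to the lower residue index; duplicate subset sizes collapse
#' to one level.
#'
#' @param cluster a cluster from [cluster_decoys()].
#' @param profile a variance profile from [variance_profile()].
#' @param cfg an [ensembler_config()].
#' @return List of truncation levels; each a list with `level`, `residues`
#'   (retained residue indices, ascending) and `models` (truncated members).
#' @export
truncate_cluster <- function(cluster, profile, cfg = ensembler_config()) {
  members <- cluster$members
  n <- length(profile)
  ord <- order(profile, seq_len(n))       # lowest variance first; ties by index
  sizes <- unique(pmax(1L, round(n * (1 - (seq_len(cfg$n_truncation_levels) - 1L) /
                                         cfg$n_truncation_levels))))
  lapply(seq_along(sizes), function(k) {
    keep <- sort(ord[seq_len(sizes[k])])
    list(level = k, residues = keep,
         models = lapply(members, subset_residues, residues = keep))
  })
}

# keep only the listed residue indices (positional, per chain-less decoy)
subset_residues <- function(model, residues) {
  resn <- sort(unique(model$resno))
  keep <- model$resno %in% resn[residues]
  out <- model[keep, , drop = FALSE]
  class(out) <- c("cc_model", "data.frame")
  out
}

#' Radius-threshold subclustering
#'
#' Greedy medoid subclustering in pairwise CA RMSD space: the model with the
#' most neighbours within `radius` seeds a subcluster containing those
#' neighbours (every member is within `radius` of the medoid); seeded
#' subclusters are removed and the process repeats. Returns subclusters by
#' decreasing size; the first is the level's ensemble for that radius.
#'
#' @param level_models list of `cc_model`s (a truncation level).
#' @param radius subcluster radius, A.
#' @return List of subclusters, each a list with `ids` (indices into
#'   `level_models`), `medoid` and `members`.
#' @export
subcluster <- function(level_models, radius) {
  if (length(level_models) == 0L) stop("empty model list")
  stopifnot(radius > 0)
  pm <- pairwise_rmsd(lapply(level_models, ca_coords))
  avail <- rep(TRUE, length(level_models))
  out <- list()
  while (any(avail)) {
    cnt <- vapply(seq_along(avail), function(i)
      if (avail[i]) sum(pm[i, avail] <= radius) else -1L, integer(1L))
    med <- which.max(cnt)
    ids <- which(avail & pm[med, ] <= radius)
    ids <- ids[order(pm[med, ids], ids)]
    out[[length(out) + 1L]] <- list(ids = ids, medoid = med,
                                    members = level_models[ids])
    avail[ids] <- FALSE
  }
  out[order(-vapply(out, function(s) length(s$ids), integer(1L)),
            vapply(out, function(s) s$medoid, integer(1L)))]
}

#' Polyalanine treatment
#'
#' Renames every residue to ALA and strips atoms other than N, CA, C, O and
#' CB. No CB is fabricated where none exists (glycine or CA-only models);
#' retained coordinates are untouched.
#'
#' @param model a `cc_model`.
#' @return The polyalanine model.
#' @export
polyalanine <- function(model) {
  out <- model[model$atom %in% c("N", "CA", "C", "O", "CB"), , drop = FALSE]
  out$resid <- rep("ALA", nrow(out))
  class(out) <- c("cc_model", "data.frame")
  out
}

#' Full decoy-to-ensemble pipeline
#'
#' Clusters the decoys, scores per-residue variance within each cluster,
#' truncates at up to 20 nested levels, subclusters each level at each
#' radius and applies polyalanine treatment, yielding one search ensemble
#' per (cluster, truncation level, radius) with provenance metadata. With
#' defaults the output is capped at 10 x 20 x 2 = 400 ensembles. When
#' `cfg$top_k_models` is set, only the best-scored decoys (ascending
#' `scores`; e.g. an external modelling energy) enter clustering.
#'
#' @param decoys list of `cc_model`s.
#' @param cfg an [ensembler_config()].
#' @param scores optional numeric vector of per-decoy model scores (lower is
#'   better), required when `cfg$top_k_models` is set.
#' @return List of ensembles; each a list with `models` (aligned polyalanine
#'   members), `residues`, and provenance fields `cluster`, `level`,
#'   `radius`.
#' @export
generate_ensembles <- function(decoys, cfg = ensembler_config(), scores = NULL) {
  if (!is.null(cfg$top_k_models)) {
    if (is.null(scores)) stop("top_k_models filter requires model scores")
    stopifnot(length(scores) == length(decoys))
    keep <- order(scores, seq_along(scores))[seq_len(min(cfg$top_k_models,
                                                         length(decoys)))]
    decoys <- decoys[sort(keep)]
  }
  clusters <- cluster_decoys(decoys, cfg)
  ensembles <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    prof <- variance_profile(cl)
    levels <- truncate_cluster(cl, prof, cfg)
    for (lv in levels) {
      for (r in cfg$subcluster_radii) {
        sub <- subcluster(lv$models, r)[[1L]]
        ensembles[[length(ensembles) + 1L]] <- list(
          models = lapply(sub$members, polyalanine),
          residues = lv$residues,
          cluster = ci, level = lv$level, radius = r)
      }
    }
  }
  ensembles
}

#' Write ensembles as PDB files with a manifest
#'
#' Each ensemble is written as a multi-model-like concatenation of its
#' members (separate PDB files per member would multiply file counts), with
#' provenance in the file name, plus a tab-separated manifest.
#'
#' @param ensembles output of [generate_ensembles()].
#' @param dir output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_ensembles <- function(ensembles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    base <- sprintf("ensemble_c%02d_t%02d_r%g", e$cluster, e$level, e$radius)
    for (k in seq_along(e$models))
      write_model_pdb(e$models[[k]],
                      file.path(dir, sprintf("%s_m%02d.pdb", base, k)))
    data.frame(ensemble = base, cluster = e$cluster, level = e$level,
               radius = e$radius, n_models = length(e$models),
               n_residues = length(e$residues))
  })
  manifest <- file.path(dir, "ensembles.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
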