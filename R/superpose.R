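# Kabsch machinery shared by the ensembler and geometry modules.

#' Least-squares rigid-body superposition
#'
#' Computes the optimal (Kabsch) rigid-body superposition of the CA atoms of
#' `model_b` onto those of `model_a`, returning the transform and the
#' post-fit RMSD.
#'
#' @param model_a,model_b `cc_model`s (or bare n x 3 coordinate matrices)
#'   with equal CA counts.
#' @return A list with `rot` (3x3 rotation), `trans` (length-3 translation;
#'   apply as `x %*% t(rot) + trans`), and `rmsd` in Angstrom.
#' @export
superpose <- function(model_a, model_b) {
  p <- if (inherits(model_a, "cc_model")) ca_coords(model_a) else as.matrix(model_a)
  q <- if (inherits(model_b, "cc_model")) ca_coords(model_b) else as.matrix(model_b)
  if (nrow(p) != nrow(q)) stop("mismatched CA counts: ", nrow(p), " vs ", nrow(q))
  if (nrow(p) < 3L) stop("need >= 3 points for a well-defined superposition")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  s <- svd(crossprod(qc, pc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- qc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - pc)^2)))
  list(rot = rot, trans = cp - as.numeric(rot %*% cq), rmsd = rmsd)
}

#' Apply a superposition transform to a whole model
#' @param model a `cc_model`.
#' @param fit result of [superpose()].
#' @return The transformed model.
#' @export
apply_superposition <- function(model, fit) {
  transform_model(model, rot = fit$rot, trans = fit$trans)
}

# RMSD between two centred coordinate sets given precomputed squared norms;
# fast path used in pairwise loops (no rotation matrix materialized).
rmsd_centred <- function(pc, qc, np, nq) {
  s <- svd(crossprod(qc, pc))
  sig <- s$d
  sig[3L] <- sig[3L] * sign(det(s$u) * det(s$v))
  sqrt(max(0, (np + nq - 2 * sum(sig)) / nrow(pc)))
}

#' Pairwise CA RMSD matrix after optimal superposition
#'
#' @param coords list of n x 3 CA coordinate matrices (equal n).
#' @return Symmetric matrix of pairwise post-fit RMSDs, A.
#' @export
pairwise_rmsd <- function(coords) {
  k <- length(coords)
  cent <- lapply(coords, function(x) sweep(x, 2L, colMeans(x)))
  nrm <- vapply(cent, function(x) sum(x * x), numeric(1L))
  out <- matrix(0, k, k)
  if (k > 1L) for (i in seq_len(k - 1L)) {
    ci <- cent[[i]]
    for (j in (i + 1L):k) {
      r <- rmsd_centred(ci, cent[[j]], nrm[i], nrm[j])
      out[i, j] <- r; out[j, i] <- r
    }
  }
  out
}
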