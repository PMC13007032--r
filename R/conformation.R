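#' Kabsch superposition: optimal proper rotation and translation
#'
#' Least-squares rigid-body alignment of `coords` onto `reference` by SVD of
#' the centered cross-covariance, with the determinant correction that
#' forbids reflections (the rotation is always proper, det = +1).
#'
#' @param coords n x 3 matrix to align (A).
#' @param reference n x 3 target matrix (A), same row order.
#' @param weights Optional nonnegative per-atom weights (default uniform).
#' @return Object of class `alignment_result`: `rotation` (3 x 3),
#'   `translation` (length 3, applied after rotation), `rmsd` (A),
#'   `aligned` (the transformed coordinates).
#' @export
kabsch_align <- function(coords, reference, weights = NULL) {
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  if (!identical(dim(coords), dim(reference)))
    stop("coordinate and reference shapes differ")
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cx <- colSums(coords * w); cr <- colSums(reference * w)
  X <- sweep(coords, 2, cx); Y <- sweep(reference, 2, cr)
  # collinearity check: rank of the centered reference
  if (svd(Y)$d[2] < 1e-9 * max(1, svd(Y)$d[1]))
    stop("degenerate (collinear) reference geometry")
  H <- t(X * w) %*% Y
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- X %*% t(R)
  aligned <- sweep(aligned, 2, cr, `+`)
  rmsd <- sqrt(sum(w * rowSums((aligned - reference)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cx),
                 rmsd = rmsd, aligned = aligned),
            class = "alignment_result")
}

#' Backbone RMSD after best-fit superposition
#'
#' Restricts both structures to the backbone subset (for a perfluoroalkyl
#' solute: the tail carbons plus the carboxylate carbon or sulfonate
#' sulfur), removes overall translation and rotation by [kabsch_align()] on
#' that subset, and returns sqrt(mean of squared deviations) over the
#' subset.
#'
#' @param coords n x 3 frame coordinates (A).
#' @param reference n x 3 reference coordinates (A), typically the extended
#'   conformation.
#' @param subset Indices of the backbone atoms (default: all).
#' @param align Superpose before measuring (default TRUE). With
#'   `align = FALSE` the raw root-mean-square deviation of the coordinates
#'   as given is returned (e.g. d/sqrt(N) for one atom displaced by d).
#' @return RMSD in A.
#' @export
backbone_rmsd <- function(coords, reference, subset = seq_len(nrow(coords)),
                          align = TRUE) {
  if (length(subset) == 0) stop("empty backbone subset")
  coords <- as.matrix(coords)[subset, , drop = FALSE]
  reference <- as.matrix(reference)[subset, , drop = FALSE]
  if (align) kabsch_align(coords, reference)$rmsd
  else sqrt(mean(rowSums((coords - reference)^2)))
}

#' RMSD of each trajectory frame against a reference conformation
#'
#' @param trajectory A `trajectory` or single `configuration`.
#' @param reference n x 3 reference coordinates for the solute backbone.
#' @param solute_species Species label of the solute.
#' @param subset Backbone subset indices within the solute.
#' @return Data frame `frame`, `rmsd` (A).
#' @export
rmsd_records <- function(trajectory, reference, solute_species = "PFAS",
                         subset = NULL) {
  frames <- if (inherits(trajectory, "configuration")) list(trajectory)
            else trajectory$frames
  out <- data.frame(frame = seq_along(frames), rmsd = NA_real_)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    s_pos <- f$positions[f$species == solute_species, , drop = FALSE]
    sub <- if (is.null(subset)) seq_len(nrow(s_pos)) else subset
    out$rmsd[i] <- backbone_rmsd(s_pos, reference, sub)
  }
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> rmsd %.4f A, det(R) = %.6f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}
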