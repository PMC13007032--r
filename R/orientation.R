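#' Solute resultant vector from 1,3-backbone geometry
#'
#' The solute orientation vector is the average of the normalized
#' 1,3-vectors x_{k+1} - x_{k-1} over the interior backbone beads
#' (k = 2..n-1), normalized to unit length. With the backbone supplied in
#' tail-to-head order the vector points from the terminal tail bead toward
#' the headgroup. The carbon of a carboxylate headgroup is excluded from the
#' backbone index list by the caller; a sulfonate sulfur never enters.
#'
#' @param coords n x 3 coordinate matrix (A).
#' @param backbone_indices Indices of backbone beads in chain order
#'   (default: all rows).
#' @return Unit length-3 vector.
#' @export
solute_vector <- function(coords, backbone_indices = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  x <- coords[backbone_indices, , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 backbone atoms")
  v13 <- x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]
  len <- sqrt(rowSums(v13^2))
  if (any(len < 1e-9)) stop("degenerate geometry: coincident 1,3 atoms")
  .unit(colMeans(v13 / len))
}

#' Cylindrical sampling region specification
#'
#' The reference volume around the solute within which slab-chain fragments
#' contribute to the local chain director: a cylinder of radius `radius` in
#' the xy-plane on the axis through the solute COM projection, spanning
#' z in [z_lower, z_upper]. Conventionally z_lower sits a fixed offset above
#' the slab center of mass and z_upper at the nearest slab-solvent Gibbs
#' dividing surface.
#'
#' @param radius Cylinder radius, A (default 13).
#' @param z_lower,z_upper Axial bounds, A.
#' @return Object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(radius = 13, z_lower, z_upper) {
  stopifnot(radius > 0, is.finite(z_lower), is.finite(z_upper))
  if (z_lower >= z_upper)
    stop("cylinder has z_lower >= z_upper (slab COM offset beyond the interface?)")
  structure(list(radius = radius, z_lower = z_lower, z_upper = z_upper),
            class = "cylinder_spec")
}

#' Cylinder bounds from slab COM and Gibbs surface
#'
#' @param slab_com_z Slab center-of-mass z (A).
#' @param gds_z Position of the Gibbs dividing surface bounding the cylinder
#'   (A).
#' @param radius Cylinder radius, A.
#' @param com_offset Lower-bound offset above the slab COM, A (default 18).
#' @return A [cylinder_spec()].
#' @export
cylinder_above_com <- function(slab_com_z, gds_z, radius = 13, com_offset = 18) {
  cylinder_spec(radius, slab_com_z + com_offset, gds_z)
}

#' Select slab-chain 1,3-fragments inside the sampling cylinder
#'
#' Walks every slab chain and keeps each (k-1, k, k+1) bead triplet whose
#' central bead lies within the cylinder: xy-distance from the axis at most
#' the radius (minimum image in x and y) and z within [z_lower, z_upper].
#' An empty result is legal and simply reported by length 0.
#'
#' @param config A `configuration` containing the slab species.
#' @param solute_com_xy Length-2 xy position of the cylinder axis (A).
#' @param cyl A [cylinder_spec()].
#' @param species Slab species label (default `"PE"`).
#' @return List of 3 x 3 coordinate matrices (rows k-1, k, k+1).
#' @export
select_cylinder <- function(config, solute_com_xy, cyl, species = "PE") {
  stopifnot(inherits(config, "configuration"), inherits(cyl, "cylinder_spec"))
  sel <- which(config$species == species)
  if (length(sel) == 0) stop("slab species ", species, " not present")
  pos <- config$positions[sel, , drop = FALSE]
  mol <- config$mol_id[sel]
  Lx <- config$box[1]; Ly <- config$box[2]
  dx <- pos[, 1] - solute_com_xy[1]; dy <- pos[, 2] - solute_com_xy[2]
  dx <- dx - Lx * round(dx / Lx)               # minimum image in xy
  dy <- dy - Ly * round(dy / Ly)
  in_cyl <- (dx^2 + dy^2 <= cyl$radius^2) &
            pos[, 3] >= cyl$z_lower & pos[, 3] <= cyl$z_upper
  # interior beads: same chain before and after (chains stored contiguously)
  n <- length(sel)
  interior <- which(in_cyl)
  interior <- interior[interior > 1 & interior < n]
  interior <- interior[mol[interior - 1] == mol[interior] &
                       mol[interior + 1] == mol[interior]]
  lapply(interior, function(k) pos[(k - 1):(k + 1), , drop = FALSE])
}

#' Local slab-chain director from cylinder fragments
#'
#' Accumulates the normalized 1,3-vectors of the selected fragments into a
#' resultant. Because chemically identical chain ends make each vector's
#' sign arbitrary, signs are chosen to build up the largest resultant:
#' the first vector is flipped to nonnegative z, every subsequent vector is
#' reversed when its dot product with the running resultant is negative,
#' and the final resultant is reversed if it points below the xy-plane so
#' the director always makes an angle < 90 degrees with +z (a resultant
#' with exactly zero z is flipped deterministically to +z by convention).
#'
#' @param fragments List of 3 x 3 coordinate matrices from
#'   [select_cylinder()], or an m x 3 matrix of raw 1,3-vectors.
#' @return Unit length-3 vector with attributes `magnitude` (of the
#'   unnormalized resultant, in units of unit vectors) and `n_fragments`.
#' @export
slab_vector <- function(fragments) {
  if (is.list(fragments)) {
    if (length(fragments) == 0) stop("empty sampling region: no fragments")
    v <- t(vapply(fragments, function(f) f[3, ] - f[1, ], numeric(3)))
  } else {
    v <- as.matrix(fragments)
    if (nrow(v) == 0) stop("empty sampling region: no fragments")
  }
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-9)) stop("degenerate fragment: coincident 1,3 atoms")
  v <- v / len
  r <- v[1, ]
  if (r[3] < 0) r <- -r
  for (i in seq_len(nrow(v))[-1]) {
    vi <- v[i, ]
    if (sum(vi * r) < 0) vi <- -vi
    r <- r + vi
  }
  if (r[3] < 0) r <- -r
  mag <- sqrt(sum(r^2))
  out <- .unit(r)
  attr(out, "magnitude") <- mag
  attr(out, "n_fragments") <- nrow(v)
  out
}

#' Orientational order parameter of two directors
#'
#' S_v = (3 cos^2(theta) - 1)/2 for the angle theta between v1 and v2:
#' 1 for parallel alignment, -0.5 for perpendicular, 0 at the magic angle
#' (and on average for isotropic orientations).
#'
#' @param v1,v2 Length-3 vectors (normalized internally; zero vectors are an
#'   error).
#' @return List with `theta_deg` (0..180) and `sv`.
#' @export
order_parameter <- function(v1, v2) {
  u1 <- .unit(as.numeric(v1)); u2 <- .unit(as.numeric(v2))
  ct <- max(-1, min(1, sum(u1 * u2)))
  list(theta_deg = acos(ct) * 180 / pi, sv = (3 * ct^2 - 1) / 2)
}

#' Bin per-frame orientation records along the reaction coordinate
#'
#' Ensemble-averages cos^2(theta) within each xi bin and converts to the
#' order parameter S_v = (3<cos^2 theta> - 1)/2, with a t confidence
#' interval computed across replica means (or across contiguous block means
#' within the single replica when only one is present), plus angle quartiles
#' for boxplot-style summaries.
#'
#' @param records Data frame with columns `xi`, `theta_deg` and optionally
#'   `replica` (defaults to 1) and `frame`.
#' @param xi_bins Increasing vector of bin edges (A).
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @param n_blocks Blocks used for the single-replica interval.
#' @return Data frame, one row per bin: `xi_lo`, `xi_hi`, `xi_mid`, `n`,
#'   `sv`, `sv_lo`, `sv_hi`, `theta_mean`, `theta_q25`, `theta_median`,
#'   `theta_q75`. Empty bins carry NA.
#' @export
orientation_profile <- function(records, xi_bins, confidence = 0.95,
                                n_blocks = 5) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            confidence > 0, confidence < 1,
            length(xi_bins) >= 2, all(diff(xi_bins) > 0))
  if (is.null(records$replica)) records$replica <- 1L
  nb <- length(xi_bins) - 1L
  cos2 <- cos(records$theta_deg * pi / 180)^2
  bin <- findInterval(records$xi, xi_bins, left.open = FALSE)
  out <- data.frame(xi_lo = xi_bins[-length(xi_bins)], xi_hi = xi_bins[-1])
  out$xi_mid <- (out$xi_lo + out$xi_hi) / 2
  out$n <- 0L
  out[c("sv", "sv_lo", "sv_hi", "theta_mean",
        "theta_q25", "theta_median", "theta_q75")] <- NA_real_
  for (j in seq_len(nb)) {
    in_bin <- which(bin == j & records$xi < xi_bins[nb + 1L])
    out$n[j] <- length(in_bin)
    if (length(in_bin) == 0) next
    c2 <- cos2[in_bin]
    th <- records$theta_deg[in_bin]
    out$sv[j] <- (3 * mean(c2) - 1) / 2
    out$theta_mean[j] <- mean(th)
    qs <- quantile(th, c(0.25, 0.5, 0.75), names = FALSE)
    out$theta_q25[j] <- qs[1]; out$theta_median[j] <- qs[2]; out$theta_q75[j] <- qs[3]
    reps <- records$replica[in_bin]
    if (length(unique(reps)) >= 2) {
      means <- tapply(c2, reps, mean)
    } else if (length(in_bin) >= 2 * n_blocks) {
      blk <- cut(seq_along(in_bin), breaks = n_blocks, labels = FALSE)
      means <- tapply(c2, blk, mean)
    } else means <- NULL
    if (!is.null(means) && length(means) >= 2) {
      m <- mean(means); s <- sd(means); k <- length(means)
      half <- qt(1 - (1 - confidence) / 2, df = k - 1) * s / sqrt(k)
      out$sv_lo[j] <- (3 * (m - half) - 1) / 2
      out$sv_hi[j] <- (3 * (m + half) - 1) / 2
    }
  }
  out
}

#' Per-frame orientation analysis of a trajectory
#'
#' For each frame: locate the solute, form its 1,3-resultant, select slab
#' fragments in the sampling cylinder above the slab COM, form the local
#' chain director, and evaluate the angle and order parameter. Frames whose
#' cylinder is empty are reported with NA angle.
#'
#' @param trajectory A `trajectory` or single `configuration`.
#' @param surfaces A `gibbs_surfaces` (bounds the cylinder and re-references
#'   xi).
#' @param solute_species,slab_species Species labels.
#' @param radius,com_offset Cylinder geometry, A.
#' @param backbone_indices Solute backbone indices passed to
#'   [solute_vector()]; default all solute beads.
#' @return Data frame with one row per frame: `frame`, `xi`, `theta_deg`,
#'   `sv`, `n_fragments`.
#' @export
orientation_records <- function(trajectory, surfaces,
                                solute_species = "PFAS", slab_species = "PE",
                                radius = 13, com_offset = 18,
                                backbone_indices = NULL) {
  frames <- if (inherits(trajectory, "configuration")) list(trajectory)
            else trajectory$frames
  out <- data.frame(frame = seq_along(frames), xi = NA_real_,
                    theta_deg = NA_real_, sv = NA_real_, n_fragments = 0L)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    s_idx <- which(f$species == solute_species)
    if (length(s_idx) < 3) stop("solute species ", solute_species, " too short")
    s_pos <- f$positions[s_idx, , drop = FALSE]
    bb <- if (is.null(backbone_indices)) seq_len(nrow(s_pos)) else backbone_indices
    v1 <- solute_vector(s_pos, bb)
    com_s <- center_of_mass(f, solute_species)
    com_slab <- center_of_mass(f, slab_species)
    # cylinder bounded by the GDS nearest the solute
    gds <- if (abs(com_s[3] - surfaces$z_upper) <= abs(com_s[3] - surfaces$z_lower))
      surfaces$z_upper else surfaces$z_lower
    out$xi[i] <- rereference(com_s[3] - com_slab[3], surfaces, com_slab[3])
    cyl <- if (gds >= com_slab[3])
      cylinder_above_com(com_slab[3], gds, radius, com_offset)
    else  # solute below the slab: mirror the cylinder under the COM
      cylinder_spec(radius, gds, com_slab[3] - com_offset)
    frags <- select_cylinder(f, com_s[1:2], cyl, slab_species)
    out$n_fragments[i] <- length(frags)
    if (length(frags) == 0) next
    v2 <- slab_vector(frags)
    op <- order_parameter(v1, v2)
    out$theta_deg[i] <- op$theta_deg
    out$sv[i] <- op$sv
  }
  out
}
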