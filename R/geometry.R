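#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation; right-handed, angle in degrees.
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Center of mass of a configuration
#'
#' @param config A `configuration`.
#' @param species Optional species label to restrict to.
#' @return Length-3 mass-weighted mean position (A).
#' @export
center_of_mass <- function(config, species = NULL) {
  stopifnot(inherits(config, "configuration"))
  sel <- if (is.null(species)) rep(TRUE, nrow(config$positions))
         else config$species == species
  if (!any(sel)) stop("no atoms of species ", species)
  m <- config$mass[sel]
  colSums(config$positions[sel, , drop = FALSE] * m) / sum(m)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}
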