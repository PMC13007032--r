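#' Analytic free-energy profile specification
#'
#' Ground-truth free-energy profiles A(xi) used by the synthetic sampler and
#' by recovery tests. Four forms are supported:
#' \describe{
#'   \item{flat}{A(xi) = 0.}
#'   \item{harmonic}{A(xi) = a/2 * (xi - xi0)^2, params `a` (kJ mol^-1 A^-2)
#'     and optional `xi0` (A, default 0).}
#'   \item{double_well}{A(xi) = barrier * ((xi - xi0)^2/half_width^2 - 1)^2,
#'     a symmetric quartic with minima at xi0 +/- half_width and a barrier of
#'     `barrier` kJ mol^-1 at xi0.}
#'   \item{tabulated}{linear interpolation of (`xi`, `energy`) nodes;
#'     abscissa strictly increasing.}
#' }
#'
#' @param form One of `"flat"`, `"harmonic"`, `"double_well"`, `"tabulated"`.
#' @param domain Closed sampling interval `c(xi_min, xi_max)` in Angstrom.
#' @param ... Form parameters (see Details).
#' @return An object of class `analytic_profile`.
#' @export
analytic_profile <- function(form = c("flat", "harmonic", "double_well", "tabulated"),
                             domain, ...) {
  form <- match.arg(form)
  stopifnot(is.numeric(domain), length(domain) == 2L, all(is.finite(domain)))
  if (domain[1] >= domain[2]) stop("profile domain is empty")
  params <- list(...)
  if (form == "harmonic") {
    if (is.null(params$a)) stop("harmonic profile needs coefficient `a`")
    if (is.null(params$xi0)) params$xi0 <- 0
  }
  if (form == "double_well") {
    if (is.null(params$barrier) || is.null(params$half_width))
      stop("double_well profile needs `barrier` and `half_width`")
    if (is.null(params$xi0)) params$xi0 <- 0
    stopifnot(params$barrier >= 0, params$half_width > 0)
  }
  if (form == "tabulated") {
    if (is.null(params$xi) || is.null(params$energy))
      stop("tabulated profile needs `xi` and `energy` nodes")
    stopifnot(length(params$xi) == length(params$energy), length(params$xi) >= 2L)
    if (any(diff(params$xi) <= 0)) stop("tabulated abscissa must be strictly increasing")
    if (!all(is.finite(params$energy))) stop("tabulated energies must be finite")
  }
  structure(list(form = form, params = params, domain = as.numeric(domain)),
            class = "analytic_profile")
}

#' Evaluate an analytic free-energy profile
#'
#' @param spec An [analytic_profile()].
#' @param xi Coordinate(s) in Angstrom; must lie inside the profile domain.
#' @return Energy in kJ mol^-1, same length as `xi`.
#' @export
evaluate_profile <- function(spec, xi) {
  stopifnot(inherits(spec, "analytic_profile"), is.numeric(xi))
  tol <- 1e-9
  if (any(xi < spec$domain[1] - tol | xi > spec$domain[2] + tol))
    stop("xi outside profile domain [", spec$domain[1], ", ", spec$domain[2], "]")
  p <- spec$params
  out <- switch(spec$form,
    flat = rep(0, length(xi)),
    harmonic = 0.5 * p$a * (xi - p$xi0)^2,
    double_well = p$barrier * ((xi - p$xi0)^2 / p$half_width^2 - 1)^2,
    tabulated = approx(p$xi, p$energy, xout = pmin(pmax(xi, p$xi[1]), p$xi[length(p$xi)]),
                       method = "linear", rule = 2)$y
  )
  if (!all(is.finite(out))) stop("profile evaluation produced non-finite energies")
  out
}

#' Interfacial free-energy profile preset
#'
#' A tabulated [analytic_profile()] shaped like the free energy of an
#' amphiphilic solute approaching a polymer-water interface from the
#' solvent: a repulsive wall toward the slab interior, an attractive
#' minimum of `depth` kJ mol^-1 at `xi_min` (just inside the interface,
#' negative xi), and a flat plateau at zero in bulk solvent. Useful as a
#' ground truth for demonstrating plateau zeroing and well-depth recovery.
#'
#' @param depth Well depth, kJ mol^-1 (positive number; the minimum is
#'   -depth).
#' @param xi_min Location of the minimum, A.
#' @param width Gaussian half-width of the well, A.
#' @param wall_pos,wall_scale Position (A) and decay length (A) of the
#'   exponential repulsive wall.
#' @param domain Profile domain, A.
#' @param spacing Tabulation step, A.
#' @return An `analytic_profile` of form `"tabulated"`.
#' @export
interfacial_profile <- function(depth = 26.5, xi_min = -4.7, width = 1.5,
                                wall_pos = -6.5, wall_scale = 0.7,
                                domain = c(-8, 12), spacing = 0.05) {
  xi <- seq(domain[1], domain[2], by = spacing)
  energy <- 5 * exp(-(xi - wall_pos) / wall_scale) -
    depth * exp(-(xi - xi_min)^2 / (2 * width^2))
  analytic_profile("tabulated", domain = domain, xi = xi, energy = energy)
}

#' Harmonic window bias specification
#'
#' The umbrella bias w_i(xi) = k/2 * (xi - center)^2 restraining the reaction
#' coordinate around a window center.
#'
#' @param center Window center xi_i' in Angstrom.
#' @param force_constant Force constant k. Interpreted in kJ mol^-1 A^-2
#'   unless `units = "kcal"`, in which case it is converted by 4.184.
#' @param units `"kJ"` (default) or `"kcal"`.
#' @return An object of class `bias_spec` with `center` and `k` (kJ mol^-1 A^-2).
#' @export
bias_spec <- function(center, force_constant, units = c("kJ", "kcal")) {
  units <- match.arg(units)
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(force_constant), length(force_constant) == 1L,
            force_constant >= 0)
  k <- if (units == "kcal") force_constant * KCAL_TO_KJ else force_constant
  structure(list(center = as.numeric(center), k = as.numeric(k)),
            class = "bias_spec")
}

#' Evaluate a window bias
#'
#' @param bias A [bias_spec()].
#' @param xi Coordinate(s) in Angstrom.
#' @return Bias energy in kJ mol^-1.
#' @export
evaluate_bias <- function(bias, xi) {
  stopifnot(inherits(bias, "bias_spec"))
  0.5 * bias$k * (xi - bias$center)^2
}

#' @export
print.analytic_profile <- function(x, ...) {
  cat("<analytic_profile>", x$form,
      sprintf(" domain [%g, %g] A\n", x$domain[1], x$domain[2]))
  invisible(x)
}

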