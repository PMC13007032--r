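# Avogadro x 1e-24: converts (g/mol per A^3) to g/cm^3
.AMU_PER_A3_TO_G_CM3 <- 1 / 0.602214076

#' Tanh model for the slab (polymer) mass-density profile
#'
#' `rho(z) = rho_b/2 tanh(2(z-h1)/D) - rho_b/2 tanh(2(z-h2)/D)`:
#' bulk density rho_b between the interface positions h1 < h2, decaying to
#' zero over an interfacial width set by D. Both edges share one D and one
#' rho_b.
#'
#' @param z Positions along the profile axis (A).
#' @param rho_b Bulk density, g cm^-3.
#' @param h1,h2 Interface positions, A.
#' @param D Interfacial width parameter, A.
#' @return Density at `z`, g cm^-3.
#' @export
rho_slab_model <- function(z, rho_b, h1, h2, D) {
  0.5 * rho_b * tanh(2 * (z - h1) / D) - 0.5 * rho_b * tanh(2 * (z - h2) / D)
}

#' Tanh model for the solvent mass-density profile
#'
#' `rho(z) = rho_b - rho_b/2 tanh(2(z-h3)/D) + rho_b/2 tanh(2(z-h4)/D)`:
#' bulk solvent density outside the slab region, excluded between h3 < h4.
#'
#' @inheritParams rho_slab_model
#' @param h3,h4 Solvent exclusion-edge positions, A.
#' @export
rho_solvent_model <- function(z, rho_b, h3, h4, D) {
  rho_b - 0.5 * rho_b * tanh(2 * (z - h3) / D) + 0.5 * rho_b * tanh(2 * (z - h4) / D)
}

#' Mass-density profile of one species along a box axis
#'
#' Bins the selected species' atoms along the chosen axis (coordinates
#' wrapped into the central box), converts to mass density with Avogadro's
#' number, and averages over frames. The box cross-section is taken from
#' each frame (fixed-volume ensembles assumed).
#'
#' @param trajectory A `trajectory` (see [read_trajectory()]), a single
#'   `configuration`, or a plain list of configurations (an ensemble of
#'   independent realizations; they must share the box).
#' @param species Species label to select.
#' @param axis `"x"`, `"y"` or `"z"` (default).
#' @param n_bins Number of uniform bins spanning the box along `axis`.
#' @return Object of class `density_profile`: `bin_centers` (A), `density`
#'   (g cm^-3), `species`, `frames_averaged`, `axis`, `box_length`.
#' @export
density_profile <- function(trajectory, species, axis = "z", n_bins = 100) {
  frames <- if (inherits(trajectory, "configuration")) list(trajectory)
            else if (inherits(trajectory, "trajectory")) trajectory$frames
            else trajectory   # plain list of configurations (an ensemble)
  stopifnot(length(frames) >= 1L, n_bins >= 1L)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  box <- frames[[1]]$box
  L <- box[ax]
  edges <- seq(-L / 2, L / 2, length.out = n_bins + 1L)
  bin_w <- L / n_bins
  cross <- prod(box[-ax])
  acc <- numeric(n_bins)
  known <- unique(unlist(lapply(frames, function(f) unique(f$species))))
  if (!species %in% known) stop("unknown species: ", species)
  for (f in frames) {
    sel <- f$species == species
    if (!any(sel)) next
    x <- f$positions[sel, ax]
    x <- ((x + L / 2) %% L) - L / 2           # wrap into central box
    idx <- pmin(pmax(findInterval(x, edges, left.open = FALSE), 1L), n_bins)
    acc <- acc + vapply(seq_len(n_bins),
                        function(j) sum(f$mass[sel][idx == j]), numeric(1))
  }
  if (sum(acc) == 0) warning("empty selection for species ", species)
  dens <- acc / length(frames) / (bin_w * cross) * .AMU_PER_A3_TO_G_CM3
  structure(list(bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 density = dens, species = species,
                 frames_averaged = length(frames), axis = axis,
                 box_length = L),
            class = "density_profile")
}

# Initial parameter guess from half-maximum crossings of the profile.
.interface_guess <- function(z, rho, model) {
  if (model == "solvent") rho <- max(rho) - rho   # treat the void as a slab
  peak <- max(rho)
  above <- which(rho > peak / 2)
  h_lo <- z[min(above)]; h_hi <- z[max(above)]
  if (h_hi - h_lo < diff(range(z)) / 50) {
    h_lo <- quantile(z, 0.4); h_hi <- quantile(z, 0.6)
  }
  list(rho_b = peak, h_lo = as.numeric(h_lo), h_hi = as.numeric(h_hi),
       D = max((h_hi - h_lo) / 10, diff(z)[1]))
}

#' Fit a tanh interface model to a density profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [rho_slab_model()] or
#' [rho_solvent_model()] to a binned density profile. Initial guesses are
#' derived from the half-maximum crossings unless supplied.
#'
#' @param profile A `density_profile`.
#' @param model `"pe_slab"` (slab form, parameters rho_b, h1, h2, D) or
#'   `"solvent"` (solvent form, parameters rho_b, h3, h4, D).
#' @param initial_guess Optional named list overriding the automatic start
#'   values (`rho_b`, `h_lo`, `h_hi`, `D`).
#' @return Object of class `interface_fit`: `model`, `rho_b`, `h` (named
#'   length-2 vector, h1/h2 or h3/h4), `D`, `residual_rms` (g cm^-3),
#'   `fit` (the nls object).
#' @export
fit_interface <- function(profile, model = c("pe_slab", "solvent"),
                          initial_guess = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$bin_centers; rho <- profile$density
  if (length(z) < 8L) stop("profile needs >= 8 bins")
  if (sd(rho) < 1e-12) stop("flat profile: nothing to fit")
  g <- .interface_guess(z, rho, model)
  if (!is.null(initial_guess)) g[names(initial_guess)] <- initial_guess
  df <- data.frame(z = z, rho = rho)
  fit <- tryCatch(
    if (model == "pe_slab")
      minpack.lm::nlsLM(rho ~ rho_slab_model(z, rho_b, h1, h2, D), data = df,
                        start = list(rho_b = g$rho_b, h1 = g$h_lo, h2 = g$h_hi, D = g$D),
                        lower = c(1e-6, min(z), min(z), 1e-3),
                        upper = c(Inf, max(z), max(z), diff(range(z))),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(rho ~ rho_solvent_model(z, rho_b, h3, h4, D), data = df,
                        start = list(rho_b = g$rho_b, h3 = g$h_lo, h4 = g$h_hi, D = g$D),
                        lower = c(1e-6, min(z), min(z), 1e-3),
                        upper = c(Inf, max(z), max(z), diff(range(z))),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("interface fit failed: ", conditionMessage(e)))
  p <- as.list(coef(fit))
  h <- if (model == "pe_slab") c(h1 = p$h1, h2 = p$h2) else c(h3 = p$h3, h4 = p$h4)
  if (h[1] > h[2]) h <- rev(setNames(h, rev(names(h))))
  structure(list(model = model, rho_b = p$rho_b, h = h, D = p$D,
                 residual_rms = sqrt(mean(residuals(fit)^2)), fit = fit),
            class = "interface_fit")
}

#' Evaluate a fitted interface model
#'
#' @param fit An `interface_fit`.
#' @param z Positions (A).
#' @return Model density at `z`, g cm^-3.
#' @export
predict_interface <- function(fit, z) {
  stopifnot(inherits(fit, "interface_fit"))
  if (fit$model == "pe_slab")
    rho_slab_model(z, fit$rho_b, fit$h[1], fit$h[2], fit$D)
  else
    rho_solvent_model(z, fit$rho_b, fit$h[1], fit$h[2], fit$D)
}

#' Locate the Gibbs dividing surfaces
#'
#' The Gibbs dividing surface at each interface is the position where the
#' fitted slab density equals the fitted solvent density. Each crossing is
#' bracketed by a coarse scan of rho_slab(z) - rho_solvent(z) over the
#' interfacial region and refined with Brent root finding to 1e-6 A.
#'
#' @param pe_fit `interface_fit` with model `"pe_slab"`.
#' @param solvent_fit `interface_fit` with model `"solvent"`.
#' @return Object of class `gibbs_surfaces`: `z_lower`, `z_upper` (A).
#' @export
gibbs_surfaces <- function(pe_fit, solvent_fit) {
  stopifnot(inherits(pe_fit, "interface_fit"), pe_fit$model == "pe_slab",
            inherits(solvent_fit, "interface_fit"), solvent_fit$model == "solvent")
  dmax <- 2 * max(pe_fit$D, solvent_fit$D)
  diff_fun <- function(z) predict_interface(pe_fit, z) - predict_interface(solvent_fit, z)
  find_crossing <- function(lo, hi) {
    zs <- seq(lo, hi, length.out = 400)
    d <- diff_fun(zs)
    sgn <- which(d[-1] * d[-length(d)] <= 0 & is.finite(d[-1]))
    if (length(sgn) == 0)
      stop("no slab/solvent density crossing in [", signif(lo, 6), ", ", signif(hi, 6), "]")
    # take the crossing closest to the interval midpoint (the interfacial one)
    mid <- (lo + hi) / 2
    j <- sgn[which.min(abs(zs[sgn] - mid))]
    uniroot(diff_fun, c(zs[j], zs[j + 1]), tol = 1e-6)$root
  }
  z_lower <- find_crossing(min(solvent_fit$h[1], pe_fit$h[1]) - dmax,
                           max(solvent_fit$h[1], pe_fit$h[1]) + dmax)
  z_upper <- find_crossing(min(solvent_fit$h[2], pe_fit$h[2]) - dmax,
                           max(solvent_fit$h[2], pe_fit$h[2]) + dmax)
  if (z_lower >= z_upper) stop("degenerate Gibbs surfaces: z_lower >= z_upper")
  structure(list(z_lower = z_lower, z_upper = z_upper), class = "gibbs_surfaces")
}

#' Re-reference the reaction coordinate to the nearest Gibbs surface
#'
#' Converts the raw center-of-mass separation xi' (solute COM z minus slab
#' COM z) into xi, the signed z-distance from the solute to the nearest
#' Gibbs dividing surface: negative toward the slab interior, positive
#' toward the solvent. Ties (exact midplane) resolve to the upper surface.
#'
#' @param xi_prime Numeric vector of raw separations (A).
#' @param surfaces A `gibbs_surfaces`.
#' @param slab_com_z Slab center-of-mass z at which xi' was measured (A).
#' @return xi, same length as `xi_prime` (A).
#' @export
rereference <- function(xi_prime, surfaces, slab_com_z = 0) {
  stopifnot(inherits(surfaces, "gibbs_surfaces"), is.numeric(xi_prime))
  z <- slab_com_z + xi_prime
  d_up <- abs(z - surfaces$z_upper)
  d_lo <- abs(z - surfaces$z_lower)
  ifelse(d_up <= d_lo, z - surfaces$z_upper, surfaces$z_lower - z)
}

#' @export
print.interface_fit <- function(x, ...) {
  cat(sprintf("<interface_fit> %s: rho_b %.4f g/cm^3, %s = %.3f, %s = %.3f A, D %.3f A, RMS %.2e\n",
              x$model, x$rho_b, names(x$h)[1], x$h[1], names(x$h)[2], x$h[2],
              x$D, x$residual_rms))
  invisible(x)
}

#' @export
print.gibbs_surfaces <- function(x, ...) {
  cat(sprintf("<gibbs_surfaces> z_lower %.4f A, z_upper %.4f A\n",
              x$z_lower, x$z_upper))
  invisible(x)
}

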