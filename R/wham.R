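#' Histogram a set of umbrella windows on a common grid
#'
#' Samples are tallied into half-open bins `[edge_j, edge_{j+1})`; samples
#' outside the grid are counted separately per window, never silently dropped.
#'
#' @param windows List of `window_samples` (see [sample_window()]).
#' @param bin_edges Strictly increasing numeric vector of bin edges (A),
#'   length >= 2. Uniform spacing is assumed by the WHAM solver.
#' @return An object of class `histogram_set`: `bin_edges`, `bin_centers`,
#'   `counts` (windows x bins integer matrix), `biases` (list of
#'   [bias_spec()]), `n_i` (total samples per window, including out-of-range),
#'   `out_of_range` (per-window count), `temperature`.
#' @export
build_histograms <- function(windows, bin_edges) {
  stopifnot(is.list(windows), length(windows) >= 1L)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with >= 2 edges")
  nb <- length(bin_edges) - 1L
  nw <- length(windows)
  counts <- matrix(0L, nrow = nw, ncol = nb)
  oor <- integer(nw)
  temps <- vapply(windows, function(w) w$temperature, numeric(1))
  if (max(temps) - min(temps) > 1e-9)
    stop("all windows must share one temperature")
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    if (length(s) == 0 || !all(is.finite(s))) stop("window ", i, " has empty or non-finite samples")
    # half-open bins [e_j, e_{j+1}): findInterval with left.open = FALSE
    idx <- findInterval(s, bin_edges, left.open = FALSE)
    inside <- idx >= 1L & idx <= nb & s < bin_edges[nb + 1L]
    oor[i] <- sum(!inside)
    counts[i, ] <- tabulate(idx[inside], nbins = nb)
  }
  structure(list(bin_edges = bin_edges,
                 bin_centers = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                 counts = counts,
                 biases = lapply(windows, `[[`, "bias"),
                 n_i = vapply(windows, function(w) length(w$samples), numeric(1)),
                 out_of_range = oor,
                 temperature = temps[1]),
            class = "histogram_set")
}

#' Overlap between adjacent umbrella windows
#'
#' Overlap coefficient sum_j min(p_j, q_j) of the normalized histograms of
#' each adjacent window pair. Adequate overlap is a prerequisite for a
#' well-conditioned WHAM combination.
#'
#' @param hists A `histogram_set` with >= 2 windows.
#' @param threshold Pairs with overlap below this value are flagged.
#' @return Data frame with columns `window_a`, `window_b`, `overlap`, `flagged`.
#' @export
window_overlap <- function(hists, threshold = 0.1) {
  stopifnot(inherits(hists, "histogram_set"))
  nw <- nrow(hists$counts)
  if (nw < 2L) stop("window_overlap requires at least 2 windows")
  res <- data.frame(window_a = seq_len(nw - 1L), window_b = seq_len(nw - 1L) + 1L,
                    overlap = NA_real_)
  for (i in seq_len(nw - 1L)) {
    p <- hists$counts[i, ]; q <- hists$counts[i + 1L, ]
    p <- if (sum(p) > 0) p / sum(p) else p
    q <- if (sum(q) > 0) q / sum(q) else q
    res$overlap[i] <- sum(pmin(p, q))
  }
  res$flagged <- res$overlap < threshold
  res
}

# Per-window, per-bin Boltzmann factor of the harmonic bias.
# "average": analytic bin mean of exp(-k(x-c)^2 / 2kT), a Gaussian integral;
# "midpoint": exp(-w(bin center)/kT).
.bias_boltzmann <- function(biases, edges, centers, kT, quadrature) {
  nb <- length(centers)
  a <- edges[-length(edges)]; b <- edges[-1]
  out <- matrix(1, length(biases), nb)
  for (i in seq_along(biases)) {
    bias <- biases[[i]]
    if (bias$k <= 0) next
    if (quadrature == "midpoint") {
      out[i, ] <- exp(-evaluate_bias(bias, centers) / kT)
    } else {
      sig <- sqrt(kT / bias$k)
      z_a <- (a - bias$center) / sig
      z_b <- (b - bias$center) / sig
      out[i, ] <- sqrt(2 * pi) * sig * (pnorm(z_b) - pnorm(z_a)) / (b - a)
      # recompute far-upper-tail bins from the survival function
      tail_up <- z_a > 6
      if (any(tail_up))
        out[i, tail_up] <- sqrt(2 * pi) * sig *
          (pnorm(z_a[tail_up], lower.tail = FALSE) -
           pnorm(z_b[tail_up], lower.tail = FALSE)) / (b - a)[tail_up]
    }
  }
  out
}

#' Solve the WHAM self-consistent equations
#'
#' Iterates the standard weighted-histogram equations
#' \deqn{P_j = \frac{\sum_i n_{ij}}{\sum_i n_i \exp[(f_i - w_i(\xi_j))/k_BT]},
#'       \qquad
#'       f_i = -k_BT \ln \sum_j P_j \exp[-w_i(\xi_j)/k_BT]}
#' with biases evaluated at bin centers and f initialized at zero, until
#' `max |delta f| < tol * kBT`. Bins with zero total counts get undefined
#' (NA) free energy and are excluded from normalization. The returned PMF
#' `-kBT ln P` is unshifted; see [zero_by_plateau()].
#'
#' @param hists A `histogram_set`.
#' @param temperature Temperature in K; defaults to the histogram set's.
#' @param tol Convergence tolerance in units of k_B T.
#' @param max_iter Iteration cap.
#' @param bias_quadrature How the Boltzmann factor of the bias is
#'   discretized per bin: `"average"` (default) uses the analytic bin
#'   average of exp(-w/kBT) (a Gaussian integral, so an erf difference),
#'   `"midpoint"` evaluates the bias at the bin center. With stiff biases
#'   the midpoint rule leaves a systematic ripple of order the within-bin
#'   bias variation; the averaged weights remove it (see the methods
#'   vignette).
#' @return Object of class `free_energy_profile`: `bin_centers`, `pmf`
#'   (kJ mol^-1, NA on empty bins), `stderr` (NA; filled by
#'   [combine_replicas()]), `n_total` per-bin counts, `f_windows`
#'   (converged window free energies, kJ mol^-1), `iterations`, `residual`
#'   (k_B T units), `temperature`, `zero_reference`.
#' @export
wham_solve <- function(hists, temperature = hists$temperature, tol = 1e-6,
                       max_iter = 1e5,
                       bias_quadrature = c("average", "midpoint")) {
  stopifnot(inherits(hists, "histogram_set"), tol > 0)
  bias_quadrature <- match.arg(bias_quadrature)
  kT <- kBT(temperature)
  centers <- hists$bin_centers
  counts <- hists$counts
  nw <- nrow(counts); nb <- ncol(counts)
  n_i <- hists$n_i - hists$out_of_range   # samples actually histogrammed
  N_j <- colSums(counts)
  defined <- N_j > 0
  if (!any(defined)) stop("all bins empty")

  expb <- .bias_boltzmann(hists$biases, hists$bin_edges, centers, kT,
                          bias_quadrature)

  f <- rep(0, nw)           # dimensionless f_i / kT
  P <- rep(0, nb)
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- colSums(n_i * exp(f) * expb)   # sum_i n_i exp(f_i - w_ij)
    P[defined] <- N_j[defined] / denom[defined]
    P[!defined] <- 0
    P <- P / sum(P)
    # f_i = -ln sum_j P_j exp(-w_ij)  (dimensionless)
    f_new <- -log(as.vector(expb %*% P))
    f_new <- f_new - f_new[1]
    residual <- max(abs(f_new - f))
    f <- f_new
    if (residual < tol) break
  }
  if (residual >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3e kBT > tol %.3e)",
                 iter, residual, tol))
  pmf <- rep(NA_real_, nb)
  pmf[defined] <- -kT * log(P[defined])
  structure(list(bin_centers = centers, pmf = pmf,
                 stderr = rep(NA_real_, nb), n_total = N_j,
                 f_windows = f * kT, iterations = iter, residual = residual,
                 temperature = temperature,
                 zero_reference = NULL),
            class = "free_energy_profile")
}

#' Zero a PMF against its bulk plateau
#'
#' Fits a constant (the arithmetic mean) to the PMF over the plateau range —
#' the large-separation region where the solute-slab interaction has decayed —
#' and subtracts it from the whole curve, so the PMF is reported relative to
#' the bulk-solvent reference state.
#'
#' @param profile A `free_energy_profile`.
#' @param plateau_range Length-2 xi interval (A). Default: the last 20% of
#'   defined bins (the solvent side).
#' @return The shifted profile; `zero_reference` records the range and the
#'   fitted constant.
#' @export
zero_by_plateau <- function(profile, plateau_range = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"))
  defined <- which(!is.na(profile$pmf))
  if (length(defined) < 2L) stop("profile has fewer than 2 defined bins")
  if (is.null(plateau_range)) {
    tail_bins <- defined[defined >= quantile(defined, 0.8, type = 1)]
    plateau_range <- range(profile$bin_centers[tail_bins])
  }
  stopifnot(length(plateau_range) == 2L, plateau_range[1] <= plateau_range[2])
  in_range <- !is.na(profile$pmf) &
    profile$bin_centers >= plateau_range[1] &
    profile$bin_centers <= plateau_range[2]
  if (sum(in_range) < 2L) stop("plateau range contains fewer than 2 defined bins")
  const <- mean(profile$pmf[in_range])
  profile$pmf <- profile$pmf - const
  profile$zero_reference <- list(range = as.numeric(plateau_range),
                                 constant = const, n_bins = sum(in_range))
  profile
}

#' Combine replica PMFs into mean and inter-replica spread
#'
#' Per-bin mean and sample standard deviation across independent replicas.
#' Each input must already be plateau-zeroed so the replicas share a common
#' reference; bins undefined in any replica are undefined in the output.
#'
#' @param profiles List of >= 2 `free_energy_profile` on identical bin grids.
#' @return A `free_energy_profile` with `pmf` = per-bin mean and `stderr` =
#'   per-bin sample SD (the statistical uncertainty reported with the PMF).
#' @export
combine_replicas <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  for (p in profiles) {
    stopifnot(inherits(p, "free_energy_profile"))
    if (is.null(p$zero_reference))
      stop("replica profiles must be plateau-zeroed before combining")
  }
  grid <- profiles[[1]]$bin_centers
  for (p in profiles[-1])
    if (length(p$bin_centers) != length(grid) ||
        max(abs(p$bin_centers - grid)) > 1e-9)
      stop("replica profiles are on mismatched bin grids")
  m <- do.call(rbind, lapply(profiles, `[[`, "pmf"))
  ok <- colSums(is.na(m)) == 0L
  pmf <- rep(NA_real_, length(grid)); se <- rep(NA_real_, length(grid))
  pmf[ok] <- colMeans(m[, ok, drop = FALSE])
  se[ok] <- apply(m[, ok, drop = FALSE], 2, sd)
  n_tot <- Reduce(`+`, lapply(profiles, `[[`, "n_total"))
  structure(list(bin_centers = grid, pmf = pmf, stderr = se, n_total = n_tot,
                 f_windows = NULL, iterations = NA_integer_, residual = NA_real_,
                 temperature = profiles[[1]]$temperature,
                 zero_reference = list(replicas = length(profiles))),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  ok <- !is.na(x$pmf)
  cat(sprintf("<free_energy_profile> %d bins (%d defined), xi [%.2f, %.2f] A\n",
              length(x$pmf), sum(ok), min(x$bin_centers), max(x$bin_centers)))
  if (any(ok))
    cat(sprintf("  PMF range [%.3f, %.3f] kJ/mol; min at xi = %.2f A\n",
                min(x$pmf[ok]), max(x$pmf[ok]),
                x$bin_centers[ok][which.min(x$pmf[ok])]))
  invisible(x)
}

#' Write a PMF as TSV with a YAML metadata sidecar
#'
#' @param profile A `free_energy_profile`.
#' @param path Output TSV path (columns bin_center, pmf, stderr, n_total);
#'   metadata is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  df <- data.frame(bin_center = profile$bin_centers, pmf = profile$pmf,
                   stderr = profile$stderr, n_total = profile$n_total)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(temperature_K = profile$temperature,
               iterations = profile$iterations,
               residual_kBT = profile$residual,
               zero_reference = profile$zero_reference)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}
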