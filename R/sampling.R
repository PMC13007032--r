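#' Draw biased samples of the reaction coordinate from an analytic profile
#'
#' Metropolis Monte Carlo sampling of xi under the total potential
#' U(xi) = A(xi) + w(xi), where A is the analytic free-energy profile and
#' w the harmonic window bias. Only the stationary distribution matters for
#' downstream histogram analysis, so Monte Carlo stands in for restrained
#' molecular dynamics. The base profile is tabulated on a fine uniform grid
#' (0.005 A) and linearly interpolated inside the compiled kernel; the bias
#' is evaluated analytically. The proposal step is tuned to a 30-50%
#' acceptance rate during burn-in.
#'
#' @param spec An [analytic_profile()].
#' @param bias A [bias_spec()]; use `force_constant = 0` for unbiased runs.
#' @param n_samples Number of post-burn-in samples (>= 1).
#' @param temperature Temperature in K.
#' @param seed Integer RNG seed.
#' @param burn_in Number of discarded equilibration steps; default 10% of
#'   `n_samples`.
#' @param thin Decorrelation stride: `thin` Metropolis steps are taken per
#'   retained sample (default 10), so successive samples are close to
#'   independent.
#' @return An object of class `window_samples`: list with `samples` (numeric
#'   vector, Angstrom), `bias`, `temperature`, `replica_id`.
#' @export
sample_window <- function(spec, bias, n_samples, temperature = 300, seed = 1L,
                          burn_in = ceiling(0.1 * n_samples), thin = 10L) {
  stopifnot(inherits(spec, "analytic_profile"), inherits(bias, "bias_spec"))
  if (!is.numeric(n_samples) || n_samples < 1) stop("n_samples must be >= 1")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  lo <- spec$domain[1]; hi <- spec$domain[2]
  dx <- 0.005
  ng <- max(2L, ceiling((hi - lo) / dx) + 1L)
  grid <- seq(lo, hi, length.out = ng)
  energies <- evaluate_profile(spec, grid)

  start <- min(max(bias$center, lo), hi)
  beta <- 1 / kBT(temperature)
  # initial step ~ width of the biased distribution, bounded by the domain
  step0 <- if (bias$k > 0) min(hi - lo, 2 * sqrt(1 / (beta * bias$k))) else (hi - lo) / 4

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  samples <- .metropolis_sample(energies, grid[1], grid[2] - grid[1], lo, hi,
                                bias$center, bias$k, as.integer(n_samples),
                                as.integer(burn_in), beta, start, step0,
                                as.integer(thin))
  structure(list(samples = samples, bias = bias, temperature = temperature,
                 replica_id = 1L, seed = as.integer(seed)),
            class = "window_samples")
}

#' Generate a full set of umbrella windows
#'
#' One [sample_window()] run per window center, with per-window seeds derived
#' deterministically from the master seed.
#'
#' @param spec An [analytic_profile()].
#' @param centers Sorted window centers in Angstrom.
#' @param force_constant Shared force constant, kJ mol^-1 A^-2. Default
#'   41.84 (= 10 kcal mol^-1 A^-2).
#' @param n_samples Samples per window.
#' @param temperature Temperature in K.
#' @param seed Master seed; window i uses `seed * 1000 + i` (kept below 2^31).
#' @param replica_id Integer tag attached to every window.
#' @inheritParams sample_window
#' @return List of `window_samples`, one per center.
#' @export
generate_window_set <- function(spec, centers, force_constant = 41.84,
                                n_samples = 10000, temperature = 300,
                                seed = 1L, replica_id = 1L,
                                burn_in = ceiling(0.1 * n_samples), thin = 10L) {
  if (length(centers) == 0) stop("centers must be nonempty")
  stopifnot(!is.unsorted(centers))
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    # derive in double precision to avoid integer overflow, then reduce
    wseed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    b <- bias_spec(centers[i], force_constant)
    w <- sample_window(spec, b, n_samples, temperature, seed = wseed,
                       burn_in = burn_in, thin = thin)
    w$replica_id <- as.integer(replica_id)
    windows[[i]] <- w
  }
  windows
}

# Preserve the caller's RNG stream across internally seeded draws.
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.window_samples <- function(x, ...) {
  cat(sprintf("<window_samples> center %.3f A, k %.3f kJ/mol/A^2, n %d, T %g K\n",
              x$bias$center, x$bias$k, length(x$samples), x$temperature))
  invisible(x)
}
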