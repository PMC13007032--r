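# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different computational route than the code
# under test.

# --- WHAM by direct minimization of the convex negative log-likelihood.
# Variables are the dimensionless window free energies g_i (g_1 = 0);
# Phi(g) = sum_j N_j log(sum_i n_i c_ij e^{g_i}) - sum_i n_i g_i
# whose stationary point satisfies the WHAM self-consistent equations.
# Bin weights c_ij are obtained by numerical quadrature of exp(-w_i/kT),
# independent of the package's closed-form expression.
wham_ml_oracle <- function(hists, temperature = hists$temperature,
                           quadrature = c("average", "midpoint")) {
  quadrature <- match.arg(quadrature)
  kT <- slabpmf::kBT(temperature)
  edges <- hists$bin_edges
  nb <- length(edges) - 1L
  nw <- nrow(hists$counts)
  n_i <- hists$n_i - hists$out_of_range
  N_j <- colSums(hists$counts)
  C <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    b <- hists$biases[[i]]
    for (j in seq_len(nb)) {
      if (quadrature == "midpoint") {
        mid <- (edges[j] + edges[j + 1]) / 2
        C[i, j] <- exp(-0.5 * b$k * (mid - b$center)^2 / kT)
      } else {
        C[i, j] <- integrate(function(x) exp(-0.5 * b$k * (x - b$center)^2 / kT),
                             edges[j], edges[j + 1], rel.tol = 1e-12,
                             abs.tol = 1e-300)$value / (edges[j + 1] - edges[j])
      }
    }
  }
  obj <- function(g2) {
    g <- c(0, g2)
    den <- colSums(n_i * exp(g) * C)
    sum(N_j[N_j > 0] * log(den[N_j > 0])) - sum(n_i * g)
  }
  grad <- function(g2) {
    g <- c(0, g2)
    den <- colSums(n_i * exp(g) * C)
    P <- ifelse(N_j > 0, N_j / den, 0)
    (n_i * exp(g) * as.vector(C %*% P) - n_i)[-1]
  }
  fit <- optim(rep(0, nw - 1), obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  g <- c(0, fit$par)
  list(f_kT = g - g[1], convergence = fit$convergence)
}

# --- exact sign maximization of |sum s_i v_i| by enumeration (n <= 15)
flip_oracle <- function(vectors) {
  v <- as.matrix(vectors)
  n <- nrow(v)
  stopifnot(n <= 15)
  best <- -Inf
  best_r <- NULL
  for (mask in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1, 1)
    r <- colSums(v * s)
    m <- sqrt(sum(r^2))
    if (m > best) { best <- m; best_r <- r }
  }
  list(magnitude = best, resultant = best_r)
}

# --- Gibbs surface by dense grid scan of |rho_slab - rho_solvent|
gds_grid_oracle <- function(pe_fit, w_fit, z_range, dz = 1e-3) {
  zs <- seq(z_range[1], z_range[2], by = dz)
  d <- abs(slabpmf::predict_interface(pe_fit, zs) -
           slabpmf::predict_interface(w_fit, zs))
  zs[which.min(d)]
}

# --- best-fit RMSD by rotation search: coarse Euler-angle grid then
# Nelder-Mead refinement (proper rotations only; never uses an SVD)
rotgrid_rmsd_oracle <- function(coords, reference) {
  X <- scale(as.matrix(coords), scale = FALSE)
  Y <- scale(as.matrix(reference), scale = FALSE)
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) sqrt(mean(rowSums((X %*% t(euler(a)) - Y)^2)))
  best <- c(0, 0, 0); bv <- f(best)
  gr <- seq(0, 2 * pi, by = 20 * pi / 180)
  gr_half <- seq(0, pi, by = 20 * pi / 180)
  for (a1 in gr) for (a2 in gr_half) for (a3 in gr) {
    v <- f(c(a1, a2, a3))
    if (v < bv) { bv <- v; best <- c(a1, a2, a3) }
  }
  opt <- optim(best, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# --- small helpers shared by tests
expect_unit_vector <- function(v, tol = 1e-9) {
  expect_equal(sqrt(sum(v^2)), 1, tolerance = tol)
}

flat_profile <- function(domain = c(-10, 10)) {
  slabpmf::analytic_profile("flat", domain = domain)
}
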