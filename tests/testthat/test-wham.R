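make_windows <- function(samples_list, centers, k = 41.84, temperature = 300) {
  lapply(seq_along(samples_list), function(i)
    structure(list(samples = samples_list[[i]],
                   bias = bias_spec(centers[i], k),
                   temperature = temperature, replica_id = 1L),
              class = "window_samples"))
}

test_that("histogramming uses half-open bins and tracks out-of-range samples", {
  w <- make_windows(list(c(rep(0.55, 10), 1.0, -3)), 0, k = 0)
  h <- build_histograms(w, seq(0, 1, by = 0.1))
  expect_equal(sum(h$counts), 10)          # -3 and the top edge 1.0 are out of range
  expect_equal(h$counts[1, 6], 10L)        # [0.5, 0.6)
  expect_equal(h$out_of_range, 2L)
  # a sample exactly on an interior edge goes right
  h2 <- build_histograms(make_windows(list(0.5), 0, k = 0), seq(0, 1, by = 0.5))
  expect_equal(h2$counts[1, ], c(0L, 1L))
  expect_error(build_histograms(w, c(0, 0, 1)), "strictly increasing")
})

test_that("uniform samples fill bins within the multinomial envelope", {
  set.seed(42)
  n <- 5e4
  w <- make_windows(list(runif(n, 0, 10)), 5, k = 0)
  h <- build_histograms(w, seq(0, 10, by = 1))
  p <- 0.1
  bound <- qnorm(1 - 0.001 / 2 / 10) * sqrt(n * p * (1 - p))  # 99.9% familywise
  expect_true(all(abs(h$counts[1, ] - n * p) < bound))
})

test_that("adjacent-window overlap coefficient behaves on known histograms", {
  # identical, disjoint and half-overlapping uniform histograms
  w <- make_windows(list(rep(c(1.5, 2.5), 50), rep(c(1.5, 2.5), 50),
                         rep(c(5.5, 6.5), 50), rep(c(2.5, 5.5), 50)),
                    c(2, 2, 6, 4), k = 0)
  h <- build_histograms(w, seq(0, 8, by = 1))
  ov <- window_overlap(h, threshold = 0.3)
  expect_equal(ov$overlap, c(1, 0, 0.5))
  expect_equal(ov$flagged, c(FALSE, TRUE, FALSE))
  expect_error(window_overlap(build_histograms(w[1], seq(0, 8, 1))), "2 windows")
})

test_that("a single unbiased window reduces WHAM to the histogram identity", {
  set.seed(7)
  samples <- rnorm(5000, 5, 1.5)
  w <- make_windows(list(samples), 5, k = 0)
  h <- build_histograms(w, seq(0, 10, by = 0.25))
  pr <- wham_solve(h)
  ok <- !is.na(pr$pmf)
  ref <- -kBT(300) * log(h$counts[1, ok] / sum(h$counts))
  # equal up to one additive constant, to near machine precision
  expect_lt(max(abs((pr$pmf[ok] - ref) - mean(pr$pmf[ok] - ref))), 1e-10)
  # reconstructed probabilities normalize
  expect_equal(sum(exp(-pr$pmf[ok] / kBT(300))), 1, tolerance = 1e-9)
})

test_that("WHAM recovers a flat free-energy profile", {
  flat <- flat_profile()
  ws <- generate_window_set(flat, seq(-10, 10, length.out = 25), 41.84,
                            1e5, seed = 3)
  h <- build_histograms(ws, seq(-10, 10, by = 0.1))
  pr <- wham_solve(h)
  ok <- !is.na(pr$pmf) & pr$n_total >= 100
  expect_lt(diff(range(pr$pmf[ok])), 0.5)
  expect_lt(pr$residual, 1e-6)
})

test_that("WHAM recovers a harmonic profile after optimal shift", {
  a <- 0.5
  harm <- analytic_profile("harmonic", domain = c(-10, 10), a = a)
  ws <- generate_window_set(harm, seq(-10, 10, length.out = 25), 41.84,
                            3e4, seed = 21)
  h <- build_histograms(ws, seq(-10, 10, by = 0.1))
  pr <- wham_solve(h)
  ok <- !is.na(pr$pmf) & pr$n_total >= 100
  err <- pr$pmf[ok] - 0.5 * a * pr$bin_centers[ok]^2
  err <- err - mean(err)
  expect_lt(sqrt(mean(err^2)), 0.3)
})

test_that("WHAM reports non-convergence with its residual", {
  flat <- flat_profile(c(-4, 4))
  ws <- generate_window_set(flat, c(-2, 0, 2), 41.84, 2000, seed = 5)
  h <- build_histograms(ws, seq(-4, 4, by = 0.2))
  expect_error(wham_solve(h, max_iter = 3), "did not converge")
})

test_that("iterative WHAM matches the maximum-likelihood oracle", {
  # small instance: 5 windows, 40 bins, both quadratures
  flat <- flat_profile(c(-4, 4))
  ws <- generate_window_set(flat, seq(-3, 3, length.out = 5), 20, 5000, seed = 8)
  h <- build_histograms(ws, seq(-4, 4, by = 0.2))
  for (q in c("average", "midpoint")) {
    pr <- wham_solve(h, tol = 1e-10, bias_quadrature = q)
    oracle <- wham_ml_oracle(h, quadrature = q)
    expect_equal(oracle$convergence, 0)
    f_pkg <- pr$f_windows / kBT(300)
    expect_lt(max(abs(f_pkg - oracle$f_kT)), 1e-6)
  }
})

test_that("plateau zeroing subtracts the plateau mean and is idempotent", {
  grid <- seq(0.1, 9.9, by = 0.2)
  mk <- function(vals) structure(
    list(bin_centers = grid, pmf = vals, stderr = rep(NA_real_, length(grid)),
         n_total = rep(100, length(grid)), f_windows = NULL,
         iterations = 1L, residual = 0, temperature = 300,
         zero_reference = NULL),
    class = "free_energy_profile")
  p <- mk(rep(3.5, length(grid)))
  z <- zero_by_plateau(p, c(8, 10))
  expect_equal(z$zero_reference$constant, 3.5)
  expect_true(all(abs(z$pmf) < 1e-12))
  expect_lt(max(abs(zero_by_plateau(z, c(8, 10))$pmf - z$pmf)), 1e-12)
  # noisy plateau: the subtracted constant is the arithmetic mean
  set.seed(1)
  noisy <- mk(rnorm(length(grid)))
  zr <- zero_by_plateau(noisy, c(5, 10))
  expect_equal(zr$zero_reference$constant,
               mean(noisy$pmf[grid >= 5 & grid <= 10]))
  expect_error(zero_by_plateau(p, c(20, 30)), "plateau")
})

test_that("replica combination gives per-bin mean and sample SD", {
  grid <- seq(0.5, 9.5, by = 1)
  mk <- function(vals) structure(
    list(bin_centers = grid, pmf = vals, stderr = rep(NA_real_, 10),
         n_total = rep(100, 10), f_windows = NULL, iterations = 1L,
         residual = 0, temperature = 300,
         zero_reference = list(constant = 0)),
    class = "free_energy_profile")
  base <- rep(1, 10)
  same <- combine_replicas(list(mk(base), mk(base)))
  expect_true(all(same$stderr == 0))
  # two replicas differing by delta in one bin
  delta <- 0.8
  shifted <- base; shifted[4] <- base[4] + delta
  two <- combine_replicas(list(mk(base), mk(shifted)))
  expect_equal(two$pmf[4], 1 + delta / 2)
  expect_equal(two$stderr[4], delta / sqrt(2))
  # undefined anywhere -> undefined in output; grid mismatch -> error
  holey <- base; holey[2] <- NA
  expect_true(is.na(combine_replicas(list(mk(base), mk(holey)))$pmf[2]))
  other <- mk(base); other$bin_centers <- grid + 0.1
  expect_error(combine_replicas(list(mk(base), other)), "mismatched")
})

test_that("inter-replica SD of noisy replicas follows the chi expectation", {
  set.seed(33)
  grid <- seq(0.05, 19.95, by = 0.1)
  nb <- length(grid); sigma <- 1; nrep <- 4
  mk <- function(vals) structure(
    list(bin_centers = grid, pmf = vals, stderr = rep(NA_real_, nb),
         n_total = rep(100, nb), f_windows = NULL, iterations = 1L,
         residual = 0, temperature = 300,
         zero_reference = list(constant = 0)),
    class = "free_energy_profile")
  reps <- lapply(1:nrep, function(r) mk(rnorm(nb, sd = sigma)))
  comb <- combine_replicas(reps)
  c4 <- sqrt(2 / (nrep - 1)) * gamma(nrep / 2) / gamma((nrep - 1) / 2)
  expect_lt(abs(mean(comb$stderr) - c4 * sigma) / (c4 * sigma), 0.15)
})
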