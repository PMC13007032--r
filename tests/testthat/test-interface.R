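uniform_box_config <- function(n = 4000, box = c(20, 20, 50), mass = 14,
                               species = "PE", seed = 1) {
  set.seed(seed)
  configuration(cbind(runif(n, -box[1]/2, box[1]/2),
                      runif(n, -box[2]/2, box[2]/2),
                      runif(n, -box[3]/2, box[3]/2)),
                rep(species, n), rep(mass, n), box = box)
}

test_that("density of a uniform box equals Nm/V in every bin", {
  cfg <- uniform_box_config()
  dp <- density_profile(cfg, "PE", n_bins = 10)
  conv <- 1 / 0.602214076
  expected <- 4000 * 14 / prod(cfg$box) * conv
  # multinomial noise: ~400 atoms/bin
  expect_true(all(abs(dp$density - expected) / expected < 0.2))
  expect_equal(mean(dp$density), expected, tolerance = 1e-9)  # mass conservation
})

test_that("density concentrates where the atoms are, and conserves mass", {
  box <- c(10, 10, 20)
  n <- 100
  pos <- cbind(runif(n, -5, 5), runif(n, -5, 5), rep(3.1, n))
  cfg <- configuration(pos, rep("W", n), rep(18, n), box = box)
  dp <- density_profile(cfg, "W", n_bins = 10)   # bins of width 2
  conv <- 1 / 0.602214076
  vbin <- 10 * 10 * 2
  expect_equal(dp$density[7], n * 18 / vbin * conv)  # bin [2, 4)
  expect_equal(sum(dp$density[-7]), 0)
  # total selected mass per frame recovered from sum(density * V_bin)
  expect_equal(sum(dp$density) * vbin / conv, n * 18)
  expect_error(density_profile(cfg, "XX"), "unknown species")
})

test_that("tanh fits recover exact generating parameters", {
  z <- seq(-40, 40, length.out = 161)
  truth <- list(rho_b = 0.93, h1 = -20, h2 = 20, D = 4)
  mk <- function(dens, species) structure(
    list(bin_centers = z, density = dens, species = species,
         frames_averaged = 1L, axis = "z", box_length = 80),
    class = "density_profile")
  pe <- mk(rho_slab_model(z, truth$rho_b, truth$h1, truth$h2, truth$D), "PE")
  fit <- fit_interface(pe, "pe_slab")
  expect_equal(fit$rho_b, truth$rho_b, tolerance = 1e-4)
  expect_equal(unname(fit$h), c(-20, 20), tolerance = 1e-4)
  expect_equal(fit$D, 4, tolerance = 1e-4)

  wtr <- mk(rho_solvent_model(z, 1.04, -21, 21, 3), "W")
  fw <- fit_interface(wtr, "solvent")
  expect_equal(fw$rho_b, 1.04, tolerance = 1e-4)
  expect_equal(unname(fw$h), c(-21, 21), tolerance = 1e-4)
  expect_equal(fw$D, 3, tolerance = 1e-4)

  # refitting the fitted curve reproduces the parameters (idempotence)
  pe2 <- mk(predict_interface(fit, z), "PE")
  fit2 <- fit_interface(pe2, "pe_slab")
  expect_lt(max(abs(unlist(fit2[c("rho_b", "D")]) -
                    unlist(fit[c("rho_b", "D")]))), 1e-8)
  expect_lt(max(abs(fit2$h - fit$h)), 1e-8)
  expect_error(fit_interface(mk(rep(1, length(z)), "PE"), "pe_slab"), "flat")
})

test_that("1% multiplicative noise moves fitted parameters by under 2%", {
  z <- seq(-40, 40, length.out = 161)
  worst <- 0
  for (seed in 1:5) {
    set.seed(seed)
    dens <- rho_slab_model(z, 0.93, -20, 20, 4) * (1 + rnorm(length(z), 0, 0.01))
    dp <- structure(list(bin_centers = z, density = dens, species = "PE",
                         frames_averaged = 1L, axis = "z", box_length = 80),
                    class = "density_profile")
    fit <- fit_interface(dp, "pe_slab")
    rel <- abs(c(fit$rho_b / 0.93, fit$h[1] / -20, fit$h[2] / 20, fit$D / 4) - 1)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.02)
})

test_that("Gibbs surfaces match a dense grid scan and honor symmetry", {
  z <- seq(-40, 40, length.out = 161)
  mk <- function(dens, sp) structure(
    list(bin_centers = z, density = dens, species = sp,
         frames_averaged = 1L, axis = "z", box_length = 80),
    class = "density_profile")
  pe <- fit_interface(mk(rho_slab_model(z, 0.93, -20, 20, 4), "PE"), "pe_slab")
  wt <- fit_interface(mk(rho_solvent_model(z, 1.04, -21, 21, 3), "W"), "solvent")
  gs <- gibbs_surfaces(pe, wt)
  # symmetric construction: crossings mirror about the midplane
  expect_equal(gs$z_lower, -gs$z_upper, tolerance = 1e-4)
  # dense scan oracle at 1e-3 A
  expect_equal(gs$z_upper, gds_grid_oracle(pe, wt, c(15, 25)), tolerance = 1e-3)
  expect_equal(gs$z_lower, gds_grid_oracle(pe, wt, c(-25, -15)), tolerance = 1e-3)
  # solvent denser than the slab everywhere -> no crossing
  hot <- fit_interface(mk(rho_solvent_model(z, 5, -21, 21, 3) + 2, "W"), "solvent")
  expect_error(gibbs_surfaces(pe, hot), "no slab/solvent density crossing")
})

test_that("raising the solvent bulk density pulls the crossings slabward", {
  z <- seq(-40, 40, length.out = 161)
  mk <- function(dens, sp) structure(
    list(bin_centers = z, density = dens, species = sp,
         frames_averaged = 1L, axis = "z", box_length = 80),
    class = "density_profile")
  pe <- fit_interface(mk(rho_slab_model(z, 0.93, -20, 20, 4), "PE"), "pe_slab")
  upper <- vapply(c(0.8, 1.0, 1.2), function(rb) {
    wt <- fit_interface(mk(rho_solvent_model(z, rb, -21, 21, 3), "W"), "solvent")
    gibbs_surfaces(pe, wt)$z_upper
  }, numeric(1))
  expect_true(all(diff(upper) < 0))
})

test_that("re-referencing measures signed distance to the nearest surface", {
  gs <- structure(list(z_lower = -20, z_upper = 20), class = "gibbs_surfaces")
  # xi' is solute-minus-slab-COM z distance; slab COM at 0
  expect_equal(rereference(20, gs), 0)                       # on the surface
  expect_equal(rereference(0, gs), -20)                      # at the COM
  expect_equal(rereference(35, gs), 15)                      # bulk solvent
  expect_equal(rereference(-35, gs), 15)                     # bulk below
  expect_equal(rereference(-12, gs), -8)
  # reflecting the system through the midplane negates nothing: |xi| symmetric
  xs <- c(-30, -22, -10, 0, 10, 22, 30)
  expect_equal(rereference(xs, gs), rereference(-xs, gs))
})
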