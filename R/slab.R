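#' Particle configuration container
#'
#' @param positions n x 3 matrix of coordinates (A).
#' @param species Character vector of species labels (length n).
#' @param mass Atomic/bead masses, g mol^-1 (length n, > 0).
#' @param charge Partial charges, e (length n).
#' @param mol_id Integer molecule/chain ids (length n).
#' @param bonds Two-column integer matrix of bonded atom pairs (1-based),
#'   or NULL.
#' @param box Length-3 box lengths (A); coordinates live in [-L/2, L/2).
#' @return Object of class `configuration`.
#' @export
configuration <- function(positions, species, mass, charge = NULL,
                          mol_id = NULL, bonds = NULL, box) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, all(is.finite(positions)),
            length(species) == n, length(mass) == n, all(mass > 0),
            length(box) == 3L, all(box > 0))
  if (is.null(charge)) charge <- numeric(n)
  if (is.null(mol_id)) mol_id <- seq_len(n)
  structure(list(positions = positions, species = as.character(species),
                 mass = as.numeric(mass), charge = as.numeric(charge),
                 mol_id = as.integer(mol_id), bonds = bonds,
                 box = as.numeric(box)),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %d atoms, species: %s; box %.1f x %.1f x %.1f A\n",
              nrow(x$positions),
              paste(sprintf("%s (%d)", names(table(x$species)), table(x$species)),
                    collapse = ", "),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Slab + solvent system specification
#'
#' Declares the synthetic polymer-slab/solvent box: box dimensions, bulk
#' densities, tanh interface positions and widths, chain geometry and
#' orientation statistics, and the solute's placement. The slab occupies
#' [h1, h2] along z and the solvent fills the box outside [h3, h4]; the
#' solvent exclusion must enclose the slab (h3 <= h1 < h2 <= h4) so the two
#' density curves cross at each interface — that crossing is the Gibbs
#' dividing surface.
#'
#' Default densities are those of a semicrystalline high-density
#' polyethylene slab in water (0.93 and 1.04 g cm^-3).
#'
#' @param box Box lengths (Lx, Ly, Lz) in A.
#' @param rho_slab,rho_solvent Bulk densities, g cm^-3.
#' @param h Length-4 vector (h1, h2, h3, h4) in A.
#' @param D1,D2 Interfacial width parameters (slab, solvent), A.
#' @param bead_spacing Along-chain z-spacing of slab beads, A (1.27 ~ the
#'   axial C-C step of an all-anti chain).
#' @param zigzag_amp Transverse zigzag offset of slab chains, A.
#' @param orientation_jitter_deg SD of the per-chain tilt away from +z,
#'   degrees (0 = perfectly aligned chains).
#' @param slab_mass,solvent_mass,solute_mass Bead masses, g mol^-1
#'   (CH2-, H2O- and CF2-like).
#' @param n_c Solute backbone length in beads (>= 3).
#' @param xi0 Solute position: signed z-distance of the solute COM from the
#'   upper Gibbs dividing surface, A.
#' @param theta0 Solute tilt from +z, degrees.
#' @param conformation `"extended"` or `"perturbed"` solute conformation.
#' @param solute_noise_amp Coordinate noise SD for the perturbed solute, A.
#' @param seed Integer RNG seed.
#' @return Object of class `slab_system_spec`.
#' @export
slab_system_spec <- function(box = c(40, 40, 140),
                             rho_slab = 0.93, rho_solvent = 1.04,
                             h = c(-20, 20, -21, 21), D1 = 3, D2 = 3,
                             bead_spacing = 1.27, zigzag_amp = 0.45,
                             orientation_jitter_deg = 5,
                             slab_mass = 14, solvent_mass = 18,
                             solute_mass = 50,
                             n_c = 8, xi0 = 0, theta0 = 0,
                             conformation = "extended",
                             solute_noise_amp = 0.1,
                             seed = 1L) {
  stopifnot(length(box) == 3L, all(box > 0), length(h) == 4L,
            rho_slab > 0, rho_solvent > 0, D1 > 0, D2 > 0,
            bead_spacing > 0, n_c >= 3)
  if (!(h[1] < h[2])) stop("slab interface positions must satisfy h1 < h2")
  if (!(h[3] < h[4])) stop("solvent edges must satisfy h3 < h4")
  if (h[3] > h[1] || h[4] < h[2])
    stop("solvent exclusion [h3, h4] must enclose the slab [h1, h2]")
  if (h[1] < -box[3] / 2 + 4 * D1 || h[2] > box[3] / 2 - 4 * D1)
    stop("box too small along z for the requested slab")
  structure(as.list(environment()), class = "slab_system_spec")
}

#' Build an all-anti zigzag solute chain with a prescribed tilt
#'
#' Constructs an n_c-bead backbone as an ideal all-anti zigzag (bond length
#' 1.54 A, bond angle 112 degrees), whose 1,3-resultant vector — the chain
#' axis, pointing from the first bead (tail terminus) toward the last bead
#' (headgroup end) — makes angle `theta0` with +z. Tilt is applied by
#' rotation about the y-axis; the chain is centered at the origin. The
#' perturbed conformation adds seeded isotropic Gaussian coordinate noise.
#'
#' @param n_c Number of backbone beads (>= 3).
#' @param theta0 Tilt from +z in degrees.
#' @param conformation `"extended"` or `"perturbed"`.
#' @param seed RNG seed (used for the perturbed form).
#' @param noise_amp Noise SD in A for the perturbed form.
#' @param bond_length C-C bond length, A.
#' @param bond_angle_deg Backbone bond angle, degrees.
#' @return n_c x 3 coordinate matrix (A).
#' @export
make_oriented_chain <- function(n_c, theta0 = 0,
                                conformation = c("extended", "perturbed"),
                                seed = 1L, noise_amp = 0.1,
                                bond_length = 1.54, bond_angle_deg = 112) {
  conformation <- match.arg(conformation)
  if (n_c < 3) stop("n_c must be >= 3")
  half <- bond_angle_deg / 2 * pi / 180
  dz <- bond_length * sin(half)          # axial step per bond
  dx <- bond_length * cos(half)          # transverse zigzag offset
  k <- seq_len(n_c) - 1
  coords <- cbind(x = (k %% 2) * dx, y = 0, z = k * dz)
  coords <- sweep(coords, 2, colMeans(coords))
  if (conformation == "perturbed" && noise_amp > 0) {
    old <- .save_rng_state(); on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    coords <- coords + matrix(rnorm(3 * n_c, sd = noise_amp), n_c, 3)
  }
  if (theta0 != 0)
    coords <- coords %*% t(rotation_about(c(0, 1, 0), theta0))
  unname(coords)
}

# inverse-CDF sampler from a tabulated nonnegative density on a fine z grid
.sample_from_density <- function(n, z_grid, dens) {
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(n)
  z_grid[findInterval(u, cdf) + 1L] +
    runif(n, -diff(z_grid)[1] / 2, diff(z_grid)[1] / 2)
}

# logistic draw: CDF 1/2 (1 + tanh(2(z-h)/D)) is logistic with scale D/4
.rlogis_edge <- function(n, h, D) {
  u <- runif(n)
  h + (D / 4) * log(u / (1 - u))
}

#' Generate a synthetic slab + solvent + solute configuration
#'
#' Builds a bead-chain polymer slab whose z-density follows the tanh slab
#' form, a single-site solvent whose z-density follows the tanh solvent
#' form, and one solute chain placed at a prescribed signed distance from
#' the upper Gibbs dividing surface with a prescribed tilt.
#'
#' Slab chains run along +z (with optional per-chain angular jitter): each
#' chain's lower and upper end z are drawn from logistic distributions
#' centred at h1 and h2 with scale D1/4, which makes the ensemble-averaged
#' bead density reproduce the tanh slab profile (exact up to terms
#' exponentially small in the slab thickness / D1). Chain bead counts
#' therefore vary around (h2 - h1)/bead_spacing. Solvent bead z-coordinates
#' are drawn by inverse-CDF sampling from the solvent tanh form.
#'
#' @param spec A [slab_system_spec()].
#' @param include_solute Set FALSE to generate the bare slab/solvent box.
#' @return A `configuration` with species `"PE"` (slab), `"W"` (solvent) and
#'   `"PFAS"` (solute; net charge -1 spread over its beads). The attribute
#'   `"generating"` carries the spec plus the analytic Gibbs surfaces
#'   (`gds_lower`, `gds_upper`) implied by the generating parameters.
#' @export
make_interface_system <- function(spec, include_solute = TRUE) {
  stopifnot(inherits(spec, "slab_system_spec"))
  old <- .save_rng_state(); on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(spec$seed))
  Lx <- spec$box[1]; Ly <- spec$box[2]; Lz <- spec$box[3]
  h <- spec$h

  # --- analytic Gibbs surfaces from the generating parameters
  dfun <- function(z) rho_slab_model(z, spec$rho_slab, h[1], h[2], spec$D1) -
                      rho_solvent_model(z, spec$rho_solvent, h[3], h[4], spec$D2)
  gds_lower <- uniroot(dfun, c(h[3] - 2 * spec$D2, (h[1] + h[2]) / 2), tol = 1e-8)$root
  gds_upper <- uniroot(dfun, c((h[1] + h[2]) / 2, h[4] + 2 * spec$D2), tol = 1e-8)$root

  # --- slab chains
  n0 <- spec$rho_slab * 0.602214076 / spec$slab_mass      # beads per A^3
  target_beads <- n0 * Lx * Ly * (h[2] - h[1])
  if (target_beads < 10) stop("box too small for a physical slab density")
  pos <- vector("list", 2000); mol <- vector("list", 2000)
  total <- 0; ic <- 0
  while (total < target_beads) {
    ic <- ic + 1
    zb <- .rlogis_edge(1, h[1], spec$D1)
    zt <- .rlogis_edge(1, h[2], spec$D1)
    if (zt - zb < 2 * spec$bead_spacing) next
    nb <- max(3L, as.integer(round((zt - zb) / spec$bead_spacing)))
    # beads at cell centers of [zb, zt] so the smeared edge stays unbiased
    zs <- zb + (seq_len(nb) - 0.5) * (zt - zb) / nb
    phi <- runif(1, 0, 2 * pi)
    tv <- c(cos(phi), sin(phi), 0)                         # zigzag plane
    xy0 <- c(runif(1, -Lx / 2, Lx / 2), runif(1, -Ly / 2, Ly / 2))
    p <- cbind(xy0[1] + (seq_len(nb) %% 2) * spec$zigzag_amp * tv[1],
               xy0[2] + (seq_len(nb) %% 2) * spec$zigzag_amp * tv[2],
               zs)
    if (spec$orientation_jitter_deg > 0) {
      ang <- rnorm(1, 0, spec$orientation_jitter_deg)
      ax <- c(cos(runif(1, 0, 2 * pi)), sin(runif(1, 0, 2 * pi)), 0)
      ctr <- colMeans(p)
      p <- sweep(sweep(p, 2, ctr) %*% t(rotation_about(ax, ang)), 2, ctr, `+`)
    }
    pos[[ic]] <- p; mol[[ic]] <- rep(ic, nb)
    total <- total + nb
  }
  slab_pos <- do.call(rbind, pos[seq_len(ic)])
  slab_mol <- unlist(mol[seq_len(ic)])
  n_slab <- nrow(slab_pos)

  # --- solvent beads (inverse CDF of the solvent tanh form)
  zg <- seq(-Lz / 2, Lz / 2, by = 0.02)
  dens_w <- rho_solvent_model(zg, spec$rho_solvent, h[3], h[4], spec$D2)
  mean_dens <- sum(dens_w) * 0.02 / Lz
  n_w <- as.integer(round(mean_dens * 0.602214076 / spec$solvent_mass * Lx * Ly * Lz))
  if (n_w < 1) stop("box too small for a physical solvent density")
  w_pos <- cbind(runif(n_w, -Lx / 2, Lx / 2), runif(n_w, -Ly / 2, Ly / 2),
                 .sample_from_density(n_w, zg, dens_w))

  # --- solute
  if (include_solute) {
    s_pos <- make_oriented_chain(spec$n_c, spec$theta0, spec$conformation,
                                 seed = spec$seed + 7L,
                                 noise_amp = spec$solute_noise_amp)
    s_pos <- sweep(s_pos, 2, c(0, 0, gds_upper + spec$xi0), `+`)
  } else s_pos <- NULL

  positions <- rbind(slab_pos, w_pos, s_pos)
  n_s <- if (include_solute) spec$n_c else 0L
  species <- c(rep("PE", n_slab), rep("W", n_w), rep("PFAS", n_s))
  mass <- c(rep(spec$slab_mass, n_slab), rep(spec$solvent_mass, n_w),
            rep(spec$solute_mass, n_s))
  charge <- c(rep(0, n_slab + n_w), rep(-1 / spec$n_c, n_s))
  mol_id <- c(slab_mol, max(slab_mol) + seq_len(n_w),
              rep(max(slab_mol) + n_w + 1L, n_s))

  bonds <- NULL
  # chain bonds: consecutive beads sharing a slab mol_id, plus the solute
  idx <- seq_len(n_slab)
  same <- slab_mol[-1] == slab_mol[-n_slab]
  bonds <- cbind(idx[-n_slab][same], idx[-1][same])
  if (include_solute && n_s >= 2) {
    s0 <- n_slab + n_w
    bonds <- rbind(bonds, cbind(s0 + seq_len(n_s - 1), s0 + seq_len(n_s - 1) + 1))
  }

  cfg <- configuration(positions, species, mass, charge, mol_id, bonds,
                       box = spec$box)
  attr(cfg, "generating") <- list(spec = spec, gds_lower = gds_lower,
                                  gds_upper = gds_upper)
  cfg
}

#' Synthetic trajectory: thermal jitter around one slab realization
#'
#' Builds one [make_interface_system()] realization and emits `n_frames`
#' frames, each with independent seeded Gaussian displacements of every
#' particle (a crude stand-in for thermal motion that preserves atom count
#' and ordering across frames, as a trajectory requires).
#'
#' @param spec A [slab_system_spec()].
#' @param n_frames Number of frames.
#' @param jitter_amp Per-coordinate displacement SD, A.
#' @return A `trajectory`; the `"generating"` attribute of the base
#'   configuration is carried on the trajectory.
#' @export
make_interface_trajectory <- function(spec, n_frames = 10, jitter_amp = 0.25) {
  stopifnot(n_frames >= 1, jitter_amp >= 0)
  base <- make_interface_system(spec)
  old <- .save_rng_state(); on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(spec$seed) + 59L)
  n <- nrow(base$positions)
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- base
    if (jitter_amp > 0)
      f$positions <- f$positions + matrix(rnorm(3 * n, sd = jitter_amp), n, 3)
    attr(f, "generating") <- NULL
    f
  })
  out <- trajectory(frames, metadata = list(source = "make_interface_trajectory",
                                            seed = spec$seed))
  attr(out, "generating") <- attr(base, "generating")
  out
}
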