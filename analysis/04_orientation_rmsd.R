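#!/usr/bin/env Rscript
# Stage 4: orientational order parameter and backbone RMSD along xi.
#
# Places a tilted 8-bead solute (theta0 = 30 degrees, perturbed conformation)
# at several signed distances xi0 from the upper Gibbs dividing surface,
# samples jittered frames over independent slab realizations, and reports
# the binned order parameter S_v(xi) with 95% confidence intervals plus the
# per-frame backbone RMSD against the extended reference conformation.
# Positions inside the slab interior are skipped: the sampling cylinder
# between slab COM + 18 A and the interface collapses there.

library(slabpmf)

seed <- 47L
theta0 <- 30
xi_positions <- c(-2, -1, 0, 1, 2, 4)
n_real <- 4
n_frames <- 3

records <- list()
for (xi0 in xi_positions) {
  for (r in seq_len(n_real)) {
    sp <- slab_system_spec(theta0 = theta0, xi0 = xi0,
                           conformation = "perturbed", solute_noise_amp = 0.15,
                           seed = seed + 1000L * match(xi0, xi_positions) + r)
    tr <- make_interface_trajectory(sp, n_frames = n_frames)
    g <- attr(tr, "generating")
    gs <- structure(list(z_lower = g$gds_lower, z_upper = g$gds_upper),
                    class = "gibbs_surfaces")
    rec <- orientation_records(tr, gs)
    rec$replica <- r
    rec$rmsd <- rmsd_records(tr, make_oriented_chain(8, 0))$rmsd
    records[[length(records) + 1L]] <- rec
  }
}
records <- do.call(rbind, records)
ok <- !is.na(records$sv)
cat(sprintf("%d frames analyzed, %d with a populated sampling cylinder\n",
            nrow(records), sum(ok)))

prof <- orientation_profile(records[ok, ], xi_bins = seq(-3, 5, by = 1),
                            confidence = 0.95)
write.table(records, "results/orientation_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prof, "results/orientation_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- (3 * cos(theta0 * pi / 180)^2 - 1) / 2
pop <- prof[prof$n > 0, ]
cat(sprintf("binned S_v over xi in [%.0f, %.0f]: %.3f-%.3f (construction target %.3f)\n",
            min(pop$xi_lo), max(pop$xi_hi), min(pop$sv), max(pop$sv), truth))
cat(sprintf("mean backbone RMSD vs extended reference: %.3f A (noise amplitude 0.15 A + 0.25 A thermal jitter)\n",
            mean(records$rmsd)))
cat("wrote results/orientation_records.tsv and results/orientation_profile.tsv\n")
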