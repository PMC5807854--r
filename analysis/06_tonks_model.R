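#!/usr/bin/env Rscript
# Hard-rod (Tonks gas) statistical mechanics of nucleosome positioning:
# 147-bp rods on a 1D lattice with Gaussian promoter energy barriers.
# Forward-simulates dyad densities at the reference barrier parameters on
# a 200-promoter lattice, refits the barrier from random initializations,
# and writes the recovered parameters and predicted tracks.

library(nuclinker)

dir.create("results", showWarnings = FALSE)
seed <- 20260920L

rec <- experiment_barrier_recovery(seed = seed, n_genes = 200L)
cat("truth     :", sprintf("H=%.2f kT sigma=%.2f bp x0=%.0f bp u-mu=%.2f kT",
                           rec$truth$H, rec$truth$sigma, rec$truth$x0,
                           rec$truth$u_minus_mu), "\n")
cat("recovered :", sprintf("H=%.2f kT sigma=%.2f bp x0=%.1f bp u-mu=%.2f kT",
                           rec$recovered$H, rec$recovered$sigma,
                           rec$recovered$x0, rec$recovered$u_minus_mu), "\n")
cat(sprintf("2D correlation at the optimum: %.6f (%d objective evaluations)\n",
            rec$correlation, rec$n_evaluations))

fit <- list(params = rec$recovered, correlation = rec$correlation,
            n_evaluations = rec$n_evaluations, seed = seed)
write_fit_yaml(fit, "results/barrier_fit.yaml")

# predicted organization on a small display lattice
lat <- synthetic_promoter_lattice(n_genes = 10L)
pred <- predict_genome(data.frame(chrom = "lattice", p_l = lat$flanks$p_l,
                                  p_r = lat$flanks$p_r),
                       rec$recovered, chrom_spec("lattice", lat$L))
write_track(prediction_profile(pred, "n"), "results/model_dyads.bedgraph")
write_track(prediction_profile(pred, "occ"), "results/model_occupancy.bedgraph")
occ <- pred$lattice$occ
barrier1 <- lat$flanks$p_l[2]:lat$flanks$p_r[2]
body1 <- (lat$flanks$p_r[2] + 100L):(lat$flanks$p_l[3] - 100L)
cat(sprintf("predicted occupancy: %.3f at a barrier center, %.3f in the array\n",
            min(occ[barrier1]), max(occ[body1])))
cat("barriers at promoters reproduce NDRs and phased flanking arrays;\n")
cat("steric exclusion alone generates the decaying oscillations\n")
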