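#!/usr/bin/env Rscript
# Stage 1: simulate every experimental input with known ground truth.
#
# Produces, under results/sim/: per-variant methyl peak lists (canonical
# CSV), triple-quantum build-up tables, binding/competition titrations,
# ATPase kinetics, SEC chromatograms and an activity profile, plus a truth/
# directory holding the planted parameters each later stage should recover.

library(allonmr)

seed <- 20260101
out <- "results/sim"
dir.create(file.path(out, "truth"), showWarnings = FALSE, recursive = TRUE)

## Two-state fast-exchange panel: 4 variants, 3 responder groups (25/10/8)
## + 100 non-responders, group-1 populations 0 -> 0.2 -> 0.5 -> 0.9
model <- two_state_model(seed = seed)
sim <- gen_panel(model, seed = seed + 1)

for (v in model$variants) {
  pk <- sim$panel$peaks
  write_peaklist(pk[pk$variant == v, ],
                 file.path(out, paste0("peaks_", v, ".csv")))
}
write.csv(cbind(sim$truth,
                attr(sim$truth, "populations")[pmax(sim$truth$group, 1), ] *
                  (sim$truth$group > 0)),
          file.path(out, "truth", "panel_groups.csv"), row.names = FALSE)

## Side-chain dynamics: eta affine in the member populations; build-up
## curves on the 2-42 ms delay grid with 2% multiplicative noise
dyn_truth <- gen_dynamics_truth(model, seed = seed + 2)
resp <- model$methyls$methyl[model$methyls$group > 0]
buildup <- gen_buildup(dyn_truth[dyn_truth$methyl %in% resp, ],
                       noise_frac = 0.02, seed = seed + 3)
write.csv(buildup, file.path(out, "buildup.csv"), row.names = FALSE)
write.csv(dyn_truth, file.path(out, "truth", "dynamics.csv"),
          row.names = FALSE)

## Biochemistry: the probe-displacement experimental designs
## (protein 0-70 uM vs 5 nM probe; competitor 0-1 mM; ATP 0-150 uM)
write.csv(gen_titration(K_D = 16.9, noise_frac = 0.01, seed = seed + 4),
          file.path(out, "titration_atp_wt.csv"), row.names = FALSE)
write.csv(gen_competition(K_I = 2.3, noise_frac = 0.01, seed = seed + 5),
          file.path(out, "competition_adp_wt.csv"), row.names = FALSE)

# per-variant kinetics: lower K_M and higher k_cat along the trajectory,
# enzyme 2 uM (WT, V156M) or 0.5 uM (V160M, R805E) in 60 uL
kin_design <- data.frame(
  variant = model$variants,
  V_max = c(0.048, 0.0648, 0.018, 0.0276),   # nmol/min
  K_M = c(20, 15, 10, 10),                   # uM
  n = 1.3,
  enzyme_uM = c(2, 2, 0.5, 0.5))
for (i in seq_len(nrow(kin_design))) {
  k <- gen_kinetics(V_max = kin_design$V_max[i], K_M = kin_design$K_M[i],
                    n = kin_design$n[i], noise_frac = 0.02,
                    seed = seed + 10 + i)
  write.csv(k, file.path(out, paste0("kinetics_", kin_design$variant[i],
                                     ".csv")), row.names = FALSE)
}
write.csv(kin_design, file.path(out, "truth", "kinetics.csv"),
          row.names = FALSE)

# SEC chromatograms with the observed dimer percentages
dimer_truth <- data.frame(variant = model$variants,
                          fraction_dimer = c(0.35, 0.64, 0.57, 0.79))
for (i in seq_len(nrow(dimer_truth))) {
  ch <- gen_chromatogram(fraction_dimer = dimer_truth$fraction_dimer[i],
                         noise_sd = 1e-4, seed = seed + 20 + i)
  write.csv(ch, file.path(out, paste0("sec_", dimer_truth$variant[i],
                                      ".csv")), row.names = FALSE)
}
write.csv(dimer_truth, file.path(out, "truth", "dimerization.csv"),
          row.names = FALSE)

# exonuclease raw fluorescence: corrected signal affine in the trajectory
p1 <- model$populations[1, ]
exo <- data.frame(variant = model$variants,
                  raw_rfu = 50 + 100 * (1 + 1.5 * p1),
                  background_rfu = 50)
write.csv(exo, file.path(out, "exonuclease.csv"), row.names = FALSE)

write.csv(gen_activity_profile(model),
          file.path(out, "truth", "activities.csv"), row.names = FALSE)

message("simulated panel: ", length(unique(sim$panel$peaks$methyl)),
        " methyls x ", length(model$variants), " variants -> ", out)
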