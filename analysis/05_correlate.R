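#!/usr/bin/env Rscript
# Stage 5: correlate per-methyl shift trajectories with the variant-level
# activities (hydrolysis, dimerization, exonuclease) and summarize the
# correlation signs per covariance cluster.

library(allonmr)

sim <- "results/sim"
out <- "results/correlations"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
variants <- c("WT", "V156M", "V160M", "R805E")

peaklists <- lapply(variants, function(v)
  read_peaklist(file.path(sim, paste0("peaks_", v, ".csv")), variant = v))
names(peaklists) <- variants
st <- shift_table(build_panel(peaklists))

csp <- mad_zscores(st)
sig <- csp$methyl[csp$significant]
cl <- chesca_cluster(shift_distance_matrix(st, sig))

activities <- read.csv("results/biochem/activities.csv")
rec <- activity_correlations(st, activities, clusters = cl,
                             threshold = 0.65)
write.csv(rec, file.path(out, "correlations.csv"), row.names = FALSE)

summ <- cluster_sign_summary(rec)
write.csv(summ, file.path(out, "cluster_summary.csv"), row.names = FALSE)
print(summ)

for (k in summ$cluster[summ$cluster != "unclustered"]) {
  row <- summ[summ$cluster == k, ]
  message(sprintf(
    "cluster %s: %d of %d methyls meaningfully correlated (|mean R_P| > 0.65), %.0f%% positive",
    k, row$n_meaningful, row$n_methyls,
    100 * ifelse(is.nan(row$frac_positive), 0, row$frac_positive)))
}

ann <- residue_annotation(rec, st)
write.csv(ann, file.path(out, "residue_annotation.csv"), row.names = FALSE)
message("residue annotation for structure colouring -> ",
        file.path(out, "residue_annotation.csv"))
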