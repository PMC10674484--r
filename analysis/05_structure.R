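#!/usr/bin/env Rscript
# Stage 5: structural descriptors of the simulated helix trajectory —
# per-frame radius of gyration and Kirkwood hydrodynamic radius, sphere
# volumes from the mean radii, and per-residue CA RMSF after rigid
# superposition — plus the sphere-formula consistency of the published
# species series (monomer to hexadecamer).

suppressPackageStartupMessages(library(lipoaggr))

traj <- read_structure("results/helix_traj.pdb")
sm <- trajectory_summary(traj, rh_selection = "C", rmsf_selection = "CA")

cat(sprintf("helix trajectory (%d frames): Rg = %.2f +- %.2f A, Rh = %.2f +- %.2f A\n",
            nrow(sm$per_frame), sm$Rg_mean_A, sm$Rg_sd_A,
            sm$Rh_mean_A, sm$Rh_sd_A))
cat(sprintf("Vg = %.2f nm^3, Vh = %.2f nm^3\n", sm$Vg_nm3, sm$Vh_nm3))
cat(sprintf("CA rmsf: median %.2f A, max %.2f A\n",
            median(sm$rmsf$rmsf_A), max(sm$rmsf$rmsf_A)))

write_structure_metrics(sm, "results/structmetrics.json",
                        "results/structmetrics_per_frame.tsv",
                        "results/structmetrics_rmsf.tsv")

# published species radii: volumes follow from the sphere relation
species <- data.frame(
  species = c("monomer", "dimer", "tetramer", "octamer", "hexadecamer"),
  Rg_A = c(13.9, 25.1, 36.1, 38.5, 45.2),
  Rh_A = c(10.8, 10.9, 11.2, 12.1, 13.8))
species$Vg_nm3 <- round(gyration_volume(species$Rg_A), 1)
species$Vh_nm3 <- round(volume_from_radius(species$Rh_A), 1)
cat("\nspecies series, volumes from the sphere formula:\n")
print(species, row.names = FALSE)
write.table(species, "results/species_volumes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
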