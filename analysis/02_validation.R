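#!/usr/bin/env Rscript
# Passive-motion validation protocols on the default knee: hamstring-loaded
# flexion sweep, Lachman (30 deg) and anterior drawer (90 deg) laxity tests,
# and the abduction-moment sweep.
#
# Findings (trend level, matching the published validation behaviour):
#  * the PL bundle slackens steeply with flexion while AM stays
#    near-isometric after a small initial drop;
#  * AM strain rises monotonically with anterior tibial force in both
#    laxity tests;
#  * valgus rotation and ACL strain rise monotonically with the abduction
#    moment.
# User-supplied digitized experimental curves (two-column CSV) can be
# scored against these model curves with compare_curves().

library(kneestrain)

dir.create("results", showWarnings = FALSE)
model <- initialize_reference_lengths(build_default_knee())

fx <- run_flexion_test(model, max_flexion = 90, n_points = 21)
write.csv(fx, "results/validation_flexion.csv", row.names = FALSE)
cat(sprintf("flexion sweep: AM %.1f%% -> %.1f%%, PL %.1f%% -> %.1f%%\n",
            100 * fx$strain_AM[1], 100 * fx$strain_AM[nrow(fx)],
            100 * fx$strain_PL[1], 100 * fx$strain_PL[nrow(fx)]))

la <- run_lachman(model, n_points = 21)
write.csv(la, "results/validation_lachman.csv", row.names = FALSE)
dr <- run_drawer(model, n_points = 21)
write.csv(dr, "results/validation_drawer.csv", row.names = FALSE)
cat(sprintf("Lachman 0 -> 200 N: AM %.2f%% -> %.2f%% (translation %.2f mm)\n",
            100 * la$strain_AM[la$anterior_force_N == 0],
            100 * la$strain_AM[la$anterior_force_N == 200],
            la$anterior_translation_mm[la$anterior_force_N == 200]))
cat(sprintf("drawer  0 -> 200 N: AM %.2f%% -> %.2f%%\n",
            100 * dr$strain_AM[dr$anterior_force_N == 0],
            100 * dr$strain_AM[dr$anterior_force_N == 200]))

ab <- run_abduction(model, n_points = 21)
write.csv(ab, "results/validation_abduction.csv", row.names = FALSE)
cat(sprintf("abduction 0 -> 50 Nm: valgus %.2f deg, ACL strain %.2f%% -> %.2f%%\n",
            ab$valgus_deg[nrow(ab)],
            100 * ab$strain_ACL[1], 100 * ab$strain_ACL[nrow(ab)]))

# score a model curve against a reference CSV if one is provided, e.g.:
#   ref <- read.csv("my_flexion_reference.csv")  # columns: flexion_deg, strain
#   compare_curves(fx[, c("flexion_deg", "strain_AM")], ref)
cat("wrote results/validation_*.csv\n")
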