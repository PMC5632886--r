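#!/usr/bin/env Rscript
# Step 1 — generate the full set of study input tables.
#
# Emulates the measurement campaign of the enzymatic-assay validation on
# the fully validated analyzer (Cobas c502): a 15-level triplicate
# linearity series, two 60-replicate blank series (water and buffer),
# within-run replicate series at the control and urine levels, 20 days of
# duplicate control measurements, a high/low carry-over sequence, a
# 39-day reagent-stability series, and the 224-patient paired cohort with
# the positive phloroglucinol-only background. Everything is seeded, so
# downstream steps are reproducible.

suppressPackageStartupMessages(library(xylassay))

seed <- 20170924L
out_dir <- "results/simdata"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# Linearity: slope/intercept/noise at the published Cobas fit values.
linearity <- simulate_linearity(
  levels = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 10, 12.5, 15),
  slope = 0.0610, intercept = 0.0006, noise_sd = 0.0038,
  replicates = 3, seed = seed
)
write.csv(linearity, file.path(out_dir, "linearity_cobas.csv"),
          row.names = FALSE)

# Blanks: water and phosphate buffer, 60 replicates each.
blanks <- rbind(
  data.frame(population = "water",
             value = simulate_blanks(60, 0.010, 0.022, seed = seed + 1)),
  data.frame(population = "buffer",
             value = simulate_blanks(60, 0.012, 0.020, seed = seed + 2))
)
write.csv(blanks, file.path(out_dir, "blanks_cobas.csv"), row.names = FALSE)

# Within-run precision: controls C1/C2 and buffer levels S1-S3 (buffer
# matrix, 20 replicates); doped urines U5/U6; low urine pools U1-U4 (the
# LLoQ study levels). The pools carry a constant positive matrix signal so
# relative inaccuracy decreases with level and only the upper pools clear
# the 20% rule, as in a real low-end characterization.
buffer_levels <- c(C1 = 0.84, C2 = 5.443, S1 = 1.5, S2 = 3.75, S3 = 7.5)
within_b <- simulate_replicates(precision_sim_config(
  nominal_levels = unname(buffer_levels), within_cv_pct = 2.0,
  n_runs = 1, replicates_per_run = 20, seed = seed + 3, matrix = "buffer"
))
within_b$level_id <- names(buffer_levels)[as.integer(substr(within_b$level_id,
                                                            2, 3))]
urine_levels <- c(U5 = 3.75, U6 = 7.5)
within_u <- simulate_replicates(precision_sim_config(
  nominal_levels = unname(urine_levels), within_cv_pct = 2.0,
  n_runs = 1, replicates_per_run = 20, seed = seed + 8
))
within_u$level_id <- names(urine_levels)[as.integer(substr(within_u$level_id,
                                                           2, 3))]
within <- rbind(within_b, within_u)
low_levels <- c(U1 = 0.5, U2 = 0.75, U3 = 0.85, U4 = 0.95)
low <- simulate_replicates(precision_sim_config(
  nominal_levels = unname(low_levels), within_cv_pct = 1.1,
  n_runs = 1, replicates_per_run = 60, seed = seed + 4
))
low$level_id <- names(low_levels)[as.integer(substr(low$level_id, 2, 3))]
# additive 0.16 mg/dL matrix signal: 32% of U1 but under 19% of U3
low$value <- low$value + 0.16
precision <- rbind(within, low)
write_replicates(precision, file.path(out_dir, "precision_cobas.csv"))

# Between-run: C1 in duplicate over 20 consecutive days.
between <- simulate_replicates(precision_sim_config(
  nominal_levels = 0.84, within_cv_pct = 1.5, between_cv_pct = 3.0,
  n_runs = 20, replicates_per_run = 2, seed = seed + 5
))
write_replicates(between, file.path(out_dir, "between_run_cobas.csv"))

# Carry-over: low 1.5 / high 9.0 mg/dL with 3.3% injected contamination.
carry <- simulate_carryover_sequence(9.0, 1.5, carryover_pct = 3.3,
                                     n_pairs = 10, n_baseline = 11,
                                     within_cv_pct = 1, seed = seed + 6)
write.csv(data.frame(order = seq_along(carry$values), tag = carry$tags,
                     value = carry$values),
          file.path(out_dir, "carryover_cobas.csv"), row.names = FALSE)

# Reagent stability: C1/C2 over 39 on-board days with a slow linear drift
# scaled so the endpoints sit near the observed day-39 recoveries.
days <- c(1, seq(3, 39, by = 3))
stab <- rbind(
  data.frame(control_id = "C1", day = days,
             measured_conc = 0.77 * (1 - 0.00376 * (days - 1))),
  data.frame(control_id = "C2", day = days,
             measured_conc = 4.95 * (1 - 0.00096 * (days - 1)))
)
write.csv(stab, file.path(out_dir, "stability_ilab.csv"), row.names = FALSE)

# Paired patient cohort (defaults: 224 patients, truncated-Gaussian
# background on the reference method).
cohort <- simulate_paired_cohort(cohort_sim_config(seed = seed + 7))
write_comparison(cohort, file.path(out_dir, "paired_cohort.csv"))

cat("Simulated study tables written to", out_dir, "\n")
cat(sprintf("  linearity: %d points; blanks: %d; precision rows: %d\n",
            nrow(linearity), nrow(blanks), nrow(precision)))
cat(sprintf("  between-run rows: %d; carry-over points: %d; cohort: %d patients\n",
            nrow(between), length(carry$values), nrow(cohort)))
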