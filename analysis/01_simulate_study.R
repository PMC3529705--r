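#!/usr/bin/env Rscript
# Generate the synthetic tracer study that stands in for the undeposited
# human dataset: 16 investigations, high between-investigation variability,
# plasma (% per kg) and pooled urine excretion rate (%/day) to 100 d.
# Writes the dataset (CSV + JSON sidecar) and a short summary table.

suppressMessages(library(zirbayes))

dir.create("results/study", recursive = TRUE, showWarnings = FALSE)
model <- zr_model("hmgu")

cfg <- study_config(n_investigations = 16, preset = "high_variability",
                    seed = 20120805)
study <- generate_study(cfg, model)
write_dataset(study, "results/study/synthetic_study.csv")

peaks <- vapply(study, function(iv) {
  tra <- solve_trajectory(model, iv$true_rates, seq(0.05, 3, by = 0.05))
  max(tra$values[, model$plasma]) / iv$plasma_mass
}, numeric(1))

summary <- data.frame(
  investigation = vapply(study, `[[`, "", "id"),
  n_plasma = vapply(study, function(iv) nrow(iv$plasma), integer(1)),
  n_urine = vapply(study, function(iv) nrow(iv$urine), integer(1)),
  peak_plasma_pct_per_kg = round(peaks, 4),
  max_plasma_obs = round(vapply(study, function(iv) max(iv$plasma$value),
                                numeric(1)), 4))
utils::write.csv(summary, "results/study/study_summary.csv",
                 row.names = FALSE)

cat(sprintf(
  "Generated %d investigations (HMGU kinetics, high-variability preset).\n",
  length(study)))
cat(sprintf("Peak plasma range: %.3f - %.3f %%/kg (ratio %.1f-fold; the\n",
            min(peaks), max(peaks), max(peaks) / min(peaks)))
cat("human study reported peaks 0.033 - 1.616 %/kg, ~50-fold).\n")
cat("Dataset: results/study/synthetic_study.csv (+ .json sidecar)\n")
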