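#!/usr/bin/env Rscript
# Simulate one recording-style session: task behavior at published defaults
# (186 trials, 16.7% catch, AV-facilitated RTs) plus a ground-truth population
# of the four movement-related neuron types, and write the session to disk.

suppressPackageStartupMessages(library(spikeroc))
seed <- 20260925L
out <- "results/session"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- task_config(seed = derive_seed(seed, "behavior"))
trials <- generate_behavior(cfg)
pop <- typed_population(n_per_type = 3L)
units <- generate_spike_trains(trials, pop, seed = derive_seed(seed, "spikes"))

write_trial_table(trials, file.path(out, "trials.tsv"))
write_spike_times(units, file.path(out, "spikes.tsv"))
jsonlite::write_json(
  lapply(pop, unclass), file.path(out, "ground_truth.json"),
  auto_unbox = TRUE, pretty = TRUE, digits = NA)

neural <- filter_trials(trials, "neural")
cat(sprintf("session: %d trials (%d catch, %.1f%% correct)\n",
            nrow(trials), sum(trials$modality == "catch"),
            100 * mean(trials$correct)))
cat(sprintf("neural-filtered trials: %d (RT >= 150 ms, correct, non-catch)\n",
            nrow(neural)))
for (m in c("V", "A", "AV")) {
  cat(sprintf("  mean RT %-3s %.1f ms (n = %d)\n", m,
              mean(trials$rt_ms[trials$modality == m], na.rm = TRUE),
              sum(trials$modality == m)))
}
cat(sprintf("population: %d units, %d spikes total\n", length(units),
            sum(vapply(units, function(u) length(u$spike_times_ms), numeric(1)))))
cat("wrote", out, "\n")
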