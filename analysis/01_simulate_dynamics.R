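#!/usr/bin/env Rscript
## Simulate ground-truth dynamic-instability event tables for the conditions
## analysed downstream: buffer control and reconstituted Elongator
## (Elp123 + 2x Elp456), both ends. Writes the event tables and a summary.

library(mtquant)
dir.create("results", showWarnings = FALSE)

conditions <- list(
  control  = dynamics_params(v_plus = 1.002, v_minus = 0.348),
  elongator = dynamics_params(v_plus = 1.380, v_minus = 0.472)
)

summary_rows <- list()
for (cond in names(conditions)) {
  ev <- simulate_dynamics(conditions[[cond]], n_seeds = 60, duration = 900,
                          rng_seed = 101 + match(cond, names(conditions)))
  write_event_table(ev, file.path("results", paste0("events_", cond, ".csv")))
  for (end in c("plus", "minus")) {
    sub <- ev[ev$end == end, ]
    summary_rows[[paste(cond, end)]] <- data.frame(
      condition = cond, end = end, n_events = nrow(sub),
      n_censored = sum(sub$censored),
      mean_lifetime_s = mean(sub$lifetime, na.rm = TRUE),
      true_speed = unique(sub$speed))
  }
}
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/01_event_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat("\nEvent tables written to results/events_{control,elongator}.csv\n")
cat("Lifetimes are gamma(3) with median 202.61 s; censored events are the\n")
cat("final still-growing episode of each seed/end.\n")
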