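#!/usr/bin/env Rscript
# Simulate the study's plate-reader datasets: the full nitrogen dilution
# series (8 levels, two conditions per 96-well checkerboard plate), the
# glucose series, and the regulated-mode reporter panel. Writes long-format
# plate CSVs plus design sidecars under results/plates/, and a manifest.

suppressPackageStartupMessages(library(monodpulse))

seed <- 101L
out_dir <- file.path("results", "plates")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

write_panel <- function(datasets, prefix) {
  paths <- vapply(datasets, function(ds) {
    p <- file.path(out_dir, paste0(ds$design$plate_id, ".csv"))
    write_plate(ds, p)
    p
  }, character(1))
  cat(sprintf("%-9s %d plates: %s\n", prefix, length(paths),
              paste(basename(paths), collapse = ", ")))
  paths
}

nitro <- simulate_growth_panel(default_nitrogen_levels(), "nitrogen",
                               seed = seed)
gluc <- simulate_growth_panel(c(default_glucose_levels(), 5.6), "glucose",
                              seed = seed + 500L)
rep_panel <- simulate_growth_panel(c(reporter_nitrogen_levels(), 18.7),
                                   "nitrogen", seed = seed + 1000L,
                                   reporter = "glnA", label = "R")

manifest <- list(
  seed = seed,
  od_period_min = 3, gfp_period_min = 8,
  nitrogen_levels_mM = default_nitrogen_levels(),
  glucose_levels_mM = c(default_glucose_levels(), 5.6),
  reporter_levels_mM = c(reporter_nitrogen_levels(), 18.7),
  noise = unclass(noise_params()),
  kinetics = list(mu0_per_h = log(2) / 59 * 60,
                  nitrogen = nutrient_defaults("nitrogen"),
                  glucose = nutrient_defaults("glucose"),
                  s_carryover_mM = 0.09, od0 = 0.002),
  files = c(write_panel(nitro, "nitrogen"),
            write_panel(gluc, "glucose"),
            write_panel(rep_panel, "reporter"))
)
jsonlite::write_json(manifest, file.path("results", "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("Manifest written to results/manifest.json\n")
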