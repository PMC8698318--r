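#!/usr/bin/env Rscript
# Generate the full set of synthetic study inputs with known ground truth:
# spent-medium metabolite concentrations (4 donors, days 1-28 with day 14
# dropped, phases planted at days 5 and 16), 13C isotopologue intensity
# vectors, and an expression study (4 time points x 3 donors) with planted
# switch regulons. Everything downstream reads these files.

suppressPackageStartupMessages(library(osteostage))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42L

cfg <- pipeline_config(out_dir = out, seed = seed)
cfg$stages[c("phases", "isotopes", "filter_degs", "regulons",
             "network")] <- FALSE
run_pipeline(cfg)

truth <- jsonlite::read_json(file.path(out, "truth.json"))
cat("Simulated inputs written to", out, "\n")
cat("Planted metabolic change points at days:",
    paste(unlist(truth$metabolites$change_point_days), collapse = ", "), "\n")
cat("Planted regulons:", length(truth$expression$regulons),
    "| isotope conditions:", length(truth$isotopes$mean_enrichments), "\n")
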