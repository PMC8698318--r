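#!/usr/bin/env Rscript
# Apply the four-rule response-gene filter to the day-28 vs day-3
# differential-expression table (significance, expression level, fold
# change, replicate stability, donor consistency) and annotate the retained
# genes as transcription factors, metabolic genes, or other.

suppressPackageStartupMessages(library(osteostage))

data_dir <- "results/data"
out <- "results/response_genes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(out_dir = out, seed = 42L)
cfg$stages[c("simulate", "phases", "isotopes", "regulons",
             "network")] <- FALSE
cfg$inputs <- list(de = file.path(data_dir, "de_day28_vs_day3.tsv"),
                   tf_list = file.path(data_dir, "tf_list.txt"),
                   metabolic_genes = file.path(data_dir, "metabolic_genes.txt"))
run_pipeline(cfg)

resp <- read.delim(file.path(out, "response_genes.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)
planted <- unique(c(names(truth$expression$regulons),
                    unlist(lapply(truth$expression$regulons, `[[`, "targets"))))
cat(sprintf("Response genes: %d (%d up, %d down)\n", nrow(resp),
            sum(resp$direction == "up"), sum(resp$direction == "down")))
print(table(direction = resp$direction, class = resp$class))
cat(sprintf("\nPlanted effect genes recovered: %d/%d; false positives: %d\n",
            sum(planted %in% resp$gene), length(planted),
            sum(!resp$gene %in% planted)))
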