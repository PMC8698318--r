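# End-to-end orchestration: simulate -> phases -> isotopes -> filter-degs ->
# regulons -> network, with a reproducibility manifest. Each stage reads and
# writes the plain-text interchange files, so stages are individually
# re-runnable.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

read_lines_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path)
}

#' Default pipeline configuration
#'
#' All stage parameters in one list; any element can be overridden. When a
#' YAML file path is given its entries override the defaults (shallow merge
#' per stage).
#'
#' @param out_dir output directory.
#' @param seed master seed recorded in the manifest; stage seeds derive from
#'   it.
#' @param yaml optional path to a YAML file with overrides.
#' @return nested configuration list.
#' @export
pipeline_config <- function(out_dir = "results/pipeline", seed = 42L,
                            yaml = NULL) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, phases = TRUE, isotopes = TRUE,
                  filter_degs = TRUE, regulons = TRUE, network = TRUE),
    inputs = list(),  # filled by the simulate stage or supplied by the user
    phases = list(sig_level = 0.05, n_permutations = 199L, min_segment = 3L,
                  standardize = TRUE,
                  # "baseline": per-day rate = (concentration - fresh-medium
                  # baseline)/dwell, batch-centred and donor-averaged —
                  # appropriate when every dwell starts from freshly changed
                  # medium. "smoothing": GCV-smoothed concentrations
                  # differenced between adjacent days.
                  rate_method = "baseline",
                  baselines = as.list(default_baselines())),
    isotopes = list(natural_abundance = 0.0107, tracer_purity = 1),
    filter = list(tpm_threshold = 2, fc_threshold = 1,
                  rel_sem_threshold = 0.5, min_consistent_donors = 2),
    regulons = list(r_threshold = 0.8, alpha = 0.1, k_min = 3, k_max = 114,
                    delta = 0.5)
  )
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    for (nm in names(ov)) {
      if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
        cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
      else cfg[[nm]] <- ov[[nm]]
    }
  }
  cfg
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the staging pipeline end to end
#'
#' Executes the enabled stages in order (simulate, phases, isotopes,
#' filter_degs, regulons, network) and writes a reproducibility manifest
#' (package version, parameters, seeds, input checksums). Outputs are a pure
#' function of (config, seed): reruns produce identical files.
#'
#' @param config a [pipeline_config()] list or a path to a YAML file.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml = config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  inputs <- config$inputs
  ran <- character(0)

  p <- function(f) file.path(out, f)

  if (isTRUE(config$stages$simulate)) {
    stage_try("simulate", {
      met <- simulate_metabolite_panel(metabolite_sim_config(seed = seed))
      iso <- simulate_isotopologues(isotope_sim_config(seed = seed + 1L))
      expr <- simulate_expression(expression_sim_config(seed = seed + 2L))
      conc <- met$series
      names(conc)[names(conc) == "concentration"] <- "concentration_mmol_per_l"
      write_tsv(conc, p("concentrations.tsv"))
      write_tsv(iso$intensities, p("isotopologues.tsv"))
      tpm_df <- data.frame(gene = rownames(expr$tpm), expr$tpm,
                           check.names = FALSE)
      write_tsv(tpm_df, p("tpm.tsv"))
      for (nm in names(expr$de))
        write_tsv(expr$de[[nm]], p(sprintf("de_%s.tsv", nm)))
      write_tsv(expr$prior, p("prior.tsv"))
      writeLines(expr$tf_list, p("tf_list.txt"))
      writeLines(expr$metabolic_genes, p("metabolic_genes.txt"))
      jsonlite::write_json(list(
        metabolites = met$truth[c("change_point_days", "days")],
        isotopes = list(mean_enrichments = as.list(iso$truth$mean_enrichments)),
        expression = expr$truth["regulons"]),
        p("truth.json"), auto_unbox = TRUE, digits = NA)
      inputs <- list(
        concentrations = p("concentrations.tsv"),
        isotopologues = p("isotopologues.tsv"),
        tpm = p("tpm.tsv"), de = p(sprintf("de_%s.tsv", names(expr$de)[1])),
        prior = p("prior.tsv"), tf_list = p("tf_list.txt"),
        metabolic_genes = p("metabolic_genes.txt"),
        tpm_timepoints = expr$timepoints)
      ran <- c(ran, "simulate")
    })
  }

  if (isTRUE(config$stages$phases)) {
    stage_try("phases", {
      conc <- read_tsv(inputs$concentrations)
      names(conc)[names(conc) == "concentration_mmol_per_l"] <- "concentration"
      panel <- if (identical(config$phases$rate_method, "smoothing")) {
        compute_rates(smooth_timecourse(conc))
      } else {
        empirical_rate_panel(conc, baselines = unlist(config$phases$baselines))
      }
      if (isTRUE(config$phases$standardize))
        panel_std <- standardize_rates(panel) else panel_std <- panel
      cp <- edivisive(panel_std, changepoint_config(
        sig_level = config$phases$sig_level,
        n_permutations = config$phases$n_permutations,
        min_segment = config$phases$min_segment, seed = seed + 10L))
      rates_df <- data.frame(day = panel$days, panel$rates,
                             check.names = FALSE)
      write_tsv(rates_df, p("rates.tsv"))
      jsonlite::write_json(list(change_days = cp$change_days,
                                p_values = cp$p_values, phases = cp$phases),
                           p("changepoints.json"), auto_unbox = TRUE,
                           digits = NA)
      # phase means and flux ratios on the model-normalized (unit-variance)
      # scale, as in the reference analysis
      summ <- phase_summary(panel_std, cp)
      stats_df <- do.call(rbind, lapply(summ, function(s)
        cbind(phase = s$phase, s$stats)))
      ratio_df <- do.call(rbind, lapply(summ, function(s)
        cbind(phase = s$phase, s$flux_ratios)))
      ratio_df$expected_perfect_ratio <- vapply(
        as.character(ratio_df$ratio),
        function(r) expected_perfect_ratio(gsub("_", "/", r)), 0)
      write_tsv(stats_df, p("phase_summary.tsv"))
      write_tsv(ratio_df, p("flux_ratios.tsv"))
      ran <- c(ran, "phases")
    })
  }

  if (isTRUE(config$stages$isotopes)) {
    stage_try("isotopes", {
      ints <- read_tsv(inputs$isotopologues)
      res <- correct_isotopologue_table(
        ints, natural_abundance = config$isotopes$natural_abundance,
        tracer_purity = config$isotopes$tracer_purity)
      write_tsv(res$corrected, p("corrected_isotopologues.tsv"))
      write_tsv(res$enrichment, p("enrichment.tsv"))
      ran <- c(ran, "isotopes")
    })
  }

  response <- NULL
  if (isTRUE(config$stages$filter_degs)) {
    stage_try("filter_degs", {
      de <- read_tsv(inputs$de)
      tf <- read_lines_file(inputs$tf_list)
      metab <- read_lines_file(inputs$metabolic_genes)
      response <- call_response_genes(
        de, tpm_threshold = config$filter$tpm_threshold,
        fc_threshold = config$filter$fc_threshold,
        rel_sem_threshold = config$filter$rel_sem_threshold,
        min_consistent_donors = config$filter$min_consistent_donors)
      cls <- annotate_gene_classes(response$gene, tf, metab)
      response$class <- cls$class
      write_tsv(response, p("response_genes.tsv"))
      ran <- c(ran, "filter_degs")
    })
  }

  regulons <- NULL
  if (isTRUE(config$stages$regulons)) {
    stage_try("regulons", {
      if (is.null(response)) response <- read_tsv(p("response_genes.tsv"))
      tpm_df <- read_tsv(inputs$tpm)
      tpm <- as.matrix(tpm_df[, -1, drop = FALSE])
      rownames(tpm) <- tpm_df$gene
      prior <- read_tsv(inputs$prior)
      timepoints <- inputs$tpm_timepoints
      if (is.null(timepoints)) {
        # column names look like d<day>_D<donor>; order time points by day
        day <- as.numeric(sub("^d([0-9]+)_.*$", "\\1", colnames(tpm)))
        if (anyNA(day)) stop("cannot parse time points from TPM column names")
        timepoints <- match(day, sort(unique(day)))
      }
      z <- zscore_genes(log2(tpm + 1))
      parts <- list(up = NULL, down = NULL)
      for (d in c("up", "down")) {
        g <- intersect(response$gene[response$direction == d], rownames(z))
        if (length(g) >= config$regulons$k_min + 1)
          parts[[d]] <- select_partition(z[g, , drop = FALSE],
                                         k_min = config$regulons$k_min,
                                         k_max = config$regulons$k_max)
      }
      regulons <- infer_regulons(z, parts$up, parts$down, prior,
                                  r_threshold = config$regulons$r_threshold,
                                  alpha = config$regulons$alpha,
                                  timepoints = timepoints,
                                  delta = config$regulons$delta)
      reg_df <- do.call(rbind, lapply(regulons, function(r)
        data.frame(name = r$name, regulator = r$regulator,
                   n_targets = r$n_targets, correlation = r$correlation,
                   direction = r$direction, deg_direction = r$deg_direction,
                   targets = paste(r$targets, collapse = ","))))
      if (is.null(reg_df))
        reg_df <- data.frame(name = character(0), regulator = character(0),
                             n_targets = integer(0), correlation = numeric(0),
                             direction = character(0),
                             deg_direction = character(0),
                             targets = character(0))
      write_tsv(reg_df, p("regulons.tsv"))
      act <- do.call(rbind, lapply(regulons, `[[`, "activity"))
      if (!is.null(act)) {
        rownames(act) <- vapply(regulons, `[[`, "", "name")
        write_tsv(data.frame(regulon = rownames(act), act,
                             check.names = FALSE), p("activity.tsv"))
      }
      ran <- c(ran, "regulons")
    })
  }

  if (isTRUE(config$stages$network)) {
    stage_try("network", {
      if (is.null(regulons)) stop("regulons stage must run before network")
      tf <- read_lines_file(inputs$tf_list)
      g <- build_tf_network(regulons, tf)
      write_network_sif(g, p("network.sif"))
      igraph::write_graph(g, p("network.graphml"), format = "graphml")
      ran <- c(ran, "network")
    })
  }

  input_files <- unlist(inputs[vapply(inputs, is.character, TRUE)])
  manifest <- list(
    package = "osteostage",
    version = as.character(utils::packageVersion("osteostage")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    parameters = config[c("phases", "isotopes", "filter", "regulons")],
    stages_run = ran,
    input_checksums = {
      ck <- tools::md5sum(input_files[file.exists(input_files)])
      as.list(stats::setNames(ck, basename(names(ck))))
    }
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a TF-TF network in SIF format
#'
#' One line per edge: `tail regulates head`, Cytoscape-compatible.
#'
#' @param g directed igraph from [build_tf_network()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_network_sif <- function(g, path) {
  e <- igraph::as_edgelist(g)
  lines <- if (nrow(e)) sprintf("%s\tregulates\t%s", e[, 1], e[, 2])
  else character(0)
  writeLines(lines, path)
  invisible(path)
}
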