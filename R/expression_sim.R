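# Synthetic expression data with planted switch-like regulons, decoy
# regulators and background genes, plus the derived inputs of the
# transcriptomic stages: TPM matrix, differential-expression tables,
# regulator->target prior database and annotation lists.

#' Default planted regulon layout
#'
#' Ten regulons (5 up, 5 down), 8-20 targets each, with regulon-specific
#' logistic switch times and steepness so target modules are separable by
#' clustering. By default a regulatory cascade TF01 -> TF03 -> TF05 is
#' planted (the downstream TF is a member of the upstream regulon's target
#' set), giving the TF-TF network a known directed path; cascade members
#' keep their own regulator profile, so their membership in the upstream
#' regulon is recoverable from the prior but not from co-expression.
#'
#' @param cascade plant the TF01 -> TF03 -> TF05 cascade (default TRUE).
#' @return list of regulon descriptors (regulator, targets, direction,
#'   amplitude, t0, steepness).
#' @export
default_planted_regulons <- function(cascade = TRUE) {
  sizes <- c(8, 10, 12, 14, 16, 9, 11, 13, 17, 20)
  dirs <- rep(c("up", "down"), each = 5)
  t0 <- rep(c(1.4, 2.0, 2.5, 3.0, 3.6), 2)
  steep <- rep(c(4, 2.5, 2, 2.5, 4), 2)
  regs <- sprintf("TF%02d", 1:10)
  next_target <- 1L
  out <- list()
  for (i in 1:10) {
    n_named <- sizes[i]
    casc <- character(0)
    if (cascade && regs[i] == "TF01") casc <- "TF03"
    if (cascade && regs[i] == "TF03") casc <- "TF05"
    n_named <- n_named - length(casc)
    targets <- c(sprintf("TG%04d", seq(next_target, next_target + n_named - 1L)),
                 casc)
    next_target <- next_target + n_named
    out[[i]] <- list(regulator = regs[i], targets = targets,
                     direction = dirs[i], amplitude = 2,
                     t0 = t0[i], steepness = steep[i])
  }
  out
}

#' Configuration for the expression simulator
#'
#' @param n_genes total genes (planted regulators + targets + decoys +
#'   background).
#' @param n_timepoints sampled time points (default 4).
#' @param n_donors donors (default 3).
#' @param n_reps replicates per donor x time point used for the DE tables.
#' @param timepoint_days day labels for the time points.
#' @param planted_regulons list of regulon descriptors (see
#'   [default_planted_regulons()]); target sets must be disjoint from
#'   regulator names and amplitudes positive.
#' @param decoy_regulators number of decoy TFs with random prior target sets
#'   and stationary expression.
#' @param prior_extra_targets decoy targets added to each planted prior
#'   entry.
#' @param noise_sd expression noise SD on the log2 scale.
#' @param donor_sd donor offset SD on the log2 scale.
#' @param seed integer seed.
#' @return object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 1000L,
                                  n_timepoints = 4L,
                                  n_donors = 3L,
                                  n_reps = 3L,
                                  timepoint_days = c(3L, 6L, 16L, 28L),
                                  planted_regulons = default_planted_regulons(),
                                  decoy_regulators = 20L,
                                  prior_extra_targets = 5L,
                                  noise_sd = 0.2,
                                  donor_sd = 0.1,
                                  seed = 1L) {
  regs <- vapply(planted_regulons, `[[`, "", "regulator")
  targets <- unlist(lapply(planted_regulons, `[[`, "targets"))
  for (r in planted_regulons) {
    if (r$regulator %in% setdiff(r$targets, regs))
      stop("planted target sets must be disjoint from regulator names")
    if (r$amplitude <= 0) stop("amplitudes must be > 0")
    if (!r$direction %in% c("up", "down")) stop("direction must be up/down")
  }
  n_planted <- length(unique(c(regs, targets))) + decoy_regulators
  if (n_planted > n_genes)
    stop("more planted genes than n_genes")
  if (length(timepoint_days) != n_timepoints)
    stop("timepoint_days must have length n_timepoints")
  structure(list(n_genes = as.integer(n_genes),
                 n_timepoints = as.integer(n_timepoints),
                 n_donors = as.integer(n_donors), n_reps = as.integer(n_reps),
                 timepoint_days = as.integer(timepoint_days),
                 planted_regulons = planted_regulons,
                 decoy_regulators = as.integer(decoy_regulators),
                 prior_extra_targets = as.integer(prior_extra_targets),
                 noise_sd = noise_sd, donor_sd = donor_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

logistic_switch <- function(t, t0, steepness) 1 / (1 + exp(-steepness * (t - t0)))

#' Simulate expression data with planted regulons
#'
#' Planted regulator profiles follow a monotone logistic switch in time (up
#' or down); each target tracks its regulator's switch with a gene-specific
#' positive amplitude; background genes and decoy regulators are stationary
#' noise. The replicate-level log2 expression is
#' `baseline + amplitude * switch(t) + donor offset + noise`. Outputs follow
#' the schemas consumed by the downstream stages: a TPM matrix averaged to
#' time point x donor columns, per-contrast DE tables (two-sided two-sample
#' t-tests on log2 expression across replicates, overall and per donor, with
#' BH adjustment), a regulator->target prior database with decoy entries, TF
#' and metabolic-gene lists, and the ground truth.
#'
#' @param config an [expression_sim_config()].
#' @param contrast integer pair `c(test, reference)` of time-point indices
#'   for the DE table (default last vs first).
#' @return list: `tpm` (gene x (timepoint x donor) matrix), `timepoints`
#'   (time-point index per tpm column), `donors` (donor per column), `de`
#'   (named list of DE data.frames), `prior` (data.frame regulator/target),
#'   `tf_list`, `metabolic_genes`, `truth`.
#' @export
simulate_expression <- function(config, contrast = NULL) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  if (is.null(contrast)) contrast <- c(config$n_timepoints, 1L)
  regs <- vapply(config$planted_regulons, `[[`, "", "regulator")
  planted_targets <- unique(unlist(lapply(config$planted_regulons, `[[`,
                                          "targets")))
  decoys <- sprintf("DEC%02d", seq_len(config$decoy_regulators))
  named <- unique(c(regs, planted_targets, decoys))
  n_bg <- config$n_genes - length(named)
  background <- sprintf("BG%04d", seq_len(n_bg))
  genes <- c(named, background)

  tp <- seq_len(config$n_timepoints)
  grid <- expand.grid(rep = seq_len(config$n_reps),
                      donor = seq_len(config$n_donors), timepoint = tp,
                      KEEP.OUT.ATTRS = FALSE)
  n_cols <- nrow(grid)
  baseline <- stats::setNames(stats::runif(length(genes), 3, 8), genes)
  donor_off <- matrix(stats::rnorm(length(genes) * config$n_donors,
                                   sd = config$donor_sd),
                      nrow = length(genes), dimnames = list(genes, NULL))

  # per-gene switch component: amplitude * s(t) (or amplitude * (1 - s(t)))
  switch_profile <- matrix(0, length(genes), config$n_timepoints,
                           dimnames = list(genes, NULL))
  truth_membership <- list()
  for (r in config$planted_regulons) {
    s <- logistic_switch(tp, r$t0, r$steepness)
    if (r$direction == "down") s <- 1 - s
    switch_profile[r$regulator, ] <- r$amplitude * s
    for (g in r$targets) {
      amp <- stats::runif(1, 0.8, 1.2) * r$amplitude
      # cascade TFs keep their own regulator profile (already set)
      if (!g %in% regs) switch_profile[g, ] <- amp * s
    }
    truth_membership[[r$regulator]] <- list(targets = r$targets,
                                            direction = r$direction)
  }

  log2e <- baseline[genes] +
    switch_profile[, grid$timepoint, drop = FALSE] +
    donor_off[, grid$donor, drop = FALSE] +
    matrix(stats::rnorm(length(genes) * n_cols, sd = config$noise_sd),
           nrow = length(genes))
  dimnames(log2e) <- list(genes, sprintf("t%d_D%d_r%d", grid$timepoint,
                                         grid$donor, grid$rep))
  tpm_rep <- 2^log2e

  # TPM matrix averaged over replicates -> timepoint x donor columns
  cond <- interaction(grid$timepoint, grid$donor, drop = TRUE)
  cond_levels <- unique(as.character(cond))
  tpm <- sapply(cond_levels, function(cl)
    rowMeans(tpm_rep[, cond == cl, drop = FALSE]))
  meta <- do.call(rbind, strsplit(cond_levels, ".", fixed = TRUE))
  timepoints <- as.integer(meta[, 1]); donors <- as.integer(meta[, 2])
  colnames(tpm) <- sprintf("d%d_D%d", config$timepoint_days[timepoints],
                           donors)

  de <- de_table(log2e, tpm_rep, grid, contrast)
  de_name <- sprintf("day%d_vs_day%d", config$timepoint_days[contrast[1]],
                     config$timepoint_days[contrast[2]])

  # prior database: planted entries plus decoy targets; decoy regulators
  # with random target sets
  prior <- list()
  for (r in config$planted_regulons) {
    extra <- sample(background, config$prior_extra_targets)
    prior[[length(prior) + 1L]] <- data.frame(
      regulator = r$regulator, target = c(r$targets, extra))
  }
  for (d in decoys) {
    k <- sample(8:20, 1)
    prior[[length(prior) + 1L]] <- data.frame(
      regulator = d, target = sample(setdiff(genes, d), k))
  }
  prior <- do.call(rbind, prior)

  tf_list <- c(regs, decoys)
  metabolic_genes <- c(sample(setdiff(planted_targets, regs),
                              min(20, length(planted_targets))),
                       sample(background, 20))

  list(tpm = tpm, timepoints = timepoints, donors = donors,
       de = stats::setNames(list(de), de_name), prior = prior,
       tf_list = tf_list, metabolic_genes = metabolic_genes,
       truth = list(regulons = truth_membership, background = background,
                    decoy_regulators = decoys,
                    contrast_days = config$timepoint_days[contrast]))
}

# Two-sided two-sample t-test p-value that tolerates zero-variance input
# (noise-free simulations): equal means -> 1, different means -> 0.
safe_t_pvalue <- function(x, y) {
  if (stats::sd(c(x - mean(x), y - mean(y))) < 1e-12)
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  stats::t.test(x, y)$p.value
}

# DE table for contrast c(test, ref) over time-point indices: overall and
# per-donor two-sided t-tests on log2 expression, means and relative SEM on
# the TPM scale, BH adjustment across genes.
de_table <- function(log2e, tpm_rep, grid, contrast) {
  a <- grid$timepoint == contrast[1]   # test condition
  b <- grid$timepoint == contrast[2]   # reference
  genes <- rownames(log2e)
  la <- log2e[, a, drop = FALSE]; lb <- log2e[, b, drop = FALSE]
  ta <- tpm_rep[, a, drop = FALSE]; tb <- tpm_rep[, b, drop = FALSE]
  log2fc <- rowMeans(la) - rowMeans(lb)
  pvalue <- vapply(genes, function(g) safe_t_pvalue(la[g, ], lb[g, ]), 0)
  rel_sem <- function(m) apply(m, 1, function(x)
    (stats::sd(x) / sqrt(length(x))) / abs(mean(x)))
  df <- data.frame(gene = genes,
                   mean_tpm_test = rowMeans(ta), mean_tpm_ref = rowMeans(tb),
                   log2fc = log2fc, pvalue = pvalue,
                   padj = stats::p.adjust(pvalue, "BH"),
                   rel_sem_test = rel_sem(ta), rel_sem_ref = rel_sem(tb),
                   row.names = NULL)
  for (d in sort(unique(grid$donor))) {
    ad <- a & grid$donor == d; bd <- b & grid$donor == d
    lad <- log2e[, ad, drop = FALSE]; lbd <- log2e[, bd, drop = FALSE]
    df[[sprintf("lfc_donor%d", d)]] <- rowMeans(lad) - rowMeans(lbd)
    df[[sprintf("sig_donor%d", d)]] <- vapply(genes, function(g)
      safe_t_pvalue(lad[g, ], lbd[g, ]), 0) < 0.05
  }
  df
}
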