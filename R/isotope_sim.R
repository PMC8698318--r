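# Synthetic stable-isotope labeling data: true isotopologue distributions
# convolved with natural 13C abundance, scaled and perturbed with
# multiplicative log-normal noise.

#' Default true isotopologue distributions for the labeling simulator
#'
#' Structured after uniformly 13C-glucose-fed cultures. Glucose and lactate
#' are two-state mixtures (unlabeled M+0 versus fully labeled M+n) whose
#' labeled weight drifts over differentiation; UDP-glucose is a three-state
#' mixture of M+0, M+6 (glycolytic hexose moiety) and M+11 (hexose plus
#' pentose-phosphate-derived ribose) with the glycolytic share rising and
#' the PPP share falling; glutamate carbons arrive scrambled through the TCA
#' cycle and follow a binomial profile with slowly rising enrichment. Other
#' metabolites default to a binomial profile.
#'
#' @param metabolites data.frame with columns `name` and `n_atoms`.
#' @param days sampling days.
#' @return nested list: `[[metabolite]][[as.character(day)]]` -> fractions.
#' @export
default_true_distributions <- function(metabolites, days) {
  traj <- function(lo, hi) lo + (hi - lo) * (seq_along(days) - 1) /
    max(1, length(days) - 1)
  two_state <- function(n, w) {
    x <- rep(0, n + 1); x[1] <- 1 - w; x[n + 1] <- w; x
  }
  out <- list()
  for (i in seq_len(nrow(metabolites))) {
    m <- metabolites$name[i]; n <- metabolites$n_atoms[i]
    dists <- switch(
      m,
      glucose = lapply(traj(0.96, 0.99), two_state, n = n),
      lactate = lapply(traj(0.70, 0.80), two_state, n = n),
      UDP_glucose = {
        w6 <- traj(0.35, 0.55); w11 <- traj(0.18, 0.06)
        lapply(seq_along(days), function(j) {
          x <- rep(0, n + 1)
          x[1] <- 1 - w6[j] - w11[j]; x[7] <- w6[j]; x[n + 1] <- w11[j]
          x
        })
      },
      glutamate = lapply(traj(0.05, 0.25), function(e) stats::dbinom(0:n, n, e)),
      lapply(traj(0.3, 0.6), function(e) stats::dbinom(0:n, n, e))
    )
    out[[m]] <- stats::setNames(dists, as.character(days))
  }
  out
}

#' Configuration for the isotopologue intensity simulator
#'
#' @param metabolites data.frame with `name` and carbon count `n_atoms`.
#' @param days sampling days.
#' @param true_distributions nested list of true fractions (length
#'   `n_atoms + 1`, non-negative, summing to 1) per metabolite/day.
#' @param natural_abundance natural 13C fraction (default 0.0107).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param protein_ug per-sample protein amount (BCA assay), micrograms.
#' @param n_replicates replicates per metabolite/day.
#' @param total_intensity arbitrary-unit intensity scale factor.
#' @param seed integer seed.
#' @return object of class `isotope_sim_config`.
#' @export
isotope_sim_config <- function(metabolites = data.frame(
                                 name = c("lactate", "glutamate",
                                          "glucose", "UDP_glucose"),
                                 n_atoms = c(3L, 5L, 6L, 11L)),
                               days = c(3L, 9L, 16L, 28L),
                               true_distributions =
                                 default_true_distributions(metabolites, days),
                               natural_abundance = 0.0107,
                               noise_cv = 0.02,
                               protein_ug = 50,
                               n_replicates = 3L,
                               total_intensity = 1e6,
                               seed = 1L) {
  stopifnot(all(c("name", "n_atoms") %in% names(metabolites)),
            natural_abundance >= 0, natural_abundance < 1,
            noise_cv >= 0, protein_ug > 0, n_replicates >= 1)
  for (i in seq_len(nrow(metabolites))) {
    m <- metabolites$name[i]; n <- metabolites$n_atoms[i]
    for (d in as.character(days)) {
      x <- true_distributions[[m]][[d]]
      if (length(x) != n + 1L)
        stop(sprintf("true distribution for %s has length %d, expected %d",
                     m, length(x), n + 1L))
      if (any(x < 0) || abs(sum(x) - 1) > 1e-12)
        stop(sprintf("true distribution for %s day %s is not a probability vector",
                     m, d))
    }
  }
  structure(list(metabolites = metabolites, days = as.integer(days),
                 true_distributions = true_distributions,
                 natural_abundance = natural_abundance, noise_cv = noise_cv,
                 protein_ug = protein_ug,
                 n_replicates = as.integer(n_replicates),
                 total_intensity = total_intensity, seed = as.integer(seed)),
            class = "isotope_sim_config")
}

#' Simulate raw isotopologue intensity vectors
#'
#' The raw vector is the forward convolution of the true distribution with
#' natural 13C abundance, `CorrectionMatrix(n, p) %*% x_true`, scaled by
#' total intensity and protein amount, with unbiased multiplicative
#' log-normal noise of the configured CV.
#'
#' @param config an [isotope_sim_config()].
#' @return list with `intensities` (data.frame: metabolite, day, replicate,
#'   mass_shift, intensity, protein_ug) and `truth` (true distributions and
#'   mean enrichments; tests only).
#' @export
simulate_isotopologues <- function(config) {
  stopifnot(inherits(config, "isotope_sim_config"))
  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  rows <- list()
  enrich <- list()
  for (i in seq_len(nrow(config$metabolites))) {
    m <- config$metabolites$name[i]; n <- config$metabolites$n_atoms[i]
    cm <- build_correction_matrix(n, config$natural_abundance)
    for (d in config$days) {
      x <- config$true_distributions[[m]][[as.character(d)]]
      expected <- as.numeric(cm$matrix %*% x) *
        config$total_intensity * config$protein_ug / 50
      for (r in seq_len(config$n_replicates)) {
        noise <- if (config$noise_cv > 0)
          stats::rlnorm(n + 1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        else rep(1, n + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = m, day = d, replicate = r, mass_shift = 0:n,
          intensity = expected * noise, protein_ug = config$protein_ug)
      }
      enrich[[paste(m, d, sep = "_")]] <- mean_enrichment(x, n)
    }
  }
  list(intensities = do.call(rbind, rows),
       truth = list(true_distributions = config$true_distributions,
                    mean_enrichments = unlist(enrich)))
}
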