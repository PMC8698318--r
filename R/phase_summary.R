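# Per-phase rate summaries, flux ratios against stoichiometric reference
# values, and the alkaline phosphatase (ALP) assay formula.

# Named metabolite pairs and the stoichiometry of the idealized conversion:
# moles of the numerator metabolite consumed per mole of reaction (uptake,
# negative rate) and moles of the denominator metabolite produced (secretion,
# positive rate).
flux_ratio_pairs <- function() {
  list(
    glucose_lactate     = list(pair = c("glucose", "lactate"),
                               consumed = 1, produced = 2),
    glutamine_glutamate = list(pair = c("glutamine", "glutamate"),
                               consumed = 1, produced = 1),
    glutamine_ammonia   = list(pair = c("glutamine", "ammonia"),
                               consumed = 1, produced = 1)
  )
}

#' Expected perfect ratio (EPR) for a metabolite rate pair
#'
#' The stoichiometric reference value of the signed rate ratio under complete
#' conversion: the numerator metabolite is taken up (negative rate, one mole
#' per reaction) and the denominator metabolite secreted (positive rate, at
#' the stoichiometric coefficient), so glucose/lactate gives
#' -1/2 (1 glucose -> 2 lactate), glutamine/glutamate and glutamine/ammonia
#' give -1/1.
#'
#' @param pair character vector `c(numerator, denominator)` or a single
#'   string "numerator/denominator"; one of glucose/lactate,
#'   glutamine/glutamate, glutamine/ammonia.
#' @return the reference ratio.
#' @export
expected_perfect_ratio <- function(pair) {
  if (length(pair) == 1) pair <- strsplit(pair, "/", fixed = TRUE)[[1]]
  if (length(pair) != 2) stop("pair must name a numerator and a denominator")
  defs <- flux_ratio_pairs()
  for (d in defs) {
    if (identical(tolower(pair), d$pair))
      return((-d$consumed) / d$produced)
  }
  stop("unknown metabolite pair: ", paste(pair, collapse = "/"))
}

#' Summarize rates and flux ratios per metabolic phase
#'
#' For each phase of a change-point result, reports the mean and SEM of the
#' daily rates per metabolite, and the phase flux ratios
#' glucose/lactate, glutamine/glutamate and glutamine/ammonia
#' (phase-mean numerator rate over phase-mean denominator rate). Single-day
#' phases carry SEM 0 by convention and are flagged; a zero denominator mean
#' yields an undefined (NA) ratio, flagged.
#'
#' @param panel a [rate_panel()].
#' @param result a [edivisive()] result whose phases partition the panel days.
#' @return list of per-phase summaries, each with `phase`, `start_day`,
#'   `end_day`, `stats` (data.frame metabolite/mean/sem/n_days/single_day)
#'   and `flux_ratios` (data.frame ratio/value/defined).
#' @export
phase_summary <- function(panel, result) {
  stopifnot(inherits(panel, "rate_panel"),
            inherits(result, "changepoint_result"))
  ph <- result$phases
  covered <- unlist(lapply(seq_len(nrow(ph)), function(i)
    panel$days[panel$days >= ph$start_day[i] & panel$days <= ph$end_day[i]]))
  if (!setequal(covered, panel$days) || anyDuplicated(covered))
    stop("phases do not partition the panel days")
  out <- vector("list", nrow(ph))
  for (i in seq_len(nrow(ph))) {
    rows <- panel$days >= ph$start_day[i] & panel$days <= ph$end_day[i]
    sub <- panel$rates[rows, , drop = FALSE]
    n <- nrow(sub)
    mu <- colMeans(sub)
    sem <- if (n > 1) apply(sub, 2, stats::sd) / sqrt(n) else
      stats::setNames(rep(0, ncol(sub)), colnames(sub))
    stats_df <- data.frame(metabolite = colnames(sub), mean = mu, sem = sem,
                           n_days = n, single_day = n == 1,
                           row.names = NULL)
    fr <- lapply(names(flux_ratio_pairs()), function(nm) {
      p <- flux_ratio_pairs()[[nm]]$pair
      if (!all(p %in% colnames(sub)))
        return(data.frame(ratio = nm, value = NA_real_, defined = FALSE))
      den <- mu[p[2]]
      if (abs(den) < .Machine$double.eps)
        return(data.frame(ratio = nm, value = NA_real_, defined = FALSE))
      data.frame(ratio = nm, value = unname(mu[p[1]] / den), defined = TRUE)
    })
    out[[i]] <- list(phase = ph$phase[i], start_day = ph$start_day[i],
                     end_day = ph$end_day[i], stats = stats_df,
                     flux_ratios = do.call(rbind, fr))
  }
  out
}

#' Alkaline phosphatase activity from optical density
#'
#' Conversion of p-nitrophenyl phosphate to p-nitrophenol:
#' `activity [nmol/min] = OD / (18.8 [1/umol] * time [min]) * 1000
#' [nmol/umol]`.
#'
#' @param optical_density dimensionless absorbance reading.
#' @param time_min incubation time in minutes (> 0).
#' @param extinction_factor molar conversion factor, 18.8 per micromole.
#' @return activity in nmol/min.
#' @export
alp_activity <- function(optical_density, time_min, extinction_factor = 18.8) {
  if (any(time_min <= 0)) stop("time_min must be > 0")
  optical_density / (extinction_factor * time_min) * 1000
}
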