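# Synthetic extracellular metabolite panel: piecewise-phase uptake/secretion
# rates with donor random intercepts, analysis batch effects and residual
# measurement noise, sampled on an irregular day grid.

#' Default per-phase mean rates (mmol/L/h) for the five panel metabolites
#'
#' Rows are metabolites, columns are phases. Signs follow the spent-medium
#' convention: secretion positive, uptake negative. Magnitudes are plausible
#' for MSC cultures in DMEM/F12-like medium with 48 h feeding cycles.
#'
#' @param n_phases number of phases (columns).
#' @return numeric matrix, metabolites x phases.
#' @export
default_phase_rates <- function(n_phases = 3) {
  base <- rbind(
    glucose   = c(-0.030, -0.010, -0.035),
    lactate   = c( 0.060,  0.020,  0.055),
    glutamine = c(-0.008, -0.010, -0.014),
    glutamate = c( 0.001,  0.0003, 0.005),
    ammonia   = c( 0.006,  0.008,  0.010)
  )
  if (n_phases == 3) return(base)
  base[, pmin(seq_len(n_phases), 3), drop = FALSE]
}

#' Fresh-medium baseline concentrations (mmol/L)
#'
#' DMEM/F12-like values; the source study does not print its fresh-medium
#' composition so these are config-exposed defaults.
#'
#' @return named numeric vector.
#' @export
default_baselines <- function() {
  c(glucose = 17.5, lactate = 0, glutamine = 2.5,
    glutamate = 0.05, ammonia = 0.05)
}

#' Configuration for the extracellular metabolite simulator
#'
#' @param n_donors number of donors.
#' @param days integer sampling days; default is days 1..28 with day 14
#'   dropped, mirroring a day removed for missingness and forcing the rate
#'   computation to handle irregular gaps.
#' @param metabolites metabolite names (rates and baselines must cover them).
#' @param phase_boundaries ground-truth change-point days: the first day of
#'   each new phase. Strictly increasing, strictly inside `range(days)`.
#'   May be empty (single phase).
#' @param phase_rates metabolite x phase matrix of mean rates, mmol/L/h.
#' @param baselines named fresh-medium concentrations, mmol/L.
#' @param donor_sd donor random-intercept SD on the rate scale (mmol/L/h).
#' @param batch_sd analysis-batch effect SD on the rate scale (mmol/L/h).
#' @param noise_sd residual concentration noise SD (mmol/L).
#' @param media_change_hours feeding interval, h.
#' @param sample_intervals dwell hours cycled over the day schedule
#'   (default alternating 24/36 h between media change and sampling).
#' @param seed integer seed; the generator is deterministic given
#'   (config, seed).
#' @return object of class `metabolite_sim_config`.
#' @export
metabolite_sim_config <- function(n_donors = 4,
                                  days = setdiff(1:28, 14),
                                  metabolites = c("glucose", "lactate",
                                                  "glutamine", "glutamate",
                                                  "ammonia"),
                                  phase_boundaries = c(5, 16),
                                  phase_rates = default_phase_rates(length(phase_boundaries) + 1),
                                  baselines = default_baselines(),
                                  donor_sd = 0.002,
                                  batch_sd = 0.001,
                                  noise_sd = 0.15,
                                  media_change_hours = 48,
                                  sample_intervals = c(24, 36),
                                  seed = 1L) {
  days <- sort(unique(as.integer(days)))
  if (length(phase_boundaries)) {
    phase_boundaries <- as.integer(phase_boundaries)
    if (is.unsorted(phase_boundaries, strictly = TRUE))
      stop("phase_boundaries must be strictly increasing")
    if (any(phase_boundaries <= min(days)) || any(phase_boundaries > max(days)))
      stop("phase boundary outside day range")
  }
  if (any(c(donor_sd, batch_sd, noise_sd) < 0))
    stop("all SDs must be >= 0")
  phase_rates <- as.matrix(phase_rates)
  if (is.null(rownames(phase_rates))) rownames(phase_rates) <- metabolites
  if (!all(metabolites %in% rownames(phase_rates)))
    stop("phase_rates must have a row per metabolite")
  if (ncol(phase_rates) != length(phase_boundaries) + 1L)
    stop("phase_rates needs one column per phase (boundaries + 1)")
  if (!all(metabolites %in% names(baselines)))
    stop("baselines must name every metabolite")
  structure(list(
    n_donors = as.integer(n_donors), days = days, metabolites = metabolites,
    phase_boundaries = phase_boundaries,
    phase_rates = phase_rates[metabolites, , drop = FALSE],
    baselines = baselines[metabolites],
    donor_sd = donor_sd, batch_sd = batch_sd, noise_sd = noise_sd,
    media_change_hours = media_change_hours,
    sample_intervals = sample_intervals, seed = as.integer(seed)
  ), class = "metabolite_sim_config")
}

#' Simulate a spent-medium concentration panel
#'
#' Each sampled concentration is
#' `baseline + (phase rate + donor intercept + batch effect) * dwell + noise`,
#' truncated at zero (detection-limit substitution). Days are assigned to two
#' analysis batches split at the median day; dwell hours cycle through
#' `sample_intervals`.
#'
#' @param config a [metabolite_sim_config()].
#' @return list with `series` (data.frame: donor, day, metabolite,
#'   concentration, dwell_hours, batch) and `truth` (ground-truth list with
#'   change-point days, per-phase rates, baselines and random effects;
#'   consumed only by tests, never by pipeline stages).
#' @export
simulate_metabolite_panel <- function(config) {
  stopifnot(inherits(config, "metabolite_sim_config"))
  set.seed(config$seed)
  days <- config$days
  mets <- config$metabolites
  n_days <- length(days)
  dwell <- rep_len(config$sample_intervals, n_days)
  # two analysis batches interleaved across sampling days, so additive batch
  # offsets are orthogonal to the phase structure and centring cannot absorb
  # a planted step
  batch <- rep_len(c("B1", "B2"), n_days)
  phase_of_day <- findInterval(days, config$phase_boundaries) + 1L

  donors <- sprintf("D%d", seq_len(config$n_donors))
  donor_int <- matrix(stats::rnorm(length(donors) * length(mets),
                                   sd = config$donor_sd),
                      nrow = length(donors),
                      dimnames = list(donors, mets))
  batches <- unique(batch)
  batch_eff <- matrix(stats::rnorm(length(batches) * length(mets),
                                   sd = config$batch_sd),
                      nrow = length(batches),
                      dimnames = list(batches, mets))

  grid <- expand.grid(donor = donors, day = days, metabolite = mets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$dwell_hours <- dwell[match(grid$day, days)]
  grid$batch <- batch[match(grid$day, days)]
  rate <- config$phase_rates[cbind(match(grid$metabolite, rownames(config$phase_rates)),
                                   phase_of_day[match(grid$day, days)])] +
    donor_int[cbind(grid$donor, grid$metabolite)] +
    batch_eff[cbind(grid$batch, grid$metabolite)]
  conc <- config$baselines[grid$metabolite] + rate * grid$dwell_hours +
    stats::rnorm(nrow(grid), sd = config$noise_sd)
  grid$concentration <- pmax(conc, 0)
  grid <- grid[, c("donor", "day", "metabolite", "concentration",
                   "dwell_hours", "batch")]
  truth <- list(
    change_point_days = config$phase_boundaries,
    phase_rates = config$phase_rates,
    baselines = config$baselines,
    donor_intercepts = donor_int,
    batch_effects = batch_eff,
    days = days, dwell_hours = dwell
  )
  list(series = grid, truth = truth)
}

#' Empirical per-day rate panel from a concentration series
#'
#' Computes the hourly rate of change for every sampled day directly from
#' the spent-medium accumulation since the last media change,
#' `(concentration - fresh baseline) / dwell_hours`, optionally removes
#' additive analysis-batch offsets (centring each batch to the grand mean per
#' metabolite) and averages across donors. This bypasses smoothing; use
#' [smooth_timecourse()] + [compute_rates()] for the model-based route.
#'
#' @param series concentration series data.frame (see
#'   [simulate_metabolite_panel()]).
#' @param baselines named fresh-medium concentrations, mmol/L.
#' @param center_batches remove per-batch additive offsets.
#' @return a [rate_panel()].
#' @export
empirical_rate_panel <- function(series, baselines = default_baselines(),
                                 center_batches = TRUE) {
  stopifnot(all(series$metabolite %in% names(baselines)))
  series$rate <- (series$concentration - baselines[series$metabolite]) /
    series$dwell_hours
  if (center_batches) {
    for (m in unique(series$metabolite)) {
      i <- series$metabolite == m
      grand <- mean(series$rate[i])
      bm <- tapply(series$rate[i], series$batch[i], mean)
      series$rate[i] <- series$rate[i] - bm[series$batch[i]] + grand
    }
  }
  agg <- stats::aggregate(rate ~ day + metabolite, data = series, FUN = mean)
  days <- sort(unique(agg$day))
  mets <- unique(series$metabolite)
  rates <- matrix(NA_real_, length(days), length(mets),
                  dimnames = list(days, mets))
  rates[cbind(match(agg$day, days), match(agg$metabolite, mets))] <- agg$rate
  rate_panel(days, mets, rates)
}

#' Construct a rate panel
#'
#' Day x metabolite matrix of hourly concentration-change rates (secretion
#' positive, uptake negative).
#'
#' @param days strictly increasing integer days.
#' @param metabolites metabolite names.
#' @param rates numeric matrix, days x metabolites, no missing entries.
#' @param standardized whether columns are scaled to unit variance.
#' @return object of class `rate_panel`.
#' @export
rate_panel <- function(days, metabolites, rates, standardized = FALSE) {
  days <- as.integer(days)
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  rates <- as.matrix(rates)
  if (anyNA(rates)) stop("rate panel has missing entries")
  stopifnot(nrow(rates) == length(days), ncol(rates) == length(metabolites))
  dimnames(rates) <- list(days, metabolites)
  structure(list(days = days, metabolites = metabolites, rates = rates,
                 standardized = standardized),
            class = "rate_panel")
}

#' @export
print.rate_panel <- function(x, ...) {
  cat(sprintf("rate_panel: %d days x %d metabolites (%s)\n",
              length(x$days), length(x$metabolites),
              if (x$standardized) "standardized" else "mmol/L/h"))
  invisible(x)
}

#' Scale each metabolite rate series to unit variance
#'
#' Applied before multivariate change-point analysis so high-concentration
#' metabolites do not dominate the Euclidean energy distance. Zero-variance
#' columns are left unscaled.
#'
#' @param panel a [rate_panel()].
#' @return standardized `rate_panel`.
#' @export
standardize_rates <- function(panel) {
  stopifnot(inherits(panel, "rate_panel"))
  s <- apply(panel$rates, 2, stats::sd)
  s[s < .Machine$double.eps] <- 1
  rate_panel(panel$days, panel$metabolites,
             sweep(panel$rates, 2, s, "/"), standardized = TRUE)
}

#' Study configuration for the change-point recovery simulation
#'
#' Builds a metabolite simulator config in which every metabolite's mean rate
#' shifts at each planted boundary by `shift_sd` residual standard deviations
#' on the concentration-per-dwell scale (`shift_sd * noise_sd / dwell` in
#' rate units, `noise_sd` being the residual concentration SD), with
#' alternating shift signs across metabolites and constant 24 h dwell so the
#' shift-to-noise ratio is uniform across days. Averaging the configured
#' donors then reduces the panel noise as in the study design. With
#' `null = TRUE` no boundaries are planted.
#'
#' @param seed integer seed.
#' @param shift_sd phase shift in units of residual SD (default 1.5).
#' @param noise_sd residual concentration noise SD, mmol/L.
#' @param n_donors donors (default 4).
#' @param boundaries planted change-point days (default 5 and 16).
#' @param null if TRUE, generate a single-phase (no change point) panel.
#' @return a [metabolite_sim_config()].
#' @export
changepoint_study_config <- function(seed, shift_sd = 1.5, noise_sd = 0.15,
                                     n_donors = 4, boundaries = c(5L, 16L),
                                     null = FALSE) {
  mets <- c("glucose", "lactate", "glutamine", "glutamate", "ammonia")
  dwell <- 24
  sigma <- noise_sd / dwell  # residual SD of a single-donor daily rate
  if (null) boundaries <- integer(0)
  n_phases <- length(boundaries) + 1L
  base <- c(glucose = -0.030, lactate = 0.060, glutamine = -0.008,
            glutamate = 0.001, ammonia = 0.006)
  rates <- matrix(base, nrow = length(mets), ncol = n_phases,
                  dimnames = list(mets, NULL))
  if (n_phases > 1) {
    for (p in 2:n_phases) {
      step <- shift_sd * sigma * (-1)^(seq_along(mets) + p)
      rates[, p] <- rates[, p - 1] + step
    }
  }
  metabolite_sim_config(
    n_donors = n_donors, days = setdiff(1:28, 14), metabolites = mets,
    phase_boundaries = boundaries, phase_rates = rates,
    donor_sd = 0.002, batch_sd = 0.001, noise_sd = noise_sd,
    sample_intervals = dwell, seed = seed
  )
}
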