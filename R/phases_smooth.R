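# Time-course smoothing and hourly-rate computation for spent-medium
# metabolite concentrations.

#' Smooth metabolite concentration time courses
#'
#' Per metabolite: (1) drop any day with more than 50% missing values across
#' donors; (2) substitute remaining missing values with the metabolite's
#' observed minimum (detection-limit substitution); (3) fit an additive model
#' of concentration over day — a cubic-regression-spline smooth with
#' smoothness chosen by generalized cross-validation — with additive donor
#' and analysis-batch effects; (4) return the population-level fitted value
#' (day smooth plus the average donor/batch contribution, preserving the
#' grand mean) at each retained day. Estimating donor/batch offsets jointly
#' with the trend avoids the leakage that naive group-mean centring suffers
#' when group membership is unbalanced along the time course.
#'
#' @param series data.frame with columns donor, day, metabolite,
#'   concentration, dwell_hours, batch (concentration may contain NA).
#' @param k_basis basis dimension for the day smooth; default
#'   `min(15, n_days - 1)`.
#' @return data.frame with columns metabolite, day, fitted_value,
#'   dwell_hours.
#' @export
smooth_timecourse <- function(series, k_basis = NULL) {
  need <- c("donor", "day", "metabolite", "concentration", "dwell_hours",
            "batch")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (m in unique(series$metabolite)) {
    s <- series[series$metabolite == m, ]
    rng <- tapply(s$day[!is.na(s$concentration)],
                  s$donor[!is.na(s$concentration)], range)
    if (length(rng) > 1) {
      lo <- max(vapply(rng, `[`, 0, 1)); hi <- min(vapply(rng, `[`, 0, 2))
      if (lo > hi)
        warning(sprintf("donor day ranges for %s do not overlap; fitting on union", m))
    }
    miss <- tapply(is.na(s$concentration), s$day, mean)
    keep_days <- as.integer(names(miss)[miss <= 0.5])
    if (length(keep_days) < 4)
      stop(sprintf("insufficient data: fewer than 4 retained days for %s", m))
    s <- s[s$day %in% keep_days, ]
    obs_min <- min(s$concentration, na.rm = TRUE)
    s$concentration[is.na(s$concentration)] <- obs_min
    s$donor <- factor(s$donor)
    s$batch <- factor(s$batch)
    days <- sort(unique(s$day))
    if (stats::sd(s$concentration) < 1e-10) {
      fit_vals <- rep(mean(s$concentration), length(days))
    } else {
      kk <- if (is.null(k_basis)) min(15L, length(days) - 1L) else k_basis
      rhs <- c(sprintf("s(day, k = %d, bs = 'cr')", kk),
               if (nlevels(s$donor) > 1) "donor",
               if (nlevels(s$batch) > 1) "batch")
      fit <- mgcv::gam(stats::reformulate(rhs, response = "concentration"),
                       data = s, method = "GCV.Cp")
      terms_obs <- stats::predict(fit, type = "terms")
      par_cols <- grep("^s\\(day", colnames(terms_obs), invert = TRUE)
      offset_mean <- if (length(par_cols))
        mean(rowSums(terms_obs[, par_cols, drop = FALSE])) else 0
      nd <- data.frame(day = days,
                       donor = factor(levels(s$donor)[1],
                                      levels = levels(s$donor)),
                       batch = factor(levels(s$batch)[1],
                                      levels = levels(s$batch)))
      terms_new <- stats::predict(fit, nd, type = "terms")
      smooth_col <- grep("^s\\(day", colnames(terms_new))
      fit_vals <- as.numeric(terms_new[, smooth_col]) +
        attr(terms_obs, "constant") + offset_mean
    }
    dw <- s$dwell_hours[match(days, s$day)]
    out[[m]] <- data.frame(metabolite = m, day = days,
                           fitted_value = fit_vals, dwell_hours = dw)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Hourly rates of change from fitted concentration values
#'
#' The rate attributed to day d is the difference between the fitted values
#' at d and at the previous retained day, divided by the hours between the
#' media change preceding d and sampling at d (`dwell_hours[d]`). An increase
#' in the medium is secretion (positive), a decrease is uptake (negative).
#' The first retained day has no preceding value and carries no rate.
#'
#' @param fitted data.frame from [smooth_timecourse()] (metabolite, day,
#'   fitted_value, dwell_hours).
#' @param standardize scale each metabolite series to unit variance
#'   (recorded on the panel).
#' @return a [rate_panel()].
#' @export
compute_rates <- function(fitted, standardize = FALSE) {
  mets <- unique(fitted$metabolite)
  days_all <- sort(unique(fitted$day))
  if (length(days_all) < 2) stop("empty panel: need fitted values at >= 2 days")
  rate_days <- days_all[-1]
  rates <- matrix(NA_real_, length(rate_days), length(mets),
                  dimnames = list(rate_days, mets))
  for (m in mets) {
    f <- fitted[fitted$metabolite == m, ]
    f <- f[order(f$day), ]
    if (nrow(f) < 2)
      stop(sprintf("need fitted values at >= 2 days for %s", m))
    r <- diff(f$fitted_value) / f$dwell_hours[-1]
    rates[as.character(f$day[-1]), m] <- r
  }
  if (anyNA(rates)) stop("rate panel has missing entries; day grids differ")
  panel <- rate_panel(rate_days, mets, rates)
  if (standardize) panel <- standardize_rates(panel)
  panel
}
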