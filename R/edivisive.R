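# E-divisive multivariate change-point detection: divisive hierarchical
# segmentation by the energy-statistic divergence, with within-segment
# permutation significance testing.

#' Energy-statistic divergence between two multivariate samples
#'
#' For samples A (m x d) and B (n x d),
#' `E = 2/(mn) sum |x - y|^alpha - choose(m,2)^-1 sum |x - x'|^alpha -
#' choose(n,2)^-1 sum |y - y'|^alpha`
#' with within-sample terms defined as 0 for singletons, and the scaled
#' statistic `Q = (mn/(m+n)) * E` used in the split search.
#'
#' @param segment_a numeric matrix (rows = observations) or vector.
#' @param segment_b numeric matrix or vector of the same dimensionality.
#' @param alpha_moment energy moment index in (0, 2), default 1.
#' @return list with `e` (divergence) and `q` (scaled statistic).
#' @export
energy_divergence <- function(segment_a, segment_b, alpha_moment = 1) {
  a <- if (is.matrix(segment_a)) segment_a else matrix(segment_a, ncol = 1)
  b <- if (is.matrix(segment_b)) segment_b else matrix(segment_b, ncol = 1)
  if (ncol(a) != ncol(b)) stop("segments have different dimensionality")
  if (nrow(a) < 1 || nrow(b) < 1) stop("segments must be non-empty")
  if (alpha_moment <= 0 || alpha_moment >= 2)
    stop("alpha_moment must be in (0, 2)")
  m <- nrow(a); n <- nrow(b)
  D <- as.matrix(stats::dist(rbind(a, b)))^alpha_moment
  between <- sum(D[seq_len(m), m + seq_len(n), drop = FALSE])
  within_a <- if (m > 1) sum(D[seq_len(m), seq_len(m)]) / (m * (m - 1)) else 0
  within_b <- if (n > 1) sum(D[m + seq_len(n), m + seq_len(n)]) / (n * (n - 1)) else 0
  e <- 2 * between / (m * n) - within_a - within_b
  list(e = e, q = (m * n) / (m + n) * e)
}

#' Configuration for E-divisive change-point detection
#'
#' @param alpha_moment energy moment index in (0, 2), default 1.
#' @param sig_level permutation significance threshold (default 0.05).
#' @param n_permutations permutations per test (default 199).
#' @param min_segment minimum observations per segment (default 3; >= 2).
#' @param seed integer seed for the permutation stream.
#' @return object of class `changepoint_config`.
#' @export
changepoint_config <- function(alpha_moment = 1, sig_level = 0.05,
                               n_permutations = 199L, min_segment = 3L,
                               seed = 1L) {
  if (alpha_moment <= 0 || alpha_moment >= 2)
    stop("alpha_moment must be in (0, 2)")
  if (min_segment < 2) stop("min_segment must be >= 2")
  structure(list(alpha_moment = alpha_moment, sig_level = sig_level,
                 n_permutations = as.integer(n_permutations),
                 min_segment = as.integer(min_segment),
                 seed = as.integer(seed)),
            class = "changepoint_config")
}

# Best split of a contiguous index block [1..L] of the (already subset,
# possibly permuted) alpha-distance matrix Dss, subject to both parts having
# at least min_segment points. Uses 2-D prefix sums so each candidate split
# is O(1). Returns list(q, tau) with tau the last index of the left part, or
# q = -Inf when no admissible split exists. Ties break toward the earliest
# split.
best_split_q <- function(Dss, min_segment) {
  L <- nrow(Dss)
  if (L < 2 * min_segment) return(list(q = -Inf, tau = NA_integer_))
  P <- apply(apply(Dss, 2, cumsum), 1, cumsum)  # P[j, i] = sum Dss[1:i, 1:j]
  total <- P[L, L]
  best_q <- -Inf; best_tau <- NA_integer_
  for (tau in min_segment:(L - min_segment)) {
    m <- tau; n <- L - tau
    within_a_sum <- P[tau, tau]
    within_b_sum <- total - 2 * (P[L, tau] - P[tau, tau]) - P[tau, tau]
    between <- P[L, tau] - P[tau, tau]
    wa <- if (m > 1) within_a_sum / (m * (m - 1)) else 0
    wb <- if (n > 1) within_b_sum / (n * (n - 1)) else 0
    e <- 2 * between / (m * n) - wa - wb
    q <- (m * n) / (m + n) * e
    if (q > best_q + 1e-12) { best_q <- q; best_tau <- tau }
  }
  list(q = best_q, tau = best_tau)
}

# Best split over all current segments. segments: list of index vectors into
# D (the full alpha-distance matrix). Returns list(q, seg, tau_global).
best_split_over_segments <- function(D, segments, min_segment) {
  best <- list(q = -Inf, seg = NA_integer_, tau_global = NA_integer_)
  for (s in seq_along(segments)) {
    idx <- segments[[s]]
    sp <- best_split_q(D[idx, idx, drop = FALSE], min_segment)
    if (sp$q > best$q + 1e-12) {
      best <- list(q = sp$q, seg = s, tau_global = idx[sp$tau])
    }
  }
  best
}

#' E-divisive change-point detection on a rate panel
#'
#' Divisive hierarchical estimation: within the current segmentation, the
#' split maximizing the scaled energy divergence Q (subject to
#' `min_segment`) is proposed and assessed by a permutation test in which
#' observations are permuted independently within each current segment and
#' the best achievable Q recomputed; `p = (1 + #\{Q_perm >= Q_obs\}) /
#' (n_permutations + 1)`. Splits are accepted while `p <= sig_level`, then
#' the procedure recurses. Metabolite series are standardized to unit
#' variance first unless the panel is already standardized.
#'
#' @param panel a [rate_panel()] with at least `2 * min_segment` rows.
#' @param config a [changepoint_config()].
#' @param standardize scale columns to unit variance before analysis
#'   (ignored if the panel is already standardized).
#' @return object of class `changepoint_result`: `change_days` (day labels
#'   starting each new phase), `p_values` (permutation p per accepted
#'   split, in acceptance order), `phases` (data.frame phase/start_day/
#'   end_day partitioning the day range).
#' @export
edivisive <- function(panel, config = changepoint_config(),
                      standardize = TRUE) {
  stopifnot(inherits(panel, "rate_panel"),
            inherits(config, "changepoint_config"))
  if (standardize && !panel$standardized) panel <- standardize_rates(panel)
  X <- panel$rates
  T_ <- nrow(X)
  if (T_ < 2 * config$min_segment)
    stop("panel too short for min_segment")
  set.seed(config$seed)
  D <- as.matrix(stats::dist(X))^config$alpha_moment
  segments <- list(seq_len(T_))
  change_idx <- integer(0); p_values <- numeric(0)
  repeat {
    obs <- best_split_over_segments(D, segments, config$min_segment)
    if (!is.finite(obs$q) || obs$q <= 0) break
    exceed <- 0L
    for (b in seq_len(config$n_permutations)) {
      perm <- unlist(lapply(segments, function(idx) idx[sample.int(length(idx))]),
                     use.names = FALSE)
      # segments keep their positions; observations shuffled within each
      perm_segments <- segments
      pos <- 1L
      for (s in seq_along(segments)) {
        len <- length(segments[[s]])
        perm_segments[[s]] <- perm[pos:(pos + len - 1L)]
        pos <- pos + len
      }
      qp <- best_split_over_segments(D, perm_segments, config$min_segment)$q
      if (qp >= obs$q - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (config$n_permutations + 1)
    if (p > config$sig_level) break
    # accept: split the segment at tau_global
    idx <- segments[[obs$seg]]
    cut <- match(obs$tau_global, idx)
    segments[[obs$seg]] <- idx[seq_len(cut)]
    segments[[length(segments) + 1L]] <- idx[(cut + 1L):length(idx)]
    segments <- segments[order(vapply(segments, min, 0L))]
    change_idx <- c(change_idx, obs$tau_global + 1L)
    p_values <- c(p_values, p)
  }
  ord <- order(change_idx)
  change_days <- panel$days[change_idx][ord]
  starts <- c(panel$days[1], change_days)
  ends <- c(change_days - 1L, panel$days[T_])
  # phase end = day before the next change day, except the final phase
  if (length(change_days))
    ends[seq_along(change_days)] <-
      panel$days[match(change_days, panel$days) - 1L]
  phases <- data.frame(phase = seq_along(starts), start_day = starts,
                       end_day = ends)
  structure(list(change_days = change_days, p_values = p_values[ord],
                 phases = phases),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  if (length(x$change_days)) {
    cat(sprintf("%d change point(s) at day(s) %s (p = %s)\n",
                length(x$change_days), paste(x$change_days, collapse = ", "),
                paste(signif(x$p_values, 3), collapse = ", ")))
  } else cat("no significant change points\n")
  invisible(x)
}
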