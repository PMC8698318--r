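# Natural-abundance correction of isotopologue distributions and mean
# label enrichment.

#' Build a natural-abundance correction matrix
#'
#' Lower-triangular (n+1) x (n+1) matrix whose entry (i, j) (0-based mass
#' shifts) is the probability that a molecule with j tracer-labeled carbons
#' is observed at mass shift i through natural 13C on its n - j unlabeled
#' positions: `choose(n - j, i - j) * p^(i-j) * (1-p)^(n-i)`. Columns are
#' probability distributions. `p = 0` yields the identity. An optional
#' tracer purity < 1 composes a second (upper-triangular) binomial matrix in
#' which each nominally labeled position carries label with probability
#' `tracer_purity`.
#'
#' @param n_atoms number of traced atoms (carbons), >= 1.
#' @param natural_abundance isotope natural abundance p in [0, 1)
#'   (13C default 0.0107; use 0.00364 for 15N with `n_atoms` = nitrogen
#'   count).
#' @param tracer_purity isotopic purity of the tracer, default 1.
#' @return object of class `correction_matrix` with fields `n_atoms`,
#'   `natural_abundance`, `tracer_purity`, `matrix`.
#' @export
build_correction_matrix <- function(n_atoms, natural_abundance = 0.0107,
                                    tracer_purity = 1) {
  if (n_atoms < 1) stop("n_atoms must be >= 1")
  p <- natural_abundance
  if (p < 0 || p >= 1) stop("natural_abundance must be in [0, 1)")
  if (tracer_purity <= 0 || tracer_purity > 1)
    stop("tracer_purity must be in (0, 1]")
  n <- as.integer(n_atoms)
  idx <- 0:n
  cm <- outer(idx, idx, function(i, j)
    ifelse(i >= j, choose(n - j, i - j) * p^(i - j) * (1 - p)^(n - i), 0))
  if (tracer_purity < 1) {
    pi_ <- tracer_purity
    pur <- outer(idx, idx, function(i, j)
      ifelse(i <= j, choose(j, i) * pi_^i * (1 - pi_)^(j - i), 0))
    cm <- cm %*% pur
  }
  dimnames(cm) <- list(paste0("M+", idx), paste0("M+", idx))
  structure(list(n_atoms = n, natural_abundance = p,
                 tracer_purity = tracer_purity, matrix = cm),
            class = "correction_matrix")
}

#' Correct a raw isotopologue intensity vector for natural abundance
#'
#' Solves `raw ~ M x` by non-negative least squares (robust to noise-induced
#' negative solutions from direct inversion), renormalizes x to sum 1, and
#' computes mean label enrichment.
#'
#' @param raw non-negative intensity vector of length `n_atoms + 1`
#'   (mass shifts 0..n), arbitrary units.
#' @param cm a [build_correction_matrix()] result.
#' @return object of class `isotopologue_vector`: `n_atoms`, `raw`,
#'   `corrected` (fractions summing to 1), `mean_enrichment`.
#' @export
correct_distribution <- function(raw, cm) {
  stopifnot(inherits(cm, "correction_matrix"))
  n <- cm$n_atoms
  if (length(raw) != n + 1L)
    stop(sprintf("raw vector has length %d, expected %d", length(raw), n + 1L))
  if (any(raw < 0)) stop("raw intensities must be non-negative")
  if (sum(raw) <= 0) stop("all-zero raw intensity vector")
  scale <- sum(raw)
  x <- pracma::lsqnonneg(cm$matrix, raw / scale)$x
  if (sum(x) <= 0) stop("degenerate NNLS solution")
  x <- x / sum(x)
  structure(list(n_atoms = n, raw = raw, corrected = x,
                 mean_enrichment = mean_enrichment(x, n)),
            class = "isotopologue_vector")
}

#' Mean label enrichment of a corrected isotopologue distribution
#'
#' Fraction of traced atom positions carrying label:
#' `sum(i * x_i) / n` over mass shifts i = 0..n. Invariant to uniform
#' scaling of the fractions (they are renormalized).
#'
#' @param fractions non-negative isotopologue fractions, length `n_atoms + 1`.
#' @param n_atoms traced atom count.
#' @return enrichment in [0, 1].
#' @export
mean_enrichment <- function(fractions, n_atoms) {
  if (length(fractions) != n_atoms + 1L)
    stop("fractions must have length n_atoms + 1")
  if (any(fractions < -1e-12)) stop("negative fraction")
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (s <= 0) stop("all-zero fractions")
  sum((0:n_atoms) * fractions / s) / n_atoms
}

#' Extract a single isotopologue fraction
#'
#' Mass-shift fractions such as M+6 (hexose moiety, glycolytic proxy) and
#' M+11 (hexose + ribose, pentose-phosphate proxy) of UDP-glucose.
#'
#' @param corrected corrected fractions, length n+1 (mass shifts 0..n).
#' @param index mass shift, 0-based.
#' @return the fraction at `index`.
#' @export
isotopologue_fraction <- function(corrected, index) {
  n <- length(corrected) - 1L
  if (index < 0 || index > n) stop("mass-shift index out of range")
  corrected[[index + 1L]]
}

#' Normalize an intensity by protein content
#'
#' @param intensity measured intensity (arbitrary units).
#' @param protein_ug protein amount from a BCA assay, micrograms (> 0).
#' @return intensity per microgram protein.
#' @export
normalize_by_protein <- function(intensity, protein_ug) {
  if (any(protein_ug <= 0)) stop("protein_ug must be > 0")
  intensity / protein_ug
}

#' Correct a long-format isotopologue intensity table
#'
#' Applies [correct_distribution()] per (metabolite, day, replicate) group
#' and reports corrected fractions, mean enrichment and protein-normalized
#' total intensity.
#'
#' @param intensities data.frame with columns metabolite, day, replicate,
#'   mass_shift, intensity, protein_ug.
#' @param natural_abundance natural abundance p.
#' @param tracer_purity tracer purity, default 1.
#' @return list with `corrected` (long data.frame: metabolite, day,
#'   replicate, mass_shift, fraction) and `enrichment` (one row per group:
#'   metabolite, day, replicate, mean_enrichment,
#'   total_intensity_per_ug).
#' @export
correct_isotopologue_table <- function(intensities, natural_abundance = 0.0107,
                                       tracer_purity = 1) {
  need <- c("metabolite", "day", "replicate", "mass_shift", "intensity",
            "protein_ug")
  if (!all(need %in% names(intensities)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(intensities$metabolite, intensities$day,
                     intensities$replicate, drop = TRUE)
  corrected <- list(); enr <- list()
  cms <- list()
  for (g in split(intensities, key)) {
    g <- g[order(g$mass_shift), ]
    n <- max(g$mass_shift)
    m <- as.character(g$metabolite[1])
    cm_key <- as.character(n)
    if (is.null(cms[[cm_key]]))
      cms[[cm_key]] <- build_correction_matrix(n, natural_abundance,
                                               tracer_purity)
    iv <- correct_distribution(g$intensity, cms[[cm_key]])
    corrected[[length(corrected) + 1L]] <- data.frame(
      metabolite = m, day = g$day[1], replicate = g$replicate[1],
      mass_shift = 0:n, fraction = iv$corrected)
    enr[[length(enr) + 1L]] <- data.frame(
      metabolite = m, day = g$day[1], replicate = g$replicate[1],
      mean_enrichment = iv$mean_enrichment,
      total_intensity_per_ug = normalize_by_protein(sum(g$intensity),
                                                    g$protein_ug[1]))
  }
  list(corrected = do.call(rbind, corrected),
       enrichment = do.call(rbind, enr))
}
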