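#' One-parameter mass law for a polyprotein family
#'
#' For mechanically labile cargos the population import rate scales with
#' the domain count as \eqn{k_I(N) = A/N} (sequential "mass law"). This
#' fits the single amplitude A by weighted least squares (weights
#' `1/sem^2`) over the family's records and reports each record's deviation
#' from the law in units of its SEM -- the diagnostic used to spot
#' mechanically suppressed low-mass constructs.
#'
#' @param records Data.frame for one protein family with columns
#'   `n_domains`, `ki_mean_ks` and optionally `ki_sem_ks`, `mass_kda`,
#'   `name` (see [construct_table()]).
#' @return List with `A` (amplitude, ks^-1), `deviations` (data.frame with
#'   per-record fitted value, residual and `dev_sem` = residual/SEM) and
#'   `rss`.
#' @export
fit_mass_law <- function(records) {
  stopifnot(all(c("n_domains", "ki_mean_ks") %in% names(records)))
  if (length(unique(records$n_domains)) < 2) {
    stop("mass-law fit needs records at >= 2 distinct N")
  }
  sem <- if ("ki_sem_ks" %in% names(records)) records$ki_sem_ks else rep(NA_real_, nrow(records))
  w <- ifelse(is.na(sem) | sem <= 0, 1, 1 / sem^2)
  x <- 1 / records$n_domains
  A <- sum(w * x * records$ki_mean_ks) / sum(w * x^2)
  fitted <- A * x
  resid <- records$ki_mean_ks - fitted
  dev <- ifelse(is.na(sem) | sem <= 0, NA_real_, resid / sem)
  out <- data.frame(records, fitted = fitted, residual = resid,
                    dev_sem = dev, stringsAsFactors = FALSE)
  list(A = A, deviations = out, rss = sum(w * resid^2))
}

#' Relative acceleration of a variant over a reference construct
#'
#' Percent change of the import rate,
#' \eqn{100 (k_I^{variant}/k_I^{reference} - 1)}, e.g. the acceleration
#' gained by adding an N-terminal soft domain or unstructured tag.
#'
#' @param kI_variant,kI_reference Import rates, ks^-1 (> 0).
#' @param round_pct Round to the nearest integer percent (half away from
#'   zero) for caption-style reporting; the raw value is always returned
#'   alongside.
#' @return List with `percent` (possibly rounded) and `raw` (unrounded
#'   percent).
#' @export
relative_acceleration <- function(kI_variant, kI_reference, round_pct = TRUE) {
  if (kI_variant <= 0 || kI_reference <= 0) stop("rates must be positive")
  raw <- 100 * (kI_variant / kI_reference - 1)
  pct <- if (round_pct) sign(raw) * floor(abs(raw) + 0.5) else raw
  list(percent = pct, raw = raw)
}

#' Mechano-directionality ratio
#'
#' Ratio of the import rate of the construct whose mechanically soft
#' domain leads (is adjacent to the NLS) to that of the mirrored construct
#' with the stiff domain leading. A ratio above 1 quantifies the pore's
#' preference for soft leading regions. SEM is propagated in quadrature on
#' the relative errors when SEMs are supplied.
#'
#' @param kI_soft_leading,kI_stiff_leading Import rates, ks^-1 (> 0).
#' @param sem_soft,sem_stiff Optional SEMs for error propagation.
#' @return List with `ratio` and `sem` (`NA` without input SEMs).
#' @export
directionality_ratio <- function(kI_soft_leading, kI_stiff_leading,
                                 sem_soft = NA_real_, sem_stiff = NA_real_) {
  if (kI_stiff_leading <= 0) stop("denominator rate must be positive")
  if (kI_soft_leading <= 0) stop("numerator rate must be positive")
  r <- kI_soft_leading / kI_stiff_leading
  s <- if (is.na(sem_soft) || is.na(sem_stiff)) NA_real_ else {
    r * sqrt((sem_soft / kI_soft_leading)^2 + (sem_stiff / kI_stiff_leading)^2)
  }
  list(ratio = r, sem = s)
}

#' Transport free-energy surface
#'
#' Maps each construct's import rate to an apparent free-energy difference
#' (in kT units) relative to a reference construct:
#' \deqn{\Delta G(M, F_U) = -\ln\left(k_I(M, F_U) / k_I^{ref}\right)}
#' so that faster-importing constructs sit at negative \eqn{\Delta G}. The
#' points are coordinates in the (mass, unfolding force) plane; an optional
#' bilinear interpolation onto a regular grid is provided for surface
#' visualization.
#'
#' @param records Data.frame with columns `mass_kda`,
#'   `unfolding_force_pn`, `ki_mean_ks` (and optionally `name`).
#' @param reference_kI Reference import rate, ks^-1 (> 0), e.g. the rate of
#'   the soft monomer.
#' @param grid_n Number of grid points per axis for the interpolated
#'   surface; `0` skips interpolation.
#' @return List with `points` (records plus `dG` column, kT units) and
#'   `grid` (`NULL`, or list `M`, `FU`, `dG` matrix from inverse-distance
#'   interpolation of the scattered points).
#' @export
free_energy_surface <- function(records, reference_kI, grid_n = 0) {
  if (reference_kI <= 0) stop("reference_kI must be positive")
  stopifnot(all(c("mass_kda", "unfolding_force_pn", "ki_mean_ks") %in%
                  names(records)))
  pts <- data.frame(records,
                    dG = -log(records$ki_mean_ks / reference_kI),
                    stringsAsFactors = FALSE)
  grid <- NULL
  if (grid_n > 0 && nrow(pts) >= 3) {
    M <- seq(min(pts$mass_kda), max(pts$mass_kda), length.out = grid_n)
    FU <- seq(min(pts$unfolding_force_pn), max(pts$unfolding_force_pn),
              length.out = grid_n)
    # inverse-distance weighting on standardized coordinates: simple,
    # exact at the data points, adequate for a visualization surface
    sm <- stats::sd(pts$mass_kda)
    sf <- stats::sd(pts$unfolding_force_pn)
    z <- outer(seq_along(M), seq_along(FU), Vectorize(function(i, j) {
      d2 <- ((M[i] - pts$mass_kda) / sm)^2 +
        ((FU[j] - pts$unfolding_force_pn) / sf)^2
      if (any(d2 < 1e-12)) return(pts$dG[which.min(d2)])
      w <- 1 / d2
      sum(w * pts$dG) / sum(w)
    }))
    grid <- list(M = M, FU = FU, dG = z)
  }
  list(points = pts, grid = grid)
}

#' Mass threshold below which mechanics dominates import
#'
#' Operationalizes the mass-threshold concept. Deviations from the mass
#' law emerge at *low* mass (where mechanical stability, not mass, limits
#' import), so the law is anchored on the mass-dominated regime: the fit
#' starts from the two largest-N records and grows downward, absorbing
#' each next record while it stays within `deviation_sd` SEMs of the
#' current law. The remaining low-N records that fall below the anchored
#' law by more than `deviation_sd` SEMs are flagged, and the threshold is
#' the largest flagged mass; `NULL` when no record deviates. (A global
#' weighted fit would let the deviant points drag the law toward
#' themselves and mask the threshold.)
#'
#' @inheritParams fit_mass_law
#' @param deviation_sd Required deviation in SEM units (default 2;
#'   configurable, this rule is this package's operationalization of a
#'   qualitative concept).
#' @return List with `threshold_mass_kda` (or `NULL`), `flagged`
#'   (sub-law records), `anchor` (records supporting the law) and the
#'   anchored `fit`. Warns when every non-anchor record deviates (the law
#'   holds only in the anchor range).
#' @export
mass_threshold <- function(records, deviation_sd = 2) {
  stopifnot(all(c("n_domains", "ki_mean_ks", "mass_kda") %in% names(records)))
  if (length(unique(records$n_domains)) < 2) {
    stop("mass-threshold analysis needs records at >= 2 distinct N")
  }
  ord <- order(records$n_domains, decreasing = TRUE)
  rec <- records[ord, , drop = FALSE]
  anchor <- 1:2
  while (max(anchor) < nrow(rec)) {
    fit <- fit_mass_law(rec[anchor, , drop = FALSE])
    nxt <- max(anchor) + 1
    sem <- rec$ki_sem_ks[nxt]
    pred <- fit$A / rec$n_domains[nxt]
    dev <- if (is.na(sem) || sem <= 0) 0 else (rec$ki_mean_ks[nxt] - pred) / sem
    if (abs(dev) > deviation_sd) break
    anchor <- c(anchor, nxt)
  }
  fit <- fit_mass_law(rec[anchor, , drop = FALSE])
  pred <- fit$A / rec$n_domains
  sem <- rec$ki_sem_ks
  dev <- ifelse(is.na(sem) | sem <= 0, NA_real_,
                (rec$ki_mean_ks - pred) / sem)
  rest <- setdiff(seq_len(nrow(rec)), anchor)
  flagged <- rec[rest[!is.na(dev[rest]) & dev[rest] < -deviation_sd], ,
                 drop = FALSE]
  if (nrow(flagged) == 0) {
    return(list(threshold_mass_kda = NULL, flagged = flagged,
                anchor = rec[anchor, , drop = FALSE], fit = fit))
  }
  if (nrow(flagged) == length(rest)) {
    warning("every record outside the anchor deviates below the mass law")
  }
  list(threshold_mass_kda = max(flagged$mass_kda), flagged = flagged,
       anchor = rec[anchor, , drop = FALSE], fit = fit)
}
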