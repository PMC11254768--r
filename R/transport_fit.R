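# Fit bounds (rates in ks^-1); chosen wide enough that real fits sit in the
# interior -- a fit pinned at a bound is flagged unphysical downstream.
.KI_MAX <- 50
.KE_ACC_MAX <- 100

#' Fitted recovery kinetics for one cell
#'
#' Container for the result of [fit_recovery()] / [fit_export()]: the kinetic
#' parameters, the initial-condition correction, diagnostics and QC flags.
#'
#' @param cell_id Cell identifier.
#' @param Ke,kI,kE Fitted accumulation and rate constants (ks^-1 for rates);
#'   `kE` is `NA` for the import-only model.
#' @param v Volume ratio used (fixed, never fitted).
#' @param n0 Residual-activation amplitude removed by the correction (a.u.).
#' @param k_act Activation-phase export rate (ks^-1), filled in by
#'   [activation_qc()]; `NA` until then.
#' @param rss Residual sum of squares of the ratio fit.
#' @param converged Logical; `FALSE` marks a degenerate or failed fit.
#' @param qc_flags Character vector, subset of
#'   `c("unphysical", "gesd_outlier", "poor_activation", "manual_reject")`.
#' @return An object of class `recovery_fit`.
#' @export
recovery_fit <- function(cell_id, Ke = NA_real_, kI = NA_real_, kE = NA_real_,
                         v = NA_real_, n0 = NA_real_, k_act = NA_real_,
                         rss = NA_real_, converged = FALSE,
                         qc_flags = character()) {
  structure(list(cell_id = as.character(cell_id), Ke = Ke, kI = kI, kE = kE,
                 v = v, n0 = n0, k_act = k_act, rss = rss,
                 converged = isTRUE(converged),
                 qc_flags = unique(as.character(qc_flags))),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> %s: Ke = %.4g, kI = %.4g ks^-1, kE = %.4g ks^-1, converged = %s%s\n",
              x$cell_id, x$Ke, x$kI, x$kE, x$converged,
              if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ";"), "]") else ""))
  invisible(x)
}

#' Is a fit retained after filtering?
#'
#' A cell is retained iff its fit converged and carries no QC flags.
#' @param fit A [recovery_fit()].
#' @return Logical scalar.
#' @export
is_retained <- function(fit) {
  fit$converged && length(fit$qc_flags) == 0
}

# Shared-rate bi-exponential n0*exp(-kt) + ne*(1-exp(-kt)) fitted by bounded
# nonlinear least squares; k in s^-1 internally.
.fit_biexp <- function(t, y) {
  rng <- max(y) - min(y)
  st <- list(n0 = max(y[1], 1e-8), ne = max(y[length(y)], 1e-8), k = 1e-3)
  fit <- tryCatch(
    stats::nls(y ~ n0 * exp(-k * t) + ne * (1 - exp(-k * t)),
               start = st, algorithm = "port",
               lower = c(n0 = 0, ne = 1e-12, k = 1e-8),
               upper = c(n0 = Inf, ne = Inf, k = 1),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  list(n0 = unname(cf["n0"]), ne = unname(cf["ne"]),
       k = unname(cf["k"]) * .KS, rss = sum(resid(fit)^2))
}

#' Correct the initial conditions of a recovery-phase nuclear signal
#'
#' At the start of the dark recovery phase a cell may retain a residual
#' nuclear pool (incomplete activation). Following the shared-rate
#' correction model, the raw recovery nuclear signal is fitted to
#' \eqn{n_0 e^{-kt} + n_e (1 - e^{-kt})} and the decaying residual
#' \eqn{n_0 e^{-kt}} is subtracted pointwise, so the corrected series
#' starts at (approximately) zero.
#'
#' @param trace A [cell_trace()] with recovery frames (import direction uses
#'   the nuclear signal; export uses the cytoplasmic signal, see
#'   [fit_export()]).
#' @param signal Which compartment signal to correct: `"nuc"` (default) or
#'   `"cyt"` (`cell - nuc`).
#' @return List with `time` (recovery clock, s), `corrected` (signal with
#'   the residual removed), `n0`, `ne`, `k` (shared rate, ks^-1), and
#'   `converged`. On non-convergence the signal is passed through
#'   uncorrected with `converged = FALSE`.
#' @export
correct_initial_conditions <- function(trace, signal = c("nuc", "cyt")) {
  signal <- match.arg(signal)
  rec <- recovery_frames(trace)
  y <- if (signal == "nuc") rec$nuc else rec$cell - rec$nuc
  fit <- .fit_biexp(rec$time, y)
  if (is.null(fit)) {
    return(list(time = rec$time, corrected = y, n0 = NA_real_,
                ne = NA_real_, k = NA_real_, converged = FALSE))
  }
  corrected <- y - fit$n0 * exp(-(fit$k / .KS) * rec$time)
  list(time = rec$time, corrected = corrected, n0 = fit$n0, ne = fit$ne,
       k = fit$k, converged = TRUE)
}

# Bounded NLS of the ratio curve to the compartmental model; returns NULL on
# failure. `v` is fixed (never a free parameter: v and Ke are collinear).
.fit_ratio_curve <- function(t, r, v) {
  st <- list(Ke = min(max(r[length(r)], 0.05), .KE_ACC_MAX / 2), kI = 1)
  fit <- tryCatch(
    stats::nls(r ~ Ke * (1 - exp(-kI / 1000 * t)) /
                 (1 + v * Ke * exp(-kI / 1000 * t)),
               start = st, algorithm = "port",
               lower = c(Ke = 1e-6, kI = 1e-6),
               upper = c(Ke = .KE_ACC_MAX, kI = .KI_MAX),
               control = stats::nls.control(maxiter = 200,
                                            tol = 1e-10, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  Ke <- unname(cf["Ke"])
  kI <- unname(cf["kI"])
  # a parameter pinned at a bound is a degenerate fit (e.g. a trace already
  # at steady state pushes the rate to its ceiling)
  if (kI >= .KI_MAX * (1 - 1e-3) || Ke >= .KE_ACC_MAX * (1 - 1e-3) ||
      kI <= 2e-6 || Ke <= 2e-6) {
    return(NULL)
  }
  list(Ke = Ke, kI = kI, rss = sum(resid(fit)^2))
}

#' Fit the import recovery of a single cell
#'
#' Builds the nucleus-to-cytoplasm ratio from the corrected signals
#' (cytoplasm = whole-cell minus raw nuclear signal; nuclear signal has its
#' activation residual subtracted by [correct_initial_conditions()]) and
#' performs a bounded nonlinear least-squares fit of the import-only
#' compartmental model. `Ke` and `kI` are independent free parameters; the
#' volume ratio `v` is fixed per cell.
#'
#' For `direction = "coupled"` traces the same two-parameter fit applies,
#' but the fitted pair are the aggregates (Ke_hat = kI/kE, k_hat = kE + v kI);
#' pass them through [rates_from_coupled_fit()] to recover the physical
#' rates.
#'
#' @param trace A [cell_trace()] of direction `"import"` (or `"coupled"`).
#' @param v Nucleus-to-cytoplasm volume ratio; default taken from the trace
#'   attribute, falling back to 0.25.
#' @param correct Apply the initial-condition correction (default `TRUE`).
#' @return A [recovery_fit()]. Non-convergence yields `converged = FALSE`
#'   and the `"unphysical"` flag rather than an error.
#' @export
fit_recovery <- function(trace, v = NULL, correct = TRUE) {
  stopifnot(inherits(trace, "cell_trace"))
  if (!attr(trace, "direction") %in% c("import", "coupled")) {
    stop("fit_recovery() expects an import-direction trace; use fit_export()")
  }
  v <- .resolve_v(trace, v)
  rec <- recovery_frames(trace)
  n0 <- 0
  nuc <- rec$nuc
  if (correct) {
    corr <- correct_initial_conditions(trace, "nuc")
    if (corr$converged) {
      nuc <- corr$corrected
      n0 <- corr$n0
    }
  }
  cyt <- rec$cell - rec$nuc
  ok <- cyt > 0
  ratio <- nuc[ok] / cyt[ok]
  fit <- if (sum(ok) >= 3) .fit_ratio_curve(rec$time[ok], ratio, v) else NULL
  if (is.null(fit)) {
    return(recovery_fit(attr(trace, "cell_id"), v = v, n0 = n0,
                        converged = FALSE, qc_flags = "unphysical"))
  }
  recovery_fit(attr(trace, "cell_id"), Ke = fit$Ke, kI = fit$kI, v = v,
               n0 = n0, rss = fit$rss, converged = TRUE)
}

#' Fit the export recovery of a single cell
#'
#' For export-direction traces (NES-driven exclusion after light off) the
#' model is mirrored: the cytoplasm-to-nucleus ratio is fitted with the
#' compartment roles swapped and the volume ratio inverted. The fitted rate
#' is reported in the `kE` slot.
#'
#' @inheritParams fit_recovery
#' @return A [recovery_fit()] with the export rate constant in `kE` and the
#'   cytoplasm-to-nucleus accumulation in `Ke`.
#' @export
fit_export <- function(trace, v = NULL, correct = TRUE) {
  stopifnot(inherits(trace, "cell_trace"))
  if (attr(trace, "direction") != "export") {
    stop("fit_export() expects an export-direction trace")
  }
  v <- .resolve_v(trace, v)
  rec <- recovery_frames(trace)
  n0 <- 0
  cyt <- rec$cell - rec$nuc
  if (any(rec$nuc <= 0)) {
    return(recovery_fit(attr(trace, "cell_id"), v = v,
                        converged = FALSE, qc_flags = "unphysical"))
  }
  ccyt <- cyt
  if (correct) {
    corr <- correct_initial_conditions(trace, "cyt")
    if (corr$converged) {
      ccyt <- corr$corrected
      n0 <- corr$n0
    }
  }
  ratio <- ccyt / rec$nuc
  fit <- .fit_ratio_curve(rec$time, ratio, 1 / v)
  if (is.null(fit)) {
    return(recovery_fit(attr(trace, "cell_id"), v = v, n0 = n0,
                        converged = FALSE, qc_flags = "unphysical"))
  }
  recovery_fit(attr(trace, "cell_id"), Ke = fit$Ke, kE = fit$kI, v = v,
               n0 = n0, rss = fit$rss, converged = TRUE)
}

.resolve_v <- function(trace, v) {
  if (is.null(v)) v <- attr(trace, "v")
  if (is.null(v) || is.na(v)) v <- 0.25
  if (v <= 0) stop("volume ratio v must be positive")
  v
}

#' Tabulate / write a collection of recovery fits
#'
#' @param fits List of [recovery_fit()] objects.
#' @return `fits_table()` returns a data.frame with one row per cell
#'   (`qc_flags` semicolon-joined); `write_fits()` writes it as CSV and
#'   returns the path invisibly.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id, Ke = f$Ke, kI = f$kI, kE = f$kE,
               v = f$v, n0 = f$n0, k_act = f$k_act, rss = f$rss,
               converged = f$converged,
               qc_flags = paste(f$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' @param path CSV file path.
#' @rdname fits_table
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits_table(fits), path, row.names = FALSE)
  invisible(path)
}
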