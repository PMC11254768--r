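#' nucshuttle: nucleocytoplasmic transport kinetics and polyprotein unfolding
#'
#' Tools to quantify how fast protein cargos shuttle across the nuclear pore
#' complex, and how that speed depends on cargo mass and local mechanical
#' stability. The package covers (i) a two-compartment import/export model
#' fitted to single-cell optogenetic recovery curves, (ii) a three-step cell
#' quality-control protocol, (iii) a force-clamp polyprotein unfolding
#' simulator with step detection and stochastic-vs-sequential scaling fits,
#' (iv) polymer-elasticity conversions (freely jointed chain, worm-like
#' chain), (v) cross-construct mechanoselectivity statistics including a
#' transport free-energy surface, and (vi) a synthetic-data generator that
#' emulates the raw inputs with known ground truth.
#'
#' Rates are reported in ks^-1 (events per 1000 s) throughout, matching the
#' convention of live-cell import kinetics; time vectors are in seconds.
#'
#' @keywords internal
#' @importFrom stats nls coef optim rnorm rlnorm runif rexp sd median
#'   setNames complete.cases wilcox.test approx quantile var predict
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

# rates are stored in ks^-1; internal kinetics run in s^-1
.KS <- 1000

#' Nucleus-to-cytoplasm ratio under import-only first-order kinetics
#'
#' Evaluates the recovery time course of the nucleus-to-cytoplasm
#' concentration ratio for a cargo that is actively imported (no active
#' export, as for an optogenetic probe whose NES is docked in the dark):
#' \deqn{[N]/[C](t) = \frac{K_e (1 - e^{-k_I t})}{1 + v K_e e^{-k_I t}}}
#' where \eqn{K_e} is the steady-state nucleus-to-cytoplasm accumulation,
#' \eqn{k_I} the import rate constant and \eqn{v} the nucleus-to-cytoplasm
#' volume ratio coupling the two compartments.
#'
#' @param t Time since the start of the recovery phase, seconds. Vectorized.
#' @param Ke Steady-state nucleus-to-cytoplasm accumulation (dimensionless,
#'   > 0).
#' @param kI Import rate constant in ks^-1 (> 0).
#' @param v Nucleus-to-cytoplasm volume ratio (>= 0; `v = 0` is accepted as
#'   the degenerate constant-cytoplasm limit).
#' @return Numeric vector of ratios, one per element of `t`. Starts at 0 at
#'   `t = 0` and saturates at `Ke`.
#' @seealso [nc_ratio_model_coupled()] for the import+export form,
#'   [fit_recovery()] to fit this model to a measured trace.
#' @examples
#' nc_ratio_model(c(0, 600, 1e6), Ke = 2, kI = 1.62, v = 0.5)
#' @export
nc_ratio_model <- function(t, Ke, kI, v) {
  stopifnot(length(Ke) == 1, length(kI) == 1, length(v) == 1)
  if (any(t < 0)) stop("time must be non-negative")
  if (Ke <= 0 || kI <= 0 || v < 0) {
    stop("Ke and kI must be positive and v non-negative")
  }
  decay <- exp(-(kI / .KS) * t)
  Ke * (1 - decay) / (1 + v * Ke * decay)
}

#' Nucleus-to-cytoplasm ratio with simultaneous import and export
#'
#' Same functional form as [nc_ratio_model()] but for a cargo with
#' non-negligible active export (e.g. MRTFA under serum stimulation), where
#' the aggregate parameters are \eqn{K_e = k_I / k_E} and the relaxation
#' rate \eqn{k = k_E + v k_I}.
#'
#' @inheritParams nc_ratio_model
#' @param kI,kE Import and export rate constants, ks^-1 (both > 0).
#' @return Numeric vector of ratios.
#' @seealso [rates_from_coupled_fit()] to invert the aggregate parameters.
#' @export
nc_ratio_model_coupled <- function(t, kI, kE, v) {
  if (kE <= 0) stop("kE must be positive; use nc_ratio_model() when export is absent")
  if (kI <= 0 || v < 0) stop("kI must be positive and v non-negative")
  nc_ratio_model(t, Ke = kI / kE, kI = kE + v * kI, v = v)
}

#' Recover (kI, kE) from the aggregate coupled-model parameters
#'
#' A fit of the coupled recovery curve yields the aggregates
#' \eqn{\hat K_e = k_I/k_E} and \eqn{\hat k = k_E + v k_I}. This solves the
#' 2x2 system back for the physical rates:
#' \eqn{k_I = \hat k \hat K_e / (1 + v \hat K_e)},
#' \eqn{k_E = \hat k / (1 + v \hat K_e)}.
#'
#' @param Ke_hat Fitted accumulation aggregate (> 0).
#' @param k_hat Fitted relaxation rate aggregate, ks^-1 (> 0).
#' @param v Nucleus-to-cytoplasm volume ratio (>= 0).
#' @return Named numeric vector `c(kI = , kE = )` in ks^-1.
#' @examples
#' rates_from_coupled_fit(Ke_hat = 2, k_hat = 2, v = 0.5) # kI = 2, kE = 1
#' @export
rates_from_coupled_fit <- function(Ke_hat, k_hat, v) {
  if (Ke_hat <= 0 || k_hat <= 0 || v < 0) {
    stop("Ke_hat and k_hat must be positive and v non-negative")
  }
  kE <- k_hat / (1 + v * Ke_hat)
  c(kI = kE * Ke_hat, kE = kE)
}

#' Normalized import rate of a test channel against an internal reference
#'
#' Ratio of the import rate fitted on the construct of interest (GFP
#' channel) to the rate of a co-transfected reference construct (mCherry
#' channel) in the same cell, removing cell-to-cell variability.
#'
#' @param kI_gfp,kI_mcherry Import rate constants, ks^-1 (both > 0).
#' @return Dimensionless normalized rate `kI_gfp / kI_mcherry`.
#' @export
normalized_import_rate <- function(kI_gfp, kI_mcherry) {
  if (any(kI_gfp <= 0) || any(kI_mcherry <= 0)) {
    stop("rates must be positive")
  }
  kI_gfp / kI_mcherry
}
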