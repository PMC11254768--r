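#' Polymer elasticity model parameters
#'
#' Holds the stiffness parameters used to interconvert forces, extensions
#' and contour lengths of an unfolded polypeptide: the Kuhn length `b` of
#' the freely jointed chain (FJC), the persistence length `p` of the
#' worm-like chain (WLC), the thermal energy `kT` and, for the WLC force
#' law, the contour length `Lc`.
#'
#' @param b Kuhn length, nm (default 1.1, the value used for polypeptides
#'   in magnetic-tweezers step-size conversions).
#' @param p Persistence length, nm (default 0.4, typical for an unfolded
#'   protein chain).
#' @param kT Thermal energy, pN nm (default 4.114, T = 298 K).
#' @param Lc Contour length, nm (needed by [wlc_force()]).
#' @return List of class `polymer_model`.
#' @export
polymer_model <- function(b = 1.1, p = 0.4, kT = 4.114, Lc = NA_real_) {
  if (b <= 0 || p <= 0 || kT <= 0 || (!is.na(Lc) && Lc <= 0)) {
    stop("all polymer parameters must be positive")
  }
  structure(list(b = b, p = p, kT = kT, Lc = Lc), class = "polymer_model")
}

#' Fractional extension of a freely jointed chain
#'
#' Langevin function of the reduced force:
#' \deqn{x/L_c = \coth(Fb/kT) - kT/(Fb)}
#' giving the end-to-end extension as a fraction of contour length for a
#' chain of Kuhn length `b` held at force `F`.
#'
#' @param F Force, pN (> 0; vectorized).
#' @param model A [polymer_model()].
#' @return Fractional extension in (0, 1).
#' @export
fjc_extension_fraction <- function(F, model = polymer_model()) {
  if (any(F <= 0)) stop("force must be positive")
  x <- F * model$b / model$kT
  # coth(x) - 1/x, stable for large and small x
  ifelse(x > 20, 1 - 1 / x, 1 / tanh(x) - 1 / x)
}

#' Contour-length increment from an observed unfolding step
#'
#' An unfolding event observed as an extension step of `step` nm at force
#' `F` releases a contour length `step / (x/Lc)(F)`, because the newly
#' released chain is only fractionally extended at that force (FJC).
#'
#' @param step Observed step size, nm.
#' @param F Force at which the step occurred, pN (> 0).
#' @param model A [polymer_model()].
#' @return Contour-length increment, nm (always >= `step`).
#' @export
contour_increment_from_step <- function(step, F, model = polymer_model()) {
  if (any(step <= 0)) stop("step size must be positive")
  step / fjc_extension_fraction(F, model)
}

#' Worm-like chain force at a given extension
#'
#' Interpolation form of the WLC force law:
#' \deqn{F(x) = \frac{kT}{p}\left[\frac{1}{4(1 - x/L_c)^2} - \frac{1}{4} +
#'   \frac{x}{L_c}\right]}
#' used to fit contour-length increments in force-extension recordings.
#' Diverges as the extension approaches the contour length.
#'
#' @param x Extension, nm (`0 <= x < Lc`; vectorized).
#' @param model A [polymer_model()] with finite `Lc`.
#' @return Force, pN.
#' @export
wlc_force <- function(x, model) {
  if (is.na(model$Lc)) stop("polymer_model must carry a contour length Lc")
  if (any(x < 0) || any(x >= model$Lc)) stop("require 0 <= x < Lc")
  z <- x / model$Lc
  (model$kT / model$p) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}
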