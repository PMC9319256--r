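# Equilibrium fluorescence titrations with explicit ligand depletion.
#
# With the fixed species at total concentration N and the titrated species at
# total concentration S (both micromolar), the 1:1 complex concentration is
# the smaller root of the mass-action quadratic
#   [PL] = ((S + N + Kd) - sqrt((S + N + Kd)^2 - 4 S N)) / 2,
# and the observed signal is F = F0 + dFmax * [PL] / N, i.e. the amplitude is
# normalized by the fixed (depletable) species. This is the standard quadratic
# isotherm for titrations where bound ligand is a non-negligible fraction of
# total, replacing the hyperbolic approximation.

#' Titration series container
#'
#' @param titrant_uM Total titrant concentrations per point (uM), non-negative
#'   and strictly increasing.
#' @param signal Blank-subtracted fluorescence per point (arbitrary units).
#' @param fixed_uM Total concentration of the species held constant (uM).
#' @param temperature_K Temperature in kelvin.
#' @return Object of class \code{"titration_series"}.
#' @export
titration_series <- function(titrant_uM, signal, fixed_uM,
                             temperature_K = 298.15) {
  titrant_uM <- as.numeric(titrant_uM); signal <- as.numeric(signal)
  if (length(titrant_uM) != length(signal))
    stop("'titrant_uM' and 'signal' must have the same length")
  if (any(titrant_uM < 0)) stop("titrant concentrations must be >= 0")
  if (any(diff(titrant_uM) <= 0))
    stop("titrant concentrations must be strictly increasing")
  if (!is.numeric(fixed_uM) || fixed_uM <= 0) stop("'fixed_uM' must be > 0")
  structure(list(titrant_uM = titrant_uM, signal = signal,
                 fixed_uM = fixed_uM, temperature_K = temperature_K),
            class = "titration_series")
}

#' Quadratic ligand-depletion binding isotherm
#'
#' Forward model for the signal of a 1:1 binding titration in which neither
#' species is in large excess. The \code{convention} records which physical
#' species is held fixed (the cargo protein, or the importin receptor); the
#' isotherm is symmetric in the two totals, so both conventions evaluate the
#' same expression with the fixed species normalizing the amplitude.
#'
#' @param kd Dissociation constant (uM, >= 0).
#' @param f0 Signal at zero titrant.
#' @param dfmax Saturating signal amplitude (signal units; may be negative
#'   for quenching).
#' @param fixed_conc Total concentration of the fixed species (uM, > 0).
#' @param titrant_conc Total titrant concentration(s) (uM, >= 0); vectorized.
#' @param convention \code{"fixed_is_cargo"} or \code{"fixed_is_receptor"}.
#' @return Model signal, same length as \code{titrant_conc}.
#' @examples
#' depletion_model(3.9, 0, 100, fixed_conc = 3, titrant_conc = c(0, 1, 5, 25))
#' @export
depletion_model <- function(kd, f0, dfmax, fixed_conc, titrant_conc,
                            convention = c("fixed_is_cargo",
                                           "fixed_is_receptor")) {
  convention <- match.arg(convention)
  if (kd < 0) stop("'kd' must be >= 0")
  if (fixed_conc <= 0) stop("'fixed_conc' must be > 0")
  if (any(titrant_conc < 0)) stop("'titrant_conc' must be >= 0")
  S <- titrant_conc; N <- fixed_conc
  b <- S + N + kd
  disc <- b^2 - 4 * S * N
  if (any(disc < -1e-9 * pmax(b^2, 1)))
    stop("negative discriminant in mass-action quadratic (invalid input)")
  bound <- (b - sqrt(pmax(disc, 0))) / 2
  f0 + dfmax * bound / N
}

#' Inner-filter correction of fluorescence intensities
#'
#' Standard correction \eqn{F_{corr} = F_{obs} 10^{(A_{ex}+A_{em})/2}} for
#' attenuation of the excitation and emission beams by sample absorbance.
#'
#' @param f_obs Observed fluorescence.
#' @param a_ex Absorbance at the excitation wavelength (>= 0).
#' @param a_em Absorbance at the emission wavelength (>= 0).
#' @return Corrected fluorescence.
#' @export
inner_filter_correct <- function(f_obs, a_ex, a_em) {
  if (any(a_ex < 0) || any(a_em < 0)) stop("absorbances must be >= 0")
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Fit a titration series to the ligand-depletion isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' \code{\link{depletion_model}} to a \code{\link{titration_series}}.
#' Starting values: \code{f0} from the first point, \code{dfmax} from the
#' last minus the first, \code{kd} from the titrant concentration at half
#' amplitude. Unweighted by default.
#'
#' @param series A \code{\link{titration_series}}.
#' @param convention Passed to \code{\link{depletion_model}}.
#' @param weights Optional per-point weights for weighted least squares.
#' @return Object of class \code{"binding_fit"}: \code{kd}, \code{f0},
#'   \code{dfmax} (estimates), \code{se} (standard errors from the local
#'   curvature), \code{residual_norm}, \code{fitted}, plus the input series.
#' @export
fit_titration <- function(series, convention = c("fixed_is_cargo",
                                                 "fixed_is_receptor"),
                          weights = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(series, "titration_series"))
  S <- series$titrant_uM; y <- series$signal
  if (length(S) < 5L) stop("need at least 5 titration points")
  amp <- y[length(y)] - y[1L]
  if (abs(amp) < 1e-12 * max(abs(y), 1) || sd(y) < 1e-14 * max(abs(y), 1))
    stop("no binding signal: flat titration curve")
  # titrant concentration at half amplitude as Kd start
  half <- y[1L] + amp / 2
  kd0 <- tryCatch(approx(y, S, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- max(S) / 4
  start <- list(kd = kd0, f0 = y[1L], dfmax = amp)
  if (is.null(weights)) weights <- rep(1, length(y))
  fixedN <- series$fixed_uM
  fit <- minpack.lm::nlsLM(
    y ~ depletion_model(kd, f0, dfmax, fixedN, S, convention),
    start = start, weights = weights,
    lower = c(kd = 0, f0 = -Inf, dfmax = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$convInfo$isConv)
    stop("titration fit did not converge; last iterate: ",
         paste(sprintf("%s=%.4g", names(coef(fit)), coef(fit)),
               collapse = ", "))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(est)))
  tq <- stats::qt(0.975, df = length(y) - 3L)
  ci <- cbind(low = est - tq * se, high = est + tq * se)
  structure(
    list(kd = unname(est["kd"]), f0 = unname(est["f0"]),
         dfmax = unname(est["dfmax"]),
         se = se, ci95 = ci, residual_norm = sqrt(sum(resid(fit)^2)),
         fitted = fitted(fit), convention = convention, series = series,
         nls = fit),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Ligand-depletion titration fit\n")
  cat(sprintf("  Kd    = %.3g +/- %.2g uM\n", x$kd, x$se["kd"]))
  cat(sprintf("  F0    = %.4g +/- %.2g\n", x$f0, x$se["f0"]))
  cat(sprintf("  dFmax = %.4g +/- %.2g\n", x$dfmax, x$se["dfmax"]))
  cat(sprintf("  residual norm = %.4g (%d points)\n", x$residual_norm,
              length(x$series$signal)))
  invisible(x)
}
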