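# DOSY hydrodynamics: mono/bi-exponential gradient decay fits and conversion
# of diffusion coefficients to hydrodynamic radii against an internal
# reference compound measured in the same tube.
#
# The decay is I(x) = I0 * sum_i a_i exp(-D_i x), where x is the
# instrument-normalized squared-gradient attenuation variable with the
# diffusion-encoding prefactor (gamma^2 g^2 delta^2 (Delta - delta/3)) folded
# in, so that D_i x is dimensionless when D is in cm^2 s^-1.

#' DOSY decay container
#'
#' @param x Attenuation variable per point (s cm^-2), non-negative increasing.
#' @param intensity Signal intensity per point (> 0 at x = 0).
#' @param species_label Optional label of the species whose signal was
#'   integrated (e.g. "methyl").
#' @return Object of class \code{"dosy_decay"}.
#' @export
dosy_decay <- function(x, intensity, species_label = "") {
  x <- as.numeric(x); intensity <- as.numeric(intensity)
  if (length(x) != length(intensity))
    stop("'x' and 'intensity' must have the same length")
  if (any(x < 0) || any(diff(x) <= 0))
    stop("'x' must be non-negative and strictly increasing")
  if (any(intensity <= 0))
    stop("intensities must be positive")
  structure(list(x = x, intensity = intensity,
                 species_label = species_label),
            class = "dosy_decay")
}

#' Build the attenuation variable from gradient parameters
#'
#' Stejskal-Tanner prefactor \eqn{x = \gamma^2 g^2 \delta^2 (\Delta -
#' \delta/3)} for a pulsed-field-gradient experiment, in s cm^-2 when the
#' inputs are in CGS-consistent units.
#'
#' @param gamma Gyromagnetic ratio (rad s^-1 G^-1).
#' @param g Gradient strengths (G cm^-1); vectorized.
#' @param delta Gradient pulse length (s).
#' @param Delta Diffusion delay (s).
#' @return Attenuation variable x (s cm^-2).
#' @export
stejskal_tanner_x <- function(gamma, g, delta, Delta) {
  if (delta <= 0 || Delta <= delta / 3)
    stop("need delta > 0 and Delta > delta/3")
  gamma^2 * g^2 * delta^2 * (Delta - delta / 3)
}

#' Fit a DOSY decay with one or two diffusing species
#'
#' Single species: \code{I0 * exp(-D x)}. Two species:
#' \code{I0 * (a exp(-D1 x) + (1 - a) exp(-D2 x))}, initialized from the
#' single-species fit with the split (D, D/3). If the two fitted coefficients
#' are closer than a factor 1.5 a warning marks them indistinguishable.
#'
#' @param decay A \code{\link{dosy_decay}} with at least 8 points.
#' @param n_species 1 or 2.
#' @return Object of class \code{"diffusion_fit"}: \code{d_values} (cm^2
#'   s^-1, sorted descending), \code{amplitudes} (fractions summing to 1),
#'   \code{i0}, \code{model}, \code{se}, \code{warnings}.
#' @export
fit_decay <- function(decay, n_species = 1L) {
  stopifnot(inherits(decay, "dosy_decay"))
  if (!n_species %in% c(1L, 2L)) stop("'n_species' must be 1 or 2")
  x <- decay$x; y <- decay$intensity
  if (length(x) < 8L) stop("need at least 8 points")
  # log-linear start for the single-species coefficient
  lf <- lm(log(y) ~ x)
  d0 <- max(-coef(lf)[["x"]], 1e-12)
  i00 <- exp(coef(lf)[["(Intercept)"]])
  single <- minpack.lm::nlsLM(y ~ i0 * exp(-d1 * x),
                              start = list(i0 = i00, d1 = d0),
                              lower = c(i0 = 0, d1 = 0),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
  if (n_species == 1L) {
    est <- coef(single)
    se <- summary(single)$coefficients[, "Std. Error"]
    tq <- stats::qt(0.975, df = length(x) - 2L)
    return(structure(list(d_values = est[["d1"]], amplitudes = 1,
                          i0 = est[["i0"]], model = "single",
                          se = c(d1 = unname(se["d1"])),
                          ci95 = rbind(d1 = est[["d1"]] +
                                         c(-tq, tq) * unname(se["d1"])),
                          rss = sum(resid(single)^2),
                          warnings = character()),
                     class = "diffusion_fit"))
  }
  s1 <- coef(single)
  fit <- NULL
  for (st in list(list(i0 = s1[["i0"]], a = 0.7, d1 = s1[["d1"]],
                       d2 = s1[["d1"]] / 3),
                  list(i0 = s1[["i0"]], a = 0.5, d1 = 1.5 * s1[["d1"]],
                       d2 = s1[["d1"]] / 4),
                  list(i0 = s1[["i0"]], a = 0.9, d1 = s1[["d1"]],
                       d2 = s1[["d1"]] / 2))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ i0 * (a * exp(-d1 * x) + (1 - a) * exp(-d2 * x)),
      start = st,
      lower = c(i0 = 0, a = 1e-6, d1 = 0, d2 = 0),
      upper = c(i0 = Inf, a = 1, d1 = Inf, d2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # the bi-exponential collapsed onto the single-species boundary (a -> 1
    # or 0), where the second coefficient is unidentifiable; report the
    # single-species solution with a degenerate second component
    warning("two-species fit collapsed to a single species; second component unidentifiable")
    est <- coef(single)
    se1 <- summary(single)$coefficients[, "Std. Error"]
    return(structure(list(d_values = c(est[["d1"]], NA_real_),
                          amplitudes = c(1, 0), i0 = est[["i0"]],
                          model = "double",
                          se = c(d1 = unname(se1["d1"]), d2 = NA_real_),
                          ci95 = NULL, rss = sum(resid(single)^2),
                          warnings = "collapsed to single species"),
                     class = "diffusion_fit"))
  }
  est <- coef(fit)
  d <- c(est[["d1"]], est[["d2"]]); amp <- c(est[["a"]], 1 - est[["a"]])
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]; amp <- amp[ord]
  warn <- character()
  if (min(d) > 0 && max(d) / min(d) < 1.5) {
    warn <- sprintf("diffusion coefficients indistinguishable (ratio %.2f < 1.5)",
                    max(d) / min(d))
    warning(warn)
  }
  se_raw <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) NULL)
  ci <- NULL
  if (!is.null(se_raw)) {
    tq <- stats::qt(0.975, df = length(x) - 4L)
    se_d <- c(se_raw[["d1"]], se_raw[["d2"]])[ord]
    ci <- cbind(low = d - tq * se_d, high = d + tq * se_d)
    rownames(ci) <- c("d1", "d2")
  }
  structure(list(d_values = d, amplitudes = amp, i0 = est[["i0"]],
                 model = "double", se = se_raw, ci95 = ci,
                 rss = sum(resid(fit)^2), warnings = warn),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("DOSY %s-species fit\n", if (x$model == "single") "one" else "two"))
  for (i in seq_along(x$d_values))
    cat(sprintf("  D%d = %.4g cm^2 s^-1 (amplitude %.2f)\n",
                i, x$d_values[i], x$amplitudes[i]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Internal reference standard for hydrodynamic radii
#'
#' @param d_ref Diffusion coefficient of the reference (cm^2 s^-1, > 0);
#'   default dioxane, 6.8e-6.
#' @param rh_ref Hydrodynamic radius of the reference (Angstrom, > 0);
#'   default 2.12 for dioxane.
#' @return Object of class \code{"reference_standard"}.
#' @export
reference_standard <- function(d_ref = 6.8e-6, rh_ref = 2.12) {
  if (d_ref <= 0 || rh_ref <= 0) stop("reference values must be > 0")
  structure(list(d_ref = d_ref, rh_ref = rh_ref),
            class = "reference_standard")
}

#' Hydrodynamic radius from a diffusion coefficient via an internal reference
#'
#' Stokes-Einstein ratio at equal temperature and viscosity (reference in the
#' same tube): \eqn{R_h = R_{h,ref} D_{ref} / D}.
#'
#' @param d Diffusion coefficient of the analyte (cm^2 s^-1, > 0).
#' @param std A \code{\link{reference_standard}}.
#' @return Hydrodynamic radius in Angstrom.
#' @examples
#' rh_from_reference(9.6e-7)  # ~15.0 A against dioxane
#' @export
rh_from_reference <- function(d, std = reference_standard()) {
  if (any(d <= 0)) stop("'d' must be > 0")
  std$rh_ref * std$d_ref / d
}
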