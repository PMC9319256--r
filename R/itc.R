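# Isothermal titration calorimetry: single-site forward model with
# perfusion (overflow) injection bookkeeping, nonlinear fitting, bootstrap
# confidence intervals and thermodynamic decomposition.
#
# Injection bookkeeping for a fixed-volume perfusion cell: while an aliquot
# dV is injected, well-mixed cell content overflows at the same rate. For a
# species with syringe concentration c_s, the cell concentration obeys
# dc/dV = (c_s - c)/V0, so after injecting dV (v = dV/V0):
#   macromolecule  M  ->  M * exp(-v)
#   ligand         L  ->  L_s + (L - L_s) * exp(-v)
# The measured heat of injection i is the enthalpy of the change in complex
# inside the cell plus the complex carried out with the displaced volume
# (trapezoidal displaced-content correction):
#   q_i = dH * V0 * ( [PL]_i - [PL]_(i-1) + v_i * ([PL]_i + [PL]_(i-1))/2 )
#         + q_bg
# with dH in kcal/mol, V0 in uL, [PL] in uM, q in ucal.

#' ITC experiment container
#'
#' @param injection_uL Injection volumes (uL), one per injection.
#' @param heat_ucal Integrated heats per injection (ucal); may be \code{NULL}
#'   for a design-only object passed to \code{\link{single_site_heats}}.
#' @param cell_uM Macromolecule (cell) concentration before the first
#'   injection (uM).
#' @param syringe_uM Ligand (syringe) concentration (uM).
#' @param cell_volume_uL Active cell volume (uL).
#' @param temperature_K Temperature (K); default 298.15 (25 C).
#' @return Object of class \code{"itc_experiment"}.
#' @export
itc_experiment <- function(injection_uL, heat_ucal = NULL, cell_uM,
                           syringe_uM, cell_volume_uL = 200,
                           temperature_K = 298.15) {
  injection_uL <- as.numeric(injection_uL)
  if (any(injection_uL <= 0)) stop("injection volumes must be > 0")
  if (cell_uM <= 0 || syringe_uM <= 0 || cell_volume_uL <= 0)
    stop("concentrations and cell volume must be > 0")
  if (!is.null(heat_ucal)) {
    heat_ucal <- as.numeric(heat_ucal)
    if (length(heat_ucal) != length(injection_uL))
      stop("'heat_ucal' must have one heat per injection")
  }
  structure(list(injection_uL = injection_uL, heat_ucal = heat_ucal,
                 cell_uM = cell_uM, syringe_uM = syringe_uM,
                 cell_volume_uL = cell_volume_uL,
                 temperature_K = temperature_K),
            class = "itc_experiment")
}

# Cell totals after each injection under the perfusion model.
# Returns a data.frame with per-injection macromolecule and ligand totals (uM)
# and the dilution fraction v = dV/V0.
.itc_cell_totals <- function(expt) {
  v <- expt$injection_uL / expt$cell_volume_uL
  n_inj <- length(v)
  M <- L <- numeric(n_inj)
  m <- expt$cell_uM; l <- 0
  for (i in seq_len(n_inj)) {
    d <- exp(-v[i])
    m <- m * d
    l <- expt$syringe_uM + (l - expt$syringe_uM) * d
    M[i] <- m; L[i] <- l
  }
  data.frame(v = v, M_uM = M, L_uM = L)
}

# Smaller root of the 1:1 mass-action quadratic, complex concentration (uM)
# given totals (uM) and Kd (uM). Numerically stable form.
.complex_quadratic <- function(M_uM, L_uM, kd_uM) {
  b <- M_uM + L_uM + kd_uM
  disc <- pmax(b^2 - 4 * M_uM * L_uM, 0)
  # stable smaller root: 2*M*L / (b + sqrt(disc))
  2 * M_uM * L_uM / (b + sqrt(disc))
}

#' Per-injection heats of a single-site ITC titration
#'
#' Forward model: the cell totals are propagated through each injection with
#' the perfusion dilution correction, the 1:1 mass-action quadratic gives the
#' complex concentration before and after each injection, and the heat is the
#' binding enthalpy times the change in complex (including the complex carried
#' out with the displaced volume) plus a constant background injection heat.
#'
#' @param ka Association constant (M^-1, > 0).
#' @param dh Binding enthalpy (kcal/mol).
#' @param n Stoichiometry / fraction of binding-competent macromolecule.
#' @param q_bg Background heat per injection (ucal).
#' @param exp An \code{\link{itc_experiment}} (heats may be NULL).
#' @return Numeric vector of per-injection heats (ucal).
#' @export
single_site_heats <- function(ka, dh, n, q_bg, exp) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (!is.finite(ka) || ka <= 0) stop("'ka' must be > 0 and finite")
  kd_uM <- 1e6 / ka
  tot <- .itc_cell_totals(exp)
  pl <- .complex_quadratic(n * tot$M_uM, tot$L_uM, kd_uM)
  pl_prev <- c(.complex_quadratic(n * exp$cell_uM, 0, kd_uM), pl[-length(pl)])
  # ucal: dh [kcal/mol] * V0 [uL] * d[PL] [uM] * 1e-3
  dh * exp$cell_volume_uL * 1e-3 *
    (pl - pl_prev + tot$v * (pl + pl_prev) / 2) + q_bg
}

#' Fit an ITC titration to the single-site model
#'
#' Nonlinear least squares over (\code{ka}, \code{dh}, \code{n},
#' \code{q_bg}), with \code{ka} optimized on the log scale. The Wiseman
#' c-value \code{ka * [M]0} is checked; values outside [1, 1e4] attach a
#' low-information warning to the fit rather than failing.
#'
#' @param exp An \code{\link{itc_experiment}} with measured heats.
#' @param drop_first Discard the first injection before fitting (common
#'   practice for a diffusion-compromised first aliquot); default keeps it.
#' @return Object of class \code{"itc_fit"}: \code{ka} (M^-1), \code{kd_uM},
#'   \code{dh} (kcal/mol), \code{n}, \code{q_bg} (ucal), \code{se},
#'   \code{ci95} (filled by \code{\link{confidence_intervals_95}}),
#'   \code{warnings}, and the residuals/fitted heats.
#' @export
fit_itc <- function(exp, drop_first = FALSE) {
  stopifnot(inherits(exp, "itc_experiment"))
  y <- exp$heat_ucal
  if (is.null(y)) stop("experiment carries no measured heats")
  if (length(y) < 10L) stop("need at least 10 injections")
  keep <- seq_along(y)
  if (drop_first) keep <- keep[-1L]
  if (sd(y[keep]) < 1e-12 * max(abs(y[keep]), 1) ||
      all(abs(y[keep] - mean(y[keep])) < 1e-10 * max(abs(y), 1)))
    stop("no binding signal: heats are constant")
  qbg0 <- median(tail(y[keep], 3L))
  v1 <- exp$injection_uL[1L] / exp$cell_volume_uL
  # first-injection complex if binding were stoichiometric
  dh0 <- (y[keep][1L] - qbg0) /
    (exp$cell_volume_uL * exp$syringe_uM * v1 * 1e-3)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -10
  model_fn <- function(log_ka, dh, n, q_bg)
    single_site_heats(base::exp(log_ka), dh, n, q_bg, exp)[keep]
  yy <- y[keep]
  best <- NULL
  for (ka0 in c(1e4, 1e5, 1e6)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ model_fn(log_ka, dh, n, q_bg),
        start = list(log_ka = log(ka0), dh = dh0, n = 1, q_bg = qbg0),
        lower = c(log_ka = log(1e-2), dh = -Inf, n = 1e-3, q_bg = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || sum(resid(fit)^2) < sum(resid(best)^2)))
      best <- fit
  }
  if (is.null(best)) stop("ITC fit did not converge from any starting point")
  est <- coef(best)
  ka <- base::exp(est[["log_ka"]])
  se_raw <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                     error = function(e) setNames(rep(NA_real_, 4),
                                                  names(est)))
  # delta method: se(ka) = ka * se(log_ka)
  se <- c(ka = ka * unname(se_raw["log_ka"]), dh = unname(se_raw["dh"]),
          n = unname(se_raw["n"]), q_bg = unname(se_raw["q_bg"]))
  warn <- character()
  cval <- ka * exp$cell_uM * 1e-6
  if (cval < 1 || cval > 1e4)
    warn <- c(warn, sprintf(
      "c-value %.3g outside [1, 1e4]: low information content", cval))
  structure(
    list(ka = ka, kd_uM = 1e6 / ka, dh = est[["dh"]], n = est[["n"]],
         q_bg = est[["q_bg"]], se = se, ci95 = NULL,
         residual_norm = sqrt(sum(resid(best)^2)),
         fitted = fitted(best), kept = keep, warnings = warn,
         experiment = exp, nls = best, drop_first = drop_first),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("Single-site ITC fit\n")
  cat(sprintf("  Ka  = %.3g M^-1  (Kd = %.3g uM)\n", x$ka, x$kd_uM))
  cat(sprintf("  dH  = %.3g kcal/mol\n", x$dh))
  cat(sprintf("  n   = %.3g\n", x$n))
  cat(sprintf("  q_bg = %.3g ucal/injection\n", x$q_bg))
  if (!is.null(x$ci95)) {
    cat("  95% CI (bootstrap):\n")
    for (p in rownames(x$ci95))
      cat(sprintf("    %-5s (%.3g, %.3g)\n", p, x$ci95[p, 1], x$ci95[p, 2]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Thermodynamic decomposition of a binding constant
#'
#' \eqn{\Delta G = -RT \ln K_a} and \eqn{-T\Delta S = \Delta G - \Delta H},
#' with R = 1.9872e-3 kcal mol^-1 K^-1, so that the identity
#' \eqn{\Delta G = \Delta H + (-T\Delta S)} holds exactly.
#'
#' @param ka Association constant (M^-1, > 0).
#' @param dh Binding enthalpy (kcal/mol).
#' @param temperature_K Temperature (K, > 0).
#' @return Object of class \code{"thermo_decomposition"} with \code{dg},
#'   \code{minus_tds} (kcal/mol) and \code{temperature_K}.
#' @examples
#' thermo_derive(2.1e5, -65.5)  # dG = -7.3, -TdS = +58.2 kcal/mol
#' @export
thermo_derive <- function(ka, dh, temperature_K = 298.15) {
  if (any(ka <= 0)) stop("'ka' must be > 0")
  if (temperature_K <= 0) stop("'temperature_K' must be > 0")
  dg <- -.R_KCAL * temperature_K * log(ka)
  structure(list(dg = dg, minus_tds = dg - dh, dh = dh,
                 temperature_K = temperature_K),
            class = "thermo_decomposition")
}

#' @export
print.thermo_decomposition <- function(x, ...) {
  cat(sprintf("dG = %.2f kcal/mol, dH = %.2f kcal/mol, -TdS = %.2f kcal/mol (T = %.2f K)\n",
              x$dg, x$dh, x$minus_tds, x$temperature_K))
  invisible(x)
}

#' Bootstrap 95\% confidence intervals for an ITC fit
#'
#' Residual-resampling bootstrap: residuals of the converged fit are resampled
#' with replacement, added back to the fitted heats, and the model is refitted
#' from the point estimates; the 2.5/97.5 percentiles of the refitted
#' parameters give (possibly asymmetric) intervals.
#'
#' @param fit A converged \code{\link{fit_itc}} result.
#' @param n_boot Number of bootstrap refits (default 200).
#' @param seed Integer seed.
#' @return The fit with \code{ci95} filled: a matrix with rows \code{ka},
#'   \code{kd_uM}, \code{dh}, \code{n}, \code{q_bg} and columns
#'   \code{low}, \code{high}.
#' @export
confidence_intervals_95 <- function(fit, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(fit, "itc_fit"))
  exp_ <- fit$experiment
  keep <- fit$kept
  res <- exp_$heat_ucal[keep] - fit$fitted
  set.seed(seed)
  start <- list(log_ka = log(fit$ka), dh = fit$dh, n = fit$n,
                q_bg = fit$q_bg)
  model_fn <- function(log_ka, dh, n, q_bg)
    single_site_heats(exp(log_ka), dh, n, q_bg, exp_)[keep]
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                  dimnames = list(NULL, c("ka", "dh", "n", "q_bg")))
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    yb <- fit$fitted + sample(res, length(res), replace = TRUE)
    fb <- tryCatch(
      minpack.lm::nlsLM(yb ~ model_fn(log_ka, dh, n, q_bg), start = start,
                        lower = c(log_ka = log(1e-2), dh = -Inf, n = 1e-3,
                                  q_bg = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fb)) { n_fail <- n_fail + 1L; next }
    cb <- coef(fb)
    draws[b, ] <- c(exp(cb[["log_ka"]]), cb[["dh"]], cb[["n"]],
                    cb[["q_bg"]])
  }
  if (n_fail > 0.2 * n_boot)
    stop(sprintf("bootstrap refit failure rate %.0f%% exceeds 20%%",
                 100 * n_fail / n_boot))
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  ci <- rbind(ka = qs[, "ka"], kd_uM = rev(1e6 / qs[, "ka"]),
              dh = qs[, "dh"], n = qs[, "n"], q_bg = qs[, "q_bg"])
  colnames(ci) <- c("low", "high")
  fit$ci95 <- ci
  fit$n_boot <- n_boot
  fit
}
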