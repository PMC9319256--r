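# Biolayer interferometry kinetics: exponential phase fits, nested-model
# F-test selection, and pseudo-first-order extraction of kon/koff/Kd.
#
# Association (pseudo-first-order, analyte in excess over immobilized sites):
#   single  R(t) = Req - Req * exp(-kobs (t - t0))
#   double  R(t) = Req - Req * exp(-kobs (t - t0)) - Req2 * exp(-kobs2 (t-t0))
# The equilibrium response at infinite time is Req in both forms: the second
# exponential is a small transient (minor phase) that decays to zero, and the
# largest-amplitude exponential carries the concentration-dependent kobs used
# downstream. Dissociation is always single-exponential:
#   R(t) = R1 * exp(-koff (t - t0)).

#' Sensorgram container
#'
#' @param time_s Time points (s), strictly increasing.
#' @param response_RU Response (RU), same length as \code{time_s}.
#' @param analyte_uM Analyte concentration during association (uM).
#' @param t0_assoc Start of the association phase (s), default 180.
#' @param t0_dissoc Start of the dissociation phase (s), default 300.
#' @return Object of class \code{"sensorgram"}.
#' @export
sensorgram <- function(time_s, response_RU, analyte_uM,
                       t0_assoc = 180, t0_dissoc = 300) {
  time_s <- as.numeric(time_s); response_RU <- as.numeric(response_RU)
  if (length(time_s) != length(response_RU))
    stop("'time_s' and 'response_RU' must have the same length")
  if (any(diff(time_s) <= 0)) stop("'time_s' must be strictly increasing")
  if (!(t0_assoc < t0_dissoc && t0_dissoc <= max(time_s)))
    stop("need t0_assoc < t0_dissoc <= max(time_s)")
  structure(list(time_s = time_s, response_RU = response_RU,
                 analyte_uM = analyte_uM, t0_assoc = t0_assoc,
                 t0_dissoc = t0_dissoc),
            class = "sensorgram")
}

.phase_fit <- function(req, kobs, req2 = NA_real_, kobs2 = NA_real_,
                       r1 = NA_real_, koff_local = NA_real_, model,
                       rss, n_points, n_par, se = NULL, flags = character()) {
  structure(list(req = req, kobs = kobs, req2 = req2, kobs2 = kobs2,
                 r1 = r1, koff_local = koff_local, model = model,
                 rss = rss, n_points = n_points, n_par = n_par, se = se,
                 minor_fraction = if (is.na(req2)) NA_real_ else
                   abs(req2) / (abs(req) + abs(req2)),
                 flags = flags),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("BLI %s-phase fit (%s)\n",
              if (is.na(x$r1)) "association" else "dissociation", x$model))
  if (is.na(x$r1)) {
    cat(sprintf("  Req = %.4g RU, kobs = %.4g s^-1\n", x$req, x$kobs))
    if (x$model == "double")
      cat(sprintf("  Req' = %.4g RU, kobs2 = %.4g s^-1 (minor fraction %.1f%%)\n",
                  x$req2, x$kobs2, 100 * x$minor_fraction))
  } else {
    cat(sprintf("  R1 = %.4g RU, koff = %.4g s^-1\n", x$r1, x$koff_local))
  }
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Fit the association phase of a sensorgram
#'
#' Least-squares fit of the association window to a single- or
#' double-exponential rise. For the double model the larger-amplitude
#' exponential is designated primary (its rate is \code{kobs}); a primary
#' amplitude fraction of 50\% or less flags the fit.
#'
#' @param sg A \code{\link{sensorgram}}.
#' @param model \code{"single"} or \code{"double"}.
#' @return A \code{"phase_fit"} with \code{req}, \code{kobs} (and
#'   \code{req2}, \code{kobs2} for the double model), residual sum of squares
#'   and point/parameter counts for F-testing.
#' @export
fit_association <- function(sg, model = c("single", "double")) {
  model <- match.arg(model)
  stopifnot(inherits(sg, "sensorgram"))
  sel <- sg$time_s >= sg$t0_assoc & sg$time_s < sg$t0_dissoc
  t <- sg$time_s[sel] - sg$t0_assoc
  y <- sg$response_RU[sel]
  if (length(t) < 20L) stop("need at least 20 samples in the association window")
  plateau <- mean(tail(y, max(3L, length(y) %/% 10L)))
  if (abs(plateau) < 1e-10 && sd(y) < 1e-12)
    stop("no association signal: flat response")
  if (sd(y) < 1e-9 * max(abs(y), 1))
    stop("no association signal: flat response")
  # time to half-plateau as rate start; the running maximum suppresses
  # noise spikes near t0
  i_half <- which(cummax(y) >= plateau / 2)[1L]
  k0 <- if (!is.na(i_half) && t[i_half] > 0) log(2) / t[i_half] else 0.05
  k0 <- min(max(k0, 0.01 / max(t)), 10 / max(t))
  try_starts <- function(fml, starts, lower) {
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(fml, start = st, lower = lower,
                          control = minpack.lm::nls.lm.control(maxiter = 400)),
        error = function(e) NULL)
      if (!is.null(fit)) return(fit)
    }
    stop("association fit did not converge from any starting point")
  }
  if (model == "single") {
    fit <- try_starts(y ~ req - req * exp(-kobs * t),
                      list(list(req = plateau, kobs = k0),
                           list(req = plateau, kobs = 2 / max(t))),
                      lower = c(req = -Inf, kobs = 0))
    est <- coef(fit)
    if (est[["kobs"]] < 0) stop("rejected fit: negative association rate")
    se <- summary(fit)$coefficients[, "Std. Error"]
    return(.phase_fit(req = est[["req"]], kobs = est[["kobs"]],
                      model = "single", rss = sum(resid(fit)^2),
                      n_points = length(y), n_par = 2L, se = se))
  }
  # the single fit's solution (with a null second amplitude) is one of the
  # starting points, so the double fit can never end with a larger residual
  # sum of squares than the single fit (Levenberg-Marquardt is monotone)
  single_fit <- tryCatch(
    try_starts(y ~ req - req * exp(-kobs * t),
               list(list(req = plateau, kobs = k0)),
               lower = c(req = -Inf, kobs = 0)),
    error = function(e) NULL)
  starts <- list(list(req = plateau, kobs = k0, req2 = 0.05 * plateau,
                      kobs2 = k0 / 5),
                 list(req = plateau, kobs = 2 / max(t),
                      req2 = 0.05 * plateau, kobs2 = 0.2 / max(t)))
  if (!is.null(single_fit)) {
    cs <- coef(single_fit)
    starts <- c(starts, list(list(req = cs[["req"]], kobs = cs[["kobs"]],
                                  req2 = 0, kobs2 = cs[["kobs"]] / 5)))
  }
  fits <- lapply(starts, function(st) tryCatch(
    minpack.lm::nlsLM(y ~ req - req * exp(-kobs * t) - req2 * exp(-kobs2 * t),
                      start = st,
                      lower = c(req = -Inf, kobs = 0, req2 = -Inf, kobs2 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("association fit did not converge from any starting point")
  fit <- fits[[which.min(vapply(fits, function(f) sum(resid(f)^2),
                                numeric(1)))]]
  est <- coef(fit)
  if (est[["kobs"]] < 0 || est[["kobs2"]] < 0)
    stop("rejected fit: negative association rate")
  req <- est[["req"]]; kobs <- est[["kobs"]]
  req2 <- est[["req2"]]; kobs2 <- est[["kobs2"]]
  flags <- character()
  # primary term is the larger-amplitude exponential
  if (abs(req2) > abs(req)) {
    tmp <- c(req, kobs); req <- req2; kobs <- kobs2
    req2 <- tmp[1L]; kobs2 <- tmp[2L]
    flags <- c(flags, "amplitudes swapped: second term dominated")
  }
  if (abs(req) / (abs(req) + abs(req2)) <= 0.5)
    flags <- c(flags, "primary amplitude fraction <= 50%")
  se <- summary(fit)$coefficients[, "Std. Error"]
  .phase_fit(req = req, kobs = kobs, req2 = req2, kobs2 = kobs2,
             model = "double", rss = sum(resid(fit)^2),
             n_points = length(y), n_par = 4L, se = se, flags = flags)
}

#' Nested F-test between single- and double-exponential association fits
#'
#' @param fit_single,fit_double \code{"phase_fit"} objects from
#'   \code{\link{fit_association}} on the same data.
#' @param n_points Number of points fitted (defaults to the count recorded in
#'   the fits).
#' @param alpha Significance level (default 0.05, i.e. 95\% confidence).
#' @return List with \code{model} ("single" or "double"), \code{fstat} and
#'   \code{p_value}.
#' @export
select_model <- function(fit_single, fit_double,
                         n_points = fit_single$n_points, alpha = 0.05) {
  stopifnot(inherits(fit_single, "phase_fit"),
            inherits(fit_double, "phase_fit"))
  if (fit_single$n_points != fit_double$n_points)
    stop("fits must be on the same data")
  p1 <- fit_single$n_par; p2 <- fit_double$n_par
  if (n_points <= p2) stop("fewer points than parameters")
  df1 <- p2 - p1; df2 <- n_points - p2
  fstat <- max(0, (fit_single$rss - fit_double$rss) / df1 /
                 (fit_double$rss / df2))
  p_value <- pf(fstat, df1, df2, lower.tail = FALSE)
  list(model = if (p_value < alpha) "double" else "single",
       fstat = fstat, p_value = p_value)
}

#' Fit the dissociation phase of a sensorgram
#'
#' Single-exponential decay from the response level at the start of
#' dissociation.
#'
#' @param sg A \code{\link{sensorgram}}.
#' @return A \code{"phase_fit"} with \code{r1} and \code{koff_local}.
#' @export
fit_dissociation <- function(sg) {
  stopifnot(inherits(sg, "sensorgram"))
  sel <- sg$time_s >= sg$t0_dissoc
  t <- sg$time_s[sel] - sg$t0_dissoc
  y <- sg$response_RU[sel]
  if (length(t) < 20L) stop("need at least 20 samples after t0_dissoc")
  r10 <- y[1L]
  flags <- character()
  if (sd(y) < 1e-9 * max(abs(y), 1)) {
    # no measurable decay
    flags <- "no dissociation detected: flat response"
    return(.phase_fit(req = NA_real_, kobs = NA_real_, r1 = mean(y),
                      koff_local = 0, model = "single", rss = sum((y - mean(y))^2),
                      n_points = length(y), n_par = 2L, flags = flags))
  }
  i_half <- which(y <= r10 / 2)[1L]
  k0 <- if (!is.na(i_half) && t[i_half] > 0) log(2) / t[i_half] else 0.05
  fit <- minpack.lm::nlsLM(y ~ r1 * exp(-koff * t),
                           start = list(r1 = r10, koff = k0),
                           lower = c(r1 = -Inf, koff = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  .phase_fit(req = NA_real_, kobs = NA_real_, r1 = est[["r1"]],
             koff_local = est[["koff"]], model = "single",
             rss = sum(resid(fit)^2), n_points = length(y), n_par = 2L,
             se = se, flags = flags)
}

#' Pseudo-first-order analysis of observed association rates
#'
#' Linear regression of kobs on analyte concentration:
#' \eqn{k_{obs} = k_{on} C + k_{off}}; the slope is kon, the intercept koff,
#' and \eqn{K_d = k_{off}/k_{on}} with error propagated by the delta method.
#'
#' @param kobs_by_conc Data frame or matrix with columns \code{conc_uM} and
#'   \code{kobs}; at least 3 distinct concentrations.
#' @param weights Optional regression weights (e.g. 1/se(kobs)^2).
#' @return Object of class \code{"kinetic_fit"}: \code{kon} (uM^-1 s^-1),
#'   \code{koff} (s^-1), \code{kd_uM}, with standard errors.
#' @examples
#' d <- data.frame(conc_uM = c(1, 2, 3, 5, 7),
#'                 kobs = 0.0037 * c(1, 2, 3, 5, 7) + 0.0685)
#' pseudo_first_order(d)  # Kd = 18.5 uM
#' @export
pseudo_first_order <- function(kobs_by_conc, weights = NULL) {
  d <- as.data.frame(kobs_by_conc)
  if (!all(c("conc_uM", "kobs") %in% names(d)))
    stop("need columns 'conc_uM' and 'kobs'")
  if (length(unique(d$conc_uM)) < 3L)
    stop("need at least 3 distinct concentrations")
  fit <- if (is.null(weights)) lm(kobs ~ conc_uM, data = d)
         else lm(kobs ~ conc_uM, data = d, weights = weights)
  co <- coef(fit)
  kon <- unname(co["conc_uM"]); koff <- unname(co["(Intercept)"])
  if (kon <= 0) stop("no concentration dependence: non-positive slope")
  # vcov on machine-precision fits triggers a spurious "perfect fit" warning
  V <- suppressWarnings(vcov(fit))
  se_kon <- sqrt(V["conc_uM", "conc_uM"])
  se_koff <- sqrt(V["(Intercept)", "(Intercept)"])
  cov_ <- V["(Intercept)", "conc_uM"]
  kd <- koff / kon
  # delta method for the ratio
  se_kd <- abs(kd) * sqrt(se_koff^2 / koff^2 + se_kon^2 / kon^2 -
                            2 * cov_ / (koff * kon))
  # 95% CIs: t-based for the regression coefficients, Fieller for the
  # intercept/slope ratio (few concentrations, so the t quantile matters)
  df <- nrow(d) - 2L
  tq <- stats::qt(0.975, df)
  ci <- rbind(kon = kon + c(-tq, tq) * se_kon,
              koff = koff + c(-tq, tq) * se_koff,
              kd_uM = .fieller_ratio_ci(koff, kon, V["(Intercept)", "(Intercept)"],
                                        V["conc_uM", "conc_uM"], cov_, tq))
  colnames(ci) <- c("low", "high")
  structure(list(kon = kon, koff = koff, kd_uM = kd,
                 se = c(kon = se_kon, koff = se_koff, kd_uM = se_kd),
                 ci95 = ci, lm = fit),
            class = "kinetic_fit")
}

# Fieller interval for a ratio a/b of two jointly normal estimates.
.fieller_ratio_ci <- function(a, b, vaa, vbb, vab, tq) {
  g <- tq^2 * vbb / b^2
  if (g >= 1) return(c(-Inf, Inf))  # slope not significantly nonzero
  r <- a / b
  center <- (r - tq^2 * vab / b^2) / (1 - g)
  half <- tq / (b * (1 - g)) *
    sqrt(vaa - 2 * r * vab + r^2 * vbb - g * (vaa - vab^2 / vbb))
  center + c(-1, 1) * abs(half)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Pseudo-first-order kinetic fit\n")
  cat(sprintf("  kon  = %.4g +/- %.2g uM^-1 s^-1\n", x$kon, x$se["kon"]))
  cat(sprintf("  koff = %.4g +/- %.2g s^-1\n", x$koff, x$se["koff"]))
  cat(sprintf("  Kd   = %.4g +/- %.2g uM\n", x$kd_uM, x$se["kd_uM"]))
  invisible(x)
}

#' Dissociation constant from kinetic rate constants
#'
#' @param koff Dissociation rate (s^-1, >= 0).
#' @param kon Association rate (uM^-1 s^-1, > 0).
#' @return Kd in uM.
#' @examples
#' kd_from_rates(0.0685, 0.0037)  # 18.5 uM
#' @export
kd_from_rates <- function(koff, kon) {
  if (any(kon <= 0)) stop("'kon' must be > 0")
  if (any(koff < 0)) stop("'koff' must be >= 0")
  koff / kon
}
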