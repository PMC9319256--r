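# Seeded generators producing instrument-style datasets with the statistical
# structure each fitting stage assumes. Every generator returns the dataset
# together with a synthetic_truth carrying the generating parameters, so
# recovery tests can compare fits against the truth.

#' Generating truth of a simulated dataset
#'
#' @param model_name Generator name.
#' @param parameters Named list of generating parameters.
#' @param noise_sd Noise standard deviation (signal units, >= 0).
#' @param seed Integer seed used.
#' @return Object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(model_name, parameters, noise_sd, seed) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(model_name = model_name, parameters = parameters,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Simulate a fluorescence titration with ligand depletion
#'
#' Titrant grid from 0 to \code{span} times the larger of Kd and the fixed
#' concentration; signal from \code{\link{depletion_model}} plus
#' homoscedastic Gaussian noise.
#'
#' @param kd,f0,dfmax,fixed_conc Generating parameters (uM / signal units).
#' @param points Number of titration points (>= 5).
#' @param noise_sd Gaussian noise SD (signal units).
#' @param seed Integer seed.
#' @param span Grid extent multiplier (default 5).
#' @return List with \code{series} (\code{\link{titration_series}}) and
#'   \code{truth} (\code{\link{synthetic_truth}}).
#' @export
gen_titration <- function(kd = 3.9, f0 = 100, dfmax = 100, fixed_conc = 3,
                          points = 12L, noise_sd = 1, seed = 1L, span = 5) {
  if (points < 5L) stop("'points' must be >= 5")
  set.seed(seed)
  titrant <- seq(0, span * max(kd, fixed_conc), length.out = points)
  mu <- depletion_model(kd, f0, dfmax, fixed_conc, titrant)
  signal <- mu + rnorm(points, 0, noise_sd)
  list(series = titration_series(titrant, signal, fixed_conc),
       truth = synthetic_truth("titration_depletion",
                               list(kd = kd, f0 = f0, dfmax = dfmax,
                                    fixed_conc = fixed_conc),
                               noise_sd, seed))
}

#' Simulate a single-site ITC titration
#'
#' Default schedule: 20 x 2 uL injections of 100 uM ligand into a 200 uL cell
#' at 10 uM, heats from \code{\link{single_site_heats}} plus Gaussian noise.
#'
#' @param ka Association constant (M^-1).
#' @param dh Binding enthalpy (kcal/mol).
#' @param n Stoichiometry.
#' @param q_bg Background heat per injection (ucal).
#' @param n_injections,injection_uL,syringe_uM,cell_uM,cell_volume_uL Design.
#' @param noise_sd Gaussian noise SD (ucal).
#' @param seed Integer seed.
#' @return List with \code{experiment} (\code{\link{itc_experiment}}) and
#'   \code{truth}.
#' @export
gen_itc <- function(ka = 2.1e5, dh = -65.5, n = 0.97, q_bg = -1.5,
                    n_injections = 20L, injection_uL = 2, syringe_uM = 100,
                    cell_uM = 10, cell_volume_uL = 200, noise_sd = 0.2,
                    seed = 1L) {
  set.seed(seed)
  design <- itc_experiment(rep(injection_uL, n_injections), NULL, cell_uM,
                           syringe_uM, cell_volume_uL)
  mu <- single_site_heats(ka, dh, n, q_bg, design)
  design$heat_ucal <- mu + rnorm(n_injections, 0, noise_sd)
  list(experiment = design,
       truth = synthetic_truth("itc_single_site",
                               list(ka = ka, dh = dh, n = n, q_bg = q_bg),
                               noise_sd, seed))
}

#' Simulate BLI sensorgrams over a concentration series
#'
#' Association per the two-exponential rise with the concentration-dependent
#' primary rate \code{kobs = kon * C + koff} and a small concentration-
#' independent minor phase (amplitude fraction \code{minor_frac}, rate
#' \code{kobs2}); dissociation is single-exponential from the response level
#' at the phase boundary. Gaussian noise is added throughout.
#'
#' @param kon Association rate (uM^-1 s^-1).
#' @param koff Dissociation rate (s^-1).
#' @param rmax Saturating response (RU).
#' @param minor_frac Minor-phase amplitude fraction of Req (<= 0.05).
#' @param kobs2 Minor-phase rate (s^-1), concentration-independent.
#' @param concs Analyte concentrations (uM).
#' @param t0,t1,tend Phase timing (s): association start, dissociation start,
#'   end of record.
#' @param dt Sampling interval (s).
#' @param noise_frac Gaussian noise SD as a fraction of each sensorgram's
#'   equilibrium response (default 0.02, i.e. 2\% of the measured signal,
#'   matching the precision of the fitted rate constants the instrument
#'   delivers).
#' @param seed Integer seed.
#' @return List with \code{sensorgrams} (list of \code{\link{sensorgram}})
#'   and \code{truth}.
#' @export
gen_bli <- function(kon = 0.0037, koff = 0.0685, rmax = 1,
                    minor_frac = 0.04, kobs2 = 0.005,
                    concs = c(1, 2, 3, 5, 7), t0 = 180, t1 = 300,
                    tend = 480, dt = 0.5, noise_frac = 0.02, seed = 1L) {
  if (minor_frac > 0.05)
    warning("minor-phase amplitude fraction above 5%")
  set.seed(seed)
  kd <- koff / kon
  sgs <- lapply(concs, function(C) {
    times <- seq(0, tend, by = dt)
    kobs <- kon * C + koff
    req <- rmax * C / (C + kd)
    req2 <- minor_frac * req
    r <- numeric(length(times))
    assoc <- times >= t0 & times < t1
    r[assoc] <- req - req * exp(-kobs * (times[assoc] - t0)) -
      req2 * exp(-kobs2 * (times[assoc] - t0))
    r1 <- req - req * exp(-kobs * (t1 - t0)) - req2 * exp(-kobs2 * (t1 - t0))
    dis <- times >= t1
    r[dis] <- r1 * exp(-koff * (times[dis] - t1))
    sensorgram(times, r + rnorm(length(times), 0, noise_frac * req), C,
               t0_assoc = t0, t0_dissoc = t1)
  })
  list(sensorgrams = sgs,
       truth = synthetic_truth("bli_two_step",
                               list(kon = kon, koff = koff, kd = kd,
                                    rmax = rmax, minor_frac = minor_frac,
                                    kobs2 = kobs2, concs = concs),
                               noise_frac, seed))
}

#' Simulate a DOSY gradient decay
#'
#' @param d_list Diffusion coefficients (cm^2 s^-1), one or two species.
#' @param amp_list Amplitude fractions (sum to 1).
#' @param i0 Intensity at x = 0.
#' @param x Attenuation variable grid (s cm^-2); the default attenuates the
#'   total signal to about 5\% at the last point for the default
#'   coefficients, the usual design for resolving a slow component.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param seed Integer seed.
#' @return List with \code{decay} (\code{\link{dosy_decay}}) and \code{truth}.
#' @export
gen_dosy <- function(d_list = c(8.8e-7, 4e-7), amp_list = c(0.7, 0.3),
                     i0 = 100, x = seq(0, 5e6, length.out = 24),
                     noise_sd = 0.3, seed = 1L) {
  if (abs(sum(amp_list) - 1) > 1e-9) stop("amplitudes must sum to 1")
  set.seed(seed)
  mu <- i0 * colSums(amp_list * exp(-outer(d_list, x)))
  y <- mu + rnorm(length(x), 0, noise_sd)
  if (any(y <= 0))
    stop("noise drove intensities non-positive; reduce noise_sd or shorten the grid")
  list(decay = dosy_decay(x, y),
       truth = synthetic_truth("dosy_decay",
                               list(d_list = d_list, amp_list = amp_list,
                                    i0 = i0),
                               noise_sd, seed))
}

#' Simulate a fragment docking score landscape with a single core minimum
#'
#' Builds a random parent peptide and per-fragment scores following a smooth
#' landscape: a flat baseline with a single Gaussian dip of depth
#' \code{core_depth} centered on \code{core_center} (parent numbering), plus
#' Gaussian noise. The truth carries the noiseless landscape and the core
#' region that \code{\link{call_core_region}} would return on it.
#'
#' @param seq_length Parent peptide length (residues).
#' @param core_center Parent residue number of the landscape minimum.
#' @param core_depth Depth of the dip (kcal/mol, > 0).
#' @param baseline Baseline fragment score (kcal/mol).
#' @param noise_sd Gaussian noise SD (kcal/mol).
#' @param seed Integer seed.
#' @param start_number Parent numbering of the first residue.
#' @param window,step Fragmentation parameters.
#' @param sigma Width of the Gaussian dip (residues).
#' @param margin Margin used to define the truth core region.
#' @return List with \code{scores} (\code{\link{fragment_scores}}),
#'   \code{parent} and \code{truth}; \code{truth$parameters$core_region} is
#'   the noiseless-landscape core call.
#' @export
gen_affinity_landscape <- function(seq_length = 27L, core_center = 68L,
                                   core_depth = 2, baseline = -6,
                                   noise_sd = 0.1, seed = 1L,
                                   start_number = 58L, window = 7L,
                                   step = 2L, sigma = 2.5, margin = 0.5) {
  set.seed(seed)
  aa <- sample(names(AA_AVERAGE_MASS), seq_length, replace = TRUE)
  parent <- peptide_sequence(paste(aa, collapse = ""),
                             start_number = start_number,
                             n_term_cap = "acetyl", c_term_cap = "amide")
  frags <- make_fragments(parent, window = window, step = step)
  centers <- frags$start_number + (window - 1) / 2
  mu <- baseline - core_depth * exp(-(centers - core_center)^2 / (2 * sigma^2))
  noiseless <- fragment_scores(frags, mu)
  true_core <- suppressWarnings(suppressMessages(
    call_core_region(aggregate_per_residue(noiseless), margin = margin)))
  scores <- fragment_scores(frags, mu + rnorm(length(mu), 0, noise_sd))
  list(scores = scores, parent = parent,
       truth = synthetic_truth("affinity_landscape",
                               list(core_center = core_center,
                                    core_depth = core_depth,
                                    baseline = baseline, sigma = sigma,
                                    core_region = true_core),
                               noise_sd, seed))
}

#' Named parameter scenarios for the synthetic generators
#'
#' The registry encodes the study conditions of the cargo/importin system the
#' package models (equilibrium, calorimetric, kinetic and hydrodynamic
#' parameter sets for PADI4 and its two NLS peptides against importin alpha-3
#' and its IBB-truncated species), read from
#' \code{inst/extdata/scenarios.json}.
#'
#' @param name Scenario name; omit to list all scenarios.
#' @return Named list of generator parameters (or a named list of all
#'   scenarios when \code{name} is missing).
#' @examples
#' scenario("padi4_impa3_itc")
#' @export
scenario <- function(name) {
  path <- system.file("extdata", "scenarios.json", package = "bindlab")
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (missing(name)) return(all)
  if (!name %in% names(all))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  all[[name]]
}
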