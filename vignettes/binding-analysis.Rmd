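---
title: "Quantifying NLS-importin binding: models, fits and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NLS-importin binding: models, fits and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindlab)
```

`bindlab` implements the quantitative analysis chain for a binding study of
a nuclear cargo protein (the citrullinating enzyme PADI4) and its two
candidate nuclear localization signal (NLS) peptides against the nuclear
carrier importin α3 and its IBB-truncated species. Four instruments, four
models: equilibrium fluorescence titrations, isothermal titration
calorimetry (ITC), biolayer interferometry (BLI) and diffusion-ordered NMR
(DOSY), plus a sliding-window fragment-docking aggregation scheme that
localizes the core binding region along an NLS sequence. Every stage has a
seeded synthetic generator so the whole chain is testable without
instrument data.

## Equilibrium titrations with ligand depletion

At the micromolar affinities and concentrations typical of NLS-importin
work, the bound complex is a substantial fraction of the total of both
species, so the hyperbolic ("excess ligand") isotherm is biased. With the
fixed species at total concentration $N$ and the titrant at total $S$, the
1:1 complex concentration is the smaller root of the mass-action quadratic,

$$[PL] = \tfrac{1}{2}\left[(S + N + K_d) - \sqrt{(S + N + K_d)^2 - 4SN}\right],$$

and the observed signal is $F = F_0 + \Delta F_{max}\,[PL]/N$. `depletion_model()`
evaluates this forward model and `fit_titration()` fits $(K_d, F_0,
\Delta F_{max})$ by Levenberg-Marquardt least squares. Either species may be
the fixed one (cargo held fixed while the carrier is titrated, or the
carrier held fixed while a peptide is titrated); the isotherm is symmetric
in the two totals, so both conventions share one implementation and the
`convention` flag only records the experiment's orientation. We treat
$\Delta F_{max}$ as the saturating signal amplitude, the dimensionally
consistent reading of the amplitude normalization.

Starting values are robust for monotone curves: $F_0$ from the first point,
$\Delta F_{max}$ from the last minus the first, $K_d$ from the titrant
concentration at half amplitude. Least squares is unweighted by default
(weights are accepted). Inner-filter attenuation is corrected with the
standard half-absorbance form $F_{corr} = F_{obs}\,10^{(A_{ex}+A_{em})/2}$,
exposed as a pluggable function.

```{r titration}
sim <- gen_titration(kd = 3.9, f0 = 100, dfmax = 80, fixed_conc = 3,
                     noise_sd = 1, seed = 42)
fit_titration(sim$series)
```

## Single-site ITC with background injection heat

The ITC forward model propagates cell totals through each injection of a
fixed-volume perfusion cell. While an aliquot $dV$ enters, well-mixed
content overflows at the same rate, so for $v = dV/V_0$ the macromolecule
dilutes as $M \to M e^{-v}$ and the ligand relaxes toward the syringe
concentration as $L \to L_s + (L - L_s)e^{-v}$ (the exact solution of the
perfusion equation). The 1:1 quadratic gives the complex before and after
each injection (with the stoichiometry $n$ acting as the fraction of
binding-competent macromolecule), and the measured heat is

$$q_i = \Delta H\, V_0 \left( [PL]_i - [PL]_{i-1} +
  v_i \tfrac{[PL]_i + [PL]_{i-1}}{2} \right) + q_{bg},$$

the trapezoidal term accounting for complex carried out with the displaced
volume. The constant per-injection background $q_{bg}$ is an adjustable fit
parameter: with glycerol-containing buffers the blank injection heat is
large, and fitting it avoids a separate blank titration. The first
injection is kept by default; `drop_first = TRUE` applies the common
practice of discarding it.

`fit_itc()` optimizes $(\log K_a, \Delta H, n, q_{bg})$ from three spread
starting points and warns when the Wiseman parameter $c = K_a[M]_0$ leaves
$[1, 10^4]$, where the isotherm carries little information. Confidence
intervals are by residual-resampling bootstrap
(`confidence_intervals_95()`), which reproduces the asymmetric intervals
typical of low-$c$ titrations; Hessian-based intervals would force
symmetry. The decomposition `thermo_derive()` uses $\Delta G = -RT\ln K_a$
with $R = 1.9872\times10^{-3}$ kcal mol$^{-1}$K$^{-1}$ at 298.15 K
(experiments at 25 °C) and reports $-T\Delta S = \Delta G - \Delta H$, so
the identity $\Delta G = \Delta H + (-T\Delta S)$ holds exactly. Note that
for a strongly exothermic binder ($K_a = 2.1\times10^5$ M$^{-1}$,
$\Delta H = -65.5$ kcal/mol) this yields $-T\Delta S = +58.2$ kcal/mol, a
positive (unfavorable) entropic term; a published table that prints the
same magnitude with a negative sign is inconsistent with its own $\Delta G$
and $\Delta H$ columns, and this package always reports the
sign-consistent value.

```{r itc}
sim <- gen_itc(ka = 2.1e5, dh = -65.5, n = 0.97, q_bg = -1.5,
               noise_sd = 0.2, seed = 7)
fit <- fit_itc(sim$experiment)
fit <- confidence_intervals_95(fit, n_boot = 100, seed = 7)
fit
thermo_derive(fit$ka, fit$dh)
```

## BLI kinetics: two-step pseudo-first-order analysis

Association phases are fitted to
$R(t) = R_{eq} - R_{eq} e^{-k_{obs}(t-t_0)}$ or, with a second transient,
$R(t) = R_{eq} - R_{eq} e^{-k_{obs}(t-t_0)} - R'_{eq} e^{-k'_{obs2}(t-t_0)}$.
The equilibrium response at infinite time is $R_{eq}$ in both forms — the
second exponential is a small transient that decays away — and the
larger-amplitude exponential is designated primary; its rate is the
concentration-dependent $k_{obs}$ used downstream, and a primary amplitude
fraction at or below 50% flags the fit. The single and double fits are
compared by a nested-model F test at the 95% level (`select_model()`), and
the double fit always starts one of its Levenberg-Marquardt runs from the
single-fit solution with a null second amplitude, which guarantees
nestedness (the double fit can never end with worse residuals).
Dissociation is always a single exponential $R_1 e^{-k_{off}(t-t_0)}$.

The study-level constants come from the pseudo-first-order line
$k_{obs} = k_{on} C + k_{off}$ across the concentration series
(`pseudo_first_order()`), not from a global multi-curve fit: the two-step
procedure keeps per-sensorgram misfit visible and matches how such data
are usually reduced. $K_d = k_{off}/k_{on}$ carries a delta-method standard
error and a Fieller interval for the coefficient ratio; with the default
five concentrations the regression has three residual degrees of freedom,
so $t$-quantiles (not 1.96) are essential for honest 95% intervals.

```{r bli}
sim <- gen_bli(kon = 0.0037, koff = 0.0685, seed = 3)
tab <- do.call(rbind, lapply(sim$sensorgrams, function(s) {
  fs <- fit_association(s, "single")
  fd <- fit_association(s, "double")
  fit <- if (select_model(fs, fd)$model == "double") fd else fs
  data.frame(conc_uM = s$analyte_uM, kobs = fit$kobs)
}))
pseudo_first_order(tab)
```

## DOSY hydrodynamics and oligomer inference

Gradient decays are fitted as $I(x) = I_0 \sum_i a_i e^{-D_i x}$ with one
or two species; $x$ is the instrument-normalized attenuation variable with
the diffusion-encoding prefactor $\gamma^2 g^2 \delta^2 (\Delta-\delta/3)$
folded in (`stejskal_tanner_x()` builds it when the raw gradient
parameters are available). Two-species fits are initialized from the
single-species solution with the split $(D, D/3)$, which is stable for the
roughly two-fold coefficient separation seen in self-associating peptides;
coefficients closer than a factor 1.5 are flagged indistinguishable, and a
fit that collapses onto the single-species boundary is returned as such
with a warning rather than failing.

Diffusion coefficients convert to hydrodynamic radii against an internal
dioxane reference measured in the same tube
($R_h = R_{h,ref} D_{ref}/D$ with $R_{h,ref} = 2.12$ Å,
$D_{ref} = 6.8\times10^{-6}$ cm$^2$s$^{-1}$), which cancels temperature and
viscosity exactly. The random-coil scaling $R_h = 0.027\,MW^{1/2}$ (nm, Da)
and its inverse then turn radii into apparent masses, and
`oligomer_order()` rounds the mass ratio half away from zero — a ratio of
5.8 calls a hexamer. Printed worked examples are only reproducible to
within their own rounding: a radius printed as 17 Å back-computes to
16.4 Å from the printed $D$, and a mass printed as 16,421.9 Da implies an
unrounded intermediate radius; the package reports its computed values and
leaves such residual differences visible.

```{r dosy}
sim <- gen_dosy(d_list = c(8.8e-7, 4e-7), amp_list = c(0.7, 0.3),
                noise_sd = 0.3, seed = 5)
fit <- fit_decay(sim$decay, n_species = 2)
fit
rh <- rh_from_reference(min(fit$d_values))
oligomer_order(mass_from_rh(rh), monomer_mass = 2819.27)
```

## Fragment docking aggregation

Peptides with more than ~100 rotatable dihedrals cannot be docked whole,
so the sequence is divided into seven-residue fragments shifted by two
(five residues shared between neighbors). Fragments carry methyl caps at
both termini — avoiding artefactual polar hydrogens that do not exist in
the parent main chain — except the last fragment, which keeps the parent's
C-terminal moiety. `aggregate_per_residue()` assigns each residue the
arithmetic mean of the scores of every fragment containing it; with window
7 and step 2 interior residues are covered by four fragments and the chain
ends by one, so terminal residues are flagged as less reliable.
`call_core_region()` takes the global minimum of the profile and extends
it to the contiguous run within a margin (default 0.5 kcal/mol — half of
the >1 kcal/mol separation that distinguishes a core region from the rest
of the profile, keeping the call compact). The docking engine itself is an
external, pluggable backend behind `run_backend()`, with CSV caching and a
mock-backend contract for tests; pose-to-site assignment
(`classify_pose_site()`) is by minimum backbone distance to reference
crystallographic NLS ligand coordinates (default cutoff 5 Å), because ARM
repeat residue ranges are structure-specific while a bound reference
ligand defines the site directly.

```{r fragscan}
sim <- gen_affinity_landscape(core_center = 68, core_depth = 2,
                              baseline = -6, noise_sd = 0.1, seed = 1)
prof <- aggregate_per_residue(sim$scores)
call_core_region(prof)
```

## What the synthetic generators emulate — and what they do not

Each generator produces data with the statistical structure its fitting
stage assumes, at the study's own design points: titrations of a 3 µM
fixed species with a grid to five times the larger of $K_d$ and the fixed
concentration; ITC schedules of 20 × 2 µL injections of 100 µM ligand
into a 200 µL cell at 10 µM; BLI series at 1-7 µM analyte with
association from 180 s and dissociation from 300 s, a minor phase below
5% amplitude, and noise of 2% of each sensorgram's equilibrium response
(matching the few-percent rate-constant precision such instruments
deliver); DOSY grids attenuating the signal to about 5% at the deepest
point, the usual design for resolving a slow component. Noise is
homoscedastic Gaussian throughout, because instrument residuals at these
signal levels are dominated by detector noise.

What passing recovery tests on these data does **not** show: robustness to
baseline drift, systematic blank mis-subtraction, mass-transport-limited
kinetics, concentration errors, or non-two-state binding — all real
phenomena the models deliberately exclude. The generators certify the
estimators, not the instruments.

Problem sizes used by the recovery benchmarks: 100 seeded replicates per
technique, with 100 bootstrap refits per ITC interval; these sizes give
binomial standard errors of about 2 percentage points on a 95% coverage
estimate, enough to distinguish calibrated intervals from broken ones.

## Numerical choices and edge cases

* The mass-action quadratic is evaluated in the numerically stable form
  $2SN/(b + \sqrt{b^2-4SN})$ inside the ITC model; a negative discriminant
  (impossible analytically) raises a defensive error in the titration
  model.
* All nonlinear fits are Levenberg-Marquardt (`minpack.lm`) with
  non-negativity bounds on rates and $K_d$, and small ladders of starting
  points; a fit that fails from every start raises an error naming the
  last iterate rather than returning silently.
* $K_a$ is optimized on the log scale; its standard error is mapped back
  by the delta method.
* Ties in `oligomer_order()` round half away from zero; base R's
  round-half-to-even would call a 2.5-fold ratio a dimer.
* Flat signals (titration, association, thermogram) are rejected with "no
  binding signal" errors; flat dissociations and flat affinity landscapes
  are flagged, not rejected, because a zero off-rate and a featureless
  landscape are legitimate results.
* If a peptide length minus window is not divisible by the step, the last
  exactly fitting window is used and a warning reports the uncovered
  tail; the study's two sequences tile exactly.

## Known limitations

Single-site 1:1 binding only — no two-site, cooperative or competitive
isotherms, and no bipartite-NLS two-transition ITC models. No raw
thermogram integration (inputs are per-injection heats), no
mass-transport or avidity corrections in BLI, no inverse-Laplace DOSY
distributions. The docking backend contract reports the engine's best
score per fragment; averaging over top poses is not implemented. Docking
scores from a real engine are stochastic; the aggregation and calling
layer is deterministic given scores.
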