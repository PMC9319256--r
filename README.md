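# bindlab

Quantitative analysis of protein–importin binding experiments in R.

Nuclear import of a cargo protein begins when importin α recognizes a short
nuclear localization signal (NLS) in the cargo. Characterizing that
interaction quantitatively takes several instruments at once — equilibrium
titrations for the dissociation constant, calorimetry for the full
thermodynamic profile, biosensor kinetics for the on/off rates, diffusion
NMR for the oligomeric state of the isolated peptides, and fragment
docking to localize the core binding region along the NLS sequence.
`bindlab` implements the full reduction chain for such a study (the
worked system is the citrullinating enzyme PADI4, its two candidate NLS
peptides, and importin α3 with and without its autoinhibitory IBB domain),
with seeded synthetic-data generators so every fitting stage is testable
end to end without instrument files.

## Models at the core

* **Equilibrium titrations with ligand depletion.** At micromolar
  affinities and concentrations the bound complex depletes both species,
  so the hyperbolic isotherm is biased. The signal is fitted with the
  quadratic mass-action isotherm
  `F = F0 + (ΔFmax/N)·½[(S+N+Kd) − √((S+N+Kd)² − 4SN)]`,
  where `N` is the fixed-species total and `S` the titrant total
  (`depletion_model()`, `fit_titration()`).
* **Single-site ITC.** Per-injection heats from a perfusion-cell forward
  model (exponential dilution of the cell totals, trapezoidal
  displaced-volume heat correction), with an adjustable constant
  background injection heat; nonlinear fit of `(Ka, ΔH, n, q_bg)`,
  residual-bootstrap 95% intervals, and the decomposition
  `ΔG = −RT ln Ka`, `−TΔS = ΔG − ΔH` (`single_site_heats()`, `fit_itc()`,
  `confidence_intervals_95()`, `thermo_derive()`).
* **BLI kinetics.** Exponential association fits (single or double, with
  the minor transient's amplitude below a few percent), nested-model
  F-test selection at 95%, single-exponential dissociation, and the
  pseudo-first-order line `kobs = kon·C + koff` across the concentration
  series, giving `Kd = koff/kon` with Fieller intervals
  (`fit_association()`, `select_model()`, `fit_dissociation()`,
  `pseudo_first_order()`).
* **DOSY hydrodynamics.** Mono/bi-exponential gradient-decay fits;
  hydrodynamic radii via an internal dioxane reference
  (`Rh = 2.12 Å · D_ref/D`); random-coil scaling `Rh = 0.027·MW^½`
  (nm, Da) and oligomer-order inference from the mass ratio
  (`fit_decay()`, `rh_from_reference()`, `oligomer_order()`).
* **Fragment-docking aggregation.** Seven-residue/two-step sliding-window
  fragments (methyl-capped except the parent's own C-terminus), per-residue
  score = mean over covering fragments, core-region calling around the
  global minimum, and pose-to-binding-site classification against
  reference ligand coordinates (`make_fragments()`,
  `aggregate_per_residue()`, `call_core_region()`,
  `classify_pose_site()`).

## Worked example

```r
library(bindlab)

# the 27-residue NLS1 peptide, parent numbering 58-84
nls1 <- peptide_sequence("AKKKSTGSSTWPLDPGVEVTLTMKVAS", start_number = 58)
average_mass(nls1)                 # 2819.27 Da
random_coil_rh(average_mass(nls1)) # 14.3 A, random-coil expectation

# equilibrium titration at 1% noise, truth Kd = 3.9 uM
sim <- gen_titration(kd = 3.9, f0 = 100, dfmax = 80, fixed_conc = 3,
                     noise_sd = 1, seed = 1)
fit_titration(sim$series)
#> Ligand-depletion titration fit
#>   Kd    = 3.87 +/- 0.27 uM
#>   F0    = 99.49 +/- 0.74
#>   dFmax = 81.2 +/- 1.3
#>   residual norm = 2.458 (12 points)

# calorimetric titration, truth Ka = 7.8e5 M^-1, dH = -38.4 kcal/mol, n = 0.84
simI <- gen_itc(ka = 7.8e5, dh = -38.4, n = 0.84, q_bg = -1.5,
                noise_sd = 0.2, seed = 1)
f <- confidence_intervals_95(fit_itc(simI$experiment), n_boot = 100, seed = 1)
f
#> Single-site ITC fit
#>   Ka  = 6.19e+05 M^-1  (Kd = 1.61 uM)
#>   dH  = -41.6 kcal/mol
#>   n   = 0.836
#>   q_bg = -1.32 ucal/injection
#>   95% CI (bootstrap):
#>     ka    (4.43e+05, 9.81e+05)
#>     kd_uM (1.02, 2.26)
#>     dh    (-46.6, -36.3)
#>     n     (0.784, 0.886)
#>     q_bg  (-1.68, -1.01)
thermo_derive(f$ka, f$dh)
#> dG = -7.90 kcal/mol, dH = -41.55 kcal/mol, -TdS = 33.65 kcal/mol (T = 298.15 K)

# biosensor kinetics, truth kon = 0.0037 uM^-1 s^-1, koff = 0.0685 s^-1
simB <- gen_bli(kon = 0.0037, koff = 0.0685, seed = 3)
tab <- do.call(rbind, lapply(simB$sensorgrams, function(s) {
  fs <- fit_association(s, "single"); fd <- fit_association(s, "double")
  fit <- if (select_model(fs, fd)$model == "double") fd else fs
  data.frame(conc_uM = s$analyte_uM, kobs = fit$kobs)
}))
pseudo_first_order(tab)
#> Pseudo-first-order kinetic fit
#>   kon  = 0.004505 +/- 0.00051 uM^-1 s^-1
#>   koff = 0.06566 +/- 0.0021 s^-1
#>   Kd   = 14.57 +/- 2.1 uM
```

Each generating truth sits inside the reported intervals; single
replicates of a low-c calorimetric titration are individually imprecise
(that is what the bootstrap intervals say), while the recovery benchmarks
in the test suite verify that across 100 seeded replicates the estimators
are unbiased and the intervals hold their nominal 95% coverage.

A scenario registry (`scenario()`) names the study's parameter sets — for
example `scenario("padi4_impa3_itc")` for the cargo/carrier calorimetric
titration — and `dispatch()` exposes the whole chain as subcommands
(`simulate`, `fit-titration`, `fit-itc`, `fit-bli`, `dosy`,
`fragscan aggregate`, `peptide mass|fragments`) for scripted use, e.g.
`Rscript inst/cli/bindlab.R peptide mass AKKKSTGSSTWPLDPGVEVTLTMKVAS`.

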