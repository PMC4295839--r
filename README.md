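# promkin

Quantitative inference of promoter regulation from reporter-gene microplate
time series, built around the FliA–FlgM module of *E. coli* motility: a
sigma factor (FliA) activates class-3 flagellar promoters, its anti-sigma
factor (FlgM) sequesters it, and the activity of the gene-expression
machinery modulates everything globally.

The package covers the full chain from raw plate reads to a fitted
mechanistic regulation function:

1. **Preprocess** — background correction, weighted smoothing splines,
   growth rate `mu(t)`, reporter concentrations and promoter activities
   with 2·SEM confidence bands (`read_plate_table()`, `process_plate()`).
2. **Reconstruct** — protein concentrations from promoter activities by
   integrating `dp/dt = f − (γ_p + μ) p` with preculture steady-state
   initial conditions; grids of candidate half-lives
   (`protein_concentration()`, `precompute_profiles()`).
3. **Regulation model** — free sigma-factor concentration under anti-sigma
   titration (a numerically safe quadratic), Hill activation, and a
   constitutive-promoter multiplier for global physiological effects
   (`free_fliA()`, `hill_activity()`, `global_activity()`,
   `alpha_activity()`).
4. **Fit** — weighted misfit `Q`, box constraints from the data, seeded
   Latin-hypercube multistart Nelder–Mead with incumbent polish, returning
   a classed `regfit` with `print`/`coef`/`summary`/`predict`/`plot`/
   `simulate`/`residuals` methods; joint half-life estimation by grid
   search; bootstrap-style confidence intervals (`fit_regulation()`,
   `fit_with_halflives()`, `bootstrap_cis()`).
5. **Sign patterns** — qualitative network validation: enumerate all
   activator/repressor/absent assignments consistent with monotonicity of
   the data, classify the expected circuit green/yellow/red, map verdicts
   over half-life grids (`minimal_sign_patterns()`, `classify_expected()`,
   `halflife_pattern_map()`).
6. **Simulation studies** — biases of simplified fits: misfit of
   activities-as-proxies versus regulator half-life, and of ignoring global
   effects versus their strength (`halflife_misfit_scan()`,
   `alpha_misfit_scan()`).
7. **Synthetic data** — a full forward generator (growth, pulses, reporter
   kinetics, measurement noise, background wells) with ground truth
   (`default_scenario()`, `simulate_scenario()`).
8. **Command line** — `promkin_cli()` / the installed `exec/promkin`
   script: `simulate`, `preprocess`, `reconstruct`, `fit`, `signpatterns`,
   `simstudy`, `run-all`, driven by a key-value config file, with
   provenance records and machine-readable reports.

## Quick start

```r
library(promkin)

# synthetic five-condition experiment with known ground truth
sim  <- simulate_scenario(default_scenario(seed = 1))
proc <- process_plate(read_plate_table(sim$plate))

# fit the titration/Hill regulation function with global effects,
# regressing on protein concentrations reconstructed at the measured
# half-lives (FliA 30 min, FlgM 18 min)
dat <- build_fit_dataset(proc, "proteins", tau_A = 30, tau_M = 18)
fit <- fit_regulation(dat, model = "hill_global", n_starts = 20, seed = 1)
print(fit)
plot(fit)

# estimate the half-lives from the data instead
parts <- promkin:::.profiles_for_halflife_fit(proc)
hl <- fit_with_halflives(parts$target, parts$fliA, parts$flgM,
                         parts$fconst, parts$mu,
                         halflives = c(7, 12, 18, 30, 60),
                         preculture = parts$preculture)
hl$half_lives[c("tau_A", "tau_M")]

# is the expected circuit (FliA +, FlgM -, global +) necessary?
classify_expected(as_regulation_data(dat),
                  sign_pattern(fliA = 1, flgM = -1, global = 1))

# compare the four analysis configurations
compare_configurations(proc)$table
```

Or from the shell:

```sh
promkin simulate  --config my.cfg
promkin run-all   --config my.cfg
promkin fit --show-config       # print all configurable defaults
```

## Input format

Plate tables are tidy CSVs with one row per (well, time):
`condition, well, reporter, replicate, role, time_min, absorbance,
fluorescence`, where `role` is `reporter`, `background_medium` (medium
blank) or `background_strain` (non-fluorescent strain for autofluorescence
correction) and `reporter` names the promoter construct (`fliA`, `flgM`,
`tar`, `pRM`, ... ; `NA` for background wells).

## Acceptance run

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

writes the main computed quantities (recovered parameters and their errors,
half-life argmin, sign-pattern verdicts, simulation-study trend statistics,
configuration misfits) as a flat JSON object, reproducibly for the given
seed.

## Tests

```r
testthat::test_dir("tests/testthat", package = "promkin",
                   load_package = "installed")
```

The suite contains unit and property tests per module plus acceptance-level
tests of the full pipeline. One expectation is red by design of the data,
not of the code: on this synthetic scenario the sequestration dip that
makes FlgM *necessary* in the sign-pattern sense also lets the data exclude
long FlgM half-lives, so the expected pattern cannot be green on ≥90% of a
full-range half-life grid; see the package vignette for the analysis.
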