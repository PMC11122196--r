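# rifkin

Absorbed-dose-driven kinetics of radiation-induced DNA double-strand-break
foci in patient blood during radionuclide therapy.

## The problem

During radioiodine therapy of thyroid cancer, the ^131I circulating in a
patient's body irradiates their blood continuously for days. DNA
double-strand breaks (DSBs) in peripheral blood mononuclear cells — counted
microscopically as co-localising γ-H2AX + 53BP1 foci ("radiation-induced
foci", RIF) — are therefore induced by a *decaying dose rate* while repair
removes them at the same time, unlike the pulse-and-decay picture after
external irradiation. `rifkin` is for physicists and biostatisticians in
nuclear medicine who want to turn serial blood activity measurements and
focus counts into patient-specific induction and repair parameters.

## The model

The absorbed dose rate to the blood combines a β self-irradiation term from
the blood activity concentration and a photon term from the whole-body
activity:

    dD/dt(t) = A0 · [ Dk_β · f_bl(t) + Dk_γ · wt^(−2/3) · f_wb(t) ]

where `f_bl` and `f_wb` are decay-inclusive bi-exponential clearance curves
fitted to the measured time–activity data, `A0` is the administered activity
and `wt` the body weight. RIF per cell follow a linear one-compartment model
with two repair pools: a fraction `α` of the induced damage is repaired fast
(rate `k1`), the rest slowly (rate `k2`):

    dN1/dt = −k1·N1 + α·c·dD/dt
    dN2/dt = −k2·N2 + (1−α)·c·dD/dt,      N(t) = N1 + N2 + N0

with induction constant `c` (foci per cell per mGy) and intercept `N0`. For
bi-exponential dosimetry the solution is closed-form (sums of exponential
differences); `rifkin` implements both the closed form and a numerical ODE
reference. Parameters are estimated per patient by 1/σ²-weighted
Levenberg–Marquardt with Poisson counting uncertainties propagated through
the baseline subtraction, followed by the cohort analysis: exclusion rules,
stratification into slow/fast-repair groups by `k1`, pooled group fits,
k-means clustering on `(k1, k2, c)`, and a normality-routed
correlation/group-comparison battery.

## Worked example

```r
library(rifkin)

# simulate an 18-patient radioiodine cohort at study scale
cohort <- generate_cohort(generator_config(n_patients = 18, seed = 42))
tables <- cohort_to_tables(cohort)

# dosimetry -> RIF preprocessing -> kinetic fits -> cohort statistics
res <- run_pipeline(tables, reference_dose_coefficients())
head(res$fits[, c("patient_id", "c", "k1", "k2", "r2", "n_points", "excluded", "group")])
#>   patient_id          c        k1          k2        r2 n_points excluded      group
#> 1       SP01 0.02086921 0.3332664 0.001968629 0.9701435        9    FALSE          1
#> 2       SP02 0.06918904 1.8693573 0.024908044 0.9901390        8    FALSE          2
#> 3       SP03 0.03656000 1.3660273 0.067645884 0.9370528        8    FALSE          2
#> 4       SP04 0.05713528 1.0233627 0.000000000 0.9777616        9    FALSE unassigned
#> 5       SP05 0.02454218 0.4704095 0.001133078 0.8246449        8    FALSE          1
#> 6       SP06 0.01643305 0.6356481 0.154521157 0.8157200        9     TRUE       <NA>
```

Each row is one patient: `c` is the damage induction constant (mGy⁻¹), `k1`
and `k2` the fast and slow repair rates (h⁻¹), `n_points` the number of fitted
RIF values (the pre-therapy baseline counts as one), and `excluded` flags
patients failing the protocol rules (too few points, or a standard error
above twice the parameter). `group` stratifies by `k1` (`1` slow, `2` fast,
`unassigned` in the 0.6–1.1 h⁻¹ gap).

```r
# the early-time dose response of the pooled cohort
res$linear$induction
#> N = (0.0072 +/- 0.0017) * D [mGy] + (0.2334 +/- 0.0527), r2 = 0.219, n = 69
```

The slope is the effective early induction coefficient: about 0.007 foci per
cell and mGy in this simulated cohort, of the same order as the induction
constant recovered by the full kinetic model once repair is accounted for.

```r
# published-cohort statistics recomputed from the shipped reference tables
rep <- reproduce_tables()
rep[c(1, 2, 6, 12, 15), ]
#>                   quantity   computed published pass
#>          median c [mGy^-1]  0.0260000   0.02600 TRUE
#>             mean alpha [%] 95.6142857  96.00000 TRUE
#>            spearman(k1, c)  0.9471389   0.94700 TRUE
#>  kmeans centroid k1 (slow)  0.3742857   0.37429 TRUE
#>  kmeans centroid k1 (fast)  1.3208000   1.32080 TRUE
```

## Layout

- `R/` — dosimetry, kinetics, fitting, cohort statistics, synthetic-cohort
  generator, pipeline.
- `inst/extdata/` — reference cohort tables (clinical covariates and
  per-patient fit parameters) and the example dose-coefficient config.
- `vignettes/rif-kinetics.Rmd` — the methods vignette: model assumptions,
  parameter meanings, numerical choices, generator design and limitations.
- `tests/testthat/` — unit, property and acceptance tests.
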