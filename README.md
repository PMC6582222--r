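# smdkin

Free-energy and kinetic analysis of stepwise chemical transformations
studied by steered molecular dynamics (SMD), at desk scale.

The package is aimed at computational chemists who work with per-step
activation and reaction free energies — typically obtained by pulling a
reaction coordinate with SMD and converting the nonequilibrium work into
Gibbs free energies via the Jarzynski equality — and who want the full
downstream chain in one tested place: transition-state-theory kinetics,
free-energy profile composition across multi-step pathways, work-ensemble
estimation with uncertainty, and a small steered Langevin engine with
analytic benchmarks to validate the whole pipeline.

Its bundled reference system is the water- and formic-acid-assisted
adenine → guanine transition (deamination to hypoxanthine, oxidation to
xanthine, amination to guanine; two elementary steps each) in gas and
aqueous solution phases at 298.15 K.

## The core quantities

For a step with activation free energy ΔG‡ and reaction free energy ΔG
(kcal·mol⁻¹) at temperature T:

    K   = exp(−ΔG / RT)                 equilibrium constant
    k_f = (k_B T / h) exp(−ΔG‡ / RT)    Eyring forward rate constant, s⁻¹
    k_r = (k_B T / h) exp(−(ΔG‡ − ΔG)/RT)
    τ   = 1 / k_r                       lifetime of the step's product, s

Steps compose into profiles of alternating stationary/transition levels;
the pathway's global activation free energy is the maximum cumulative
transition level, its global reaction free energy the final level, and
the transition state at the maximum is the rate-determining step.

Work ensembles from repeated pulls convert to free energies with the
Jarzynski exponential average, `ΔG = −RT ln ⟨exp(−W/RT)⟩` (log-sum-exp
implementation), with a second-cumulant diagnostic and percentile
bootstrap confidence intervals.

## Worked example

```r
library(smdkin)

# 1. derived kinetics of the bundled step-energetics table
tab <- ag_energetics("gas")
head(annotate_steps(tab[, c("label", "phase", "dG_act", "dG_rxn")]), 3)
#> Step kinetics at T = 298.15 K (3 rows)
#>      label phase dG_act dG_rxn        K      k_f dG_rev      k_r      tau
#>    1A-step   gas  61.11  21.72 1.20e-16 9.98e-33  39.39 8.32e-17 1.20e+16
#>    2A-step   gas  47.72 -27.48 1.39e+20 6.52e-23  75.20 4.69e-43 2.13e+42
#>  A-process   gas  71.05  -5.76 1.67e+04 5.17e-40  76.81 3.10e-44 3.23e+43

# 2. compose the lowest-cost A-C-E pathway and read off the global result
st <- ag_pathway("gas", "process")
pathway_global(lapply(split(st, st$process), compose_profile))
#> Composed pathway at T = 298.15 K
#>   global dG_act = 74.15 kcal/mol (rate-determining TS: TS4)
#>   global dG_rxn = 4.47 kcal/mol
#>   K = 5.29e-04   k = 2.76e-42 s^-1   tau = 1.92e+38 s

# 3. Jarzynski estimation on synthetic near-equilibrium work
#    (Gaussian work with mu = 10, sigma^2 = 2RT implies dG = 9 exactly)
s <- gen_gaussian_works(10, 1.18497, n = 1e5, seed = 1)
bootstrap_ci(s, "exponential", B = 1000, seed = 1)
#> dG = 8.9869 kcal/mol (exponential estimator, n = 100000, seed = 1)
#>   95% bootstrap CI [8.9678, 9.0063]
```

The first block says that the initial nucleophilic attack of water on
adenine (step 1A) faces a 61.11 kcal·mol⁻¹ barrier and is strongly
endergonic, while the subsequent proton transfer (2A) is the most
exergonic step, making hypoxanthine extremely long-lived (τ ≈ 10⁴² s).
The second block composes the three processes: the global transformation
is limited by TS4 — the rupture of the formate–base linkage during
oxidation — with a 74.15 kcal·mol⁻¹ cumulative barrier, and is slightly
endergonic overall. The third block recovers a known free-energy
difference from synthetic work values to ~0.01 kcal·mol⁻¹.

A steered Langevin engine (`toy_system()`, `run_pull_ensemble()`) and
analytic benchmarks (`gen_pull_benchmark()`) validate the simulation →
estimation chain end to end; see the methods vignette
(`vignettes/smdkin-methods.Rmd`) for the model, parameter defaults and
their rationale.

A command-line wrapper is installed at `exec/smdkin` (subcommands
`kinetics`, `compose`, `jarzynski`, `pull`, `synth`, `geometry`); the
same functionality is exported as `run_cli()`.

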