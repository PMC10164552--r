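# nmrcsp

Chemical shift perturbation (CSP) analysis for protein-observed NMR
titrations in the fast-exchange regime.

When a ¹⁵N-labelled protein is titrated with a ligand and followed by
¹H–¹⁵N HSQC spectra, each residue's amide peak drifts from its apo position
toward its bound position. `nmrcsp` turns the per-point peak lists of such
an experiment into binding answers:

1. **Track** each residue's peak across titration points (by assignment, or
   by nearest neighbour in the weighted shift plane for unassigned lists),
   flagging unassigned (`*`), overlapped (`**`) and broadened (`***`)
   residues.
2. **Quantify** the perturbation at every point as
   Δδ = √(Δδ<sub>H</sub>² + (0.154·Δδ<sub>N</sub>)²).
3. **Classify** significantly perturbed residues: Δδ above the mean + 2 SD
   of all residues after trimming the 10 % with the largest Δδ (so the
   binders themselves don't inflate the statistic).
4. **Fit** each significant residue independently to the single-site
   binding isotherm that accounts for ligand depletion,

   Δδ = Δδ<sub>max</sub> · ( ([L]+[P]+K<sub>d</sub>) −
   √( ([L]+[P]+K<sub>d</sub>)² − 4[P][L] ) ) / (2[P]),

   the regime where ligand concentrations are comparable to the 0.1 mM
   protein concentration and the free ≈ total approximation fails.
5. **Aggregate** the per-residue K<sub>d</sub>s into the reported
   mean ± SD, reporting a mean below [P]/10 as an upper limit
   ("< 0.01 mM"), and **compare** conditions (binding-deficient mutants,
   ternary experiments with a pre-bound second ligand) by fold-change with
   a Welch test across residues.

A seeded simulator (`simulate_titration()`, `simulate_scenario()`)
generates fast-exchange titrations with known ground truth — binder
subsets, per-residue Δδ<sub>max</sub>, noise, broadening dropout — and
backs every stage's tests.

## Worked example

```r
library(nmrcsp)

cfg <- simulation_config(seed = 1)       # 0.1 mM protein, ratios 0-6,
sim <- simulate_titration(cfg)           # true Kd 0.025 mM, 15% binders
bundle <- run_pipeline(sim)
#> track: 100 residues over 8 points (simulated)
#> csp_profile: reference point 7, 99 residues with defined CSP
#> significance: threshold 0.0387 ppm, 14 significant residue(s)
#> aggregate: Kd = 0.026 ± 0.007 mM from residues 1, 7, 14, 27, 34, ...
bundle$aggregate
#> <aggregate_kd> Kd = 0.026 ± 0.007 mM (n = 14 residue(s))
```

The threshold (0.0387 ppm) is the "grey line" of a per-residue CSP profile
plot; the 14 residues above it are the binding-site reporters, and the
aggregate 0.026 ± 0.007 mM recovers the simulation's true 0.025 mM. A
mutant with 8-fold weaker designed affinity, analysed through the same
pipeline and compared run-vs-run:

```r
pair <- simulate_scenario(cfg, scenario("mutant", kd_scale = 8))
cmp <- compare_runs(run_pipeline(pair$condition, verbose = FALSE),
                    run_pipeline(pair$reference, verbose = FALSE))
cmp
#> <run_comparison> simulated_mutant vs simulated_reference
#>   Kd: 0.18 ± 0.056 mM vs 0.026 ± 0.007 mM; fold-change (A/B): 7.2
#>   Welch two-sided p = 8.08e-08
```

Real data enter through `read_peaklist()` (headed CSV or Sparky-style
`.list`) and `read_series_config()` (a small YAML naming the protein
concentration, the molar-ratio schedule and one peak list per point);
`run_pipeline()` also accepts the config path directly and can write a
per-residue TSV, a one-row summary TSV and a structure-attribute file for
molecular-graphics colouring. A thin command-line front end with
`simulate` / `run` / `compare` subcommands ships in `inst/cli/nmrcsp.R`.

See `vignettes/csp-titration-analysis.Rmd` for the model, the conventions
inside the significance rule, fitting details and known limitations.

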