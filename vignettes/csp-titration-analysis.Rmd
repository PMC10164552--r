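---
title: "Chemical shift perturbation analysis of fast-exchange titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical shift perturbation analysis of fast-exchange titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcsp)
```

## The measurement and the model

In a protein-observed NMR titration, a ¹H–¹⁵N HSQC spectrum is recorded on
an isotopically labelled protein at a fixed concentration \[P\] while a
ligand is added in steps of increasing molar ratio. When binding is in fast
exchange on the chemical-shift timescale, each residue's amide peak sits at
the population-weighted average of its free and bound positions, so the
peak slides continuously along a straight line from the apo position toward
the bound position as the ligand is titrated in.

The displacement of a peak between the apo spectrum and a titration point is
summarised by the normalized chemical shift perturbation

$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2},$$

where the 0.154 weight compresses the ¹⁵N axis to the effective dispersion
of the ¹H axis. `compute_csp()` implements this; the same weighted metric is
used for peak tracking (`track_residues()`), so quantification and geometry
are consistent.

Because NMR needs high protein concentrations (0.1 mM here), ligand is
depleted by binding: the free-ligand concentration cannot be approximated by
the total. The bound fraction then follows the closed-form root of the
mass-action quadratic, and the observed CSP of a residue with saturation
perturbation $\Delta\delta_{max}$ is

$$\Delta\delta = \Delta\delta_{max}\,
  \frac{([L]+[P]+K_d) - \sqrt{([L]+[P]+K_d)^2 - 4[P][L]}}{2[P]}.$$

`predict_csp()` evaluates this in the conjugate form
$2[L]/(s + \sqrt{s^2 - 4[P][L]})$, $s = [L]+[P]+K_d$, which is algebraically
identical but avoids catastrophic cancellation when $K_d \gg [P]$. The
implementation is tested against an independent bisection solver of the
mass-action equilibrium to $10^{-9}$ over a wide grid, and against its three
analytic limits (stoichiometric line at $K_d = 0$, non-depleted hyperbola at
$K_d \geq 100[P]$, saturation at $[L] \to \infty$).

## Which residues count: the trimmed significance rule

Many residues shift a little for uninteresting reasons; the ones that report
the binding site shift a lot. A residue is called significantly perturbed
when its $\Delta\delta$ at the reference point (by default the last
titration point) strictly exceeds

$$\text{mean} + 2 \times \text{SD}$$

of the per-residue CSPs **after removing the 10 % of residues with the
largest CSP from the statistic**. Trimming matters: the expected binders are
exactly the residues that would otherwise inflate the mean and SD and mask
themselves. Trimmed residues remain eligible for the significance call —
only the statistic excludes them. Residues with no defined CSP (unassigned
in the apo spectrum, overlapped, or broadened beyond detection — the `*`,
`**`, `***` categories) are excluded entirely.

Conventions the rule needs but that admit choices:

* **Trim count** is `ceiling(0.10 * N)` — conservative, removing at least
  one residue whenever trimming is requested. Ties at the trim boundary are
  broken by residue number, the lower number staying in the statistic.
* **SD denominator.** We use the population SD (divisor $n$), the default of
  the numerical tooling this analysis style is built on. With the 80–100
  residues of a typical domain the difference from the sample SD is well
  under 1 % and no significance call in our test fixtures changes; the
  package's worked examples and oracle tests fix the convention so it cannot
  drift silently.
* **Strict inequality**: a residue exactly at the threshold is not
  significant. With all CSPs equal the threshold equals the common value and
  the significant set is empty.

A property worth understanding before trusting any "recovered the planted
binders" claim: a mean + 2 SD threshold on ~90 noise-only residues *will*
let the occasional upper-tail noise excursion through (the noise CSP is
Rayleigh-like and its tail fraction is scale-invariant, so lowering the
noise does not help). Exact recovery of a planted binder set is therefore
only guaranteed at zero noise; under noise the guarantee is that every
strong binder is flagged and false positives are rare and marginal. The test
suite asserts exactly that, no more.

Also note the interaction between the binder fraction and the trim
fraction: if more than 10 % of residues are genuine binders, the trimmed
statistic still contains binders, the threshold moves into the binder
$\Delta\delta_{max}$ distribution, and weak binders are — by design of the
rule — not called. That is a property of the published rule, not an
implementation artifact.

## Per-residue fitting and the reported Kd

Each significant residue is fit independently by nonlinear least squares of
the depletion isotherm against its $(\,[L], \Delta\delta\,)$ curve
(`fit_residue()`, Levenberg–Marquardt via minpack.lm), with its own
$\Delta\delta_{max}$; there is no global shared-$K_d$ fit, because the
reported value is defined as the **average of individual residue $K_d$s**
(with across-residue sample SD) — `aggregate_kd()`. Fitting details:

* starts: $\Delta\delta_{max,0} = 1.2\times$ the largest observed CSP;
  $K_{d,0}$ = the linearly interpolated ligand concentration at half-maximal
  CSP; multi-start fallback at $K_{d,0} \in \{0.1, 1, 10\}\times[P]$ if the
  first attempt does not converge, keeping the lowest-RSS solution;
* bounds: $K_d \geq 0$, $\Delta\delta_{max} > 0$; a fit settling on the
  $K_d = 0$ bound is reported converged and handled by the upper-limit rule;
* at least 4 observed points (including the apo zero) and at least 2
  nonzero CSPs are required; a residue whose largest CSP stays below 3× the
  CSP noise floor (default 0.002 ppm) is flagged a non-binder and not fit;
* non-converged or non-binder fits among the significant residues are
  listed in the aggregate's diagnostics, never averaged.

**Upper-limit rule.** A protein-observed titration cannot quantify binding
much tighter than the protein concentration: below $[P]/10$ the curve is
indistinguishable from the stoichiometric line. An aggregate mean $K_d$
strictly below $[P]/10$ is therefore reported as "< $[P]/10$ mM"
(`apply_upper_limit()`); a mean exactly at the limit remains a point value.

**Condition comparisons.** `compare_kd_sets()` reports the fold-change of
the mean $K_d$ (A over B) and a two-sided Welch two-sample t-test on the two
per-residue $K_d$ sets; Welch is our choice for across-residue scatter with
no variance pooling, and the output labels it. When either aggregate is an
upper limit, `compare_runs()` reports the fold-change as a bound, since one
of the means is itself only a bound.

## What the simulator emulates — and what it does not

`simulate_titration()` generates ground-truthed series with the statistical
structure the analysis assumes: linear two-state fast-exchange trajectories
(bound fraction from the same depletion quadratic, direction drawn per
residue, $\Delta\delta_{max}$ log-uniform), Gaussian peak-position noise at
every point *including the apo reference* (so CSPs carry a shared apo-noise
offset, as in real data), a deterministic stratified binder subset (exactly
$\lceil f \cdot n\rceil$ binders, stable as the panel grows), and sticky
broadening dropout of binders past half saturation. Residues consume
independent per-residue random streams derived from one master seed, so
enlarging the panel does not perturb existing residues, and the caller's
RNG state is left untouched.

Defaults mirror a realistic tight-binding experiment: $[P] = 0.1$ mM, ratio
schedule $0, 0.1, 0.25, 0.5, 1, 2, 4, 6$, true $K_d = 0.025$ mM, 100
residues of which 15 % report binding with
$\Delta\delta_{max} \in [0.05, 0.3]$ ppm,
$\sigma_H = 0.005$ / $\sigma_N = 0.02$ ppm, 2 % per-point broadening
probability.

Not emulated: lineshapes and intensities (beyond presence/absence),
intermediate-exchange curvature of trajectories, relaxation, titration
dilution of the protein. Passing tests on these simulations therefore
validate the *analysis chain* — tracking, thresholding, fitting,
aggregation — under the model's own assumptions; they say nothing about
peak-picking quality or exchange-regime violations in real spectra.

## Numerical choices and problem sizes

* Tracking: nearest-neighbour assignment (used only for unassigned peak
  lists) shares the 0.154-weighted metric; `max_step` 0.05 ppm rejects
  implausible jumps, `merge_tol` 0.01 ppm marks unresolvable peak pairs,
  both sticky and symmetric, both configurable. These are engineering
  defaults at typical HSQC digital resolution.
* Optimizer tolerances: parameter/residual tolerances $10^{-12}$/$10^{-14}$,
  10 000 function evaluations — noiseless inversion is exact to
  $10^{-4}$ relative or better in the tests.
* Reported precision: display strings round to 2 significant figures
  ("0.025 ± 0.008 mM" style); files carry full precision, and every file
  writer is deterministic (byte-identical rewrites) with exact numeric
  round-trips.
* Test problem sizes: oracle grids of a few thousand points, 100 noisy
  replicates per $K_d$ for recovery, 50 replicate pairs for the fold-change
  study, 1000-residue panels only for distributional checks — sizes chosen
  so the entire suite exercises every claim in a few minutes on one core.

## Known limitations

* A $K_d$ near the top of the quantifiable range ($\sim 10\times[P]$) is
  recoverable to ~20 % median error only when the schedule reaches
  $[L] \approx K_d$ (e.g. the ratio-10 schedule); with the ratio-6 schedule
  the weak-binding tail of the isotherm is unsampled and per-residue
  estimates scatter more than 30 %. Choose schedules accordingly.
* The significance rule has no multiple-testing control; it is the field's
  descriptive convention, not an error-rate guarantee.
* Fold-changes of upper-limited aggregates are bounds; the Welch p-value is
  not meaningful in that case and comparisons should be read qualitatively.
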