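---
title: "Probabilistic modeling of volume-overload hypertrophy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic modeling of volume-overload hypertrophy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voHypertrophyNet)
```

## The problem

Chronic ventricular volume overload (VO) — experimental mitral
regurgitation in dogs, aorto-caval shunt in rats — produces eccentric
hypertrophy: myocytes lengthen by adding sarcomeres in series and the
left ventricle dilates with little wall thickening. The remodeling is
driven simultaneously by altered mechanics (end-diastolic myofiber
stretch) and by a neurohormonal response (elevated circulating AngII,
NE, ET1, ANP, BNP). Disentangling the relative influence of these
stimuli requires integrating many heterogeneous animal studies, each
reporting only a mean and a standard deviation of some fold change at
some time point.

This package implements a probabilistic meta-analysis pipeline around a
logic-based ODE model of cardiomyocyte hypertrophic signaling:

1. cross-species time normalization and fitting of time-varying
   hormonal fold-change curves (`fitGrowthTimescale`, `normalizeTime`,
   `fitStimulusCurve`);
2. a thin-walled-sphere model of end-diastolic stretch and Lagrangian
   strain with growth feedback, mapped onto the network's mechanical
   input (`strainTrajectory`, `myoStrainMap`);
3. normalized-Hill logic-network simulation (`parseModelTables`,
   `simulateNetwork`, `steadyState`);
4. two-stage Metropolis–Hastings/Gibbs calibration of input reaction
   weights against mean ± SD observations (`calibrateNetwork`);
5. Monte Carlo scenario ensembles — untreated VO, agonist infusion,
   receptor blockade — with confidence intervals, a 75% classification
   rule, coverage counts and Pearson-correlation sensitivity
   (`simulateScenario` and friends); and
6. a synthetic-data module that generates toy networks and
   literature-like observation tables from known ground truth, so the
   entire pipeline is testable without any external data
   (`makeToyNetwork`, `syntheticTruth`, `generateObservations`).

The published 106-node, 192-reaction hypertrophy-signaling network is
distributed by its authors as a spreadsheet for the Netflux tool; this
package reads that table dialect (`parseModelTables`) but does not
bundle the network itself. All shipped analyses run on a bundled
eight-node synthetic analogue (`makeToyNetwork("vo")`) that preserves
the structural motifs that matter for the method: per-hormone receptor
inputs, a mechanical input, a shared background input, OR-convergence
on a Ras-like hub, opposing gene outputs, and a slow cell-size output.
Quantitative predictions on the synthetic network are therefore
method demonstrations, not reproductions of the published model's
numbers.

## The network model

Each node carries a normalized activity $y \in [0, y_{max}]$. A
reaction with rule `"!A & B => C"` contributes the activation
$w \prod_i \phi_i$, where $\phi_i = f(y_i)$ for activators and
$1 - f(y_i)$ for inhibitors, and $f$ is the normalized Hill function

$$f(x) = \frac{B x^n}{K^n + x^n}, \qquad
B = \frac{EC_{50}^n - 1}{2\,EC_{50}^n - 1},\; K^n = B - 1,$$

fixed so that $f(0)=0$, $f(EC_{50})=\tfrac12$, $f(1)=1$. Reactions
sharing a target OR-combine by inclusion–exclusion
($a + b - ab$); input rules (`"=> X"`) contribute their weight
directly. Node dynamics follow

$$\frac{dy}{dt} = \frac{y_{max}\,\mathrm{drive}(t) - y}{\tau},$$

with category-driven time constants in normalized time $t/\tau$:
0.005 for intracellular nodes, 0.02 for gene-expression outputs, and 1
for the cell-size output (CellArea), whose fold change is the model's
proxy for myocyte size and LV mass. $EC_{50}$ values equal to
$0.5^{1/n}$ make the normalization singular and are rejected; a table
row lacking $n$ or $EC_{50}$ is an error rather than a silent default.

Two integration engines are provided. `simulateNetwork` defaults to
adaptive stiff-capable `lsoda` (absolute/relative tolerances
$10^{-8}/10^{-6}$), appropriate for the 200-fold spread of time
constants in a full model. Calibration and Monte Carlo workloads run
thousands of short simulations of a small network, so `voConfig`
defaults them to a compiled fixed-step RK4 kernel (step = fastest
$\tau$ / 4, time-varying weights tabulated on a 256-point grid); the
test suite verifies the two engines agree to a few times $10^{-5}$ and
that both match a brute-force explicit-Euler oracle. Steady states are
located by integration until $\max|dy/dt| < 10^{-6}$ holds across a
trailing window of 0.1 $t/\tau$; a damped fixed-point iteration serves
as a warm start and, on acyclic networks, usually already satisfies
the criterion.

## Geometry and the myoStrain input

The LV is idealized as a thin-walled sphere. Stretch relative to the
unloaded state is $\lambda = (V_{ED}/V_0)^{1/3}$ and Lagrangian strain
$\varepsilon_f = \tfrac12(\lambda^2 - 1)$. Eccentric growth enlarges
the unloaded volume; the default rule assumes constant wall thickness,
$V_0 \propto \mathrm{LVM}^{3/2}$, and is pluggable (`v0Rule`) because
the exact mass-to-unloaded-volume relation used by the published
analysis is not part of the model distribution this package can read. With the default rule
the mean chronic condition (+36% LVM, +67% $V_{ED}$) leaves stretch
within a few percent of baseline, which is why sampled strain
trajectories straddle baseline chronically rather than sitting 75%
below it as the published analysis found — the fraction below baseline
is sensitive to the exact $V_0$ rule, and we report our honestly
computed value rather than tuning the rule toward the published one.
The strong negative correlation between chronic strain and chronic
mass gain is robust to this choice.

Strain maps onto the mechanical input weight through
$w(\varepsilon_f) = C_{myo}\,(e^{D_{myo}\varepsilon_f/\varepsilon_f^0} - 1)$,
with $D_{myo} = \log(1 + w^0/C_{myo})$ solved so that the baseline
anchor $w(\varepsilon_f^0) = w^0$ holds exactly and $w(0) = 0$ by
construction. The baseline weight $w^0$ (`wMyoStrain0`) is fixed per
calibration run and scanned over a grid (`scanWmyoStrain`); the gain
$C_{myo}$ is calibrated. Negative strain maps to negative values by
the same formula; scenario code clamps all input weights to $[0,1]$.
Baseline stretch $\lambda_{ED}^0$ is sampled per Monte Carlo iteration
from a configurable normal PDF (default $1.10 \pm 0.02$, a
literature-scale estimate for healthy canine end-diastolic myofiber
stretch).

## Input curves and time normalization

Mass growth is fitted per species with
$FC(t) = 1 + A(1 - e^{-t/\tau})$ by weighted nonlinear least squares
(weights $1/\mathrm{sd}^2$); dividing each species' time axis by its
fitted $\tau$ aligns dog and rat data on a common $t/\tau$ axis. Note
that $\tau$ itself is only weakly identified at realistic
between-study scatter (SD ≈ 0.15 fold gives a coefficient of variation
of 30–50% even with ~50 datasets per species); the tests therefore
verify exact recovery in the low-noise limit and error shrinkage with
noise, not a tight tolerance at full scatter.

Hormone and volume/mass fold-change curves support four
baseline-anchored families: constant, linear ($1 + bt$), saturating
exponential ($1 + A(1 - e^{-t/k})$) and fast-onset exponential decay
($1 + A e^{-t/k}(1 - e^{-t/0.02})$, an acute surge returning toward
baseline; the 0.02 onset constant keeps the anchor $FC(0)=1$ exact).
Two refinements matter in practice. First, the LVM fold family is
fitted with its shape constant pinned at $k = 1$ (`fixK`): the t/τ
axis is *defined* by normalizing with the fitted mass-growth constant,
so letting $k$ float merely re-creates the amplitude/time-constant
ridge the normalization removed (free fits produce degenerate
near-linear solutions). Second, each family can carry either the
"mean" parameter PDF (the fit's linearized covariance — uncertainty of
the pooled mean curve) or a "predictive" PDF whose amplitude variance
is inflated to the study-to-study scatter; per-case analyses such as
the chronic-strain ensemble use the predictive PDF, because there each
Monte Carlo draw represents one possible study-level outcome.

Each fit stores the linearized parameter covariance; `sampleCurve`
draws parameters from the multivariate normal and rejects curves that
go nonpositive anywhere on the requested domain. Stimuli are sampled
independently of each other per iteration; a correlation structure
between hormones could be added at the sampling layer but is not
modeled, mirroring the independence assumption of the analysis this
package operationalizes.

## Calibration

The likelihood of a parameter vector
$(w_{AngII}, w_{NE}, w_{ET1}, w_{bg}, C_{myo})$ compares predicted
node-activity fold changes (activity at $t/\tau$ over baseline
activity) with each observation row under a normal density, and adds a
preference for a baseline CellArea activity near 0.5 — the most
responsive region of the sigmoid — as
$-(y_{CA}^0 - 0.5)^2 / (2\sigma_b^2)$ with $\sigma_b = 0.1$. Uniform
prior bounds restrict each hormonal weight to the range where CellArea
responds (AngII 0.01–0.15, NE 0.01–0.24, ET1 0.01–0.17, background
0.01–0.4); $C_{myo}$ bounds default to 0.5–20 and are
configuration-exposed.

Curve uncertainty is marginalized by Monte Carlo over a pool of
`nPool` (default 6) curve draws fixed per run, averaging the per-draw
likelihoods (log-mean-exp) and sharing the parameter-dependent
baseline steady state across the pool. We deliberately do not redraw
curves on every iteration: with realistic curve-PDF widths the
per-draw log-likelihood fluctuates by tens of nats, so a
fresh-draw-per-iteration Metropolis rule degenerates into a lottery
over draws — chains either freeze on a lucky draw or diffuse without
drift. A fixed pool makes the target deterministic and acceptance
meaningful; enlarging the pool tightens the marginalization.

Sampling combines, per sweep: one Metropolis independence move
proposed from the prior (uniform in stage 1; the stage-1 posterior KDE
in stage 2, with the proper proposal-density correction), an optional
joint random-walk move using the stage-1 sample covariance (scaled by
$2.38^2/d$), and a Metropolis-within-Gibbs sweep with per-parameter
Gaussian proposals (5% of each prior range; out-of-bounds proposals
rejected). Stage 2 is a continuation of stage 1: the stage-1 posterior
informs the proposals and the starting point, while the target remains
likelihood × the original uniform prior. Folding the stage-1 posterior
into the stage-2 target as a density factor would evaluate the same
data twice and was observed to shrink credible intervals enough to
break nominal coverage. Convergence diagnostics (block means of the
log-likelihood and parameters, relative change between consecutive
blocks) are recorded every `checkEvery` sweeps.

After sampling, solutions incompatible with the chronic plateau of LV
mass are filtered: growth reversal (CellArea below baseline by more
than 1%, relative, at any time) and runaway growth (relative slope
above 0.005 per unit $t/\tau$ at the horizon $t/\tau = 5$). The
thresholds are arguments of `filterUnlikely`. `scanWmyoStrain` repeats
the whole calibration at fixed `wMyoStrain0` values and reports mean
log-likelihood and the unlikely-solution fraction per value, the
quantities used to pick the working baseline strain weight.

At desk scale (toy eight-node network, 80–200 stage-1 and 160–400
stage-2 sweeps, pool of 4–6), credible intervals from this sampler
cover interior ground-truth parameters in at least 85% of seeded
repeats; the acceptance suite re-runs that experiment end to end and
asserts exactly that bound. Two structural
caveats: a truth sitting exactly on a prior bound (as the published
AngII weight does) cannot be covered by a central interval, and truths
violating the baseline-CellArea≈0.5 preference are genuinely — and
correctly — downweighted.

## Scenario ensembles

`simulateScenario` draws, per iteration, a posterior parameter row and
(for VO kinds) one curve set, builds the perturbation — hormonal input
weights $w^0 \times FC(t)$, mechanical input from the mapped strain
curve, agonist infusions as weight overrides (1 at saturation, or
$w^0 \times$ a truncated-normal fold draw), blockers as receptor
$y_{max} = 0$ — and integrates from the pre-intervention baseline
steady state to the horizon ($t/\tau = 5$ for chronic endpoints, 3 for
sensitivity). Failed integrations are dropped and counted. Drug
effects are computed on paired arms sharing posterior rows, curve
seeds and dose draws (common random numbers), which minimizes the
Monte Carlo variance of the difference; the paired-arm identity (zero
effect when the blocked receptor has no path to CellArea) is tested
exactly.

Summaries follow the conventions of the analysis: normalized growth
$(y_T - y_0)/y_0$; normalized drug effect
$(y_T^{drug} - y_T^{no\,drug})/y_0$; central CI50 ([25th, 75th]) and
CI90 ([5th, 95th]) percentile intervals (linear interpolation, at
least 20 samples); a classification of "increase"/"decrease" when at
least 75% of iterations move in one direction (threshold inclusive,
exact zeros counting toward neither side); counts of experimental
means falling inside CI50/CI90; and input–output sensitivity as
Pearson correlations (with regression slopes) across iterations, with
zero-variance inputs reported as missing.

## The synthetic-data module

`syntheticTruth` fixes a ground truth in the calibrated VO regime:
input weights at the published posterior means, saturating-exponential
stimulus curves reaching literature-scale chronic folds (LVM +36%,
VED +67%, hormones 2–2.5×), species time constants 1095 h (dog) and
283 h (rat), within-study SD 0.25 (typical of Western-blot fold
changes) and between-study SD 0.15. `generateObservations` simulates
the truth and emits one row per "study": the true value plus a
between-study normal offset as the mean, the within-study scale as the
SD, species alternating with raw-hour time axes. What the generator
does **not** emulate: correlated hormone excursions, systematic
inter-laboratory bias, censoring/selective reporting, and measurement
physics; passing tests therefore demonstrate the pipeline's
statistical correctness under its own assumptions, not robustness to
every pathology of real literature data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: toy networks of 3–8
nodes; 4–6 synthetic studies per variable–timepoint pair over 6 time
points; calibration runs of 80–200 + 160–400 sweeps with curve pools
of 4–6; Monte Carlo ensembles of 200–1000 iterations; strain ensembles
of 1000 draws. These sizes were chosen so a complete pipeline run
finishes in minutes on one core while leaving Monte Carlo standard
errors well below the tolerances asserted. Key numerical defaults:
lsoda tolerances $10^{-8}/10^{-6}$ (scenario configs use
$10^{-7}/10^{-5}$), RK4 step $\min\tau/4$, steady-state criterion
$10^{-6}$ over a 0.1 window, Hill identities exact to $10^{-12}$,
curve-sampling positivity enforced by rejection (100 tries), KDE
bandwidths by Silverman's rule.

## Known limitations

- The published network is consumed, not bundled; all shipped
  quantitative results are properties of the synthetic analogue.
- The $V_0(\mathrm{LVM})$ growth rule is a documented stand-in; the
  chronic strain distribution (though not its correlation structure)
  depends on it.
- Hormone curves are sampled independently per iteration.
- The two-stage sampler's stage-2 is a continuation rather than a
  posterior-as-prior density product, for the coverage reasons given
  above.
- No hemodynamic or contractility feedback: blockers and agonists act
  only through the signaling network, so secondary effects of drugs on
  heart rate, blood pressure or ventricular mechanics are outside the
  model.
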