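---
title: "Equilibrium and kinetic models of ligand–receptor binding in bindfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium and kinetic models of ligand–receptor binding in bindfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindfit)
```

bindfit analyzes two classes of binding measurements that arise when a
secreted ligand is titrated against a membrane receptor reconstituted in
nanodiscs: real-time biolayer interferometry (BLI) traces, and endpoint
competition/saturation assays read out as fraction of ligand bound. All
models are exact mass-action treatments — no free-ligand ≈ total-ligand
approximation — because the assays of interest are run with total
concentrations comparable to the dissociation constants, i.e. deep in the
ligand-depletion regime.

## The binary depletion isotherm

For a ligand with total binding-site concentration $A$, receptor at total
$R$, and dissociation constant $K_A$, the occupied fraction of ligand sites
is the small root of the binding quadratic:

$$Y_0 = \frac{A + K_A + R - \sqrt{(A + K_A + R)^2 - 4AR}}{2A}.$$

`bound_fraction_no_competitor()` evaluates this with the numerically stable
small-root form. For the bead-assay composition used throughout the
examples ($A = 64$ nM of sites — a 32 nM disulfide-linked dimer with two
sites, see `dimer_to_sites()` — $R = 50$ nM, $K_A = 10.4$ nM), $Y_0
\approx 0.568$: approximately half of the ligand is receptor-bound in the
absence of competitor, which is the design target of that assay.

## Exact competitive displacement (trigonometric root of the cubic)

`wang_competition_curve()` implements the exact analytical solution of the
three-species competitive equilibrium (Wang 1995, FEBS Lett 360:111),
in which the free concentration of the shared species is a root of a cubic
polynomial with coefficients

$$h = K_A + K_B + A + X - R,\qquad
  k = K_B(A-R) + K_A(X-R) + K_A K_B,\qquad
  l = -K_A K_B R,$$

and the physical root is selected in trigonometric form through
$\theta = \arccos[(-2h^3 + 9hk - 27l) / (2\sqrt{(h^2-3k)^3})]$. The bound
fraction is $Y = g/(3K_A + g)$ with $g = 2\sqrt{h^2-3k}\cos(\theta/3) - h$.

A topology note: written this way, the equation system describes the
ligand (total $A$) and the competitor (total $X$) competing for the shared
receptor pool $R$; the root of the cubic is the free receptor
concentration. At the depletion levels of the bead assay this differs only
at the few-per-mil level from the alternative topology in which receptor
and competitor both bind the ligand, and it is the form in which the model
is conventionally fitted. The affinity-shift model below uses the
ligand-shared topology, which is the natural frame for a competitor that
binds the ligand; the two coincide as depletion vanishes, which is also
the regime in which the package's Cheng–Prusoff consistency property is
stated.

### Numerical evaluation

Two guards make the closed form reliable in floating point:

* The $\arccos$ argument is clamped to $[-1, 1]$ when it falls outside by
  at most $10^{-9}$ (pure rounding); larger excursions raise an error,
  since they indicate an invalid parameter set rather than rounding.
* When the physical root is many orders of magnitude smaller than $h$
  (large competitor excess), the trigonometric expression suffers
  catastrophic cancellation — the raw double-precision formula can be off
  by orders of magnitude at $X \gtrsim 10^6$ nM with small $K_A, K_B$. The
  implementation therefore polishes the trigonometric seed with a
  safeguarded bracketed Newton iteration on the cubic itself (the root is
  bracketed in $(0, R]$ because free receptor cannot exceed total). This
  restores agreement with an independent brute-force mass-action solver to
  better than $10^{-12}$ relative across the full tested domain
  ($A, R \in [1, 500]$ nM, $K_A, K_B \in [0.1, 10^4]$ nM,
  $X \in [0, 10^6]$ nM).

## The affinity-shift (allosteric ternary complex) model

Displacement data that plateau at a non-zero level cannot come from pure
competition. The minimal mass-action model producing such a plateau is the
allosteric ternary-complex model: species $L$, $LR$, $LC$, $LRC$ with
constants $K_A$ ($L + R$), $K_B$ ($L + C$), and $\alpha K_A$ for $R$
binding $LC$; detailed balance then forces $\alpha K_B$ for $C$ binding
$LR$. A single cooperativity factor $\alpha$ captures the effect:
$\alpha = 1$ is a silent competitor, $\alpha > 1$ weakens receptor binding
(negative cooperativity) and produces a plateau equal to the binary
isotherm with $K_A$ replaced by $\alpha K_A$; the competitive model is the
$\alpha \to \infty$ boundary. The functional form of the "competitor
shifts ligand–receptor affinity" hypothesis is not uniquely determined by
the data it is usually invoked for; the ATCM was chosen here because it is
the standard minimal model with the required limiting behaviour, and the
choice is surfaced in the API name rather than hidden.

`affinity_shift_competition()` solves the coupled conservation equations
by deterministic bracketed bisection on free ligand in $[0, A]$ (64
iterations, i.e. interval width $A\,2^{-64}$, far below the $10^{-10}$
relative tolerance documented in the API); for fixed free ligand the free
competitor satisfies an explicit stable quadratic, so no inner iteration
is needed. The solver is validated in the test suite against an
independent oracle that integrates the mass-action ODE system to steady
state with `deSolve`.

## Steady-state saturation and the Hill parameterization

`hill_binding()` and `fit_steady_state()` use
$S(c) = B_{max} c^h / (c^h + K_D^h)$, so the reported $K_D$ is the
half-saturation concentration for any Hill slope $h$ — matching the
convention of "one-site specific binding with variable Hill slope" fits,
in which a $K_D$ and a Hill slope are reported together. Fits operate on
all replicate points jointly; parameter SEMs come from independent
per-replicate refits when at least two replicates are present (the
headline uncertainty), otherwise from the asymptotic covariance. A fitted
$B_{max}$ more than 40% above the top-concentration signal is flagged as
extrapolated rather than rejected.

## BLI kinetics

The 1:1 Langmuir model gives an association phase
$R(t) = R_{eq}(1 - e^{-K_{obs} t})$ with $K_{obs} = K_{on} C + K_{off}$
and $R_{eq} = B_{max} C / (C + K_D)$, and a dissociation phase
$R_0 e^{-K_{off} t}$. The analysis pipeline (`fit_kinetics()`) follows the
standard two-source procedure:

* `fit_kobs()` fits each association trace to a one-phase exponential;
  `kon_from_kobs()` takes $K_{on}$ as the slope of the ordinary
  least-squares line through $(C, K_{obs})$. The intercept of that line is
  reported as a cross-check but is *not* constrained to equal the
  dissociation-fit $K_{off}$ — the two estimates come from different data.
* `mean_koff()` fits each dissociation trace to a one-phase decay and
  averages over traces with fit $R^2$ above 0.8 (configurable; a
  threshold ≤ 0 disables the filter). The filter exists because
  low-concentration traces have little signal to lose and their decay
  fits are noise-dominated; the number of excluded traces is always
  reported.
* `kinetic_kd()` forms $K_D = K_{off}/K_{on}$ with the uncertainty
  propagated in quadrature from the two relative SEMs.

For single-concentration experiments,
`fit_association_then_dissociation()` fits both phases jointly with shared
$K_{on}$, $K_{off}$, $B_{max}$ and signal continuity at the phase
boundary.

Conventions that the raw data do not dictate and that are therefore fixed
here: phase times are re-zeroed at the boundary sample (the last point of
the preceding phase), so the first point of an exponential phase already
carries one sampling interval of evolution; the baseline is re-zeroed on
the mean of its final 10 s; Savitzky–Golay smoothing
(`signal::sgolayfilt`, default window 11 points, order 3, applied per
phase so boundaries are not smeared) is available in
`preprocess_trace()` but disabled in the package's own validation fits,
which operate on synthetic data whose noise is already well-behaved.
Nonlinear fits are initialized from log-linear regressions on the rising /
decaying segments and the tail mean for plateaus, and run through
`minpack.lm::nlsLM` with tight convergence tolerances
(`ftol = ptol = 10^{-15}`), which is what makes the noiseless round-trip
tests meaningful at $10^{-6}$ relative accuracy.

## Displacement fitting, Cheng–Prusoff, and model comparison

`fit_ic50()` fits a descending logistic with the bottom fixed at 0 and the
slope fixed at 1 by default (both releasable); in the no-depletion limit
the exact competitive curve *is* a slope-1 logistic in competitor
concentration, so the defaults are the correct model there, and the
conversion $K_i = IC_{50}/(1 + [L]/K_D)$ (`cheng_prusoff_ki()`) recovers
the competitor constant exactly. Under depletion the IC50 is inflated
relative to the no-depletion value at matched $[L]/K_D$, and the
Cheng–Prusoff conversion is no longer exact — which is precisely why
`fit_competition_model()` fits the exact depletion-aware models with
$A$, $R$, $K_A$ fixed at independently measured values and only $K_B$
(plus $\alpha$ for the affinity-shift model) free.

Confidence intervals are parametric-bootstrap percentile intervals
(default 1000 resamples, seeded; Gaussian noise at the fitted residual SD),
chosen because the sampling distribution of $\log K_B$ from 6-point
triplicate designs is visibly skewed, making the asymptotic Wald interval
optimistic. The fitted parameters are searched in $\log_{10}$ space with a
coarse grid initialization, which makes the fits deterministic given the
data.

`compare_models()` performs the nested comparison between the competitive
and affinity-shift descriptions: an extra-sum-of-squares F-test with one
numerator degree of freedom combined with AICc; the verdict is the model
both agree on, otherwise `"ambiguous"` (including the degenerate case of
zero residuals under both models). Only one planned comparison is made per
dataset, so no multiplicity correction applies.

## The synthetic-data generator

`experiment_design()` plus the three `generate_*()` functions emulate the
experiments the analysis layer consumes, with defaults matching the
designs the models were built for:

* BLI trace families on the analyte grid {3.2, 10, 32, 100} nM, 60 s
  baseline, 300 s association, 600 s dissociation at 1 Hz, truth
  $K_{on} = 1.9\times10^{-4}$ nM$^{-1}$s$^{-1}$,
  $K_{off} = 1.4\times10^{-3}$ s$^{-1}$, with paired receptor-free
  reference traces carrying drift and noise only;
* steady-state series on a 3.16-fold (half-log) dilution ladder from 0.1
  to 1000 nM in triplicate;
* bead-competition datasets on the competitor grid
  {0, 0.1, 0.4, 1.6, 25, 100} µM in triplicate, from either the
  competitive or the affinity-shift equilibrium.

The noise model is additive homoscedastic Gaussian by default (replicate
endpoint data are typically summarized as mean ± SD without a stated error
model; homoscedastic noise is the neutral choice), with an optional
signal-proportional mode. Default noise SDs are 2% of $B_{max}$ for
traces, 3% for saturation series, and 3–5 percentage points of fraction
bound for competition data — the scatter visible in replicate endpoint
assays of this kind. Everything is deterministic given the design seed.

What the generator deliberately does not emulate: mass-transport-limited
or heterogeneous-ligand kinetics, sensor-jump artifacts between phases,
western-blot quantification nonlinearity, or correlated replicate errors.
Passing the package's round-trip tests therefore demonstrates correctness
of the estimators under the stated statistical model, not robustness to
every instrument pathology; with real traces the preprocessing options
(reference subtraction, smoothing) carry that load.

## Validation scale and determinism

The test suite and `scripts/acceptance.R` validate, among other things:
oracle equivalence of the closed-form competition curve over 200
randomized systems; bootstrap CI coverage of the competitor constant over
200 simulated triplicate datasets (100 bootstrap resamples each — enough
for a percentile interval at this noise level, and sized so the whole
sweep runs in minutes on one CPU); and model selection accuracy over 100
simulations per generating model. All stochastic steps take explicit
seeds, and every simulation in the package is bitwise reproducible from
its design plus seed.

## Known limitations

* The competitive and affinity-shift models use slightly different
  topologies (receptor-shared vs ligand-shared, see above); their nested
  comparison is exact only in the low-depletion limit, and the F-test at
  bead-assay depletion carries a few-per-mil model mismatch that is small
  relative to assay noise.
* Four-species equilibria (two receptors plus competitor) are out of
  scope, as are structural interpretations of fitted constants.
* The IC50 logistic defaults assume no residual binding at saturating
  competitor; for partially displaceable signals, release the bottom or
  fit the affinity-shift model instead.
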