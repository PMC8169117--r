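---
title: "A stochastic ABA-GA bistable switch for seed germination timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic ABA-GA bistable switch for seed germination timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedswitch)
```

## The model

Germination of a seed is decided by the balance of two hormones: abscisic
acid (ABA), which represses germination, and gibberellic acid (GA), which
promotes it. Both act on a common set of transcriptional inhibitors of
germination (DELLAs, ABI4, ABI5) that this package lumps into a single
variable, the *Integrator* `I`. The seed is treated as one well-mixed
compartment with four concentrations, `[ABA]`, `[GA]`, `[I]` and a sowing
factor `[Z]`:

* ABA production is promoted by the Integrator (`f_ABA(I)`, increasing
  Hill), creating a mutual-activation loop ABA ↔ I;
* GA production is repressed by the Integrator (`g_GA(I)`, decreasing
  Hill), and GA in turn promotes Integrator degradation
  (`f_I_GA(GA)` scales a first-order decay of `I`), creating a
  mutual-inhibition loop GA ↔ I;
* Integrator production is promoted by ABA (`f_I(ABA)`);
* `Z` rises after sowing with first-order kinetics
  (`dZ/dt = beta_Z - v_Z Z` from `Z(0) = 0`) and feeds GA production
  through the coupling term `beta_GA_Z * Z`, modelling the light-induced
  increase in GA synthesis on sowing.

Together the two loops form a double-positive feedback that can act as a
bistable switch between a high-ABA/high-I (dormant) state and a
high-GA/low-I (germinating) state. All regulatory functions are Hill
functions with a shared exponent `h`; the threshold `theta_X_Y` is the
concentration of `Y` at which its effect on `X` is half-maximal, so
`1/theta` reads as a sensitivity. A seed *germinates* the first time `I`
drops below a germination threshold.

Exogenous hormone treatments are modelled as constant additive
concentrations entering **only** the Integrator equation
(`f_I(ABA + ABA_exo)`, `f_I_GA(GA + GA_exo)`): added hormone acts on the
Integrator but is not subject to, and does not alter, the endogenous
production/degradation balance.

## Stochastic dynamics

Intrinsic reaction noise is modelled with chemical Langevin equations:
each variable's deterministic rate is supplemented by a Gaussian white
noise whose squared amplitude is `(sum of production terms + sum of
degradation terms) / (2V)`, where `V` is an effective system volume. Noise
intensity is `1/V`; as `V -> Inf` every equation recovers its
deterministic limit. The typeset source of this model renders the radical
ambiguously (`1/(2V)` vs `1/V` inside the square root); we adopt `1/(2V)`
and isolate the prefactor in a single internal function
(`.langevin_prefactor`) so the alternative convention is a one-line
change — the `V^(-1/2)` scaling, which is what the analyses rely on, holds
under either reading.

Integration uses the stochastic Heun scheme under the Itô interpretation:
the predictor takes drift and diffusion at the current state, the
corrector averages the drift between current and predictor states, and the
*same* Gaussian increment is reused in both stages. Concentrations are
clamped to zero after both stages (absorptive barrier; the placement
within the step is our choice, the source states only "a barrier at 0").
Defaults: `dt = 0.1`, simulations stop at `t = 1000`; seeds whose
Integrator never crosses the threshold by then are *censored* and counted
as non-germinated, emulating the finite scoring window of a germination
experiment. Crossings are detected after each full step, with no
within-step interpolation (the step-end convention; the source does not
state its convention, and at `dt = 0.1` the difference is far below the
day-level resolution of any reported trait).

Per-seed noise streams come from a counter-based RNG keyed by
`(master seed, seed index)`, so ensembles are reproducible, independent of
R's global RNG, and order-independent: an `n`-seed ensemble is a prefix of
a larger one with the same master seed.

## Fixed points, stability and regimes

At steady state, ABA and GA are explicit functions of `I`, and
substituting them into the Integrator equation leaves one scalar equation
in `I`. `solve_fixed_points()` brackets its roots by sign changes on a
geometric grid (default `1e-6` to `1e4`, 50 points per decade — the source
states log-spaced intervals but not range or density) and refines them by
bracketed root-finding to a residual below `1e-10`. Stability is read from
the sign of the reduced `dI/dt` just below and above each root (with ABA
and GA slaved to their steady-state expressions), exactly the scalar
heuristic used in the source analyses; a full 4-D Jacobian classification
is deliberately out of scope. Sorted by `I`, stable and unstable roots
alternate, starting and ending stable.

The *pre-rise* system (before sowing) is evaluated with the Z-coupled GA
production term absent (`z = 0`, equivalent to `beta_GA_Z = 0`); the
*post-rise* system uses `z = beta_Z / v_Z`. A seed's initial condition is
the pre-rise stable fixed point with the highest Integrator value, with
`Z(0) = 0` so the GA rise unfolds with timescale `1/v_Z` during the
simulation. Dose simulations start from the same untreated initial state.

`classify_regime()` labels a parameter set monostable / bistable /
tristable by counting stable post-rise fixed points, and flags three
less-biologically-relevant regions:

* *instantaneous germination*: the highest pre-rise stable `I` is already
  below the germination threshold;
* *deterministic non-germination*: the lowest post-rise stable `I` is
  above the threshold, so only fluctuations can germinate the seed;
* *germination without the GA rise*: seeds germinate even with
  `beta_GA_Z = 0`, i.e. before sowing.

For the last flag the default is a stochastic check (simulate 40 seeds
with the rise removed), not the deterministic proxy "lowest pre-rise
stable `I` below threshold". This is a considered choice: at the reference
defaults the pre-rise system is itself bistable with a low stable branch
at `I ~ 0.185`, below the threshold of 1.0 — the proxy would therefore
flag *every* reference parameterization, while seeds started in the
high-`I` state essentially never reach that branch within the simulation
window. The proxy remains available (`check_no_rise = "deterministic"`)
and is conservative: whenever the stochastic check trips, the proxy trips
too (tested as a property).

## The germination threshold

The threshold is not part of the published parameter table. The package
default is 1.0, chosen to lie between the post-rise germination-branch
stable state (`I ~ 0.06` at defaults) and the pre-rise high-`I` initial
state (`I ~ 23`); `check_threshold_bracketing()` asserts this bracketing
for any parameter set. Within that bracket the qualitative analyses are
insensitive to the exact value because the switch transition is fast
compared to the waiting time in the high-`I` state.

## Traits, filters and the day scale

`summarize_times()` computes CV (sample `n-1` standard deviation over
mean), mean, mode and percentage germination, with CV/mean/mode computed
over germinated seeds only — censored seeds contribute to `n_sown` and the
percentage. The mode is the label of the most populated right-closed bin
`((k-1)w, kw]` anchored at 0, ties resolved to the earliest bin; with
`w = 1` on day-binned data this is simply the most frequent day. Traits
are withheld (not reportable) below 1% germination — more than nine seeds
out of 1000 must germinate, with the 10/1000 boundary inclusive.
Experimental-style count tables additionally exclude whole plates with
fewer than 10 germinated seeds (`summarize_counts()`), and a line's traits
are the unweighted mean over its included replicate plates
(`aggregate_line()`).

One deliberate deviation from a unit-bin default for simulated times: the
scans and dose-response analyses estimate the mode on bins of 20 time
units, the package's one-day scale. Estimating a mode from a few hundred
continuous times on unit bins is degenerate (hundreds of bins with 2-3
counts each; replicate-mean modes then fail monotonicity for about half of
arbitrary master seeds on the reference sweep), whereas the experimental
mode is by construction a daily-resolution quantity. The day scale
`day = ceiling(t / 20)` was fixed from the deterministic monostable
crossing time (`t = 50` at the low-sensitivity reference parameterization,
mapping to day 3, matching low-variability accessions that complete
germination within about 4 days) before any acceptance measurement, and
the same scale drives the synthetic generator's model-driven lines.

## Scans and dose-response protocols

`parameter_scan()` sweeps one or two parameters over geometric grids (4-5
values per decade by default), classifying the regime and running
independent replicate ensembles per point (3 replicates; 4000 seeds for 1D
headline sweeps, 400 for 2D scans). Excluded points keep their regime data
but are marked not biologically relevant. `dose_response()` contrasts a
low-variability (`theta_I_ABA = 7`, monostable) and a high-variability
(`theta_I_ABA = 5.8`, bistable) class over a dose grid that must include
the vehicle control; controls failing the spontaneous-germination,
no-rise-germination or deterministic-non-germination checks raise an
error, while non-control doses record their flags. Per-point seeds are
derived from the master seed and the point's parameter *values* (not its
index), so grid order cannot change any result.

## What the synthetic generator does and does not emulate

`generate_dataset()` produces day-binned count tables with the structure
of a multiparent-line germination experiment: multiple genotypic lines, 3
replicate parent plants per line, one plate of ~150 seeds per replicate,
daily radicle-emergence scoring, censoring beyond the last scoring day.
Parametric lines draw days from discretized normal (peaked), shifted gamma
(long-tailed) or two-component mixture (bimodal) distributions whose
analytic CV targets are computed by exact enumeration
(`line_target_traits()`); the bundled `reference_design()` spans CV
targets from ~0.1 to >1 (peaked < 0.2, bimodal > 0.6, e.g. 85% of seeds
near day 4 and 15% near day 25), includes a near-dormant line that fails
the plate filter on purpose, and arranges modes to increase with CV so the
observed weak positive CV-mode coupling is realized by construction — a
green correlation test validates the pipeline, not the biology.
Model-driven lines bin simulated germination times by the day scale. The
generator does not emulate maternal-environment, silique-position or
storage-duration effects, between-plate environmental covariance, or
scoring error; green tests on synthetic data establish correctness of the
statistics pipeline, not fidelity to any particular real dataset.

## Numerical choices and limitations

* Root bracketing can in principle miss a pair of roots closer than the
  grid spacing (50/decade); the dense-grid oracle test (10^4 points) over
  100 random parameter draws around the defaults detects no such case.
* Stability labelling assumes simple roots; tangencies (bifurcation
  points) would produce repeated labels and are not handled specially.
* Tristable parameterizations are counted and labelled but not otherwise
  analysed.
* The Heun scheme is weak order 1 for multiplicative noise; `dt = 0.1`
  follows the source protocol and the deterministic-limit acceptance test
  bounds the discretization error at the crossing (within `5 dt`).
* First-passage times use the step-end convention; quantities are
  therefore quantized at `dt`, which is invisible at day resolution.
* With very small `V` or extreme parameters the absorptive barrier is
  visited often and the Langevin approximation itself (not just the
  integrator) becomes questionable; the package does not warn about this.
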