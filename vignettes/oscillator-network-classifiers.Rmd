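---
title: "Classifying drug response with networks of chemical oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying drug response with networks of chemical oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concilium)
```

## The classification problem

Multiple-myeloma patients respond unevenly to bortezomib (PS341) and
dexamethasone (DEX): for some the therapy works, for others it does not.
The hope is that microarray expression values of a small panel of genes —
15 in the panel this package works with (`gene_ranges`) — carry enough
signal to anticipate the outcome. The signal is weak: for any single gene
the responsive and nonresponsive expression distributions overlap heavily,
and a 10-bin histogram vote on the best single gene only modestly beats the
constant classifier.

`concilium` implements an unconventional classifier for this problem: a
simulated network of three coupled chemical oscillators whose *dynamics*
perform the computation. The package covers the full pipeline — oscillator
simulation, input encoding, readout-rule induction, evolutionary training,
and a 15-member majority-voting ensemble (the eponymous concilium) — plus
the histogram baseline it is compared against and a synthetic patient-table
generator for self-contained validation.

## The oscillator model

Each node is a two-variable Oregonator, the standard reduced kinetics of
the photosensitive Belousov–Zhabotinsky (BZ) reaction, with activator $u$
(HBrO$_2$) and inhibitor $v$ (the oxidized catalyst). For a network of $m$
oscillators coupled by activator exchange,

$$
\frac{du_j}{dt} = \frac{1}{\varepsilon}\!\left[u_j - u_j^2 -
 \bigl(f v_j + \phi_j(t)\bigr)\frac{u_j - q}{u_j + q}\right]
 - \Bigl(\alpha + \beta\sum_i s_{ji}\Bigr) u_j + \beta\sum_i s_{ji} u_i,
 \qquad
\frac{dv_j}{dt} = u_j - v_j,
$$

with $s_{ji} \in \{0,1\}$ a symmetric, zero-diagonal coupling matrix
(all-to-all in the three-oscillator family), $\alpha$ a lumped activator
decay rate and $\beta$ a lumped exchange rate. Throughout the package the
kinetic constants default to $\varepsilon = 0.3$, $q = 0.002$, $f = 1.1$
(`oscillator_params()`).

Illumination controls whether a node oscillates. Each oscillator $j$ is
driven by

$$
\phi_j(t) = 0.1\,\bigl[1.001 + \tanh(-10\,(t - t_{\mathrm{illum}, j}))\bigr],
$$

which holds it at the suppressing level $\approx 0.2001$ until its switch
time $t_{\mathrm{illum},j}$ and then releases it towards
$\approx 0.0001$, where the kinetics settle on a limit cycle. Two
dynamical anchors characterize the model at the default constants, and both
are recomputed by the test-suite and the acceptance script rather than
assumed: the suppressed steady state at $\phi = 0.2$ is
$u^* = v^* \approx 0.00204$ (`steady_state()`), and the free-running
period at $\phi = 10^{-4}$ is $\approx 8.2$ time units
(`measure_period()`).

## Encoding, readout, and rule induction

A patient record enters the network through normalization and timing.
Expression value $e_{i}$ of gene $i$ is mapped to
$p_i = (e_i - \mathrm{Min}_i)/(\mathrm{Max}_i - \mathrm{Min}_i)$ against
the fixed training ranges in `gene_ranges`; values outside the range give
$p$ outside $[0,1]$ and are deliberately accepted, since the affine switch
map

$$ t_{\mathrm{illum}} = t_{start} + (t_{end} - t_{start})\,p $$

remains meaningful there (including decreasing maps with
$t_{start} > t_{end}$, which several of the bundled networks use).
*Input* oscillators receive this data-dependent switch time — when a
network has two input oscillators they share the same gene and the same
map — while *normal* oscillators use fixed, trained switch times.

The readout is deliberately crude: the number of strict local maxima of
$u$ exceeding 0.05 on one designated output oscillator within
$[0, t_{max}]$. `induce_rule()` turns training counts into a classifier by
mapping every observed count to its majority outcome; per-count majority
is provably the training-error-optimal count-to-class map, which the test
suite checks against exhaustive enumeration. The output oscillator is the
one whose induced map makes the fewest training errors.

Ties and gaps need conventions the dynamics do not dictate. The package
resolves an exactly tied count (or histogram bin) to *nonresponsive*,
breaks output-oscillator ties toward the lowest index, and sends counts
never seen in training to the global training-majority class — except for
the bundled readout rules, which are phrased as "any other count means
nonresponsive" and are loaded with fallback 0 verbatim. One bundled rule
lists count 3 on both sides, an internal inconsistency in its source table;
the fixture stores it as printed and the loader resolves the duplicate to
nonresponsive, with a warning, matching the tie rule.

## Numerical choices

* **Integration.** Fixed-step 5th-order Cash–Karp with $dt = 10^{-3}$ is
  the reference mode. The stepper walks an exact step-index grid
  ($t = k\,dt$) so recorded times carry no accumulation drift, and a final
  partial step lands exactly on $t_{max}$. An adaptive mode (embedded
  4th/5th-order error estimate, tolerances $10^{-9}/10^{-7}$ by default)
  is available; the suite asserts it reproduces the fixed-step readout.
* **Initial condition.** Every oscillator starts at the stable steady
  state of its own $\phi_j(0)$ — the physically prepared, suppressed
  state. An oscillator whose switch time is early enough (or negative,
  from out-of-range inputs) has no stable state at $\phi_j(0)$; it is then
  started on the unstable nullcline root, from which oscillations develop
  immediately.
* **Peak detection.** A strict discrete local maximum
  $u_{k-1} < u_k \ge u_{k+1}$ on the recorded grid (every 10th step,
  i.e. 0.01 time units at the default $dt$), then the 0.05 threshold;
  plateaus count once at their leftmost sample. The suite verifies counts
  are identical at stride 1.
* **"No oscillation."** `measure_period()` reports `NA` when fewer than
  two supra-threshold peaks occur in a 50-unit window after a 30-unit
  transient — the verdict for any suppressing illumination.
* **Coarse exploration step.** Network-level training in the test suite
  runs at $dt = 10^{-2}$. The scheme is 5th order, so this is far inside
  its stability region for these kinetics, and the suite asserts that
  maxima counts at $dt = 10^{-2}$ are *identical* to the $dt = 10^{-3}$
  reference on the bundled RPS7 network across a grid of inputs. (At
  $dt = 5\times10^{-2}$ the spike phase is genuinely unstable, so the
  margin is about a factor five.)

## Evolutionary training

`evolve_network()` is an elitist genetic algorithm over the
three-oscillator family (oscillator 1 input, oscillator 3 normal,
oscillator 2's role itself optimized): population 100, the 5 fittest
carried unchanged, 95 offspring recombined from the 40 fittest and then
mutated, by default for 500 generations. Fitness is the training accuracy
of the best induced readout over all three oscillators. Elitism makes the
best-fitness trace non-decreasing, which the suite asserts.

Where the search mechanics were open, the package chose: parents are drawn
uniformly from the top-40 pool; recombination inherits each parameter (and
oscillator 2's role) verbatim from either parent with equal probability;
mutation perturbs each parameter independently with probability 0.2 by a
Gaussian of 0.1 times the parameter's admissible width, clipped to bounds,
and flips the role with probability 0.1. Bounds are
$t_{max} \in (10, 80]$, $\alpha \in [0,1]$, $\beta \in [0, 0.2]$, and
$[0, t_{max}]$ for all switch times and map endpoints — the envelope of
the bundled trained networks. A latent oscillator-2 switch time is carried
through input phases of the genome so the role flip is reversible. Because
recombined offspring can pair a switch time with a shorter inherited
horizon, switch times beyond $t_{max}$ are legal network configurations:
that oscillator simply never releases within the observation window.
Fitness evaluations are cached on the genome (the latent time excluded
while inert), which mainly spares the re-evaluated elite.

The bundled trained networks are treated as versioned fixtures to load,
not as configurations the search is expected to rediscover: with unstated
mutation magnitudes and initialization bounds the search is reproducible
only under its own seed.

## The concilium and its robustness probe

`concilium()` bundles 15 single-gene members; each casts one vote, and a
record is called responsive when at least $k$ members vote responsive
($k = 8$ is strict majority). `threshold_sweep()` scores every $k$ —
including $k > 8$, where the same "responsive iff $\ge k$ votes" reading
is applied against both classes, driving accuracy toward the responsive
prior complement at large $k$ — and accepts a drug filter for
per-treatment evaluation. `perturb_network()` implements the robustness
probe: one parameter scaled by $\pm 1\%$ (the bundled
`published_perturbations` table records which parameter moved for each
gene), after which the readout rule is *re-induced* on the training table,
because the optimal output oscillator can change under perturbation.

## What the synthetic generator does and does not emulate

`synthesize_patients()` draws class-conditional truncated normals inside
each gene's training range, with class means at fractions
$0.5 \mp 0.3(1 - \mathrm{overlap})$ of the range and sd 0.15 of the range,
the clinical 126:113 outcome balance and 169:70 drug balance scaled to
$n$. `overlap = 1` yields identically distributed classes (the suite
checks held-out histogram accuracy is statistically indistinguishable from
the prior); `overlap = 0` yields nearly separable classes. The defaults
emulate the *structure* of the clinical table — bounded per-gene ranges,
weak overlapping signal, its class balance — but the generator is a
single-Gaussian-per-class caricature: it has no inter-gene correlation, no
multimodality, and no drug-conditional structure. Green tests on synthetic
data therefore validate the machinery (encoding, simulation, induction,
search, voting), not the clinical accuracy figures.

The clinical training table itself (239 records) is third-party patient
data and is not redistributed. Every pipeline that reproduces its headline
accuracies is implemented and tested end-to-end; the corresponding checks
run against `inst/extdata/clinical/clinical_table.{csv,xlsx}` and report a
failure when the file is absent. The README describes how to drop the
table in.

## Problem sizes used by the automated checks

The suite exercises the evolutionary search at a reduced scale chosen to
demonstrate learning while keeping the run practical on one core: 50
generations, 200 synthetic records at overlap 0.3, $t_{max}$ bounds
$(10, 20]$, $dt = 10^{-2}$, fixed seeds, asserting a non-decreasing trace
and at least 0.9 training accuracy. Dynamics-level checks (steady state,
period, decoupled and permutation limits, order checks) all run at the
reference $dt = 10^{-3}$. The acceptance script integrates 100 time units
to confirm the steady state and 130 to measure the period, at the
reference step.

## Known limitations

* Counts are a coarse, discontinuous readout; nearby inputs can classify
  differently at count boundaries, and the induced rules can overfit
  sparsely populated counts (mitigated, not removed, by the fallback
  class).
* The GA is single-objective and single-population; no attempt is made to
  optimize topology beyond oscillator 2's role, and $m > 3$ networks,
  weighted or inhibitory coupling, and multi-gene inputs are out of scope.
* Accuracy is the only score: no probabilistic calibration or ROC
  analysis.
* Spatial (reaction–diffusion) BZ media and stochastic kinetics are not
  modeled; oscillators are well-stirred points.
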