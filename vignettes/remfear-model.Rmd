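---
title: "The remfear model of recent and remote context fear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The remfear model of recent and remote context fear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remfear)
```

remfear simulates how a rodent-like agent learns which places are
dangerous, and what changes when those memories move from the hippocampus
to the neocortex (systems consolidation). This vignette is the package's
own account of the model: its assumptions, its equations, the parameters
that matter, and the choices made where the design was genuinely open.

## Contexts and the synthetic world

A context (a place or situation) is a fixed set of `N_atr = 100`
attributes drawn from a universe of `N_ctx = 1000` representable
attributes. Attributes come in two strata: `N_cat = 20` *categorical*
attributes shared bit-identically by every context in a category (all
forests have trees), and `N_ptc = 80` *particular* attributes specific to
one context (this forest's terrain). The world generator builds overlaps
constructively — a requested overlap proportion between two contexts is
realized exactly as its rounded attribute count, never by rejection
sampling — because overlap is an experimental condition, not a random
variable. Unrelated contexts are given the standard background overlaps
(`O_ptcHom = O_ptcHet = O_catHet = 0.2`, close to what random draws of
sets this size would produce).

The standard preparation behind every scripted experiment is: a
to-be-conditioned context `A` in category `X`; one long-established
context in the same category (`EX`, particular overlap 0.2 with `A`) and
one in a different category (`EY`); test contexts added per protocol. An
"established" context is one the agent consolidated long ago: `Z_oRec =
85` of its 100 attributes were known when it went remote. Sessions
observe one new attribute per computational interval (roughly half a
second of behavioral time, which the model does not track); conditioning
sessions last 76 intervals with the shock at interval 75, test sessions
95, reminder exposures 60. What the generator does *not* emulate:
attribute noise or occlusion, continuous or weighted attributes, and
category structure learned from experience — known categories are seeded
complete. Passing tests therefore speak to the model's internal logic
under idealized perception, not to robustness against noisy input.

## The weight of evidence

After observing `Z_cur` attributes, with `Z_com` of them matching the
`Z_rec` attributes a candidate representation recalls, the agent scores
the candidate by a log (base 10) likelihood ratio of two hypergeometric
sampling models:

$$B = \log_{10}\frac{P(Z_{com}\mid \text{same context})}{P(Z_{com}\mid
\text{random place})}$$

Under the same-context hypothesis the draws come from the context's
`N_atr` attributes of which `Z_rec` are recalled; under the null they
come from all `N_ctx` representable attributes. Base 10 follows the
classical weight-of-evidence convention and matches the magnitudes of the
decision thresholds (−5 … 15). The ratio is computed on log masses
(`dhyper(..., log = TRUE)`), so no underflow occurs at these sizes. Two
degenerate outcomes are sentinels: a match count impossible under the
same-context hypothesis yields −∞ (conclusive rejection), impossible only
under the null yields +∞. Sentinels saturate comparisons but never enter
weight arithmetic; a count impossible under both hypotheses is an error.

The characteristic shapes follow directly: for a valid representation the
curve rises monotonically with `Z_cur`, and the more is known
(`Z_rec` larger) the faster; for a mismatched representation it rises
while the early evidence is compatible, then collapses — eventually to
−∞, because with enough observations a mismatch becomes impossible to
reconcile with the same-context hypothesis.

```{r brep-curve}
valid <- expected_brep_curve(z_rec = 85, true_overlap_count = 85,
                             n_atr = 100, n_ctx = 1000, length = 40)
tail(valid, 3)
```

## Expected-value and stochastic modes

The package's default mode is deterministic: evidence is based on
*expected* match counts. Within a session, `Z_com =
round(Z_cur * n_shared / N_atr)` (sampling without replacement), and —
equally important — what a representation is taken to share with a
context is itself an expectation over the agent's prior experience. In
expected-value mode a representation's associated attributes are tracked
as expected counts per stratum, `(k_cat, k_ptc)`, each uniform within its
stratum, so the shared count with any context `D` built from context `C`
is

$$n_{shared} = \mathrm{round}\!\left(k_{cat}\frac{|cat(C)\cap D|}{N_{cat}}
 + k_{ptc}\frac{|ptc(C)\cap D|}{N_{ptc}}\right).$$

This makes every trajectory, event coordinate and arm mean exactly
reproducible regardless of the seed. Set unions (end-of-session updating)
use the stratum-wise inclusion–exclusion expectation for independent
samples, and a stratum-wise maximum when the existing associations are a
prefix of the same session's observations. Stochastic mode replaces all
of this with concrete seeded draws and actual set intersections; it
exists for distributional property tests and reproduces the same
qualitative behavior.

Consequences of integer rounding are visible in the trajectories: a ±1
ripple whose parity alternates with `Z_cur`, and a spike at the last
interval at which the same-context hypothesis is still feasible. Both are
inherent to working with integer match counts. Event coordinates —
threshold crossings and the onset of the evidence decline — are therefore
read off the *continuous relaxation* of the trajectory (non-integer
`Z_com` through log-gamma generalized binomial coefficients). On the
integer trajectory the global maximum can sit on the boundary spike,
which would misreport the decline onset by several intervals; the smooth
curve has a unique peak and unambiguous crossings. This is a
numerical-analysis choice of the package: the underlying decision rules
(representation creation, conditioning, updating) always act on the
integer-valued evidence.

## Hippocampal representations

Each of `N_dg = 100000` dentate gyrus cells is innervated by a random set
of `F = 60` attribute cells and drives one dedicated CA3 partner through
an innately effective synapse (a deliberate simplification; CA1 is
omitted throughout). When a representation is created, the `K = 60` DG
cells most richly innervated by the currently observed attributes win,
and their CA3 partners are the representation — a sparse code
(`K/N_dg = 0.06%`) with strong pattern separation: contexts sharing most
of their attributes still get mostly distinct CA3 sets unless nearly
everything was known at creation. Ties among equally innervated cells are
broken by a random permutation fixed at wiring time, so identical inputs
always select identical winners. Wiring is held as a sparse incidence
matrix; scoring an observation set is one sparse matrix–vector product,
and the Monte-Carlo overlap machinery batches many sets through one
multiplication.

Representation overlap (the fraction of shared CA3 cells) is what fear
generalization between hippocampally coded contexts rides on. Its
expectation as a function of attribute overlap and of how much was known
at creation (`Z_o`) is estimated by Monte-Carlo (`expected_overlap()`)
rather than by a closed-form combinatorial approximation: the estimator
is itself the quantity the cortical generalization table consumes, and a
seeded simulation is the more verifiable oracle.

## Cortical representations and systems consolidation

A remote representation is localist: one cortical cell per context. Its
content differs systematically from its hippocampal progenitor's:

* If the context's category can be identified — best weight of evidence
  across known categories above `B_cat = 5` — the category cell is
  linked, which in effect associates *all* of the category's known
  attributes, observed in this context or not.
* Of the attributes not known to be categorical (the *Unc* set), only a
  random subset survives, capped at a proportion of `N_ptc` given by
  $\kappa + (1-\kappa)\,(Z_{rec}/N_{atr})^{\epsilon}$ with
  `kappa = 0.3`, `epsilon = 20`: essentially `kappa` unless nearly
  everything is known, rising to 1 for an exhaustively known context.
  With no category identified the cap is the fixed high `kappa_o = 0.8`
  (better to remember more of a context that cannot yet be classified).

Remote memory thus gains generic (categorical) information and loses
detail — the root of every generalization result below.

Consolidation is a three-stage state machine per context record. Stage I:
hippocampal representation controls behavior; the cortical version is
constructed (category identification, Unc transfer, and a permanent link
from the cortical cell to its progenitor's CA3 cells). Stage II: both
versions compete for activation in every decision; fear remains
hippocampal. Stage III: the cortical synapse onto the amygdala takes over
the cumulative conditioned weight, the hippocampal representation's
associations are erased (its CA3 set survives for the progenitor links),
and only the cortical version competes thereafter. Stage transitions are
explicit driver events, not timed: the biological Stage II duration is
too variable to model, and every protocol specifies recent / Stage II /
remote conditions directly.

Two transfer details are worth stating. First, the cortical weight is
*incremented* by the cumulative hippocampal weight rather than assigned,
which conserves the total amygdala drive; for a first consolidation the
two rules coincide (the cortical weight starts at zero), but after a
reminder-driven reconsolidation assignment would erase remote fear that
the update cycle never touched. Second, under an amygdala NMDA block the
replacement still happens but no weight moves — remote fear is abolished
while the remote representation itself is intact.

**Updating.** If at session end the evidence for the active
representation exceeds `B_add = 15`, newly observed attributes are
learned. For a hippocampal record this is a set union. For a remote
record the representation returns to Stage I: the hippocampal version is
reconstructed on the stored progenitor CA3 set, associated with
everything known (cortical content, category attributes, session
observations), and consolidation starts over. While the cortical version
is being revised it does not compete for activation, but fear conditioned
to it remains expressible through the CA3–cortical pathway — which is
exactly why a reminder makes remote fear hippocampus-dependent again.
Updating routes through the hippocampal version even when the Stage II
cortical sibling won the session. The retained-Unc subset is redrawn at
each consolidation episode, so updating can lose previously retained
detail (documented lossiness, inherent to the capped random draw).

## The amygdala readout

Fear conditioning and expression follow a small fixed equation set. An
unconditioned stimulus increments each of the active hippocampal
representation's `K` CA3→amygdala synapses by `Cnd * alpha` (cortical
cell: `K * Cnd * alpha`, one cell standing in for `K`), where
conditionability `Cnd = linsig(B, B_cnd = 2, B_mxCnd = 12)` and `linsig`
is the clipped linear ramp. With `alpha = 1/K`, one maximal shock makes
the total weight exactly 1. Expression: drive `g` (activation-weighted
synaptic sum in leakage-conductance units) depolarizes the cell to
`V = E g/(1+g)`; activation `A_F = linsig(V, 0, E/2)` is calibrated so
that `g = 1` (one maximal shock) gives full activation; expressed fear is
`A_F * linsig(B, 0, B_mxF = 4)`. `E` is a free positive constant (default
1) — only ratios to `E` matter. Representation-cell activation is binary;
partial activation enters only through overlap scaling:

* active hippocampal representation: its own CA3 weights, plus each
  conditioned cortical cell's weight scaled by the CA3 overlap with that
  cell's progenitor;
* active cortical representation: its own weight, plus its progenitor
  CA3 weights, plus other conditioned cortical cells' weights scaled by
  the generalization function G of context similarity.

Every CA3-routed term vanishes under hippocampal inactivation, and no new
representation can form while the hippocampus is off. Inhibitory
extinction circuitry is deliberately absent.

## Generalization between remote representations

Between two remote, categorized representations, similarity is
$S_{AB} = \gamma\,O_{ptcAB} + (1-\gamma)\,O_{catAB}$ with `gamma = 0.6`;
if the pair is not both categorized, similarity falls back to the total
attribute overlap. The microcircuit that computes this (normalized
synapses from known attribute cells onto p- and c-cells, divisive
inhibition by the active counts, outputs weighted `gamma` and
`1 - gamma`) reduces exactly to the closed form, which is what the
package implements; a test verifies the circuit arithmetic. The
generalized response is `G(S_AB)`: the expected CA3 overlap of
hippocampal representations of contexts with that attribute overlap when
*all* attributes are known — so remote–remote generalization depends only
on similarity, not on what happened to be sampled at creation. G is
tabulated by Monte-Carlo on a grid (21 points by default in
`make_g_table()`, monotone piecewise-linear interpolation, `G(1) = 1`
exactly since identical inputs select identical winners) on the agent's
own fixed wiring, with contexts redrawn per replicate.

## What the simulations show

With the default calibration the scripted experiments reproduce the
phenomenology the model was built for, all from the same machinery:

* a novel context in a known category is mistaken for the established
  same-category context until `Z_cur ≈ 73`, when its evidence collapses
  and a new representation forms (a long immediate shock deficit); in an
  unknown category this happens several times earlier;
* after a pre-exposure session, conditioning in the same context becomes
  possible at `Z_cur = 4` and half-maximal at 12 — and later for a
  remote than a recent representation;
* recent fear generalizes moderately to an unfamiliar similar context
  (the conditioned representation's evidence starts declining at
  `Z_cur = 47` and the unfeared test-context representation forms
  mid-session), while remote fear hyper-generalizes: the cortical
  representation, rich in shared categorical attributes, is rejected
  only at the session's very end;
* hyper-generalization does not occur when the test context is familiar,
  when the conditioned context is extremely well-known (pre-exposed to
  `Z_cur = 98`, so the retention ceiling is high), and reverses across
  categories;
* during Stage II the hippocampal version wins in similar test contexts
  and the cortical version in dissimilar ones, with fear
  hippocampus-dependent either way;
* a 60-interval reminder exposure triggers updating, returning the
  record to Stage I: generalization drops back to the recent level and
  fear is hippocampus-dependent again — with all hippocampal detail
  having been erased at consolidation, and none of it recovered; the
  effect disappears when new learning is blocked.

These statements are exactly the assertions of the package's test suite
(`tests/testthat/`), and the four event coordinates above are what
`scripts/acceptance.R` recomputes.

## Numerical and testing choices

Rounding everywhere is R's `round` (half to even); match counts, shared
counts and recalled counts are integers at the points the model consumes
them, fractional in the internal stratum bookkeeping. Decision ties favor
the hippocampal version, then registry order. A new representation
requires the winner below `B_new = -5` *and* a margin above
`delta = 5` over the runner-up; a runner-up at −∞ cannot block creation.
A representation created mid-session is scored with the same
expected-count formula as any candidate; its evidence is very large and
positive either way.

The test suite runs the full protocols at a reduced dentate profile
(`N_dg = 20000`, and 5000 for pure coding tests): every evidence
trajectory, decision and event coordinate is independent of `N_dg`,
which only sharpens the CA3-overlap tails of the fear readout. The
acceptance checks and `scripts/acceptance.R` use the full
`N_dg = 100000`. Monte-Carlo sizes default to 8–20 replicates where the
consumers are qualitative (the G table, overlap property tests); the
estimator's `sd` is reported alongside every mean.

## Limitations

No extinction (and hence no exposure-therapy simulation); no learning of
new categories or category attributes from experience — Stage II's
knowledge-upgrading is represented only as an event with a driver-chosen
duration; a single amygdala unit with binary representation-cell
activation; no attribute noise; no wall-clock time. The hypergeometric
null assumes the recalled attributes are scattered uniformly over the
attribute universe; structured environments would need a different null.
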