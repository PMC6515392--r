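---
title: "Rank-order spiking network classification of electronic-nose data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-order spiking network classification of electronic-nose data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A metal-oxide (MOX) gas-sensor array — here a 4 × 4 array, sixteen sensors —
responds to an odour exposure with a vector of steady-state resistance
changes. Classifying these multivariate responses quickly and robustly is
the central computational task of an electronic nose. Rank-order coding
offers a biologically inspired route: instead of the absolute response
amplitudes, only the *order* in which the sensors would fire is kept. The
resulting signature is a permutation of the sixteen sensors, largely
invariant to overall concentration (a common gain shifts all latencies
equally), cheap to transmit as a spike train, and classifiable before the
frame is even complete.

`rosnn` implements this pipeline end to end in software: encoding,
reference derivation, a simulator of the nearest-neighbour spiking
network that performs the classification, per-spike streaming readout,
open-set anomaly detection, and a synthetic data generator that makes
every stage testable without any external dataset.

## Encoding: from resistance to rank order

The firing latency of sensor $i$ exposed to gas $j$ is

$$ t_i = \frac{\ln R_{ij}}{\gamma_{ij}}, $$

where $R_{ij}$ is the steady-state resistance-derived feature and
$\gamma_{ij} > 0$ a sensor/gas characteristic. Sensor- and gas-specific
$\gamma$ values are rarely available in practice, so the package defaults
to $\gamma = 1$ for every sensor, under which the firing order is simply
the order of the raw responses; per-sensor (or per-exposure) $\gamma$
remains configurable, and `estimate_gamma()` back-solves
$\gamma = \ln R / t_\mathrm{ref}$ from a designated reference exposure
when target latencies are known. Non-positive features are rejected, not
clamped: a clamped value would silently corrupt the rank order, which is
the entire signal here.

`to_rank_order()` converts latencies to the signature: component $i$ is
the rank (0 = earliest) at which sensor $i$ fires. Ties are broken in
favour of the lower sensor index — an arbitrary but deterministic rule,
so repeated runs and platforms agree bit for bit.

### Byte representation and the footrule identity

The network stores and compares byte vectors. A signature is mapped to
bytes *rank-by-sensor*: component $i$ equals
$\mathrm{scale} \times \mathrm{rank}(i)$, with `scale = 16` so the
sixteen rank levels span 0–240 of the byte range and influence fields
have integer headroom. Under this layout the full-frame Manhattan
distance between two encoded signatures is exactly
$\mathrm{scale} \times$ the Spearman footrule distance
$\sum_i |a_i - b_i|$ between the two permutations — an ordinal distance
under which a mild shuffle of adjacent spikes moves a pattern only
slightly, which is precisely the robustness rank-order classification
needs. The alternative *sensor-by-rank* layout (component $j$ = index of
the $j$-th firing sensor) would make a single adjacent swap look like two
arbitrary byte substitutions; it is documented here as the road not
taken. A component mask marks which sensors have fired, which makes the
streaming window (below) a property of the broadcast vector rather than
of the network.

## The network: RCE nearest-neighbour neurons with influence fields

The classifier is a software simulation of a daisy-chain network of up
to 1024 pattern-matching neurons (restricted-Coulomb-energy family).
Each committed neuron holds a byte prototype $P$, a category, and an
active influence field (AIF). On a broadcast $V$ every neuron evaluates
the Manhattan distance $D = \sum_i |V_i - P_i|$ over the masked window;
in RBF mode it *fires* when $D$ is strictly below its AIF. The
winner-takes-all readout returns the $k$ best firing neurons by
increasing distance ($k = 2$ by default), ties resolved by lower neuron
id, matching the deterministic search order of a daisy chain. The result
status is `unknown` when nothing fires (the open-set case), `identified`
when all firing neurons agree, `uncertain` otherwise. KNN mode ignores
the AIF — every committed neuron answers — and therefore can never
return `unknown`; with a multi-category network its status is
effectively always `uncertain`, so the WTA hit list carries the
decision there.

Learning commits and shrinks neurons:

* no neuron fires → commit the pattern with AIF = `max_if`;
* neurons fire, none with the target category → commit with AIF equal to
  the distance of the closest firing neuron, and shrink every
  wrong-category firing neuron's AIF to its own distance from the
  broadcast;
* a firing neuron already carries the category → no commit (the pattern
  is absorbed); wrong-category firing neurons still shrink.

Shrinkage clamps at `min_if` and flags the neuron *degenerate* rather
than deleting it, preserving its category at minimal reach. AIFs never
grow after commit. Two consequences are worth stating plainly. First,
learning is order-dependent (the committed set depends on presentation
order) while classification is order-invariant given the same committed
set. Second, exact recall of every training pattern at distance 0 holds
only in regimes where every pattern actually commits — i.e. when
`max_if` is below typical same-category distances; with the default
large `max_if`, later same-category patterns are absorbed by case three
and are recalled by the *category* of a nearby prototype, not at
distance 0. Both regimes are exercised in the test suite.

The default registers tie AIF granularity to the encoder scale:
`max_if = 3840` (a conservative bound: 16 components × 240, above any
achievable frame distance at scale 16, so a first-committed neuron
initially covers the whole space) and `min_if = 16`, one rank step. The
firing condition uses strict inequality ($D < \mathrm{AIF}$).

## Reference derivation: probabilistic rank-score coding

Rather than training on many noisy exemplars, one reference signature
per gas is derived from the empirical rank statistics. For gas $k$,

$$ P_{ij}(k) = \frac{N_{ij}(k)}{N(k)} $$

is the probability that sensor $i$ spikes at rank $j$, estimated over
the $N(k)$ recorded frames. On complete frames each column of
$P(k)$ sums to one. The matrix is collapsed to a single permutation by a
greedy maximum-probability assignment: cells are visited in decreasing
probability (ties by lower rank, then lower sensor index) and accepted
when both their sensor and rank are still free. The greedy rule is
transparent and reproducible; an exact linear-assignment alternative
(`method = "optimal"`, an $O(n^3)$ shortest-augmenting-path solver
written for this package) is available behind a flag and is checked
against exhaustive enumeration on small instances in the tests. The two
coincide whenever the probability mass is unambiguous, which is the
typical case at realistic noise levels; greedy can fall short of the
optimum on near-uniform matrices, where no single signature is
meaningful anyway. The learning set that reaches the network is then one
signature per class — completely distinct from, and roughly two orders
of magnitude smaller than, the classified data.

## Streaming: the increasing pattern-matching window

Spikes arrive in firing order, so after $m$ spikes the receiver knows
the ranks $0..m-1$ of the $m$ sensors seen so far. Each arrival enlarges
the window mask and triggers a classification of the partial signature,
giving a result from the very first spike. Masked distances are
deliberately *not* rescaled for window size: a small window yields small
distances, so early spikes fire many neurons and the candidate set
narrows as evidence accumulates — this is the mechanism, not an
artefact. For a fixed frame and neuron the masked distance is
non-decreasing in $m$ (Manhattan sums non-negative terms), and the
per-spike results are identical to batch classification of the
equivalent masked vectors; both are enforced as tests.

Two decision-latch policies convert a 16-result trace into a decision
with its spikes-to-decision count $m$:

* **stable** (default, used for all reported metrics): the smallest $m$
  such that a top-1 category exists at every window $m..16$ and never
  changes again. This is a retrospective criterion, appropriate for
  reporting averages over recorded frames.
* **first-identified**: the smallest window whose status is
  `identified`; usable online but more optimistic.

The fraction of the pattern frame used is $100\,m/16$ percent — three
spikes are 18.75 %. Frames whose full signature fires no neuron are
logged to an anomaly store with the category `"unknown"` for later
labelling; this is the intended hook for detecting consistent signature
changes caused by sensor drift. Partial frames (a dead sensor, a
truncated stream) are classified on the available mask and flagged
incomplete rather than rejected; they are never logged as anomalies.

## The synthetic generator

`enose_config()` / `sample_dataset()` emulate the statistical structure
the pipeline assumes, so every claim above is testable offline. The log
steady-state response of sensor $i$ to gas $k$ at concentration $C$ in
batch $b$ is

$$ \ln R = \beta_i(k) - \alpha_i(k)\,\ln (C/C_0) + b\,\delta +
\varepsilon, \qquad \varepsilon \sim \mathcal N(0, \sigma^2), $$

a power law in concentration on the natural scale with Gaussian noise on
the log response (equivalently, latency jitter at $\gamma = 1$ — noise
is applied where the physics applies it, on the response, not on the
ranks). $\beta_i(k)$ increases by a fixed `spacing` (default 1 log unit)
per template rank, so with sensor-constant $\alpha$ the noise-free rank
order equals the class template at every concentration; heterogeneous
$\alpha$ lets rank orders cross between concentrations, reproducing the
concentration inconsistencies that steady-state encoding exhibits in
practice. $\delta$ is an optional monotone drift per batch.

Defaults are fixed to a six-gas benchmark design: analytes ammonia,
acetaldehyde, acetone, ethylene, ethanol, toluene with concentration
grids of 50–275, 50–300, 150–500, 50–275, 50–300 and 20–75 ppmv and
per-class sample counts 55, 23, 40, 64, 46, 57 (285 exposures). The six
templates are five random permutations (internal seed 0) with pairwise
footrule separation ≥ 40, plus ethanol built from ethylene by swapping
the sensors at rank pairs (2,3), (6,7), (10,11), (14,15) — footrule
distance exactly 8 — to mimic a pair of closely related odours whose
signatures agree on their first two elements and must therefore wait for
the third spike to be told apart. The jitter dial is calibrated in
interpretable units: `noise_for_swaps(s)` returns the sd for which two
latencies one spacing apart swap with probability $s/15$, i.e. an
expected $s$ adjacent swaps per frame; the default is one swap per frame,
a moderate shuffle. The generator's seed fully determines its output,
and generation restores the caller's RNG state.

What the generator does **not** model: real electrochemical sensor
dynamics, transient features, correlated sensor noise, humidity and
temperature covariates, or the batch statistics of any real drift
archive. Passing tests on synthetic data therefore demonstrate the
correctness and the qualitative behaviour of the pipeline — not field
performance on a physical array.

## Evaluation conventions

`evaluate_traces()` reports the confusion matrix (rows = truth) with a
trailing `"unknown"` column for frames that never latch or end unknown;
row sums equal the per-class counts and such frames count as errors in
the accuracy (a conservative convention), while being excluded from
spikes-to-decision averages. Percentages and spike counts are printed to
two decimals; stored values are exact.

In the bundled six-gas experiment (seed 0, defaults throughout) the
streamed accuracy is above 99 % with a mean of about 1.8 spikes (≈ 11 %
of the frame) to a stable decision, and the ethylene/ethanol pair needs
about 3 spikes against 1 for the well-separated gases — the per-analyte
frame-fraction variance is concentrated in the confusable pair. These
numbers are recomputed, not quoted, by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`.

For open-set experiments, "distant" is defined from the RBF notion of
unknown itself: an untrained gas template is rejection-sampled at
footrule distance at least $\lceil \max(\mathrm{AIF})/\mathrm{scale}
\rceil + 6$ (a three-swap noise margin) from every reference, i.e.
demonstrably beyond every learned influence field. A fixed separation
threshold would not guarantee this, because learned AIFs equal
nearest-reference distances and can legitimately be large.

## Numerical and design notes

* All distances, prototypes and AIFs are integers; there is no floating
  point in the decision path, so results are platform-exact.
* Tie-breaks everywhere are deterministic: lower sensor index (rank
  ties), lower neuron id (distance ties), lower rank then sensor
  (rank-score ties).
* Learning at capacity raises an error only when a commit is actually
  required; absorbing presentations still succeed.
* Network state round-trips bit-exactly through JSON
  (`rce_serialize()` / `rce_deserialize()`).
* Problem sizes in the test suite (285-frame benchmark, 1000-frame
  stream/batch sweeps, 10,000-case distance oracle) were chosen as the
  smallest sizes at which the corresponding claims are meaningfully
  exercised.

## Limitations

* The learning rule follows the published register semantics literally;
  hardware subtleties (cycle timing, serial protocols, on-chip save
  formats, the L-sup distance option) are out of scope.
* Spikes-to-decision figures depend on the latch policy; the stable
  policy is retrospective and cannot be evaluated online before frame
  end (the first-identified policy can, at some optimism).
* Concentration-invariant encoding via full power-law characterisation
  of each sensor/gas pair is not implemented; with $\gamma = 1$ the
  encoding is concentration-robust only insofar as sensitivities are
  sensor-constant within a gas.
* With sparse reference-only learning, influence fields equal
  nearest-reference distances and can over-generalise; open-set
  detection of gases *near* a trained class is correspondingly weak.
  Committing more exemplars per class (`learn = "exemplars"`) tightens
  the fields at the cost of more neurons.
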