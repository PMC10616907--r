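---
title: "Inferring cortical microconnectomes from spike trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cortical microconnectomes from spike trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multielectrode-array recordings from acute cortical slices yield
millisecond-resolved spike trains from hundreds of sorted units. `microte`
turns such binned rasters into *effective networks*: directed, weighted
graphs of statistically validated causal interactions between neurons,
with each neuron classified as excitatory or inhibitory from the spiking
data alone. On top of the inferred networks it computes the topological
and physiological summaries used to compare cortical region groups:
degrees, k-cores, weighted minimum feedback vertex sets, layer-resolved
densities and firing rates, interlayer weight matrices, and
permutation-based group statistics.

Because raw slice recordings are rarely shared, the package ships a
spiking-network simulator with known ground truth, so every stage of the
pipeline is testable end to end.

# Connectivity model

## Transfer entropy over delays

For a source neuron $j$ and target neuron $i$, binned at 1 ms, the
delay-resolved plug-in transfer entropy is

$$TE_{J \to I}(d) = \sum_{i_t,\,i_{t-1},\,j_{t-d}}
  p(i_t, i_{t-1}, j_{t-d})
  \log \frac{p(i_t \mid i_{t-1}, j_{t-d})}{p(i_t \mid i_{t-1})},$$

with empirical frequencies over every bin $t$ where all three indices
exist ($t \in [\max(1, d),\, T-1]$, 0-based; no padding), and
$0 \log 0 \equiv 0$. Only one past bin of the target is conditioned on:
for 1 ms binary spike trains, deeper target histories do not materially
change the delay profile, and the single-bin form keeps the estimator's
state space at eight cells. Natural logarithms are used throughout; the
base is a presentational choice that cancels in every derived ratio.

A direct synaptic connection produces a strong, sharp peak of $TE(d)$ at
the synaptic delay. Two summaries capture this:

* **Strength** $= TE(d_{peak})$, the profile maximum (smallest delay on
  ties — a documented, tested tie-break);
* **Sharpness** $= \sum_{d=0}^{d_{peak}+\tau} TE(d) \, / \,
  \sum_{d=0}^{30} TE(d)$ with $\tau = 4$ ms; the numerator window is
  clipped at 30, keeping the value in $(0, 1]$. The 30 ms window
  comfortably covers conduction delays across a millimetre-scale array.

Delay $d = 0$ is included in every sum. A pair whose TE profile is
identically zero carries no signal; its sharpness is undefined and the
pair can never become an edge.

## Sorted local transfer entropy and E/I identity

The local (per-configuration) terms of TE are sign-weighted by
$(-1)^{(i_t - j_{t-d})}$: $+1$ when source and target bins hold the same
event, $-1$ otherwise. Summed, this *sorted local transfer entropy*
(SLTE) is positive for excitatory and negative for inhibitory
interactions. The SLTE value at the TE-peak delay is the pair's **E-I
bias**.

Per sending neuron, outgoing E-I bias values are ranked by absolute
value, the bottom 10% (floor of $0.1 \times$ count, per sender) dropped
as a noise filter, and the remainder summed into a per-neuron score. Ties
in $|$E-I bias$|$ are broken by the firing-rate-normalized peak TE,
$TE_{nor} = TE_{peak} / |FR \log FR + (1-FR)\log(1-FR)|$ (the magnitude
of the binary entropy is used: the raw denominator is negative on
$(0,1)$ and would invert orderings). The score is paired with log firing
rate, standardized, and Ward-clustered; clusters are labeled by the sign
of their mean score, as Dale's principle predicts.

Two design choices here were genuinely open and deserve justification:

* **Cluster count.** Cutting the Ward tree at $k = 2$ is the obvious
  reading of a binary classification, but at desk scale (100 neurons, 3%
  connectivity) a sender's score is roughly proportional to its
  out-degree, which is Binomial with mean 3 — the excitatory score
  distribution has a heavy upper tail, and the two-cluster split
  reliably isolates that tail instead of the E/I boundary. The default
  is therefore $k = 4$: the tail forms its own (strongly positive)
  cluster and the sign rule labels every cluster correctly. Both $k$ and
  the margin are exposed parameters.
* **Same-side degenerate rule.** Network-wide common drive shifts every
  score slightly positive, so the inhibitory cluster's mean can sit just
  above zero. When all cluster means share a sign, the extreme cluster
  nearest zero is labeled with the opposite class only if its mean is
  below `margin` (default 0.25) times the median of the others;
  otherwise the population is treated as single-class, with a warning.
  This keeps genuinely all-excitatory populations labeled as such while
  tolerating the common-drive shift in mixed populations.

## Jitter surrogates and the connection decision

The null model relocates every spike of the *presynaptic* series
uniformly among bins within $\pm 10$ ms that were spike-free in the
original series, preserving per-neuron spike counts exactly and rates on
slow timescales while destroying millisecond timing. Spikes move one at
a time in temporal order against the original occupancy; destination
collisions are resolved by resampling among the remaining free bins, and
a spike with no admissible destination stays put (counted and reported).
The ensemble default is 100 surrogates; 10 is adequate for the detection
decision and is what the test suite uses.

Detection proceeds per E/I connection category (EE, EI, IE, II):
real and surrogate pairs are histogrammed on a 20×20 grid over
$\log_{10}$(Strength) × Sharpness (log scaling because effective-weight
distributions are approximately logarithmic), surrogate counts divided
by the ensemble size, and a cell is accepted when the real count is at
least `excess_ratio` (default 3) times the surrogate expectation *and*
strictly exceeds every individual surrogate's count in that cell. The
strict-max guard is what keeps sparse cells honest: with ten surrogates,
a lone real pair in a cell whose surrogate expectation is 0.3 would pass
any reasonable ratio test, and on a no-edge Poisson control such cells
alone produce a few percent of false density. The defaults were
calibrated on the simulator to land in the low-percent density regime on
the default recording while keeping the no-edge control below 1%
detected density.

Accepted pairs become edges with the information-theoretic weight
$IT_{j \to i} = TE^{real}(d_{peak}) - \overline{TE^{shuffle}(d_{peak})}$
(surrogate mean at the real peak delay; the mean is the default summary,
the median available). Edges with nonpositive weight are dropped.

# The synthetic study conditions

The simulator emulates the recordings the method was designed for; its
defaults are the study conditions of every calibration experiment and
are not tuning knobs.

* **Structure**: directed Erdős–Rényi adjacency at density 0.03
  (matching the low-percent connection probabilities reported for slice
  effective networks), no self-edges, exactly
  $\mathrm{round}(0.2\,n)$ inhibitory senders, Dale-conforming signs,
  integer delays uniform on 1–10 ms (inside the 30 ms TE window — the
  true slice delay distribution is unknown; this is a stand-in, not an
  inference), per-edge weights equal to a class gain times a
  $\mathrm{lognormal}(0, 0.3)$ multiplier.
* **Dynamics**: discrete-time Bernoulli GLM,
  $P(\text{spike}_i \text{ at } t) = \mathrm{logistic}\big(b_i + \sum_j
  s_j w_{ji} x_j(t - d_{ji})\big)$, with a 2 ms absolute refractory
  period. This is the cheapest dynamics with genuine millisecond-lagged
  causal structure.
* **Gains**: excitatory 2, inhibitory 6 (logit units). Suppressing an
  already-rare event leaves a far fainter information trace than
  eliciting one, so inhibition needs the larger gain to be detectable at
  all; both values keep the network in an asynchronous regime (branching
  well below 1, no runaway).
* **Rates**: baselines log-uniform on 0.5–4 Hz for excitatory and
  4–10 Hz for inhibitory neurons. The contrast mirrors the well-known
  elevated firing of fast-spiking interneurons relative to pyramidal
  cells — the same contrast the slice data show — and makes the log-rate
  clustering axis informative, as intended by the classification design.
  Keeping the network quiet overall matters: strong recurrent excitation
  floods every pair with common-drive correlations that shift all SLTE
  scores positive.
* **Duration**: 2.5 h (9 × 10⁶ bins) by default, the protocol length of
  the recordings this pipeline targets; long recordings are essential
  because the estimator bias of TE falls as $1/T$ while true-edge signal
  is $T$-independent. Shorter recordings (30 min) are used where an
  experiment specifies them, and edge-level recovery is already
  excellent there.
* **Geometry**: positions uniform on the 2.0 × 4.0 mm array sheet;
  depths sampled from a three-Gaussian depth–density profile with peaks
  at 300/550/900 μm (the centers of layers 3, 4, 6) in an 1100 μm
  cortex; layers assigned from the boundary rules below.

What the simulator does *not* emulate: bursting and up/down states,
distance-dependent connectivity, conduction-delay/distance correlation,
electrode-level noise, spike-sorting errors, and non-stationary rates.
Passing tests therefore demonstrate correctness of the estimation
machinery under clean, stationary, asynchronous conditions — not
robustness to every pathology of real slice data.

# Layer analysis

Cortical depth–density profiles show three convex points (centers of
layers 3, 4, 6) and two concave points between them. After
moving-average smoothing (default window 5 bins; landmarks are detected
on the smoothed profile only), the five boundaries are:

| boundary | rule |
|----------|------|
| L1/2 | 1/3 of the way from the surface to the first convex point |
| L2/3 | 2/3 of the way from the surface to the first convex point |
| L3/4 | the concave point between the first and second convex points |
| L4/5 | midpoint of the second convex and second concave points |
| L5/6 | midpoint of the second concave and third convex points |

Two of the published rules are internally inconsistent with the stated
landmark count, so both readings are preserved: the L2/3 rule's
reference point (`rule_l23`: first vs second convex point; the first is
the default as the geometrically coherent reading, since the first
convex point is the layer-3 center) and the L5/6 rule (`rule_l56`:
concave–convex midpoint by default; the literal concave–concave reading
is available when a third concave point exists). Layers occupy half-open
depth intervals, boundary ties going to the deeper layer; layer-1
neurons are excluded from per-layer metrics; thicknesses partition the
cortex exactly.

Active neurons are those firing strictly above 0.1 Hz; densities are
counts per recording area (mm²), deliberately not volume-normalized
(fixed 300 μm slice thickness).

# Network metrics and group statistics

Degrees and k-cores are computed on the thresholded binary network
(weights enter only through node weights); the k-core uses total degree
on the underlying undirected simple graph, the degree-based reading of
the peeling definition. Minimum feedback vertex sets are solved exactly
per strongly connected component by subset search in order of
cardinality, with the weighted variant maximizing total node weight
(recomputed in-strength) among minimum-cardinality sets — a strictly
lexicographic objective. The component-size limit (default 20) exists
because the search is exponential; every returned set is verified by an
independent acyclicity check after removing its in-edges.

Group comparisons use the two-sided Mann–Whitney test (exact null when
both samples are ≤ 8 and tie-free) with Bonferroni correction, reporting
the common-language effect size $U/(n_1 n_2)$ with ties counted half —
the unfolded form, so swapping group roles maps $e \mapsto 1-e$.
Interlayer weight matrices (mean edge weight per sender-layer ×
receiver-layer cell) are compared between region groups by a per-cell
permutation test on the two-sample $t$ statistic with the add-one
estimator $p = (1 + \#\{|t_\pi| \ge |t_{obs}|\})/(1 + n_\pi)$, 10,000
permutations by default, and difference-in-means effect sizes. This is
the per-cell form of the network-based-statistic family; cells missing
in more than half of either group's recordings are marked untestable.

# Numerical choices and problem sizes

* All TE quantities are computed by a cross-correlogram-style counting
  kernel whose cost scales with spike pairs inside the 30 ms window, not
  with bins × delays; a 100-neuron, 2.5 h all-pairs computation takes
  seconds.
* Plug-in TE is clamped at zero against floating-point roundoff only
  (tolerance $10^{-12}$); the suite verifies equality with an
  exhaustive-histogram oracle to $10^{-12}$.
* Reproducibility: every stochastic stage takes a seed; surrogate
  ensembles keep a per-surrogate seed ledger; the full pipeline is
  byte-identical under a fixed seed.
* The test suite exercises: classification on five 2.5 h default
  recordings; delay/sign recovery on a 30 min recording; detection on
  one default recording with 10 surrogates plus a matched no-edge
  Poisson control; surrogate validity on 1000 shuffles of a 50-neuron
  raster; statistics calibration at 2000 permutations × 200 null
  repeats; and end-to-end determinism on a 100-neuron, 5 min, 5
  surrogate configuration (determinism is representation-level and does
  not depend on problem size).

# Known limitations

* Inhibitory edges whose receivers fire slowly are close to
  information-theoretically invisible; recovery statistics are quoted
  for strong edges (planted weight at or above the median).
* The per-sender SLTE sum has poor signal-to-noise when out-degrees are
  very small; classification accuracy at 100 neurons and 3% density
  leans on the firing-rate axis in a way it would not at the several
  hundred neurons of a full recording.
* The FVS solver is exact but exponential; networks whose largest
  strongly connected component exceeds the configured limit need either
  a higher limit (moderate sizes only) or subsampling.
* Detection calibration (grid, excess ratio, strict-max guard) was tuned
  on the simulator's clean conditions; real recordings with common-input
  structure from unobserved neurons will need the knobs revisited.
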