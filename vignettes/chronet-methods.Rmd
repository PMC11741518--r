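---
title: "Temporal causal discovery from live-cell features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal causal discovery from live-cell features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronet)
```

chronet learns temporal causal networks from multivariate, mixed-type time
series — typically morphodynamic and interaction descriptors of tracked
cells under controlled experimental conditions — and ships the feature
extractor that produces such descriptor tables from time-lapse microscopy.
This vignette is the package's own account of the underlying models, the
tunable parameters, the numerical choices, and what the synthetic
benchmarks do and do not demonstrate.

## The time-unfolded graph

A stationary multivariate process $\{X^v_t\}$ is represented by a
*time-unfolded* graph: each variable $v$ appears as a set of lagged nodes
$(v, \ell)$ with $\ell \in \{0, \delta\tau, 2\delta\tau, \dots, \tau\}$,
where lag 0 is the running (contemporaneous) layer, $\tau$ is the maximum
lag considered, and $\delta\tau$ the spacing between layers (so there are
$\nu = \tau/\delta\tau$ lagged layers).  Stationarity makes the structure
translation invariant: an edge learned between $(v, \ell_a)$ and
$(w, \ell_b)$ must also hold between $(v, \ell_a + \delta\tau)$ and
$(w, \ell_b + \delta\tau)$.  The engine therefore only tests node pairs
with at least one contemporaneous endpoint and duplicates the retained
edges across shifts (`close_translation()`).  Contextual variables —
time-invariant experimental conditions such as treatment or co-culture
presence — live at lag 0 only and never receive arrowheads.

The learned unfolded graph is collapsed to a *summary graph*
(`collapse_summary()`): one edge per (variable pair, lag), annotated with
the delay in original time steps, an orientation (directed, undirected, or
bidirected for a latent common cause), the sign of the pairwise
association, and a confidence.

### Choice of the lag window

`estimate_tau()` sets $\tau$ to twice the mean relaxation time of the
variables, where a variable's relaxation time is the smallest lag at which
its autocorrelation falls below $1/e$ (averaged over trajectories);
$\delta\tau = \max(1, \mathrm{round}(\tau/\texttt{target\_layers}))$ with
12 target layers by default, and $\tau$ is snapped down to a multiple of
$\delta\tau$.  The window is intentionally generous: on stationary data an
overestimated $\tau$ leaves the summary graph essentially unchanged (the
extra layers are separated away), which `robustness_tau()` quantifies.
Nonstationary variables instead accumulate lagged self-loops across many
layers — a useful diagnostic rather than a failure mode.  A variable whose
autocorrelation never crosses $1/e$ within half the series length is
excluded from the relaxation average.  (For a mean-centered sample ACF
such a variable is nearly a mathematical impossibility — the sample
autocorrelations sum to about $-1/2$ — so in practice the exclusion rule
is triggered by degenerate series and the real guard against
nonstationarity is the self-loop diagnostic.)

## Penalized information estimates

All independence decisions use one primitive: penalized (conditional)
mutual information, in nats.  For a pair $(X, Y)$ given a set $Z$:

* continuous margins are discretized by equal-frequency binning, and the
  penalized statistic $n\hat I - k$ is maximized over a grid of bin counts
  (2, 3, 5, 8, 12, 16, 22, capped so the table keeps several samples per
  cell) — a finite-sample supremum principle.  Categorical variables use
  their observed levels directly, so continuous and categorical data are
  handled on the same footing;
* the complexity penalty is $k = \tfrac12 \chi^2_{1-\alpha}(\mathrm{df})$
  with $\mathrm{df} = (|X|-1)(|Y|-1)\,|Z_{\mathrm{cells}}|$ and
  $\alpha = 10^{-4}$ by default.  This calibrates the test: independent
  data give a negative penalized value in far more than 95% of runs at any
  sample size, while the penalty grows with the number of bins, levels and
  conditioning cells;
* the reported `raw_info` is Miller–Madow debiased
  ($\hat I - \mathrm{df}/2n$), which keeps the estimate within a few
  percent of the Gaussian closed form $-\tfrac12\log(1-\rho^2)$ at
  $n = 10{,}000$;
* conditioning cells are built at two resolutions (a coarse one for
  power, a finer one so that dependence *mediated* by $Z$ does not leak
  through wide cells), and the penalized value of a cell-based conditional
  test is the minimum over the two;
* for all-continuous triples the conditional test instead uses a
  *residual route*: both variables are partialled on $Z$ by binned-mean
  backfitting (two rounds over the conditioners, plus one joint
  coarse-cell pass that absorbs interactions), and penalized MI is
  computed between the residuals.  This keeps full power for additive
  conditional dependences — where cell-based conditioning pays an
  exponential price in $|Z|$ — and is authoritative whenever it applies;
  the cell route remains the test when categorical or contextual
  variables are involved.

The signed three-point information
$I(X;Y;Z\mid U) = I(X;Y\mid U) - I(X;Y\mid U,Z)$ carries its own penalty
(the complexity increment of adding $Z$, floored at the one-degree-of-
freedom penalty): significantly positive values mark $Z$ as an information
*contributor* to the $X$–$Y$ dependence, significantly negative values are
the signature of a collider.

Transfer entropy is the same primitive applied to lagged blocks:
$T_{X\to Y} = I(Y_t; X_{t-1..t-L} \mid Y_{t-1..t-L})$, with the source
block scanned over small per-lag resolutions (a lag may drop out
entirely).  A penalized value at or below zero means the transfer entropy
is indistinguishable from zero — the Granger–Schreiber signature of
temporal non-causality.

## Skeleton learning

Candidate edges are all pairs with at least one lag-0 endpoint
(contextual variables pair with lag-0 nodes only).  Learning proceeds in
three phases:

1. *Screening*: pairs whose unconditional penalized MI is non-positive
   are removed immediately.
2. *Iterative contributors*: for each surviving pair (weakest first), the
   neighbor $z$ with the largest positive penalized three-point
   information joins the conditioning set; the edge is removed as soon as
   the penalized conditional MI drops to zero or below (the set is then
   the recorded separating set), and retained when no significant
   contributor remains (conditioning sets are capped at 3).  For lagged
   pairs, strictly-past contributors are preferred over contemporaneous
   ones: conditioning on a contemporaneous descendant can cancel a
   genuine dependence by explaining-away, corrupting separating sets.
3. *Forced-depth re-examination*: the greedy step requires each
   contributor to be individually significant and so can miss separating
   sets whose members are individually weak (e.g. a faint common parent
   spreading dependence over several lags).  Every retained pair is
   re-tested conditioning on its most relevant past-side neighbors
   (ranked by a quick coarse pairwise-information score), sequentially up
   to the same depth cap.

Every decision — status, contributors, separating set, final penalized
information — is retained in an audit table.

## Orientation

1. Lagged edges receive a first arrowhead at their lag-0 endpoint (the
   future cannot cause the past); contextual edges point from the
   condition into the feature.
2. Unshielded triples $a - z - b$ are examined at their anchored
   representative (smallest lags).  If $z$ belongs to the separating set
   of $(a, b)$ the triple is a definite non-collider.  Otherwise the
   three-point information of the triple, conditioned on that separating
   set, is evaluated: a significantly negative score proposes the
   collider $a \to z \gets b$ with confidence
   $1/(1+e^{\mathrm{score}})$, accepted above `conf_cutoff` (default
   0.95, i.e. roughly 3 nats of evidence).  A proposed collider is still
   *refuted* if some conditioning set containing $z$ (searched over the
   endpoints' neighborhoods) separates the pair — in that case the
   apparent activation came from an unblocked side path.  This is the
   only rule able to place a *backward* arrowhead on a lagged edge;
   arrow–arrow lagged edges are reported as bidirected, the signature of
   a time-lagged latent common cause.
3. Orientations propagate along definite non-collider triples (the
   standard first propagation rule only, applied conservatively: never
   into the past, never into a contextual node).  Conflicting marks are
   downgraded to unknown and counted.
4. Marks are re-closed by translation; disagreements among shifted copies
   are likewise downgraded.

Edge signs use the Pearson correlation of the endpoint columns for
continuous pairs, the point-biserial correlation for mixed pairs, and the
sign of the dominant Pearson residual of the contingency table for
categorical pairs.

## Feature extraction from time-lapse videos

The extractor mirrors a standard live-cell pipeline: circular-Hough
detection of the two disk-like cell populations (default theoretical radii
4 px for immune cells and 14 px for the main cancer cell, at
0.645 µm/px), optimal-assignment tracking, and per-frame descriptors.

*Detection* votes gradient orientations along their inward direction at
each candidate radius; votes are smoothed, normalized by the circle
perimeter, and discounted by the coherence of the incoming vote
directions (a genuine center collects votes from all sides, an edge or
arc fragment from one).  Peaks above a sensitivity threshold are returned
with non-maximum suppression.

*Tracking* links detections frame to frame by the Hungarian algorithm
with an assignment cost equal to the (negated) inverse distance
$-1/(d+\varepsilon)$, $\varepsilon = 10^{-6}$ px for numerical safety;
pairings beyond the population gate (40 px for cancer, 20 px for immune
cells) are forbidden, unmatched detections open tracks, unmatched tracks
carry gaps and expire after `max_gap` frames.  Two tracks may briefly
(≤ 2 consecutive frames) share one detection — cell overlap from the
projection of a 3-D scene — before the share is dropped.

*Segmentation* of the main cancer cell is an edge-adherent morphological
procedure seeded at the detection: Otsu thresholding of the local window,
connected component at the seed, hole filling and majority smoothing,
with a collapse flag when the window has no usable contrast (descriptors
are then missing for that frame).

The 15 per-frame descriptors follow their textbook definitions: area,
perimeter (length of the lightly smoothed 0.5-level contour — the
smoothing reduces the stair-casing bias of a rasterized boundary),
circularity $4\pi A/P^2$, eccentricity of the second-moment ellipse,
equivalent diameter $\sqrt{4A/\pi}$, instantaneous shape change
$|d_i - d_{i-1}|$, velocity, net displacement, directionality (net over
curvilinear distance, defined as 0 for a stationary cell), apoptosis and
division step flags (consumed as annotations; automatic event detection
is out of scope), and the cancer–immune interaction descriptors built on
the radii $r_1 = r_{im} + r_{ca} + 2 = 20$ px (physical contact) and
$r_2 = 2(r_{im} + r_{ca}) = 36$ px (close vicinity): counts within each
radius, minimal distance within $r_2$, and mean instantaneous immune
velocity within each radius.

## Synthetic benchmarks: what they emulate

`generate_linear()` draws 15-node stationary linear autoregressive
structural models: every node keeps a self-dependence at lag 1
(coefficient 0.3–0.7), cross edges (one per node on average, i.e. mean
cross degree ≈ 2) get lags in $\{1, 2\}$ and signed weights of magnitude
0.2–0.8, innovations are unit Gaussian, and stability is enforced by
redrawing until the companion spectral radius is below 0.98.  Sample
cross-covariances agree with the analytic Yule–Walker solution.
`generate_nonlinear()` keeps the same lagged structure but passes each
cross-edge contribution through a bounded nonlinearity (quadratic,
cosine, saturating piecewise-linear, or multiplicative pairing with a
second parent), which keeps the process stationary without explicit
renormalization.  Cross edges are purely lagged: these are autoregressive
benchmarks, and orientation of lagged edges is then fixed by time, so the
oriented and skeleton scores differ only through genuine orientation
mistakes (spurious backward arrowheads).

The two-variable counterexample models (`generate_te_models()`) encode
the relation between transfer entropy and temporal v-structures: in case
"a" the source X is autonomous (AR(1), coefficient 0.6) and
$Y_t = 0.5 X_t + 0.5 Y_{t-1} + \varepsilon$, so $T_{Y\to X}$ vanishes
structurally and the learned graph contains the temporal v-structure
$Y_{t'} \to Y_t \gets X_t$; case "b" adds the feedback
$Y_{t-2} \to X_t$ with weight 0.3, chosen to keep the loop comfortably
stable (companion radius 0.94; a weight of 0.4 would sit exactly at the
unit root) while remaining clearly detectable, so the same
v-structure coexists with a retained feedback edge and strictly positive
$T_{Y\to X}$.

The video generator renders soft-edged bright disks of the two radius
classes on a noisy background, moving as random walks with slowly varying
drift; divisions split a disk, apoptoses shrink and fade it.  Ground
truth (positions, radii, events) ships with every dataset, so the
detection/tracking loop can be scored directly.

What passing these benchmarks shows — and what it does not: the
generators produce stationary, regularly sampled, complete data with
known functional forms and Gaussian innovations, and videos with
well-separated, high-contrast cells.  Real microscopy features are
irregular, heteroscedastic, partially missing (the package rejects
missing values by design), and their crops contain clutter the renderer
does not emulate.  Scores on these benchmarks are evidence about the
algorithms, not about any particular biological dataset.

## Numerical choices and problem sizes

The replicated benchmarks used in the tests and in the acceptance script
run 10 datasets of 10,000 time steps per generator with $\tau = 2$,
$\delta\tau = 1$ (the generating lag depth); the lag-robustness
experiment compares $\tau \in \{2, 5, 10\}$ on 4,000-step series, and the
nonstationarity experiment adds a slow random walk (innovation s.d. 0.25)
to two variables at $\tau = 5$.  These sizes make each experiment a
few-minute computation on a single core while leaving the conclusions
unchanged at larger sizes.  Window stride defaults to 1 (maximally
overlapping windows maximize the sample count; overlap induces sample
dependence, which the penalty's conservatism absorbs in practice — a
configurable trade-off).  Ties in greedy choices are broken
lexicographically by node identifier; given a dataset and configuration
the whole fit is deterministic.

## Known limitations

* Missing values are rejected, not imputed.
* Contemporaneous cycles cannot be represented; dense contemporaneous
  structure is only oriented as far as v-structures and the first
  propagation rule allow.
* The latent-cause mechanism is the single backward-arrowhead rule; full
  latent-variable orientation calculi are out of scope.
* The residual conditional test assumes approximately additive
  conditioning for continuous triples; strongly interactive conditioning
  is only absorbed at coarse-cell resolution.
* The event flags (division, apoptosis) are annotations, not detections.
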