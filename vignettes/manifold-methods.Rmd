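---
title: "Manifold analysis of population activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manifold analysis of population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popmanifold)
```

## The analysis in one paragraph

`popmanifold` treats the z-scored, 0.5-s-binned activity of a population of
simultaneously imaged neurons as a cloud of points in neuron space — the
*activity manifold* — and characterizes that cloud without reference to
behavior: its intrinsic dimensionality, its nonlinear low-dimensional
coordinates, its topological shape, and a partition of time bins into a
dense *central point cloud* plus peripheral *manifold clusters*. Behavior
enters only afterwards: cluster labels are related to task variables by
mutual information, trials become 20-bin cluster-label sequences, and those
sequences support cosine-similarity decoding of trial outcome across
recording sessions after the cluster labels of the two sessions have been
aligned through their transition-probability matrices. Because the kind of
two-photon data this pipeline was designed for cannot be redistributed, the
package ships a synthetic-session generator with full latent ground truth;
every stage is validated against that ground truth or against closed-form
oracles.

## Preprocessing

Raw sessions are neuron-by-frame \(\Delta F/F\) traces at 31 Hz. Neurons
whose maximum \(\Delta F/F\) exceeds a microscope-specific threshold
(2000% or 5000%) are discarded as extraction artifacts; the statistic is
the session maximum of the raw trace, and exclusion happens before
binning. Traces are then averaged over every 15 consecutive frames
(~0.48 s per bin; we track the exact duration `frames_per_bin / frame_hz`
rather than the nominal 0.5 s so event-to-bin assignment cannot drift over
a long session — events map to bins through frame counts). Each neuron is
z-scored with the population-SD convention (divisor \(n\)); per-run
z-scoring is available for sessions with breaks or z-plane shifts between
runs, and the default is whole-session.

## Intrinsic dimensionality

For each time bin (a point in neuron space) we take the distances to its
nearest and second-nearest neighbors and form \(\mu = r_2 / r_1 \ge 1\).
On a locally uniform d-dimensional manifold \(\mu\) is Pareto with shape
d, so \(-\log(1 - F(\mu))\) is linear in \(\log \mu\) with slope d; we fit
through the origin with \(F\) the empirical percentile \(r/(n+1)\), after
discarding the top 4% of ratios (boundary and noise effects live in that
tail). We note that this statistic is sometimes written with the inverted
ratio \(r_1/r_2\); the two conventions differ only by a sign that the
estimator absorbs, and we use the orientation that makes the regression
slope positive. Ties in neighbor distances are broken by point index and
duplicate points are an error — a zero nearest-neighbor distance makes the
ratio undefined.

Because the estimate is invariant to the embedding dimension but not to
additive noise, the estimate is also computed after spectral reductions to
a descending list of dimensions (20, 10, 6 by default); the reported value
is taken at the *plateau*, defined as the first stage whose estimate lies
within 1 of the preceding stage (the rule itself is a package decision —
only the existence of a plateau is assumed). A neuron-subsampling control
re-estimates the dimension on random neuron subsets of a common size so
that comparisons across sessions with different neuron counts are not
confounded by count.

## Two-round spectral embedding

The manifold coordinates come from Laplacian eigenmaps on the *mutual*
kNN graph: bins i and j are connected iff each is within the K nearest
neighbors of the other. With `L = D - W`, the generalized eigenproblem
`L f = lambda D f` is solved (equivalently, eigenvectors of the
symmetrically normalized adjacency), the constant leading eigenvector is
dropped, and the next m eigenvectors, D-orthonormal and in ascending
eigenvalue order, are the coordinates. Two rounds are applied: neurons ->
20 dimensions with `K = round(0.075 T)`, then 20 -> 6 dimensions with
`K = round(0.025 T)`; 6 is the typical intrinsic-dimension estimate for
this kind of data. Numerical choices: K is floored at 2; for T up to 1500
a dense symmetric eigensolver is used and above that ARPACK with a fixed
deterministic start vector, so the embedding is reproducible; each
coordinate's sign is fixed by making its largest-magnitude entry positive
(all downstream consumers are sign-agnostic regardless). If the mutual-kNN
graph is disconnected — rare at these K fractions — connectivity is
restored by adding the minimum-spanning-tree edges of the Euclidean
distance matrix that join components; the repair count is recorded in the
embedding's graph summary.

## Topology

Shape is summarized by persistent homology of Vietoris–Rips filtrations in
degrees 0 (components) and 1 (holes). Exact persistence on thousands of
bins is not needed: the embedding is condensed to the 80 centroids of a
K-means clustering, repeated 20 times because K-means is stochastic. The
persistence computation itself is implemented in compiled code (union-find
for degree 0, whose death radii provably equal single-linkage merge
heights — a property the test suite checks against `hclust`; boundary-matrix
reduction over GF(2) for degree 1). Every finite feature contributes its
lifespan (death − birth); the one never-dying component is excluded since
it exists for every point set. Two datasets are compared by the order-1
Wasserstein distance between their pooled lifespan samples — lifespans are
treated as plain 1-D distributions, not as persistence diagrams — averaged
over all 20 × 20 pairings of their clustering repetitions. Significance
uses a permutation test that pools and re-splits the two lifespan samples
of each repetition 200 times; the p-value is the fraction of permuted
distances *below* the observed one, averaged over repetitions. Note the
direction: a small p means the two datasets are unusually *similar*; the
package implements and documents this direction rather than inverting it.

## Clustering the manifold

The partition model is one dense central cloud plus K* peripheral
clusters. Bins are sorted by distance to the embedding centroid (ties by
bin index); the first n candidates form the central cloud. On a grid of
central-cloud sizes (a geometric progression from 40 to T/2 in 12 steps —
the progression's exact rule is a package decision) crossed with K from 2
to 20, each cell gets the mean over 20 seeded K-means repetitions of the
mean squared point-to-centroid distance on the non-excluded bins. Both
grid axes and the MSE are min–max scaled to [0, 1] and the optimum is the
valid cell closest to the origin of that 3-D system: prefer few excluded
bins, few clusters, low error. Cells that cannot form K distinct clusters
are invalid; if all points coincide the error is zero everywhere and the
smallest cell wins by the deterministic tie rule (row-major order).

Final labels must be deterministic although K-means is not: 500 seeded
K-means runs at K* are reduced to a co-association matrix (the fraction of
runs in which two bins share a cluster — a quantity invariant to each
run's arbitrary label numbering), and the bins are hierarchically
clustered on 1 − co-association with Ward linkage, cut at K* groups.
"Ward" and "complete" are both plausible readings of the linkage
tradition in this analysis family; Ward on the co-association is the
default and complete linkage is kept as an option. Central bins receive
the sentinel label −1; clusters are numbered 1..K* by first appearance in
time.

## Behavior: labels, mutual information, trials

Each of the six go/no-go outcome classes (reward hit/miss, aversive and
neutral false alarm/correct rejection) yields a binary per-bin label: 1 in
the window 3–6 s after the cue onsets of that class — after the visual cue,
during the outcome period — and 0 elsewhere. Pupil size and cumulative
consumed rewards are continuous; they are reduced to eight equal-count
levels by ranks (rank-based bins keep all eight levels populated even for
discrete covariates such as reward counts; a constant covariate is an
error), and their valid mask is restricted to the final 3 s of inter-trial
intervals following correct rejections, where ongoing activity is
unperturbed by task events. Mutual information between the cluster-label
vector (sentinel included as a level) and a behavior vector is the plug-in
estimate in nats from the joint contingency table. Its null distribution
is built by circular shifts of the behavior labels along the valid bins —
shifts preserve the autocorrelation that a naive permutation would
destroy — and p is the fraction of null MI values at or above the observed
(the shuffle scheme is a package decision; the log base only affects
units).

Trials become rows of an M × 20 matrix holding the cluster-label sequence
of the 20 bins from cue onset; trials whose window overruns the session
are dropped. Trial similarity is the cosine between two label sequences
treated as numeric vectors (the sentinel's −1 makes central-cloud
agreement count positively); the pooled lower triangle of the M × M matrix
is the dataset's similarity distribution.

## Cross-session decoding

Cluster indices are arbitrary per session, so decoding across sessions
needs an alignment. Each session's transition-probability matrix over its
8 labels (sentinel + 7 clusters; self-transitions included by default —
dwell is part of a cluster's signature, and an excluded-diagonal mode is a
flag) is hierarchically clustered by Ward on the row profiles, and the two
leaf orders define the label translation: k-th label here maps to k-th
label there. One subtlety is that a dendrogram's leaf order is only
defined up to branch flips, and the flips `hclust` picks follow original
label indices — exactly what a translation must not depend on. The package
therefore canonicalizes the dendrogram by reordering with each label's
dwell probability, aggregating subtrees by their *minimum* leaf dwell.
The minimum (rather than mean) makes each comparison depend on the
best-separated label in a subtree, which keeps the order stable under
sampling noise; with the mean, a high-dwell sentinel inside one subtree
can tie the comparison. Any data-derived key is permutation-equivariant,
so the order is comparable across sessions.

A trial of the test session is assigned the class whose training trials
(after translation) have the greatest summed cosine similarity to it. The
null shuffles trial classes in both sessions 200 times; p is the fraction
of null accuracies at or above the observed (the ≥ convention is the
conservative reading). Two baseline decoders replace the label sequence
by scalar per-bin features — mean population activity, or the projection
onto the thirsty–quenched axis \( \bar x_T - \bar x_Q \), scaled so the
anchor patterns map to exactly 1 and 0 — and decode with the same rule;
they test whether outcome information lives in cluster identity rather
than overall amplitude.

## Lick analysis

Anticipatory-lick onset: the bout threshold is
\(1/(\mu + C\,\sigma)\) seconds, where \(\mu,\sigma\) summarize per-trial
lick rates over the first 0.5 s of cue presentation across trials and C is
0.1 (water) or 0.35 (food). The onset is the first lick of the first pair
of licks closer together than the threshold whose leading lick falls in
the response window (0.5–4 s post cue by default); no such pair means no
onset, which is a valid outcome. Cluster-sequence onset: among the two
clusters with highest occupancy in the response window (2–4 s post cue,
configurable — the window extent is a package decision), the one whose
per-trial first sentinel-to-cluster transition times correlate best with
the lick onsets is chosen; onsets are reported at bin centers so the 0.5-s
quantization is unbiased. Lick-pattern similarity smooths the binary
31-Hz lick vector with a forward 100-frame mean (truncated at the trial
end) and returns \(1/(\varepsilon + \lVert SL_i - SL_j\rVert_2)\) with
\(\varepsilon = 10^{-6}\) — the printed reciprocal is infinite for
identical patterns, so the cap is needed. Free-consumption pseudo-trials
start at the second lick of any pair separated by more than 1 s (0.5 s
fallback when fewer than 5 result), span 2 s before to 4 s after,
drop overlapping windows greedily in time order, and can be filtered to
task-matched lick rates (within mean ± SD of the task trials' first-2-s
rates).

## The synthetic-session generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth. Its defaults are one imaging day: 200 neurons at
31 Hz, 35 trials of each of the six outcome classes (30 bins per trial
including a 10-bin inter-trial interval), and a 600-bin free-consumption
epoch — about 6,900 bins. The latent process is a Markov chain over one
central state and seven peripheral states whose dwell probabilities lie on
a wide gradient (0.24–0.78) with occupancy-balancing excursion weights:
distinct dwell levels are what give each cluster an identifiable
transition profile, and the wide gaps keep the profile geometry stable
under sampling noise, which the cross-session translation relies on. On
rewarded trials the latent state is scripted: central until the
cluster-sequence onset (anticipatory-lick onset plus a lag drawn from
N(1.0 s, 0.15 s)), then a back-and-forth semi-Markov traversal of the
two reward-sequence clusters (dwell 1–4 bins) for ~5 s. Licking is
rhythmic, not Poisson — regular inter-lick intervals with small jitter
(~4 Hz early cue, ~1.5 Hz pre-onset, 8 Hz bursts) — because the bout
threshold formula separates rates, and Poisson trains would produce
spurious short intervals at any rate. Satiety drift is the normalized
cumulative reward count; it damps excursions from the central state,
scales a slow additive component of the traces, and drives the pupil
covariate, which also carries a fast arousal transient during excursions
(this fast component is what gives the mutual-information shuffle test its
power; a purely slow coupling survives circular shifts). Emission adds a
per-state mean pattern (a dedicated neuron block at 2.5 z plus dense
N(0, 0.3) loadings), a slow 3-factor wander of ongoing activity during the
central state (making the central cloud diffuse, as in real recordings),
and white noise of 0.6 z per bin.

What the generator does *not* emulate: calcium-indicator dynamics (no
rise/decay kernels, no spike inference), nonstationary cell registration,
correlated (shared-noise) variability beyond the latent states, video or
pupil extraction artifacts, and the licking microstructure of real mice.
Tests passing on this generator therefore certify the *analysis code* —
that each estimator recovers planted structure under the model the
analysis assumes — not that the biological claims would replicate on new
imaging data.

Geometric fixtures complement the sessions: uniform d-cubes for the
dimension estimator, noisy or exact rings for embedding and degree-1
persistence, and a blobs-and-cloud fixture (seven tight Gaussian blobs at
the vertices of a regular simplex — arms pointing in distinct directions
of a 6-D space — around a diffuse central Gaussian, 10% of points) for the
clustering optimizer.

## Problem sizes used by the tests and the acceptance script

The test suite runs on small sessions (4–20 trials per class, 10–40
neurons) for unit checks, 800-point geometric fixtures for clustering
recovery, ~20,000-bin label sequences for translation recovery, and one
default-size session (200 neurons, ~6,900 bins) through the complete
pipeline. The acceptance script repeats the default-size pipeline run and
reports its headline quantities; its denoised dimension estimate runs on
a 5-fold temporal decimation of the session, which preserves the point
cloud's geometry while keeping the eigenproblem in the dense solver's
range. On one CPU the full pipeline takes about 5 minutes, dominated by
the grid optimization (4,560 K-means fits) and the consensus stage.

## Known limitations

* The grid optimum balances scaled axes against scaled MSE; when cluster
  separations are modest relative to total variance the K axis can absorb
  one cluster (K* one below the planted count, merging the two closest
  states). This is a property of the selection rule, visible on the
  synthetic sessions, and is why cluster-recovery guarantees are stated on
  the well-separated fixture.
* Leaf-order label translation assumes the two sessions share a cluster
  count and reasonably distinct transition profiles; the package refuses
  sessions with differing label counts rather than guessing.
* The topology permutation test's p-value measures similarity, not
  difference; users wanting a difference test must interpret 1 − p with
  care, which is why the package reports the direction explicitly.
* Exact Rips reduction is cubic in landmark count; the implementation
  guards at 400 points. With the default 80 landmarks it is fast.
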