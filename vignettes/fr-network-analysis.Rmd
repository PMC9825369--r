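---
title: "Fast ripple network measures of residual epileptogenic tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast ripple network measures of residual epileptogenic tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frnet)
```

## The analysis model

`frnet` starts where an HFO detector stops: per-contact catalogs of fast
ripple (FR) events — onset time, class (fRonO/fRonS/RonO/RonS), spectral
frequency — together with contact coordinates (mm), a clinical seizure
onset zone (SOZ) mask, a resection mask, the analyzed recording duration
and the Engel outcome class. Everything downstream is deterministic given
those inputs.

### Event selection

The default rule keeps fRonO with spectral frequency **strictly above
350 Hz** together with **all** fRonS (fast ripples on spikes are not
frequency-filtered); ripples are never analyzed. An `all_fr` rule keeps
every fast ripple. A third mode, FR superimposed on ripples, would need a
per-event co-occurrence annotation that plain catalogs do not carry and
therefore raises an informative error rather than guessing.

### Spatial networks

Distance-type networks treat edge weights directly as path lengths. The
rate–distance network is the complete graph on FR-generating contacts
(at least one selected event) with weight
$w_{ij} = \frac{r_i + r_j}{2}\, d_{ij}$ (events/min × mm). The *radius*
is the minimum node eccentricity under all-pairs shortest paths. The
outcome measure is

$$\Delta = \mathrm{radius}(\text{all FR nodes}) -
           \mathrm{radius}(\text{resected FR nodes only}),$$

with the convention that a network of fewer than two nodes has radius 0,
so the measure stays defined for extreme resections. Contacts excluded by
a mask are represented as absent nodes (the equivalent of infinite
adjacency entries). Note that $\Delta$ is **not** guaranteed nonnegative:
the radius is a minimum over eccentricities, and contacts with very low
FR rates create low-weight edges that can give the whole network a
smaller radius than its resected subnetwork. On synthetic cohorts a
substantial fraction of patients have $\Delta < 0$; the measure still
orders patients by residual burden, which is what the diagnostics use.

### Mutual information between event trains

Dependence between the FR trains of two contacts is estimated from
paired inter-event intervals (ISIs):

1. events of the sparser train are matched to their nearest-in-time
   events on the other train, greedily by time difference, each event
   used at most once;
2. each matched pair contributes the *preceding* ISI on both sides (the
   first event of a train has none and is dropped), giving a joint
   ISI–ISI sample;
3. the sample is mapped to ranks — MI is invariant under monotone
   transforms, and ranks make the marginals uniform so conditional-median
   splits are well behaved under heavy-tailed ISI distributions;
4. recursive adaptive partitioning: a cell splits 2×2 at its conditional
   medians whenever a chi-square test rejects equidistribution of its
   points over the four quadrants at $\alpha = 0.05$; cells with fewer
   than $4 \times 5$ points are never split (at least 5 expected samples
   per candidate subcell);
5. $\widehat{MI} = \sum_c p_c \log_2 \frac{p_c}{p^x_c\, p^y_c}$ over
   terminal cells, clipped at 0 and symmetrized over the two argument
   orders. Trains with fewer than 3 events get MI 0 by contract.

The estimator is conservative by construction: with fewer than about 20
paired samples no split can occur and the estimate is exactly 0. This is
the main driver of "no MI network" patients at short recording
durations, mirroring the indeterminate patients real cohorts contain.

### MI network metrics

Edges with MI 0 are absent; path lengths are $1/MI$. The package reports,
per patient: the characteristic path length (CPL, mean finite shortest
path; pairs with no connecting path are excluded — a documented choice,
since including them would make the mean infinite), the **CPL resected
ratio** (CPL of the subgraph induced on resected nodes over whole-network
CPL, paths confined to the subgraph), Onnela's geometric-mean weighted
clustering coefficient and weighted local efficiency (both after
normalizing weights by the within-graph maximum), stratified into
resected and unresected node sets, plus zero-efficiency percentages, an
unweighted control (all MI > 0 edges set to 1), and k-means clusters
(k = 3, z-scored features, 50 restarts, fixed seed) of (rate, local
efficiency) pooled across patients. Patients whose MI network is empty
(`no_network`) or entirely inside the resection (`fully_resected`) carry
an explicit indeterminate reason; the ratio is flagged rather than
silently NaN, and the diagnostic layer imputes them by a configurable
rule (`as_misclassified` by default — the conservative choice;
`as_test_negative` and `exclude` are available because the precise
clinical convention varies).

### Propagation

For every unordered pair of fRonO-generating contacts, all cross-pair
onset delays with magnitude below 250 ms (full cross product, not
one-to-one matching) feed a two-sided exact binomial sign test (zeros
discarded). An edge is reported at $p < 0.005$ with the leading contact
as its out-node; no multiple-comparison correction is applied — the fixed
threshold *is* the test, and the package mirrors that convention. Single
edges are rare by design of the test, so cohort summaries report the
coverage of leading contacts as undefined for edge-free patients.

### Diagnostics

Spearman correlation merges Engel 2 and 3 into one ordinal level
(1 < 2/3 < 4). ROC curves sweep every observed threshold after orienting
each measure by its declared polarity (larger resection ratio, smaller
rate-distance difference, larger MI metric predict the positive class);
the trapezoidal AUC is then identical to the Mann–Whitney concordance
statistic, which the tests exploit as an oracle. The operating point
maximizes Youden's J, ties broken toward higher specificity (the clinical
framing penalizes falsely promising seizure freedom). Confusion-matrix
metrics carry exact Clopper–Pearson 95% CIs, chosen over asymptotic
intervals because cohorts of this kind are small. Reflex testing
re-classifies only primary-test positives with a second measure at its
own Youden threshold; primary negatives are never touched.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` creates
catalogs with the statistical structure the analysis assumes.

* **Geometry.** 8–16 linear depth electrodes of 7–15 contacts at 5 mm
  pitch, random insertion points and orientations in a 140 mm cube —
  counts follow typical SEEG implants; the pitch is a standard electrode
  spec.
* **Primary pathological zone.** The `n_hot` contacts nearest a random
  focus (12 of 15 by default). Each re-emits a homogeneous Poisson
  "mother" process (default 8 events/min) thinned by a participation
  probability that decays from `coupling_rho` (0.8) at the focus to half
  that at the zone edge, plus ~10% independent background, with Gaussian
  timing jitter (truncated at 3 SD) growing from 15 ms at the core to
  60 ms at the edge. Rates therefore *arise from* the coupling: the
  strongest FR generators are also the most synchronized, which is what
  makes rate-targeted resections informative for the MI network. Mother
  events carry one class/frequency draw shared by every contact that
  re-emits them, since a synchronized FR event has coherent spectral
  content across sites.
* **Secondary focus.** A distant set (3 contacts by default) of
  *desynchronized* generators: comparable rates (0.4–0.6 of the mother
  rate), no shared events. They are the spatial-undersampling story — the
  residual tissue a compact resection misses — and they populate the
  high-rate/zero-local-efficiency corner of the rate–efficiency plane.
* **Periphery.** Five moderate-rate contacts just outside the primary
  zone share the mother process (rate factor 0.45); they give the MI
  network an unresected fringe so that resections of the core leave a
  measurable residual network.
* **Resection.** A per-patient coverage fraction (uniform on 0.3–0.95 by
  default) removes the focus-nearest (strongest) primary contacts
  proportionally and each secondary contact once coverage clears a
  per-contact threshold (uniform on 0.55–0.95); each resected contact
  drags in its nearest neighbor. More extensive surgeries therefore
  progressively reach the distant generators.
* **Outcome.** `outcome_rule = "coupled"` ranks patients by residual
  (unresected) hot-contact rate mass and assigns Engel classes by rank
  quartile; `"random"` assigns classes uniformly. The coupled rule gives
  a monotone ground truth for parameter-recovery tests without asserting
  any clinical dose–response model.
* **Determinism.** All randomness flows from one mandatory seed through
  R's Mersenne–Twister generator (recorded in every run-config echo);
  identical parameters give byte-identical cohorts.

### What the generator does and does not emulate

It reproduces the *structure* the measures rely on: heterogeneous rates
with a coupled high-rate minority, jittered shared-event dependence,
spatially compact resections of varying extent, outcome tied to residual
burden, and indeterminate patients at short durations. It does not
emulate waveform-level properties (no raw iEEG), non-stationary rates
across sleep stages, anatomically constrained electrode trajectories, or
artifact review. Two visible divergences from clinical catalogs: the
dominant-generator criterion (a contact above mean + 3 SD of normalized
rates) essentially never fires because synthetic hot-zone rates are too
homogeneous, so every synthetic patient is flagged as potentially
undersampled; and background FR outside the pathological zones is rarer
than in real recordings. Passing tests therefore demonstrate the
pipeline's internal correctness and its ability to recover a planted
effect — not clinical performance on real SEEG data.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (`quantile(type = 5)`), the convention of common clinical-EEG tooling.
* The spatial-undersampling criterion is computed on rates normalized by
  their within-patient maximum; the criterion is scale-invariant, so the
  raw-rate variant gives the same answer (both are exposed).
* Shortest paths use a dense vectorized Floyd–Warshall relaxation for
  graphs of at most 30 nodes and igraph's Dijkstra above that; the two
  agree to machine precision and the tests pin both against a
  triple-loop oracle.
* Radius of a sub-two-node network is 0; CPL of such a network, or of one
  with no finite pair, is indeterminate (`NA` with a reason), never a
  silent 0. Empty catalogs give `NA` resection ratios (0/0 is undefined,
  not zero). The exact sign test with no nonzero delay reports
  an insufficient-data marker.
* Youden ties break toward the higher threshold (fewer positives, higher
  specificity). AUC uses the trapezoidal rule over all empirical
  thresholds, making ties count 1/2.

## Problem sizes used by the test-suite and acceptance script

Property checks run on 200 random graphs of up to 8 nodes against
brute-force oracles; MI calibration uses 100 independent and 100 paired
coupled/uncoupled train pairs of roughly 200 events; parameter recovery
uses 20 cohorts of 40 patients under the coupled outcome rule (and 10
under the random rule); reflex testing uses 50 cohorts of 30 patients;
the acceptance script reruns one 40-patient cohort end to end plus the
calibration blocks. These sizes give stable medians for the stochastic
checks while keeping a full run in the minutes range on one core.

## Known limitations

* The MI estimator's detection floor (~20 paired samples) makes
  short-duration patients network-free; with 10-minute recordings weak
  coupling is invisible. This is a property of any partition-based MI
  estimate at small n, not a removable bug.
* The rate–distance radius difference can be negative (see above); users
  comparing against analyses that report root-transformed differences
  should square-root only after checking sign conventions.
* Propagation detection on cross-product delays treats dependent pairs
  as exchangeable; the sign test is exact under independence and
  anticonservative when one event participates in many pairs. The fixed
  p < 0.005 threshold with no correction mirrors common practice and is
  kept deliberately.
* Outcome classes in the coupled rule are exact rank quartiles; real
  cohorts have unbalanced Engel distributions, which mainly widens CIs.

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(sim_params(n_patients = 20, seed = 7))
res <- run_pipeline(cohort, run_config(seed = 7), out_dir = tempdir())
res$spearman
res$diagnostics[, c("measure", "outcome", "auc", "sensitivity",
                    "specificity")]
```
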