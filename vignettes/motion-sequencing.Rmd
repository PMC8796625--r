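---
title: "Ensemble motion sequencing and fast-ripple detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble motion sequencing and fast-ripple detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moseqr)
```

## The problem

Mouse models of movement disorders often show behavioral changes too subtle
for standard assays: an animal that sits a little less and walks a little
more can look normal in an open field summary. Motion sequencing addresses
this by decomposing unchallenged behavior into *syllables* — short,
stereotyped movement motifs (a sitting posture, a forward move, a rear) —
and comparing how often, how long, and in what order genotypes use them.
`moseqr` implements this pipeline for pose-feature time series (depth-video
descriptors or their principal-component scores, 30 frames/s over 20-minute
sessions), together with a companion detector for fast ripples
(200–550 Hz high-frequency oscillations) in epicranial EEG, used to check
mutants for epileptiform activity.

Because depth-video recordings of this kind are rarely deposited, the
package ships first-class synthetic-data generators with known ground
truth; every stage of the pipeline is validated by recovering what the
generator planted.

## The ARHMM

Pose dynamics are modeled by a K-state autoregressive hidden Markov model.
A hidden Markov chain \(s_t \in \{1,\dots,K\}\) with transition matrix
\(\Pi\) selects, at each frame, a linear dynamical law for the
P-dimensional score vector \(y_t\):

\[
y_t \mid s_t = k \;\sim\; N\!\left(\textstyle\sum_{l=1}^{L} A_k^{(l)} y_{t-l} + b_k,\; Q_k\right).
\]

Syllables are recurring states of these switching dynamics: each state has
its own fixed point and rotational flow, so both posture and movement
style distinguish states. The study-scale defaults are \(P = 15\)
principal components, \(K = 15\) states, and \(L = 1\) (first-order
dynamics, the minimal switching-linear-dynamics model; the lag is
configurable).

Fitting is by expectation–maximization (Baum–Welch with AR-Gaussian
emissions), deterministic given a seed. Design choices that matter:

* **Initialization.** k-means on lag-stacked scores \([y_t, y_{t-1}]\),
  with 10 restarts (on at most 20,000 subsampled frames; remaining frames
  join their nearest center). Single-start k-means tends to merge the two
  closest states, a basin EM cannot always escape; the multi-start
  initialization removes essentially all such failures while staying
  seed-deterministic.
* **Acquisition gaps.** Sessions are recorded in roughly 20-second blocks
  separated by 1–2 s storage interruptions. The likelihood factorizes over
  contiguous valid blocks: no transition is counted across a gap, and each
  block restarts from the initial state distribution.
* **Warm-up frames.** The first \(L\) frames of a block have no AR
  context. Their emission factor is a state-independent constant, which
  keeps EM exact (the factor cancels from every responsibility); those
  frames are still labeled by the decoder through the transition structure.
* **Stopping.** Iteration stops when the mean per-frame log-likelihood
  improvement falls below `tol` (default \(10^{-4}\) nats) or at
  `max_iter = 200` — the "equilibrium" at which further iterations no
  longer change the fit. The total log-likelihood is non-decreasing, and a
  tiny ridge (\(10^{-10}\)) and covariance floor (\(10^{-9}\)) guard the
  M-step against degenerate numerics without disturbing monotonicity on
  well-conditioned data.
* **Degenerate states.** A state that loses essentially all its frames
  triggers a re-seeded restart (at most 3, each logged as a warning).
* **Decoding.** Viterbi per valid block, ties broken toward the lowest
  state index for determinism. Blocks shorter than \(L + 1\) frames carry
  no dynamics evidence; they are labeled by the most probable initial
  state and flagged.

## Ensemble consensus syllables

On realistic data sizes the per-frame state assignment is partially
stochastic: independent EM runs converge to equally good fits that
nevertheless disagree on some frames. Rather than trusting one arbitrary
run, the pipeline fits the model \(R = 8\) times independently (seeds
`master_seed + 0 … R-1`) and gives every frame its *signature* — the
ordered 8-tuple of state labels it received across fits. Unique signatures
are clustered and the clusters become the consensus syllables.

* **Distance.** Normalized Hamming distance between signatures (fraction
  of fits that disagree), weighting each fit equally. Frames on which all
  fits agree up to a relabeling land in the same cluster automatically.
* **Linkage.** WPGMA (weighted pair-group method with arithmetic mean;
  `hclust` method `"mcquitty"`): the distance from a merged cluster to an
  outsider is the unweighted mean of its children's distances, so rare
  signatures are not swamped by common ones. A count-weighted variant
  (average linkage over frame-replicated points) is available.
* **Cut.** The tree is cut to a fixed number of syllables (study default
  44), and syllables are re-indexed by descending frame count so syllable
  1 is always the most used. A fixed-count cut replaces curatorial tree
  splitting for reproducibility; the dendrogram (Newick + merge-height
  table) is exported for review.
* **Deduplicated catalog.** Unique signatures enter the tree unweighted by
  default, mirroring clustering of a deduplicated catalog; signatures
  rarer than `min_count` can be held out and attached by nearest neighbor,
  bounding the distance matrix.

The consensus step is validated by two properties on synthetic cohorts:
recovered syllables must match the generator's states (adjusted Rand
index ≥ 0.8), and the consensus must never fall more than 0.02 ARI below
the best single fit — the ensemble may only help.

## Syllable statistics and comparison

For every animal and syllable, three measures are computed from bouts
(maximal uninterrupted runs of one syllable; runs never bridge a gap):

* **frequency** — bouts initiated per minute of valid recording
  (min\(^{-1}\)); "per minute of mouse activity" is interpreted as per
  minute of valid recorded frames, as no immobility-exclusion rule is
  defined;
* **mean length** — mean bout duration (s);
* **proportion** — percentage of valid recording time in the syllable.

On gap-free data the three are algebraically locked:
frequency × mean length = 0.6 × proportion, and proportions sum to 100 per
animal — both used as exact self-checks.

Genotypes are compared per syllable and metric with a Kruskal–Wallis
omnibus test followed by Dunn's pairwise z-tests on tie-corrected ranks.
Flags default to unadjusted per-syllable p < 0.05 (gated on the omnibus);
Benjamini–Hochberg adjustment across syllables is available via
`p_adjust = "BH"`. Animals lacking a syllable have no mean length and are
dropped from that test only. The procedure is calibrated on null cohorts
(type-I rate within [0.02, 0.09] at α = 0.05) and powered against a
planted halved-occupancy syllable (flagged in ≥ 80% of replicates with 6
vs 6 animals and 2-minute sessions).

Transition networks count ordered pairs of consecutive *distinct*
syllables, pooled per genotype (per-animal graphs remain available through
subsetting); self-edges are structurally impossible and transitions never
bridge gaps. Edge weights are percentages of all transitions and sum to
100 before thresholding; edges below 0.01% are excluded from the exported
graph but kept in the full matrix.

## Synthetic cohorts: what they emulate, and what not

`simulate_arhmm_session` draws the state chain continuously over the whole
session (gaps affect only the observation mask — storage interruptions do
not freeze the animal) and emits features by the state-conditional AR
recursion, starting from the initial state's stationary observation
distribution. `make_cohort` supports the study's group sizes (6 wild-type,
10 heterozygous, 5 homozygous) and implements genotype effects by scaling
the transition-matrix columns of target states and re-normalizing rows —
the simplest mechanism that shifts occupancy in a controlled direction.
Because column scaling acts on bout structure as well as occupancy,
`occupancy_multiplier` solves for the multiplier that achieves an exact
target occupancy ratio (e.g. a genotype that halves time spent sitting).

Default generator conditions follow the study design: 20-minute sessions
at 30 fps acquired in ~20 s blocks with 1–2 s gaps; `random_arhmm` draws
states with distinct fixed points (separation 10 innovation-SDs) and
rotational dynamics, and a sticky chain (stay probability 0.94–0.95, mean
bout ≈ 0.3–0.7 s, the duration scale of behavioral syllables). Test and
validation studies use reduced sizes chosen once: 5 states in 5
dimensions, 6 animals × 10 minutes for recovery; 6 vs 6 animals × 2
minutes for the statistical calibration and power studies; the package's
own validation reports come from exactly these conditions.

The generator does **not** emulate: real pose-descriptor statistics
(non-Gaussian innovations, heteroscedastic tracking noise), preprocessing
artifacts behind the validity mask, session-to-session nonstationarity, or
individual-animal heterogeneity beyond the Markov sampling. Passing
recovery tests therefore demonstrates correctness of the inference and
consensus machinery under the model's own assumptions, not performance on
real depth-video data.

## Synthetic EEG and the fast-ripple detector

`simulate_eeg` builds background as Gaussian noise with a 1/f amplitude
spectrum up to a 150 Hz corner and a flat instrument-noise floor above it,
low-passed at the 2 kHz anti-alias corner of a 4 kHz acquisition chain —
so the 200–550 Hz detection band sees broadband noise, as a real recording
chain's floor does. Injected events are sinusoidal bursts of `n_cycles`
shaped by a tapered-cosine (Tukey, α = 0.5) window and calibrated so the
peak of the band-pass-filtered burst equals `amplitude_ratio` × the SD of
the band-pass-filtered background of that channel. The flat-topped window
is deliberate: it holds at least `min_oscillations` interior cycles at the
calibrated amplitude, so a "4 × baseline" burst is unambiguously above a
3 × threshold cycle-by-cycle, while a fully tapered (Hann) 6-cycle burst
calibrated by its peak would hold only ~2 cycles above that threshold and
would not constitute a well-posed detectable event.

Detection band-passes each channel with an order-2 Butterworth filter
(200–550 Hz), forward–backward by default (zero phase preserves event
timing; effective attenuation doubles — single-pass mode gives the literal
order-2, −3 dB-at-edges response). In the filtered trace:

* an **oscillation** is a full cycle between consecutive rising zero
  crossings, *band-legitimate* if its period lies in the band's period
  range (≈1.8–5 ms, 10% slack) — slow artifacts cannot be counted;
* a cycle's **amplitude** is half its peak-to-peak excursion;
* a candidate window of `min_oscillations = 4` consecutive legitimate
  cycles qualifies when its mean amplitude exceeds
  `amplitude_ratio = 3` × the SD of the surrounding 250 ms of signal
  (125 ms each side), **excluding the candidate samples** — including the
  candidate would let a large event raise its own threshold;
* qualifying windows merge into maximal events, and events separated by
  less than 10 ms merge (one physiological event should not fragment).

Thresholds are baseline-relative, so detection is exactly invariant under
trace rescaling. A fixed global baseline SD can be supplied instead of the
local estimate — the standard mode for deterministic threshold-margin
checks and for recordings with a known noise floor. Note that with
additive in-band noise, bursts just below threshold (e.g. 2.5 × SD against
a 3 × criterion, a 0.5 SD margin against ~1 SD per-oscillation noise) will
occasionally cross any local threshold; the sub-threshold margin checks
therefore run in fixed-baseline mode, where they are exact. Events are
reported with sample bounds, oscillation count, peak ratio and mean
intra-event frequency, supporting the exportable-snippet review that
replaces manual visual confirmation. Rates are summarized per channel as
events/min with group medians and linear-interpolation quartiles.

## Validation problem sizes

The shipped tests and the acceptance script re-derive every headline
property at these sizes, chosen once as the smallest cohorts at which the
statistical criteria are meaningful: recovery ARI on 6 × 10-min 5-state
cohorts (ensemble of 8); consensus margin across replicate cohorts; exact
metric identities on gap-free label cohorts; type-I calibration on 500
null cohorts and power on 100 halved-occupancy cohorts (6 vs 6 × 2 min);
Viterbi against exhaustive enumeration at \(K^T = 3^{10}\); WPGMA against
a hand-computed four-point linkage; Dunn p-values against a 10,000-draw
permutation reference; detector recall/precision on 20 × 60-s traces with
10 injected bursts each.

## Known limitations

* Gaussian AR emissions; no robust/heavy-tailed option yet.
* EM finds local optima; the ensemble and multi-start initialization
  mitigate but do not eliminate this (a Gibbs-sampling fit would be the
  natural extension).
* `K` is fixed by configuration (no model selection), matching the
  fixed-K study design.
* The consensus follows the majority of fits; it is designed to resolve
  assignment stochasticity among comparable fits, not to rescue a
  systematically misspecified model.
* Semantic syllable names ("Sitting", "Forward move") are human
  annotations and enter only as an optional label map.
* On-disk artifacts use plain-text formats (CSV/JSON/YAML/GraphML/Newick).
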