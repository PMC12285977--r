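---
title: "Hierarchical GMM-HMM classification of eye movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical GMM-HMM classification of eye movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazehmm)
```

## The problem

Gaze-based interfaces need to know, sample by sample, what the eye is doing:
holding still on a target (**fixation**), tracking a moving target at an
intermediate, sustained velocity (**smooth pursuit**), or jumping
ballistically between targets (**saccade**). Threshold rules (I-VT, I-DT and
relatives) answer this with fixed cutoffs, which transfer poorly across
subjects and tasks; the classifier implemented here instead learns a
probabilistic model of each recording and decodes the most likely behaviour
sequence from it. Downstream, the same labels drive a gaze-guided robot
workflow: sufficiently long fixation pauses become grasp waypoints, and the
geometry subpackage maps them from screen pixels into a robot arm's frame.

## The model

Each hidden behaviour state $i$ emits observations through a Gaussian
mixture,

$$P(x) = \sum_{k=1}^{K} c_k\, \mathcal{N}(x \mid \mu_k, \Sigma_k),
\qquad c_k \ge 0,\ \textstyle\sum_k c_k = 1,$$

and the state sequence follows a first-order hidden Markov model with
initial distribution $\pi$, transition matrix $A$ and per-state emission
mixtures $B$. Parameters are re-estimated by Baum–Welch
(expectation-maximisation over state paths, with per-component
responsibilities inside each state's mixture), and the behaviour sequence is
decoded with the Viterbi algorithm. All recursions run in log space, so
long sequences cannot underflow; Viterbi ties break deterministically toward
the lower state index.

Classification is **hierarchical**:

* **Step 0 — path segmentation.** A sum-of-squared-errors (SSE) curve from
  seeded-restart k-means on the spatial coordinates, for $k = 1..K_m$, is
  passed to an elbow rule: the selected $k$ maximises the perpendicular
  distance between $(k, \mathrm{SSE}_k)$ and the chord joining the curve's
  endpoints. Because fixations form dense spatial clusters, $k$ tracks the
  number of coarse gaze regions.
* **Step 1 — coarse round.** A $k$-state GMM-HMM on the $(x, y)$
  coordinates is fitted with Baum–Welch and decoded with Viterbi; maximal
  runs of the decoded path become contiguous segments. Runs shorter than
  `min_run_length` are merged into their longer temporal neighbour.
* **Step 2 — fine round.** Each segment's velocity trace is modelled with a
  3-state GMM-HMM and decoded; states are mapped to event labels by their
  learned mean velocity (see below).
* **Step 3 — fusion.** Per-segment labels are concatenated in temporal
  order into one labelled sequence.

## Velocity definition

The velocity trace is the backward finite difference of position,
$v_i = \lVert p_i - p_{i-1}\rVert / (t_i - t_{i-1})$ in px/s, with the
first value copied from the second. No smoothing is applied by default —
smoothing materially changes classification and is exposed as an opt-in
moving-average window (`smooth_window`). Units are pixels and seconds
throughout; conversion to degrees of visual angle would require screen
geometry that the package deliberately does not assume.

## How hidden states acquire labels

A 3-state velocity HMM fitted inside a single segment has no intrinsic
semantics, and labelling its states purely by *within-segment* velocity rank
fails structurally: the middle of three ranks always exists, so a segment
containing only fixation samples plus a saccade edge would always
manufacture a spurious pursuit state. The default mapping
(`state_mapping = "global"`) therefore estimates three *recording-level*
velocity regimes once per recording — seeded 3-means on the transformed
velocity trace, regimes sorted ascending and labelled fixation < pursuit <
saccade — and each segment state takes the label of the nearest regime to
its learned mean. This keeps the ascending-velocity ordering, stays free of
fixed thresholds (the regimes are re-estimated from every recording), and
lets any number of the three behaviours appear in a segment. The
within-segment rank mapping remains available via
`state_mapping = "rank"`.

Two data-driven guards handle recordings without three distinguishable
regimes. If the whole recording's velocity spread, or the spread across the
three regime medians, is below `degenerate_velocity_spread` (default 30
px/s), the recording is a single fixation-like behaviour and is labelled
accordingly. If only *two* regimes are distinguishable, the upper one is
called a saccade when its occupancy runs are ballistic-brief (median run
below roughly 150 ms) and pursuit otherwise — duration, not magnitude, is
what separates those two behaviours in the oculomotor literature.

## Numerical choices

* **Offset-log velocity feature.** Gaze speeds span four decades (tens of
  px/s during fixation to above $10^4$ px/s at saccade peak). Gaussian
  mixtures on the raw scale are dominated by the saccade spread, while a
  plain log transform magnifies meaningless differences among near-zero
  fixation speeds. The fine round therefore models
  $z = \log(v + s)$ with $s$ = `degenerate_velocity_spread`: differences
  below the indistinguishability scale $s$ are compressed, larger speeds
  are compared multiplicatively. The transform is monotone, so the velocity
  ordering used for labelling is unchanged. Raw-scale fitting is available
  with `log_velocity = FALSE`.
* **Covariance regularisation.** Every covariance diagonal is floored by
  $\varepsilon = 10^{-6}$; near-stationary fixation samples otherwise
  produce singular covariances.
* **Initialisation.** Emissions start from k-means on the feature space
  (seeded restarts, empty clusters re-seeded at the sample farthest from
  its centre); $A$ starts diagonal-dominant with 0.9 self-transition,
  reflecting the persistence of eye-movement behaviours; $\pi$ is uniform.
* **Convergence.** Baum–Welch stops when the mean per-observation
  log-likelihood improves by less than `tol` ($10^{-4}$) or after
  `n_iter_round1`/`n_iter_round2` (100) iterations. A state whose total
  responsibility collapses is re-initialised from a random observation,
  with a warning.
* **Determinism.** One user seed fans out to fixed sub-seeds for every
  stochastic stage (restart seeds are `seed + restart index`), so a run is
  exactly reproducible.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `K_m` | 10 | clusters | elbow scan range (clipped to sequence length) |
| `n_restarts` | 10 | — | seeded k-means restarts; single random inits are unstable |
| `n_iter_round1`, `n_iter_round2` | 100 | iterations | Baum–Welch caps per round |
| `gmm_k_round1`, `gmm_k_round2` | 2 | components | mixture order per HMM state (1–5) |
| `min_run_length` | 3 | samples | ~33 ms at 90 Hz; suppresses single-sample Viterbi flicker |
| `degenerate_velocity_spread` | 30 | px/s | velocity-indistinguishability scale for all degeneracy guards |
| `features_round1` / `features_round2` | `"xy"` / `"v"` | — | coarse round on coordinates, fine round on velocity; the joint `(x, y, v)` reading is selectable in both rounds |
| `smooth_window` | 0 | samples | opt-in velocity smoothing |

The split of features across rounds — coordinates first, velocity second —
is the default because spatial structure determines *where* behaviour
changes while velocity determines *what* the behaviour is; the
`"xyv"` overrides preserve the alternative single-feature-space reading.
Whether the coarse-round states correspond one-to-one to the elbow clusters
or merely to $k$ temporal regimes is left open by the method's description;
they are implemented as $k$ temporal regimes, which is the weaker and safer
reading. Baum–Welch is run as standard soft EM with one final Viterbi
decode; `viterbi_training = TRUE` selects the hard-EM alternative in which
decoding feeds re-estimation.

## The synthetic generator

Tests and the benchmark run on seeded synthetic recordings
(`simulate_gaze()`, `standard_benchmark()`) that emulate a 90 Hz tracker on
a 1920×1080 display:

* **Fixation** — anchor + linear drift at 10 px/s (random direction per
  episode) + smooth jitter with marginal SD 8 px. Jitter is white noise
  filtered by a Gaussian kernel with a 0.35 s correlation length: gaze
  traces from commercial trackers are dominated by slow fixational
  drift/wander (and the tracker's own filtering), not by white pixel noise,
  and white 8 px jitter at 90 Hz would produce finite-difference speeds of
  order $10^3$ px/s — physically wrong for fixation and indistinguishable
  from pursuit.
* **Pursuit** — linear target motion at 200 px/s plus the same jitter.
* **Saccade** — 400 px minimum-jerk jump completed in 44 ms, giving the
  smooth, strongly peaked velocity profile (peak $\approx 1.7\times10^4$
  px/s) that finite differencing of tracker output shows.

The worked-example scenario (`fig4_scenario()`) packs all three behaviours
into 4.5 s: fixation to 0.5 s, pursuit to 1.5 s, fixation to 2.5 s, a
saccade, fixation to 3.5 s, a second saccade, fixation to 4.5 s — 405
samples at 90 Hz. (An alternative reading of that timeline would put an
extra fixation before the pursuit; the reconstruction above keeps the total
duration, the pursuit window and both saccade onsets, which is the
constrained part.) A `drift_burst` flag adds elevated drift at 3.6 s inside
the final fixation.

What the generator does **not** emulate: blinks and tracker dropouts,
saccadic main-sequence scaling, binocular disparity, pupil-size artefacts,
or heavy-tailed measurement noise. Passing the synthetic benchmark
therefore demonstrates that the pipeline recovers the behavioural structure
it models — clean, well-separated velocity bands — not that it is robust to
every artefact of real recordings.

## Problem sizes used by the test-suite and benchmark

The shipped checks use sizes chosen to exercise every code path while
remaining quick on a laptop: exhaustive-enumeration checks of the forward
and Viterbi recursions on 200 random instances with $T \le 6$, $N \le 3$;
likelihood-monotonicity checks over 100 seeded Baum–Welch runs; transition
recovery from a single $T = 3000$ two-state sequence; and a benchmark of 50
worked-example-style sequences (20,250 samples) for the headline accuracy
and per-class F1 scores, which `scripts/acceptance.R` recomputes from
scratch.

## Baselines

I-VT, I-VDT and I-BDT are re-implemented as comparison baselines behind the
same `labeled_sequence` interface. Their published descriptions leave the
operating parameters open; the defaults here are 1000 px/s saccade
threshold, 40 px dispersion threshold, 110 ms duration window and a 1 s
rolling prior window, all recorded in every benchmark report. I-BDT follows
its cited description at contract level — rolling priors, velocity-based
likelihoods, a window-shift-over-time pursuit feature, arg-max posterior
with ties to fixation; the exact parametric forms are documented in the
function and visible in its configuration.

## Geometry subpackage

The gaze-to-robot chain is implemented as pure, hardware-free linear
algebra: pinhole projection (`world_to_pixel()`), polynomial gaze-to-pixel
calibration on the basis $(1, x, y, x^2, y^2, xy)$ (`fit_gaze_mapping()`),
depth-scaled ray back-projection (`pixel_to_camera()`), and the hand–eye
rigid transform (`camera_to_robot()`). Intrinsic and hand–eye *estimation*
are out of scope; the transforms are consumed as given matrices, and depth
comes from the caller (a missing or non-positive depth value is an error —
the known failure mode of depth-camera capture). Units are meters for all
3-D quantities; the source system's depth units are not stated anywhere, so
meters are assumed and documented here.

Trajectory smoothness is summarised per interior point by the discrete
curvature $\kappa_i = \lVert v_1 \times v_2 \rVert / \lVert v_1 \rVert^3$
(defined 0 when $\lVert v_1\rVert = 0$, and likewise when the trailing step
is degenerate) and an angular variation rate. The printed formula for the
latter is typographically ambiguous; the default reading is the squared
sine of the inter-tangent angle,
$(\lVert v_1 \times v_2\rVert / (\lVert v_1\rVert\,\lVert v_2\rVert))^2$,
with the alternative
$\lVert v_1 \times v_2\rVert / (\lVert v_1\rVert\,\lVert v_2\rVert^2)$
selectable via `variant = "normalized_cross"`. Two-dimensional waypoint
paths are lifted to 3-D with $Z = 0$ so the cross-product form applies
uniformly, and the mean curvature is compared against the 3 m$^{-1}$
smoothness threshold used for feasible robot trajectories
(`smooth_feasible`).

## Known limitations

* The recording-level regime estimate assumes the recording contains enough
  fixation to anchor the lowest velocity regime; a recording consisting of
  pursuit only would see its pursuit labelled as fixation.
* Per-sample labels are reported raw — no minimum-duration or merge
  post-filter is applied, matching the method's raw-output reporting (a
  slow drift inside a fixation can legitimately come out as pursuit).
* Blink/dropout handling, online (streaming) classification and
  degrees-of-visual-angle conversion are out of scope.

## A complete run

```{r example, eval = FALSE}
s <- simulate_gaze(fig4_scenario(), seed = 0)   # ground-truth labels included
pred <- classify_gaze(s, classifier_config(), seed = 0)
report(confusion(s, pred))
extract_waypoints(pred, min_pause = 0.5)
```
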