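---
title: "Assessing facial-expression production from AU time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing facial-expression production from AU time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facexpr)
```

## The problem

Request–response protocols for assessing expression production ask a
subject — in the motivating application, a child with an autism spectrum
disorder (ASD) diagnosis — to produce one of the four basic expressions
(happiness, sadness, fear, anger), twenty times per session. Observers then
judge each attempt as produced / not produced. `facexpr` turns the judgment
into a number. It consumes what a video AU tracker emits (per-frame Facial
Action Coding System action-unit intensities on a 0–5 scale, head-pose
angles, a tracking-success flag) and produces, per request and per face
part (upper: brows and lids; lower: cheeks, mouth, jaw), a continuous
production score and an ability label.

Two properties of the target population drive the design. First,
non-emotional resting faces differ across subjects and drift within a
session (engagement, fatigue), so any fixed neutral template misleads.
Second, stereotyped movements — repetitive, unsolicited activations, e.g. a
continuously re-raised upper lid — would look like expressions to any
static detector. Both are handled by the same device: a *short-term,
personalized* statistical baseline refitted just before each evaluation
instant, so that whatever the face was recently doing (including
stereotypies) is part of the model, and only novel departures score high.

## Pipeline and model

### Gating and smoothing

Frames whose head pose deviates from frontal by more than 30° on any of
pitch, yaw, roll are marked invalid (`gate_by_pose()`; the inequality is
strict, so a frame at exactly the limit survives). Invalid frames are
excluded from every later computation, never interpolated: AU estimates off
a 30°-rotated face are not merely noisy but biased, and fabricating values
there would feed the baseline model artifacts.

Tracker AU estimates are frame-independent, so they carry high-frequency
estimation noise. `smooth_stream()` applies adaptive-degree polynomial
(Savitzky–Golay family) filtering: each output sample is the center of a
least-squares polynomial fit over a 0.5 s window, with the degree chosen
per window from {2, 3, 4} by the smallest residual sum of squares per
residual degree of freedom (RSS / (w − d − 1)). On plateaus the penalty
favors degree 2 (strongest denoising); across rapid onsets the higher
degrees win and preserve the attack of the expression. The window length,
degree set and the gate-then-smooth order are package choices — none is
forced by the method — and all are exposed as parameters. Smoothing runs
only across contiguous valid runs: a pose-gated gap splits the series and
the two sides are fitted independently, because bridging a gap would smear
pre- and post-occlusion face states into each other. Runs shorter than one
window pass through untouched. Edge samples of a run are evaluated from the
nearest full window's fitted polynomial.

### Co-occurrence regularization

Facial muscles move together; independent per-AU estimation ignores this.
With pairwise weights $p_{ij}$ — the empirical probability that AUs $i$ and
$j$ are active in the same sample — each intensity receives the correction

$$\bar{AU}_i(t) = AU_i(t) + R_i(t),\qquad
  R_i(t)=\frac{\sum_{j\neq i} p_{ij}\,(AU_i(t)-AU_j(t))}{n},\quad n=14 .$$

For symmetric $p$ the corrections cancel frame-wise
($\sum_i R_i(t) = 0$ exactly; the package verifies this to 1e-9 in its
tests before the final clipping of negatives at 0). Note the rule's sign
semantics: an AU sitting *above* its correlated peers is pushed further up,
i.e. discrepancies are sharpened, not shrunk toward the peers. Users should
keep this in mind when interpreting isolated single-AU excursions.
`estimate_cooccurrence()` learns $p$ from any binary occurrence table
(annotated data, or intensities binarized at > 1.0 via `au_occurrence()`);
no canonical matrix is shipped, because there is no redistributable
reference corpus to learn one from — `expression_cooccurrence()` provides
the structural matrix implied by the four expressions' AU sets, which is
also the simulator's generating structure.

### The personalized baseline and the variation score

At evaluation instant $t$, a univariate Gaussian mixture
$P(X)=\sum_{i=1}^{K} w_i\,\eta(X;\mu_i,\Sigma_i)$ with $K=3$ is fitted per
AU on the modeling window $W_m(t-\Delta_m;t-1)$, and the score is

$$V_{AU_i}(t) = -\log\!\big(P(\max(AU_i(t'): t' \in W_o(t+1;t+\Delta_o)))\big).$$

Three components are enough to hold a drifting resting level plus one or
two recurring stereotyped configurations. The mixture is univariate per AU
(the covariance of a single intensity is a scalar); cross-AU structure is
handled by the regularization step, not the baseline.

EM details, all configurable: initialization assigns samples to their
nearest sample-quantile centers (k-means-style seeding, deterministic given
the data — deliberately so, because per-frame refits on nearly identical
windows should produce nearly identical models); at most 100 iterations or
a log-likelihood improvement below 1e-6; variances floored at 1e-4, which
bounds the density above by $1/(0.01\sqrt{2\pi})$ and hence $V$ below by
$\log(0.01\sqrt{2\pi}) \approx -3.69$, keeping a degenerate point-mass
window from producing infinite scores; empty components are reseeded once
from a random sample point, then dropped with weight renormalization. A
window with fewer valid samples than $K$, or either window keeping less
than half its frames valid, masks the score (`NA`) rather than guessing.
Underflow far in the tails (densities below the double-precision range) is
handled by falling back to the best component's log-density, so $V$ stays
finite and ordered.

### Production scores, ability bands, detection

Per expression, the per-AU scores compose into upper/lower-face measures
(`expression_scores()`): happiness uses $V_{AU6}$ / $V_{AU12}$; sadness
$\max(V_{AU1},V_{AU4})$ / $V_{AU15}$; fear
$\min(\max(V_{AU1},V_{AU2}),V_{AU4},V_{AU5})$ /
$\max(V_{AU20},V_{AU26})$; anger $\max(V_{AU4},V_{AU5},V_{AU7})$ /
$\max(\max(V_{AU9},V_{AU23}),\min(V_{AU17},V_{AU25}))$. `max` encodes
alternative sufficient routes, `min` conjunctions that must co-occur; every
composition is monotone in every argument, a property the test suite
checks under random perturbations.

Scores below 100 read as *no* ability, within [100; 500] as *moderate*,
strictly above 500 as *strong* — the calibration that separates neutral
from expressive reference material. Boundary conventions: 100 belongs to
the moderate band (closed interval), 500 to moderate (strong requires
strictly greater). `detect_expression()` declares an expression present
only when *both* its face-part scores exceed 500; among several present,
the larger two-score mean prevails, with the fixed order H, S, F, A
breaking exact ties (ties cannot occur on continuous data; the convention
only pins down degenerate inputs).

### Session and clip modes

`score_session()` anchors the modeling window at the request instant
(frames $[t_r-\Delta_m, t_r-1]$, defaults $\Delta_m = 2$ s,
$\Delta_o = 4$ s): one mixture per involved AU per request. Evaluation
points then slide through the 4 s response window at `refit_stride` frames;
at evaluation point $e$ the observed maximum is taken over the *remaining*
response window $(e, t_r+\Delta_o]$, and the per-request score per face
part is the maximum of the composed measure over evaluation points. Keeping
the observation window inside the response interval makes a request's score
depend only on $[t_r-\Delta_m,\, t_r+\Delta_o]$ (verified in the tests),
and sliding matters for the `min` compositions: fear counts only when its
conjunct AUs are simultaneously novel at some common evaluation point.
Anchoring at the request (rather than re-sliding $W_m$) is the package's
resolution of a genuinely open design point: the question the protocol asks
is "did the face change relative to its state *at the moment of the
request*", and anchoring also makes the per-request computation one fit per
AU instead of one per frame.

`variation_series()` is the unanchored variant — $V$ for all 14 AUs at
every frame, refitting every `refit_stride` frames and reusing the model in
between — used for exploration and plotting. Reusing a stale model trades
accuracy for speed: $V$ is a negative log-density, quadratically sensitive
in its tails, so on drifting signals the relative deviation from per-frame
refits grows roughly linearly in `refit_stride`/$\Delta_m$ and is
concentrated at score spikes. At refit frames the strided series coincides
exactly with the per-frame series. Strides above ~10% of the modeling
window are not recommended when the absolute magnitude of spikes matters.

`score_clip()` handles short pre-segmented videos (one expression, neutral
start to apex): the baseline is fitted once per AU on the first quarter of
the valid frames, the remainder provides the maximum, giving one $V$ per AU
and one set of eight scores for the clip. Clips whose first quarter holds
fewer than $K$ valid samples are scored `NA` — on such material the
statistical baseline is meaningless, which is also why very short clips are
treated as outliers in this kind of analysis.

## The simulator, and what passing tests do and do not show

`simulate_session()` generates the statistical structure the method
*assumes*: per-AU baselines (defaults spread over 0.2–0.8) with slow
sinusoidal drift (amplitude 0.1, period 60 s — the scale of engagement
changes), white Gaussian estimation noise (sd 0.1, a mid-grade tracker on
unconstrained video), Poisson-timed stereotyped half-sine bursts (2/min,
amplitude 1.5, 0.2–1 s, on AU5 by default, mimicking a continuously
re-activated upper lid), and request-locked trapezoidal events (0.5 s
onset, 1 s apex, 0.5 s offset, amplitude 2, starting 0.5 s after the
request) on each expression's AU set. The standard protocol is
happiness–sadness–fear–anger repeated five times, first request at 10 s,
7 s spacing (protocols require ≥ 4 s; real sessions run 2–4 min), 25 fps.
Events overlapping on a shared AU are rejected so the ground-truth table
stays unambiguous. All of these defaults were fixed once, as the study
conditions the synthetic experiments run under.

What the simulator does *not* emulate: tracker-specific error structure
(correlated, heteroscedastic, pose-dependent), true expression kinematics
(asymmetric onsets, partial apexes), inter-AU leakage of the estimation
front-end, or children who produce the *wrong* expression rather than
none. Passing the synthetic end-to-end checks therefore shows the
statistical machinery is correct and well-calibrated under its own
assumptions — it does not certify performance on any particular tracker or
population. The detection study (20 simulated sessions, 70% compliance —
most but not all requests answered, as in real cohorts) yields sensitivity
above 0.9 with false alarms below 0.1 at the 500 bound; these are
properties of the stated conditions.

## Numerical choices and degenerate inputs

* Intensities are clipped at 0 after smoothing and after regularization
  (they are non-negative by definition; the conservation identity is
  checked pre-clip).
* Negative tracker intensities and non-finite entries are clipped/zeroed on
  read; a missing AU column is an error, not a silent default.
* Request timestamps map to the last frame at or before the request time;
  requests outside the stream's span yield `NA` scores with a warning.
* `V` can be slightly negative (down to about −3.69) when the observed
  maximum sits exactly on a near-degenerate baseline mode; ability bands
  only care about large positive values.
* Per-clip scores have a heavy left tail: occasionally the EM keeps a wide,
  low-weight component whose tail inflates the density at the observed
  maximum, and a genuinely strong event then lands in the moderate band
  instead of the strong one. This is the price of a flexible baseline that
  must also absorb stereotypies; it is visible in the simulator and should
  be expected on real short clips.
* Determinism: every random element (simulation, EM reseeding) flows from
  the caller's seed, and seeded runs reproduce bit for bit; seeded calls
  save and restore the ambient RNG state.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run 20 simulated 160 s sessions
(20 requests each) for the detection study, 5 + 5 clips of 16 s for the
clip-mode contrast, 20 replicates of 2000 samples for mixture recovery, and
100 random frames for the regularization oracle — sizes chosen so the whole
battery completes in a few minutes on one CPU while keeping the binomial
margins of the detection rates informative.

## Limitations

The package starts at AU intensities: face detection, landmark fitting,
pose estimation and AU regression are upstream concerns, and their biases
propagate. The 100/500 calibration is inherited from reference material
processed with one particular front-end; a different AU estimator may need
re-calibration (`low_bound`/`high_bound` are parameters everywhere).
Disgust and surprise are out of scope by design (four-expression Ekman
protocol). The co-occurrence matrix is assumed symmetric and in [0, 1];
directed or model-derived dependency structures are not supported.
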