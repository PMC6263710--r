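# facexpr

Quantitative assessment of facial-expression *production* from facial
Action Unit (AU) time series.

In behavioral-imaging protocols for children with autism spectrum disorder
(ASD), a therapist asks the child to produce one of the four basic Ekman
expressions — happiness, sadness, fear, anger — and observers judge whether
the child managed to. Human judgment is binary and biased; stereotyped
(unsolicited, repetitive) facial movements and atypical resting faces make
it worse. `facexpr` replaces the binary judgment with a continuous,
personalized score computed from the per-frame AU intensities that a video
AU tracker (e.g. OpenFace) has already extracted. The package is aimed at
researchers in affective computing and behavioral imaging, and at
methodologists who need a fully synthetic, ground-truthed testbed for this
class of pipeline.

## Method

Given AU intensities $AU_i(t)$ for the 14 AUs that carry the four basic
expressions (AU1, 2, 4, 5, 6, 7, 9, 12, 15, 17, 20, 23, 25, 26; 0–5
intensity scale):

1. **Reliability gating** — frames where head pose deviates from frontal by
   more than 30° in pitch, yaw or roll are discarded (never interpolated).
2. **Temporal smoothing** — adaptive-degree polynomial (Savitzky–Golay
   family) filtering per AU, fitted only across contiguous runs of valid
   frames.
3. **Co-occurrence regularization** — with pairwise activation
   probabilities $p_{ij}$ learned from a binary AU occurrence table,

   $$\bar{AU}_i(t) = AU_i(t) + \frac{\sum_{j\neq i} p_{ij}\,(AU_i(t) - AU_j(t))}{n}, \qquad n = 14 .$$

4. **Personalized short-term baseline** — per AU, a Gaussian mixture
   $P(X) = \sum_{i=1}^{K} w_i\,\eta(X;\mu_i,\Sigma_i)$ (K = 3) is fitted on
   a modeling window $W_m(t-\Delta_m;\,t-1)$ just before the evaluation
   instant; the largest AU value in the observation window
   $W_o(t+1;\,t+\Delta_o)$ is scored by its negative log-density,
   $V_{AU_i}(t) = -\log P(\max AU_i \in W_o)$. Because stereotypies recur,
   they end up inside $W_m$ and are absorbed by the mixture; only novel,
   request-locked muscle configurations score high.
5. **Production scores** — per expression, upper-face (uf) and lower-face
   (lf) scores compose the $V$ values (e.g.
   $M_{uf}^{F} = \min(\max(V_{AU1}, V_{AU2}), V_{AU4}, V_{AU5})$,
   $M_{lf}^{H} = V_{AU12}$), and are classified as **no** ability (< 100),
   **moderate** ([100; 500]) or **strong** (> 500).

Session mode scores each request against the 2 s of face just before it,
with a 4 s response window. Clip mode scores a whole short video against
its first quarter. A built-in simulator generates sessions with drifting
baselines, stereotyped bursts, pose excursions and request-locked
trapezoidal events, with ground truth.

## Worked example

```r
library(facexpr)

# a synthetic 160 s session: 4 expressions x 5 requests, stereotypies on AU5
sim    <- simulate_session(sim_config(seed = 11))
scores <- score_session(sim$stream, sim$requests,
                        cooccurrence = expression_cooccurrence(), seed = 11)
scores
#> # A tibble: 20 × 9
#>   request time_s expression  m_uf  m_lf ability_uf ability_lf valid_fraction
#> 1       1     10 H          1069. 3648. strong     strong                  1
#> 2       2     17 S          3574.  878. strong     strong                  1
#> 3       3     24 F          1221. 5150. strong     strong                  1
#> ...

session_summary(scores)
#> # A tibble: 4 × 5
#>   expression n_requests n_scored mean_m_uf mean_m_lf
#> 1 H                   5        5     1403.     2129.
#> 2 S                   5        5     3242.     2735.
#> 3 F                   5        5     1404.     2991.
#> 4 A                   5        5     3494.     2414.
```

Every request was answered in this simulation, so both face parts score in
the *strong* band (> 500) for all 20 requests; the per-expression means are
the session-level summary one would compare across subjects or sessions.

Clip mode on a 16 s clip with one strong happiness event at 10 s:

```r
clip <- simulate_session(sim_config(duration_s = 16, requests = NULL,
  events = data.frame(time_s = 10, expression = "H", amplitude = 2),
  stereotypy_rate_per_min = 0, seed = 11))
score_clip(clip$stream, seed = 11)
#> # A tibble: 8 × 4
#>   expression part    score ability
#> 1 H          uf    2231.   strong
#> 2 H          lf    3744.   strong
#> 3 S          uf       2.98 no
#> 4 S          lf      15.8  no
#> 5 F          uf      -1.31 no
#> ...
```

Both happiness scores clear the 500 bound while the six other scores stay
far below 100, so `detect_expression()` on this table returns `"H"`.

`autoplot()` methods exist for AU streams, variation series and session
scores; `tidy()`/`glance()` for mixtures and session results. A thin CLI
(`inst/scripts/facexpr`) exposes `analyze`, `clip-score`, `learn-cooccur`
and `simulate` subcommands.

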