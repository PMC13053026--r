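---
title: "Models and methods behind refgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind refgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refgame)
```

## The paradigm

`refgame` simulates and analyzes a dyadic referential communication game in
which a **sender** communicates one of six fruit/vegetable referents
(banana, eggplant, strawberry, blueberry, orange, kiwi) to a **receiver**
by moving a finger on a trackpad. The medium is the experimental
manipulation: in the *high iconicity* condition the finger position drives
a continuous colorspace and both players see the resulting color, so
iconic signals (yellow for banana) are easy to produce and transparent to
interpret; in the *low iconicity* condition both players see only a dot at
the finger position, so signals are necessarily arbitrary; in the
*one-sided* condition the sender sees colors while the receiver —
unknowingly — sees only the dot. The one-sided cell isolates a
*production* benefit of iconicity (anchoring and recall for the sender)
from the usual *comprehension* benefit (semantic transparency for the
receiver).

## The signal space

Pad coordinates are normalized to the unit square, `u` from the left edge
and `v` from the **bottom** edge. The color map is

* `a* = -128 + (1 - u) * 256` — red at the left, green at the right;
* `b* = -128 + (1 - v) * 256` — yellow at the bottom, blue at the top;
* `L* = 75` for `v <= 0.5`, otherwise `L* = 120 - 90 v`.

Both lightness branches give 75 at the midpoint, so the map is continuous;
lightness falls to 30 at the top edge, darkening the blue/green region.
Measuring `v` bottom-up is forced jointly by the bottom-left corner being
red and by `L*` having to stay within `[0, 100]`; the vertical coordinate
is normalized by the pad height so that the same formulas apply to any pad
aspect ratio. Much of this Lab rectangle lies outside the sRGB gamut;
`lab_to_rgb()` uses the standard D65 transform (via
`grDevices::convertColor`) and clamps each channel to `[0, 1]`, which is
the conventional display behavior when no gamut-mapping rule is given.
Whether the original display software clamped or gamut-mapped is unknown;
clamping is the simplest defensible choice and only affects rendering,
never the Lab coordinates the agents reason over.

## The game engine

A session is eight practice rounds (90 s cap each) followed by main rounds
(30 s cap), every round followed by 2 s of feedback. Each round the server
draws a target uniformly at random (no balancing, no repeat-gap rule), the
sender produces one pad point, condition-specific views are rendered, the
receiver guesses, and both sides see the outcome. A referent is
**established** when it has been the target at least four times and at
least three of its four most recent guesses were correct; the **winning
condition** — checked after every correct guess — is all six referents
established at once, and ends the game immediately. Otherwise the game
ends at the first round boundary at or past 60 minutes of cumulative play
(the round in progress completes; practice time counts toward the hour,
since it is wall time spent at the table). Practice outcomes never feed
the winning ledger.

Two recording conventions are worth making explicit:

* a receiver timeout is recorded as an **incorrect** outcome, because the
  winning criterion must allow negative progress — treating a timeout as a
  non-event would let an established referent survive unlimited silence;
* referents with fewer than four occurrences are never established, so no
  dyad can begin the game with credit in hand and the success index is
  strictly below 1.

Simulated response latency is lognormal (default `meanlog = log(8)`,
`sdlog = 0.5`, i.e. a median of 8 s), truncated at the round cap; the 1 s
hold-to-send dwell is folded into this latency rather than modeled
separately. The engine emits one sent signal per round; the metrics layer
nevertheless accepts external logs with several sends in a round and by
default scores the **last** send before the guess (it is the signal the
guess responded to; a first-send toggle is provided).

## The agent model (synthetic-data generator)

The generator's purpose is to reproduce the *statistical structure* the
analysis pipeline assumes, so every metric and model can be exercised at
will, with known ground truth.

**Sender.** With colors visible, production is anchored: a draw from an
isotropic Gaussian (`sigma_motor`, default 0.03 pad units) around the
referent's iconic anchor, clamped to the pad. The default anchors place
each referent's associated color at well-separated pad positions (yellow,
red, orange, green, dark blue, dark purple; minimum pairwise separation
about 0.2) and are overridable. Without colors there is no anchor: the
sender maintains an arbitrary convention point per referent that drifts by
`sigma_drift` (0.15) at each reuse and is forgotten outright with
probability `p_forget` (0.25), being resampled uniformly. Successive
anchored productions then have mean distance `sigma_motor * sqrt(pi)`
(about 0.053 at the default), the closed form used by the
parameter-recovery checks, while unanchored conventions wander.

**Receiver.** Classification mixes exemplar memory with an iconic prior.
Up to `memory_capacity` (6) recent `(signal, referent)` pairs are stored
per referent; a candidate's exemplar score is the best Gaussian-kernel
similarity between the viewed signal and its exemplars (`tau_color = 40`
Lab units, `tau_dot = 0.12` pad units). For **color** views only, an
iconic prior scores each candidate by the similarity of the viewed color
to that candidate's anchor color, mixed in with weight `lambda_prior`
(0.6); for dot views the prior weight is forced to zero — there is nothing
transparent about a dot. Dot exemplars are stored with positional encoding
noise `sigma_encode_dot` (0.28), reflecting how costly arbitrary positions
are to memorize precisely; color exemplars are stored faithfully. A lapse
rate `epsilon_guess` (0.1) produces uniform guesses.

These defaults were fixed once, at design time, so that default cohorts
occupy the regime the paradigm describes: high-iconicity dyads win in
roughly ten minutes; one-sided dyads get a clear head-start (stable
signals, early establishment) but struggle to hold all six referents at
once and often play the hour out; low-iconicity dyads hover near chance
with most rounds at zero established signals; and production stability is
indistinguishable between the two color-sender conditions while far worse
with the dot. They are statements about what the generator emulates, not
estimates fitted to any human data — fitting the agent parameters to
deposited logs is explicitly future work.

What the generator does **not** emulate: strategic audience design,
pre-send exploration of the medium (exploration time is absorbed into the
latency distribution), non-stationary motivation or fatigue, and any
receiver strategy beyond similarity matching. Passing condition-ordering
tests on synthetic cohorts therefore shows the pipeline detects the
structure the generator encodes — it is not evidence about human behavior.

## Metrics

* **Established series** `s_t`: the number of referents established at
  round `t`, under the same 3-of-last-4 rule as the engine. For the
  success index the histories include practice rounds (the high-iconicity
  condition does much of its establishing there); a main-rounds-only
  variant reproduces the in-game ledger.
* **Success index**: `sum(s_t) / (6 n_r)`. Won games are padded with
  *dummy rounds* at `s = 6`: the remaining session time divided by the
  mean duration of the final four rounds, rounded **down** (a dyad cannot
  play a fraction of a round), with round length including the 2 s
  feedback since that is what fills the hour. Both the practice and dummy
  inclusions can be toggled for sensitivity variants.
* **Stability**: per referent, the Euclidean distance between successive
  sent pad points; the first occurrence contributes nothing.
* **Accuracy**: fraction correct, timeouts counting as misses. The default
  scope is main rounds (the rounds that count); an all-rounds toggle is
  provided because either convention is defensible.
* **Set-size proportions**: the distribution of `s_t` over rounds, pooled
  within condition; practice rounds in, dummy rounds out.

## Statistical summaries

Dyad-level contrasts use OLS with treatment coding and low iconicity as
the reference level (`fit_condition_lm`), refittable against any
reference. Stability uses a REML linear mixed model with crossed random
intercepts for dyad and referent and Satterthwaite degrees of freedom
(`lmerTest`). The round-by-round analysis splits the zero-inflated
established-count series into a binomial GLMM on `1(s_t > 0)` (`lme4`) and
a negative-binomial GLMM on the positive counts (`glmmTMB`, `nbinom2`,
dispersion estimated by maximum likelihood), both with a scaled-round by
condition interaction and dyad intercepts. Round number is z-scored across
the pooled round table; per-dyad scaling is a documented alternative for
replication work. For the mixed model we report both marginal and
conditional r-squared (computed from the fixed-effect, random-intercept,
and residual variance components) rather than guessing which single value
an unlabeled r-squared denotes. Non-convergence is reported via warnings
and a `converged` attribute, never silently.

## Numerical and testing choices

Truncation to the pad is implemented as clamping; with the default motor
noise and near-edge anchors this biases the mean successive distance
about 5% low, which the parameter-recovery tolerance (10%) absorbs.
Receiver score ties are broken uniformly at random. All randomness in a
cohort flows from one master seed through per-dyad derived seeds, so
cohorts are reproducible bit for bit. The package's own test suite runs
the ledger against an exhaustive re-scan oracle on a thousand random
100-round logs, sweeps ten thousand random logs for the success-index
bound, recovers `sigma_motor` from 100 simulated dyads of 100 rounds,
checks the condition orderings over 50 cohorts of 4 dyads per condition,
and calibrates the contrast's type-I error on a thousand null cohorts of
68 dyads — sizes chosen to make the checks sharp while keeping the suite
quick on a laptop.

## Limitations

The agents are deliberately minimal: exemplar memory with a Gaussian
kernel and a fixed-weight prior is one of many receiver models consistent
with the paradigm, and the kernel bandwidths are conventions, not
measurements. The adapter for externally deposited logs requires a
column-mapping configuration because the deposited layout is not
standardized; nothing about it is hard-coded. Reproducing published
human-cohort coefficients requires those human logs; everything this
package computes on its own is synthetic and labeled as such.
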