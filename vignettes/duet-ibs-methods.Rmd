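---
title: "Amplitude-envelope inter-brain synchrony in duetting musicians: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-envelope inter-brain synchrony: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duetIBS)
```

## The scientific problem

When two people act in tight temporal coordination — here, two pianists
performing complementary parts of a duet — their EEG signals tend to
synchronize. The contentious question is *why*: because both brains receive
the same sounds and produce similar movements (a shared-input epiphenomenon),
or because genuinely endogenous processes, such as the covert planning of a
musical tempo, align between partners. The paradigm this package analyzes
separates the two accounts with a duet that contains a silent pause: each
trial runs cue → metronome (4 beats, 120 bpm) → first phrase (7 crotchets +
rest, played together with sound) → 4-s silent pause (internally timed) →
second phrase at a *covertly instructed* new tempo (150 or 96 bpm), with the
two players' instructions either congruent or incongruent, and the pieces
either familiar or unfamiliar to the partner (a fully within-pair 2 × 2
design, TEMPO × FAMILIARITY). Inter-brain synchrony (IBS) during the pause
cannot be driven by shared input — there is none — so condition differences
there index the alignment of endogenous temporal plans.

## The IBS measure

The synchrony metric is the phase-locking value (PLV) between the two
players' *amplitude envelopes*. Per frequency band (delta 1–3, theta 4–7,
alpha 8–12, beta 13–30, gamma 30–40 Hz) the pipeline

1. band-passes each epoch (zero-phase Butterworth, order 4 per pass) and
   takes the modulus of the analytic signal — the band's amplitude envelope;
2. band-passes the envelope at 1–3 Hz — the range of the task's tempi
   (96–150 bpm = 1.6–2.5 Hz) — and takes the analytic phase
   $\theta_p(t)$ of the result;
3. computes, per trial $n$, homologous electrode pair, and 2-s window $w$
   stepped at 100 ms,

$$\mathrm{PLV}_{(w,n)} = \frac{1}{T}\left|\sum_{t=1}^{T}
   e^{i\,(\theta_{1}(t) - \theta_{2}(t))}\right|,$$

the modulus of the mean unit phasor of the between-player envelope-phase
difference ($T = 1000$ samples at 500 Hz). PLVs are averaged first across
the channel pairs of a region of interest (GLOBAL = all 29 homologous
pairs; RP = C4, CP2, CP6, P4, P8; LP = their left homologs), then across
trials per condition.

Window timestamps are window *centers*. This is forced by the arithmetic
of the coverage relation: a run of significant centers 7.7–8.3 s covers
the data from 6.7 to 9.3 s (± half the window width). The first window
spans [1, 3) s (left edge at the metronome onset), the last ends at
14.2 s, where fast trials finish — 113 windows in the default grid.
Windows are half-open so each sample belongs to exactly one window
position, and all Hilbert transforms and filters run over the whole
−1…16 s epoch so that the pre-cue second and the tail absorb filter
transients. Filter orders follow the convention "order per pass" of the
two-pass (zero-phase) Butterworth design: order 3 for the 0.5–95 Hz
band-pass and 45–55 Hz band-stop of preprocessing, order 4 for band and
envelope filters.

## Statistics

Per window, ROI and band, the four condition cell means per pair enter a
fully within-pairs 2 × 2 rmANOVA. With 2-level factors each effect F on
df (1, n−1) equals the squared paired t of the corresponding marginal
difference, which the implementation exploits (closed-form contrast F;
`stats::aov` with error strata is the independent oracle in the test
suite, and no sphericity correction is needed). Multiple comparisons over
time are controlled by cluster-based permutation: clusters are maximal
runs of ≥ 2 consecutive windows with pointwise p < 0.01 (the stringent
cluster-forming alpha compensates for testing five bands); the cluster
mass is the summed F. Under the null, trial-to-condition assignment is
exchangeable within pair, so each of the N = 1000 permutations re-shuffles
all four cell labels within every pair (preserving cell counts), re-runs
the pointwise rmANOVA, and records the largest cluster mass per effect
family (0 if none forms). Observed clusters get
$p = (b + 1)/(N + 1)$ (add-one convention, so p is never 0 and the test
remains exactly valid); significance is declared at cluster p < 0.05.
Permutations that produce no cluster contribute mass 0, which is
conservative. Because the design is 2 × 2 within, no Greenhouse–Geisser
correction applies.

Two design points were genuinely open and are resolved as follows. The
permutation scheme re-shuffles *all four* cell labels jointly (rather than
only the tested factor's margin): it matches the literal "assignment of
trials to the experimental conditions" most closely, keeps one null
distribution family per effect from the same permutation stream, and
preserves trial counts. And cluster formation is applied uniformly to all
three effects (both main effects and the interaction), since nothing
favors treating the interaction differently.

### Controls

*Baseline PLV* re-pairs trials **within** each dyad (player 1's trial *i*
with player 2's trial σ(*i*), σ a random derangement) and re-runs the PLV
pipeline; it captures locking driven by the task structure common to all
trials. The package averages 20 derangements by default — the number is a
free parameter (no canonical value exists); 20 stabilizes the curve at
modest cost. *Surrogate pairs* re-pair players **across** dyads
(deterministic cyclic shift by default, so no real pair can survive;
optionally a random fixed-point-free permutation), matching trials of the
same condition and equalizing counts to player 1's by deleting spare
player-2 trials or duplicating its first trials in order — so surrogate
analyses run at exactly the real analyses' statistical power. The *power
confound* check compares band power (mean squared envelope — the
convention chosen here, consistent with an envelope-based pipeline) across
conditions in the window/ROI/band of any PLV effect, by paired t-tests.

### Brain–behavior models

Trial-level behavioral outcomes are regressed on window-averaged PLV with
a pair random intercept, `outcome ~ PLV + (1 | pair)` (ML), and assessed
by a likelihood-ratio test against the intercept-only null with the same
random structure. Outcomes with |skewness| > 1 are log-transformed when
strictly positive, square-root-transformed when non-negative; the choice
is recorded in the output ("if necessary" is the only guidance available,
so the rule is made explicit and deterministic). The bimodal phrase-2
IKI-difference outcome is median-split (ties to the lower bin, for
determinism) and fit with a binomial mixed model. Mixed-model machinery
is deliberately off-the-shelf (lme4); the package's contribution is the
harness: transforms, null comparison, and convergence/singularity
reporting.

## The synthetic dyad generator

The study's recordings are not openly archived, so the package ships a
generator that emulates the paradigm with known ground truth; every
downstream stage is validated against it.

**EEG.** Each band × topography entry of the coupling map drives one
latent source per player: band-limited Gaussian noise multiplied by
$1 + d\cos(\Phi_{\text{beat}}(t) - \varphi_p(t))$, where
$\Phi_{\text{beat}}$ integrates the beat rate (2 Hz up to the second
phrase, then the player's instructed tempo) and $\varphi_p$ is a slow
(≤ ~0.4 Hz) phase wander. Channels are topography-weighted source
mixtures plus 1/f background noise. Envelopes therefore peak on every
beat, and the property tests verify that the beat-filtered gamma envelope
has its spectral peak at 2 Hz during the first phrase.

**Coupling.** The measured quantity is the between-player envelope-phase
difference, so the condition manipulation is injected exactly there. The
wander is a mixture of a dyad-and-trial-specific shared process $s(t)$
and player-individual processes $w_p(t)$:
$\varphi_p = \sigma_0\,(\rho\, s + \sqrt{1-\rho^2}\, w_p)$ with
$\rho = \sqrt{\kappa/(1+\kappa)}$, so the stationary phase-difference
variance is $2\sigma_0^2/(1+\kappa)$: κ → ∞ gives identical modulation
phases (PLV → 1), κ = 0 independent wander, and windowed PLV is monotone
in κ. A constant per-trial von Mises offset (condition-independent,
concentration `offset_kappa`) captures trial-to-trial alignment
variability and is retrievable from the ground truth. Two consequences
are deliberate: a *constant* condition-dependent offset would be
invisible to windowed PLV (any constant offset gives PLV 1), so
concentration acts on the *time-varying* offset process instead; and
because the shared component is dyad-specific, surrogate re-pairing
destroys the condition contrast exactly — the phase-difference variance
of a surrogate pair is $2\sigma_0^2$ regardless of condition — which is
the dissociation the surrogate control is designed to detect. The default
map injects the qualitative effect pattern of the paradigm: unfamiliar >
familiar GLOBAL gamma coupling in phrase 1, congruent > incongruent RP
gamma coupling in the pause, incongruent > congruent GLOBAL delta/theta
coupling in phrase 1, and a condition-independent base concentration
everywhere else.

A lightweight ROI-level variant (`simulate_phase_session()`) draws the
envelope-phase series directly, skipping carriers and channels; it makes
hundreds-of-sessions calibration studies tractable while exercising the
identical PLV, ANOVA, clustering, permutation and surrogate code paths.
Its beat is modelled at the shared 2 Hz task tempo only, so conditions
differ through coupling alone and surrogate re-pairings are null by
construction.

**Keystrokes.** Onsets follow a first-order mutual phase-correction
model on an internal beat: next onset = previous onset + own period +
α × (partner − own onset at the last audible beat) + Gaussian motor noise
(σ = 10 ms, a typical duet ensemble-timing scale). The own period starts
at 500 ms and drifts toward the instructed second-phrase period by β per
beat during phrase 1 and the pause (capped at the target); mutual
correction operates only while partners can hear each other (phrase-1
keystrokes; the second phrase is muted in the paradigm and the pause is
silent). The interval into the phrase-2 entry still runs at the drifting
120 bpm pulse; the instructed period applies from the entry onward. The
default β = 0.5 ms/beat keeps the anticipatory drift in the
"milliseconds" range: up-down instructions produce negative (player 1 −
player 2) phrase-1 asynchronies of a few to tens of ms, down-up positive
ones, congruent pairs stay near zero, and the accumulated drift yields an
incongruent entry asynchrony of ~0.14 s against ~0.04 s for congruent
pairs (where only the random-walk of motor noise over the internally
timed pause remains). Higher correction gain α produces more negative lag-0
cross-correlations of the players' inter-keystroke intervals — the
signature of stronger mutual adaptation. First-order phase correction
(without a separate period-correction term beyond the deterministic
drift) is the simplest model that reproduces these sign and adaptation
patterns.

**What the generator does not emulate.** Ocular/muscle artifacts,
volume-conduction forward modelling, audio, and performance errors are
out of scope; the keep-mask stands in for interactive artifact rejection.
Passing tests on synthetic sessions therefore demonstrate the
*statistical machinery* — calibration, power, surrogate dissociation,
parameter recovery — not the physiological realism of any particular
effect size. One consequence worth noting: in the full EEG generator each
player's carrier noise is individual, so envelope PLV saturates below 1
even under perfect modulation-phase coupling (as in real EEG); the exact
PLV → 1 limit is reached in the ROI-level generator, where the measured
phase itself is simulated.

## Numerical choices and degenerate inputs

- Fisher z uses r clamped to ±(1 − 10⁻¹⁰) so perfectly correlated IKI
  series stay finite in averages; zero-variance IKI series, missing entry
  keystrokes and empty IKI overlaps are flagged (`NA` + reason) and
  excluded from averaging rather than erroring a whole session.
- The contrast-based rmANOVA guards the 0/0 case (identical cell means →
  F = 0); incomplete cells are an error, never silently dropped.
- Cluster p-values use the add-one convention, so the smallest attainable
  p is 1/(N+1); permutations without clusters contribute mass 0.
- Trial validity requires the correct 7 keystrokes per phrase (score
  pitches matched by position, never nearest-onset — keystrokes are
  "complementary" by the score) and a mean phrase-2 IKI that moves at
  least 50% of the way from 500 ms toward the instructed 400/625 ms
  target in the right direction; the exclusion rules of the original
  behavioral cleaning are not published in detail, so this
  direction-plus-magnitude criterion is the package's own robust stand-in,
  and retention percentages are not comparable to the study's 86.4%.
- The asynchrony sign convention is player 1 − player 2 (the source
  leaves it unstated); it is recorded in output metadata and all absolute
  measures are invariant to it.
- Entry asynchronies use raw absolute onset differences (per-position
  normalization before the entry measure is not prescribed anywhere).
- Singular mixed-model fits are flagged, not dropped; a single-pair table
  degenerates to ordinary regression with a warning.

## Validation problem sizes

The shipped tests calibrate the cluster test on 200 null sessions
(14 pairs, 36 kept trials per cell — the cleaned-data scale — ROI-level
series of 40 windows, 200 permutations each), recover an injected
congruent-pause coupling advantage (κ 16 vs 1) in 50 replicate sessions
with the full 113-window grid while scoring surrogate re-pairings of the
same data, verify the Rayleigh small-sample mean of the PLV on 10⁵
uniform-phase windows, and check mixed-model slope-sign recovery on 100
replicates. ROI-level phase series for the calibration studies are drawn
at 50–100 Hz: the PLV is scale-free in time, so a reduced rate only
coarsens the within-window average without changing the statistics under
test. The full EEG generator is exercised at 125 Hz in unit tests (the
gamma band edge at 40 Hz still sits comfortably below Nyquist); the
default remains 500 Hz.

## Known limitations

- The generator's effect sizes are free parameters chosen for realistic
  orders of magnitude; the original study's cluster masses and F values
  depend on its restricted data and are not reproduction targets.
- Surrogate and baseline repetition counts are exposed as parameters; no
  canonical values exist.
- The pipeline analyzes time courses after ROI averaging; electrode-space
  (adjacency) clustering and carrier-phase IBS metrics are out of scope.
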