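---
title: "Timing of odor encounters in turbulent plumes: model, encoding, and search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing of odor encounters in turbulent plumes: model, encoding, and search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumetime)
set.seed(1)
```

## The scientific question

A turbulent plume does not deliver odor as a smooth gradient.  A sensor held
at a fixed point registers intermittent whiffs separated by blanks, and the
*timing* of those whiffs — not just their concentration — varies
systematically with position relative to the source.  `plumetime` provides a
full computational chain for studying whether that timing is a usable
navigational cue: a statistical model of plume intermittency, recurrence-time
statistics that quantify the timing structure, a model of bursting olfactory
receptor neurons (bORNs) that can encode the time since the last odor
encounter peripherally, and an agent-based searcher that navigates on either
the timing cue or instantaneous concentration.

## The statistical plume model

`plume_params()` holds the constants of a parametric model with the source at
the origin and `+x` downstream (cm, s, % of source concentration):

* **Whiff timing.** Times between threshold up-crossings at a point are
  exponential with mean
  $\bar\Delta(x,0)=\Delta_0 e^{\lambda x}$ on the centerline and
  $\bar\Delta(x,y)=a(x)\,e^{\eta(x)|y|}$ off it, where
  $a(x)=g\,e^{hx}+n$ and $\eta(x)=p\,x^{q}+n$.
* **Instantaneous concentration.** Gamma distributed with mean
  $\bar C(x,0)=C_0e^{-\beta x}$ on the centerline and a Gaussian cross-stream
  profile $\bar C(x,y)=c(x)\,e^{-y^2/\sigma(x)^2}$, with $c(x)=k\,e^{bx}+n$
  and $\sigma(x)=m\,x^{d}+n$.  The Gamma scale parameter follows the same
  functional form as the mean, and the shape parameter is mean divided by
  scale.

$n$ is optional zero-mean Gaussian evaluation noise (standard deviation
`noise_sd`).  It defaults to 0 so that every deterministic quantity is
reproducible bit for bit; switching it on perturbs $a$, $\eta$, $c$ and
$\sigma$ independently at each evaluation, emulating fitting error.

### Calibration of the default constants

The functional forms above are fit to flume measurements in the literature,
but the fitted constants themselves are not tabulated anywhere we could take
them from.  The package therefore ships *calibration choices*, fixed once:
over the measurement grid (x from 50 to 250 cm, y from 0 to 10 cm) the
defaults give centerline mean whiff intervals of about 0.3–3 s, growing to
roughly 8 s at 10 cm off-axis, and mean concentrations of about 2–10% of
source with a plume half-width near 10 cm at x = 150 cm — the qualitative
ranges a flume plume of this scale exhibits.  The detection threshold
(2.55% of source), frame rate (60 frames/s), recording length (1025 frames),
and flow speed (4.6 cm/s) are the study's stated values.  Users holding
site-wise summary statistics (e.g. the 45-measurement grid of the original
flume dataset) can re-estimate every constant with `fit_plume_params()`,
which performs the same log-linear / log-log least-squares chain the original
fits describe.

### Whiff rendering

`generate_site_series()` renders the renewal encounter process as a
concentration series.  Two choices matter and are worth making explicit:

* **Peak amplitudes** are drawn from the site Gamma distribution
  *conditioned on exceeding the detection threshold* (inverse-CDF sampling on
  the truncated upper tail).  An encounter in the timing model *is* a
  threshold up-crossing, so a rendered whiff that never reached threshold
  would contradict the process it renders; conditioning keeps the up-crossing
  count consistent with the renewal rate.  This identity holds in the sparse
  regime where the mean interval clearly exceeds the whiff width; very close
  to the source whiffs begin to merge and the up-crossing count falls below
  the encounter count, as it does in real plumes.
* **Whiff shape** defaults to a triangle (linear rise to the peak, linear
  fall) of width 0.2 s rather than a rectangle.  The recurrence analysis
  probes the neighborhood of the detection threshold; a series with
  instantaneous edges jumps across that neighborhood and almost never visits
  it, which would starve the very statistic the generator exists to feed.
  The triangular ramp makes every whiff pass continuously through the
  near-threshold band, as a continuously sampled physical signal does.
  `whiff_shape = "rect"` is available for sensitivity checks.

## Recurrence-time statistics

`delay_embed()` reconstructs a state space from the scalar series (Takens
embedding; row $i$ is $(s_i, s_{i+\tau}, \dots, s_{i+(m-1)\tau})$), and
`recurrence_matrix()` computes
$R(i,j) = \Theta(r - \lVert x_i - x_j\rVert)$ with the strict-inequality
convention $\Theta(0)=0$ (configurable).  The delay defaults to 1 sample and
can be chosen per series as the first local minimum of the auto mutual
information, falling back to the first autocorrelation zero crossing
(`choose_delay()`).

Given a reference state $x_0$, the visits of the trajectory to its
$r$-neighborhood form the set $S_1$; successive differences of the visit
times are the **first-type recurrence times** $T_1$.  Removing *sojourn
points* — visits whose predecessor is also a visit — leaves the returning
points $S_2$, whose successive differences are the **second-type recurrence
times** $T_2$.  $\bar T_1$ counts every revisit however brief; $\bar T_2$
counts only genuine returns, the analogue of a sensor with a refractory
period.

Three implementation decisions:

* **Reference state.**  For site analyses the reference is the observed
  state whose first coordinate is closest to the detection threshold.  If no
  observed state comes within $r$ of the threshold the series has no
  recurrences *at the threshold* and the replicate is flagged undefined
  rather than silently recentered — without this guard, a recording that
  never leaves baseline would nominate the baseline itself as reference and
  report a spurious flood of recurrences.
* **Sojourn clustering window.**  The literal sojourn rule removes only
  *consecutive-sample* repeats, which at 60 frames/s means a 17 ms window —
  far shorter than any neural refractory period.  `min_separation` (seconds)
  generalizes the rule: visits closer than the window to their predecessor
  count as sojourns.  The default is 0 (the literal rule); the experiment
  driver uses 0.3 s, a physiological refractory scale that treats one whiff
  as one encounter.
* **Pooling order.**  `site_profile()` either averages per-replicate means
  (`pool = "replicates"`, mirroring mean-and-standard-deviation error bars
  across repeated recordings) or pools all intervals of a site before
  averaging (`pool = "intervals"`).  The experiment driver pools intervals:
  with 17-second recordings the sparsest sites yield only a handful of
  intervals per replicate, and weighting a two-interval replicate equally
  with a fifty-interval one is a substantially noisier estimator.

The experiment driver profiles the *raw* (dimension-1) series by default.
Recurrence-time statistics are reliably estimated without embedding, and the
un-embedded estimate is the one a sensor population could plausibly form;
the embedding dimension remains configurable (the original analysis used 10)
for state-space work.

## The bORN population model

Each neuron (`born_params()`) is a renewal process: spontaneous bursts with
Gamma-distributed inter-burst intervals (IBI; mean and coefficient of
variation parameterized, lognormal available), plus odor-evoked bursts.  An
odor arriving at phase $\tau$ (time since the neuron's last burst) evokes an
immediate burst — resetting the cycle — with probability given by a sigmoid
in $\tau$; composing that sigmoid with the spontaneous survival function
$1-F_{IBI}(\tau)$ yields the neuron's *time entrainment tuning curve*, peaked
at the odor period it encodes best.

`make_population()` draws heterogeneous populations: IBI means log-uniform
over 0.2–20 s (the observed span from sub-second to tens of seconds), CV
uniform on 0.2–0.45, sigmoid plateau uniform on 0.85–1, and the sigmoid
midpoint at $0.4\,\times$ the neuron's own IBI mean (with log jitter), which
places each tuning-curve peak near the neuron's intrinsic period.  The
scheme needs heterogeneity, not fine tuning; the priors are deliberately
broad.

### Decoding

`decode_elapsed_time()` reads the time since the last odor encounter out of
the vector of phases $\tau_i$.  Under the hypothesis that the odor arrived
$t$ seconds ago, each neuron's phase follows a two-component mixture:

* with weight $w_i(t) = \mathrm{E}[\text{evoked}_i] \cdot S_i(t)$ the neuron
  responded to that odor and has not burst since, so $\tau_i$ concentrates
  near $t$ (Gaussian kernel, bandwidth 0.25 s);
* with weight $1-w_i(t)$ the neuron free-runs and $\tau_i$ follows the
  stationary backward-recurrence-time density $S_i(\tau)/\mu_i$.

$\mathrm{E}[\text{evoked}_i]$ averages the evoked sigmoid over the stationary
phase density, because the decoder cannot know the phase the neuron happened
to have when the odor arrived.  The decoded time is the grid argmax of the
summed log likelihood (default grid 0–30 s at 0.1 s), ties breaking toward
the smaller elapsed time.  This likelihood is an engineering reconstruction:
the original electrophysiological study delegates its exact decoder to prior
work, so the package's decoder reproduces the *behavior* (accurate, low
variance interval readout from a heterogeneous population) rather than any
specific published likelihood.  `winner_take_all()` provides the cheap
modal-phase variant.

The decode experiment delivers two stimuli a known interval apart after a
30-s lead-in (so the population is near stationarity), and reads the state
just before the second stimulus's responses arrive — except for coincident
stimuli, where the elapsed time is zero and the state just after the
combined response is the meaningful readout.

## The bilateral searcher

The agent (`search_config()`) carries two sensors 5 cm from the body,
separated by 60° about its heading; it starts heading up-current (180°),
advances 5 cm per step, waits at most 10 s per observation, and succeeds
when a sensor comes within 5 cm of the source.  Per step it compares its two
readings — time since last encounter for the bORN strategy (smaller wins),
one Gamma concentration draw for the concentration strategy (larger wins; a
draw below the detection threshold counts as silence) — turns 30° toward the
winning sensor, and advances along the new heading.  If both sensors are
silent it backtracks to its previous position *and re-orients by a random
turn within ±90°*: searchers that lose a plume turn to re-enter it, and
without the re-orientation the silence boundary of the plume acts as a pure
reflector the searcher can jitter against indefinitely.

The timing cue is measured by an ideal timer by default: the waiting time at
the sensor is exponential, and by memorylessness its distribution equals the
distribution of the time since the last encounter, so a single exponential
draw is a faithful stand-in.  The mechanistic alternative
(`delta_source = "born_decoder"`) drives a per-sensor bORN population with
sampled encounter times and reads the cue with the maximum-likelihood
decoder; it links the search module to the neural module at a substantial
runtime cost.

Single-sensor variants cannot compare bilaterally; they compare
*sequentially* (continue straight while the cue has not deteriorated, turn
randomly by 30° when it has, backtrack on silence).  An earlier candidate
rule — continue straight on any cue — degenerates on centerline starts into
a beeline that outperforms the bilateral strategy, which contradicts the
point of modeling a handicapped searcher; the sequential-comparison rule is
the standard run-and-tumble reading of one-sensor chemotaxis.

`monte_carlo()` repeats runs per start with per-run seeds derived from a
base seed, so two strategies evaluated under the same base seed face paired
random streams.  Runs that exhaust the step cap (default 5000) are censored
at the cap and flagged; summaries report both censored and success-only
means.

## Problem sizes and numerical choices

The experiment drivers default to the study's scale: 15 sites (x = 50–250 cm
by 50, y = 0, 5, 10 cm), 10 replicate recordings of 1025 frames at 60
frames/s per site, a 210-neuron population, 100 Monte-Carlo search
replicates per start.  At these sizes the recurrence experiment runs in
seconds, a single population decode in ~0.1 s, and the full two-strategy
search comparison in a few minutes on one core.  Degenerate inputs are
handled explicitly: sites whose series never approach the detection
threshold, neurons that have not burst by the readout time (flagged invalid
and excluded from the likelihood), populations with no valid neuron
(an error), and searches that exhaust the step cap (censored results, not
exceptions).  Likelihood factors are floored at `1e-300` before taking logs;
ties in the decoder and the searcher are broken deterministically toward
smaller elapsed time and by a seeded fair coin respectively.

## What the synthetic generator does and does not emulate

The generator reproduces the *statistical* structure the analysis rests on —
exponential inter-arrival times with position-dependent means, Gamma
concentration amplitudes, threshold-crossing whiffs on a sub-threshold
baseline — under seeded determinism.  It does not emulate fine-grained
turbulent microstructure: within-whiff concentration fluctuations,
correlated arrival times, meander of the instantaneous plume centerline, or
vertical structure.  Passing tests on synthetic plumes therefore demonstrate
that the statistics-to-navigation chain works when the plume matches the
fitted statistical laws; they do not by themselves certify performance on
raw flume recordings, which is what the optional MAT-file ingestion path
(`read_plif_dataset()`, `extract_annulus_series()`) exists to support.

A second caveat follows from the 17-second recording length: at the
sparsest site (10 cm off-axis at 150 cm downstream, mean interval ≈ 8 s)
a site estimate rests on a few dozen intervals pooled across replicates, so
first-type recurrence-time estimates — whose definition includes every
brief revisit — retain appreciable sampling variance there even though their
expectations order the sites correctly.  The second-type statistic with the
refractory clustering window is markedly more stable, which is itself a
point in favor of refractory (second-type) timing sensors.

## Known limitations

* The decoder likelihood is a reconstruction (above), so decoded values for
  any specific stimulus protocol are reproducible in distribution, not as
  exact published numbers.
* The MAT v5 reader handles numeric arrays (compressed elements on a
  best-effort basis) and infers site layout from variable names; the
  original supplementary dataset's internal naming is described only in
  metadata not available here, so ingestion of arbitrary layouts is
  deliberately schema-tolerant and may require the user to map variables to
  sites manually.
* The search domain is the statistical plume's region of validity (x > 0);
  sensors outside it register silence rather than a modeled off-plume
  concentration field.
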