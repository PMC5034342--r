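---
title: "Methods: a simulated neural bypass for rhythmic movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a simulated neural bypass for rhythmic movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, signal-processing choices and design
decisions behind `neurobypass`, in the spirit of a methods section: what
each stage computes, which knobs matter, and what the synthetic test bed
does and does not demonstrate about real recordings.

## The oscillator

The rhythm generator is the canonical two-neuron mutually inhibitive
half-center model with adaptation,

$$\tau_1 \dot x_i = -x_i - \beta v_i - \mu_{ji}\,y_j + c, \qquad
  \tau_2 \dot v_i = -v_i + y_i, \qquad y_i = \max(0, x_i),$$

with oscillator output $y_{out} = y_1 - y_2$. The symbols follow common
usage: $x_i$ membrane potential, $v_i$ adaptation ("membrane current"),
$\beta$ adaptive self-inhibition gain, $\mu_{ij}$ the inhibitory
interaction weights, $c$ the shared tonic drive, $\tau_1, \tau_2$ the
membrane and adaptation time constants (seconds). Two conventions were
genuinely open and are fixed here once: the output sign ($y_1 - y_2$;
the other choice only flips stimulation polarity) and the weight
subscript reading ($\mu_{ji}$ is the weight of neuron $j$'s output in
neuron $i$'s equation; swapping the reading relabels the two neurons and
leaves every reported quantity unchanged).

Assumptions worth making explicit: the two half-centers are symmetric in
$\tau$, $\beta$ and $c$; there is no sensory feedback into the
oscillator; and amplitude is not separately controlled — the system
downstream uses only the *sign* of $y_{out}$, discretized at the 10 Hz
stimulation update rate, because the virtual stimulator (like a
practical one) delivers only maximal flexion or extension drive.

**Integration.** Fixed-step classical RK4, default `dt = 1 ms`, i.e.
hundreds of steps per cycle for the time constants of interest and well
inside the stability region for $\tau_1 = 0.1$ s. Fixed-step was chosen
over adaptive solvers for bit-reproducibility: identical inputs give
identical traces on any platform. The rectification makes the
right-hand side non-smooth, so the effective accuracy at the switching
corners is $O(dt^2)$ rather than $O(dt^4)$; the test suite checks
agreement with an adaptive multistep solver to $10^{-4}$ at 2 s and with
a finely subdivided forward-Euler oracle to $10^{-6}$ per step.

**Symmetry breaking.** The perfectly symmetric state is a non-oscillating
equilibrium of the symmetric network, so a simulation started there
would stay there forever. `cpg_simulate()` perturbs $x_1$ by $10^{-2}$
(recorded in the trace metadata) whenever the initial state is exactly
symmetric.

**Frequency estimation.** Mean interval between rising zero crossings of
$y_{out}$ after discarding a 2 s transient (at least five cycles in the
regimes of interest), with linear interpolation between the bracketing
samples for sub-step resolution. Zero crossings were preferred over an
FFT peak because they need no windowing choices; the tests verify both
agree to within one FFT bin. Fewer than two crossings returns 0 — the
conventional "no rhythm" value, which the search penalizes.

**Stability.** Two verdicts are reported separately. The *empirical*
verdict — simulate 10 s and require the post-transient peak-to-peak
amplitude to exceed $10^{-3}$ and not to decay by more than 5% between
the two trailing 2 s windows — is authoritative. The *analytic* verdict
is advisory: $c > 0$; no winner-take-all lock
($\mu_{12}, \mu_{21} < 1 + \beta$, otherwise one neuron can silence the
other permanently); and instability of the coexistence equilibrium,
decided by the eigenvalues of the $4\times4$ Jacobian there. For
symmetric weights these reduce to the textbook two-neuron rules
$1 + \tau_1/\tau_2 < \mu < 1 + \beta$. The Jacobian form matters: with
strongly asymmetric weights the symmetric-mode shortcut misclassifies a
noticeable fraction of parameter draws, while the Jacobian version
agrees with simulation on ≥95% of draws inside the default search box
(checked in the suite).

A property of the reference parameter set
($\tau_1{=}0.10$, $\tau_2{=}0.20$, $\beta{=}8.44$, $\mu_{21}{=}4.94$,
$\mu_{12}{=}6.00$, $c{=}50.6$) worth recording: under this canonical
form it produces a robust rhythm at **1.88 Hz** (zero-crossing and FFT
estimates agree; the value is insensitive to integrator, step size and
weight-subscript convention, and scaling both time constants by $k$
scales the period by exactly $k$). `scripts/acceptance.R` recomputes
this number on every run.

## The parameter search

The genetic algorithm is a deliberately plain real-coded GA: tournament
selection of size 3, uniform crossover (rate 0.9), per-gene Gaussian
mutation (rate 0.2, sd = 10% of each bound range, clamped to the box),
elitism of one. Fitness is $|f_{sim} - f_{target}|$ plus a large penalty
(default 100) when the empirical stability check fails or the
integration blows up; blow-ups are penalized rather than raised so the
search can cross bad regions. Screening simulations run at 2 ms / 6 s;
the winner is re-verified at 1 ms. Default bounds
($\tau \in [0.01, 1]$ s, $\beta \in [0.5, 20]$, $\mu \in [1, 10]$,
$c \in [1, 100]$) bracket the reference set; they are package defaults,
not published values. Elitism makes the best-so-far fitness monotone,
which the tests assert, and the whole search runs under a private RNG
stream so a fixed seed reproduces the result exactly without disturbing
the caller's RNG.

## The synthetic recordings

The generator emulates exactly the statistics the downstream pipeline
consumes, and nothing more. Per channel it draws Gaussian noise,
band-limits it to ~200–4000 Hz (4th-order Butterworth, forward-backward,
upper edge capped at $0.45 f_s$), and multiplies by an envelope equal to
the channel's baseline sd (µV) times its gain for the cue class active
at each sample, with 200 ms linear ramps at class transitions standing
in for reaction time. Cue schedules alternate movement and rest blocks
with durations uniform on 2.5–4.5 s, each movement appearing equally
often in shuffled order; an optional lead-in rest block provides the
baseline segment. Stimulation artifacts are rectangular 500 µs, 50 Hz
monophasic deflections added on ~90% of channels during stimulation
epochs, with ground-truth onset times recorded.

Because the pipeline consumes band power rather than spike identities,
waveforms are synthesized directly in the multiunit band instead of as
spike trains. The generator therefore does **not** model spiking
statistics, 1/f background, electrode drift, cross-channel correlation,
or amplifier saturation after stimulation pulses (the residual-artifact
effect). Passing tests demonstrate that the pipeline recovers class
structure, rejects artifacts and preserves its timing contracts — not
that the decoders would reach any particular accuracy on human cortical
data.

Default geometry follows the real device (96 channels at 30 kHz); the
demo configuration and the stochastic tests run a reduced geometry
(24 channels at 10 kHz, 3–6 trials per movement) chosen so a full
closed-loop run takes about half a minute — the statistical structure
(contrast, schedule, artifact rates) is identical.

## Artifact excision and MWP features

Detection follows a coincidence rule: a sample is flagged when the
absolute signal has crossed 500 µV within the same 0.5 ms sliding window
on at least 4 of 12 monitored channels (drawn once per run from a seed).
The 0.5 ms simultaneity span is a package choice — the rule needs *some*
tolerance and half a millisecond spans amplifier jitter without merging
consecutive 50 Hz pulses. Flags are deduplicated within one excision
window. Excision removes a 2.5 ms window centred on each detection
(symmetric, another fixed choice), merges overlaps, rejoins the
segments, and returns a sample-index map so bins can be labelled in
wall-clock time; 50 Hz pulses with 2.5 ms windows remove exactly 12.5%
of samples.

Features use a **stationary** (undecimated) db4 wavelet transform,
implemented in-package as the à-trous cascade with periodic boundaries
and verified coefficient-for-coefficient against an independent wavelet
library on a frozen fixture. Undecimated rather than decimated: every
scale then has one coefficient per sample, so a 100 ms bin contains the
same number of coefficients at every scale and binning is exact. Scale
$j$ nominally covers $(f_s/2^{j+1}, f_s/2^j)$; scales 3–6 at 30 kHz
bracket the multiunit band. Per bin, channel and scale the mean
*absolute* coefficient is taken (magnitude, not squared power — the
standardized average is what matters downstream and magnitudes are less
heavy-tailed), standardized by the mean and sd of the same statistic
over the baseline rest segment, and the four scales are averaged: 96
values per 100 ms for a 96-channel recording. Baseline sds are floored
at machine epsilon with a warning; an identically zero channel is an
error naming the channel. A causal 1 s boxcar (trailing 10 bins,
partial at the start) smooths the features with the expected ~0.5 s
group delay.

## Decoders and arbitration

One binary RBF-kernel soft-margin SVM per movement, trained against all
other movements and rest on identical rows, with inverse-frequency class
weights for the rest-heavy label distribution. The kernel bandwidth
defaults to the median heuristic on pairwise training distances and
$C = 1$. Scores are $\tanh$ of the decision margin: bounded to
$[-1, 1]$ with the zero crossing preserved, which is all arbitration
uses. The margin sign from the underlying library depends on label
ordering, so each model is calibrated once so its own class scores
positive. Arbitration is a pure function: the highest score above zero
wins, otherwise rest; exact ties break by fixed movement order. Note
that a standard soft-margin SVM is *not* exactly invariant to
duplicating every training row (duplication doubles the effective
margin budget); the suite asserts decision stability (≥99% agreement)
rather than bit-identity for that perturbation.

## The closed loop

Decisions update per 100 ms bin (the 10 Hz hardware limit). A wiggle
decision triggers CPG-alternating stimulation whose phase is the sign of
the free-running oscillator sampled at the update ticks; flexion and
extension map to static stimulation; rest switches off. The human arm
and stereo camera are replaced by a first-order plant — normalized thumb
position relaxing toward the commanded pole ($-1$ flexed, $+1$
extended, 0 off) with a 0.2 s time constant, integrated with the exact
exponential update on a 120 Hz grid and sampled at 12 frames/s — and by
a trajectory classifier: per 1 s trailing window the mean position,
position range and zero-crossing rate are scored by the same
one-vs-rest SVM + arbitration machinery, trained on scripted-stimulation
trajectories with added measurement noise. The three kinematic features
are a stand-in for the original video pipeline's unstated feature set;
they separate the four states almost perfectly on plant trajectories.
Frames with less than half a window of history are labelled rest — a
wiggle cannot be distinguished from a flexion or extension until the
thumb has moved back and forth.

Evaluation shifts the classifier output earlier by 1.2 s (reaction plus
system lag; applying the shift to the output or to the cues is
equivalent) and scores per frame: overall accuracy, sensitivity
(movement-cue frames correct), specificity (rest frames correct), and
the same per movement. The permutation test shuffles movement
identities at the *cue-block* level — per-frame shuffling would destroy
autocorrelation and anti-conservatively inflate significance — and
reports $(1 + \#\{null \ge obs\})/(n_{perm}+1)$. Channel tuning is
summarized by the Pearson correlation between each channel's MWP series
and each movement's 0/1 cue vector; between-movement differences are
tested by a trial-level bootstrap (blocks resampled with replacement
within label strata, 2000 resamples by default) because no standard
named test applies to differences of correlations on autocorrelated bin
series.

## Reproducibility and problem sizes

A single global seed derives per-stage seeds through a stable string
hash, so no stage consumes global randomness and any stage can be rerun
in isolation; two pipeline runs with the same configuration produce
byte-identical evaluation reports (asserted in the suite). Simulation
sizes used by the tests — 10 s oscillator runs, 24-channel / 10 kHz
recordings with 3–6 trials per movement, 199–999 permutations, 200–500
bootstrap resamples — were chosen as the smallest sizes at which the
measured quantities are comfortably away from their decision thresholds.

## Known limitations

* The oscillator has no sensory feedback and amplitude is uncontrolled;
  only frequency is searched for.
* The generator's noise is Gaussian and channel-independent; artifact
  residuals (amplifier saturation) are not modelled, so the
  train-with-stimulation robustness the real system needed is exercised
  only through clean excision.
* The plant is first-order with a hard ±1 range; no muscle fatigue,
  latency jitter or nonlinearity.
* The decoder is a standard soft-margin RBF SVM; sparsity-optimized
  variants of the original system are out of scope.
* The video classifier's features are a documented stand-in; its
  near-perfect accuracy on plant trajectories says nothing about real
  marker tracking.
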