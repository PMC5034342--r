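# neurobypass

A desk-scale, fully testable simulator of an intracortical **neural
bypass** for restoring rhythmic hand movements: cortical multiunit
activity is decoded into movement intent, the intent gates a
central-pattern-generator (CPG) oscillator, and the oscillator drives
alternating neuromuscular electrical stimulation (NMES) of a virtual
thumb. Every stage of the real system — 96-channel 30 kHz recordings,
stimulation-artifact excision, mean-wavelet-power features, one-vs-rest
SVM decoders, decoder-gated stimulation, video-based movement
classification and frame-level statistics — is reproduced in software on
synthetic data, so the whole closed loop can be exercised, measured and
regression-tested without hardware or human recordings.

It is aimed at neural-engineering researchers who want a reference
implementation of this decoding/stimulation stack, and at methods
developers who need a controllable test bed where ground truth (class
structure, artifact times, channel tuning) is known exactly.

## The model

The rhythm generator is the canonical two-neuron Matsuoka half-center
oscillator. Each neuron has a membrane potential `x_i` and an adaptation
variable `v_i`:

    tau1 * dx_i/dt = -x_i - beta * v_i - mu_ji * y_j + c
    tau2 * dv_i/dt = -v_i + y_i
    y_i   = max(0, x_i)
    y_out = y_1 - y_2

with mutual inhibition weights `mu_12`, `mu_21`, self-adaptation gain
`beta`, and shared tonic drive `c`. The rectified outputs of the
extensor (1) and flexor (2) half-centers alternate; the sign of `y_out`,
discretized at the 10 Hz stimulation update rate, selects which muscle
group is stimulated. A constrained genetic algorithm searches the
parameter box for a set whose simulated rhythm matches a target
frequency.

The decoding side bins standardized stationary-db4 wavelet detail
magnitudes (scales 3–6, the multiunit band of roughly 234–3750 Hz at
30 kHz) into 100 ms mean-wavelet-power (MWP) features — one value per
channel per bin — after excising 2.5 ms windows around stimulation
artifacts detected by a 500 µV, 4-of-12-channel coincidence rule. One
RBF-kernel SVM per movement scores every bin in [-1, 1]; the decoder
with the highest score above zero drives stimulation, otherwise the
system rests.

## Worked example

```r
library(neurobypass)

## the reference oscillator parameter set
p <- cpg_params()          # tau1 = 0.10 s, tau2 = 0.20 s, beta = 8.44,
                           # mu21 = 4.94, mu12 = 6.00, c = 50.6
tr <- cpg_simulate(p, duration = 10, dt = 0.001)
estimate_frequency(tr, discard = 2)
#> [1] 1.879779
check_stability(p)
#> CPG stability report
#>   stable (empirical, authoritative): TRUE
#>   empirical amplitude: last 29.19, previous 29.19
#>   analytic (advisory): oscillatory = TRUE (no lock TRUE,
#>   coexistence unstable TRUE, drive TRUE; g = 5.444)

## search for a 1 Hz parameter set instead
res <- cpg_search(cpg_search_config(target_freq = 1.0,
                                    population_size = 30,
                                    generations = 15, seed = 7))
res$verified_freq
#> [1] 0.9995626

## the full closed loop on synthetic data (about half a minute)
out <- run_pipeline(default_config(seed = 1))
print(out$report)
#> Frame-level evaluation (764 frames, 1.2 s lag):
#>   overall accuracy 0.904 | sensitivity 0.839 | specificity 0.965
#>   flexion    acc 0.965  sens 0.780  spec 1.000
#>   extension  acc 0.962  sens 0.734  spec 1.000
#>   wiggle     acc 0.976  sens 0.978  spec 0.976
out$permutation$p_value
#> [1] 0.005
```

The pipeline synthesizes a cued training recording (movement/rest blocks
of 2.5–4.5 s with class-dependent band-power modulation and injected
50 Hz stimulation artifacts), excises the artifacts, extracts MWP
features, trains the decoder bank, and then runs a *held-out* test
recording through decoding, stimulation encoding, the first-order thumb
plant and the trajectory classifier. The report scores the classifier's
per-frame output against the cue schedule after a 1.2 s reaction/system
lag; the permutation p-value compares the observed frame accuracy with
cue-block-shuffled nulls.

## Command line

A thin CLI over the same functions ships in `inst/cli/neurobypass.R`:

```sh
Rscript inst/cli/neurobypass.R cpg-search --target 2.5 --seed 7 --out params.yaml
Rscript inst/cli/neurobypass.R cpg-simulate --params params.yaml --out trace.csv
Rscript inst/cli/neurobypass.R cpg-freq trace.csv --discard 2
Rscript inst/cli/neurobypass.R run --seed 1 --out rundir
```
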