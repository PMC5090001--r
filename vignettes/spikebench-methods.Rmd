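---
title: "Methods: encoders, simulation and metrics in spikebench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoders, simulation and metrics in spikebench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in spikebench, the
parameters that matter, the numerical choices behind them, and what the
synthetic fixtures do and do not establish about real data.

## 1. Rate coding: intensities to Poisson trains

A grayscale image becomes a population of independent Poisson spike
sources, one per pixel. Rates are linear in intensity and normalized so
their sum equals a protocol constant:

$$ r_i = R \cdot \frac{I_i}{\sum_j I_j}, \qquad \sum_i r_i = R . $$

`R` is 2000 Hz in the training protocol and 5000 Hz in the testing
sweeps; both are arguments everywhere. Raw 8-bit values are used as-is
(no gamma): the linearity of the map is the model. Zero pixels emit
nothing; an all-zero image yields an all-zero rate map with a warning
rather than a division error.

Trains are sampled by **exponential inter-arrival times**, not
per-timestep Bernoulli draws, so the encoder has no hidden dependence on
any simulator step. A master seed spawns one Mersenne-Twister substream
per `(image, neuron)` pair (`substream seed = hash(master, image,
neuron) mod 2^31`), which makes any single neuron's train reproducible in
isolation — regenerating neuron 412 does not require regenerating the
other 783. The same convention would not reproduce another toolkit's
trains bit-for-bit (generator and pairing scheme differ); counts and all
rate statistics match any correct Poisson encoder.

Presentation schedules place image `k` (1-based) in the window
`[(k-1)(t_on + t_blank), (k-1)(t_on + t_blank) + t_on)` with silent
blanks; defaults are the protocol's 1000 ms on / 200 ms blank, giving the
duty factor 1/1.2 that appears throughout the event accounting.

## 2. Rank-order coding: DoG filtering plus overlap correction

The retinal front end is four ganglion-cell layers, each a
difference-of-Gaussians kernel

$$ \mathrm{DoG}_w(x,y) = \pm G_{\sigma_{w,c}}(x,y) \mp
   G_{\sigma_{w,s}}(x,y), $$

ON-center layers taking (+, −) and OFF-center (−, +). Each Gaussian is
normalized to unit *discrete* mass on the truncated grid before
subtraction, so the kernel's DC response is ≤ 1e-3 rather than exactly 0.
Defaults: σ_c = 0.8, 1.6, 3.2, 6.4 px with σ_s = 2 σ_c, layers 0–1 ON
and 2–3 OFF, truncation radius `ceil(3 σ_s)`. These scales quadruple
across layers — fine detail in the small layers, blob detectors in the
large ones. They are configuration, not constants: reproducing a specific
published encoder requires substituting its σ table.

**Convolution.** One discrete 2-D convolution per layer (the kernels are
even-symmetric, so convolution equals cross-correlation), zero-padded at
the borders; border coefficients therefore see truncated kernels, which
is documented behavior rather than an artifact to hide. Only positive
responses become spike candidates: emission times must be positive and
value-ordered, and the ON/OFF split carries the two signs.

**Overlap correction.** DoG kernels are not orthogonal, so neighboring
coefficients encode shared information. The greedy pass repeatedly
extracts the global maximum `m`, appends it to the corrected list, and
subtracts `m · Q(m, c)` from every remaining coefficient whose kernel
overlaps, with

$$ Q(m, c) = \frac{\langle K_m \,\text{shifted}, K_c\rangle}
                  {\langle K_m, K_m \rangle}. $$

Normalizing by the *selected* coefficient's kernel energy makes each step
an exact matching-pursuit update: `value / ⟨K, K⟩` is the amount of
kernel present in the residual, and the same amplitude is used when
stamping kernels back for reconstruction. Whether the published encoder
normalizes symmetrically instead is unresolved; the asymmetric choice is
the one that makes the subtraction an exact residual update, which is why
we adopted it. `Q` tables are computed once per bank by FFT
cross-correlation and verified in the tests against direct inner
products.

Numerical choices: exact value ties select the lowest `(layer, y, x)`
(full determinism); the loop runs until every coefficient has been moved,
as specified, with an optional early-stop floor (`value_floor`) under
which the remainder is flushed unadjusted; coefficients driven negative
by the correction stay in the corrected list as bookkeeping but are never
emitted as spikes, and the default reconstruction drops them for the same
reason — the spike code transmits only the positive ranks.

**Emission.** Corrected coefficients are sorted descending; the top 30%
(configurable) fire one spike each at `rank × 1 ms`. A continuous
`t ∝ 1/value` variant is available (`timing = "inverse"`) since emission
time is, in the underlying model, inversely proportional to coefficient
value; the ranked 1 ms grid is the default because it matches the
published raster convention and downstream tooling.

**Reconstruction quality** is compared by mean-squared error after the
MSE-minimizing affine rescaling of the reconstruction onto the image's
intensity scale (`reconstruction_mse`). A min–max rescale is available
for display but is dominated by single extreme pixels and therefore not
used for comparisons. On every fixture digit the corrected
reconstruction beats the uncorrected one; the test suite asserts exactly
that, and no more.

## 3. LIF simulation

Membrane dynamics follow

$$ \tau_m \frac{dV}{dt} = (V_{rest} - V) + R_m I_{syn}(t),
   \qquad R_m = \tau_m / C_m , $$

with a spike when `V ≥ V_thresh` at a step boundary, reset to `V_reset`,
and an absolute refractory period during which the membrane is clamped.
Units are ms / mV / nF / nA (so R_m is in MΩ); delta-synapse weights are
charges in pC (`ΔV = w / C_m`).

The integrator is the **exact exponential propagator** per step — for
exponential-current synapses the two-exponential closed form, for
delta-current an instantaneous kick followed by exact decay — so the only
discretization effect is threshold detection at step boundaries: each
inter-spike interval is lengthened by at most one step. The suite checks
free decay against the closed form at 1e-9 and the constant-current rate
against
`f = 1 / (τ_refrac + τ_m ln((R_m I + V_{rest} − V_{reset}) /
(R_m I + V_{rest} − V_{thresh})))`
within 2% over a 10-point sweep at dt = 0.1 ms, with currents chosen so
the per-ISI quantum stays inside that tolerance.

Defaults (τ_m = 20 ms, V_rest = V_reset = −65 mV, V_thresh = −50 mV,
C_m = 0.25 nF, τ_refrac = 1 ms; exponential synapse τ_syn = 5 ms for the
template classifier, delta synapses for the feed-forward evaluator) are
biologically conventional placeholders: a published network's exact
tables must be substituted for bit-level reproduction. dt defaults to
0.1 ms for training and 1 ms for throughput runs; spikes travel one step
between populations.

**STDP** is pair-based, additive, nearest-neighbor (each post spike pairs
with the latest earlier pre spike, each pre with the latest earlier
post), clamped to `[0, w_max]`. Nearest-neighbor was chosen over
all-pairs for boundedness; simultaneous spikes do not pair. The default
amplitudes (a+ = 0.003, a− = 0.0018 nA, τ± = 20 ms, w_max = 0.03 nA) are
sized from the membrane arithmetic: a saturated ~150-pixel template
sharing a 2000 Hz input puts its decision neuron near threshold
(`w_max · R · τ_syn · R_m ≈ 15 mV`), so firing stays template-dependent
instead of saturating for every stimulus.

**Teaching signal.** A 50 Hz Poisson source attached to one decision
neuron through a delta-current projection whose single-spike charge is
1.5× the rest-to-threshold distance, forcing one output spike per
teaching spike (less the ~5% lost to refractory collisions at 50 Hz).
The delta projection is used even on exponential-synapse populations
precisely so teaching spikes map 1:1 onto forced spikes; a slow EPSP
would merge close teaching spikes and blur the supervision.

**Training loop.** Decision neurons are trained independently, one at a
time, on their own subclass's images — the template protocol, not a
competitive network. Weight updates are applied at presentation
boundaries: each image is simulated with frozen weights and the pair rule
is then applied to the collected spike trains. With the teaching signal
dictating the post spikes, within-presentation feedback of the weight
change is negligible, and the batch update makes a 300 ms presentation
one simulator call. Whether images are presented in fixed or shuffled
order is unstated in the protocol; shuffled (seeded) is the default.

## 4. The testing network and event accounting

`weak_to_inhibitory` freezes training and replaces every weight below a
threshold with one fixed negative value. "Weak" and the common strength
are protocol-open; defaults are threshold = 10% of w_max and magnitude =
the mean of the replaced weights, both exposed. Each input neuron then
projects to every decision neuron twice — the excitatory and inhibitory
halves of the signed matrix are two dense projections — so one input
spike generates exactly `2 n_dec` inter-layer synaptic events; with 100
decision neurons that is the ×200 multiplier the event accounting is
built on.

Sopbs counts one operation per spike per outgoing synapse and divides by
biological time. Decision-layer spikes, which have no outgoing synapses,
count one event each (their delivery to the recorder/readout), matching
the convention in which the output layer contributes the 0.1–1.5%
residual on top of the input-layer term `2 n_dec R_in / 1.2`. Blank
windows are silent but remain in the denominator: event rates average
over the full duty cycle, while classification ignores blank-window
spikes. Ties in the max-count readout go to the lowest neuron index (and
are counted); a seeded random tie-break is available.

Latency is first-output minus first-input spike per trial window; trials
with no output are excluded and counted, and the summary reports both the
excluded-mean and a convention scoring excluded trials at the full window
length. Negative latencies (output before any input — possible in
principle with background drive) are reported with a warning, not
clamped.

## 5. Fixed-point evaluation and the surrogate network

Qm.f quantization maps to the grid `2^-f` with round-half-even (base R's
`round`), saturating at `[−2^(m−1), 2^(m−1) − 2^-f]`; rounding toward
zero is available since the hardware convention is unstated. The
round-half-even choice bounds the non-saturating error at `2^(-f-1)`.

The published deep networks' weights are external artifacts that
`read_layered_weights()` loads from `.npy` files. The shipped
**surrogate** is deliberately synthetic and conventionally trained:
layer 1 holds k-means sub-centroid matched filters, layer 2 pools each
class's templates with positive random weights, and the readout pools
class units. Each layer's summed afferent weight is calibrated so its
mean drive is a small multiple (default 2) of the leak rate at threshold
`(V_thresh − V_rest)/τ_m` — layer 1 analytically from the input rate,
deeper layers from rates measured by simulating the stack — keeping every
layer stimulus-dependent rather than silent or saturated, and keeping all
weights inside the Q3.8 range so precision sweeps measure resolution
loss, not saturation. An earlier least-squares readout was rejected: its
signed weights achieved their margin by fine cancellation that collapsed
at low weight precision and under rate changes, which is not a property
of the generatively trained networks the harness emulates.

## 6. Synthetic fixtures: what they do and do not show

`generate_digits` renders seven-segment-style stroke glyphs at 28×28 with
affine jitter (translation sd = `jitter` px, rotation sd = 0.03·jitter
rad, scale sd = 0.02·jitter) and additive Gaussian pixel noise (sd 8 on
the 0–255 scale by default), deterministic under the seed. At generation
a held-out one-vs-all ridge linear probe estimates separability; below
95% the set warns. The default 3-class tasks use digits {1, 2, 5}: in
idealized glyph geometry some digit pairs are strict stroke *subsets* of
others (1's strokes are a subset of 0's), an artifact real handwriting
does not share, and subset pairs make the max-rate readout ill-posed
regardless of training quality; {1, 2, 5} avoids subset relations while
keeping shared strokes.

Passing the fixture tasks shows the *protocols* work — templates form
under STDP, the readout classifies linearly separable spike-coded
classes, event accounting and latency trends behave as the model
predicts. It does not show MNIST-level accuracy: fixture classes are far
cleaner than handwriting, and the published full-scale accuracies require
the real IDX files plus hours of biological time. That recipe is:
`load_mnist_idx()` on a local MNIST copy, `kmeans_subclasses(K = 10)`
over the 60 000 training images, `train_case1` at 300 ms per image
(18 000 s biological), `weak_to_inhibitory`, then `test_case1` over the
10 000-image test set (12 000 s biological) — a long-running job best
driven from a script, not a test.

Problem sizes used by the shipped checks were chosen to exercise every
code path at desk scale: the event-accounting run uses 500 decision
neurons (50 subclasses × 10 digits, k-means over 600 synthetic images)
and 20 presentations — the input-layer fan-out term dominates Sopbs at
any presentation count, so 20 windows already estimate it to a fraction
of a percent; the classification benchmark uses 3 classes with a
200/100 train/test split and K = 2; oracle-equivalence checks for the
greedy correction run on instances up to 16×16, where the brute-force
re-scan is still fast.

## 7. Known limitations

- AEDAT 3.x / AEDAT4 containers are out of scope; only the 1.0/2.0
  dialects are implemented, and the DVS128 bit layout is a configurable
  assumption.
- The simulator is clock-driven and dense; it is sized for hundreds of
  neurons at desk scale, not for event-driven sparse efficiency.
- Ring-buffer saturation and membrane-potential quantization — hardware
  effects that depress accuracy on fixed-point platforms — are not
  modelled; only weight quantization is.
- The FoCal σ table and the LIF parameter tables of specific published
  networks are configuration placeholders until replaced with the
  published values; encoder outputs are structurally, not bit-level,
  comparable.
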