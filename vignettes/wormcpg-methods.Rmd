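---
title: "Methods: a connectome-constrained neuromuscular network for C. elegans locomotion"
author: "wormcpg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a connectome-constrained neuromuscular network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wormcpg)
```

## The model

*Caenorhabditis elegans* crawls by propagating a dorsoventral bending wave
along its body: head to tail for forward locomotion, tail to head for
reversal.  The wave is produced by 95 body-wall muscle cells arranged in
four longitudinal rows (left/right × dorsal/ventral), innervated by 69
ventral-cord motor neurons of seven classes — the cholinergic excitors DA,
DB, VA, VB and AS and the GABAergic inhibitors DD and VD.  Locomotion
direction is selected by command interneurons: PVC and AVB drive forward
movement, AVA, AVD and AVE drive reversal.

`wormcpg` models this circuit as a discrete-time recurrent network.  Each
cell (neuron $i$ or muscle $u$) carries a current $x(t)$ and emits a
logistic output $y(t) = 1/(1+e^{-x(t)})$.  One step of duration
$F_s = 0.05$ s updates

$$
x_i^N(t+1) = \frac{1}{1+F_s\tau_i}\,x_i^N(t) + \frac{F_s\tau_i}{1+F_s\tau_i}
\Big\{ \textstyle\sum_j w^{NN}_{ij} y^N_j + \sum_u w^{MN}_{iu} y^M_u
+ \sum_j g^{NN}_{ij}\,(x^N_j - x^N_i) + \sum_u g^{MN}_{iu}\,(x^M_u - x^N_i)
+ \sum_p w^{IN}_{ip} L_p + w^{l0}_i \Big\}
$$

and analogously for muscles, which receive neuron output through
$w^{NM}$, electrical coupling through $g^{MN}$ (shared with the neuron
equation) and $g^{MM}$, and a bias $w^{l1}$.  Gap junctions are symmetric
($g_{ij}=g_{ji}$, no self-coupling) and pass current proportional to the
difference of the membrane variables.  The command input $L(t)$ is binary:
four forward lines at 1 and six backward lines at 0 during forward epochs,
reversed during backward epochs, with half-open epochs delimited by the
switch times of a `command_schedule()`.

A note on the update constants: the lag factor uses the product
$F_s\tau$ — decay $1/(1+F_s\tau)$ and drive gain $F_s\tau/(1+F_s\tau)$ —
with $F_s$ treated as a fixed dimensionless step constant and 0.05 s used
for time bookkeeping.  An alternative discretisation would use
$\Delta t/\tau$ in those factors; the two differ only in how $\tau$ is
scaled, and this package fixes the $F_s\tau$ form throughout.  Initial
currents are zero (outputs 0.5) unless the caller supplies a state; the
update is synchronous (all time-$(t{+}1)$ values computed from time-$t$
values).

### Proprioceptive feedback

Stretch-sensitive input is modelled, without a body, by feeding muscle
activity back to the A- and B-class neurons: each B-class neuron receives
up to $S = 7$ muscles *posterior* to it, each A-class neuron up to $S = 7$
muscles *anterior*, on both rows of its side, clipped at head and tail.
There is no canonical neuron-to-segment correspondence across the seven
classes (their counts differ), so the package anchors each neuron by
linear interpolation of its class-local rank onto the 24 body segments —
the $r$-th of $R$ neurons in a class sits at segment
$\mathrm{round}(24r/R)$; the feedback entries
live inside the single muscle→neuron weight matrix (mask `syn_mn`), so no
pathway is counted twice.

### Connectivity

Structure is a boolean mask per weight matrix: a weight can be nonzero
only where the mask allows, and masked entries are exactly zero before,
during and after training.  Masks come either from real adjacency tables
in the wormwiring dialect (`load_adjacency()`; cells outside the model are
dropped with a count, gap counts are symmetrized with a warning if
asymmetric) or from `synthesize_connectome()`, which reproduces the
qualitative circuit: cholinergic classes excite muscles of their side and
the D-class; DD/VD inhibit muscles and cholinergic neurons; connections
are local within `locality_span` body segments; gap junctions chain
consecutive neurons within a class, couple near-anchored neuron pairs,
couple each neuron to the muscles at its anchor segment, and chain
neighbouring muscles along each row, which lets activity propagate
longitudinally.  Forward command lines reach the B classes, backward lines
the A classes.  With all densities at 1 (the default) the synthetic mask
is deterministic.

## Teacher data

Two generators produce the target muscle activation $d_u(t)$:

**Analytic travelling wave** (`analytic_teacher()`).  Dorsal muscles
follow $\sin(\omega t + \phi_q)$ and ventral muscles
$\sin(\omega t - \pi + \phi_q)$ (dorsoventral antiphase), with
$\omega = 1.6\pi$ rad/s and initial phase $\phi_q = -2\pi q/24$ falling
head to tail, i.e. one body wavelength travelling forward.  At every
command switch $T_v$ the phase is replaced by
$\pi - 2\omega T_v - \phi$, which time-reverses the wave without a jump
in value (the identity $\sin(\omega T_v + \phi_{new}) =
\sin(\omega T_v + \phi_{old})$ holds exactly).  Because muscle outputs are
sigmoids confined to $(0,1)$, the raw sine is affinely rescaled to
$[0.25, 0.75]$ by default — without this the evaluation function has a
large unattainable floor.  Left and right rows receive identical targets
(planar crawling on agar).

**Emulated fluorescence recording** (`emulate_measured_teacher()`).
Stands in for calcium imaging of a GCaMP-expressing strain, for which no
public recording is deposited.  Per body segment and side it synthesizes a
fluorescence trace on a fine imaging grid — one forward wave cycle
followed by one backward cycle, per-segment response amplitudes jittered
by `amp_heterogeneity`, additive Gaussian sensor noise `noise_sd` (both
expressed relative to the response amplitude; defaults 0.2 and 0.05 are
plausible for single-worm epifluorescence but are *choices*, as the
original noise statistics are unreported) — converts it to rates
$R = (F - F_0)/F_0$ with $F_0$ the per-trace minimum, smooths each cycle
with an $n = 8$ sum of sinusoids, concatenates the fitted cycles to three
repetitions, maps the 24 segments onto the four muscle rows (the
23-cell right-ventral row simply lacks segment 24) and normalizes each
muscle trace to $[0.25, 0.75]$.

The sum-of-sines smoother (`fit_sum_of_sines()`) fits
$c + \sum_{i=1}^n a_i \sin(\omega_i t + \varphi_i)$ by variable
projection: for any candidate frequency set the offset and sin/cos
coefficients are solved linearly, and the frequencies are optimised
quasi-Newton from the top-$n$ spectral peaks within the Nyquist band —
deterministic, no random restarts.  The constant offset is a deliberate
extension of the pure sine sum: fluorescence rates have a nonzero mean,
which pure sines can only represent through a degenerate near-zero
frequency.  Fitting is per cycle (forward and backward separately): a
single stationary sine sum cannot represent the derivative kink at the
phase reversal, whereas each half is a clean sinusoid, which is also how a
"trim one cycle, fit, then concatenate" pipeline naturally operates.

With noise and heterogeneity at zero the emulated teacher reproduces the
analytic wave to machine precision *after both are normalized per muscle
trace*; the analytic teacher's default fixed rescale and min/max
normalization differ by up to $1-\cos(\pi/25)\approx 0.8\%$ because the
0.05-s grid misses the sine extrema, so equivalence checks normalize both
sides identically.

What a green teacher test establishes: the generator has the travelling
wave, reversal, antiphase, amplitude heterogeneity and noise features it
claims.  What it does not establish: that real HBR4 recordings look like
this in detail — bleaching trends, motion artefacts, segmentation errors
and non-Gaussian shot noise are all absent.

## Training

`train_network()` minimises the evaluation function

$$E = \frac{1}{T}\frac{1}{U}\sum_{t=1}^{T}\sum_{u=1}^{U}
\tfrac12\,\{y_u^M(t) - d_u(t)\}^2$$

by exact backpropagation through the fully unrolled recursion
(`bptt_gradients()`, compiled): gap-difference terms, the shared
neuron–muscle gap matrix, proprioceptive entries, biases and the lag
constants $\tau$ all receive analytic gradients, and each symmetric gap
pair is one tied parameter whose gradient sums both directions.  The
finite-difference oracle (`fd_gradient()`) is the primary correctness
gate: on random small instances every parameter family matches central
differences to $10^{-5}$ relative error.

Constraints are enforced by projection (clipping) after every update
rather than by reparameterisation — projection keeps exact zeros, which
the sparsity analysis relies on: excitatory synaptic columns clipped to
$\ge 0$, inhibitory to $\le 0$, conductances and lags to $\ge 0$, gaps
re-symmetrized, masked entries re-zeroed.  Initial parameters are uniform
draws in the stated ranges (excitatory $[0,1]$, inhibitory $[-1,0]$,
muscle-to-neuron/command/biases $[-1,1]$, gaps $[0,1]$,
$\tau \in [0, 0.01]$), and training stops when $E \le 0.005$.

**Optimizer.**  BPTT fixes how gradients are computed, not how parameters
are updated.  Plain gradient descent is impractical here: with $\tau \sim 10^{-2}$ at
initialization the drive gain $F_s\tau/(1+F_s\tau) \approx 2.5\times
10^{-4}$, so the circuit starts two orders of magnitude too sluggish to
oscillate at $\omega = 1.6\pi$, and $\tau$ must travel to $O(10{-}100)$
before the loss surface rewards oscillation at all.  The default is
therefore adaptive per-parameter scaling (Adam-style, rate 0.1, moment
decays 0.9/0.99) with three safeguards that matter in practice for this
stiff saturating system: global gradient-norm clipping; rewind-on-blow-up
(if an iteration's $E$ exceeds twice the best seen, or the state goes
non-finite, or $E$ freezes exactly for 25 iterations — the signature of a
saturated attractor with vanishing sigmoid slope — parameters rewind to
the best seen, the step halves and the moments restart); and an end-game
step decay once $E$ is within 4× of tolerance.  Plain GD and momentum
remain available via `training_config(optimizer=)`.

At full size (69/95, 600 steps) training converges in roughly 3 000–6 500
iterations (a few minutes on one CPU).  Within the $E \le 0.005$ budget a
trained model may leave a handful of muscles flat (the anterior muscles
in particular — consistent with the nerve-ring innervation the model
deliberately lacks); this is visible in reduced circuits, where a
muscle row has so few cells that a flat one can spoil direction
estimates.

## Wave-direction readout

`wave_direction()` quantifies what the activity kymographs show: within a
time window it measures per-muscle phase as accumulated
consecutive-muscle cross-correlation lags (robust to total phase spans
exceeding one period), excludes the head-most third of segments (eight of
24 at full size; those muscles are nerve-ring territory), drops muscles
below an amplitude floor, and reports the sign of the phase-vs-segment
slope: `head_to_tail`, `tail_to_head`, or `undetermined`.  Epochs shorter
than one oscillation period are rejected, which constrains reduced
protocols: scaling the switch times compresses epochs but the wave period
does not scale, so the reduced verification schedule keeps its last epoch
at least one period long.

## Weight-distribution analysis

`pool_weights()` pools $|w|$ over structurally allowed connections across
trials — synaptic source: neuron→neuron, neuron→muscle, muscle→neuron and
command weights; conductance source: unique unordered gap pairs — into 20
equal-width bins (configurable).  Exact zeros are excluded: the fitted
law diverges at zero strength and describes the strength of *existing*
connections.  `fit_modified_boltzmann()` then fits

$$p(w) = A\,\frac{e^{-\beta (a|w|)}}{(a|w|)^{1-1/n}}$$

to the mean frequencies with $n$ fixed to the structural connection count.
Numerical facts worth knowing:

* Only $C$ (scale) and $\lambda = \beta a$ are identifiable; $A$, $a$ and
  $\beta$ are reported under the convention $a = 1/\overline{|w|}$.
* The scale is profiled out exactly (the model is linear in it) and
  $\lambda$ is found by a deterministic log-grid scan seeded by a
  log-domain linear pre-fit, then polished quasi-Newton.  A single
  pre-fit start can land in a degenerate basin ($\lambda \to 0$ or
  $\infty$); the grid makes the fit reliable without randomness.
* `method = "density"` (default) evaluates the density at bin centres —
  the conventional frequency-vs-strength fit and the one whose $R^2$ is
  reported.  `method = "mass"` integrates the density over each bin
  (incomplete-gamma form); for data *sampled* from the law it is the
  consistent estimator, because for large $n$ the $w^{1/n-1}$ singularity
  concentrates the mass near zero and centre densities are badly biased
  there.  For $n$ in the hundreds, $10^4$ samples put essentially
  everything into the first bin and *no* estimator recovers $\lambda$
  from the binned counts — an information limit, not a fitting defect;
  recovery properties are therefore tested at moderate $n$.

On trained full-size models (three to five trials pooled) the fit attains
$R^2 \approx 0.95$–$0.97$ for synaptic weights and $\approx 0.99$ for
conductances.  This is descriptive: it says the trained strengths are
compatible with a sparse, Boltzmann-type distribution, not that real
synaptic strengths follow it.

## Reproducibility and scale

`run_experiment()` chains mask → teacher → $n$ trials → verification →
residual summary → weight-distribution fits with every stage seeded from
one master seed; rerunning a config reproduces every output file hash.
Reduced circuits (`neuron_index_map(n_segments)`) keep the seven-class
architecture with proportionally scaled class sizes and are used
throughout the test suite to keep runtimes in seconds; the full-size
model is exercised by the acceptance suite.  All serialization is plain
text (JSON/CSV).

## Known limitations

* No body, no agar mechanics: gait adaptation through real proprioception
  is outside the model, as in the source.
* The polarity assignment (cholinergic excitatory, GABAergic inhibitory)
  is conventional, not experimentally confirmed per connection.
* The emulated recording is a stated stand-in; its noise model is not fit
  to data.
* Head muscles are expected to fail to oscillate — the nerve-ring motor
  neurons that drive them are deliberately excluded.
* Identifiability: training recovers a *function* (muscle activation
  pattern), not the true weights; weight-level claims are restricted to
  distributional shape.
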