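---
title: "Perturbing a sampling-based observer and its circuit implementation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbing a sampling-based observer and its circuit implementation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gsmring` implements two parallel perturbation experiments on a
sampling-based account of perceptual inference in early visual cortex, and
the dynamical analyses that connect them.

At the **computational level**, the observer's world model is a Gaussian
scale mixture (GSM) of oriented features: an image patch is

$$ x = z\,A y + \varepsilon, \qquad y \sim \mathcal N(0, C), \quad
   z \sim \mathrm{Gamma}(k_z, \theta_z), \quad
   \varepsilon \sim \mathcal N(0, \sigma_x^2 I), $$

where the columns of $A$ are oriented Gabor filters, $y$ are feature
intensities with a rotation-symmetric prior covariance $C$, and $z$ is a
global contrast variable that scales the reliability of the evidence.
Perception is cast as posterior inference over $y$; a *hypoprior* — the
hypothesis advanced for autistic perception — is a chronically broadened
prior, implemented exactly as $C \mapsto \alpha C$ with $\alpha = 1.5$.

At the **circuit level**, a stochastic excitatory–inhibitory ring network
with a supralinear transfer function represents the posterior by sampling:
the stationary distribution of E-cell membrane potentials stands for the
posterior over feature intensities (latent $i$ ↔ E cell $i$). The second
perturbation is an inhibitory deficit: all inhibitory synaptic columns are
scaled by $1-\delta_I$, followed by homeostatic scaling of the excitatory
columns by $1-\delta_E$ chosen by grid search to restore the baseline
(spontaneous) activity level.

The package's claim-level output is a set of sign comparisons: the
hypoprior raises posterior means and posterior uncertainty at every
positive contrast, and the compensated inhibitory deficit raises response
variability, gamma-band LFP power, and transient onset peaks — two
different levers with the same perceptual signature.

## The ideal observer

Conditionally on contrast, the GSM posterior is Gaussian and exact:

$$ \Sigma(z) = \left(C^{-1} + \tfrac{z^2}{\sigma_x^2}A^\top A\right)^{-1},
   \qquad \mu(z) = \Sigma(z)\, \tfrac{z}{\sigma_x^2} A^\top x. $$

At $z = 0$ the code returns $(0, C)$ literally — the posterior *is* the
prior at zero contrast, and the identity holds bitwise, which the tests
assert. Contrast is marginalized by quadrature: $p(z \mid x)$ is evaluated
in log space on a grid (80 log-spaced points on $[10^{-3}, 12]$ by
default, covering the effective support of the default
$\mathrm{Gamma}(2,1)$ prior), using one eigendecomposition of $A C A^\top$
so each grid point costs $O(\text{rank})$; the mixture moments follow by
the law of total variance. Correctness is established against independent
dense-grid quadrature over $y$ (relative error $\le 10^{-6}$ on 3-latent
instances) and against a 10×-finer $z$ grid ($\le 10^{-3}$).

The one-dimensional conjugate toy model (prior variance $C = 4$, feature
weight $A = 10$, noise variance $\sigma_x^2 = 100$) treats $z$ as known,
so contrast indexes likelihood precision; its closed-form curves are
cross-checked by scalar quadrature. At $z = 1$, $x = 10$: posterior mean
0.8 and SD 0.894 under the true prior versus 0.857 and 0.926 under the
$\alpha = 1.5$ hypoprior.

**Gabor bank defaults** (unspecified upstream): isotropic Gaussian
envelope $\sigma = \mathrm{side}/5$, cosine carrier of wavelength
$\mathrm{side}/2$, zero phase, mean-corrected, unit-norm columns. All
columns are exact rotations of one template on the pixel grid, which the
tests verify by explicit image rotation. **Prior kernel**: Gaussian in
wrapped orientation distance (period 180°), width 25°, variance 1. All
ring kernels in the package are periodized over the circle (sum over ±2
wrap-around images); the bare min-distance Gaussian is not positive
definite for wide kernels, the periodized one always is. **Pixel noise**
$\sigma_x^2 = 0.25$ puts the signal-to-noise ratio of a unit-contrast
patch near 3, so the default contrast range $\{0, 0.25, 0.5, 1, 2, 4\}$
spans prior-dominated to likelihood-dominated inference.

## The stimulus stage

Inputs are self-generated. The deterministic evaluation bank renders, for
each (orientation, contrast), the noiseless patch $z\,A y^\*$ with $y^\*$
a positive wrapped-Gaussian bump of feature intensities (width 20°,
height 2) centred on the nominal orientation; positive intensities keep
the mean-ordering claims well-posed, and zero-contrast rows are exactly
zero (the spontaneous-activity stimulus). `make_training_sample()` draws
from the full generative model with $z$ from the gamma prior, retaining
the latent records; its marginal pixel covariance
$E[z^2] A C A^\top + \sigma_x^2 I$ is a test oracle.

What the generator deliberately does not emulate: natural-image structure
beyond the GSM (occlusions, phase alignments, $1/f$ spectra), eye
movements, or any stimulus dynamics. Passing tests therefore demonstrate
internal consistency of observer and network under the model's own
statistics, not fit to natural scenes.

## The stochastic ring network

Membrane potentials follow

$$ \tau_i\,\dot u_i = -u_i + h_i + \sum_j W_{ij}\, r_j + \eta_i, \qquad
   r_j = k \lfloor u_j \rfloor_+^{\,m}, $$

integrated by Euler–Maruyama (compiled code; R's RNG, so trajectories are
bit-reproducible given parameters, seed, and step). The threshold-power
rate keeps rates real and nonnegative for negative potentials. $\eta$ is
an Ornstein–Uhlenbeck input with a ring-kernel spatial covariance
(correlation width 60°, half the covariance shared across cells) and
correlation time 5 ms.

*Why 5 ms and not a slower noise process*: the gamma-band comparison
requires the resonance near 20–50 Hz to be fed by the input fluctuations.
An OU process with a 50 ms correlation time has a 3 Hz cutoff and
essentially no power left at gamma frequencies; with such noise the
measured band power *falls* as contrast moves the resonance up in
frequency, inverting the contrast–gamma relation the analyses are about.
5 ms (32 Hz cutoff) keeps the band fed while still being a colored,
correlated process; it is a plain parameter (`noise$tau_ms`) for anyone
who wants the slow-noise regime.

**Connectivity.** E–I pairs sit on a ring of preferred orientations;
every block of $W$ is a circulant Gaussian kernel of wrapped orientation
difference, row-normalized so the block amplitude $J$ is the total
synaptic weight a neuron receives from that block — the mean-field
dynamics are then independent of `n_pairs` (32 by default, seconds-scale
simulations). Dale's principle is enforced structurally and asserted.

**Default operating regime.** The upstream description leaves amplitudes,
widths, gains and noise open. The defaults —
$J = (1.65, 0.75, 2.50, 0.90)$ for (E→E, I→E, E→I, I→I), widths
$(30°, 75°, 30°, 75°)$, $\tau_E/\tau_I = 20/10$ ms, $k = 0.3$, $m = 2$,
feedforward gains $(0.15, 0.026)$ with baselines $(1.6, 1.3)$, noise SD
1.6 — were fixed by a design search against the qualitative phenomena the
pipeline must exhibit simultaneously: (i) stable stochastic dynamics over
the whole contrast bank and under the deficit sweep; (ii) per-cell
response variability that *decreases* with contrast; (iii) gamma-band LFP
power that *increases* with contrast, with an in-band spectral peak when
driven; (iv) a spontaneous state in which scaling down the excitatory
columns lowers activity (required for the homeostatic grid search to have
an interior solution — strongly inhibition-stabilized spontaneous states
behave paradoxically under that scaling and push the compensation to the
boundary); and (v) narrow E projections with broad I projections, the
standard orientation-selective-amplification arrangement. These are the
package's own calibration constants, set once; `calibrate()` exists to
re-fit them against observer targets.

**Feedforward path.** Drive is $h = b + \lfloor W^{\mathrm{ff}} x
\rfloor_+$ with $W^{\mathrm{ff}}$ the observer's own Gabor bank (each
pair filters the patch with its preferred-orientation feature), a
rectifying nonlinearity, and a constant baseline that represents
stimulus-independent input; the baseline alone is the zero-contrast
drive.

## Calibration

Training the full network by moment-matching backprop is out of scope
(and noted as expensive upstream); `calibrate()` is a desk-scale
substitute: derivative-free search over a low-dimensional log-parameter
vector, with every loss evaluation using common random numbers so the
simulated-moment loss is a deterministic, smooth function of the
parameters. The loss is the squared mismatch of per-stimulus stationary
E-cell mean potentials plus $\lambda\times$ the SD mismatch. The default
engine is Nelder-Mead (the kernel-parameter landscape has curved,
correlated valleys that defeat pure coordinate descent); a Hooke-Jeeves
pattern search with random diagonal probes is available as a second
engine. Both are monotone in the accepted iterate.

*What the loss identifies.* E-cell moments pin down the two recurrent
amplitudes E cells receive — $J_{EE}$ and $J_{EI}$ — sharply. The
I-side parameters are close to unidentifiable from E-cell moments alone:
raising the inhibitory drive gain $J_{IE}$ while raising the I-cell
self-inhibition $J_{II}$ (or trading $J_{EI}$ against $J_{II}$) leaves
the inhibition delivered to E cells almost unchanged, so the loss has
flat valleys along which those parameters drift by tens of percent at
near-floor loss values. The parameter-recovery experiment in the
acceptance suite therefore calibrates $(J_{EE}, J_{EI})$: with targets
generated by a known 32-pair ring, driven stimuli only (the spontaneous
bump wanders, which roughens the loss), and initial values perturbed by
±20%, the search recovers both amplitudes to within 10% and drives the
loss below twice the common-random-number noise floor in ≲150
evaluations at reduced simulation length (4 s per stimulus, 20 ms
thinning). Calibration evaluations default to 30 s per stimulus
(`calib_sim_cfg()`), the protocol for fitting to observer targets.

## The inhibitory deficit and homeostasis

`scale_inhibition()` multiplies the inhibitory columns by $1-\delta_I$
(exactly, preserving signs and zero pattern); `scale_excitation()`
mirrors it on the excitatory columns; composition order is inhibition
first. The homeostatic cost $\mathcal C_h(\delta_E) = |\mu_s^{NT} -
\mu_s^{ASD}|$ is evaluated on a grid from 0 to $\delta_I$ in steps of
0.002 with one refinement (step/5) around the coarse argmin, under a
fixed-seed spontaneous protocol (zero-contrast drive, 10 s, common random
numbers across the grid so the cost curve is smooth).

$\mu_s$ is the mean spontaneous **E-cell membrane potential** by default.
The rationale is the sampling semantics itself: at zero contrast the
stationary distribution of $u_E$ represents the prior over feature
intensities, so "maintaining the baseline level of activity" means
maintaining the represented prior's baseline. It also matters
dynamically: in this kernel family, compensating on mean *rates* returns
$\delta_E \approx \delta_I$ — a nearly uniform shrink of $W$ that leaves
variability and gamma power unchanged or reduced, erasing the phenomena
under study — whereas compensating on potentials gives
$\delta_E = 0.020/0.042/0.066$ for $\delta_I = 0.05/0.10/0.15$:
monotone, strictly smaller than the deficit, and leaving the network
genuinely disinhibited at fixed baseline. A rate-based $\mu_s$ (and an
all-cells variant) remain as switches on `spontaneous_protocol()`.

## Response analyses

All analyses are pure functions of stored trajectories and settings.

- **Stationary moments**: per-cell mean and SD of $u$ and $r$ from
  samples every `thin` ms after burn-in; the reference protocol is
  20,000 samples 200 ms apart, and desk-scale runs thin at 20 ms over
  20 s (the vignette's and the tests' problem size).
- **LFP**: unweighted across-cell average potential (all cells by
  default; an E-only switch exists because the upstream definition is
  ambiguous).
- **Spectra**: Welch averaged periodogram, 1 s Hann windows, 50%
  overlap, per-segment mean removal, one-sided density normalized so the
  integral matches the variance (checked via Parseval to 2%).
- **Gamma statistics**: the peak is the largest local maximum strictly
  inside 20–80 Hz (monotone spectra have none — that is a value, not an
  error; ties go to the lower frequency); band power is the trapezoidal
  integral over 20–80 Hz.
- **Transients**: per trial, each E–I pair's drive switches from baseline
  to stimulus at onset plus a truncated-Gaussian delay (mean 45 ms, SD
  5 ms, truncated at 0, inverse-CDF sampling; shared within the pair,
  redrawn per trial); the mean E-cell rate across trials is smoothed
  with a 10 ms moving average and its post-onset maximum reported.
  The reference trial count is 100 (the acceptance script's setting);
  unit tests use 12–15 trials with common random numbers.
- **Input decomposition**: time-averaged recurrent excitatory input and
  inhibitory input magnitude per E cell, the quantity behind the
  paradoxical-effect check (the compensated deficit network shows
  *larger* mean inhibitory input at high contrast despite 10% weaker
  inhibitory synapses — rates rebalance upward).

## Numerical choices and degenerate inputs

Integration step 0.2 ms (enforced $\le \min\tau/10$); halving the step
moves stationary means by less than the Monte-Carlo error (tested).
Divergent trajectories raise an error naming the first bad time and
neuron rather than returning NaNs; unstable calibration candidates return
a large finite penalty instead. `fixed_point()` is damped-Euler
warm-started Newton with step halving and a $10^{-10}$ residual
postcondition; on the symmetric ring under uniform drive the bump
position is nearly marginal, so equilibrium checks pin the bump with an
oriented stimulus. Zero-width kernels, non-PD covariances, negative
contrasts, Dale violations and shape mismatches all error early with
specific messages.

## Known limitations

- The network is not trained to match the observer quantitatively; means
  and SDs agree in ordering and shape across contrast, not in scale.
  Full moment-matching training of the original work is explicitly out
  of scope.
- The LFP is a mean potential, not a biophysical field model; gamma
  statistics are therefore comparative, not quantitative predictions.
- The deterministic ring under uniform drive breaks symmetry into a
  bump; analyses always use oriented stimuli or the noisy regime, where
  this is immaterial.
- Orientation-anisotropy effects (e.g. the oblique effect) are outside
  the model by construction: every kernel is rotation symmetric.
- Sign-test conclusions are established at desk scale (32 pairs, tens of
  seconds of simulated time, fixed seeds); they are reproducible under
  the shipped seeds and stable across the seeds we tried, but they are
  Monte-Carlo statements, not proofs.
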