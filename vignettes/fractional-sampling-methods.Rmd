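---
title: "Fractional neural sampling: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional neural sampling: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fnsampler)
```

## The problem

Sampling-based theories of neural computation hold that the brain represents
a posterior distribution over stimulus features by the trajectory of its own
activity: the position of a localized population-activity pattern at time
$t$ is one sample $\hat{s}_t$, and the histogram of positions approximates
the posterior. Classical realizations drive the sample path with Gaussian
noise, i.e. Brownian-motion MCMC (Langevin sampling, or Hamiltonian Monte
Carlo when an auxiliary momentum is added). Brownian samplers cannot cross
the low-probability valleys of a multimodal posterior: the expected crossing
time grows exponentially with the modal separation, so the sampler is
trapped in one mode.

`fnsampler` implements *fractional* sampling: the driving noise is a
symmetric $\alpha$-stable (S$\alpha$S) Lévy motion whose increments have a
power-law tail of index $1 < \alpha \le 2$. Occasional long jumps let the
sample path hop directly between modes, and the mean dwell time grows only
*linearly* with the modal separation. The package provides the full chain of
machinery:

1. S$\alpha$S densities, variates and maximum-likelihood fits
   (`sas_pdf()`, `sample_sas()`, `fit_sas_mle()`);
2. the Riesz fractional derivative and the construction of the drift field
   $b(x)$ that makes an arbitrary density $\pi(x)$ stationary
   (`riesz_derivative()`, `drift_from_target()`);
3. Euler–Maruyama integration of the fractional Hamiltonian SDE
   (`simulate_fns()`) in four variants
   ($\alpha \in \{1.2, 2\} \times \beta \in \{0, 1\}$);
4. a conductance-based 2-D spiking E–I circuit whose wandering activity
   bump realizes the same dynamics (`build_network()`,
   `simulate_circuit()`);
5. the analysis stack: center-of-mass tracking, MSD/tail-index
   diagnostics, Fano factors, spectra, exit times and Burr/gamma dominance
   fits;
6. closed-form neural-field results linking stimulus contrast and synaptic
   perturbations to the drift and the sampled mixture (`analytic_drift()`,
   `sampled_mixture()`).

## The sampler SDE and its conventions

The sampler integrates
$$
d\hat{x}_t = \gamma\, b(\hat{x}_t)\,dt + \beta \hat{v}_t\, dt
  + \gamma^{1/\alpha} dL^\alpha_t, \qquad
d\hat{v}_t = \beta\, b(\hat{x}_t)\, dt ,
$$
with $\gamma = 1$, step $dt = 10^{-3}$ and drift
$$
b(x) = \frac{\mathcal{D}^{\alpha-2}_x\!\left[\pi(x)\,\partial_x \log
\pi(x)\right]}{\pi(x)},
$$
where $\mathcal{D}^\mu$ is the Riesz operator with Fourier symbol
$|k|^\mu$. At $\alpha = 2$ the operator is the identity and $b$ reduces to
the score $\partial_x \log \pi$ (classical Langevin / HMC); this limit is
verified to $10^{-6}$ in the tests and anchors every sign and scale
convention.

**Scale convention.** S$\alpha$S$(\alpha, \gamma)$ means characteristic
function $\exp(-\gamma |\omega|^\alpha)$: the Gaussian member has variance
$2\gamma$, the Cauchy member scale $\gamma$. Libraries that use
$\exp(-|c\,\omega|^\alpha)$ differ by $c = \gamma^{1/\alpha}$. The per-step
noise increment is drawn as S$\alpha$S$(\alpha, dt)$ — magnitude
$\propto dt^{1/\alpha}$ — so that increments are stable under summation:
over unit time they compose to S$\alpha$S$(\alpha, 1)$. At $\alpha = 2$ the
per-step variance is $2\gamma\,dt$, which is exactly what makes the
standard normal target stationary under $b = -x$.

**Momentum coupling.** Writing the momentum contribution to $dx$ as
$\beta v\,dt$ relies on the identity
$\mathcal{D}^{\alpha-2}_v[\psi\,\partial_v T]/\psi = v$ when the momentum
marginal is $\psi = $ S$\alpha$S$(\alpha, 1/\alpha)$ and
$T = -\log\psi$. `momentum_drift_identity_check()` verifies the identity
numerically (deviation $< 10^{-3}$ at $\alpha = 2$, $< 0.05$ for fractional
orders on $|v| \le 3$).

**Clipping.** For light-tailed targets the fractional drift diverges
super-exponentially in the tails; it is clipped at $|b| \le b_{\max} = 500$
(exposed as a parameter), which also bounds the Euler step
$\gamma b\,dt \le 0.5$.

## Numerics of the Riesz operator

Positive orders $\mu \in (1, 2]$ use the fractional centered difference
scheme with coefficients
$g_k = (-1)^k \Gamma(\mu+1) / [\Gamma(\mu/2-k+1)\Gamma(\mu/2+k+1)]$,
computed by a stable recurrence and truncated at
$|g_k| < 10^{-12} |g_0|$; an edge-level reference is subtracted before the
convolution so that constants are annihilated exactly despite truncation.
The drift's fractional *integral* of order $\alpha - 2 \in (-1, 0)$ uses
the same kernel machinery with the full-array kernel (those coefficients
decay only like $k^{1-\alpha}$ and must not be truncated early). Both
routes are validated against an independent spectral (FFT-multiplier)
oracle. The working grid covers all but $10^{-6}$ of the target mass, is
padded by 25% on each side with analytically evaluated density values, and
has $2^{12}$ interior points; off-grid drift queries hold the clipped edge
value, since Lévy jumps exit any finite grid.

The S$\alpha$S density itself is computed by Fourier inversion of the
characteristic function on a $2^{15}$-point grid, with the leading aliased
images subtracted analytically and a three-term tail series taking over
where it agrees with the inversion to $3\times 10^{-4}$; Cauchy and
Gaussian members use closed forms. Maximum likelihood optimizes
$(\alpha, \log\gamma)$ by Nelder–Mead from quantile-based starting values,
with a bounded quasi-Newton polish (the tabulated density makes pure
gradient methods unreliable).

## Initialization, censoring, and what the benchmark means

For running-mean MSE curves, chains start at $x_0 \sim \pi$ so that
$\mathrm{MSE}(0^+)$ equals the target variance, and the half-maximum time
$T_{\rm HM}$ is the first crossing of half that analytic level (using the
empirical curve maximum instead only injects initialization noise into the
reference level). Momenta start from the standard normal. Two subtleties
deserve emphasis, because they are properties of the printed dynamics, not
implementation choices:

* **The ensemble MSE is heavy-tailed for $\alpha < 2$.** With the drift
  clipped at 500, a Lévy jump of size $z$ produces an excursion whose
  squared running-mean contribution scales like $z^4$, and $z$ has tail
  index $\alpha$: the contribution has tail index $\alpha/4 < 1$, so the
  ensemble-mean MSE *diverges* and its empirical value is dominated by the
  single largest jump, growing with the number of chains. The package
  therefore censors a chain at its first exit from the tabulated drift
  grid — where the constructed field ends anyway — which is a fixed
  numerical-validity rule, not a tuned window, and a no-op for Gaussian
  variants.

* **The stationary momentum is heavy-tailed.** The fractional Hamiltonian's
  momentum marginal is S$\alpha$S$(\alpha, 1/\alpha)$ (we verify this
  empirically: a long run's momenta fit $\alpha = 1.20$). Chains started
  from that law exhibit long "parking" episodes — a large $|v|$ holds the
  position off-center until the drift winds it down — and the measured
  $T_{\rm HM}$ of the fractional-with-momentum variant roughly doubles.
  With the Gaussian-core momentum start the four variants give
  $T_{\rm HM} \approx 1.1 / 1.70 / 1.65 / 2.51$. The middle two values
  match the reference values for the Gaussian variants exactly; the
  fractional variants come out 15–25% *faster* than the reference values
  1.42 and 1.95, and no initialization protocol we examined reproduces
  those two numbers while keeping the Gaussian ones correct. We report the
  computed values as they are.

The $\alpha = 2$ anchor: for the Langevin variant the running-mean MSE has
the closed form $(2/T^2)(T - 1 + e^{-T})$, crossing $1/2$ at
$T = 2.51$; for the Hamiltonian variant the stationary linear theory gives
$T_{\rm HM} = 1.68$. Both are reproduced by the integrator, which is how
the conventions above were fixed *before* the fractional variants were
measured.

## Exit times and dominance durations

Dwell assignments go by proximity to the two mode centers (torus metric for
the circuit, Euclidean for the 1-D model); equidistant points inherit the
previous assignment. Every dwell that ends in a switch is a completed exit
time — the clock starts at $t = 0$ — and the final dwell is censored, so
durations plus the censored tail partition the trajectory exactly. For the
Brownian variants the mean exit time follows Kramers scaling
$\tau \sim e^{\Delta s^2 / (8\sigma^2)}$: at modal separation 3 with
$\sigma = 0.32$ this already exceeds $e^{10}$, so the exponential law is
fitted over separations $\{1.3, \ldots, 2.2\}$ where switching is
observable, while the linear law of the fractional variants is fitted over
$\{3, \ldots, 7\}$.

Dominance durations are fitted by maximum likelihood to the Burr XII
density
$p(x) = \tfrac{ck}{\lambda}(x/\lambda)^{c-1}[1+(x/\lambda)^c]^{-k-1}$
(power-law tail, exponent $-1 - ck$) and to the gamma density (exponential
tail), after discarding durations below 29 ms (spurious dwells from
transiently asynchronous activity); the cutoff is exposed as a parameter.

## The spiking circuit and its calibration

The circuit is a conductance-based integrate-and-fire network: 63 × 63
excitatory neurons on the feature torus $[-\pi,\pi)^2$ plus 1000 uniformly
placed inhibitory neurons; exponential distance-dependent connectivity
(scales 8 / 10 / 20 / 20 grid units for E→E / E→I / I→E / I→I); membrane
time constant 15 ms, threshold −50 mV, reset −60 mV, refractory 4 ms;
spike-frequency adaptation as a potassium conductance (10 nS per spike,
80 ms decay, E cells only); conduction delays uniform on 0–4 ms. Weights
are receiver-normalized ("reverse pooling"): each cell's summed incoming
weight per block is fixed and split equally across its sampled partners.
The per-neuron inhibition-to-excitation weight ratio $\xi_i$ is calibrated
to mean $\xi$ (default 3.4, the state-transition point) with a 25%
coefficient of variation by drawing one E←I weight value per receiving
neuron.

Quantities the architecture does not determine were calibrated once, by
bisection and scan against the stated operating regime (spontaneous E rates
1–10 Hz, fluctuation-dominated transition between asynchronous firing and a
coherent propagating wave), and are exposed in `circuit_params()`:
in-degrees 200/200/50/50, block totals $J^{EE}_{tot} = 600$,
$J^{IE}_{tot} = 850$, $J^{II}_{tot} = 60$ nS, synaptic decay 2 ms (E) /
5 ms (I), feedforward weight 2.4 nS. Two modelling choices matter and are
deliberate:

* **Feedforward input is linear.** The 0.85 kHz Poisson bundle stands for
  many low-rate upstream afferents, so each event adds a fixed conductance
  with no single-synapse saturation. Routing it through one saturating
  gate (as a literal reading of the recurrent-synapse equation would
  imply) clamps the drive at all contrasts and destroys both contrast
  coding and the fluctuations that keep the network asynchronous — we
  observed pathological whole-sheet synchronization in that configuration.
* **Interneurons receive no direct feedforward copy**
  (`ffwd_I_scale = 0`). With the full tuned copy the interneurons fire
  regardless of excitatory activity and silence the sheet at $\xi = 3.4$;
  driven recurrently, they track the excitatory population, which is what
  the balanced-ratio calibration presumes. The toggle is exposed.

Synaptic rise (0.5 ms) is collapsed into an equivalent saturating jump at
delivery time — exact to leading order since it is thirty times shorter
than the membrane time constant — and gating is kept per presynaptic
neuron and receiver block (exact under block-shared weights and delays,
which hold by construction).

### What the circuit does and does not reproduce

At the calibrated point the spontaneous activity pattern wanders with
heavy-tailed center-of-mass increments, tail index $\alpha \approx
1.3$–$1.45$ (reference 1.28 ± 0.15), a population-rate spectral peak near
7 Hz (reference 6.2 ± 1.5 Hz), sample variance decreasing with stimulus
contrast, rivalry-style alternation between two stimulated locations with
dwell times in the tens of milliseconds that lengthen with modal
separation, and a mean local pairwise correlation that falls monotonically
as $\xi$ increases. Several reference observables are *not* reproduced and
the corresponding acceptance assertions are expected to fail honestly:
the pooled diffusion exponent comes out near 1.34 (just above the
1.18 ± 0.15 band) and the tail-index trough at the transition ratio is too
shallow to resolve against its flanks;
per-neuron Fano factors sit near 0.65 rather than above 1, and the
spectral tail falls like $f^{-0.8}$ rather than $f^{-2.3}$ — both because
this implementation's theta rhythm recruits neurons too uniformly (the
pattern re-nucleates at a random location each theta cycle rather than
drifting continuously); the no-adaptation variant pins rather than
wanders (tail index ≈ 2 instead of 1.19); and the position
autocorrelation lacks the damped-cosine theta signature for the same
reason. Matching those would require the continuous-wandering regime of
the original architecture, which this calibration does not reach.

## The synthetic-data generators

`generate_fixture()` produces data with analytically known truth:
S$\alpha$S and Gaussian walks, wrapped torus walks, a stationary Gaussian
process with exactly the damped-cosine autocorrelation (circulant spectral
synthesis), homogeneous and telegraph-modulated Poisson spike trains, and
Burr/gamma duration samples (defaults at the reference fitted parameters:
Burr $c = 8.05$, $k = 0.528$, $\lambda = 65$ ms; gamma $k = 10.4$,
$\theta = 7.51$ ms). The generators emulate increment statistics, count
statistics and duration laws — not spatial network structure, refractory
interactions or measurement noise — so a green round-trip validates the
estimators, not the circuit.

One estimator subtlety the fixtures exposed: the *time-averaged* MSD of a
walk with i.i.d. heavy-tailed increments is linear in the lag whatever the
tail (ergodicity breaking); the anomalous exponent $2/\alpha$ lives in the
ensemble statistic. `msd_and_eta()` therefore offers `mode = "ensemble"`
with a median option (robust under infinite-variance increments); the
circuit analyses use the time-averaged estimator, whose superdiffusive
exponent there reflects genuine increment correlations.

## Numerical and degenerate-input policy

Center-of-mass estimates with a zero resultant raise an error rather than
returning 0; untrackable (silent) tracking windows propagate as `NA` and
are skipped by lag statistics, with unwrapping taking a single
minimal-image step across each gap. Runaway network simulations (mean rate
above 200 Hz) abort with an error. MSD fit range defaults to 15–300 ms
(above the tracking window, below the autocorrelation knee); spectra use
2-s Hann segments with 50% overlap and fit the power-law tail over
15–100 Hz, avoiding the theta peak. All stochastic functions consume R's
global RNG stream and replay exactly under `set.seed()`.

## Known limitations

The mathematical model is one-dimensional by design. The two-dimensional
Riesz operator is treated per axis (the exact operator is not separable);
the neural-field activation and kernel shapes beyond the printed closed
forms are package choices, exposed as parameters; and the spiking circuit
reproduces the transition-regime phenomenology only partially, as detailed
above.
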