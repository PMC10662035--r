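---
title: "Bragg reflection and seagrass pattern formation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bragg reflection and seagrass pattern formation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Seagrass meadows in wave-exposed, micro-tidal seas (the western Mediterranean
is the motivating setting) develop strikingly regular spatial patterns —
bands and hexagonal gap arrays — whose wavelength is close to **half** the
wavelength of the most energetic incoming surface waves, over depths from a
few metres to 25 m. Half-wavelength periodicity is the signature of **Bragg
resonance**: a wave travelling over a periodic medium is maximally reflected
when its wavelength is twice the pattern period. This package implements a
one-horizontal-dimension model of the feedback loop that could create such
patterns:

1. wave-induced bed shear stress raises seagrass mortality;
2. seagrass builds bed elevation ("matte"), so mortality modulations become
   topographic modulations;
3. topographic modulations Bragg-reflect the incoming wave, and the partially
   standing wave imposes a stress pattern — closing the loop.

The package has four computational layers: linear wave theory and wave-climate
analysis, the spatially uniform equilibrium of the coupled system, a
pseudo-spectral simulator of the linearized perturbation dynamics, and
diagnostics (spectra, growth rates, reflection coefficients).

# Wave climate and the half-wavelength relation

Linear wave theory supplies everything the climate layer needs. The
dispersion relation $\sigma^2 = g\kappa\tanh(\kappa H)$ is solved by Brent
root-finding on an analytic bracket; under a conserved period it can be
rewritten as the shoaling fixed point
$\lambda = \lambda_\infty \tanh(2\pi H/\lambda)$ with
$\lambda_\infty = gT^2/(2\pi)$. Bed shear stress uses the standard quadratic
friction law $\tau_b = \tfrac12 \rho f_w U_b^2$ with
$U_b = \pi H_s / (T \sinh \kappa H)$.

```{r}
library(braggrass)
round(shoal_wavelength(180, c(2, 7)))    # 10.7-s swell into 2-7 m of water
round(shoal_wavelength(168, c(7, 25)))   # 10.4-s swell into 7-25 m
```

Because no wave-reanalysis archive ships with the package, the climate layer
is exercised end to end with a synthetic generator: log-normal peak periods
(defaults tuned so the 99th percentile is near 10.4 s), and significant
heights following a power law in the period with log-normal scatter so that
the highest-stress records are long-period swell. From a climate series the
pipeline selects the records at or above the 0.99 quantile of $\tau_b$
(type-7 quantiles, ties kept), shoals each record's deep-water wavelength
over a depth grid (default 1–30 m in 0.25-m steps), and compares the
2.5/50/97.5% wavelength envelope with *twice* the observed pattern
wavelengths. The observation generator plants patterns at exactly half the
shoaled wavelength plus multiplicative noise, so the recovery test is
by construction a consistency check of the pipeline, not evidence about real
meadows; what passing it shows is that every transformation in the chain is
implemented coherently.

# The coupled model

Water is an ideal fluid with velocity potential $\phi(x, z, t)$ and surface
$\eta(x, t)$; the Laplace equation holds in the fluid, with the linearized
Bernoulli and kinematic conditions at $z = 0$ and a kinematic condition at
the bed. Seagrass density $n(x, t)$ obeys

$$\partial_t n = -\omega n + \alpha n^2 - \beta n^3 + \delta\,\partial_{xx} n,
\qquad \omega = \omega_b + \omega_c \tau_b,$$

and the bed sits at depth $H = h - s\,n$: the topography coefficient $s$
converts density to matte elevation. The bed stress uses the trailing
one-wave-period average of the squared bottom velocity.

Because matte modulations are small compared with the depth, fields are
expanded about a uniform basic state: a monochromatic linear wave of
amplitude $a$ over the uniform meadow $n_0$, plus perturbations
$(\phi_1, \eta_1, n_1)$. The basic state is closed-form except for the
self-consistency between $n_0$, the meadow-raised depth $H_0 = h - s n_0$
and the stress at that depth; the package solves the per-capita growth rate
$R(n) = -\omega(\tau_{b0}(n, a)) + \alpha n - \beta n^2$ for its root by
bracketed bisection between the bare state and the calm-water density. (A
damped fixed-point iteration was tried first and abandoned: near the
bifurcation its map leaves the root's basin and falsely reports a missing
branch.) With weak facilitation the vegetated branch connects continuously
to $n_0 = 0$ at the closed-form transcritical amplitude

$$a^* = \frac{\sinh(\kappa_h h)}{\sigma}
\sqrt{\frac{-2\omega_b}{\rho f_w \omega_c}},$$

below which the bare state is invadable and above which it is the only
(stable) uniform state. This is the branch topology observed for the default
parameter set; it is not asserted for arbitrary $(\alpha, \beta, \omega_c)$,
where a fold can precede $a^*$.

## Perturbation dynamics

The perturbation hydrodynamics are linear:
$\partial_t\phi_{1s} = -g\eta_1 - \gamma\phi_{1s}$ and
$\partial_t\eta_1 = w_{1s} - \gamma\eta_1$, with $\gamma(x)$ the sponge
profile. The vertical structure is solved exactly per Fourier mode by the
flat-strip Dirichlet-to-Neumann map; the seagrass bed enters as a bottom
normal velocity

$$w_b = s\,\partial_t n_1 + \partial_x\!\left(s\,n_1 u_{0b}\right),$$

the standard small-ripple transfer of the bottom condition to the flat level
$z = -H_0$, in flux form so the domain integral vanishes. The stress
perturbation is the leading cross term of the quadratic law,
$\tau_{b1} = 2\rho f_w \langle u_{0b} u_{1b}\rangle$ over a trailing-period
circular buffer. The $n_1$ equation keeps its nonlinear facilitation and
competition terms (so growth can saturate) and is advanced every hydrodynamic
step with a morphological acceleration factor $M$.

Numerics: Fourier collocation in $x$ (periodicity is admissible because the
sponges force the wave fields to zero at the ends), classical RK4 at
$dt = T/128$ for the wave fields, forward Euler with step $M\,dt$ for $n_1$,
quadratic sponge ramps of width $2\lambda$ with $\gamma_{max} = 1\,s^{-1}$
(packet tests show returned amplitude below $10^{-3}$), white-noise $n_1$
initialization with interior rms $10^{-4} n_0$, zero in the sponges, and a
5-period hydrodynamics-only spin-up that establishes the scattered wave and
fills the stress buffer before the biological clock starts. The $k = 0$ mode
of the strip map uses its analytic limits; the Nyquist mode is dropped from
odd derivatives. Total density is clipped at zero (i.e. $n_1 \ge -n_0$) with
a warning if clipping touches more than 10% of the interior.

# Default study conditions and how they were chosen

All defaults are stated in `seagrass_params()`, `sim_config()` and
`default_pattern_config()`; the choices below were fixed once, from physical
reasoning plus explicit measurement of the model's feedback gain, and define
the package's reference conditions.

* **Wave and site**: $T = 8$ s over $h = 10$ m (intermediate depth,
  $\kappa h \approx 0.9$), seawater density 1025 kg m⁻³, friction factor
  $f_w = 0.05$.
* **Biology**: rates are expressed in s⁻¹ at a $10^{-4}$ scale
  ($\omega_b = -10^{-4}$ s⁻¹), with $M = 1000$ bringing the effective rates
  to order 0.1 per wave period so that the linear onset completes within the
  25-period observation window. $M$ deliberately stays at 1000: at
  $M \gtrsim 3000$ the accelerated bed-motion term radiates at frequencies
  approaching the wave band and excites a spurious triad resonance near
  $0.5\kappa$ (verified time-step-convergent and attributed by term
  switches) — the morphological acceleration must keep bed rates far below
  wave rates.
* **Facilitation/competition**: $\alpha, \beta$ are set so the calm-water
  density is 1 and facilitation is weak
  ($\alpha = 0.05, \beta = 1.05$ at the $10^{-4}$ scale). Weak facilitation
  matters: the local recovery rate of the uniform meadow,
  $2\beta n_0^2 - \alpha n_0$, then falls toward zero as forcing approaches
  $a^*$, which is what lets the measured reflection feedback gain overcome
  local decay. With strong facilitation/competition (e.g. $\alpha : \beta =
  3 : 2$ at order one) the local decay exceeds the attainable Bragg gain
  everywhere below $a^*$ and no modulation instability exists.
* **Topography**: $s = 2$ m per unit density — a 2-m matte under the calm
  meadow, well within the several-metre range built by long-lived meadows;
  at the pattern-forming states ($n_0 \approx 0.2$) the uniform matte is
  ~0.4 m and its modulations are centimetres, so the small-amplitude
  expansion holds comfortably.
* **Stress coupling**: $\omega_c = 2.5\times10^{-5}$ Pa⁻¹s⁻¹, giving
  $a^* \approx 0.51$ m.
* **Domain**: interior of 20 forcing wavelengths. The Bragg gain grows with
  patch length; at 10 wavelengths the measured gain stays below the local
  decay and patterns never emerge, at 20 the instability window is
  comfortably wide.
* **Reference amplitude**: $a = 0.96\,a^*$, inside the modulation-instability
  window and where the Bragg mode dominates the spectrum cleanly.

# What the model reproduces, and its limitations

Under the reference conditions, 25 periods of coupled integration turn seeded
white noise into a pattern whose interior spectrum peaks at
$\kappa_{n1}^* = 2\kappa$ (within one spectral bin) and whose crest spacing
is $0.50\lambda$; the scattered wave is leftward-travelling (verified by a
directional mode split), and the pattern migrates against the waves. Growth
rates are measured operationally as $\ln(A(25T)/A(0))/25$ at the bin nearest
$2\kappa$ — the same window-limited definition used to draw the
growth-rate diagrams this package emulates. With that definition the
threshold sits at $a_{MI} \approx 0.32\,a^*$ for the default set; the
threshold's existence and ordering $0 < a_{MI} < a^*$ are the robust
statements, while its numerical ratio depends strongly on the biological
parameters and domain length and is **not** treated as a reproducible
quantity.

Freezing the grown topography and scanning the forcing wavenumber yields a
reflection curve $K_R(\kappa)$ — with $K_R$ the envelope-maximum estimator,
the maximum over interior nodes of the final-period envelope of $|\eta_1|/a$ —
that peaks exactly at $\kappa = \kappa_{n1}^*/2$, falls by an order of
magnitude a few percent off resonance, and scales linearly with the pattern
amplitude (halved and doubled copies bracket the reference curve). Because
the solver is linear in the perturbation, the amplitude scaling is exact by
construction; the informative content of the scan is the resonance location
and selectivity.

Known limitations, stated plainly:

* The instability is convective: patterns grow while migrating toward the
  up-wave sponge, and beyond the ~25-period window the domain-integrated
  mode amplitude decays again as the pattern is absorbed. All acceptance
  diagnostics therefore address the linear onset, not long-time saturation.
* At intermediate amplitudes ($\sim 0.4$–$0.9\,a^*$) long-wavelength
  envelope modes compete with the Bragg mode and can dominate the raw
  spectrum; the reference amplitude was chosen where selection is clean.
* The $K_R$ estimator conflates standing-wave structure with reflected
  amplitude (it measures envelope maxima, not a directional decomposition);
  it is retained because it is the reference definition.
* One horizontal dimension only; no canopy drag or wave damping; no
  sediment transport; fully nonlinear free-surface dynamics out of scope.
* The synthetic climate emulates only the marginal distributions of a
  reanalysis record (no storm clustering or seasonality), so climate-layer
  tests validate the pipeline's mathematics, not any specific sea.

# Problem sizes

The reference coupled run uses 1536 nodes (24 wavelengths at 64 nodes per
wavelength), 128 steps per period and 30 periods including spin-up; it takes
a few seconds on one core. The reflection scan runs 7 frozen-topography
simulations to dynamic equilibrium (interior envelope drift below 1% per
period over 5 periods), and the threshold bisection about 10 coupled runs.
These sizes were chosen so the full analysis suite completes on a laptop in
minutes while keeping at least 64 nodes per wavelength and the domain- and
resolution-independence checks (halved $dt$, doubled $N_x$, longer domains)
within 2%.
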