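---
title: "Channel noise by diffusion approximation: models, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel noise by diffusion approximation: models, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channoise)
```

## The problem

Ion channels are discrete stochastic devices. In a membrane patch carrying
`N` identical channels the conductance is proportional to the fraction of
channels in the conducting state,
$$ g(t) = \gamma N\, z(t) / A = \bar g\, z(t), $$
and `z` fluctuates because individual channels open and close at random.
These fluctuations — *channel noise* — make small neurons fire
spontaneously below rheobase, smooth the deterministic type-II f–I
discontinuity, shape spike-time reliability, and leave a characteristic
signature in the subthreshold voltage power spectrum. Simulating them
exactly requires Monte-Carlo tracking of channel states, which is costly;
`channoise` implements an effective (diffusion) approximation that
reproduces the exact statistics at a fraction of the cost, together with
the exact simulator and the classical Fox–Lu comparator so that every
claim about accuracy can be checked within the package.

## Channel models

A single channel is a continuous-time Markov chain over `M` conformational
states with gating-variable-dependent transition rates and exactly one
conducting state. Two representations are supported:

* **Composed** ([`channel_scheme()`]): products of independent 2-state
  subunits, the Hodgkin–Huxley structure. The sodium channel is
  $m^3 h$ — an 8-state ladder over (number of active $m$ subunits,
  $h$ state); potassium is $n^4$, a 5-state ladder. Rates come from four
  parametric families ([`rate_law()`]) covering the classical
  expressions; the `linexp` family evaluates its removable singularity
  ($0/0$ at one voltage) by a guarded series so no `NaN` can appear.
* **General** ([`general_scheme()`]): an arbitrary state list with a
  user-supplied rate-matrix builder. All kinetic analyses and voltage
  clamp accept these; see *Limitations* for current clamp.

The modelling assumptions inherited from the underlying theory:
channels are identical and independent; one conducting state; `N` is
large enough for the Gaussian (de Moivre–Laplace) limit of the binomial
open-channel count; Markov gating; and the gating variable changes slowly
relative to channel kinetics.

## Stationary statistics of the open fraction

At a frozen gating point the open fraction has mean $p_\infty$ (the
stationary occupancy of the conducting state) and autocovariance a sum of
$M-1$ decaying exponentials,
$$ C(t) \;=\; \sum_{i} \sigma_i^2\, e^{-t/\tau_i},
   \qquad \sum_i \sigma_i^2 = \frac{p_\infty (1-p_\infty)}{N}. $$

For composed schemes the pairs $\{\sigma_i^2, \tau_i\}$ follow from the
product of per-subunit 2-state autocovariances, expanded multinomially:
a term indexed by exponents $k_j \le q_j$ has
$$ \sigma_{(k)}^2 = \frac{1}{N} \prod_j \binom{q_j}{k_j}
   x_{\infty,j}^{2(q_j-k_j)} \left[x_{\infty,j}(1-x_{\infty,j})\right]^{k_j},
   \qquad \frac{1}{\tau_{(k)}} = \sum_j \frac{k_j}{\tau_j}, $$
giving 7 terms for $m^3h$ and 4 terms for $n^4$ (with
$\tau = \tau_n/\{1,2,3,4\}$). For general schemes the same pairs come from
the eigendecomposition of the rate matrix: $\tau_i = 1/|\lambda_i|$ and
weights from the spectral projection of the conducting-state indicator.
Both routes are implemented independently and are required by the test
suite to agree term by term and to satisfy the binomial conservation
identity to $10^{-10}$ relative — this identity is the package's central
invariant. Schemes with complex relaxation eigenvalues (oscillatory
covariance) and defective matrices are rejected explicitly rather than
approximated, as the exponential-mixture form does not hold for them.
Terms whose variance contribution falls below $10^{-15}$ of the total are
pruned; ties in $\tau$ are merged; the canonical term order is decreasing
$\tau$ (ties: decreasing $\sigma^2$) so spectra compare deterministically.

## The three stochastic backends

**Microscopic** (exact): the occupancy count of every state is tracked;
each step, the number of channels leaving a state towards each neighbour
is a multinomial draw with probabilities `rate * dt` (realised as
sequential conditional binomials — statistically identical to per-channel
uniforms at a cost that scales with states, not channels). Counts are
conserved exactly. Validity requires `sum(exit rates) * dt < 1`
everywhere; voltage-clamp runs additionally enforce the stricter
accuracy guard `< 0.1`. Because exit probabilities are linear in `dt`,
the simulated fast-term covariance carries an $O(dt)$ truncation error —
visible as a percent-level power deficit in the fastest spectral bands at
`dt = 0.01` ms, which is why converged reference runs use `dt = 0.005`.

**Effective** (the diffusion approximation): deterministic subunit gates
$x_j$ plus one zero-mean Ornstein–Uhlenbeck process per spectrum term,
$$ z = \prod_j x_j^{q_j} + \sum_i \zeta_i, $$
with $(\sigma_i, \tau_i)$ refreshed every step from the *instantaneous*
gating point (the slow-gating assumption) before the OU update. The OU
update is the exact conditional law,
$$ \zeta \leftarrow \zeta\, e^{-\Delta t/\tau} +
   \sigma \sqrt{1 - e^{-2\Delta t/\tau}}\; \xi, $$
valid for any step size; a first-order Euler variant exists for
comparison and carries a $+\Delta t/(2\tau)$ relative variance bias
(0.5 % at $\Delta t = 0.01\tau$). Each OU term has its own stream of
normal deviates drawn from the single seeded RNG, so runs are
reproducible bit for bit. A **reduced** variant collapses the sum to one
OU term with the total variance and the tangent-matching time constant
$\tau = \sum_i \sigma_i^2 / \sum_i (\sigma_i^2/\tau_i)$ (a least-squares
alternative is available); it preserves the stationary variance exactly
and the covariance shape only approximately.

**Fox–Lu** (comparator): white noise added to each gating-variable ODE
with covariance $(\alpha(1-x) + \beta x)/N\,\delta(t-t')$, gates clipped
to $[0,1]$, conductances formed as $m^3h$, $n^4$. For a single 2-state
gate this is equivalent to the effective model (both give variance
$x_\infty(1-x_\infty)/N$ and a single-exponential ACF), but powers and
products of noisy gates do not reproduce multi-subunit statistics: the
package's tests verify the classical failure directions — potassium
$n^4$ variance overestimated (ratio ≈ 2.3 at −35 mV, N = 360), sodium
$m^3h$ variance underestimated (ratio ≈ 0.29 at N = 1200) — and a larger
ACF mismatch than the effective model's.

## Membrane integration

The single-compartment current balance
$$ C_m \dot V = I_{ext} - g_L (V - E_L) - \sum_c \bar g_c\, z_c (V - E_{rev,c}) $$
is advanced by forward Euler (default `dt` = 0.01 ms; 0.001 ms for
pulse-latency protocols where sub-millisecond jitter matters), while
deterministic gates use the exponential (Rush–Larsen) update
$x \leftarrow x_\infty + (x - x_\infty) e^{-\Delta t / \tau_x}$ —
unconditionally stable and exact at frozen voltage. All backends share
this deterministic core and add their noise on top of it, so zeroing the
noise makes every backend reproduce the deterministic trajectory
*exactly*; this by-construction equivalence is what the noise-off
regression test asserts. The membrane area is the lateral cylinder
surface $\pi d L$ (end caps excluded, the convention of compartmental
simulators), and $\bar g = \gamma N / A$ links single-channel and
macroscopic conductances consistently across backends.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| $C_m$ | 1 µF/cm² | canonical squid-axon value |
| $g_L$, $E_L$ | 0.3 mS/cm², −54.387 mV | canonical; rest ≈ −65 mV |
| $E_{Na}$, $E_K$ | 50, −77 mV | canonical modern convention |
| rate laws | 1952 squid set | the standard $\alpha_m, \beta_m, \ldots$ |
| $\gamma$ | 20 pS | with the densities below, recovers $\bar g_{Na} = 120$, $\bar g_K = 36$ mS/cm² |
| densities | 60 (Na), 18 (K) µm⁻² | standard stochastic-HH values |
| geometry | 30 µm × 30 µm cylinder | configurable; small-patch studies use 10 × 10 µm |
| spike detection | 0 mV, 2 ms refractory | unambiguous for full-height APs |
| reliability kernel | Gaussian SD 2 ms, threshold 2× mean rate | event-based measure defaults; both exposed |
| Welch | Hann, 50 % overlap | normalised so the integrated PSD equals the variance (checked by Parseval) |
| spike blanking | 2 ms pre / 8 ms post | covers AP + afterpotential at these kinetics |

The single-channel conductance deserves a note: 10 pS is also defensible
from single-channel recordings, but 20 pS is the value that makes
density × γ reproduce the canonical deterministic maximal conductances,
keeping the deterministic limit of every stochastic backend identical to
the textbook model; that consistency is worth more here than any
particular patch-clamp estimate, and γ is a constructor argument.

## Clipping

The Gaussian open fraction can leave $[0,1]$ — most visibly for sodium at
rest, where $p_\infty \sim 2\times10^{-5}$ is *below* the noise SD.
Clipping `z` at the conductance evaluation guarantees non-negative
conductances but truncates the fluctuation distribution, and measurement
shows the cost is real: clipped effective simulations fire at
33.1 ± 0.7 Hz where microscopic gives 38.7 ± 1.1 Hz and the unclipped
effective model 38.8 ± 0.6 Hz (6 µA/cm², 10 × 10 µm, six repetitions) —
truncation removes a third of the sodium conductance variance at rest,
and it is exactly that variance which drives noise-assisted firing.
Meanwhile the negative excursions it guards against are of order
$10^{-4}$ in `z` (0.01 mS/cm² against a 0.3 mS/cm² leak) and never
destabilise the integration. The default is therefore **no clipping**;
`clip = TRUE` restores the guard, state variables are never modified
either way, and the policy in force is recorded in the result metadata.
Voltage-clamp moment comparisons are likewise computed on the unclipped
process, which is the process whose mean and covariance the theory
matches.

## Protocols, seeding and reproducibility

`run_protocol()` orchestrates the standard experiments (voltage-clamp
statistics, f–I curves, pulse trials, frozen-stimulus reliability, PSD
recordings) with per-trial seeds derived from a master seed by a
counter-based map (`derive_seed()`), so trial `k` is reproducible in
isolation and independent of how many trials precede it. A frozen
OU stimulus carries its own seed and restores the caller's RNG stream
after realisation. All random draws — R level and C++ level — go through
R's RNG, so `(config, master seed)` determines every result bit for bit.

## What the validation suite shows — and what it cannot

The test suite validates, among others: the binomial conservation
identity and composed/general path equivalence at machine-level
tolerances; microscopic stationary means and variances against the
analytic values within three (analytically derived) standard errors at
five clamp voltages for both channel types (N = 1800, 20 s runs);
effective-vs-microscopic agreement of means, variances and fitted ACF
time constants (15 %); the Fox directional mismatch at ≥95 % confidence
per voltage; sub-rheobase spontaneous firing (silent deterministic trace,
irregular stochastic firing with CV > 0.3, microscopic and effective CV
within 20 % over 20-s runs); f–I smoothing with overlapping ±1 SD bands
(3 × 5 s repetitions); reliability ordering (frozen OU > DC, 20 trials);
and band-wise subthreshold PSD agreement within 2 block-SE plus a 2 %
allowance for the stated discretization and Gaussian approximations
(100-s traces), with a 5 % Parseval check. Problem sizes are the
package's choices, set for estimator stability at desk scale.

All of this is synthetic-on-synthetic validation: it shows the
approximation matches its own exact microscopic counterpart under the
stated assumptions, not that either matches a biological membrane. Real
neurons violate several assumptions at once — non-Markovian gating modes,
channel cooperativity, spatial heterogeneity, many coexisting channel
types — so passing tests certify the numerics and the approximation
theory, nothing more.

## Limitations

* Current-clamp integration requires subunit-composed schemes with
  parametric rate laws. General M-state schemes are fully supported for
  kinetic analysis and voltage clamp; extending them to current clamp
  would need a per-step eigendecomposition of a user-supplied R matrix
  and is deliberately out of scope.
* The OU coefficients are refreshed from the instantaneous voltage; during
  the fast phases of an action potential the slow-gating assumption fails
  and the effective noise momentarily lags the true conditional
  statistics. Voltage-clamp statistics are unaffected; current-clamp
  spike shapes show no measurable consequence at the tested sizes, but
  this is an approximation, not a theorem.
* For very small open-channel numbers ($N p_\infty \lesssim$ a few) the
  Gaussian limit is marginal; percent-level deviations in spectra and
  firing statistics at very small membrane areas are expected and
  observed.
* The microscopic stepper is fixed-step with per-step linearised
  probabilities ($O(dt)$); it is not an exact-event-time (Gillespie)
  simulator.
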