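# channoise

Fast, accurate simulation of **channel noise** — the conductance
fluctuations caused by stochastic gating of finite ion-channel populations
— in single-compartment conductance-based model neurons.

Small neurons fire spontaneously below rheobase, respond with graded
rather than all-or-none f–I curves, and time their spikes more reliably
under fluctuating than constant drive: all consequences of channel noise
that deterministic Hodgkin–Huxley-type models cannot show. Simulating the
noise exactly means Monte-Carlo tracking of every channel state, which is
expensive. `channoise` implements the *diffusion approximation*: any
Markov kinetic scheme is translated into an effective stochastic
conductance in which the deterministic gating variables are complemented
by a sum of Ornstein–Uhlenbeck (OU) processes whose variances and time
constants are derived **analytically** from the scheme — no heuristic
noise parameters. The exact microscopic simulator and the classical
Fox–Lu Langevin approximation are included as reference and comparator
backends behind the same interface, so every accuracy claim can be
checked in-package.

## The model in brief

For `N` independent `M`-state channels with one conducting state, the
stationary open fraction `z` has mean `p∞` and autocovariance

    C(t) = Σᵢ σᵢ² exp(−t/τᵢ),    Σᵢ σᵢ² = p∞(1 − p∞)/N,

a sum of `M − 1` exponentials. For subunit-composed schemes (sodium
`m³h`, potassium `n⁴`) the pairs `(σᵢ², τᵢ)` follow in closed form from a
multinomial expansion of the per-subunit covariances — 7 terms for Na,
4 for K with `τ = τₙ/{1,2,3,4}`; for general schemes they come from the
eigendecomposition of the transition-rate matrix. The effective model
simulates

    z(t) = Πⱼ xⱼ(t)^qⱼ + Σᵢ ζᵢ(t),

with deterministic gates `xⱼ` and one OU process `ζᵢ` per term, stepped
by the distributionally exact update
`ζ ← ζ e^(−Δt/τ) + σ √(1 − e^(−2Δt/τ)) ξ` and with `(σᵢ, τᵢ)` refreshed
from the instantaneous voltage. The membrane then obeys the usual current
balance `Cₘ dV/dt = I_ext − g_L(V−E_L) − Σ ḡ z (V−E_rev)`.

Backends: `deterministic`, `microscopic` (exact occupancy-count
Monte-Carlo), `effective`, `reduced` (single OU term), `fox` (Fox–Lu
comparator). With noise off, every backend reproduces the deterministic
trajectory exactly.

## Worked example

Derive the potassium noise spectrum at −40 mV, then check the three
stochastic backends against it under voltage clamp (10 s, dt = 0.01 ms,
N = 1800 channels):

```r
library(channoise)

kn <- hh_potassium_scheme()
derive_coefficients(kn, -40, n_channels = 1800)
#>    v term  sigma_sq    tau p_open
#>  -40    1 4.733e-05 3.5145  0.212
#>  -40    2 3.362e-05 1.7573  0.212
#>  -40    3 1.062e-05 1.1715  0.212
#>  -40    4 1.257e-06 0.8786  0.212

pop <- channel_population(kn, 1800L, e_rev = -77, name = "k")
r  <- run_voltage_clamp(pop, -40, 10000, dt = 0.01,
                        backend = "microscopic", burn_in = 500, seed = 1)
st <- stationary_stats(r$z, 0.01)
```

The four `(σᵢ², τᵢ)` rows are the OU coefficients of the effective model;
their variances sum to `p∞(1−p∞)/N = 9.28e-05`. The backends give:

```
microscopic: mean 0.2118  variance 9.061e-05  fitted ACF tau 2.30 ms
theory:      mean 0.2120  variance 9.282e-05
effective:   mean 0.2119  variance 9.296e-05  fitted ACF tau 2.33 ms
fox:         variance 1.867e-04 (overestimated)
```

The exact and effective models agree with theory in mean, variance and
correlation time; the Fox comparator overestimates the potassium variance
roughly twofold — the classical failure the diffusion approximation
corrects. Note the fitted single-exponential time constant (≈2.3 ms) is
neither `τₙ` (3.5 ms) nor `τₙ/4`: no kinetic time constant summarises the
multi-exponential decay, which is why the effective model carries one OU
process per term.

Current-clamp use goes through a fixture and the same integrator:

```r
fx <- build_hh_fixture(list(diameter_um = 10, length_um = 10))
r  <- integrate_membrane(fx$membrane, fx$geometry, fx$populations,
                         stim_dc(2), 10000, dt = 0.01,
                         backend = "effective", seed = 1)
isi_statistics(r$spikes, 10000)   # irregular sub-rheobase firing, CV ~ 1
```

A thin command-line interface wraps the same functions
(`exec/channoise vclamp|iclamp|fi|pulse-trials|reliability|psd|
derive-coefficients|selftest`); every run writes a TSV table plus a JSON
metadata sidecar containing all resolved parameters and seeds.

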