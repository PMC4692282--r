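# oscnoise

Where does the variability of a synthetic gene oscillator come from?
`oscnoise` is an R package for decomposing the noise of the dual-feedback
oscillator — the three-gene *E. coli* circuit in which AraC activates and
LacI represses a shared hybrid promoter driving both regulators and a GFP
reporter — into **intrinsic** noise (finite molecule numbers), **cell-cycle**
noise (growth-rate and division-size variability, binomial partitioning at
division) and **extrinsic parameter** noise (heritable cell-to-cell
variability of production rates).  It is aimed at quantitative/systems
biologists who have branched single-cell fluorescence trajectories (lineage
trees from time-lapse microscopy) and want mechanistic noise levels, and at
modelers studying stochastic oscillators.

## The model

The deterministic core is a delay model for LacI (r), AraC (a), immature
GFP (g) and mature GFP (G):

    r' = α_r h(r_τr, a_τr) − γ_r r/(R0 + S) − β r         S = r + a + g + G
    a' = α_a h(r_τa, a_τa) − γ_a a/(R0 + S) − β a
    g' = α_g h(r_τg, a_τg) − γ_g g/(R0 + S) − λ g − β g
    G' = λ g − γ_G G/(R0 + S) − β G

with the composite promoter activity
`h(r, a) = (1/f + a/C_a) / ((1 + a/C_a)(1 + r/C_r)²)` and x_τ = x(t − τ).
With the default parameters it oscillates with a 41-min period.  The
stochastic version is simulated exactly with a **delayed Gillespie
algorithm** (production completions are queued for one transcriptional
delay); the scaling family P_Ω = (Ωα, Ωγ, f, ΩR0, ΩC_a, ΩC_r) changes
molecule numbers by Ω without touching deterministic dynamics, making Ω a
clean intrinsic-noise dial.  Lineage simulations add exponential volume
growth V' = βV, division at a sampled size V_max with binomial
partitioning (including the delay queue), and division-time resampling of
the production rates,

    p' = (q p_mother + (1 − q)⟨p⟩)(1 + Γη),   η ~ N(0, 1),

with sister pairs constrained to the mean exactly; Γ is the extrinsic
noise level and q = e^(−ln2/5) a five-generation memory.

(Ω, Γ) are inferred by simulating lineages over a grid and intersecting
the two curves Γ*(Ω) that minimize, respectively, the amplitude-CV
mismatch and the L2 distance between sister-cell correlation functions —
the two statistics have complementary sensitivities (correlations respond
mostly to Ω, amplitude variability mostly to Γ).

## Worked example

Simulate 30 lineages (6 generations each) at the fitted noise levels and
summarize them:

```r
library(oscnoise)
set.seed(1)
tree <- simulate_lineages(30, params = oscillator_params(),
                          noise = noise_params(),       # omega 2.1, gamma 0.12
                          cc = cell_cycle_params(), n_generations = 6)
summary_stats(tree)
#> Lineage summary statistics:
#>   amplitude CV : 0.548  (mean 318 AU, 2014 peaks)
#>   period CV    : 0.152  (mean 38.5 min, 1933 intervals)
#>   sister corr  : rho(3) = 0.994 ... rho(30) = 0.683
```

Peak heights vary by ~50% while peak-to-peak intervals vary by ~15%, and
sisters are nearly identical right after division (ρ(3) ≈ 0.99) but
decorrelate over tens of minutes — the qualitative signature that needs
both a moderate molecule-number scale and slow heritable parameter noise.
Estimate the noise levels back from such data with `estimate_noise()`, or
validate the whole estimator on the analytically tractable amplitude-phase
toy oscillator:

```r
set.seed(2)
est <- toy_recovery_experiment(true_omega = 200, true_gamma = 0.15)
est
#> Noise estimate: omega = 188, gamma = 0.147 (contour gap 0)
```

Other entry points: `integrate_dde()` / `fit_parameters()` (deterministic
model and its fit), `simulate_cell()` / `amplitude_cv_vs_omega()`
(single-cell intrinsic noise), `generate_synthetic()` /
`read_lineage_table()` (synthetic data and I/O on the shared lineage CSV
schema), `run_experiment()` (named, seeded, manifest-logged workflows).
The methods vignette (`vignettes/noise-decomposition.Rmd`) documents the
model, conventions and known limitations.

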