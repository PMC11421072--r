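# phosbind

Quantifying magnesium binding to adenosine diphosphate (ADP) from 31P
NMR observables and molecular-dynamics trajectories.

## Who this is for

Mg2+ exchanges with ADP far faster than the chemical-shift separation
between its binding states, so a 31P spectrum shows one
population-averaged peak per phosphate site. The binding populations,
the exchange-rate bound, and the accompanying changes in molecular
mobility must all be inferred from how that peak's shift, relaxation and
diffusion behave during a titration. phosbind is for NMR spectroscopists
and modellers who have such titration, relaxation, DOSY or trajectory
data (or want to simulate it) and need the standard chain of analyses
done reproducibly.

## What it computes

- **Two-state fast-exchange populations** (alpha-phosphate):
  p_b = (δ_obs − δ_f)/(δ_b − δ_f), p_f = 1 − p_b.
- **Sequential three-state populations** (beta-phosphate): free,
  singly- and doubly-bound ADP from the shift balance
  δ_obs,β = p_f δ_f,β + p_b1 δ_b1,β + p_b2 δ_b2,β, closed by a 0.5-eq
  anchor (p_b2 = 0 there), the stoichiometric cap p_b1 + 2 p_b2 ≤ χ_Mg,
  and minimum end-member separation.
- **Exchange-rate lower bound** k_ex > f · 2π · Δδ · ν0.
- **R1/R2 fits** (inversion recovery with fitted inversion efficiency;
  mono-exponential echo decay) and a **CSA relaxation model**
  R1 = (2/15) ω0² ||σ_sym||² J(ω0; τ2) + (1/3) ω0² ||σ_anti||² J(ω0; τ1),
  inverted by bisection for the rank-2 correlation time τ2, then
  converted to a rotational hydrodynamic radius via
  τ2 = 4πη R_H³ / (3kT).
- **Stejskal-Tanner diffusion fits**
  I = I0 exp(−D γ²g²δ²(Δ − δ/3)) with a log-linear cross-check, and the
  translational radius R_H = kT/(6πηD).
- **Trajectory coordination analysis**: minimum-image distance traces,
  radial distribution functions, and tight-vs-diffuse coordination
  summaries from multi-frame XYZ files.
- **Seeded synthetic generators** for every input above, so the whole
  pipeline runs and is tested without a spectrometer or MD engine.

## Worked example

Simulate a noiseless stoichiometric titration of 10 mM ADP at Mg2+
equivalents 0–2 and recover the binding populations:

```r
library(phosbind)
ser <- gen_titration(adp_conc = 10,
                     deltas = list(alpha = c(f = 0, b = 0.89),
                                   beta  = c(f = -5.60, b1 = -5.16, b2 = -5.30)))
two <- two_state_populations(ser, "alpha")
two
#> <two_state_solution> channel alpha, delta_f = 0 ppm, delta_b = 0.89 ppm
#>  mg_equiv delta_obs p_f p_b clipped
#>       0.0     0.000 1.0 0.0   FALSE
#>       0.5     0.445 0.5 0.5   FALSE
#>       1.0     0.890 0.0 1.0   FALSE
#>       1.5     0.890 0.0 1.0   FALSE
#>       2.0     0.890 0.0 1.0   FALSE
```

Half the ADP is bound at 0.5 equivalents and binding saturates at one —
the signature of strong 1:1 association. The beta channel needs the
three-state model, seeded with the alpha-channel free fractions:

```r
three_state_populations(ser, two$p_f)
#> <three_state_solution> delta_f = -5.6000, delta_b1 = -5.1600, delta_b2 = -5.3000 ppm (anchor 0.5 eq)
#>  mg_equiv delta_obs_beta p_f         p_b1 p_b2
#>       0.0          -5.60 1.0 0.000000e+00  0.0
#>       0.5          -5.38 0.5 5.000000e-01  0.0
#>       1.0          -5.16 0.0 1.000000e+00  0.0
#>       1.5          -5.23 0.0 5.000000e-01  0.5
#>       2.0          -5.30 0.0 6.328271e-15  1.0
```

The solver recovers the three end-member shifts exactly and shows the
second equivalent of Mg2+ converting singly- to doubly-bound ADP. The
single averaged peak also bounds the exchange rate:

```r
kex_lower_bound(0.89, 202.4)
#> k_ex > 5659 s^-1 (5 x 2 pi x 0.89 ppm at 202.4 MHz)
```

Relaxation closes the loop from rates to size: generate an
inversion-recovery curve from the CSA model at τ2 = 200 ps, fit it, and
invert back:

```r
m <- csa_model(sigma_sym_F = 163, nu0_mhz = 202.4)
curve <- gen_relaxation_curve("inversion_recovery", rate = csa_r1(m, 2e-10),
                              delays = seq(0.05, 6, length.out = 12))
fit <- fit_inversion_recovery(curve)
fit
#> <relaxation_fit> R1 = 1.07622 s^-1, I0 = 1, rms = 9.61e-17
inv <- invert_r1_for_tau2(fit$rate, m)
tau2_to_hydrodynamic_radius(inv$tau2)
#> [1] 5.64e-10
```

R1 of about 1.08 s⁻¹ maps back to τ2 = 200 ps and a rotational
hydrodynamic radius of 5.6 Å — the size scale expected for a compact
nucleotide-cation complex.

The whole chain — titration, relaxation, diffusion and trajectory
stages, each writing a provenance-stamped CSV plus a run manifest — runs
from one YAML config through `run_full_analysis()`; see the vignette in
`vignettes/mg-adp-binding.Rmd` for the model details and design choices.

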