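---
title: "Quantifying Mg2+ binding to ADP from 31P NMR observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Mg2+ binding to ADP from 31P NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosbind)
```

## The problem

Magnesium is the cation that makes adenosine nucleotides biologically
active: ATP and ADP are almost never found without it in enzymatic
environments. When Mg2+ associates with the phosphate groups of ADP, the
31P chemical shifts, relaxation rates and translational diffusion of the
nucleotide all change. Because the Mg2+/ADP interconversion is much
faster than the chemical-shift separation between bound and free forms,
the spectrometer reports a single population-averaged peak per phosphate
site, and the binding populations must be inferred from how that peak
moves during a titration. This package implements that inference,
together with the relaxation- and diffusion-based hydrodynamic analyses
that accompany it and the coordination analysis of MD trajectories.

Every input the pipeline consumes can also be produced by a seeded
synthetic generator, so the full analysis is testable with no
spectrometer or MD engine attached.

## Fast-exchange population models

**Two-state model (alpha-phosphate).** In the fast-exchange limit the
observed shift is the population-weighted mean of the free and bound
end-member shifts, so

$$p_b = \frac{\delta_{obs} - \delta_f}{\delta_b - \delta_f},
\qquad p_f = 1 - p_b.$$

`two_state_populations()` takes $\delta_f$ as the observed shift with no
Mg2+ added and $\delta_b$ as the largest shift observed at that ADP
concentration (both overridable). Populations that land slightly outside
$[0,1]$ — within 0.02, a magnitude consistent with shift-reading noise of
a few thousandths of a ppm against end-member separations of order
0.5-1 ppm — are clipped with a warning; anything larger is treated as
model failure and raised as an error rather than masked.

**Three-state model (beta-phosphate).** The beta shift first moves
downfield and then partially reverses at high Mg2+, which a two-state
average cannot produce. The package therefore models sequential binding
of a second cation:

$$\delta_{obs,\beta} = p_f\,\delta_{f,\beta} + p_{b1}\,\delta_{b1,\beta}
  + p_{b2}\,\delta_{b2,\beta},\qquad p_f + p_{b1} + p_{b2} = 1,$$

with $p_f$ transferred from the alpha-channel fit (the second binding
event is assumed to touch only the beta shift) and the end-member
ordering $\delta_{f,\beta} < \delta_{b2,\beta} < \delta_{b1,\beta}$.
Three assumptions close the under-determined system:

1. no doubly-bound ADP at the 0.5-eq anchor, which fixes
   $\delta_{b1,\beta}$ from that single point;
2. a stoichiometric cap — bound cations cannot outnumber added ones,
   rendered as $p_{b1} + 2p_{b2} \le \chi_{Mg}$ since each doubly-bound
   ADP consumes two Mg2+;
3. $\delta_{b2,\beta}$ takes the minimum separation from
   $\delta_{b1,\beta}$ compatible with the cap, ties broken toward
   $\delta_{b1,\beta}$.

Given a candidate separation $s = \delta_{b1,\beta} - \delta_{b2,\beta}$,
each point's $p_{b2}$ follows by substitution, and its feasibility
constraints are monotone in $s$: each point that requires doubly-bound
character imposes a lower bound $s \ge -r_i/(\chi_i - p_{b,i})$ and
$s \ge -r_i/p_{b,i}$, where $r_i$ is the part of the observed shift not
explained by the free and singly-bound states. The minimization in
assumption 3 therefore reduces exactly to the largest per-point lower
bound, computed in closed form (tolerance $10^{-9}$ ppm) and verified by
substitution — no iterative search is needed, and the degenerate case of
purely two-state data resolves the tie at $\delta_{b2} = \delta_{b1}$
with $p_{b2} = 0$ everywhere. Infeasible inputs (no separation satisfies
every point) are reported with the violating equivalents, and a
transferred $p_f$ that already violates the cap triggers a warning
naming the points rather than silent renormalization.

**Exchange-rate bound.** A single averaged peak implies
$k_{ex} \gg \Delta\omega$; `kex_lower_bound()` computes
$k_{ex} > f \cdot 2\pi\,\Delta\delta\,\nu_0$ with the dispersion in ppm
and $\nu_0$ in MHz. Both the dispersion and the multiplier are explicit
arguments because the bound can reasonably be quoted either as five
times the 0.89-ppm titration shift change or as one times the ~4.3-ppm
alpha-beta separation; the function takes no position on which
convention the caller wants.

## Relaxation: CSA model, correlation time, rotational radius

R1 and R2 are obtained by nonlinear least squares
(Levenberg-Marquardt, via minpack.lm) on

$$I(t) = I_0\,(1 - 2a\,e^{-R_1 t}) \qquad\text{and}\qquad
  I(t) = I_0\,e^{-R_2 t},$$

with the inversion efficiency $a$ fitted rather than fixed at 1, since
imperfect 180-degree pulses are the norm. Starting values come from the
zero-crossing time (inversion recovery) or a log-linear regression
(echo decay); four points is the hard minimum, and constant intensities
are rejected as unidentifiable.

At 11.7 T the 31P R1 of phosphates is dominated by chemical shift
anisotropy:

$$R_1 = C_{sym}\,\omega_0^2\,\|\sigma_{sym}\|_F^2\,J(\omega_0;\tau_2)
      + C_{anti}\,\omega_0^2\,\|\sigma_{anti}\|_F^2\,J(\omega_0;\tau_1),
  \qquad J(\omega;\tau) = \frac{\tau}{1+\omega^2\tau^2},$$

with $C_{sym} = 2/15$ and $C_{anti} = 1/3$ under the Frobenius-norm
convention, both isolated as `csa_model()` arguments so an alternative
tensor convention is a one-argument change. The defaults are
$\|\sigma_{sym}\|_F = 163$ ppm for the alpha phosphate (a DFT-derived
scalar taken as a config input) and $\|\sigma_{anti}\|_F = 0$, the
antisymmetric part being negligible by comparison. Isotropic tumbling
ties the rank-1 to the rank-2 correlation time, $\tau_1 = 3\tau_2$.

`invert_r1_for_tau2()` inverts this map. $R_1(\tau_2)$ has a single
maximum near $\omega_0\tau_2 = 1$, so any attainable rate has two roots;
the fast-motion branch ($\omega_0\tau_2 < 1$) is returned because
small-molecule correlation times at 11.7 T sit two orders of magnitude
below the peak. The root is bracketed geometrically (it can span many
decades) and bisected to a relative width of $10^{-12}$; rates above the
attainable maximum raise an error, and rates within 1% of it raise a
warning that the branches are nearly degenerate. The correlation time
then maps to a rotational hydrodynamic radius through the
Stokes-Einstein-Debye relation for a stick-boundary sphere,
$\tau_2 = 4\pi\eta R_H^3/(3kT)$.

## Diffusion: Stejskal-Tanner fit and translational radius

Pulsed-gradient attenuation is fitted as

$$I = I_0 \exp\!\big(-D\,\gamma^2 g^2 \delta^2 (\Delta - \delta/3)\big)$$

(rectangular gradients; shaped-gradient corrections are out of scope).
The primary estimator is nonlinear least squares on the intensities; a
log-linear regression of $\log I$ on the b-values is always computed as
an independent cross-check, and disagreement beyond three standard
errors of the nonlinear $D$ raises a warning. The translational radius
follows from the Stokes-Einstein relation $R_H = kT/(6\pi\eta D)$, the
6-pi stick factor being a configurable argument since only the
spherical-particle assumption, not the boundary condition, is forced by
the physics. The two radius conventions are mutually consistent: tests
feed both pipelines a common ground-truth sphere and require the same
$R_H$ back to $10^{-6}$ relative.

## Trajectory analysis

Trajectories are multi-frame XYZ with an optional `box=Lx,Ly,Lz` comment
field (orthorhombic boxes only — the emulated solvated systems are
cubic, ~35 A). `distance_trace()` applies the minimum-image convention
whenever a box is present. `radial_distribution()` bins all
reference-target pair distances per frame and normalizes by shell volume
$4\pi r^2\,dr$, target number density and the reference and frame
counts, so $g(r) \to 1$ for a homogeneous fluid; `r_max` may not exceed
half the smallest box length, where minimum-image distances become
ambiguous. Bin width and range default to 0.05 A and 10 A and are
plain arguments — no claim is made that these match any particular
published figure. `coordination_stability()` reduces a trace to mean,
sample sd and fraction of frames within a cutoff (default 2.5 A),
formalizing the tight-versus-diffuse comparison: Mg2+-like coordination
shows a near-constant ~1.9 A contact, Na+-like coordination a broad
distribution with excursions.

## The synthetic generators

The generators define the study conditions and double as the
inverse-problem oracles for every fit:

- `gen_titration()` defaults to the emulated sample design — five
  samples at 0, 0.5, 1, 1.5 and 2 equivalents of Mg2+ on 10 mM ADP —
  with stoichiometric strong binding (each added cation binds until
  saturation; the second equivalent converts singly- to doubly-bound)
  or, alternatively, populations from the exact 1:1 equilibrium
  quadratic at the stated concentrations. Noise is i.i.d. Gaussian on
  the ppm values.
- `gen_relaxation_curve()` and `gen_diffusion_decay()` evaluate the
  exact model curves plus Gaussian noise scaled to the unattenuated
  intensity, the standard thermal-noise model.
- `gen_coordination_trajectory()` fixes the ion at the box center and
  places tight partners at Gaussian-jittered radial distances
  (default mean 1.9 A, sd 0.05 A) and loose partners with a large sd
  plus occasional uniform repositioning (default probability 0.02 per
  frame), mimicking unbinding excursions.

Each generator takes one integer seed, uses a private stream, and
restores the caller's RNG state, so fixed-seed outputs are bit-identical
across runs. What the generators deliberately do *not* emulate:
J-coupled multiplet structure, lineshapes, baseline and phase artifacts,
heteroscedastic noise, convection in diffusion data, or force-field
physics in trajectories. Passing tests therefore demonstrate that the
solvers invert their stated models correctly at realistic noise levels,
not that those models exhaust real spectrometer or MD output.

## Numerical choices

- Populations in $(-0.02, 0)$ or $(1, 1.02)$ are clipped with a warning;
  larger violations are errors. The same 0.02 band governs the
  three-state negative-$p_{b2}$ clip.
- The extreme-narrowing limit of the CSA model deviates from the exact
  Lorentzian by exactly $(\omega_0\tau_2)^2$, so the closed-form
  agreement test is run at $\omega_0\tau_2 = 10^{-5}$, where that
  deviation ($10^{-10}$) is an order below the $10^{-9}$ tolerance being
  asserted.
- Result CSVs serialize doubles with the shortest of 15-17 significant
  digits that round-trips exactly, so write-then-read is bit-identical;
  missing values are empty cells, never zeros.
- Test problem sizes were chosen to make the statistical checks sharp at
  interactive runtimes: 100 seeded ground truths for the population
  invariants, 16-point decays at 1% noise for rate/D recovery, 1000
  frames for coordination means, 150-200 frames of a 64-particle ideal
  gas for the RDF homogeneous limit. The whole suite runs in seconds.

## Known limitations

- The three-state solver inherits whatever bias the alpha-channel
  two-state fit puts into $p_f$; it reports cap violations caused by the
  transfer but does not re-estimate $p_f$.
- Only CSA relaxation is modeled; dipolar and scalar contributions, and
  anisotropic rotational diffusion, are out of scope, as are
  multi-component (DOSY inversion) diffusion analyses.
- Hydrodynamic radii assume a sphere; for a flexible nucleotide they are
  effective radii whose value depends on the chosen boundary condition,
  which is why the friction factors are exposed rather than hidden.
- Binding equilibrium constants are generator-side only; the analysis
  modules infer populations, not $K_d$.
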