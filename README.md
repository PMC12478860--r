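# cgdroplet

Coarse-grained simulation and analysis of protein–DNA biomolecular
condensates in R.

Membraneless organelles form when proteins and nucleic acids demix into a
dense, liquid-like phase. `cgdroplet` implements a minimal model of this
process for people who want a transparent, fully inspectable simulation and
analysis chain rather than a black-box MD engine: proteins are single
spherical beads (σ_P = 50 Å, 5000 g/mol), DNA is a bead-spring polymer with
one bead per base pair (σ_D = 5 Å, 500 g/mol), harmonic bonds
U = K_b(r − r₀)² with K_b = 20 kcal/mol/Å², r₀ = 5.5 Å, and harmonic angles
U = K_θ(θ − π)² whose stiffness sets the DNA persistence length. All
nonbonded pairs interact through an Ashbaugh–Hatch potential,

    U(r) = U_LJ(r) + (1 − λ_ij) ε     for r ≤ 2^(1/6) σ_ij
    U(r) = λ_ij U_LJ(r)               for r >  2^(1/6) σ_ij

with ε = 0.2 kcal/mol, σ_ij = (σ_i + σ_j)/2 and λ_DD = −1: the hydropathies
λ_PP (homotypic) and λ_PD (heterotypic) are the two dials that control
whether condensates form, whether DNA is recruited, and whether the droplet
develops a phase-in-phase architecture. Dynamics are underdamped Langevin
(BAOAB velocity Verlet, γ_i = m_i/t_damp, defaults 300 K / 10 fs / 1000 ps)
in a periodic cube, with a compiled force core.

On top of the engine sits the analysis stack used to characterise
condensates:

- distance-based clustering with largest-cluster composition fractions
  (f_P, f_D) and the DNA-bound protein fraction,
- per-chain radius of gyration, compaction ratios, and persistence length
  from bond-correlation decay (plus a pivot Monte Carlo sampler for
  isolated-chain equilibrium averages),
- radial density profiles about the condensate centre with single/double
  hyperbolic-tangent fits, interphase radii, gradients, and coexistence
  (dilute/dense) concentrations,
- radial displacement distributions P(r, t) decomposed into n diffusive
  modes P(r,t) = Σ p_i [4πr²/(4πD_i t)^{3/2}] exp(−r²/4D_i t), with
  data-driven mode-count selection and bin-size robustness checks,
- five-block block averaging (first block discarded) for every reported
  mean ± standard error,
- a YAML-configured pipeline (`run_pipeline()`, plus the `exec/cgdroplet`
  command line) that builds, simulates, analyses and writes a manifest for
  bit-reproducible reruns.

## Worked example

```r
library(cgdroplet)

ff <- ff_params(lambda_PP = 4, lambda_PD = 0.3)
ff
#> Coarse-grained protein-DNA force field
#>   epsilon  0.2 kcal/mol   cutoff 3 sigma_ij
#>   protein: sigma 50 A, mass 5000 g/mol
#>   dna    : sigma 5 A, mass 500 g/mol
#>   lambda : PP 4  PD 0.3  DD -1
#>   bonds  : K_b 20 kcal/mol/A^2, r0 5.5 A
#>   angles : K_theta 20 kcal/mol/rad^2, theta0 3.142 rad

## equilibrium size of one 250-bp DNA chain (pivot Monte Carlo)
traj <- sample_chain_mc(250, ff_params(), n_samples = 1000, thin = 60,
                        burn = 5000, seed = 1)
rg <- sapply(seq_len(n_frames(traj)), function(i)
  radius_of_gyration(frame_positions(traj, i)))
mean(rg)
#> mean R_g = 292.5 A over 1000 conformations
```

292 Å is the relaxed coil size of the model's double-stranded DNA; chains
recruited into a condensate compact to a fraction of this
(`compaction_ratio()`).

```r
## diffusion-mode decomposition on known-truth displacements
disp <- sample_displacements(p = c(0.6, 0.4), D = c(5000, 200), t = 1,
                             n_samples = 1e5, seed = 2)
dist <- displacement_histogram(disp, lag = 1, n_bins = 500)
select_mode_count(dist, n_max = 4)
#> [1] 2
fit_diffusion_modes(dist, 2)
#> diffusion_mode_fit: 2 mode(s), rms residual 0.000152
#>   mode 1: D = 4874 A^2/ns, p = 0.597
#>   mode 2: D = 199.8 A^2/ns, p = 0.403
```

The selection rule finds the generating mode count and the fit recovers
both diffusivities within a few percent — the same machinery applied to
simulation trajectories via `displacement_distribution()`.

A full build → simulate → analyze run from a config file:

```sh
exec/cgdroplet pipeline --config my_run.yaml --out run1/
```

writes the trajectory (extended XYZ), per-frame composition, profiles,
fits and a JSON manifest under `run1/`; every omitted config key takes the
published default (5000 proteins + 5000 DNA beads, 2000 Å box, 300 K).

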