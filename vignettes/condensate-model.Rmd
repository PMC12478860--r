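---
title: "A minimal coarse-grained model of protein-DNA condensates: methods and design"
author: "cgdroplet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal coarse-grained model of protein-DNA condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdroplet)
```

## The model

`cgdroplet` implements a deliberately minimal coarse-grained model of
protein-DNA biomolecular condensates.  Each protein is a single spherical
bead of diameter $\sigma_P = 50$ Å and mass 5000 g/mol; DNA is a bead-spring
polymer with one bead per base pair ($\sigma_D = 5$ Å, 500 g/mol).  DNA
connectivity carries two bonded terms, both harmonic and written without a
1/2 prefactor:

$$U_{bond} = K_b (r - r_0)^2, \qquad U_{angle} = K_\theta (\theta - \theta_0)^2,$$

with $K_b = 20$ kcal/mol/Å², $r_0 = 5.5$ Å and $\theta_0 = \pi$ (a straight
chain).  $K_\theta$ tunes bending rigidity; $K_\theta = 20$ kcal/mol/rad²
gives a persistence length in the double-stranded DNA range (see below).

All nonbonded pairs interact through an Ashbaugh–Hatch potential, a
Lennard-Jones form whose attractive branch is scaled by a hydropathy
$\lambda_{ij}$ while the repulsive core is untouched:

$$U_{nb}(r) = \begin{cases}
U_{LJ}(r) + (1-\lambda_{ij})\,\epsilon, & r \le 2^{1/6}\sigma_{ij} \\
\lambda_{ij}\, U_{LJ}(r), & r > 2^{1/6}\sigma_{ij}
\end{cases}$$

with $U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$,
$\epsilon = 0.2$ kcal/mol and the arithmetic (Lorentz) combining rule
$\sigma_{ij} = (\sigma_i + \sigma_j)/2$.  Both branches equal
$-\lambda\epsilon$ at $2^{1/6}\sigma$, so the potential is continuous for
every $\lambda$.  Homotypic (protein-protein, $\lambda_{PP}$) and
heterotypic (protein-DNA, $\lambda_{PD}$) couplings are the two control
parameters of the phase behaviour; DNA-DNA interactions are purely
repulsive ($\lambda_{DD} = -1$).  Directly bonded DNA beads are excluded
from nonbonded interactions; 1-3 (angle-partner) pairs are not, following
the narrow reading that only direct bonds are excluded.

**Cutoff.** The model definition does not name a nonbonded cutoff.  We
truncate, without shifting, at $r_c = 3\,\sigma_{ij}$ (configurable via
`cutoff_factor`).  At $3\sigma$ the residual attraction is
$\sim 1.1\times10^{-3}$ kcal/mol, about half a percent of the well depth,
and the discontinuity at the cutoff is of the same size.  The factor is a
package-level choice held fixed across all analyses.

## Dynamics

`run_langevin()` integrates underdamped Langevin dynamics with the BAOAB
splitting: deterministic half-kicks (B) and half-drifts (A) around an
exact Ornstein-Uhlenbeck velocity refresh (O).  The friction on bead $i$
is $\gamma_i = m_i / t_{damp}$, so the O step uses
$c_1 = e^{-\Delta t/t_{damp}}$ and $c_2 = \sqrt{(1 - c_1^2)\,k_BT/m_i}$,
which satisfies fluctuation-dissipation exactly at finite time step.  With
$t_{damp} = \infty$ the scheme reduces to plain velocity Verlet (used by
the energy-conservation tests).  Internally the package works in
Å / (g/mol) / (kcal/mol) units, whose derived time unit is
$\tau \approx 48.89$ fs; user-facing times (fs, ps, ns) are converted at
the interface.  Defaults follow the published protocol: 300 K, 10 fs time
step, $t_{damp} = 1000$ ps, a cubic 2000 Å box with periodic boundaries,
and a 1:1 protein:DNA bead stoichiometry.

A damping time of 1000 ps needs far more than a nanosecond to thermalise,
so short runs in the test-suite use small $t_{damp}$ (0.1-10 ps) for
thermostat accuracy checks and larger values (up to 100 ps) when fast
diffusive exploration matters; these are run-length choices, not model
changes.

Nonbonded forces are evaluated through a cell list whenever the box admits
at least three cells per edge at the largest cutoff, and by a direct
all-pairs loop otherwise.  The two paths are algebraically identical and
the test-suite holds them to each other at $10^{-10}$ relative.  Forces
are analytic derivatives of the pair potential; a central-finite-difference
oracle pins them at $10^{-6}$ relative across species pairs and
hydropathies.

**Initial configurations.** `build_mixture()` emulates the "dense random
droplet" start: proteins are placed by random sequential addition inside a
central sphere (default radius box/4) with overlap rejection at
$0.8\,\sigma_{ij}$, and each DNA chain grows as a persistent random walk
with bonds at exactly $r_0$.  Exact reproduction of any particular initial
transient is not attempted; builds are deterministic per seed.

## Single-chain sampling

For isolated-chain equilibrium averages the package provides a pivot Monte
Carlo sampler (`sample_chain_mc()`): a random tail rotation about a random
bead, accepted by Metropolis on the change in angle plus intrachain
nonbonded energy.  Bond lengths are frozen at $r_0$; their thermal rms at
300 K is $\sqrt{k_BT/2K_b} \approx 0.12$ Å, negligible for chain-scale
observables.  Pivot moves decorrelate the radius of gyration within tens
of accepted moves, so a 250-bead chain equilibrates in seconds where
Langevin sampling would need hours.  Two estimates validate the sampler:

* the mean $R_g$ of a 250-bead chain at $K_\theta = 20$ is $\approx 290$ Å
  (the worm-like-chain closed form with the measured persistence length
  gives 294 Å), matching the relaxed-DNA value the model was built to
  reproduce;
* the persistence length from the bond-correlation fit
  $\langle \hat u_i \cdot \hat u_{i+s}\rangle = e^{-sb/l_p}$ agrees within
  a few percent with an independent single-angle Boltzmann quadrature
  oracle, $l_p = -b/\ln\langle\cos\phi\rangle$ with
  $\langle\cos\phi\rangle$ computed by 1-D integration of the angle
  Boltzmann weight.

The correlation tail mixes much more slowly than $R_g$, so persistence
length estimates use heavier thinning (hundreds of attempts per stored
sample).  The fit uses separations with correlation above `fit_window`
(default 0.2, the point where statistical noise begins to dominate a
250-bead chain).  For $K_\theta = 0$ the correlation at $s = 1$ is
already near zero and the estimator flags the result as sub-bond instead
of reporting a number.

## Condensate analyses

**Clustering.** Condensates are identified as connected components of the
graph linking beads within a distance cutoff under the minimum-image
convention (union-find in compiled code; the test-suite checks it against
an independent graph-components oracle).  The published criterion is a
single cutoff of $1.5\,\sigma_{PD} = 41.25$ Å.  Taken literally for all
bead pairs this cannot link two touching proteins, whose centres sit near
$2^{1/6}\sigma_P \approx 56$ Å, so a protein-only condensate would never
register as one cluster.  `cluster_beads()` therefore keeps the single
cutoff as the default and offers a per-species-pair mode
(`per_pair = TRUE`, cutoffs $1.5\,\sigma_{ij}$) that resolves
protein-protein contacts; the regime analyses in the test-suite use the
per-pair mode.  Largest-cluster composition follows the published
definitions $f_P = N_P^{cluster}/N_P^{total}$ and
$f_D = N_D^{cluster}/N_D^{total}$, where a DNA chain counts in full if any
of its beads touches the cluster.  A protein is "bound to DNA" when its
minimum-image distance to the nearest DNA bead is at most
$\sigma_P + \sigma_D = 55$ Å; the dense phase is operationally the largest
cluster.

**Block averaging.** Time series are summarised by splitting into five
equal blocks (truncating any remainder), discarding the first block as
equilibration, and reporting the mean and standard error of the remaining
block means.

**Density profiles and coexistence.** Radial protein profiles are measured
about the centre of mass of the largest-cluster proteins, computed with the
circular mean so that clusters straddling the periodic boundary are handled
exactly.  Shell densities are reported in beads/nm³ (multiply by
$10^{24}/N_A \approx 1.66$ to convert to mM).  Multiphasic organisation is
captured by a double hyperbolic tangent fit,

$$\rho(r) = \rho_{dil}
  + \frac{\rho_{II}-\rho_{dil}}{2}\left[1-\tanh\frac{r-R_{II}}{w_{II}}\right]
  + \frac{\rho_{I}-\rho_{II}}{2}\left[1-\tanh\frac{r-R_{I}}{w_{I}}\right],$$

whose step positions $R_I < R_{II}$ are the two interphases (inner
DNA-associated protein-rich core, outer protein-rich shell, dilute
background); the functional form is our own choice of the simplest
two-step superposition that reduces to a single interface when the inner
amplitude vanishes.  Fits use Levenberg-Marquardt with box constraints and
ten deterministic starts seeded from profile quantiles; ties break towards
smaller $R_I$.  A profile is declared multiphasic when the fitted inner
step exceeds three times the rms residual *and* two percent of the total
density drop - the second condition prevents a vanishing-amplitude fit on
noise-free single-step data from being called multiphasic.  Coexistence
concentrations average the fitted profile inside the innermost plateau
($r < R_{in} - 2w$) and beyond the outermost interface
($r > R_{out} + 2w$), block-averaged over frames; when the largest cluster
holds less than a configurable fraction of the proteins the dense branch
is reported absent and the dilute branch is the global density.

## Diffusion decomposition

Protein dynamics are analysed through the distribution of radial
single-particle displacements at lag $t$, modelled as a population-weighted
sum of 3-D Gaussian propagators:

$$P(r,t) = \sum_{i=1}^{n} p_i \frac{4\pi r^2}{(4\pi D_i t)^{3/2}}
  e^{-r^2/4D_i t}, \qquad \sum_i p_i = 1 .$$

Histograms pool all proteins and all overlapping time origins; origin
correlation affects error bars, not expectations.  Fitting is weighted
least squares on the binned density with weights $1/\max(P, \epsilon)$,
fractions constrained to the simplex by a softmax parameterisation and
diffusivities kept positive on a log scale, with ten deterministic
multi-starts whose log-spaced diffusivity ladders span the data's
$r^2/4t$ range.  Each lag is fitted separately so that the constancy of
$D_i$ across lags can be verified.  The mode count is selected as the
smallest $n$ for which adding a mode improves the rms residual by less
than 20% (relative) or introduces a population below $p_{min} = 0.01$;
both thresholds are configurable and logged.  A known-truth sampler
(`sample_displacements()`) closes the loop: for decade-separated
diffusivities and $n \in \{1,2,3,5\}$ the fit recovers $D$ within 5% and
$p$ within 0.02, the selected mode count equals the generating one, and
both are unchanged across 300/500/1000/2000 histogram bins.

## What the synthetic generators do and do not show

The displacement sampler, synthetic tanh profiles and sphere-in-gas
configurations provide exact ground truth for the *analysis* stack; tests
against them demonstrate estimator correctness, not that the physical
model produces multiphasic condensates or five diffusive populations.
Those are properties of production-scale simulations (thousands of beads,
microseconds).  Desk-scale runs in the test-suite (about 100 proteins +
four 25-bead chains at the published number density, a 0.2 ns
strong-friction quench followed by a few ns of production) do reproduce
the qualitative phase behaviour - a $\lambda_{PP} = 4$ droplet persists
with $f_P \approx 1$ while a $\lambda_{PP} = 2$ droplet dissolves - but
they cannot resolve the multi-mode diffusion decomposition: with
$\sim 3\times10^4$ displacement samples per lag, histogram shot noise
exceeds the residual improvement that distinguishes a second mode, and the
selection criterion correctly returns $n = 1$.  Resolving the published
three- versus five-mode contrast requires roughly the published sampling
($10^6$ or more displacements over microsecond trajectories).  Similarly,
expulsion of DNA from a protein condensate under weak heterotypic coupling
is far slower than a desk-scale run, so composition tests assert the
protein-fraction contrast only.

## Numerical choices and degenerate inputs

* Harmonic prefactors are used exactly as printed (no 1/2).
* The angle force divides by $\sin\theta$, which vanishes at the straight
  equilibrium; the implementation switches to the analytic limit
  ($\theta \to \pi$) below $\sin\theta = 10^{-8}$.
* Positions are stored wrapped in $[0, L)$ with integer image counts;
  all chain metrics are computed on unwrapped coordinates, and
  `radius_of_gyration()` rejects chains whose bonds exceed half the box as
  evidence of wrapped input.
* The integrator aborts with a diagnostic when any half-step displacement
  exceeds half the box (time step too large, or overlapping start).
* Cell lists cap the cell count at roughly the bead count so sparse
  systems in large boxes do not pay for empty cells; below three cells per
  edge the all-pairs path is used.
* Degenerate analysis inputs reject loudly: empty profile member sets,
  lags that are not multiples of the frame interval, cutoffs at or above
  half the box, block schemes longer than the series.

## Problem sizes

Test and acceptance runs are sized for a single CPU: single-chain
equilibrium averages use a 250-bead chain with $10^3$-$1.5\times10^3$
pivot samples; condensation experiments use 100 proteins plus 100 DNA
beads at the published density (box 543 Å) for $3$-$4$ ns; property
suites use 150-500 beads.  The engine itself has no size constants and
accepts the full published geometry (10,000 beads, 2000 Å box).

## Known limitations

* No electrostatics, solvent, sequence specificity or DNA helical
  structure - deliberate absences of the minimal model.
* NVT Langevin only; no constant-pressure ensemble or constraints.
* The pivot sampler freezes bond lengths; use `run_langevin()` when bond
  fluctuations matter.
* Mode-count selection is only as good as the displacement statistics;
  with few samples it deliberately errs towards fewer modes.
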