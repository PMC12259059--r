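---
title: "A minimal coarse-grained model of protein-DNA condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal coarse-grained model of protein-DNA condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensr)
```

## The model

`condensr` implements a deliberately minimal coarse-grained model of
biomolecular condensates formed by DNA-binding proteins and DNA.  Each
protein is a single spherical bead (diameter $\sigma_P = 50$ Å, mass
5000 g/mol, roughly twice the radius of gyration of typical condensate
proteins); DNA is a bead-spring polymer with one bead per base pair
($\sigma_D = 5$ Å, 500 g/mol).  The DNA Hamiltonian has two bonded terms,

$$U_\text{bond} = K_b (r - r_0)^2, \qquad
  U_\text{angle} = K_\theta (\theta - \theta_0)^2,$$

with $K_b = 20$ kcal/mol/Å², $r_0 = 5.5$ Å, $\theta_0 = 180^\circ$, and
$K_\theta$ the knob controlling chain stiffness.  Note there is **no** 1/2
prefactor in either term: the spring constants multiply the squared
deviation directly, and the analytic forces implemented (and tested against
finite differences) correspond to exactly this form.

All nonbonded interactions use the Ashbaugh–Hatch potential, a
Lennard-Jones variant whose attractive well is scaled by a hydropathy
parameter $\lambda$ while the repulsive core is untouched:

$$U_{nb}(r) = \begin{cases}
  U_\text{LJ}(r) + (1 - \lambda)\,\epsilon, & r \le 2^{1/6}\sigma \\
  \lambda\, U_\text{LJ}(r), & r > 2^{1/6}\sigma,
\end{cases}$$

with $\epsilon = 0.2$ kcal/mol and the arithmetic mean as the combination
rule for $\sigma$ (so $\sigma_{PD} = 27.5$ Å).  Both branches meet
continuously at $-\lambda\epsilon$.  The two interaction strengths that
span the phase diagrams are the homotypic $\lambda_{PP}$ (protein–protein)
and heterotypic $\lambda_{PD}$ (protein–DNA) hydropathies; DNA–DNA
interactions are made purely repulsive with $\lambda_{DD} = -1$.  The
formula is applied literally for any $\lambda$, negative or above one.

### Numerical choices the model statement leaves open

* **Cutoff.** No cutoff is stated for the pair potential.  We truncate at
  $r_c = 3\sigma_{ij}$ per species pair and shift the energy so
  $U(r_c) = 0$: at $3\sigma$ the LJ tail is below 0.3 % of $\epsilon$, and
  shifting avoids the energy drift a plain truncation would inject into
  microcanonical integration.
* **Bonded exclusions.** Nonbonded interactions are excluded between 1–2
  and 1–3 bonded DNA neighbors.  With $r_0 = 5.5 \approx \sigma_D$, bonded
  neighbors sit inside the repulsive core and would otherwise fight the
  bond term.  The policy is exposed in the model object
  (`exclude_bonded`).
* **DNA–DNA repulsion.** Whether the $\lambda = -1$ interaction should
  additionally be truncated at the LJ minimum (WCA-style) is unstated; we
  apply the printed form literally, which leaves a weak repulsive tail
  beyond the minimum.  A dedicated test asserts the interaction is
  monotonically repulsive over its whole range.
* **Units.** Å, kcal/mol, g/mol internally, giving a derived time unit of
  $\sqrt{\text{g Å}^2\text{mol}/\text{kcal}} \approx 48.888$ fs; the user
  interface takes femtoseconds and $k_B = 0.0019872041$ kcal/mol/K.

## Dynamics

Langevin dynamics at 300 K with friction $\gamma_i = m_i/t_\text{damp}$,
$t_\text{damp} = 1000$ ps, integrated with a velocity-Verlet scheme at
$dt = 10$ fs.  The exact splitting within velocity-Verlet is not pinned
down by that description; we use the BAOAB discretization (friction and
fluctuation applied mid-step), which gives accurate configurational
sampling at this time step.  Three consequences we verify in the test
suite:

* with friction and noise off the integrator is symplectic velocity-Verlet
  (energy drift $< 10^{-3}$ relative over $10^4$ steps of a 400-bead
  fixture, linear momentum conserved to round-off);
* sampled kinetic temperature is within 2 % of 300 K;
* a free bead diffuses with $D = k_B T\, t_\text{damp}/m$ to within 5 %
  (about $4.99\times10^4$ Å²/ns for a protein bead).

Thermal noise comes from a counter-based RNG keyed by (seed, step,
particle), so trajectories are bit-reproducible, restartable mid-stream,
and independent of evaluation order.  Neighbor search uses a cell list
with a 15 Å skin rebuilt on half-skin displacement, and is tested for
exact equivalence with a brute-force $O(N^2)$ scan.

## Builders and the study conditions

The reference mixed system is 1:1 protein:DNA-bead stoichiometry — 5000
protein beads and 5000 DNA beads split into chains — in a 2000 Å periodic
cube, with all molecules initially placed randomly "at the center" of the
box.  We read that as uniform random placement of molecule centers inside
the central cube of half the box edge (the exact extent is unstated), which
seeds a single condensate; DNA chains are placed as equilibrium worm-like
conformations drawn by direct Boltzmann sampling, then a short force-capped
Langevin ramp (plus a brief cool quench) removes placement overlaps before
production.  Tests assert a minimum interparticle distance of
$0.8\,\sigma_{ij}$ after relaxation.

Desk-scale work uses reduced replicas of these conditions: the bundled
`mini-condensate` fixture (200 proteins + 4 × 50 bp, 600 Å box) and
two-chain 250-bp systems for compaction studies.

## Analyses

**Clustering.** Molecules are connected when any bead of one is within a
cutoff of any bead of the other (minimum image); clusters are connected
components, computed molecule-level.  The quoted criterion is a single
cutoff of $1.5\sigma_{PD} = 41.25$ Å — but that distance is *smaller than
the protein–protein contact distance* $2^{1/6}\sigma_P \approx 56$ Å, so
taken literally it can never connect two touching proteins: a stable
protein droplet reads as a gas of singletons (we verified this on a
60-protein droplet at $\lambda_{PP} = 4$).  Since protein-only condensates
manifestly do appear in the phase diagrams, `find_clusters()` keeps the
literal fixed cutoff as its default (so the printed threshold arithmetic
holds exactly) and offers a per-pair *contact* criterion,
$d \le 1.5\sigma_{ij}$ (75 Å for P–P, 41.25 Å for P–D), which reduces to
the quoted value for protein–DNA pairs and resolves protein-only
condensates.  Trajectory-level observables (largest-cluster fractions,
density-profile centering) default to the contact criterion.
Largest-cluster protein and DNA fractions are the phase-diagram
observables; molecule counting is the default with a bead-count option,
since which of the two the original fractions used is ambiguous.

**DNA shape.** Per-chain radius of gyration on unwrapped coordinates
(image flags are carried in every frame; unwrapped trajectories are
continuous, so chains stay whole).  The persistence length comes from the
bond-vector correlation $\langle\cos\theta(s)\rangle = e^{-s r_0/l_p}$,
fitted on a window from one bond up to $\min(l_p, L/4)$, iterated once —
wider windows pick up finite-chain end effects, shorter ones waste data.
For the bonded-only chain the model factorizes, so direct Boltzmann
sampling of bond lengths ($\propto r^2 e^{-\beta K_b(r-r_0)^2}$) and bend
angles ($\propto \sin\delta\, e^{-\beta K_\theta \delta^2}$) generates
exact equilibrium conformations; the test suite cross-validates this
sampler against Langevin dynamics and uses the discrete worm-like-chain
closed form
$R_g^2 = l_p L/3 - l_p^2 + 2 l_p^3/L\,[1 - (l_p/L)(1 - e^{-L/l_p})]$
as an independent oracle (294 Å for the 250-bp chain at
$K_\theta = 20$, matching the ~295 Å plateau of the free chain).

**Binding.** A protein is DNA-bound when its minimum distance to any DNA
bead is at most $\sigma_P + \sigma_D = 55$ Å.

**Density profiles and coexistence.** Protein number density in spherical
shells about the largest cluster's protein center of mass.  The center is
computed by circular-coordinate averaging per axis, which is robust when a
cluster straddles the periodic boundary.  Shells are fitted with

$$\rho(r) = \rho_\text{dil} + \sum_{k} \frac{\Delta\rho_k}{2}
  \left[1 - \tanh\!\left(\frac{r - R_k}{w_k}\right)\right],$$

with one interface for ordinary droplets and two for multiphasic
condensates (a DNA-bound core inside a protein shell); any algebraically
equivalent two-interface sigmoid would do, and correctness is defined by
recovery tests on synthetic profiles (exact on noiseless data, interface
radii within 5 % under 5 % multiplicative noise).  The fit is
Levenberg–Marquardt with multiple starts, weighted by the square root of
the shell volume because Poisson shot noise scales as
$1/\sqrt{\text{volume}}$ — without this the tiny innermost shells dominate
and bias the plateau.  The double form is preferred over the single one
only when it cuts the residual norm by a configurable factor (default
10 %) and neither interface has collapsed.  Dense/dilute coexistence
concentrations come from the innermost plateau and from the
volume-weighted density beyond the outermost interface plus two widths;
a system is declared homogeneous (dense phase undefined, dilute $= N/V$)
unless the measured — not merely fitted — density contrast exceeds 2 and
the putative dense region holds at least 10 particles.  Densities are
reported natively in beads/Å³ with a configurable conversion factor
(× $1.66\times10^6$ for mM), since the original axis units are not stated
in the text available to us.

**Block averaging.** Time series are cut into five equal blocks, the first
(20 %) discarded for equilibration, and means/standard errors computed over
the remaining four — the stated protocol, with both knobs configurable.

**Diffusion modes.** The radial displacement distribution of proteins at
lag $t$,

$$P(r, t) = \sum_{i=1}^{n} p_i\, \frac{4\pi r^2}{(4\pi D_i t)^{3/2}}
  e^{-r^2/4 D_i t}, \qquad \sum_i p_i = 1,$$

is fitted in histogram space by Poisson-weighted least squares with a
softmax parameterization of the weights (simplex constraint) and log
diffusivities (positivity).  Displacements are accumulated over all
proteins and sliding origins strided by the lag to curb autocorrelation.
Binning is Freedman–Diaconis on the pooled sample, with the width capped
at half the 2nd percentile of the displacements: diffusivities spread over
decades would otherwise bury the slowest mode inside a single bin.
Initialization combines an expectation-maximization pass on the raw radii
(exact for this mixture family) with 20 random log-spaced starts, because
the least-squares surface is multimodal.  "Increase $n$ until the fit
achieves minimal residuals" is made operational as: accept $n+1$ only if
the weighted residual norm improves by more than 10 % (configurable).
Recovery tests: a 3-mode and a 5-mode synthetic mixture with 10× separated
diffusivities are recovered with weights within ±0.05 and diffusivities
within ±10 %, $\sum_i p_i 6 D_i t$ matches the sample $\langle r^2\rangle$
within 5 %, and the selector returns $n = 1, 3, 5$ on matching data.
Lag-stability reports per-mode coefficients of variation across lags
(diffusive modes are lag-stable; a ballistic control is flagged).

## What the synthetic generators emulate — and what they do not

The closed-loop generators (`generate_synthetic`) produce Brownian
trajectories, mixture displacements, tanh profiles, sphere-in-gas
configurations and worm-like-chain ensembles with known ground truth, so
every analysis has a test in which the right answer is known exactly.
They emulate the *statistical shape* of condensate data: they do not
contain interacting dynamics, interconversion of proteins between modes
within a lag, interface fluctuations, or correlated noise.  Passing the
recovery tests therefore certifies the estimators, not the realism of any
particular simulation; the simulation-side tests (condensation of the
mini-condensate, DNA compaction) close that second half at reduced scale.

## Problem sizes and equilibration choices

Desk-scale defaults were chosen so the whole suite runs on one CPU in
minutes: 400-bead fixtures for integrator checks, 343 free beads over 6 ns
for the Einstein relation, 400 chains for free-chain statistics, and
$2\text{–}4\times10^5$ displacement samples for mixture recovery.

The compaction experiment (two 250-bp chains + 500 proteins at
$\lambda_{PP} = \lambda_{PD} = 2$, 900 Å box at the reference particle
density) is the one observable whose equilibration genuinely exceeds desk
scale: a protein-bridged, semi-stiff 250-bp chain folds over microseconds
of model time, and the full-scale study equilibrated for 400 ns before
sampling 1.6 µs.  The package therefore ships an equilibrated snapshot of
this reduced system (`inst/extdata`, loaded by
`read_equilibrated_state()`), prepared with the package itself in three
stages: a central-random build; a collapse anneal at temporarily
strengthened heterotypic coupling (which accelerates folding but arrests
if pushed too far — a fully protein-coated chain stiffens); and a long
re-equilibration at the target Hamiltonian.  The preparation was
validated by bracketing: an independent run started from the extended
(freshly built) state descends into the same radius-of-gyration band that
the annealed state relaxes into, so the snapshot sits in the equilibrium
basin rather than in an artifact of the anneal.  The compaction test then
runs production from this snapshot, checks stationarity (the state
neither collapses further nor unfolds over the measurement window) and
measures the block-averaged DNA radius of gyration.  Equilibration legs
use $t_\text{damp} = 100$ ps and $dt = 20$ fs: equilibrium conformations
are independent of the friction and, at these soft potentials, of the
step within the stable range — the tighter coupling simply removes
condensation heat faster (the reference damping of 1000 ps takes
~$10^5$ steps just to relax temperature).  With only two chains the
condensate is smaller and bridging partners fewer than in the 20-chain
system, so the reduced system's equilibrium compaction is expected to be
somewhat weaker than the full-scale band.

## Known limitations

* No electrostatics, sequence specificity, helical geometry or solvent —
  inherited from the minimal model itself.
* The reduced-scale sweeps classify phase regimes qualitatively; absolute
  largest-cluster fractions at 200–1000 beads are not converged to the
  full-system values.
* Glassy kinetics at strong heterotypic coupling: deep DNA compaction can
  take microseconds of model time; desk-scale runs bracket it from the
  extended side and are validated against the regime boundaries rather
  than the fully converged values.
* The trajectory container is R-native serialization plus extended-XYZ
  text export; there is no GSD/DCD writer in this environment.

## A worked micro-example

```{r example, eval = FALSE}
model <- interaction_model(lambda_pp = 2, lambda_pd = 0.5)
sys <- make_fixture("mini-condensate", model)
traj <- run_simulation(sys$topology, sys$config, model,
                       thermostat_params(seed = 1), n_steps = 2e4,
                       cadence = 1e3)
largest_cluster_fractions(traj)$protein
dna_rg(traj)$stats
```
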