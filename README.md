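# condensr

Coarse-grained simulation and analysis of protein–DNA biomolecular
condensates in R.

Membraneless organelles form when DNA-binding proteins and DNA phase
separate into dense droplets.  `condensr` implements a minimal
coarse-grained model of that process — single-bead proteins
(σ<sub>P</sub> = 50 Å, 5000 g/mol) and bead-spring DNA (one bead per base
pair, σ<sub>D</sub> = 5 Å, 500 g/mol) — together with every analysis a
condensate study needs, for researchers who want a fully scriptable,
deterministic, desk-scale sandbox for condensate physics.

**Energy function.**  DNA is held together by harmonic bonds and angles
(no 1/2 prefactors),

    U_bond  = K_b (r − r₀)²            K_b = 20 kcal/mol/Å²,  r₀ = 5.5 Å
    U_angle = K_θ (θ − θ₀)²            θ₀ = 180°, K_θ sets DNA stiffness

and all nonbonded pairs interact through the Ashbaugh–Hatch potential, a
Lennard-Jones variant whose attractive branch is scaled by a hydropathy
parameter λ:

    U(r) = U_LJ(r) + (1 − λ) ε      for r ≤ 2^(1/6) σ
         = λ U_LJ(r)                otherwise            (ε = 0.2 kcal/mol)

Homotypic (λ_PP, protein–protein) and heterotypic (λ_PD, protein–DNA)
interaction strengths are the control parameters of the phase diagram;
DNA–DNA is purely repulsive (λ_DD = −1).  Dynamics are Langevin at 300 K
(γ_i = m_i / 1000 ps) with a BAOAB velocity-Verlet integrator at 10 fs,
compiled in C++ for desk-scale throughput.

Analyses: molecule-level clustering (any-bead cutoff 1.5 σ_PD) and
largest-cluster composition; DNA radius of gyration and persistence
length; DNA-bound protein fraction (cutoff σ_P + σ_D); radial density
profiles about the condensate with single/double hyperbolic-tangent
interface fits and coexistence concentrations; block averaging; and a
multi-mode decomposition of protein displacement distributions

    P(r, t) = Σᵢ pᵢ 4πr² (4πDᵢt)^(−3/2) exp(−r²/4Dᵢt),   Σᵢ pᵢ = 1,

which resolves coexisting fast (dilute), interfacial, condensed and
DNA-bound protein populations that a plain mean-square displacement would
average away.

## A worked example

```r
library(condensr)

model <- interaction_model(lambda_pp = 2, lambda_pd = 0.5)
sys   <- make_fixture("mini-condensate", model)   # 200 proteins + 4 x 50 bp
traj  <- run_simulation(sys$topology, sys$config, model,
                        thermostat_params(seed = 1),
                        n_steps = 20000, cadence = 1000)
#> condensr: 400 particles, 20000 steps, dt = 10 fs, T = 300 K

largest_cluster_fractions(traj)$protein
#> block mean = 0.930312 +/- 0.0261 (SE over 4 blocks)

dna_rg(traj)$stats
#> block mean = 73.2509 +/- 0.178 (SE over 4 blocks)
```

The largest-cluster protein fraction ~0.93 says that in this centrally
seeded fixture most proteins sit in a single cluster throughout the run;
the mean DNA radius of gyration ~73 Å for a 50-bp chain (close to the
free-chain value of ~78 Å) says that at this moderate heterotypic
coupling the chains are recruited but barely compacted.

A single free 250-bp chain is best sampled directly (the bonded chain
Hamiltonian factorizes, so `sample_wlc_chain()` draws exact equilibrium
conformations):

```r
ens <- generate_synthetic("wlc-chain-ensemble",
                          list(n_beads = 250L, n_chains = 400L), seed = 101)
mean(vapply(ens$chains, radius_of_gyration, numeric(1)))
#> [1] 293.2271
wlc_rg_theory(250)$rg   # discrete worm-like-chain closed form
#> [1] 294.0993
```

## Command line

A thin CLI ships in `inst/cli/condensr`:

```sh
condensr simulate --config run.yaml --out traj.rds
condensr analyze-structure --traj traj.rds --out structure.csv --report rep.json
condensr analyze-dynamics --traj traj.rds --lags 1,2,4 --out dynamics.json
condensr sweep --config run.yaml --grid grid.csv --out sweep.csv
```

Configs are validated YAML (unknown keys rejected); every run writes a
manifest (config hash, seed, versions) sufficient to reproduce it exactly.

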