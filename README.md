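# qneo

Quantum-circuit simulation of proton-transfer kinetics with a
quantum-mechanically treated proton, in the nuclear–electronic orbital (NEO)
framework — implemented end to end in R.

## The problem

Proton-transfer reactions (enzyme catalysis, redox chemistry, tautomerization)
are governed by light nuclei for which the classical Arrhenius picture fails:
zero-point energy, delocalization and tunneling change the effective barrier.
The NEO approach treats the transferring proton quantum mechanically alongside
the electrons, with a coupled second-quantized Hamiltonian

    H = E_core + Σ_pq h_pq a†_p a_q + ½ Σ_pqrs ⟨pq|rs⟩ a†_p a†_q a_s a_r
        + Σ_PQ v_PQ a†_P a_Q + Σ_PQpq g_PQpq a†_P a_Q a†_p a_q

(lower-case indices: electronic orbitals; upper-case: protonic orbitals; all
integrals in Hartree, the protonic kinetic energy folded into `v_PQ`). A
reaction pathway is described by three such Hamiltonians — reactant (Left),
transition (Middle), product (Right) — and a convex interpolation

    H(t) = α(t) H_Left + β(t) H_Middle + γ(t) H_Right,

labelled by digit triples `300 … 003`. The quantity of interest is the
effective quantum barrier ΔE = E_Middle − E_Left and the Eyring-type rate

    k(T) = (k_B T / h) · exp(−ΔE / k_B T),

whose exponential sensitivity makes barrier accuracy the central figure of
merit: a barrier error δE produces a fractional rate error δk/k ≈ −δE/k_B T.

## What the package does

For whom: method developers studying how quantum-circuit state preparation,
circuit compression and error mitigation degrade barrier heights and kinetics,
at desk scale, without any quantum-computing runtime dependency.

* `neo_hamiltonian`, `hamiltonian_io` — data model with validated symmetries
  and two text dialects (`neo-json`, FCIDUMP-style `neo-fcidump` with
  `&NEO_V1P` / `&NEO_GEP` extension blocks); `interpolate_hamiltonians`,
  `lmr_weights`, `lowdin_orthogonalize`, `fno_select`.
* `map_to_qubits` — Jordan–Wigner encoding (electronic spin-up block,
  spin-down block, protonic block).
* `casci_solve` — exact sector diagonalization (determinant CI), plus
  `hf_product_energy`, `reduced_density_matrices`, `entanglement_entropy`,
  `proton_density_and_position`.
* `build_pool`, `run_adapt_vqe` — ADAPT-VQE over the coupled
  electronic/protonic/mixed excitation pool (fermionic or split-Pauli qubit
  variant), BFGS with analytic gradients.
* `run_adapt_aqc`, `compress_with_prefix`, `circuit_metrics` — adaptive
  approximate quantum compiling into two-qubit blocks (rx/ry/rz/cx gate set).
* `build_noise_model`, `fold_circuit`, `noisy_expectation`,
  `zne_extrapolate` — device-style noise (depolarizing + thermal relaxation +
  readout flips), randomized gate folding, and zero-noise extrapolation of the
  barrier in fit-first and difference-first modes with bootstrap errors.
* `tst_rate`, `rate_suppression`, `barrier_tolerance` — TST kinetics and
  sensitivity analysis.
* `make_double_well_triple`, `make_random_neo` — seeded synthetic fixtures
  with exact symmetries and closed-form limits.
* `run_pipeline` — the full workflow with tabular reports.

## Worked example

```r
library(qneo)
spec <- double_well_spec()           # 2 electronic spatial + 2 protonic orbitals
tri  <- make_double_well_triple(spec)
h    <- interpolate_hamiltonians(tri$left, tri$middle, tri$right, lmr_weights("030"))
exact <- casci_solve(h)
ref  <- hf_reference_bits(tri$left)
vqe  <- run_adapt_vqe(map_to_qubits(h), build_pool(h$space, ref), ref,
                      preset = "custom", tol = 1e-8, reference_energy = exact$energy)
aqc  <- run_adapt_aqc(vqe$state, preset = "high", seed = 1)
bL   <- casci_solve(tri$left)$energy
```

printed output (deterministic):

```
<casci_result> E = 0.1039584318 Ha over 12 determinants
<vqe_result> E = 0.1039584411 Ha after 6 iterations (custom, converged)
<aqc_result> high: cost 9.591e-05, fidelity 0.9999, 1 blocks, 2Q count 3 depth 3
barrier: 11.2115 mHa
k(120 K) = 3.848e-01 1/s
rate suppression for a +1.57 mHa barrier error: 98%
entanglement entropy (middle): 0.00098
```

Reading: the exact (CASCI) transition-state energy over the 12-determinant
sector; ADAPT-VQE converging to it within 1e-8 Ha in 6 iterations; the
compiled circuit reproducing the state with fidelity 0.9999 using three CX
gates; an 11.2 mHa barrier giving a rate of 0.38 s⁻¹ at 120 K; and the
kinetic stake — overestimating that barrier by just 1.57 mHa suppresses the
computed rate by 98%.

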