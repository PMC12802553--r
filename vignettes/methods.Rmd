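---
title: "Methods: coupled electron-proton quantum simulation of transfer kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled electron-proton quantum simulation of transfer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qneo)
```

# The model

`qneo` simulates proton transfer with one quantum proton in the
nuclear-electronic orbital (NEO) picture. The Hamiltonian over a declared
orbital space couples an electronic block (one- and two-body integrals
`h_pq`, `<pq|rs>` over spatial orbitals, physicist ordering, 8-fold real
permutational symmetry), a protonic one-body block `v_PQ` with the proton
kinetic energy folded in, and a bilinear electron-proton coupling tensor
`g_PQpq`. Because exactly one proton is present it is kept in a single spin
channel: one Jordan-Wigner qubit per protonic orbital, two per electronic
spatial orbital. The qubit layout is fixed and documented (spin-up block,
spin-down block, protonic block, ascending orbital index) so that circuits,
determinants and serialized states are interchangeable across runs.

The reaction pathway is represented by a Left/Middle/Right Hamiltonian triple
and the convex interpolation `H = alpha H_L + beta H_M + gamma H_R`. Digit
labels (`300`, `210`, ..., `003`) are normalized by their digit sum; this
normalization is this package's own convention (the three-digit labels fix
only relative weights), chosen so every trajectory point is a convex
combination and the canonical seven labels sum to 3.

The kinetic observable is the Eyring-type rate
`k(T) = (k_B T/h) exp(-dE / k_B T)` with the effective quantum barrier
`dE = E_Middle - E_Left`. The prefactor convention is recorded in every
`rate_curve`; all suppression and sensitivity results are formulated as rate
*ratios*, which are prefactor-free (the package asserts this in its tests).
Constants: CODATA, with `k_B = 3.166811563e-6 Ha/K` centralized in
`qneo_constants`. Thermal and entropic corrections are intentionally outside
the model.

# Exact reference

`casci_solve` enumerates the fixed-particle-number determinant basis
(lexicographic occupation bitmasks, electronic index fastest, fermionic signs
from ascending creation order) and evaluates matrix elements by direct ladder
operator application -- deliberately a different route from the Pauli/qubit
representation, so the two can cross-validate each other. Sectors at desk
scale are small (tens to hundreds of determinants); dense symmetric
diagonalization is used throughout with an eigenpair residual check at 1e-8.
A matrix-free iterative solver is unnecessary at the problem sizes this
package targets and was left out; `max_dim` guards against accidental
explosions.

Reduced one-particle density matrices are computed per species; the
proton-electron entanglement entropy is the von Neumann entropy of the proton
subsystem obtained by contracting the CI amplitude matrix (with one proton
this coincides with the protonic 1-RDM spectrum). The logarithm base is
natural by default with a base-2 option, since reference entropy tables in
this field rarely state the base and the package should allow both readings.

Real-space proton densities assume an *orthonormal* orbital grid
representation. Non-orthogonal Gaussian site bases must be Loewdin-
orthogonalized first (`lowdin_orthogonalize`); the acceptance tests
demonstrate this workflow. Densities are non-negative by construction for a
PSD density matrix and integrate to the matrix trace within quadrature error.

# ADAPT-VQE

The ansatz grows one generator at a time from the pool of spin- and
number-conserving excitations (electronic singles/doubles, protonic singles
-- protonic doubles require at least two protons and are empty here -- and
mixed electron-proton doubles), each mapped to its anti-Hermitian
Jordan-Wigner image. Selection uses the commutator gradient
`<[H, tau]> = 2 Re <psi|H tau|psi>`, ties broken by lowest pool index. After
each addition all parameters are re-optimized (BFGS, analytic reverse-sweep
gradients, gradient infinity-norm 1e-7 scale); a `reoptimize = FALSE` mode
optimizes only the newest parameter, since published ADAPT protocols differ
on this point and both are defensible. Exponentials of generators act on
statevectors through a scaled Taylor expansion (sub-step norm kept at or
below 1, each sub-step converged to 1e-15), which is exact to round-off for
any parameter value the optimizer visits.

Stopping: with a reference energy, `|E - E_ref| < tol` (deep preset 1e-3 Ha,
shallow 1e-2 Ha -- the two accuracy tiers of the workflow); without one, the
maximum pool gradient. A stagnation guard halts with a warning if the
gradient stays above tolerance while the energy no longer moves. Energies are
non-increasing across iterations by construction (the previous parameter
vector is always feasible); the test suite asserts this on every logged run.

The qubit-pool variant splits each fermionic generator into its individual
Pauli strings (each `i P` is anti-Hermitian) and deduplicates. Full JW
strings including Z chains are the default; a `drop_z` flag provides the
Z-dropped variant found in parts of the qubit-pool literature. Neither is
asserted to be "the" reference choice.

# Adaptive approximate quantum compiling

The compiler grows a two-qubit-block circuit `V(theta)|0>` that approximates
a target state under the fidelity cost `C = 1 - |<target|V|0>|^2`. The
design choice that matters: a strictly greedy overlap maximizer dead-ends on
fidelity plateaus -- for a GHZ-type target *no* single two-qubit block can
raise the overlap of a product state beyond 1/2, yet three blocks prepare it
exactly. The implementation therefore builds the inverse circuit by
*disentangling* the target toward a product state. For each candidate pair it
considers (a) a closed-form SVD-optimal block alternated with product-state
re-alignment, and (b) rank-sorting disentanglers from the pair's reduced
density matrix; candidates are ranked by achieved product overlap, with total
single-qubit purity as the plateau tie-break. The reported per-block cost
`1 - F` is non-increasing by construction, and stagnation (no fidelity *and*
no purity progress) is flagged not-converged. The final single-qubit
alignment layer is free (it does not count toward two-qubit metrics).

Every block is emitted in the rx/ry/rz/cx gate set through a 15-parameter
universal two-qubit template (3 CX), fitted to the closed-form block unitary
by seeded BFGS restarts to ~1e-13; a closed-form ZYZ decomposition handles
the local layer. Presets: `high` stops at cost 1e-2 with a generous block
budget (8n), `low` at 5e-2 with a tight budget (n/2 blocks). These presets
are this package's own calibration of the high/low-fidelity trade-off; they
guarantee, run against run with the same seed, that the high-preset result
extends the low-preset one, hence fidelity(high) >= fidelity(low) and
depth(low) <= depth(high). Statevector evaluation limits targets to about 24
qubits; tensor-network backends are out of scope, but the prefix
factorization contract (`compress_with_prefix`: compress `U_0|0>`, keep
`U_1`) is implemented and tested.

# Noise and zero-noise extrapolation

`build_noise_model` ingests a per-qubit device table (T1/T2, gate error
rates, durations, readout flip probabilities; validated, including
T2 <= 2 T1). Composition order is fixed: a depolarizing Pauli error drawn
from the gate's error rate, then per-qubit thermal relaxation over the gate
duration (amplitude damping as a sampled generalized measurement; residual
pure dephasing `1/T_phi = 1/T2 - 1/(2 T1)` as a stochastic Z), and readout
bit-flips on sampled outcomes. Simulation is by Kraus-sampled statevector
trajectories -- one channel realization per shot -- matching a shot-based
protocol and avoiding density matrices. Expectation values partition the
Hamiltonian into qubit-wise commuting groups measured in rotated bases; per
shot one trajectory is shared across groups (unbiased, cheaper, outcomes
across groups correlated within a shot). All sampling is bit-reproducible
given the seed.

Gate folding replaces randomly selected two-qubit gates `G` by `G G' G`
(uniform without replacement) until the two-qubit count is the nearest
achievable integer to `lambda` times the original; the noiseless unitary is
preserved to 1e-10 and `lambda = 3` folds every gate once. The default
lambda grid is the integers 1..4 (the reference protocol states only the
interval [1, 4]; the grid is configurable) with randomized-folding
replicates per lambda.

`zne_extrapolate` implements both estimators for the barrier: *fit first*
(per-configuration OLS fit of the per-lambda mean energies, quadratic by
default; barrier = difference of intercepts, uncertainties in quadrature)
and *difference first* (per-lambda Middle-Left differences, linear fit by
default; intercept and its standard error). Model defaults follow the usage
of the two estimators in the reference protocol. The nonparametric bootstrap
resamples circuits within each lambda independently per configuration --
appropriate because Left and Middle runs share no randomness; consequently
for artificially common-mode noise the bootstrap does not reproduce the
pairing advantage that the analytic difference-first standard error shows,
and the tests construct both situations explicitly.

# Synthetic world

`make_double_well_triple` is the package's stated test world: a proton in a
two-site double well (tunneling `t_p = 4 mHa`, site asymmetry
`delta = 6 mHa`, Middle well raise `8 mHa`) coupled with strength
`g0 = 3 mHa` to the 1<->2 transition of a two-orbital electronic space (gap
0.5 Ha, on-site repulsion 0.1 Ha), 2 electrons -- six qubits in total.
Values were chosen once so that the exact barrier (11.2 mHa) and the
correlation energies (1-10 mHa) sit in the regime typical of small coupled
electron-proton active spaces, and are not revisited. Known limits are exact:
at `g0 = 0` the protonic ground energy is `-sqrt(delta^2 + t_p^2)` relative
to the well mean, Left and Right are exact mirror images (site swap combined
with an electronic phase flip), the barrier is monotone in the well raise,
and the proton-electron entanglement entropy grows strictly with `g0` from
exactly zero.

What the generator does *not* emulate: realistic integral magnitudes and
orbital shapes of a molecular NEO calculation, basis-set and frozen-core
effects, and correlation strong enough to separate the deep/shallow VQE
tiers -- at these couplings the Hartree-Fock product already sits within the
shallow (1e-2 Ha) tolerance, so shallow runs may legitimately terminate at
the reference determinant and compress to zero two-qubit gates. A green
pipeline test therefore establishes internal consistency of the method
stack, not chemical accuracy for any real molecule. `make_random_neo`
provides unstructured seeded instances (exactly symmetrized) for
property-style testing against the dense-diagonalization oracle.

# Numerical choices

* Validation tolerances: Hermiticity/permutation symmetry 1e-8 on read
  (configurable); round trips are exact to 1e-12.
* Degenerate inputs: zero-digit labels, empty pools and sectors, T2 > 2 T1,
  non-SPD overlaps, and dimension mismatches raise immediate, named errors.
* Determinism: every stochastic stage takes an explicit seed; the pipeline
  re-run with an identical config is byte-identical.
* The optional display offset (+265 mHa, off by default) only shifts printed
  absolute energies in reports, never stored data, mirroring the common
  practice of offsetting absolute energies for readability.
* The accession-data route (loading the published Hamiltonians) is an I/O
  exercise by construction -- `hamiltonian_io` defines this package's own
  dialects; no claim is made that they match the deposited serialization,
  and a converter would be needed to ingest it.

# Limitations

Statevector scale (<= ~24 qubits aligned with desk hardware); ground states
only; one quantum proton; no vendor transpilation (two-qubit metrics are
computed on the logical circuit, so gate counts are not comparable to
device-routed figures); no probabilistic error amplification/cancellation;
kinetics without thermal/entropic corrections or transmission coefficients.
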