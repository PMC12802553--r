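# Pool construction, gradients, the ADAPT loop, fidelity.

test_that("pool enumeration matches direct combinatorics", {
  sp <- orbital_space(2, 2, n_electrons = 2)
  tri <- make_double_well_triple()
  ref <- hf_reference_bits(tri$left)  # up0, dn0, proton site 1
  pool <- build_pool(sp, ref)
  kinds <- vapply(pool, `[[`, character(1), "kind")
  # 1 occupied + 1 virtual per spin -> 2 e-singles; 1 p-single;
  # Sz-conserving ee-doubles from occupied pair (up0, dn0): virtual pairs with
  # one up + one dn -> 1; ep-doubles: 2 e-singles x 1 p-single -> 2
  expect_equal(sum(kinds == "e-single"), 2L)
  expect_equal(sum(kinds == "p-single"), 1L)
  expect_equal(sum(kinds == "ee-double"), 1L)
  expect_equal(sum(kinds == "pp-double"), 0L)  # single proton
  expect_equal(sum(kinds == "ep-double"), 2L)
  # all generators are anti-Hermitian and particle conserving
  for (op in pool) {
    M <- qneo:::pauli_matrix(op$pauli)
    expect_lt(max(Mod(M + Conj(t(M)))), 1e-12)
  }
  expect_error(build_pool(orbital_space(1, 1, 2), 7L), "empty-pool")
})

test_that("qubit pool splits generators into distinct Pauli strings", {
  sp <- orbital_space(2, 2, n_electrons = 2)
  ref <- qneo:::determinant_bits(sp, 1, 1, 1)
  pool <- build_pool(sp, ref)
  ep <- pool[vapply(pool, `[[`, character(1), "kind") == "ep-double"][[1]]
  qops <- qneo:::split_qubit_pool(list(ep), qneo:::space_n_qubits(sp))
  # string count equals the number of distinct Pauli terms in the JW image
  expect_equal(length(qops), length(ep$pauli$x))
  for (op in qops) {
    expect_equal(length(op$pauli$x), 1L)
    M <- qneo:::pauli_matrix(op$pauli)
    expect_lt(max(Mod(M + Conj(t(M)))), 1e-12)  # i * P is anti-Hermitian
  }
  # full qubit pool deduplicates across generators
  qpool <- build_pool(sp, ref, variant = "qubit")
  keys <- vapply(qpool, function(o) paste(o$pauli$x, o$pauli$z), character(1))
  expect_false(anyDuplicated(keys) > 0)
  # Z-dropped variant only shortens strings
  qz <- build_pool(sp, ref, variant = "qubit", drop_z = TRUE)
  expect_lte(length(qz), length(qpool))
})

test_that("commutator gradient matches central finite differences", {
  h <- make_double_well_triple()$middle
  H <- map_to_qubits(h)
  ref <- hf_reference_bits(h)
  pool <- build_pool(h$space, ref)
  for (s in 1:8) {
    v <- random_state(H$n_qubits, seed = 400 + s)
    op <- pool[[1 + (s %% length(pool))]]
    g <- pool_gradient(op, v, H)
    ee <- function(th) {
      w <- qneo:::pauli_exp_apply(op$pauli, th, v)
      Re(qneo:::pauli_expectation(H$pauli, w))
    }
    fd <- (ee(1e-5) - ee(-1e-5)) / 2e-5
    expect_lt(abs(g - fd), 1e-6)
  }
})

test_that("gradients vanish at the HF reference of a non-interacting H", {
  sp <- orbital_space(2, 2, n_electrons = 2)
  h <- neo_hamiltonian(sp, 0, diag(c(-1, 1)), array(0, rep(2, 4)),
                       diag(c(-0.5, 0.5)), array(0, c(2, 2, 2, 2)))
  H <- map_to_qubits(h)
  ref <- hf_reference_bits(h)
  v <- complex(2^H$n_qubits); v[ref + 1] <- 1
  pool <- build_pool(h$space, ref)
  for (op in pool) expect_lt(abs(pool_gradient(op, v, H)), 1e-12)
  res <- run_adapt_vqe(H, pool, ref, preset = "custom", gradient_tol = 1e-8)
  expect_equal(res$iterations, 0L)
  expect_equal(res$energy, hf_product_energy(h), tolerance = 1e-12)
  expect_true(res$converged)
})

test_that("full-pool ADAPT-VQE reaches CASCI; energies monotone", {
  tri <- make_double_well_triple()
  h <- tri$middle
  H <- map_to_qubits(h)
  exact <- casci_solve(h)
  ref <- hf_reference_bits(tri$left)
  pool <- build_pool(h$space, ref)
  res <- run_adapt_vqe(H, pool, ref, preset = "custom", tol = 1e-8,
                       reference_energy = exact$energy)
  expect_true(res$converged)
  expect_lt(abs(res$energy - exact$energy), 1e-7)
  expect_true(all(diff(res$trace$energy) <= 1e-10))
  # particle numbers conserved on the ansatz state
  nums <- number_expectations(h$space, res$state)
  expect_equal(nums$electrons, 2, tolerance = 1e-10)
  expect_equal(nums$protons, 1, tolerance = 1e-10)
  # fidelity against the exact state
  expect_gt(state_fidelity(casci_statevector(exact), res$state), 1 - 1e-6)
})

test_that("newest-parameter-only optimization mode also descends", {
  tri <- make_double_well_triple()
  h <- tri$left
  H <- map_to_qubits(h)
  exact <- casci_solve(h)
  ref <- hf_reference_bits(tri$left)
  pool <- build_pool(h$space, ref)
  res <- run_adapt_vqe(H, pool, ref, preset = "custom", tol = 1e-6,
                       reference_energy = exact$energy, reoptimize = FALSE)
  expect_true(all(diff(res$trace$energy) <= 1e-10))
  expect_lt(res$energy - exact$energy, 1e-3)
})

test_that("state_fidelity basics", {
  v <- random_state(3, seed = 9)
  expect_equal(state_fidelity(v, v), 1, tolerance = 1e-12)
  e1 <- complex(8); e1[1] <- 1
  e2 <- complex(8); e2[2] <- 1
  expect_equal(state_fidelity(e1, e2), 0)
  w <- random_state(3, seed = 10)
  expect_equal(state_fidelity(v, w), state_fidelity(w, v), tolerance = 1e-12)
  expect_error(state_fidelity(v, random_state(2, 1)), "dimensions differ")
})
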