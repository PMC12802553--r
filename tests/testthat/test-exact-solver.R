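# CASCI solver, reference energies, density matrices, entropy, densities.

test_that("separable limit: energy is the sum of occupied one-body levels", {
  sp <- orbital_space(2, 2, n_electrons = 2)
  h <- neo_hamiltonian(sp, core_energy = 0.25,
                       h1e = diag(c(-2, 1)), h2e = array(0, rep(2, 4)),
                       v1p = diag(c(0.4, -0.6)), gep = array(0, c(2, 2, 2, 2)))
  res <- casci_solve(h)
  expect_equal(res$energy, 0.25 + 2 * (-2) + (-0.6), tolerance = 1e-12)
  expect_equal(hf_product_energy(h), res$energy, tolerance = 1e-12)
  expect_equal(sum(Mod(res$ci_vector)^2), 1, tolerance = 1e-12)
})

test_that("casci agrees with the JW-side dense sector oracle (seeded)", {
  for (s in 1:12) {
    h <- make_random_neo(2, 2, 2, seed = 100 + s)
    expect_lt(abs(casci_solve(h)$energy - jw_sector_ground(h)), 1e-10)
  }
  # one larger instance
  h8 <- make_random_neo(3, 2, 2, seed = 200)
  expect_lt(abs(casci_solve(h8)$energy - jw_sector_ground(h8)), 1e-10)
})

test_that("HF-product energy bounds CASCI and matches the dense oracle", {
  for (s in 1:6) {
    h <- make_random_neo(2, 2, 2, seed = 300 + s)
    e_hf <- hf_product_energy(h)
    expect_gte(e_hf, casci_solve(h)$energy - 1e-12)
    # dense oracle: diagonal element of the kron matrix at the HF bitstring
    M <- kron_neo_matrix(h)
    bits <- hf_reference_bits(h)
    expect_equal(e_hf, Re(M[bits + 1, bits + 1]), tolerance = 1e-10)
  }
})

test_that("barrier arithmetic reproduces printed reference differences", {
  expect_equal(barrier_height(-565.358, -578.785), 13.427, tolerance = 1e-9)
  expect_equal(barrier_height(-588.809, -600.666), 11.857, tolerance = 1e-9)
  expect_equal(barrier_height(1.5, 1.5), 0)
})

test_that("reduced density matrices match the statevector oracle", {
  h <- make_random_neo(2, 2, 2, seed = 31)
  res <- casci_solve(h)
  rdms <- reduced_density_matrices(res)
  expect_equal(sum(diag(rdms$electronic$matrix)), 2, tolerance = 1e-10)
  expect_equal(sum(diag(rdms$protonic$matrix)), 1, tolerance = 1e-10)
  # oracle: <a+_a a_b> from the embedded statevector and kron operators
  v <- casci_statevector(res)
  n <- h$space$n_electronic_spin + h$space$n_protonic
  for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
    op <- Conj(t(kron_annihilation(n, a))) %*% kron_annihilation(n, b)
    val <- Re(sum(Conj(v) * (op %*% v)))
    if (a < 4 && b < 4) expect_equal(rdms$electronic$matrix[a + 1, b + 1], val,
                                     tolerance = 1e-10)
    if (a >= 4 && b >= 4) expect_equal(rdms$protonic$matrix[a - 3, b - 3], val,
                                       tolerance = 1e-10)
  }
  # product state: proton pinned in one orbital
  sp <- h$space
  hp <- neo_hamiltonian(sp, 0, diag(c(-1, 1)), array(0, rep(2, 4)),
                        diag(c(-1, 1)), array(0, c(2, 2, 2, 2)))
  rp <- reduced_density_matrices(casci_solve(hp))
  expect_lt(max(abs(rp$protonic$matrix - diag(c(1, 0)))), 1e-12)
})

test_that("entanglement entropy: product zero, Bell log 2, SVD oracle", {
  # decoupled double well: exact product ground state
  tri0 <- make_double_well_triple(double_well_spec(g0 = 0))
  res0 <- casci_solve(tri0$middle)
  expect_equal(entanglement_entropy(res0), 0, tolerance = 1e-10)
  # synthetic maximally entangled CI vector over 2 x 2 configurations
  h <- make_random_neo(2, 2, 2, seed = 41)
  res <- casci_solve(h)
  n_e <- length(res$basis$e_dets); n_p <- length(res$basis$p_dets)
  fake <- res
  ci <- matrix(0, n_e, n_p)
  ci[1, 1] <- 1 / sqrt(2); ci[2, 2] <- 1 / sqrt(2)
  fake$ci_vector <- as.vector(ci)
  expect_equal(entanglement_entropy(fake), log(2), tolerance = 1e-12)
  expect_equal(entanglement_entropy(fake, base = "2"), 1, tolerance = 1e-12)
  # seeded random CI vector against the Schmidt (SVD) oracle
  set.seed(42)
  for (rep in 1:5) {
    amp <- matrix(stats::rnorm(n_e * n_p), n_e, n_p)
    amp <- amp / sqrt(sum(amp^2))
    fake$ci_vector <- as.vector(amp)
    lam <- svd(amp)$d^2
    lam <- lam[lam > 1e-14]
    expect_equal(entanglement_entropy(fake), -sum(lam * log(lam)),
                 tolerance = 1e-10)
  }
  # invariance under separate protonic basis rotation of the amplitudes
  amp <- matrix(stats::rnorm(n_e * n_p), n_e, n_p); amp <- amp / sqrt(sum(amp^2))
  Q <- qr.Q(qr(matrix(stats::rnorm(n_p^2), n_p, n_p)))
  f1 <- fake; f1$ci_vector <- as.vector(amp)
  f2 <- fake; f2$ci_vector <- as.vector(amp %*% Q)
  expect_equal(entanglement_entropy(f1), entanglement_entropy(f2),
               tolerance = 1e-10)
})

test_that("proton density normalizes and position matches quadrature", {
  # single Gaussian: density |phi|^2, position at its center
  g1 <- gaussian_orbital_grid(matrix(c(0.3, -0.2, 0.1), 1, 3), 1.2,
                              lower = c(-4, -4, -4), upper = c(4.6, 4, 4),
                              n_points = 31)
  d1 <- proton_density_and_position(matrix(1, 1, 1), g1, g1$position)
  expect_equal(d1$norm, 1, tolerance = 1e-3)
  expect_equal(d1$position_expectation, c(0.3, -0.2, 0.1), tolerance = 1e-6)
  expect_true(all(d1$values >= 0))
  # mirror-symmetric dm over two Gaussians at +/- d: <x> = 0
  g2 <- gaussian_orbital_grid(rbind(c(-0.8, 0, 0), c(0.8, 0, 0)), c(1, 1),
                              n_points = 25)
  d2 <- proton_density_and_position(diag(c(0.5, 0.5)), g2, g2$position)
  expect_equal(d2$position_expectation[1], 0, tolerance = 1e-12)
  # seeded random dm over 3 Gaussians vs dense quadrature of integral x rho(r)
  set.seed(5)
  g3 <- gaussian_orbital_grid(rbind(c(-0.6, 0, 0), c(0, 0.4, 0), c(0.7, 0, 0.2)),
                              c(1.3, 1.1, 0.9), n_points = 29)
  A <- matrix(stats::rnorm(9), 3, 3); dm <- crossprod(A); dm <- dm / sum(diag(dm))
  d3 <- proton_density_and_position(dm, g3, g3$position)
  x_quad <- sum(d3$values * g3$points[, 1] * g3$weights)
  # analytic position uses exact integrals; quadrature should agree closely
  expect_equal(d3$position_expectation[1], x_quad, tolerance = 1e-4)
  expect_error(proton_density_and_position(diag(2), g3, g3$position),
               "dimension error")
})
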