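# Fixture generators: determinism, symmetry, known limits.

test_that("random generator is deterministic and exactly symmetric", {
  h1 <- make_random_neo(2, 2, 2, seed = 77)
  h2 <- make_random_neo(2, 2, 2, seed = 77)
  expect_identical(h1, h2)
  expect_equal(qneo:::h2e_symmetry_residual(h1$h2e), 0)
  expect_equal(max(abs(h1$h1e - t(h1$h1e))), 0)
  # variational ordering holds over seeds
  for (s in 1:10) {
    h <- make_random_neo(2, 2, 2, seed = 1000 + s)
    e <- casci_solve(h)$energy
    expect_true(is.finite(e))
    expect_gte(hf_product_energy(h), e - 1e-12)
  }
})

test_that("decoupled double well has the closed-form ground energy", {
  spec <- double_well_spec(g0 = 0)
  tri <- make_double_well_triple(spec)
  # electronic-only energy: solve the same electronic block with the proton
  # frozen far away (no coupling, protonic part handled by the closed form)
  for (setup in c("left", "middle", "right")) {
    res <- casci_solve(tri[[setup]])
    ep <- double_well_proton_energy(spec, setup)
    # electronic part identical across setups: recover it from one setup and
    # check consistency across the others
    if (setup == "left") e_elec <- res$energy - ep
    expect_equal(res$energy, e_elec + ep, tolerance = 1e-12)
  }
  # barrier equals the closed-form proton barrier when g0 = 0
  bL <- casci_solve(tri$left)$energy
  bM <- casci_solve(tri$middle)$energy
  expect_equal(bM - bL,
               double_well_proton_energy(spec, "middle") -
                 double_well_proton_energy(spec, "left"),
               tolerance = 1e-12)
})

test_that("left and right setups are exact mirrors", {
  tri <- make_double_well_triple()
  eL <- casci_solve(tri$left)$energy
  eR <- casci_solve(tri$right)$energy
  expect_equal(eL, eR, tolerance = 1e-12)
})

test_that("barrier is continuous and monotone in the well raise", {
  raises <- seq(2e-3, 12e-3, length.out = 5)
  barriers <- vapply(raises, function(w) {
    tri <- make_double_well_triple(double_well_spec(well_raise = w))
    casci_solve(tri$middle)$energy - casci_solve(tri$left)$energy
  }, numeric(1))
  expect_true(all(diff(barriers) > 0))
  expect_lt(max(abs(diff(barriers) - diff(raises))), 1e-3)
})

test_that("entanglement entropy increases strictly with the coupling g0", {
  g_grid <- c(0, 1e-3, 2e-3, 4e-3)
  ent <- vapply(g_grid, function(g) {
    tri <- make_double_well_triple(double_well_spec(g0 = g))
    entanglement_entropy(casci_solve(tri$middle))
  }, numeric(1))
  expect_equal(ent[1], 0, tolerance = 1e-10)
  expect_true(all(diff(ent) > 0))
})

test_that("middle proton density is symmetric, left density localized", {
  tri <- make_double_well_triple()
  rdm_m <- reduced_density_matrices(casci_solve(tri$middle))$protonic$matrix
  rdm_l <- reduced_density_matrices(casci_solve(tri$left))$protonic$matrix
  # site populations: middle symmetric, left pushed toward the lower well
  expect_equal(rdm_m[1, 1], rdm_m[2, 2], tolerance = 1e-10)
  expect_gt(rdm_l[1, 1], rdm_l[2, 2])
  # on a two-Gaussian site basis the density follows the same pattern
  g <- gaussian_orbital_grid(rbind(c(-0.6, 0, 0), c(0.6, 0, 0)), c(2, 2),
                             n_points = 21)
  dm <- proton_density_and_position(rdm_m, g, g$position)
  expect_lt(abs(dm$position_expectation[1]), 1e-8)
  dl <- proton_density_and_position(rdm_l, g, g$position)
  expect_lt(dl$position_expectation[1], 0)
})

test_that("gaussian grids match analytic overlap and position", {
  g <- gaussian_orbital_grid(rbind(c(0, 0, 0), c(1.1, 0, 0)), c(1.4, 1.4),
                             lower = c(-4, -3.5, -3.5), upper = c(5, 3.5, 3.5),
                             n_points = 29)
  # quadrature overlap vs analytic (Gaussian product theorem)
  S_quad <- t(g$values) %*% (g$values * g$weights)
  expect_lt(max(abs(S_quad - g$overlap)), 1e-4)
  a <- 1.4; d <- 1.1
  expect_equal(g$overlap[1, 2], exp(-a * d^2 / 2), tolerance = 1e-12)
  expect_equal(g$position[1, 1, ], c(0, 0, 0), tolerance = 1e-12)
  expect_equal(g$position[2, 2, 1], 1.1, tolerance = 1e-12)
  expect_error(gaussian_orbital_grid(matrix(0, 1, 3), -1), "exponents")
})

test_that("triple writer emits loadable files and a manifest", {
  d <- withr::local_tempdir()
  spec <- double_well_spec()
  man <- write_double_well_triple(spec, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  h <- hamiltonian_io(file.path(d, "left.json"), "neo-json")
  tri <- make_double_well_triple(spec)
  expect_lt(max(abs(h$v1p - tri$left$v1p)), 1e-12)
  expect_equal(man$proton_energy_closed_form$left,
               double_well_proton_energy(spec, "left"))
})
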