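# Data model: validation, interpolation, LMR weights, Loewdin, FNO.

test_that("orbital_space enforces its invariants", {
  sp <- orbital_space(2, 2, n_electrons = 2)
  expect_equal(sp$n_electronic_spin, 4L)
  expect_error(orbital_space(2, 2, n_electrons = 5), "n_electrons")
  expect_error(orbital_space(2, 2, 2, n_protons = 2), "one quantum proton")
  expect_error(orbital_space(2, 2, 2, electronic_labels = c("a", "a")), "unique")
})

test_that("neo_hamiltonian validation rejects broken symmetry", {
  h <- make_random_neo(2, 2, 2, seed = 1)
  expect_silent(validate_neo_hamiltonian(h))
  bad <- h
  bad$h1e[1, 2] <- bad$h1e[1, 2] + 1e-3  # breaks Hermiticity by 1e-3
  expect_error(validate_neo_hamiltonian(bad), "h1e is not Hermitian")
  bad2 <- h
  bad2$h2e[1, 2, 1, 1] <- bad2$h2e[1, 2, 1, 1] + 1e-3
  expect_error(validate_neo_hamiltonian(bad2), "permutational symmetry")
  bad3 <- h
  bad3$gep[1, 2, 1, 1] <- bad3$gep[1, 2, 1, 1] + 1e-3
  expect_error(validate_neo_hamiltonian(bad3), "gep")
})

test_that("interpolation: endpoints exact, interior entrywise convex", {
  hs <- lapply(1:3, function(s) make_random_neo(2, 2, 2, seed = s))
  for (k in 1:3) {
    w <- weight_triple(k == 1, k == 2, k == 3)
    hi <- interpolate_hamiltonians(hs[[1]], hs[[2]], hs[[3]], w)
    for (f in c("core_energy", "h1e", "h2e", "v1p", "gep"))
      expect_identical(hi[[f]], hs[[k]][[f]])
  }
  hm <- interpolate_hamiltonians(hs[[1]], hs[[2]], hs[[3]],
                                 weight_triple(1, 1, 1))
  for (f in c("h1e", "h2e", "v1p", "gep"))
    expect_lt(max(abs(hm[[f]] - (hs[[1]][[f]] + hs[[2]][[f]] + hs[[3]][[f]]) / 3)),
              1e-14)
  # linearity: interpolation commutes with entrywise linear combination
  w <- weight_triple(0.2, 0.5, 0.3)
  hw <- interpolate_hamiltonians(hs[[1]], hs[[2]], hs[[3]], w)
  expect_lt(max(abs(hw$h2e - (0.2 * hs[[1]]$h2e + 0.5 * hs[[2]]$h2e +
                                0.3 * hs[[3]]$h2e))), 1e-14)
})

test_that("lmr_weights normalizes digit labels", {
  expect_equal(unlist(lmr_weights("300")[c("alpha", "beta", "gamma")]),
               c(alpha = 1, beta = 0, gamma = 0))
  expect_equal(unlist(lmr_weights("210")[c("alpha", "beta", "gamma")]),
               c(alpha = 2 / 3, beta = 1 / 3, gamma = 0))
  expect_equal(lmr_weights("030")$beta, 1)
  expect_equal(lmr_trajectory_labels(),
               c("300", "210", "120", "030", "021", "012", "003"))
  expect_error(lmr_weights("000"), "digit sum")
  expect_error(lmr_weights("3x0"), "3-digit")
})

test_that("Loewdin orthogonalization returns S^(-1/2)", {
  expect_equal(lowdin_orthogonalize(diag(3)), diag(3))
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  X <- lowdin_orthogonalize(S)
  expect_lt(max(abs(t(X) %*% S %*% X - diag(2))), 1e-12)
  # closed form via eigendecomposition of the 2x2
  ev <- eigen(S, symmetric = TRUE)
  X_or <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  expect_lt(max(abs(X - X_or)), 1e-12)
  # random SPD 6x6 (the shared protonic active space has 6 orbitals)
  set.seed(4)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(36), 6, 6)
    S6 <- crossprod(A) + diag(6) * 0.1
    X6 <- lowdin_orthogonalize(S6)
    expect_lt(max(abs(t(X6) %*% S6 %*% X6 - diag(6))), 1e-10)
  }
  expect_error(lowdin_orthogonalize(matrix(c(1, 2, 2, 1), 2, 2)),
               "not positive definite")
})

test_that("FNO selection keeps the largest occupations", {
  sel <- fno_select(diag(c(1.9, 0.05, 0.001)), 2)
  expect_equal(sel$occupations[1:2], c(1.9, 0.05))
  expect_equal(sort(abs(sel$rotation[, sel$kept]) > 0.5, decreasing = TRUE)[1:2],
               c(TRUE, TRUE))
  # idempotent (pure-state) dm has occupations in {0, 1}
  v <- c(1, 2, -1); v <- v / sqrt(sum(v^2))
  P <- outer(v, v)
  occ <- fno_select(P, 1)$occupations
  expect_lt(max(abs(occ - round(occ))), 1e-10)
  # full eigendecomposition reconstructs the dm
  set.seed(8)
  A <- matrix(stats::rnorm(16), 4, 4); dm <- crossprod(A)
  sel2 <- fno_select(dm, 4)
  rec <- sel2$rotation %*% diag(sel2$occupations) %*% t(sel2$rotation)
  expect_lt(max(abs(rec - dm)), 1e-12)
  expect_lt(max(abs(crossprod(sel2$rotation) - diag(4))), 1e-12)
  # trace bookkeeping: dropped occupations = truncation error in trace
  expect_equal(sum(sel2$occupations), sum(diag(dm)), tolerance = 1e-10)
  expect_error(fno_select(dm, 0), "empty-space")
})

test_that("one_pdm validates Hermiticity, positivity and trace", {
  expect_error(one_pdm(matrix(c(1, 0.2, 0.3, 1), 2, 2)), "Hermitian")
  expect_error(one_pdm(diag(c(1, -0.5)), "protonic"), "semidefinite")
  expect_error(one_pdm(diag(c(0.6, 0.2)), "protonic", trace_target = 1), "trace")
  expect_s3_class(one_pdm(diag(c(0.5, 0.5)), "protonic", trace_target = 1),
                  "one_pdm")
})
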