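# Noise model construction, folding, trajectory sampling, extrapolation.

test_that("noise model validation", {
  tb <- synthetic_device_table(3)
  nm <- build_noise_model(tb)
  expect_s3_class(nm, "noise_model")
  bad <- tb; bad$T2_us[2] <- 3 * bad$T1_us[2]
  expect_error(build_noise_model(bad), "T2 > 2\\*T1")
  expect_error(build_noise_model(tb[, -3]), "missing column")
  expect_error(qneo:::noise_row(nm, 7), "no entry for qubit 7")
  # table read from a delimited file
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tb, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_s3_class(build_noise_model(f), "noise_model")
})

test_that("packaged synthetic device table loads at the reported EPLG scale", {
  f <- system.file("extdata", "device_table_synthetic.tsv", package = "qneo")
  nm <- build_noise_model(f)
  expect_equal(nrow(nm$table), 6L)
  # two-qubit error rates sit at the error-per-layered-gate scale 0.001471
  expect_lt(abs(mean(nm$table$err_2q) - 0.001471), 5e-4)
  expect_true(all(nm$table$T2_us <= 2 * nm$table$T1_us))
})

test_that("zero-rate table reproduces the statevector exactly", {
  circ <- gate_circuit(3, list(qneo:::gate("h", 0), qneo:::gate("cx", c(0, 1)),
                               qneo:::gate("ry", 2, 0.4)))
  nm <- noiseless_model(3)
  v_ideal <- simulate_circuit(circ)
  v_traj <- qneo:::noisy_trajectory(circ, nm)
  expect_lt(max(Mod(v_ideal - v_traj)), 1e-12)
  H <- qneo:::qubit_hamiltonian_from_pauli(
    qneo:::pauli_from_labels(c(ZII = 0.5, IIZ = -0.3, XXI = 0.2)))
  est <- noisy_expectation(circ, H, nm, shots = Inf)
  expect_equal(est$mean, qubit_expectation(H, v_ideal), tolerance = 1e-12)
})

test_that("noiseless diagonal measurement has zero variance", {
  H <- qneo:::qubit_hamiltonian_from_pauli(
    qneo:::pauli_from_labels(c(ZII = 0.5, IZI = -0.3, III = 1.0)))
  circ <- gate_circuit(3, list(qneo:::gate("x", 0)))
  est <- noisy_expectation(circ, H, shots = 40, seed = 3)
  expect_equal(est$mean, 1.0 - 0.5 - 0.3, tolerance = 1e-12)
  expect_equal(est$se, 0)
})

test_that("depolarizing channel shrinks <Z> by (1 - 4p/3)", {
  p <- 0.3
  nm <- build_noise_model(data.frame(qubit = 0, T1_us = Inf, T2_us = Inf,
                                     err_1q = p, err_2q = 0, dur_1q_ns = 35,
                                     dur_2q_ns = 300, p01 = 0, p10 = 0))
  Hz <- qneo:::qubit_hamiltonian_from_pauli(qneo:::pauli_from_labels(c(Z = 1)))
  circ <- gate_circuit(1, list(qneo:::gate("ry", 0, 0)))  # |0>, <Z> = 1
  est <- noisy_expectation(circ, Hz, nm, shots = 20000, seed = 5)
  # channel (1-p) rho + p/3 (X rho X + Y rho Y + Z rho Z): <Z> -> (1 - 4p/3)
  expect_lt(abs(est$mean - (1 - 4 * p / 3)), 3 * est$se + 1e-9)
})

test_that("pure T1 decay matches the closed-form excited population", {
  T1 <- 1; dur <- 500  # one gate of 0.5 us on T1 = 1 us
  nm <- build_noise_model(data.frame(qubit = 0, T1_us = T1, T2_us = 2 * T1,
                                     err_1q = 0, err_2q = 0, dur_1q_ns = dur,
                                     dur_2q_ns = 300, p01 = 0, p10 = 0))
  Hz <- qneo:::qubit_hamiltonian_from_pauli(qneo:::pauli_from_labels(c(Z = 1)))
  circ <- gate_circuit(1, list(qneo:::gate("x", 0)))
  est <- noisy_expectation(circ, Hz, nm, shots = 20000, seed = 6)
  p_exc <- exp(-dur * 1e-3 / T1)
  expect_lt(abs(est$mean - (1 - 2 * p_exc)), 3.5 * est$se)
})

test_that("readout flips bias the sampled eigenvalues as expected", {
  nm <- build_noise_model(data.frame(qubit = 0, T1_us = Inf, T2_us = Inf,
                                     err_1q = 0, err_2q = 0, dur_1q_ns = 35,
                                     dur_2q_ns = 300, p01 = 0.1, p10 = 0.2))
  Hz <- qneo:::qubit_hamiltonian_from_pauli(qneo:::pauli_from_labels(c(Z = 1)))
  circ <- gate_circuit(1, list(qneo:::gate("x", 0)))
  est <- noisy_expectation(circ, Hz, nm, shots = 20000, seed = 7)
  expect_lt(abs(est$mean - (-1 * 0.8 + 1 * 0.2)), 3.5 * est$se)
})

test_that("shot-noise variance scales like 1/shots", {
  nm <- build_noise_model(synthetic_device_table(2, err_1q = 0.02, err_2q = 0.05))
  H <- qneo:::qubit_hamiltonian_from_pauli(
    qneo:::pauli_from_labels(c(ZI = 1, XX = 0.5)))
  circ <- gate_circuit(2, list(qneo:::gate("h", 0), qneo:::gate("cx", c(0, 1))))
  e1 <- noisy_expectation(circ, H, nm, shots = 1000, seed = 11)
  e4 <- noisy_expectation(circ, H, nm, shots = 4000, seed = 12)
  # se ~ shots^(-1/2): ratio of standard errors about 2, generous band
  expect_gt(e1$se / e4$se, 1.4)
  expect_lt(e1$se / e4$se, 2.9)
  # identical seed reproduces bit-identical output
  e1b <- noisy_expectation(circ, H, nm, shots = 1000, seed = 11)
  expect_identical(e1, e1b)
})

test_that("folding preserves counts and the noiseless unitary", {
  circ <- run_adapt_aqc(ghz_state(3), preset = "custom", cost_tol = 1e-7,
                        max_blocks = 2, seed = 1)$circuit
  m0 <- circuit_metrics(circ)$two_qubit_count
  expect_identical(fold_circuit(circ, 1), circ)
  f3 <- fold_circuit(circ, 3, seed = 2)
  expect_equal(circuit_metrics(f3)$two_qubit_count, 3L * m0)
  v0 <- simulate_circuit(circ)
  for (lam in c(1.5, 2, 3, 3.7)) for (s in 1:3) {
    fc <- fold_circuit(circ, lam, seed = s)
    expect_equal(circuit_metrics(fc)$two_qubit_count, round(lam * m0) -
                   (round(lam * m0) - m0) %% 2)
    expect_lt(max(Mod(simulate_circuit(fc) - v0)), 1e-10)
  }
  expect_error(fold_circuit(circ, 0.5), "lam must be >= 1")
})

test_that("ZNE recovers exact polynomial data with both methods", {
  lam <- 1:4
  mk <- function(cfg, y) data.frame(lambda = rep(lam, each = 3), config = cfg,
                                    energy = rep(y, each = 3))
  sL <- mk("left", -1.0 + 0.05 * lam)
  sM <- mk("middle", -0.7 + 0.08 * lam)
  z_lin <- zne_extrapolate(rbind(sL, sM), "fit_first", model = "linear")
  z_dif <- zne_extrapolate(rbind(sL, sM), "difference_first")
  expect_equal(z_lin$barrier, 0.3, tolerance = 1e-10)
  expect_equal(z_dif$barrier, 0.3, tolerance = 1e-10)
  # quadratic data, quadratic fit-first (the default) is exact
  sLq <- mk("left", -1.0 + 0.05 * lam + 0.01 * lam^2)
  sMq <- mk("middle", -0.7 + 0.08 * lam - 0.02 * lam^2)
  zq <- zne_extrapolate(rbind(sLq, sMq), "fit_first")
  expect_equal(zq$barrier, 0.3, tolerance = 1e-9)
  expect_error(zne_extrapolate(rbind(sL, sM)[rbind(sL, sM)$lambda == 1, ]),
               "degenerate design")
})

test_that("exponential decay: linear difference-first recovery bound", {
  lam <- 1:4
  E0 <- -0.6; dE <- 0.012
  for (p in c(0.002, 0.01)) {
    mk <- function(cfg, y) data.frame(lambda = lam, config = cfg, energy = y)
    sL <- mk("left", E0 * (1 - p)^lam)
    sM <- mk("middle", (E0 + dE) * (1 - p)^lam)
    z <- zne_extrapolate(rbind(sL, sM), "difference_first")
    expect_lt(abs(z$barrier - dE), 2 * p^2 * abs(E0))
    # fitted intercept lies between the lambda = 1 value and the true one
    d1 <- sM$energy[1] - sL$energy[1]
    expect_true((z$barrier - d1) * (dE - z$barrier) >= -1e-12)
  }
})

test_that("difference-first uncertainty beats fit-first on paired noise", {
  set.seed(9)
  lam <- 1:4; reps <- 40
  rows <- list()
  for (l in lam) for (r in seq_len(reps)) {
    common <- stats::rnorm(1, 0, 0.02)
    rows[[length(rows) + 1]] <- data.frame(lambda = l, config = "left",
      energy = -1 + 0.03 * l + common + stats::rnorm(1, 0, 0.002))
    rows[[length(rows) + 1]] <- data.frame(lambda = l, config = "middle",
      energy = -0.99 + 0.03 * l + common + stats::rnorm(1, 0, 0.002))
  }
  smp <- do.call(rbind, rows)
  zf <- zne_extrapolate(smp, "fit_first", model = "linear")
  zd <- zne_extrapolate(smp, "difference_first")
  expect_lte(zd$barrier_se, zf$barrier_se)
  # bootstrap runs and is reproducible
  zb1 <- zne_extrapolate(smp, "difference_first", bootstrap = 50, seed = 2)
  zb2 <- zne_extrapolate(smp, "difference_first", bootstrap = 50, seed = 2)
  expect_identical(zb1$bootstrap_se, zb2$bootstrap_se)
  expect_gt(zb1$bootstrap_se, 0)
})
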