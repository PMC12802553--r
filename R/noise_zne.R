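# ---------------------------------------------------------------------------
# Device-style noise model, gate folding, shot-sampled noisy expectation
# values, and zero-noise extrapolation.
#
# Noisy simulation uses Kraus-sampled statevector trajectories: after each
# ideal gate a depolarizing Pauli error is drawn from the gate's error rate
# (depolarize first), then per-qubit thermal relaxation over the gate
# duration (amplitude damping from T1 as a generalized measurement, residual
# pure dephasing from T2 as a stochastic Z). Readout bit-flips are applied to
# the sampled measurement outcomes.
# ---------------------------------------------------------------------------

#' Build a noise model from a device characterization table
#'
#' @param device_table path to a delimited text file, or a data.frame, with
#'   columns `qubit, T1_us, T2_us, err_1q, err_2q, dur_1q_ns, dur_2q_ns,
#'   p01, p10` (`p01` = probability of reading 1 given 0).
#' @return A `noise_model`.
#' @export
build_noise_model <- function(device_table) {
  tb <- if (is.data.frame(device_table)) device_table
        else utils::read.table(device_table, header = TRUE)
  need <- c("qubit", "T1_us", "T2_us", "err_1q", "err_2q",
            "dur_1q_ns", "dur_2q_ns", "p01", "p10")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("device table missing column(s): ",
                         paste(miss, collapse = ", "))
  probs <- c(tb$err_1q, tb$err_2q, tb$p01, tb$p10)
  if (any(probs < 0 | probs > 1)) stop("error probabilities must lie in [0, 1]")
  if (any(tb$T2_us > 2 * tb$T1_us + 1e-12))
    stop("validation error: T2 > 2*T1 for qubit(s) ",
         paste(tb$qubit[tb$T2_us > 2 * tb$T1_us + 1e-12], collapse = ", "))
  if (any(tb$dur_1q_ns <= 0 | tb$dur_2q_ns <= 0)) stop("durations must be > 0")
  structure(list(table = tb[order(tb$qubit), ]), class = "noise_model")
}

#' An identity (noiseless) noise model
#' @param n_qubits register width.
#' @export
noiseless_model <- function(n_qubits) {
  build_noise_model(data.frame(
    qubit = 0:(n_qubits - 1), T1_us = Inf, T2_us = Inf,
    err_1q = 0, err_2q = 0, dur_1q_ns = 35, dur_2q_ns = 300,
    p01 = 0, p10 = 0))
}

noise_row <- function(nm, q) {
  r <- nm$table[nm$table$qubit == q, ]
  if (nrow(r) != 1) stop("noise model has no entry for qubit ", q)
  r
}

is_noiseless <- function(nm) {
  tb <- nm$table
  all(tb$err_1q == 0, tb$err_2q == 0, tb$p01 == 0, tb$p10 == 0,
      is.infinite(tb$T1_us), is.infinite(tb$T2_us))
}

# sample one depolarizing Pauli error on the given qubits: with probability p
# a Pauli drawn uniformly from the non-identity strings on those qubits
sample_depolarizing <- function(v, qubits, p, n) {
  if (p <= 0 || stats::runif(1) >= p) return(v)
  d <- 4^length(qubits) - 1
  pick <- sample.int(d, 1)
  for (q in qubits) {
    code <- pick %% 4L
    pick <- pick %/% 4L
    if (code == 1L) v <- apply_1q(v, gate_matrix_1q("x", NULL), q, n)
    if (code == 2L) v <- apply_1q(v, matrix(c(0, 1i, -1i, 0), 2, 2), q, n)  # Y
    if (code == 3L) v <- apply_1q(v, diag(c(1, -1)), q, n)                  # Z
  }
  v
}

# amplitude damping as a sampled generalized measurement + stochastic Z for
# the residual pure dephasing
sample_relaxation <- function(v, q, t_ns, T1_us, T2_us, n) {
  if (is.infinite(T1_us) && is.infinite(T2_us)) return(v)
  t <- t_ns * 1e-3  # us
  p_ad <- if (is.infinite(T1_us)) 0 else 1 - exp(-t / T1_us)
  if (p_ad > 0) {
    K0 <- diag(c(1, sqrt(1 - p_ad)))
    K1 <- matrix(c(0, 0, sqrt(p_ad), 0), 2, 2)  # |0><1| * sqrt(p)
    v0 <- apply_1q(v, K0, q, n)
    p0 <- sum(Mod(v0)^2)
    if (stats::runif(1) < p0) {
      v <- v0 / sqrt(p0)
    } else {
      v1 <- apply_1q(v, K1, q, n)
      v <- v1 / sqrt(sum(Mod(v1)^2))
    }
  }
  # residual dephasing: 1/Tphi = 1/T2 - 1/(2 T1)
  inv_tphi <- (if (is.infinite(T2_us)) 0 else 1 / T2_us) -
    (if (is.infinite(T1_us)) 0 else 1 / (2 * T1_us))
  if (inv_tphi > 1e-15) {
    p_z <- (1 - exp(-t * inv_tphi)) / 2
    if (stats::runif(1) < p_z) v <- apply_1q(v, diag(c(1, -1)), q, n)
  }
  v
}

# one noisy trajectory through a circuit
noisy_trajectory <- function(circ, nm) {
  n <- circ$n_qubits
  v <- complex(2^n); v[1] <- 1 + 0i
  for (g in circ$gates) {
    if (g$name == "cx") {
      v <- apply_cx(v, g$qubits[1], g$qubits[2], n)
      r1 <- noise_row(nm, g$qubits[1])
      v <- sample_depolarizing(v, g$qubits, r1$err_2q, n)
      for (q in g$qubits) {
        r <- noise_row(nm, q)
        v <- sample_relaxation(v, q, r$dur_2q_ns, r$T1_us, r$T2_us, n)
      }
    } else {
      v <- apply_1q(v, gate_matrix_1q(g$name, g$params), g$qubits[1], n)
      r <- noise_row(nm, g$qubits[1])
      v <- sample_depolarizing(v, g$qubits[1], r$err_1q, n)
      v <- sample_relaxation(v, g$qubits[1], r$dur_1q_ns, r$T1_us, r$T2_us, n)
    }
  }
  v
}

# greedy qubit-wise-commuting grouping of Pauli terms; returns list of groups,
# each with term indices and a per-qubit measurement code (0 I, 1 X, 2 Z, 3 Y)
group_pauli_terms <- function(ps) {
  m <- length(ps$x)
  n <- ps$n_qubits
  codes <- matrix(0L, m, n)
  for (k in seq_len(m)) {
    xb <- bitwAnd(ps$x[k] %/% 2L^(0:(n - 1)), 1L)
    zb <- bitwAnd(ps$z[k] %/% 2L^(0:(n - 1)), 1L)
    codes[k, ] <- xb + 2L * zb  # 1 X, 2 Z, 3 Y
  }
  groups <- list()
  assigned <- rep(FALSE, m)
  for (k in seq_len(m)) {
    if (assigned[k]) next
    if (all(codes[k, ] == 0L)) { assigned[k] <- TRUE; next }  # identity
    basis <- codes[k, ]
    members <- k
    assigned[k] <- TRUE
    for (j in seq_len(m)) {
      if (assigned[j] || all(codes[j, ] == 0L)) next
      ok <- all(codes[j, ] == 0L | basis == 0L | codes[j, ] == basis)
      if (ok) {
        basis[basis == 0L] <- codes[j, basis == 0L]
        members <- c(members, j)
        assigned[j] <- TRUE
      }
    }
    groups[[length(groups) + 1L]] <- list(members = members, basis = basis,
                                          codes = codes[members, , drop = FALSE])
  }
  groups
}

#' Shot-sampled noisy expectation value of a qubit Hamiltonian
#'
#' For each shot one Kraus-sampled trajectory is run; the Pauli terms are
#' partitioned into qubit-wise commuting groups, each group is rotated to the
#' computational basis, one bitstring is sampled, readout bit-flips applied,
#' and the term eigenvalues accumulated. `shots = Inf` returns the exact
#' noiseless expectation (only valid with a noiseless model).
#'
#' @param circuit a `gate_circuit`.
#' @param H a `qubit_hamiltonian` on the same register.
#' @param noise a `noise_model` (default noiseless).
#' @param shots number of shots (>= 1), or `Inf`.
#' @param seed RNG seed; identical seeds give bit-identical results.
#' @return list with `mean` (Ha), `se` (standard error of the mean), `shots`.
#' @export
noisy_expectation <- function(circuit, H, noise = NULL, shots = 1000L,
                              seed = 1L) {
  n <- circuit$n_qubits
  if (H$n_qubits != n) stop("qubit count mismatch between circuit and Hamiltonian")
  if (is.null(noise)) noise <- noiseless_model(n)
  if (is.infinite(shots)) {
    if (!is_noiseless(noise))
      stop("shots = Inf is only exact for a noiseless model")
    v <- simulate_circuit(circuit)
    return(list(mean = qubit_expectation(H, v), se = 0, shots = Inf))
  }
  shots <- as.integer(shots)
  if (shots < 1) stop("shots must be >= 1")
  set.seed(seed)
  ps <- H$pauli
  lab <- pauli_labels(ps)
  coefs <- Re(lab$coef)
  id_terms <- ps$x == 0L & ps$z == 0L
  const <- sum(coefs[id_terms])
  groups <- group_pauli_terms(ps)
  tb <- noise$table
  p01 <- tb$p01[match(0:(n - 1), tb$qubit)]
  p10 <- tb$p10[match(0:(n - 1), tb$qubit)]
  vals <- numeric(shots)
  noiseless <- is_noiseless(noise)
  base_v <- if (noiseless) simulate_circuit(circuit) else NULL
  for (s in seq_len(shots)) {
    v <- if (noiseless) base_v else noisy_trajectory(circuit, noise)
    tot <- const
    for (g in groups) {
      w <- v
      for (q in seq_len(n)) {
        if (g$basis[q] == 1L) w <- apply_1q(w, gate_matrix_1q("h", NULL), q - 1L, n)
        if (g$basis[q] == 3L) {  # Y: rx(pi/2) maps Y -> Z
          w <- apply_1q(w, gate_matrix_1q("rx", pi / 2), q - 1L, n)
        }
      }
      probs <- Mod(w)^2
      out <- sample.int(length(probs), 1, prob = probs) - 1L
      bits <- bitwAnd(out %/% 2L^(0:(n - 1)), 1L)
      flip0 <- stats::runif(n) < p01
      flip1 <- stats::runif(n) < p10
      bits <- ifelse(bits == 0L, as.integer(flip0), 1L - as.integer(flip1))
      for (j in seq_along(g$members)) {
        k <- g$members[j]
        supp <- g$codes[j, ] != 0L
        eig <- 1 - 2 * (sum(bits[supp]) %% 2L)
        tot <- tot + coefs[k] * eig
      }
    }
    vals[s] <- tot
  }
  list(mean = mean(vals),
       se = if (shots > 1) stats::sd(vals) / sqrt(shots) else NA_real_,
       shots = shots)
}

#' Fold two-qubit gates to amplify noise
#'
#' Randomly selected two-qubit gates `G` are replaced by `G G^dagger G`
#' (sampled uniformly without replacement) until the two-qubit gate count is
#' the nearest integer to `lam` times the original; the noiseless unitary is
#' unchanged. `lam = 3` folds every two-qubit gate once.
#'
#' @param circuit a `gate_circuit`.
#' @param lam noise amplification factor (>= 1).
#' @param seed RNG seed for the gate selection.
#' @return the folded `gate_circuit`.
#' @export
fold_circuit <- function(circuit, lam, seed = 1L) {
  if (lam < 1) stop("lam must be >= 1")
  two_q <- which(vapply(circuit$gates, function(g) length(g$qubits) == 2L,
                        logical(1)))
  m <- length(two_q)
  if (m == 0 || lam == 1) return(circuit)
  target <- round(lam * m)
  n_folds <- (target - m) %/% 2L  # each fold adds two gates
  full_rounds <- n_folds %/% m
  remainder <- n_folds %% m
  set.seed(seed)
  fold_count <- rep(full_rounds, m)
  if (remainder > 0) {
    extra <- sample.int(m, remainder)
    fold_count[extra] <- fold_count[extra] + 1L
  }
  gates <- list()
  k2 <- 0L
  for (g in circuit$gates) {
    gates[[length(gates) + 1L]] <- g
    if (length(g$qubits) == 2L) {
      k2 <- k2 + 1L
      if (fold_count[k2] > 0) {
        gdag <- g
        if (g$name %in% c("rx", "ry", "rz")) gdag$params <- -g$params
        for (r in seq_len(fold_count[k2])) {
          gates[[length(gates) + 1L]] <- gdag
          gates[[length(gates) + 1L]] <- g
        }
      }
    }
  }
  gate_circuit(circuit$n_qubits, gates, metadata = c(circuit$metadata,
                                                     list(lambda = lam)))
}

# OLS polynomial fit of y on lambda; returns intercept and its standard error
zne_fit <- function(lambda, y, model = c("linear", "quadratic")) {
  model <- match.arg(model)
  df <- data.frame(lambda = lambda, y = y)
  fit <- if (model == "linear") stats::lm(y ~ lambda, data = df)
         else stats::lm(y ~ lambda + I(lambda^2), data = df)
  # suppressWarnings: an exactly polynomial input is a legitimate use
  # (summary.lm warns about the perfect fit)
  list(intercept = unname(stats::coef(fit)[1]),
       se = suppressWarnings(sqrt(stats::vcov(fit)[1, 1])),
       fit = fit)
}

#' Zero-noise extrapolation of a barrier height
#'
#' `samples` holds per-circuit energies at each noise amplification factor
#' for the Left and Middle configurations. In `fit_first` mode each
#' configuration's per-lambda mean energies are fitted (quadratic default)
#' and the barrier is the difference of the intercepts with uncertainties
#' added in quadrature; in `difference_first` mode the per-lambda mean
#' differences are fitted (linear default) and the intercept and its standard
#' error are reported directly.
#'
#' @param samples data.frame with columns `lambda`, `config` (`"left"` /
#'   `"middle"`), `energy` (one row per folded-circuit replicate).
#' @param method `"fit_first"` or `"difference_first"`.
#' @param model `"linear"` or `"quadratic"`; default quadratic for fit_first,
#'   linear for difference_first.
#' @param bootstrap optional number of nonparametric bootstrap resamples of
#'   the circuits within each lambda (default 0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return A `zne_estimate`: `barrier`, `barrier_se`, per-config intercepts
#'   (fit_first), `lambdas`, `method`, `model`, optional `bootstrap_se`.
#' @export
zne_extrapolate <- function(samples, method = c("fit_first", "difference_first"),
                            model = NULL, bootstrap = 0L, seed = 1L) {
  method <- match.arg(method)
  if (!all(c("lambda", "config", "energy") %in% names(samples)))
    stop("samples must have columns lambda, config, energy")
  lambdas <- sort(unique(samples$lambda))
  if (length(lambdas) < 2) stop("degenerate design: need >= 2 distinct lambda values")
  if (is.null(model)) model <- if (method == "fit_first") "quadratic" else "linear"
  min_pts <- if (model == "quadratic") 3L else 2L
  if (length(lambdas) < min_pts)
    stop("need >= ", min_pts, " lambda values for a ", model, " fit")
  means <- function(df) {
    agg <- stats::aggregate(energy ~ lambda, data = df, FUN = mean)
    agg[order(agg$lambda), ]
  }
  left <- samples[samples$config == "left", ]
  middle <- samples[samples$config == "middle", ]
  if (nrow(left) == 0 || nrow(middle) == 0)
    stop("samples must contain both 'left' and 'middle' configurations")
  estimate <- function(smp_left, smp_middle) {
    ml <- means(smp_left); mm <- means(smp_middle)
    if (method == "fit_first") {
      fl <- zne_fit(ml$lambda, ml$energy, model)
      fm <- zne_fit(mm$lambda, mm$energy, model)
      list(barrier = fm$intercept - fl$intercept,
           se = sqrt(fl$se^2 + fm$se^2),
           intercept_left = fl$intercept, intercept_middle = fm$intercept,
           se_left = fl$se, se_middle = fm$se)
    } else {
      if (!identical(ml$lambda, mm$lambda))
        stop("difference_first requires matching lambda grids")
      fd <- zne_fit(ml$lambda, mm$energy - ml$energy, model)
      list(barrier = fd$intercept, se = fd$se,
           intercept_left = NA_real_, intercept_middle = NA_real_,
           se_left = NA_real_, se_middle = NA_real_)
    }
  }
  est <- estimate(left, middle)
  boot_se <- NULL
  if (bootstrap > 0) {
    set.seed(seed)
    draws <- numeric(bootstrap)
    resample <- function(df) {
      parts <- split(df, df$lambda)
      do.call(rbind, lapply(parts, function(p) p[sample.int(nrow(p), replace = TRUE), ]))
    }
    for (b in seq_len(bootstrap))
      draws[b] <- estimate(resample(left), resample(middle))$barrier
    boot_se <- stats::sd(draws)
  }
  structure(list(barrier = est$barrier, barrier_se = est$se,
                 intercept_left = est$intercept_left,
                 intercept_middle = est$intercept_middle,
                 se_left = est$se_left, se_middle = est$se_middle,
                 lambdas = lambdas, method = method, model = model,
                 bootstrap_se = boot_se),
            class = "zne_estimate")
}

#' @export
print.zne_estimate <- function(x, ...) {
  cat(sprintf("<zne_estimate> %s/%s barrier = %.6f +/- %.6f Ha\n",
              x$method, x$model, x$barrier, x$barrier_se))
  invisible(x)
}

#' Full ZNE sweep over folded circuits
#'
#' Convenience driver: for each lambda in `lambdas` and each configuration
#' circuit, builds `replicates` randomly folded circuits, estimates each with
#' [noisy_expectation()], and returns the samples table for
#' [zne_extrapolate()].
#'
#' @param circuits named list `list(left = , middle = )` of `gate_circuit`s.
#' @param H a `qubit_hamiltonian`.
#' @param noise a `noise_model`.
#' @param lambdas amplification grid (default `1:4`).
#' @param replicates folded circuits per lambda (default 100).
#' @param shots shots per circuit (default 1000).
#' @param seed master seed.
#' @return data.frame with columns `lambda, config, replicate, energy`.
#' @export
zne_sweep <- function(circuits, H, noise, lambdas = 1:4, replicates = 100L,
                      shots = 1000L, seed = 1L) {
  stopifnot(all(c("left", "middle") %in% names(circuits)))
  rows <- list()
  for (cfg in c("left", "middle")) {
    for (li in seq_along(lambdas)) {
      lam <- lambdas[li]
      for (r in seq_len(replicates)) {
        sub_seed <- (seed * 7L + li * 1009L + r * 13L +
                       if (cfg == "middle") 500000L else 0L) %% .Machine$integer.max
        folded <- fold_circuit(circuits[[cfg]], lam, seed = sub_seed)
        est <- noisy_expectation(folded, H, noise, shots = shots,
                                 seed = sub_seed + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          lambda = lam, config = cfg, replicate = r, energy = est$mean)
      }
    }
  }
  do.call(rbind, rows)
}
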