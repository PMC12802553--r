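# ---------------------------------------------------------------------------
# ADAPT-VQE over the coupled electron-proton excitation pool.
#
# The ansatz |psi> = exp(th_n tau_n) ... exp(th_1 tau_1) |HF> grows one
# anti-Hermitian generator at a time, chosen by the magnitude of the energy
# gradient <[H, tau]> at the current state; all parameters are re-optimized
# (BFGS, analytic gradients) after each addition.
# ---------------------------------------------------------------------------

#' Build the NEO excitation operator pool
#'
#' Enumerates spin- and particle-number-conserving excitations from the
#' occupied to the virtual orbitals of a reference determinant: electronic
#' singles and doubles, protonic singles (and doubles when more than one
#' proton is present), and mixed electron-proton doubles. Each fermionic
#' generator `tau = T - T^dagger` is mapped to its anti-Hermitian
#' Jordan-Wigner image. The `"qubit"` variant splits every mapped generator
#' into its individual Pauli strings (each `i * P` is itself anti-Hermitian)
#' and removes duplicates.
#'
#' @param space an [orbital_space()].
#' @param reference_bits occupation bitmask of the reference determinant.
#' @param variant `"fermionic"` (default) or `"qubit"`.
#' @param drop_z for the qubit variant, drop pure-Z factors (Z chains) from
#'   each string (default `FALSE`: full JW strings retained).
#' @return list of `pool_operator`s: each has `kind`, `indices` (JW modes,
#'   occupied then virtual), and `pauli` (anti-Hermitian `pauli_sum`).
#' @export
build_pool <- function(space, reference_bits, variant = c("fermionic", "qubit"),
                       drop_z = FALSE) {
  variant <- match.arg(variant)
  n <- space_n_qubits(space)
  occ <- which(bitwAnd(as.integer(reference_bits), as.integer(2^(0:(n - 1)))) > 0L) - 1L
  e_modes <- 0:(space$n_electronic_spin - 1)
  p_modes <- space$n_electronic_spin + 0:(space$n_protonic - 1)
  occ_e <- intersect(occ, e_modes); vir_e <- setdiff(e_modes, occ_e)
  occ_p <- intersect(occ, p_modes); vir_p <- setdiff(p_modes, occ_p)
  if (length(vir_e) == 0 && length(vir_p) == 0)
    stop("empty-pool error: no virtual orbitals in the reference")
  spin_of <- function(m) ifelse(m < space$n_electronic_spatial, 0L, 1L)
  ops <- list()
  add <- function(kind, occ_idx, vir_idx, modes, daggers) {
    Tdag <- jw_product(n, modes, daggers)
    tau <- pauli_add(Tdag, pauli_scale(pauli_dagger(Tdag), -1))
    if (length(tau$x) == 0) return(invisible(NULL))
    ops[[length(ops) + 1L]] <<- structure(
      list(kind = kind, indices = list(occupied = occ_idx, virtual = vir_idx),
           pauli = tau), class = "pool_operator")
  }
  # electronic singles (same spin)
  for (i in occ_e) for (a in vir_e)
    if (spin_of(i) == spin_of(a))
      add("e-single", i, a, c(a, i), c(TRUE, FALSE))
  # protonic singles
  for (I in occ_p) for (A in vir_p)
    add("p-single", I, A, c(A, I), c(TRUE, FALSE))
  # electronic doubles (Sz conserving)
  if (length(occ_e) >= 2 && length(vir_e) >= 2) {
    oc <- utils::combn(occ_e, 2); vc <- utils::combn(vir_e, 2)
    for (ko in seq_len(ncol(oc))) for (kv in seq_len(ncol(vc))) {
      i <- oc[1, ko]; j <- oc[2, ko]; a <- vc[1, kv]; b <- vc[2, kv]
      if (spin_of(i) + spin_of(j) != spin_of(a) + spin_of(b)) next
      add("ee-double", c(i, j), c(a, b), c(a, b, j, i), c(TRUE, TRUE, FALSE, FALSE))
    }
  }
  # protonic doubles (require >= 2 protons; empty for the single-proton case)
  if (length(occ_p) >= 2 && length(vir_p) >= 2) {
    oc <- utils::combn(occ_p, 2); vc <- utils::combn(vir_p, 2)
    for (ko in seq_len(ncol(oc))) for (kv in seq_len(ncol(vc)))
      add("pp-double", oc[, ko], vc[, kv],
          c(vc[1, kv], vc[2, kv], oc[2, ko], oc[1, ko]),
          c(TRUE, TRUE, FALSE, FALSE))
  }
  # mixed electron-proton doubles (same electronic spin)
  for (i in occ_e) for (a in vir_e) {
    if (spin_of(i) != spin_of(a)) next
    for (I in occ_p) for (A in vir_p)
      add("ep-double", c(i, I), c(a, A), c(a, A, i, I),
          c(TRUE, TRUE, FALSE, FALSE))
  }
  if (variant == "qubit") ops <- split_qubit_pool(ops, n, drop_z = drop_z)
  ops
}

# split fermionic pool operators into single-Pauli-string generators i*P.
# In the XZ basis the named string is P = i^{#Y} X^x Z^z, so the
# anti-Hermitian unit generator is i*P = i^{#Y + 1} X^x Z^z.
split_qubit_pool <- function(ops, n, drop_z = FALSE) {
  seen <- character(0)
  out <- list()
  for (op in ops) {
    ps <- op$pauli
    for (k in seq_along(ps$x)) {
      x <- ps$x[k]; z <- ps$z[k]
      if (drop_z) z <- bitwAnd(z, x)  # keep z bits only under Y; drop Z chains
      if (x == 0L && z == 0L) next    # identity: no generator
      key <- paste(x, z, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      nY <- popcount(bitwAnd(x, z))
      tau <- pauli_sum(n, x, z, (1i)^(nY + 1L))
      out[[length(out) + 1L]] <- structure(
        list(kind = "pauli-string", indices = op$indices, pauli = tau),
        class = "pool_operator")
    }
  }
  out
}

#' Energy gradient of a pool operator
#'
#' Returns `<psi|[H, tau]|psi> = 2 Re <psi| H tau |psi>`, the derivative of
#' `<exp(-th tau) psi|H|exp(th tau) psi>` at `th = 0`.
#'
#' @param op a `pool_operator`.
#' @param state complex statevector (normalized).
#' @param H a `qubit_hamiltonian`.
#' @param Hstate optional precomputed `H |state>`.
#' @return real gradient.
#' @export
pool_gradient <- function(op, state, H, Hstate = NULL) {
  if (is.null(Hstate)) Hstate <- pauli_apply(H$pauli, state)
  tau_state <- pauli_apply(op$pauli, state)
  2 * Re(sum(Conj(Hstate) * tau_state))
}

# apply the ansatz generators to the reference and cache intermediate states;
# returns list of states s[[k]] = state after exp(th_k tau_k), s[[0]] = ref
ansatz_states <- function(generators, theta, ref_state) {
  states <- vector("list", length(generators) + 1L)
  states[[1]] <- ref_state
  for (k in seq_along(generators))
    states[[k + 1]] <- pauli_exp_apply(generators[[k]]$pauli, theta[k], states[[k]])
  states
}

# energy and analytic gradient of the ansatz via one reverse sweep
ansatz_energy_gradient <- function(generators, theta, ref_state, H) {
  states <- ansatz_states(generators, theta, ref_state)
  psi <- states[[length(states)]]
  lambda <- pauli_apply(H$pauli, psi)
  energy <- Re(sum(Conj(psi) * lambda))
  m <- length(generators)
  grad <- numeric(m)
  if (m > 0) {
    for (k in m:1) {
      # grad_k = 2 Re <lambda | tau_k | psi_k>, with psi_k the state after U_k
      psi_k <- states[[k + 1]]
      grad[k] <- 2 * Re(sum(Conj(lambda) * pauli_apply(generators[[k]]$pauli, psi_k)))
      if (k > 1) {
        lambda <- pauli_exp_apply(generators[[k]]$pauli, -theta[k], lambda)
      }
    }
  }
  list(energy = energy, gradient = grad, state = psi)
}

#' Run ADAPT-VQE
#'
#' Iteratively grows the ansatz: at each macro-iteration the pool operator
#' with the largest absolute energy gradient is appended (ties broken by
#' lowest pool index) and all parameters are re-optimized by BFGS with
#' analytic gradients. Stops when `|E - reference_energy| < tol` if a
#' reference is supplied (deep preset: `1e-3` Ha, shallow: `1e-2` Ha), or
#' when the largest pool gradient falls below `gradient_tol`.
#'
#' @param H a `qubit_hamiltonian`.
#' @param pool list of `pool_operator`s from [build_pool()].
#' @param reference_bits reference determinant bitmask.
#' @param preset `"deep"`, `"shallow"`, or `"custom"`.
#' @param tol energy tolerance for `"custom"` preset.
#' @param reference_energy optional target energy (Ha).
#' @param gradient_tol stopping threshold on the max pool gradient when no
#'   reference energy is given.
#' @param max_iter maximum macro-iterations (default 500 deep / 200 shallow).
#' @param reoptimize re-optimize all parameters each iteration (default
#'   `TRUE`); `FALSE` optimizes only the newest parameter.
#' @return A `vqe_result`: `energy`, `iterations`, per-iteration `trace`
#'   (energy, max gradient, chosen operator), `generators`, `theta`, `state`,
#'   `converged`, `preset`.
#' @export
run_adapt_vqe <- function(H, pool, reference_bits,
                          preset = c("deep", "shallow", "custom"),
                          tol = NULL, reference_energy = NULL,
                          gradient_tol = 1e-6, max_iter = NULL,
                          reoptimize = TRUE) {
  preset <- match.arg(preset)
  if (is.null(tol)) tol <- switch(preset, deep = 1e-3, shallow = 1e-2, custom = 1e-6)
  if (is.null(max_iter)) max_iter <- switch(preset, deep = 500L, shallow = 200L,
                                            custom = 500L)
  if (length(pool) == 0) stop("pool must be non-empty")
  n <- H$n_qubits
  ref_state <- complex(2^n); ref_state[as.integer(reference_bits) + 1L] <- 1 + 0i
  generators <- list(); theta <- numeric(0)
  state <- ref_state
  energy <- Re(pauli_expectation(H$pauli, state))
  trace <- data.frame(iteration = 0L, energy = energy, max_gradient = NA_real_,
                      operator = NA_integer_)
  converged <- FALSE
  stop_reason <- "max_iter"
  for (it in seq_len(max_iter)) {
    if (!is.null(reference_energy) && abs(energy - reference_energy) < tol) {
      converged <- TRUE; stop_reason <- "energy"; break
    }
    Hstate <- pauli_apply(H$pauli, state)
    grads <- vapply(pool, pool_gradient, numeric(1),
                    state = state, H = H, Hstate = Hstate)
    gmax <- max(abs(grads))
    if (is.null(reference_energy) && gmax < gradient_tol) {
      converged <- TRUE; stop_reason <- "gradient"; break
    }
    pick <- which.max(abs(grads))  # which.max returns the first (lowest) index on ties
    generators[[length(generators) + 1L]] <- pool[[pick]]
    theta <- c(theta, 0)
    m <- length(theta)
    free <- if (reoptimize) seq_len(m) else m
    fixed_theta <- theta
    fn <- function(par) {
      th <- fixed_theta; th[free] <- par
      ansatz_energy_gradient(generators, th, ref_state, H)$energy
    }
    gr <- function(par) {
      th <- fixed_theta; th[free] <- par
      ansatz_energy_gradient(generators, th, ref_state, H)$gradient[free]
    }
    opt <- stats::optim(theta[free], fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    theta[free] <- opt$par
    res <- ansatz_energy_gradient(generators, theta, ref_state, H)
    new_energy <- res$energy
    if (new_energy > energy + 1e-10) {
      # optimizer failure would break monotonicity: keep the better point
      theta[m] <- 0
      res <- ansatz_energy_gradient(generators, theta, ref_state, H)
      new_energy <- res$energy
    }
    if (abs(new_energy - energy) < 1e-13 && gmax > gradient_tol) {
      warning("ADAPT-VQE stagnation: gradient ", format(gmax),
              " above tolerance but energy unchanged; halting")
      generators <- generators[-m]; theta <- theta[-m]
      stop_reason <- "stagnation"
      break
    }
    energy <- new_energy
    state <- res$state
    trace <- rbind(trace, data.frame(iteration = it, energy = energy,
                                     max_gradient = gmax, operator = pick))
  }
  if (!is.null(reference_energy) && abs(energy - reference_energy) < tol) {
    converged <- TRUE
    if (stop_reason == "max_iter") stop_reason <- "energy"
  }
  structure(list(energy = energy, iterations = nrow(trace) - 1L, trace = trace,
                 generators = generators, theta = theta, state = state,
                 reference_bits = as.integer(reference_bits),
                 converged = converged, stop_reason = stop_reason,
                 preset = preset),
            class = "vqe_result")
}

#' @export
print.vqe_result <- function(x, ...) {
  cat(sprintf("<vqe_result> E = %.10f Ha after %d iterations (%s, %s)\n",
              x$energy, x$iterations, x$preset,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Serialize a VQE ansatz as an ordered (kind, indices, theta) list
#' @param res a `vqe_result`.
#' @param path output JSON file.
#' @export
write_ansatz_json <- function(res, path) {
  doc <- list(
    energy = res$energy,
    reference_bits = res$reference_bits,
    ansatz = lapply(seq_along(res$generators), function(k) {
      g <- res$generators[[k]]
      list(kind = g$kind, occupied = g$indices$occupied,
           virtual = g$indices$virtual, theta = res$theta[k])
    }))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Expectation of particle-number operators on a statevector
#'
#' @param space an [orbital_space()].
#' @param state statevector over the JW register.
#' @return list with `electrons` and `protons` expectations.
#' @export
number_expectations <- function(space, state) {
  n <- space_n_qubits(space)
  probs <- Mod(state)^2
  idx <- 0:(2^n - 1)
  e_mask <- as.integer(2^space$n_electronic_spin - 1)
  p_mask <- bitwShiftL(as.integer(2^space$n_protonic - 1), space$n_electronic_spin)
  list(electrons = sum(probs * popcount(bitwAnd(idx, e_mask))),
       protons = sum(probs * popcount(bitwAnd(idx, p_mask))))
}
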