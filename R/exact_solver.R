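# ---------------------------------------------------------------------------
# Exact CASCI reference solver in the fixed-particle-number determinant basis.
#
# Determinants are occupation bitmasks over the JW mode ordering (spin-up
# electronic block, spin-down block, protonic block). Basis states are
# creation strings in ascending mode order applied to the vacuum; matrix
# elements are evaluated by direct second-quantized operator application with
# fermionic signs -- an independent route from the Pauli/statevector path.
# ---------------------------------------------------------------------------

# all bitmasks with k bits set among the given mode indices (0-based),
# in ascending bitmask order
enumerate_determinants <- function(modes, k) {
  if (k == 0) return(0L)
  cmb <- utils::combn(modes, k)
  det <- apply(cmb, 2, function(m) sum(2^m))
  sort(as.integer(det))
}

#' Enumerate the (n_electrons, n_protons) sector basis
#'
#' @param space an [orbital_space()].
#' @return list with `bits` (integer bitmasks, protonic index slowest /
#'   electronic index fastest), `e_dets`, `p_dets`.
#' @keywords internal
sector_basis <- function(space) {
  e_modes <- 0:(space$n_electronic_spin - 1)
  p_modes <- space$n_electronic_spin + 0:(space$n_protonic - 1)
  e_dets <- enumerate_determinants(e_modes, space$n_electrons)
  p_dets <- enumerate_determinants(p_modes, space$n_protons)
  bits <- as.integer(outer(e_dets, p_dets, FUN = bitwOr))  # electronic fastest
  list(bits = bits, e_dets = e_dets, p_dets = p_dets)
}

# apply a+_m (dagger=TRUE) or a_m to a determinant bitmask; returns
# list(bits, sign) or NULL if annihilated
apply_ladder <- function(bits, mode, dagger) {
  b <- as.integer(2^mode)
  occupied <- bitwAnd(bits, b) > 0L
  if (dagger && occupied) return(NULL)
  if (!dagger && !occupied) return(NULL)
  below <- bitwAnd(bits, b - 1L)
  sign <- if (popcount(below) %% 2L == 0L) 1 else -1
  list(bits = bitwXor(bits, b), sign = sign)
}

# apply a product of ladder operators (leftmost listed first; rightmost acts
# first on the ket)
apply_ladder_product <- function(bits, modes, daggers) {
  sign <- 1
  for (k in rev(seq_along(modes))) {
    res <- apply_ladder(bits, modes[k], daggers[k])
    if (is.null(res)) return(NULL)
    bits <- res$bits
    sign <- sign * res$sign
  }
  list(bits = bits, sign = sign)
}

# enumerate the second-quantized terms of a NEO Hamiltonian as a list of
# (coefficient, modes, daggers); core handled separately
neo_term_list <- function(h) {
  sp <- h$space
  nsp <- sp$n_electronic_spatial
  terms <- vector("list", 0)
  add <- function(val, modes, daggers)
    terms[[length(terms) + 1L]] <<- list(val = val, modes = modes, daggers = daggers)
  for (p in 1:nsp) for (q in 1:nsp) {
    val <- h$h1e[p, q]
    if (abs(val) < 1e-14) next
    for (s in c("up", "dn"))
      add(val, c(mode_electronic(sp, p, s), mode_electronic(sp, q, s)),
          c(TRUE, FALSE))
  }
  for (p in 1:nsp) for (q in 1:nsp) for (r in 1:nsp) for (s in 1:nsp) {
    val <- h$h2e[p, q, r, s]
    if (abs(val) < 1e-14) next
    for (s1 in c("up", "dn")) for (s2 in c("up", "dn"))
      add(0.5 * val,
          c(mode_electronic(sp, p, s1), mode_electronic(sp, q, s2),
            mode_electronic(sp, s, s2), mode_electronic(sp, r, s1)),
          c(TRUE, TRUE, FALSE, FALSE))
  }
  for (P in 1:sp$n_protonic) for (Q in 1:sp$n_protonic) {
    val <- h$v1p[P, Q]
    if (abs(val) < 1e-14) next
    add(val, c(mode_protonic(sp, P), mode_protonic(sp, Q)), c(TRUE, FALSE))
  }
  for (P in 1:sp$n_protonic) for (Q in 1:sp$n_protonic)
    for (p in 1:nsp) for (q in 1:nsp) {
      val <- h$gep[P, Q, p, q]
      if (abs(val) < 1e-14) next
      for (s1 in c("up", "dn"))
        add(val, c(mode_protonic(sp, P), mode_protonic(sp, Q),
                   mode_electronic(sp, p, s1), mode_electronic(sp, q, s1)),
            c(TRUE, FALSE, TRUE, FALSE))
    }
  terms
}

# dense sector Hamiltonian matrix in the determinant basis
sector_matrix <- function(h, basis = sector_basis(h$space)) {
  terms <- neo_term_list(h)
  D <- length(basis$bits)
  pos <- new.env(hash = TRUE, size = D)
  for (j in seq_len(D)) assign(as.character(basis$bits[j]), j, envir = pos)
  M <- matrix(0, D, D)
  for (tm in terms) {
    for (j in seq_len(D)) {
      res <- apply_ladder_product(basis$bits[j], tm$modes, tm$daggers)
      if (is.null(res)) next
      i <- get0(as.character(res$bits), envir = pos)
      if (is.null(i)) next  # leaves the sector (cannot happen for these terms)
      M[i, j] <- M[i, j] + tm$val * res$sign
    }
  }
  M + diag(h$core_energy, D)
}

#' Exact CASCI ground state in the fixed-particle-number sector
#'
#' Builds the dense sector Hamiltonian by second-quantized operator
#' application over the determinant basis and diagonalizes it. The reported
#' energy is the minimum eigenvalue; the eigenvector residual is verified.
#'
#' @param h a `neo_hamiltonian`.
#' @param n_electrons,n_protons sector particle numbers; default from
#'   `h$space`.
#' @param max_dim refuse (with an error) sectors larger than this.
#' @return A `casci_result`: `energy` (Ha), `ci_vector` (normalized, real),
#'   `basis` (bitmasks plus electronic/protonic factor lists), `space`.
#' @export
casci_solve <- function(h, n_electrons = h$space$n_electrons,
                        n_protons = h$space$n_protons, max_dim = 20000L) {
  sp <- h$space
  if (n_electrons != sp$n_electrons || n_protons != sp$n_protons) {
    sp <- orbital_space(sp$n_electronic_spatial, sp$n_protonic,
                        n_electrons, n_protons,
                        electronic_labels = sp$electronic_labels,
                        protonic_labels = sp$protonic_labels)
    h$space <- sp
  }
  basis <- sector_basis(sp)
  D <- length(basis$bits)
  if (D == 0) stop("empty sector")
  if (D > max_dim) stop("sector dimension ", D, " exceeds max_dim ", max_dim)
  M <- sector_matrix(h, basis)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- which.min(e$values)
  energy <- e$values[k]
  vec <- e$vectors[, k]
  # deterministic global sign: largest-magnitude amplitude positive
  imax <- which.max(abs(vec))
  if (vec[imax] < 0) vec <- -vec
  resid <- max(abs(M %*% vec - energy * vec))
  if (resid > 1e-8)
    stop("convergence error: eigenpair residual ", format(resid))
  structure(list(energy = energy, ci_vector = vec, basis = basis, space = sp),
            class = "casci_result")
}

#' @export
print.casci_result <- function(x, ...) {
  cat(sprintf("<casci_result> E = %.10f Ha over %d determinants\n",
              x$energy, length(x$ci_vector)))
  invisible(x)
}

#' Aufbau Hartree-Fock product determinant of a NEO Hamiltonian
#'
#' Electrons fill the spin orbitals with the lowest one-body diagonal
#' energies (both spins of a spatial orbital share its diagonal; spin-up
#' before spin-down on ties); the proton occupies the orbital with the lowest
#' `v1p` diagonal.
#'
#' @param h a `neo_hamiltonian`.
#' @return integer bitmask of the reference determinant.
#' @export
hf_reference_bits <- function(h) {
  sp <- h$space
  diag_so <- rep(diag(h$h1e), 2)                 # up block then down block
  modes <- 0:(sp$n_electronic_spin - 1)
  occ_e <- modes[order(diag_so, modes)][seq_len(sp$n_electrons)]
  occ_p <- sp$n_electronic_spin + (which.min(diag(h$v1p)) - 1L)
  as.integer(sum(2^occ_e) + 2^occ_p)
}

#' Energy of the Hartree-Fock product determinant
#'
#' Expectation value of the full Hamiltonian in the single aufbau product
#' determinant (or an explicitly supplied determinant). By the variational
#' principle it is an upper bound on the CASCI energy.
#'
#' @param h a `neo_hamiltonian`.
#' @param reference_bits optional determinant bitmask (default aufbau).
#' @return energy in Ha.
#' @export
hf_product_energy <- function(h, reference_bits = NULL) {
  bits <- if (is.null(reference_bits)) hf_reference_bits(h) else as.integer(reference_bits)
  terms <- neo_term_list(h)
  e <- h$core_energy
  for (tm in terms) {
    res <- apply_ladder_product(bits, tm$modes, tm$daggers)
    if (is.null(res) || res$bits != bits) next
    e <- e + tm$val * res$sign
  }
  e
}

#' Proton-transfer barrier height
#'
#' `dE = E_middle - E_left`, the energy of the transition (Middle) setup
#' relative to the reactant (Left) setup.
#'
#' @param E_middle,E_left energies (any common unit).
#' @return barrier in the same unit.
#' @export
barrier_height <- function(E_middle, E_left) E_middle - E_left

#' One-particle reduced density matrices of a CASCI state
#'
#' Computes `<a+_a a_b>` for both species by operator application over the
#' determinant basis. The electronic matrix is over spin orbitals (trace
#' `n_electrons`); the protonic matrix over protonic orbitals (trace 1).
#'
#' @param res a `casci_result`.
#' @param space optional [orbital_space()] (default `res$space`).
#' @return list of two [one_pdm()] objects, `electronic` and `protonic`.
#' @export
reduced_density_matrices <- function(res, space = res$space) {
  bits <- res$basis$bits
  v <- res$ci_vector
  pos <- new.env(hash = TRUE, size = length(bits))
  for (j in seq_along(bits)) assign(as.character(bits[j]), j, envir = pos)
  rdm_block <- function(modes) {
    d <- length(modes)
    G <- matrix(0, d, d)
    for (a in seq_len(d)) for (b in seq_len(d)) {
      acc <- 0
      for (j in seq_along(bits)) {
        if (v[j] == 0) next
        r <- apply_ladder_product(bits[j], c(modes[a], modes[b]), c(TRUE, FALSE))
        if (is.null(r)) next
        i <- get0(as.character(r$bits), envir = pos)
        if (is.null(i)) next
        acc <- acc + v[i] * r$sign * v[j]
      }
      G[a, b] <- acc
    }
    G
  }
  sp <- space
  e_modes <- 0:(sp$n_electronic_spin - 1)
  p_modes <- sp$n_electronic_spin + 0:(sp$n_protonic - 1)
  list(electronic = one_pdm(rdm_block(e_modes), "electronic",
                            trace_target = sp$n_electrons),
       protonic = one_pdm(rdm_block(p_modes), "protonic",
                          trace_target = sp$n_protons))
}

#' Proton-electron entanglement entropy of a CASCI state
#'
#' Von Neumann entropy of the proton subsystem density matrix obtained by
#' tracing out the electronic degrees of freedom: the CI amplitude matrix
#' over (electronic determinant, protonic determinant) pairs is contracted
#' into `rho_p = t(C) %*% C`, and `S = -sum(lambda * log(lambda))` over its
#' eigenvalues. With one proton the subsystem basis is the protonic orbital
#' basis, so this equals the entropy of the protonic 1-RDM.
#'
#' @param res a `casci_result`.
#' @param space optional [orbital_space()].
#' @param base logarithm base: `"e"` (natural, default) or `"2"`.
#' @return entropy (dimensionless, >= 0; 0 iff the state factorizes).
#' @export
entanglement_entropy <- function(res, space = res$space, base = c("e", "2")) {
  base <- match.arg(base)
  n_e <- length(res$basis$e_dets)
  n_p <- length(res$basis$p_dets)
  C <- matrix(res$ci_vector, nrow = n_e, ncol = n_p)  # electronic index fastest
  rho_p <- crossprod(C)                                # t(C) %*% C
  lam <- eigen((rho_p + t(rho_p)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-14]
  s <- -sum(lam * log(lam))
  if (base == "2") s <- s / log(2)
  max(s, 0)
}

#' Embed a CASCI state into the full qubit register
#'
#' @param res a `casci_result`.
#' @return complex statevector of length `2^n_qubits` with amplitudes at the
#'   determinant bitmask indices.
#' @export
casci_statevector <- function(res) {
  n <- space_n_qubits(res$space)
  v <- complex(2^n)
  v[res$basis$bits + 1L] <- res$ci_vector
  v
}

#' Real-space proton density and position expectation
#'
#' Evaluates `rho(r) = sum_AB dm[A, B] * phi_A(r) * phi_B(r)` on a grid and
#' the position expectation `<r> = trace(dm %*% <A|r|B>)` per Cartesian
#' component.
#'
#' @param dm protonic [one_pdm()] (or plain matrix).
#' @param orbital_grid list with `points` (n x 3 matrix, Angstrom), `values`
#'   (n x n_orb matrix of orbital amplitudes), `weights` (quadrature weights).
#' @param position_integrals n_orb x n_orb x 3 array of `<A|r|B>` (Angstrom).
#' @return A `proton_density_grid`: `points`, `values` (density, >= 0 up to
#'   round-off), `position_expectation` (3-vector), `norm` (quadrature
#'   integral of the density).
#' @export
proton_density_and_position <- function(dm, orbital_grid, position_integrals) {
  m <- if (inherits(dm, "one_pdm")) dm$matrix else as.matrix(dm)
  d <- nrow(m)
  phi <- orbital_grid$values
  if (ncol(phi) != d) stop("dimension error: grid orbitals vs density matrix")
  if (!all(dim(position_integrals)[1:2] == d))
    stop("dimension error: position integrals vs density matrix")
  for (comp in 1:3) {
    P <- position_integrals[, , comp]
    if (max(abs(P - t(Conj(P)))) > 1e-8)
      stop("position integrals must be Hermitian per component")
  }
  dens <- rowSums((phi %*% m) * phi)
  pos <- vapply(1:3, function(comp) sum(diag(m %*% position_integrals[, , comp])),
                numeric(1))
  structure(list(points = orbital_grid$points, values = dens,
                 position_expectation = pos,
                 norm = sum(dens * orbital_grid$weights)),
            class = "proton_density_grid")
}
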