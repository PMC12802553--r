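# ---------------------------------------------------------------------------
# Jordan-Wigner encoding.
#
# Mode ordering (also the qubit ordering; qubit q is bit 2^q of the basis
# index): electronic spin-up spatial orbitals in ascending index, then the
# spin-down block, then the protonic orbitals. a_j carries a Z chain over all
# modes below j.
# ---------------------------------------------------------------------------

# mode index (0-based) of electronic spatial orbital p (1-based) with spin
# ("up"/"dn"), or of protonic orbital P
mode_electronic <- function(space, p, spin) {
  if (spin == "up") p - 1L else space$n_electronic_spatial + p - 1L
}
mode_protonic <- function(space, P) space$n_electronic_spin + P - 1L

# JW image of the annihilation operator on mode j (0-based) over n qubits:
# a_j = Z_{0..j-1} (X_j + i Y_j)/2 = (X_j Z_chain - X_j Z_{chain|j}) / 2
jw_annihilation <- function(n, j) {
  chain <- as.integer(2^j - 1)
  bit <- as.integer(2^j)
  pauli_sum(n, x = c(bit, bit), z = c(chain, bitwOr(chain, bit)),
            coef = c(0.5 + 0i, -0.5 + 0i))
}

jw_creation <- function(n, j) pauli_dagger(jw_annihilation(n, j))

# JW image of a normal-ordered product of creation/annihilation operators.
# ops: list of c(mode, dagger) pairs applied right-to-left in the order given
# (first element acts first on the ket, i.e. is rightmost in the product).
jw_product <- function(n, modes, daggers) {
  acc <- pauli_identity(n)
  # product written left-to-right: modes[1] is the leftmost operator
  for (k in seq_along(modes)) {
    op <- if (daggers[k]) jw_creation(n, modes[k]) else jw_annihilation(n, modes[k])
    acc <- pauli_mult(acc, op)
  }
  acc
}

#' Map a NEO Hamiltonian to a qubit operator
#'
#' Applies the Jordan-Wigner encoding with the package's fixed qubit layout
#' (electronic spin-up block, spin-down block, protonic block, ascending
#' orbital index within each). The identity coefficient absorbs the core
#' constant. The spectrum of the result restricted to the
#' `(n_electrons, n_protons)` occupation sector equals the CASCI spectrum of
#' `h`.
#'
#' @param h a `neo_hamiltonian`.
#' @param encoding currently only `"jordan-wigner"`.
#' @return A `qubit_hamiltonian`: list with `n_qubits`, `terms` (named real
#'   vector, names are Pauli strings with qubit 0 leftmost), and the internal
#'   `pauli` representation used by the simulators.
#' @export
map_to_qubits <- function(h, encoding = "jordan-wigner") {
  if (!identical(encoding, "jordan-wigner"))
    stop("unsupported encoding '", encoding, "'")
  sp <- h$space
  nsp <- sp$n_electronic_spatial
  n <- space_n_qubits(sp)
  acc <- pauli_identity(n, coef = h$core_energy)
  terms_x <- list(); terms_z <- list(); terms_c <- list(); tix <- 0L
  push <- function(ps) {
    tix <<- tix + 1L
    terms_x[[tix]] <<- ps$x; terms_z[[tix]] <<- ps$z; terms_c[[tix]] <<- ps$coef
  }
  # electronic one-body, both spins
  for (p in 1:nsp) for (q in 1:nsp) {
    val <- h$h1e[p, q]
    if (abs(val) < 1e-14) next
    for (s in c("up", "dn")) {
      ps <- jw_product(n, c(mode_electronic(sp, p, s), mode_electronic(sp, q, s)),
                       c(TRUE, FALSE))
      push(pauli_scale(ps, val))
    }
  }
  # electronic two-body: 1/2 sum <pq|rs> a+_ps a+_qt a_st a_rs
  for (p in 1:nsp) for (q in 1:nsp) for (r in 1:nsp) for (s in 1:nsp) {
    val <- h$h2e[p, q, r, s]
    if (abs(val) < 1e-14) next
    for (s1 in c("up", "dn")) for (s2 in c("up", "dn")) {
      m <- c(mode_electronic(sp, p, s1), mode_electronic(sp, q, s2),
             mode_electronic(sp, s, s2), mode_electronic(sp, r, s1))
      ps <- jw_product(n, m, c(TRUE, TRUE, FALSE, FALSE))
      push(pauli_scale(ps, 0.5 * val))
    }
  }
  # protonic one-body
  for (P in 1:sp$n_protonic) for (Q in 1:sp$n_protonic) {
    val <- h$v1p[P, Q]
    if (abs(val) < 1e-14) next
    ps <- jw_product(n, c(mode_protonic(sp, P), mode_protonic(sp, Q)),
                     c(TRUE, FALSE))
    push(pauli_scale(ps, val))
  }
  # electron-proton coupling: g_PQpq a+_P a_Q a+_ps a_qs
  for (P in 1:sp$n_protonic) for (Q in 1:sp$n_protonic)
    for (p in 1:nsp) for (q in 1:nsp) {
      val <- h$gep[P, Q, p, q]
      if (abs(val) < 1e-14) next
      for (s1 in c("up", "dn")) {
        m <- c(mode_protonic(sp, P), mode_protonic(sp, Q),
               mode_electronic(sp, p, s1), mode_electronic(sp, q, s1))
        ps <- jw_product(n, m, c(TRUE, FALSE, TRUE, FALSE))
        push(pauli_scale(ps, val))
      }
    }
  if (tix > 0L) {
    acc <- pauli_add(acc, pauli_sum(n, unlist(terms_x), unlist(terms_z),
                                    unlist(terms_c)))
  }
  qubit_hamiltonian_from_pauli(acc, space = sp)
}

#' Assemble a qubit Hamiltonian object from a pauli_sum
#'
#' Validates Hermiticity (all label-basis coefficients real within `tol`).
#' @keywords internal
qubit_hamiltonian_from_pauli <- function(ps, space = NULL, tol = 1e-9) {
  lab <- pauli_labels(ps)
  if (length(lab$coef) && max(abs(Im(lab$coef))) > tol)
    stop("mapped operator is not Hermitian (max imaginary coefficient ",
         format(max(abs(Im(lab$coef)))), ")")
  terms <- Re(lab$coef)
  names(terms) <- lab$labels
  structure(list(n_qubits = ps$n_qubits, terms = terms, pauli = ps,
                 space = space),
            class = "qubit_hamiltonian")
}

#' @export
print.qubit_hamiltonian <- function(x, ...) {
  cat(sprintf("<qubit_hamiltonian> %d qubits, %d Pauli terms\n",
              x$n_qubits, length(x$terms)))
  invisible(x)
}

#' Expectation value of a qubit Hamiltonian in a statevector
#' @param H a `qubit_hamiltonian`.
#' @param v complex statevector of length `2^n_qubits`.
#' @return real expectation value (Ha).
#' @export
qubit_expectation <- function(H, v) {
  Re(pauli_expectation(H$pauli, v))
}

#' Basis index (0-based) of a determinant pair in the qubit register
#'
#' @param space an [orbital_space()].
#' @param e_occ_up,e_occ_dn 1-based occupied spatial orbital indices per spin.
#' @param p_occ 1-based occupied protonic orbital index (length 1).
#' @return integer basis index whose set bits are the occupied JW modes.
#' @keywords internal
determinant_bits <- function(space, e_occ_up, e_occ_dn, p_occ) {
  bits <- 0L
  for (p in e_occ_up) bits <- bitwOr(bits, as.integer(2^mode_electronic(space, p, "up")))
  for (p in e_occ_dn) bits <- bitwOr(bits, as.integer(2^mode_electronic(space, p, "dn")))
  for (P in p_occ) bits <- bitwOr(bits, as.integer(2^mode_protonic(space, P)))
  bits
}
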