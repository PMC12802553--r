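# ---------------------------------------------------------------------------
# Data model for coupled electron-proton second-quantized Hamiltonians.
#
# H = E_core
#   + sum_pq h_pq a+_p a_q                      (electronic, spatial indices)
#   + 1/2 sum_pqrs <pq|rs> a+_p a+_q a_s a_r    (physicist ordering)
#   + sum_PQ v_PQ a+_P a_Q                      (protonic, kinetic folded in)
#   + sum_PQpq g_PQpq a+_P a_Q a+_p a_q         (electron-proton coupling)
#
# Electronic tensors are stored over SPATIAL orbitals (spin is restored at
# mapping / CI time); the single proton lives in one spin channel, one mode
# per protonic orbital.
# ---------------------------------------------------------------------------

#' Declare an orbital space for a coupled electron-proton system
#'
#' @param n_electronic_spatial number of electronic spatial orbitals.
#' @param n_protonic number of protonic orbitals (single spin channel).
#' @param n_electrons number of electrons in the active space.
#' @param n_protons number of quantum protons (must be 1).
#' @param electronic_labels,protonic_labels optional unique identifier vectors.
#' @return An `orbital_space` object with derived field `n_electronic_spin =
#'   2 * n_electronic_spatial`.
#' @examples
#' sp <- orbital_space(2, 2, n_electrons = 2)
#' sp$n_electronic_spin
#' @export
orbital_space <- function(n_electronic_spatial, n_protonic, n_electrons,
                          n_protons = 1L,
                          electronic_labels = NULL, protonic_labels = NULL) {
  n_electronic_spatial <- as.integer(n_electronic_spatial)
  n_protonic <- as.integer(n_protonic)
  n_electrons <- as.integer(n_electrons)
  n_protons <- as.integer(n_protons)
  if (n_electronic_spatial < 1 || n_protonic < 1)
    stop("orbital counts must be positive")
  if (n_protons != 1L)
    stop("exactly one quantum proton is supported (n_protons = 1)")
  if (n_electrons < 0 || n_electrons > 2L * n_electronic_spatial)
    stop("n_electrons must satisfy 0 <= n_electrons <= n_electronic_spin")
  if (n_protons > n_protonic)
    stop("n_protons exceeds the number of protonic orbitals")
  if (is.null(electronic_labels))
    electronic_labels <- paste0("e", seq_len(n_electronic_spatial))
  if (is.null(protonic_labels))
    protonic_labels <- paste0("p", seq_len(n_protonic))
  if (anyDuplicated(electronic_labels) || anyDuplicated(protonic_labels))
    stop("orbital labels must be unique")
  structure(list(
    n_electronic_spatial = n_electronic_spatial,
    n_electronic_spin = 2L * n_electronic_spatial,
    n_protonic = n_protonic,
    n_electrons = n_electrons,
    n_protons = n_protons,
    electronic_labels = as.character(electronic_labels),
    protonic_labels = as.character(protonic_labels)
  ), class = "orbital_space")
}

#' @export
print.orbital_space <- function(x, ...) {
  cat(sprintf(
    "<orbital_space> %d electronic spatial (%d spin) / %d protonic orbitals; %d e-, %d p+\n",
    x$n_electronic_spatial, x$n_electronic_spin, x$n_protonic,
    x$n_electrons, x$n_protons))
  invisible(x)
}

# total Jordan-Wigner qubits: spin-up block + spin-down block + protonic block
space_n_qubits <- function(space) space$n_electronic_spin + space$n_protonic

# the 8 index images of the real-orbital permutational symmetry of <pq|rs>
h2e_symmetrize <- function(h2e) {
  s <- h2e
  s <- s + aperm(h2e, c(2, 1, 4, 3))  # <qp|sr>
  s <- s + aperm(h2e, c(3, 4, 1, 2))  # <rs|pq>
  s <- s + aperm(h2e, c(4, 3, 2, 1))  # <sr|qp>
  s <- s + aperm(h2e, c(3, 2, 1, 4))  # <rq|ps>
  s <- s + aperm(h2e, c(1, 4, 3, 2))  # <ps|rq>
  s <- s + aperm(h2e, c(2, 3, 4, 1))  # <qr|sp>? (real-orbital image)
  s <- s + aperm(h2e, c(4, 1, 2, 3))
  s / 8
}

h2e_symmetry_residual <- function(h2e) {
  perms <- list(c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1),
                c(3, 2, 1, 4), c(1, 4, 3, 2), c(2, 3, 4, 1), c(4, 1, 2, 3))
  max(vapply(perms, function(p) max(abs(h2e - aperm(h2e, p))), numeric(1)))
}

#' Construct a NEO Hamiltonian
#'
#' Bundles the core constant and integral tensors of a coupled
#' electron-proton second-quantized Hamiltonian over a declared
#' [orbital_space()]. All tensors are real, in Hartree, with the electronic
#' two-body tensor in physicist `<pq|rs>` ordering carrying the 8-fold
#' real-orbital permutational symmetry.
#'
#' @param space an [orbital_space()].
#' @param core_energy scalar core constant (Ha).
#' @param h1e electronic one-body matrix over spatial orbitals (Ha).
#' @param h2e electronic two-body 4-d array `<pq|rs>` over spatial orbitals (Ha).
#' @param v1p protonic one-body matrix (kinetic energy folded in, Ha).
#' @param gep electron-proton coupling array indexed `[P, Q, p, q]` (Ha).
#' @param validate check all invariants (default `TRUE`).
#' @param tol absolute tolerance for symmetry validation.
#' @return A `neo_hamiltonian` object.
#' @export
neo_hamiltonian <- function(space, core_energy, h1e, h2e, v1p, gep,
                            validate = TRUE, tol = 1e-8) {
  ne <- space$n_electronic_spatial
  np <- space$n_protonic
  h1e <- as.matrix(h1e)
  v1p <- as.matrix(v1p)
  h2e <- array(as.numeric(h2e), dim = c(ne, ne, ne, ne))
  gep <- array(as.numeric(gep), dim = c(np, np, ne, ne))
  h <- structure(list(space = space, core_energy = as.numeric(core_energy),
                      h1e = h1e, h2e = h2e, v1p = v1p, gep = gep),
                 class = "neo_hamiltonian")
  if (validate) validate_neo_hamiltonian(h, tol = tol)
  h
}

#' Validate NEO Hamiltonian invariants
#'
#' Checks tensor shapes, finiteness, Hermiticity of `h1e` and `v1p`,
#' Hermiticity of `gep` in each index pair, and the declared permutational
#' symmetry of `h2e`.
#'
#' @param h a `neo_hamiltonian`.
#' @param tol absolute tolerance (default `1e-8`).
#' @return `h`, invisibly; otherwise an error describing the violation.
#' @export
validate_neo_hamiltonian <- function(h, tol = 1e-8) {
  sp <- h$space
  ne <- sp$n_electronic_spatial; np <- sp$n_protonic
  if (!all(dim(h$h1e) == c(ne, ne))) stop("h1e dimension mismatch: expected ", ne, "x", ne)
  if (!all(dim(h$v1p) == c(np, np))) stop("v1p dimension mismatch: expected ", np, "x", np)
  if (!all(dim(h$h2e) == c(ne, ne, ne, ne))) stop("h2e dimension mismatch")
  if (!all(dim(h$gep) == c(np, np, ne, ne))) stop("gep dimension mismatch")
  vals <- c(h$core_energy, h$h1e, h$h2e, h$v1p, h$gep)
  if (any(!is.finite(vals))) stop("non-finite entries in Hamiltonian tensors")
  if (max(abs(h$h1e - t(h$h1e))) > tol)
    stop("validation error: h1e is not Hermitian (residual ",
         format(max(abs(h$h1e - t(h$h1e)))), ")")
  if (max(abs(h$v1p - t(h$v1p))) > tol)
    stop("validation error: v1p is not Hermitian")
  if (max(abs(h$gep - aperm(h$gep, c(2, 1, 3, 4)))) > tol ||
      max(abs(h$gep - aperm(h$gep, c(1, 2, 4, 3)))) > tol)
    stop("validation error: gep is not Hermitian in each index pair")
  if (h2e_symmetry_residual(h$h2e) > tol)
    stop("validation error: h2e violates 8-fold permutational symmetry (residual ",
         format(h2e_symmetry_residual(h$h2e)), ")")
  invisible(h)
}

#' @export
print.neo_hamiltonian <- function(x, ...) {
  cat("<neo_hamiltonian>\n")
  print(x$space)
  cat(sprintf("  core energy: %.8f Ha; %d JW qubits\n",
              x$core_energy, space_n_qubits(x$space)))
  invisible(x)
}

same_space <- function(a, b) {
  identical(a$n_electronic_spatial, b$n_electronic_spatial) &&
    identical(a$n_protonic, b$n_protonic) &&
    identical(a$n_electrons, b$n_electrons)
}

#' Weight triple for Left/Middle/Right interpolation
#'
#' @param alpha,beta,gamma non-negative weights; normalized to sum 1.
#' @param label optional LMR label string.
#' @return A `weight_triple` with `alpha + beta + gamma == 1`.
#' @export
weight_triple <- function(alpha, beta, gamma, label = NULL) {
  w <- c(alpha, beta, gamma)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  s <- sum(w)
  if (s <= 0) stop("weights must have positive sum")
  structure(list(alpha = w[1] / s, beta = w[2] / s, gamma = w[3] / s,
                 label = label), class = "weight_triple")
}

#' Convert a 3-digit LMR label into interpolation weights
#'
#' Each digit gives the relative weight of the Left, Middle and Right
#' Hamiltonians; weights are the digits divided by their sum. The canonical
#' seven-point adiabatic trajectory is `300, 210, 120, 030, 021, 012, 003`.
#'
#' @param label a 3-digit string with positive digit sum, e.g. `"210"`.
#' @return A [weight_triple()].
#' @examples
#' lmr_weights("210")  # (2/3, 1/3, 0)
#' @export
lmr_weights <- function(label) {
  label <- as.character(label)
  if (!grepl("^[0-9]{3}$", label))
    stop("invalid label '", label, "': expected a 3-digit string")
  d <- as.integer(strsplit(label, "")[[1]])
  if (sum(d) == 0) stop("invalid label '000': digit sum must be positive")
  weight_triple(d[1], d[2], d[3], label = label)
}

#' The canonical seven-point LMR trajectory labels
#' @return character vector `300 ... 003`.
#' @export
lmr_trajectory_labels <- function() {
  c("300", "210", "120", "030", "021", "012", "003")
}

#' Convex interpolation of three NEO Hamiltonians
#'
#' Forms `H = alpha * H_L + beta * H_M + gamma * H_R` entrywise on every
#' tensor and on the core constant. The three Hamiltonians must share one
#' orbital space; linearity guarantees the result satisfies all invariants.
#'
#' @param hL,hM,hR `neo_hamiltonian` objects on a common space.
#' @param w a [weight_triple()] (or LMR label string).
#' @return The interpolated `neo_hamiltonian`.
#' @export
interpolate_hamiltonians <- function(hL, hM, hR, w) {
  if (is.character(w)) w <- lmr_weights(w)
  stopifnot(inherits(w, "weight_triple"))
  if (!same_space(hL$space, hM$space) || !same_space(hL$space, hR$space))
    stop("the three Hamiltonians must share one orbital space")
  mix <- function(f) w$alpha * hL[[f]] + w$beta * hM[[f]] + w$gamma * hR[[f]]
  neo_hamiltonian(hL$space, mix("core_energy"), mix("h1e"), mix("h2e"),
                  mix("v1p"), mix("gep"), validate = FALSE)
}

#' Loewdin symmetric orthogonalization
#'
#' Returns `X = S^(-1/2)` for a symmetric positive-definite overlap matrix,
#' so that `t(X) %*% S %*% X` is the identity.
#'
#' @param S symmetric positive definite overlap matrix.
#' @param tol smallest admissible eigenvalue (relative to the largest).
#' @return The transformation matrix `X`.
#' @export
lowdin_orthogonalize <- function(S, tol = 1e-12) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-10) stop("overlap matrix must be symmetric")
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= tol * max(e$values)) || any(e$values <= 0))
    stop("overlap matrix is not positive definite (min eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*% t(e$vectors)
}

#' One-particle density matrix container
#'
#' @param matrix Hermitian PSD matrix over one particle type's orbitals.
#' @param particle_type `"electronic"` or `"protonic"`.
#' @param trace_target expected particle count (checked within `tol`).
#' @param tol validation tolerance.
#' @return A `one_pdm` object.
#' @export
one_pdm <- function(matrix, particle_type = c("electronic", "protonic"),
                    trace_target = NULL, tol = 1e-8) {
  particle_type <- match.arg(particle_type)
  m <- as.matrix(matrix)
  if (max(abs(m - t(Conj(m)))) > tol) stop("density matrix must be Hermitian")
  ev <- eigen((m + t(Conj(m))) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop("density matrix must be positive semidefinite")
  if (!is.null(trace_target) && abs(sum(diag(m)) - trace_target) > 1e-6)
    stop("density matrix trace ", format(sum(diag(m))),
         " differs from target ", trace_target)
  structure(list(matrix = m, particle_type = particle_type,
                 trace_target = trace_target), class = "one_pdm")
}

#' Frozen-natural-orbital selection from a one-particle density matrix
#'
#' Diagonalizes the density matrix and keeps the `n_keep` eigenvectors with
#' the largest occupation numbers (natural orbitals). The truncation error in
#' the trace equals the sum of the dropped occupations.
#'
#' @param dm a [one_pdm()] or plain Hermitian matrix.
#' @param n_keep number of natural orbitals to keep (>= 1).
#' @return list with `rotation` (orthonormal columns, all natural orbitals in
#'   descending occupation order), `kept` (indices `1:n_keep` into that
#'   order), and `occupations` (all occupations, descending).
#' @export
fno_select <- function(dm, n_keep) {
  m <- if (inherits(dm, "one_pdm")) dm$matrix else as.matrix(dm)
  d <- nrow(m)
  n_keep <- as.integer(n_keep)
  if (n_keep < 1) stop("empty-space error: n_keep must be >= 1")
  if (n_keep > d) stop("n_keep exceeds the density-matrix dimension")
  e <- eigen((m + t(Conj(m))) / 2, symmetric = TRUE)
  # eigen returns descending order already
  list(rotation = e$vectors, kept = seq_len(n_keep), occupations = e$values)
}
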