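# Independent oracles used across the suite. These deliberately avoid the
# package's bitmask Pauli representation: operators are realized as dense
# Kronecker products and states manipulated as plain vectors/matrices.

pauli_mats <- list(I = diag(2),
                   X = matrix(c(0, 1, 1, 0), 2, 2),
                   Y = matrix(c(0, 1i, -1i, 0), 2, 2),
                   Z = diag(c(1, -1)))

# dense matrix of a named Pauli-sum (qubit 0 leftmost in the label = lowest
# bit of the basis index, so it is the LAST factor of the Kronecker product)
kron_pauli_matrix <- function(terms) {
  labs <- names(terms)
  n <- nchar(labs[1])
  M <- matrix(0 + 0i, 2^n, 2^n)
  for (k in seq_along(terms)) {
    ch <- strsplit(labs[k], "")[[1]]
    Tk <- Reduce(kronecker, lapply(rev(ch), function(c) pauli_mats[[c]]))
    M <- M + terms[k] * Tk
  }
  M
}

# dense JW mode operators over n modes (bit j of the index = occupation of
# mode j), built directly from kron: a_j = Z^(j) (x) sigma_minus (x) I^(n-j-1)
kron_annihilation <- function(n, j) {
  sm <- matrix(c(0, 0, 1, 0), 2, 2)  # |0><1|
  facs <- c(rep(list(pauli_mats$Z), j), list(sm), rep(list(pauli_mats$I), n - j - 1))
  Reduce(kronecker, rev(facs))
}

# dense full-space matrix of a NEO Hamiltonian via kron JW operators
kron_neo_matrix <- function(h) {
  sp <- h$space
  nsp <- sp$n_electronic_spatial
  n <- sp$n_electronic_spin + sp$n_protonic
  N <- 2^n
  a <- lapply(0:(n - 1), function(j) kron_annihilation(n, j))
  ad <- lapply(a, function(m) Conj(t(m)))
  me <- function(p, s) if (s == 1) p - 1L else nsp + p - 1L
  mp <- function(P) sp$n_electronic_spin + P - 1L
  M <- diag(N) * h$core_energy
  for (p in 1:nsp) for (q in 1:nsp) {
    if (abs(h$h1e[p, q]) < 1e-14) next
    for (s in 1:2)
      M <- M + h$h1e[p, q] * ad[[me(p, s) + 1]] %*% a[[me(q, s) + 1]]
  }
  for (p in 1:nsp) for (q in 1:nsp) for (r in 1:nsp) for (s in 1:nsp) {
    v <- h$h2e[p, q, r, s]
    if (abs(v) < 1e-14) next
    for (s1 in 1:2) for (s2 in 1:2)
      M <- M + 0.5 * v * ad[[me(p, s1) + 1]] %*% ad[[me(q, s2) + 1]] %*%
        a[[me(s, s2) + 1]] %*% a[[me(r, s1) + 1]]
  }
  for (P in 1:sp$n_protonic) for (Q in 1:sp$n_protonic) {
    if (abs(h$v1p[P, Q]) < 1e-14) next
    M <- M + h$v1p[P, Q] * ad[[mp(P) + 1]] %*% a[[mp(Q) + 1]]
  }
  for (P in 1:sp$n_protonic) for (Q in 1:sp$n_protonic)
    for (p in 1:nsp) for (q in 1:nsp) {
      v <- h$gep[P, Q, p, q]
      if (abs(v) < 1e-14) next
      for (s1 in 1:2)
        M <- M + v * ad[[mp(P) + 1]] %*% a[[mp(Q) + 1]] %*%
          ad[[me(p, s1) + 1]] %*% a[[me(q, s1) + 1]]
    }
  M
}

# indices (1-based) of the (n_electrons, n_protons) sector in the full space
sector_indices <- function(space) {
  n <- space$n_electronic_spin + space$n_protonic
  idx <- 0:(2^n - 1)
  nbits <- function(v, mask) {
    out <- integer(length(v))
    x <- bitwAnd(v, mask)
    while (any(x > 0)) { out <- out + x %% 2L; x <- x %/% 2L }
    out
  }
  e_mask <- as.integer(2^space$n_electronic_spin - 1)
  p_mask <- bitwShiftL(as.integer(2^space$n_protonic - 1), space$n_electronic_spin)
  which(nbits(idx, e_mask) == space$n_electrons &
          nbits(idx, p_mask) == space$n_protons)
}

# ground energy of the sector by dense diagonalization of the qubit-side
# Hamiltonian restricted to the sector basis (route: map_to_qubits + dense
# eigen, fully separate from the determinant CI path)
jw_sector_ground <- function(h) {
  H <- qneo::map_to_qubits(h)
  sel <- sector_indices(h$space)
  N <- 2^H$n_qubits
  cols <- lapply(sel, function(j) {
    v <- complex(N); v[j] <- 1 + 0i
    qneo:::pauli_apply(H$pauli, v)[sel]
  })
  M <- do.call(cbind, cols)
  min(eigen((M + Conj(t(M))) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

random_state <- function(n, seed) {
  set.seed(seed)
  v <- complex(real = stats::rnorm(2^n), imaginary = stats::rnorm(2^n))
  v / sqrt(sum(Mod(v)^2))
}

# structured target: state of a random shallow two-qubit-block circuit
random_block_target <- function(n, nblocks, seed) {
  set.seed(seed)
  v <- complex(2^n); v[1] <- 1 + 0i
  for (b in seq_len(nblocks)) {
    pq <- sort(sample(0:(n - 1), 2))
    th <- stats::runif(15, -pi, pi)
    v <- qneo:::apply_2q(v, qneo:::su4_block_matrix(th), pq[1], pq[2], n)
  }
  v
}

ghz_state <- function(n) {
  v <- complex(2^n)
  v[1] <- 1 / sqrt(2)
  v[2^n] <- 1 / sqrt(2)
  v
}

synthetic_device_table <- function(n_qubits, err_1q = 2.5e-4, err_2q = 3e-3,
                                   T1 = 180, T2 = 120, p01 = 0.01, p10 = 0.02) {
  data.frame(qubit = 0:(n_qubits - 1), T1_us = T1, T2_us = T2,
             err_1q = err_1q, err_2q = err_2q,
             dur_1q_ns = 32, dur_2q_ns = 68, p01 = p01, p10 = p10)
}
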