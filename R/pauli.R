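# ---------------------------------------------------------------------------
# Pauli-sum algebra in the symplectic (x, z) representation.
#
# A term is  w * X^x Z^z  where x and z are bitmasks over qubits (qubit q is
# bit 2^q of the basis-state index) and w is a complex weight.  The named
# Pauli on qubit q is I (00), X (10), Z (01) or Y (11, since Y = i X Z).
# This representation makes string products and statevector application
# cheap bit arithmetic; conversion to/from human-readable labels happens only
# at the API boundary (QubitHamiltonian terms).
# ---------------------------------------------------------------------------

#' Construct a Pauli-sum operator
#'
#' Internal representation of an operator as a sum of weighted Pauli strings
#' over `n_qubits` qubits. Terms are stored in the symplectic `(x, z)` bitmask
#' form with complex weights; duplicate strings are combined and negligible
#' weights dropped.
#'
#' @param n_qubits number of qubits (<= 30).
#' @param x,z integer bitmask vectors (one entry per term).
#' @param coef complex (or numeric) weights, same length as `x`.
#' @return An object of class `pauli_sum`.
#' @keywords internal
pauli_sum <- function(n_qubits, x = integer(0), z = integer(0), coef = complex(0)) {
  stopifnot(length(x) == length(z), length(x) == length(coef), n_qubits >= 1)
  ps <- list(n_qubits = as.integer(n_qubits), x = as.integer(x),
             z = as.integer(z), coef = as.complex(coef))
  class(ps) <- "pauli_sum"
  pauli_simplify(ps)
}

#' Combine duplicate Pauli strings and drop zero terms
#' @param ps a `pauli_sum`
#' @param tol weights with modulus below `tol` are dropped.
#' @keywords internal
pauli_simplify <- function(ps, tol = 1e-14) {
  if (length(ps$x) == 0) return(ps)
  key <- paste(ps$x, ps$z, sep = ":")
  if (anyDuplicated(key)) {
    re <- rowsum(Re(ps$coef), key)
    im <- rowsum(Im(ps$coef), key)
    keys <- rownames(re)
    parts <- matrix(as.integer(unlist(strsplit(keys, ":", fixed = TRUE))),
                    ncol = 2, byrow = TRUE)
    ps$x <- parts[, 1]; ps$z <- parts[, 2]
    ps$coef <- complex(real = re[, 1], imaginary = im[, 1])
  }
  keep <- Mod(ps$coef) > tol
  ps$x <- ps$x[keep]; ps$z <- ps$z[keep]; ps$coef <- ps$coef[keep]
  ord <- order(ps$x, ps$z)
  ps$x <- ps$x[ord]; ps$z <- ps$z[ord]; ps$coef <- ps$coef[ord]
  ps
}

#' Identity operator as a pauli_sum
#' @keywords internal
pauli_identity <- function(n_qubits, coef = 1 + 0i) {
  pauli_sum(n_qubits, 0L, 0L, as.complex(coef))
}

#' Sum of two pauli_sums
#' @keywords internal
pauli_add <- function(a, b) {
  stopifnot(a$n_qubits == b$n_qubits)
  pauli_sum(a$n_qubits, c(a$x, b$x), c(a$z, b$z), c(a$coef, b$coef))
}

#' Scale a pauli_sum by a scalar
#' @keywords internal
pauli_scale <- function(a, s) {
  a$coef <- a$coef * as.complex(s)
  pauli_simplify(a)
}

# popcount for non-negative integers < 2^30 (vectorized)
popcount <- function(v) {
  v <- as.integer(v)
  n <- integer(length(v))
  while (any(v > 0L)) {
    n <- n + (v %% 2L)
    v <- v %/% 2L
  }
  n
}

#' Product of two pauli_sums
#'
#' Uses `(X^x1 Z^z1)(X^x2 Z^z2) = (-1)^popcount(z1 & x2) X^(x1 xor x2)
#' Z^(z1 xor z2)`.
#' @keywords internal
pauli_mult <- function(a, b) {
  stopifnot(a$n_qubits == b$n_qubits)
  na <- length(a$x); nb <- length(b$x)
  if (na == 0 || nb == 0) return(pauli_sum(a$n_qubits))
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  sign <- 1 - 2 * (popcount(bitwAnd(a$z[ia], b$x[ib])) %% 2L)
  pauli_sum(a$n_qubits,
            bitwXor(a$x[ia], b$x[ib]),
            bitwXor(a$z[ia], b$z[ib]),
            a$coef[ia] * b$coef[ib] * sign)
}

#' Hermitian conjugate of a pauli_sum
#' @keywords internal
pauli_dagger <- function(a) {
  # (w X^x Z^z)^dag = conj(w) Z^z X^x = conj(w) (-1)^popcount(x & z) X^x Z^z
  sign <- 1 - 2 * (popcount(bitwAnd(a$x, a$z)) %% 2L)
  a$coef <- Conj(a$coef) * sign
  pauli_simplify(a)
}

#' Human-readable labels of the Pauli strings in a pauli_sum
#'
#' Qubit 0 is the leftmost character. Returns the label vector and the
#' label-basis coefficients (`X^x Z^z = (-i)^{#Y} * named string`).
#' @keywords internal
pauli_labels <- function(ps) {
  n <- ps$n_qubits
  m <- length(ps$x)
  labs <- character(m)
  coefs <- ps$coef
  codes <- c("I", "X", "Z", "Y")
  for (k in seq_len(m)) {
    xb <- bitwAnd(ps$x[k] %/% 2L^(0:(n - 1)), 1L)
    zb <- bitwAnd(ps$z[k] %/% 2L^(0:(n - 1)), 1L)
    idx <- 1L + xb + 2L * zb
    labs[k] <- paste(codes[idx], collapse = "")
    nY <- sum(idx == 4L)
    coefs[k] <- coefs[k] * (-1i)^nY
  }
  list(labels = labs, coef = coefs)
}

#' Build a pauli_sum from labelled terms
#'
#' @param terms named numeric/complex vector; names are Pauli strings over
#'   `{I,X,Y,Z}` with qubit 0 leftmost.
#' @param n_qubits optional; inferred from the label length.
#' @keywords internal
pauli_from_labels <- function(terms, n_qubits = NULL) {
  labs <- names(terms)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("terms must be a named vector of Pauli strings")
  if (is.null(n_qubits)) n_qubits <- nchar(labs[1])
  if (any(nchar(labs) != n_qubits))
    stop("all Pauli strings must have length ", n_qubits)
  m <- length(terms)
  x <- integer(m); z <- integer(m); coef <- as.complex(terms)
  for (k in seq_len(m)) {
    ch <- strsplit(labs[k], "")[[1]]
    if (any(!ch %in% c("I", "X", "Y", "Z")))
      stop("invalid Pauli character in '", labs[k], "'")
    xb <- as.integer(ch %in% c("X", "Y"))
    zb <- as.integer(ch %in% c("Z", "Y"))
    x[k] <- sum(xb * 2L^(seq_len(n_qubits) - 1L))
    z[k] <- sum(zb * 2L^(seq_len(n_qubits) - 1L))
    coef[k] <- coef[k] * (1i)^sum(ch == "Y")  # named Y = i * XZ => XZ-basis weight
  }
  pauli_sum(n_qubits, x, z, coef)
}

# parity of popcount(i & mask) for i = 0 .. N-1, as +/-1 vector
parity_signs <- function(n_qubits, mask) {
  N <- 2L^n_qubits
  idx <- 0:(N - 1)
  1 - 2 * (popcount(bitwAnd(idx, mask)) %% 2L)
}

#' Apply a pauli_sum to a statevector
#'
#' @param ps a `pauli_sum`
#' @param v complex statevector of length `2^n_qubits` (basis index bit q =
#'   qubit q).
#' @return the complex vector `ps %*% v`.
#' @keywords internal
pauli_apply <- function(ps, v) {
  N <- 2L^ps$n_qubits
  stopifnot(length(v) == N)
  out <- complex(N)
  idx <- 0:(N - 1)
  for (k in seq_along(ps$x)) {
    sgn <- parity_signs(ps$n_qubits, ps$z[k])
    out[bitwXor(idx, ps$x[k]) + 1L] <- out[bitwXor(idx, ps$x[k]) + 1L] +
      ps$coef[k] * sgn * v
  }
  out
}

#' Expectation value of a pauli_sum in a statevector
#' @keywords internal
pauli_expectation <- function(ps, v) {
  sum(Conj(v) * pauli_apply(ps, v))
}

#' Dense matrix of a pauli_sum (small systems only)
#'
#' Row/column index `i + 1` corresponds to basis state with occupation bits
#' `i`. Intended for tests and small oracles.
#' @param ps a `pauli_sum`
#' @return complex matrix of dimension `2^n x 2^n`.
#' @keywords internal
pauli_matrix <- function(ps) {
  N <- 2L^ps$n_qubits
  M <- matrix(0 + 0i, N, N)
  idx <- 0:(N - 1)
  for (k in seq_along(ps$x)) {
    sgn <- parity_signs(ps$n_qubits, ps$z[k])
    rows <- bitwXor(idx, ps$x[k]) + 1L
    M[cbind(rows, idx + 1L)] <- M[cbind(rows, idx + 1L)] + ps$coef[k] * sgn
  }
  M
}

#' Action of exp(theta * ps) on a statevector by truncated Taylor series
#'
#' Converges for the modest-norm anti-Hermitian generators used by the
#' ADAPT-VQE ansatz; terminates when the next term's norm falls below `tol`.
#' @keywords internal
pauli_exp_apply <- function(ps, theta, v, tol = 1e-15, max_terms = 60L) {
  if (theta == 0 || length(ps$x) == 0) return(v)
  # scaling: keep the sub-step norm |theta| * sum|c| <= 1 so the series is
  # numerically benign for any theta the optimizer may visit
  s <- abs(theta) * sum(Mod(ps$coef))
  m <- max(1L, ceiling(s))
  th <- theta / m
  for (chunk in seq_len(m)) {
    out <- v
    term <- v
    for (k in seq_len(max_terms)) {
      term <- pauli_apply(ps, term) * (th / k)
      out <- out + term
      if (sqrt(sum(Mod(term)^2)) < tol) break
    }
    v <- out
  }
  v
}
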