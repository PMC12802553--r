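# ---------------------------------------------------------------------------
# Minimal gate-level statevector simulator.
#
# Gate set: rx, ry, rz (one parameter each), x, h, cx. Qubit q is bit 2^q of
# the basis index. Circuits are plain ordered gate lists so they can be
# serialized as JSON and folded/gates counted without a backend.
# ---------------------------------------------------------------------------

#' Construct a gate circuit
#'
#' @param n_qubits register width.
#' @param gates list of gates, each `list(name, qubits, params)` with 0-based
#'   qubit indices.
#' @param metadata optional named list (preset, seed, ...).
#' @return A `gate_circuit`.
#' @export
gate_circuit <- function(n_qubits, gates = list(), metadata = list()) {
  n_qubits <- as.integer(n_qubits)
  for (g in gates) validate_gate(g, n_qubits)
  structure(list(n_qubits = n_qubits, gates = gates, metadata = metadata),
            class = "gate_circuit")
}

gate_arity <- c(rx = 1L, ry = 1L, rz = 1L, x = 1L, h = 1L, cx = 2L)
gate_nparams <- c(rx = 1L, ry = 1L, rz = 1L, x = 0L, h = 0L, cx = 0L)

validate_gate <- function(g, n_qubits) {
  if (!g$name %in% names(gate_arity)) stop("unknown gate '", g$name, "'")
  if (length(g$qubits) != gate_arity[[g$name]])
    stop("gate '", g$name, "' expects ", gate_arity[[g$name]], " qubit(s)")
  if (any(g$qubits < 0 | g$qubits >= n_qubits)) stop("qubit index out of range")
  np <- gate_nparams[[g$name]]
  if (np > 0 && length(g$params) != np)
    stop("gate '", g$name, "' expects ", np, " parameter(s)")
  invisible(g)
}

gate <- function(name, qubits, params = numeric(0)) {
  list(name = name, qubits = as.integer(qubits), params = as.numeric(params))
}

#' Append a gate to a circuit
#' @keywords internal
circuit_append <- function(circ, g) {
  validate_gate(g, circ$n_qubits)
  circ$gates[[length(circ$gates) + 1L]] <- g
  circ
}

#' @export
print.gate_circuit <- function(x, ...) {
  m <- circuit_metrics(x)
  cat(sprintf("<gate_circuit> %d qubits, %d gates (%d two-qubit, depth %d)\n",
              x$n_qubits, length(x$gates), m$two_qubit_count, m$two_qubit_depth))
  invisible(x)
}

# 2x2 single-qubit gate matrices
gate_matrix_1q <- function(name, params) {
  switch(name,
         rx = { t <- params[1] / 2
                matrix(c(cos(t), -1i * sin(t), -1i * sin(t), cos(t)), 2, 2) },
         ry = { t <- params[1] / 2
                matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2) },
         rz = { t <- params[1] / 2
                diag(c(exp(-1i * t), exp(1i * t))) },
         x = matrix(c(0, 1, 1, 0), 2, 2),
         h = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
         stop("not a one-qubit gate: ", name))
}

# apply a 2x2 matrix U on qubit q of statevector v
apply_1q <- function(v, U, q, n) {
  idx <- 0:(2^n - 1)
  b <- as.integer(2^q)
  lo <- idx[bitwAnd(idx, b) == 0L]
  hi <- lo + b
  v0 <- v[lo + 1L]; v1 <- v[hi + 1L]
  v[lo + 1L] <- U[1, 1] * v0 + U[1, 2] * v1
  v[hi + 1L] <- U[2, 1] * v0 + U[2, 2] * v1
  v
}

# apply CX with control c, target t
apply_cx <- function(v, cq, tq, n) {
  idx <- 0:(2^n - 1)
  bc <- as.integer(2^cq); bt <- as.integer(2^tq)
  sel <- idx[bitwAnd(idx, bc) > 0L & bitwAnd(idx, bt) == 0L]
  a <- sel + 1L; b <- sel + bt + 1L
  tmp <- v[a]; v[a] <- v[b]; v[b] <- tmp
  v
}

# apply a 4x4 matrix on (q0, q1), where q0 indexes the low bit of the 2-qubit
# subspace basis |q1 q0> = |00>,|01>,|10>,|11>
apply_2q <- function(v, U, q0, q1, n) {
  idx <- 0:(2^n - 1)
  b0 <- as.integer(2^q0); b1 <- as.integer(2^q1)
  base <- idx[bitwAnd(idx, b0) == 0L & bitwAnd(idx, b1) == 0L]
  i00 <- base + 1L; i01 <- base + b0 + 1L
  i10 <- base + b1 + 1L; i11 <- base + b0 + b1 + 1L
  w <- rbind(v[i00], v[i01], v[i10], v[i11])
  out <- U %*% w
  v[i00] <- out[1, ]; v[i01] <- out[2, ]; v[i10] <- out[3, ]; v[i11] <- out[4, ]
  v
}

#' Apply a circuit to a statevector
#'
#' @param circ a `gate_circuit`.
#' @param v initial statevector; default `|0...0>`.
#' @return final complex statevector.
#' @export
simulate_circuit <- function(circ, v = NULL) {
  n <- circ$n_qubits
  if (is.null(v)) { v <- complex(2^n); v[1] <- 1 + 0i }
  for (g in circ$gates) {
    if (g$name == "cx") {
      v <- apply_cx(v, g$qubits[1], g$qubits[2], n)
    } else {
      v <- apply_1q(v, gate_matrix_1q(g$name, g$params), g$qubits[1], n)
    }
  }
  v
}

#' Two-qubit gate count and depth of a circuit
#'
#' Depth is the longest chain of two-qubit gates under qubit-sharing
#' precedence; single-qubit gates are free.
#'
#' @param circuit a `gate_circuit`.
#' @return list with `two_qubit_count` and `two_qubit_depth`.
#' @export
circuit_metrics <- function(circuit) {
  depth <- integer(circuit$n_qubits)
  count <- 0L
  for (g in circuit$gates) {
    if (length(g$qubits) == 2L) {
      count <- count + 1L
      d <- max(depth[g$qubits + 1L]) + 1L
      depth[g$qubits + 1L] <- d
    }
  }
  list(two_qubit_count = count,
       two_qubit_depth = if (count == 0L) 0L else max(depth))
}

#' Inverse (dagger) of a circuit
#' @keywords internal
circuit_inverse <- function(circ) {
  inv <- lapply(rev(circ$gates), function(g) {
    if (g$name %in% c("rx", "ry", "rz")) g$params <- -g$params
    g  # x, h, cx are self-inverse
  })
  gate_circuit(circ$n_qubits, inv, metadata = circ$metadata)
}

#' Serialize a circuit to JSON
#' @param circ a `gate_circuit`.
#' @param path output file.
#' @export
write_circuit_json <- function(circ, path) {
  doc <- list(version = "qneo-circuit-1", n_qubits = circ$n_qubits,
              metadata = circ$metadata,
              gates = lapply(circ$gates, function(g)
                list(name = g$name, qubits = g$qubits, params = g$params)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a circuit from JSON
#' @param path file written by [write_circuit_json()].
#' @export
read_circuit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  gates <- lapply(doc$gates, function(g)
    gate(g$name, unlist(g$qubits), if (length(g$params)) unlist(g$params) else numeric(0)))
  gate_circuit(doc$n_qubits, gates,
               metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}

#' Export a circuit as OpenQASM-like text
#' @param circ a `gate_circuit`.
#' @param path output file.
#' @export
write_circuit_qasm <- function(circ, path) {
  lines <- c("OPENQASM 2.0;", "include \"qelib1.inc\";",
             sprintf("qreg q[%d];", circ$n_qubits))
  for (g in circ$gates) {
    lines <- c(lines, if (g$name == "cx") {
      sprintf("cx q[%d],q[%d];", g$qubits[1], g$qubits[2])
    } else if (gate_nparams[[g$name]] > 0) {
      sprintf("%s(%.17g) q[%d];", g$name, g$params[1], g$qubits[1])
    } else {
      sprintf("%s q[%d];", g$name, g$qubits[1])
    })
  }
  writeLines(lines, path)
  invisible(path)
}

#' Fidelity between two pure states
#'
#' `|<a|b>|^2`, symmetric in its arguments.
#'
#' @param a,b normalized complex statevectors of equal length.
#' @return real number in `[0, 1]`.
#' @export
state_fidelity <- function(a, b) {
  if (length(a) != length(b)) stop("statevector dimensions differ")
  min(1, Mod(sum(Conj(a) * b))^2)
}
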