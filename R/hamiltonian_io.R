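# ---------------------------------------------------------------------------
# Text serializations for NEO Hamiltonians.
#
# neo-json:    one JSON document with keys version, space, core_energy, h1e,
#              h2e, v1p, gep (dense nested arrays, row-major, Hartree).
# neo-fcidump: standard FCIDUMP records for the electronic block (chemist
#              (ij|kl) indices, 1-based, value-first lines, core constant as
#              the 0 0 0 0 record) plus extension sections &NEO_V1P and
#              &NEO_GEP with index-value lines for the protonic one-body and
#              electron-proton coupling tensors.
# ---------------------------------------------------------------------------

#' Read or write a NEO Hamiltonian
#'
#' One entry point for both directions: pass `h` to write, omit it to read.
#' Reading validates all Hamiltonian invariants (Hermiticity, permutational
#' symmetry) to `tol` and rejects malformed files with an error naming the
#' offending key or line.
#'
#' @param path file path.
#' @param dialect `"neo-json"` or `"neo-fcidump"`.
#' @param h optional `neo_hamiltonian` to write.
#' @param tol symmetry-validation tolerance on read (default `1e-8`).
#' @return On read, the parsed `neo_hamiltonian`; on write, `path` invisibly.
#' @export
hamiltonian_io <- function(path, dialect = c("neo-json", "neo-fcidump"),
                           h = NULL, tol = 1e-8) {
  dialect <- match.arg(dialect)
  if (is.null(h)) {
    switch(dialect,
           "neo-json" = read_neo_json(path, tol = tol),
           "neo-fcidump" = read_neo_fcidump(path, tol = tol))
  } else {
    switch(dialect,
           "neo-json" = write_neo_json(h, path),
           "neo-fcidump" = write_neo_fcidump(h, path))
    invisible(path)
  }
}

write_neo_json <- function(h, path) {
  doc <- list(
    version = "qneo-1",
    space = list(
      n_electronic_spatial = h$space$n_electronic_spatial,
      n_protonic = h$space$n_protonic,
      n_electrons = h$space$n_electrons,
      n_protons = h$space$n_protons,
      electronic_labels = h$space$electronic_labels,
      protonic_labels = h$space$protonic_labels
    ),
    core_energy = h$core_energy,
    h1e = h$h1e,
    h2e = h$h2e,
    v1p = h$v1p,
    gep = h$gep
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
}

read_neo_json <- function(path, tol = 1e-8) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  for (key in c("space", "core_energy", "h1e", "h2e", "v1p", "gep"))
    if (is.null(doc[[key]])) stop("parse error: missing key '", key, "'")
  sp <- doc$space
  space <- orbital_space(sp$n_electronic_spatial, sp$n_protonic,
                         sp$n_electrons, sp$n_protons,
                         electronic_labels = sp$electronic_labels,
                         protonic_labels = sp$protonic_labels)
  ne <- space$n_electronic_spatial; np <- space$n_protonic
  h2e <- doc$h2e
  gep <- doc$gep
  if (!all(dim(as.matrix(doc$h1e)) == c(ne, ne)))
    stop("dimension error: h1e does not match declared space")
  if (length(unlist(h2e)) != ne^4)
    stop("dimension error: h2e does not match declared space")
  if (length(unlist(gep)) != np^2 * ne^2)
    stop("dimension error: gep does not match declared space")
  # jsonlite parses nested arrays with the outermost index slowest: undo
  neo_hamiltonian(space, doc$core_energy,
                  as.matrix(doc$h1e),
                  json_array_to_tensor(h2e, c(ne, ne, ne, ne)),
                  as.matrix(doc$v1p),
                  json_array_to_tensor(gep, c(np, np, ne, ne)),
                  tol = tol)
}

json_array_to_tensor <- function(x, dims) {
  if (is.array(x) && length(dim(x)) == length(dims)) return(array(x, dims))
  # nested lists: flatten with the last index fastest, then permute
  flat <- unlist(x)
  aperm(array(flat, rev(dims)), rev(seq_along(dims)))
}

# --- FCIDUMP-style dialect -------------------------------------------------

fcidump_fmt <- function(val, i, j, k, l) {
  sprintf(" %23.16E %4d %4d %4d %4d", val, i, j, k, l)
}

write_neo_fcidump <- function(h, path) {
  ne <- h$space$n_electronic_spatial
  np <- h$space$n_protonic
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("&FCI NORB=%d,NELEC=%d,MS2=0,", ne, h$space$n_electrons), con)
  writeLines(sprintf(" NPORB=%d,NPROT=%d,TWOBODY=PHYSICIST,", np, h$space$n_protons), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)
  lines <- character(0)
  # two-body: write unique representatives of the 8-fold symmetry.
  # FCIDUMP stores chemist (ij|kl); we hold physicist <pq|rs> = (pr|qs).
  for (p in 1:ne) for (q in 1:ne) for (r in 1:ne) for (s in 1:ne) {
    val <- h$h2e[p, q, r, s]
    if (abs(val) < 1e-14) next
    i <- p; j <- r; k <- q; l <- s   # chemist indices
    ij <- (max(i, j) * (max(i, j) - 1)) / 2 + min(i, j)
    kl <- (max(k, l) * (max(k, l) - 1)) / 2 + min(k, l)
    if (i < j || k < l || ij < kl) next  # canonical representative only
    lines <- c(lines, fcidump_fmt(val, i, j, k, l))
  }
  for (p in 1:ne) for (q in p:ne) {
    val <- h$h1e[p, q]
    if (abs(val) >= 1e-14 || p == q)
      lines <- c(lines, fcidump_fmt(val, q, p, 0, 0))
  }
  lines <- c(lines, fcidump_fmt(h$core_energy, 0, 0, 0, 0))
  writeLines(lines, con)
  writeLines("&NEO_V1P", con)
  vl <- character(0)
  for (p in 1:np) for (q in p:np) {
    val <- h$v1p[p, q]
    if (abs(val) >= 1e-14 || p == q) vl <- c(vl, fcidump_fmt(val, p, q, 0, 0))
  }
  writeLines(vl, con)
  writeLines("&END", con)
  writeLines("&NEO_GEP", con)
  gl <- character(0)
  for (P in 1:np) for (Q in P:np) for (p in 1:ne) for (q in p:ne) {
    val <- h$gep[P, Q, p, q]
    if (abs(val) >= 1e-14) gl <- c(gl, fcidump_fmt(val, P, Q, p, q))
  }
  writeLines(gl, con)
  writeLines("&END", con)
  invisible(path)
}

parse_fcidump_line <- function(line, lineno) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(toks) != 5)
    stop("parse error at line ", lineno, ": expected 'value i j k l'")
  val <- suppressWarnings(as.numeric(toks[1]))
  idx <- suppressWarnings(as.integer(toks[2:5]))
  if (is.na(val) || any(is.na(idx)))
    stop("parse error at line ", lineno, ": non-numeric field")
  list(val = val, idx = idx)
}

read_neo_fcidump <- function(path, tol = 1e-8) {
  lines <- readLines(path)
  # header namelist
  hdr_end <- grep("^\\s*&END\\s*$", lines)[1]
  if (is.na(hdr_end)) stop("parse error: missing &END of header namelist")
  hdr <- paste(lines[1:hdr_end], collapse = " ")
  grab <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*(-?[0-9]+)"), hdr))[[1]]
    if (length(m) < 2) stop("parse error: header key ", key, " missing")
    as.integer(m[2])
  }
  ne <- grab("NORB"); nel <- grab("NELEC")
  np <- grab("NPORB"); nprot <- grab("NPROT")
  space <- orbital_space(ne, np, nel, nprot)
  h1e <- matrix(0, ne, ne); h2e <- array(0, c(ne, ne, ne, ne))
  v1p <- matrix(0, np, np); gep <- array(0, c(np, np, ne, ne))
  core <- 0
  section <- "electronic"
  for (ln in seq((hdr_end + 1), length(lines))) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (grepl("^&NEO_V1P", line)) { section <- "v1p"; next }
    if (grepl("^&NEO_GEP", line)) { section <- "gep"; next }
    if (grepl("^&END", line)) { section <- "done"; next }
    rec <- parse_fcidump_line(line, ln)
    i <- rec$idx[1]; j <- rec$idx[2]; k <- rec$idx[3]; l <- rec$idx[4]
    if (section == "electronic") {
      if (all(rec$idx == 0)) {
        core <- rec$val
      } else if (k == 0 && l == 0) {
        h1e[i, j] <- rec$val; h1e[j, i] <- rec$val
      } else {
        # chemist (ij|kl) -> physicist <ik|jl>, fan out the 8-fold images
        for (ij in list(c(i, j), c(j, i))) for (kl in list(c(k, l), c(l, k))) {
          h2e[ij[1], kl[1], ij[2], kl[2]] <- rec$val
          h2e[kl[1], ij[1], kl[2], ij[2]] <- rec$val
        }
      }
    } else if (section == "v1p") {
      v1p[i, j] <- rec$val; v1p[j, i] <- rec$val
    } else if (section == "gep") {
      P <- i; Q <- j; p <- k; q <- l
      gep[P, Q, p, q] <- rec$val; gep[Q, P, p, q] <- rec$val
      gep[P, Q, q, p] <- rec$val; gep[Q, P, q, p] <- rec$val
    } else {
      stop("parse error at line ", ln, ": data after final &END")
    }
  }
  neo_hamiltonian(space, core, h1e, h2e, v1p, gep, tol = tol)
}
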