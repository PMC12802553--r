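# ---------------------------------------------------------------------------
# Synthetic fixtures: seeded random NEO Hamiltonians with exact symmetries,
# and a physically structured Left/Middle/Right double-well proton-transfer
# triple with known separable limits, plus Gaussian orbital grids.
# ---------------------------------------------------------------------------

#' Seeded random NEO Hamiltonian with exact symmetries
#'
#' Tensors are drawn from seeded normal distributions and symmetrized so
#' every invariant holds exactly. Interaction scales are chosen so that
#' correlation energies land in the few-mHa regime typical of small coupled
#' electron-proton active spaces.
#'
#' @param n_electronic_spatial,n_protonic orbital counts.
#' @param n_electrons electron number.
#' @param seed RNG seed.
#' @param scale_1e,scale_2e,scale_1p,scale_ep tensor magnitudes (Ha).
#' @return a `neo_hamiltonian`.
#' @export
make_random_neo <- function(n_electronic_spatial, n_protonic, n_electrons,
                            seed = 1L, scale_1e = 0.5, scale_2e = 0.05,
                            scale_1p = 0.2, scale_ep = 0.02) {
  set.seed(seed)
  ne <- n_electronic_spatial; np <- n_protonic
  space <- orbital_space(ne, np, n_electrons)
  h1e <- matrix(stats::rnorm(ne^2, sd = scale_1e), ne, ne)
  h1e <- (h1e + t(h1e)) / 2
  diag(h1e) <- diag(h1e) - 1  # push occupied levels down
  h2e <- h2e_symmetrize(array(stats::rnorm(ne^4, sd = scale_2e), rep(ne, 4)))
  v1p <- matrix(stats::rnorm(np^2, sd = scale_1p), np, np)
  v1p <- (v1p + t(v1p)) / 2
  gep <- array(stats::rnorm(np^2 * ne^2, sd = scale_ep), c(np, np, ne, ne))
  gep <- (gep + aperm(gep, c(2, 1, 3, 4))) / 2
  gep <- (gep + aperm(gep, c(1, 2, 4, 3))) / 2
  neo_hamiltonian(space, core_energy = stats::rnorm(1), h1e = h1e, h2e = h2e,
                  v1p = v1p, gep = gep)
}

#' Specification of the synthetic double-well proton-transfer triple
#'
#' @param n_protonic protonic orbitals (>= 2; orbitals 1 and 2 are the two
#'   well sites, extra orbitals are high-lying spectators).
#' @param n_electronic_spatial electronic spatial orbitals (>= 2).
#' @param n_electrons electrons (default 2).
#' @param t_p proton tunneling matrix element (Ha), > 0.
#' @param delta site asymmetry (Ha): Left has site energies `(-delta, +delta)`,
#'   Right the mirror image, Middle is symmetric.
#' @param well_raise Middle-state well-bottom raise (Ha), sets the barrier.
#' @param g0 electron-proton coupling strength (Ha).
#' @param electronic_gap gap between the two electronic spatial orbitals (Ha).
#' @param u_ee on-site electron repulsion (Ha), gives correlation.
#' @param seed seed for the (tiny) random spectator entries.
#' @return a `double_well_spec` list.
#' @export
double_well_spec <- function(n_protonic = 2L, n_electronic_spatial = 2L,
                             n_electrons = 2L, t_p = 4e-3, delta = 6e-3,
                             well_raise = 8e-3, g0 = 3e-3,
                             electronic_gap = 0.5, u_ee = 0.1, seed = 1L) {
  if (t_p <= 0) stop("t_p must be > 0")
  if (n_protonic < 2 || n_electronic_spatial < 2)
    stop("need >= 2 protonic and >= 2 electronic spatial orbitals")
  structure(list(n_protonic = as.integer(n_protonic),
                 n_electronic_spatial = as.integer(n_electronic_spatial),
                 n_electrons = as.integer(n_electrons),
                 t_p = t_p, delta = delta, well_raise = well_raise, g0 = g0,
                 electronic_gap = electronic_gap, u_ee = u_ee,
                 seed = as.integer(seed)),
            class = "double_well_spec")
}

#' Left/Middle/Right double-well NEO Hamiltonian triple
#'
#' A proton in a two-site double well (sites = protonic orbitals 1 and 2,
#' tunneling `-t_p`, site asymmetry `+/-delta`) coupled to a small electronic
#' space. Left and Right are mirror images; Middle is symmetric with both
#' well bottoms raised by `well_raise`. The electron-proton coupling `g0`
#' ties the proton's site imbalance to the electronic 1<->2 transition, so
#' entanglement grows with `g0`. At `g0 = 0` the protonic block decouples and
#' its ground energy is `-sqrt(delta^2 + t_p^2)` relative to the well mean.
#'
#' @param spec a [double_well_spec()].
#' @return named list `list(left =, middle =, right =)` of `neo_hamiltonian`s
#'   sharing one orbital space.
#' @export
make_double_well_triple <- function(spec = double_well_spec()) {
  ne <- spec$n_electronic_spatial; np <- spec$n_protonic
  space <- orbital_space(ne, np, spec$n_electrons)
  # electronic block shared by all three setups
  h1e <- diag(seq(0, by = spec$electronic_gap, length.out = ne))
  h2e <- array(0, rep(ne, 4))
  for (p in 1:ne) h2e[p, p, p, p] <- spec$u_ee     # on-site repulsion <pp|pp>
  # small same-spin-safe exchange-like element between orbitals 1 and 2
  h2e[1, 2, 1, 2] <- h2e[2, 1, 2, 1] <- spec$u_ee / 4
  h2e <- h2e_symmetrize(h2e)
  # protonic one-body: two well sites plus optional high-lying spectators
  base_v1p <- function(e1, e2, raise = 0) {
    v <- diag(np) * 0
    set.seed(spec$seed)
    if (np > 2) {
      spect <- 0.5 + abs(stats::rnorm(np - 2, sd = 0.05))
      diag(v)[3:np] <- spect
    }
    v[1, 1] <- e1 + raise
    v[2, 2] <- e2 + raise
    v[1, 2] <- v[2, 1] <- -spec$t_p
    v
  }
  # coupling: proton site imbalance (site1 - site2) x electronic 1<->2 hop
  gep <- array(0, c(np, np, ne, ne))
  gep[1, 1, 1, 2] <- gep[1, 1, 2, 1] <- spec$g0
  gep[2, 2, 1, 2] <- gep[2, 2, 2, 1] <- -spec$g0
  make_h <- function(e1, e2, raise) {
    neo_hamiltonian(space, core_energy = 0, h1e = h1e, h2e = h2e,
                    v1p = base_v1p(e1, e2, raise), gep = gep)
  }
  list(left = make_h(-spec$delta, +spec$delta, 0),
       middle = make_h(0, 0, spec$well_raise),
       right = make_h(+spec$delta, -spec$delta, 0))
}

#' Closed-form protonic ground energy of the decoupled two-site well
#'
#' For `g0 = 0`, `n_protonic = 2` the protonic block is the 2x2 tunneling
#' Hamiltonian with eigenvalues `mean(diag) -/+ sqrt(delta^2 + t_p^2)`.
#'
#' @param spec a [double_well_spec()].
#' @param setup `"left"`, `"middle"`, or `"right"`.
#' @return ground protonic energy (Ha).
#' @export
double_well_proton_energy <- function(spec, setup = c("left", "middle", "right")) {
  setup <- match.arg(setup)
  raise <- if (setup == "middle") spec$well_raise else 0
  d <- if (setup == "middle") 0 else spec$delta
  raise - sqrt(d^2 + spec$t_p^2)
}

#' Gaussian orbital basis evaluated on a Cartesian grid
#'
#' Normalized 3D Gaussians `phi_A(r) = (2 a / pi)^(3/4) exp(-a |r - c_A|^2)`
#' evaluated on a regular grid, together with their analytic overlap and
#' position-integral matrices.
#'
#' @param centers n_orb x 3 matrix of Gaussian centers (Angstrom).
#' @param exponents length-n_orb vector of exponents `a` (1/Angstrom^2), > 0.
#' @param lower,upper grid bounds per axis (Angstrom).
#' @param n_points grid points per axis.
#' @return list with `points` (n x 3), `values` (n x n_orb), `weights`
#'   (quadrature weights), `overlap` (analytic), `position` (n_orb x n_orb x 3
#'   analytic `<A|r|B>`), `spacing`.
#' @export
gaussian_orbital_grid <- function(centers, exponents,
                                  lower = c(-3, -3, -3), upper = c(3, 3, 3),
                                  n_points = 25L) {
  centers <- as.matrix(centers)
  n_orb <- nrow(centers)
  if (length(exponents) != n_orb) stop("one exponent per center required")
  if (any(exponents <= 0)) stop("exponents must be > 0")
  ax <- lapply(1:3, function(k) seq(lower[k], upper[k], length.out = n_points))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  spacing <- vapply(ax, function(a) a[2] - a[1], numeric(1))
  w <- prod(spacing)
  vals <- matrix(0, nrow(pts), n_orb)
  for (A in seq_len(n_orb)) {
    a <- exponents[A]
    norm <- (2 * a / pi)^(3 / 4)
    d2 <- rowSums((pts - matrix(centers[A, ], nrow(pts), 3, byrow = TRUE))^2)
    vals[, A] <- norm * exp(-a * d2)
  }
  S <- matrix(0, n_orb, n_orb)
  P <- array(0, c(n_orb, n_orb, 3))
  for (A in seq_len(n_orb)) for (B in seq_len(n_orb)) {
    a <- exponents[A]; b <- exponents[B]
    mu <- a * b / (a + b)
    d2 <- sum((centers[A, ] - centers[B, ])^2)
    # Gaussian product theorem with normalized primitives
    S[A, B] <- (2 * sqrt(a * b) / (a + b))^(3 / 2) * exp(-mu * d2)
    cen <- (a * centers[A, ] + b * centers[B, ]) / (a + b)
    P[A, B, ] <- S[A, B] * cen
  }
  list(points = pts, values = vals, weights = rep(w, nrow(pts)),
       overlap = S, position = P, spacing = spacing)
}

#' Write a synthetic double-well triple to disk with a manifest
#'
#' @param spec a [double_well_spec()].
#' @param dir output directory (created if needed).
#' @param dialect serialization dialect for [hamiltonian_io()].
#' @return invisibly, the manifest list.
#' @export
write_double_well_triple <- function(spec, dir, dialect = "neo-json") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  triple <- make_double_well_triple(spec)
  ext <- if (dialect == "neo-json") "json" else "fcidump"
  paths <- list()
  for (nm in names(triple)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".", ext))
    hamiltonian_io(paths[[nm]], dialect, h = triple[[nm]])
  }
  manifest <- list(spec = unclass(spec), dialect = dialect, files = paths,
                   proton_energy_closed_form = list(
                     left = double_well_proton_energy(spec, "left"),
                     middle = double_well_proton_energy(spec, "middle"),
                     right = double_well_proton_energy(spec, "right")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
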