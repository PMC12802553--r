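# ---------------------------------------------------------------------------
# Transition-state-theory kinetics with an effective quantum barrier.
#
# k(T) = (k_B T / h) * exp(-dE / (k_B T))  (Eyring prefactor convention).
# The barrier dE incorporates proton zero-point and delocalization effects;
# thermal and entropic contributions are omitted. Ratio and suppression
# results are independent of the prefactor convention.
# ---------------------------------------------------------------------------

#' Physical constants used by the kinetics module (CODATA)
#' @format list with `k_B_Ha_per_K` (Boltzmann constant, Ha/K),
#'   `k_B_J_per_K` (J/K), `h_J_s` (Planck constant, J s),
#'   `mHa_per_Ha` (1000).
#' @export
qneo_constants <- list(
  k_B_Ha_per_K = 3.166811563e-6,
  k_B_J_per_K = 1.380649e-23,
  h_J_s = 6.62607015e-34,
  mHa_per_Ha = 1000
)

#' Eyring-type TST rate constant with an effective quantum barrier
#'
#' `k(T) = (k_B T / h) * exp(-barrier / (k_B T))`. A zero barrier gives the
#' bare prefactor `k_B T / h`.
#'
#' @param barrier effective barrier (Ha).
#' @param T temperature (K), > 0.
#' @return rate constant (1/s).
#' @export
tst_rate <- function(barrier, T) {
  if (any(T <= 0)) stop("domain error: T must be > 0")
  prefactor <- qneo_constants$k_B_J_per_K * T / qneo_constants$h_J_s
  prefactor * exp(-barrier / (qneo_constants$k_B_Ha_per_K * T))
}

#' Rate curve over a temperature grid
#'
#' @param barrier effective barrier (Ha).
#' @param temperatures temperature grid (K).
#' @return A `rate_curve`: data.frame-backed list with `temperatures`,
#'   `rates`, `barrier`, and the prefactor convention tag.
#' @export
rate_curve <- function(barrier, temperatures) {
  if (any(temperatures <= 0)) stop("domain error: temperatures must be > 0")
  structure(list(temperatures = temperatures,
                 rates = tst_rate(barrier, temperatures),
                 barrier = barrier,
                 prefactor = "eyring_kBT_over_h"),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("<rate_curve> dE = %.4f mHa over %d temperatures [%g, %g] K\n",
              x$barrier * 1000, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Export a rate curve as a delimited (T, k) table
#' @param curve a [rate_curve()].
#' @param path output file (TSV).
#' @export
write_rate_curve <- function(curve, path) {
  utils::write.table(data.frame(T_K = curve$temperatures, k_per_s = curve$rates),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fractional rate suppression caused by a barrier overestimate
#'
#' `1 - k(approx)/k(ref) = 1 - exp(-(barrier_approx - barrier_ref)/(k_B T))`.
#' The prefactor cancels exactly, so the result is convention-free. Positive
#' values mean the approximate barrier suppresses (underestimates) the rate.
#'
#' @param barrier_approx,barrier_ref barriers (Ha).
#' @param T temperature (K), > 0.
#' @return fractional suppression in `(-Inf, 1]`.
#' @export
rate_suppression <- function(barrier_approx, barrier_ref, T) {
  if (any(T <= 0)) stop("domain error: T must be > 0")
  1 - exp(-(barrier_approx - barrier_ref) / (qneo_constants$k_B_Ha_per_K * T))
}

#' Barrier accuracy needed for a target rate-constant accuracy
#'
#' Linearized sensitivity `dk/k ~ -dE/(k_B T)` gives the admissible barrier
#' error `dE = max_rate_error * k_B * T`, reported in mHa.
#'
#' @param T temperature (K), > 0.
#' @param max_rate_error admissible fractional rate error in `(0, 1)`.
#' @return barrier tolerance (mHa).
#' @export
barrier_tolerance <- function(T, max_rate_error) {
  if (any(T <= 0)) stop("domain error: T must be > 0")
  if (any(max_rate_error <= 0 | max_rate_error >= 1))
    stop("max_rate_error must lie in (0, 1)")
  max_rate_error * qneo_constants$k_B_Ha_per_K * T * qneo_constants$mHa_per_Ha
}
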