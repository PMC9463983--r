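# Voltage-dependent rate functions for the Hodgkin-Huxley cells.
# Removable singularities are handled by an explicit |V - V0| < 1e-6 mV
# branch returning the analytic limit, so grid-aligned voltages never hit
# 0/0.

#' O-cell gating rate functions
#'
#' Opening/closing rates for the delayed-rectifier (n), transient sodium
#' (m, h) and persistent sodium (p) gates, and steady state / time constant
#' for the fast and slow components of the hyperpolarization-activated
#' current.  Vectorized over \code{V}.
#'
#' @param V membrane potential (mV); must be finite
#' @return a data.frame with columns \code{alpha_n, beta_n, alpha_m, beta_m,
#'   alpha_h, beta_h, alpha_p, beta_p, hf_inf, tau_hf, hs_inf, tau_hs}
#' @examples
#' ocell_rates(-37)$beta_n   # 0.125: zero exponent
#' ocell_rates(-27)$alpha_n  # 0.1: analytic limit at the singularity
#' @export
ocell_rates <- function(V) {
  if (!all(is.finite(V))) stop("V must be finite")
  alpha_n <- -0.01 * (V + 27) / (exp(-0.1 * (V + 27)) - 1)
  alpha_n[abs(V + 27) < 1e-6] <- 0.1
  alpha_m <- -0.1 * (V + 23) / (exp(-0.1 * (V + 23)) - 1)
  alpha_m[abs(V + 23) < 1e-6] <- 1.0
  ep <- exp(-(V + 38) / 6.5)
  data.frame(
    alpha_n = alpha_n,
    beta_n = 0.125 * exp(-(V + 37) / 80),
    alpha_m = alpha_m,
    beta_m = 4 * exp(-(V + 48) / 18),
    alpha_h = 0.07 * exp(-(V + 37) / 20),
    beta_h = 1 / (exp(-0.1 * (V + 7)) + 1),
    alpha_p = 1 / (0.15 * (1 + ep)),
    beta_p = ep / (0.15 * (1 + ep)),
    hf_inf = 1 / (1 + exp((V + 79.2) / 9.78)),
    tau_hf = 0.51 / (exp((V - 1.7) / 10) + exp(-(V + 340) / 52)) + 1,
    hs_inf = (1 / (1 + exp((V + 2.83) / 15.9)))^58,
    tau_hs = 5.6 / (exp((V - 1.7) / 14) + exp(-(V + 260) / 43)) + 1
  )
}

#' I-cell gating rate functions
#'
#' Fast-spiking interneuron kinetics; singular points at V = -52 (alpha_n),
#' V = -54 (alpha_m) and V = -27 mV (beta_m) return their analytic limits.
#'
#' @inheritParams ocell_rates
#' @return a data.frame with columns \code{alpha_n, beta_n, alpha_m, beta_m,
#'   alpha_h, beta_h}
#' @examples
#' icell_rates(-52)$alpha_n  # 0.16 = 0.032 * 5
#' @export
icell_rates <- function(V) {
  if (!all(is.finite(V))) stop("V must be finite")
  alpha_n <- 0.032 * (V + 52) / (1 - exp(-(V + 52) / 5))
  alpha_n[abs(V + 52) < 1e-6] <- 0.16
  alpha_m <- 0.32 * (V + 54) / (1 - exp(-(V + 54) / 4))
  alpha_m[abs(V + 54) < 1e-6] <- 1.28
  beta_m <- 0.28 * (V + 27) / (exp((V + 27) / 5) - 1)
  beta_m[abs(V + 27) < 1e-6] <- 1.4
  data.frame(
    alpha_n = alpha_n,
    beta_n = 0.5 * exp(-(V + 57) / 40),
    alpha_m = alpha_m,
    beta_m = beta_m,
    alpha_h = 0.128 * exp(-(V + 50) / 18),
    beta_h = 4 / (1 + exp(-(V + 27) / 5))
  )
}
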