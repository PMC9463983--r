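# Membrane and synaptic currents, and the single-cell derivative used for
# fixed-point checks.  The time-stepping itself lives in the compiled engine;
# these R versions define the model and serve as its reference
# implementation.

#' Ionic currents of one cell
#'
#' Each current is g * (gate product) * (V - E) in pA.  The persistent
#' sodium and hyperpolarization-activated currents exist only on the O-cell.
#'
#' @param state named list/vector with \code{V_m} and the cell's gating
#'   variables (O-cell: \code{m, h, n, p, h_f, h_s}; I-cell: \code{m, h, n};
#'   E_D: none)
#' @param params an \code{ocell_params}, \code{icell_params} or
#'   \code{ed_params} object
#' @return named list of currents (pA): \code{I_leak}, and where applicable
#'   \code{I_K}, \code{I_Na}, \code{I_p}, \code{I_h}
#' @export
ionic_currents <- function(state, params) {
  V <- state$V_m
  out <- list(I_leak = params$g_leak * (V - params$E_leak))
  if (inherits(params, c("ocell_params", "icell_params"))) {
    out$I_K <- params$g_K_bar * state$n^4 * (V - params$E_K)
    out$I_Na <- params$g_Na_bar * state$m^3 * state$h * (V - params$E_Na)
  }
  if (inherits(params, "ocell_params")) {
    out$I_p <- params$g_p_bar * state$p * (V - params$E_Na)
    out$I_h <- params$g_h_bar * (0.65 * state$h_f + 0.35 * state$h_s) *
      (V - params$E_h)
  }
  out
}

#' NMDA magnesium-block factor
#'
#' B(V) = 1 / (1 + exp(-0.062 V) [Mg] / 3.57), in (0, 1], strictly
#' increasing in V, equal to 1 when Mg = 0.
#'
#' @param V membrane potential (mV)
#' @param Mg magnesium concentration (mM)
#' @return block factor, same length as \code{V}
#' @export
nmda_block <- function(V, Mg = 1) {
  stopifnot(all(Mg >= 0))
  1 / (1 + exp(-0.062 * V) * Mg / 3.57)
}

#' Postsynaptic receptor current
#'
#' I = g_bar r (V - E_rev), with the additional voltage-dependent block
#' factor for NMDA.
#'
#' @param r open fraction of the receptor
#' @param V postsynaptic membrane potential (mV)
#' @param g_bar maximal conductance (nS)
#' @param E_rev reversal potential (mV)
#' @param nmda if TRUE, multiply by the magnesium block \code{nmda_block(V, Mg)}
#' @param Mg magnesium concentration (mM), used only when \code{nmda}
#' @return current in pA
#' @export
synaptic_current <- function(r, V, g_bar, E_rev = 0, nmda = FALSE, Mg = 1) {
  stopifnot(all(r >= 0), all(r <= 1))
  b <- if (nmda) nmda_block(V, Mg) else 1
  g_bar * r * b * (V - E_rev)
}

# steady-state gate values for a given voltage (used to initialize cells)
gate_steady <- function(cell = c("ocell", "icell"), V) {
  cell <- match.arg(cell)
  if (cell == "ocell") {
    r <- ocell_rates(V)
    list(m = r$alpha_m / (r$alpha_m + r$beta_m),
         h = r$alpha_h / (r$alpha_h + r$beta_h),
         n = r$alpha_n / (r$alpha_n + r$beta_n),
         p = r$alpha_p / (r$alpha_p + r$beta_p),
         h_f = r$hf_inf, h_s = r$hs_inf)
  } else {
    r <- icell_rates(V)
    list(m = r$alpha_m / (r$alpha_m + r$beta_m),
         h = r$alpha_h / (r$alpha_h + r$beta_h),
         n = r$alpha_n / (r$alpha_n + r$beta_n))
  }
}

#' Time derivative of a single cell's state
#'
#' dV/dt = (-sum of ionic currents - I_syn + I_app) / C_m (the applied
#' current exists only on the O-cell), with gate derivatives in
#' alpha/beta form for m, h, n, p and steady-state/tau form for h_f, h_s.
#'
#' @inheritParams ionic_currents
#' @param I_syn summed synaptic current for the cell (pA)
#' @return named list of derivatives: \code{dV} (mV/ms) and one entry per
#'   gating variable (1/ms)
#' @export
neuron_derivative <- function(state, params, I_syn = 0) {
  ion <- ionic_currents(state, params)
  I_app <- if (inherits(params, "ocell_params")) params$I_app else 0
  out <- list(dV = (-sum(unlist(ion)) - I_syn + I_app) / params$C_m)
  if (inherits(params, "ocell_params")) {
    r <- ocell_rates(state$V_m)
    out$dm <- r$alpha_m * (1 - state$m) - r$beta_m * state$m
    out$dh <- r$alpha_h * (1 - state$h) - r$beta_h * state$h
    out$dn <- r$alpha_n * (1 - state$n) - r$beta_n * state$n
    out$dp <- r$alpha_p * (1 - state$p) - r$beta_p * state$p
    out$dh_f <- (r$hf_inf - state$h_f) / r$tau_hf
    out$dh_s <- (r$hs_inf - state$h_s) / r$tau_hs
  } else if (inherits(params, "icell_params")) {
    r <- icell_rates(state$V_m)
    out$dm <- r$alpha_m * (1 - state$m) - r$beta_m * state$m
    out$dh <- r$alpha_h * (1 - state$h) - r$beta_h * state$h
    out$dn <- r$alpha_n * (1 - state$n) - r$beta_n * state$n
  }
  out
}
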