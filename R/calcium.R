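# Calcium dynamics (CICR at the O-cell terminal; NMDA-driven dendritic
# calcium) and the calcium-based AMPAR plasticity rule with its analysis
# statistics.

#' One Euler step of the CICR system
#'
#' Cytosolic calcium gains the calcium fraction of the (inward, negative)
#' alpha7 current, exchanges antisymmetrically with the internal store
#' through channels opened with probability w = Ca_i/(Ca_i + k_d) (cubed:
#' three binding sites), and decays; the store relaxes back to its resting
#' level.
#'
#' @param ca_i cytosolic calcium (mM); \code{ca_is} store calcium (mM)
#' @param ca_is store calcium (mM)
#' @param I_a7 alpha7 nAChR current (pA; inward currents are negative)
#' @param params a \code{\link{cicr_params}} object
#' @param dt time step (ms), > 0
#' @return list with updated \code{ca_i}, \code{ca_is} and \code{clipped}
#'   (count of negative concentrations clipped to 0)
#' @export
cicr_step <- function(ca_i, ca_is, I_a7, params = cicr_params(), dt) {
  if (dt <= 0) stop("dt must be > 0")
  w <- ca_i / (ca_i + params$k_d)
  exch <- w^3 * (ca_is - ca_i)
  new_i <- ca_i + dt * (-params$xi_prime * params$alpha_prime * I_a7 +
                          exch - ca_i / params$tau_ca_o)
  new_is <- ca_is + dt * (-exch - (ca_is - params$ca_is_rest) / params$tau_is)
  clipped <- sum(new_i < 0) + sum(new_is < 0)
  list(ca_i = pmax(new_i, 0), ca_is = pmax(new_is, 0), clipped = clipped)
}

#' One Euler step of dendritic calcium
#'
#' dCa/dt = -xi alpha I_NMDA - Ca/tau_ca; calcium in uM, current in pA.
#'
#' @param ca_d dendritic calcium (uM)
#' @param I_nmda NMDA current (pA; inward currents are negative)
#' @param params a \code{\link{dendritic_ca_params}} object
#' @param dt time step (ms), > 0
#' @return updated calcium (uM), floored at 0
#' @export
dendritic_ca_step <- function(ca_d, I_nmda, params = dendritic_ca_params(),
                              dt) {
  if (dt <= 0) stop("dt must be > 0")
  pmax(ca_d + dt * (-params$xi * params$alpha_frac * I_nmda -
                      ca_d / params$tau_ca), 0)
}

#' Calcium-dependent learning rate
#'
#' eta(Ca) = (P1 / (P2 + Ca^P3) + P4)^-1; monotone increasing, bounded by
#' 1/P4.
#'
#' @param Ca dendritic calcium (uM), >= 0
#' @param params a \code{\link{plasticity_params}} object
#' @return learning-rate factor, same length as \code{Ca}
#' @export
learning_rate <- function(Ca, params = plasticity_params()) {
  stopifnot(all(Ca >= 0))
  1 / (params$P1 / (params$P2 + Ca^params$P3) + params$P4)
}

#' Calcium-dependent plasticity drift
#'
#' Omega(Ca): difference of two steep sigmoids centred on the potentiation
#' onset theta_up and the depression onset theta_down, bounded in
#' [-gamma_down, gamma_up - gamma_down].  Evaluated in overflow-safe form.
#'
#' @inheritParams learning_rate
#' @return drift (nS/ms), same length as \code{Ca}
#' @export
omega <- function(Ca, params = plasticity_params()) {
  stopifnot(all(Ca >= 0))
  s <- params$steepness
  params$gamma_up * logistic_safe(s * (Ca - params$theta_up)) -
    params$gamma_down * logistic_safe(s * (Ca - params$theta_down))
}

#' One Euler step of the AMPAR conductance
#'
#' dg/dt = eta(Ca) (Omega(Ca) - sigma (g - g0)); the learning rate
#' multiplies both the calcium drift and the decay toward baseline.
#'
#' @param g AMPAR maximal conductance (nS)
#' @param Ca dendritic calcium (uM)
#' @inheritParams learning_rate
#' @param dt time step (ms), > 0
#' @return updated conductance (nS), floored at 0
#' @export
plasticity_step <- function(g, Ca, params = plasticity_params(), dt) {
  if (dt <= 0) stop("dt must be > 0")
  eta <- learning_rate(Ca, params)
  pmax(g + dt * eta * (omega(Ca, params) - params$sigma * (g - params$g0)), 0)
}

#' Learning-rate-weighted calcium area ratio
#'
#' Classifier of the sign of plasticity for a calcium transient: the
#' trapezoidal integral of Ca * eta(Ca) over the samples where Ca exceeds
#' the potentiation onset, divided by the same integral over the samples
#' where Ca lies between the depression and potentiation onsets.  Ratios
#' above about 3 mark net potentiation; below, net depression.
#'
#' @param time timestamps (ms) of the sampled trace
#' @param ca calcium samples (uM), same length as \code{time}
#' @inheritParams learning_rate
#' @return the ratio; \code{Inf} if there is supra-onset calcium but no
#'   between-onset area, \code{NaN} if calcium never exceeds the depression
#'   onset
#' @export
weighted_area_ratio <- function(time, ca, params = plasticity_params()) {
  stopifnot(length(time) == length(ca), !is.unsorted(time))
  w <- ca * learning_rate(ca, params)
  up <- ca > params$theta_up
  mid <- ca > params$theta_down & !up
  trap_masked <- function(mask) {
    if (!any(mask)) return(0)
    # trapezoid over contiguous runs of the mask
    keep <- mask[-length(mask)] & mask[-1]
    if (!any(keep)) return(0)
    dt <- diff(time)[keep]
    pair_sum <- (w[-length(w)] + w[-1])[keep]
    sum(dt * pair_sum / 2)
  }
  num <- trap_masked(up)
  den <- trap_masked(mid)
  if (num == 0 && den == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}
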