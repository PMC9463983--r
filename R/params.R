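# Parameter sets for the three cells, the synapses, calcium dynamics and the
# plasticity rule.  Units: mV, ms, pA, nS, pF; transmitter and O-cell calcium
# in mM, dendritic calcium in uM.

#' OLM interneuron (O-cell) membrane parameters
#'
#' Hodgkin-Huxley O-cell with transient Na, delayed-rectifier K, leak,
#' persistent Na and a two-component hyperpolarization-activated inward
#' current, plus a constant applied current holding the cell near -60 mV.
#'
#' @param C_m membrane capacitance (pF)
#' @param g_leak,g_K_bar,g_Na_bar,g_p_bar,g_h_bar maximal conductances (nS)
#' @param E_leak,E_K,E_Na,E_h reversal potentials (mV)
#' @param I_app applied holding current (pA)
#' @return a named list of class \code{"ocell_params"}
#' @export
ocell_params <- function(C_m = 100, g_leak = 50, E_leak = -70,
                         g_K_bar = 1100, E_K = -90, g_Na_bar = 5200,
                         E_Na = 55, g_p_bar = 50, g_h_bar = 145, E_h = -20,
                         I_app = -260) {
  p <- list(C_m = C_m, g_leak = g_leak, E_leak = E_leak, g_K_bar = g_K_bar,
            E_K = E_K, g_Na_bar = g_Na_bar, E_Na = E_Na, g_p_bar = g_p_bar,
            g_h_bar = g_h_bar, E_h = E_h, I_app = I_app)
  stopifnot(all(vapply(p[c("g_leak", "g_K_bar", "g_Na_bar", "g_p_bar",
                           "g_h_bar")], function(x) x >= 0, logical(1))))
  structure(p, class = "ocell_params")
}

#' Fast-spiking interneuron (I-cell) membrane parameters
#'
#' @inheritParams ocell_params
#' @return a named list of class \code{"icell_params"}
#' @export
icell_params <- function(C_m = 100, g_leak = 10, E_leak = -67,
                         g_K_bar = 8000, E_K = -100, g_Na_bar = 10000,
                         E_Na = 50) {
  p <- list(C_m = C_m, g_leak = g_leak, E_leak = E_leak, g_K_bar = g_K_bar,
            E_K = E_K, g_Na_bar = g_Na_bar, E_Na = E_Na)
  stopifnot(g_leak >= 0, g_K_bar >= 0, g_Na_bar >= 0)
  structure(p, class = "icell_params")
}

#' Passive pyramidal dendritic compartment (E_D) parameters
#'
#' @inheritParams ocell_params
#' @return a named list of class \code{"ed_params"}
#' @export
ed_params <- function(C_m = 100, g_leak = 1, E_leak = -68) {
  stopifnot(g_leak >= 0)
  structure(list(C_m = C_m, g_leak = g_leak, E_leak = E_leak),
            class = "ed_params")
}

#' Kinetic receptor parameters (AMPA, NMDA, GABA-A, alpha7 nAChR)
#'
#' Two-state binding kinetics dr/dt = alpha [T] (1 - r) - beta r for
#' AMPA/NMDA/GABA-A; Hill activation with first-order relaxation for the
#' alpha7 nicotinic receptor.  Conductances are per-target: the fast-spiking
#' interneuron carries stronger AMPA/GABA-A than the dendritic compartment.
#'
#' @param alpha_A,beta_A AMPA binding/unbinding rates (1/(ms mM), 1/ms)
#' @param alpha_N,beta_N NMDA binding/unbinding rates
#' @param alpha_G,beta_G GABA-A binding/unbinding rates
#' @param g_N NMDA maximal conductance on E_D (nS)
#' @param E_A,E_N,E_G reversal potentials (mV)
#' @param Mg extracellular magnesium (mM), sets the NMDA voltage block
#' @param g_ampa_I,g_gaba_I AMPA / GABA-A maximal conductance on the I-cell
#'   (nS).  These two are calibrated behaviorally rather than taken from the
#'   receptor-fit literature: \code{g_ampa_I} is the smallest integer
#'   conductance at which one 5-ms glutamate pulse evokes a volley (two or
#'   more spikes) in the I-cell, and \code{g_gaba_I} (kept at twice
#'   \code{g_ampa_I}) is the smallest at which OLM GABA release silences the
#'   SC-evoked I-cell response; both constraints are required by the
#'   feedforward-disinhibition mechanism and sit on a knife edge in this
#'   cell model
#' @param g_gaba_E GABA-A maximal conductance on E_D (nS)
#' @param g_a7 alpha7 nAChR maximal conductance on the O-cell (nS)
#' @param E_a7 alpha7 reversal potential (mV)
#' @param ec50 alpha7 half-activation ACh concentration (mM)
#' @param n_hill alpha7 Hill coefficient
#' @param tau_ra7 alpha7 activation time constant (ms)
#' @return a named list of class \code{"receptor_params"}
#' @export
receptor_params <- function(alpha_A = 1.1, beta_A = 0.19, E_A = 0,
                            alpha_N = 0.072, beta_N = 6.6e-3, g_N = 25,
                            E_N = 0, Mg = 1,
                            alpha_G = 5, beta_G = 0.18, E_G = -80,
                            g_ampa_I = 8, g_gaba_I = 16, g_gaba_E = 7,
                            g_a7 = 3, E_a7 = 0, ec50 = 80e-3,
                            n_hill = 1.73, tau_ra7 = 5) {
  p <- as.list(environment())
  stopifnot(alpha_A >= 0, beta_A >= 0, alpha_N >= 0, beta_N >= 0,
            alpha_G >= 0, beta_G >= 0, g_N >= 0, g_ampa_I >= 0,
            g_gaba_I >= 0, g_gaba_E >= 0, g_a7 >= 0, Mg >= 0)
  structure(p, class = "receptor_params")
}

#' Transmitter-release parameters
#'
#' Sigmoid stationary release: GABA from the I-cell depends on its membrane
#' potential; GABA from the O-cell terminal depends on cytosolic calcium.
#'
#' @param T_max maximal transmitter concentration (mM)
#' @param K_p voltage steepness (mV); \code{V_p} half-activation voltage (mV)
#' @param V_p half-activation voltage (mV)
#' @param K_Ca_p calcium steepness (mM); \code{Ca_p} half-activation (mM)
#' @param Ca_p calcium half-activation (mM)
#' @return a named list of class \code{"release_params"}
#' @export
release_params <- function(T_max = 1, K_p = 5, V_p = 2,
                           K_Ca_p = 1e-6, Ca_p = 4e-5) {
  stopifnot(T_max > 0)
  structure(list(T_max = T_max, K_p = K_p, V_p = V_p, K_Ca_p = K_Ca_p,
                 Ca_p = Ca_p), class = "release_params")
}

#' Calcium-induced calcium release (CICR) parameters for the O-cell terminal
#'
#' @param xi_prime current-to-concentration factor (mM/(ms pA))
#' @param alpha_prime calcium fraction of the alpha7 current (dimensionless)
#' @param tau_ca_o cytosolic calcium decay constant (ms)
#' @param tau_is internal-store relaxation constant (ms)
#' @param k_d store-channel half-activation (mM)
#' @param ca_is_rest store resting calcium (mM)
#' @return a named list of class \code{"cicr_params"}
#' @export
cicr_params <- function(xi_prime = 2.1e-6, alpha_prime = 0.05,
                        tau_ca_o = 12, tau_is = 10, k_d = 2e-4,
                        ca_is_rest = 0.44e-3) {
  stopifnot(tau_ca_o > 0, tau_is > 0, k_d > 0)
  structure(list(xi_prime = xi_prime, alpha_prime = alpha_prime,
                 tau_ca_o = tau_ca_o, tau_is = tau_is, k_d = k_d,
                 ca_is_rest = ca_is_rest), class = "cicr_params")
}

#' Dendritic calcium parameters for E_D
#'
#' NMDA-driven calcium: dCa/dt = -xi alpha I_NMDA - Ca/tau_ca.  Calcium is
#' carried in uM here (the plasticity thresholds are in uM); \code{xi}
#' differs between the copairing and disinhibition presets.
#'
#' @param xi current-to-concentration factor (uM/(ms pA))
#' @param alpha_frac calcium fraction of the NMDA current
#' @param tau_ca decay constant (ms)
#' @return a named list of class \code{"dendritic_ca_params"}
#' @export
dendritic_ca_params <- function(xi = 0.045, alpha_frac = 0.1, tau_ca = 12) {
  stopifnot(tau_ca > 0)
  structure(list(xi = xi, alpha_frac = alpha_frac, tau_ca = tau_ca),
            class = "dendritic_ca_params")
}

#' Calcium-based AMPAR plasticity-rule parameters
#'
#' dg/dt = eta(Ca) (Omega(Ca) - sigma (g - g0)) with a monotone
#' calcium-dependent learning rate eta and a two-sigmoid drift Omega with
#' potentiation onset \code{theta_up} and depression onset \code{theta_down}.
#'
#' @param sigma conductance decay rate (1/ms)
#' @param g0 baseline AMPAR maximal conductance (nS)
#' @param theta_up,theta_down potentiation / depression onsets (uM)
#' @param gamma_up,gamma_down maximal AMPAR insertion / removal rates (nS/ms)
#' @param P1,P2,P3,P4 learning-rate constants
#' @param steepness Omega sigmoid steepness (1/uM)
#' @return a named list of class \code{"plasticity_params"}
#' @export
plasticity_params <- function(sigma = 0.0040, g0 = 4, theta_up = 0.34,
                              theta_down = 0.31, gamma_up = 0.0699,
                              gamma_down = 0.0375, P1 = 1.5e-6,
                              P2 = P1 * 1e-4, P3 = 13, P4 = 1,
                              steepness = 900) {
  stopifnot(theta_up > theta_down, gamma_up > gamma_down, sigma >= 0)
  p <- list(sigma = sigma, g0 = g0, theta_up = theta_up,
            theta_down = theta_down, gamma_up = gamma_up,
            gamma_down = gamma_down, P1 = P1, P2 = P2, P3 = P3, P4 = P4,
            steepness = steepness)
  structure(p, class = "plasticity_params")
}

#' Voltage-noise configuration
#'
#' Euler-Maruyama noise added to the voltage updates only (sqrt(dt) scaling);
#' gates and concentrations are noise-free.
#'
#' @param sigma_O,sigma_I,sigma_ED per-cell noise amplitudes
#' @return a named list of class \code{"noise_config"}
#' @export
noise_config <- function(sigma_O = 1.1, sigma_I = 0.1, sigma_ED = 0.3) {
  stopifnot(sigma_O >= 0, sigma_I >= 0, sigma_ED >= 0)
  structure(list(sigma_O = sigma_O, sigma_I = sigma_I, sigma_ED = sigma_ED),
            class = "noise_config")
}

#' Full circuit parameter set
#'
#' Bundles all cell, synapse, calcium and plasticity parameters.  Two named
#' presets select the published calibrations: \code{"copairing"}
#' (ACh-to-O-cell pairing protocols; gamma_up = 0.0687 nS/ms, xi = 0.006
#' uM/(ms pA)) and \code{"disinhibition"} (dendrite-only glutamate+GABA
#' pairing protocols; gamma_up = 0.0699 nS/ms, xi = 0.045 uM/(ms pA)).
#' Any component can be overridden key-by-key via \code{...}, e.g.
#' \code{circuit_params("copairing", receptors = list(g_a7 = 1.7))}.
#'
#' @param preset \code{"disinhibition"} or \code{"copairing"}
#' @param ... named lists of overrides for components \code{ocell},
#'   \code{icell}, \code{ed}, \code{receptors}, \code{release}, \code{cicr},
#'   \code{dca}, \code{plasticity}, \code{noise}
#' @return a nested list of class \code{"circuit_params"}
#' @examples
#' p <- circuit_params("disinhibition")
#' p$plasticity$gamma_up
#' @export
circuit_params <- function(preset = c("disinhibition", "copairing"), ...) {
  preset <- match.arg(preset)
  gamma_up <- if (preset == "copairing") 0.0687 else 0.0699
  xi <- if (preset == "copairing") 0.006 else 0.045
  p <- list(
    preset = preset,
    ocell = ocell_params(),
    icell = icell_params(),
    ed = ed_params(),
    receptors = receptor_params(),
    release = release_params(),
    cicr = cicr_params(),
    dca = dendritic_ca_params(xi = xi),
    plasticity = plasticity_params(gamma_up = gamma_up),
    noise = noise_config()
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(p)) stop("unknown parameter component: ", nm)
    cls <- class(p[[nm]])
    p[[nm]] <- modifyList(p[[nm]], ov[[nm]])
    class(p[[nm]]) <- cls
  }
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("CA1 microcircuit parameter set (preset: ", x$preset, ")\n", sep = "")
  cat("  plasticity: g0 =", x$plasticity$g0, "nS, gamma_up =",
      x$plasticity$gamma_up, "nS/ms, gamma_down =", x$plasticity$gamma_down,
      "nS/ms\n")
  cat("  dendritic calcium: xi =", x$dca$xi, "uM/(ms pA), tau =",
      x$dca$tau_ca, "ms\n")
  cat("  alpha7 nAChR: g =", x$receptors$g_a7, "nS, EC50 =",
      x$receptors$ec50, "mM\n")
  invisible(x)
}

# Flatten a circuit_params object into the scalar list the C++ engine expects.
flatten_params <- function(p) {
  stopifnot(inherits(p, "circuit_params"))
  list(
    o_C = p$ocell$C_m, o_gl = p$ocell$g_leak, o_El = p$ocell$E_leak,
    o_gK = p$ocell$g_K_bar, o_EK = p$ocell$E_K, o_gNa = p$ocell$g_Na_bar,
    o_ENa = p$ocell$E_Na, o_gp = p$ocell$g_p_bar, o_gh = p$ocell$g_h_bar,
    o_Eh = p$ocell$E_h, o_Iapp = p$ocell$I_app,
    i_C = p$icell$C_m, i_gl = p$icell$g_leak, i_El = p$icell$E_leak,
    i_gK = p$icell$g_K_bar, i_EK = p$icell$E_K, i_gNa = p$icell$g_Na_bar,
    i_ENa = p$icell$E_Na,
    e_C = p$ed$C_m, e_gl = p$ed$g_leak, e_El = p$ed$E_leak,
    alpha_A = p$receptors$alpha_A, beta_A = p$receptors$beta_A,
    E_A = p$receptors$E_A, alpha_N = p$receptors$alpha_N,
    beta_N = p$receptors$beta_N, g_N = p$receptors$g_N,
    E_N = p$receptors$E_N, Mg = p$receptors$Mg,
    alpha_G = p$receptors$alpha_G, beta_G = p$receptors$beta_G,
    E_G = p$receptors$E_G, g_ampa_I = p$receptors$g_ampa_I,
    g_gaba_I = p$receptors$g_gaba_I, g_gaba_E = p$receptors$g_gaba_E,
    g_a7 = p$receptors$g_a7, E_a7 = p$receptors$E_a7,
    ec50 = p$receptors$ec50, n_hill = p$receptors$n_hill,
    tau_ra7 = p$receptors$tau_ra7,
    T_max = p$release$T_max, K_p = p$release$K_p, V_p = p$release$V_p,
    K_Ca_p = p$release$K_Ca_p, Ca_p = p$release$Ca_p,
    xi_prime = p$cicr$xi_prime, alpha_prime = p$cicr$alpha_prime,
    tau_ca_o = p$cicr$tau_ca_o, tau_is = p$cicr$tau_is, k_d = p$cicr$k_d,
    ca_is_rest = p$cicr$ca_is_rest,
    xi = p$dca$xi, alpha_frac = p$dca$alpha_frac, tau_ca_d = p$dca$tau_ca,
    sigma_plast = p$plasticity$sigma, g0 = p$plasticity$g0,
    theta_up = p$plasticity$theta_up, theta_down = p$plasticity$theta_down,
    gamma_up = p$plasticity$gamma_up, gamma_down = p$plasticity$gamma_down,
    P1 = p$plasticity$P1, P2 = p$plasticity$P2, P3 = p$plasticity$P3,
    P4 = p$plasticity$P4, steepness = p$plasticity$steepness
  )
}
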