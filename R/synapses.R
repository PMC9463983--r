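# Receptor gating kinetics, transmitter-release functions and stimulus
# pulse trains.

#' One Euler step of two-state receptor gating
#'
#' dr/dt = alpha [T] (1 - r) - beta r.
#'
#' @param r open fraction in [0, 1]
#' @param T_conc transmitter concentration (mM), >= 0
#' @param alpha binding rate (1/(ms mM)); \code{beta} unbinding rate (1/ms)
#' @param beta unbinding rate (1/ms)
#' @param dt time step (ms), > 0
#' @return updated open fraction
#' @export
gate_update <- function(r, T_conc, alpha, beta, dt) {
  if (any(dt <= 0)) stop("dt must be > 0")
  stopifnot(all(r >= 0), all(r <= 1), all(T_conc >= 0))
  r + dt * (alpha * T_conc * (1 - r) - beta * r)
}

# closed-form steady state of the two-state gate under sustained transmitter
gate_steady_state <- function(T_conc, alpha, beta) {
  alpha * T_conc / (alpha * T_conc + beta)
}

#' alpha7 nAChR activation step
#'
#' Hill-type steady state r_inf = ACh^n / (EC50^n + ACh^n) approached with a
#' constant time constant (first-order relaxation).
#'
#' @param ACh acetylcholine concentration (mM), >= 0
#' @param r current open fraction
#' @param dt time step (ms)
#' @param ec50 half-activation concentration (mM)
#' @param n_hill Hill coefficient
#' @param tau_r relaxation time constant (ms)
#' @return updated open fraction
#' @export
alpha7_activation <- function(ACh, r, dt, ec50 = 80e-3, n_hill = 1.73,
                              tau_r = 5) {
  stopifnot(all(ACh >= 0))
  r_inf <- ifelse(ACh > 0, ACh^n_hill / (ec50^n_hill + ACh^n_hill), 0)
  r + dt * (r_inf - r) / tau_r
}

# numerically safe logistic
logistic_safe <- function(x) {
  out <- numeric(length(x))
  hi <- x > 500; lo <- x < -500; mid <- !hi & !lo
  out[hi] <- 1
  out[lo] <- 0
  out[mid] <- 1 / (1 + exp(-x[mid]))
  out
}

#' Voltage-dependent transmitter release
#'
#' Stationary sigmoid mapping presynaptic voltage to released GABA:
#' T_max / (1 + exp(-(V - V_p)/K_p)).  Used for the I-cell terminal.
#'
#' @param V presynaptic membrane potential (mV)
#' @param params a \code{\link{release_params}} object
#' @return transmitter concentration (mM) in (0, T_max)
#' @export
release_from_voltage <- function(V, params = release_params()) {
  if (!all(is.finite(V))) stop("V must be finite")
  params$T_max * logistic_safe((V - params$V_p) / params$K_p)
}

#' Calcium-dependent transmitter release
#'
#' Steep sigmoid mapping cytosolic calcium to released GABA at the O-cell
#' terminal: T_max / (1 + exp(-(Ca - Ca_p)/K_Ca_p)).
#'
#' @param Ca_i cytosolic calcium (mM), >= 0
#' @inheritParams release_from_voltage
#' @return transmitter concentration (mM) in (0, T_max)
#' @export
release_from_calcium <- function(Ca_i, params = release_params()) {
  stopifnot(all(Ca_i >= 0))
  params$T_max * logistic_safe((Ca_i - params$Ca_p) / params$K_Ca_p)
}

#' Stimulus pulse train
#'
#' A declarative train of transmitter pulses: square pulses (amplitude held
#' over a half-open interval [onset, onset + duration)) or alpha-function
#' pulses (instantaneous rise to amplitude, exponential decay).
#'
#' @param species \code{"glutamate"}, \code{"GABA"}, \code{"ACh"} or
#'   \code{"calcium"} (an exogenous dendritic calcium source, uM/ms)
#' @param amplitude pulse amplitude (mM; uM/ms for calcium injection)
#' @param onsets strictly increasing onset times (ms)
#' @param duration square-pulse duration (ms)
#' @param shape \code{"square"} or \code{"alpha"}
#' @param decay alpha-function decay constant (ms)
#' @return an object of class \code{"stim_train"}
#' @examples
#' tr <- stim_train("glutamate", 1, onsets = 100, duration = 5)
#' stimulus_value(tr, c(99, 102, 105))
#' @export
stim_train <- function(species = c("glutamate", "GABA", "ACh", "calcium"),
                       amplitude, onsets, duration = 5,
                       shape = c("square", "alpha"), decay = 4) {
  species <- match.arg(species)
  shape <- match.arg(shape)
  stopifnot(amplitude >= 0, !is.unsorted(onsets, strictly = TRUE))
  structure(list(species = species, shape = shape, amplitude = amplitude,
                 duration = duration, decay = decay,
                 onsets = as.numeric(onsets)),
            class = "stim_train")
}

#' Evaluate a stimulus train
#'
#' Overlapping pulses combine by maximum, capping the concentration at the
#' pulse amplitude.
#'
#' @param train a \code{\link{stim_train}}
#' @param t times (ms), >= 0
#' @return concentration at each \code{t}
#' @export
stimulus_value <- function(train, t) {
  stopifnot(inherits(train, "stim_train"), all(t >= 0))
  vapply(t, function(tt) {
    idx <- which(train$onsets <= tt)
    if (!length(idx)) return(0)
    dts <- tt - train$onsets[idx]
    if (train$shape == "square") {
      if (any(dts < train$duration)) train$amplitude else 0
    } else {
      max(train$amplitude * exp(-dts / train$decay))
    }
  }, numeric(1))
}

# convert a list of stim_train objects into the engine's format
stims_for_engine <- function(trains) {
  lapply(trains, function(tr) {
    list(onsets = tr$onsets, amplitude = tr$amplitude,
         duration = tr$duration, decay = tr$decay, shape = tr$shape)
  })
}
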