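# Time integration of the coupled network (forward Euler, fixed step,
# optional Euler-Maruyama voltage noise) and the event-windowed accelerator
# for minutes-long protocols.

STATE_NAMES <- c("v_o", "m_o", "h_o", "n_o", "p_o", "hf_o", "hs_o", "r_a7",
                 "ca_i", "ca_is",
                 "v_i", "m_i", "h_i", "n_i", "r_ampa_i", "r_gaba_i",
                 "v_e", "r_ampa_e", "r_nmda_e", "r_gaba_e", "ca_d", "g_ampa")

# crude initial guess: leak reversal + steady-state gates; refined by
# relaxation in resting_state()
initial_state_guess <- function(params, g_init = params$plasticity$g0) {
  Vo <- params$ocell$E_leak
  Vi <- params$icell$E_leak
  Ve <- params$ed$E_leak
  go <- gate_steady("ocell", Vo)
  gi <- gate_steady("icell", Vi)
  setNames(c(Vo, go$m, go$h, go$n, go$p, go$h_f, go$h_s, 0, 0,
             params$cicr$ca_is_rest,
             Vi, gi$m, gi$h, gi$n, 0, 0,
             Ve, 0, 0, 0, 0, g_init), STATE_NAMES)
}

.rest_cache <- new.env(parent = emptyenv())

#' Resting state of the circuit or of one cell
#'
#' Relaxes the model with no synaptic input for \code{t_relax} ms and
#' returns the final state.  A cell that fails to settle (e.g. spontaneous
#' spiking) is reported through the \code{limit_cycle} flag rather than an
#' error.
#'
#' @param params a \code{\link{circuit_params}} object
#' @param cell \code{"network"} (full circuit), \code{"ocell"},
#'   \code{"icell"} or \code{"ed"} (E_D relaxed in isolation)
#' @param t_relax relaxation time (ms)
#' @param dt integration step (ms)
#' @return list with \code{V} (resting potential, mV), \code{state} (full
#'   named state vector) and \code{limit_cycle} (logical)
#' @export
resting_state <- function(params = circuit_params(),
                          cell = c("network", "ocell", "icell", "ed"),
                          t_relax = 3000, dt = 0.02) {
  cell <- match.arg(cell)
  mode <- if (cell == "ed") "ed_only" else "full"
  key <- paste(mode, t_relax, dt,
               paste(unlist(flatten_params(params)), collapse = ","),
               sep = "|")
  if (!is.null(.rest_cache[[key]])) {
    res <- .rest_cache[[key]]
  } else {
    out <- engine_run(flatten_params(params), list(), list(), list(), list(),
                      initial_state_guess(params), 0, t_relax, dt,
                      mode == "ed_only", 0L, FALSE, 0, 0, 0, NA_real_, 1)
    tr <- out$trace
    tail_idx <- tr[, "t"] >= t_relax - 300
    vcol <- switch(cell, network = , ocell = "v_o", icell = "v_i",
                   ed = "v_e")
    vr <- range(tr[tail_idx, vcol])
    res <- list(state = out$final, limit_cycle = diff(vr) > 1e-3,
                trace_tail = tr[tail_idx, c("t", "v_o", "v_i", "v_e")])
    .rest_cache[[key]] <- res
  }
  V <- switch(cell,
              network = res$state[c("v_o", "v_i", "v_e")],
              ocell = unname(res$state["v_o"]),
              icell = unname(res$state["v_i"]),
              ed = unname(res$state["v_e"]))
  list(V = V, state = res$state, limit_cycle = res$limit_cycle)
}

split_stimuli <- function(stimuli) {
  if (inherits(stimuli, "stim_train")) stimuli <- list(stimuli)
  sp <- vapply(stimuli, function(s) s$species, character(1))
  list(glu = stims_for_engine(stimuli[sp == "glutamate"]),
       ach = stims_for_engine(stimuli[sp == "ACh"]),
       gaba = stims_for_engine(stimuli[sp == "GABA"]),
       cainj = stims_for_engine(stimuli[sp == "calcium"]))
}

#' Simulate the circuit with forward Euler
#'
#' Integrates the full three-cell network, or the dendritic compartment
#' alone (\code{mode = "ed_only"}, used by the disinhibition protocols where
#' GABA arrives as an exogenous pulse train).  Noise, when enabled, enters
#' the voltage updates only, as an additive sqrt(dt)-scaled Gaussian term.
#' A diverging trajectory (|V| > 200 mV or non-finite) aborts with a
#' diagnostic naming the offending variable and time.
#'
#' @param params a \code{\link{circuit_params}} object
#' @param stimuli a list of \code{\link{stim_train}} objects (any mix of
#'   species); glutamate drives the I-cell and E_D, ACh the O-cell, GABA
#'   and exogenous calcium drive E_D (GABA trains are used in
#'   \code{"ed_only"} mode only)
#' @param t_end end time (ms); \code{dt} integration step (ms, default 0.02)
#' @param dt integration step (ms)
#' @param mode \code{"full"} or \code{"ed_only"}
#' @param g_init initial AMPAR maximal conductance (nS)
#' @param init full initial state vector (default: relaxed resting state)
#' @param noise logical; use \code{params$noise} amplitudes
#' @param clamp_ed if finite, hold the E_D membrane at this voltage (mV)
#' @param record_stride recording stride (ms)
#' @param gaba_o_mode O-cell GABA release: \code{"calcium"} (default) or
#'   \code{"both"} (calcium- plus voltage-dependent release, capped at
#'   T_max; used with noisy spiking)
#' @return an object of class \code{"ca1_sim"}: list with \code{trace}
#'   (data.frame), \code{final} (named state vector), \code{gate_range},
#'   \code{n_ca_clip}, \code{dt}, \code{mode}
#' @examples
#' p <- circuit_params("disinhibition")
#' sim <- simulate_circuit(p, list(stim_train("glutamate", 1, 50, 1)),
#'                         t_end = 300, mode = "ed_only")
#' max(sim$trace$ca_d)
#' @export
simulate_circuit <- function(params = circuit_params(), stimuli = list(),
                             t_end, dt = 0.02,
                             mode = c("full", "ed_only"),
                             g_init = params$plasticity$g0, init = NULL,
                             noise = FALSE, clamp_ed = NA_real_,
                             record_stride = 0.1,
                             gaba_o_mode = c("calcium", "both")) {
  mode <- match.arg(mode)
  gaba_o_mode <- match.arg(gaba_o_mode)
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= 0) stop("t_end must be > 0")
  if (is.null(init)) {
    init <- resting_state(params, if (mode == "ed_only") "ed" else "network",
                          dt = dt)$state
  }
  init <- init[STATE_NAMES]
  init["g_ampa"] <- g_init
  st <- split_stimuli(stimuli)
  out <- engine_run(flatten_params(params), st$glu, st$ach, st$gaba,
                    st$cainj, unname(init), 0, t_end, dt,
                    mode == "ed_only", if (gaba_o_mode == "both") 1L else 0L,
                    isTRUE(noise), params$noise$sigma_O,
                    params$noise$sigma_I, params$noise$sigma_ED,
                    clamp_ed, record_stride)
  if (isTRUE(out$diverged)) {
    stop("simulation diverged: ", out$diverged_var, " at t = ",
         signif(out$diverged_time, 6), " ms")
  }
  trace <- as.data.frame(out$trace)
  structure(list(trace = trace, final = out$final,
                 gate_range = out$gate_range, n_ca_clip = out$n_ca_clip,
                 dt = dt, mode = mode, t_end = t_end),
            class = "ca1_sim")
}

#' @export
print.ca1_sim <- function(x, ...) {
  cat("ca1plast simulation (", x$mode, "), ", x$t_end, " ms at dt = ",
      x$dt, " ms\n", sep = "")
  cat("  final g_ampa:", signif(x$final[["g_ampa"]], 5), "nS;",
      nrow(x$trace), "recorded samples\n")
  invisible(x)
}

#' @export
plot.ca1_sim <- function(x, vars = c("v_e", "ca_d", "g_ampa"), ...) {
  op <- graphics::par(mfrow = c(length(vars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    graphics::plot(x$trace$t, x$trace[[v]], type = "l", xlab = "t (ms)",
                   ylab = v, ...)
  }
  invisible(x)
}

# peak EPSC magnitude (|I_AMPA + I_NMDA|, pA) within `within` ms of a
# glutamate pulse onset
measure_epsc <- function(trace, onset, within = 200) {
  sel <- trace$t >= onset & trace$t <= onset + within
  if (!any(sel)) return(NA_real_)
  max(abs(trace$i_ampa[sel] + trace$i_nmda[sel]))
}

#' Event-windowed integration of a long protocol
#'
#' Minutes-long protocols with sparse stimulation are integrated by
#' simulating a window (default 2000 ms) around each stimulus event, started
#' from the relaxed resting state with the current AMPAR conductance;
#' between windows all fast state is at rest and the conductance is
#' propagated analytically, g(t + D) = g0 + (g - g0) exp(-eta(0) sigma D).
#' The window must be long enough for the fast state to relax before its
#' end; if it is not, the run aborts and suggests a longer window.
#'
#' @param params a \code{\link{circuit_params}} object
#' @param events list of events, each a list with \code{t} (anchor time, ms)
#'   and \code{trains} (list of \code{\link{stim_train}} with onsets relative
#'   to the anchor)
#' @param mode \code{"full"} or \code{"ed_only"}
#' @param g_init initial AMPAR conductance (nS)
#' @param t_total optional protocol end time (ms); the returned
#'   \code{final_g} is propagated to it
#' @param window window length (ms) simulated from each event anchor
#' @param pre lead time (ms) simulated before each anchor
#' @param dt integration step (ms)
#' @param record_stride recording stride inside windows (ms)
#' @param noise logical, per-window voltage noise
#' @param keep_traces keep each window's trace (memory permitting)
#' @param epsc_within EPSC search window after each glutamate onset (ms)
#' @return class \code{"ca1_windowed"}: \code{g_series} (t_ms, g at window
#'   starts/ends), \code{epsc} (t_ms, amp per glutamate pulse),
#'   \code{final_g}, optionally \code{traces}
#' @export
windowed_integrate <- function(params, events, mode = c("full", "ed_only"),
                               g_init = params$plasticity$g0,
                               t_total = NULL, window = 2000, pre = 100,
                               dt = 0.02, record_stride = 0.1,
                               noise = FALSE, keep_traces = FALSE,
                               epsc_within = 200) {
  mode <- match.arg(mode)
  if (!length(events)) stop("no events")
  tt <- vapply(events, function(e) e$t, numeric(1))
  if (is.unsorted(tt, strictly = TRUE)) stop("event times must increase")
  rest <- resting_state(params, if (mode == "ed_only") "ed" else "network",
                        dt = dt)$state
  pp <- params$plasticity
  krate <- learning_rate(0, pp) * pp$sigma  # 1/ms decay of g toward g0
  g <- g_init
  g_series <- list()
  epsc <- list()
  traces <- if (keep_traces) vector("list", length(events)) else NULL
  for (i in seq_along(events)) {
    ev <- events[[i]]
    t0_abs <- ev$t - pre
    trains <- lapply(ev$trains, function(tr) {
      tr$onsets <- tr$onsets + pre
      tr
    })
    sim <- simulate_circuit(params, trains, t_end = window + pre, dt = dt,
                            mode = mode, g_init = g, init = rest,
                            noise = noise, record_stride = record_stride)
    # window-adequacy check: fast state must be back at rest at window end
    vres <- if (mode == "ed_only") "v_e" else c("v_o", "v_i", "v_e")
    drift <- abs(sim$final[vres] - rest[vres])
    if (!noise && any(drift > 0.5)) {
      stop("window too short: membrane potential ",
           names(drift)[which.max(drift)], " is ",
           signif(max(drift), 3), " mV from rest at the window end; ",
           "increase `window`")
    }
    g_series[[length(g_series) + 1]] <-
      data.frame(t_ms = t0_abs, g = g)
    for (tr in ev$trains) {
      if (tr$species == "glutamate") {
        for (on in tr$onsets) {
          amp <- measure_epsc(sim$trace, on + pre, epsc_within)
          epsc[[length(epsc) + 1]] <-
            data.frame(t_ms = ev$t + on, amp = amp)
        }
      }
    }
    g <- unname(sim$final[["g_ampa"]])
    g_series[[length(g_series) + 1]] <-
      data.frame(t_ms = t0_abs + window + pre, g = g)
    if (keep_traces) {
      tr <- sim$trace
      tr$t <- tr$t + t0_abs
      traces[[i]] <- tr
    }
    # analytic conductance propagation across the silent gap
    t_next <- if (i < length(events)) events[[i + 1]]$t - pre else
      max(t_total %||% (t0_abs + window + pre), t0_abs + window + pre)
    gap <- t_next - (t0_abs + window + pre)
    if (gap > 0) g <- pp$g0 + (g - pp$g0) * exp(-krate * gap)
  }
  structure(list(g_series = do.call(rbind, g_series),
                 epsc = do.call(rbind, epsc),
                 final_g = g, t_total = t_total, window = window,
                 traces = traces, mode = mode),
            class = "ca1_windowed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ca1_windowed <- function(x, ...) {
  cat("ca1plast windowed protocol run (", x$mode, "): ",
      nrow(x$g_series) / 2, " events, window ", x$window, " ms\n", sep = "")
  if (!is.null(x$epsc) && nrow(x$epsc)) {
    cat("  EPSC pulses:", nrow(x$epsc), " range:",
        paste(signif(range(x$epsc$amp), 5), collapse = " - "), "pA\n")
  }
  cat("  final g_ampa:", signif(x$final_g, 5), "nS\n")
  if (!is.null(x$g_end_window)) {
    cat("  g at end of window:", signif(x$g_end_window, 5), "nS\n")
  }
  invisible(x)
}

#' Full (non-windowed) integration of an event protocol
#'
#' Integrates the whole protocol in one continuous forward-Euler run, as a
#' reference for \code{\link{windowed_integrate}}.  Event trains are
#' converted to absolute onset times and merged per species.
#'
#' @inheritParams windowed_integrate
#' @param t_end protocol end time (ms)
#' @param record_stride recording stride (ms); keep coarse for long runs
#' @return a \code{\link{simulate_circuit}} result (\code{"ca1_sim"})
#' @export
integrate_protocol_full <- function(params, events,
                                    mode = c("full", "ed_only"),
                                    g_init = params$plasticity$g0,
                                    t_end, dt = 0.02,
                                    record_stride = 100) {
  mode <- match.arg(mode)
  trains <- list()
  for (ev in events) {
    for (tr in ev$trains) {
      tr$onsets <- tr$onsets + ev$t
      key <- paste(tr$species, tr$amplitude, tr$duration, tr$shape, tr$decay)
      if (is.null(trains[[key]])) {
        trains[[key]] <- tr
      } else {
        trains[[key]]$onsets <- sort(c(trains[[key]]$onsets, tr$onsets))
      }
    }
  }
  simulate_circuit(params, unname(trains), t_end = t_end, dt = dt,
                   mode = mode, g_init = g_init,
                   record_stride = record_stride)
}

# g propagated analytically to an arbitrary time inside the silent tail
propagate_g <- function(g, from_ms, to_ms, params) {
  pp <- params$plasticity
  k <- learning_rate(0, pp) * pp$sigma
  pp$g0 + (g - pp$g0) * exp(-k * max(0, to_ms - from_ms))
}

#' Replicated runs with per-replicate seeds
#'
#' Runs a (typically stochastic) simulation callback once per seed and
#' averages the numeric columns of the returned data.frames pointwise.
#'
#' @param fun function of one argument (the seed) returning a data.frame
#'   whose first column is a time axis shared across replicates
#' @param n number of replicates; \code{seeds} the RNG seeds (defaults to
#'   \code{1:n}); duplicates draw a warning
#' @param seeds integer vector of seeds
#' @return list with \code{mean} (data.frame) and \code{replicates} (list)
#' @export
run_replicates <- function(fun, n = 10, seeds = seq_len(n)) {
  stopifnot(n >= 1, length(seeds) == n)
  if (anyDuplicated(seeds)) warning("duplicate seeds")
  reps <- lapply(seeds, function(s) {
    set.seed(s)
    fun(s)
  })
  m <- reps[[1]]
  if (n > 1) {
    for (j in seq(2, ncol(m))) {
      m[[j]] <- rowMeans(do.call(cbind, lapply(reps, function(r) r[[j]])))
    }
  }
  list(mean = m, replicates = reps)
}
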