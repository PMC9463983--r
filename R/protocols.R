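# Declarative builders and runners for the in-silico experiments:
# cholinergic copairing, dendritic disinhibition, pairing-lag scans,
# single-pairing analyses and GABA-timing phase maps.

MS_PER_MIN <- 60000

#' Cholinergic copairing protocol
#'
#' The I-cell and E_D receive one glutamate pulse (1 mM, 5 ms) per minute
#' throughout.  During the copairing window the O-cell additionally receives
#' an ACh pulse (1 mM, 5 ms) \code{delta_t} ms before each glutamate pulse;
#' the in-window pairing rate can be raised above one per minute.  EPSC
#' amplitude (peak |I_AMPA + I_NMDA| on E_D) is measured on every glutamate
#' pulse.
#'
#' @param params a \code{\link{circuit_params}} (copairing preset by
#'   default)
#' @param t_pair_min copairing window length (min); 0 gives a pure baseline
#' @param pair_start_min window start (min)
#' @param total_min total simulated protocol length (min)
#' @param delta_t ACh-to-glutamate lag (ms, positive = ACh first)
#' @param period_s_in_window seconds between pairings inside the window
#'   (default 60 = one per minute; 20 or 30 reproduce the frequency scans)
#' @param glu_amp,glu_dur,ach_amp,ach_dur pulse amplitude (mM) and duration (ms)
#' @param dt,window,noise,keep_traces passed to
#'   \code{\link{windowed_integrate}}
#' @return class \code{"copairing_run"}: the \code{\link{windowed_integrate}}
#'   result plus \code{baseline} (mean pre-window EPSC), \code{pair_end_min}
#'   and the configuration
#' @export
run_copairing <- function(params = circuit_params("copairing"),
                          t_pair_min = 8, pair_start_min = 10,
                          total_min = 45, delta_t = 100,
                          period_s_in_window = 60,
                          glu_amp = 1, glu_dur = 5, ach_amp = 1, ach_dur = 5,
                          dt = 0.02, window = 2000, noise = FALSE,
                          keep_traces = FALSE) {
  stopifnot(t_pair_min >= 0, pair_start_min + t_pair_min <= total_min)
  pair_start <- pair_start_min * MS_PER_MIN
  pair_end <- (pair_start_min + t_pair_min) * MS_PER_MIN
  # baseline glutamate pulses on the minute grid
  glu_times <- seq(0, (total_min - 1) * MS_PER_MIN, by = MS_PER_MIN)
  glu_times <- glu_times[glu_times < pair_start | glu_times >= pair_end]
  # paired pulses inside the window at the requested rate
  pair_times <- if (t_pair_min > 0) {
    seq(pair_start, pair_end - 1, by = period_s_in_window * 1000)
  } else numeric(0)
  events <- list()
  for (tg in sort(c(glu_times, pair_times))) {
    paired <- tg >= pair_start && tg < pair_end
    anchor <- if (paired) tg - max(delta_t, 0) else tg
    trains <- list(stim_train("glutamate", glu_amp, tg - anchor, glu_dur))
    if (paired) {
      trains <- c(trains, list(
        stim_train("ACh", ach_amp, tg - delta_t - anchor, ach_dur)))
    }
    events[[length(events) + 1]] <- list(t = anchor, trains = trains)
  }
  wi <- windowed_integrate(params, events, mode = "full",
                           t_total = total_min * MS_PER_MIN, window = window,
                           dt = dt, noise = noise,
                           keep_traces = keep_traces)
  base_sel <- wi$epsc$t_ms < pair_start
  structure(c(unclass(wi),
              list(baseline = mean(wi$epsc$amp[base_sel]),
                   pair_start_min = pair_start_min,
                   pair_end_min = pair_start_min + t_pair_min,
                   t_pair_min = t_pair_min, delta_t = delta_t,
                   params = params)),
            class = c("copairing_run", "ca1_windowed"))
}

#' Disinhibition protocol on the isolated dendritic compartment
#'
#' E_D receives one glutamate pulse (1 mM, 1 ms) per minute, each followed
#' 2 ms later by a GABA pulse (1 mM, 1 ms), except during the disinhibition
#' window when the GABA pulse is omitted.
#'
#' @param params a \code{\link{circuit_params}} (disinhibition preset)
#' @param period_min disinhibition window length (min)
#' @param start_min window start (min)
#' @param total_min total protocol length (min)
#' @param gaba_lag GABA onset after glutamate (ms)
#' @param amp,dur shared pulse amplitude (mM) and duration (ms) for
#'   glutamate and GABA
#' @param g_init initial AMPAR conductance (nS)
#' @param dt,window,keep_traces passed to \code{\link{windowed_integrate}}
#' @return class \code{"disinhibition_run"}: windowed results plus
#'   \code{g_end_window} (conductance at the end of the disinhibition
#'   window), \code{epsc_end_window} (EPSC on its final glutamate pulse) and
#'   \code{baseline} (mean pre-window EPSC)
#' @examples
#' \donttest{
#' run <- run_disinhibition(period_min = 5, total_min = 11)
#' run$g_end_window
#' }
#' @export
run_disinhibition <- function(params = circuit_params("disinhibition"),
                              period_min = 5, start_min = 5,
                              total_min = 45, gaba_lag = 2,
                              amp = 1, dur = 1,
                              g_init = params$plasticity$g0,
                              dt = 0.02, window = 2000,
                              keep_traces = FALSE) {
  stopifnot(period_min >= 0, start_min + period_min <= total_min)
  w_start <- start_min * MS_PER_MIN
  w_end <- (start_min + period_min) * MS_PER_MIN
  events <- lapply(seq(0, (total_min - 1) * MS_PER_MIN, by = MS_PER_MIN),
                   function(tg) {
    disinhibited <- tg >= w_start && tg < w_end
    trains <- list(stim_train("glutamate", amp, 0, dur))
    if (!disinhibited) {
      trains <- c(trains, list(stim_train("GABA", amp, gaba_lag, dur)))
    }
    list(t = tg, trains = trains)
  })
  wi <- windowed_integrate(params, events, mode = "ed_only",
                           g_init = g_init,
                           t_total = total_min * MS_PER_MIN,
                           window = window, dt = dt,
                           keep_traces = keep_traces)
  gs <- wi$g_series
  # conductance at the end of the disinhibition window: last computed value
  # before w_end, propagated analytically through the silent gap
  g_end_window <- if (period_min > 0) {
    idx <- max(which(gs$t_ms <= w_end))
    propagate_g(gs$g[idx], gs$t_ms[idx], w_end, params)
  } else g_init
  # EPSC at the end of the window: the read-out pulse delivered at the
  # window-end minute, i.e. with the end-of-window conductance
  epsc_end <- if (period_min > 0 && any(wi$epsc$t_ms == w_end)) {
    wi$epsc$amp[wi$epsc$t_ms == w_end]
  } else NA_real_
  structure(c(unclass(wi),
              list(g_end_window = g_end_window,
                   epsc_end_window = epsc_end,
                   baseline = mean(wi$epsc$amp[wi$epsc$t_ms < w_start]),
                   start_min = start_min, period_min = period_min,
                   params = params)),
            class = c("disinhibition_run", "ca1_windowed"))
}

# change in g_ampa from one ACh+glutamate pairing at lag `delta_t`
# (full network, measured 60 ms after the last stimulus onset)
pairing_delta_g <- function(params, delta_t, doublet = FALSE,
                            doublet_period = 500, dt = 0.02,
                            glu_amp = 1, glu_dur = 5,
                            ach_amp = 1, ach_dur = 5, readout = 60) {
  base <- 50 + max(0, -delta_t)
  ach_on <- base + c(0, if (doublet) doublet_period)
  glu_on <- base + delta_t + c(0, if (doublet) doublet_period)
  t_end <- max(ach_on, glu_on) + readout
  sim <- simulate_circuit(
    params,
    list(stim_train("ACh", ach_amp, ach_on, ach_dur),
         stim_train("glutamate", glu_amp, glu_on, glu_dur)),
    t_end = t_end, dt = dt, mode = "full",
    record_stride = t_end)
  unname(sim$final[["g_ampa"]] - params$plasticity$g0)
}

classify_dg <- function(dg, eps = 0.05) {
  if (dg > eps) "potentiation" else if (dg < -eps) "depression" else "none"
}

#' Pairing-lag scan of single or doublet ACh + glutamate pairings
#'
#' Measures the change in AMPAR conductance 60 ms after a single pairing of
#' an ACh pulse to the O-cell with a glutamate pulse to the I-cell and E_D,
#' across a grid of lags delta_t = t_glutamate - t_ACh (positive = ACh
#' first).  Region boundaries (depression / potentiation / no plasticity)
#' are refined by bisection.
#'
#' @param params a \code{\link{circuit_params}} (copairing preset)
#' @param dt_grid lag grid (ms)
#' @param doublet pair two pulses of each species at 2 Hz instead of one
#' @param dt integration step (ms)
#' @param eps classification threshold on |delta g| (nS): responses
#'   smaller than this (about 5 percent of the maximal single-pairing
#'   response) count as no plasticity
#' @param refine_to bisection bracket width (ms)
#' @return list with \code{table} (data.frame: delta_t, delta_g, region) and
#'   \code{boundaries} (data.frame: delta_t, from, to)
#' @export
scan_pairing_dt <- function(params = circuit_params("copairing"),
                            dt_grid = seq(-40, if (doublet) 360 else 220,
                                          by = 5),
                            doublet = FALSE, dt = 0.02, eps = 0.05,
                            refine_to = 0.05) {
  dg <- vapply(dt_grid, function(d)
    pairing_delta_g(params, d, doublet = doublet, dt = dt), numeric(1))
  cls <- vapply(dg, classify_dg, character(1), eps = eps)
  tab <- data.frame(delta_t = dt_grid, delta_g = dg, region = cls)
  bounds <- list()
  f <- function(d) classify_dg(
    pairing_delta_g(params, d, doublet = doublet, dt = dt), eps)
  for (i in seq_len(length(dt_grid) - 1)) {
    if (cls[i] != cls[i + 1]) {
      lo <- dt_grid[i]; hi <- dt_grid[i + 1]
      cl <- cls[i]; ch <- cls[i + 1]
      while (hi - lo > refine_to) {
        mid <- (lo + hi) / 2
        cm <- f(mid)
        if (cm == cl) lo <- mid else { hi <- mid; ch <- cm }
      }
      bounds[[length(bounds) + 1]] <-
        data.frame(delta_t = (lo + hi) / 2, from = cl, to = ch)
    }
  }
  list(table = tab,
       boundaries = if (length(bounds)) do.call(rbind, bounds) else
         data.frame(delta_t = numeric(0), from = character(0),
                    to = character(0)))
}

#' Copairing duration and frequency scans
#'
#' Transient duration is the time after the copairing window until the EPSC
#' first returns to within a tolerance band of the pre-window baseline.
#'
#' @param params a \code{\link{circuit_params}} (copairing preset)
#' @param durations_min copairing durations to scan at one pairing/min
#' @param periods_s in-window pairing periods (s) to scan at a fixed window
#' @param fixed_window_min window length used for the frequency scan (min)
#' @param horizon_min simulated time after the window end (min)
#' @param tol relative EPSC tolerance defining "back at baseline"
#' @param dt integration step (ms)
#' @return data.frame with columns \code{kind}, \code{value},
#'   \code{transient_min} (Inf = not returned within the horizon)
#' @export
scan_duration_and_frequency <- function(params = circuit_params("copairing"),
                                        durations_min = c(2, 4, 6, 8),
                                        periods_s = c(60, 30, 20),
                                        fixed_window_min = 4,
                                        horizon_min = 30, tol = 0.02,
                                        dt = 0.02) {
  transient <- function(run) {
    post <- run$epsc[run$epsc$t_ms >= run$pair_end_min * MS_PER_MIN, ]
    ok <- post$amp <= run$baseline * (1 + tol)
    if (!any(ok)) return(Inf)
    post$t_ms[which(ok)[1]] / MS_PER_MIN - run$pair_end_min
  }
  rows <- list()
  for (d in durations_min) {
    run <- run_copairing(params, t_pair_min = d, pair_start_min = 5,
                         total_min = 5 + d + horizon_min, dt = dt)
    rows[[length(rows) + 1]] <-
      data.frame(kind = "duration", value = d, transient_min = transient(run))
  }
  for (ps in periods_s) {
    run <- run_copairing(params, t_pair_min = fixed_window_min,
                         pair_start_min = 5, period_s_in_window = ps,
                         total_min = 5 + fixed_window_min + horizon_min,
                         dt = dt)
    rows[[length(rows) + 1]] <-
      data.frame(kind = "frequency", value = 60 / ps,
                 transient_min = transient(run))
  }
  do.call(rbind, rows)
}

#' Single glutamate + GABA pairing on the dendritic compartment
#'
#' One glutamate pulse followed \code{gaba_lag} ms later by a GABA pulse
#' (disinhibition preset).  Returns the peak dendritic calcium, the net
#' conductance change once the calcium transient has settled (the dendritic
#' calcium tail outlives a 60-ms epoch, so the settled value is the
#' trajectory endpoint), and the learning-rate-weighted calcium area ratio
#' of the transient.  The 60-ms read-out used by the pairing-lag scans is
#' also reported as \code{dg_60}.
#'
#' @param params a \code{\link{circuit_params}} (disinhibition preset)
#' @param g_init initial AMPAR conductance (nS)
#' @param gaba_amp GABA amplitude (mM); 0 gives a glutamate-only pulse
#' @param gaba_lag GABA onset after glutamate (ms)
#' @param glu_amp,glu_dur,gaba_dur remaining pulse parameters
#' @param ca_inj optional exogenous dendritic calcium source, a
#'   \code{\link{stim_train}} with species \code{"calcium"} and onsets
#'   relative to the glutamate onset
#' @param dt integration step (ms)
#' @param t_post simulated time after the pairing (ms); the settled
#'   conductance is read at its end
#' @return list with \code{ca_max} (uM), \code{dg} (nS, settled),
#'   \code{dg_60} (nS, 60 ms after the glutamate onset), \code{g_after}
#'   (nS, settled), \code{ratio}, and the simulated \code{sim}
#' @export
single_pairing_delta <- function(params = circuit_params("disinhibition"),
                                 g_init = params$plasticity$g0,
                                 gaba_amp = 1, gaba_lag = 2,
                                 glu_amp = 1, glu_dur = 1, gaba_dur = 1,
                                 ca_inj = NULL, dt = 0.02, t_post = 600) {
  on <- 50
  trains <- list(stim_train("glutamate", glu_amp, on, glu_dur))
  if (gaba_amp > 0) {
    trains <- c(trains, list(stim_train("GABA", gaba_amp, on + gaba_lag,
                                        gaba_dur)))
  }
  if (!is.null(ca_inj)) {
    ca_inj$onsets <- ca_inj$onsets + on
    trains <- c(trains, list(ca_inj))
  }
  sim <- simulate_circuit(params, trains, t_end = on + t_post, dt = dt,
                          mode = "ed_only", g_init = g_init,
                          record_stride = dt)
  tr <- sim$trace
  g_after <- unname(sim$final[["g_ampa"]])
  i60 <- which.min(abs(tr$t - (on + 60)))
  list(ca_max = max(tr$ca_d), dg = g_after - g_init,
       dg_60 = tr$g_ampa[i60] - g_init, g_after = g_after,
       ratio = weighted_area_ratio(tr$t, tr$ca_d, params$plasticity),
       sim = sim)
}

#' Potentiation threshold of peak calcium for single pairings
#'
#' Scans the initial AMPAR conductance (which maps monotonically onto the
#' peak calcium of a single glutamate+GABA pairing), bisecting for the point
#' where the net conductance change 60 ms after the pairing flips sign.
#' Returns the peak calcium at that point (the potentiation threshold,
#' above the potentiation onset whenever the removal rate is positive)
#' together with the weighted area ratio there.
#'
#' @param params a \code{\link{circuit_params}} (disinhibition preset)
#' @param g_range conductance search interval (nS)
#' @param tol_ca bisection tolerance on peak calcium (uM)
#' @param ... passed to \code{\link{single_pairing_delta}}
#' @return list with \code{theta_pot} (uM), \code{g_at_threshold} (nS),
#'   \code{ratio_at_threshold}; or a not-found sentinel (\code{theta_pot =
#'   NA}) if no sign change is bracketed
#' @export
find_theta_pot <- function(params = circuit_params("disinhibition"),
                           g_range = c(4, 14), tol_ca = 1e-3, ...) {
  f <- function(g) single_pairing_delta(params, g_init = g, ...)
  # locate a no-change-to-potentiation bracket on a coarse grid first: the
  # response is not monotone in g (the conductance-decay term wins again at
  # large g), so a blind endpoint bracket can miss the sign change
  grid <- seq(g_range[1], g_range[2], length.out = 21)
  res <- lapply(grid, f)
  dg <- vapply(res, function(r) r$dg, numeric(1))
  i <- which(dg[-length(dg)] <= 0 & dg[-1] > 0)
  if (!length(i)) {
    return(list(theta_pot = NA_real_, g_at_threshold = NA_real_,
                ratio_at_threshold = NA_real_))
  }
  i <- i[1]
  lo <- grid[i]; hi <- grid[i + 1]
  rlo <- res[[i]]; rhi <- res[[i + 1]]
  while (abs(rhi$ca_max - rlo$ca_max) >= tol_ca) {
    mid <- (lo + hi) / 2
    rm <- f(mid)
    if (rm$dg > 0) { hi <- mid; rhi <- rm } else { lo <- mid; rlo <- rm }
  }
  list(theta_pot = (rlo$ca_max + rhi$ca_max) / 2,
       g_at_threshold = (lo + hi) / 2,
       ratio_at_threshold = mean(c(rlo$ratio, rhi$ratio)))
}

#' GABA amplitude / timing phase map
#'
#' Signed conductance change of a single glutamate+GABA pairing over a grid
#' of GABA amplitudes and GABA-after-glutamate lags, for one or more initial
#' conductances.
#'
#' @param params a \code{\link{circuit_params}} (disinhibition preset)
#' @param g_inits initial conductances (nS)
#' @param gaba_max_grid GABA amplitudes (mM)
#' @param lag_grid GABA lags after glutamate (ms)
#' @param dt integration step (ms)
#' @return data.frame with columns \code{g_init}, \code{gaba_max},
#'   \code{lag}, \code{dg}
#' @export
scan_gaba_phase_map <- function(params = circuit_params("disinhibition"),
                                g_inits = c(4, 6.9, 8.83),
                                gaba_max_grid = seq(0, 2, by = 0.25),
                                lag_grid = seq(-10, 60, by = 5),
                                dt = 0.02) {
  grid <- expand.grid(g_init = g_inits, gaba_max = gaba_max_grid,
                      lag = lag_grid)
  grid$dg <- mapply(function(g, a, l) {
    single_pairing_delta(params, g_init = g, gaba_amp = a, gaba_lag = l,
                         dt = dt, t_post = 300)$dg
  }, grid$g_init, grid$gaba_max, grid$lag)
  grid
}
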