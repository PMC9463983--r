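# Integration engine: quiescence, spiking, determinism, noise, event
# windowing and replicate averaging.

test_that("the unstimulated network is quiescent at its resting state", {
  p <- disinh()
  rest <- resting_state(p, "network")$state
  sim <- simulate_circuit(p, list(), t_end = 2000, init = rest,
                          record_stride = 1)
  fin <- sim$final
  for (v in c("v_o", "v_i", "v_e")) {
    expect_lt(abs(fin[[v]] - rest[[v]]), 1e-3)
  }
  expect_equal(fin[["g_ampa"]], 4)
  # gating variables remain valid fractions along the whole trajectory
  expect_gte(sim$gate_range[1], 0)
  expect_lte(sim$gate_range[2], 1)
})

test_that("one glutamate pulse evokes an I-cell volley", {
  sim <- simulate_circuit(copair(), list(stim_train("glutamate", 1, 50, 5)),
                          t_end = 200, mode = "full", record_stride = 0.02)
  spikes <- sum(diff(sim$trace$v_i > 0) == 1)
  expect_gte(spikes, 2)
  expect_gte(sim$gate_range[1], 0)
  expect_lte(sim$gate_range[2], 1)
})

test_that("identical seeds give bit-identical noisy runs", {
  p <- disinh()
  run <- function(seed) {
    set.seed(seed)
    simulate_circuit(p, list(stim_train("glutamate", 1, 20, 1)),
                     t_end = 200, mode = "ed_only", noise = TRUE,
                     record_stride = 0.1)$trace
  }
  expect_identical(run(42), run(42))
  expect_false(identical(run(42)$v_e, run(43)$v_e))
})

test_that("noise perturbs only the voltage trajectory scale-appropriately", {
  p <- disinh()
  set.seed(7)
  sim <- simulate_circuit(p, list(), t_end = 1000, mode = "ed_only",
                          noise = TRUE, record_stride = 0.1)
  dev <- sim$trace$v_e + 68
  expect_gt(sd(dev), 0.5)       # noise visible
  expect_lt(max(abs(dev)), 15)  # but bounded fluctuation
})

test_that("divergent trajectories abort with a diagnostic", {
  bad <- disinh(ed = list(g_leak = -5))   # negative leak: runaway
  expect_error(
    suppressWarnings(
      simulate_circuit(bad, list(stim_train("glutamate", 1, 10, 5)),
                       t_end = 3000, mode = "ed_only")),
    "diverged.*v_e")
})

test_that("windowed integration agrees with full integration", {
  p <- disinh()
  # disinhibition-style protocol compressed to 20-s pulse spacing
  gap <- 20000
  ev <- lapply(0:5 * gap, function(tg) {
    trains <- list(stim_train("glutamate", 1, 0, 1))
    if (tg < 2 * gap || tg >= 5 * gap)
      trains <- c(trains, list(stim_train("GABA", 1, 2, 1)))
    list(t = tg, trains = trains)
  })
  wi <- windowed_integrate(p, ev, mode = "ed_only", t_total = 6 * gap,
                           window = 2000)
  fu <- integrate_protocol_full(p, ev, mode = "ed_only", t_end = 6 * gap)
  expect_equal(wi$final_g, unname(fu$final[["g_ampa"]]), tolerance = 0.01)
  expect_gt(wi$final_g, 4.5)   # the disinhibited pulses potentiated

  # full-network copairing events
  pc <- copair()
  evc <- lapply(0:2 * gap, function(tg) {
    list(t = tg, trains = list(stim_train("glutamate", 1, 100, 5),
                               stim_train("ACh", 1, 0, 5)))
  })
  wic <- windowed_integrate(pc, evc, mode = "full", t_total = 3 * gap)
  fuc <- integrate_protocol_full(pc, evc, mode = "full", t_end = 3 * gap)
  expect_equal(wic$final_g, unname(fuc$final[["g_ampa"]]), tolerance = 0.01)
})

test_that("windowed integration refuses windows too short to relax", {
  p <- disinh()
  ev <- list(list(t = 0, trains = list(stim_train("glutamate", 1, 0, 1))),
             list(t = 60000,
                  trains = list(stim_train("glutamate", 1, 0, 1))))
  expect_error(
    windowed_integrate(p, ev, mode = "ed_only", window = 40),
    "window too short")
})

test_that("single-event windowed run equals a plain simulation", {
  p <- disinh()
  ev <- list(list(t = 0, trains = list(stim_train("glutamate", 1, 0, 1))))
  wi <- windowed_integrate(p, ev, mode = "ed_only", window = 2000)
  sim <- simulate_circuit(p, list(stim_train("glutamate", 1, 100, 1)),
                          t_end = 2100, mode = "ed_only")
  expect_equal(wi$final_g, unname(sim$final[["g_ampa"]]), tolerance = 1e-10)
})

test_that("replicate runner averages pointwise and flags seed reuse", {
  p <- disinh()
  fun <- function(seed) {
    sim <- simulate_circuit(p, list(stim_train("glutamate", 1, 20, 1)),
                            t_end = 100, mode = "ed_only", noise = TRUE,
                            record_stride = 1)
    sim$trace[, c("t", "v_e")]
  }
  rr <- run_replicates(fun, n = 3, seeds = c(1, 2, 3))
  expect_equal(nrow(rr$mean), nrow(rr$replicates[[1]]))
  expect_equal(rr$mean$v_e,
               (rr$replicates[[1]]$v_e + rr$replicates[[2]]$v_e +
                  rr$replicates[[3]]$v_e) / 3)
  expect_warning(run_replicates(fun, n = 2, seeds = c(5, 5)), "duplicate")
  # n = 1 without noise reduces to the deterministic trace
  fun0 <- function(seed) {
    simulate_circuit(p, list(), t_end = 50, mode = "ed_only",
                     record_stride = 1)$trace[, c("t", "v_e")]
  }
  rr0 <- run_replicates(fun0, n = 1, seeds = 1)
  expect_identical(rr0$mean, rr0$replicates[[1]])
})
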