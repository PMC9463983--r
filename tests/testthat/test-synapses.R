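# Receptor kinetics, transmitter release functions and stimulus trains.

test_that("two-state gates relax to the closed-form steady state", {
  # no drive: stays shut
  r <- 0
  for (i in 1:100) r <- gate_update(r, 0, 5, 0.18, 0.05)
  expect_equal(r, 0)
  # sustained 1 mM: alpha T / (alpha T + beta)
  step_to_ss <- function(alpha, beta) {
    r <- 0
    for (i in 1:40000) r <- gate_update(r, 1, alpha, beta, 0.02)
    r
  }
  expect_equal(step_to_ss(5, 0.18), 5 / 5.18, tolerance = 1e-6)
  expect_equal(step_to_ss(0.072, 0.0066), 0.072 / 0.0786, tolerance = 1e-4)
  expect_error(gate_update(0.5, 1, 1.1, 0.19, 0), "dt")
})

test_that("alpha7 activation follows Hill steady state with tau = 5 ms", {
  hill <- function(a) a^1.73 / (0.08^1.73 + a^1.73)   # independent oracle
  r <- 0
  for (i in 1:5000) r <- alpha7_activation(0.08, r, 0.01)
  expect_equal(r, 0.5, tolerance = 1e-4)
  expect_equal(alpha7_activation(0, 0, 1) , 0)
  r <- 0
  for (i in 1:5000) r <- alpha7_activation(1, r, 0.01)
  expect_equal(r, hill(1), tolerance = 1e-4)
  expect_equal(hill(1), 0.9875, tolerance = 1e-3)
  # relaxation time constant: one tau (5 ms) covers 1 - 1/e of the gap
  r <- 0
  for (i in 1:500) r <- alpha7_activation(1, r, 0.01)
  expect_equal(r / hill(1), 1 - exp(-1), tolerance = 1e-3)
})

test_that("release functions are bounded, monotone sigmoids", {
  rp <- release_params()
  expect_equal(release_from_voltage(2, rp), 0.5)
  expect_equal(release_from_voltage(-60, rp), 1 / (1 + exp(12.4)))
  expect_equal(release_from_voltage(1e4, rp), 1)
  v <- seq(-100, 60, by = 1)
  expect_true(all(diff(release_from_voltage(v, rp)) > 0))
  expect_true(all(release_from_voltage(v, rp) <= rp$T_max))

  expect_equal(release_from_calcium(4e-5, rp), 0.5)
  expect_equal(release_from_calcium(0, rp), 1 / (1 + exp(40)))
  expect_lt(abs(release_from_calcium(1e-4, rp) - 1), 1e-20)
  ca <- seq(0, 2e-4, by = 1e-6)
  expect_true(all(diff(release_from_calcium(ca, rp)) >= 0))
})

test_that("NMDA magnesium block is increasing in V and vanishes with Mg", {
  expect_equal(nmda_block(c(-90, 0, 50), Mg = 0), c(1, 1, 1))
  expect_equal(nmda_block(0, 1), 1 / (1 + 1 / 3.57))
  expect_equal(nmda_block(-70, 1), 1 / (1 + exp(0.062 * 70) / 3.57))
  v <- seq(-100, 40, by = 1)
  expect_true(all(diff(nmda_block(v, 1)) > 0))
})

test_that("synaptic currents respect reversal and closed channels", {
  expect_equal(synaptic_current(0.7, -80, 7, E_rev = -80), 0)
  expect_equal(synaptic_current(0, -60, 7, E_rev = 0), 0)
  expect_lt(synaptic_current(0.5, -60, 4, 0), 0)   # inward below reversal
})

test_that("voltage-clamped glutamate pulse reproduces the AMPA/NMDA
          current calibration", {
  # at -70 mV a 1 mM, 10 ms glutamate pulse was used to set the E_D
  # conductances: AMPA ~240 pA, NMDA ~40 pA
  sim <- simulate_circuit(disinh(), list(stim_train("glutamate", 1, 50, 10)),
                          t_end = 200, mode = "ed_only", clamp_ed = -70,
                          record_stride = 0.02)
  expect_equal(max(abs(sim$trace$i_ampa)), 240, tolerance = 0.05)
  expect_equal(max(abs(sim$trace$i_nmda)), 40, tolerance = 0.05)
})

test_that("stimulus trains evaluate square and alpha shapes", {
  sq <- stim_train("glutamate", 1, onsets = 100, duration = 5)
  expect_equal(stimulus_value(sq, c(99.9, 100, 102, 104.99, 105, 200)),
               c(0, 1, 1, 1, 0, 0))                 # half-open interval
  al <- stim_train("ACh", 1, onsets = 0, shape = "alpha", decay = 4)
  expect_equal(stimulus_value(al, 4), exp(-1))
  expect_equal(stimulus_value(al, 0), 1)
  # overlapping squares cap at the amplitude (combine by maximum)
  ov <- stim_train("GABA", 0.5, onsets = c(10, 12), duration = 5)
  expect_equal(stimulus_value(ov, 13), 0.5)
  expect_error(stim_train("GABA", 1, onsets = c(5, 5)))
})

test_that("simplified calcium-driven release matches an equal-area square
          transient in evoked receptor activation", {
  # a 0.10 uM (1e-4 mM), 1 ms calcium square saturates the release sigmoid;
  # the reference transient is a square GABA pulse of equal transmitter area
  rp <- release_params()
  dt <- 0.01
  tt <- seq(0, 60, by = dt)
  ca <- ifelse(tt >= 5 & tt < 6, 1e-4, 0)
  gaba <- release_from_calcium(ca, rp)
  area <- sum(gaba) * dt
  ref <- ifelse(tt >= 5 & tt < 5 + area, 1, 0)      # equal-area square
  act <- function(tr) {
    r <- 0; peak <- 0
    for (i in seq_along(tt)) {
      r <- gate_update(r, tr[i], 5, 0.18, dt)
      peak <- max(peak, r)
    }
    peak
  }
  expect_lt(abs(act(gaba) - act(ref)) / act(ref), 0.2)
})
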