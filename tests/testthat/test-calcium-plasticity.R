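# CICR, dendritic calcium, the AMPAR plasticity rule and its analysis
# statistics.

test_that("CICR step arithmetic and conservation", {
  cp <- cicr_params()
  # closed store channel at zero calcium, store at rest: nothing moves
  s <- cicr_step(0, cp$ca_is_rest, 0, cp, dt = 0.02)
  expect_equal(s$ca_i, 0)
  expect_equal(s$ca_is, cp$ca_is_rest)
  # influx arithmetic: dCa = -xi' a' I = 2.1e-6 * 0.05 * 35 per ms
  s <- cicr_step(0, cp$ca_is_rest, -35, cp, dt = 1)
  expect_equal(s$ca_i, 2.1e-6 * 0.05 * 35, tolerance = 1e-12)
  # cytosol/store exchange is antisymmetric: with leak and influx disabled
  # the total calcium is conserved
  cons <- cicr_params(tau_ca_o = 1e15, tau_is = 1e15)
  ca_i <- 1e-4; ca_is <- 4e-4
  tot0 <- ca_i + ca_is
  for (i in 1:5000) {
    s <- cicr_step(ca_i, ca_is, 0, cons, dt = 0.02)
    ca_i <- s$ca_i; ca_is <- s$ca_is
  }
  expect_equal(ca_i + ca_is, tot0, tolerance = 1e-12)
  expect_gt(ca_i, 1e-4)   # store released into cytosol
})

test_that("dendritic calcium decays with tau = 12 ms and has the stated
          driven fixed point", {
  dp <- dendritic_ca_params(xi = 0.045)
  ca <- 1
  n_half <- round(12 * log(2) / 0.01)
  for (i in 1:n_half) ca <- dendritic_ca_step(ca, 0, dp, 0.01)
  expect_equal(ca, 0.5, tolerance = 1e-3)
  expect_equal(dendritic_ca_step(0, 0, dp, 0.02), 0)
  # sustained -10 pA: fixed point xi * alpha * 10 * tau = 0.54 uM
  ca <- 0
  for (i in 1:20000) ca <- dendritic_ca_step(ca, -10, dp, 0.02)
  expect_equal(ca, 0.54, tolerance = 1e-6)
})

test_that("learning rate is monotone with the stated limits", {
  pp <- plasticity_params()
  expect_equal(learning_rate(1e6, pp), 1, tolerance = 1e-6)
  expect_equal(learning_rate(0, pp), 1 / (1e4 + 1))
  expect_equal(learning_rate(0.31, pp),
               1 / (1.5e-6 / (1.5e-10 + 0.31^13) + 1))
  expect_equal(learning_rate(0.31, pp), 0.14, tolerance = 0.01)
  ca <- seq(0, 2, by = 0.01)
  expect_true(all(diff(learning_rate(ca, pp)) >= 0))
})

test_that("plasticity drift Omega has the three-plateau structure", {
  pp <- plasticity_params()   # disinhibition preset gamma_up
  expect_lt(abs(omega(0, pp)), 1e-60)
  expect_equal(omega(0.325, pp), -pp$gamma_down, tolerance = 1e-3)
  expect_equal(omega(1, pp), pp$gamma_up - pp$gamma_down, tolerance = 1e-6)
  expect_equal(omega(1, pp), 0.0324, tolerance = 1e-3)
  ca <- seq(0, 2, by = 1e-3)
  om <- omega(ca, pp)
  expect_true(all(om >= -pp$gamma_down - 1e-12))
  expect_true(all(om <= pp$gamma_up - pp$gamma_down + 1e-12))
})

test_that("conductance dynamics: fixed point, slow decay, no bistability", {
  pp <- plasticity_params()
  expect_equal(plasticity_step(4, 0, pp, 0.02), 4)    # exact fixed point
  # decay rate at zero calcium: eta(0) sigma (g - g0)
  g1 <- plasticity_step(8.83, 0, pp, 1)
  expect_equal(g1 - 8.83, -1 / (1e4 + 1) * 0.004 * 4.83, tolerance = 1e-9)
  # repeated bounded calcium transients followed by silence: g always
  # relaxes back toward g0 (single stable fixed point)
  g <- 4
  for (pulse in 1:5) {
    for (i in 1:1500) {   # 30 ms transient, peak 0.5 uM
      ca <- 0.5 * exp(-i * 0.02 / 12)
      g <- plasticity_step(g, ca, pp, 0.02)
    }
  }
  expect_gt(g, 4)
  gs <- numeric(100)
  for (k in 1:100) {
    for (i in 1:500) g <- plasticity_step(g, 0, pp, 1000)
    gs[k] <- g
  }
  expect_true(all(diff(gs) < 0))          # monotone decay
  expect_equal(gs[100], 4, tolerance = 1e-3)
})

test_that("weighted area ratio matches a fine-grid trapezoid oracle", {
  pp <- plasticity_params()
  oracle <- function(tt, ca) {
    # independent masked-trapezoid implementation
    w <- ca / (pp$P1 / (pp$P2 + ca^pp$P3) + pp$P4)
    num <- den <- 0
    for (i in seq_len(length(tt) - 1)) {
      if (ca[i] > pp$theta_up && ca[i + 1] > pp$theta_up) {
        num <- num + (tt[i + 1] - tt[i]) * (w[i] + w[i + 1]) / 2
      } else if (ca[i] > pp$theta_down && ca[i + 1] > pp$theta_down &&
                 ca[i] <= pp$theta_up && ca[i + 1] <= pp$theta_up) {
        den <- den + (tt[i + 1] - tt[i]) * (w[i] + w[i + 1]) / 2
      }
    }
    num / den
  }
  tri <- function(dt) {
    tt <- seq(0, 20, by = dt)
    ca <- 0.40 * (1 - abs(tt - 10) / 10)
    list(t = tt, ca = ca)
  }
  coarse <- tri(0.02)
  fine <- tri(0.001)
  r <- weighted_area_ratio(coarse$t, coarse$ca, pp)
  expect_equal(r, oracle(coarse$t, coarse$ca), tolerance = 1e-12)
  expect_equal(r, oracle(fine$t, fine$ca), tolerance = 5e-3)
  # trace that never leaves the sub-onset region is unclassifiable
  expect_true(is.nan(weighted_area_ratio(coarse$t, coarse$ca * 0.5, pp)))
  # supra-onset area with no between-onset area: infinite ratio
  tt <- seq(0, 10, by = 0.1)
  expect_equal(weighted_area_ratio(tt, rep(0.5, length(tt)), pp), Inf)
})

test_that("the potentiation threshold exceeds the potentiation onset and
          collapses onto it without AMPAR removal", {
  tp <- acc("theta_pot", find_theta_pot(disinh()))
  expect_gt(tp$theta_pot, 0.34)
  # with gamma_down = 0 any crossing of theta_up potentiates
  p0 <- disinh(plasticity = list(gamma_down = 1e-9))
  tp0 <- find_theta_pot(p0)
  expect_lt(tp0$theta_pot, 0.345)
})
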