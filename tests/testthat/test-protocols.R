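# Protocol builders: disinhibition, copairing, pairing scans, phase maps.

test_that("paired pulses at baseline conductance are plasticity-neutral", {
  p <- disinh()
  sp <- single_pairing_delta(p, g_init = 4)
  expect_lt(abs(sp$dg), 1e-3)
  expect_lt(sp$ca_max, p$plasticity$theta_down)
  # glutamate alone at the same conductance is not neutral
  sp0 <- single_pairing_delta(p, g_init = 4, gaba_amp = 0)
  expect_gt(sp0$dg, 0.1)
  expect_gt(sp0$ca_max, p$plasticity$theta_up)
  # with no drive at all nothing happens
  spz <- single_pairing_delta(p, g_init = 0, gaba_amp = 0, glu_amp = 0)
  expect_equal(spz$ca_max, 0)
  # only the slow relaxation toward g0 moves g; nothing synaptic
  expect_lt(abs(spz$dg_60), 2e-4)
})

test_that("matched glutamate/GABA amplitude-duration pairs stay neutral", {
  p <- disinh()
  for (cfg in list(c(0.5, 2), c(2, 0.5))) {
    sp <- single_pairing_delta(p, g_init = 4, gaba_amp = cfg[1],
                               glu_amp = cfg[1], glu_dur = cfg[2],
                               gaba_dur = cfg[2])
    expect_lt(abs(sp$dg), 1e-3)
  }
})

test_that("a zero-length disinhibition period leaves everything at
          baseline", {
  run <- acc("disinh0",
             run_disinhibition(disinh(), period_min = 0, total_min = 6))
  expect_equal(run$final_g, 4, tolerance = 1e-4)
  expect_lt(diff(range(run$epsc$amp)) / mean(run$epsc$amp), 1e-4)
})

test_that("disinhibition conductance endpoint grows with the period", {
  r5 <- acc("disinh5", run_disinhibition(disinh(), period_min = 5,
                                         total_min = 12))
  r8 <- acc("disinh8", run_disinhibition(disinh(), period_min = 8,
                                         total_min = 15))
  expect_gt(r5$g_end_window, 4)
  expect_gt(r8$g_end_window, r5$g_end_window)
  expect_gt(r8$epsc_end_window, r5$epsc_end_window)
  expect_gt(r5$epsc_end_window, r5$baseline)
})

test_that("zero-length copairing window gives a flat EPSC series", {
  run <- run_copairing(copair(), t_pair_min = 0, pair_start_min = 2,
                       total_min = 6)
  expect_lt(diff(range(run$epsc$amp)) / mean(run$epsc$amp), 1e-4)
  expect_equal(run$final_g, 4, tolerance = 1e-4)
})

test_that("copairing potentiates and the alpha7 knockout abolishes it", {
  run <- acc("copair3",
             run_copairing(copair(), t_pair_min = 3, pair_start_min = 3,
                           total_min = 12))
  post <- run$epsc[run$epsc$t_ms / 60000 >= run$pair_end_min, ]
  expect_gt(min(post$amp), run$baseline * 1.2)
  ko <- acc("copair3_ko",
            run_copairing(copair(receptors = list(g_a7 = 1.7)),
                          t_pair_min = 3, pair_start_min = 3,
                          total_min = 12))
  post_ko <- ko$epsc[ko$epsc$t_ms / 60000 >= ko$pair_end_min, ]
  expect_lt(max(abs(post_ko$amp - ko$baseline)) / ko$baseline, 0.05)
})

test_that("post-pairing potentiation is non-decreasing in the alpha7
          conductance", {
  elevation <- vapply(c(1.7, 2.4, 3), function(ga) {
    run <- acc(paste0("ko_", ga),
               run_copairing(copair(receptors = list(g_a7 = ga)),
                             t_pair_min = 3, pair_start_min = 3,
                             total_min = 9))
    run$final_g - 4
  }, numeric(1))
  expect_true(all(diff(elevation) >= -1e-9))
  expect_lt(elevation[1], 1e-3)   # knockout: none
  expect_gt(elevation[3], 0.5)    # wild type: strong
})

test_that("single-pairing lag scan recovers the suppression-window
          structure", {
  sc <- acc("scan_single", scan_pairing_dt(copair()))
  tab <- sc$table
  expect_equal(tab$region[tab$delta_t == -40], "none")
  expect_equal(tab$region[tab$delta_t == 0], "depression")
  expect_equal(tab$region[tab$delta_t == 100], "potentiation")
  expect_equal(tab$region[tab$delta_t == 220], "none")
  b <- sc$boundaries
  expect_true(any(b$to == "potentiation"))
  expect_true(any(b$from == "potentiation"))
  # potentiation region is contiguous: exactly one entry and one exit
  expect_equal(sum(b$to == "potentiation"), 1)
  expect_equal(sum(b$from == "potentiation"), 1)
})

test_that("two-source calcium pairing potentiates without either pulse
          crossing the potentiation threshold", {
  p <- disinh()
  tp <- acc("theta_pot", find_theta_pot(p))
  inj <- stim_train("calcium", 0.012, 80, 35)
  sp <- single_pairing_delta(p, g_init = 6.9, ca_inj = inj, t_post = 800)
  tr <- sp$sim$trace
  pk1 <- max(tr$ca_d[tr$t < 125])
  pk2 <- max(tr$ca_d[tr$t >= 125])
  expect_lt(pk1, tp$theta_pot)
  expect_lt(pk2, tp$theta_pot)
  expect_gt(sp$dg, 0)          # yet net potentiation
  expect_gt(sp$ratio, 3)       # and the ratio classifies it as such
})

test_that("GABA phase map: zero-GABA column is lag-independent and maps
          depend on the conductance state", {
  pm <- acc("phase_map",
             scan_gaba_phase_map(disinh(), g_inits = c(4, 6.9, 8.83),
                                 gaba_max_grid = c(0, 1),
                                 lag_grid = seq(-5, 40, by = 5)))
  z <- pm[pm$gaba_max == 0, ]
  for (g in unique(z$g_init)) {
    expect_lt(diff(range(z$dg[z$g_init == g])), 1e-6)
  }
  # state dependence: the same pairing has different outcomes at the three
  # conductance states (sign pattern over the lag grid differs)
  d1 <- pm[pm$gaba_max == 1, ]
  pat <- vapply(c(4, 6.9, 8.83), function(g)
    paste(sign(round(d1$dg[d1$g_init == g], 2)), collapse = ","),
    character(1))
  expect_equal(length(unique(pat)), 3)
})
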