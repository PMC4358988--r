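# Synapse kinetics, stimulation protocols, and the simulation engine.

test_that("NMDA conductance matches independent evaluation of its formula", {
  # direct evaluation, written out separately from the implementation
  direct <- function(v, t, g) g * (exp(-t / 70) - exp(-t / 3)) /
    (1 + 0.3 * exp(-0.08 * v))
  expect_equal(nmda_conductance(v = 12, t = 0, g_max = 1), 0)
  expect_equal(nmda_conductance(0, 10, 1),
               (exp(-10 / 70) - exp(-10 / 3)) / 1.3, tolerance = 1e-12)
  expect_equal(nmda_conductance(0, 10, 1), 0.6394, tolerance = 1e-4)
  expect_equal(nmda_conductance(-65, 10, 1), 0.0150, tolerance = 1e-3)
  for (v in c(-80, -40, 0, 20))
    for (t in c(0.5, 5, 50))
      expect_equal(nmda_conductance(v, t, 2.5), direct(v, t, 2.5))
  # strictly increasing in v at fixed t; bounded by g_max
  v <- seq(-90, 30, by = 5)
  g <- nmda_conductance(v, t = 10, g_max = 1)
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g < 1))
  # 0 at onset, positive after, vanishing at long times
  expect_equal(nmda_conductance(-60, 0, 3), 0)
  expect_gt(nmda_conductance(-60, 1, 3), 0)
  expect_lt(nmda_conductance(-60, 2000, 3), 1e-8)
  expect_error(nmda_conductance(0, -1, 1), "non-negative")
  expect_error(nmda_conductance(0, 1, -1), "non-negative")
})

test_that("AMPA conductance is a 0.5 ms exponential with instantaneous rise", {
  expect_equal(ampa_conductance(0, 2), 2)
  expect_equal(ampa_conductance(0.5, 1), exp(-1))
  expect_equal(ampa_conductance(5, 1), exp(-10))
  expect_error(ampa_conductance(-0.1, 1), "non-negative")
})

test_that("barrages have the requested composition and are reproducible", {
  ev <- make_barrage(100, 175, window = 100, seed = 7)
  expect_equal(sum(ev$compartment == "dend"), 100)
  expect_equal(sum(ev$compartment == "soma"), 175)
  expect_true(all(ev$onset >= 0 & ev$onset <= 100))
  expect_equal(ev$g_nmda, ev$g_ampa)  # NMDA:AMPA ratio 1:1
  ev2 <- make_barrage(100, 175, window = 100, seed = 7)
  expect_identical(ev, ev2)
  ev3 <- make_barrage(100, 175, window = 100, seed = 8)
  expect_false(identical(ev$onset, ev3$onset))
  empty <- make_barrage(0, 0, window = 100, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(make_barrage(-1, 0, 100, 1), "non-negative")
  # barrage generation leaves the session RNG untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_barrage(5, 5, 100, seed = 99))
  expect_identical(runif(1), before)
})

test_that("scale_ca scales only the Ca2+ conductance, multiplicatively", {
  p <- default_params()
  expect_identical(scale_ca(p, 1), p)
  p5 <- scale_ca(p, 0.5)
  expect_equal(p5$ca_scale, 0.5)
  expect_equal(p5$g_ca, p$g_ca)  # tracked via ca_scale, g_ca untouched
  expect_equal(scale_ca(p5, 0.5)$ca_scale, 0.25)
  expect_error(scale_ca(p, 1.5), "\\[0, 1\\]")
  expect_error(scale_ca(p, -0.1), "\\[0, 1\\]")
})

test_that("pulse-train protocol arithmetic follows the frequency", {
  pr <- protocol_pulse_train(amplitude = 7000, frequency = 100)
  expect_equal(pr$interval, 10)
  expect_equal(pr$duration, 2 * 10 + 2)
  expect_error(protocol_pulse_train(amplitude = 1, frequency = 600,
                                    pulse_width = 2), "interval")
  run <- run_cf_protocol(default_params(), freqs = c(70, 100),
                         pulse_amp = 7000)
  expect_length(run, 2)
  expect_true(all(vapply(run, function(r) r$n_spikes, numeric(1)) == 3))
})

test_that("the resting state is a stable fixed point", {
  sim <- simulate(protocol_dc_step("soma", 0, 800), default_params(),
                  total = 1000)
  for (tr in list(sim$soma, sim$dend)) {
    v <- tr$v[trace_time(tr) > 200]  # after settling
    expect_lt(max(v) - min(v), 0.5)
  }
  expect_equal(length(sim$soma$v), 1000 / 0.025 + 1)
})

test_that("suprathreshold somatic DC drives a regular spike train", {
  sim <- simulate(protocol_dc_step("soma", 1800, 1000),
                  default_params(), total = 1300)
  sp <- detect_spikes(sim$soma)
  tt <- sp$times[sp$times > 200 & sp$times < 1100]  # drop onset transient
  expect_gt(length(tt), 20)
  expect_lt(sd(diff(tt)) / mean(diff(tt)), 0.2)
})

test_that("the calibration barrage elicits the coincidence-detection counts", {
  p <- default_params()
  count <- function(ev, ca = 1) {
    sim <- simulate(protocol_barrage(ev), scale_ca(p, ca), total = 300)
    length(detect_spikes(sim$soma)$times)
  }
  n_both <- count(calibration_barrage())
  expect_equal(n_both, 4)
  expect_equal(count(calibration_barrage(n_tuft = 0)), 1)
  expect_equal(count(calibration_barrage(n_basal = 0)), 0)
  expect_lt(count(calibration_barrage(), ca = 0.5), n_both)
})

test_that("halving the integration step preserves the burst spike count", {
  p <- default_params()
  ev <- calibration_barrage()
  n1 <- length(detect_spikes(simulate(protocol_barrage(ev), p,
                                      dt = 0.025, total = 300)$soma)$times)
  n2 <- length(detect_spikes(simulate(protocol_barrage(ev), p,
                                      dt = 0.0125, total = 300)$soma)$times)
  expect_equal(n1, n2)
})

test_that("nested sweep pools subset consistently", {
  pool <- make_barrage(200, 300, 100, seed = 3)
  sub <- tuftburst:::subset_barrage(pool, 50, 100)
  expect_equal(sum(sub$compartment == "dend"), 50)
  expect_equal(sum(sub$compartment == "soma"), 100)
  # the subset is a prefix: shared events are identical
  sub2 <- tuftburst:::subset_barrage(pool, 60, 120)
  expect_equal(sub$onset[sub$compartment == "dend"],
               sub2$onset[sub2$compartment == "dend"][1:50])
  expect_error(tuftburst:::subset_barrage(pool, 300, 100), "exceed")
})

test_that("parameter YAML round-trips through read/write", {
  p <- default_params()
  path <- tempfile(fileext = ".yaml")
  write_params(p, path)
  expect_equal(read_params(path), p)
})

test_that("the fixed-step integrator agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  amp <- 100  # subthreshold somatic step
  # same equations, independent integrator (lsoda, adaptive step)
  rhs <- function(t, y, parms) {
    with(as.list(y), {
      i_inj <- if (t >= 100 && t < 400) amp else 0
      vtrap <- function(x, yy) ifelse(abs(x / yy) < 1e-6,
                                      yy * (1 - x / yy / 2),
                                      x / (1 - exp(-x / yy)))
      am <- 0.1 * vtrap(vs + 35, 10); bm <- 4 * exp(-(vs + 60) / 18)
      minf <- am / (am + bm)
      ah <- 0.07 * exp(-(vs + 58) / 20)
      bh <- 1 / (1 + exp(-(vs + 18) / 10))
      an <- 0.01 * vtrap(vs + 34, 10); bn <- 0.125 * exp(-(vs + 44) / 80)
      mca_inf <- 1 / (1 + exp(-(vd - p$mca_mid) / p$mca_slope))
      q_inf <- 1 / (1 + exp(-(vd - p$q_mid) / p$q_slope))
      r_inf <- 1 / (1 + exp((vd + 82) / 7))
      z_inf <- 1 / (1 + exp(-(vs - p$z_mid) / 4))
      w_inf <- 1 / (1 + exp(-(vs + 45) / 5))
      g_na <- p$g_na * minf^3 * h; g_kd <- p$g_kd * n^4
      g_ca <- p$g_ca * p$ca_scale * mca^2
      g_ks <- p$g_ks * q; g_hc <- p$g_h * r
      g_z <- p$g_adapt * z + p$g_m * w
      i_s <- p$gl_soma * (p$el_soma - vs) + g_na * (p$e_na - vs) +
        g_kd * (p$e_k - vs) + g_z * (p$e_k - vs) +
        p$g_c * (vd - vs) + p$g_cb * (vb - vs) + i_inj
      i_d <- p$gl_dend * (p$el_dend - vd) + g_ca * (p$e_ca - vd) +
        g_ks * (p$e_k - vd) + g_hc * (p$e_h - vd) + p$g_c * (vs - vd)
      i_b <- p$gl_bas * (p$el_bas - vb) + p$g_cb * (vs - vb)
      list(c(vs = i_s / p$c_soma, vd = i_d / p$c_dend, vb = i_b / p$c_bas,
             h = 5 * (ah * (1 - h) - bh * h),
             n = 5 * (an * (1 - n) - bn * n),
             mca = (mca_inf - mca) / p$tau_mca,
             q = (q_inf - q) /
               ifelse(q_inf > q, p$tau_q, p$tau_q_off),
             r = (r_inf - r) / 50,
             z = (z_inf - z) /
               ifelse(z_inf > z, p$tau_z_on, p$tau_z_off),
             w = (w_inf - w) / p$tau_m))
    })
  }
  v0 <- p$el_soma
  ah0 <- 0.07 * exp(-(v0 + 58) / 20); bh0 <- 1 / (1 + exp(-(v0 + 18) / 10))
  an0 <- 0.01 * (v0 + 34) / (1 - exp(-(v0 + 34) / 10))
  bn0 <- 0.125 * exp(-(v0 + 44) / 80)
  y0 <- c(vs = v0, vd = p$el_dend, vb = p$el_bas,
          h = ah0 / (ah0 + bh0), n = an0 / (an0 + bn0),
          mca = 1 / (1 + exp(-(v0 - p$mca_mid) / p$mca_slope)),
          q = 1 / (1 + exp(-(v0 - p$q_mid) / p$q_slope)),
          r = 1 / (1 + exp((v0 + 82) / 7)), z = 0,
          w = 1 / (1 + exp(-(v0 + 45) / 5)))
  times <- seq(0, 500, by = 1)
  ref <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-8)
  sim <- simulate(protocol_dc_step("soma", amp, 300), p, total = 500)
  mine <- sim$soma$v[match(times, trace_time(sim$soma))]
  expect_lt(max(abs(mine - ref[, "vs"])), 0.2)
})
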