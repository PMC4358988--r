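# Feature extraction: spike detection, ISI statistics, plateau width, ADP,
# the critical-frequency sigmoid fit, event ordering, slope test.

test_that("spike detection finds template spikes and honors the refractory rule", {
  expect_length(detect_spikes(flat_trace())$times, 0)
  spec <- trace_spec(spike_times = c(10, 20, 30, 40), sigma = 0,
                     duration = 60, dt = 0.05)
  tr <- gen_trace(spec)
  sp <- detect_spikes(tr)
  expect_length(sp$times, 4)
  expect_equal(sp$times, c(10, 20, 30, 40), tolerance = 0.06)
  # two peaks 1 ms apart with a 2 ms refractory gap: keep the larger
  v <- rep(-70, 201)
  v[51] <- 10   # t = 5 ms
  v[61] <- 20   # t = 6 ms, larger
  tr2 <- voltage_trace(v, dt = 0.1)
  sp2 <- detect_spikes(tr2, refractory = 2)
  expect_length(sp2$times, 1)
  expect_equal(sp2$peaks, 20)
})

test_that("ISI CV follows its definition and invariances", {
  expect_equal(isi_cv(spike_train(c(0, 10, 20, 30))), 0)
  expect_equal(isi_cv(spike_train(c(0, 5, 20))), sqrt(50) / 10)
  expect_true(is.na(isi_cv(spike_train(c(0, 10)))))
  tr <- spike_train(c(3, 9, 21, 30))
  expect_equal(isi_cv(spike_train(2 * tr$times)), isi_cv(tr))
  expect_equal(isi_cv(spike_train(tr$times + 100)), isi_cv(tr))
})

test_that("output frequency follows the (N-1)/span convention", {
  expect_equal(output_frequency(spike_train(numeric(0))), 0)
  expect_equal(output_frequency(spike_train(42)), 0)
  expect_equal(output_frequency(spike_train(c(0, 10, 20, 30))), 100)
  expect_equal(output_frequency(spike_train(c(0, 5))), 200)
  tr <- spike_train(c(5, 12, 30, 41))
  expect_equal(output_frequency(spike_train(tr$times + 57)),
               output_frequency(tr))
  expect_equal(output_frequency(spike_train(2 * tr$times)),
               output_frequency(tr) / 2)
  expect_equal(output_frequency(spike_train(c(1, 2, 3)), mode = "count",
                                window = 100), 30)
})

test_that("plateau width uses the fractional 20%-above-baseline rule", {
  # square plateau -70 -> -40 mV for 50 ms: threshold -64 mV
  spec <- trace_spec(plateaus = data.frame(onset = 20, duration = 50,
                                           level = 30),
                     sigma = 0, duration = 100, dt = 0.05)
  expect_equal(dp_width(gen_trace(spec, "dend"), c(0, 100)), 50,
               tolerance = 0.01)
  expect_equal(dp_width(flat_trace(compartment = "dend"), c(0, 100)), 0)
  spec2 <- trace_spec(plateaus = data.frame(onset = c(5, 45),
                                            duration = c(20, 50),
                                            level = c(30, 30)),
                      sigma = 0, duration = 120, dt = 0.05)
  expect_equal(dp_width(gen_trace(spec2, "dend"), c(0, 120)), 50,
               tolerance = 0.01)
  # never exceeds the stimulus window
  expect_lte(dp_width(gen_trace(spec2, "dend"), c(40, 100)), 60)
  expect_error(dp_width(flat_trace(), c(-10, 200)), "within the trace")
})

test_that("ADP amplitude is read at a fixed latency against baseline", {
  expect_equal(adp_size_at(flat_trace(), last_spike = 60, latency = 10), 0)
  # exponential ADP with known geometry
  spec <- trace_spec(spike_times = 50, adp_amp = 6, adp_tau = 20,
                     sigma = 0, duration = 150, dt = 0.05)
  tr <- gen_trace(spec)
  expect_equal(adp_size_at(tr, 50, 10, baseline = -70),
               6 * exp(-10 / 20), tolerance = 0.01)
  expect_error(adp_size_at(tr, 50, 200), "outside the trace")
})

test_that("the CF sigmoid fit recovers known parameters", {
  d <- gen_cf_dataset(inflection = 84, plateau_low = 1, plateau_high = 5.4,
                      slope = 6, sigma = 0)
  fit <- fit_cf_curve(d$freqs, d$adps)
  expect_equal(fit$critical_frequency, 84, tolerance = 1e-3)
  expect_equal(fit$adp_size, 4.4, tolerance = 1e-3)
  expect_false(fit$degenerate)
  flat <- fit_cf_curve(seq(10, 200, 10), rep(2, 20) + 1e-9 * (1:20))
  expect_true(flat$degenerate)
})

test_that("CF inflection recovery is accurate under measurement noise", {
  errs <- vapply(1:100, function(s) {
    d <- gen_cf_dataset(sigma = 0.2, seed = s)
    fit <- fit_cf_curve(d$freqs, d$adps, n_restarts = 10, seed = s)
    abs(fit$critical_frequency - d$truth$inflection)
  }, numeric(1))
  expect_lt(median(errs), 2)
})

test_that("event ordering separates dendrite-first from soma-first", {
  # dendritic plateau starting 5 ms before the first somatic spike
  dend <- gen_trace(trace_spec(plateaus = data.frame(onset = 40,
                                                     duration = 60,
                                                     level = 30),
                               sigma = 0, duration = 150, dt = 0.05),
                    "dend")
  soma <- spike_train(c(45, 55, 65))
  expect_equal(classify_event_order(soma, dend, c(0, 150)),
               "dendrite_first")
  # bAP-only: dendritic depolarization follows each somatic spike
  dend2 <- gen_trace(trace_spec(spike_times = c(47, 57), spike_amp = 25,
                                spike_width = 0.5, sigma = 0,
                                duration = 150, dt = 0.05), "dend")
  expect_equal(classify_event_order(soma, dend2, c(0, 150)), "soma_first")
  expect_error(classify_event_order(soma, flat_trace(compartment = "dend"),
                                    c(0, 100)), "flat")
})

test_that("distal dendritic DC injection gives dendrite-first electrogenesis", {
  sim <- simulate(protocol_dc_step("dend", 1000, 1000), default_params(),
                  total = 1300)
  sp <- detect_spikes(sim$soma)
  expect_gt(length(sp$times), 0)
  expect_equal(classify_event_order(sp, sim$dend, c(100, 1100)),
               "dendrite_first")
})

test_that("slope test reports OLS slope with a two-tailed t-test", {
  x <- 1:20
  st <- slope_test(x, 2 * x)
  expect_equal(st$slope, 2)
  expect_lt(st$p_value, 1e-10)
  expect_equal(slope_test(x, rep(3, 20))$slope, 0)
  expect_error(slope_test(rep(1, 10), rnorm(10)), "constant")
  # agrees with lm on noisy data
  set.seed(4)
  y <- 0.3 * x + rnorm(20)
  ref <- summary(lm(y ~ x))$coefficients["x", ]
  st2 <- slope_test(x, y)
  expect_equal(st2$slope, unname(ref["Estimate"]))
  expect_equal(st2$p_value, unname(ref["Pr(>|t|)"]))
})

test_that("slope test has the nominal type-I error rate", {
  set.seed(202)
  rejected <- vapply(1:2000, function(i) {
    slope_test(1:15, rnorm(15))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.035)
  expect_lte(mean(rejected), 0.065)
})
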