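# The composite, multiplicative and additive input-output models, surface
# fitting, and per-tuft M/T slice extraction.

test_that("the 4-parameter sigmoid evaluates to its closed form", {
  p <- sigmoid_params(offset = 0, amplitude = 100, midpoint = 50,
                      scale = 10)
  expect_equal(eval_sigmoid(p, 50), 50)
  expect_equal(eval_sigmoid(p, 50 + 10 * log(3)), 75)
  p0 <- sigmoid_params(7, 0, 50, 10)
  expect_equal(eval_sigmoid(p0, c(-100, 0, 200)), rep(7, 3))
  # limits for positive slope scale
  expect_equal(eval_sigmoid(p, -1e4), 0, tolerance = 1e-8)
  expect_equal(eval_sigmoid(p, 1e4), 100, tolerance = 1e-8)
  expect_error(sigmoid_params(0, 1, 0, 0), "nonzero")
})

test_that("additive and multiplicative models combine independent sigmoids", {
  f0 <- sigmoid_params(0, 0, 50, 10)       # identically zero
  g <- sigmoid_params(5, 80, 120, 30)
  expect_equal(eval_additive(f0, g, 40, 150), eval_sigmoid(g, 150))
  expect_equal(eval_multiplicative(f0, g, 40, 150), 0)
  # symmetric parameters: invariant under (n_T, n_B) swap
  s <- sigmoid_params(2, 60, 100, 25)
  expect_equal(eval_additive(s, s, 30, 170), eval_additive(s, s, 170, 30))
  expect_equal(eval_multiplicative(s, s, 30, 170),
               eval_multiplicative(s, s, 170, 30))
  # hand-evaluated point
  f <- sigmoid_params(1, 10, 60, 20)
  expect_equal(eval_additive(f, g, 60, 120),
               (1 + 5) + (10 + 80) / 2)
  expect_equal(eval_multiplicative(f, g, 60, 120), 6 * 45)
})

test_that("the composite model has unit basal slope exactly as defined", {
  cp <- truth_composite()
  nT <- 120
  Tn <- eval_sigmoid(cp$T, nT)
  Mn <- eval_sigmoid(cp$M, nT)
  expect_equal(eval_composite(cp, nT, Tn), Mn / 2)
  expect_equal(eval_composite(cp, nT, Tn + 40), Mn, tolerance = 1e-8)
  # hand evaluation at an arbitrary point
  expect_equal(eval_composite(cp, 50, 180),
               eval_sigmoid(cp$M, 50) /
                 (1 + exp(-(180 - eval_sigmoid(cp$T, 50)))))
})

test_that("each model kind wins on its own noiseless surface", {
  kinds <- c("composite", "multiplicative", "additive")
  ve <- matrix(NA_real_, 3, 3, dimnames = list(kinds, kinds))
  for (gen in kinds) {
    surf <- noiseless_surface(gen)
    for (k in kinds)
      ve[gen, k] <- fit_surface(surf, k, n_restarts = 30,
                                seed = 2)$variance_explained
    expect_gte(ve[gen, gen], 99.9)
    expect_true(all(ve[gen, gen] >= ve[gen, ] - 1e-6))
  }
})

test_that("constant surfaces are flagged instead of fitted", {
  surf <- frequency_surface(0:10, 0:5, matrix(40, 6, 11),
                            provenance = "synthetic")
  fit <- fit_surface(surf, "composite")
  expect_false(fit$converged)
  expect_true(is.na(fit$variance_explained))
})

test_that("composite parameters are recovered under surface noise", {
  cp <- truth_composite()
  nt <- seq(0, 200, by = 25)
  M_true <- eval_sigmoid(cp$M, nt)
  T_true <- eval_sigmoid(cp$T, nt)
  rms <- function(a, b) sqrt(mean((a - b)^2)) / diff(range(b))
  errs <- t(vapply(1:20, function(s) {
    surf <- gen_surface(surface_spec(cp, basal = seq(0, 300, 25),
                                     tuft = nt, sigma = 5, seed = s))
    fit <- fit_surface(surf, "composite", n_restarts = 20, seed = s)
    c(rms(eval_sigmoid(fit$params$M, nt), M_true),
      rms(eval_sigmoid(fit$params$T, nt), T_true))
  }, numeric(2)))
  expect_lt(mean(errs[, 1]), 0.10)
  expect_lt(mean(errs[, 2]), 0.10)
})

test_that("slice-extracted M and T agree with the composite fit (two routes)", {
  cp <- truth_composite()
  surf <- gen_surface(surface_spec(cp, basal = seq(0, 300, 20),
                                   tuft = seq(0, 200, 25), sigma = 0))
  sl <- extract_slice_MT(surf)
  ok <- sl$ok & sl$n_tuft >= 25  # interior slices with resolvable threshold
  expect_gt(sum(ok), 5)
  M_true <- eval_sigmoid(cp$M, sl$n_tuft[ok])
  T_true <- eval_sigmoid(cp$T, sl$n_tuft[ok])
  expect_lt(sqrt(mean((sl$M[ok] - M_true)^2)) / diff(range(M_true)), 0.05)
  expect_lt(sqrt(mean((sl$T[ok] - T_true)^2)) / diff(range(T_true)), 0.05)
  # whole-surface fit route
  fit <- fit_surface(surf, "composite", n_restarts = 30, seed = 3)
  expect_lt(sqrt(mean((eval_sigmoid(fit$params$M, sl$n_tuft[ok]) -
                         M_true)^2)) / diff(range(M_true)), 0.05)
  expect_lt(sqrt(mean((eval_sigmoid(fit$params$T, sl$n_tuft[ok]) -
                         T_true)^2)) / diff(range(T_true)), 0.05)
})

test_that("degenerate slices are flagged", {
  surf <- frequency_surface(seq(0, 100, 20), c(0, 50),
                            matrix(0, 2, 6), provenance = "synthetic")
  sl <- extract_slice_MT(surf)
  expect_true(all(!sl$ok))
  expect_equal(sl$M, c(0, 0))
  expect_true(all(is.na(sl$T)))
})

test_that("sigmoid canonicalization leaves the curve unchanged", {
  # (amplitude, scale) -> (-amplitude, -scale) with adjusted offset is the
  # same curve; fits report the positive-scale form
  x <- seq(-50, 250, by = 10)
  a <- tuftburst:::logistic4(x, 5, 40, 100, 20)
  b <- tuftburst:::logistic4(x, 45, -40, 100, -20)
  expect_equal(a, b)
  p <- tuftburst:::canonicalize4(c(offset = 45, amplitude = -40,
                                   midpoint = 100, scale = -20))
  expect_equal(unname(p[c("offset", "amplitude", "scale")]), c(5, 40, 20))
})

test_that("the frozen control-surface fit has rising M and falling T", {
  cp <- default_tuning_params()$composite
  nt <- seq(0, 200, 10)
  M <- eval_sigmoid(cp$M, nt)
  T <- eval_sigmoid(cp$T, nt)
  expect_true(all(diff(M) >= -1e-6 * max(abs(M))))
  expect_true(all(diff(T) <= 1e-6 * max(abs(T))))
})
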