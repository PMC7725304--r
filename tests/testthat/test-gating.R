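test_that("open probability has the Boltzmann shape and limits", {
  p <- boltzmann_params(a = 0.6, v_half = -95.7, rt_over_f = 25.2)
  expect_equal(open_probability(-95.7, p), 0.5)
  expect_equal(open_probability(-150, p),
               1 / (1 + exp((0.6 / 25.2) * (-150 + 95.7))), tolerance = 1e-12)
  expect_equal(open_probability(-150, p), 0.785, tolerance = 1e-3)
  expect_equal(open_probability(-1e4, p), 1, tolerance = 1e-10)
  expect_equal(open_probability(1e4, p), 0, tolerance = 1e-10)
  v <- seq(-200, 0, by = 10)
  expect_true(all(diff(open_probability(v, p)) < 0)) # hyperpolarization-activated
  # the curve depends on voltage only through (V - V_half) * a / (RT/F)
  p2 <- boltzmann_params(a = 1.2, v_half = -120, rt_over_f = 50.4)
  expect_equal(open_probability(v, boltzmann_params(0.6, -120, 25.2)),
               open_probability(v, p2), tolerance = 1e-12)
})

test_that("pH model reproduces the published half-activation voltages", {
  wt <- kdm1_wt_gating()
  expect_equal(wt$vs, 42, tolerance = 1e-12)
  # measured values: -95.7 mV at pH 4, -176.1 mV at pH 7 (both within 1 mV)
  expect_equal(v_half_at_ph(4, wt), -95.7, tolerance = 1 / 95.7)
  expect_equal(v_half_at_ph(7, wt), -176.1, tolerance = 1 / 176.1)
  # saturation at high pH
  expect_equal(v_half_at_ph(12, wt), wt$v_half_inf, tolerance = 1e-3)
  # the H147S mutant's pH 7 -> 4 shift is compressed to about 30 mV
  mut <- kdm1_h147s_gating()
  shift <- v_half_at_ph(4, mut) - v_half_at_ph(7, mut)
  expect_equal(shift, 30.2, tolerance = 0.01)
  # acidification shifts V_half positive when pK_O > pK_C
  expect_true(all(diff(v_half_at_ph(seq(7, 4, by = -0.5), wt)) > 0))
})

test_that("tail currents map onto a relative open-probability curve", {
  cv <- tail_to_open_probability(c(-200, -120, -60), c(-10, -5, -1))
  expect_equal(cv$rel_po, c(1, 0.5, 0.1))
  expect_error(tail_to_open_probability(c(-200, -120, -60), c(0, 0, 0)), "zero")
  expect_error(tail_to_open_probability(c(-200, -120, -60), c(-1, 2, -3)), "sign")
  expect_error(tail_to_open_probability(c(-200, -120), c(-1, -2)), "3 distinct")
  # round trip: tails generated as po * I_max recover po exactly
  truth <- boltzmann_params(a = 0.6, v_half = -120)
  v <- seq(-200, -40, by = 20)
  cv2 <- tail_to_open_probability(v, -8 * open_probability(v, truth))
  expect_equal(cv2$rel_po,
               open_probability(v, truth) / max(open_probability(v, truth)),
               tolerance = 1e-12)
})

test_that("Boltzmann fitting recovers parameters and flags bad curves", {
  truth <- boltzmann_params(a = 0.6, v_half = -120)
  v <- seq(-200, -50, by = 10)
  curve <- data.frame(v_mv = v, rel_po = open_probability(v, truth))
  fit <- fit_boltzmann(curve)
  expect_equal(fit$params$a, 0.6, tolerance = 1e-6)
  expect_equal(fit$params$v_half, -120, tolerance = 1e-6)
  expect_true(fit$hyperpolarization_activated)
  # with the gating charge fixed only v_half is estimated
  fitf <- fit_boltzmann(curve, fixed_a = 0.6)
  expect_equal(fitf$params$v_half, -120, tolerance = 1e-6)
  # a monotone-increasing curve converges to a < 0 and is flagged
  rev_curve <- data.frame(v_mv = v, rel_po = 1 - curve$rel_po)
  rfit <- fit_boltzmann(rev_curve)
  expect_lt(rfit$params$a, 0)
  expect_false(rfit$hyperpolarization_activated)
  # degenerate inputs
  flat <- data.frame(v_mv = v, rel_po = rep(0.5, length(v)) + 1e-3)
  expect_error(fit_boltzmann(flat), "dynamic range")
  expect_error(fit_boltzmann(curve[1:3, ]), "5 distinct")
})

test_that("Boltzmann fits are nearly unbiased on noisy curves", {
  truth <- boltzmann_params(a = 0.6, v_half = -120)
  v <- seq(-200, -50, by = 10) # 16 voltages
  est <- vapply(1:200, function(s) {
    cv <- simulate_activation_curves(truth, voltages = v, sigma = 0.03,
                                     seed = s)
    fit_boltzmann(cv)$params$v_half
  }, numeric(1))
  expect_lt(abs(mean(est) - (-120)), 1) # bias below 1 mV
})

test_that("pH-model fitting recovers parameters from noiseless data", {
  wt <- kdm1_wt_gating()
  ph <- c(4, 5, 6, 7)
  fit <- fit_ph_model(ph, v_half_at_ph(ph, wt))
  expect_equal(fit$params$v_half_inf, wt$v_half_inf, tolerance = 1e-4)
  expect_equal(fit$params$pk_o, wt$pk_o, tolerance = 1e-4)
  expect_equal(fit$params$pk_c, wt$pk_c, tolerance = 1e-4)
  expect_true(fit$acid_activated)
  expect_false(fit$degenerate)
  expect_error(fit_ph_model(c(4, 5, 6), v_half_at_ph(c(4, 5, 6), wt)),
               "4 distinct")
})

test_that("pH-model fits recover v_half_inf within 3 mV under 2 mV noise", {
  wt <- kdm1_wt_gating()
  ph <- c(4, 4.5, 5, 5.5, 6, 7)
  mu <- v_half_at_ph(ph, wt)
  err <- vapply(1:200, function(s) {
    vh <- withr::with_seed(s, mu + rnorm(length(ph), 0, 2))
    abs(fit_ph_model(ph, vh)$params$v_half_inf - wt$v_half_inf)
  }, numeric(1))
  expect_lt(median(err), 3)
})

test_that("reversal-potential regression recovers the Nernst slope", {
  k <- c(3, 10, 30, 100)
  ideal <- 25 * log(10) * log10(k) - 150
  ns <- nernst_shift_per_decade(ideal, k)
  expect_equal(ns$slope, 25 * log(10), tolerance = 1e-9) # 57.56 mV/decade
  expect_error(nernst_shift_per_decade(c(-100, -90), c(10, 10)), "distinct")
  # noisy regression: slope within 2 SE of the generating slope
  set.seed(42)
  noisy <- rep(ideal, each = 5) + rnorm(20, 0, 3)
  nf <- nernst_shift_per_decade(noisy, rep(k, each = 5))
  expect_lt(abs(nf$slope - 25 * log(10)), 2 * nf$se)
})

test_that("fractional block covers the Cs+ and TEA+/Ba2+ magnitudes", {
  expect_equal(as.numeric(fractional_block(-10, -1)), 0.9)
  expect_equal(as.numeric(fractional_block(-10, -10)), 0)
  expect_equal(as.numeric(fractional_block(-10, -4)), 0.6)
  expect_error(fractional_block(0, -1), "zero")
  over <- fractional_block(-10, 2) # 'blocked' current changed sign
  expect_equal(as.numeric(over), 1)
  expect_true(attr(over, "out_of_range"))
})

test_that("current normalization is per-cell and scale invariant", {
  v <- c(-150, -100, -50)
  shape <- c(-1, -0.5, -0.1)
  d <- rbind(data.frame(cell_id = "c1", condition = "ref", v_mv = v,
                        i = 8 * shape),
             data.frame(cell_id = "c2", condition = "ref", v_mv = v,
                        i = 16 * shape))
  nr <- normalize_currents(d, ref_condition = "ref", ref_v = -150)
  n1 <- nr$normalized$i_norm[nr$normalized$cell_id == "c1"]
  n2 <- nr$normalized$i_norm[nr$normalized$cell_id == "c2"]
  expect_equal(n1, n2) # identical shapes normalize identically
  expect_equal(abs(n1[1]), 1) # reference magnitude is 1, sign kept
  expect_equal(nr$summary$mean[nr$summary$v_mv == -150], -1)
  d_bad <- d[d$v_mv != -150 | d$cell_id != "c2", ]
  expect_error(normalize_currents(d_bad, "ref", -150), "c2")
})
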