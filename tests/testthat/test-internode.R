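test_that("logistic cumulative-length law matches hand-evaluated values", {
  p <- list(qi = 0.62, si = 0.12)
  expect_equal(logistic_ndi(0.62, p), 0.5)
  expect_equal(logistic_ndi(1, p), 1 / (1 + exp(-0.38 / 0.12)))
  expect_equal(round(logistic_ndi(1, p), 4), 0.9596)
  expect_equal(round(logistic_ndi(0, p), 4), 0.0057)
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(logistic_ndi(x, p)) > 0))
  expect_error(logistic_ndi(0.5, list(qi = 0.6, si = 0)), "positive")
})

test_that("predicted cumulative length scales the logistic by BL + BSL", {
  p <- list(qi = 0.62, si = 0.12)
  # midpoint: R_I / nl = qi gives half the total length
  expect_equal(predict_cumulative_length(62, 100, 8, 12, p), 10)
  expect_equal(round(predict_cumulative_length(18, 18, 10, 20, p), 2), 28.79)
  d <- predict_cumulative_length(1:18, 18, 10, 20, p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d < 30))
  # normalization consistency: exact factorization
  expect_equal(d, 30 * logistic_ndi((1:18) / 18, p), tolerance = 1e-15)
})

test_that("internode length sequence is short basally, longest mid-shoot", {
  d <- predict_cumulative_length(1:15, 15, 4, 12, list(qi = 0.62, si = 0.12))
  internodes <- diff(d)
  expect_true(all(internodes > 0))
  peak <- which.max(internodes)
  expect_true(peak > 1 && peak < length(internodes))
  expect_true(all(diff(internodes[seq_len(peak)]) > 0))       # rising zone
  expect_true(all(diff(internodes[peak:length(internodes)]) < 0))  # flattening
})

test_that("logistic fit recovers exactly from noise-free data", {
  cfg <- synthetic_config()
  cfg$internode$noise_sd <- 0
  gen <- generate_internode_dataset(cfg, seed = 3)
  fit <- fit_internode_model(gen$internodes)
  expect_equal(fit$qi, 0.62, tolerance = 1e-6)
  expect_equal(fit$si, 0.12, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-6)  # zero up to nls convergence tolerance
})

test_that("logistic fit agrees with the self-starting logistic cross-check", {
  # independent route: SSlogis estimates (Asym, xmid, scal); on data generated
  # with asymptote 1 its (xmid, scal) must match our fixed-asymptote fit
  cfg <- synthetic_config()
  cfg$internode$noise_sd <- 0.02
  gen <- generate_internode_dataset(cfg, seed = 9)
  rec <- gen$internodes
  nl <- stats::ave(rec$rank_continuum, rec$spur_id, FUN = max)
  nri <- rec$rank_continuum / nl
  ndi <- rec$cum_length_cm / (rec$bourse_length_cm + rec$bourse_shoot_length_cm)
  ref <- stats::nls(ndi ~ SSlogis(nri, Asym, xmid, scal))
  ours <- fit_internode_model(rec)
  expect_equal(ours$qi, unname(coef(ref)[["xmid"]]), tolerance = 0.01)
  expect_equal(ours$si, unname(coef(ref)[["scal"]]), tolerance = 0.01)
})

test_that("logistic fit recovers qi and si from noisy spur continua", {
  gen <- generate_internode_dataset(synthetic_config(), seed = 21)
  fit <- fit_internode_model(gen$internodes)
  expect_equal(fit$qi, 0.62, tolerance = 0.03)
  expect_equal(fit$si, 0.12, tolerance = 0.03)
  expect_gt(fit$fit_r2, 0.9)
})

test_that("degenerate internode data are rejected", {
  flat <- data.frame(spur_id = "S", rank_continuum = 1:6,
                     cum_length_cm = rep(5, 6), bourse_length_cm = 3,
                     bourse_shoot_length_cm = 9)
  expect_error(fit_internode_model(flat), "degenerate")
  expect_error(fit_internode_model(flat[, -3]), "lack column")
})
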