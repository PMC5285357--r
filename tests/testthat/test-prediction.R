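test_that("bourse-shoot forward model matches hand-evaluated areas", {
  m <- calibrated_model("BS", "FU", alpha = 1)
  m$s <- stats::setNames(rep(0.36, 18), as.character(1:18))  # printed nl = 5 cell
  m$k <- 0.64
  # peak leaf: (pi/4) * 0.64 * 100
  expect_equal(predict_leaf_area(2, 5, 10, m), 16 * pi, tolerance = 1e-12)
  # two ranks above the peak: 50.265 / (1 + 4 / (25 * 0.1296))
  expect_equal(predict_leaf_area(4, 5, 10, m), 16 * pi / (1 + 4 / (25 * 0.36^2)),
               tolerance = 1e-12)
  expect_equal(round(predict_leaf_area(4, 5, 10, m), 2), 22.49)
  # brute-force oracle: sum the five per-rank values directly
  oracle <- sum(16 * pi / (1 + ((1:5) - 2)^2 / (25 * 0.36^2)))
  expect_equal(predict_total_leaf_area(5, 10, m), oracle, tolerance = 1e-12)
  expect_equal(oracle, 162.886, tolerance = 1e-3)
})

test_that("rosette model peaks at nl * x0 and the peak value is alpha (pi/4) k Lmax^2", {
  m <- calibrated_model("RO", "FU", alpha = 1)
  # nl chosen so nl * x0 is an integer (x0 = 0.63, nl = 100 -> rank 63)
  a <- predict_leaf_area(63, 100, 9, m)
  expect_equal(a, (pi / 4) * m$k * 81, tolerance = 1e-12)
  expect_true(all(predict_leaf_area(setdiff(1:100, 63), 100, 9, m) < a))
})

test_that("vegetative-shoot areas are linear in rank", {
  vs <- list(p = 0.95, k = 0.56)
  expect_equal(predict_vs_leaf_area(10, 10, 8, vs), 0.95 * (pi / 4) * 0.56 * 64,
               tolerance = 1e-12)
  expect_equal(round(predict_vs_leaf_area(10, 10, 8, vs), 2), 26.74)
  expect_equal(predict_vs_leaf_area(5, 10, 8, vs),
               predict_vs_leaf_area(10, 10, 8, vs) / 2)
  # p = 1 apical leaf equals the shoot's Amax under the ellipse model
  expect_equal(predict_vs_leaf_area(10, 10, 8, list(p = 1, k = 0.56)),
               (pi / 4) * 0.56 * 64)
  areas <- predict_vs_leaf_area(1:12, 12, 8, vs)
  expect_true(all(diff(areas) > 0))  # increases with rank
})

test_that("structural properties: peak rank, symmetry, Lmax^2 scaling", {
  for (g in c("AR", "FU", "RB")) {
    m <- calibrated_model("BS", g)
    for (nl in c(2, 5, 9, 18)) {
      areas <- predict_leaf_area(seq_len(nl), nl, 8, m)
      expect_equal(which.max(areas), 2)  # biggest leaf at rank 2
    }
  }
  m <- calibrated_model("BS", "AR")
  # symmetric in (R - R_peak) about the peak
  expect_equal(predict_leaf_area(1, 9, 8, m), predict_leaf_area(3, 9, 8, m))
  m_ro <- calibrated_model("RO", "AR")
  expect_equal(predict_leaf_area(62, 100, 8, m_ro), predict_leaf_area(64, 100, 8, m_ro))
  expect_equal(predict_leaf_area(50, 100, 8, m_ro), predict_leaf_area(76, 100, 8, m_ro))
  # scaling: Lmax -> c * Lmax multiplies every area by c^2
  expect_equal(predict_leaf_area(1:9, 9, 16, m),
               4 * predict_leaf_area(1:9, 9, 8, m), tolerance = 1e-12)
  expect_error(predict_leaf_area(10, 9, 8, m), "rank out of range")
  expect_error(predict_leaf_area(1, 9, -2, m), "Lmax")
})

test_that("total leaf area approaches beta * nl * peak area as nl grows", {
  m <- calibrated_model("BS", "FU", alpha = 1)
  for (nl in c(12, 15, 18)) {
    tla <- predict_total_leaf_area(nl, 10, m)
    peak <- (pi / 4) * m$k * 100
    expect_lt(abs(tla / (nl * peak) - 0.67), 0.03)
  }
})

test_that("alpha calibration is a through-origin slope with exact recovery", {
  expect_equal(calibrate_alpha(c(10, 20, 30), c(10, 20, 30)), 1)
  expect_equal(calibrate_alpha(c(20, 40), c(10, 20)), 2)
  set.seed(5)
  calc <- rlnorm(100, log(100), 0.4)
  meas <- 1.2 * calc * (1 + rnorm(100, 0, 0.05))
  expect_equal(calibrate_alpha(meas, calc), 1.2, tolerance = 0.03)
  expect_error(calibrate_alpha(1:3, 1:2), "equal length")
  expect_error(calibrate_alpha(numeric(0), numeric(0)), "nonempty")
})

test_that("spur reconstruction assembles a consistent continuum table", {
  tab <- reconstruct_spur(6, 7, 8, 9.5, 3, 14, "FU")
  expect_equal(nrow(tab), 14)
  expect_equal(tab$rank_continuum, 1:14)
  expect_equal(tab$shoot, rep(c("RO", "BS"), c(6, 8)))
  # distances along the spur: nondecreasing and below the total length
  expect_true(all(diff(tab$distance_cm) > 0))
  expect_true(all(tab$distance_cm < 17))
  # additivity: table total equals the two shoot totals
  m_ro <- calibrated_model("RO", "FU")
  m_bs <- calibrated_model("BS", "FU")
  expect_equal(sum(tab$area_cm2),
               predict_total_leaf_area(6, 7, m_ro) +
                 predict_total_leaf_area(8, 9.5, m_bs), tolerance = 1e-12)
  expect_error(reconstruct_spur(0, 7, 8, 9.5, 3, 14, "FU"), "at least one")
  expect_error(calibrated_model("BS", "XX"), "no BS parameter set")
})
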