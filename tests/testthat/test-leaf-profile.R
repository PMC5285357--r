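test_that("normalized rank shifts bourse shoots so the modal peak sits at zero", {
  expect_equal(normalized_rank(2, 7, "BS"), 0)
  expect_equal(normalized_rank(7, 7, "RO"), 1)
  expect_equal(normalized_rank(1, 4, "BS"), -0.25)
  expect_equal(normalized_rank(1:4, 4, "VS"), c(0.25, 0.5, 0.75, 1))
  expect_error(normalized_rank(5, 4, "BS"), "rank out of range")
  expect_error(normalized_rank(0, 4, "RO"), "rank out of range")
})

test_that("normalized area is a clean ratio with guarded degenerate cases", {
  expect_equal(normalized_area(50, 50), 1)
  expect_equal(normalized_area(0, 50), 0)
  expect_equal(normalized_area(12.5, 50), 0.25)
  expect_error(normalized_area(1, 0), "degenerate")
  expect_error(normalized_area(60, 50), "Amax")
})

test_that("the Lorentz profile peaks at 1, halves at one scale unit, is symmetric", {
  expect_equal(lorentz(0.4, 0.4, 0.2), 1)
  expect_equal(lorentz(0.6, 0.4, 0.2), 0.5)
  expect_equal(lorentz(0.2, 0.4, 0.2), 0.5)
  x <- seq(-1, 1, by = 0.05)
  expect_equal(lorentz(0.3 + x, 0.3, 0.17), lorentz(0.3 - x, 0.3, 0.17))
  expect_error(lorentz(0, 0, -1), "positive")
})

test_that("arctan closed form equals adaptive quadrature of the profile", {
  for (s in c(0.05, 0.22, 0.36, 1.3)) {
    for (b in list(c(-0.4, 0.6), c(0, 1), c(-2, 0))) {
      for (x0 in c(0, 0.35, 0.63)) {
        quad <- integrate(function(x) lorentz(x, x0, s), b[1], b[2],
                          rel.tol = 1e-12)$value
        expect_equal(beta_closed_form(s, b[1], b[2], x0), quad, tolerance = 1e-8)
      }
    }
  }
})

test_that("closed form is strictly increasing in s and bounded by interval width", {
  s_grid <- 10^seq(-3, 3, length.out = 40)
  vals <- beta_closed_form(s_grid, -0.4, 0.6, 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 1))
  expect_equal(beta_closed_form(1e6, 0, 1, 0.5), 1, tolerance = 1e-6)
})

test_that("solve_s round-trips beta across the whole feasible range", {
  for (beta in seq(0.1, 0.9, by = 0.1)) {
    s_bs <- solve_s(beta, "BS", nl = 7)
    expect_equal(beta_closed_form(s_bs, -2 / 7, 5 / 7, 0), beta, tolerance = 1e-9)
    s_ro <- solve_s(beta, "RO", x0 = 0.63)
    expect_equal(beta_closed_form(s_ro, 0, 1, 0.63), beta, tolerance = 1e-9)
  }
  expect_error(solve_s(1.0, "BS", nl = 5), "no solution")
  expect_error(solve_s(-0.1, "BS", nl = 5), "positive")
  expect_error(solve_s(0.5, "BS"), "nl is required")
})

test_that("scale-table spot values match the published parameterization", {
  expect_equal(round(solve_s(0.67, "BS", nl = 1), 2), 2.13)
  expect_equal(round(solve_s(0.50, "BS", nl = 18), 2), 0.32)
  expect_lt(abs(solve_s(0.69, "RO", x0 = 0.63) - 0.38), 0.01)
  tab <- s_table(0.67, 18)
  expect_named(tab, as.character(1:18))
  expect_lt(abs(unname(tab[5]) - 0.36), 0.01)
})

test_that("discrete profile sums approach the closed-form integral as nl grows", {
  # Riemann property: the mean of the profile over integer ranks converges to
  # its integral like O(1/nl); the gap drops below 0.03 from nl = 12 on
  # (oracle values: 0.034 at nl = 8, 0.031 at nl = 10, 0.028 at nl = 12)
  gap <- sapply(c(12, 15, 18, 30), function(nl) {
    s <- solve_s(0.67, "BS", nl = nl)
    abs(mean(lorentz(normalized_rank(1:nl, nl, "BS"), 0, s)) - 0.67)
  })
  expect_true(all(gap < 0.03))
  expect_lt(gap[4], gap[1])  # shrinking with nl
})

test_that("fit_beta recovers the allometric slope", {
  # all leaves equal to Amax: TLA = nl * Amax exactly
  flat <- data.frame(TLA_cm2 = c(50, 80), nl = c(5, 8), Amax_cm2 = c(10, 10))
  expect_equal(fit_beta(flat)$beta, 1)
  # exact-profile shoots at nl = 12: the slope equals the discrete profile
  # mean, within 0.03 of the generating integral value (sum-vs-integral
  # oracle: the gap is 0.028 at nl = 12)
  lv <- make_profile_dataset(12, nl = 12, s = solve_s(0.67, "BS", nl = 12))
  sm <- shoot_summaries(lv)
  disc_oracle <- mean(1 / (1 + ((1:12) - 2)^2 / (144 * solve_s(0.67, "BS", nl = 12)^2)))
  expect_equal(fit_beta(sm)$beta, disc_oracle, tolerance = 1e-9)
  expect_lt(abs(fit_beta(sm)$beta - 0.67), 0.03)
  expect_error(fit_beta(NULL), "no shoots")
})

test_that("fit_beta recovers 0.67 from 200 noisy synthetic bourse shoots", {
  cfg <- synthetic_config(n_shoots = list(BS = c(AR = 100, FU = 100)))
  gen <- generate_leaf_dataset(cfg, seed = 7)
  sm <- shoot_summaries(gen$leaves)
  expect_equal(fit_beta(sm)$beta, 0.67, tolerance = 0.02)
})

test_that("estimate_x0 averages the normalized peak rank of informative rosettes", {
  one <- data.frame(RAmax = 5, nl = 8)
  expect_equal(estimate_x0(one), 0.625)
  many <- data.frame(RAmax = c(63, 63, 63), nl = c(100, 100, 100))
  expect_equal(estimate_x0(many), 0.63)
  expect_error(estimate_x0(data.frame(RAmax = NA_real_, nl = 5)), "missing")
  expect_error(estimate_x0(data.frame(RAmax = 1, nl = 1)), "2 or more leaves")
})

test_that("estimate_x0 recovers 0.63 from synthetic rosettes", {
  cfg <- synthetic_config(n_shoots = list(RO = c(AR = 40, FU = 40)))
  gen <- generate_leaf_dataset(cfg, seed = 11)
  sm <- shoot_summaries(gen$leaves)
  expect_equal(estimate_x0(sm), 0.63, tolerance = 0.03)
})
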