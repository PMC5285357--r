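test_that("generation is deterministic for a given seed and differs across seeds", {
  cfg <- synthetic_config(n_shoots = list(BS = c(FU = 15)))
  g1 <- generate_leaf_dataset(cfg, seed = 3)
  g2 <- generate_leaf_dataset(cfg, seed = 3)
  expect_identical(g1$leaves, g2$leaves)
  expect_identical(g1$truth$shoots, g2$truth$shoots)
  g3 <- generate_leaf_dataset(cfg, seed = 4)
  expect_false(identical(g1$leaves, g3$leaves))
  # substreams are independent: the internode stage does not disturb leaves
  gi <- generate_internode_dataset(cfg, seed = 3)
  expect_identical(generate_leaf_dataset(cfg, seed = 3)$leaves, g1$leaves)
})

test_that("generated tables satisfy the domain invariants", {
  gen <- generate_leaf_dataset(synthetic_config(
    n_shoots = list(BS = c(AR = 20), RO = c(RB = 20), VS = c(FU = 10))), seed = 8)
  lv <- gen$leaves
  expect_true(all(lv$blade_width_cm <= lv$blade_length_cm))
  expect_equal(lv$area_cm2, pi * lv$blade_length_cm * lv$blade_width_cm / 4,
               tolerance = 1e-12)
  sm <- shoot_summaries(lv)
  expect_true(all(sm$TLA_cm2 <= sm$nl * sm$Amax_cm2 + 1e-9))
  # realized biggest-leaf rank equals the drawn peak (noise is anchored there)
  tr <- gen$truth$shoots
  expect_equal(sm$RAmax[match(tr$shoot_id, sm$shoot_id)], tr$peak_rank)
  gi <- generate_internode_dataset(synthetic_config(), seed = 8)
  rec <- gi$internodes
  expect_true(all(rec$cum_length_cm >= 0))
  expect_true(all(rec$cum_length_cm <=
                    rec$bourse_length_cm + rec$bourse_shoot_length_cm))
})

test_that("zero-noise generation followed by fitting returns the truth", {
  cfg <- synthetic_config(area_cv = 0, ecc_sd = 0, nl_min = 2)
  gen <- generate_leaf_dataset(cfg, seed = 13)
  sm <- shoot_summaries(gen$leaves)
  bs <- sm[sm$shoot_type == "BS" & sm$genotype %in% c("AR", "FU"), ]
  expect_equal(fit_beta(bs)$beta, 0.67, tolerance = 1e-9)
  rb <- sm[sm$shoot_type == "BS" & sm$genotype == "RB", ]
  expect_equal(fit_beta(rb)$beta, 0.50, tolerance = 1e-9)
  ro <- sm[sm$shoot_type == "RO", ]
  expect_equal(fit_beta(ro)$beta, 0.69, tolerance = 1e-9)
  tr <- gen$truth$shoots
  tro <- tr[tr$shoot_type == "RO" & tr$nl >= 2, ]
  expect_equal(estimate_x0(ro), mean(tro$peak_rank / tro$nl), tolerance = 1e-12)
  for (g in c("AR", "FU", "RB")) {
    lv <- gen$leaves[gen$leaves$shoot_type == "BS" & gen$leaves$genotype == g, ]
    expect_equal(fit_k(lv)$k, gen$truth$k$BS[[g]], tolerance = 1e-9)
  }
  czero <- synthetic_config()
  czero$internode$noise_sd <- 0
  gi <- generate_internode_dataset(czero, seed = 13)
  fi <- fit_internode_model(gi$internodes)
  expect_equal(fi$qi, 0.62, tolerance = 1e-6)
  expect_equal(fi$si, 0.12, tolerance = 1e-6)
})

test_that("bourse-shoot biggest-leaf ranks have mode 2, concentrated for RB", {
  gen <- generate_leaf_dataset(synthetic_config(
    n_shoots = list(BS = c(RB = 500)), nl_min = 2), seed = 17)
  sm <- shoot_summaries(gen$leaves)
  tab <- table(sm$RAmax)
  expect_equal(names(tab)[which.max(tab)], "2")
  # published concentration: 87.5 percent of RB peaks at rank 2
  expect_equal(unname(tab[["2"]]) / 500, 0.875, tolerance = 0.05)
})

test_that("temperature fixtures have 24 readings per day and behave additively", {
  tt <- generate_temperature_series(5, mean_C = 12, amplitude_C = 5)
  expect_equal(nrow(tt), 120)
  daily <- gdh_series(tt)
  expect_equal(nrow(daily), 5)
  expect_equal(cumulative_gdd(daily, daily$date[1], daily$date[5]),
               sum(daily$gdh) / 24)
  # identical days: GDD is days x daily GDH / 24
  flat <- generate_temperature_series(10, mean_C = 17, amplitude_C = 0)
  df <- gdh_series(flat)
  expect_equal(cumulative_gdd(df, df$date[1], df$date[10]), 10 * 240 / 24)
})
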