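# In-code fixtures shared across test files.

# A leaf table for one shoot whose areas follow an exact Lorentz profile
# (or a linear ramp for VS), with widths at a fixed k.
make_profile_shoot <- function(shoot_id = "S1", genotype = "FU",
                               shoot_type = "BS", nl = 10, s = 0.46,
                               r_peak = 2, amax = 30, k = 0.64) {
  R <- seq_len(nl)
  n_area <- if (shoot_type == "VS") R / nl else 1 / (1 + (R - r_peak)^2 / (nl^2 * s^2))
  area <- amax * n_area
  len <- sqrt(4 * area / (pi * k))
  data.frame(shoot_id = shoot_id, genotype = genotype, shoot_type = shoot_type,
             rank = R, blade_length_cm = len, blade_width_cm = k * len,
             area_cm2 = area, stringsAsFactors = FALSE)
}

# Several exact-profile shoots with varying sizes.
make_profile_dataset <- function(n_shoots = 12, shoot_type = "BS",
                                 genotype = "FU", nl = 10, s = 0.46,
                                 k = 0.64) {
  do.call(rbind, lapply(seq_len(n_shoots), function(i) {
    make_profile_shoot(sprintf("%s_%02d", shoot_type, i), genotype, shoot_type,
                       nl = nl, s = s, amax = 20 + 2 * i, k = k)
  }))
}

# Published per-nl scale table (2-dp as printed) for spot checks.
printed_s_table <- list(
  ARFU = c(2.13, 0.70, 0.38, 0.35, 0.36, 0.38, 0.40, 0.42, 0.44, 0.46,
           0.48, 0.49, 0.51, 0.52, 0.53, 0.54, 0.55, 0.55),
  RB = c(1.48, 0.43, 0.23, 0.22, 0.22, 0.23, 0.24, 0.25, 0.25, 0.26,
         0.27, 0.28, 0.29, 0.30, 0.31, 0.31, 0.32, 0.32)
)
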