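#' Shipped parameter sets for the apple leaf-area models
#'
#' The parameter values fitted on the original orchard data for the three
#' cultivars Ariane (AR), Fuji (FU) and Rome Beauty (RB):
#' \itemize{
#'   \item bourse shoots: `beta` 0.67 for the pooled AR/FU group and 0.50 for
#'     RB, with the per-`nl` scale table solved from the arctan closed form;
#'     `k` 0.60/0.64/0.66 and calibration slope `alpha` 1.2/0.99/1.87
#'     (AR/FU/RB);
#'   \item rosettes: `beta` 0.69 (all genotypes), `s` 0.38, peak position
#'     `x0` 0.63, `k` 0.75/0.74/0.71, `alpha` 0.86/0.92/0.92;
#'   \item vegetative shoots: linear profile slope `p` 0.95, `k` 0.56
#'     (AR and FU pooled; descriptive, no calibration);
#'   \item internodes: logistic midpoint `qi` 0.62, scale `si` 0.12;
#'   \item phenology: base temperature 7 degC and full-development thresholds
#'     345/201/275 GDD for AR/FU/RB bourse shoots.
#' }
#' The scale tables are re-solved from `beta` at call time (full precision)
#' rather than stored as the published 2-decimal roundings.
#'
#' @return Nested list of parameter sets, class `allom_params`.
#' @export
default_params <- function() {
  structure(list(
    schema_version = 1L,
    BS = list(
      beta = list("AR|FU" = 0.67, "RB" = 0.50),
      groups = list("AR|FU" = c("AR", "FU"), "RB" = "RB"),
      s_table = list("AR|FU" = s_table(0.67), "RB" = s_table(0.50)),
      k = c(AR = 0.60, FU = 0.64, RB = 0.66),
      alpha = c(AR = 1.2, FU = 0.99, RB = 1.87)
    ),
    RO = list(
      beta = list("AR|FU|RB" = 0.69),
      groups = list("AR|FU|RB" = c("AR", "FU", "RB")),
      s = 0.38,
      x0 = 0.63,
      k = c(AR = 0.75, FU = 0.74, RB = 0.71),
      alpha = c(AR = 0.86, FU = 0.92, RB = 0.92)
    ),
    VS = list(
      p = 0.95,
      k = c(AR = 0.56, FU = 0.56)
    ),
    internode = list(qi = 0.62, si = 0.12),
    phenology = list(
      t_base_C = 7,
      gdd_thresholds = c(AR = 345, FU = 201, RB = 275)
    )
  ), class = "allom_params")
}

#' Resolve a calibrated leaf-area model for one shoot type and genotype
#'
#' @param shoot_type `"BS"` or `"RO"`.
#' @param genotype `"AR"`, `"FU"` or `"RB"`.
#' @param params Parameter set, default [default_params()].
#' @param alpha Override for the calibration slope (e.g. 1 for the
#'   uncalibrated model). Default taken from `params`.
#' @return List with `shoot_type`, `genotype`, `beta`, `s` (scalar for RO,
#'   named per-`nl` table for BS), `x0`, `k`, `alpha`.
#' @export
calibrated_model <- function(shoot_type = c("BS", "RO"), genotype,
                             params = default_params(), alpha = NULL) {
  shoot_type <- match.arg(shoot_type)
  p <- params[[shoot_type]]
  grp <- which(vapply(p$groups, function(g) genotype %in% g, logical(1)))
  if (length(grp) != 1L || !genotype %in% names(p$k)) {
    stop(sprintf("no %s parameter set for genotype '%s'", shoot_type, genotype),
         call. = FALSE)
  }
  beta <- p$beta[[grp]]
  out <- list(
    shoot_type = shoot_type,
    genotype = genotype,
    beta = beta,
    s = if (shoot_type == "BS") p$s_table[[grp]] else p$s,
    x0 = if (shoot_type == "BS") 0 else p$x0,
    k = unname(p$k[[genotype]]),
    alpha = if (is.null(alpha)) unname(p$alpha[[genotype]]) else alpha
  )
  class(out) <- "calibrated_model"
  out
}

# Scale parameter for a given leaf count: table lookup for BS (solving on the
# fly beyond the tabulated range), scalar for RO.
model_s <- function(model, nl) {
  if (model$shoot_type == "BS") {
    key <- as.character(nl)
    if (key %in% names(model$s)) unname(model$s[[key]])
    else solve_s(model$beta, "BS", nl = nl)
  } else {
    model$s
  }
}

#' Predict individual leaf area from leaf count and biggest-leaf length
#'
#' The calibrated forward model: for a shoot with `nl` leaves whose biggest
#' leaf has blade length `Lmax`, the leaf at rank `R` has area
#' `alpha * (pi/4) * k * Lmax^2 / (1 + (R - R_peak)^2 / (nl^2 * s^2))`,
#' where the peak rank is 2 for bourse shoots and `nl * x0` for rosettes
#' (used as-is when not an integer; the profile is continuous in the offset).
#'
#' @param R Leaf rank(s), integers in `1..nl`.
#' @param nl Number of leaves on the shoot.
#' @param Lmax Blade length of the biggest leaf, cm, positive.
#' @param model A [calibrated_model()].
#' @return Predicted area(s), cm2.
#' @export
predict_leaf_area <- function(R, nl, Lmax, model) {
  check_rank(R, nl)
  if (!is.finite(Lmax) || Lmax <= 0) stop("Lmax must be positive", call. = FALSE)
  s <- model_s(model, nl)
  r_peak <- if (model$shoot_type == "BS") 2 else nl * model$x0
  peak_area <- model$alpha * (pi / 4) * model$k * Lmax^2
  peak_area / (1 + (R - r_peak)^2 / (nl^2 * s^2))
}

#' Predict vegetative-shoot leaf area
#'
#' Vegetative shoots show leaf area increasing linearly with rank:
#' `A_R = p * (R/nl) * (pi/4) * k * Lmax^2`. This model is descriptive (no
#' calibration stage; testing data were insufficient in the source study).
#'
#' @inheritParams predict_leaf_area
#' @param vs List with elements `p` (profile slope) and `k` (width/length
#'   ratio); default the shipped vegetative-shoot parameters.
#' @return Predicted area(s), cm2.
#' @export
predict_vs_leaf_area <- function(R, nl, Lmax,
                                 vs = list(p = 0.95, k = 0.56)) {
  check_rank(R, nl)
  if (!is.finite(Lmax) || Lmax <= 0) stop("Lmax must be positive", call. = FALSE)
  vs$p * (R / nl) * (pi / 4) * vs$k * Lmax^2
}

#' Predict total shoot leaf area
#'
#' Sum of [predict_leaf_area()] over ranks `1..nl`.
#'
#' @inheritParams predict_leaf_area
#' @return Total leaf area, cm2.
#' @export
predict_total_leaf_area <- function(nl, Lmax, model) {
  sum(predict_leaf_area(seq_len(nl), nl, Lmax, model))
}

#' Calibration slope between measured and calculated total leaf area
#'
#' `alpha` is the through-origin slope of measured total leaf area on
#' model-calculated total leaf area over the training shoots; applied per
#' leaf in the calibrated model, it cancels identically between per-leaf and
#' total predictions.
#'
#' @param measured_TLA Measured total leaf areas, cm2.
#' @param calculated_TLA Calculated total leaf areas, cm2, positive.
#' @return The slope `alpha`.
#' @export
calibrate_alpha <- function(measured_TLA, calculated_TLA) {
  if (length(measured_TLA) == 0L || length(measured_TLA) != length(calculated_TLA)) {
    stop("measured and calculated TLA must be nonempty and equal length", call. = FALSE)
  }
  if (any(!is.finite(calculated_TLA)) || any(calculated_TLA <= 0)) {
    stop("calculated TLA must be positive", call. = FALSE)
  }
  sum(measured_TLA * calculated_TLA) / sum(calculated_TLA^2)
}

#' Reconstruct the leaf table of a whole spur
#'
#' Assembles the rosette + bourse-shoot continuum of a bearing spur: one row
#' per leaf with its continuum rank, source shoot, predicted blade area and
#' predicted insertion distance from the bourse base (via the logistic
#' internode model). This is the table a functional-structural plant model
#' consumes to rebuild branch architecture.
#'
#' @param nl_RO,nl_BS Leaf counts of the rosette and the bourse shoot
#'   (both at least 1).
#' @param Lmax_RO,Lmax_BS Biggest-leaf blade lengths, cm.
#' @param BL Bourse length, cm.
#' @param BSL Bourse-shoot length, cm.
#' @param genotype `"AR"`, `"FU"` or `"RB"`.
#' @param params Parameter set, default [default_params()].
#' @return Data frame with columns `rank_continuum`, `shoot`, `rank_in_shoot`,
#'   `area_cm2`, `distance_cm`; distances are nondecreasing and below
#'   `BL + BSL`.
#' @export
reconstruct_spur <- function(nl_RO, Lmax_RO, nl_BS, Lmax_BS, BL, BSL,
                             genotype, params = default_params()) {
  if (!is.finite(nl_RO) || nl_RO < 1 || !is.finite(nl_BS) || nl_BS < 1) {
    stop("a spur needs at least one rosette leaf and one bourse-shoot leaf",
         call. = FALSE)
  }
  if (BL <= 0 || BSL <= 0) stop("BL and BSL must be positive", call. = FALSE)
  m_ro <- calibrated_model("RO", genotype, params)
  m_bs <- calibrated_model("BS", genotype, params)
  nl_tot <- nl_RO + nl_BS
  rank_cont <- seq_len(nl_tot)
  area <- c(
    predict_leaf_area(seq_len(nl_RO), nl_RO, Lmax_RO, m_ro),
    predict_leaf_area(seq_len(nl_BS), nl_BS, Lmax_BS, m_bs)
  )
  dist <- predict_cumulative_length(rank_cont, nl_tot, BL, BSL, params$internode)
  data.frame(
    rank_continuum = rank_cont,
    shoot = rep(c("RO", "BS"), c(nl_RO, nl_BS)),
    rank_in_shoot = c(seq_len(nl_RO), seq_len(nl_BS)),
    area_cm2 = area,
    distance_cm = dist
  )
}
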