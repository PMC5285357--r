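#' Logistic normalized cumulative shoot length
#'
#' Treating the bourse and its bourse shoot as one morphogenetic continuum,
#' the normalized cumulative length from the bourse base to the insertion
#' node of the leaf at normalized rank `nri` follows
#' `1 / (1 + exp((qi - nri) / si))`: short basal (rosette) internodes, a
#' steep median zone at the bourse-shoot base, flattening toward the apex.
#'
#' @param nri Normalized continuum rank(s), `R_I / nl`.
#' @param params List with logistic midpoint `qi` and scale `si > 0`.
#' @return Normalized cumulative length(s) in `(0, 1)`; equals 0.5 at
#'   `nri = qi` and is strictly increasing.
#' @export
logistic_ndi <- function(nri, params) {
  if (!is.finite(params$si) || params$si <= 0) {
    stop("logistic scale si must be positive", call. = FALSE)
  }
  1 / (1 + exp((params$qi - nri) / params$si))
}

#' Fit the logistic internode model
#'
#' Nonlinear least squares fit of the 2-parameter logistic (asymptote fixed
#' at 1 by the normalization) to pooled normalized cumulative lengths
#' `N(D_I) = D_I / (BL + BSL)` against normalized continuum ranks
#' `N(R_I) = R_I / nl` across spurs.
#'
#' @param records Data frame with columns `spur_id`, `rank_continuum`,
#'   `cum_length_cm`, `bourse_length_cm`, `bourse_shoot_length_cm` (see
#'   [read_internode_table()]). The continuum leaf count of each spur is its
#'   largest recorded rank.
#' @return List of class `internode_params`: `qi`, `si`, `fit_r2` (squared
#'   Pearson correlation of observed and fitted), `rmse` (normalized scale),
#'   `n` (points).
#' @export
fit_internode_model <- function(records) {
  records <- as.data.frame(records)
  need <- c("spur_id", "rank_continuum", "cum_length_cm",
            "bourse_length_cm", "bourse_shoot_length_cm")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("internode records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nl <- stats::ave(records$rank_continuum, records$spur_id, FUN = max)
  nri <- records$rank_continuum / nl
  ndi <- records$cum_length_cm /
    (records$bourse_length_cm + records$bourse_shoot_length_cm)
  if (length(nri) < 4L || stats::sd(ndi) == 0) {
    stop("degenerate internode data: need >= 4 points with varying cumulative length",
         call. = FALSE)
  }
  start <- list(qi = stats::median(nri), si = 0.1)
  fit <- tryCatch(
    stats::nls(ndi ~ 1 / (1 + exp((qi - nri) / si)), start = start,
               # scaleOffset makes the convergence test valid for
               # zero-residual (noise-free) data
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      stop(sprintf(
        "internode logistic fit did not converge (n = %d, start qi = %.3f): %s",
        length(nri), start$qi, conditionMessage(e)), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  fitted_vals <- stats::fitted(fit)
  structure(list(
    qi = unname(est[["qi"]]),
    si = unname(est[["si"]]),
    fit_r2 = stats::cor(ndi, fitted_vals)^2,
    rmse = sqrt(mean((ndi - fitted_vals)^2)),
    n = length(nri)
  ), class = "internode_params")
}

#' @export
print.internode_params <- function(x, ...) {
  cat(sprintf("Logistic internode model: qi = %.4f, si = %.4f (n = %d, R2 = %.3f, RMSE = %.3f)\n",
              x$qi, x$si, x$n, x$fit_r2, x$rmse))
  invisible(x)
}

#' Predict cumulative shoot length at a continuum rank
#'
#' `D_I = (BL + BSL) / (1 + exp((qi - R_I/nl) / si))`: the distance from the
#' bourse base to the insertion node of the leaf at continuum rank `R_I`,
#' given the total continuum length `BL + BSL`.
#'
#' @param R_I Continuum rank(s), integers in `1..nl`.
#' @param nl Total leaf count of the bourse + bourse-shoot continuum.
#' @param BL Bourse length, cm.
#' @param BSL Bourse-shoot length, cm.
#' @param params List with `qi` and `si` (default the shipped values).
#' @return Cumulative length(s) in cm, strictly increasing in `R_I` and
#'   always below `BL + BSL`.
#' @export
predict_cumulative_length <- function(R_I, nl, BL, BSL,
                                      params = list(qi = 0.62, si = 0.12)) {
  check_rank(R_I, nl)
  if (!is.finite(BL + BSL) || BL + BSL <= 0) {
    stop("BL + BSL must be positive", call. = FALSE)
  }
  logistic_ndi(R_I / nl, params) * (BL + BSL)
}
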