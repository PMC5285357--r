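#' Normalized leaf rank
#'
#' Ranks are counted acropetally (1 = basal leaf). For rosettes and vegetative
#' shoots the normalized rank is `R/nl`. For bourse shoots the biggest leaf
#' sits overwhelmingly at rank 2, so ranks are shifted by two before dividing:
#' `(R - 2)/nl`, which places the profile peak at normalized rank zero for
#' every shoot and aligns the curves without stretching them.
#'
#' @param R Leaf rank(s), integers in `1..nl`.
#' @param nl Number of leaves on the shoot.
#' @param shoot_type One of `"BS"`, `"RO"`, `"VS"`.
#' @return Normalized rank(s).
#' @export
normalized_rank <- function(R, nl, shoot_type = c("BS", "RO", "VS")) {
  shoot_type <- match.arg(shoot_type)
  check_rank(R, nl)
  if (shoot_type == "BS") (R - 2) / nl else R / nl
}

#' Normalized leaf area
#'
#' Individual leaf area divided by the area of the biggest leaf on the same
#' shoot; lies in `[0, 1]` and equals 1 exactly for the biggest leaf.
#'
#' @param A_R Leaf area(s), cm2, with `0 <= A_R <= Amax`.
#' @param Amax Area of the biggest leaf on the shoot, cm2, positive.
#' @return Normalized area(s) in `[0, 1]`.
#' @export
normalized_area <- function(A_R, Amax) {
  if (!is.finite(Amax) || Amax <= 0) {
    stop("degenerate shoot: Amax must be positive", call. = FALSE)
  }
  if (any(!is.finite(A_R)) || any(A_R < 0) || any(A_R > Amax + 1e-9 * Amax)) {
    stop("leaf areas must lie in [0, Amax]", call. = FALSE)
  }
  pmin(A_R / Amax, 1)
}

#' Lorentz leaf-size profile
#'
#' The unimodal curve `1 / (1 + (x - x0)^2 / s^2)` describing normalized leaf
#' area as a function of normalized rank. Its maximum is 1 at `x = x0` (the
#' normalized rank of the biggest leaf) and `s` controls how fast leaf size
#' falls off away from the peak.
#'
#' @param x Normalized rank(s).
#' @param x0 Peak position (normalized rank of the biggest leaf).
#' @param s Scale parameter, positive.
#' @return Profile value(s) in `(0, 1]`.
#' @export
lorentz <- function(x, x0, s) {
  if (!is.finite(s) || s <= 0) stop("Lorentz scale s must be positive", call. = FALSE)
  1 / (1 + (x - x0)^2 / s^2)
}

#' Closed-form integral of the Lorentz profile
#'
#' The definite integral of [lorentz()] over `[lower, upper]` has the arctan
#' closed form `s * (atan((upper - x0)/s) - atan((lower - x0)/s))`. Averaged
#' over the normalized-rank interval of width 1 it equals the slope `beta`
#' relating total leaf area to `nl * Amax`, which is what makes the profile
#' scale `s` recoverable from `beta` alone (see [solve_s()]).
#'
#' @param s Scale parameter, positive.
#' @param lower,upper Integration bounds on normalized rank, `lower < upper`.
#' @param x0 Peak position.
#' @return Value of the integral; strictly increasing in `s` with supremum
#'   `upper - lower`.
#' @export
beta_closed_form <- function(s, lower, upper, x0 = 0) {
  if (any(!is.finite(s)) || any(s <= 0)) stop("s must be positive", call. = FALSE)
  if (!(lower < upper)) stop("lower bound must be below upper bound", call. = FALSE)
  s * (atan((upper - x0) / s) - atan((lower - x0) / s))
}

#' Integration bounds for the bourse-shoot profile
#'
#' With the rank-2 shift, a bourse shoot with `nl` leaves spans normalized
#' ranks `-2/nl` to `(nl - 2)/nl` (total width 1). The bounds are used
#' literally for every `nl >= 1`, including `nl` of 1 or 2 where the whole
#' interval lies at or below zero.
#'
#' @param nl Number of leaves.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bs_bounds <- function(nl) {
  if (!is.finite(nl) || nl < 1) stop("nl must be a positive count", call. = FALSE)
  c(-2 / nl, (nl - 2) / nl)
}

#' Solve the profile scale s from beta
#'
#' Inverts the arctan closed form: finds the unique `s > 0` such that the
#' integral of the Lorentz profile over the shoot's normalized-rank interval
#' equals `beta`. For bourse shoots the interval depends on `nl`
#' (see [bs_bounds()]) and the peak is fixed at normalized rank 0; for
#' rosettes the interval is `[0, 1]` with the peak at `x0`. Because the
#' closed form is strictly increasing in `s` with supremum equal to the
#' interval width (1 in both cases), the root exists and is unique for any
#' `0 < beta < 1`; it is found by bracketed root finding to
#' `|delta beta| <= 1e-10`.
#'
#' @param beta Through-origin slope of total leaf area on `nl * Amax`,
#'   in `(0, 1)`.
#' @param shoot_type `"BS"` or `"RO"`.
#' @param nl Leaf count (required for `"BS"`).
#' @param x0 Peak position (required for `"RO"`).
#' @return The scale parameter `s`.
#' @examples
#' solve_s(0.67, "BS", nl = 5)        # about 0.357
#' solve_s(0.69, "RO", x0 = 0.63)     # about 0.387
#' @export
solve_s <- function(beta, shoot_type = c("BS", "RO"), nl = NULL, x0 = NULL) {
  shoot_type <- match.arg(shoot_type)
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive", call. = FALSE)
  if (shoot_type == "BS") {
    if (is.null(nl)) stop("nl is required for the bourse-shoot profile", call. = FALSE)
    b <- bs_bounds(nl)
    lower <- b[1]; upper <- b[2]; x0 <- 0
  } else {
    if (is.null(x0)) stop("x0 is required for the rosette profile", call. = FALSE)
    lower <- 0; upper <- 1
  }
  width <- upper - lower
  if (beta >= width) {
    stop(sprintf(
      "no solution: beta (%.4f) must be below the interval width (%.4f)",
      beta, width
    ), call. = FALSE)
  }
  g <- function(s) beta_closed_form(s, lower, upper, x0) - beta
  root <- stats::uniroot(g, lower = 1e-9, upper = 1e9,
                         tol = .Machine$double.eps^0.75)$root
  stopifnot(abs(g(root)) <= 1e-10)
  root
}

#' Tabulate the bourse-shoot scale parameter per leaf count
#'
#' The bourse-shoot model keeps one `s` per leaf count, obtained by solving
#' the closed form at the group's `beta` for each `nl` — mirroring how the
#' scale table is fixed once at parameterization time and then looked up.
#'
#' @param beta Group slope parameter, in `(0, 1)`.
#' @param nl_max Largest leaf count to tabulate (default 18, the largest
#'   observed on a bourse shoot).
#' @return Named numeric vector of length `nl_max`, names `"1"..as.character(nl_max)`.
#' @export
s_table <- function(beta, nl_max = 18L) {
  s <- vapply(seq_len(nl_max), function(nl) solve_s(beta, "BS", nl = nl), numeric(1))
  stats::setNames(s, as.character(seq_len(nl_max)))
}

#' Fit the allometric slope beta
#'
#' `beta` is the through-origin least-squares slope of total shoot leaf area
#' (`TLA`) on the product `nl * Amax`. Physically `TLA <= nl * Amax` on every
#' shoot, so the slope lies in `(0, 1]`.
#'
#' @param shoots Data frame of per-shoot summaries with columns `TLA_cm2`,
#'   `nl`, `Amax_cm2` (as produced by [shoot_summaries()]).
#' @return List with `beta`, `fit_r2` (squared Pearson correlation of `TLA`
#'   and `nl * Amax`; `NA` when degenerate) and `n`.
#' @export
fit_beta <- function(shoots) {
  if (is.null(shoots) || nrow(as.data.frame(shoots)) == 0L) {
    stop("no shoots supplied to fit_beta", call. = FALSE)
  }
  shoots <- as.data.frame(shoots)
  x <- shoots$nl * shoots$Amax_cm2
  y <- shoots$TLA_cm2
  if (any(!is.finite(x)) || any(!is.finite(y)) || sum(x^2) <= 0) {
    stop("fit_beta needs finite TLA and positive nl * Amax", call. = FALSE)
  }
  beta <- sum(x * y) / sum(x^2)
  r2 <- if (length(x) >= 2L && stats::sd(x) > 0 && stats::sd(y) > 0) {
    stats::cor(x, y)^2
  } else {
    NA_real_
  }
  list(beta = beta, fit_r2 = r2, n = length(x))
}

#' Estimate the rosette peak position x0
#'
#' The normalized rank of the biggest leaf for the rosette profile, estimated
#' as the mean of `RAmax / nl` across rosettes. (The original workflow fixed
#' this jointly with `s` without detailing the procedure; the mean normalized
#' peak rank is this package's choice and is flagged as such in the methods
#' vignette.) Single-leaf rosettes are excluded: their peak-rank ratio is 1
#' by construction and carries no information about peak position.
#'
#' @param rosettes Data frame of per-shoot summaries with columns `RAmax`
#'   and `nl`.
#' @return Mean normalized peak rank, in `(0, 1]`.
#' @export
estimate_x0 <- function(rosettes) {
  rosettes <- as.data.frame(rosettes)
  if (nrow(rosettes) == 0L) stop("no rosettes supplied", call. = FALSE)
  if (is.null(rosettes$RAmax) || any(!is.finite(rosettes$RAmax))) {
    stop("rosette ranks are missing: x0 cannot be estimated", call. = FALSE)
  }
  rosettes <- rosettes[rosettes$nl >= 2L, , drop = FALSE]
  if (nrow(rosettes) == 0L) {
    stop("x0 needs at least one rosette with 2 or more leaves", call. = FALSE)
  }
  mean(rosettes$RAmax / rosettes$nl)
}

check_rank <- function(R, nl) {
  if (any(!is.finite(R)) || any(R < 1) || any(R > nl) || any(R != round(R))) {
    stop(sprintf("rank out of range: ranks must be integers in 1..%d", as.integer(nl)),
         call. = FALSE)
  }
  invisible(TRUE)
}
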