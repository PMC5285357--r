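#' Elliptical leaf-blade area
#'
#' Apple leaf blades are treated as ellipses with major axis along the midrib,
#' so blade area is `pi * L * W / 4` with `L` the blade length and `W` the
#' blade width.
#'
#' @param L Blade length in cm (major axis). Must be positive.
#' @param W Blade width in cm (minor axis). Must be positive and not exceed
#'   `L`; the caller is responsible for assigning the major axis to `L`.
#' @return Blade area in cm2. Vectorized over `L` and `W`.
#' @examples
#' ellipse_area(5, 3)  # 11.781 cm2
#' @export
ellipse_area <- function(L, W) {
  check_blade_axes(L, W)
  pi * L * W / 4
}

#' Eccentricity of an elliptical leaf blade
#'
#' `e = sqrt(L^2 - W^2) / L`, an indicator of blade shape: 0 for a circular
#' blade, approaching 1 for a very elongated one.
#'
#' @inheritParams ellipse_area
#' @return Eccentricity in `[0, 1)`. Vectorized.
#' @export
eccentricity <- function(L, W) {
  check_blade_axes(L, W)
  sqrt(L^2 - W^2) / L
}

#' Width/length ratio from eccentricity
#'
#' The blade width/length ratio `k = W/L` relates to eccentricity through
#' `k = sqrt(1 - e^2)`; `k` is the shape constant carried by the leaf-area
#' models, assumed invariant within a shoot type and genotype.
#'
#' @param e Eccentricity, in `[0, 1)`.
#' @return `k` in `(0, 1]`. Vectorized.
#' @export
k_from_e <- function(e) {
  if (any(!is.finite(e)) || any(e < 0) || any(e >= 1)) {
    stop("eccentricity must lie in [0, 1)", call. = FALSE)
  }
  sqrt(1 - e^2)
}

#' Fit the blade width/length ratio k
#'
#' Estimates the shape constant `k` for a set of leaves by least squares
#' through the origin (`W = k L`); the shape model has no intercept. The
#' reported fit statistic is the squared Pearson correlation between width
#' and length.
#'
#' @param leaves Data frame with columns `blade_length_cm` and
#'   `blade_width_cm` (one row per leaf), or a list with elements `L` and `W`.
#' @return An object of class `shape_params`: list with `k`, `e`
#'   (`sqrt(1 - k^2)`), `fit_r2` (`NA` when fewer than 2 distinct leaves) and
#'   `n`.
#' @export
fit_k <- function(leaves) {
  if (is.data.frame(leaves)) {
    L <- leaves$blade_length_cm
    W <- leaves$blade_width_cm
  } else {
    L <- leaves$L
    W <- leaves$W
  }
  if (is.null(L) || is.null(W)) {
    stop("leaves must provide blade_length_cm and blade_width_cm", call. = FALSE)
  }
  keep <- is.finite(L) & is.finite(W)
  L <- L[keep]
  W <- W[keep]
  if (length(L) < 1L) stop("no usable leaves for the k fit", call. = FALSE)
  check_blade_axes(L, W)
  if (sum(L^2) <= 0) stop("degenerate k fit: all blade lengths are zero", call. = FALSE)
  k <- sum(L * W) / sum(L^2)
  r2 <- if (length(L) >= 2L && stats::sd(L) > 0 && stats::sd(W) > 0) {
    stats::cor(L, W)^2
  } else {
    NA_real_
  }
  structure(
    list(k = k, e = sqrt(max(0, 1 - k^2)), fit_r2 = r2, n = length(L)),
    class = "shape_params"
  )
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf("Leaf shape: k = %.4f (e = %.4f), n = %d leaves", x$k, x$e, x$n))
  if (!is.na(x$fit_r2)) cat(sprintf(", R2 = %.3f", x$fit_r2))
  cat("\n")
  invisible(x)
}

# Shared validation: positive axes, width not exceeding length. A width
# larger than the length is an orientation error the caller must fix, never
# silently swapped.
check_blade_axes <- function(L, W) {
  if (any(!is.finite(L)) || any(!is.finite(W)) || any(L <= 0) || any(W <= 0)) {
    stop("blade length and width must be positive finite numbers", call. = FALSE)
  }
  if (any(W > L)) {
    stop("blade width exceeds length: assign the major axis to L", call. = FALSE)
  }
  invisible(TRUE)
}
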