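#' Configuration of the synthetic orchard world
#'
#' Defaults emulate the structure and sample sizes of the original orchard
#' measurements: per-genotype shoot counts close to the published ones
#' (about 260 bourse shoots, 232 rosettes, 40 vegetative shoots, 24 spur
#' continua), leaf counts from a truncated Poisson on 1..18 (mean 6 for
#' bourse shoots, 5 for rosettes, 12 for vegetative shoots), lognormal
#' biggest-leaf lengths (median 8 cm, sigma-log 0.2), multiplicative
#' lognormal area noise (CV 10 percent), Gaussian eccentricity noise
#' (sd 0.03), the published biggest-leaf rank distribution for bourse shoots,
#' and Gaussian noise (sd 0.05) on normalized cumulative internode length.
#' The generating ("truth") parameters default to the shipped published
#' values.
#'
#' @param n_shoots Named list of per-genotype shoot counts per shoot type.
#' @param nl_mean Mean leaf count per shoot type (truncated Poisson).
#' @param lmax_meanlog,lmax_sdlog Lognormal parameters of the biggest-leaf
#'   blade length, cm.
#' @param area_cv Coefficient of variation of the multiplicative leaf-area
#'   noise (0 switches noise off).
#' @param nl_min Smallest leaf count drawn (default 1). Single-leaf shoots
#'   carry no profile information and always satisfy `TLA = nl * Amax`
#'   whatever the generating `beta`; closure experiments set `nl_min = 2`.
#' @param ecc_sd Standard deviation of the Gaussian noise on leaf
#'   eccentricity (0 switches it off).
#' @param peak_rank_probs Matrix of biggest-leaf rank probabilities for
#'   bourse shoots, rows AR/FU/RB, columns ranks 1..6 (defaults to the
#'   published distribution; the mode is rank 2 in every genotype).
#' @param internode List: `n_spurs`, `nl_mean` (continuum leaf count),
#'   `bl_meanlog`, `bsl_meanlog`, `len_sdlog` (lognormal bourse and
#'   bourse-shoot lengths, cm), `noise_sd` (Gaussian, on normalized length).
#' @param truth Generating parameters: `beta` per shoot type and genotype,
#'   `x0`, `k` per shoot type and genotype, `qi`, `si`.
#' @return Configuration list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_shoots = list(BS = c(AR = 100, FU = 80, RB = 80),
                    RO = c(AR = 78, FU = 77, RB = 77),
                    VS = c(AR = 20, FU = 20)),
    nl_mean = c(BS = 6, RO = 5, VS = 12),
    lmax_meanlog = log(8), lmax_sdlog = 0.2,
    area_cv = 0.10, ecc_sd = 0.03, nl_min = 1L,
    peak_rank_probs = rbind(
      AR = c(0.0065, 0.5000, 0.2662, 0.1558, 0.0584, 0.0130),
      FU = c(0.0808, 0.6869, 0.1414, 0.0357, 0.0089, 0),
      RB = c(0, 0.8750, 0.0804, 0.0357, 0.0089, 0)
    ),
    internode = list(n_spurs = 24, nl_mean = 12, bl_meanlog = log(3),
                     bsl_meanlog = log(12), len_sdlog = 0.2, noise_sd = 0.05),
    truth = list(
      beta = list(BS = c(AR = 0.67, FU = 0.67, RB = 0.50),
                  RO = c(AR = 0.69, FU = 0.69, RB = 0.69)),
      x0 = 0.63,
      k = list(BS = c(AR = 0.60, FU = 0.64, RB = 0.66),
               RO = c(AR = 0.75, FU = 0.74, RB = 0.71),
               VS = c(AR = 0.56, FU = 0.56)),
      qi = 0.62, si = 0.12
    )) {
  structure(list(n_shoots = n_shoots, nl_mean = nl_mean,
                 lmax_meanlog = lmax_meanlog, lmax_sdlog = lmax_sdlog,
                 area_cv = area_cv, ecc_sd = ecc_sd, nl_min = as.integer(nl_min),
                 peak_rank_probs = peak_rank_probs, internode = internode,
                 truth = truth), class = "synthetic_config")
}

# Truncated Poisson on [lo, hi] by rejection.
rtrunc_pois <- function(n, lambda, lo = 1L, hi = 18L) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- stats::rpois(2L * n + 10L, lambda)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# Scale parameter making the *discrete* mean of the Lorentz profile over the
# shoot's integer ranks equal beta, so the allometric relation
# TLA = beta * nl * Amax holds exactly on every generated shoot. Returns the
# lower bracket when beta is at/below the attainable minimum (single-leaf
# shoots, or the boundary case of the widest profiles).
solve_s_discrete <- function(beta, nl, r_peak) {
  m <- function(s) mean(1 / (1 + (seq_len(nl) - r_peak)^2 / (nl^2 * s^2)))
  if (m(1e-6) >= beta) return(1e-6)
  stats::uniroot(function(s) m(s) - beta, c(1e-6, 1e6),
                 tol = .Machine$double.eps^0.75)$root
}

#' Generate a synthetic per-leaf dataset
#'
#' For every shoot: draw the leaf count and the biggest-leaf length; place
#' the biggest leaf (bourse shoots: published rank distribution, clamped to
#' `nl`; rosettes: nearest rank to `nl * x0`; vegetative shoots: apical
#' leaf); lay down the leaf-size profile (Lorentz for bourse shoots and
#' rosettes — with the scale solved so the discrete profile mean equals the
#' generating `beta` exactly — linear ramp for vegetative shoots); apply
#' multiplicative lognormal noise to the normalized profile, anchored at the
#' biggest leaf (its normalized area is 1 by construction) and capped at 1;
#' derive blade widths from the genotype eccentricity plus Gaussian noise and
#' blade lengths back from area and width, so `A = pi L W / 4` holds on
#' every row.
#'
#' @param config See [synthetic_config()].
#' @param seed Integer master seed; all stages draw from named substreams of
#'   it.
#' @return List: `leaves` (validated leaf table), `truth` (the generating
#'   parameters plus per-shoot realized draws: `nl`, `Lmax_in`, `peak_rank`,
#'   `s_gen`).
#' @export
generate_leaf_dataset <- function(config = synthetic_config(), seed = 1L) {
  with_seed(substream_seed(seed, "leaves"), {
    rows <- list(); draws <- list()
    noise_sdlog <- if (config$area_cv > 0) sqrt(log(1 + config$area_cv^2)) else 0
    for (st in names(config$n_shoots)) {
      for (g in names(config$n_shoots[[st]])) {
        n <- config$n_shoots[[st]][[g]]
        if (n < 1) next
        k_g <- config$truth$k[[st]][[g]]
        e_g <- sqrt(max(0, 1 - k_g^2))
        for (i in seq_len(n)) {
          nl <- rtrunc_pois(1L, config$nl_mean[[st]],
                            lo = if (is.null(config$nl_min)) 1L else config$nl_min)
          lmax <- stats::rlnorm(1L, config$lmax_meanlog, config$lmax_sdlog)
          amax <- (pi / 4) * k_g * lmax^2
          if (st == "BS") {
            r_peak <- min(sample.int(6L, 1L, prob = config$peak_rank_probs[g, ]), nl)
            s_gen <- solve_s_discrete(config$truth$beta$BS[[g]], nl, r_peak)
            prof <- 1 / (1 + (seq_len(nl) - r_peak)^2 / (nl^2 * s_gen^2))
          } else if (st == "RO") {
            r_peak <- min(max(round(nl * config$truth$x0), 1L), nl)
            s_gen <- solve_s_discrete(config$truth$beta$RO[[g]], nl, r_peak)
            prof <- 1 / (1 + (seq_len(nl) - r_peak)^2 / (nl^2 * s_gen^2))
          } else {
            r_peak <- nl
            s_gen <- NA_real_
            prof <- seq_len(nl) / nl
          }
          eps <- if (noise_sdlog > 0) exp(stats::rnorm(nl, 0, noise_sdlog)) else rep(1, nl)
          eps[r_peak] <- 1  # the biggest leaf anchors the normalization
          n_area <- pmin(prof * eps, 1 - 1e-9)
          n_area[r_peak] <- 1
          area <- amax * n_area
          e_leaf <- pmin(pmax(e_g + stats::rnorm(nl, 0, config$ecc_sd), 0), 0.98)
          k_leaf <- sqrt(1 - e_leaf^2)
          len <- sqrt(4 * area / (pi * k_leaf))
          wid <- k_leaf * len
          id <- sprintf("%s_%s_%03d", st, g, i)
          rows[[id]] <- data.frame(
            shoot_id = id, genotype = g, shoot_type = st, rank = seq_len(nl),
            blade_length_cm = len, blade_width_cm = wid, area_cm2 = area,
            stringsAsFactors = FALSE
          )
          draws[[id]] <- data.frame(
            shoot_id = id, genotype = g, shoot_type = st, nl = nl,
            Lmax_in = lmax, peak_rank = r_peak, s_gen = s_gen,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    leaves <- do.call(rbind, rows)
    rownames(leaves) <- NULL
    realized <- do.call(rbind, draws)
    rownames(realized) <- NULL
    list(leaves = validate_leaf_table(leaves),
         truth = c(config$truth, list(seed = seed, shoots = realized)))
  })
}

#' Generate a synthetic spur internode dataset
#'
#' Per spur: draw the continuum leaf count and the bourse and bourse-shoot
#' lengths; normalized cumulative lengths follow the logistic law at the
#' generating `(qi, si)` plus clamped Gaussian noise, repaired to be
#' nondecreasing by isotonic projection (cumulative length is physically
#' nondecreasing); cumulative lengths are the normalized values times
#' `BL + BSL`.
#'
#' @inheritParams generate_leaf_dataset
#' @return List: `internodes` (validated internode table), `truth`.
#' @export
generate_internode_dataset <- function(config = synthetic_config(), seed = 1L) {
  with_seed(substream_seed(seed, "internodes"), {
    ic <- config$internode
    rows <- lapply(seq_len(ic$n_spurs), function(i) {
      nl <- rtrunc_pois(1L, ic$nl_mean, lo = 4L)
      bl <- stats::rlnorm(1L, ic$bl_meanlog, ic$len_sdlog)
      bsl <- stats::rlnorm(1L, ic$bsl_meanlog, ic$len_sdlog)
      nd <- logistic_ndi(seq_len(nl) / nl, list(qi = config$truth$qi,
                                                si = config$truth$si))
      if (ic$noise_sd > 0) {
        nd <- nd + stats::rnorm(nl, 0, ic$noise_sd)
        nd <- pmin(pmax(nd, 1e-4), 1 - 1e-4)
        nd <- stats::isoreg(seq_len(nl), nd)$yf  # monotone repair
      }
      data.frame(
        spur_id = sprintf("SP_%03d", i), rank_continuum = seq_len(nl),
        cum_length_cm = nd * (bl + bsl), bourse_length_cm = bl,
        bourse_shoot_length_cm = bsl, stringsAsFactors = FALSE
      )
    })
    internodes <- do.call(rbind, rows)
    rownames(internodes) <- NULL
    list(internodes = validate_internode_table(internodes),
         truth = list(qi = config$truth$qi, si = config$truth$si, seed = seed))
  })
}

#' Generate an hourly temperature series
#'
#' Sinusoidal daily cycle (24 readings per day): minimum near 03:00,
#' maximum near 15:00, with optional day-to-day Gaussian jitter of the daily
#' mean. Deterministic for a given seed.
#'
#' @param days Number of days.
#' @param start Date of the first day.
#' @param mean_C Mean daily temperature, degC.
#' @param amplitude_C Half-range of the daily cycle, degC.
#' @param day_jitter_sd Standard deviation of daily-mean jitter (default 0).
#' @param seed Integer seed.
#' @return Data frame with columns `timestamp_iso`, `temp_C`
#'   (`24 * days` rows).
#' @export
generate_temperature_series <- function(days, start = "2014-04-10",
                                        mean_C = 17, amplitude_C = 6,
                                        day_jitter_sd = 0, seed = 1L) {
  with_seed(substream_seed(seed, "temperature"), {
    dates <- seq(as.Date(start), by = "day", length.out = days)
    jitter <- if (day_jitter_sd > 0) stats::rnorm(days, 0, day_jitter_sd) else rep(0, days)
    hours <- 0:23
    cycle <- -cos(2 * pi * (hours - 3) / 24)  # min at 03:00, max at 15:00
    data.frame(
      timestamp_iso = as.vector(t(outer(format(dates), sprintf("%02d:00:00", hours),
                                        paste))),
      temp_C = as.vector(t(outer(mean_C + jitter, amplitude_C * cycle, `+`)))
    )
  })
}
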