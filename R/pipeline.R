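#' Pipeline configuration
#'
#' @param split_fraction Fraction of shoots assigned to the training set
#'   (default 2/3).
#' @param seed Integer seed controlling the random split.
#' @param grouping Explicit genotype groups per shoot type used for the
#'   `beta` fits. Default: bourse shoots pool AR with FU against RB; rosettes
#'   pool all three genotypes; vegetative shoots pool AR and FU.
#' @param significance_level Level for the grouping tests (default 0.05).
#' @return Configuration list.
#' @export
pipeline_config <- function(split_fraction = 2 / 3, seed = 1L,
                            grouping = list(
                              BS = list(c("AR", "FU"), "RB"),
                              RO = list(c("AR", "FU", "RB")),
                              VS = list(c("AR", "FU"))
                            ),
                            significance_level = 0.05) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  list(split_fraction = split_fraction, seed = as.integer(seed),
       grouping = grouping, significance_level = significance_level)
}

#' Split shoots into training and testing sets
#'
#' Random, seed-reproducible partition: `round(fraction * n)` shoots go to
#' the training set, the rest to the testing set.
#'
#' @param shoots Data frame (one row per shoot).
#' @param fraction Training fraction, default 2/3.
#' @param seed Integer seed.
#' @return List with data frames `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(shoots, fraction = 2 / 3, seed = 1L) {
  shoots <- as.data.frame(shoots)
  n <- nrow(shoots)
  if (n < 3L) stop("need at least 3 shoots to split", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, round(fraction * n)))
  list(train = shoots[idx, , drop = FALSE],
       test = shoots[-idx, , drop = FALSE])
}

#' Normality-routed group comparison
#'
#' Tests whether groups differ on a variable the way the original analysis
#' did: Shapiro-Wilk on the residuals about group means decides the route —
#' ANOVA when residuals look normal, Kruskal-Wallis otherwise. When the
#' omnibus test is significant and there are more than two groups, pairwise
#' tests (uncorrected, matching the source analysis) identify which groups
#' may still be pooled; poolable sets are the connected components of the
#' graph of non-significant pairs.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length as `values`; at least 2 groups
#'   with at least 3 observations each.
#' @param level Significance level (default 0.05).
#' @return List: `method`, `p_value`, `normal_residuals`, `pool` (TRUE when
#'   the omnibus test finds no difference), `pooled_groups` (list of label
#'   sets that may share one parameter), `pairwise` (matrix of pairwise
#'   p-values or `NULL`).
#' @export
compare_groups <- function(values, groups, level = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 3L)) {
    stop("group(s) with fewer than 3 observations: ",
         paste(names(sizes)[sizes < 3L], collapse = ", "), call. = FALSE)
  }
  res <- values - stats::ave(values, groups)
  if (stats::sd(res) < 1e-12) {
    # all groups internally constant: compare means directly
    means <- tapply(values, groups, mean)
    same <- max(means) - min(means) < 1e-12
    return(list(method = "degenerate", p_value = if (same) 1 else 0,
                normal_residuals = NA, pool = same,
                pooled_groups = if (same) list(levels(groups))
                                else as.list(levels(groups)),
                pairwise = NULL))
  }
  sw_sample <- if (length(res) > 5000L) res[seq_len(5000L)] else res
  normal <- stats::shapiro.test(sw_sample)$p.value > 0.05
  if (normal) {
    method <- "anova"
    p <- summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1]
  } else {
    method <- "kruskal-wallis"
    p <- stats::kruskal.test(values, groups)$p.value
  }
  pool <- p >= level
  pairwise <- NULL
  if (pool) {
    pooled <- list(levels(groups))
  } else if (nlevels(groups) == 2L) {
    pooled <- as.list(levels(groups))
  } else {
    pw_fun <- if (normal) {
      function(a, b) stats::t.test(values[groups == a], values[groups == b])$p.value
    } else {
      function(a, b) suppressWarnings(
        stats::wilcox.test(values[groups == a], values[groups == b])$p.value)
    }
    lev <- levels(groups)
    pairwise <- matrix(NA_real_, nlevels(groups), nlevels(groups),
                       dimnames = list(lev, lev))
    parent <- seq_along(lev)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(lev)[-1]) for (j in seq_len(i - 1)) {
      pairwise[i, j] <- pw_fun(lev[i], lev[j])
      if (pairwise[i, j] >= level) parent[find(i)] <- find(j)
    }
    comp <- vapply(seq_along(lev), find, integer(1))
    pooled <- unname(lapply(split(lev, comp), identity))
  }
  list(method = method, p_value = p, normal_residuals = normal, pool = pool,
       pooled_groups = pooled, pairwise = pairwise)
}

#' Goodness-of-fit summary for predictions
#'
#' @param observed Observed values.
#' @param predicted Predicted values, same length.
#' @return List: `slope` (through-origin slope of observed on predicted),
#'   `slope_lm` (slope of the with-intercept regression, also reported since
#'   the source testing regressions are ambiguous on this point), `r2`
#'   (squared Pearson correlation), `rmse`, `n`.
#' @export
evaluate_fit <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted)) {
    stop("observed and predicted must be nonempty and equal length", call. = FALSE)
  }
  if (stats::sd(observed) == 0) {
    stop("degenerate evaluation: observed values have zero variance", call. = FALSE)
  }
  slope <- sum(observed * predicted) / sum(predicted^2)
  slope_lm <- if (stats::sd(predicted) > 0) {
    unname(stats::coef(stats::lm(observed ~ predicted))[2])
  } else {
    NA_real_
  }
  list(slope = slope, slope_lm = slope_lm,
       r2 = stats::cor(observed, predicted)^2,
       rmse = sqrt(mean((observed - predicted)^2)),
       n = length(observed))
}

#' Run the full parameterization / calibration / testing workflow
#'
#' Executes, per shoot type present in the data, the staged workflow used to
#' build the leaf-area models:
#' \enumerate{
#'   \item group comparison of the per-shoot slope ratio `TLA / (nl Amax)`
#'     across genotypes (reported; parameters use the configured grouping);
#'   \item per group: train/test split, through-origin `beta` fit on the
#'     training shoots;
#'   \item scale parameter: per-`nl` table solved from `beta` (bourse
#'     shoots), or peak position `x0` estimated from training rosettes and a
#'     single `s` solved from `beta` (rosettes);
#'   \item per genotype: `k` fit on training leaves;
#'   \item per genotype: calculated total leaf areas on the training shoots
#'     (uncalibrated model) against measured ones give the calibration slope
#'     `alpha`;
#'   \item evaluation of the calibrated model on the testing shoots (slope,
#'     R2, RMSE).
#' }
#' Vegetative shoots get the descriptive fit: pooled `k` and the
#' through-origin slope `p` of normalized area on normalized rank. When an
#' internode table is supplied the logistic internode model is fitted too.
#'
#' @param leaves Validated leaf table (see [validate_leaf_table()]).
#' @param config See [pipeline_config()].
#' @param internodes Optional validated internode table.
#' @return List of class `fit_report`: `params` (an `allom_params` set built
#'   from the fitted values), `report` (data frame of per-stage statistics),
#'   `grouping_tests`, `config`.
#' @export
run_parameterization <- function(leaves, config = pipeline_config(),
                                 internodes = NULL) {
  leaves <- validate_leaf_table(leaves)
  summaries <- shoot_summaries(leaves)
  params <- list(schema_version = 1L)
  report <- list()
  grouping_tests <- list()
  add_report <- function(...) {
    report[[length(report) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  }

  for (st in intersect(c("BS", "RO"), unique(summaries$shoot_type))) {
    sm <- summaries[summaries$shoot_type == st, , drop = FALSE]
    lv <- leaves[leaves$shoot_type == st, , drop = FALSE]
    ratio <- sm$TLA_cm2 / (sm$nl * sm$Amax_cm2)
    grouping_tests[[st]] <- if (length(unique(sm$genotype)) >= 2L &&
                                all(table(sm$genotype) >= 3L)) {
      compare_groups(ratio, sm$genotype, config$significance_level)
    } else {
      NULL
    }
    groups <- config$grouping[[st]]
    names(groups) <- vapply(groups, paste, character(1), collapse = "|")
    p_st <- list(beta = list(), groups = groups)
    if (st == "BS") p_st$s_table <- list()

    split_by_geno <- list()
    for (g in unique(sm$genotype)) {
      split_by_geno[[g]] <- split_train_test(
        sm[sm$genotype == g, , drop = FALSE],
        config$split_fraction,
        # distinct, reproducible substream per (type, genotype)
        substream_seed(config$seed, paste0(st, "_", g))
      )
    }
    for (gn in names(groups)) {
      train <- do.call(rbind, lapply(intersect(groups[[gn]], names(split_by_geno)),
                                     function(g) split_by_geno[[g]]$train))
      if (is.null(train) || nrow(train) == 0L) {
        stop(sprintf("stage beta [%s %s]: no training shoots", st, gn), call. = FALSE)
      }
      bfit <- fit_beta(train)
      p_st$beta[[gn]] <- bfit$beta
      add_report(stage = "beta", shoot_type = st, group = gn, n = bfit$n,
                 estimate = bfit$beta, r2 = bfit$fit_r2,
                 slope = NA_real_, rmse = NA_real_)
      if (st == "BS") {
        p_st$s_table[[gn]] <- s_table(bfit$beta, max(18L, max(sm$nl)))
      }
    }
    if (st == "RO") {
      train_all <- do.call(rbind, lapply(split_by_geno, `[[`, "train"))
      if (any(!is.finite(train_all$RAmax))) {
        stop("stage x0 [RO]: rosette ranks are missing", call. = FALSE)
      }
      p_st$x0 <- estimate_x0(train_all)
      beta_pooled <- p_st$beta[[1]]
      p_st$s <- solve_s(beta_pooled, "RO", x0 = p_st$x0)
      add_report(stage = "x0", shoot_type = "RO", group = "pooled",
                 n = nrow(train_all), estimate = p_st$x0, r2 = NA_real_,
                 slope = NA_real_, rmse = NA_real_)
      add_report(stage = "s", shoot_type = "RO", group = "pooled",
                 n = nrow(train_all), estimate = p_st$s, r2 = NA_real_,
                 slope = NA_real_, rmse = NA_real_)
    }

    p_st$k <- numeric(0); p_st$alpha <- numeric(0)
    for (g in sort(unique(sm$genotype))) {
      train_ids <- split_by_geno[[g]]$train$shoot_id
      kfit <- fit_k(lv[lv$shoot_id %in% train_ids, , drop = FALSE])
      p_st$k[[g]] <- kfit$k
      add_report(stage = "k", shoot_type = st, group = g, n = kfit$n,
                 estimate = kfit$k, r2 = kfit$fit_r2,
                 slope = NA_real_, rmse = NA_real_)
    }
    # calibration and testing need the assembled parameter set
    params[[st]] <- p_st
    for (g in sort(unique(sm$genotype))) {
      model0 <- calibrated_model(st, g, structure(params, class = "allom_params"),
                                 alpha = 1)
      ctla <- function(df) vapply(seq_len(nrow(df)), function(i) {
        predict_total_leaf_area(df$nl[i], df$Lmax_cm[i], model0)
      }, numeric(1))
      train <- split_by_geno[[g]]$train
      alpha <- calibrate_alpha(train$TLA_cm2, ctla(train))
      p_st$alpha[[g]] <- alpha
      add_report(stage = "alpha", shoot_type = st, group = g, n = nrow(train),
                 estimate = alpha, r2 = NA_real_, slope = NA_real_,
                 rmse = NA_real_)
      test <- split_by_geno[[g]]$test
      if (nrow(test) >= 2L) {
        ev <- evaluate_fit(test$TLA_cm2, alpha * ctla(test))
        add_report(stage = "test_TLA", shoot_type = st, group = g, n = ev$n,
                   estimate = NA_real_, r2 = ev$r2, slope = ev$slope,
                   rmse = ev$rmse)
      }
    }
    params[[st]] <- p_st
  }

  if ("VS" %in% summaries$shoot_type) {
    lv <- leaves[leaves$shoot_type == "VS", , drop = FALSE]
    sm <- summaries[summaries$shoot_type == "VS", , drop = FALSE]
    kfit <- fit_k(lv)
    amax <- stats::setNames(sm$Amax_cm2, sm$shoot_id)
    nlv <- stats::setNames(sm$nl, sm$shoot_id)
    na <- lv$area_cm2 / amax[lv$shoot_id]
    nr <- lv$rank / nlv[lv$shoot_id]
    p_slope <- sum(na * nr) / sum(nr^2)
    params$VS <- list(p = p_slope, k = stats::setNames(rep(kfit$k, 2), c("AR", "FU")))
    add_report(stage = "k", shoot_type = "VS", group = "pooled", n = kfit$n,
               estimate = kfit$k, r2 = kfit$fit_r2, slope = NA_real_,
               rmse = NA_real_)
    add_report(stage = "p", shoot_type = "VS", group = "pooled", n = length(na),
               estimate = p_slope, r2 = stats::cor(na, nr)^2, slope = NA_real_,
               rmse = NA_real_)
  }

  if (!is.null(internodes)) {
    internodes <- validate_internode_table(internodes)
    ifit <- fit_internode_model(internodes)
    params$internode <- list(qi = ifit$qi, si = ifit$si)
    add_report(stage = "internode", shoot_type = "spur", group = "pooled",
               n = ifit$n, estimate = ifit$qi, r2 = ifit$fit_r2,
               slope = ifit$si, rmse = ifit$rmse)
  }

  structure(list(
    params = structure(params, class = "allom_params"),
    report = do.call(rbind, report),
    grouping_tests = grouping_tests,
    config = config
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Allometric shoot model parameterization\n")
  print(x$report, digits = 4)
  invisible(x)
}

# Evaluate an expression under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic substream seed derived from a master seed and a stage name;
# reduced before multiplying so the product stays below 2^31 for any seed.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100000
  s <- as.numeric(seed) %% 2128043
  as.integer((s * 1009 + h) %% 2147483587)
}
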