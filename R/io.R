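#' Read and validate a per-leaf measurement table
#'
#' Expected CSV columns: `shoot_id`, `genotype` (AR/FU/RB), `shoot_type`
#' (BS/RO/VS), `rank`, `blade_length_cm`, `blade_width_cm` and optionally
#' `area_cm2` (recomputed from the ellipse model when absent). Validation is
#' row-addressed: duplicate `(shoot_id, rank)` pairs, non-contiguous ranks
#' within a shoot, non-numeric cells and widths exceeding lengths are all
#' rejected with the offending rows named.
#'
#' @param path CSV file path.
#' @return Validated leaf data frame (always including `area_cm2`).
#' @export
read_leaf_table <- function(path) {
  leaves <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_leaf_table(leaves)
}

#' Validate an in-memory leaf table
#'
#' Same checks as [read_leaf_table()] for tables built in code.
#'
#' @param leaves Data frame of per-leaf measurements.
#' @return The validated data frame, with `area_cm2` derived if absent.
#' @export
validate_leaf_table <- function(leaves) {
  leaves <- as.data.frame(leaves)
  need <- c("shoot_id", "genotype", "shoot_type", "rank",
            "blade_length_cm", "blade_width_cm")
  miss <- setdiff(need, names(leaves))
  if (length(miss)) {
    stop("leaf table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("rank", "blade_length_cm", "blade_width_cm",
                intersect("area_cm2", names(leaves)))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(leaves[[cl]]))
    bad <- which(is.na(v) & !is.na(leaves[[cl]]) | is.na(leaves[[cl]]))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing '%s' in row(s): %s", cl,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    leaves[[cl]] <- v
  }
  bad_geno <- which(!leaves$genotype %in% c("AR", "FU", "RB"))
  if (length(bad_geno)) {
    stop("unknown genotype in row(s): ",
         paste(utils::head(bad_geno, 5), collapse = ", "), call. = FALSE)
  }
  bad_type <- which(!leaves$shoot_type %in% c("BS", "RO", "VS"))
  if (length(bad_type)) {
    stop("unknown shoot_type in row(s): ",
         paste(utils::head(bad_type, 5), collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(leaves[c("shoot_id", "rank")]))
  if (length(dup)) {
    stop("duplicated (shoot_id, rank) in row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  by_shoot <- split(seq_len(nrow(leaves)), leaves$shoot_id)
  for (rows in by_shoot) {
    rk <- sort(leaves$rank[rows])
    if (!identical(as.integer(rk), seq_len(length(rk)))) {
      stop(sprintf("shoot '%s': ranks are not contiguous 1..nl (rows %s)",
                   leaves$shoot_id[rows[1]],
                   paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
    }
  }
  bad_axes <- which(leaves$blade_length_cm <= 0 | leaves$blade_width_cm <= 0 |
                      leaves$blade_width_cm > leaves$blade_length_cm)
  if (length(bad_axes)) {
    stop("invalid blade axes (nonpositive, or width > length) in row(s): ",
         paste(utils::head(bad_axes, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(leaves$area_cm2)) {
    leaves$area_cm2 <- ellipse_area(leaves$blade_length_cm, leaves$blade_width_cm)
  } else if (any(leaves$area_cm2 < 0)) {
    stop("negative leaf area", call. = FALSE)
  }
  leaves
}

#' Per-shoot summaries from a leaf table
#'
#' Derives, for every shoot: leaf count `nl`, biggest leaf area `Amax_cm2`,
#' the blade length of that biggest-area leaf `Lmax_cm`, total leaf area
#' `TLA_cm2` and the rank of the biggest leaf `RAmax` (ties broken toward the
#' lowest rank).
#'
#' @param leaves Validated leaf data frame.
#' @return Data frame, one row per shoot.
#' @export
shoot_summaries <- function(leaves) {
  leaves <- as.data.frame(leaves)
  if (is.null(leaves$area_cm2)) leaves <- validate_leaf_table(leaves)
  rows <- split(seq_len(nrow(leaves)), leaves$shoot_id)
  out <- lapply(rows, function(i) {
    a <- leaves$area_cm2[i]
    rk <- leaves$rank[i]
    best <- i[order(-a, rk)][1]  # ties toward the lowest rank
    data.frame(
      shoot_id = leaves$shoot_id[i[1]],
      genotype = leaves$genotype[i[1]],
      shoot_type = leaves$shoot_type[i[1]],
      nl = length(i),
      Amax_cm2 = leaves$area_cm2[best],
      Lmax_cm = leaves$blade_length_cm[best],
      TLA_cm2 = sum(a),
      RAmax = leaves$rank[best]
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and validate a spur internode table
#'
#' Expected CSV columns: `spur_id`, `rank_continuum` (1 = first rosette
#' leaf; the first bourse-shoot internode carries the insertion-node rank
#' plus one, so ranks are contiguous along the continuum), `cum_length_cm`,
#' `bourse_length_cm`, `bourse_shoot_length_cm`. Cumulative lengths must be
#' nondecreasing within a spur and never exceed `BL + BSL`.
#'
#' @param path CSV file path.
#' @return Validated internode data frame.
#' @export
read_internode_table <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_internode_table(rec)
}

#' Validate an in-memory spur internode table
#'
#' @param rec Data frame of spur internode records.
#' @return The validated data frame.
#' @export
validate_internode_table <- function(rec) {
  rec <- as.data.frame(rec)
  need <- c("spur_id", "rank_continuum", "cum_length_cm",
            "bourse_length_cm", "bourse_shoot_length_cm")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("internode table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (rows in split(seq_len(nrow(rec)), rec$spur_id)) {
    rows <- rows[order(rec$rank_continuum[rows])]
    id <- rec$spur_id[rows[1]]
    rk <- rec$rank_continuum[rows]
    if (!identical(as.integer(rk), seq_len(length(rk)))) {
      stop(sprintf("spur '%s': continuum ranks are not contiguous 1..nl", id),
           call. = FALSE)
    }
    d <- rec$cum_length_cm[rows]
    if (any(diff(d) < -1e-9)) {
      stop(sprintf("spur '%s': cumulative lengths decrease along the continuum", id),
           call. = FALSE)
    }
    tot <- rec$bourse_length_cm[rows] + rec$bourse_shoot_length_cm[rows]
    if (any(d > tot + 1e-9)) {
      stop(sprintf("spur '%s': cumulative length exceeds BL + BSL", id),
           call. = FALSE)
    }
  }
  rec
}

#' Read an hourly temperature table
#'
#' Expected CSV columns: `timestamp_iso`, `temp_C`.
#'
#' @param path CSV file path.
#' @return Data frame with the two columns.
#' @export
read_temperature_table <- function(path) {
  temps <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("timestamp_iso", "temp_C"), names(temps))
  if (length(miss)) {
    stop("temperature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(temps$temp_C))) stop("non-numeric temperatures", call. = FALSE)
  temps
}

#' Write a parameter set to JSON
#'
#' Numeric payloads round-trip bit-for-bit (`digits = NA`); the file carries
#' a `schema_version` field checked on read.
#'
#' @param params An `allom_params` list (see [default_params()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  if (is.null(params$schema_version)) params$schema_version <- 1L
  # jsonlite drops names on atomic vectors; named vectors (k, alpha,
  # s tables, thresholds) must become JSON objects, so listify them
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  # 17 significant digits: exact binary round trip for doubles
  jsonlite::write_json(named_to_list(unclass(params)), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path JSON path written by [write_params()].
#' @return An `allom_params` list.
#' @export
read_params <- function(path) {
  params <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE),
    error = function(e) stop("cannot parse parameter file: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(params$schema_version) || params$schema_version != 1L) {
    stop("parameter file schema_version mismatch (expected 1)", call. = FALSE)
  }
  for (st in c("BS", "RO")) {
    kn <- names(params[[st]]$k)
    if (!is.null(kn) && any(!kn %in% c("AR", "FU", "RB"))) {
      stop("unknown genotype key in parameter file: ",
           paste(setdiff(kn, c("AR", "FU", "RB")), collapse = ", "), call. = FALSE)
    }
  }
  # jsonlite returns lists for named vectors; restore the numeric vectors
  for (st in intersect(c("BS", "RO", "VS"), names(params))) {
    for (fld in intersect(c("k", "alpha"), names(params[[st]]))) {
      params[[st]][[fld]] <- unlist(params[[st]][[fld]])
    }
    if (!is.null(params[[st]]$s_table)) {
      params[[st]]$s_table <- lapply(params[[st]]$s_table, unlist)
    }
  }
  if (!is.null(params$phenology$gdd_thresholds)) {
    th <- unlist(params$phenology$gdd_thresholds)
    storage.mode(th) <- "double"
    params$phenology$gdd_thresholds <- th
  }
  structure(params, class = "allom_params")
}
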