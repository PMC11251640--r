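# Per-polygon count summaries, densities, and observer agreement.

#' Summarise repeated observer counts of one model polygon
#'
#' Mean, sample SD (n - 1 denominator) and coefficient of variation
#' (SD/mean, in percent) of the counts a polygon received. With a single
#' observer neither the SD nor the CV can be estimated and both are `NA`;
#' the CV is also `NA` when the mean is zero (rather than infinite).
#'
#' @param counts integer vector of per-observer counts (all >= 0).
#' @return A list with `n_observers`, `mean_count`, `sd_count`, `cv`
#'   (percent).
#' @export
summarize_counts <- function(counts) {
  if (length(counts) < 1L) stop("at least one count is required")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- length(counts)
  m <- mean(counts)
  s <- if (n >= 2L) sd(counts) else NA_real_
  cv <- if (n >= 2L && m > 0) 100 * s / m else NA_real_
  list(n_observers = n, mean_count = m, sd_count = s, cv = cv)
}

#' Walrus density of a model polygon
#'
#' @param mean_count mean walrus count of the polygon.
#' @param area polygon area in m² (> 0).
#' @return Walruses per m².
#' @export
polygon_density <- function(mean_count, area) {
  if (any(area <= 0)) stop("polygon area must be positive")
  mean_count / area
}

#' Reduce an observer-count table to per-polygon summaries
#'
#' Joins the long count table (`polygon_id`, `observer_id`, `count`) to
#' the model-polygon set, drops QC-excluded polygons, and computes the
#' per-polygon mean, SD, CV and density.
#'
#' @param counts data frame with columns `polygon_id`, `observer_id`,
#'   `count`.
#' @param cells a `model_polygon_set` (or a data frame with `polygon_id`,
#'   `area_m2` and optionally `qc_excluded`).
#' @return Data frame with one row per counted, non-excluded polygon:
#'   `polygon_id`, `n_observers`, `mean_count`, `sd_count`, `cv`,
#'   `area_m2`, `density`.
#' @export
summarize_polygon_counts <- function(counts, cells) {
  req <- c("polygon_id", "observer_id", "count")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns polygon_id, observer_id, count")
  }
  info <- if (inherits(cells, "model_polygon_set")) as.data.frame(cells) else cells
  if (is.null(info$qc_excluded)) info$qc_excluded <- FALSE
  unknown <- setdiff(unique(counts$polygon_id), info$polygon_id)
  if (length(unknown)) {
    stop("counts reference unknown polygon_id(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- info[!info$qc_excluded, , drop = FALSE]
  counts <- counts[counts$polygon_id %in% keep$polygon_id, , drop = FALSE]
  ids <- unique(counts$polygon_id)
  rows <- lapply(ids, function(id) {
    s <- summarize_counts(counts$count[counts$polygon_id == id])
    a <- keep$area_m2[match(id, keep$polygon_id)]
    data.frame(polygon_id = id, n_observers = s$n_observers,
               mean_count = s$mean_count, sd_count = s$sd_count, cv = s$cv,
               area_m2 = a, density = polygon_density(s$mean_count, a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$polygon_id), , drop = FALSE]
}

#' Area-weighted mean density across model polygons
#'
#' The mean density weighted by polygon area, which algebraically equals
#' total mean count over total area (the ratio-estimator identity), plus
#' its area-weighted SD (frequency weights normalised to the total area).
#' The unweighted mean/SD of the polygon densities are reported alongside.
#'
#' @param densities per-polygon densities (walrus/m²), or the data frame
#'   from [summarize_polygon_counts()] (then `areas` is ignored).
#' @param areas polygon areas in m².
#' @return List with `mean` (area-weighted), `sd` (area-weighted),
#'   `mean_unweighted`, `sd_unweighted`, `n`.
#' @export
weighted_mean_density <- function(densities, areas = NULL) {
  if (is.data.frame(densities)) {
    areas <- densities$area_m2
    densities <- densities$density
  }
  ok <- !is.na(densities)
  densities <- densities[ok]; areas <- areas[ok]
  if (!length(densities)) stop("no polygons with a defined density")
  stopifnot(length(areas) == length(densities), all(areas > 0))
  w <- areas / sum(areas)
  m <- sum(w * densities)
  list(
    mean = m,
    sd = sqrt(sum(w * (densities - m)^2)),
    mean_unweighted = mean(densities),
    sd_unweighted = if (length(densities) >= 2L) sd(densities) else NA_real_,
    n = length(densities)
  )
}

#' Observer-agreement report
#'
#' Descriptive statistics of the per-polygon CVs over polygons counted by
#' at least two observers, quantifying the relative agreement of repeated
#' counts.
#'
#' @param summaries data frame from [summarize_polygon_counts()].
#' @return List with `n_multi_observer`, `n_single_observer`, `min_cv`,
#'   `mean_cv`, `sd_cv`, `max_cv` (percent; `NA` where not estimable).
#' @export
agreement_report <- function(summaries) {
  multi <- summaries[summaries$n_observers >= 2L & !is.na(summaries$cv), ,
                     drop = FALSE]
  single <- sum(summaries$n_observers == 1L)
  if (!nrow(multi)) {
    return(list(n_multi_observer = 0L, n_single_observer = single,
                min_cv = NA_real_, mean_cv = NA_real_, sd_cv = NA_real_,
                max_cv = NA_real_))
  }
  list(
    n_multi_observer = nrow(multi),
    n_single_observer = single,
    min_cv = min(multi$cv),
    mean_cv = mean(multi$cv),
    sd_cv = if (nrow(multi) >= 2L) sd(multi$cv) else NA_real_,
    max_cv = max(multi$cv)
  )
}
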