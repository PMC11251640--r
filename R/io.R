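# Readers, writers, configuration and the end-to-end pipeline driver.
#
# GeoJSON files here carry planar meter coordinates; the projected CRS is
# recorded as a file-level "crs_label" property (GeoJSON's own convention
# is geographic coordinates — the deviation is deliberate and documented),
# never interpreted. Dates are ISO-8601 strings. Writers emit stable row
# order and fixed float formatting so identical inputs give byte-identical
# files.

ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1L, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1L], closed[i, 2L]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2])))
  if (nrow(m) < 4L || any(m[1L, ] != m[nrow(m), ])) {
    stop("GeoJSON ring is not closed")
  }
  m
}

rings_to_geojson <- function(rings) {
  list(type = "Polygon",
       coordinates = c(list(ring_to_coords(rings$exterior)),
                       lapply(rings$holes, ring_to_coords)))
}

geojson_to_rings <- function(geom) {
  if (!identical(geom$type, "Polygon")) {
    stop("unsupported geometry type: ", geom$type %||% "missing")
  }
  rings <- lapply(geom$coordinates, coords_to_ring)
  pr <- polygon_rings(rings[[1L]], holes = rings[-1L])
  if (ring_self_intersects(pr$exterior)) stop("self-intersecting exterior ring")
  pr
}

check_terrain <- function(terrain) {
  if (!terrain %in% TERRAIN_LEVELS) {
    stop(sprintf("unknown terrain label '%s'; allowed: %s", terrain,
                 paste(TERRAIN_LEVELS, collapse = ", ")))
  }
  terrain
}

#' Write haulout outlines to GeoJSON
#'
#' @param outlines a [haulout_outline()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_outlines_geojson <- function(outlines, path) {
  if (inherits(outlines, "haulout_outline")) outlines <- list(outlines)
  fc <- list(
    type = "FeatureCollection",
    crs_label = outlines[[1L]]$crs_label,
    features = lapply(outlines, function(o) {
      list(type = "Feature",
           properties = list(site_id = o$site_id,
                             survey_date = o$survey_date,
                             terrain = o$terrain, area_m2 = o$area),
           geometry = rings_to_geojson(o$rings))
    })
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read haulout outlines from GeoJSON
#'
#' Validates on load: closed, non-self-intersecting rings; a known
#' terrain label; positive area.
#'
#' @param path GeoJSON file written by [write_outlines_geojson()] (or
#'   compatible: Polygon features with `site_id`, `survey_date`,
#'   `terrain` properties).
#' @return List of [haulout_outline()] objects.
#' @export
read_outlines_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  crs <- fc$crs_label %||% "unspecified"
  lapply(fc$features, function(f) {
    p <- f$properties
    for (field in c("site_id", "survey_date", "terrain")) {
      if (is.null(p[[field]])) stop("outline feature missing property ", field)
    }
    haulout_outline(geojson_to_rings(f$geometry), site_id = p$site_id,
                    survey_date = p$survey_date,
                    terrain = check_terrain(p$terrain), crs_label = crs)
  })
}

#' Write model polygons (clipped grid cells) to GeoJSON
#'
#' @param cells a `model_polygon_set` or plain list of model polygons.
#' @param path output file.
#' @param crs_label CRS label recorded at file level.
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(cells, path, crs_label = "EPSG:32602") {
  fc <- list(
    type = "FeatureCollection",
    crs_label = crs_label,
    features = lapply(unclass(cells), function(c_) {
      list(type = "Feature",
           properties = list(polygon_id = c_$polygon_id,
                             site_id = c_$site_id,
                             survey_date = c_$survey_date,
                             terrain = c_$terrain, area_m2 = c_$area,
                             selected = c_$selected,
                             qc_excluded = c_$qc_excluded),
           geometry = rings_to_geojson(c_$geometry))
    })
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model polygons from GeoJSON
#'
#' @param path file written by [write_cells_geojson()].
#' @return A `model_polygon_set`.
#' @export
read_cells_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  cells <- lapply(fc$features, function(f) {
    p <- f$properties
    if (is.null(p$polygon_id)) stop("cell feature missing polygon_id")
    geom <- geojson_to_rings(f$geometry)
    list(polygon_id = p$polygon_id, site_id = p$site_id %||% NA_character_,
         survey_date = p$survey_date %||% NA_character_,
         terrain = check_terrain(p$terrain %||% "rocky_type"),
         geometry = geom, area = p$area_m2 %||% polygon_area(geom),
         row = NA_integer_, col = NA_integer_,
         selected = isTRUE(p$selected), qc_excluded = isTRUE(p$qc_excluded))
  })
  structure(cells, class = "model_polygon_set")
}

#' Write a walrus point set to GeoJSON
#'
#' @param pts a `walrus_point_set` from [simulate_walruses()].
#' @param path output file.
#' @param crs_label CRS label.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(pts, path, crs_label = "EPSG:32602") {
  fc <- list(
    type = "FeatureCollection",
    crs_label = crs_label,
    features = list(list(
      type = "Feature",
      properties = list(site_id = pts$site_id,
                        survey_date = pts$survey_date,
                        complete_count = pts$complete_count),
      geometry = list(type = "MultiPoint",
                      coordinates = lapply(seq_len(nrow(pts$points)),
                                           function(i) pts$points[i, ]))
    ))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an observer-count table from CSV
#'
#' Expects columns `polygon_id`, `observer_id`, `count`; optionally
#' validates that every `polygon_id` is linked to a known model polygon.
#'
#' @param path CSV file.
#' @param cells optional `model_polygon_set` (or data frame with
#'   `polygon_id`) to validate linkage against.
#' @return Data frame of counts.
#' @export
read_counts_csv <- function(path, cells = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("polygon_id", "observer_id", "count")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    stop("counts CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(is.na(d$count)) || any(d$count < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (!is.null(cells)) {
    known <- if (inherits(cells, "model_polygon_set")) {
      vapply(cells, `[[`, "", "polygon_id")
    } else cells$polygon_id
    unknown <- setdiff(unique(d$polygon_id), known)
    if (length(unknown)) {
      stop("counts reference unknown polygon_id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  d
}

write_stable_csv <- function(d, path, digits = 6) {
  num <- vapply(d, is.double, TRUE)
  d[num] <- lapply(d[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf(paste0("%.", digits, "f"), x))
  })
  write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write an observer-count table to CSV
#'
#' @param counts data frame with `polygon_id`, `observer_id`, `count`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  counts <- counts[order(counts$polygon_id, counts$observer_id), ,
                   drop = FALSE]
  write_stable_csv(counts, path)
}

#' Write abundance estimates to CSV
#'
#' One row per site, date and method with point estimate and CI bounds,
#' sorted for stable output.
#'
#' @param estimates data frame from [estimates_df()], or a list of
#'   `abundance_estimate` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (!is.data.frame(estimates)) estimates <- estimates_df(estimates)
  estimates <- estimates[order(estimates$site_id, estimates$survey_date,
                               estimates$method), , drop = FALSE]
  write_stable_csv(estimates, path)
}

#' Dump a fitted count model to JSON
#'
#' @param fit an [nb_count_fit()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nb_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "nb_count_fit"))
  jsonlite::write_json(list(
    intercept = fit$intercept, sandy = fit$sandy,
    se = sqrt(diag(fit$vcov)), vcov = fit$vcov, theta = fit$theta,
    se_theta = fit$se_theta, null_deviance = fit$null_deviance,
    residual_deviance = fit$residual_deviance,
    deviance_explained = deviance_explained(fit), n = fit$n,
    converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Build and validate a pipeline configuration
#'
#' @param scenarios list of [simulation_scenario()] objects (or parameter
#'   lists passed to `simulation_scenario()`); the self-contained
#'   simulate mode.
#' @param cell_size grid cell edge, m.
#' @param fraction fraction of cells selected.
#' @param n_sims draws for the simulation CI.
#' @param z critical value for the linear-model CI.
#' @param k log-scale half-width multiplier for the NB CI.
#' @param seed master seed.
#' @param methods subset of `c("extrapolation", "linear", "nbglm")`.
#' @param out_dir output directory.
#' @param crs_label CRS label recorded in outputs.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(scenarios, cell_size = 19.68, fraction = 0.30,
                            n_sims = 10000L, z = 1.96, k = 2, seed = 1L,
                            methods = c("extrapolation", "linear", "nbglm"),
                            out_dir = NULL, crs_label = "EPSG:32602") {
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  if (n_sims < 100L) stop("n_sims must be >= 100")
  methods <- match.arg(methods, c("extrapolation", "linear", "nbglm"),
                       several.ok = TRUE)
  scenarios <- lapply(scenarios, function(s) {
    if (inherits(s, "simulation_scenario")) s
    else do.call(simulation_scenario, s)
  })
  structure(list(scenarios = scenarios, cell_size = cell_size,
                 fraction = fraction, n_sims = as.integer(n_sims), z = z,
                 k = k, seed = as.integer(seed), methods = methods,
                 out_dir = out_dir, crs_label = crs_label),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The file holds the fields of [pipeline_config()]; `scenarios` is a
#' list of parameter lists passed to [simulation_scenario()]. YAML files
#' need the `yaml` package.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (is.null(raw$scenarios)) stop("config must define 'scenarios'")
  do.call(pipeline_config, raw)
}

config_hash <- function(x) {
  s <- jsonlite::toJSON(lapply(x[setdiff(names(x), "scenarios")], unclass),
                        auto_unbox = TRUE, digits = NA)
  h <- 216613626
  for (v in utf8ToInt(as.character(s))) {
    h <- (bitwXor(as.integer(h), v) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline on simulated surveys
#'
#' Executes grid generation, cell selection, observer-count summarisation,
#' all requested estimators, and comparison against the known complete
#' counts for every scenario in the configuration. The negative-binomial
#' model is fitted once on the polygons pooled across all surveys. When
#' `out_dir` is set, writes GeoJSON/CSV/JSON outputs plus a manifest
#' (configuration, seed, package version, config hash) sufficient to
#' reproduce the run; identical configurations give byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return List with per-survey results, pooled `summaries`, `estimates`
#'   (data frame), the pooled `nb_fit`, the `comparison` against complete
#'   counts, and the `agreement` report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  surveys <- stage("simulate", lapply(config$scenarios, function(s) {
    s$cell_size <- config$cell_size
    s$sampling_fraction <- config$fraction
    simulate_survey(s)
  }))
  summaries <- stage("summarize", lapply(surveys, function(sv) {
    summarize_polygon_counts(sv$observer_counts,
                             sv$cells[vapply(sv$cells, `[[`, TRUE, "selected")])
  }))
  estimates <- list()
  for (i in seq_along(surveys)) {
    sv <- surveys[[i]]; sm <- summaries[[i]]; sc <- sv$scenario
    A <- sv$outline$area
    if ("extrapolation" %in% config$methods) {
      wd <- weighted_mean_density(sm)
      estimates <- c(estimates, list(stage("extrapolation",
        direct_extrapolation(A, wd$mean, wd$sd, n_sims = config$n_sims,
                             seed = derive_seed(sc$seed, "ci"),
                             n_polygons = wd$n, site_id = sc$site_id,
                             survey_date = sc$survey_date))))
    }
    if ("linear" %in% config$methods) {
      estimates <- c(estimates, list(stage("linear", withCallingHandlers(
        predict_linear(fit_linear(sm$mean_count, sm$area_m2), A,
                       z = config$z, site_id = sc$site_id,
                       survey_date = sc$survey_date),
        hauloutr_extrapolation = function(w) invokeRestart("muffleWarning")))))
    }
  }
  nb_fit <- NULL
  if ("nbglm" %in% config$methods) {
    pooled <- do.call(rbind, lapply(seq_along(surveys), function(i) {
      sm <- summaries[[i]]
      sm$terrain <- surveys[[i]]$scenario$terrain
      sm
    }))
    nb_fit <- stage("nbglm", {
      if (length(unique(pooled$terrain)) == 2L) {
        fit_nb_glm(pooled$mean_count, pooled$area_m2, pooled$terrain)
      } else {
        suppressWarnings(
          fit_nb_glm(pooled$mean_count, pooled$area_m2, pooled$terrain))
      }
    })
    for (sv in surveys) {
      sc <- sv$scenario
      estimates <- c(estimates, list(stage("nbglm",
        predict_nb(nb_fit, sv$outline$area, sc$terrain, k = config$k,
                   site_id = sc$site_id, survey_date = sc$survey_date))))
    }
  }
  est_df <- estimates_df(estimates)
  complete <- do.call(rbind, lapply(surveys, function(sv) {
    data.frame(site_id = sv$scenario$site_id,
               survey_date = sv$scenario$survey_date,
               count = sv$complete_count, land_count = sv$land_count,
               stringsAsFactors = FALSE)
  }))
  comparison <- stage("compare", compare_to_complete(est_df, complete))
  agreement <- stage("agreement",
                     agreement_report(do.call(rbind, summaries)))
  out <- list(surveys = surveys, summaries = summaries,
              estimates = est_df, nb_fit = nb_fit, comparison = comparison,
              agreement = agreement, complete = complete, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out)
  out
}

write_pipeline_outputs <- function(res) {
  dir_ <- res$config$out_dir
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  write_outlines_geojson(lapply(res$surveys, `[[`, "outline"),
                         file.path(dir_, "outlines.geojson"))
  all_cells <- do.call(c, lapply(res$surveys, function(sv) unclass(sv$cells)))
  write_cells_geojson(all_cells, file.path(dir_, "cells.geojson"),
                      crs_label = res$config$crs_label)
  write_counts_csv(do.call(rbind, lapply(res$surveys, `[[`,
                                         "observer_counts")),
                   file.path(dir_, "observer_counts.csv"))
  write_stable_csv(do.call(rbind, res$summaries),
                   file.path(dir_, "polygon_summaries.csv"))
  write_estimates_csv(res$estimates, file.path(dir_, "estimates.csv"))
  write_stable_csv(res$comparison$records, file.path(dir_, "comparison.csv"))
  jsonlite::write_json(res$agreement, file.path(dir_, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(res$nb_fit)) {
    write_nb_fit_json(res$nb_fit, file.path(dir_, "nb_fit.json"))
  }
  jsonlite::write_json(
    list(package = "hauloutr",
         version = as.character(packageVersion("hauloutr")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = res$config$seed,
         config_hash = config_hash(res$config),
         cell_size = res$config$cell_size, fraction = res$config$fraction,
         n_sims = res$config$n_sims,
         n_scenarios = length(res$config$scenarios)),
    file.path(dir_, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir_)
}
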