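# Abundance estimators: direct density extrapolation, linear regression of
# counts on polygon area, and the pooled negative-binomial GLM with a
# terrain covariate and log-area offset.

new_abundance_estimate <- function(method, point, lower, upper,
                                   site_id = NA_character_,
                                   survey_date = NA_character_,
                                   n_polygons = NA_integer_,
                                   lower_floored = FALSE) {
  floored <- FALSE
  if (lower < 0) { lower <- 0; floored <- TRUE }
  stopifnot(lower <= point + 1e-9, point <= upper + 1e-9)
  structure(
    list(method = method, site_id = site_id, survey_date = survey_date,
         point = point, ci_lower = lower, ci_upper = upper,
         n_polygons = n_polygons, lower_floored = floored || lower_floored),
    class = "abundance_estimate"
  )
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("<abundance_estimate> %s %s %s: %.0f (95%% CI %.0f-%.0f)\n",
              x$method, x$site_id, x$survey_date, x$point, x$ci_lower,
              x$ci_upper))
  invisible(x)
}

#' Collect abundance estimates into a data frame
#'
#' @param estimates list of `abundance_estimate` objects.
#' @return One row per estimate: site, date, method, point, lower, upper,
#'   n_polygons.
#' @export
estimates_df <- function(estimates) {
  if (inherits(estimates, "abundance_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(site_id = e$site_id, survey_date = e$survey_date,
               method = e$method, point = e$point, ci_lower = e$ci_lower,
               ci_upper = e$ci_upper, n_polygons = e$n_polygons,
               stringsAsFactors = FALSE)
  }))
}

#' Direct extrapolation of the area-weighted mean density
#'
#' Point estimate: haulout area times the area-weighted mean polygon
#' density. The 95% interval is built by simulation: `n_sims` draws from
#' `N(mean_density, sd_density)`, whose empirical 2.5% and 97.5% quantiles
#' are multiplied by the haulout area. The SD used is the spread of
#' polygon densities themselves (not the standard error of their mean), so
#' the interval reflects between-polygon density variability;
#' `use_se_of_mean = TRUE` switches to `sd/sqrt(n)` for the conventional
#' interval on the mean. A negative lower bound is floored at zero and
#' flagged.
#'
#' @param area haulout area in m² (> 0).
#' @param mean_density area-weighted mean density (walrus/m²).
#' @param sd_density SD of polygon densities (>= 0).
#' @param n_sims number of normal draws (>= 100; default 10000).
#' @param seed RNG seed for the draws.
#' @param use_se_of_mean use `sd_density/sqrt(n_polygons)` instead of
#'   `sd_density`.
#' @param n_polygons number of polygons behind the density (metadata;
#'   required when `use_se_of_mean`).
#' @param site_id,survey_date identifiers carried into the estimate.
#' @return An `abundance_estimate` with method `"direct_extrapolation"`.
#' @export
direct_extrapolation <- function(area, mean_density, sd_density,
                                 n_sims = 10000L, seed = NULL,
                                 use_se_of_mean = FALSE,
                                 n_polygons = NA_integer_,
                                 site_id = NA_character_,
                                 survey_date = NA_character_) {
  stopifnot(area > 0)
  if (sd_density < 0) stop("sd_density must be >= 0")
  if (n_sims < 100L) stop("n_sims must be at least 100")
  s <- sd_density
  if (use_se_of_mean) {
    if (is.na(n_polygons)) stop("use_se_of_mean requires n_polygons")
    s <- sd_density / sqrt(n_polygons)
  }
  q <- if (s == 0) c(mean_density, mean_density) else with_seed(seed, {
    quantile(rnorm(n_sims, mean_density, s), c(0.025, 0.975), names = FALSE)
  })
  new_abundance_estimate("direct_extrapolation", point = area * mean_density,
                         lower = area * q[1L], upper = area * q[2L],
                         site_id = site_id, survey_date = survey_date,
                         n_polygons = n_polygons)
}

#' Linear regression of polygon counts on polygon area
#'
#' Ordinary least squares of mean polygon count on polygon area with an
#' intercept, fitted by [stats::lm()].
#'
#' @param counts per-polygon mean counts.
#' @param areas polygon areas in m².
#' @return A `linear_count_fit` with `slope`, `intercept`, coefficient
#'   covariance `vcov`, `sigma2` (residual variance), `n`, the area range
#'   of the training polygons, and the underlying `lm` fit.
#' @export
fit_linear <- function(counts, areas) {
  stopifnot(length(counts) == length(areas))
  if (length(counts) < 3L) stop("at least 3 polygons are required")
  if (length(unique(areas)) < 2L) stop("areas must not all be equal")
  fit <- lm(counts ~ areas)
  df <- fit$df.residual
  # vcov on an exact fit warns about the zero residual variance; the
  # zero covariance it returns is the correct degenerate answer here
  V <- withCallingHandlers(vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  structure(
    list(intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L]),
         vcov = unname(V),
         sigma2 = if (df > 0) sum(fit$residuals^2) / df else 0,
         n = length(counts), area_range = range(areas), lm = fit),
    class = "linear_count_fit"
  )
}

#' Predict whole-haulout abundance from the linear fit
#'
#' Point estimate `intercept + slope * area`, with a z-interval on the
#' mean response: `point -/+ z * SE(mean prediction at area)`. A haulout
#' area far outside the polygon-area range the model was trained on is an
#' extrapolation; the prediction is still made (that is the point of the
#' method) but a condition of class `hauloutr_extrapolation` is signalled.
#'
#' @param fit a `linear_count_fit`.
#' @param area haulout area in m² (> 0).
#' @param z critical value (default 1.96 for 95%).
#' @param site_id,survey_date identifiers.
#' @return An `abundance_estimate` with method `"linear_model"`.
#' @export
predict_linear <- function(fit, area, z = 1.96, site_id = NA_character_,
                           survey_date = NA_character_) {
  stopifnot(inherits(fit, "linear_count_fit"), area > 0)
  if (area > fit$area_range[2L] || area < fit$area_range[1L]) {
    warning(structure(
      class = c("hauloutr_extrapolation", "warning", "condition"),
      list(message = sprintf(
        "predicting at area %.0f m^2, outside the training range [%.0f, %.0f] m^2",
        area, fit$area_range[1L], fit$area_range[2L]), call = NULL)
    ))
  }
  x <- c(1, area)
  point <- sum(x * c(fit$intercept, fit$slope))
  se <- sqrt(drop(t(x) %*% fit$vcov %*% x))
  new_abundance_estimate("linear_model", point = point,
                         lower = point - z * se, upper = point + z * se,
                         site_id = site_id, survey_date = survey_date,
                         n_polygons = fit$n)
}

#' Construct a negative-binomial count-model fit
#'
#' Container for the pooled count model `count ~ terrain +
#' offset(log(area))` with log link: intercept (log density on the rocky
#' reference terrain), sandy-terrain coefficient (log density ratio), NB
#' dispersion theta (`Var = mu + mu^2/theta`), their standard errors, and
#' deviances. Usually produced by [fit_nb_glm()]; building one directly
#' from published coefficients allows predictions from a reported fit.
#'
#' @param intercept log density (walrus/m²) on rocky terrain.
#' @param sandy log density ratio of sandy to rocky terrain (`NA` for an
#'   intercept-only fit).
#' @param vcov coefficient covariance matrix (defaults to zero: treat the
#'   coefficients as known).
#' @param theta NB dispersion.
#' @param se_theta its standard error.
#' @param null_deviance,residual_deviance model deviances.
#' @param n number of observations.
#' @param converged logical.
#' @param glm optional underlying `glm.nb` fit.
#' @return An `nb_count_fit` object.
#' @export
nb_count_fit <- function(intercept, sandy = NA_real_, vcov = NULL,
                         theta = NA_real_, se_theta = NA_real_,
                         null_deviance = NA_real_,
                         residual_deviance = NA_real_, n = NA_integer_,
                         converged = NA, glm = NULL) {
  p <- if (is.na(sandy)) 1L else 2L
  if (is.null(vcov)) vcov <- matrix(0, p, p)
  stopifnot(nrow(vcov) == p, ncol(vcov) == p)
  if (!is.na(theta) && theta <= 0) stop("theta must be positive")
  structure(
    list(intercept = intercept, sandy = sandy, vcov = vcov, theta = theta,
         se_theta = se_theta, null_deviance = null_deviance,
         residual_deviance = residual_deviance, n = n,
         converged = converged, glm = glm),
    class = "nb_count_fit"
  )
}

#' @export
print.nb_count_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<nb_count_fit> intercept %.3f, sandy %.3f, theta %.3f (SE %.3f)\n",
    "  deviance %.1f / null %.1f (%.2f%% explained), n = %d\n"),
    x$intercept, x$sandy, x$theta, x$se_theta, x$residual_deviance,
    x$null_deviance, deviance_explained(x), x$n))
  invisible(x)
}

#' Fit the pooled negative-binomial count model
#'
#' Fits `count ~ terrain + offset(log(area))` with a log link by
#' [MASS::glm.nb()] (alternating IRLS for the coefficients with ML
#' updates of theta), starting from `theta_init = 0.1`. The rocky terrain
#' is the reference level, so the intercept is the log mean density on
#' rocky shores and the sandy coefficient the log density ratio. Counts
#' are rounded to integers if needed (mean observer counts can be
#' fractional).
#'
#' With a single terrain level present an intercept-only model is fitted
#' and a warning issued.
#'
#' @param counts per-polygon counts.
#' @param areas polygon areas in m² (all > 0).
#' @param terrain per-polygon terrain labels (see [terrain_levels()]).
#' @param theta_init initial dispersion for the alternating fit.
#' @return An [nb_count_fit()].
#' @export
fit_nb_glm <- function(counts, areas, terrain, theta_init = 0.1) {
  stopifnot(length(counts) == length(areas),
            length(terrain) == length(counts), all(areas > 0))
  terrain <- factor(as.character(terrain), levels = TERRAIN_LEVELS)
  if (anyNA(terrain)) stop("unknown terrain label; allowed: ",
                           paste(TERRAIN_LEVELS, collapse = ", "))
  terrain <- droplevels(terrain)
  dat <- data.frame(count = round(counts), area = areas, terrain = terrain)
  two_levels <- nlevels(terrain) == 2L
  if (!two_levels) {
    warning("single terrain level present; fitting an intercept-only model")
    form <- count ~ 1 + offset(log(area))
  } else {
    if (min(table(terrain)) < 2L) {
      stop("at least 2 polygons per terrain level are required")
    }
    form <- count ~ terrain + offset(log(area))
  }
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(form, data = dat, init.theta = theta_init,
                   control = glm.control(maxit = 100)),
      warning = function(w) {
        # theta iteration hitting its limit on near-equidispersed data is
        # informational here; convergence is recorded on the fit object
        if (grepl("iteration limit|alternation limit|NaNs produced",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # theta ML diverges when counts are (near-)equidispersed; the NB then
    # degenerates to its Poisson limit (theta -> infinity)
    warning("dispersion estimate diverged (counts not overdispersed); ",
            "reporting the Poisson-limit fit with theta = Inf")
    fit <- stats::glm(form, data = dat, family = stats::poisson())
    cf <- coef(fit)
    return(nb_count_fit(
      intercept = unname(cf[1L]),
      sandy = if (two_levels) unname(cf["terrainsandy_type"]) else NA_real_,
      vcov = unname(vcov(fit)),
      theta = Inf, se_theta = NA_real_,
      null_deviance = fit$null.deviance, residual_deviance = fit$deviance,
      n = nrow(dat), converged = fit$converged, glm = fit
    ))
  }
  cf <- coef(fit)
  sandy_name <- "terrainsandy_type"
  nb_count_fit(
    intercept = unname(cf[1L]),
    sandy = if (two_levels) unname(cf[sandy_name]) else NA_real_,
    vcov = unname(vcov(fit)),
    theta = fit$theta,
    se_theta = if (is.finite(fit$SE.theta)) fit$SE.theta else NA_real_,
    null_deviance = fit$null.deviance, residual_deviance = fit$deviance,
    n = nrow(dat), converged = fit$converged, glm = fit
  )
}

#' Predict whole-haulout abundance from the count model
#'
#' Expected count for a haulout of the given area and terrain:
#' `exp(intercept + sandy * [terrain == sandy] + log(area))`. The 95%
#' interval uses the delta method on the log scale: with `var(count) =
#' count^2 * var(eta)` from the coefficient covariance, the log-scale
#' variance is `var(log(count)) = log(1 + var(count)/count^2)` and the
#' interval is `exp(log(count) -/+ k * sd(log(count)))` — asymmetric and
#' strictly positive. With a zero coefficient covariance (published
#' coefficients) the interval collapses to the point estimate.
#'
#' @param fit an [nb_count_fit()].
#' @param area haulout area in m² (> 0).
#' @param terrain `"rocky_type"` or `"sandy_type"`; must have been in the
#'   fit.
#' @param k half-width multiplier on the log scale (default 2).
#' @param site_id,survey_date identifiers.
#' @return An `abundance_estimate` with method `"nb_glm"`.
#' @export
predict_nb <- function(fit, area, terrain, k = 2,
                       site_id = NA_character_, survey_date = NA_character_) {
  stopifnot(inherits(fit, "nb_count_fit"), area > 0)
  terrain <- match.arg(terrain, TERRAIN_LEVELS)
  sandy <- terrain == "sandy_type"
  if (sandy && is.na(fit$sandy)) {
    stop("terrain level 'sandy_type' was not in the fitted model")
  }
  x <- if (is.na(fit$sandy)) 1 else c(1, as.numeric(sandy))
  eta <- fit$intercept + (if (sandy) fit$sandy else 0) + log(area)
  point <- exp(eta)
  var_eta <- drop(t(x) %*% fit$vcov %*% x)
  # var(count) = count^2 var(eta); on the log scale this gives
  # log(1 + var(count)/count^2) = log(1 + var(eta))
  sd_log <- sqrt(log(1 + var_eta))
  new_abundance_estimate("nb_glm", point = point,
                         lower = point * exp(-k * sd_log),
                         upper = point * exp(+k * sd_log),
                         site_id = site_id, survey_date = survey_date,
                         n_polygons = fit$n)
}

#' Percent deviance explained by the count model
#'
#' `100 * (1 - residual deviance / null deviance)`, the GLM analogue of
#' R²: how much of the deviance in polygon counts the terrain covariate
#' accounts for.
#'
#' @param fit an [nb_count_fit()].
#' @return Percent in `[0, 100]`.
#' @export
deviance_explained <- function(fit) {
  stopifnot(inherits(fit, "nb_count_fit"))
  if (is.na(fit$null_deviance) || fit$null_deviance == 0) {
    stop("null deviance is zero or unavailable")
  }
  100 * (1 - fit$residual_deviance / fit$null_deviance)
}
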