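# Planar polygon primitives and the sampling grid.
#
# All coordinates are planar meters (the caller is responsible for
# projecting, e.g. to a UTM zone); no geodesy happens here. A polygon is a
# list with an `exterior` ring and an optional list of `holes`, each ring a
# two-column matrix of vertices stored open (first vertex not repeated).

as_ring <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 2L) {
    stop("a ring must be a numeric matrix with two columns (x, y)")
  }
  n <- nrow(m)
  # accept closed input
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) stop("a ring needs at least 3 distinct vertices")
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' Build a polygon from rings
#'
#' @param exterior two-column matrix of exterior-ring vertices (closed or
#'   open; a repeated final vertex is dropped).
#' @param holes optional list of hole rings, each strictly inside the
#'   exterior.
#' @return A `polygon_rings` object.
#' @export
polygon_rings <- function(exterior, holes = list()) {
  out <- list(exterior = as_ring(exterior), holes = lapply(holes, as_ring))
  class(out) <- "polygon_rings"
  out
}

ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Shoelace area of a polygon
#'
#' Area of the exterior ring minus the area of any holes. Invariant to
#' vertex order (absolute values are used) and to translation.
#'
#' @param rings a `polygon_rings` object, or a bare two-column matrix
#'   treated as a single exterior ring.
#' @return Area in square meters (non-negative).
#' @export
polygon_area <- function(rings) {
  if (!inherits(rings, "polygon_rings")) rings <- polygon_rings(rings)
  a <- abs(ring_signed_area(rings$exterior))
  if (length(rings$holes)) {
    a <- a - sum(vapply(rings$holes, function(h) abs(ring_signed_area(h)), 0))
  }
  if (a < 0) stop("holes larger than the exterior ring")
  a
}

# even-odd ray cast; boundary points count as inside
point_in_ring <- function(x, y, ring) {
  rx <- ring[, 1L]; ry <- ring[, 2L]
  n <- nrow(ring)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ry[i] > y) != (ry[j] > y)) {
      xint <- rx[i] + (y - ry[i]) / (ry[j] - ry[i]) * (rx[j] - rx[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Test whether points fall inside a polygon
#'
#' Even-odd rule over the exterior and hole rings: a point inside an odd
#' number of rings is inside the polygon.
#'
#' @param pts two-column matrix of points.
#' @param rings a `polygon_rings` object.
#' @return Logical vector, one element per point.
#' @export
points_in_polygon <- function(pts, rings) {
  if (!inherits(rings, "polygon_rings")) rings <- polygon_rings(rings)
  pts <- matrix(as.numeric(pts), ncol = 2L)
  all_rings <- c(list(rings$exterior), rings$holes)
  vapply(seq_len(nrow(pts)), function(i) {
    crossings <- sum(vapply(
      all_rings, function(r) point_in_ring(pts[i, 1L], pts[i, 2L], r), TRUE
    ))
    crossings %% 2L == 1L
  }, TRUE)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# O(n^2) proper-crossing check between non-adjacent edges; used when
# validating rings loaded from files, where n is small.
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1L], 1L)))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap
      if (segments_intersect(ring[idx[i, 1L], ], ring[idx[i, 2L], ],
                             ring[idx[j, 1L], ], ring[idx[j, 2L], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1L]), xmax = max(ring[, 1L]),
    ymin = min(ring[, 2L]), ymax = max(ring[, 2L]))
}

# Sutherland-Hodgman clip of a ring against one half-plane value(p) >= 0.
clip_halfplane <- function(ring, value) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  keep <- value(ring)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- keep[i] >= 0; cj <- keep[j] >= 0
    if (ci) out <- rbind(out, ring[i, ])
    if (ci != cj) {
      t <- keep[i] / (keep[i] - keep[j])
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  out
}

# Clip a ring to an axis-aligned rectangle. Returns a matrix with zero rows
# when the intersection is empty. For a concave subject ring the result can
# contain degenerate zero-width bridges; its shoelace area is still the
# exact intersection area.
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  r <- ring
  r <- clip_halfplane(r, function(m) m[, 1L] - xmin)
  r <- clip_halfplane(r, function(m) xmax - m[, 1L])
  r <- clip_halfplane(r, function(m) m[, 2L] - ymin)
  r <- clip_halfplane(r, function(m) ymax - m[, 2L])
  if (nrow(r) < 3L) r <- matrix(numeric(0), ncol = 2L)
  r
}

#' Construct a haulout outline
#'
#' A dated, terrain-typed planar polygon delimiting a resting herd. Area is
#' computed from the rings, never supplied.
#'
#' @param rings a `polygon_rings` object (or exterior-ring matrix).
#' @param site_id,survey_date identifiers carried through all outputs;
#'   `survey_date` is an ISO-8601 string.
#' @param terrain one of [terrain_levels()].
#' @param crs_label free-text label of the projected CRS the coordinates
#'   are in (e.g. `"EPSG:32602"`); recorded in I/O, not interpreted.
#' @return A `haulout_outline` object with computed `area` in m².
#' @export
haulout_outline <- function(rings, site_id = "site", survey_date = "2018-01-01",
                            terrain = "rocky_type", crs_label = "EPSG:32602") {
  if (!inherits(rings, "polygon_rings")) rings <- polygon_rings(rings)
  terrain <- match.arg(terrain, TERRAIN_LEVELS)
  area <- polygon_area(rings)
  if (area <= 0) stop("outline has zero area")
  structure(
    list(site_id = site_id, survey_date = survey_date, terrain = terrain,
         rings = rings, area = area, crs_label = crs_label),
    class = "haulout_outline"
  )
}

#' @export
print.haulout_outline <- function(x, ...) {
  cat(sprintf("<haulout_outline> %s %s [%s] area = %.1f m^2 (%d vertices)\n",
              x$site_id, x$survey_date, x$terrain, x$area,
              nrow(x$rings$exterior)))
  invisible(x)
}

#' Generate synthetic haulout outlines
#'
#' Shape families used by the synthetic surveys: an axis-aligned rectangle,
#' a polygonized ellipse, or a star-shaped "blob" with a seeded random
#' radial profile. All shapes are rescaled so the shoelace area matches
#' `area` exactly.
#'
#' @param shape `"rectangle"`, `"ellipse"` or `"blob"`.
#' @param area target area in m² (> 0).
#' @param aspect width/height ratio for rectangle and ellipse.
#' @param seed RNG seed (needed for `"blob"`); the same seed always yields
#'   the same vertex list.
#' @param n_vertices vertices used to polygonize curved shapes.
#' @inheritParams haulout_outline
#' @return A [haulout_outline()].
#' @export
make_outline <- function(shape = c("rectangle", "ellipse", "blob"), area,
                         aspect = 2, seed = NULL, n_vertices = 180L,
                         site_id = "site", survey_date = "2018-01-01",
                         terrain = "rocky_type", crs_label = "EPSG:32602") {
  shape <- match.arg(shape)
  if (!is.numeric(area) || area <= 0) stop("outline area must be positive")
  ring <- switch(shape,
    rectangle = {
      w <- sqrt(area * aspect); h <- sqrt(area / aspect)
      cbind(c(0, w, w, 0), c(0, 0, h, h))
    },
    ellipse = {
      th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
      a <- sqrt(aspect); b <- 1 / sqrt(aspect)
      cbind(a * cos(th), b * sin(th))
    },
    blob = {
      if (is.null(seed)) stop("blob outlines need a seed")
      with_seed(seed, {
        th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
        amp <- runif(4L, 0, 0.12)
        phase <- runif(4L, 0, 2 * pi)
        r <- 1
        for (k in 1:4) r <- r + amp[k] * cos((k + 1) * th + phase[k])
        cbind(r * cos(th), r * sin(th))
      })
    }
  )
  if (shape != "rectangle") {
    scale <- sqrt(area / abs(ring_signed_area(ring)))
    ring <- ring * scale
    # shift into the positive quadrant for convenience
    ring <- sweep(ring, 2L, apply(ring, 2L, min))
  }
  haulout_outline(polygon_rings(ring), site_id = site_id,
                  survey_date = survey_date, terrain = terrain,
                  crs_label = crs_label)
}

#' Generate the clipped sampling grid over an outline
#'
#' Axis-aligned square cells cover the outline's bounding box and each cell
#' is intersected with the outline; empty intersections are dropped and
#' sliver fragments below `min_area` discarded. The clipped areas sum to
#' the outline area (to numerical tolerance), so the grid partitions the
#' haulout.
#'
#' @param outline a [haulout_outline()].
#' @param cell_size cell edge length in meters (default 19.68 m).
#' @param offset optional `c(dx, dy)` shift of the grid origin away from
#'   the bounding-box minimum corner, for sensitivity checks; values are
#'   wrapped into `[-cell_size, 0]`.
#' @param min_area sliver threshold in m²; clipped fragments smaller than
#'   this are dropped (default 0.01 m²).
#' @return A `model_polygon_set`: a list of model polygons, each with
#'   `polygon_id`, `geometry` ([polygon_rings()]), `area`, grid indices
#'   `row`/`col`, and `selected`/`qc_excluded` flags; the grid origin and
#'   cell size are attached as attributes.
#' @export
generate_grid <- function(outline, cell_size = 19.68, offset = NULL,
                          min_area = 0.01) {
  stopifnot(inherits(outline, "haulout_outline"))
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("cell_size must be positive")
  }
  bb <- ring_bbox(outline$rings$exterior)
  ox <- bb["xmin"]; oy <- bb["ymin"]
  if (!is.null(offset)) {
    ox <- ox - (offset[1L] %% cell_size)
    oy <- oy - (offset[2L] %% cell_size)
  }
  ncol_ <- ceiling((bb["xmax"] - ox) / cell_size - 1e-12)
  nrow_ <- ceiling((bb["ymax"] - oy) / cell_size - 1e-12)
  cells <- list()
  for (i in seq_len(nrow_)) {
    ymin <- oy + (i - 1L) * cell_size; ymax <- ymin + cell_size
    for (j in seq_len(ncol_)) {
      xmin <- ox + (j - 1L) * cell_size; xmax <- xmin + cell_size
      ext <- clip_ring_rect(outline$rings$exterior, xmin, xmax, ymin, ymax)
      if (nrow(ext) < 3L) next
      holes <- list()
      for (h in outline$rings$holes) {
        hc <- clip_ring_rect(h, xmin, xmax, ymin, ymax)
        if (nrow(hc) >= 3L) holes <- c(holes, list(hc))
      }
      geom <- list(exterior = as_ring(round(ext, 9)), holes = lapply(holes, as_ring))
      class(geom) <- "polygon_rings"
      area <- polygon_area(geom)
      if (area < min_area) next
      cells[[length(cells) + 1L]] <- list(
        polygon_id = sprintf("%s_r%03d_c%03d", outline$site_id, i, j),
        site_id = outline$site_id, survey_date = outline$survey_date,
        terrain = outline$terrain, geometry = geom, area = area,
        row = i, col = j, selected = FALSE, qc_excluded = FALSE
      )
    }
  }
  if (!length(cells)) stop("degenerate outline: no grid cells produced")
  structure(cells, class = "model_polygon_set",
            origin = c(x = unname(ox), y = unname(oy)),
            cell_size = cell_size)
}

#' @export
print.model_polygon_set <- function(x, ...) {
  cat(sprintf("<model_polygon_set> %d cells, %.1f m^2 total, %d selected\n",
              length(x), sum(vapply(x, `[[`, 0, "area")),
              sum(vapply(x, `[[`, TRUE, "selected"))))
  invisible(x)
}

#' @export
`[.model_polygon_set` <- function(x, i) {
  structure(unclass(x)[i], class = "model_polygon_set",
            origin = attr(x, "origin"), cell_size = attr(x, "cell_size"))
}

#' Summarise a model-polygon set as a data frame
#'
#' @param x a `model_polygon_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return One row per model polygon: id, site, date, terrain, area,
#'   selection and QC flags.
#' @export
as.data.frame.model_polygon_set <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(
    polygon_id = vapply(x, `[[`, "", "polygon_id"),
    site_id = vapply(x, `[[`, "", "site_id"),
    survey_date = vapply(x, `[[`, "", "survey_date"),
    terrain = vapply(x, `[[`, "", "terrain"),
    area_m2 = vapply(x, `[[`, 0, "area"),
    selected = vapply(x, `[[`, TRUE, "selected"),
    qc_excluded = vapply(x, `[[`, TRUE, "qc_excluded"),
    stringsAsFactors = FALSE
  )
}

#' Randomly select model polygons from a clipped grid
#'
#' Selects `round(fraction * n)` cells (round half up, minimum 1) by
#' uniform sampling without replacement, mirroring a uniform random number
#' generator choosing 30% of the clipped grid cells.
#'
#' @param cells a `model_polygon_set` from [generate_grid()].
#' @param fraction fraction of cells to select, in (0, 1].
#' @param seed RNG seed; selection is deterministic per seed.
#' @return The cell set with `selected` flags set.
#' @export
select_model_polygons <- function(cells, fraction = 0.30, seed = NULL) {
  stopifnot(inherits(cells, "model_polygon_set"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  n <- length(cells)
  if (n == 0L) stop("empty cell list")
  k <- max(1L, as.integer(floor(fraction * n + 0.5)))
  idx <- with_seed(seed, sample.int(n, k))
  for (i in seq_len(n)) cells[[i]]$selected <- i %in% idx
  cells
}
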