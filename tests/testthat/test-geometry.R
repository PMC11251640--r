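test_that("shoelace area handles simple shapes, holes, and invariances", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  rect <- rbind(c(0, 0), c(40, 0), c(40, 20), c(0, 20))
  expect_equal(polygon_area(rect), 800)
  # vertex order and translation do not matter
  expect_equal(polygon_area(rect[4:1, ]), 800)
  expect_equal(polygon_area(sweep(rect, 2, c(-500, 1e6), "+")), 800)
  # 3x3 square with a centered 1x1 hole
  outer <- rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3))
  hole <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))
  expect_equal(polygon_area(polygon_rings(outer, list(hole))), 8)
  expect_error(polygon_rings(rbind(c(0, 0), c(1, 1))), "3 distinct")
})

test_that("point-in-polygon respects holes", {
  outer <- rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3))
  hole <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))
  p <- polygon_rings(outer, list(hole))
  pts <- rbind(c(0.5, 0.5), c(1.5, 1.5), c(2.5, 2.5), c(3.5, 1))
  expect_equal(points_in_polygon(pts, p), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("outline constructors hit the target area and are seeded", {
  r <- make_outline("rectangle", 800, aspect = 2)
  expect_equal(r$area, 800)
  expect_equal(diff(range(r$rings$exterior[, 1])), 40)
  expect_equal(diff(range(r$rings$exterior[, 2])), 20)
  e <- make_outline("ellipse", 12345.6)
  expect_equal(e$area, 12345.6, tolerance = 1e-9)
  b1 <- make_outline("blob", 5000, seed = 42)
  b2 <- make_outline("blob", 5000, seed = 42)
  expect_identical(b1$rings$exterior, b2$rings$exterior)
  expect_equal(b1$area, 5000, tolerance = 1e-9)
  b3 <- make_outline("blob", 5000, seed = 43)
  expect_false(identical(b1$rings$exterior, b3$rings$exterior))
  expect_error(make_outline("rectangle", -1), "positive")
  expect_error(make_outline("hexagon", 10))
})

test_that("grid tiles aligned rectangles exactly", {
  # 2 x 1 cells of 19.68 m: two full cells
  o <- haulout_outline(rbind(c(0, 0), c(39.36, 0), c(39.36, 19.68), c(0, 19.68)))
  g <- generate_grid(o)
  expect_length(g, 2L)
  areas <- vapply(g, `[[`, 0, "area")
  expect_equal(areas, rep(19.68^2, 2), tolerance = 1e-9)
  # one full cell plus a half-width clip
  o2 <- haulout_outline(rbind(c(0, 0), c(29.52, 0), c(29.52, 19.68), c(0, 19.68)))
  g2 <- generate_grid(o2)
  expect_length(g2, 2L)
  expect_equal(sort(vapply(g2, `[[`, 0, "area")),
               sort(c(19.68^2, 9.84 * 19.68)), tolerance = 1e-9)
})

test_that("clipped grid conserves area over every outline family", {
  shapes <- list(
    make_outline("rectangle", 8000, aspect = 3),
    make_outline("ellipse", 12000, aspect = 1.5),
    make_outline("blob", 15000, seed = 7),
    make_outline("blob", 5000, seed = 19)
  )
  for (o in shapes) {
    g <- generate_grid(o)
    expect_equal(sum(vapply(g, `[[`, 0, "area")), o$area,
                 tolerance = 1e-6 * o$area)
  }
  # outline with a hole
  outer <- rbind(c(0, 0), c(60, 0), c(60, 50), c(0, 50))
  hole <- rbind(c(20, 20), c(30, 20), c(30, 30), c(20, 30))
  oh <- haulout_outline(polygon_rings(outer, list(hole)))
  gh <- generate_grid(oh)
  expect_equal(sum(vapply(gh, `[[`, 0, "area")), 3000 - 100, tolerance = 1e-6)
})

test_that("clipping is idempotent and cells stay inside the outline", {
  o <- make_outline("blob", 9000, seed = 3)
  g <- generate_grid(o)
  cs <- attr(g, "cell_size")
  for (cell in g[seq(1, length(g), by = 3)]) {
    # re-clipping a clipped cell against its own cell window changes nothing
    bb <- c(xmin = attr(g, "origin")["x"] + (cell$col - 1) * cs,
            ymin = attr(g, "origin")["y"] + (cell$row - 1) * cs)
    re <- hauloutr:::clip_ring_rect(cell$geometry$exterior,
                                    bb[1], bb[1] + cs, bb[2], bb[2] + cs)
    expect_equal(abs(hauloutr:::ring_signed_area(re)), cell$area,
                 tolerance = 1e-9 * max(cell$area, 1))
    # interior sample points of the cell lie inside the parent outline
    pts <- hauloutr:::sample_points_in_polygon(10, cell$geometry)
    expect_true(all(points_in_polygon(pts, o$rings)))
  }
})

test_that("a seeded random grid offset preserves area conservation", {
  o <- make_outline("ellipse", 7000)
  g <- generate_grid(o, offset = c(5.3, 11.1))
  expect_equal(sum(vapply(g, `[[`, 0, "area")), o$area, tolerance = 1e-6 * o$area)
})

test_that("model-polygon selection follows the round-half-up rule", {
  o <- make_outline("rectangle", 10 * 19.68^2 - 1, aspect = 10)
  g <- generate_grid(o)
  stopifnot(length(g) >= 10)
  g10 <- g[1:10]
  s <- select_model_polygons(g10, fraction = 0.30, seed = 1)
  expect_equal(sum(vapply(s, `[[`, TRUE, "selected")), 3L)
  s_all <- select_model_polygons(g10, fraction = 1.0, seed = 1)
  expect_true(all(vapply(s_all, `[[`, TRUE, "selected")))
  # minimum of one cell selected
  s1 <- select_model_polygons(g10[1:2], fraction = 0.1, seed = 1)
  expect_equal(sum(vapply(s1, `[[`, TRUE, "selected")), 1L)
  # deterministic per seed
  a <- select_model_polygons(g10, 0.3, seed = 99)
  b <- select_model_polygons(g10, 0.3, seed = 99)
  expect_identical(vapply(a, `[[`, TRUE, "selected"),
                   vapply(b, `[[`, TRUE, "selected"))
  expect_error(select_model_polygons(g10, 0), "fraction")
})

test_that("selection is uniform across cells", {
  o <- make_outline("rectangle", 10 * 19.68^2 - 1, aspect = 10)
  g <- generate_grid(o)[1:10]
  n_rep <- 2000L
  freq <- rep(0, 10)
  for (k in seq_len(n_rep)) {
    s <- select_model_polygons(g, 0.30, seed = k)
    freq <- freq + vapply(s, `[[`, TRUE, "selected")
  }
  p_hat <- freq / n_rep
  se <- sqrt(0.3 * 0.7 / n_rep)
  expect_true(all(abs(p_hat - 0.30) < 3 * se + 0.01))
})
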