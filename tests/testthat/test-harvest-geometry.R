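rect_boundary <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

test_that("two points split a rectangle along the perpendicular bisector", {
  pts <- data.frame(point_id = 1:2, x = c(5, 15), y = c(5, 5))
  polys <- thiessen_polygons(pts, rect_boundary(0, 0, 20, 10))
  expect_length(polys, 2)
  expect_equal(polys[[1]]$area, 100, tolerance = 1e-9)
  expect_equal(polys[[2]]$area, 100, tolerance = 1e-9)
  # both cells touch the outer ring
  expect_true(all(vapply(polys, `[[`, TRUE, "is_edge")))
  # the shared edge is x = 10
  xs <- polys[[1]]$vertices[, 1]
  expect_equal(max(xs), 10, tolerance = 1e-9)
})

test_that("Voronoi cells partition the boundary and obey the nearest-point rule", {
  set.seed(21)
  n <- 60
  pts <- data.frame(point_id = seq_len(n),
                    x = runif(n, 1, 39), y = runif(n, 1, 29))
  bnd <- rect_boundary(0, 0, 40, 30)
  polys <- thiessen_polygons(pts, bnd)
  expect_equal(sum(vapply(polys, `[[`, 0, "area")), 40 * 30,
               tolerance = 1e-6 * 1200)
  # spot-check nearest-generator property at random interior probes
  probes <- cbind(runif(200, 0, 40), runif(200, 0, 30))
  for (k in sample(n, 8)) {
    v <- polys[[k]]$vertices
    inside <- canopyield:::points_in_polygon(probes[, 1], probes[, 2], v)
    if (!any(inside)) next
    d_own <- sqrt((probes[inside, 1] - pts$x[k])^2 +
                    (probes[inside, 2] - pts$y[k])^2)
    d_min <- apply(cbind(probes[inside, 1], probes[inside, 2]), 1, function(p)
      min(sqrt((pts$x - p[1])^2 + (pts$y - p[2])^2)))
    expect_true(all(d_own <= d_min + 1e-9))
  }
})

test_that("a regular lattice of points yields square interior cells", {
  g <- expand.grid(x = seq(2.5, 27.5, by = 5), y = seq(2.5, 27.5, by = 5))
  pts <- data.frame(point_id = seq_len(nrow(g)), x = g$x, y = g$y)
  polys <- thiessen_polygons(pts, rect_boundary(0, 0, 30, 30))
  interior <- Filter(function(p) !p$is_edge, polys)
  expect_length(interior, 16)  # 4x4 interior of a 6x6 lattice
  for (p in interior) {
    expect_equal(p$area, 25, tolerance = 1e-9)
    expect_equal(p$perimeter, 20, tolerance = 1e-9)
  }
})

test_that("coincident points are rejected with their ids", {
  pts <- data.frame(point_id = c(7, 8, 9), x = c(1, 1, 2), y = c(1, 1, 2))
  expect_error(thiessen_polygons(pts, rect_boundary(0, 0, 5, 5)),
               "duplicate-point.*7.*8")
})

test_that("shape metrics match closed forms", {
  theta <- seq(0, 2 * pi, length.out = 257)[-257]
  circle <- list(vertices = cbind(2 * cos(theta), 2 * sin(theta)))
  m <- shape_metrics(circle)
  expect_equal(m$roundness, 1, tolerance = 1e-3)
  square <- list(vertices = cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))
  m <- shape_metrics(square)
  expect_equal(m$area, 16)
  expect_equal(m$perimeter, 16)
  expect_equal(m$roundness, 4 / pi, tolerance = 1e-12)
  rect <- list(vertices = cbind(c(0, 8, 8, 0), c(0, 0, 2, 2)))
  m <- shape_metrics(rect)
  expect_equal(m$roundness, 400 / (4 * pi * 16), tolerance = 1e-12)
  expect_error(shape_metrics(list(vertices = cbind(0:1, 0:1))),
               "invalid-polygon")
})

test_that("polygon filtering applies area, roundness and edge rules", {
  pts <- data.frame(point_id = 1:2, x = c(5, 15), y = c(5, 5))
  polys <- thiessen_polygons(pts, rect_boundary(0, 0, 20, 10))
  expect_length(filter_polygons(polys, c(0, Inf), Inf, drop_edges = FALSE), 2)
  expect_length(filter_polygons(polys, c(0, Inf), Inf, drop_edges = TRUE), 0)
  expect_error(filter_polygons(polys, c(10, 5)), "invalid-config")
  # synthetic metric set: 10 polygons, 3 violating the stated thresholds
  fake <- lapply(1:10, function(i) {
    structure(list(polygon_id = i, vertices = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                   area = c(15, 16, 17, 3, 40, 16, 17, 15, 16, 17)[i],
                   roundness = c(1.3, 1.3, 1.3, 1.3, 1.3, 5, 1.4, 1.3, 1.2, 1.5)[i],
                   is_edge = FALSE), class = "field_polygon")
  })
  kept <- filter_polygons(structure(fake, class = "field_polygon_set"),
                          area_bounds = c(10, 30), roundness_max = 3)
  expect_equal(vapply(kept, `[[`, 0, "polygon_id"), c(1, 2, 3, 7, 8, 9, 10))
})

test_that("zonal means equal constants, tiny closed forms, and the full oracle", {
  g <- grid_spec(10, 10, 1)
  const <- field_raster(matrix(3.5, 10, 10), g)
  pts <- data.frame(point_id = 1:4, x = c(2.5, 7.5, 2.5, 7.5),
                    y = c(2.5, 2.5, 7.5, 7.5))
  polys <- thiessen_polygons(pts, rect_boundary(0, 0, 10, 10))
  zm <- zonal_mean(const, polys)
  expect_equal(zm$mean, rep(3.5, 4))
  expect_equal(sum(zm$n_valid_pixels), 100)

  # polygon covering exactly two pixel centers valued 2 and 4
  vals <- matrix(0, 10, 10); vals[10, 1] <- 2; vals[10, 2] <- 4
  two <- structure(list(list(
    polygon_id = 1L,
    vertices = cbind(c(0.1, 1.9, 1.9, 0.1), c(0.1, 0.1, 0.9, 0.9)),
    area = 1.44, roundness = 1.5, is_edge = FALSE)),
    class = "field_polygon_set")
  expect_equal(zonal_mean(field_raster(vals, g), two)$mean, 3)

  # random raster + random polygons vs mgcv::in.out full enumeration
  skip_if_not_installed("mgcv")
  set.seed(31)
  r <- field_raster(matrix(rnorm(100), 10, 10), g)
  rpts <- data.frame(point_id = 1:12, x = runif(12, 0.5, 9.5),
                     y = runif(12, 0.5, 9.5))
  rpolys <- thiessen_polygons(rpts, rect_boundary(0, 0, 10, 10))
  got <- zonal_mean(r, rpolys)
  ctr <- pixel_centers(g)
  xx <- rep(ctr$x, each = 10); yy <- rep(ctr$y, times = 10)
  for (i in seq_along(rpolys)) {
    v <- rpolys[[i]]$vertices
    inside <- mgcv::in.out(rbind(v, v[1, ]), cbind(xx, yy))
    vals_in <- unclass(r)[matrix(inside, 10)]
    if (length(vals_in) == 0) next
    expect_equal(got$mean[i], mean(vals_in), info = paste("polygon", i))
    expect_equal(got$n_valid_pixels[i], length(vals_in))
  }

  # empty zone flagged, not fatal
  sliver <- structure(list(list(
    polygon_id = 99L,
    vertices = cbind(c(0.6, 0.9, 0.9, 0.6), c(0.6, 0.6, 0.9, 0.9)),
    area = 0.09, roundness = 1.3, is_edge = FALSE)),
    class = "field_polygon_set")
  zs <- zonal_mean(const, sliver)
  expect_true(zs$empty)
  expect_true(is.na(zs$mean))
})

test_that("zonal means ignore nodata pixels", {
  g <- grid_spec(4, 4, 1)
  m <- matrix(1:16, 4, 4)
  m[1, 1] <- NA
  poly <- structure(list(list(
    polygon_id = 1L, vertices = cbind(c(-1, 5, 5, -1), c(-1, -1, 5, 5)),
    area = 36, roundness = 1.3, is_edge = TRUE)),
    class = "field_polygon_set")
  zm <- zonal_mean(field_raster(m, g), poly)
  expect_equal(zm$n_valid_pixels, 15)
  expect_equal(zm$mean, mean(m, na.rm = TRUE))
})
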