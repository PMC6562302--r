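unit_square5 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))

test_that("MCP peels by centroid distance and reports exact hull areas", {
  hr <- mcp(unit_square5, percent = 100)
  expect_equal(hr$area_km2, 1e-6)  # 1 m^2 in km^2
  expect_equal(hr$achieved, 1)
  set.seed(8)
  pts <- cbind(runif(100, 0, 1000), runif(100, 0, 1000))
  hr95 <- mcp(pts, percent = 95)
  # brute-force re-implementation: keep the 95 centroid-nearest, hull, area
  ctr <- colMeans(pts)
  d <- sqrt(rowSums((pts - matrix(ctr, 100, 2, byrow = TRUE))^2))
  kept <- pts[order(d)[1:95], ]
  hull <- kept[rev(chull(kept)), ]
  shoelace <- function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  expect_equal(hr95$area_km2, shoelace(hull) * 1e-6, tolerance = 1e-12)
  # monotone in percent
  areas <- vapply(c(50, 70, 90, 100), function(p)
    mcp(pts, percent = p)$area_km2, 1)
  expect_true(all(diff(areas) >= 0))
  expect_error(mcp(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(4, 0)), 100),
               "collinear")
})

test_that("maximum pairwise distance is exact", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(max_pairwise_distance(sq), sqrt(2))
  expect_equal(max_pairwise_distance(cbind(c(0, 3, 7), 0)), 7)
  set.seed(12)
  pts <- cbind(rnorm(1000, sd = 500), rnorm(1000, sd = 500))
  expect_equal(max_pairwise_distance(pts), max(dist(pts)))
  # large sets go through the convex hull and must agree with all pairs
  big <- cbind(rnorm(2500, sd = 500), rnorm(2500, sd = 500))
  expect_equal(max_pairwise_distance(big), max(dist(big)))
})

test_that("a-LoCoH cumulative-distance rule and degenerate inputs", {
  # equilateral triangle, a = side: each hull is a 2-point segment
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_error(alocoh(tri, a = 1), "at least 5")
  # five collinear points: every local hull degenerate regardless of a
  line5 <- cbind(0:4 * 10, 0)
  expect_error(alocoh(line5), "degenerate")
  # dense grid with a = max distance: one global hull, area <= MCP(100)
  g <- as.matrix(expand.grid(x = seq(0, 950, by = 50),
                             y = seq(0, 950, by = 50)))
  iso <- alocoh(g, isopleth_targets = c(0.95, 1))
  m100 <- mcp(g, percent = 100)
  expect_lte(iso[[2]]$area_km2, m100$area_km2 + 1e-12)
  expect_equal(iso[[2]]$achieved, 1)
  # duplicated points are always absorbed (zero distance to the root)
  dup <- rbind(unit_square5 * 100, c(50, 50), c(50, 50))
  expect_s3_class(alocoh(dup, a = 500)[[1]], "homerange")
})

test_that("a-LoCoH isopleths stay within the overall hull on random clouds", {
  set.seed(33)
  for (i in 1:10) {
    pts <- cbind(rnorm(40, sd = 300), rnorm(40, sd = 300))
    iso <- alocoh(pts, isopleth_targets = 0.95)[[1]]
    m <- mcp(pts, percent = 100)
    expect_lte(iso$area_km2, m$area_km2 + 1e-12)
    expect_lte(abs(iso$achieved - 0.95), 0.5 / 40 + 1 / 40)
  }
})

test_that("exact union areas agree with a fine-grid Monte Carlo oracle", {
  set.seed(19)
  polys <- lapply(1:6, function(i) {
    ctr <- runif(2, 0, 100)
    pts <- cbind(ctr[1] + rnorm(12, sd = 20), ctr[2] + rnorm(12, sd = 20))
    pts[rev(chull(pts)), ]
  })
  exact <- urbanmove:::union_area(polys)
  xs <- seq(-50, 150, length.out = 400)
  ys <- seq(-50, 150, length.out = 400)
  grid <- as.matrix(expand.grid(xs, ys))
  inside <- rep(FALSE, nrow(grid))
  for (p in polys) {
    todo <- which(!inside)
    inside[todo] <- urbanmove:::point_in_convex(grid[todo, 1], grid[todo, 2], p)
  }
  cell <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  expect_equal(exact, sum(inside) * cell, tolerance = 0.02)
})

test_that("complexity index contracts and clamping", {
  expect_equal(complexity_index(2.0, 2.0), 0)
  expect_equal(complexity_index(2.0, 1.0), 0.5)
  expect_equal(complexity_index(4.05, 3.24), 0.2)
  expect_warning(ci <- complexity_index(1.0, 1.2), "clamp")
  expect_equal(ci, 0)
  expect_error(complexity_index(0, 1), "positive")
})

square_at <- function(x0, y0, s = 1) {
  rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s))
}

test_that("component counting treats touching polygons as connected", {
  expect_equal(count_components(list(square_at(0, 0))), 1)
  expect_equal(count_components(list(square_at(0, 0), square_at(5, 5))), 2)
  expect_equal(count_components(list(square_at(0, 0),
                                     square_at(0.5, 0.5))), 1)
  # touching at a single corner counts as connected
  expect_equal(count_components(list(square_at(0, 0), square_at(1, 1))), 1)
})

fake_hr <- function(polys, level = 0.95, coverage = 100, id = "x") {
  urbanmove:::new_homerange(id, "aLoCoH", level, level, polys,
                            urbanmove:::union_area(polys), 10, coverage, 1L)
}

test_that("overlap fractions use the smaller range as denominator", {
  a <- fake_hr(list(square_at(0, 0)))
  b <- fake_hr(list(square_at(0.5, 0)))
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(a, b), 0.5)
  far <- fake_hr(list(square_at(10, 10)))
  expect_equal(overlap_fraction(a, far), 0)
  expect_error(overlap_fraction(a, fake_hr(list(square_at(0, 0)),
                                           level = 0.5)), "level")
})

test_that("deduplication keeps the range with greater temporal coverage", {
  a <- fake_hr(list(square_at(0, 0)), coverage = 120, id = "a")
  b <- fake_hr(list(square_at(0.01, 0)), coverage = 300, id = "b")
  c <- fake_hr(list(square_at(20, 20)), coverage = 90, id = "c")
  dd <- dedup_homeranges(list(a, b, c))
  ids <- vapply(dd$retained, `[[`, "", "animal_id")
  expect_setequal(ids, c("b", "c"))
  expect_equal(dd$dropped_idx, 1L)
  # disjoint ranges are never deduplicated
  dd2 <- dedup_homeranges(list(a, c))
  expect_length(dd2$retained, 2)
  # both members of a pair are never dropped
  expect_lt(length(dd$dropped_idx), 3)
})

test_that("landscape classes follow the imperviousness thresholds", {
  ext <- c(0, 300, 0, 300)
  poly <- list(square_at(0, 0, 300))
  for (case in list(list(10, "natural_fragment"), list(35, "suburban"),
                    list(60, "highly_urbanized"), list(20, "suburban"),
                    list(50, "suburban"))) {
    r <- make_imperviousness_raster(ext, 30, "uniform", level = case[[1]])
    expect_equal(classify_landscape(poly, r)$class, case[[2]])
  }
  r <- make_imperviousness_raster(ext, 30, "uniform", level = 10)
  expect_error(classify_landscape(list(square_at(1000, 1000)), r),
               "no raster cell")
})

test_that("GeoJSON export writes valid multipolygon features", {
  hr <- fake_hr(list(square_at(0, 0), square_at(5, 5)))
  path <- tempfile(fileext = ".geojson")
  write_homeranges_geojson(hr, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$type, "FeatureCollection")
  expect_length(doc$features, 1)
  geom <- doc$features[[1]]$geometry
  expect_equal(geom$type, "MultiPolygon")
  expect_length(geom$coordinates, 2)
})
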