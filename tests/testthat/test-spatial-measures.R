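square_poly <- function(s, x0 = 0, y0 = 0)
  rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s))

region_from_polys <- function(outer, holes = list()) {
  stmc:::make_region(outer, holes,
                     matrix(c(0, 0), ncol = 2,
                            dimnames = list(NULL, c("row", "col"))))
}

test_that("region clusteredness follows area / (area + holes)", {
  grid <- matrix(1, 30, 30)
  r0 <- region_from_polys(square_poly(10))
  expect_equal(region_measures(r0, grid)$clusteredness, 1)
  # outer area 120, hole area 20: region area 100, clusteredness 100/120
  outer <- rbind(c(0, 0), c(12, 0), c(12, 10), c(0, 10))
  hole <- rbind(c(1, 1), c(6, 1), c(6, 5), c(1, 5))
  r1 <- region_from_polys(outer, list(hole))
  m <- region_measures(r1, grid)
  expect_equal(m$area, 100)
  expect_equal(m$clusteredness, 100 / 120)
  # monotone decrease with growing hole area
  holes <- seq(0, 9, by = 1.5)
  vals <- vapply(holes, function(h) {
    hh <- if (h == 0) list() else
      list(rbind(c(1, 1), c(1 + h, 1), c(1 + h, 2), c(1, 2)))
    region_measures(region_from_polys(outer, hh), grid)$clusteredness
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("area, perimeter and origin distance agree with geometry oracles", {
  grid <- rasterize_shape("square", 10, c(101, 101))
  regions <- detect_regions(grid_to_grayscale(grid),
                            region_detection_config(thresholdValue = 127))
  expect_length(regions, 1)
  m <- region_measures(regions[[1]], grid)
  expect_equal(m$area, oracle_shoelace_area(regions[[1]]$outerContour),
               tolerance = 1e-9)
  expect_equal(m$perimeter,
               oracle_edge_walk_perimeter(regions[[1]]$outerContour),
               tolerance = 1e-9)
  expect_equal(m$area, 81)        # 10x10 pixel block traced at pixel centres
  expect_equal(m$perimeter, 36)
  expect_equal(m$distanceFromOrigin, 0)  # grid centre lies inside
  expect_equal(m$angle, 360)
  expect_equal(m$density, mean(grid[grid > 0]))
  expect_equal(c(m$centroidX, m$centroidY), c(49.5, 49.5))
})

test_that("cluster measures use inverse mean centroid distance and hulls", {
  grid <- matrix(1, 40, 40)
  single <- detect_clusters(list(synthetic_point_region(5, 5)),
                            cluster_detection_config(5, 0))
  expect_equal(cluster_measures(single[[1]], grid)$clusteredness, 1)

  pair <- stmc:::make_cluster(list(synthetic_point_region(0, 0),
                                   synthetic_point_region(0, 4)))
  expect_equal(cluster_measures(pair, grid)$clusteredness, 1 / 4)

  collinear <- stmc:::make_cluster(list(synthetic_point_region(0, 5),
                                        synthetic_point_region(10, 5),
                                        synthetic_point_region(20, 5)))
  mc <- cluster_measures(collinear, grid)
  expect_equal(mc$area, 0)
  expect_equal(mc$perimeter, 2 * 20)
})

test_that("collection statistics match a brute-force pairwise oracle", {
  grid <- matrix(2, 50, 50)
  two <- list(synthetic_point_region(0, 0), synthetic_point_region(5, 0))
  cs <- collection_statistics(two, grid)
  expect_equal(cs$clusteredness, 0.2)
  expect_equal(collection_statistics(list(synthetic_point_region(3, 3)),
                                     grid)$clusteredness, 1)
  set.seed(5)
  ents <- lapply(1:5, function(i)
    synthetic_point_region(runif(1, 0, 20), runif(1, 0, 20)))
  cs5 <- collection_statistics(ents, grid)
  cents <- t(sapply(ents, function(e) e$centroid))
  pd <- numeric(0)
  for (i in 1:4) for (j in (i + 1):5)
    pd <- c(pd, sqrt(sum((cents[i, ] - cents[j, ])^2)))
  expect_equal(cs5$clusteredness, 1 / mean(pd), tolerance = 1e-9)
  expect_equal(cs5$density, 2 / mean(pd), tolerance = 1e-9)
})

test_that("shape measures match their minimal enclosures", {
  tri <- rbind(c(0, 0), c(4, 0), c(1, 3))
  expect_equal(shape_measure(tri, "triangular"), 1, tolerance = 1e-9)
  sq <- square_poly(1)
  expect_equal(shape_measure(sq, "circular"), 2 / pi, tolerance = 1e-9)
  expect_equal(shape_measure(sq, "rectangular"), 1, tolerance = 1e-9)
  expect_equal(shape_measure(sq, "triangular"), 0.5, tolerance = 1e-9)
  # regular hexagon: minimal triangle has 1.5x its area
  hexa <- t(sapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3))))
  expect_equal(shape_measure(hexa, "triangular"), 2 / 3, tolerance = 1e-7)
  # regular 64-gon approximates a disc: rectangular measure tends to pi/4
  ng <- t(sapply(0:63, function(k) c(cos(k * pi / 32), sin(k * pi / 32))))
  expect_equal(shape_measure(ng, "rectangular"), pi / 4, tolerance = 0.01)
  expect_equal(shape_measure(ng, "circular"), 1, tolerance = 0.01)
  # degenerate polygons score 0
  expect_equal(shape_measure(rbind(c(0, 0), c(1, 1)), "circular"), 0)
})

test_that("enclosing shapes agree with exhaustive oracles on random hulls", {
  set.seed(13)
  for (i in 1:12) {
    pts <- matrix(runif(2 * sample(4:12, 1), 0, 10), ncol = 2)
    expect_equal(min_enclosing_circle(pts)$r, oracle_min_circle_radius(pts),
                 tolerance = 1e-6)
    expect_equal(min_area_rectangle(pts)$area, oracle_min_rect_area(pts),
                 tolerance = 1e-6)
    expect_equal(min_area_triangle(pts), oracle_min_triangle_area(pts),
                 tolerance = 1e-5)
  }
})

test_that("shape measures are scale invariant and bounded by 1", {
  set.seed(99)
  for (i in 1:8) {
    pts <- matrix(runif(16, 0, 10), ncol = 2)
    for (s in c("triangular", "rectangular", "circular")) {
      v <- shape_measure(pts, s)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(shape_measure(pts * 3.7, s), v, tolerance = 1e-6)
    }
  }
})

test_that("the subtended angle follows the perpendicular construction", {
  geom <- space_geometry(101, 101)  # origin (50, 50)
  # segment of half-length 3 at distance 10, perpendicular to PC
  seg <- rbind(c(60, 47), c(60, 53))
  expect_equal(angle_degrees(seg, geom), 2 * atan(3 / 10) * 180 / pi,
               tolerance = 1e-9)
  # origin inside the hull
  expect_equal(angle_degrees(square_poly(10, 45, 45), geom), 360)
  # point-like hull
  expect_equal(angle_degrees(rbind(c(70, 70)), geom), 0)
  # centroid coinciding with the origin but hull not containing it cannot
  # happen for convex hulls; a point at the origin itself returns 0
  expect_equal(angle_degrees(rbind(c(50, 50)), geom), 0)
  # full polygon: width 2h at distance D gives 2*atan(h/D) as well
  rect <- rbind(c(70, 45), c(72, 45), c(72, 55), c(70, 55))
  expect_equal(angle_degrees(rect, geom), 2 * atan(5 / 21) * 180 / pi,
               tolerance = 1e-9)
})

test_that("silhouette index matches the brute-force formula", {
  c1 <- stmc:::make_cluster(lapply(list(c(0, 0), c(1, 0), c(0, 1)),
                                   function(p)
                                     synthetic_point_region(p[1], p[2])))
  c2 <- stmc:::make_cluster(lapply(list(c(50, 50), c(51, 50), c(50, 51)),
                                   function(p)
                                     synthetic_point_region(p[1], p[2])))
  s <- silhouette_index(list(c1, c2))
  expect_gt(s, 0.9)
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(50, 50), c(51, 50), c(50, 51))
  expect_equal(s, oracle_silhouette(pts, c(1, 1, 1, 2, 2, 2)),
               tolerance = 1e-9)
  # undefined cases yield NA (no state variable should be emitted)
  expect_true(is.na(silhouette_index(list(c1))))
  single1 <- stmc:::make_cluster(list(synthetic_point_region(0, 0)))
  single2 <- stmc:::make_cluster(list(synthetic_point_region(9, 9)))
  expect_true(is.na(silhouette_index(list(single1, single2))))
  # random clusterings stay in [-1, 1] and match the oracle
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    sizes <- sample(1:4, k, replace = TRUE)
    pts <- matrix(runif(2 * sum(sizes), 0, 20), ncol = 2)
    labels <- rep(seq_len(k), sizes)
    clusters <- lapply(seq_len(k), function(l) {
      idx <- which(labels == l)
      stmc:::make_cluster(lapply(idx, function(j)
        synthetic_point_region(pts[j, 1], pts[j, 2])))
    })
    v <- silhouette_index(clusters)
    if (all(sizes <= 1)) {
      expect_true(is.na(v))
    } else {
      expect_gte(v, -1); expect_lte(v, 1)
      expect_equal(v, oracle_silhouette(pts, labels), tolerance = 1e-9)
    }
  }
})
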