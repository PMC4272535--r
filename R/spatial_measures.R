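#' @title Spatial measures
#'
#' @description The eleven spatial measures characterising detected regions
#' and clusters (clusteredness, density, area, perimeter, distance from the
#' origin, angle, the three fuzzy shape measures and the centroid), the
#' collection-level statistics, and the Silhouette cluster-validity index.
#'
#' @name spatial-measures
NULL

#' Geometry of the discretised space
#'
#' @param rows,cols Dimensions of the m x n grid.
#' @return A `space_geometry` object whose `origin` is the centre point of
#'   the discretised space in (x, y) coordinates: `((cols-1)/2, (rows-1)/2)`.
#' @export
space_geometry <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 origin = c((cols - 1) / 2, (rows - 1) / 2)),
            class = "space_geometry")
}

mean_pairwise_distance <- function(centroids) {
  n <- nrow(centroids)
  if (n < 2) return(NA_real_)
  mean(stats::dist(centroids))
}

# Divisor convention for <2-member collections (and coincident centroids):
# the mean pairwise distance divisor defaults to 1 so values stay finite.
inverse_mean_distance <- function(centroids) {
  d <- mean_pairwise_distance(centroids)
  if (is.na(d) || d <= 0) 1 else 1 / d
}

#' Fuzzy shape similarity measure
#'
#' Ratio of the polygon area (or an explicitly supplied entity area, e.g.
#' net of holes) to the area of the polygon's minimum-area enclosing
#' triangle, rectangle or circle. Lies in \[0, 1\]; equals 1 exactly when
#' the polygon coincides with its minimal enclosure. Degenerate (zero-area)
#' polygons score 0 for every shape.
#'
#' @param polygon Vertex matrix, columns (x, y).
#' @param shape One of "triangular", "rectangular", "circular".
#' @param area Numerator area; defaults to the polygon's shoelace area.
#' @return Similarity in \[0, 1\].
#' @export
shape_measure <- function(polygon,
                          shape = c("triangular", "rectangular", "circular"),
                          area = NULL) {
  shape <- match.arg(shape)
  polygon <- poly_matrix(polygon)
  a <- if (is.null(area)) polygon_area(polygon) else area
  if (a <= 1e-12) return(0)
  enc <- switch(shape,
    triangular = min_area_triangle(polygon),
    rectangular = min_area_rectangle(polygon)$area,
    circular = { circ <- min_enclosing_circle(polygon); pi * circ$r^2 })
  if (enc <= 0) return(0)
  min(1, a / enc)
}

shape_label <- function(tri, rect, circ) {
  # fixed tie order: triangular > rectangular > circular
  c("triangular", "rectangular", "circular")[
    which.max(c(tri, rect, circ))]
}

#' Angle subtended by an entity at the origin
#'
#' Let P be the space origin and C the polygon centroid. The convex hull of
#' the polygon is intersected with the line through C perpendicular to the
#' segment PC; the two extreme intersection points A and B define the
#' returned angle APB in degrees. Conventions: 360 when P lies inside the
#' hull, 0 when the hull degenerates to a point or no direction is defined
#' (C coincides with P).
#'
#' @param polygon Vertex matrix, columns (x, y).
#' @param geom A [space_geometry()].
#' @return Angle in degrees, in \[0, 360\].
#' @export
angle_degrees <- function(polygon, geom) {
  stopifnot(inherits(geom, "space_geometry"))
  hull <- convex_hull(polygon)
  P <- geom$origin
  if (nrow(hull) == 1L)
    return(0)
  if (nrow(hull) >= 3 && point_in_polygon(P, hull)) return(360)
  if (nrow(hull) == 2L &&
      point_on_segment(P, hull[1, ], hull[2, ])) return(360)
  C <- polygon_centroid(hull)
  pc <- C - P
  if (sqrt(sum(pc^2)) < 1e-12) return(0)
  v <- c(-pc[2], pc[1]) / sqrt(sum(pc^2))  # perpendicular direction
  ts <- line_polygon_params(C, v, hull)
  if (!length(ts)) return(0)
  A <- C + min(ts) * v
  B <- C + max(ts) * v
  va <- A - P; vb <- B - P
  na <- sqrt(sum(va^2)); nb2 <- sqrt(sum(vb^2))
  if (na < 1e-12 || nb2 < 1e-12) return(0)
  cosang <- max(-1, min(1, sum(va * vb) / (na * nb2)))
  acos(cosang) * 180 / pi
}

# Parameters t of intersections of the line {C + t v} with the boundary of
# polygon `p`; collinear overlapping edges contribute both endpoints.
line_polygon_params <- function(C, v, p) {
  p <- poly_matrix(p)
  n <- nrow(p)
  if (n < 2) return(numeric(0))
  j <- if (n == 2) 2 else c(2:n, 1)
  ts <- numeric(0)
  segs <- if (n == 2) 1 else seq_len(n)
  for (i in segs) {
    a <- p[i, ]; b <- p[j[i], ]
    e <- b - a
    denom <- v[1] * (-e[2]) - v[2] * (-e[1])  # cross(v, e) with sign
    w <- a - C
    if (abs(denom) < 1e-12) {
      # parallel; collinear overlap contributes both endpoints
      if (abs(w[1] * v[2] - w[2] * v[1]) < 1e-9) {
        ts <- c(ts, sum((a - C) * v), sum((b - C) * v))
      }
      next
    }
    # solve C + t v = a + s e
    t <- (w[1] * (-e[2]) - w[2] * (-e[1])) / denom
    s <- (v[1] * w[2] - v[2] * w[1]) / denom
    if (s >= -1e-9 && s <= 1 + 1e-9) ts <- c(ts, t)
  }
  ts
}

measure_set <- function(clusteredness, density, area, perimeter,
                        distanceFromOrigin, angle, tri, rect, circ,
                        centroid) {
  list(clusteredness = clusteredness, density = density, area = area,
       perimeter = perimeter, distanceFromOrigin = distanceFromOrigin,
       angle = angle,
       triangularMeasure = tri, rectangularMeasure = rect,
       circularMeasure = circ,
       centroidX = centroid[1], centroidY = centroid[2],
       shape = shape_label(tri, rect, circ))
}

polygon_measures <- function(outer, geom, area, perimeter = NULL) {
  perimeter <- if (is.null(perimeter)) polygon_perimeter(outer) else perimeter
  centroid <- if (nrow(poly_matrix(outer)) >= 3 &&
                  polygon_area(outer) > 1e-12) polygon_centroid(outer)
              else colMeans(poly_matrix(outer))
  list(
    area = area,
    perimeter = perimeter,
    distanceFromOrigin = dist_point_polygon(geom$origin, outer),
    angle = angle_degrees(outer, geom),
    tri = shape_measure(outer, "triangular", area = area),
    rect = shape_measure(outer, "rectangular", area = area),
    circ = shape_measure(outer, "circular", area = area),
    centroid = as.numeric(centroid))
}

#' Spatial measures of a single region
#'
#' Computes the full measure set of one detected region: clusteredness
#' (area over area plus hole areas), density (mean grid value over the
#' covered positions), polygon area minus holes, outer perimeter (holes
#' ignored), minimum distance from the space origin, subtended angle, the
#' three shape measures with the fuzzy shape label, and the polygon-moment
#' centroid.
#'
#' @param region A `stmc_region` from [detect_regions()].
#' @param grid The originating state grid (used for density).
#' @param geom A [space_geometry()]; defaults to the grid's own geometry.
#' @return Named list with the eleven measures plus `shape`.
#' @export
region_measures <- function(region, grid, geom = NULL) {
  stopifnot(inherits(region, "stmc_region"))
  check_state_grid(grid)
  if (is.null(geom)) geom <- space_geometry(nrow(grid), ncol(grid))
  outer <- region$outerContour
  outer_area <- polygon_area(outer)
  hole_areas <- vapply(region$holes, polygon_area, numeric(1))
  total_holes <- sum(hole_areas)
  area <- max(0, outer_area - total_holes)
  clusteredness <- if (area + total_holes <= 0) 1
                   else area / (area + total_holes)
  dens <- mean(grid[region$positions[, 1] + 1L +
                      nrow(grid) * region$positions[, 2]])
  pm <- polygon_measures(outer, geom, area)
  pm$centroid <- region$centroid
  measure_set(clusteredness, dens, pm$area, pm$perimeter,
              pm$distanceFromOrigin, pm$angle, pm$tri, pm$rect, pm$circ,
              pm$centroid)
}

#' Spatial measures of a cluster
#'
#' Clusteredness is the inverse of the mean pairwise centroid distance of
#' the member regions (1 for a single-member cluster). Density is the mean
#' grid value over all member positions. The remaining measures are
#' computed on the convex hull of all member regions, exactly as for a
#' region (holes between regions are ignored).
#'
#' @param cluster A `stmc_cluster` from [detect_clusters()].
#' @param grid The originating state grid.
#' @param geom A [space_geometry()]; defaults to the grid's own geometry.
#' @return Named list with the eleven measures plus `shape`.
#' @export
cluster_measures <- function(cluster, grid, geom = NULL) {
  stopifnot(inherits(cluster, "stmc_cluster"))
  check_state_grid(grid)
  if (is.null(geom)) geom <- space_geometry(nrow(grid), ncol(grid))
  cents <- t(vapply(cluster$members, function(r) r$centroid, numeric(2)))
  clusteredness <- inverse_mean_distance(cents)
  pos <- do.call(rbind, lapply(cluster$members, function(r) r$positions))
  dens <- mean(grid[pos[, 1] + 1L + nrow(grid) * pos[, 2]])
  hull <- cluster$hull
  pm <- polygon_measures(hull, geom, polygon_area(hull))
  measure_set(clusteredness, dens, pm$area, pm$perimeter,
              pm$distanceFromOrigin, pm$angle, pm$tri, pm$rect, pm$circ,
              as.numeric(cluster$centroid))
}

#' Collection-level clusteredness and density
#'
#' For a set of entities (regions or clusters), the clusteredness of the
#' set is the inverse of the mean pairwise centroid distance and the
#' density of the set is the mean member density divided by the same mean
#' distance. Collections with fewer than two members use divisor 1, so a
#' singleton set has clusteredness 1.
#'
#' @param entities List of `stmc_region` or `stmc_cluster` objects.
#' @param grid The originating state grid.
#' @param geom A [space_geometry()]; defaults to the grid's own geometry.
#' @return List with `clusteredness` and `density`.
#' @export
collection_statistics <- function(entities, grid, geom = NULL) {
  if (!length(entities)) return(list(clusteredness = 1, density = 0))
  check_state_grid(grid)
  if (is.null(geom)) geom <- space_geometry(nrow(grid), ncol(grid))
  cents <- t(vapply(entities, function(e) e$centroid, numeric(2)))
  inv <- inverse_mean_distance(cents)
  dens <- vapply(entities, function(e) {
    if (inherits(e, "stmc_cluster")) cluster_measures(e, grid, geom)$density
    else region_measures(e, grid, geom)$density
  }, numeric(1))
  list(clusteredness = inv, density = mean(dens) * inv)
}

#' Silhouette index of a clustering of regions
#'
#' Mean Silhouette width over all member regions of at least two clusters,
#' with the centroid distance as the dissimilarity. Regions in singleton
#' clusters contribute 0 (the usual convention). Returns `NA` when fewer
#' than two clusters are present or every cluster is a singleton, in which
#' case no `avgClusterednessClusters` state variable should be emitted.
#'
#' @param clusters List of `stmc_cluster` objects.
#' @return Mean Silhouette value in \[-1, 1\], or `NA` when undefined.
#' @export
silhouette_index <- function(clusters) {
  if (length(clusters) < 2L) return(NA_real_)
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  if (all(sizes <= 1L)) return(NA_real_)
  labels <- rep(seq_along(clusters), sizes)
  cents <- do.call(rbind, lapply(clusters, function(cl)
    t(vapply(cl$members, function(r) r$centroid, numeric(2)))))
  sil <- cluster::silhouette(labels, dist(cents))
  mean(sil[, "sil_width"])
}
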