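# Planar geometry primitives shared by the pattern-detection and
# spatial-measure modules. All polygons are matrices with columns (x, y);
# pixel-centre coordinates, y growing downward (image convention).

poly_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

# Signed shoelace area: positive for counter-clockwise vertex order
# in a y-up frame.
polygon_signed_area <- function(p) {
  p <- poly_matrix(p)
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_area <- function(p) abs(polygon_signed_area(p))

polygon_perimeter <- function(p) {
  p <- poly_matrix(p)
  n <- nrow(p)
  if (n < 2) return(0)
  j <- c(2:n, 1)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}

# Centroid from the area moments of the polygon; degenerate (area ~ 0)
# polygons fall back to the vertex mean.
polygon_centroid <- function(p) {
  p <- poly_matrix(p)
  n <- nrow(p)
  a <- polygon_signed_area(p)
  if (n < 3 || abs(a) < 1e-12) return(colMeans(p))
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Convex hull vertices in counter-clockwise order (shoelace-positive).
convex_hull <- function(p) {
  p <- poly_matrix(p)
  p <- unique(p)
  if (nrow(p) <= 2) return(p)
  h <- p[grDevices::chull(p), , drop = FALSE]
  if (nrow(h) >= 3 && polygon_signed_area(h) < 0)
    h <- h[nrow(h):1, , drop = FALSE]
  h
}

point_on_segment <- function(pt, a, b, tol = 1e-9) {
  cross <- (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  if (abs(cross) > tol * (1 + max(abs(b - a)))) return(FALSE)
  dot <- (pt[1] - a[1]) * (b[1] - a[1]) + (pt[2] - a[2]) * (b[2] - a[2])
  len2 <- sum((b - a)^2)
  if (len2 == 0) return(sum((pt - a)^2) <= tol^2)
  dot >= -tol && dot <= len2 + tol
}

# Point-in-polygon by crossing number; boundary points count as inside.
point_in_polygon <- function(pt, p) {
  p <- poly_matrix(p)
  n <- nrow(p)
  if (n == 0) return(FALSE)
  if (n == 1) return(all(abs(pt - p[1, ]) < 1e-9))
  j <- c(2:n, 1)
  for (i in seq_len(n))
    if (point_on_segment(pt, p[i, ], p[j[i], ])) return(TRUE)
  if (n < 3) return(FALSE)
  inside <- FALSE
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[j[i], ]
    if ((a[2] > pt[2]) != (b[2] > pt[2])) {
      xcross <- a[1] + (pt[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
      if (pt[1] < xcross) inside <- !inside
    }
  }
  inside
}

dist_point_segment <- function(pt, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((pt - a)^2)))
  t <- max(0, min(1, sum((pt - a) * ab) / len2))
  sqrt(sum((pt - (a + t * ab))^2))
}

# Minimum distance from a point to a polygon (0 when inside or on boundary).
dist_point_polygon <- function(pt, p) {
  p <- poly_matrix(p)
  n <- nrow(p)
  if (n == 0) return(NA_real_)
  if (n == 1) return(sqrt(sum((pt - p[1, ])^2)))
  if (n >= 3 && point_in_polygon(pt, p)) return(0)
  j <- c(2:n, 1)
  min(vapply(seq_len(n), function(i)
    dist_point_segment(pt, p[i, ], p[j[i], ]), numeric(1)))
}

# ---- minimum enclosing circle (Welzl, deterministic incremental) ----------

circle_from2 <- function(a, b) list(c = (a + b) / 2,
                                    r = sqrt(sum((a - b)^2)) / 2)

circle_from3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    # collinear: fall back to the widest pair
    cands <- list(circle_from2(a, b), circle_from2(a, c), circle_from2(b, c))
    return(cands[[which.max(vapply(cands, function(x) x$r, numeric(1)))]])
  }
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
         sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
         sum(c^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(c = ctr, r = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(p, circ, tol = 1e-9) {
  sqrt(sum((p - circ$c)^2)) <= circ$r + tol
}

#' Minimum enclosing circle of a point set
#'
#' Deterministic incremental (Welzl-style) construction of the smallest
#' circle containing all points.
#'
#' @param p Matrix of points, columns (x, y).
#' @return List with elements `c` (centre) and `r` (radius).
#' @export
min_enclosing_circle <- function(p) {
  p <- poly_matrix(p)
  p <- unique(p)
  n <- nrow(p)
  if (n == 0) stop("empty point set", call. = FALSE)
  if (n == 1) return(list(c = p[1, ], r = 0))
  circ <- circle_from2(p[1, ], p[2, ])
  if (n == 2) return(circ)
  for (i in 3:n) {
    if (in_circle(p[i, ], circ)) next
    # p[i] lies on the boundary of the new circle
    circ <- circle_from2(p[1, ], p[i, ])
    for (j in 2:(i - 1)) {
      if (in_circle(p[j, ], circ)) next
      circ <- circle_from2(p[i, ], p[j, ])
      for (k in seq_len(j - 1)) {
        if (in_circle(p[k, ], circ)) next
        circ <- circle_from3(p[i, ], p[j, ], p[k, ])
      }
    }
  }
  circ
}

# ---- minimum-area enclosing rectangle (rotating calipers) ------------------

#' Minimum-area enclosing rectangle
#'
#' Rotating-calipers search over hull edge directions; the minimum-area
#' rectangle containing a convex polygon has one side flush with a hull edge.
#'
#' @param p Matrix of points, columns (x, y).
#' @return List with `area`, `width`, `height` and `angle` (radians of the
#'   flush edge).
#' @export
min_area_rectangle <- function(p) {
  h <- convex_hull(p)
  n <- nrow(h)
  if (n < 3) {
    len <- if (n == 2) sqrt(sum((h[2, ] - h[1, ])^2)) else 0
    return(list(area = 0, width = len, height = 0, angle = 0))
  }
  j <- c(2:n, 1)
  best <- list(area = Inf, width = NA, height = NA, angle = NA)
  for (i in seq_len(n)) {
    e <- h[j[i], ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2], u[1])
    proj_u <- h %*% u
    proj_v <- h %*% v
    w <- max(proj_u) - min(proj_u)
    ht <- max(proj_v) - min(proj_v)
    if (w * ht < best$area)
      best <- list(area = w * ht, width = w, height = ht,
                   angle = atan2(u[2], u[1]))
  }
  best
}

# ---- minimum-area enclosing triangle ---------------------------------------

# Support value of the hull in direction theta.
hull_support <- function(h, theta) {
  max(h[, 1] * cos(theta) + h[, 2] * sin(theta))
}

# Area of the triangle bounded by the three support lines with outward
# normal angles th (sorted); Inf when the normals do not positively span
# the plane (no bounded triangle).
triangle_area_from_angles <- function(h, th) {
  th <- sort(th %% (2 * pi))
  gaps <- c(diff(th), 2 * pi - (th[3] - th[1]))
  if (any(gaps <= 1e-12) || any(gaps >= pi - 1e-12)) return(Inf)
  hs <- vapply(th, function(t) hull_support(h, t), numeric(1))
  area_from_lines(th, hs)
}

area_from_lines <- function(th, hs) {
  vert <- function(i, jj) {
    d <- sin(th[jj] - th[i])
    c((hs[i] * sin(th[jj]) - hs[jj] * sin(th[i])) / d,
      (hs[jj] * cos(th[i]) - hs[i] * cos(th[jj])) / d)
  }
  v1 <- vert(1, 2); v2 <- vert(2, 3); v3 <- vert(3, 1)
  abs((v1[1] * (v2[2] - v3[2]) + v2[1] * (v3[2] - v1[2]) +
       v3[1] * (v1[2] - v2[2])) / 2)
}

#' Minimum-area enclosing triangle
#'
#' Computes the area of the smallest-area triangle containing a point set.
#' The search exploits the classical flush-side property (at least one
#' triangle side lies on a hull edge): for every hull edge the remaining two
#' support-line directions are optimised by a vectorised grid scan refined
#' with coordinate-wise golden-section descent. The result is deterministic.
#'
#' @param p Matrix of points, columns (x, y).
#' @return The minimal enclosing triangle area (0 for degenerate inputs).
#' @export
min_area_triangle <- function(p) {
  h <- convex_hull(p)
  n <- nrow(h)
  if (n < 3 || polygon_area(h) < 1e-12) return(0)
  j <- c(2:n, 1)
  edges <- h[j, , drop = FALSE] - h
  keep <- which(sqrt(rowSums(edges^2)) > 1e-12)
  # outward normal of each edge: the orientation in which the edge's own
  # vertices attain the hull support value
  scale <- max(abs(h)) + 1
  normals <- vapply(keep, function(i) {
    e <- edges[i, ]
    t <- atan2(-e[1], e[2]) %% (2 * pi)
    u <- c(cos(t), sin(t))
    if (abs(max(h[i, ] %*% u, h[j[i], ] %*% u) - hull_support(h, t)) >
        1e-9 * scale)
      t <- (t + pi) %% (2 * pi)
    t
  }, numeric(1))
  normals <- sort(unique(normals))
  # stage 1: vectorised grid scan over the two free support directions for
  # every flush edge; stage 2: coordinate-descent refinement of the edges
  # whose grid optimum is close to the global one
  grid_best <- vapply(normals, function(th1)
    min_triangle_grid(h, th1, normals)$area, numeric(1))
  best <- Inf
  for (i in order(grid_best)) {
    if (grid_best[i] > 1.1 * min(grid_best)) break
    res <- min_triangle_fixed_base(h, normals[i], normals)
    if (res < best) best <- res
  }
  best
}

# Vectorised scan: for base normal th1, evaluate the enclosing-triangle
# area on a grid of absolute directions th2 in (th1, th1+pi) and th3 in
# (th1+pi, th1+2pi), augmented with the hull edge normals in range.
min_triangle_grid <- function(h, th1, normals) {
  hx <- h[, 1]; hy <- h[, 2]
  supp <- function(th) {
    vapply(th, function(t) max(hx * cos(t) + hy * sin(t)), numeric(1))
  }
  margin <- 1e-4
  base2 <- seq(th1 + margin, th1 + pi - margin, length.out = 26)
  base3 <- seq(th1 + pi + margin, th1 + 2 * pi - margin, length.out = 26)
  rel <- (normals - th1) %% (2 * pi)
  V2 <- sort(unique(c(base2, th1 + rel[rel > margin & rel < pi - margin])))
  V3 <- sort(unique(c(base3,
                      th1 + rel[rel > pi + margin & rel < 2 * pi - margin])))
  h1 <- supp(th1); h2 <- supp(V2); h3 <- supp(V3)
  n2 <- length(V2); n3 <- length(V3)
  # triangle vertices from pairwise support-line intersections
  vx <- function(ta, ha, tb, hb) {
    d <- sin(tb - ta)
    list(x = (ha * sin(tb) - hb * sin(ta)) / d,
         y = (hb * cos(ta) - ha * cos(tb)) / d)
  }
  v12 <- vx(th1, h1, V2, h2)                      # length n2
  v31 <- vx(V3, h3, th1, h1)                      # length n3
  T2 <- matrix(V2, n2, n3); H2 <- matrix(h2, n2, n3)
  T3 <- matrix(V3, n2, n3, byrow = TRUE); H3 <- matrix(h3, n2, n3,
                                                       byrow = TRUE)
  d23 <- sin(T3 - T2)
  x23 <- (H2 * sin(T3) - H3 * sin(T2)) / d23
  y23 <- (H3 * cos(T2) - H2 * cos(T3)) / d23
  X12 <- matrix(v12$x, n2, n3); Y12 <- matrix(v12$y, n2, n3)
  X31 <- matrix(v31$x, n2, n3, byrow = TRUE)
  Y31 <- matrix(v31$y, n2, n3, byrow = TRUE)
  area <- abs(X12 * (y23 - Y31) + x23 * (Y31 - Y12) + X31 * (Y12 - y23)) / 2
  invalid <- (T3 - T2 >= pi - 1e-9) | (T3 - T2 <= 1e-9)
  area[invalid] <- Inf
  k <- arrayInd(which.min(area), dim(area))
  list(area = min(area), a2 = V2[k[1]] - th1, a3 = V3[k[2]] - V2[k[1]])
}

# Optimal enclosing triangle with one side's outward normal fixed at th1.
min_triangle_fixed_base <- function(h, th1, normals) {
  hx <- h[, 1]; hy <- h[, 2]
  obj <- function(a2, a3) {
    th <- c(th1, th1 + a2, th1 + a2 + a3)
    g3 <- 2 * pi - a2 - a3
    if (a2 <= 1e-9 || a3 <= 1e-9 || g3 <= 1e-9 ||
        a2 >= pi - 1e-9 || a3 >= pi - 1e-9 || g3 >= pi - 1e-9) return(1e300)
    hs <- vapply(th, function(t) max(hx * cos(t) + hy * sin(t)), numeric(1))
    area_from_lines(th, hs)
  }
  g <- min_triangle_grid(h, th1, normals)
  best <- g$area
  ba <- c(g$a2, g$a3)
  if (!is.finite(best)) return(Inf)
  # coordinate-wise golden-section polish (robust at flush kinks)
  for (pass in 1:4) {
    o2 <- stats::optimize(function(a) obj(a, ba[2]),
                          lower = max(1e-8, ba[1] - 0.3),
                          upper = min(pi - 1e-8, ba[1] + 0.3),
                          tol = 1e-12)
    if (o2$objective < best) { best <- o2$objective; ba[1] <- o2$minimum }
    o3 <- stats::optimize(function(a) obj(ba[1], a),
                          lower = max(1e-8, ba[2] - 0.3),
                          upper = min(pi - 1e-8, ba[2] + 0.3),
                          tol = 1e-12)
    if (o3$objective < best) { best <- o3$objective; ba[2] <- o3$minimum }
    # re-snap to nearby flush normals, which golden section can skip past
    rel <- ((normals - th1) %% (2 * pi))
    for (r2 in rel[abs(rel - ba[1]) < 0.05]) {
      v <- obj(r2, ba[2]); if (v < best) { best <- v; ba[1] <- r2 }
    }
    for (r3 in rel[abs(rel - ba[1] - ba[2]) < 0.05]) {
      v <- obj(ba[1], r3 - ba[1]); if (v < best) { best <- v; ba[2] <- r3 - ba[1] }
    }
  }
  best
}

# ---- polygonal approximation (Douglas-Peucker) -----------------------------

dp_chain <- function(p, eps) {
  n <- nrow(p)
  if (n <= 2) return(p)
  a <- p[1, ]; b <- p[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-12) sqrt(rowSums(sweep(p, 2, a)^2))
       else abs((p[, 1] - a[1]) * ab[2] - (p[, 2] - a[2]) * ab[1]) / len
  i <- which.max(d)
  if (d[i] <= eps) return(p[c(1, n), , drop = FALSE])
  left <- dp_chain(p[1:i, , drop = FALSE], eps)
  right <- dp_chain(p[i:n, , drop = FALSE], eps)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# Douglas-Peucker simplification of a closed polygon with tolerance eps.
approx_polygon <- function(p, eps) {
  p <- poly_matrix(p)
  n <- nrow(p)
  if (eps <= 0 || n <= 3) return(p)
  # split the ring at the two mutually farthest of (v1, farthest-from-v1)
  d1 <- rowSums(sweep(p, 2, p[1, ])^2)
  k <- which.max(d1)
  if (k == 1) return(p)
  c1 <- dp_chain(p[1:k, , drop = FALSE], eps)
  c2 <- dp_chain(p[c(k:n, 1), , drop = FALSE], eps)
  out <- rbind(c1[-nrow(c1), , drop = FALSE], c2[-nrow(c2), , drop = FALSE])
  out
}
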