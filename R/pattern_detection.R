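#' @title Region and cluster detection
#'
#' @description Detection of spatial patterns ("regions") in pseudo-3D state
#' grids via a parameterised image-processing pipeline (brightness/contrast,
#' morphological closing, Gaussian blur, binary threshold, two-level contour
#' extraction with holes, polygonal approximation), and of groups of regions
#' ("clusters") via an order-independent DBSCAN variant over the
#' centroid-distance pseudometric.
#'
#' @name pattern-detection
NULL

check_state_grid <- function(grid) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("state grid must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("state grid entries must be finite and non-negative", call. = FALSE)
  invisible(TRUE)
}

round_half_up <- function(x) floor(x + 0.5)

#' Convert a state grid to a grayscale image
#'
#' Each grid value is normalised by `normalizationMax` (clipped at 1) and
#' scaled to the 0-255 intensity range with round-half-up.
#'
#' @param grid Numeric m x n matrix of non-negative values.
#' @param normalizationMax Positive normalisation constant, or `"auto"` to
#'   use the grid maximum (an all-zero grid maps to the all-zero image).
#' @return Integer matrix of intensities in \[0, 255\].
#' @export
grid_to_grayscale <- function(grid, normalizationMax = "auto") {
  check_state_grid(grid)
  if (identical(normalizationMax, "auto")) {
    normalizationMax <- max(grid)
    if (normalizationMax <= 0)
      return(matrix(0L, nrow(grid), ncol(grid)))
  }
  if (!is.numeric(normalizationMax) || normalizationMax <= 0)
    stop("'normalizationMax' must be a positive number or \"auto\"",
         call. = FALSE)
  img <- round_half_up(255 * pmin(grid / normalizationMax, 1))
  storage.mode(img) <- "integer"
  img
}

#' Region detection parameters
#'
#' @param alpha Contrast gain (> 0).
#' @param beta Brightness offset.
#' @param morphCloseNrOfIter Number of morphological closing iterations
#'   (3 x 3 box structuring element; 0 disables the step).
#' @param blurKernelSize Odd positive Gaussian kernel size (1 disables
#'   blurring).
#' @param blurStandardDev Gaussian standard deviation; when <= 0 it is
#'   derived from the kernel size as `0.3 * ((k - 1) / 2 - 1) + 0.8`.
#' @param thresholdValue Binary threshold on the 0-255 intensity scale;
#'   intensities strictly above it are foreground.
#' @param epsilonSize Minimum region cardinality: only regions with strictly
#'   more pixels are kept.
#' @param approximationLevel Tolerance of the Douglas-Peucker contour
#'   approximation (0 keeps the raw contour).
#' @param pointMode When `TRUE`, skip closing/blur/contours and return every
#'   position with intensity >= `thresholdValue` as a one-pixel region (used
#'   for single-cell entities where pileup is carried by the grid value).
#' @return A `region_detection_config` object.
#' @export
region_detection_config <- function(alpha = 1, beta = 0,
                                    morphCloseNrOfIter = 0L,
                                    blurKernelSize = 1L,
                                    blurStandardDev = 0,
                                    thresholdValue = 127L,
                                    epsilonSize = 0,
                                    approximationLevel = 0,
                                    pointMode = FALSE) {
  stopifnot(is.numeric(alpha), alpha > 0,
            is.numeric(beta),
            morphCloseNrOfIter >= 0,
            blurKernelSize >= 1,
            thresholdValue >= 0, thresholdValue <= 255,
            epsilonSize >= 0, approximationLevel >= 0,
            is.logical(pointMode))
  if (blurKernelSize %% 2 != 1)
    stop("'blurKernelSize' must be an odd positive integer", call. = FALSE)
  structure(list(alpha = alpha, beta = beta,
                 morphCloseNrOfIter = as.integer(morphCloseNrOfIter),
                 blurKernelSize = as.integer(blurKernelSize),
                 blurStandardDev = blurStandardDev,
                 thresholdValue = as.integer(thresholdValue),
                 epsilonSize = epsilonSize,
                 approximationLevel = approximationLevel,
                 pointMode = pointMode),
            class = "region_detection_config")
}

# Grayscale morphology with a 3 x 3 box structuring element. Outside pixels
# do not influence the result (-Inf for the max filter, +Inf for the min
# filter), so components touching the image border are not eroded away.
shift_fill <- function(x, dr, dc, fill) {
  m <- nrow(x); n <- ncol(x)
  out <- matrix(fill, m, n)
  rs <- max(1, 1 + dr):min(m, m + dr)
  cs <- max(1, 1 + dc):min(n, n + dc)
  out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

box_filter3 <- function(x, op, fill) {
  out <- x
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- op(out, shift_fill(x, dr, dc, fill))
  }
  out
}

gray_dilate3 <- function(x) box_filter3(x, pmax, -Inf)
gray_erode3 <- function(x) box_filter3(x, pmin, Inf)

# Separable Gaussian blur with replicated borders; kernel built as in the
# classical image-processing convention (sigma derived from kernel size when
# not given).
gaussian_blur <- function(img, ksize, sigma) {
  if (ksize <= 1) return(img)
  if (sigma <= 0) sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  half <- (ksize - 1) / 2
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- w / sum(w)
  conv_cols <- function(m) {
    n <- ncol(m)
    padded <- m[, c(rep(1, half), seq_len(n), rep(n, half)), drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (i in seq_len(ksize))
      out <- out + w[i] * padded[, i:(i + n - 1), drop = FALSE]
    out
  }
  out <- conv_cols(img)
  out <- t(conv_cols(t(out)))
  pmin(pmax(round_half_up(out), 0), 255)
}

# 8- or 4-connected component labelling via column runs and union-find.
label_components <- function(mask, eight = TRUE) {
  m <- nrow(mask); n <- ncol(mask)
  labels <- matrix(NA_integer_, m, n)
  runs <- vector("list", n)
  total <- 0L
  for (j in seq_len(n)) {
    v <- mask[, j]
    if (!any(v)) next  # runs[[j]] stays NULL
    d <- diff(c(FALSE, v, FALSE))
    starts <- which(d == 1)
    ends <- which(d == -1) - 1L
    runs[[j]] <- cbind(start = starts, end = ends,
                       id = total + seq_along(starts))
    total <- total + length(starts)
  }
  if (total == 0L) return(list(labels = labels, n = 0L))
  parent <- seq_len(total)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  tol <- if (eight) 1L else 0L
  for (j in 2:n) {
    a <- runs[[j]]; b <- runs[[j - 1L]]
    if (is.null(a) || is.null(b)) next
    for (ia in seq_len(nrow(a))) for (ib in seq_len(nrow(b))) {
      if (a[ia, "start"] <= b[ib, "end"] + tol &&
          b[ib, "start"] <= a[ia, "end"] + tol) {
        ra <- find_root(a[ia, "id"]); rb <- find_root(b[ib, "id"])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(total), find_root, integer(1))
  ids <- match(roots, sort(unique(roots)))
  for (j in seq_len(n)) {
    rr <- runs[[j]]
    if (is.null(rr)) next
    for (k in seq_len(nrow(rr)))
      labels[rr[k, "start"]:rr[k, "end"], j] <- ids[rr[k, "id"]]
  }
  list(labels = labels, n = max(ids))
}

# Moore-neighbour boundary tracing on the pixel set given by `mask`,
# returning the closed boundary polygon through pixel centres in
# (x = col - 1, y = row - 1) coordinates. Clockwise in image coordinates
# (y growing downward).
trace_contour <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1L)
    return(matrix(c(idx[1, 2] - 1, idx[1, 1] - 1), ncol = 2))
  start <- unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ])
  # 8 neighbour offsets in clockwise order starting from W, as (drow, dcol)
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  dir_of <- function(off) which(nb[, 1] == off[1] & nb[, 2] == off[2])
  inside <- function(q) q[1] >= 1 && q[1] <= m && q[2] >= 1 && q[2] <= n &&
    mask[q[1], q[2]]
  contour <- list(start)
  p <- start
  b_dir <- 1L  # backtrack: the W neighbour of the topmost-leftmost pixel
  first_move <- NA_integer_
  guard <- 8L * nrow(idx) + 16L
  repeat {
    d <- NA_integer_
    for (k in 0:7) {
      dd <- ((b_dir - 1L + k) %% 8L) + 1L
      q <- p + nb[dd, ]
      if (inside(q)) { d <- dd; break }
    }
    if (is.na(d)) break
    # Jacob's criterion: stop on re-entering the start in the same direction
    if (!is.na(first_move) && all(p == start) && d == first_move) break
    if (is.na(first_move)) first_move <- d
    prev_probe <- p + nb[((d - 2L) %% 8L) + 1L, ]  # background, probed last
    contour[[length(contour) + 1L]] <- q
    b_dir <- dir_of(prev_probe - q)
    p <- q
    if (length(contour) > guard) break
  }
  pts <- do.call(rbind, contour)
  if (nrow(pts) > 1L && all(pts[nrow(pts), ] == pts[1, ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  cbind(pts[, 2] - 1, pts[, 1] - 1)
}

make_region <- function(outer, holes, positions, value_at = NULL) {
  centroid <- if (nrow(outer) >= 3) polygon_centroid(outer)
              else colMeans(poly_matrix(outer))
  structure(list(outerContour = poly_matrix(outer),
                 holes = lapply(holes, poly_matrix),
                 positions = positions,
                 centroid = as.numeric(centroid)),
            class = "stmc_region")
}

#' @export
print.stmc_region <- function(x, ...) {
  cat(sprintf("region: %d pixel(s), %d hole(s), centroid (%.2f, %.2f)\n",
              nrow(x$positions), length(x$holes),
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Detect regions in a grayscale image
#'
#' Applies, in order: brightness/contrast adjustment, morphological closing,
#' Gaussian blur, binary thresholding (strictly above `thresholdValue` is
#' foreground), 8-connected component extraction with hole detection
#' (two-level contour hierarchy), Douglas-Peucker polygonal approximation,
#' and a strict minimum-size filter. Regions are returned sorted by
#' (centroidY, centroidX) so the output is reproducible.
#'
#' @param image Integer matrix of intensities in \[0, 255\].
#' @param config A [region_detection_config()].
#' @return List of `stmc_region` objects. Each carries its outer contour and
#'   hole polygons (pixel-centre coordinates, x = column, y = row, 0-based),
#'   the set of covered grid positions and the polygon-moment centroid.
#' @export
detect_regions <- function(image, config = region_detection_config()) {
  stopifnot(inherits(config, "region_detection_config"))
  if (!is.matrix(image) || any(image < 0) || any(image > 255))
    stop("'image' must be a matrix of intensities in [0, 255]", call. = FALSE)
  img <- pmin(pmax(round_half_up(config$alpha * image + config$beta), 0), 255)

  if (config$pointMode) {
    hits <- which(img >= config$thresholdValue & img > 0, arr.ind = TRUE)
    regions <- lapply(seq_len(nrow(hits)), function(i) {
      r <- hits[i, 1]; c <- hits[i, 2]
      make_region(matrix(c(c - 1, r - 1), ncol = 2), list(),
                  matrix(c(r - 1, c - 1), ncol = 2,
                         dimnames = list(NULL, c("row", "col"))))
    })
    return(sort_regions(Filter(function(r) nrow(r$positions) >
                                 config$epsilonSize, regions)))
  }

  if (config$morphCloseNrOfIter > 0) {
    for (i in seq_len(config$morphCloseNrOfIter)) img <- gray_dilate3(img)
    for (i in seq_len(config$morphCloseNrOfIter)) img <- gray_erode3(img)
  }
  img <- gaussian_blur(img, config$blurKernelSize, config$blurStandardDev)
  fg <- img > config$thresholdValue

  if (!any(fg)) return(list())
  comp <- label_components(fg, eight = TRUE)

  # background components (4-connected) not touching the border are holes
  bg <- !fg
  bgcomp <- label_components(bg, eight = FALSE)
  border_ids <- unique(c(bgcomp$labels[1, ], bgcomp$labels[nrow(bg), ],
                         bgcomp$labels[, 1], bgcomp$labels[, ncol(bg)]))
  border_ids <- border_ids[!is.na(border_ids)]
  hole_ids <- setdiff(seq_len(bgcomp$n), border_ids)

  # owner region of each hole: the label of any 4-neighbouring foreground px
  hole_owner <- integer(0)
  hole_masks <- list()
  for (h in hole_ids) {
    hm <- !is.na(bgcomp$labels) & bgcomp$labels == h
    hole_masks[[length(hole_masks) + 1L]] <- hm
    px <- which(hm, arr.ind = TRUE)[1, ]
    owner <- NA_integer_
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- px[1] + d[1]; cc <- px[2] + d[2]
      if (rr >= 1 && rr <= nrow(fg) && cc >= 1 && cc <= ncol(fg) &&
          !is.na(comp$labels[rr, cc])) {
        owner <- comp$labels[rr, cc]
        break
      }
    }
    hole_owner <- c(hole_owner, owner)
  }

  regions <- lapply(seq_len(comp$n), function(lab) {
    mask <- !is.na(comp$labels) & comp$labels == lab
    pos <- which(mask, arr.ind = TRUE)
    if (nrow(pos) <= config$epsilonSize) return(NULL)
    outer <- trace_contour(mask)
    holes <- lapply(which(hole_owner == lab), function(hi)
      trace_contour(hole_masks[[hi]]))
    if (config$approximationLevel > 0) {
      outer <- approx_polygon(outer, config$approximationLevel)
      holes <- lapply(holes, approx_polygon, eps = config$approximationLevel)
    }
    make_region(outer, holes,
                matrix(c(pos[, 1] - 1L, pos[, 2] - 1L), ncol = 2,
                       dimnames = list(NULL, c("row", "col"))))
  })
  sort_regions(Filter(Negate(is.null), regions))
}

sort_regions <- function(regions) {
  if (length(regions) <= 1L) return(regions)
  cy <- vapply(regions, function(r) r$centroid[2], numeric(1))
  cx <- vapply(regions, function(r) r$centroid[1], numeric(1))
  regions[order(cy, cx)]
}

#' Euclidean distance between entity centroids
#'
#' The pseudometric used by the cluster detector: the Euclidean distance
#' between the centroids of two spatial entities (regions or clusters).
#'
#' @param a,b `stmc_region` or `stmc_cluster` objects (anything carrying a
#'   `$centroid`), or bare numeric (x, y) vectors.
#' @return Non-negative distance.
#' @export
centroid_distance <- function(a, b) {
  ca <- if (is.numeric(a)) a else a$centroid
  cb <- if (is.numeric(b)) b else b$centroid
  if (is.null(ca) || is.null(cb))
    stop("both entities must have defined centroids", call. = FALSE)
  sqrt(sum((ca - cb)^2))
}

#' Cluster detection parameters
#'
#' @param epsilonDistance Neighbourhood radius of the DBSCAN variant:
#'   regions whose centroids lie within this distance are neighbours.
#' @param epsilonSize Strict minimum cluster cardinality; a region is a core
#'   region when its closed neighbourhood holds more than `epsilonSize`
#'   regions, and final clusters must contain more than `epsilonSize`
#'   members.
#' @return A `cluster_detection_config` object.
#' @export
cluster_detection_config <- function(epsilonDistance, epsilonSize = 0) {
  stopifnot(is.numeric(epsilonDistance), epsilonDistance >= 0,
            is.numeric(epsilonSize), epsilonSize >= 0)
  structure(list(epsilonDistance = epsilonDistance,
                 epsilonSize = epsilonSize),
            class = "cluster_detection_config")
}

make_cluster <- function(members) {
  pts <- do.call(rbind, lapply(members, function(r) r$outerContour))
  hull <- convex_hull(pts)
  centroid <- if (nrow(hull) >= 3 && polygon_area(hull) > 1e-12)
    polygon_centroid(hull)
  else colMeans(poly_matrix(pts))
  structure(list(members = members, hull = hull,
                 centroid = as.numeric(centroid)),
            class = "stmc_cluster")
}

#' @export
print.stmc_cluster <- function(x, ...) {
  cat(sprintf("cluster: %d member region(s), centroid (%.2f, %.2f)\n",
              length(x$members), x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Detect clusters of regions
#'
#' Density-based clustering (DBSCAN) of regions under the centroid-distance
#' pseudometric, with an order-independence fix: regions are first brought
#' into canonical (centroidY, centroidX) order, and border regions that are
#' density-reachable from several clusters are assigned to the cluster whose
#' nearest core region is closest, ties broken by the lowest cluster label.
#' The output is therefore invariant under any permutation of the input
#' list. Clusters with at most `epsilonSize` members are discarded.
#'
#' @param regions List of `stmc_region` objects.
#' @param config A [cluster_detection_config()].
#' @return List of `stmc_cluster` objects (each a non-overlapping subset of
#'   the input regions), sorted by (centroidY, centroidX).
#' @export
detect_clusters <- function(regions, config) {
  stopifnot(inherits(config, "cluster_detection_config"))
  n <- length(regions)
  if (n == 0L) return(list())
  regions <- sort_regions(regions)
  cents <- t(vapply(regions, function(r) r$centroid, numeric(2)))
  dmat <- as.matrix(stats::dist(cents))
  nbhd <- dmat <= config$epsilonDistance + 1e-12
  core <- rowSums(nbhd) > config$epsilonSize

  # clusters = connected components of the core-core reachability graph
  labels <- integer(n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    next_label <- next_label + 1L
    queue <- i
    labels[i] <- next_label
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      reach <- which(nbhd[cur, ] & core & labels == 0L)
      labels[reach] <- next_label
      queue <- c(queue, reach)
    }
  }

  # border regions: assigned to the cluster of the closest core region
  for (i in which(!core)) {
    cand <- which(nbhd[i, ] & core)
    if (!length(cand)) next
    dc <- dmat[i, cand]
    best <- cand[dc <= min(dc) + 1e-12]
    labels[i] <- min(labels[best])
  }

  clusters <- lapply(seq_len(next_label), function(lab)
    regions[labels == lab])
  clusters <- Filter(function(ms) length(ms) > config$epsilonSize, clusters)
  clusters <- lapply(clusters, make_cluster)
  if (length(clusters) > 1L) {
    cy <- vapply(clusters, function(cl) cl$centroid[2], numeric(1))
    cx <- vapply(clusters, function(cl) cl$centroid[1], numeric(1))
    clusters <- clusters[order(cy, cx)]
  }
  clusters
}
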