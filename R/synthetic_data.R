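#' @title Synthetic case-study generators
#'
#' @description Lightweight stochastic generators reproducing the
#' qualitative spatio-temporal phenomenology of the two benchmark systems:
#' sector patterning in a growing bacterial colony with stochastic
#' phenotype switching (regions with triangular wedges), and chemotactic
#' aggregation of cells toward a static 2-D Gaussian attractant on a
#' lattice (clusters of single-cell entities). The generators emulate only
#' what the checker consumes; they are not mechanistic reimplementations of
#' the originating Petri-net or Cellular Potts models.
#'
#' @name synthetic-data
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate sector patterning in a growing colony
#'
#' Radial colony growth on a square grid from a single wild-type founder at
#' the centre. At each timepoint every empty position adjacent (4-connected)
#' to the colony is colonised; the new cell takes the majority type of its
#' occupied neighbours (ties resolved at random) and, if that type is
#' wild-type, switches to the mutant phenotype with probability
#' `switchProbability` (the switch is one-directional, as in gene
#' expression switching that is rare in the reverse direction on colony
#' time scales). Switched lineages persist and form angular sectors whose
#' width grows with the colony radius.
#'
#' @param gridSize Grid dimensions (rows, cols); default 101 x 101.
#' @param nTimepoints Number of recorded timepoints (the first records the
#'   founder state; the colony radius grows by `growthRatePerStep` rings per
#'   subsequent timepoint).
#' @param switchProbability Per-colonisation phenotype switch probability.
#' @param growthRatePerStep Colonisation sweeps per timepoint.
#' @param seed RNG seed; the trace is bit-identical for a fixed seed.
#' @return A `colony_trace`: list of per-timepoint lists with `wildtype`
#'   and `mutant` count grids.
#' @export
generate_colony_trace <- function(gridSize = c(101, 101), nTimepoints = 40,
                                  switchProbability = 0.05,
                                  growthRatePerStep = 1, seed = 1L) {
  stopifnot(length(gridSize) == 2, all(gridSize >= 3), nTimepoints >= 1,
            switchProbability >= 0, switchProbability <= 1,
            growthRatePerStep >= 1)
  m <- gridSize[1]; n <- gridSize[2]
  with_seed(seed, {
    type <- matrix(0L, m, n)  # 0 empty, 1 wild-type, 2 mutant
    type[ceiling(m / 2), ceiling(n / 2)] <- 1L
    snap <- function() list(wildtype = (type == 1L) * 1,
                            mutant = (type == 2L) * 1)
    states <- vector("list", nTimepoints)
    states[[1]] <- snap()
    if (nTimepoints > 1) for (tp in 2:nTimepoints) {
      for (sweep in seq_len(growthRatePerStep)) {
        occ <- type > 0L
        nb_occ <- shift_fill(occ, 1, 0, FALSE) | shift_fill(occ, -1, 0, FALSE) |
          shift_fill(occ, 0, 1, FALSE) | shift_fill(occ, 0, -1, FALSE)
        frontier <- which(!occ & nb_occ, arr.ind = TRUE)
        if (!nrow(frontier)) break
        old_type <- type
        for (f in seq_len(nrow(frontier))) {
          r <- frontier[f, 1]; c <- frontier[f, 2]
          nbr <- c(if (r > 1) old_type[r - 1, c],
                   if (r < m) old_type[r + 1, c],
                   if (c > 1) old_type[r, c - 1],
                   if (c < n) old_type[r, c + 1])
          nbr <- nbr[nbr > 0L]
          counts <- tabulate(nbr, 2L)
          new_type <- if (counts[1] > counts[2]) 1L
                      else if (counts[2] > counts[1]) 2L
                      else sample(1:2, 1)
          if (new_type == 1L && stats::runif(1) < switchProbability)
            new_type <- 2L
          type[r, c] <- new_type
        }
      }
      states[[tp]] <- snap()
    }
    structure(states, class = "colony_trace",
              gridSize = gridSize, seed = seed)
  })
}

#' Simulate chemotactic aggregation on a lattice
#'
#' `nCells` cells start at distinct random lattice positions; a static
#' chemical attractant follows a 2-D Gaussian surface centred at
#' `(muX, muY)`. Each step, each cell performs a chemotactic move with
#' probability `attractionStrength`: among staying put and the four lattice
#' neighbours it picks uniformly among the near-maximal attractant values
#' (within a relative `tieTolerance` of the best). Far from the peak this
#' is strict uphill motion; on the near-flat plateau around the peak it
#' degenerates into local diffusion, so aggregated cells form a persistent
#' pile-up blob rather than a single-pixel stack. With probability
#' `1 - attractionStrength` the cell diffuses to a uniformly random
#' in-lattice neighbour instead. Cells may pile up; the total cell count is
#' conserved.
#'
#' @param latticeSize Lattice dimensions (rows, cols); default 100 x 100.
#' @param nCells Number of cells (default 100, i.e. 1% occupancy).
#' @param muX,muY,sigmaX,sigmaY Attractant Gaussian parameters in grid
#'   coordinates (x = column, y = row, 0-based); defaults centre the
#'   gradient on the lattice with standard deviation 10.
#' @param attractionStrength Probability in \[0, 1\] of following the
#'   gradient rather than diffusing.
#' @param tieTolerance Relative tolerance within which candidate attractant
#'   values count as tied during a chemotactic move; controls the width of
#'   the aggregation plateau around the peak.
#' @param nTimepoints Number of recorded timepoints.
#' @param stepsPerTimepoint Simulation steps between recordings; timepoint
#'   values are step counts (0, s, 2s, ...).
#' @param seed RNG seed; the trace is bit-identical for a fixed seed.
#' @return A `chemotaxis_trace`: list of per-timepoint lists with `cells`
#'   (cell-count grid) and `attractant` (static concentration grid), with
#'   attribute `times` holding the step values.
#' @export
generate_chemotaxis_trace <- function(latticeSize = c(100, 100),
                                      nCells = 100,
                                      muX = 50, muY = 50,
                                      sigmaX = 10, sigmaY = 10,
                                      attractionStrength = 1,
                                      tieTolerance = 0.03,
                                      nTimepoints = 41,
                                      stepsPerTimepoint = 5,
                                      seed = 1L) {
  stopifnot(length(latticeSize) == 2, all(latticeSize >= 2),
            nCells >= 1, nCells <= prod(latticeSize),
            sigmaX > 0, sigmaY > 0,
            attractionStrength >= 0, attractionStrength <= 1,
            tieTolerance >= 0, tieTolerance < 1,
            nTimepoints >= 1, stepsPerTimepoint >= 1)
  m <- latticeSize[1]; n <- latticeSize[2]
  xs <- matrix(rep(0:(n - 1), each = m), m, n)
  ys <- matrix(rep(0:(m - 1), n), m, n)
  attractant <- exp(-((xs - muX)^2 / (2 * sigmaX^2) +
                      (ys - muY)^2 / (2 * sigmaY^2)))
  with_seed(seed, {
    pos <- arrayInd(sample.int(m * n, nCells), c(m, n))
    count_grid <- function() {
      g <- matrix(0, m, n)
      for (i in seq_len(nrow(pos)))
        g[pos[i, 1], pos[i, 2]] <- g[pos[i, 1], pos[i, 2]] + 1
      g
    }
    states <- vector("list", nTimepoints)
    times <- integer(nTimepoints)
    states[[1]] <- list(cells = count_grid(), attractant = attractant)
    if (nTimepoints > 1) for (tp in 2:nTimepoints) {
      for (step in seq_len(stepsPerTimepoint)) {
        for (i in seq_len(nrow(pos))) {
          r <- pos[i, 1]; c <- pos[i, 2]
          moves <- rbind(c(r, c),
                         c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
          ok <- moves[, 1] >= 1 & moves[, 1] <= m &
            moves[, 2] >= 1 & moves[, 2] <= n
          if (stats::runif(1) < attractionStrength) {
            cand <- moves[ok, , drop = FALSE]
            av <- attractant[cbind(cand[, 1], cand[, 2])]
            near <- which(av >= max(av) * (1 - tieTolerance))
            pos[i, ] <- cand[near[sample.int(length(near), 1L)], ]
          } else {
            cand <- moves[-1, , drop = FALSE][ok[-1], , drop = FALSE]
            pos[i, ] <- cand[sample.int(nrow(cand), 1L), ]
          }
        }
      }
      states[[tp]] <- list(cells = count_grid(), attractant = attractant)
      times[tp] <- times[tp - 1] + stepsPerTimepoint
    }
    structure(states, class = "chemotaxis_trace",
              times = as.integer(times),
              latticeSize = latticeSize, seed = seed)
  })
}

#' Rasterise an analytic shape onto a binary grid
#'
#' Pixel membership is decided by the exact analytic inequality at pixel
#' centres (0-based x = column, y = row), providing ground-truth fixtures
#' for the geometry oracles.
#'
#' @param shape "square", "disc" or "triangle".
#' @param size Square: side length (pixels). Disc: radius. Triangle: base
#'   and height `c(b, h)` of an isosceles triangle (apex up).
#' @param gridSize Grid dimensions (rows, cols).
#' @param center Shape centre (x, y); defaults to the grid centre.
#' @return Binary (0/1) state grid.
#' @export
rasterize_shape <- function(shape = c("square", "disc", "triangle"),
                            size, gridSize = c(101, 101), center = NULL) {
  shape <- match.arg(shape)
  m <- gridSize[1]; n <- gridSize[2]
  if (is.null(center)) center <- c((n - 1) / 2, (m - 1) / 2)
  xs <- matrix(rep(0:(n - 1), each = m), m, n)
  ys <- matrix(rep(0:(m - 1), n), m, n)
  g <- switch(shape,
    square = {
      s <- size[1]
      if (s < 1 || s > min(m, n))
        stop("square side exceeds the grid", call. = FALSE)
      x0 <- floor(center[1] - (s - 1) / 2)
      y0 <- floor(center[2] - (s - 1) / 2)
      if (x0 < 0 || y0 < 0 || x0 + s > n || y0 + s > m)
        stop("square does not fit in the grid", call. = FALSE)
      (xs >= x0 & xs <= x0 + s - 1 & ys >= y0 & ys <= y0 + s - 1) * 1
    },
    disc = {
      r <- size[1]
      if (center[1] - r < 0 || center[1] + r > n - 1 ||
          center[2] - r < 0 || center[2] + r > m - 1)
        stop("disc does not fit in the grid", call. = FALSE)
      ((xs - center[1])^2 + (ys - center[2])^2 <= r^2) * 1
    },
    triangle = {
      b <- size[1]; h <- if (length(size) > 1) size[2] else size[1]
      apex <- c(center[1], center[2] - h / 2)
      base_y <- center[2] + h / 2
      if (apex[2] < 0 || base_y > m - 1 ||
          center[1] - b / 2 < 0 || center[1] + b / 2 > n - 1)
        stop("triangle does not fit in the grid", call. = FALSE)
      # inside iff below both slanted edges and above the base
      frac <- (ys - apex[2]) / h
      (ys >= apex[2] & ys <= base_y &
         abs(xs - apex[1]) <= frac * b / 2) * 1
    })
  g
}

#' Translate a synthetic trace to an STML experiment
#'
#' Runs the detection and measurement pipeline per timepoint and assembles
#' the STML data model. For colony traces (`mode = "regions"`) the analysed
#' grid is the mutant fraction `mutant / (wildtype + mutant)` (0 at empty
#' positions) and the detected regions are emitted. For `mode = "clusters"`
#' regions are additionally grouped with [detect_clusters()] and the
#' clusters are emitted. For chemotaxis traces (`mode = "pointClusters"`)
#' the cell-count grid is analysed with the point detector, clusters of
#' cells are emitted, and the Silhouette index is recorded as the
#' `avgClusterednessClusters` numeric state variable whenever it is defined
#' (at least two clusters, not all singletons).
#'
#' @param trace A `colony_trace` or `chemotaxis_trace`.
#' @param regionConfig A [region_detection_config()]; a mode-appropriate
#'   default is used when `NULL`.
#' @param clusterConfig A [cluster_detection_config()] (cluster modes).
#' @param mode "regions", "clusters" or "pointClusters".
#' @return A validated [experiment()].
#' @export
trace_to_stml <- function(trace, regionConfig = NULL, clusterConfig = NULL,
                          mode = c("regions", "clusters", "pointClusters")) {
  mode <- match.arg(mode)
  is_colony <- inherits(trace, "colony_trace")
  is_chemo <- inherits(trace, "chemotaxis_trace")
  if (!is_colony && !is_chemo)
    stop("'trace' must be a colony_trace or chemotaxis_trace", call. = FALSE)
  if (is.null(regionConfig))
    regionConfig <- if (mode == "pointClusters")
      region_detection_config(thresholdValue = 127, pointMode = TRUE)
    else region_detection_config(thresholdValue = 127, morphCloseNrOfIter = 1,
                                 epsilonSize = 4)
  if (mode %in% c("clusters", "pointClusters") && is.null(clusterConfig))
    clusterConfig <- cluster_detection_config(epsilonDistance = 5,
                                              epsilonSize = 4)
  times <- if (is_chemo) attr(trace, "times") else seq_along(trace) - 1L

  timepoints <- lapply(seq_along(trace), function(i) {
    state <- trace[[i]]
    grid <- if (is_colony) {
      tot <- state$wildtype + state$mutant
      frac <- state$mutant / ifelse(tot > 0, tot, 1)
      frac
    } else state$cells
    geom <- space_geometry(nrow(grid), ncol(grid))
    img <- grid_to_grayscale(grid, normalizationMax = 1)
    regions <- detect_regions(img, regionConfig)
    entities <- list()
    vars <- list()
    if (mode == "regions") {
      entities <- lapply(regions, function(r) {
        ms <- region_measures(r, grid, geom)
        measures_to_record("region", ms)
      })
    } else {
      clusters <- detect_clusters(regions, clusterConfig)
      entities <- lapply(clusters, function(cl) {
        ms <- cluster_measures(cl, grid, geom)
        measures_to_record("cluster", ms)
      })
      sil <- silhouette_index(clusters)
      if (!is.na(sil))
        vars <- c(vars, list(numeric_state_variable(
          "avgClusterednessClusters", sil)))
    }
    if (is_colony) {
      vars <- c(vars,
                list(numeric_state_variable("wildtypeTotal",
                                            sum(state$wildtype)),
                     numeric_state_variable("mutantTotal",
                                            sum(state$mutant))))
    } else {
      vars <- c(vars, list(numeric_state_variable("cellTotal",
                                                  sum(state$cells))))
    }
    timepoint(value = times[i], spatialEntities = entities,
              numericStateVariables = vars)
  })
  experiment(timepoints)
}

measures_to_record <- function(entityType, ms) {
  spatial_entity_record(
    entityType = entityType,
    clusteredness = ms$clusteredness, density = ms$density,
    area = ms$area, perimeter = ms$perimeter,
    distanceFromOrigin = ms$distanceFromOrigin,
    angle = ms$angle,
    triangularMeasure = ms$triangularMeasure,
    rectangularMeasure = ms$rectangularMeasure,
    circularMeasure = ms$circularMeasure,
    centroidX = max(0, ms$centroidX), centroidY = max(0, ms$centroidY),
    shape = ms$shape)
}

#' Generate an STML dataset for one synthetic case study
#'
#' Convenience wrapper used by the command-line tool and the worked
#' examples: simulates `n` traces of the chosen case study and writes one
#' STML file per trace (`trace_001.xml`, ...) into `dir`.
#'
#' @param case "colony" or "chemotaxis".
#' @param n Number of traces.
#' @param dir Output directory (created if missing).
#' @param seed Master seed; trace `i` uses `seed + i - 1`.
#' @param ... Passed to the respective generator.
#' @return Character vector of written file paths, invisibly.
#' @export
generate_stml_dataset <- function(case = c("colony", "chemotaxis"), n, dir,
                                  seed = 1L, ...) {
  case <- match.arg(case)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n)
  for (i in seq_len(n)) {
    tr <- if (case == "colony")
      generate_colony_trace(seed = seed + i - 1L, ...)
    else generate_chemotaxis_trace(seed = seed + i - 1L, ...)
    exp <- trace_to_stml(tr, mode = if (case == "colony") "regions"
                                    else "pointClusters")
    paths[i] <- file.path(dir, sprintf("trace_%03d.xml", i))
    write_stml(exp, paths[i])
  }
  invisible(paths)
}
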