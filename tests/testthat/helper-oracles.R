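# Independent oracles used across the test files. Everything here is
# written directly from first principles (shoelace sums, exhaustive
# enumeration, naive recursion) and shares no code with the package
# internals it checks.

# signed shoelace area and edge-walk perimeter of a closed polygon
oracle_shoelace_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

oracle_edge_walk_perimeter <- function(p) {
  n <- nrow(p)
  if (n < 2) return(0)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + sqrt(sum((p[j, ] - p[i, ])^2))
  }
  s
}

# flood-fill pixel count of the 8-connected component containing (r0, c0)
oracle_flood_fill_count <- function(mask, r0, c0) {
  m <- nrow(mask); n <- ncol(mask)
  seen <- matrix(FALSE, m, n)
  stack <- list(c(r0, c0))
  count <- 0L
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- p[1]; c <- p[2]
    if (r < 1 || r > m || c < 1 || c > n || seen[r, c] || !mask[r, c]) next
    seen[r, c] <- TRUE
    count <- count + 1L
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) stack[[length(stack) + 1L]] <- c(r + dr, c + dc)
  }
  count
}

# number of 8-connected components of a mask, by repeated flood fill
oracle_component_count <- function(mask) {
  mask <- mask
  k <- 0L
  while (any(mask)) {
    p <- which(mask, arr.ind = TRUE)[1, ]
    m <- nrow(mask); n <- ncol(mask)
    seen <- matrix(FALSE, m, n)
    stack <- list(c(p[1], p[2]))
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      r <- q[1]; c <- q[2]
      if (r < 1 || r > m || c < 1 || c > n || seen[r, c] || !mask[r, c]) next
      seen[r, c] <- TRUE
      for (dr in -1:1) for (dc in -1:1)
        if (dr != 0 || dc != 0) stack[[length(stack) + 1L]] <- c(r + dr, c + dc)
    }
    mask[seen] <- FALSE
    k <- k + 1L
  }
  k
}

# exhaustive minimum enclosing circle: best circle through every pair
# (diameter) and every triple (circumcircle) that contains all points
oracle_min_circle_radius <- function(pts) {
  n <- nrow(pts)
  contains_all <- function(cx, cy, r) {
    all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) <= r + 1e-9)
  }
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    cx <- (pts[i, 1] + pts[j, 1]) / 2; cy <- (pts[i, 2] + pts[j, 2]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best && contains_all(cx, cy, r)) best <- r
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1))
    for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
             sum(cc^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
             sum(cc^2) * (b[1] - a[1])) / d
      r <- sqrt(sum((a - c(ux, uy))^2))
      if (r < best && contains_all(ux, uy, r)) best <- r
    }
  best
}

# independent rotating-calipers rectangle: rotate the point cloud through
# each edge direction of its hull and take the best axis-aligned bounding
# box area
oracle_min_rect_area <- function(pts) {
  hull_idx <- grDevices::chull(pts)
  h <- pts[hull_idx, , drop = FALSE]
  n <- nrow(h)
  if (n < 3) return(0)
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ang <- atan2(h[j, 2] - h[i, 2], h[j, 1] - h[i, 1])
    # rotate by -ang so the edge becomes axis-aligned
    q <- cbind(pts[, 1] * cos(ang) + pts[, 2] * sin(ang),
               -pts[, 1] * sin(ang) + pts[, 2] * cos(ang))
    area <- (max(q[, 1]) - min(q[, 1])) * (max(q[, 2]) - min(q[, 2]))
    if (area < best) best <- area
  }
  best
}

# numerical minimum-area enclosing triangle: optimisation over the three
# support-line directions with many deterministic restarts (independent of
# the package's flush-edge search)
oracle_min_triangle_area <- function(pts) {
  hull_idx <- grDevices::chull(pts)
  h <- pts[hull_idx, , drop = FALSE]
  supp <- function(t) max(h[, 1] * cos(t) + h[, 2] * sin(t))
  area3 <- function(v) {
    th <- sort(v %% (2 * pi))
    gaps <- c(diff(th), 2 * pi - (th[3] - th[1]))
    if (any(gaps <= 1e-8) || any(gaps >= pi - 1e-8)) return(Inf)
    hs <- vapply(th, supp, numeric(1))
    pt <- function(i, j) {
      d <- sin(th[j] - th[i])
      c((hs[i] * sin(th[j]) - hs[j] * sin(th[i])) / d,
        (hs[j] * cos(th[i]) - hs[i] * cos(th[j])) / d)
    }
    a <- pt(1, 2); b <- pt(2, 3); cc <- pt(3, 1)
    abs((a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
         cc[1] * (a[2] - b[2])) / 2)
  }
  best <- Inf
  starts <- seq(0, 2 * pi, length.out = 13)[-13]
  for (s1 in starts) {
    v0 <- c(s1, s1 + 2 * pi / 3, s1 + 4 * pi / 3)
    o <- stats::optim(v0, area3, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# brute-force mean Silhouette width over labelled points (singleton
# clusters contribute 0)
oracle_silhouette <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ---- naive reference evaluator for BLSTL ----------------------------------
# Direct recursive transcription of the bounded semantics, enumerating all
# states; used as the principal oracle for the inference engine. States are
# lists with $time, $regions, $clusters (lists of measure lists), $vars
# (named numeric vector).

ref_evaluate <- function(node, states, i) {
  times <- vapply(states, function(s) s$time, numeric(1))
  n <- length(states)
  too_short <- function() stop(structure(
    class = c("stmc_trace_too_short", "error", "condition"),
    list(message = "reference: trace too short", call = NULL)))
  undef <- function() stop(structure(
    class = c("ref_undefined", "error", "condition"),
    list(message = "undefined", call = NULL)))

  num <- function(nd, j) {
    switch(nd$kind,
      num = nd$value,
      var = {
        if (!nd$name %in% names(states[[j]]$vars)) undef()
        unname(states[[j]]$vars[[nd$name]])
      },
      diff = {
        if (j + 1 > n) too_short()
        num(nd$child, j + 1) - num(nd$child, j)
      },
      unary = {
        x <- num(nd$child, j)
        switch(nd$fn, abs = abs(x), ceil = ceiling(x), floor = floor(x),
               round = floor(x + 0.5), sign = sign(x), sqrt = sqrt(x),
               trunc = trunc(x), negate = -x)
      },
      binary = {
        x <- num(nd$left, j); y <- num(nd$right, j)
        switch(nd$fn, add = x + y, subtract = x - y, multiply = x * y,
               divide = x / y, power = x^y, min = min(x, y), max = max(x, y))
      },
      stat = {
        coll <- collect(nd$collection, j)
        if (nd$fn == "count") return(length(coll))
        if (!length(coll)) undef()
        vals <- vapply(coll, function(e) e[[nd$measure]], numeric(1))
        switch(nd$fn,
          mean = sum(vals) / length(vals),
          median = stats::median(vals),
          min = min(vals), max = max(vals), sum = sum(vals),
          stdev = if (length(vals) < 2) 0 else stats::sd(vals),
          mode = {
            uv <- sort(unique(vals))
            counts <- vapply(uv, function(v) sum(vals == v), numeric(1))
            uv[which.max(counts)]
          },
          percentile = {
            sorted <- sort(vals)
            sorted[max(1, ceiling(nd$q / 100 * length(sorted)))]
          },
          covariance = {
            coll2 <- collect(nd$collection2, j)
            if (!length(coll2)) undef()
            v2 <- vapply(coll2, function(e) e[[nd$measure2]], numeric(1))
            k <- min(length(vals), length(v2))
            if (k < 2) undef()
            stats::cov(vals[1:k], v2[1:k])
          })
      })
  }

  collect <- function(coll, j) {
    es <- states[[j]][[coll$which]]
    if (is.null(coll$filter)) return(es)
    Filter(function(e) cst(coll$filter, e), es)
  }

  cst <- function(nd, e) {
    switch(nd$kind,
      mcmp = {
        v <- e[[nd$measure]]
        if (is.null(v)) return(FALSE)
        r <- cval(nd$rhs)
        out <- switch(nd$op, "<" = v < r, "<=" = v <= r,
                      "=" = abs(v - r) <= 1e-9, ">=" = v >= r, ">" = v > r)
        isTRUE(out)
      },
      not = !cst(nd$child, e),
      and = cst(nd$left, e) && cst(nd$right, e),
      or = cst(nd$left, e) || cst(nd$right, e),
      implies = !cst(nd$left, e) || cst(nd$right, e),
      iff = cst(nd$left, e) == cst(nd$right, e))
  }

  cval <- function(nd) {
    switch(nd$kind,
      num = nd$value,
      unary = {
        x <- cval(nd$child)
        switch(nd$fn, abs = abs(x), ceil = ceiling(x), floor = floor(x),
               round = floor(x + 0.5), sign = sign(x), sqrt = sqrt(x),
               trunc = trunc(x), negate = -x)
      },
      binary = {
        x <- cval(nd$left); y <- cval(nd$right)
        switch(nd$fn, add = x + y, subtract = x - y, multiply = x * y,
               divide = x / y, power = x^y, min = min(x, y), max = max(x, y))
      })
  }

  cmp <- function(nd, j) {
    out <- tryCatch({
      l <- num(nd$lhs, j); r <- num(nd$rhs, j)
      v <- switch(nd$op, "<" = l < r, "<=" = l <= r,
                  "=" = abs(l - r) <= 1e-9, ">=" = l >= r, ">" = l > r)
      if (is.na(v)) FALSE else v
    }, ref_undefined = function(e) FALSE)
    out
  }

  go <- function(nd, j) {
    switch(nd$kind,
      cmp = cmp(nd, j),
      not = !go(nd$child, j),
      and = go(nd$left, j) && go(nd$right, j),
      or = go(nd$left, j) || go(nd$right, j),
      implies = !go(nd$left, j) || go(nd$right, j),
      iff = go(nd$left, j) == go(nd$right, j),
      F = {
        if (times[n] - times[j] < nd$b) too_short()
        found <- FALSE
        for (k in j:n)
          if (times[k] - times[j] >= nd$a && times[k] - times[j] <= nd$b &&
              go(nd$child, k)) found <- TRUE
        found
      },
      G = {
        if (times[n] - times[j] < nd$b) too_short()
        holds <- TRUE
        for (k in j:n)
          if (times[k] - times[j] >= nd$a && times[k] - times[j] <= nd$b &&
              !go(nd$child, k)) holds <- FALSE
        holds
      },
      until = {
        if (times[n] - times[j] < nd$b) too_short()
        out <- FALSE
        for (k in j:n) {
          if (times[k] - times[j] < nd$a || times[k] - times[j] > nd$b) next
          if (!go(nd$right, k)) next
          pre_ok <- TRUE
          if (k > j) for (q in j:(k - 1)) if (!go(nd$left, q)) pre_ok <- FALSE
          if (pre_ok) { out <- TRUE; break }
        }
        out
      },
      X = {
        if (j + nd$k > n) too_short()
        go(nd$child, j + nd$k)
      })
  }
  go(node, i)
}

# ---- random instance generators -------------------------------------------

random_entity <- function() {
  ms <- list(entityType = "region",
             clusteredness = runif(1), density = runif(1, 0, 5),
             area = runif(1, 0, 50), perimeter = runif(1, 0, 30),
             distanceFromOrigin = runif(1, 0, 20), angle = runif(1, 0, 360),
             triangularMeasure = runif(1), rectangularMeasure = runif(1),
             circularMeasure = runif(1),
             centroidX = runif(1, 0, 40), centroidY = runif(1, 0, 40))
  ms
}

random_state <- function(t) {
  nr <- sample(0:3, 1)
  nc <- sample(0:2, 1)
  regions <- replicate(nr, random_entity(), simplify = FALSE)
  clusters <- replicate(nc, {
    e <- random_entity(); e$entityType <- "cluster"; e
  }, simplify = FALSE)
  vars <- c(A = round(runif(1, 0, 10), 2), B = round(runif(1, -5, 5), 2))
  if (runif(1) < 0.2) vars <- vars["A"]  # sometimes B is missing
  list(time = t, regions = regions, clusters = clusters, vars = vars)
}

random_trace_states <- function(len = sample(4:10, 1)) {
  lapply(seq_len(len) - 1L, random_state)
}

states_to_trace <- function(states) {
  structure(list(states = states,
                 times = vapply(states, function(s) s$time, numeric(1))),
            class = "blstl_trace")
}

random_numeric_node <- function(depth) {
  choice <- sample(c("num", "var", "stat", "unary", "binary", "diff"), 1,
                   prob = c(0.25, 0.2, 0.25, 0.1, 0.1, 0.1))
  if (depth <= 0) choice <- sample(c("num", "var"), 1)
  switch(choice,
    num = list(kind = "num", value = round(runif(1, -5, 15), 2)),
    var = list(kind = "var", name = sample(c("A", "B"), 1)),
    diff = list(kind = "diff", child = random_numeric_node(depth - 1)),
    unary = list(kind = "unary", fn = sample(c("abs", "floor", "round"), 1),
                 child = random_numeric_node(depth - 1)),
    binary = list(kind = "binary",
                  fn = sample(c("add", "subtract", "multiply", "min", "max"),
                              1),
                  left = random_numeric_node(depth - 1),
                  right = random_numeric_node(depth - 1)),
    stat = {
      fn <- sample(c("count", "mean", "min", "max", "sum", "median",
                     "stdev", "percentile"), 1)
      coll <- list(kind = "coll", which = sample(c("regions", "clusters"), 1),
                   filter = if (runif(1) < 0.3)
                     list(kind = "mcmp", op = sample(c("<", ">", ">="), 1),
                          measure = sample(c("area", "density",
                                             "clusteredness"), 1),
                          rhs = list(kind = "num",
                                     value = round(runif(1, 0, 30), 1)))
                   else NULL)
      nd <- list(kind = "stat", fn = fn, collection = coll)
      if (fn != "count")
        nd$measure <- sample(c("area", "density", "perimeter",
                               "clusteredness"), 1)
      if (fn == "percentile") nd$q <- sample(c(0, 25, 50, 75, 100), 1)
      nd
    })
}

random_formula_node <- function(depth, horizon) {
  choice <- sample(c("cmp", "not", "and", "or", "implies", "F", "G",
                     "until", "X"), 1,
                   prob = c(0.3, 0.1, 0.1, 0.08, 0.07, 0.12, 0.12,
                            0.06, 0.05))
  if (depth <= 0) choice <- "cmp"
  mk_bounds <- function() {
    a <- sample(0:min(2, horizon), 1)
    b <- a + sample(0:max(0, min(3, horizon - a)), 1)
    c(a, b)
  }
  switch(choice,
    cmp = list(kind = "cmp", op = sample(c("<", "<=", "=", ">=", ">"), 1),
               lhs = random_numeric_node(depth),
               rhs = random_numeric_node(depth)),
    not = list(kind = "not", child = random_formula_node(depth - 1, horizon)),
    and = list(kind = "and", left = random_formula_node(depth - 1, horizon),
               right = random_formula_node(depth - 1, horizon)),
    or = list(kind = "or", left = random_formula_node(depth - 1, horizon),
              right = random_formula_node(depth - 1, horizon)),
    implies = list(kind = "implies",
                   left = random_formula_node(depth - 1, horizon),
                   right = random_formula_node(depth - 1, horizon)),
    F = { b <- mk_bounds()
      list(kind = "F", a = b[1], b = b[2],
           child = random_formula_node(depth - 1, horizon - b[2])) },
    G = { b <- mk_bounds()
      list(kind = "G", a = b[1], b = b[2],
           child = random_formula_node(depth - 1, horizon - b[2])) },
    until = { b <- mk_bounds()
      list(kind = "until", a = b[1], b = b[2],
           left = random_formula_node(depth - 1, horizon - b[2]),
           right = random_formula_node(depth - 1, horizon - b[2])) },
    X = { k <- sample(1:min(2, max(1, horizon)), 1)
      list(kind = "X", k = k,
           child = random_formula_node(depth - 1, horizon - k)) })
}

# evaluate both engines, mapping errors to comparable sentinels
both_results <- function(formula, trace_states, index = 1L) {
  tr <- states_to_trace(trace_states)
  pkg <- tryCatch(evaluate_blstl(formula, tr, index),
                  stmc_trace_too_short = function(e) "too_short")
  ref <- tryCatch(ref_evaluate(formula, trace_states, index),
                  stmc_trace_too_short = function(e) "too_short")
  list(pkg = pkg, ref = ref)
}

# synthetic region factory for cluster tests
synthetic_point_region <- function(x, y) {
  stmc:::make_region(matrix(c(x, y), ncol = 2), list(),
              matrix(c(round(y), round(x)), ncol = 2,
                     dimnames = list(NULL, c("row", "col"))))
}

cluster_signature <- function(clusters) {
  paste(sort(vapply(clusters, function(cl) {
    paste(sort(vapply(cl$members, function(r)
      paste(sprintf("%.6f", r$centroid), collapse = ","), character(1))),
      collapse = ";")
  }, character(1))), collapse = "|")
}
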