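#' @title STML data model
#'
#' @description Constructors and validators for the in-memory representation
#' of Spatial Temporal Markup Language (STML) experiments: time-ordered
#' records of detected spatial entities (regions and clusters, each carrying
#' eleven spatial measures) together with scalar numeric state variables.
#'
#' @name stml-model
NULL

#' Names of the eleven spatial measures
#'
#' The measure set characterising every detected region or cluster:
#' clusteredness, density, area, perimeter, distance from the origin, angle
#' (degrees), the three fuzzy shape measures and the centroid coordinates.
#'
#' @return Character vector of measure names.
#' @export
spatial_measure_names <- function() {
  c("clusteredness", "density", "area", "perimeter", "distanceFromOrigin",
    "angle", "triangularMeasure", "rectangularMeasure", "circularMeasure",
    "centroidX", "centroidY")
}

#' Create a spatial entity record
#'
#' A spatial entity record is the STML serialisation unit for one detected
#' region or cluster at one timepoint, carrying the eleven spatial measures
#' plus an optional fuzzy shape label.
#'
#' @param entityType "region" or "cluster".
#' @param clusteredness,density,area,perimeter,distanceFromOrigin Non-negative
#'   reals.
#' @param angle Real in \[0, 360\] (degrees subtended at the space origin).
#' @param triangularMeasure,rectangularMeasure,circularMeasure Reals in
#'   \[0, 1\]; similarity of the entity outline to its minimum enclosing
#'   triangle, rectangle and circle.
#' @param centroidX,centroidY Non-negative reals (grid coordinates).
#' @param shape Optional; one of "triangular", "rectangular", "circular" or
#'   `NA`.
#' @return An object of class `stml_spatial_entity`.
#' @export
spatial_entity_record <- function(entityType, clusteredness, density, area,
                                  perimeter, distanceFromOrigin, angle,
                                  triangularMeasure, rectangularMeasure,
                                  circularMeasure, centroidX, centroidY,
                                  shape = NA_character_) {
  rec <- structure(
    list(entityType = as.character(entityType),
         clusteredness = as.numeric(clusteredness),
         density = as.numeric(density),
         area = as.numeric(area),
         perimeter = as.numeric(perimeter),
         distanceFromOrigin = as.numeric(distanceFromOrigin),
         angle = as.numeric(angle),
         triangularMeasure = as.numeric(triangularMeasure),
         rectangularMeasure = as.numeric(rectangularMeasure),
         circularMeasure = as.numeric(circularMeasure),
         centroidX = as.numeric(centroidX),
         centroidY = as.numeric(centroidY),
         shape = if (is.na(shape)) NA_character_ else as.character(shape)),
    class = "stml_spatial_entity")
  validate_spatial_entity(rec)
  rec
}

#' Create a numeric state variable record
#'
#' @param name Non-empty variable name.
#' @param value Real value.
#' @return An object of class `stml_numeric_variable`.
#' @export
numeric_state_variable <- function(name, value) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("numericStateVariable: 'name' must be a non-empty string",
         call. = FALSE)
  structure(list(name = name, value = as.numeric(value)),
            class = "stml_numeric_variable")
}

#' Create a timepoint
#'
#' @param value Non-negative integer time index, or `NA` when the value is to
#'   be resolved later by [resolve_timepoint_values()].
#' @param spatialEntities List of [spatial_entity_record()] objects.
#' @param numericStateVariables List of [numeric_state_variable()] objects
#'   with unique names.
#' @return An object of class `stml_timepoint`.
#' @export
timepoint <- function(value = NA, spatialEntities = list(),
                      numericStateVariables = list()) {
  tp <- structure(
    list(value = if (is.na(value)) NA_integer_ else as.integer(value),
         spatialEntities = spatialEntities,
         numericStateVariables = numericStateVariables),
    class = "stml_timepoint")
  validate_timepoint(tp)
  tp
}

#' Create an experiment
#'
#' An experiment is the root of the STML data model: a sequence of at least
#' one timepoint.
#'
#' @param timepoints Non-empty list of [timepoint()] objects.
#' @return An object of class `stml_experiment`.
#' @export
experiment <- function(timepoints) {
  exp <- structure(list(timepoints = timepoints), class = "stml_experiment")
  validate_experiment(exp)
  exp
}

stml_validation_error <- function(element, constraint) {
  stop(structure(
    class = c("stml_validation_error", "error", "condition"),
    list(message = sprintf("STML validation error in <%s>: %s",
                           element, constraint),
         call = NULL)))
}

check_range <- function(x, field, lo = 0, hi = Inf, element = "pseudo3D") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stml_validation_error(
      element,
      sprintf("'%s' = %s violates the [%s, %s] range constraint",
              field, format(x), format(lo),
              if (is.finite(hi)) format(hi) else "Inf"))
  invisible(TRUE)
}

#' Validate a spatial entity record
#'
#' Checks every range constraint of the STML `pseudo3D` element: non-negative
#' measures, `angle` in \[0, 360\], shape measures in \[0, 1\] and a valid
#' entity type / shape label.
#'
#' @param rec A `stml_spatial_entity`.
#' @return `TRUE` invisibly; signals a `stml_validation_error` otherwise.
#' @export
validate_spatial_entity <- function(rec) {
  if (!rec$entityType %in% c("region", "cluster"))
    stml_validation_error("pseudo3D",
                          "'type' must be either 'region' or 'cluster'")
  for (f in c("clusteredness", "density", "area", "perimeter",
              "distanceFromOrigin", "centroidX", "centroidY"))
    check_range(rec[[f]], f)
  check_range(rec$angle, "angle", 0, 360)
  for (f in c("triangularMeasure", "rectangularMeasure", "circularMeasure"))
    check_range(rec[[f]], f, 0, 1)
  if (!is.na(rec$shape) &&
      !rec$shape %in% c("triangular", "rectangular", "circular"))
    stml_validation_error(
      "shape", "must be 'triangular', 'rectangular' or 'circular'")
  invisible(TRUE)
}

#' Validate a timepoint
#'
#' @param tp A `stml_timepoint`.
#' @return `TRUE` invisibly; signals a `stml_validation_error` otherwise.
#' @export
validate_timepoint <- function(tp) {
  if (!is.na(tp$value) && tp$value < 0L)
    stml_validation_error("timepoint", "'value' must be a non-negative integer")
  for (se in tp$spatialEntities) validate_spatial_entity(se)
  nm <- vapply(tp$numericStateVariables, function(v) v$name, character(1))
  if (anyDuplicated(nm))
    stml_validation_error(
      "numericStateVariable",
      sprintf("duplicate variable name '%s' within a timepoint",
              nm[duplicated(nm)][1L]))
  invisible(TRUE)
}

#' Validate an experiment
#'
#' @param exp A `stml_experiment`.
#' @return `TRUE` invisibly; signals a `stml_validation_error` otherwise.
#' @export
validate_experiment <- function(exp) {
  if (length(exp$timepoints) < 1L)
    stml_validation_error("experiment", "must contain at least one timepoint")
  for (tp in exp$timepoints) validate_timepoint(tp)
  vals <- vapply(exp$timepoints, function(tp) tp$value, integer(1))
  known <- vals[!is.na(vals)]
  if (length(known) > 1L) {
    idx <- which(!is.na(vals))
    if (any(diff(known) <= 0L) && all(!is.na(vals)))
      stml_validation_error("experiment",
                            "timepoint values must be strictly increasing")
  }
  invisible(TRUE)
}

#' Resolve missing timepoint values
#'
#' Timepoints missing an explicit value receive one automatically: the first
#' timepoint defaults to 0 and every later unset timepoint takes the previous
#' resolved value plus one. Predefined values are kept as given.
#'
#' @param exp A `stml_experiment`, possibly with unset timepoint values.
#' @return The experiment with all timepoint values resolved. The operation is
#'   idempotent.
#' @export
resolve_timepoint_values <- function(exp) {
  stopifnot(inherits(exp, "stml_experiment"))
  vals <- vapply(exp$timepoints, function(tp)
    if (is.null(tp$value) || is.na(tp$value)) NA_integer_ else tp$value,
    integer(1))
  out <- integer(length(vals))
  for (i in seq_along(vals)) {
    out[i] <- if (!is.na(vals[i])) vals[i]
              else if (i == 1L) 0L
              else out[i - 1L] + 1L
  }
  if (length(out) > 1L && any(diff(out) <= 0L))
    stml_validation_error(
      "experiment",
      sprintf("resolved timepoint values are not strictly increasing (%s)",
              paste(out, collapse = ", ")))
  for (i in seq_along(out)) exp$timepoints[[i]]$value <- out[i]
  exp
}

#' @export
print.stml_experiment <- function(x, ...) {
  n <- length(x$timepoints)
  vals <- vapply(x$timepoints, function(tp) tp$value, integer(1))
  ne <- sum(vapply(x$timepoints, function(tp) length(tp$spatialEntities),
                   integer(1)))
  cat(sprintf("STML experiment: %d timepoint(s), %d spatial entit%s\n",
              n, ne, if (ne == 1) "y" else "ies"))
  if (!anyNA(vals))
    cat(sprintf("  time values: %s%s\n",
                paste(utils::head(vals, 8), collapse = ", "),
                if (n > 8) ", ..." else ""))
  invisible(x)
}
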