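#' @title STML reading and writing
#' @description Serialisation of [experiment()] objects to the STML XML
#'   dialect defined by the schema shipped in
#'   `system.file("extdata", "STML_L1V1.xsd", package = "stmc")`, and the
#'   corresponding validating reader.
#' @name stml-io
NULL

stml_schema_version <- "L1V1"

stml_schema_path <- function() {
  system.file("extdata", paste0("STML_", stml_schema_version, ".xsd"),
              package = "stmc", mustWork = TRUE)
}

# Full-precision decimal serialisation: no scientific notation (the schema
# uses xs:decimal), locale-independent, round-trips doubles exactly.
format_stml_number <- function(x) {
  if (is.na(x)) stop("cannot serialise NA numeric value", call. = FALSE)
  s <- format(x, scientific = FALSE, trim = TRUE, digits = 17)
  # format() may keep scientific notation for extreme magnitudes; expand.
  if (grepl("[eE]", s)) s <- format(x, scientific = FALSE, trim = TRUE,
                                    nsmall = 17)
  s
}

#' Write an experiment to an STML file
#'
#' Emits XML conforming to the shipped STML schema with deterministic element
#' ordering: timepoints in sequence, spatial entities before numeric state
#' variables, and the eleven measures of each `pseudo3D` element in fixed
#' order. Numbers are serialised in full decimal notation so that a
#' write/read round trip is the identity.
#'
#' @param exp A valid [experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stml <- function(exp, path) {
  validate_experiment(exp)
  doc <- xml2::xml_new_root("experiment", version = stml_schema_version)
  for (tp in exp$timepoints) {
    tp_node <- xml2::xml_add_child(doc, "timepoint")
    if (!is.na(tp$value))
      xml2::xml_set_attr(tp_node, "value", as.character(tp$value))
    for (se in tp$spatialEntities) {
      se_node <- xml2::xml_add_child(tp_node, "spatialEntity")
      p3d <- xml2::xml_add_child(se_node, "pseudo3D", type = se$entityType)
      for (m in spatial_measure_names())
        xml2::xml_add_child(p3d, m, format_stml_number(se[[m]]))
      if (!is.na(se$shape))
        xml2::xml_add_child(p3d, "shape", se$shape)
    }
    for (v in tp$numericStateVariables) {
      v_node <- xml2::xml_add_child(tp_node, "numericStateVariable")
      xml2::xml_add_child(v_node, "name", v$name)
      xml2::xml_add_child(v_node, "value", format_stml_number(v$value))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_number <- function(node, name, element) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing"))
    stml_validation_error(element, sprintf("missing required element '%s'",
                                           name))
  val <- suppressWarnings(as.numeric(xml2::xml_text(child)))
  if (is.na(val))
    stml_validation_error(element,
                          sprintf("'%s' is not a decimal number", name))
  val
}

#' Read an STML file
#'
#' Parses and validates an STML XML file. Validation is performed both
#' against the shipped XSD schema and programmatically, so that violations
#' are reported with the offending element and constraint. Timepoint values
#' missing from the file are resolved via [resolve_timepoint_values()].
#'
#' @param path Path to an STML file.
#' @param validate_schema Also validate against the shipped XSD (default
#'   `TRUE`).
#' @return A validated [experiment()] with resolved timepoint values.
#' @export
read_stml <- function(path, validate_schema = TRUE) {
  if (!file.exists(path))
    stop(sprintf("STML file not found: '%s'", path), call. = FALSE)
  doc <- xml2::read_xml(path)  # malformed XML raises a parse error here
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "experiment")
    stml_validation_error("experiment",
                          sprintf("root element is <%s>, expected <experiment>",
                                  xml2::xml_name(root)))
  version <- xml2::xml_attr(root, "version")
  if (!is.na(version) && !identical(version, stml_schema_version))
    warning(sprintf(
      "STML file declares version '%s'; validating against '%s' only",
      version, stml_schema_version), call. = FALSE)
  if (validate_schema && (is.na(version) ||
                          identical(version, stml_schema_version))) {
    schema <- xml2::read_xml(stml_schema_path())
    ok <- xml2::xml_validate(doc, schema)
    if (!ok) {
      errs <- attr(ok, "errors")
      stml_validation_error("experiment",
                            paste("schema validation failed:",
                                  paste(utils::head(errs, 3), collapse = "; ")))
    }
  }

  tp_nodes <- xml2::xml_find_all(root, "timepoint")
  if (length(tp_nodes) == 0L)
    stml_validation_error("experiment", "must contain at least one timepoint")

  timepoints <- lapply(tp_nodes, function(tp_node) {
    val_attr <- xml2::xml_attr(tp_node, "value")
    value <- if (is.na(val_attr)) NA_integer_ else {
      v <- suppressWarnings(as.integer(val_attr))
      if (is.na(v) || v < 0L)
        stml_validation_error("timepoint",
                              "'value' must be a non-negative integer")
      v
    }
    entities <- lapply(xml2::xml_find_all(tp_node, "spatialEntity"),
                       function(se_node) {
      p3d <- xml2::xml_find_first(se_node, "pseudo3D")
      if (inherits(p3d, "xml_missing"))
        stml_validation_error("spatialEntity", "missing <pseudo3D> child")
      type <- xml2::xml_attr(p3d, "type")
      if (is.na(type))
        stml_validation_error("pseudo3D", "missing required 'type' attribute")
      shape_node <- xml2::xml_find_first(p3d, "shape")
      shape <- if (inherits(shape_node, "xml_missing")) NA_character_
               else xml2::xml_text(shape_node)
      measures <- lapply(spatial_measure_names(), function(m)
        read_number(p3d, m, "pseudo3D"))
      names(measures) <- spatial_measure_names()
      do.call(spatial_entity_record,
              c(list(entityType = type), measures, list(shape = shape)))
    })
    vars <- lapply(xml2::xml_find_all(tp_node, "numericStateVariable"),
                   function(v_node) {
      name_node <- xml2::xml_find_first(v_node, "name")
      if (inherits(name_node, "xml_missing"))
        stml_validation_error("numericStateVariable", "missing <name> child")
      numeric_state_variable(xml2::xml_text(name_node),
                             read_number(v_node, "value",
                                         "numericStateVariable"))
    })
    timepoint(value = value, spatialEntities = entities,
              numericStateVariables = vars)
  })

  resolve_timepoint_values(experiment(timepoints))
}
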