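# Runtime registry of spatial entity types and spatial measures. The
# methodology is "meta": the entity types that can appear in traces and
# formulas, and the measures attached to them, are configuration rather than
# code. The default instance provides {regions, clusters} and the eleven
# standard measures; alternative instances are loaded from an XML
# configuration file and validated against the table of built-in detection
# and measure procedures.

MEASURE_PROCEDURES <- c(
  "clusteredness", "density", "area", "perimeter", "distanceFromOrigin",
  "angle", "triangleMeasure", "rectangleMeasure", "circleMeasure",
  "centroidX", "centroidY")

ENTITY_DETECTORS <- c("regions", "clusters")

default_measure_table <- function() {
  data.frame(
    name = MEASURE_PROCEDURES,
    procedure = MEASURE_PROCEDURES,
    min = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    max = c(1, 1, Inf, Inf, Inf, 360, 1, 1, 1, Inf, Inf),
    stringsAsFactors = FALSE)
}

#' Default spatial registry
#'
#' The registry holds the active collections of spatial entity types and
#' spatial measures. The default instance registers the entity types
#' \code{regions} and \code{clusters} (serialized in trace files with the
#' singular tags \code{region} / \code{cluster}) and the eleven measures
#' \code{clusteredness}, \code{density}, \code{area}, \code{perimeter},
#' \code{distanceFromOrigin}, \code{angle}, \code{triangleMeasure},
#' \code{rectangleMeasure}, \code{circleMeasure}, \code{centroidX} and
#' \code{centroidY}, each with its valid value range.
#'
#' @return An object of class \code{spatial_registry} with elements
#'   \code{entity_types} (data frame: name, tag, detector) and
#'   \code{measures} (data frame: name, procedure, min, max).
#' @export
default_spatial_registry <- function() {
  new_spatial_registry(
    entity_types = data.frame(
      name = c("regions", "clusters"),
      tag = c("region", "cluster"),
      detector = c("regions", "clusters"),
      stringsAsFactors = FALSE),
    measures = default_measure_table())
}

new_spatial_registry <- function(entity_types, measures) {
  if (anyDuplicated(entity_types$name) || anyDuplicated(entity_types$tag))
    abort_config("duplicate entity type names in spatial configuration")
  if (anyDuplicated(measures$name))
    abort_config("duplicate measure names in spatial configuration")
  bad <- setdiff(entity_types$detector, ENTITY_DETECTORS)
  if (length(bad))
    abort_config(sprintf("unknown detection procedure '%s'", bad[1L]))
  bad <- setdiff(measures$procedure, MEASURE_PROCEDURES)
  if (length(bad))
    abort_config(sprintf("measure with no bound procedure: '%s'", bad[1L]))
  if (any(measures$min > measures$max))
    abort_config("measure range lower bound exceeds upper bound")
  structure(list(entity_types = entity_types, measures = measures),
            class = "spatial_registry")
}

#' @export
print.spatial_registry <- function(x, ...) {
  cat(sprintf("<spatial_registry> entity types: %s; %d measures\n",
              paste(x$entity_types$name, collapse = ", "),
              nrow(x$measures)))
  invisible(x)
}

registry_entity_by_tag <- function(registry, tag) {
  i <- match(tag, registry$entity_types$tag)
  if (is.na(i)) i <- match(tag, registry$entity_types$name)
  if (is.na(i)) return(NULL)
  registry$entity_types[i, , drop = FALSE]
}

registry_measure_range <- function(registry, name) {
  i <- match(name, registry$measures$name)
  if (is.na(i))
    abort_registry(sprintf("unregistered spatial measure '%s'", name))
  c(registry$measures$min[i], registry$measures$max[i])
}

#' Load a spatial entity-type / measure configuration
#'
#' Reads an XML document declaring the entity types and measures of the
#' active model-checking instance:
#' \preformatted{
#' <spatialConfig>
#'   <entityType name="regions" tag="region" detector="regions"/>
#'   <measure name="area" procedure="area" min="0" max="Inf"/>
#' </spatialConfig>
#' }
#' \code{detector} and \code{procedure} must name built-in procedures;
#' unknown identifiers are rejected, as are duplicate names and inverted
#' ranges.
#'
#' @param source Path, XML string or \code{xml2} document.
#' @return A \code{spatial_registry}.
#' @export
read_spatial_config <- function(source) {
  doc <- as_xml_doc(source)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "spatialConfig")
    abort_format("expected root element <spatialConfig>")
  et_nodes <- xml2::xml_find_all(root, "./entityType")
  m_nodes <- xml2::xml_find_all(root, "./measure")
  if (!length(et_nodes)) abort_config("spatial configuration declares no entity types")
  if (!length(m_nodes)) abort_config("spatial configuration declares no measures")
  req <- function(node, attr) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) abort_format(sprintf("<%s> missing attribute '%s'",
                                       xml2::xml_name(node), attr))
    v
  }
  entity_types <- data.frame(
    name = vapply(et_nodes, req, character(1), "name"),
    tag = vapply(et_nodes, function(n) {
      v <- xml2::xml_attr(n, "tag"); if (is.na(v)) req(n, "name") else v
    }, character(1)),
    detector = vapply(et_nodes, req, character(1), "detector"),
    stringsAsFactors = FALSE)
  num_attr <- function(node, attr) {
    v <- suppressWarnings(as.numeric(req(node, attr)))
    if (is.na(v)) abort_format(sprintf("non-numeric '%s' attribute", attr))
    v
  }
  measures <- data.frame(
    name = vapply(m_nodes, req, character(1), "name"),
    procedure = vapply(m_nodes, req, character(1), "procedure"),
    min = vapply(m_nodes, num_attr, numeric(1), "min"),
    max = vapply(m_nodes, num_attr, numeric(1), "max"),
    stringsAsFactors = FALSE)
  new_spatial_registry(entity_types, measures)
}

#' Serialize a spatial registry to configuration XML
#'
#' @param registry A \code{spatial_registry}.
#' @param path Optional output path.
#' @return Invisibly the \code{xml2} document.
#' @export
write_spatial_config <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "spatial_registry"))
  doc <- xml2::xml_new_root("spatialConfig")
  root <- xml2::xml_root(doc)
  for (i in seq_len(nrow(registry$entity_types))) {
    xml2::xml_add_child(root, "entityType",
                        name = registry$entity_types$name[i],
                        tag = registry$entity_types$tag[i],
                        detector = registry$entity_types$detector[i])
  }
  for (i in seq_len(nrow(registry$measures))) {
    xml2::xml_add_child(root, "measure",
                        name = registry$measures$name[i],
                        procedure = registry$measures$procedure[i],
                        min = format(registry$measures$min[i]),
                        max = format(registry$measures$max[i]))
  }
  if (!is.null(path))
    xml2::write_xml(doc, path, options = c("format", "no_declaration"))
  invisible(doc)
}
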