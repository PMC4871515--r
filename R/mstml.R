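# MSTML reader/writer. MSTML is an XML trace format: an <experiment> holds
# <timepoint value="t"> elements; each timepoint holds <spatialEntity
# spatialType=".." scaleAndSubsystem=".."> elements with one child element
# per spatial measure, and <numericStateVariable scaleAndSubsystem="..">
# elements with <name> and <value> children. The timepoint `value` attribute
# is the timestamp, not an index. Numeric values round-trip through decimal
# text at 17 significant digits, which is lossless for doubles.

format_mstml_number <- function(x) {
  # %.17g is the shortest representation guaranteed to round-trip a double
  sub("e([+-])0(\\d\\d)$", "e\\1\\2", sprintf("%.17g", x))
}

parse_mstml_number <- function(text, where) {
  v <- suppressWarnings(as.numeric(trimws(text)))
  if (is.na(v) && !identical(trimws(text), "NaN"))
    abort_format(sprintf("non-numeric value '%s' in %s", trimws(text), where))
  v
}

#' Read an MSTML trace document
#'
#' @param source Path to an MSTML file, literal XML string, or \code{xml2}
#'   document.
#' @param registry Spatial registry against which entity types, measure
#'   completeness and measure ranges are validated.
#' @param validate If \code{FALSE}, entity records are accepted without
#'   registry validation (every measure child is kept as-is).
#' @return An \code{mst_trace}; timepoints in document order, timestamps
#'   required to be strictly increasing.
#' @examples
#' tr <- read_mstml(write_mstml(mst_trace(list(
#'   timepoint(0, list(numeric_observation("x", 1, "Organ.Liver")))))))
#' @export
read_mstml <- function(source, registry = default_spatial_registry(),
                       validate = TRUE) {
  doc <- as_xml_doc(source)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "experiment")
    abort_format("expected root element <experiment>")
  tps <- list()
  last_time <- -Inf
  for (tp_node in xml2::xml_find_all(root, "./timepoint")) {
    t_attr <- xml2::xml_attr(tp_node, "value")
    if (is.na(t_attr)) abort_format("<timepoint> missing value attribute")
    t <- parse_mstml_number(t_attr, "timepoint value")
    if (t <= last_time)
      abort_order(sprintf("timepoint %s does not increase on its predecessor %s",
                          format(t), format(last_time)))
    last_time <- t
    numeric <- list()
    entities <- list()
    for (node in xml2::xml_children(tp_node)) {
      nm <- xml2::xml_name(node)
      if (nm == "numericStateVariable") {
        ss <- xml2::xml_attr(node, "scaleAndSubsystem")
        if (is.na(ss)) abort_format("<numericStateVariable> missing scaleAndSubsystem")
        name_node <- xml2::xml_find_first(node, "./name")
        value_node <- xml2::xml_find_first(node, "./value")
        if (inherits(name_node, "xml_missing") || inherits(value_node, "xml_missing"))
          abort_format("<numericStateVariable> requires <name> and <value> children")
        numeric[[length(numeric) + 1L]] <- numeric_observation(
          xml2::xml_text(name_node),
          parse_mstml_number(xml2::xml_text(value_node), "numericStateVariable value"),
          ss)
      } else if (nm == "spatialEntity") {
        st <- xml2::xml_attr(node, "spatialType")
        ss <- xml2::xml_attr(node, "scaleAndSubsystem")
        if (is.na(st) || is.na(ss))
          abort_format("<spatialEntity> requires spatialType and scaleAndSubsystem")
        kids <- xml2::xml_children(node)
        measures <- vapply(kids, function(k)
          parse_mstml_number(xml2::xml_text(k),
                             sprintf("measure <%s>", xml2::xml_name(k))),
          numeric(1))
        names(measures) <- vapply(kids, xml2::xml_name, character(1))
        if (validate) {
          ent <- registry_entity_by_tag(registry, st)
          if (is.null(ent))
            abort_format(sprintf("unregistered spatial entity type '%s'", st))
          entities[[length(entities) + 1L]] <-
            spatial_entity_record(st, ss, measures, registry)
        } else {
          entities[[length(entities) + 1L]] <-
            spatial_entity_record(st, ss, measures, registry = NULL)
        }
      } else {
        abort_format(sprintf("unexpected element <%s> inside <timepoint>", nm))
      }
    }
    tps[[length(tps) + 1L]] <- timepoint(t, numeric, entities)
  }
  mst_trace(tps)
}

#' Write a trace as an MSTML document
#'
#' @param trace An \code{mst_trace}.
#' @param path Optional output path; when omitted the XML document is
#'   returned (convenient for piping back into [read_mstml()]).
#' @param registry Registry controlling the spatial type tag used for each
#'   entity record.
#' @return The \code{xml2} document, invisibly when written to \code{path}.
#' @export
write_mstml <- function(trace, path = NULL,
                        registry = default_spatial_registry()) {
  stopifnot(inherits(trace, "mst_trace"))
  doc <- xml2::xml_new_root("experiment")
  root <- xml2::xml_root(doc)
  for (tp in trace$timepoints) {
    tp_node <- xml2::xml_add_child(root, "timepoint",
                                   value = format_mstml_number(tp$time))
    for (ent in tp$entities) {
      reg_ent <- registry_entity_by_tag(registry, ent$entity_type)
      tag <- if (is.null(reg_ent)) ent$entity_type else reg_ent$tag
      ent_node <- xml2::xml_add_child(tp_node, "spatialEntity",
                                      spatialType = tag,
                                      scaleAndSubsystem = ent$scale_subsystem)
      for (m in names(ent$measures)) {
        xml2::xml_add_child(ent_node, m, format_mstml_number(ent$measures[[m]]))
      }
    }
    for (obs in tp$numeric) {
      nv_node <- xml2::xml_add_child(tp_node, "numericStateVariable",
                                     scaleAndSubsystem = obs$scale_subsystem)
      xml2::xml_add_child(nv_node, "name", obs$name)
      xml2::xml_add_child(nv_node, "value", format_mstml_number(obs$value))
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path, options = "format")
    return(invisible(doc))
  }
  doc
}

#' Read numeric time series from CSV
#'
#' Column convention: first column \code{time}; every further column header
#' is \code{name@scale.subsystem}. Each row is one timepoint.
#'
#' @param source CSV path or connection.
#' @param ma \code{ma_graph} against which each column's scale.subsystem is
#'   validated (a typo becomes a binding error, not a silent mismatch).
#' @return An \code{mst_trace} holding numeric observations only.
#' @export
read_numeric_csv <- function(source, ma) {
  df <- tryCatch(
    utils::read.csv(source, check.names = FALSE, colClasses = "numeric",
                    fill = FALSE),
    error = function(e) abort_format(conditionMessage(e)))
  if (ncol(df) < 1L || names(df)[1L] != "time")
    abort_format("first CSV column must be 'time'")
  cols <- names(df)[-1L]
  bindings <- lapply(cols, function(col) {
    parts <- strsplit(col, "@", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      abort_format(sprintf("column '%s' is not of the form name@scale.subsystem", col))
    key <- ss_key(as_scale_subsystem(parts[[2L]]))
    if (!key %in% ma$vertices)
      abort_binding(sprintf("column '%s': unknown scale.subsystem '%s'", col, key))
    list(name = parts[[1L]], ss = key)
  })
  tps <- lapply(seq_len(nrow(df)), function(i) {
    obs <- lapply(seq_along(bindings), function(j) {
      numeric_observation(bindings[[j]]$name, df[i, j + 1L], bindings[[j]]$ss)
    })
    timepoint(df$time[i], obs)
  })
  mst_trace(tps)
}

#' Read a grid snapshot from CSV
#'
#' The CSV body is a rectangular numeric matrix with values in \code{[0, 1]};
#' the first file row is the top grid row.
#'
#' @param source CSV path or connection.
#' @param scale_subsystem Vertex annotation for the snapshot.
#' @param variable Spatial state-variable name.
#' @param time Timestamp.
#' @return A \code{grid_snapshot}.
#' @export
read_grid_csv <- function(source, scale_subsystem, variable = "value",
                          time = 0) {
  df <- tryCatch(
    utils::read.csv(source, header = FALSE, colClasses = "numeric",
                    fill = FALSE),
    error = function(e) abort_format(conditionMessage(e)))
  values <- as.matrix(df)
  dimnames(values) <- NULL
  grid_snapshot(values, scale_subsystem, variable, time)
}
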