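# Multiscale architecture (MA) graph: a rooted directed tree whose vertices
# are (scale, subsystem) pairs. Coarse-grained scales sit near the root,
# fine-grained scales near the leaves. Two partial orders are defined over
# the vertex set: a < b iff the unique root-to-a path passes through b
# (a is a strict descendant, i.e. a finer-grained constituent of b), and
# a <= b additionally admits a == b.

#' Create a scale.subsystem identifier
#'
#' A vertex of the multiscale architecture graph is identified by the pair
#' (scale, subsystem), rendered in text as \code{"scale.subsystem"}
#' (e.g. \code{"Organ.Liver"}). Both tokens must be non-empty and free of
#' whitespace and \code{"."}.
#'
#' @param scale Scale token, e.g. \code{"Organ"}.
#' @param subsystem Subsystem token, e.g. \code{"Liver"}.
#' @return A length-one character string of class \code{scale_subsystem}.
#' @examples
#' scale_subsystem("Cellular", "Microorganism")
#' as_scale_subsystem("Organ.Liver")
#' @export
scale_subsystem <- function(scale, subsystem) {
  check_ss_token(scale, "scale")
  check_ss_token(subsystem, "subsystem")
  structure(paste0(scale, ".", subsystem), class = "scale_subsystem")
}

check_ss_token <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    abort_format(sprintf("%s token must be a non-empty string", what))
  if (grepl("[[:space:].]", x))
    abort_format(sprintf("%s token '%s' contains whitespace or '.'", what, x))
  invisible(x)
}

#' @rdname scale_subsystem
#' @param x A string of the form \code{"scale.subsystem"}.
#' @export
as_scale_subsystem <- function(x) {
  if (inherits(x, "scale_subsystem")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    abort_format("scale.subsystem must be a single string")
  parts <- strsplit(x, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    abort_format(sprintf("'%s' is not of the form scale.subsystem", x))
  scale_subsystem(parts[[1L]], parts[[2L]])
}

#' @export
format.scale_subsystem <- function(x, ...) unclass(x)

#' @export
print.scale_subsystem <- function(x, ...) {
  cat("<scale.subsystem>", unclass(x), "\n")
  invisible(x)
}

ss_key <- function(x) unclass(as_scale_subsystem(x))

#' Construct a multiscale architecture graph
#'
#' @param vertices Character vector of \code{"scale.subsystem"} identifiers in
#'   the order they should be reported (document / pre-order).
#' @param parent Named character vector mapping each non-root vertex to its
#'   parent; the root is absent from \code{names(parent)}.
#' @return An object of class \code{ma_graph} with elements \code{vertices},
#'   \code{parent} (named character, \code{NA} for the root), \code{children}
#'   (named list) and \code{root}.
#' @keywords internal
new_ma_graph <- function(vertices, parent) {
  vertices <- vapply(vertices, ss_key, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(vertices))
    abort_format(sprintf(
      "duplicate vertex '%s' in multiscale architecture",
      vertices[duplicated(vertices)][1L]))
  full_parent <- rep(NA_character_, length(vertices))
  names(full_parent) <- vertices
  if (length(parent)) {
    unknown <- setdiff(c(names(parent), unname(parent)), vertices)
    if (length(unknown))
      abort_structure(sprintf("edge references unknown vertex '%s'", unknown[1L]))
    full_parent[names(parent)] <- parent
  }
  roots <- vertices[is.na(full_parent)]
  if (length(roots) != 1L)
    abort_structure(sprintf(
      "multiscale architecture must have exactly one root, found %d", length(roots)))
  children <- lapply(vertices, function(v) vertices[!is.na(full_parent) & full_parent == v])
  names(children) <- vertices
  g <- structure(
    list(vertices = vertices, parent = full_parent,
         children = children, root = roots),
    class = "ma_graph")
  # acyclicity + connectedness: every vertex must reach the root
  for (v in vertices) {
    seen <- character(0)
    while (!is.na(v)) {
      if (v %in% seen) abort_structure("multiscale architecture contains a cycle")
      seen <- c(seen, v)
      v <- full_parent[[v]]
    }
    if (seen[length(seen)] != roots)
      abort_structure("multiscale architecture is disconnected")
  }
  g
}

#' @export
print.ma_graph <- function(x, ...) {
  cat(sprintf("<ma_graph> %d vertices, root %s\n", length(x$vertices), x$root))
  invisible(x)
}

#' Read a multiscale architecture graph from XML
#'
#' The XML dialect encodes the tree structure through element nesting:
#' \preformatted{
#' <multiscaleArchitecture rootScale="Environment" rootSubsystem="GrowthMedia">
#'   <vertex scale="Cellular" subsystem="Microorganism">
#'     <vertex scale="Intracellular" subsystem="EnergyProductionReactionNetwork"/>
#'   </vertex>
#' </multiscaleArchitecture>
#' }
#'
#' @param source Path to an XML file, a literal XML string, or an
#'   \code{xml2} document.
#' @return An \code{ma_graph}.
#' @seealso [write_ma_graph()], [ma_leq()], [ma_select()]
#' @export
read_ma_graph <- function(source) {
  doc <- as_xml_doc(source)
  root_node <- xml2::xml_root(doc)
  if (xml2::xml_name(root_node) != "multiscaleArchitecture")
    abort_format("expected root element <multiscaleArchitecture>")
  rs <- xml2::xml_attr(root_node, "rootScale")
  rb <- xml2::xml_attr(root_node, "rootSubsystem")
  if (is.na(rs) || is.na(rb))
    abort_format("<multiscaleArchitecture> requires rootScale and rootSubsystem")
  root <- scale_subsystem(rs, rb)
  vertices <- character(0)
  parent <- character(0)
  walk <- function(node, ss) {
    vertices <<- c(vertices, ss)
    for (child in xml2::xml_find_all(node, "./vertex")) {
      cs <- xml2::xml_attr(child, "scale")
      cb <- xml2::xml_attr(child, "subsystem")
      if (is.na(cs) || is.na(cb))
        abort_format("<vertex> requires scale and subsystem attributes")
      css <- ss_key(scale_subsystem(cs, cb))
      if (css %in% names(parent) || css == ss_key(root))
        abort_format(sprintf("duplicate vertex '%s' in multiscale architecture", css))
      parent[css] <<- ss
      walk(child, css)
    }
  }
  walk(root_node, ss_key(root))
  new_ma_graph(vertices, parent)
}

#' Serialize a multiscale architecture graph to XML
#'
#' @param g An \code{ma_graph}.
#' @param path Optional file path; when omitted the XML document is returned.
#' @return Invisibly the \code{xml2} document (written to \code{path} when
#'   given, UTF-8 with 2-space indentation).
#' @export
write_ma_graph <- function(g, path = NULL) {
  stopifnot(inherits(g, "ma_graph"))
  root_parts <- strsplit(g$root, ".", fixed = TRUE)[[1L]]
  doc <- xml2::xml_new_root(
    "multiscaleArchitecture",
    rootScale = root_parts[[1L]], rootSubsystem = root_parts[[2L]])
  add_children <- function(node, v) {
    for (child in g$children[[v]]) {
      parts <- strsplit(child, ".", fixed = TRUE)[[1L]]
      cn <- xml2::xml_add_child(node, "vertex",
                                scale = parts[[1L]], subsystem = parts[[2L]])
      add_children(cn, child)
    }
  }
  add_children(xml2::xml_root(doc), g$root)
  if (!is.null(path))
    xml2::write_xml(doc, path, options = c("format", "no_declaration"))
  invisible(doc)
}

ma_check_vertex <- function(g, v) {
  key <- ss_key(v)
  if (!key %in% g$vertices)
    abort_lookup(sprintf("unknown scale.subsystem '%s'", key))
  key
}

ma_ancestors_or_self <- function(g, v) {
  key <- ma_check_vertex(g, v)
  out <- character(0)
  while (!is.na(key)) {
    out <- c(out, key)
    key <- g$parent[[key]]
  }
  out
}

#' Partial orders over the multiscale architecture
#'
#' \code{ma_leq(g, a, b)} is \code{TRUE} iff the unique root-to-\code{a} path
#' passes through \code{b}, or \code{a == b}; it reads "\code{a} is at or
#' below \code{b}" in the subsystem hierarchy (\code{a} is a constituent of
#' \code{b}). \code{ma_lt} is the strict variant.
#'
#' @param g An \code{ma_graph}.
#' @param a,b Vertices (\code{scale_subsystem} or \code{"scale.subsystem"}
#'   strings); both must exist in \code{g}.
#' @return Logical scalar.
#' @export
ma_leq <- function(g, a, b) {
  key_b <- ma_check_vertex(g, b)
  key_b %in% ma_ancestors_or_self(g, a)
}

#' @rdname ma_leq
#' @export
ma_lt <- function(g, a, b) {
  key_a <- ma_check_vertex(g, a)
  key_b <- ma_check_vertex(g, b)
  key_a != key_b && ma_leq(g, a, b)
}

#' Select vertices by partial-order relation
#'
#' Returns all vertices \code{v} with \code{v rel ref}, in pre-order
#' (document order), where \code{rel} is one of \code{"="}, \code{"<"} and
#' \code{"<="}.
#'
#' @param g An \code{ma_graph}.
#' @param relation One of \code{"="}, \code{"<"}, \code{"<="}.
#' @param ref Reference vertex; must exist in \code{g}.
#' @return Character vector of \code{"scale.subsystem"} keys.
#' @export
ma_select <- function(g, relation, ref) {
  relation <- match.arg(relation, c("=", "<", "<="))
  key <- ma_check_vertex(g, ref)
  if (relation == "=") return(key)
  hits <- vapply(g$vertices, function(v) ma_leq(g, v, key), logical(1))
  out <- g$vertices[hits]
  if (relation == "<") out <- setdiff(out, key)
  out
}

as_xml_doc <- function(source) {
  if (inherits(source, "xml_document")) return(source)
  if (inherits(source, "xml_node")) return(source)
  if (is.character(source) && length(source) == 1L) {
    if (file.exists(source) && !startsWith(trimws(source), "<"))
      return(tryCatch(xml2::read_xml(source),
                      error = function(e) abort_format(conditionMessage(e))))
    return(tryCatch(xml2::read_xml(source),
                    error = function(e) abort_format(conditionMessage(e))))
  }
  abort_format("expected a file path, XML string or xml2 document")
}
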