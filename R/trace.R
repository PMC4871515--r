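# In-memory data model for timed multiscale traces. A trace is an ordered
# sequence of timepoints; each timepoint carries numeric observations
# (value of a named numeric state variable at some scale.subsystem) and
# spatial entity records (a detected region/cluster with its measure
# values, annotated with the scale.subsystem of the grid it came from).

#' Construct a numeric observation
#'
#' @param name Variable identifier.
#' @param value Finite numeric value.
#' @param scale_subsystem Vertex annotation, \code{"scale.subsystem"}.
#' @return A list of class \code{numeric_observation}.
#' @export
numeric_observation <- function(name, value, scale_subsystem) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_format("observation name must be a non-empty string")
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    abort_format(sprintf("value of '%s' must be a finite number", name))
  structure(list(name = name, value = as.numeric(value),
                 scale_subsystem = ss_key(scale_subsystem)),
            class = "numeric_observation")
}

#' Construct a spatial entity record
#'
#' @param entity_type Registered entity type name (e.g. \code{"clusters"}).
#' @param scale_subsystem Vertex annotation.
#' @param measures Named numeric vector of measure values.
#' @param registry Spatial registry used to validate measure completeness and
#'   ranges; \code{NULL} skips validation.
#' @return A list of class \code{spatial_entity_record}.
#' @export
spatial_entity_record <- function(entity_type, scale_subsystem, measures,
                                  registry = default_spatial_registry()) {
  measures <- unlist(measures)
  if (is.null(names(measures)) || any(!nzchar(names(measures))))
    abort_format("measures must be a named numeric vector")
  if (!is.null(registry)) {
    ent <- registry_entity_by_tag(registry, entity_type)
    if (is.null(ent))
      abort_format(sprintf("entity type '%s' is not registered", entity_type))
    entity_type <- ent$name
    missing <- setdiff(registry$measures$name, names(measures))
    if (length(missing))
      abort_format(sprintf("entity missing registered measure(s): %s",
                           paste(missing, collapse = ", ")))
    unknown <- setdiff(names(measures), registry$measures$name)
    if (length(unknown))
      abort_format(sprintf("unregistered measure(s): %s",
                           paste(unknown, collapse = ", ")))
    for (m in names(measures)) {
      rng <- registry_measure_range(registry, m)
      v <- measures[[m]]
      if (!is.finite(v) || v < rng[1] || v > rng[2])
        abort_range(sprintf("measure %s = %g outside registered range [%g, %g]",
                            m, v, rng[1], rng[2]))
    }
  }
  structure(list(entity_type = entity_type,
                 scale_subsystem = ss_key(scale_subsystem),
                 measures = measures),
            class = "spatial_entity_record")
}

#' Construct a timepoint
#'
#' @param time Non-negative finite timestamp.
#' @param numeric List of \code{numeric_observation}s.
#' @param entities List of \code{spatial_entity_record}s.
#' @return A list of class \code{mst_timepoint}.
#' @export
timepoint <- function(time, numeric = list(), entities = list()) {
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0)
    abort_format("timepoint time must be a finite non-negative number")
  structure(list(time = as.numeric(time), numeric = numeric,
                 entities = entities),
            class = "mst_timepoint")
}

#' Construct a trace
#'
#' @param timepoints List of \code{mst_timepoint}s with strictly increasing
#'   timestamps.
#' @return A list of class \code{mst_trace}.
#' @export
mst_trace <- function(timepoints = list()) {
  times <- vapply(timepoints, function(tp) tp$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0))
    abort_order("timepoint timestamps must be strictly increasing")
  structure(list(timepoints = timepoints), class = "mst_trace")
}

#' @export
print.mst_trace <- function(x, ...) {
  n <- length(x$timepoints)
  if (n == 0) {
    cat("<mst_trace> empty\n")
  } else {
    cat(sprintf("<mst_trace> %d timepoints, t in [%g, %g]\n",
                n, x$timepoints[[1]]$time, x$timepoints[[n]]$time))
  }
  invisible(x)
}

#' @export
length.mst_trace <- function(x) length(x$timepoints)

trace_times <- function(trace) {
  vapply(trace$timepoints, function(tp) tp$time, numeric(1))
}

#' Look up a numeric state variable at one timepoint
#'
#' @param trace An \code{mst_trace}.
#' @param index Timepoint index (1-based).
#' @param name Variable name.
#' @param scale_subsystem Vertex annotation.
#' @param locf If \code{TRUE}, a variable missing at this timepoint is
#'   carried forward from the most recent earlier timepoint that has it
#'   (last observation carried forward); the default is an error, because a
#'   silently imputed value can mask simulator bugs.
#' @return Numeric scalar.
#' @export
trace_lookup_numeric <- function(trace, index, name, scale_subsystem,
                                 locf = FALSE) {
  key <- ss_key(scale_subsystem)
  find_at <- function(i) {
    for (obs in trace$timepoints[[i]]$numeric) {
      if (obs$name == name && obs$scale_subsystem == key) return(obs$value)
    }
    NULL
  }
  v <- find_at(index)
  if (!is.null(v)) return(v)
  if (locf) {
    for (i in rev(seq_len(index - 1L))) {
      v <- find_at(i)
      if (!is.null(v)) return(v)
    }
  }
  abort_lookup(sprintf("numeric state variable {%s}(%s) missing at t = %g",
                       name, key, trace$timepoints[[index]]$time))
}

#' Construct a grid snapshot
#'
#' A rectangular spatial state-variable snapshot at one timepoint, with all
#' values normalized to \code{[0, 1]} by the caller (this fixes the range of
#' the density measure). Row 1 is the top row of the grid; coordinates used
#' by the spatial analysis are 0-based with \code{centroidX} along columns
#' and \code{centroidY} along rows.
#'
#' @param values Numeric matrix with values in \code{[0, 1]}.
#' @param scale_subsystem Vertex annotation.
#' @param variable Spatial state-variable name.
#' @param time Timestamp.
#' @return A list of class \code{grid_snapshot}.
#' @export
grid_snapshot <- function(values, scale_subsystem, variable = "value",
                          time = 0) {
  if (!is.matrix(values) || !is.numeric(values) ||
      nrow(values) < 1L || ncol(values) < 1L)
    abort_format("grid values must be a non-empty numeric matrix")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    abort_range("grid values must lie in [0, 1]; pre-normalize the data")
  structure(list(values = values, scale_subsystem = ss_key(scale_subsystem),
                 variable = variable, time = as.numeric(time)),
            class = "grid_snapshot")
}
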