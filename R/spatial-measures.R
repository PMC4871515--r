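# The spatial measures. Each measure maps a detected entity to a scalar in
# its registered range:
#   area                number of occupied grid positions
#   density             mean grid value over the occupied positions
#   perimeter           arc length of the outer pixel-center contour
#                       (region) / of the convex hull (cluster)
#   distanceFromOrigin  min distance from contour/hull to the grid centre
#   angle               angular width (deg) of the tangent cone from the
#                       grid centre to the contour/hull
#   triangleMeasure     hull area / minimum-area enclosing triangle area
#   rectangleMeasure    hull area / minimum-area rotated rectangle area
#   circleMeasure       hull area / minimum enclosing circle area
#   centroidX/Y         geometric centre of the contour (region) or hull
#                       (cluster); X along columns, Y along rows, 0-based
#   clusteredness       region: area / area of the hole-filled mask (1 iff
#                       hole-free); cluster: 1 - mean pairwise distance
#                       between occupied positions / grid diagonal
# Degenerate entities (hull area 0: single point or collinear set) take the
# three shape measures equal to 1 and perimeter equal to the closed path
# length over the degenerate hull.

grid_centre_point <- function(grid) {
  c(x = (ncol(grid$values) - 1) / 2, y = (nrow(grid$values) - 1) / 2)
}

entity_boundary_xy <- function(entity) {
  if (inherits(entity, "detected_region")) {
    pts <- unique(entity$contour)
    cbind(x = pts[, "col"], y = pts[, "row"])
  } else {
    entity$hull
  }
}

entity_cells <- function(entity) {
  if (inherits(entity, "detected_region")) entity$cells else entity$positions
}

shape_measures <- function(hull) {
  hull_area <- polygon_area(hull)
  if (hull_area < GEOM_TOL)
    return(c(triangleMeasure = 1, rectangleMeasure = 1, circleMeasure = 1))
  tri <- min_enclosing_triangle_area(hull)
  rect <- min_enclosing_rectangle_area(hull)
  circ <- min_enclosing_circle(hull)
  c(triangleMeasure = if (tri > 0) min(1, hull_area / tri) else 1,
    rectangleMeasure = if (rect > 0) min(1, hull_area / rect) else 1,
    circleMeasure = min(1, hull_area / (pi * circ$r^2)))
}

measure_region <- function(name, region, grid) {
  cells <- region$cells
  boundary <- entity_boundary_xy(region)
  centre <- grid_centre_point(grid)
  switch(name,
    area = nrow(cells),
    density = mean(grid$values[cells + 1L]),
    perimeter = {
      pts <- region$contour   # ordered closed boundary through centers
      closed_path_length(cbind(pts[, "col"], pts[, "row"]))
    },
    distanceFromOrigin = {
      pts <- region$contour
      point_polyline_distance(centre, cbind(pts[, "col"], pts[, "row"]))
    },
    angle = angular_width(convex_hull(boundary), centre),
    triangleMeasure = shape_measures(convex_hull(boundary))[["triangleMeasure"]],
    rectangleMeasure = shape_measures(convex_hull(boundary))[["rectangleMeasure"]],
    circleMeasure = shape_measures(convex_hull(boundary))[["circleMeasure"]],
    centroidX = mean(boundary[, "x"]),
    centroidY = mean(boundary[, "y"]),
    clusteredness = nrow(cells) / sum(fill_holes(region$mask)),
    abort_registry(sprintf("no region procedure for measure '%s'", name)))
}

measure_cluster <- function(name, cluster, grid) {
  positions <- cluster$positions
  hull <- cluster$hull
  centre <- grid_centre_point(grid)
  switch(name,
    area = nrow(positions),
    density = mean(grid$values[positions + 1L]),
    perimeter = closed_path_length(hull),
    distanceFromOrigin = point_polyline_distance(centre, hull),
    angle = angular_width(hull, centre),
    triangleMeasure = shape_measures(hull)[["triangleMeasure"]],
    rectangleMeasure = shape_measures(hull)[["rectangleMeasure"]],
    circleMeasure = shape_measures(hull)[["circleMeasure"]],
    centroidX = mean(hull[, "x"]),
    centroidY = mean(hull[, "y"]),
    clusteredness = {
      if (nrow(positions) < 2L) 1 else {
        diag_len <- sqrt((nrow(grid$values) - 1)^2 + (ncol(grid$values) - 1)^2)
        if (diag_len == 0) 1 else {
          xy <- cbind(positions[, "col"], positions[, "row"])
          max(0, 1 - mean(stats::dist(xy)) / diag_len)
        }
      }
    },
    abort_registry(sprintf("no cluster procedure for measure '%s'", name)))
}

#' Compute the registered spatial measures of a detected entity
#'
#' @param entity A \code{detected_region} or \code{detected_cluster}.
#' @param grid The \code{grid_snapshot} the entity was detected from.
#' @param registry Active \code{spatial_registry}; every registered measure
#'   is computed via its bound procedure.
#' @return Named numeric vector, one value per registered measure.
#' @export
compute_measures <- function(entity, grid,
                             registry = default_spatial_registry()) {
  stopifnot(inherits(grid, "grid_snapshot"))
  fn <- if (inherits(entity, "detected_region")) {
    measure_region
  } else if (inherits(entity, "detected_cluster")) {
    measure_cluster
  } else {
    abort_format("entity must be a detected_region or detected_cluster")
  }
  out <- vapply(seq_len(nrow(registry$measures)), function(i)
    fn(registry$measures$procedure[i], entity, grid), numeric(1))
  names(out) <- registry$measures$name
  out
}

#' Detect and measure all spatial entities in one snapshot
#'
#' Runs region detection, clusters the detected regions, computes every
#' registered measure for every entity, and annotates each record with the
#' snapshot's scale.subsystem. Region records come first (detection order),
#' then cluster records (earliest-member order).
#'
#' @param grid A \code{grid_snapshot}.
#' @param rp \code{region_params}.
#' @param cp \code{cluster_params}.
#' @param registry Active \code{spatial_registry}.
#' @return List of \code{spatial_entity_record}s. The integer attribute
#'   \code{"noise"} carries the indices of noise regions (still reported as
#'   region records; just never members of any cluster record).
#' @export
analyse_snapshot <- function(grid, rp = region_params(),
                             cp = cluster_params(),
                             registry = default_spatial_registry()) {
  regions <- detect_regions(grid, rp)
  clusters <- detect_clusters(regions, cp)
  has_regions <- "regions" %in% registry$entity_types$detector
  has_clusters <- "clusters" %in% registry$entity_types$detector
  records <- list()
  if (has_regions) {
    rname <- registry$entity_types$name[registry$entity_types$detector == "regions"][1L]
    for (r in regions) {
      records[[length(records) + 1L]] <- spatial_entity_record(
        rname, grid$scale_subsystem, compute_measures(r, grid, registry),
        registry)
    }
  }
  if (has_clusters) {
    cname <- registry$entity_types$name[registry$entity_types$detector == "clusters"][1L]
    for (cl in clusters) {
      records[[length(records) + 1L]] <- spatial_entity_record(
        cname, grid$scale_subsystem, compute_measures(cl, grid, registry),
        registry)
    }
  }
  attr(records, "noise") <- attr(clusters, "noise")
  records
}

#' Export entity records as a data frame
#'
#' One row per entity, one column per measure; convenient for CSV export.
#'
#' @param records List of \code{spatial_entity_record}s.
#' @return A data frame with columns \code{entity_type},
#'   \code{scale_subsystem} and one column per measure.
#' @export
entity_records_table <- function(records) {
  if (!length(records)) {
    return(data.frame(entity_type = character(0),
                      scale_subsystem = character(0)))
  }
  measures <- do.call(rbind, lapply(records, function(r) r$measures))
  cbind(
    data.frame(
      entity_type = vapply(records, `[[`, character(1), "entity_type"),
      scale_subsystem = vapply(records, `[[`, character(1), "scale_subsystem"),
      stringsAsFactors = FALSE),
    as.data.frame(measures))
}
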