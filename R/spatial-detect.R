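# Detection of emergent spatial entities in grid snapshots.
#
# Regions: Moore-connected (8-connectivity) components of grid positions
# with value >= threshold; a component survives only if its position count
# is strictly greater than the size cutoff.
#
# Clusters: DBSCAN over region centroids with the Euclidean centroid
# pseudometric. A region is core iff its neighbour count (including
# itself) meets the minimum; clusters are maximal density-reachable sets of
# regions. Iteration order is deterministic (region index order) and a
# border region reachable from several clusters is assigned to the cluster
# of the earliest-indexed core that neighbours it. Non-core regions not
# reachable from any core are reported as noise, not clustered.

#' Region detection parameters
#'
#' @param threshold Occupancy threshold: a position belongs to the
#'   foreground iff its value is \code{>= threshold}.
#' @param min_size Size cutoff: a connected component is kept iff its
#'   position count is strictly greater than \code{min_size} (so
#'   \code{min_size = 1} discards single-pixel components).
#' @return A list of class \code{region_params}.
#' @export
region_params <- function(threshold = 0.5, min_size = 1L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    abort_parameter("threshold must be a finite number")
  min_size <- as.integer(min_size)
  if (is.na(min_size) || min_size < 1L)
    abort_parameter("min_size must be a positive integer")
  structure(list(threshold = threshold, min_size = min_size),
            class = "region_params")
}

#' Cluster detection parameters
#'
#' @param eps_distance Maximum Euclidean distance between the centroids of
#'   two neighbouring regions (inclusive bound).
#' @param min_regions Minimum number of neighbouring regions (including the
#'   region itself) for a region to count as core.
#' @return A list of class \code{cluster_params}.
#' @export
cluster_params <- function(eps_distance = 1, min_regions = 1L) {
  if (!is.numeric(eps_distance) || length(eps_distance) != 1L ||
      !is.finite(eps_distance) || eps_distance <= 0)
    abort_parameter("eps_distance must be a positive number")
  min_regions <- as.integer(min_regions)
  if (is.na(min_regions) || min_regions < 1L)
    abort_parameter("min_regions must be a positive integer")
  structure(list(eps_distance = eps_distance, min_regions = min_regions),
            class = "cluster_params")
}

# 8-connected component labelling; mask logical m x n. Returns integer
# label matrix; labels assigned in row-major (top-most, left-most seed)
# order, so component k's seed precedes component k+1's.
label_components8 <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  labels <- matrix(0L, m, n)
  cur <- 0L
  # row-major scan over cells: order by row then column
  cells <- which(t(mask))          # index in transposed = row-major order
  for (p in cells) {
    r0 <- (p - 1L) %/% n + 1L
    c0 <- (p - 1L) %% n + 1L
    if (labels[r0, c0] > 0L) next
    cur <- cur + 1L
    stack <- (c0 - 1L) * m + r0
    labels[r0, c0] <- cur
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      r <- (q - 1L) %% m + 1L; c <- (q - 1L) %/% m + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        rr <- r + dr; cc <- c + dc
        if ((dr != 0L || dc != 0L) && rr >= 1L && rr <= m && cc >= 1L &&
            cc <= n && mask[rr, cc] && labels[rr, cc] == 0L) {
          labels[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- (cc - 1L) * m + rr
        }
      }
    }
  }
  labels
}

#' Detect regions in a grid snapshot
#'
#' @param grid A \code{grid_snapshot}.
#' @param p \code{region_params}.
#' @return A list of \code{detected_region} objects ordered by the
#'   row-major position of their seed (top-most, then left-most). Each
#'   carries the binary \code{mask}, the occupied \code{cells} (0-based
#'   row/col), and the ordered boundary \code{contour} through pixel
#'   centers.
#' @export
detect_regions <- function(grid, p = region_params()) {
  stopifnot(inherits(grid, "grid_snapshot"), inherits(p, "region_params"))
  mask <- grid$values >= p$threshold
  labels <- label_components8(mask)
  k <- max(labels)
  out <- list()
  for (i in seq_len(k)) {
    comp <- labels == i
    count <- sum(comp)
    if (count <= p$min_size) next   # strict: survive iff count > min_size
    cells <- which(comp, arr.ind = TRUE) - 1L
    colnames(cells) <- c("row", "col")
    cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
    contour <- trace_contour(comp)
    out[[length(out) + 1L]] <- structure(
      list(mask = comp, cells = cells, contour = contour),
      class = "detected_region")
  }
  out
}

#' @export
print.detected_region <- function(x, ...) {
  cat(sprintf("<detected_region> area %d\n", nrow(x$cells)))
  invisible(x)
}

region_centroid <- function(region) {
  pts <- unique(region$contour)
  c(x = mean(pts[, "col"]), y = mean(pts[, "row"]))
}

#' Detect clusters over a set of regions
#'
#' DBSCAN with the Euclidean distance between region centroids as the
#' pseudometric.
#'
#' @param regions List of \code{detected_region}s from one snapshot.
#' @param p \code{cluster_params}.
#' @return A list of \code{detected_cluster} objects ordered by their
#'   earliest member region index, with an integer attribute \code{"noise"}
#'   holding the indices of unclustered regions.
#' @export
detect_clusters <- function(regions, p = cluster_params()) {
  stopifnot(inherits(p, "cluster_params"))
  n <- length(regions)
  noise_attr <- function(x, noise) { attr(x, "noise") <- noise; x }
  if (n == 0L) return(noise_attr(list(), integer(0)))
  cent <- t(vapply(regions, region_centroid, numeric(2)))
  dmat <- as.matrix(stats::dist(cent))
  neighbours <- dmat <= p$eps_distance       # includes self (d = 0)
  core <- rowSums(neighbours) >= p$min_regions
  assignment <- rep(NA_integer_, n)
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(assignment[i])) next
    cluster_id <- cluster_id + 1L
    # expand over density-connected cores, index order
    frontier <- i
    assignment[i] <- cluster_id
    while (length(frontier)) {
      j <- frontier[[1L]]; frontier <- frontier[-1L]
      reach <- which(neighbours[j, ] & core & is.na(assignment))
      assignment[reach] <- cluster_id
      frontier <- c(frontier, reach)
    }
  }
  # border regions: non-core neighbours of a core; tie-break to the cluster
  # of the earliest-indexed neighbouring core
  for (i in seq_len(n)) {
    if (core[i] || !is.na(assignment[i])) next
    adj_cores <- which(neighbours[i, ] & core)
    if (length(adj_cores))
      assignment[i] <- assignment[min(adj_cores)]
  }
  noise <- which(is.na(assignment))
  clusters <- list()
  if (cluster_id > 0L) {
    # order clusters by earliest member region index
    first_member <- vapply(seq_len(cluster_id), function(cid)
      min(which(assignment == cid)), integer(1))
    for (cid in order(first_member)) {
      members <- which(assignment == cid)
      member_regions <- regions[members]
      positions <- do.call(rbind, lapply(member_regions, function(r) r$cells))
      hull <- convex_hull(cbind(x = positions[, "col"], y = positions[, "row"]))
      clusters[[length(clusters) + 1L]] <- structure(
        list(member_indices = members, regions = member_regions,
             positions = positions, hull = hull),
        class = "detected_cluster")
    }
  }
  noise_attr(clusters, noise)
}

#' @export
print.detected_cluster <- function(x, ...) {
  cat(sprintf("<detected_cluster> %d member region(s), area %d\n",
              length(x$member_indices), nrow(x$positions)))
  invisible(x)
}
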