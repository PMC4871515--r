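# Computational-geometry primitives used by the spatial measures. All
# positions are pixel centers: a grid cell at (row r, col c), 0-based, is the
# point (x = c, y = r). Contours run through pixel centers, so a single
# pixel degenerates to a point with perimeter 0. This convention avoids
# library-specific half-pixel offsets and makes the expected values in the
# tests exact.

GEOM_TOL <- 1e-9

# --- Moore boundary tracing -------------------------------------------------

# Clockwise ring of 8-neighbour offsets (row, col), starting West. With rows
# growing downward this is the standard clockwise scan used by
# Moore-neighbour tracing.
MOORE_RING <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                     ncol = 2, byrow = TRUE)

# mask: logical matrix holding exactly one 8-connected component.
# Returns an ordered matrix of 0-based (row, col) boundary positions.
trace_contour <- function(mask) {
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 1L)
    return(matrix(c(cells[1, 1] - 1L, cells[1, 2] - 1L), ncol = 2,
                  dimnames = list(NULL, c("row", "col"))))
  # top-most then left-most foreground pixel
  ord <- order(cells[, 1], cells[, 2])
  start <- cells[ord[1L], ]
  m <- nrow(mask); n <- ncol(mask)
  inside <- function(p) p[1] >= 1 && p[1] <= m && p[2] >= 1 && p[2] <= n
  fg <- function(p) inside(p) && mask[p[1], p[2]]
  ring_index <- function(offset) {
    which(MOORE_RING[, 1] == offset[1] & MOORE_RING[, 2] == offset[2])
  }
  # One tracing step: from pixel p entered with backtrack b, scan the Moore
  # ring clockwise starting just after b; the first foreground pixel is the
  # next boundary pixel, the background pixel examined just before it the
  # next backtrack.
  step <- function(p, b) {
    i0 <- ring_index(b - p)
    for (k in seq_len(8L)) {
      idx <- ((i0 - 1L + k) %% 8L) + 1L
      cand <- p + MOORE_RING[idx, ]
      if (fg(cand)) {
        prev_idx <- ((i0 - 1L + k - 1L) %% 8L) + 1L
        return(list(p = cand, b = p + MOORE_RING[prev_idx, ]))
      }
    }
    NULL
  }
  # The map (p, b) -> step(p, b) is deterministic and the initial state
  # (top-left-most pixel, entered from its West) lies on its cycle, so the
  # full closed boundary is traced exactly once by stopping when the initial
  # state recurs.
  p <- start
  b <- start + c(0L, -1L)
  state_key <- function(p, b) paste(p[1], p[2], b[1], b[2])
  seen <- character(0)
  contour <- list()
  repeat {
    key <- state_key(p, b)
    if (key %in% seen) break
    seen <- c(seen, key)
    contour[[length(contour) + 1L]] <- p
    nxt <- step(p, b)
    if (is.null(nxt)) break
    p <- nxt$p
    b <- nxt$b
  }
  pts <- do.call(rbind, contour) - 1L
  colnames(pts) <- c("row", "col")
  pts
}

closed_path_length <- function(pts_xy) {
  k <- nrow(pts_xy)
  if (k < 2L) return(0)
  nxt <- c(2:k, 1L)
  sum(sqrt((pts_xy[nxt, 1] - pts_xy[, 1])^2 + (pts_xy[nxt, 2] - pts_xy[, 2])^2))
}

# --- hole filling -----------------------------------------------------------

# Background complementary to 8-connected foreground is 4-connected. A hole
# is a background component not reachable from the grid border.
fill_holes <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  reach <- matrix(FALSE, m, n)
  queue <- integer(0)
  push <- function(r, c) {
    if (r >= 1 && r <= m && c >= 1 && c <= n && !mask[r, c] && !reach[r, c]) {
      reach[r, c] <<- TRUE
      queue[[length(queue) + 1L]] <<- (c - 1L) * m + r
    }
  }
  for (r in seq_len(m)) { push(r, 1L); push(r, n) }
  for (c in seq_len(n)) { push(1L, c); push(m, c) }
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue <- queue[-length(queue)]
    r <- (p - 1L) %% m + 1L; c <- (p - 1L) %/% m + 1L
    push(r - 1L, c); push(r + 1L, c); push(r, c - 1L); push(r, c + 1L)
  }
  mask | (!reach & !mask)
}

# --- convex hull ------------------------------------------------------------

# points: k x 2 matrix (x, y). Returns hull vertices counter-clockwise in
# the mathematical sense (grDevices::chull returns clockwise indices in
# screen coordinates, which is counter-clockwise when y grows downward; the
# orientation only matters internally and is normalized here).
convex_hull <- function(points) {
  pts <- unique(points)
  if (nrow(pts) <= 2L) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  if (polygon_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  hull
}

polygon_signed_area <- function(pts) {
  k <- nrow(pts)
  if (k < 3L) return(0)
  nxt <- c(2:k, 1L)
  sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]) / 2
}

polygon_area <- function(pts) abs(polygon_signed_area(pts))

point_in_convex_hull <- function(p, hull, tol = GEOM_TOL) {
  k <- nrow(hull)
  if (k == 1L) return(all(abs(p - hull[1, ]) <= tol))
  if (k == 2L) return(point_segment_distance(p, hull[1, ], hull[2, ]) <= tol)
  nxt <- c(2:k, 1L)
  cross <- (hull[nxt, 1] - hull[, 1]) * (p[2] - hull[, 2]) -
    (hull[nxt, 2] - hull[, 2]) * (p[1] - hull[, 1])
  all(cross >= -tol) || all(cross <= tol)
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

# Minimum distance from point p to the closed polyline through pts (k x 2).
point_polyline_distance <- function(p, pts) {
  k <- nrow(pts)
  if (k == 1L) return(sqrt(sum((p - pts[1, ])^2)))
  nxt <- c(2:k, 1L)
  min(vapply(seq_len(k), function(i)
    point_segment_distance(p, pts[i, ], pts[nxt[i], ]), numeric(1)))
}

# --- minimum-area enclosing rectangle (rotating calipers) -------------------

min_enclosing_rectangle_area <- function(hull) {
  k <- nrow(hull)
  if (k < 3L) return(0)
  nxt <- c(2:k, 1L)
  best <- Inf
  for (i in seq_len(k)) {
    d <- hull[nxt[i], ] - hull[i, ]
    len <- sqrt(sum(d^2))
    if (len < GEOM_TOL) next
    u <- d / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    area <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (area < best) best <- area
  }
  if (is.finite(best)) best else 0
}

# --- minimum enclosing circle (Welzl) ---------------------------------------

circle_from2 <- function(a, b) {
  list(center = (a + b) / 2, r = sqrt(sum((a - b)^2)) / 2)
}

circle_from3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < GEOM_TOL) return(NULL)
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  center <- c(ux, uy)
  list(center = center, r = sqrt(sum((a - center)^2)))
}

in_circle <- function(p, circ, tol = 1e-7) {
  !is.null(circ) && sqrt(sum((p - circ$center)^2)) <= circ$r * (1 + tol) + tol
}

trivial_circle <- function(R) {
  n <- length(R)
  if (n == 0L) return(list(center = c(0, 0), r = -1))
  if (n == 1L) return(list(center = R[[1]], r = 0))
  if (n == 2L) return(circle_from2(R[[1]], R[[2]]))
  circ <- circle_from3(R[[1]], R[[2]], R[[3]])
  if (!is.null(circ)) return(circ)
  # collinear support: largest diametral pair
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  circs <- lapply(pairs, function(ij) circle_from2(R[[ij[1]]], R[[ij[2]]]))
  circs[[which.max(vapply(circs, `[[`, numeric(1), "r"))]]
}

welzl <- function(P, R = list()) {
  if (length(P) == 0L || length(R) == 3L) return(trivial_circle(R))
  p <- P[[1L]]
  circ <- welzl(P[-1L], R)
  if (in_circle(p, circ)) return(circ)
  welzl(P[-1L], c(R, list(p)))
}

min_enclosing_circle <- function(points) {
  pts <- unique(points)
  P <- lapply(seq_len(nrow(pts)), function(i) pts[i, ])
  welzl(P)
}

# --- minimum-area enclosing triangle (flush supporting lines) ---------------

# Enumerate triangles bounded by lines through triples of hull edges. Every
# such line is a supporting line of the convex hull, so whenever the three
# pairwise intersections form a triangle containing the hull it is a valid
# enclosing triangle. The minimum over all triples is used; it is an upper
# bound on the true minimum area (the optimum is guaranteed to have at
# least one flush side) and always yields a shape-similarity ratio in
# [0, 1]. Vectorized over triples for speed.
min_enclosing_triangle_area <- function(hull) {
  k <- nrow(hull)
  if (k < 3L || polygon_area(hull) < GEOM_TOL) return(0)
  nxt <- c(2:k, 1L)
  # line i: point hull[i, ], direction d_i
  dx <- hull[nxt, 1] - hull[, 1]
  dy <- hull[nxt, 2] - hull[, 2]
  px <- hull[, 1]; py <- hull[, 2]
  # pairwise intersections of lines i and j
  IX <- matrix(NA_real_, k, k); IY <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    den <- dx[i] * dy - dy[i] * dx
    tt <- ((px - px[i]) * dy - (py - py[i]) * dx) / den
    ok <- abs(den) > GEOM_TOL
    IX[i, ok] <- px[i] + tt[ok] * dx[i]
    IY[i, ok] <- py[i] + tt[ok] * dy[i]
  }
  triples <- utils::combn(k, 3L)
  ax <- IX[cbind(triples[1, ], triples[2, ])]
  ay <- IY[cbind(triples[1, ], triples[2, ])]
  bx <- IX[cbind(triples[2, ], triples[3, ])]
  by <- IY[cbind(triples[2, ], triples[3, ])]
  cx <- IX[cbind(triples[1, ], triples[3, ])]
  cy <- IY[cbind(triples[1, ], triples[3, ])]
  area2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  areas <- abs(area2) / 2
  valid <- is.finite(areas) & areas > GEOM_TOL
  if (!any(valid)) return(0)
  # containment of all hull vertices, vectorized: same-sign cross products
  tol <- 1e-7 * (1 + max(abs(hull)))
  contains <- rep(TRUE, length(areas))
  contains[!valid] <- FALSE
  s <- sign(area2)
  for (i in seq_len(k)) {
    c1 <- (bx - ax) * (hull[i, 2] - ay) - (by - ay) * (hull[i, 1] - ax)
    c2 <- (cx - bx) * (hull[i, 2] - by) - (cy - by) * (hull[i, 1] - bx)
    c3 <- (ax - cx) * (hull[i, 2] - cy) - (ay - cy) * (hull[i, 1] - cx)
    contains <- contains & (s * c1 >= -tol) & (s * c2 >= -tol) & (s * c3 >= -tol)
  }
  if (!any(contains)) return(0)
  min(areas[contains])
}

# --- angular width from a viewpoint -----------------------------------------

# Angular width (degrees) of the tangent-line cone from viewpoint `centre`
# to the convex hull `hull`. 360 when the viewpoint is in the hull; 0 for a
# single point.
angular_width <- function(hull, centre) {
  k <- nrow(hull)
  if (k == 1L) return(0)
  if (point_in_convex_hull(centre, hull)) return(360)
  ang <- atan2(hull[, 2] - centre[2], hull[, 1] - centre[1])
  ang <- sort(ang)
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  (2 * pi - max(gaps)) * 180 / pi
}
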