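#' Joint delineation: an open polyline with anchor lines
#'
#' Represents one observer-drawn sacroiliac joint line on one slice: an open
#' polyline (a connected series of straight segments) in millimetre
#' coordinates, plus two anchor segments that define the angle the joint makes
#' with the cortex at each end. The anchors control the direction of the end
#' edges of the subchondral ROIs generated by [propagate_rois()].
#'
#' Coordinates are continuous mm with the origin at the centre of pixel
#' (1, 1); x runs along columns, y along rows.
#'
#' @param vertices numeric matrix (n >= 2 rows) of `[x_mm, y_mm]` polyline
#'   vertices, in drawing order.
#' @param anchor_start,anchor_end 2x2 matrices, each row an `[x_mm, y_mm]`
#'   endpoint of the anchor segment at the first / last polyline vertex.
#'   Default `NULL` uses anchors perpendicular to the terminal segments.
#' @param slice 1-based slice index the delineation belongs to.
#' @param joint `"left"` or `"right"` sacroiliac joint.
#' @return An object of class `joint_delineation`.
#' @export
joint_delineation <- function(vertices, anchor_start = NULL, anchor_end = NULL,
                              slice = 1L, joint = c("left", "right")) {
  joint <- match.arg(joint)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("'vertices' must be an n x 2 matrix with n >= 2")
  seg <- diff(vertices)
  if (any(rowSums(seg^2) < 1e-12))
    stop("consecutive polyline vertices must be distinct")
  if (.polyline_self_intersects(vertices))
    stop("polyline must be simple (non-self-intersecting)")
  if (is.null(anchor_start)) anchor_start <- .perp_anchor(vertices, at = "start")
  if (is.null(anchor_end))   anchor_end   <- .perp_anchor(vertices, at = "end")
  anchor_start <- .check_anchor(anchor_start, "anchor_start")
  anchor_end   <- .check_anchor(anchor_end, "anchor_end")
  structure(list(vertices = vertices, anchor_start = anchor_start,
                 anchor_end = anchor_end, slice = as.integer(slice),
                 joint = joint),
            class = "joint_delineation")
}

.check_anchor <- function(a, what) {
  a <- as.matrix(a)
  storage.mode(a) <- "double"
  if (!all(dim(a) == c(2L, 2L))) stop("'", what, "' must be a 2 x 2 matrix")
  if (sum((a[2, ] - a[1, ])^2) < 1e-12) stop("'", what, "' is degenerate")
  a
}

# Anchor perpendicular to the terminal segment, centred on the end vertex.
.perp_anchor <- function(vertices, at = c("start", "end")) {
  at <- match.arg(at)
  n <- nrow(vertices)
  if (at == "start") { p <- vertices[1, ]; d <- vertices[2, ] - vertices[1, ] }
  else               { p <- vertices[n, ]; d <- vertices[n, ] - vertices[n - 1, ] }
  d <- d / sqrt(sum(d^2))
  nrm <- c(-d[2], d[1])
  rbind(p - nrm, p + nrm)
}

#' @export
print.joint_delineation <- function(x, ...) {
  cat(sprintf("<joint_delineation> %s joint, slice %d, %d vertices, length %.1f mm\n",
              x$joint, x$slice, nrow(x$vertices), polyline_length(x$vertices)))
  invisible(x)
}

#' Total length of an open polyline
#' @param vertices n x 2 matrix of vertices.
#' @return Length in the units of the coordinates.
#' @export
polyline_length <- function(vertices) {
  sum(sqrt(rowSums(diff(as.matrix(vertices))^2)))
}

#' Signed area-free polygon area (shoelace)
#' @param polygon n x 2 matrix of polygon vertices (closed implicitly).
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(polygon) {
  p <- as.matrix(polygon)
  n <- nrow(p)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# segment intersection test (proper crossings only, shared endpoints allowed)
.segments_cross <- function(p1, p2, q1, q2) {
  d1 <- .cross2(q2 - q1, p1 - q1)
  d2 <- .cross2(q2 - q1, p2 - q1)
  d3 <- .cross2(p2 - p1, q1 - p1)
  d4 <- .cross2(p2 - p1, q2 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

.polyline_self_intersects <- function(v) {
  n <- nrow(v) - 1L
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (.segments_cross(v[i, ], v[i + 1L, ], v[j, ], v[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

# Offset an open polyline perpendicular by `depth` toward side `s` (+1 = left
# of drawing direction, -1 = right), with mitered joins (miter limit
# 2 * depth, bevel fallback) and end points placed along the anchor directions.
# Returns the offset chain (matrix). Errors if local curvature reverses an
# offset edge (curvature radius < depth).
.offset_polyline <- function(vertices, depth, side, anchor_start, anchor_end) {
  v <- vertices
  n <- nrow(v)
  e <- diff(v)                              # edge vectors
  len <- sqrt(rowSums(e^2))
  u <- e / len                              # unit edge directions
  nrm <- cbind(-u[, 2], u[, 1]) * side      # unit normals toward requested side

  # end points: intersect the anchor line through the end vertex with the
  # offset line of the terminal edge
  p_start <- .anchor_cap(v[1, ], anchor_start, v[1, ] + depth * nrm[1, ],
                         u[1, ], depth)
  p_end <- .anchor_cap(v[n, ], anchor_end,
                       v[n, ] + depth * nrm[n - 1L, ], u[n - 1L, ], depth)

  pts <- list(p_start)
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      a0 <- v[k - 1L, ] + depth * nrm[k - 1L, ]   # offset line of edge k-1
      b0 <- v[k, ] + depth * nrm[k, ]             # offset line of edge k
      m <- .line_intersect(a0, u[k - 1L, ], b0, u[k, ])
      if (is.null(m)) {                            # collinear edges
        pts[[length(pts) + 1L]] <- b0
      } else if (sqrt(sum((m - v[k, ])^2)) > 2 * depth && depth > 0) {
        # miter too long: bevel with the two edge-offset corner points
        pts[[length(pts) + 1L]] <- v[k, ] + depth * nrm[k - 1L, ]
        pts[[length(pts) + 1L]] <- v[k, ] + depth * nrm[k, ]
      } else {
        pts[[length(pts) + 1L]] <- m
      }
    }
  }
  pts[[length(pts) + 1L]] <- p_end
  off <- do.call(rbind, pts)

  off
}

# first proper self-crossing of a closed polygon boundary, or NULL
.polygon_self_crossing <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (j == i + 1L || (i == 1L && j == n)) next   # adjacent edges
      if (.segments_cross(poly[i, ], poly[nxt[i], ],
                          poly[j, ], poly[nxt[j], ]))
        return((poly[i, ] + poly[nxt[i], ]) / 2)
    }
  }
  NULL
}

.nearest_edge <- function(v, p) {
  n <- nrow(v) - 1L
  d <- numeric(n)
  for (j in seq_len(n)) d[j] <- .point_segment_dist(p, v[j, ], v[j + 1L, ])
  which.min(d)
}

.point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# Intersect the line through `vertex` along the anchor direction with the
# offset line (point `off_pt`, direction `edge_dir`). Falls back to the
# perpendicular foot when the anchor is nearly parallel to the edge or the
# cap would exceed the miter limit (2 x depth from the end vertex).
.anchor_cap <- function(vertex, anchor, off_pt, edge_dir, depth) {
  ad <- anchor[2, ] - anchor[1, ]
  ad <- ad / sqrt(sum(ad^2))
  sin_ang <- abs(.cross2(ad, edge_dir))
  if (sin_ang < 0.05) return(off_pt)
  m <- .line_intersect(vertex, ad, off_pt, edge_dir)
  if (is.null(m)) return(off_pt)
  if (depth > 0 && sqrt(sum((m - vertex)^2)) > 2 * depth * (1 + 1e-9))
    return(off_pt)
  m
}

# intersection of lines p + t*u and q + s*w; NULL if parallel
.line_intersect <- function(p, u, q, w) {
  den <- .cross2(u, w)
  if (abs(den) < 1e-12) return(NULL)
  t <- .cross2(q - p, w) / den
  p + t * u
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon;
#' centres exactly on the boundary count as inside. Pixel (r, c) has its
#' centre at x = (c-1) * spacing_col, y = (r-1) * spacing_row.
#'
#' @param polygon n x 2 matrix of `[x_mm, y_mm]` vertices (closed implicitly).
#' @param grid_shape integer `(rows, cols)`.
#' @param pixel_spacing_mm numeric `(row, col)` spacing in mm.
#' @return Logical `rows x cols` matrix. A polygon entirely outside the grid
#'   yields an empty mask with a warning.
#' @export
rasterize_polygon <- function(polygon, grid_shape, pixel_spacing_mm) {
  rows <- as.integer(grid_shape[1]); cols <- as.integer(grid_shape[2])
  sp <- rep(as.numeric(pixel_spacing_mm), length.out = 2L)
  if (any(sp <= 0)) stop("pixel spacing must be positive")
  mask <- matrix(FALSE, rows, cols)
  p <- as.matrix(polygon)
  if (nrow(p) < 3L) return(mask)

  # candidate pixel centres restricted to the polygon bounding box
  r_rng <- range(p[, 2]) / sp[1] + 1    # y -> row
  c_rng <- range(p[, 1]) / sp[2] + 1    # x -> col
  ri <- max(1L, floor(r_rng[1] - 1e-9)):min(rows, ceiling(r_rng[2] + 1e-9))
  ci <- max(1L, floor(c_rng[1] - 1e-9)):min(cols, ceiling(c_rng[2] + 1e-9))
  if (ri[1] > ri[length(ri)] || ci[1] > ci[length(ci)] ||
      r_rng[2] < 1 || c_rng[2] < 1 || r_rng[1] > rows || c_rng[1] > cols) {
    warning("polygon lies outside the pixel grid; empty mask")
    return(mask)
  }
  ctr <- expand.grid(r = ri, c = ci)
  px <- (ctr$c - 1) * sp[2]
  py <- (ctr$r - 1) * sp[1]
  inside <- .points_in_polygon(px, py, p)
  mask[cbind(ctr$r, ctr$c)] <- inside
  mask
}

# Vectorized even-odd crossing test with boundary-inclusive ties.
.points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  xv <- poly[, 1]; yv <- poly[, 2]
  xw <- c(xv, xv[1]); yw <- c(yv, yv[1])
  m <- length(px)
  crossings <- integer(m)
  on_edge <- logical(m)
  for (j in seq_len(n)) {
    x1 <- xw[j]; y1 <- yw[j]; x2 <- xw[j + 1L]; y2 <- yw[j + 1L]
    # boundary test: zero cross product and within the segment's span
    cx <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (seg_len2 > 0) {
      t <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / seg_len2
      on_edge <- on_edge |
        (abs(cx) <= eps * sqrt(seg_len2) & t >= -eps & t <= 1 + eps)
    }
    cond <- (y1 > py) != (y2 > py)
    if (any(cond)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + as.integer(cond & (px < xint))
    }
  }
  (crossings %% 2L == 1L) | on_edge
}
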