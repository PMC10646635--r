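#' SPARCC quadrant annotation
#'
#' Quadrant-level lesion calls for SPARCC scoring: for each of 6 consecutive
#' slices and both sacroiliac joints, four bone-marrow-oedema (BME) quadrant
#' flags, a per-joint-slice depth flag (BME deeper than 10 mm) and a
#' per-joint-slice intensity flag (BME at least as intense as cerebrospinal
#' fluid), plus per-quadrant fat-lesion flags for the structural score.
#'
#' Bonus (depth/intensity) flags are valid only where at least one BME
#' quadrant flag is set for that joint-slice; the constructor enforces this.
#'
#' @param bme 0/1 array `(slices, joints = 2, quadrants = 4)` of BME calls
#'   (default 6 slices).
#' @param depth,intensity 0/1 matrices `(slices, joints)`; default all zero.
#' @param fat 0/1 array `(slices, joints, quadrants)` of fat-lesion calls for
#'   the structural score slice set; default all zero, same shape as `bme`.
#' @return An object of class `sparcc_annotation`.
#' @export
sparcc_annotation <- function(bme = array(0L, c(6, 2, 4)),
                              depth = NULL, intensity = NULL, fat = NULL) {
  bme <- .check_flags(bme, 3L, "bme")
  ns <- dim(bme)[1]; nj <- dim(bme)[2]
  if (is.null(depth)) depth <- matrix(0L, ns, nj)
  if (is.null(intensity)) intensity <- matrix(0L, ns, nj)
  if (is.null(fat)) fat <- array(0L, dim(bme))
  depth <- .check_flags(depth, 2L, "depth")
  intensity <- .check_flags(intensity, 2L, "intensity")
  fat <- .check_flags(fat, 3L, "fat")
  if (!all(dim(depth) == c(ns, nj)) || !all(dim(intensity) == c(ns, nj)))
    stop("'depth' and 'intensity' must be (slices x joints) matrices matching 'bme'")
  present <- apply(bme, c(1, 2), max)
  if (any(depth > present))
    stop("depth flag set for a joint-slice without any BME quadrant flag")
  if (any(intensity > present))
    stop("intensity flag set for a joint-slice without any BME quadrant flag")
  structure(list(bme = bme, depth = depth, intensity = intensity, fat = fat),
            class = "sparcc_annotation")
}

.check_flags <- function(x, ndim, what) {
  x <- if (ndim == 2L) as.matrix(x) else x
  if (length(dim(x)) != ndim) stop("'", what, "' has wrong dimensionality")
  if (!all(x %in% c(0, 1))) stop("'", what, "' flags must be 0/1")
  storage.mode(x) <- "integer"
  x
}

#' SPARCC bone marrow oedema score
#'
#' Sum of all BME quadrant flags plus, per joint per slice, one point if the
#' oedema is more than 10 mm deep and one point if it is at least as intense
#' as cerebrospinal fluid. With 6 slices, 2 joints and 4 quadrants the
#' maximum is 6 x 2 x (4 + 1 + 1) = 72.
#'
#' @param annotation a [sparcc_annotation()].
#' @return Integer total score.
#' @export
score_bme <- function(annotation) {
  stopifnot(inherits(annotation, "sparcc_annotation"))
  sum(annotation$bme) + sum(annotation$depth) + sum(annotation$intensity)
}

#' SPARCC structural score, fat-lesion component
#'
#' Count of fat-metaplasia quadrant flags over the structural-score slice
#' set. The default configuration (6 slices x 2 joints x 4 quadrants) has a
#' maximum of 48; the slice set, and hence the maximum, is set by the shape
#' of the `fat` array in the annotation.
#'
#' @param annotation a [sparcc_annotation()].
#' @return Integer total score.
#' @export
score_sss_fat <- function(annotation) {
  stopifnot(inherits(annotation, "sparcc_annotation"))
  sum(annotation$fat)
}

#' Maximum attainable scores for an annotation configuration
#' @param annotation a [sparcc_annotation()].
#' @return List with `bme` and `sss_fat` maxima.
#' @export
sparcc_maxima <- function(annotation) {
  d <- dim(annotation$bme)
  list(bme = d[1] * d[2] * (d[3] + 2L), sss_fat = prod(dim(annotation$fat)))
}

#' @export
print.sparcc_annotation <- function(x, ...) {
  mx <- sparcc_maxima(x)
  cat(sprintf("<sparcc_annotation> BME %d/%d, SSS fat %d/%d (%d slices x %d joints)\n",
              score_bme(x), mx$bme, score_sss_fat(x), mx$sss_fat,
              dim(x$bme)[1], dim(x$bme)[2]))
  invisible(x)
}

#' Ideal-rater annotation from ground-truth lesion masks
#'
#' Maps planted lesion masks to SPARCC quadrant calls geometrically: each
#' joint-slice ROI is split into sacral/iliac halves by the joint polyline
#' and into upper/lower halves by the normal at the polyline midpoint. A
#' quadrant is flagged iff the lesion mask intersects it; the depth flag is
#' set iff oedema extends more than `depth_threshold_mm` perpendicular from
#' the joint line; the intensity flag reproduces the ground truth's
#' CSF-intensity flag, gated on oedema presence.
#'
#' @param truth a [sij_truth()] ground-truth object.
#' @param depth_threshold_mm perpendicular depth for the bonus point
#'   (default 10).
#' @return A [sparcc_annotation()] over the truth's scored slices.
#' @export
annotate_from_truth <- function(truth, depth_threshold_mm = 10) {
  stopifnot(inherits(truth, "sij_truth"))
  sl <- truth$scored_slices
  ns <- length(sl)
  bme <- array(0L, c(ns, 2, 4))
  fat <- array(0L, c(ns, 2, 4))
  depth <- matrix(0L, ns, 2)
  inten <- matrix(0L, ns, 2)
  for (i in seq_len(ns)) {
    s <- sl[i]
    dels <- truth$delineations[[s]]
    if (is.null(dels) || length(dels) < 2L)
      stop("missing joint geometry for slice ", s)
    for (j in 1:2) {
      q_oed <- .quadrant_hits(truth$oedema_mask[s, , ], dels, j,
                              truth$pixel_spacing_mm, depth_threshold_mm)
      q_fat <- .quadrant_hits(truth$fat_mask[s, , ], dels, j,
                              truth$pixel_spacing_mm, depth_threshold_mm)
      bme[i, j, ] <- q_oed$flags
      fat[i, j, ] <- q_fat$flags
      if (any(q_oed$flags == 1L)) {
        depth[i, j] <- as.integer(q_oed$too_deep)
        inten[i, j] <- as.integer(truth$csf_intensity[s, j] > 0)
      }
    }
  }
  sparcc_annotation(bme = bme, depth = depth, intensity = inten, fat = fat)
}

# Quadrant flags for one lesion-mask plane and one joint.
# Quadrants are ordered: 1 sacral-upper, 2 sacral-lower, 3 iliac-upper,
# 4 iliac-lower. Pixels are assigned to the nearest joint, split by signed
# side of the polyline and by arc position relative to the midpoint.
.quadrant_hits <- function(plane_mask, dels, joint_idx, spacing, depth_thr) {
  flags <- integer(4)
  idx <- which(plane_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(list(flags = flags, too_deep = FALSE))
  px <- (idx[, 2] - 1) * spacing[2]
  py <- (idx[, 1] - 1) * spacing[1]
  frames <- lapply(dels, function(d) .polyline_frame(d$vertices, px, py))
  dists <- vapply(frames, function(f) f$dist, numeric(length(px)))
  dists <- matrix(dists, ncol = length(dels))
  nearest <- max.col(-dists, ties.method = "first")
  sel <- nearest == joint_idx
  if (!any(sel)) return(list(flags = flags, too_deep = FALSE))
  f <- frames[[joint_idx]]
  d <- dels[[joint_idx]]
  # medial (+x for left joint, -x for right) is the sacral side
  medial_sign <- if (d$joint == "left") +1 else -1
  sacral <- (f$side[sel] * medial_sign) >= 0
  upper <- f$t[sel] <= 0.5
  hit <- function(s, u) any(sacral == s & upper == u)
  flags[1] <- as.integer(hit(TRUE, TRUE))
  flags[2] <- as.integer(hit(TRUE, FALSE))
  flags[3] <- as.integer(hit(FALSE, TRUE))
  flags[4] <- as.integer(hit(FALSE, FALSE))
  list(flags = flags, too_deep = any(f$dist[sel] > depth_thr))
}

# For each point: unsigned perpendicular distance to the polyline, the side
# (+1 left of drawing direction / -1 right, in x-direction terms the sign of
# the offset normal's x component times ... plain signed cross), and the
# normalized arc position t in [0, 1] of the closest point.
.polyline_frame <- function(vertices, px, py) {
  v <- as.matrix(vertices)
  nseg <- nrow(v) - 1L
  npt <- length(px)
  best_d <- rep(Inf, npt)
  best_t <- numeric(npt)
  best_side <- numeric(npt)
  seg_len <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[nseg + 1L]
  for (j in seq_len(nseg)) {
    ax <- v[j, 1]; ay <- v[j, 2]
    bx <- v[j + 1L, 1]; by <- v[j + 1L, 2]
    abx <- bx - ax; aby <- by - ay
    l2 <- abx^2 + aby^2
    t <- ((px - ax) * abx + (py - ay) * aby) / l2
    tc <- pmin(pmax(t, 0), 1)
    dx <- ax + tc * abx - px
    dy <- ay + tc * aby - py
    dist <- sqrt(dx^2 + dy^2)
    upd <- dist < best_d
    if (any(upd)) {
      # cross > 0 <=> point on the same side as the +1 offset normal
      side <- sign(abx * (py - ay) - aby * (px - ax))
      best_d[upd] <- dist[upd]
      best_t[upd] <- (cum[j] + tc[upd] * seg_len[j]) / total
      best_side[upd] <- side[upd]
    }
  }
  # translate the offset-side sign into the x-direction sign of the normal
  e1 <- v[2, ] - v[1, ]
  left_normal_x <- -e1[2]
  xsign <- best_side * sign(if (left_normal_x != 0) left_normal_x else 1)
  list(dist = best_d, t = best_t, side = xsign)
}
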