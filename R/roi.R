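#' Propagate subchondral ROIs from a joint delineation
#'
#' Automatically constructs a pair of closed polygonal ROIs in the subchondral
#' bone, one on either side of the joint line, each extending `depth_mm`
#' perpendicular from the polyline. Joins between segments are mitered (miter
#' limit 2 x depth, bevelled beyond it) and the end edges run parallel to the
#' anchor lines, so the ROI shape follows the joint-cortex angle drawn by the
#' observer. The two polygons share the polyline as their common boundary and
#' do not overlap.
#'
#' Sides are labelled anatomically: for a roughly vertical joint line, the
#' sacral side is medial (towards the sacrum, i.e. towards the image midline)
#' and the iliac side lateral. The medial direction is `+x` for the left
#' joint and `-x` for the right joint.
#'
#' @param delineation a [joint_delineation()].
#' @param depth_mm perpendicular ROI depth in mm (default 10).
#' @return An object of class `subchondral_rois`: list with elements
#'   `sacral` and `iliac` (closed polygon vertex matrices), `depth_mm`,
#'   `slice`, `joint`.
#' @export
propagate_rois <- function(delineation, depth_mm = 10) {
  if (!inherits(delineation, "joint_delineation"))
    stop("'delineation' must be a joint_delineation")
  if (!is.numeric(depth_mm) || depth_mm < 0) stop("'depth_mm' must be >= 0")
  v <- delineation$vertices

  side_polygon <- function(s) {
    off <- .offset_polyline(v, depth_mm, s, delineation$anchor_start,
                            delineation$anchor_end)
    poly <- rbind(v, off[rev(seq_len(nrow(off))), , drop = FALSE])
    if (depth_mm > 0) {
      xing <- .polygon_self_crossing(poly)
      if (!is.null(xing)) {
        k <- which.min(rowSums(sweep(v, 2, xing)^2))
        stop(sprintf(
          "offset ROI self-intersects near vertex %d (joint curvature radius < depth %.3g mm)",
          k, depth_mm))
      }
    }
    poly
  }
  left_poly <- side_polygon(+1)   # left of drawing direction
  right_poly <- side_polygon(-1)

  # decide which geometric side is medial (+x for left joint, -x for right)
  e1 <- v[2, ] - v[1, ]
  left_normal_x <- -e1[2] / sqrt(sum(e1^2))
  medial_is_left_side <- if (delineation$joint == "left")
    left_normal_x > 0 else left_normal_x < 0
  sacral <- if (medial_is_left_side) left_poly else right_poly
  iliac <- if (medial_is_left_side) right_poly else left_poly

  structure(list(sacral = sacral, iliac = iliac, depth_mm = depth_mm,
                 slice = delineation$slice, joint = delineation$joint),
            class = "subchondral_rois")
}

#' @export
print.subchondral_rois <- function(x, ...) {
  cat(sprintf(
    "<subchondral_rois> %s joint, slice %d, depth %.1f mm, areas %.0f / %.0f mm^2 (sacral/iliac)\n",
    x$joint, x$slice, x$depth_mm, polygon_area(x$sacral), polygon_area(x$iliac)))
  invisible(x)
}

#' Select map slices for histographic analysis
#'
#' ADC maps use every slice in which the synovial joint is visible; PDFF maps
#' (acquired at much thinner slices) use alternate slices, starting at the
#' first synovial slice.
#'
#' @param kind `"ADC"` or `"PDFF"`.
#' @param n_slices total number of slices in the volume.
#' @param synovial_slice_range integer `(first, last)` synovial slice.
#' @return Integer vector of 1-based slice indices.
#' @export
select_slices <- function(kind = c("ADC", "PDFF"), n_slices,
                          synovial_slice_range) {
  kind <- match.arg(kind)
  r <- as.integer(synovial_slice_range)
  if (length(r) != 2L || r[1] > r[2]) stop("empty synovial slice range")
  if (r[1] < 1L || r[2] > n_slices)
    stop("synovial slice range outside the volume")
  if (kind == "ADC") seq(r[1], r[2]) else seq(r[1], r[2], by = 2L)
}

#' Pool subchondral pixel values across ROIs and slices
#'
#' Collects map pixel values from every ROI polygon (both joints, both sides
#' of each joint) over the included slices into one flat sample for
#' histographic analysis. Where the rasterized sacral and iliac masks of a
#' joint touch (a pixel centre exactly on the shared polyline), the pixel is
#' counted once, on the sacral side.
#'
#' @param map a [quant_map()].
#' @param roi_sets list of [propagate_rois()] results (any slices/joints).
#' @param slice_indices slices to include, e.g. from [select_slices()].
#' @return An object of class `pixel_sample`: list with `values`, `n_pixels`,
#'   `kind`.
#' @export
pool_pixels <- function(map, roi_sets, slice_indices) {
  stopifnot(inherits(map, "quant_map"))
  slice_of <- vapply(roi_sets, function(r) r$slice, integer(1))
  missing <- setdiff(slice_indices, slice_of)
  if (length(missing))
    stop("no ROI available for included slice(s): ",
         paste(missing, collapse = ", "))
  gs <- dim(map$values)[2:3]
  vals <- list()
  for (s in slice_indices) {
    plane <- map$values[s, , ]
    for (roi in roi_sets[slice_of == s]) {
      m_sac <- rasterize_polygon(roi$sacral, gs, map$pixel_spacing_mm)
      m_ili <- rasterize_polygon(roi$iliac, gs, map$pixel_spacing_mm)
      m_ili[m_sac] <- FALSE
      vals[[length(vals) + 1L]] <- plane[m_sac]
      vals[[length(vals) + 1L]] <- plane[m_ili]
    }
  }
  v <- unlist(vals, use.names = FALSE)
  if (is.null(v)) v <- numeric(0)
  structure(list(values = v, n_pixels = length(v), kind = map$kind),
            class = "pixel_sample")
}

#' Construct a pixel sample directly from values
#' @param values numeric vector of pooled pixel values.
#' @param kind `"ADC"` or `"PDFF"`.
#' @return A `pixel_sample` object.
#' @export
pixel_sample <- function(values, kind = c("ADC", "PDFF")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  structure(list(values = values, n_pixels = length(values), kind = kind),
            class = "pixel_sample")
}

#' @export
print.pixel_sample <- function(x, ...) {
  cat(sprintf("<pixel_sample> %s, %d pixels, median %.4g\n",
              x$kind, x$n_pixels,
              if (x$n_pixels) stats::median(x$values) else NA_real_))
  invisible(x)
}
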