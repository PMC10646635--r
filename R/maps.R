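#' Quantitative parameter map volume
#'
#' A 3-D quantitative MRI parameter map: ADC (units 1e-6 mm^2/s) or proton
#' density fat fraction (percent), with pixel geometry. Values are stored as a
#' `(slice, row, col)` array.
#'
#' @param values 3-D numeric array `(slice, row, col)`.
#' @param kind `"ADC"` or `"PDFF"`.
#' @param pixel_spacing_mm numeric `(row, col)` in-plane spacing, mm.
#' @param slice_thickness_mm slice thickness, mm.
#' @return An object of class `quant_map`.
#' @export
quant_map <- function(values, kind = c("ADC", "PDFF"),
                      pixel_spacing_mm = c(1, 1), slice_thickness_mm = 1) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) stop("'values' must be a 3-D array")
  sp <- rep(as.numeric(pixel_spacing_mm), length.out = 2L)
  if (any(sp <= 0) || slice_thickness_mm <= 0) stop("spacing must be positive")
  if (kind == "PDFF" && (min(values) < 0 || max(values) > 100))
    stop("PDFF values must lie in [0, 100]")
  if (kind == "ADC" && min(values) < 0) stop("ADC values must be >= 0")
  structure(list(values = values, kind = kind, pixel_spacing_mm = sp,
                 slice_thickness_mm = as.numeric(slice_thickness_mm)),
            class = "quant_map")
}

#' @export
print.quant_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<quant_map> %s, %d slices of %d x %d px (%.2f x %.2f mm, thickness %.1f mm)\n",
              x$kind, d[1], d[2], d[3], x$pixel_spacing_mm[1],
              x$pixel_spacing_mm[2], x$slice_thickness_mm))
  invisible(x)
}

#' Write a quantitative map as NIfTI
#'
#' @param map a [quant_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "quant_map"))
  # NIfTI stores x (col) fastest: reorder (slice,row,col) -> (col,row,slice)
  arr <- aperm(map$values, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(map$pixel_spacing_mm[2], map$pixel_spacing_mm[1],
                           map$slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a quantitative map from NIfTI
#'
#' @param path NIfTI file written by [write_map_nifti()].
#' @param kind `"ADC"` or `"PDFF"`.
#' @return A [quant_map()].
#' @export
read_map_nifti <- function(path, kind = c("ADC", "PDFF")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3, 2, 1))
  quant_map(arr, kind = kind, pixel_spacing_mm = c(pd[2], pd[1]),
            slice_thickness_mm = pd[3])
}

#' Write joint delineations as JSON
#'
#' One record per delineation: slice, joint, vertex list and the two anchor
#' segments, all in mm coordinates.
#'
#' @param delineations list of [joint_delineation()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_delineations_json <- function(delineations, path) {
  recs <- lapply(delineations, function(d) list(
    slice = d$slice, joint = d$joint,
    vertices = unname(apply(d$vertices, 1, as.numeric, simplify = FALSE)),
    anchor_start = unname(apply(d$anchor_start, 1, as.numeric, simplify = FALSE)),
    anchor_end = unname(apply(d$anchor_end, 1, as.numeric, simplify = FALSE))))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read joint delineations from JSON
#' @param path JSON file written by [write_delineations_json()].
#' @return List of [joint_delineation()] objects.
#' @export
read_delineations_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) joint_delineation(
    vertices = do.call(rbind, lapply(r$vertices, unlist)),
    anchor_start = do.call(rbind, lapply(r$anchor_start, unlist)),
    anchor_end = do.call(rbind, lapply(r$anchor_end, unlist)),
    slice = r$slice, joint = r$joint))
}
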