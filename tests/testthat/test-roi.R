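test_that("straight vertical joint with perpendicular anchors gives exact rectangles", {
  d <- joint_delineation(cbind(c(30, 30), c(10, 50)), slice = 1, joint = "left")
  r <- propagate_rois(d, depth_mm = 10)
  expect_equal(polygon_area(r$sacral), 400)   # 40 mm x 10 mm
  expect_equal(polygon_area(r$iliac), 400)
  # sacral side of the left joint is medial (+x)
  expect_gt(mean(r$sacral[, 1]), 30)
  expect_lt(mean(r$iliac[, 1]), 30)
})

test_that("depth 0 gives degenerate zero-area polygons and depth is monotone", {
  d <- joint_delineation(cbind(c(30, 32, 30), c(10, 30, 50)))
  r0 <- propagate_rois(d, depth_mm = 0)
  expect_equal(polygon_area(r0$sacral), 0)
  expect_equal(polygon_area(r0$iliac), 0)
  areas <- vapply(c(2, 5, 8, 12), function(dep) {
    r <- propagate_rois(d, dep)
    polygon_area(r$sacral) + polygon_area(r$iliac)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  # n_pixels is non-decreasing in depth too
  gs <- c(80, 80); sp <- c(1.5, 1.5)
  np <- vapply(c(2, 5, 8, 12), function(dep) {
    r <- propagate_rois(d, dep)
    sum(rasterize_polygon(r$sacral, gs, sp)) +
      sum(rasterize_polygon(r$iliac, gs, sp))
  }, numeric(1))
  expect_true(all(diff(np) >= 0))
})

test_that("offset strip area for a bent polyline matches the mitre closed form and a grid oracle", {
  # one 45-degree bend: vertical 30 mm then 30 mm at 45 degrees
  v <- rbind(c(50, 20), c(50, 50), c(50 + 30 / sqrt(2), 50 + 30 / sqrt(2)))
  d <- joint_delineation(v)
  r <- propagate_rois(d, depth_mm = 10)
  len <- polyline_length(v)
  theta <- pi / 4                      # exterior turn angle
  correction <- 10^2 * tan(theta / 2)  # mitre adds on one side, removes on other
  expect_equal(polygon_area(r$sacral) + polygon_area(r$iliac), 2 * len * 10,
               tolerance = 1e-9)
  a_outer <- max(polygon_area(r$sacral), polygon_area(r$iliac))
  expect_equal(a_outer, len * 10 + correction, tolerance = 1e-9)
  # brute-force fine-grid classification of the outer polygon
  outer_poly <- if (polygon_area(r$sacral) > polygon_area(r$iliac))
    r$sacral else r$iliac
  h <- 0.04
  gx <- seq(min(outer_poly[, 1]) - 1, max(outer_poly[, 1]) + 1, by = h)
  gy <- seq(min(outer_poly[, 2]) - 1, max(outer_poly[, 2]) + 1, by = h)
  g <- expand.grid(x = gx, y = gy)
  inside <- pracma::inpolygon(g$x, g$y, outer_poly[, 1], outer_poly[, 2])
  expect_lt(abs(sum(inside) * h^2 - a_outer) / a_outer, 0.005)
})

test_that("anchor lines tilt the ROI end edges", {
  v <- cbind(c(30, 30), c(10, 50))
  a1 <- rbind(c(30, 10) - c(cos(pi / 3), sin(pi / 3)),
              c(30, 10) + c(cos(pi / 3), sin(pi / 3)))
  d <- joint_delineation(v, anchor_start = a1)
  r <- propagate_rois(d, 10)
  # end edge no longer perpendicular: areas change from the rectangle by the
  # anchor-tilt triangle (legs depth and depth * tan(tilt)), total conserved
  tri <- 0.5 * 10^2 * tan(pi / 3)
  expect_equal(polygon_area(r$sacral) + polygon_area(r$iliac), 800,
               tolerance = 1e-9)
  expect_equal(abs(polygon_area(r$sacral) - 400), tri, tolerance = 1e-9)
})

test_that("offsetting a polyline curving tighter than the depth is an error naming a vertex", {
  # hairpin: curvature radius ~2 mm << depth 10 mm
  v <- rbind(c(30, 10), c(30, 30), c(32, 32), c(34, 30), c(34, 10))
  d <- joint_delineation(v)
  expect_error(propagate_rois(d, depth_mm = 10), "vertex")
})

test_that("rasterization counts a 10x10 mm square at 1 mm spacing as 100 pixels (boundary inclusive)", {
  sq <- rbind(c(2, 2), c(11, 2), c(11, 11), c(2, 11))
  m <- rasterize_polygon(sq, c(20, 20), c(1, 1))
  expect_equal(sum(m), 100)            # centres on the edge count as inside
  expect_true(m[3, 3] && m[12, 12])
  expect_false(m[1, 1])
})

test_that("degenerate and out-of-grid polygons rasterize to empty masks", {
  expect_equal(sum(rasterize_polygon(matrix(numeric(0), 0, 2), c(10, 10),
                                     c(1, 1))), 0)
  expect_warning(
    m <- rasterize_polygon(rbind(c(50, 50), c(60, 50), c(55, 60)),
                           c(10, 10), c(1, 1)),
    "outside")
  expect_equal(sum(m), 0)
})

test_that("rasterized masks equal the exhaustive point-in-polygon oracle on random ROIs", {
  set.seed(42)
  gs <- c(80, 80); sp <- c(1.5, 1.5)
  for (i in 1:25) {
    d <- random_delineation()
    r <- propagate_rois(d, depth_mm = 10)
    for (side in c("sacral", "iliac")) {
      expect_identical(rasterize_polygon(r[[side]], gs, sp),
                       oracle_mask(r[[side]], gs, sp))
    }
  }
})

test_that("slice selection uses all synovial slices for ADC and alternate slices for PDFF", {
  expect_equal(select_slices("ADC", 12, c(3, 12)), 3:12)
  expect_equal(select_slices("PDFF", 12, c(3, 12)), c(3, 5, 7, 9, 11))
  expect_equal(select_slices("ADC", 12, c(5, 5)), 5)
  expect_equal(select_slices("PDFF", 12, c(5, 5)), 5)
  expect_error(select_slices("ADC", 12, c(8, 3)), "empty")
  expect_error(select_slices("ADC", 4, c(1, 6)), "outside")
})

test_that("pixel pooling concatenates masked values across slices, joints and sides", {
  vol <- array(7, c(3, 80, 80))
  map <- quant_map(vol, "ADC", c(1.5, 1.5), 3)
  dl <- joint_delineation(cbind(c(30, 30), c(15, 55)), slice = 1, joint = "left")
  dr <- joint_delineation(cbind(c(90, 90), c(15, 55)), slice = 1, joint = "right")
  rois <- list(propagate_rois(dl, 10), propagate_rois(dr, 10))
  s <- pool_pixels(map, rois, 1L)
  expect_true(all(s$values == 7))
  # shared-boundary pixels (centres exactly on the joint line) count once
  n_expect <- sum(vapply(rois, function(r) {
    m1 <- rasterize_polygon(r$sacral, c(80, 80), c(1.5, 1.5))
    m2 <- rasterize_polygon(r$iliac, c(80, 80), c(1.5, 1.5))
    m2[m1] <- FALSE
    sum(m1) + sum(m2)
  }, numeric(1)))
  expect_equal(s$n_pixels, n_expect)
  expect_error(pool_pixels(map, rois, c(1L, 2L)), "slice")
})

test_that("pooled multiset equals brute-force per-pixel collection over oracle masks", {
  set.seed(9)
  vol <- array(rnorm(3 * 80 * 80, 100, 10), c(3, 80, 80))
  vol[vol < 0] <- 0
  map <- quant_map(vol, "ADC", c(1.5, 1.5), 3)
  rois <- lapply(1:3, function(s) {
    d <- random_delineation()
    d$slice <- as.integer(s)
    propagate_rois(d, 10)
  })
  s <- pool_pixels(map, rois, 1:3)
  brute <- unlist(lapply(1:3, function(sl) {
    m1 <- oracle_mask(rois[[sl]]$sacral, c(80, 80), c(1.5, 1.5))
    m2 <- oracle_mask(rois[[sl]]$iliac, c(80, 80), c(1.5, 1.5))
    m2[m1] <- FALSE
    c(vol[sl, , ][m1], vol[sl, , ][m2])
  }))
  expect_equal(sort(s$values), sort(brute))
})

test_that("translating delineation and grid together leaves the pixel count unchanged", {
  set.seed(5)
  d <- random_delineation()
  r <- propagate_rois(d, 10)
  sp <- c(1.5, 1.5)
  n0 <- sum(rasterize_polygon(r$sacral, c(80, 80), sp))
  shift <- c(4 * sp[2], 6 * sp[1])    # whole-pixel shift
  v2 <- sweep(d$vertices, 2, shift, "+")
  d2 <- joint_delineation(v2,
                          sweep(d$anchor_start, 2, shift, "+"),
                          sweep(d$anchor_end, 2, shift, "+"),
                          slice = d$slice, joint = d$joint)
  r2 <- propagate_rois(d2, 10)
  n2 <- sum(rasterize_polygon(r2$sacral, c(90, 90), sp))
  expect_equal(n2, n0)
})

test_that("delineations survive a JSON round trip", {
  set.seed(3)
  dels <- list(random_delineation("left"), random_delineation("right"))
  path <- tempfile(fileext = ".json")
  write_delineations_json(dels, path)
  back <- read_delineations_json(path)
  expect_equal(back[[1]]$vertices, dels[[1]]$vertices)
  expect_equal(back[[2]]$anchor_end, dels[[2]]$anchor_end)
  expect_equal(back[[2]]$joint, "right")
})

test_that("quantitative maps survive a NIfTI round trip", {
  vol <- array(runif(2 * 10 * 12, 0, 100), c(2, 10, 12))
  map <- quant_map(vol, "PDFF", c(1.5, 1.75), 3)
  path <- tempfile(fileext = ".nii.gz")
  write_map_nifti(map, path)
  back <- read_map_nifti(path, "PDFF")
  expect_equal(back$values, map$values, tolerance = 1e-6)
  expect_equal(back$pixel_spacing_mm, map$pixel_spacing_mm, tolerance = 1e-6)
})
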