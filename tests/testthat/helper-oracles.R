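# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and where possible the library
# calls) used inside the package.

# linear-interpolation empirical quantile, coded from the order statistics
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, numeric(1))
}

oracle_paired_t <- function(pre, post) {
  d <- pre - post
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  se <- s / sqrt(n)
  t <- m / se
  crit <- stats::qt(0.975, n - 1)
  list(t_stat = t, df = n - 1,
       p_value = 2 * stats::pt(-abs(t), n - 1),
       ci_low = m - crit * se, ci_high = m + crit * se,
       mean_change = m, sd_change = s)
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_bland_altman <- function(r1, r2) {
  d <- r1 - r2
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

# ICC(2,1) through R's own two-way ANOVA decomposition
oracle_icc_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# exhaustive point-in-polygon mask over all pixel centers (pracma backend)
oracle_mask <- function(polygon, grid_shape, spacing) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  ctr <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  px <- (ctr$c - 1) * spacing[2]
  py <- (ctr$r - 1) * spacing[1]
  inside <- pracma::inpolygon(px, py, polygon[, 1], polygon[, 2],
                              boundary = TRUE)
  mask <- matrix(FALSE, rows, cols)
  mask[cbind(ctr$r, ctr$c)] <- inside
  mask
}

# random but well-behaved joint delineation inside an 80x80 grid at 1.5 mm
random_delineation <- function(joint = "left") {
  nv <- sample(3:6, 1)
  x0 <- stats::runif(1, 25, 85)
  y <- seq(stats::runif(1, 15, 25), stats::runif(1, 75, 95),
           length.out = nv)
  x <- x0 + cumsum(c(0, stats::runif(nv - 1, -3, 3)))
  v <- cbind(x, y)
  tilt <- stats::runif(2, -0.3, 0.3)
  a1 <- beachsij:::.tilted_anchor(v, "start", tilt[1])
  a2 <- beachsij:::.tilted_anchor(v, "end", tilt[2])
  joint_delineation(v, a1, a2, slice = 1L, joint = joint)
}

full_sparcc_annotation <- function() {
  sparcc_annotation(bme = array(1L, c(6, 2, 4)),
                    depth = matrix(1L, 6, 2),
                    intensity = matrix(1L, 6, 2),
                    fat = array(1L, c(6, 2, 4)))
}

# one-joint truth with a hand-placed spherical oedema lesion; joint line is
# vertical at x = x_joint, second joint far right so assignment is unambiguous
manual_truth <- function(lesion_center, lesion_radius_mm,
                         grid_shape = c(80, 80), spacing = c(1.5, 1.5),
                         n_slices = 6, x_joint = 36, csf = 0L,
                         kind = "oedema", thickness = 6) {
  fov_h <- (grid_shape[1] - 1) * spacing[1]
  mk <- function(x, joint) {
    v <- cbind(rep(x, 4), seq(0.15 * fov_h, 0.85 * fov_h, length.out = 4))
    joint_delineation(v, slice = 1L, joint = joint)
  }
  dels <- lapply(seq_len(n_slices), function(s) {
    list(mk(x_joint, "left"), mk(90, "right"))
  })
  px <- outer(rep(1, grid_shape[1]), (seq_len(grid_shape[2]) - 1) * spacing[2])
  py <- outer((seq_len(grid_shape[1]) - 1) * spacing[1], rep(1, grid_shape[2]))
  mask <- array(FALSE, c(n_slices, grid_shape))
  for (s in seq_len(n_slices)) {
    dz <- (s - lesion_center[1]) * thickness
    d2 <- (px - lesion_center[2])^2 + (py - lesion_center[3])^2 + dz^2
    mask[s, , ] <- d2 < lesion_radius_mm^2
  }
  empty <- array(FALSE, c(n_slices, grid_shape))
  csf_m <- matrix(0L, n_slices, 2)
  if (csf) csf_m[, 1] <- 1L
  sij_truth(delineations = dels,
            oedema_mask = if (kind == "oedema") mask else empty,
            fat_mask = if (kind == "fat") mask else empty,
            csf_intensity = csf_m,
            pixel_spacing_mm = spacing, slice_thickness_mm = thickness)
}
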