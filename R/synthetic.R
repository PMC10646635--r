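#' Configuration for the synthetic sacroiliac-joint generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort and
#' volume geometry, baseline marrow ADC/PDFF distributions, planted oedema
#' and fat-metaplasia lesions, the pre/post treatment effect on oedema, the
#' noise of the two delineating readers and of the visual raters, and the
#' paired clinical score distributions.
#'
#' Defaults reproduce the magnitudes of a typical biologic-therapy cohort:
#' baseline marrow ADC around 195 (1e-6 mm^2/s), PDFF around 57%, oedema
#' raising ADC and lowering PDFF, fat metaplasia raising PDFF, and spinal
#' VAS improving by mean 2.14 (SD 2.52) with analogous changes for BASDAI,
#' ASDAS and CRP.
#'
#' @param n_patients number of patients (default 30).
#' @param n_slices slices per volume (default 6).
#' @param grid_shape pixels `(rows, cols)` (default 80 x 80).
#' @param pixel_spacing_mm in-plane spacing `(row, col)` mm (default 1.5).
#' @param slice_thickness_mm slice thickness mm (default 3).
#' @param adc_marrow_mean,adc_marrow_sd baseline marrow ADC distribution
#'   (1e-6 mm^2/s).
#' @param pdff_marrow_mean,pdff_marrow_sd baseline marrow PDFF (%).
#' @param oedema_adc_shift peak ADC offset of an oedema lesion (> 0).
#' @param oedema_pdff_shift peak PDFF offset of an oedema lesion (< 0).
#' @param fat_lesion_pdff_shift peak PDFF offset of a fat lesion (> 0).
#' @param lesion_count_range integer `(min, max)` oedema lesions per joint.
#' @param fat_lesion_count_range integer `(min, max)` fat lesions per joint.
#' @param lesion_radius_range_mm lesion radius range, mm.
#' @param lesion_max_depth_mm lesions are confined to this perpendicular
#'   distance from the joint line (anatomic subchondral bone; default 15,
#'   deeper than the 10 mm sampling ROI so the SPARCC depth bonus can occur).
#' @param treatment_effect fraction in `[0, 1]` by which oedema lesion
#'   intensity and radius shrink post treatment (fat lesions unchanged).
#' @param reader_jitter_sd_mm SD of the isotropic vertex jitter of a
#'   simulated delineating reader.
#' @param rater_sensitivity,rater_specificity per-quadrant probabilities of
#'   the simulated visual rater.
#' @param clinical_effects `data.frame` with columns `score`,
#'   `baseline_mean`, `baseline_sd`, `change_mean`, `change_sd`, `lower`,
#'   `upper`; one row per clinical score.
#' @param imaging_clinical_correlation correlation between the standardized
#'   imaging oedema-burden change and clinical change scores (default 0:
#'   independent, matching cohorts where imaging and clinical change do not
#'   correlate).
#' @param synovial_slice_range slices in which the synovial joint is visible
#'   (default: all slices).
#' @param seed global integer seed; per-patient/per-role substreams are
#'   derived from it by fixed offsets.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 30L, n_slices = 6L,
                         grid_shape = c(80L, 80L),
                         pixel_spacing_mm = c(1.5, 1.5),
                         slice_thickness_mm = 3,
                         adc_marrow_mean = 195, adc_marrow_sd = 60,
                         pdff_marrow_mean = 57, pdff_marrow_sd = 10,
                         oedema_adc_shift = 300, oedema_pdff_shift = -30,
                         fat_lesion_pdff_shift = 25,
                         lesion_count_range = c(0L, 3L),
                         fat_lesion_count_range = c(0L, 2L),
                         lesion_radius_range_mm = c(3, 8),
                         lesion_max_depth_mm = 15,
                         treatment_effect = 0.5,
                         reader_jitter_sd_mm = 1,
                         rater_sensitivity = 0.9,
                         rater_specificity = 0.95,
                         clinical_effects = default_clinical_effects(),
                         imaging_clinical_correlation = 0,
                         synovial_slice_range = NULL,
                         seed = 1L) {
  if (is.null(synovial_slice_range)) synovial_slice_range <- c(1L, n_slices)
  cfg <- list(n_patients = as.integer(n_patients),
              n_slices = as.integer(n_slices),
              grid_shape = as.integer(grid_shape),
              pixel_spacing_mm = rep(as.numeric(pixel_spacing_mm),
                                     length.out = 2L),
              slice_thickness_mm = as.numeric(slice_thickness_mm),
              adc_marrow_mean = adc_marrow_mean,
              adc_marrow_sd = adc_marrow_sd,
              pdff_marrow_mean = pdff_marrow_mean,
              pdff_marrow_sd = pdff_marrow_sd,
              oedema_adc_shift = oedema_adc_shift,
              oedema_pdff_shift = oedema_pdff_shift,
              fat_lesion_pdff_shift = fat_lesion_pdff_shift,
              lesion_count_range = as.integer(lesion_count_range),
              fat_lesion_count_range = as.integer(fat_lesion_count_range),
              lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
              lesion_max_depth_mm = as.numeric(lesion_max_depth_mm),
              treatment_effect = treatment_effect,
              reader_jitter_sd_mm = reader_jitter_sd_mm,
              rater_sensitivity = rater_sensitivity,
              rater_specificity = rater_specificity,
              clinical_effects = clinical_effects,
              imaging_clinical_correlation = imaging_clinical_correlation,
              synovial_slice_range = as.integer(synovial_slice_range),
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "synth_config")
}

.validate_config <- function(cfg) {
  sds <- c(cfg$adc_marrow_sd, cfg$pdff_marrow_sd, cfg$reader_jitter_sd_mm,
           cfg$clinical_effects$baseline_sd, cfg$clinical_effects$change_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  pr <- c(cfg$rater_sensitivity, cfg$rater_specificity)
  if (any(pr < 0 | pr > 1)) stop("rater probabilities must lie in [0, 1]")
  if (cfg$treatment_effect < 0 || cfg$treatment_effect > 1)
    stop("'treatment_effect' must lie in [0, 1]")
  if (abs(cfg$imaging_clinical_correlation) > 1)
    stop("'imaging_clinical_correlation' must lie in [-1, 1]")
  if (cfg$n_patients < 1L || cfg$n_slices < 1L)
    stop("need at least one patient and one slice")
  if (diff(cfg$lesion_count_range) < 0 || min(cfg$lesion_count_range) < 0)
    stop("invalid lesion_count_range")
  fov <- (cfg$grid_shape - 1L) * cfg$pixel_spacing_mm
  # both joints plus 10 mm subchondral margins must fit in-plane
  if (any(fov < 60))
    stop("configuration error: grid too small to contain both joints plus 10 mm margins")
  r <- cfg$synovial_slice_range
  if (r[1] < 1L || r[2] > cfg$n_slices || r[1] > r[2])
    stop("invalid synovial_slice_range")
  invisible(cfg)
}

#' Default clinical score change structure
#'
#' Baseline and change distributions per clinical score (spinal VAS change
#' mean 2.14, SD 2.52, and analogous BASDAI/ASDAS/CRP/ESR magnitudes), with
#' each score's valid range. Baselines are drawn from a truncated normal and
#' post = pre - change is clamped to the valid range.
#'
#' @return `data.frame` with columns `score`, `baseline_mean`,
#'   `baseline_sd`, `change_mean`, `change_sd`, `lower`, `upper`.
#' @export
default_clinical_effects <- function() {
  data.frame(
    score = c("basdai", "spinal_vas", "asdas_crp", "asdas_esr", "crp", "esr"),
    baseline_mean = c(6.88, 6.90, 3.32, 3.19, 5.35, 15),
    baseline_sd = c(1.0, 1.0, 0.6, 0.6, 3.0, 8),
    change_mean = c(1.97, 2.14, 0.92, 0.90, 3.36, 4),
    change_sd = c(2.50, 2.52, 1.06, 0.91, 7.44, 10),
    lower = c(0, 0, 0, 0, 0, 0),
    upper = c(10, 10, Inf, Inf, Inf, Inf),
    stringsAsFactors = FALSE)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d patients, %d slices of %d x %d px, seed %d\n",
              x$n_patients, x$n_slices, x$grid_shape[1], x$grid_shape[2],
              x$seed))
  cat(sprintf("  marrow ADC %g (SD %g), PDFF %g%% (SD %g); treatment effect %.2f\n",
              x$adc_marrow_mean, x$adc_marrow_sd, x$pdff_marrow_mean,
              x$pdff_marrow_sd, x$treatment_effect))
  invisible(x)
}

# fixed-offset substreams: reproducible per patient and role
.substream <- function(seed, patient, role) {
  (as.integer(seed) + 7919L * as.integer(patient) + 101L * as.integer(role)) %%
    2147483587L
}
.ROLE <- c(geometry = 1L, noise_pre = 2L, noise_post = 3L, clinical = 4L,
           reader = 10L, rater = 20L)

#' Ground truth for one synthetic patient-timepoint
#'
#' Container for the true joint geometry and planted lesions underlying a
#' synthetic volume: per-slice true delineations for both joints, 3-D oedema
#' and fat lesion masks, per-joint-slice CSF-intensity flags, the slice sets
#' used for SPARCC scoring and synovial coverage, and the grid geometry.
#'
#' @param delineations list (length `n_slices`) of lists of two
#'   [joint_delineation()] (left, right).
#' @param oedema_mask,fat_mask logical arrays `(slice, row, col)`.
#' @param csf_intensity 0/1 matrix `(slice, joint)`: a CSF-intense oedema
#'   lesion touches this joint-slice.
#' @param scored_slices slices scored by SPARCC (6 consecutive).
#' @param synovial_slices slices where the synovial joint is visible.
#' @param pixel_spacing_mm,slice_thickness_mm grid geometry.
#' @return An object of class `sij_truth`.
#' @export
sij_truth <- function(delineations, oedema_mask, fat_mask,
                      csf_intensity = NULL, scored_slices = NULL,
                      synovial_slices = NULL,
                      pixel_spacing_mm = c(1.5, 1.5),
                      slice_thickness_mm = 3) {
  d <- dim(oedema_mask)
  if (!all(dim(fat_mask) == d)) stop("mask dimensions differ")
  ns <- d[1]
  if (is.null(csf_intensity)) csf_intensity <- matrix(0L, ns, 2)
  if (is.null(scored_slices))
    scored_slices <- if (ns >= 6) seq_len(6L) else seq_len(ns)
  if (is.null(synovial_slices)) synovial_slices <- seq_len(ns)
  structure(list(delineations = delineations,
                 oedema_mask = oedema_mask, fat_mask = fat_mask,
                 csf_intensity = csf_intensity,
                 scored_slices = as.integer(scored_slices),
                 synovial_slices = as.integer(synovial_slices),
                 grid_shape = d[2:3],
                 pixel_spacing_mm = rep(as.numeric(pixel_spacing_mm),
                                        length.out = 2L),
                 slice_thickness_mm = slice_thickness_mm),
            class = "sij_truth")
}

# ---- internal generator pieces ------------------------------------------

# gently curved, roughly vertical open polyline for one joint
.draw_joint_polyline <- function(base_x, fov_h, n_vertices = 5L) {
  y <- seq(0.2 * fov_h, 0.8 * fov_h, length.out = n_vertices)
  bow <- stats::runif(1, 2, 5) * sample(c(-1, 1), 1)
  t <- seq(0, 1, length.out = n_vertices)
  x <- base_x + bow * sin(pi * t) + stats::runif(n_vertices, -0.8, 0.8)
  cbind(x, y)
}

# anchor: perpendicular to the terminal edge, rotated by a random tilt
.tilted_anchor <- function(vertices, at, tilt_rad) {
  a <- .perp_anchor(vertices, at)
  p <- if (at == "start") vertices[1, ] else vertices[nrow(vertices), ]
  .rotate_segment(a, p, tilt_rad)
}

.rotate_segment <- function(seg, centre, theta) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t(apply(seg, 1, function(q) centre + rot %*% (q - centre)))
}

# rejection-sampled normal field within (lo, hi): keeps lesion offsets
# strictly monotone after physical-bound saturation
.trunc_noise <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

# inverse-CDF truncated normal draw; exact even for far-tail windows
.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(stats::runif(1, p_lo, p_hi), mean, sd)
  if (!is.finite(x))  # window numerically collapsed in a far tail
    x <- if (is.finite(lo) && lo > mean) lo else hi
  min(max(x, lo), hi)
}

.sample_count <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1)
}

# lesion table for one patient (positions fixed across timepoints)
.draw_lesions <- function(cfg, dels_base) {
  les <- list()
  for (j in 1:2) {
    v <- dels_base[[j]]$vertices
    n_oed <- .sample_count(cfg$lesion_count_range)
    n_fat <- .sample_count(cfg$fat_lesion_count_range)
    kinds <- c(rep("oedema", n_oed), rep("fat", n_fat))
    for (kind in kinds) {
      t_arc <- stats::runif(1, 0.1, 0.9)
      side <- sample(c(-1, 1), 1)
      perp <- stats::runif(1, 0, 0.6 * cfg$lesion_max_depth_mm)
      r <- stats::runif(1, cfg$lesion_radius_range_mm[1],
                        cfg$lesion_radius_range_mm[2])
      a <- stats::runif(1, 0.6, 1.2)
      z <- stats::runif(1, 1, cfg$n_slices)
      ctr <- .point_on_polyline(v, t_arc, side * perp)
      les[[length(les) + 1L]] <- list(kind = kind, joint = j, x = ctr[1],
                                      y = ctr[2], z = z, r = r, a = a)
    }
  }
  les
}

.point_on_polyline <- function(v, t_arc, offset) {
  seg <- diff(v)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s <- t_arc * cum[length(cum)]
  j <- min(max(findInterval(s, cum), 1L), nrow(seg))
  u <- seg[j, ] / len[j]
  nrm <- c(-u[2], u[1])
  p <- v[j, ] + (s - cum[j]) * u
  p + offset * nrm
}

# saturating (max-combined) lesion profile fields for one timepoint
# returns list(oedema = array, fat = array, csf = matrix)
.lesion_fields <- function(cfg, lesions, band, px, py, attenuate) {
  d <- c(cfg$n_slices, cfg$grid_shape)
  oed <- array(0, d); fat <- array(0, d)
  csf <- matrix(0L, cfg$n_slices, 2)
  for (l in lesions) {
    r_eff <- if (l$kind == "oedema") l$r * (1 - attenuate) else l$r
    a_eff <- if (l$kind == "oedema") l$a * (1 - attenuate) else l$a
    if (r_eff <= 0 || a_eff <= 0) next
    for (s in seq_len(cfg$n_slices)) {
      dz <- (s - l$z) * cfg$slice_thickness_mm
      if (abs(dz) >= r_eff) next
      d2 <- (px - l$x)^2 + (py - l$y)^2 + dz^2
      prof <- a_eff * pmax(0, 1 - d2 / r_eff^2) * band[s, , ]
      if (l$kind == "oedema") {
        oed[s, , ] <- pmax(oed[s, , ], prof)
        if (a_eff >= 1 && any(prof > 0)) csf[s, l$joint] <- 1L
      } else {
        fat[s, , ] <- pmax(fat[s, , ], prof)
      }
    }
  }
  list(oedema = oed, fat = fat, csf = csf)
}

# subchondral band mask (perpendicular distance to either joint line <=
# lesion_max_depth_mm), per slice
.band_mask <- function(cfg, dels_by_slice, px, py) {
  d <- c(cfg$n_slices, cfg$grid_shape)
  band <- array(FALSE, d)
  for (s in seq_len(cfg$n_slices)) {
    dmin <- rep(Inf, length(px))
    for (j in 1:2) {
      f <- .polyline_frame(dels_by_slice[[s]][[j]]$vertices,
                           as.vector(px), as.vector(py))
      dmin <- pmin(dmin, f$dist)
    }
    band[s, , ] <- matrix(dmin <= cfg$lesion_max_depth_mm, cfg$grid_shape[1],
                          cfg$grid_shape[2])
  }
  band
}

# ---- public generator ----------------------------------------------------

#' Generate a synthetic sacroiliac-joint cohort
#'
#' For each patient: true joint delineations for both joints on every slice,
#' planted oedema and fat-metaplasia lesions, pre- and post-treatment ADC
#' and PDFF volumes (oedema attenuated multiplicatively post treatment; fat
#' lesions unchanged), ground-truth quadrant tables, and paired clinical
#' visits whose change scores follow the configured mean/SD.
#'
#' Fully deterministic for a fixed `config$seed`; any single patient is
#' reproducible on their own through fixed per-patient substreams.
#'
#' @param config a [synth_config()].
#' @param components which parts to generate: subset of
#'   `c("imaging", "clinical")`. Dropping `"imaging"` skips volumes and
#'   lesions (fast, for clinical-statistics simulation).
#' @return An object of class `beach_cohort`: list with `patients` (each a
#'   list `id`, `maps` (`pre`/`post`, each `ADC`/`PDFF` [quant_map()]),
#'   `truth` (`pre`/`post` [sij_truth()]), `clinical` (`data.frame`, two
#'   rows)) and `config`.
#' @export
generate_cohort <- function(config, components = c("imaging", "clinical")) {
  stopifnot(inherits(config, "synth_config"))
  components <- match.arg(components, several.ok = TRUE)
  if (config$imaging_clinical_correlation != 0 &&
      !("imaging" %in% components))
    stop("imaging-clinical correlation requires the imaging component")
  cfg <- config
  fov <- (cfg$grid_shape - 1L) * cfg$pixel_spacing_mm
  px <- outer(rep(1, cfg$grid_shape[1]),
              (seq_len(cfg$grid_shape[2]) - 1) * cfg$pixel_spacing_mm[2])
  py <- outer((seq_len(cfg$grid_shape[1]) - 1) * cfg$pixel_spacing_mm[1],
              rep(1, cfg$grid_shape[2]))

  patients <- vector("list", cfg$n_patients)
  burden_change <- rep(NA_real_, cfg$n_patients)

  for (p in seq_len(cfg$n_patients)) {
    pat <- list(id = p)
    if ("imaging" %in% components) {
      set.seed(.substream(cfg$seed, p, .ROLE[["geometry"]]))
      base_left <- .draw_joint_polyline(0.30 * fov[2] + stats::runif(1, -2, 2),
                                        fov[1])
      base_right <- .draw_joint_polyline(0.70 * fov[2] + stats::runif(1, -2, 2),
                                         fov[1])
      dels <- vector("list", cfg$n_slices)
      for (s in seq_len(cfg$n_slices)) {
        shift <- stats::runif(2, -1, 1)
        tilts <- stats::runif(4, -0.26, 0.26)
        vl <- base_left; vl[, 1] <- vl[, 1] + shift[1]
        vr <- base_right; vr[, 1] <- vr[, 1] + shift[2]
        dels[[s]] <- list(
          joint_delineation(vl, .tilted_anchor(vl, "start", tilts[1]),
                            .tilted_anchor(vl, "end", tilts[2]),
                            slice = s, joint = "left"),
          joint_delineation(vr, .tilted_anchor(vr, "start", tilts[3]),
                            .tilted_anchor(vr, "end", tilts[4]),
                            slice = s, joint = "right"))
      }
      lesions <- .draw_lesions(cfg, dels[[ceiling(cfg$n_slices / 2)]])
      band <- .band_mask(cfg, dels, px, py)
      fields_pre <- .lesion_fields(cfg, lesions, band, px, py, attenuate = 0)
      fields_post <- .lesion_fields(cfg, lesions, band, px, py,
                                    attenuate = cfg$treatment_effect)
      scored <- if (cfg$n_slices >= 6L) {
        first <- max(1L, ceiling(cfg$n_slices / 2) - 2L)
        seq(first, first + 5L)
      } else seq_len(cfg$n_slices)
      syn <- seq(cfg$synovial_slice_range[1], cfg$synovial_slice_range[2])
      mk_truth <- function(f) sij_truth(
        delineations = dels, oedema_mask = f$oedema > 0, fat_mask = f$fat > 0,
        csf_intensity = f$csf, scored_slices = intersect(scored, seq_len(cfg$n_slices)),
        synovial_slices = syn, pixel_spacing_mm = cfg$pixel_spacing_mm,
        slice_thickness_mm = cfg$slice_thickness_mm)
      pat$truth <- list(pre = mk_truth(fields_pre), post = mk_truth(fields_post))

      nvox <- prod(c(cfg$n_slices, cfg$grid_shape))
      mk_maps <- function(role, fields) {
        set.seed(.substream(cfg$seed, p, .ROLE[[role]]))
        adc_base <- array(.trunc_noise(nvox, cfg$adc_marrow_mean,
                                       cfg$adc_marrow_sd, lo = 0),
                          dim = c(cfg$n_slices, cfg$grid_shape))
        pdff_base <- array(.trunc_noise(nvox, cfg$pdff_marrow_mean,
                                        cfg$pdff_marrow_sd, lo = 0, hi = 100),
                           dim = c(cfg$n_slices, cfg$grid_shape))
        adc <- adc_base + fields$oedema * cfg$oedema_adc_shift
        pdff <- pdff_base + fields$oedema * cfg$oedema_pdff_shift +
          fields$fat * cfg$fat_lesion_pdff_shift
        pdff[pdff < 0] <- 0           # saturate at the physical bounds
        pdff[pdff > 100] <- 100
        list(ADC = quant_map(adc, "ADC", cfg$pixel_spacing_mm,
                             cfg$slice_thickness_mm),
             PDFF = quant_map(pdff, "PDFF", cfg$pixel_spacing_mm,
                              cfg$slice_thickness_mm))
      }
      pat$maps <- list(pre = mk_maps("noise_pre", fields_pre),
                       post = mk_maps("noise_post", fields_post))
      burden_change[p] <- sum(fields_pre$oedema) - sum(fields_post$oedema)
    }
    patients[[p]] <- pat
  }

  if ("clinical" %in% components) {
    rho <- cfg$imaging_clinical_correlation
    z_img <- if (rho != 0) {
      b <- burden_change
      if (stats::sd(b) > 0) (b - mean(b)) / stats::sd(b) else b * 0
    } else NULL
    eff <- cfg$clinical_effects
    for (p in seq_len(cfg$n_patients)) {
      set.seed(.substream(cfg$seed, p, .ROLE[["clinical"]]))
      pre <- post <- list()
      for (i in seq_len(nrow(eff))) {
        e <- eff[i, ]
        z <- stats::rnorm(1)
        if (!is.null(z_img))
          z <- rho * z_img[p] + sqrt(1 - rho^2) * z
        change <- e$change_mean + e$change_sd * z
        # the change keeps its configured distribution; the baseline is drawn
        # conditionally so that both visits stay inside the score's range
        lo_pre <- max(e$lower, e$lower + change)
        hi_pre <- min(e$upper, e$upper + change)
        if (lo_pre > hi_pre) {    # |change| exceeds the scale width (rare)
          change <- sign(change) * (e$upper - e$lower)
          lo_pre <- max(e$lower, e$lower + change)
          hi_pre <- min(e$upper, e$upper + change)
        }
        pre_v <- .rtruncnorm1(e$baseline_mean, e$baseline_sd, lo_pre, hi_pre)
        pre[[e$score]] <- pre_v
        post[[e$score]] <- pre_v - change
      }
      clin <- rbind(data.frame(timepoint = "pre", as.data.frame(pre)),
                    data.frame(timepoint = "post", as.data.frame(post)))
      patients[[p]]$clinical <- clin
    }
  }

  structure(list(patients = patients, config = cfg,
                 components = components),
            class = "beach_cohort")
}

#' @export
print.beach_cohort <- function(x, ...) {
  cat(sprintf("<beach_cohort> %d patients (%s), seed %d\n",
              length(x$patients), paste(x$components, collapse = " + "),
              x$config$seed))
  invisible(x)
}

#' Simulate a delineating reader
#'
#' Produces one reader's joint delineations from the ground truth: every
#' polyline vertex is displaced by isotropic Gaussian noise of SD
#' `jitter_sd`, and each anchor line is rotated about its end vertex by an
#' angle with SD proportional to the jitter (`jitter_sd / 10` radians).
#' `jitter_sd = 0` reproduces the truth exactly.
#'
#' @param truth a [sij_truth()].
#' @param jitter_sd vertex jitter SD, mm (>= 0).
#' @param seed integer seed for this reader.
#' @return List (per slice) of lists of two [joint_delineation()].
#' @export
simulate_reader_delineation <- function(truth, jitter_sd, seed) {
  stopifnot(inherits(truth, "sij_truth"))
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0")
  set.seed(as.integer(seed) %% 2147483587L)
  lapply(truth$delineations, function(slice_dels) {
    lapply(slice_dels, function(d) {
      v <- d$vertices + matrix(stats::rnorm(length(d$vertices), 0, jitter_sd),
                               ncol = 2)
      th <- stats::rnorm(2, 0, jitter_sd / 10)
      a1 <- .rotate_segment(d$anchor_start, d$vertices[1, ], th[1])
      a1 <- a1 + matrix(v[1, ] - d$vertices[1, ], 2, 2, byrow = TRUE)
      nn <- nrow(d$vertices)
      a2 <- .rotate_segment(d$anchor_end, d$vertices[nn, ], th[2])
      a2 <- a2 + matrix(v[nn, ] - d$vertices[nn, ], 2, 2, byrow = TRUE)
      joint_delineation(v, a1, a2, slice = d$slice, joint = d$joint)
    })
  })
}

#' Simulate a visual SPARCC rater
#'
#' Starts from the ideal-rater annotation of the ground truth
#' ([annotate_from_truth()]); each truly involved quadrant is called present
#' with probability `sensitivity` and each uninvolved quadrant with
#' probability `1 - specificity` (independently, for BME and fat alike).
#' Depth and intensity bonus flags are carried over from the truth but only
#' where the rater called at least one quadrant in that joint-slice.
#'
#' @param truth a [sij_truth()].
#' @param sensitivity,specificity per-quadrant probabilities in `[0, 1]`.
#' @param seed integer seed for this rater.
#' @return A [sparcc_annotation()].
#' @export
simulate_visual_rater <- function(truth, sensitivity, specificity, seed) {
  stopifnot(inherits(truth, "sij_truth"))
  if (any(c(sensitivity, specificity) < 0 | c(sensitivity, specificity) > 1))
    stop("probabilities must lie in [0, 1]")
  ideal <- annotate_from_truth(truth)
  set.seed(as.integer(seed) %% 2147483587L)
  call_flags <- function(tr) {
    pr <- ifelse(tr == 1L, sensitivity, 1 - specificity)
    array(as.integer(stats::runif(length(tr)) < pr), dim = dim(tr))
  }
  bme <- call_flags(ideal$bme)
  fat <- call_flags(ideal$fat)
  present <- apply(bme, c(1, 2), max)
  depth <- ideal$depth * present
  inten <- ideal$intensity * present
  sparcc_annotation(bme = bme, depth = depth, intensity = inten, fat = fat)
}
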