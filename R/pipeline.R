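#' Reader-level quantitative-biomarker table for a synthetic cohort
#'
#' Runs the full measurement chain for every patient, timepoint and
#' simulated reader: the reader's noisy delineations are propagated to
#' subchondral ROIs, pixel values pooled over the kind-specific slice set
#' (all synovial slices for ADC, alternate slices for PDFF), and the
#' histographic biomarkers computed.
#'
#' @param cohort a [generate_cohort()] result with the imaging component.
#' @param depth_mm ROI depth (default 10 mm).
#' @param n_readers number of simulated readers (default 2).
#' @param jitter_sd_mm reader jitter; default taken from the cohort config.
#' @return Long `data.frame` with columns `patient`, `metric`, `reader`,
#'   `pre`, `post`. Metrics: `ADC_mean`, `ADC_p25`, `ADC_median`, `ADC_p75`,
#'   `ADC_p90` and the PDFF equivalents.
#' @export
extract_qib_table <- function(cohort, depth_mm = 10, n_readers = 2,
                              jitter_sd_mm = NULL) {
  stopifnot(inherits(cohort, "beach_cohort"))
  if (!("imaging" %in% cohort$components))
    stop("cohort was generated without the imaging component")
  cfg <- cohort$config
  if (is.null(jitter_sd_mm)) jitter_sd_mm <- cfg$reader_jitter_sd_mm
  rows <- list()
  for (pat in cohort$patients) {
    for (rd in seq_len(n_readers)) {
      vals <- list()
      for (tp in c("pre", "post")) {
        truth <- pat$truth[[tp]]
        seed <- .substream(cfg$seed, pat$id,
                           .ROLE[["reader"]] + 2L * rd + (tp == "post"))
        vals[[tp]] <- .measure_patient(pat$maps[[tp]], truth, jitter_sd_mm,
                                       seed, depth_mm)
      }
      for (metric in names(vals$pre)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = pat$id, metric = metric, reader = rd,
          pre = vals$pre[[metric]], post = vals$post[[metric]])
      }
    }
  }
  do.call(rbind, rows)
}

# one reader's ROI sets over the synovial slices; a delineation whose offset
# folds back at the requested depth is redrawn (as an interactive reader
# whose contour the tool rejects would redraw it)
.reader_rois <- function(truth, jitter_sd, seed, depth_mm, max_redraws = 25L) {
  syn <- truth$synovial_slices
  for (attempt in 0:max_redraws) {
    dels <- simulate_reader_delineation(truth, jitter_sd,
                                        seed + attempt * 1000003L)
    rois <- tryCatch({
      rl <- list()
      for (s in syn) for (d in dels[[s]])
        rl[[length(rl) + 1L]] <- propagate_rois(d, depth_mm)
      rl
    }, error = function(e) NULL)
    if (!is.null(rois)) return(rois)
  }
  stop("simulated reader repeatedly produced joints curving tighter than the ROI depth")
}

# histographic biomarkers of one patient-timepoint for one simulated reader
.measure_patient <- function(maps, truth, jitter_sd, seed, depth_mm) {
  out <- list()
  syn_range <- range(truth$synovial_slices)
  rois <- .reader_rois(truth, jitter_sd, seed, depth_mm)
  for (kind in c("ADC", "PDFF")) {
    map <- maps[[kind]]
    slices <- select_slices(kind, dim(map$values)[1], syn_range)
    slices <- intersect(slices, truth$synovial_slices)
    m <- compute_metrics(pool_pixels(map, rois, slices))
    out[[paste0(kind, "_mean")]] <- m$mean
    out[[paste0(kind, "_p25")]] <- m$p25
    out[[paste0(kind, "_median")]] <- m$p50
    out[[paste0(kind, "_p75")]] <- m$p75
    out[[paste0(kind, "_p90")]] <- m$p90
  }
  out
}

#' Rater-level SPARCC score table for a synthetic cohort
#'
#' Each simulated visual rater scores the pre- and post-treatment ground
#' truth independently at the configured sensitivity/specificity.
#'
#' @param cohort a [generate_cohort()] result with imaging.
#' @param n_raters number of raters (default 2).
#' @return Long `data.frame` (`patient`, `metric`, `reader`, `pre`, `post`)
#'   with metrics `SPARCC_BME` and `SPARCC_SSS_fat`.
#' @export
extract_sparcc_table <- function(cohort, n_raters = 2) {
  stopifnot(inherits(cohort, "beach_cohort"))
  if (!("imaging" %in% cohort$components))
    stop("cohort was generated without the imaging component")
  cfg <- cohort$config
  rows <- list()
  for (pat in cohort$patients) {
    for (rt in seq_len(n_raters)) {
      sc <- list()
      for (tp in c("pre", "post")) {
        seed <- .substream(cfg$seed, pat$id,
                           .ROLE[["rater"]] + 2L * rt + (tp == "post"))
        ann <- simulate_visual_rater(pat$truth[[tp]], cfg$rater_sensitivity,
                                     cfg$rater_specificity, seed)
        sc[[tp]] <- c(SPARCC_BME = score_bme(ann),
                      SPARCC_SSS_fat = score_sss_fat(ann))
      }
      for (metric in names(sc$pre)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient = pat$id, metric = metric, reader = rt,
          pre = sc$pre[[metric]], post = sc$post[[metric]])
      }
    }
  }
  do.call(rbind, rows)
}

#' Clinical score table for a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result with the clinical component.
#' @return Long `data.frame` (`patient`, `metric`, `reader` = 1, `pre`,
#'   `post`), one metric per clinical score.
#' @export
extract_clinical_table <- function(cohort) {
  stopifnot(inherits(cohort, "beach_cohort"))
  rows <- list()
  for (pat in cohort$patients) {
    cl <- pat$clinical
    if (is.null(cl)) stop("cohort was generated without the clinical component")
    pre <- cl[cl$timepoint == "pre", , drop = FALSE]
    post <- cl[cl$timepoint == "post", , drop = FALSE]
    for (metric in setdiff(names(cl), "timepoint")) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pat$id, metric = metric, reader = 1L,
        pre = pre[[metric]], post = post[[metric]])
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generate -> delineate -> propagate -> pool -> metrics ->
#' score -> statistics and writes all report tables plus a machine-readable
#' run manifest. Outputs are identical for identical config and seed.
#'
#' Files written to `out_dir`: `config.yaml`, reader-level
#' `qib_reader_level.csv` / `sparcc_rater_level.csv` / `clinical.csv`,
#' `responsiveness.csv` (pre/post means, t, CI, SRM per metric),
#' `correlations.csv` (baseline QIB vs SPARCC Pearson r),
#' `agreement.csv` (inter-reader bias, limits of agreement, ICC) with
#' `bland_altman_*.csv` plot data, `clinical_response.csv`,
#' `logistic.csv`, and `manifest.json`.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param depth_mm ROI depth, mm.
#' @param agreement_metrics metrics for the inter-reader agreement report.
#' @param write_maps also write every ADC/PDFF volume as NIfTI under
#'   `out_dir/maps/` (default `FALSE`).
#' @return An object of class `beach_run` with the in-memory tables and
#'   file paths.
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         depth_mm = 10,
                         agreement_metrics = c("ADC_median", "PDFF_median",
                                               "SPARCC_BME"),
                         write_maps = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wpath <- function(f) file.path(out_dir, f)
  wcsv <- function(df, f) {
    utils::write.csv(df, wpath(f), row.names = FALSE)
    f
  }
  files <- character(0)

  cohort <- generate_cohort(config)
  qib <- extract_qib_table(cohort, depth_mm = depth_mm)
  sparcc <- extract_sparcc_table(cohort)
  clinical <- extract_clinical_table(cohort)
  files <- c(files, wcsv(qib, "qib_reader_level.csv"),
             wcsv(sparcc, "sparcc_rater_level.csv"),
             wcsv(clinical, "clinical.csv"))

  if (isTRUE(write_maps)) {
    dir.create(wpath("maps"), showWarnings = FALSE)
    for (pat in cohort$patients) {
      for (tp in c("pre", "post")) for (kind in c("ADC", "PDFF")) {
        f <- sprintf("maps/patient%02d_%s_%s.nii.gz", pat$id, tp, kind)
        write_map_nifti(pat$maps[[tp]][[kind]], wpath(f))
        files <- c(files, f)
      }
    }
  }

  all_tab <- rbind(qib, sparcc, clinical)
  resp <- responsiveness(all_tab)
  files <- c(files, wcsv(as.data.frame(resp), "responsiveness.csv"))

  # baseline correlations: QIBs vs visual SPARCC scores
  avg <- average_readers(all_tab)
  base <- function(metric) {
    d <- avg[avg$metric == metric, ]
    d$pre[order(d$patient)]
  }
  qib_names <- sort(unique(qib$metric))
  cor_rows <- lapply(qib_names, function(qm) {
    r_bme <- tryCatch(pearson_r(base(qm), base("SPARCC_BME")),
                      error = function(e) NA_real_)
    r_fat <- tryCatch(pearson_r(base(qm), base("SPARCC_SSS_fat")),
                      error = function(e) NA_real_)
    data.frame(qib = qm, r_sparcc_bme = r_bme, r_sparcc_fat = r_fat)
  })
  correlations <- do.call(rbind, cor_rows)
  files <- c(files, wcsv(correlations, "correlations.csv"))

  # inter-reader agreement (Bland-Altman + ICC) at baseline, repeat, change
  rl <- rbind(qib, sparcc)
  agr_rows <- list(); agreement_objs <- list()
  for (metric in agreement_metrics) {
    d1 <- rl[rl$metric == metric & rl$reader == 1, ]
    d2 <- rl[rl$metric == metric & rl$reader == 2, ]
    d1 <- d1[order(d1$patient), ]; d2 <- d2[order(d2$patient), ]
    phases <- list(baseline = cbind(d1$pre, d2$pre),
                   repeat_scan = cbind(d1$post, d2$post),
                   change = cbind(d1$pre - d1$post, d2$pre - d2$post))
    for (ph in names(phases)) {
      m <- phases[[ph]]
      ba <- bland_altman(m[, 1], m[, 2], icc = icc(m))
      agreement_objs[[paste(metric, ph, sep = "_")]] <- ba
      agr_rows[[length(agr_rows) + 1L]] <- data.frame(
        metric = metric, phase = ph, bias = ba$bias, loa_low = ba$loa_low,
        loa_high = ba$loa_high, icc = ba$icc, n = ba$n)
      files <- c(files, wcsv(data.frame(mean = ba$means, diff = ba$diffs),
                             sprintf("bland_altman_%s_%s.csv", metric, ph)))
    }
  }
  agreement <- do.call(rbind, agr_rows)
  files <- c(files, wcsv(agreement, "agreement.csv"))

  # clinical response classification + logistic association with ADC
  resp_rows <- lapply(cohort$patients, function(pat) {
    cl <- pat$clinical
    fl <- classify_clinical_response(
      as.list(cl[cl$timepoint == "pre", ]), as.list(cl[cl$timepoint == "post", ]))
    data.frame(patient = pat$id, nice_response = fl$nice_response,
               basdai50 = fl$basdai50, cii_asdas = fl$cii_asdas,
               asdas_id = fl$asdas_id)
  })
  response <- do.call(rbind, resp_rows)
  files <- c(files, wcsv(response, "clinical_response.csv"))

  adc_b <- base("ADC_median")
  adc_delta <- {
    d <- avg[avg$metric == "ADC_median", ]
    d <- d[order(d$patient), ]
    d$pre - d$post
  }
  log_rows <- list()
  for (spec_ in list(list(name = "nice~baseline_ADC_median", x = adc_b),
                     list(name = "nice~change_ADC_median", x = adc_delta))) {
    fit <- tryCatch(logistic_response(response$nice_response, spec_$x),
                    error = function(e) NULL)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      model = spec_$name,
      odds_ratio = if (is.null(fit)) NA_real_ else fit$odds_ratio,
      p_value = if (is.null(fit)) NA_real_ else fit$p_value,
      note = if (is.null(fit)) "not estimable" else "")
  }
  logistic <- do.call(rbind, log_rows)
  files <- c(files, wcsv(logistic, "logistic.csv"))

  # manifest: config hash, seed, version (no timestamp: runs must be
  # byte-identical for identical config + seed)
  cfg_plain <- unclass(config)
  cfg_plain$clinical_effects <- as.list(cfg_plain$clinical_effects)
  yaml::write_yaml(cfg_plain, wpath("config.yaml"))
  files <- c(files, "config.yaml")
  manifest <- list(
    config_hash = unname(tools::md5sum(wpath("config.yaml"))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("beachsij")),
    n_patients = config$n_patients,
    files = sort(files))
  jsonlite::write_json(manifest, wpath("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  structure(list(out_dir = out_dir, cohort = cohort, qib = qib,
                 sparcc = sparcc, clinical = clinical,
                 responsiveness = resp, correlations = correlations,
                 agreement = agreement, agreement_objs = agreement_objs,
                 response = response, logistic = logistic,
                 manifest = manifest),
            class = "beach_run")
}

#' @export
print.beach_run <- function(x, ...) {
  cat(sprintf("<beach_run> %d patients -> %s (%d files)\n",
              x$manifest$n_patients, x$out_dir, length(x$manifest$files)))
  print(x$responsiveness)
  invisible(x)
}

#' @export
summary.beach_run <- function(object, ...) {
  print(object)
  cat("\nInter-reader agreement:\n")
  print(object$agreement, row.names = FALSE)
  invisible(object)
}

#' Inter-reader agreement as a function of delineation jitter
#'
#' Monte-Carlo experiment: for each jitter level, two simulated readers
#' independently delineate every patient's joints at baseline, the ADC
#' median is measured through the full ROI-propagation chain for each
#' reader, and the Bland-Altman 95% limits of agreement between the readers
#' are computed. Wider delineation noise should widen the limits of
#' agreement.
#'
#' @param cohort a [generate_cohort()] result with imaging.
#' @param jitter_levels numeric vector of vertex jitter SDs (mm).
#' @param depth_mm ROI depth.
#' @return `data.frame` with `jitter_sd_mm`, `loa_width`
#'   (`loa_high - loa_low`), `bias` and `icc` per level.
#' @export
jitter_agreement <- function(cohort, jitter_levels, depth_mm = 10) {
  stopifnot(inherits(cohort, "beach_cohort"))
  cfg <- cohort$config
  n <- length(cohort$patients)
  out <- data.frame(jitter_sd_mm = jitter_levels, loa_width = NA_real_,
                    bias = NA_real_, icc = NA_real_)
  for (k in seq_along(jitter_levels)) {
    jl <- jitter_levels[k]
    r1 <- r2 <- numeric(n)
    for (i in seq_len(n)) {
      pat <- cohort$patients[[i]]
      truth <- pat$truth$pre
      slices <- select_slices("ADC", cfg$n_slices,
                              range(truth$synovial_slices))
      slices <- intersect(slices, truth$synovial_slices)
      med <- function(rd) {
        seed <- .substream(cfg$seed, pat$id,
                           .ROLE[["reader"]] + 50L * k + rd)
        rois <- .reader_rois(truth, jl, seed, depth_mm)
        compute_metrics(pool_pixels(pat$maps$pre$ADC, rois, slices))$p50
      }
      r1[i] <- med(1L); r2[i] <- med(2L)
    }
    ba <- bland_altman(r1, r2, icc = icc(cbind(r1, r2)))
    out$loa_width[k] <- ba$loa_high - ba$loa_low
    out$bias[k] <- ba$bias
    out$icc[k] <- ba$icc
  }
  out
}

#' Audit a printed responsiveness summary table
#'
#' Reconstructs the SRM of every row of a printed summary table (pre/post
#' means and the 95% CI of the mean change for `n` pairs) via
#' [srm_from_summary()] and reports the absolute deviation from the printed
#' SRM. Rows that cannot be reconstructed (missing or non-positive CI
#' width) are kept with `NA` and a warning. The packaged table
#' (`system.file("extdata", "table2_summary.csv", package = "beachsij")`)
#' holds the transcribed rows of a published biologic-therapy cohort
#' summary (n = 30).
#'
#' @param path CSV with columns `metric`, `mean_pre`, `mean_post`,
#'   `ci_low`, `ci_high`, `printed_srm`; defaults to the packaged table.
#' @param n number of pairs behind the printed CIs (default 30).
#' @param out optional path to write the audit CSV.
#' @return `data.frame` with reconstructed SRM, printed SRM, absolute
#'   deviation, and a `consistent` flag (deviation <= 0.02, the printed
#'   rounding tolerance).
#' @export
reproduce_table2 <- function(path = system.file("extdata",
                                                "table2_summary.csv",
                                                package = "beachsij"),
                             n = 30, out = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("metric", "mean_pre", "mean_post", "ci_low", "ci_high",
            "printed_srm")
  if (!all(need %in% names(tab)))
    stop("summary table must have columns: ", paste(need, collapse = ", "))
  rec <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    rec[i] <- tryCatch(
      srm_from_summary(r$mean_pre, r$mean_post, r$ci_low, r$ci_high, n),
      error = function(e) {
        warning("row '", r$metric, "' skipped: ", conditionMessage(e))
        NA_real_
      })
  }
  res <- data.frame(metric = tab$metric, mean_pre = tab$mean_pre,
                    mean_post = tab$mean_post, ci_low = tab$ci_low,
                    ci_high = tab$ci_high, printed_srm = tab$printed_srm,
                    reconstructed_srm = rec,
                    abs_deviation = abs(rec - tab$printed_srm))
  res$consistent <- !is.na(res$abs_deviation) & res$abs_deviation <= 0.02
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
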