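#' Average a reader-level cohort table over readers
#'
#' Cohort tables are long data frames with columns `patient`, `metric`,
#' `reader`, `pre`, `post`. Measurements are averaged over readers so that
#' each patient contributes one value per metric per timepoint, the first
#' step of the responsiveness analysis.
#'
#' @param table reader-level cohort `data.frame`.
#' @return `data.frame` with one row per patient x metric (reader dropped).
#' @export
average_readers <- function(table) {
  need <- c("patient", "metric", "reader", "pre", "post")
  if (!all(need %in% names(table)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  if (nrow(table) == 0L) stop("empty cohort table: no readers to average")
  agg <- stats::aggregate(cbind(pre, post) ~ patient + metric, data = table,
                          FUN = mean)
  agg[order(agg$metric, agg$patient), c("patient", "metric", "pre", "post")]
}

#' Paired t test on pre/post measurements
#'
#' Change is `pre - post` (positive change = reduction with treatment).
#'
#' @param pre,post paired numeric vectors (same length, n >= 2).
#' @return List with `t_stat`, `df`, `p_value`, `ci_low`, `ci_high` (95% CI
#'   of the mean change), `mean_change`, `sd_change`, `n`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("'pre' and 'post' must be paired")
  ok <- stats::complete.cases(pre, post)
  d <- pre[ok] - post[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0)
    stop("degenerate: change scores have zero variance")
  tt <- stats::t.test(pre[ok], post[ok], paired = TRUE, conf.level = 0.95)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, ci_low = tt$conf.int[1],
       ci_high = tt$conf.int[2], mean_change = mean(d),
       sd_change = stats::sd(d), n = n)
}

#' Standardized response mean
#'
#' SRM = mean change / SD of change (sample SD, n-1 denominator). The
#' magnitude is banded as negligible (< 0.2), small (0.2-0.5), moderate
#' (0.5-0.8) or large (>= 0.8); bands are half-open upward.
#'
#' @param changes numeric vector of change scores (n >= 2, non-zero SD).
#' @return List with `srm` and `band`.
#' @export
srm <- function(changes) {
  changes <- changes[!is.na(changes)]
  if (length(changes) < 2L) stop("need at least 2 change scores")
  s <- stats::sd(changes)
  if (s == 0) stop("degenerate: change scores have zero variance")
  value <- mean(changes) / s
  list(srm = value, band = srm_band(value))
}

#' Effect-size band of an SRM value
#' @param srm_value numeric SRM (sign ignored).
#' @return `"negligible"`, `"small"`, `"moderate"` or `"large"`.
#' @export
srm_band <- function(srm_value) {
  a <- abs(srm_value)
  if (a < 0.2) "negligible"
  else if (a < 0.5) "small"
  else if (a < 0.8) "moderate"
  else "large"
}

#' Reconstruct an SRM from printed summary statistics
#'
#' Inverts the paired-t confidence interval: given the printed pre/post means
#' and the 95% CI of the mean change for `n` pairs, the standard error is
#' `(ci_high - ci_low) / (2 * qt(0.975, n - 1))`, the change SD is
#' `SE * sqrt(n)`, and the SRM is `(mean_pre - mean_post) / SD`. This lets
#' published summary tables be audited for internal consistency without the
#' underlying data.
#'
#' @param mean_pre,mean_post printed group means.
#' @param ci_low,ci_high printed 95% CI bounds of the mean change
#'   (`ci_high > ci_low`).
#' @param n number of pairs.
#' @return Reconstructed SRM value.
#' @export
srm_from_summary <- function(mean_pre, mean_post, ci_low, ci_high, n) {
  if (n < 2L) stop("need n >= 2")
  if (!(ci_high > ci_low)) stop("CI width must be positive")
  se <- (ci_high - ci_low) / (2 * stats::qt(0.975, df = n - 1))
  sd_change <- se * sqrt(n)
  (mean_pre - mean_post) / sd_change
}

#' Pearson product-moment correlation
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'")
  stats::cor(x, y, method = "pearson")
}

#' Bland-Altman limits of agreement between two readers
#'
#' Differences are `reader1 - reader2`; bias is their mean and the 95%
#' limits of agreement are bias +/- 1.96 x sample SD of the differences
#' (fixed 1.96 multiplier, standard Bland-Altman practice).
#'
#' @param reader1,reader2 paired numeric vectors (n >= 2).
#' @param icc optional intraclass correlation to attach (see [icc()]).
#' @return An object of class `agreement_stats`: list with `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `n`, `icc`, and plot data `means`,
#'   `diffs`.
#' @export
bland_altman <- function(reader1, reader2, icc = NA_real_) {
  if (length(reader1) != length(reader2))
    stop("readers must supply paired measurements")
  ok <- stats::complete.cases(reader1, reader2)
  r1 <- reader1[ok]; r2 <- reader2[ok]
  if (length(r1) < 2L) stop("need at least 2 pairs")
  d <- r1 - r2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = length(d),
                 icc = icc, means = (r1 + r2) / 2, diffs = d),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> bias %.3g (95%% LoA %.3g to %.3g), n = %d",
              x$bias, x$loa_low, x$loa_high, x$n))
  if (!is.na(x$icc)) cat(sprintf(", ICC %.3f", x$icc))
  cat("\n")
  invisible(x)
}

#' Bland-Altman plot
#' @param x an `agreement_stats` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.agreement_stats <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of readers",
                 ylab = "reader 1 - reader 2", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' two-way ANOVA mean squares: with `n` subjects and `k` readers,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` where MSR,
#' MSC and MSE are the subject, reader and residual mean squares.
#'
#' @param ratings numeric matrix, subjects in rows, readers in columns
#'   (complete, >= 2 rows and >= 2 columns).
#' @return ICC value (<= 1).
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings matrix must be complete")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 readers")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Binary logistic regression of clinical response on one predictor
#'
#' Single-predictor logit model fitted by iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 100 iterations). Reports the
#' odds ratio per unit predictor and the Wald p value. Perfect or
#' quasi-perfect separation is detected and raised as an error rather than
#' reported as an estimate.
#'
#' @param outcome 0/1 (or logical) response vector with both classes present.
#' @param predictor numeric predictor, same length, n >= 10.
#' @return List with `odds_ratio`, `coef`, `se`, `p_value`, `n`.
#' @export
logistic_response <- function(outcome, predictor) {
  outcome <- as.integer(outcome)
  ok <- stats::complete.cases(outcome, predictor)
  y <- outcome[ok]; x <- predictor[ok]
  if (length(y) < 10L) stop("need at least 10 observations")
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (sep_warn || abs(co["x", "Estimate"]) > 15)
    stop("perfect (or quasi-perfect) separation: no finite odds ratio")
  list(odds_ratio = exp(co["x", "Estimate"]), coef = co["x", "Estimate"],
       se = co["x", "Std. Error"], p_value = co["x", "Pr(>|z|)"],
       n = length(y))
}

#' Classify clinical treatment response
#'
#' Four binary response definitions from paired clinical visits, with
#' improvement computed as `pre - post`:
#' \itemize{
#'   \item `nice_response`: BASDAI improvement >= 1.2 AND spinal VAS
#'     improvement >= 1 (boundary inclusive);
#'   \item `basdai50`: BASDAI reduced by at least 50%;
#'   \item `cii_asdas`: clinically important improvement, ASDAS change
#'     strictly > 1.1;
#'   \item `asdas_id`: inactive disease, post-treatment ASDAS strictly < 1.3.
#' }
#' ASDAS criteria use the CRP-based ASDAS. A missing component score leaves
#' the affected flag `NA`.
#'
#' @param pre,post named lists / one-row data frames with fields `basdai`,
#'   `spinal_vas`, `asdas_crp` (others ignored).
#' @return List of the four logical flags.
#' @export
classify_clinical_response <- function(pre, post) {
  g <- function(v, f) {
    x <- v[[f]]
    if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
  }
  d_basdai <- g(pre, "basdai") - g(post, "basdai")
  d_vas <- g(pre, "spinal_vas") - g(post, "spinal_vas")
  d_asdas <- g(pre, "asdas_crp") - g(post, "asdas_crp")
  list(
    nice_response = (d_basdai >= 1.2) & (d_vas >= 1),
    basdai50 = d_basdai >= 0.5 * g(pre, "basdai"),
    cii_asdas = d_asdas > 1.1,
    asdas_id = g(post, "asdas_crp") < 1.3
  )
}

#' Responsiveness analysis of a cohort table
#'
#' Averages the table over readers, then computes the paired t test, mean
#' and SD of change, SRM and its effect-size band for every metric. Change
#' is `pre - post` except for metrics listed in `post_minus_pre` (those that
#' increase with treatment, e.g. PDFF), which are reported as `post - pre`.
#'
#' @param table reader-level cohort `data.frame` (see [average_readers()]).
#' @param post_minus_pre character vector of metric names whose change is
#'   reported as `post - pre`; defaults to PDFF metrics.
#' @return An object of class `response_stats`: `data.frame` with one row
#'   per metric (`metric`, `n`, `mean_pre`, `mean_post`, `mean_change`,
#'   `sd_change`, `t_stat`, `df`, `p_value`, `ci_low`, `ci_high`, `srm`,
#'   `band`).
#' @export
responsiveness <- function(table, post_minus_pre = NULL) {
  if (is.null(post_minus_pre))
    post_minus_pre <- grep("^PDFF", unique(table$metric), value = TRUE)
  avg <- average_readers(table)
  rows <- lapply(split(avg, avg$metric), function(df) {
    flip <- df$metric[1] %in% post_minus_pre
    pre <- df$pre; post <- df$post
    if (flip) { tmp <- pre; pre <- post; post <- tmp }
    tt <- paired_t(pre, post)
    sr <- srm(pre - post)
    data.frame(metric = df$metric[1], n = tt$n,
               mean_pre = mean(df$pre), mean_post = mean(df$post),
               mean_change = tt$mean_change, sd_change = tt$sd_change,
               t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
               ci_low = tt$ci_low, ci_high = tt$ci_high,
               srm = sr$srm, band = sr$band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("response_stats", "data.frame")
  out
}

#' @export
print.response_stats <- function(x, digits = 3, ...) {
  cat("Responsiveness (paired t / standardized response mean)\n")
  df <- as.data.frame(x)
  df$p_value <- format.pval(df$p_value, digits = digits)
  show <- df[, c("metric", "n", "mean_pre", "mean_post", "ci_low",
                 "ci_high", "p_value", "srm", "band")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], signif, digits = digits)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.response_stats <- function(object, ...) {
  cat(sprintf("%d metrics, n = %d patients\n", nrow(object), object$n[1]))
  sig <- object$metric[object$p_value < 0.05]
  cat("significant change (p < 0.05): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  lg <- object$metric[abs(object$srm) >= 0.5]
  cat("moderate-or-large SRM: ",
      if (length(lg)) paste(lg, collapse = ", ") else "none", "\n", sep = "")
  invisible(object)
}
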