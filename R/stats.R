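# Repeated-measures statistics over the per-ROI metric tables: percent
# differences between frame counts, one-way within-subject ANOVA with the
# Greenhouse-Geisser sphericity correction, Bonferroni-adjusted sequential
# post hoc t-tests, the optimal-frame-count rule, the length-density to
# area-coverage conversion, and the normative (box-plot) comparison of
# patient densities against healthy controls.

#' Subjects x frame-counts matrix for one metric in one region
#'
#' Builds the wide matrix consumed by the ANOVA stage from a tidy metrics
#' table. Subjects with any missing or excluded cell are dropped listwise,
#' matching whole-ROI exclusion.
#'
#' @param metrics Tidy data.frame with columns subject, region, n_frames,
#'   the metric columns, and optionally excluded.
#' @param metric Name of the metric column.
#' @param region Region label to keep.
#' @param n_values Frame counts (columns), default 1:10.
#' @return Numeric matrix subjects x frame counts with subject rownames.
#' @export
metric_matrix <- function(metrics, metric, region, n_values = 1:10) {
  d <- metrics[metrics$region == region & metrics$n_frames %in% n_values, ]
  if ("excluded" %in% names(d)) d[[metric]][d$excluded %in% TRUE] <- NA_real_
  subs <- unique(d$subject)
  M <- matrix(NA_real_, length(subs), length(n_values),
              dimnames = list(subs, n_values))
  for (i in seq_len(nrow(d))) {
    M[as.character(d$subject[i]), as.character(d$n_frames[i])] <- d[[metric]][i]
  }
  M[stats::complete.cases(M), , drop = FALSE]
}

#' Signed percent difference from a reference mean
#'
#' 100 * (avg_mean - ref_mean) / ref_mean; negative when the averaged
#' value is below the reference (e.g. endpoint counts).
#'
#' @param ref_mean Reference (single-frame) mean; must be nonzero.
#' @param avg_mean Averaged-image mean.
#' @return Percent difference.
#' @export
percent_difference <- function(ref_mean, avg_mean) {
  if (any(ref_mean == 0)) stop("reference mean is zero")
  100 * (avg_mean - ref_mean) / ref_mean
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject decomposition (subjects, condition, error) with
#' the Greenhouse-Geisser epsilon estimated from the double-centred sample
#' covariance of the condition columns; F is tested on ((k-1)e,
#' (n-1)(k-1)e) degrees of freedom.
#'
#' @param data Numeric matrix subjects x conditions (>= 2 of each).
#' @return An \code{rm_anova} list: F, df_num, df_den, epsilon_gg, p_gg,
#'   and the sums of squares.
#' @export
rm_anova_gg <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  if (anyNA(data)) stop("missing cells; drop incomplete subjects first")
  grand <- mean(data)
  ss_total <- sum((data - grand)^2)
  ss_subj <- k * sum((rowMeans(data) - grand)^2)
  ss_cond <- n * sum((colMeans(data) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df_cond <- k - 1; df_err <- (n - 1) * (k - 1)
  ms_err <- ss_err / df_err
  F <- if (ms_err > 0) (ss_cond / df_cond) / ms_err
       else if (ss_cond == 0) 0 else Inf
  S <- stats::cov(data)
  C <- diag(k) - 1 / k
  A <- C %*% S %*% C
  trA <- sum(diag(A)); trA2 <- sum(A * A)  # tr(A^2) for symmetric A
  eps <- if (trA2 > 0) trA^2 / ((k - 1) * trA2) else 1
  eps <- clamp(eps, 1 / (k - 1), 1)
  df_num <- df_cond * eps; df_den <- df_err * eps
  p <- if (is.finite(F)) stats::pf(F, df_num, df_den, lower.tail = FALSE) else 0
  out <- list(F = F, df_num = df_num, df_den = df_den,
              epsilon_gg = eps, p_gg = p,
              ss_condition = ss_cond, ss_subjects = ss_subj, ss_error = ss_err,
              n_subjects = n, k_levels = k)
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%.2f, %.2f) = %.3f, GG epsilon = %.3f, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$epsilon_gg, x$p_gg))
  invisible(x)
}

#' Sequential paired post hoc tests with Bonferroni correction
#'
#' Paired two-sided t-tests on each sequential pair of frame counts (1v2,
#' 2v3, ...), Bonferroni-adjusted by the number of pairs (9 for 10
#' levels). A pair with zero within-subject variance gets p = 1 when the
#' columns are identical and p = 0 when they differ by a constant, and is
#' flagged.
#'
#' @param data Numeric matrix subjects x conditions.
#' @param alpha Significance level (default 0.05).
#' @return A \code{posthoc} data.frame: pair, p_raw, p_adj, significant,
#'   degenerate; with attribute \code{alpha}.
#' @export
sequential_posthoc <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  m <- k - 1
  lvl <- colnames(data); if (is.null(lvl)) lvl <- as.character(seq_len(k))
  res <- lapply(seq_len(m), function(j) {
    d <- data[, j + 1] - data[, j]
    degen <- stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)
    p <- if (degen) {
      if (mean(d) == 0) 1 else 0
    } else {
      stats::t.test(d)$p.value
    }
    data.frame(pair = paste0(lvl[j], "v", lvl[j + 1]),
               p_raw = p, p_adj = min(1, p * m),
               degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_adj < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("posthoc", class(out))
  out
}

#' Optimal number of averaged frames
#'
#' The smallest n such that every sequential comparison from (n vs n+1)
#' onward is non-significant: averaging beyond n buys no further
#' significant change. Returns 1 when no comparison is significant and
#' the highest level when the last comparison is still significant.
#'
#' @param posthoc Result of \code{sequential_posthoc}.
#' @param alpha Significance level (default the posthoc's alpha).
#' @return Integer frame count.
#' @export
optimal_frames <- function(posthoc, alpha = attr(posthoc, "alpha") %||% 0.05) {
  sig <- posthoc$p_adj < alpha
  m <- length(sig)
  if (!any(sig)) return(1L)
  last_sig <- max(which(sig))
  if (last_sig == m) return(m + 1L)  # still improving at the top level
  as.integer(last_sig + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert length density to area-coverage density
#'
#' Assuming a uniform capillary diameter, a skeleton length density d
#' (mm^-1) covers a fraction d * diameter of the area: percent coverage =
#' 100 * density * diameter_um / 1000.
#'
#' @param density_mm_inv Length density, mm^-1 (>= 0).
#' @param diameter_um Assumed capillary diameter (default 9 um).
#' @return Percent area coverage.
#' @export
area_coverage_from_length_density <- function(density_mm_inv, diameter_um = 9) {
  if (any(density_mm_inv < 0)) stop("density must be >= 0")
  100 * density_mm_inv * (diameter_um / 1000)
}

#' Compare patient densities against a healthy-control distribution
#'
#' For each region, returns the case value's empirical quantile within the
#' control sample and flags values below the lower box-plot whisker
#' (Q1 - 1.5 IQR) or below the control minimum.
#'
#' @param control_densities Named list (by region) of control samples,
#'   each with >= 5 values.
#' @param case_density Named numeric vector of per-region case values.
#' @return data.frame: region, value, quantile, below_lower_whisker,
#'   below_minimum.
#' @export
normative_comparison <- function(control_densities, case_density) {
  regions <- names(case_density)
  missing <- setdiff(regions, names(control_densities))
  if (length(missing)) {
    stop("regions absent from controls: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(regions, function(rg) {
    ctrl <- control_densities[[rg]]
    if (length(ctrl) < 5) stop("need >= 5 controls in region ", rg)
    v <- case_density[[rg]]
    q1 <- stats::quantile(ctrl, 0.25, names = FALSE)
    iqr <- stats::IQR(ctrl)
    data.frame(region = rg, value = v,
               quantile = stats::ecdf(ctrl)(v),
               below_lower_whisker = v < q1 - 1.5 * iqr,
               below_minimum = v < min(ctrl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full statistics stage over a tidy metrics table
#'
#' For every metric x region: RM-ANOVA with Greenhouse-Geisser correction,
#' sequential Bonferroni post hoc tests, the optimal frame count, and the
#' percent differences from the reference to the 5- and 10-frame averages
#' (computed on across-subject means).
#'
#' @param metrics Tidy metrics data.frame (see \code{quantify_roi}).
#' @param metric_cols Metric column names to analyse.
#' @param n_values Frame-count levels.
#' @param alpha Significance level.
#' @return List: \code{percent_diff} (Table-1 style), \code{optimal}
#'   (Table-2 style), \code{anova} (per metric x region results).
#' @export
stats_stage <- function(metrics,
                        metric_cols = c("snr", "n_endpoints",
                                        "mean_segment_length_um",
                                        "density_mm_inv", "icd_um"),
                        n_values = 1:10, alpha = 0.05) {
  regions <- unique(metrics$region)
  pd <- list(); opt <- list(); an <- list()
  for (m in metric_cols) {
    for (rg in regions) {
      M <- metric_matrix(metrics, m, rg, n_values)
      key <- paste(m, rg, sep = ".")
      if (nrow(M) < 2) next
      a <- rm_anova_gg(M)
      ph <- sequential_posthoc(M, alpha = alpha)
      an[[key]] <- list(metric = m, region = rg, anova = a, posthoc = ph)
      opt[[key]] <- data.frame(metric = m, region = rg,
                               optimal_frames = optimal_frames(ph, alpha),
                               stringsAsFactors = FALSE)
      cm <- colMeans(M)
      ref <- cm[as.character(min(n_values))]
      pd[[key]] <- data.frame(
        metric = m, region = rg,
        pct_diff_5 = if ("5" %in% names(cm)) percent_difference(ref, cm[["5"]]) else NA_real_,
        pct_diff_10 = if ("10" %in% names(cm)) percent_difference(ref, cm[["10"]]) else NA_real_,
        n_subjects = nrow(M), stringsAsFactors = FALSE)
    }
  }
  list(percent_diff = do.call(rbind, pd),
       optimal = do.call(rbind, opt),
       anova = an)
}
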