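# End-to-end orchestration: simulate (or load) a cohort of multi-frame
# stacks, register, place ROIs, quantify across frame counts, and run the
# statistics stage. Configuration is a single list (YAML-able); every run
# writes the fully resolved configuration beside its outputs and is
# deterministic given the config seed.

#' Default pipeline configuration
#'
#' @param n_subjects Number of synthetic subjects.
#' @param n_frames Frames per stack.
#' @param seed Global seed.
#' @param outdir Output directory (NULL = no files written).
#' @return Nested configuration list.
#' @export
default_config <- function(n_subjects = 4, n_frames = 10, seed = 1,
                           outdir = NULL) {
  list(
    seed = seed,
    outdir = outdir,
    synthetic = list(n_subjects = n_subjects, n_frames = n_frames,
                     image_size_px = c(304L, 304L),
                     true_icd_um_mean = 38, true_icd_um_sd = 2,
                     orientation_sd_deg = 5,
                     speckle_sigma = 0.3, additive_sigma = 0.05,
                     motion_line_prob = 0.01,
                     shift_range_px = 3, rot_range_deg = 1),
    scale = list(px_per_degree = 30.4, axial_length_mm = 24,
                 resize_factor = 6L),
    disc = list(center_px = c(152, 112), semi_axes_px = c(34, 28),
                tilt_deg = 80),
    rois = list(laterality = "OD", side_px = 60L,
                orientation_from_scene = TRUE),
    register = list(enabled = TRUE, rot_range_deg = 2),
    quantify = list(n_values = 1:10, mask_diameter_um = 15,
                    icd_prominence = 0.1, icd_min_sep_px = 2,
                    length_metric = "steps"),
    stats = list(alpha = 0.05)
  )
}

config_scale <- function(config) {
  scale_model(px_per_degree = config$scale$px_per_degree,
              axial_length_mm = config$scale$axial_length_mm,
              resize_factor = config$scale$resize_factor)
}

#' Simulate and quantify one synthetic subject
#'
#' Draws per-subject capillary spacing and orientation from the cohort
#' distribution, simulates a misaligned noisy stack, registers it, places
#' the five peripapillary ROIs around the configured disc ellipse
#' (capillary orientation overridden with the scene's true orientation),
#' and quantifies every ROI across the configured frame counts.
#'
#' @param config Pipeline configuration (see \code{default_config}).
#' @param subject_index 1-based subject number.
#' @return List: \code{metrics} (data.frame), \code{stack}, \code{truth},
#'   \code{scene}, \code{rois}.
#' @export
run_subject <- function(config, subject_index = 1) {
  sc <- config_scale(config)
  syn <- config$synthetic
  set.seed(derive_seed(config$seed, 10000 + subject_index))
  icd <- max(stats::rnorm(1, syn$true_icd_um_mean, syn$true_icd_um_sd), 25)
  orient <- stats::rnorm(1, 0, syn$orientation_sd_deg)
  scene <- synthetic_scene(
    image_size_px = syn$image_size_px,
    orientation_deg = orient,
    true_icd_um = icd,
    speckle_sigma = syn$speckle_sigma,
    additive_sigma = syn$additive_sigma,
    motion_line_prob = syn$motion_line_prob,
    shift_range_px = syn$shift_range_px,
    rot_range_deg = syn$rot_range_deg,
    seed = derive_seed(config$seed, 20000 + subject_index))
  sim <- simulate_stack(scene, sc, n_frames = syn$n_frames)
  stack <- sim$stack
  if (isTRUE(config$register$enabled)) {
    stack <- register_stack(stack, rot_range_deg = config$register$rot_range_deg)
  } else {
    stack$registered <- TRUE
    stack$transforms <- rep(list(rigid_transform(0, 0, 0)), n_frames(stack))
  }
  ell <- disc_ellipse(config$disc$center_px, config$disc$semi_axes_px,
                      config$disc$tilt_deg)
  rois <- place_rois(ell, sc, laterality = config$rois$laterality,
                     image_size_px = dim(stack$frames[[1]]),
                     side_px = config$rois$side_px)
  if (isTRUE(config$rois$orientation_from_scene)) {
    rois <- lapply(rois, function(r) {
      r$vessel_orientation_deg <- scene$orientation_deg
      r
    })
  }
  q <- config$quantify
  metrics <- do.call(rbind, lapply(rois, function(roi) {
    quantify_roi(stack, roi, sc, n_values = q$n_values,
                 subject_id = sprintf("sub%02d", subject_index),
                 mask_diameter_um = q$mask_diameter_um,
                 icd_prominence = q$icd_prominence,
                 icd_min_sep_px = q$icd_min_sep_px,
                 length_metric = q$length_metric)
  }))
  list(metrics = metrics, stack = stack, truth = sim$truth, scene = scene,
       rois = rois)
}

#' Run the full pipeline over a synthetic cohort
#'
#' @param config Configuration list (see \code{default_config}) or a path
#'   to a YAML file with the same structure.
#' @return List: \code{metrics} (tidy table over all subjects),
#'   \code{stats} (the statistics stage), \code{config} (resolved),
#'   \code{log} (per-stage counts). When \code{config$outdir} is set,
#'   metrics.csv, stats tables, the resolved config and a density box plot
#'   are written there.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  syn <- config$synthetic
  if (max(config$quantify$n_values) > syn$n_frames) {
    stop("config requests ", max(config$quantify$n_values),
         "-frame averaging but stacks have only ", syn$n_frames, " frames")
  }
  subj <- lapply(seq_len(syn$n_subjects), function(i) run_subject(config, i))
  metrics <- do.call(rbind, lapply(subj, `[[`, "metrics"))
  rownames(metrics) <- NULL
  st <- stats_stage(metrics, n_values = config$quantify$n_values,
                    alpha = config$stats$alpha)
  log <- list(
    n_subjects = syn$n_subjects,
    n_rois = sum(vapply(subj, function(s) length(s$rois), integer(1))),
    n_rois_excluded = sum(metrics$excluded & metrics$n_frames == 1),
    n_rows = nrow(metrics),
    n_icd_unmeasurable = sum(!metrics$excluded &
                               !is.na(metrics$reason), na.rm = TRUE))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    cfg_hash <- substr(digest_config(config), 1, 12)
    metrics_out <- metrics
    metrics_out$config_hash <- cfg_hash
    utils::write.csv(metrics_out, file.path(config$outdir, "metrics.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config, file.path(config$outdir, "config_resolved.yaml"))
    if (!is.null(st$percent_diff)) {
      utils::write.csv(st$percent_diff,
                       file.path(config$outdir, "percent_differences.csv"),
                       row.names = FALSE)
    }
    if (!is.null(st$optimal)) {
      utils::write.csv(st$optimal,
                       file.path(config$outdir, "optimal_frames.csv"),
                       row.names = FALSE)
    }
    anova_json <- lapply(st$anova, function(x)
      list(metric = x$metric, region = x$region,
           F = x$anova$F, df_num = x$anova$df_num, df_den = x$anova$df_den,
           epsilon_gg = x$anova$epsilon_gg, p_gg = x$anova$p_gg))
    jsonlite::write_json(anova_json, file.path(config$outdir, "anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    plot_density_boxplot(metrics,
                         file.path(config$outdir, "density_boxplot.png"))
  }
  list(metrics = metrics, stats = st, config = config, log = log)
}

# Stable hash of the resolved configuration (provenance column in outputs).
# The output directory is not part of the scientific configuration.
digest_config <- function(config) {
  config$outdir <- NULL
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}

#' Box plot of 10-frame capillary density by region
#'
#' Normative display in the style of a control-vs-patient comparison:
#' control densities as per-region boxes, optional case values overlaid
#' as points.
#'
#' @param metrics Tidy metrics table (controls).
#' @param path Output PNG path.
#' @param case_density Optional named vector of per-region patient values.
#' @param n_frames Frame count to display (default the maximum present).
#' @return \code{path}, invisibly.
#' @export
plot_density_boxplot <- function(metrics, path, case_density = NULL,
                                 n_frames = max(metrics$n_frames)) {
  d <- metrics[metrics$n_frames == n_frames & !metrics$excluded, ]
  regions <- intersect(c("S", "ST", "T", "IT", "I"), unique(d$region))
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  graphics::boxplot(density_mm_inv ~ factor(region, levels = regions),
                    data = d, xlab = "Peripapillary region",
                    ylab = sprintf("Capillary density (mm^-1), %d-frame avg",
                                   n_frames),
                    col = "grey85")
  if (!is.null(case_density)) {
    idx <- match(names(case_density), regions)
    graphics::points(idx, case_density, pch = 17, col = "red", cex = 1.5)
  }
  invisible(path)
}

#' Write a small bundled fixture set
#'
#' Two synthetic subjects (one noise-free, one noisy) as multi-page TIFF
#' stacks with JSON sidecars, plus a manifest with md5 checksums. Fixtures
#' regenerate byte-identically from the same seed.
#'
#' @param dir Output directory.
#' @param seed Seed.
#' @param n_frames Frames per stack (default 10).
#' @param image_size_px Frame size (small by default to keep fixtures
#'   light).
#' @return Manifest list, invisibly; written to manifest.json.
#' @export
make_fixtures <- function(dir, seed = 1, n_frames = 10,
                          image_size_px = c(96L, 96L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- scale_model()
  scenes <- list(
    clean = synthetic_scene(image_size_px = image_size_px, speckle_sigma = 0,
                            additive_sigma = 0, motion_line_prob = 0,
                            shift_range_px = 0, rot_range_deg = 0,
                            seed = derive_seed(seed, 1)),
    noisy = synthetic_scene(image_size_px = image_size_px,
                            seed = derive_seed(seed, 2)))
  entries <- list()
  for (nm in names(scenes)) {
    sim <- simulate_stack(scenes[[nm]], sc, n_frames = n_frames)
    path <- file.path(dir, paste0("stack_", nm, ".tif"))
    write_stack_tiff(sim$stack, path, scene = scenes[[nm]], truth = sim$truth)
    entries[[nm]] <- list(file = basename(path),
                          n_frames = n_frames,
                          md5 = unname(tools::md5sum(path)))
  }
  manifest <- list(seed = seed, stacks = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate fixture checksums against their manifest
#' @param dir Fixture directory containing manifest.json.
#' @return TRUE if all checksums match, otherwise an error.
#' @export
validate_fixtures <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (nm in names(manifest$stacks)) {
    e <- manifest$stacks[[nm]]
    got <- unname(tools::md5sum(file.path(dir, e$file)))
    if (!identical(got, e$md5)) stop("checksum mismatch for ", e$file)
  }
  TRUE
}

#' Read a deposited per-subject metric workbook (S1-table layout)
#'
#' Accepts the layout of the source study's supplementary workbook as
#' plain CSV files: one file per metric (sheets A-E), each with columns
#' subject, region, n_frames, value; plus optionally a patients file
#' (sheet F) with subject, region, density_mm_inv. Used for
#' statistics-only runs on deposited data.
#'
#' @param dir Directory containing snr.csv, endpoints.csv,
#'   segment_length.csv, density.csv, icd.csv and optionally
#'   poag_density.csv.
#' @return Tidy metrics data.frame (plus attribute \code{poag} when
#'   present).
#' @export
read_metric_sheets <- function(dir) {
  files <- c(snr = "snr.csv", n_endpoints = "endpoints.csv",
             mean_segment_length_um = "segment_length.csv",
             density_mm_inv = "density.csv", icd_um = "icd.csv")
  out <- NULL
  for (m in names(files)) {
    p <- file.path(dir, files[[m]])
    if (!file.exists(p)) stop("missing metric sheet: ", files[[m]])
    d <- utils::read.csv(p)
    stopifnot(all(c("subject", "region", "n_frames", "value") %in% names(d)))
    d <- d[, c("subject", "region", "n_frames", "value")]
    names(d)[4] <- m
    out <- if (is.null(out)) d else
      merge(out, d, by = c("subject", "region", "n_frames"), all = TRUE)
  }
  out$excluded <- FALSE
  pf <- file.path(dir, "poag_density.csv")
  if (file.exists(pf)) attr(out, "poag") <- utils::read.csv(pf)
  out
}
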