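#!/usr/bin/env Rscript
# Stage 3: place the peripapillary ROIs and quantify every stack at each
# number of averaged frames (1-10).
#
# ROIs sit one degree outside a disc-margin ellipse in the five sectors
# (S, ST, T, IT, I); the stored registration transforms are applied to
# the raw stacks before averaging. For each ROI and frame count the five
# metrics are computed: mask-based SNR (mask fixed from the 10-frame
# average), skeleton endpoints, mean segment length, capillary length
# density, and peak-to-peak intercapillary distance.

suppressMessages(library(rpcavg))

stacks <- sort(Sys.glob("results/stacks/sub*.tif"))
stopifnot(length(stacks) > 0)
sc <- scale_model()
disc <- disc_ellipse(c(152, 112), c(34, 28), 80)

all_metrics <- list()
for (path in stacks) {
  subject <- sub("\\.tif$", "", basename(path))
  stack <- read_stack_tiff(path)
  tf <- read_transforms_json(file.path("results/transforms",
                                       sub("\\.tif$", ".json", basename(path))))
  stack$reference_index <- tf$reference_index
  stack <- transfer_transforms(stack, tf$transforms)

  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rois <- place_rois(disc, sc, "OD", image_size_px = dim(stack$frames[[1]]))
  rois <- lapply(rois, function(r) {
    r$vessel_orientation_deg <- side$scene$orientation_deg
    r
  })
  m <- do.call(rbind, lapply(rois, function(roi) {
    quantify_roi(stack, roi, sc, n_values = 1:10, subject_id = subject)
  }))
  all_metrics[[subject]] <- m
  message(sprintf("%s: %d ROI x frame-count rows, %d excluded",
                  subject, nrow(m), sum(m$excluded)))
}
metrics <- do.call(rbind, all_metrics)
rownames(metrics) <- NULL
write.csv(metrics, "results/metrics.csv", row.names = FALSE)
message("metrics table -> results/metrics.csv (", nrow(metrics), " rows)")

# one QC panel from the first subject's temporal ROI, 10-frame average
stack <- read_stack_tiff(stacks[1])
tf <- read_transforms_json(file.path("results/transforms",
                                     sub("\\.tif$", ".json", basename(stacks[1]))))
stack$reference_index <- tf$reference_index
stack <- transfer_transforms(stack, tf$transforms)
roi_t <- place_rois(disc, sc, "OD", image_size_px = dim(stack$frames[[1]]))[[3]]
avg <- average_frames(stack, 10, roi_t)
if (!avg$excluded) {
  plot_roi_qc(avg$image, sc, "results/qc_temporal_roi.png")
  message("QC panel -> results/qc_temporal_roi.png")
}
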