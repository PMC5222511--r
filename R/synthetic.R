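# Synthetic RPC scene simulation.
#
# The radial peripapillary capillaries are long, nearly straight and
# nearly parallel vessels with few anastomoses, ~9 um true diameter and
# 30-40 um centre-to-centre spacing. The generator draws jittered,
# slightly tortuous parallel centrelines, renders them with a Gaussian
# cross-section (FWHM = true diameter; sub-pixel diameters remain
# representable on the ~9.6 um/px grid), and produces per-frame noisy
# realisations with rigid misalignment, multiplicative speckle, additive
# background noise and occasional whole-row motion-artifact lines.

#' Parameters of a synthetic capillary scene
#'
#' Defaults describe a healthy peripapillary capillary field as imaged at
#' 10x10 degrees / 304 px: 38 um spacing (length density ~26 mm^-1, i.e.
#' ~23% area coverage at 9 um diameter), mild tortuosity, sparse
#' anastomoses, and noise strong enough that single frames look grainy
#' while 10-frame averages look smooth.
#'
#' @param image_size_px Integer (rows, cols) of the rendered field.
#' @param orientation_deg Dominant capillary direction, degrees; 0 =
#'   horizontal, positive rotates towards the top of the image.
#' @param true_icd_um Mean centre-to-centre capillary spacing, microns.
#' @param icd_jitter_frac SD of per-capillary spacing jitter as a fraction
#'   of \code{true_icd_um}.
#' @param true_diameter_um Capillary diameter (Gaussian FWHM), microns.
#' @param tortuosity_amp_um Amplitude of the sinusoidal centreline wobble,
#'   microns (period fixed at 100 px).
#' @param anastomosis_rate Expected number of cross-links per adjacent
#'   capillary pair.
#' @param speckle_sigma SD of the multiplicative Normal(1, .) speckle.
#' @param additive_sigma SD of the additive Normal(0, .) background noise.
#' @param motion_line_prob Per-row probability of a motion-artifact line.
#' @param shift_range_px,rot_range_deg Bounds of the uniform per-frame
#'   rigid misalignment.
#' @param seed Integer RNG seed; identical (scene, seed) pairs reproduce
#'   outputs bit-for-bit.
#' @return A \code{synthetic_scene} object.
#' @export
synthetic_scene <- function(image_size_px = c(304L, 304L),
                            orientation_deg = 0,
                            true_icd_um = 38,
                            icd_jitter_frac = 0.08,
                            true_diameter_um = 9,
                            tortuosity_amp_um = 3,
                            anastomosis_rate = 0.08,
                            speckle_sigma = 0.3,
                            additive_sigma = 0.05,
                            motion_line_prob = 0.01,
                            shift_range_px = 3,
                            rot_range_deg = 1,
                            seed = 1L) {
  stopifnot(true_icd_um > true_diameter_um, true_diameter_um > 0,
            icd_jitter_frac >= 0, motion_line_prob >= 0, motion_line_prob <= 1,
            speckle_sigma >= 0, additive_sigma >= 0,
            shift_range_px >= 0, rot_range_deg >= 0, anastomosis_rate >= 0)
  out <- list(image_size_px = as.integer(image_size_px),
              orientation_deg = orientation_deg,
              true_icd_um = true_icd_um,
              icd_jitter_frac = icd_jitter_frac,
              true_diameter_um = true_diameter_um,
              tortuosity_amp_um = tortuosity_amp_um,
              anastomosis_rate = anastomosis_rate,
              speckle_sigma = speckle_sigma,
              additive_sigma = additive_sigma,
              motion_line_prob = motion_line_prob,
              shift_range_px = shift_range_px,
              rot_range_deg = rot_range_deg,
              seed = as.integer(seed))
  class(out) <- "synthetic_scene"
  out
}

# Deterministic sub-seed for independent per-frame noise streams.
derive_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 65521) * 31013 + stream * 7919 + 17) %% 2147483629
}

#' Generate the ground-truth capillary geometry and noise-free render
#'
#' @param scene A \code{synthetic_scene}.
#' @param scale A \code{scale_model}.
#' @return A \code{ground_truth} list: \code{centerline_map} (logical
#'   matrix), \code{clean_image} (noise-free render in [0,1]),
#'   \code{true_density_mm_inv} (centreline length of the rasterised map
#'   per ROI-free field area), \code{true_icd_um}, and (once frames are
#'   simulated) \code{true_transforms}.
#' @export
generate_capillary_map <- function(scene, scale) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(scale, "scale_model"))
  nr <- scene$image_size_px[1]; nc <- scene$image_size_px[2]
  upp <- um_per_px(scale)
  spacing_px <- scene$true_icd_um / upp
  half_diag <- sqrt(nr^2 + nc^2) / 2
  if (2 * spacing_px > min(nr, nc)) {
    stop("image too small to contain at least 2 capillaries at spacing ",
         scene$true_icd_um, " um")
  }
  set.seed(scene$seed)
  th <- scene$orientation_deg * pi / 180
  u <- c(cos(th), -sin(th))   # along-capillary direction (dc, dr)
  v <- c(-u[2], u[1])         # across direction
  centre <- c((nc + 1) / 2, (nr + 1) / 2)  # (x, y)
  offs <- seq(-half_diag, half_diag, by = spacing_px)
  offs <- offs + stats::rnorm(length(offs), 0, scene$icd_jitter_frac * spacing_px)
  amp_px <- scene$tortuosity_amp_um / upp
  period_px <- 100
  tstep <- 0.5
  tt <- seq(-half_diag, half_diag, by = tstep)
  sigma_px <- (scene$true_diameter_um / upp) / (2 * sqrt(2 * log(2)))

  pts_x <- list(); pts_y <- list(); pts_w <- list()
  phases <- stats::runif(length(offs), 0, 2 * pi)
  for (i in seq_along(offs)) {
    w <- amp_px * sin(2 * pi * tt / period_px + phases[i])
    x <- centre[1] + tt * u[1] + (offs[i] + w) * v[1]
    y <- centre[2] + tt * u[2] + (offs[i] + w) * v[2]
    # along-vessel brightness modulation: OCTA decorrelation signal is not
    # uniform along a capillary; this texture also makes the along-vessel
    # translation component observable to registration
    bright <- stats::runif(1, 0.75, 1)
    lam <- stats::runif(2, 30, 90); ph2 <- stats::runif(2, 0, 2 * pi)
    mod <- pmax(1 + 0.18 * sin(2 * pi * tt / lam[1] + ph2[1]) +
                    0.12 * sin(2 * pi * tt / lam[2] + ph2[2]), 0.3)
    keep <- x >= 1 & x <= nc & y >= 1 & y <= nr
    pts_x[[i]] <- x[keep]; pts_y[[i]] <- y[keep]
    pts_w[[i]] <- bright * mod[keep]
  }
  # sparse anastomoses: short links between adjacent capillaries
  n_links <- stats::rpois(1, scene$anastomosis_rate * max(length(offs) - 1, 0))
  if (n_links > 0) {
    for (k in seq_len(n_links)) {
      i <- sample(length(offs) - 1, 1)
      t0 <- stats::runif(1, -half_diag / 2, half_diag / 2)
      svals <- seq(offs[i], offs[i + 1], by = tstep * sign(offs[i + 1] - offs[i]))
      x <- centre[1] + t0 * u[1] + svals * v[1]
      y <- centre[2] + t0 * u[2] + svals * v[2]
      keep <- x >= 1 & x <= nc & y >= 1 & y <= nr
      pts_x[[length(pts_x) + 1]] <- x[keep]
      pts_y[[length(pts_y) + 1]] <- y[keep]
      pts_w[[length(pts_w) + 1]] <- rep(stats::runif(1, 0.6, 0.9), sum(keep))
    }
  }
  xs <- unlist(pts_x); ys <- unlist(pts_y); ws <- unlist(pts_w)
  if (length(xs) == 0) stop("no capillary points fall inside the image")

  # rasterised centreline map
  cmap <- matrix(FALSE, nr, nc)
  cmap[cbind(round(ys), round(xs))] <- TRUE

  # noise-free render: accumulate Gaussian cross-sections around each
  # centreline sample on a 5x5 neighbourhood, then normalise to [0,1]
  rad <- max(2L, ceiling(3 * sigma_px))
  offgrid <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  n <- length(xs)
  ii <- jj <- vv <- vector("list", nrow(offgrid))
  r0 <- round(ys); c0 <- round(xs)
  for (g in seq_len(nrow(offgrid))) {
    rr <- r0 + offgrid$dr[g]; cc <- c0 + offgrid$dc[g]
    d2 <- (rr - ys)^2 + (cc - xs)^2
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ii[[g]] <- rr[ok]; jj[[g]] <- cc[ok]
    vv[[g]] <- ws[ok] * exp(-d2[ok] / (2 * sigma_px^2))
  }
  acc <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                              dims = c(nr, nc))
  clean <- as.matrix(acc)
  clean <- clean / max(clean)

  # ground-truth density from the rasterised map (what a perfect skeleton
  # of this field would measure): geometric step lengths / field area
  len_px <- skeleton_path_length(cmap)
  area_mm2 <- (nr * upp / 1000) * (nc * upp / 1000)
  truth <- list(centerline_map = cmap,
                clean_image = clean,
                true_density_mm_inv = (len_px * upp / 1000) / area_mm2,
                true_icd_um = scene$true_icd_um,
                true_transforms = NULL)
  class(truth) <- "ground_truth"
  truth
}

#' Render one noisy frame of a scene
#'
#' Applies, in order: the frame's rigid misalignment (frame 1 is the
#' untransformed reference), multiplicative speckle with pixelwise factor
#' Normal(1, speckle_sigma) clipped at 0, additive Normal(0,
#' additive_sigma) noise, then per-row motion-artifact lines (a row is
#' replaced by a brightened or attenuated copy of itself with probability
#' \code{motion_line_prob}); the result is clipped to [0,1]. Each frame
#' uses its own deterministic noise stream derived from (seed, frame).
#'
#' @param truth A \code{ground_truth} from \code{generate_capillary_map}.
#' @param scene The \code{synthetic_scene}.
#' @param frame_index 1-based frame number.
#' @return Numeric matrix in [0,1]; NA where the misaligned frame has no
#'   data.
#' @export
render_frame <- function(truth, scene, frame_index) {
  stopifnot(frame_index >= 1)
  img <- truth$clean_image
  tf <- NULL
  if (!is.null(truth$true_transforms) &&
      frame_index <= length(truth$true_transforms)) {
    tf <- truth$true_transforms[[frame_index]]
  }
  if (!is.null(tf) && !is_identity_transform(tf)) img <- apply_transform(img, tf)
  set.seed(derive_seed(scene$seed, frame_index))
  nr <- nrow(img); nc <- ncol(img)
  if (scene$speckle_sigma > 0) {
    img <- img * pmax(matrix(stats::rnorm(nr * nc, 1, scene$speckle_sigma), nr), 0)
  }
  if (scene$additive_sigma > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, scene$additive_sigma), nr)
  }
  if (scene$motion_line_prob > 0) {
    hit <- stats::runif(nr) < scene$motion_line_prob
    for (r in which(hit)) {
      gain <- if (stats::runif(1) < 0.5) stats::runif(1, 0.2, 0.6)
              else stats::runif(1, 1.5, 2.0)
      img[r, ] <- img[r, ] * gain + stats::runif(1, 0, 0.1)
    }
  }
  clamp(img, 0, 1)
}

#' Simulate a multi-frame en-face stack with known misalignment
#'
#' Frame 1 is the untransformed reference; frames 2..n receive independent
#' uniform rigid misalignments within \code{shift_range_px} /
#' \code{rot_range_deg}. Every applied transform is recorded in the
#' returned ground truth.
#'
#' @param scene A \code{synthetic_scene}.
#' @param scale A \code{scale_model}.
#' @param n_frames Number of frames (>= 1).
#' @return List with \code{stack} (a \code{frame_stack}) and \code{truth}
#'   (a \code{ground_truth} with \code{true_transforms}).
#' @export
simulate_stack <- function(scene, scale, n_frames = 10L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  truth <- generate_capillary_map(scene, scale)
  set.seed(derive_seed(scene$seed, 999983))
  tfs <- vector("list", n_frames)
  tfs[[1]] <- rigid_transform(0, 0, 0)
  if (n_frames > 1) {
    for (i in 2:n_frames) {
      tfs[[i]] <- rigid_transform(
        dx_px = stats::runif(1, -scene$shift_range_px, scene$shift_range_px),
        dy_px = stats::runif(1, -scene$shift_range_px, scene$shift_range_px),
        theta_deg = stats::runif(1, -scene$rot_range_deg, scene$rot_range_deg))
    }
  }
  truth$true_transforms <- tfs
  frames <- lapply(seq_len(n_frames), function(i) render_frame(truth, scene, i))
  list(stack = frame_stack(frames, scale = scale), truth = truth)
}

#' An ordered stack of en-face frames
#'
#' @param frames List of numeric matrices sharing dimensions.
#' @param scale A \code{scale_model}.
#' @param reference_index 1-based index of the reference frame.
#' @return A \code{frame_stack}.
#' @export
frame_stack <- function(frames, scale = scale_model(), reference_index = 1L) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share dimensions")
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(frames)) {
    stop("reference_index out of range")
  }
  out <- list(frames = frames, scale = scale,
              reference_index = reference_index,
              registered = FALSE, transforms = NULL,
              unregistrable = logical(length(frames)))
  class(out) <- "frame_stack"
  out
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frame(s) %dx%d, reference %d, %s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$reference_index,
              if (x$registered) "registered" else "unregistered"))
  invisible(x)
}

n_frames <- function(stack) length(stack$frames)

#' Write a frame stack as a multi-page TIFF with a JSON sidecar
#'
#' @param stack A \code{frame_stack}.
#' @param path Output TIFF path; the sidecar is written at
#'   \code{<path>.json}.
#' @param scene Optional \code{synthetic_scene} to record.
#' @param truth Optional \code{ground_truth}; its transforms are recorded.
#' @param bits 8 or 16 bits per sample.
#' @return \code{path}, invisibly.
#' @export
write_stack_tiff <- function(stack, path, scene = NULL, truth = NULL, bits = 16L) {
  frames <- lapply(stack$frames, function(f) { f[is.na(f)] <- 0; clamp(f, 0, 1) })
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits))
  side <- list(reference_index = stack$reference_index,
               n_frames = length(frames),
               bits = bits,
               scale = unclass(stack$scale))
  if (!is.null(scene)) side$scene <- unclass(scene)
  if (!is.null(truth) && !is.null(truth$true_transforms)) {
    side$true_transforms <- lapply(truth$true_transforms, unclass)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF stack written by \code{write_stack_tiff}
#' @param path TIFF path.
#' @return A \code{frame_stack}; scale and reference index are restored
#'   from the JSON sidecar when present.
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  scale <- scale_model(); ref <- 1L
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$scale)) {
      scale <- scale_model(px_per_degree = side$scale$px_per_degree,
                           axial_length_mm = side$scale$axial_length_mm,
                           um_per_degree = side$scale$um_per_degree,
                           resize_factor = side$scale$resize_factor)
    }
    if (!is.null(side$reference_index)) ref <- as.integer(side$reference_index)
  }
  frame_stack(frames, scale = scale, reference_index = ref)
}
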