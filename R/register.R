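# Rigid stack registration: reference selection, phase-correlation
# translation estimation with a 1-D angular search for rotation, and
# transform transfer between stacks (the deep-layer fallback, where
# transforms estimated on a higher-contrast stack of the same eye are
# applied to the low-contrast superficial stack).

#' Select the reference frame of a stack
#'
#' Automated proxy for picking the frame with "highest contrast and least
#' motion artifact": score = interquartile range of intensity minus
#' \code{lambda} times the fraction of rows/columns whose mean deviates
#' more than 3 SD from the mean row/column level. Ties break to the lowest
#' index.
#'
#' @param stack A \code{frame_stack}.
#' @param lambda Weight of the artifact-line penalty (default 1).
#' @return Integer frame index.
#' @export
select_reference <- function(stack, lambda = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  if (n_frames(stack) == 0L) stop("empty stack")
  score <- vapply(stack$frames, function(f) {
    v <- f[!is.na(f)]
    iqr <- stats::IQR(v)
    rm_ <- rowMeans(f, na.rm = TRUE); cm_ <- colMeans(f, na.rm = TRUE)
    bad <- sum(abs(rm_ - mean(rm_)) > 3 * stats::sd(rm_)) +
           sum(abs(cm_ - mean(cm_)) > 3 * stats::sd(cm_))
    iqr - lambda * bad / (length(rm_) + length(cm_))
  }, numeric(1))
  which.max(score)  # ties -> lowest index
}

hann_window <- function(nr, nc) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wr, wc)
}

# Mild low-pass before correlation: suppresses the white speckle that
# otherwise swamps the weak along-vessel texture carrying the
# along-stripe translation component.
prep_for_corr <- function(img, blur_sigma = 1.5) {
  m <- mean(img, na.rm = TRUE)
  img[is.na(img)] <- m
  if (blur_sigma > 0) img <- gaussian_local_mean(img, 6 * blur_sigma)
  (img - mean(img)) * hann_window(nrow(img), ncol(img))
}

# Windowed cross-correlation of two preprocessed images; integer peak from
# the FFT correlation surface, then sub-pixel refinement by evaluating the
# correlation on an upsampled neighbourhood directly from the cross-power
# spectrum (matrix-DFT local upsampling). Returns the (dx, dy) shifting
# `mov` onto `ref` plus the peak score.
cross_correlate <- function(ref_f, mov_w, up = 20, halfw = 1.5) {
  G <- ref_f * Conj(stats::fft(mov_w))
  r <- Re(stats::fft(G, inverse = TRUE)) / length(G)
  nr <- nrow(r); nc <- ncol(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  s0 <- c(pk[1] - 1, pk[2] - 1)
  s0 <- ifelse(s0 > c(nr, nc) / 2, s0 - c(nr, nc), s0)
  kr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1))
  kc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  ur <- seq(s0[1] - halfw, s0[1] + halfw, by = 1 / up)
  uc <- seq(s0[2] - halfw, s0[2] + halfw, by = 1 / up)
  Er <- exp(2i * pi * outer(ur, kr) / nr)
  Ec <- exp(2i * pi * outer(kc, uc) / nc)
  cc <- Re(Er %*% G %*% Ec)
  pk2 <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  list(dy = ur[pk2[1]], dx = uc[pk2[2]], score = max(cc))
}

#' Estimate the rigid transform aligning a moving frame to a reference
#'
#' Phase correlation for translation combined with a coarse-to-fine search
#' over rotation: each candidate angle rotates the moving frame, phase
#' correlation scores the residual translation, and the best angle is
#' refined by a parabolic fit over the score curve.
#'
#' @param moving,reference Numeric matrices of equal size.
#' @param rot_range_deg Half-width of the rotation search (degrees). Set
#'   to 0 to estimate translation only.
#' @param coarse_step_deg,fine_step_deg Angular search steps.
#' @return A \code{rigid_transform} t such that
#'   \code{apply_transform(moving, t)} aligns with \code{reference}.
#' @export
estimate_rigid <- function(moving, reference, rot_range_deg = 3,
                           coarse_step_deg = 0.5, fine_step_deg = 0.1) {
  stopifnot(all(dim(moving) == dim(reference)))
  if (stats::sd(moving, na.rm = TRUE) == 0 ||
      stats::sd(reference, na.rm = TRUE) == 0) {
    stop("unregistrable: constant image")
  }
  ref_f <- stats::fft(prep_for_corr(reference))
  score_at <- function(theta) {
    rot <- if (theta == 0) moving else
      apply_transform(moving, rigid_transform(0, 0, theta))
    pc <- cross_correlate(ref_f, prep_for_corr(rot))
    pc$theta <- theta
    pc
  }
  if (rot_range_deg <= 0) {
    best <- score_at(0)
    theta <- 0
  } else {
    thetas <- seq(-rot_range_deg, rot_range_deg, by = coarse_step_deg)
    coarse <- lapply(thetas, score_at)
    sc <- vapply(coarse, `[[`, numeric(1), "score")
    t0 <- thetas[which.max(sc)]
    fine <- seq(t0 - coarse_step_deg, t0 + coarse_step_deg, by = fine_step_deg)
    finesc <- vapply(fine, function(th) score_at(th)$score, numeric(1))
    i <- which.max(finesc)
    theta <- fine[i]
    if (i > 1 && i < length(fine)) {  # parabolic refinement on the score
      den <- finesc[i - 1] - 2 * finesc[i] + finesc[i + 1]
      if (den < 0) {
        theta <- theta + clamp(0.5 * (finesc[i - 1] - finesc[i + 1]) / den,
                               -1, 1) * fine_step_deg
      }
    }
    best <- score_at(theta)
  }
  t1 <- rigid_transform(dx_px = best$dx, dy_px = best$dy, theta_deg = theta)
  # second pass: re-estimate the residual translation after warping, which
  # removes the small window-induced bias of the first correlation
  warped <- apply_transform(moving, t1)
  res <- cross_correlate(ref_f, prep_for_corr(warped))
  rigid_transform(dx_px = t1$dx_px + res$dx, dy_px = t1$dy_px + res$dy,
                  theta_deg = theta)
}

#' Register every frame of a stack to its reference frame
#'
#' Frames are resampled into the reference frame's coordinates with
#' bicubic interpolation; out-of-field pixels become invalid (NA). The
#' reference frame itself is untouched. A frame whose registration fails
#' is flagged \code{unregistrable}, never silently dropped.
#'
#' @param stack A \code{frame_stack}.
#' @param rot_range_deg Rotation search half-width (0 disables rotation).
#' @return The registered \code{frame_stack} with per-frame
#'   \code{transforms} recorded.
#' @export
register_stack <- function(stack, rot_range_deg = 3) {
  stopifnot(inherits(stack, "frame_stack"))
  ref_i <- stack$reference_index
  if (n_frames(stack) == 1L) {
    stack$registered <- TRUE
    stack$transforms <- list(rigid_transform(0, 0, 0))
    return(stack)
  }
  ref <- stack$frames[[ref_i]]
  tfs <- vector("list", n_frames(stack))
  for (i in seq_len(n_frames(stack))) {
    if (i == ref_i) {
      tfs[[i]] <- rigid_transform(0, 0, 0)
      next
    }
    t_i <- tryCatch(
      estimate_rigid(stack$frames[[i]], ref, rot_range_deg = rot_range_deg),
      error = function(e) NULL)
    if (is.null(t_i)) {
      stack$unregistrable[i] <- TRUE
      tfs[[i]] <- rigid_transform(0, 0, 0)
      next
    }
    tfs[[i]] <- t_i
    stack$frames[[i]] <- apply_transform(stack$frames[[i]], t_i)
  }
  stack$transforms <- tfs
  stack$registered <- TRUE
  stack
}

#' Apply externally estimated transforms to a stack
#'
#' The deep-layer fallback: transforms estimated on a second stack of the
#' same eye (e.g. a deeper, higher-contrast slab) are applied frame by
#' frame without re-estimation.
#'
#' @param target A \code{frame_stack}.
#' @param transforms List of \code{rigid_transform}, one per frame.
#' @return The transformed, registered \code{frame_stack}.
#' @export
transfer_transforms <- function(target, transforms) {
  stopifnot(inherits(target, "frame_stack"))
  if (length(transforms) != n_frames(target)) {
    stop("need exactly one transform per frame (got ", length(transforms),
         " for ", n_frames(target), " frames)")
  }
  for (i in seq_len(n_frames(target))) {
    if (!is_identity_transform(transforms[[i]])) {
      target$frames[[i]] <- apply_transform(target$frames[[i]], transforms[[i]])
    }
  }
  target$transforms <- transforms
  target$registered <- TRUE
  target
}

#' Serialize stack transforms to JSON
#' @param stack A registered \code{frame_stack}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_transforms_json <- function(stack, path) {
  stopifnot(stack$registered)
  jsonlite::write_json(
    list(reference_index = stack$reference_index,
         transforms = lapply(stack$transforms, unclass)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read transforms serialized by \code{write_transforms_json}
#' @param path JSON path.
#' @return List with \code{reference_index} and \code{transforms}.
#' @export
read_transforms_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(reference_index = as.integer(x$reference_index),
       transforms = lapply(x$transforms, function(t)
         rigid_transform(t$dx_px, t$dy_px, t$theta_deg)))
}
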