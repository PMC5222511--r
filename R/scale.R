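#' Physical scale of an en-face angiogram
#'
#' Captures the sampling of a 10x10 degree, 304x304 pixel en-face OCTA scan
#' and the retinal magnification implied by the eye's axial length. The
#' retinal extent of one degree of visual angle is scaled linearly with
#' axial length around a 24 mm emmetropic eye (Bennett-style correction),
#' so \code{um_per_degree = 291 * axial_length_mm / 24}.
#'
#' @param px_per_degree Pixels per degree of visual angle. The default
#'   304/10 = 30.4 matches a 304-pixel, 10-degree scan.
#' @param axial_length_mm Axial length of the imaged eye in millimetres.
#' @param um_per_degree Retinal microns per degree. Defaults to the
#'   axial-length-scaled value; pass explicitly to override.
#' @param resize_factor Integer upsampling factor applied before
#'   binarization/skeletonization (default 6, i.e. 60 px ROI -> 360 px).
#' @return An object of class \code{scale_model}.
#' @examples
#' sc <- scale_model()
#' um_per_px(sc)   # ~9.57 um per original pixel
#' @export
scale_model <- function(px_per_degree = 30.4, axial_length_mm = 24,
                        um_per_degree = 291 * axial_length_mm / 24,
                        resize_factor = 6L) {
  stopifnot(px_per_degree > 0, um_per_degree > 0, axial_length_mm > 0)
  resize_factor <- as.integer(resize_factor)
  if (resize_factor < 1L) stop("resize_factor must be >= 1")
  out <- list(px_per_degree = px_per_degree,
              um_per_degree = um_per_degree,
              axial_length_mm = axial_length_mm,
              resize_factor = resize_factor)
  class(out) <- "scale_model"
  out
}

#' Microns per pixel at the original scan resolution
#' @param scale A \code{scale_model}.
#' @param resized If \code{TRUE}, return microns per pixel at the upsampled
#'   (quantification) resolution.
#' @return Microns per pixel (positive scalar).
#' @export
um_per_px <- function(scale, resized = FALSE) {
  v <- scale$um_per_degree / scale$px_per_degree
  if (resized) v <- v / scale$resize_factor
  stopifnot(is.finite(v), v > 0)
  v
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("scale_model: %.2f px/deg, %.1f um/deg (AL %.1f mm), %.3f um/px, resize x%d\n",
              x$px_per_degree, x$um_per_degree, x$axial_length_mm,
              um_per_px(x), x$resize_factor))
  invisible(x)
}
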