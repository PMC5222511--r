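# Optic-disc geometry: least-squares ellipse fit to clicked disc-margin
# points, placement of the five peripapillary ROIs (S, ST, T, IT, I) one
# degree outside the disc margin, and the narrow ICD sampling box whose
# long axis runs perpendicular to the local capillary direction.
#
# Geometry works in the (x = col, y = row) plane. Direction angles follow
# the fundus convention: 0 deg = temporal (+x for a right eye), 90 deg =
# superior (towards the top of the image, i.e. decreasing row).

#' An optic-disc ellipse
#' @param center_px Numeric (row, col) of the centre.
#' @param semi_axes_px Numeric (a, b), a >= b > 0.
#' @param tilt_deg Rotation of the major axis from the +x (column) axis,
#'   degrees, positive towards the top of the image.
#' @param rms_residual_px Optional fit residual.
#' @return A \code{disc_ellipse}.
#' @export
disc_ellipse <- function(center_px, semi_axes_px, tilt_deg = 0,
                         rms_residual_px = NA_real_) {
  a <- unname(semi_axes_px[1]); b <- unname(semi_axes_px[2])
  tilt_deg <- unname(tilt_deg)
  if (b > a) { tmp <- a; a <- b; b <- tmp; tilt_deg <- tilt_deg + 90 }
  stopifnot(a >= b, b > 0)
  out <- list(center_px = unname(as.numeric(center_px)),
              semi_axes_px = c(a, b),
              tilt_deg = ((tilt_deg + 90) %% 180) - 90,
              rms_residual_px = rms_residual_px)
  class(out) <- "disc_ellipse"
  out
}

#' Fit an ellipse to disc-margin points by direct least squares
#'
#' Numerically stable direct conic fit constrained to an ellipse
#' (Halir-Flusser formulation of the Fitzgibbon method).
#'
#' @param points Two-column matrix or data.frame of (row, col) pixel
#'   coordinates; at least 5 non-collinear points.
#' @return A \code{disc_ellipse} with the RMS point-to-ellipse residual.
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5) stop("need at least 5 margin points")
  y <- points[, 1]; x <- points[, 2]
  # centre and scale for conditioning
  mx <- mean(x); my <- mean(y); s <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(s) || s == 0) stop("degenerate point configuration")
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration"))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("points do not determine an ellipse")
  a1 <- V[, ok[1]]
  coef <- c(a1, Tm %*% a1)          # A,B,C,D,E,F in scaled frame
  names(coef) <- c("A", "B", "C", "D", "E", "F")
  # unscale: substitute x = (X - mx)/s etc.
  A <- coef["A"] / s^2; B <- coef["B"] / s^2; C <- coef["C"] / s^2
  D <- -2 * coef["A"] * mx / s^2 - coef["B"] * my / s^2 + coef["D"] / s
  E <- -2 * coef["C"] * my / s^2 - coef["B"] * mx / s^2 + coef["E"] / s
  Fc <- coef["A"] * mx^2 / s^2 + coef["B"] * mx * my / s^2 +
    coef["C"] * my^2 / s^2 - coef["D"] * mx / s - coef["E"] * my / s +
    coef["F"]
  # conic -> geometric parameters
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  root <- sqrt((A - C)^2 + B^2)
  a_ax <- -sqrt(num * (A + C + root)) / den
  b_ax <- -sqrt(num * (A + C - root)) / den
  tilt <- if (B == 0 && A <= C) 0 else if (B == 0) 90 else
    atan2(C - A - root, B) * 180 / pi
  # y is row (down); tilt in image terms: angle towards top is -atan in xy
  ell <- disc_ellipse(center_px = c(cy, cx), semi_axes_px = c(a_ax, b_ax),
                      tilt_deg = -tilt)
  ell$rms_residual_px <- ellipse_rms_residual(ell, points)
  ell
}

# Approximate geometric residual: radial distance from each point to the
# ellipse along the ray from the centre.
ellipse_rms_residual <- function(ell, points) {
  y <- points[, 1] - ell$center_px[1]
  x <- points[, 2] - ell$center_px[2]
  th <- -ell$tilt_deg * pi / 180   # back to xy angle
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  q <- sqrt((xr / ell$semi_axes_px[1])^2 + (yr / ell$semi_axes_px[2])^2)
  r <- sqrt(x^2 + y^2)
  sqrt(mean((r * (1 - 1 / pmax(q, 1e-12)))^2))
}

# Distance from the ellipse centre to its boundary along fundus-direction
# angle (deg).
ellipse_boundary_distance <- function(ell, angle_deg) {
  # unit direction in (x, y=row) with angle measured towards image top
  ux <- cos(angle_deg * pi / 180)
  uy <- -sin(angle_deg * pi / 180)
  th <- -ell$tilt_deg * pi / 180
  xr <- cos(th) * ux + sin(th) * uy
  yr <- -sin(th) * ux + cos(th) * uy
  1 / sqrt((xr / ell$semi_axes_px[1])^2 + (yr / ell$semi_axes_px[2])^2)
}

roi_angles <- function(laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  ang <- c(S = 90, ST = 45, T = 0, IT = -45, I = -90)
  if (laterality == "OS") ang <- c(S = 90, ST = 135, T = 180, IT = -135, I = -90)
  ang
}

#' Place the five peripapillary ROIs around the disc
#'
#' Each ~2x2 degree box is centred one degree outside the disc margin
#' along its sector direction (superior, superotemporal, temporal,
#' inferotemporal, inferior; mirrored horizontally for left eyes). The
#' expected capillary orientation in each ROI is radial, i.e. the sector
#' direction itself. Boxes extending beyond the image are flagged
#' excluded rather than clipped.
#'
#' @param ellipse A \code{disc_ellipse}.
#' @param scale A \code{scale_model}.
#' @param laterality "OD" (right eye) or "OS".
#' @param image_size_px Integer (rows, cols) of the full image.
#' @param manual_offsets Optional named list of (drow, dcol) pixel shifts
#'   per label, emulating the manual nudge used to avoid major vessels.
#' @param side_px ROI side length in pixels (default 60, i.e. ~2 deg).
#' @return List of \code{roi_spec}: label, box (r0, r1, c0, c1 inclusive),
#'   center_px, vessel_orientation_deg, excluded, reason.
#' @export
place_rois <- function(ellipse, scale, laterality = "OD",
                       image_size_px = c(304L, 304L),
                       manual_offsets = NULL, side_px = 60L) {
  angles <- roi_angles(laterality)
  half <- side_px / 2
  one_deg <- scale$px_per_degree
  lapply(names(angles), function(lbl) {
    ang <- angles[[lbl]]
    d <- ellipse_boundary_distance(ellipse, ang) + one_deg
    cx <- ellipse$center_px[2] + d * cos(ang * pi / 180)
    cy <- ellipse$center_px[1] - d * sin(ang * pi / 180)
    if (!is.null(manual_offsets[[lbl]])) {
      cy <- cy + manual_offsets[[lbl]][1]
      cx <- cx + manual_offsets[[lbl]][2]
    }
    r0 <- round(cy - half) + 1L; c0 <- round(cx - half) + 1L
    box <- c(r0 = r0, r1 = r0 + side_px - 1L, c0 = c0, c1 = c0 + side_px - 1L)
    excluded <- box["r0"] < 1 || box["c0"] < 1 ||
      box["r1"] > image_size_px[1] || box["c1"] > image_size_px[2]
    out <- list(label = lbl, box = box, center_px = c(cy, cx),
                vessel_orientation_deg = ang,
                excluded = excluded,
                reason = if (excluded) "ROI extends beyond image" else NA_character_)
    class(out) <- "roi_spec"
    out
  })
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("roi_spec %s: rows %d..%d, cols %d..%d, orient %g deg%s\n",
              x$label, x$box["r0"], x$box["r1"], x$box["c0"], x$box["c1"],
              x$vessel_orientation_deg,
              if (isTRUE(x$excluded)) paste0(" [excluded: ", x$reason, "]") else ""))
  invisible(x)
}

#' The 0.1 x 1 degree ICD sampling box of an ROI
#'
#' Returns the sampling geometry for the intercapillary-distance profile:
#' a box 0.1 degree wide and 1 degree long, centred in the ROI, with its
#' long axis perpendicular to the expected vessel orientation. The
#' averaged intensity profile runs along the long axis.
#'
#' @param roi A non-excluded \code{roi_spec}.
#' @param scale A \code{scale_model}.
#' @return List: \code{center_px} (row, col), \code{length_px} (long
#'   axis), \code{width_px}, \code{profile_angle_deg} (direction of the
#'   long axis, fundus convention), and unit vectors \code{u_long},
#'   \code{u_wide} as (drow, dcol).
#' @export
icd_sampling_box <- function(roi, scale) {
  if (isTRUE(roi$excluded)) stop("ROI is excluded")
  len <- max(1L, round(1 * scale$px_per_degree))
  wid <- max(1L, round(0.1 * scale$px_per_degree))
  ang <- roi$vessel_orientation_deg + 90
  u_long <- c(-sin(ang * pi / 180), cos(ang * pi / 180))   # (drow, dcol)
  u_wide <- c(-sin(roi$vessel_orientation_deg * pi / 180),
              cos(roi$vessel_orientation_deg * pi / 180))
  ctr <- c(mean(roi$box[c("r0", "r1")]), mean(roi$box[c("c0", "c1")]))
  list(center_px = unname(ctr), length_px = len, width_px = wid,
       profile_angle_deg = ang, u_long = u_long, u_wide = u_wide)
}

#' Read clicked disc-margin points from CSV
#'
#' The CSV has columns x, y in 0-based pixel coordinates (x = column);
#' they are converted to 1-based (row, col).
#'
#' @param path CSV path.
#' @return Two-column matrix (row, col).
#' @export
read_margin_points <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x", "y") %in% names(d)))
  cbind(row = d$y + 1, col = d$x + 1)
}
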