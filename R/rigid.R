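#' Rigid (translation + rotation) transform of an en-face frame
#'
#' The transform rotates image content by \code{theta_deg} about the image
#' centre (positive = counter-clockwise in standard x/y axes, i.e. with
#' the row axis pointing down the rotation appears clockwise on screen)
#' and then translates it by \code{dx_px} columns and \code{dy_px} rows.
#'
#' @param dx_px,dy_px Translation in pixels (columns, rows).
#' @param theta_deg Rotation in degrees about the image centre.
#' @return A \code{rigid_transform} object.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0) {
  out <- list(dx_px = dx_px, dy_px = dy_px, theta_deg = theta_deg)
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: dx %.3f px, dy %.3f px, theta %.3f deg\n",
              x$dx_px, x$dy_px, x$theta_deg))
  invisible(x)
}

is_identity_transform <- function(t, tol = 0) {
  abs(t$dx_px) <= tol && abs(t$dy_px) <= tol && abs(t$theta_deg) <= tol
}

#' Invert a rigid transform
#' @param t A \code{rigid_transform}.
#' @return The inverse transform (same class).
#' @export
invert_transform <- function(t) {
  th <- -t$theta_deg * pi / 180
  # inverse: undo translation, then rotate back
  rigid_transform(dx_px = -(cos(th) * t$dx_px - sin(th) * t$dy_px),
                  dy_px = -(sin(th) * t$dx_px + cos(th) * t$dy_px),
                  theta_deg = -t$theta_deg)
}

#' Compose two rigid transforms (apply \code{a} first, then \code{b})
#' @param a,b \code{rigid_transform} objects.
#' @return The composed transform.
#' @export
compose_transforms <- function(a, b) {
  thb <- b$theta_deg * pi / 180
  rigid_transform(
    dx_px = cos(thb) * a$dx_px - sin(thb) * a$dy_px + b$dx_px,
    dy_px = sin(thb) * a$dx_px + cos(thb) * a$dy_px + b$dy_px,
    theta_deg = a$theta_deg + b$theta_deg)
}

# Map output-pixel coordinates back to source coordinates under t.
inverse_map <- function(t, r, c, centre) {
  th <- t$theta_deg * pi / 180
  x <- c - t$dx_px - centre[2]
  y <- r - t$dy_px - centre[1]
  # rotate by -theta (x right, y down: screen-clockwise positive theta)
  xs <- cos(th) * x + sin(th) * y
  ys <- -sin(th) * x + cos(th) * y
  list(r = ys + centre[1], c = xs + centre[2])
}

#' Resample a frame under a rigid transform
#'
#' Bicubic resampling; output pixels whose source location falls outside
#' the input field are marked invalid (NA) rather than zero-filled, so
#' downstream ROI averaging can detect missing coverage.
#'
#' @param image Numeric matrix (NA = invalid).
#' @param t A \code{rigid_transform}.
#' @return Transformed matrix, same size.
#' @export
apply_transform <- function(image, t) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is_identity_transform(t)) return(image)
  nr <- nrow(image); nc <- ncol(image)
  centre <- c((nr + 1) / 2, (nc + 1) / 2)
  rr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  src <- inverse_map(t, rr, cc, centre)
  matrix(interp_bicubic(image, src$r, src$c), nrow = nr)
}
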