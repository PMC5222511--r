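# Low-level raster utilities shared by the simulation, registration and
# quantification stages. Images are plain numeric matrices, [row, col],
# row 1 at the top; invalid (out-of-field) pixels are NA.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Cubic-convolution interpolation kernel (Keys, a = -0.5); the classic
# "bicubic" used by imresize-style resampling.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

#' Sample an image at fractional coordinates with bicubic interpolation
#'
#' @param img Numeric matrix; NA marks invalid pixels.
#' @param r,c Equal-length vectors of fractional row/col coordinates
#'   (1-based).
#' @param fill Value returned for samples outside the image (default NA,
#'   i.e. invalid).
#' @return Numeric vector of sampled values; a sample touching an NA pixel
#'   is NA.
#' @keywords internal
interp_bicubic <- function(img, r, c, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  inside <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(inside)) return(out)
  r <- r[inside]; c <- c[inside]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  acc <- numeric(length(r))
  wr <- list(); wc <- list()
  for (k in -1:2) {
    wr[[k + 2]] <- cubic_kernel(fr - k)
    wc[[k + 2]] <- cubic_kernel(fc - k)
  }
  for (k in -1:2) {
    rr <- clamp(r0 + k, 1, nr)
    for (l in -1:2) {
      cc <- clamp(c0 + l, 1, nc)
      acc <- acc + wr[[k + 2]] * wc[[l + 2]] * img[cbind(rr, cc)]
    }
  }
  out[inside] <- acc
  out
}

#' Bilinear sampling at fractional coordinates
#' @inheritParams interp_bicubic
#' @keywords internal
interp_bilinear <- function(img, r, c, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  inside <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(inside)) return(out)
  r <- r[inside]; c <- c[inside]
  r0 <- clamp(floor(r), 1, nr - 1); c0 <- clamp(floor(c), 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
       (1 - fr) * fc       * img[cbind(r0, c0 + 1)] +
       fr       * (1 - fc) * img[cbind(r0 + 1, c0)] +
       fr       * fc       * img[cbind(r0 + 1, c0 + 1)]
  out[inside] <- v
  out
}

#' Upsample an image by an integer factor with bicubic interpolation
#'
#' Uses pixel-centre alignment: output pixel i samples input coordinate
#' (i - 0.5)/factor + 0.5, so a 60x60 ROI at factor 6 becomes 360x360.
#'
#' @param img Numeric matrix.
#' @param factor Integer >= 1.
#' @return Matrix of size dim(img) * factor.
#' @export
resize_bicubic <- function(img, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(img)
  B <- function(n) {
    x <- clamp(((seq_len(n * factor) - 0.5) / factor) + 0.5, 1, n)
    x0 <- floor(x)
    i <- integer(0); j <- integer(0); w <- numeric(0)
    for (k in -1:2) {
      i <- c(i, seq_len(n * factor))
      j <- c(j, clamp(x0 + k, 1, n))
      w <- c(w, cubic_kernel(x - x0 - k))
    }
    Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n * factor, n))
  }
  Br <- B(nrow(img))
  Bc <- if (ncol(img) == nrow(img)) Br else B(ncol(img))
  as.matrix(Br %*% img %*% Matrix::t(Bc))
}

# Gaussian-weighted local mean with edge renormalisation, computed as
# band-matrix products L %*% img %*% R. Near the border the truncated
# kernel is renormalised, which is equivalent to a normalised convolution.
gaussian_local_mean <- function(img, window) {
  sigma <- window / 6
  radius <- floor(window / 2)
  band <- function(n) {
    offs <- -radius:radius
    w <- exp(-offs^2 / (2 * sigma^2))
    M <- matrix(0, n, n)
    for (j in seq_along(offs)) {
      idx <- seq_len(n) + offs[j]
      ok <- idx >= 1 & idx <= n
      M[cbind(which(ok), idx[ok])] <- w[j]
    }
    M / rowSums(M)
  }
  L <- band(nrow(img))
  R <- band(ncol(img))
  L %*% img %*% t(R)
}

#' 8-connected component labeling of a binary matrix
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 for background, components numbered from 1.
#' @keywords internal
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- match(idx, idx)  # 1..n
  lut <- integer(nrow(mask) * ncol(mask))
  lut[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in c(1L, nr, nr + 1L, nr - 1L)) {  # down, right, down-right, up-right
    j <- idx + off
    r <- ((idx - 1L) %% nr) + 1L
    valid <- j >= 1L & j <= length(lut) &
      !(off == 1L & r == nr) & !(off == nr + 1L & r == nr) &
      !(off == nr - 1L & r == 1L)
    j <- j[valid]; i <- idx[valid]
    on <- lut[j] > 0L
    if (any(on)) edges <- c(edges, rbind(lut[i[on]], lut[j[on]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Count of 8-neighbourhood foreground pixels at every pixel (binary input).
neighbor_count8 <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  s <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + m[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  s
}
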