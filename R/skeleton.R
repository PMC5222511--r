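# Binary thinning and skeleton graph analysis.
#
# Skeletons are one-pixel-wide 8-connected centrelines. Endpoints are
# skeleton pixels with at most one 8-neighbour, branch points have at
# least three; 8-connected groups of branch pixels count as a single
# branch-point cluster. Segments are the connected components left after
# deleting branch clusters. Geometric length counts 1 per orthogonal step
# and sqrt(2) per diagonal step (diagonals that merely shortcut an
# orthogonal path are not double-counted).

# One Zhang-Suen thinning pass (vectorised); sub = 1 or 2.
zs_pass <- function(S, sub) {
  nr <- nrow(S); nc <- ncol(S)
  P <- matrix(0L, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- S
  sh <- function(dr, dc) P[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
       (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
       (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  if (sub == 1) {
    cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
  } else {
    cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
  }
  del <- S == 1 & B >= 2 & B <= 6 & A == 1 & cond
  S[del] <- 0L
  list(S = S, changed = any(del))
}

#' Thin a binary image to a one-pixel-wide skeleton (Zhang-Suen)
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same size.
#' @export
thin_binary <- function(mask) {
  S <- matrix(as.integer(mask != 0 & !is.na(mask)), nrow(mask))
  repeat {
    a <- zs_pass(S, 1); b <- zs_pass(a$S, 2)
    S <- b$S
    if (!a$changed && !b$changed) break
  }
  S == 1L
}

# Geometric path length of a thin binary structure: orthogonal adjacencies
# count 1, diagonal adjacencies sqrt(2) unless the two pixels already share
# an orthogonal skeleton neighbour (the diagonal would duplicate that path).
skeleton_path_length <- function(S) {
  S <- matrix(as.integer(S != 0), nrow(S))
  nr <- nrow(S); nc <- ncol(S)
  if (sum(S) == 0) return(0)
  P <- matrix(0L, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- S
  sh <- function(dr, dc) P[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  right <- sh(0, 1); down <- sh(1, 0); dr_ <- sh(1, 1); dl_ <- sh(1, -1)
  n_orth <- sum(S & right) + sum(S & down)
  # diagonal down-right between p=(i,j) and q=(i+1,j+1); common orth
  # neighbours are (i,j+1) and (i+1,j)
  keep_dr <- S & dr_ & !(right & down)
  # diagonal down-left between (i,j) and (i+1,j-1); common orth neighbours
  # are (i,j-1) and (i+1,j)
  left <- sh(0, -1)
  keep_dl <- S & dl_ & !(left & down)
  n_orth + sqrt(2) * (sum(keep_dr) + sum(keep_dl))
}

#' Skeletonize a binary vessel map and analyse its graph structure
#'
#' @param binary Logical or 0/1 matrix (at the resized quantification
#'   resolution).
#' @return A \code{skeleton_graph}: \code{skeleton} (logical matrix),
#'   \code{endpoints} / \code{branchpoints} (two-column row/col matrices;
#'   branch points are one representative pixel per 8-connected branch
#'   cluster), \code{n_branch_clusters}, \code{segments} (list of pixel
#'   index matrices), and \code{total_length_px_units}.
#' @export
skeletonize_roi <- function(binary) {
  skel <- thin_binary(binary)
  ncount <- neighbor_count8(skel)
  ep <- which(skel & ncount <= 1, arr.ind = TRUE)
  branch_pix <- skel & ncount >= 3
  bl <- label8(branch_pix)
  n_clusters <- max(bl)
  bp <- matrix(integer(0), 0, 2)
  if (n_clusters > 0) {
    idx <- which(bl > 0, arr.ind = TRUE)
    lab <- bl[bl > 0]
    # representative pixel: first pixel of each cluster
    first <- !duplicated(lab)
    bp <- idx[first, , drop = FALSE]
  }
  seg_mask <- skel & !branch_pix
  sl <- label8(seg_mask)
  nseg <- max(sl)
  segments <- vector("list", nseg)
  if (nseg > 0) {
    idx <- which(sl > 0, arr.ind = TRUE)
    segments <- split.data.frame(idx, sl[sl > 0])
  }
  out <- list(skeleton = skel,
              endpoints = ep,
              branchpoints = bp,
              n_branch_clusters = n_clusters,
              segments = segments,
              total_length_px_units = skeleton_path_length(skel))
  class(out) <- "skeleton_graph"
  out
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "skeleton_graph: %d px, %d endpoints, %d branch cluster(s), %d segment(s), length %.1f px\n",
    sum(x$skeleton), nrow(x$endpoints), x$n_branch_clusters,
    length(x$segments), x$total_length_px_units))
  invisible(x)
}
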