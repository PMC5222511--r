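# Shared fixtures and independent oracles, kept deliberately separate from
# the package's own code paths.

default_scale <- scale_model()

# a full-frame square ROI for ROI-sized test stacks
full_roi <- function(side = 60L, orientation = 0) {
  structure(list(label = "T",
                 box = c(r0 = 1L, r1 = side, c0 = 1L, c1 = side),
                 vessel_orientation_deg = orientation, excluded = FALSE,
                 reason = NA_character_),
            class = "roi_spec")
}

quiet_scene <- function(side = 60L, seed = 1L, ...) {
  args <- list(image_size_px = c(side, side), speckle_sigma = 0,
               additive_sigma = 0, motion_line_prob = 0,
               shift_range_px = 0, rot_range_deg = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_scene, args)
}

# Brute-force per-pixel endpoint/branch classification by explicit 3x3
# neighbour counting (loop-based, independent of the package's shifted-
# matrix implementation).
brute_neighbor_labels <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  ep <- matrix(FALSE, nr, nc); bp <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!skel[r, c]) next
      cnt <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && skel[rr, cc]) {
          cnt <- cnt + 1
        }
      }
      if (cnt <= 1) ep[r, c] <- TRUE
      if (cnt >= 3) bp[r, c] <- TRUE
    }
  }
  list(endpoints = ep, branchpoints = bp)
}

# Loop-based one-way within-subject ANOVA oracle: explicit sums of squares
# plus the Greenhouse-Geisser epsilon from eigenvalues of the
# double-centred covariance, written as plain loops.
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  g <- mean(Y)
  ss_s <- 0; for (i in 1:n) ss_s <- ss_s + k * (mean(Y[i, ]) - g)^2
  ss_c <- 0; for (j in 1:k) ss_c <- ss_c + n * (mean(Y[, j]) - g)^2
  ss_t <- 0; for (i in 1:n) for (j in 1:k) ss_t <- ss_t + (Y[i, j] - g)^2
  ss_e <- ss_t - ss_s - ss_c
  Fv <- (ss_c / (k - 1)) / (ss_e / ((n - 1) * (k - 1)))
  S <- matrix(0, k, k)
  cm <- colMeans(Y)
  for (a in 1:k) for (b in 1:k) {
    S[a, b] <- sum((Y[, a] - cm[a]) * (Y[, b] - cm[b])) / (n - 1)
  }
  C <- diag(k) - matrix(1 / k, k, k)
  lam <- eigen(C %*% S %*% C, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  list(F = Fv, eps = eps)
}
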