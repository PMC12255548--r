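# Independent brute-force oracles: naive, loop-based re-derivations of the
# texture matrices, Yen's criterion and morphological erosion, used to verify
# the package implementations on small instances.

bf_glcm <- function(W, dir) {
  lv <- sort(unique(as.vector(W)))
  n <- length(lv)
  M <- matrix(0L, n, n, dimnames = list(lv, lv))
  for (r in seq_len(nrow(W))) {
    for (c in seq_len(ncol(W))) {
      r2 <- r + dir[1]; c2 <- c + dir[2]
      if (r2 >= 1 && r2 <= nrow(W) && c2 >= 1 && c2 <= ncol(W)) {
        i <- match(W[r, c], lv); j <- match(W[r2, c2], lv)
        M[i, j] <- M[i, j] + 1L
        M[j, i] <- M[j, i] + 1L
      }
    }
  }
  M
}

bf_glrlm <- function(W, dir) {
  lv <- sort(unique(as.vector(W)))
  runs <- list()
  inb <- function(r, c) r >= 1 && r <= nrow(W) && c >= 1 && c <= ncol(W)
  for (r0 in seq_len(nrow(W))) {
    for (c0 in seq_len(ncol(W))) {
      # start of a line iff the previous cell along dir is outside
      if (inb(r0 - dir[1], c0 - dir[2])) next
      r <- r0; c <- c0
      cur <- W[r, c]; len <- 0L
      while (inb(r, c)) {
        if (W[r, c] == cur) {
          len <- len + 1L
        } else {
          runs[[length(runs) + 1]] <- c(cur, len)
          cur <- W[r, c]; len <- 1L
        }
        r <- r + dir[1]; c <- c + dir[2]
      }
      runs[[length(runs) + 1]] <- c(cur, len)
    }
  }
  runs <- do.call(rbind, runs)
  lmax <- max(runs[, 2])
  M <- matrix(0L, length(lv), lmax, dimnames = list(lv, seq_len(lmax)))
  for (k in seq_len(nrow(runs))) {
    i <- match(runs[k, 1], lv)
    M[i, runs[k, 2]] <- M[i, runs[k, 2]] + 1L
  }
  M
}

bf_gldm <- function(W, alpha = 0) {
  lv <- sort(unique(as.vector(W)))
  dep <- matrix(0L, nrow(W), ncol(W))
  for (r in seq_len(nrow(W))) {
    for (c in seq_len(ncol(W))) {
      d <- 0L
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- r + dr; c2 <- c + dc
          if (r2 >= 1 && r2 <= nrow(W) && c2 >= 1 && c2 <= ncol(W) &&
              abs(W[r2, c2] - W[r, c]) <= alpha) {
            d <- d + 1L
          }
        }
      }
      dep[r, c] <- d
    }
  }
  jmax <- max(dep) + 1L
  M <- matrix(0L, length(lv), jmax, dimnames = list(lv, seq_len(jmax)))
  for (r in seq_len(nrow(W))) {
    for (c in seq_len(ncol(W))) {
      i <- match(W[r, c], lv)
      M[i, dep[r, c] + 1L] <- M[i, dep[r, c] + 1L] + 1L
    }
  }
  M
}

bf_ngtdm <- function(W) {
  lv <- sort(unique(as.vector(W)))
  s <- stats::setNames(numeric(length(lv)), lv)
  n <- stats::setNames(integer(length(lv)), lv)
  for (r in seq_len(nrow(W))) {
    for (c in seq_len(ncol(W))) {
      nb <- c()
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- r + dr; c2 <- c + dc
          if (r2 >= 1 && r2 <= nrow(W) && c2 >= 1 && c2 <= ncol(W)) {
            nb <- c(nb, W[r2, c2])
          }
        }
      }
      i <- match(W[r, c], lv)
      s[i] <- s[i] + abs(W[r, c] - mean(nb))
      n[i] <- n[i] + 1L
    }
  }
  list(levels = lv, n = unname(n), p = unname(n) / sum(n), s = unname(s))
}

# Exhaustive sweep of Yen's criterion over every histogram split point.
bf_yen_argmax <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf; best_t <- 1L
  for (t in seq_len(length(p) - 1)) {
    P1 <- sum(p[1:t])
    P1sq <- sum(p[1:t]^2)
    P2sq <- sum(p[(t + 1):length(p)]^2)
    crit <- 2 * log(max(P1 * (1 - P1), .Machine$double.xmin)) -
      log(max(P1sq * P2sq, .Machine$double.xmin))
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t
}

# Voxel-wise distance-based erosion: keep a voxel iff every voxel whose centre
# lies within `radius` mm is inside the mask (outside the grid = background).
bf_erode <- function(mask, radius, spacing) {
  d <- dim(mask)
  out <- array(FALSE, d)
  rv <- ceiling(radius / spacing)
  keep_voxel <- function(i, j, k) {
    for (di in -rv[1]:rv[1]) for (dj in -rv[2]:rv[2]) for (dk in -rv[3]:rv[3]) {
      if (sqrt(sum((c(di, dj, dk) * spacing)^2)) > radius) next
      i2 <- i + di; j2 <- j + dj; k2 <- k + dk
      inside <- i2 >= 1 && i2 <= d[1] && j2 >= 1 && j2 <= d[2] &&
        k2 >= 1 && k2 <= d[3]
      if (!inside || !mask[i2, j2, k2]) return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) out[i, j, k] <- keep_voxel(i, j, k)
  }
  out
}
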