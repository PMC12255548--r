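# Texture matrices and the 59-feature set.
#
# All four matrix classes are computed on a 2D integer-label window (one
# in-plane sliding window of the discretised image). Feature formulas follow
# the IBSI-compliant definitions used by the standard radiomics libraries:
# 24 GLCM + 16 GLRLM + 14 GLDM + 5 NGTDM = 59 features. Gray "values" entering
# the formulas are the discretised labels themselves.
#
# Conventions for degenerate (single gray level) windows: correlation-type
# features are 1, difference/variance-type features are 0, and NGTDM
# coarseness takes the customary cap of 1e6.

#' Gray level co-occurrence matrix of a 2D window
#'
#' Symmetric co-occurrence counts at distance 1 along one in-plane direction.
#'
#' @param window Integer matrix of gray labels.
#' @param direction Length-2 offset `(d_row, d_col)`: one of `c(0,1)`,
#'   `c(1,0)`, `c(1,1)`, `c(1,-1)`.
#' @return Integer matrix of pair counts with `dimnames` the gray levels
#'   present in the window; symmetric (both orderings of a pair are counted).
#' @export
glcm_matrix <- function(window, direction = c(0, 1)) {
  lv <- sort(unique(as.vector(window)))
  n <- length(lv)
  ab <- offset_pairs(window, direction)
  if (is.null(ab)) {
    return(matrix(0L, n, n, dimnames = list(lv, lv)))
  }
  ai <- match(ab$a, lv); bi <- match(ab$b, lv)
  M <- matrix(tabulate((ai - 1L) * n + bi, n * n), n, n,
              dimnames = list(lv, lv))
  M + t(M)
}

# Paired values of adjacent voxels along (d_row, d_col); NULL if the window is
# too small for the offset.
offset_pairs <- function(W, dir) {
  nr <- nrow(W); nc <- ncol(W)
  ri <- seq_len(nr - abs(dir[1])); ci <- seq_len(nc - abs(dir[2]))
  if (!length(ri) || !length(ci)) return(NULL)
  ra <- if (dir[1] >= 0) ri else ri + abs(dir[1])
  rb <- ra + dir[1]
  ca <- if (dir[2] >= 0) ci else ci + abs(dir[2])
  cb <- ca + dir[2]
  list(a = W[ra, ca, drop = FALSE], b = W[rb, cb, drop = FALSE])
}

glcm_directions <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))

#' Gray level run length matrix of a 2D window
#'
#' Counts of maximal constant runs per gray level and run length along one
#' in-plane direction.
#'
#' @inheritParams glcm_matrix
#' @return Integer matrix: rows are the gray levels present (dimnames), columns
#'   run lengths 1..max.
#' @export
glrlm_matrix <- function(window, direction = c(0, 1)) {
  lv <- sort(unique(as.vector(window)))
  lines <- window_lines(window, direction)
  runs_v <- integer(0); runs_l <- integer(0)
  for (ln in lines) {
    r <- rle(ln)
    runs_v <- c(runs_v, r$values)
    runs_l <- c(runs_l, r$lengths)
  }
  lmax <- max(runs_l)
  vi <- match(runs_v, lv)
  matrix(tabulate((runs_l - 1L) * length(lv) + vi, length(lv) * lmax),
         length(lv), lmax, dimnames = list(lv, seq_len(lmax)))
}

# Decompose a matrix into the scan lines of one direction.
window_lines <- function(W, dir) {
  nr <- nrow(W); nc <- ncol(W)
  if (identical(as.integer(dir), c(0L, 1L))) {
    lapply(seq_len(nr), function(r) W[r, ])
  } else if (identical(as.integer(dir), c(1L, 0L))) {
    lapply(seq_len(nc), function(c) W[, c])
  } else if (identical(as.integer(dir), c(1L, 1L))) {
    split(W, row(W) - col(W))
  } else if (identical(as.integer(dir), c(1L, -1L))) {
    split(W, row(W) + col(W))
  } else {
    stop("unsupported direction", call. = FALSE)
  }
}

#' Gray level dependence matrix of a 2D window
#'
#' For each voxel the dependence `d` is the number of its (up to 8) in-plane
#' neighbours whose absolute gray difference is at most `alpha`. Counts are
#' tabulated over (gray level, d + 1); the `+ 1` column convention matches the
#' common library implementation so that dependence sizes enter the feature
#' formulas as `j = d + 1 >= 1`.
#'
#' @param window Integer matrix of gray labels.
#' @param alpha Dependence tolerance (default 0: exact equality).
#' @return Integer matrix: rows the gray levels present (dimnames), columns
#'   dependence sizes `1..max`.
#' @export
gldm_matrix <- function(window, alpha = 0) {
  lv <- sort(unique(as.vector(window)))
  nb <- neighbour_stats(window)
  d <- nb$n_equal
  if (alpha > 0) d <- neighbour_stats(window, alpha)$n_equal
  j <- as.vector(d) + 1L
  vi <- match(as.vector(window), lv)
  jmax <- max(j)
  matrix(tabulate((j - 1L) * length(lv) + vi, length(lv) * jmax),
         length(lv), jmax, dimnames = list(lv, seq_len(jmax)))
}

#' Neighbouring gray tone difference components of a 2D window
#'
#' For each gray level `i` present: the voxel count `n_i`, the probability
#' `p_i = n_i / N`, and `s_i`, the summed absolute difference between the
#' level and the mean of each voxel's valid in-plane neighbours.
#'
#' @param window Integer matrix of gray labels.
#' @return A list with `levels`, `n`, `p`, `s`.
#' @export
ngtdm_components <- function(window) {
  lv <- sort(unique(as.vector(window)))
  nb <- neighbour_stats(window)
  diffs <- abs(as.vector(window) - as.vector(nb$mean))
  vi <- match(as.vector(window), lv)
  s <- as.vector(rowsum(diffs, vi))
  n <- tabulate(vi, length(lv))
  list(levels = lv, n = n, p = n / sum(n), s = s)
}

# 8-neighbour statistics via padded shifts: per voxel, the number of equal
# neighbours (within alpha) and the mean neighbour value.
neighbour_stats <- function(W, alpha = 0) {
  nr <- nrow(W); nc <- ncol(W)
  P <- matrix(NA_real_, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- W
  sum_v <- matrix(0, nr, nc); cnt <- matrix(0L, nr, nc)
  n_eq <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    S <- P[2:(nr + 1) + dr, 2:(nc + 1) + dc, drop = FALSE]
    ok <- !is.na(S)
    sum_v[ok] <- sum_v[ok] + S[ok]
    cnt <- cnt + ok
    n_eq <- n_eq + (ok & abs(S - W) <= alpha)
  }
  list(mean = sum_v / cnt, n_equal = n_eq)
}

# --- feature evaluation ------------------------------------------------------

glcm_feature_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

glrlm_feature_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

gldm_feature_names <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

ngtdm_feature_names <- c(
  "Busyness", "Coarseness", "Complexity", "Contrast", "Strength")

#' Catalogue of the 59 texture features
#'
#' @return A tibble with columns `class` (GLCM/GLRLM/GLDM/NGTDM) and `name`;
#'   59 rows.
#' @export
feature_catalog <- function() {
  tibble::tibble(
    class = rep(c("GLCM", "GLRLM", "GLDM", "NGTDM"),
                c(length(glcm_feature_names), length(glrlm_feature_names),
                  length(gldm_feature_names), length(ngtdm_feature_names))),
    name = c(glcm_feature_names, glrlm_feature_names, gldm_feature_names,
             ngtdm_feature_names))
}

entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

# 24 GLCM features from one direction's count matrix. Levels that occur in no
# pair of this direction carry zero marginals and are dropped before the
# marginal-based formulas (and before the level count entering Idmn/Idn).
glcm_features_dir <- function(M, v) {
  part <- rowSums(M) > 0
  M <- M[part, part, drop = FALSE]
  v <- v[part]
  n <- length(v)
  out <- stats::setNames(numeric(24), glcm_feature_names)
  tot <- sum(M)
  if (n <= 1 || tot == 0) {
    val <- if (n == 1) v[1] else 0
    out[] <- 0
    out["Autocorrelation"] <- val^2
    out["JointAverage"] <- val
    out["SumAverage"] <- 2 * val
    out[c("Correlation", "MCC", "Id", "Idm", "Idmn", "Idn",
          "JointEnergy", "MaximumProbability")] <- 1
    return(out)
  }
  p <- M / tot
  px <- rowSums(p)
  vi <- matrix(v, n, n)
  vj <- t(vi)
  mu <- sum(px * v)
  sig2 <- sum(px * (v - mu)^2)
  adiff <- abs(vi - vj)
  vsum <- vi + vj
  out["Autocorrelation"] <- sum(p * vi * vj)
  out["ClusterProminence"] <- sum(p * (vsum - 2 * mu)^4)
  out["ClusterShade"] <- sum(p * (vsum - 2 * mu)^3)
  out["ClusterTendency"] <- sum(p * (vsum - 2 * mu)^2)
  out["Contrast"] <- sum(p * (vi - vj)^2)
  out["Correlation"] <- if (sig2 > 0) {
    (sum(p * vi * vj) - mu^2) / sig2
  } else 1
  da <- sum(p * adiff)
  out["DifferenceAverage"] <- da
  pd <- as.vector(rowsum(as.vector(p), as.vector(adiff)))
  out["DifferenceEntropy"] <- entropy2(pd)
  out["DifferenceVariance"] <- sum(p * (adiff - da)^2)
  out["Id"] <- sum(p / (1 + adiff))
  out["Idm"] <- sum(p / (1 + adiff^2))
  out["Idmn"] <- sum(p / (1 + adiff^2 / n^2))
  out["Idn"] <- sum(p / (1 + adiff / n))
  hx <- entropy2(px)
  hxy <- entropy2(as.vector(p))
  pxy <- outer(px, px)
  pos <- p > 0 & pxy > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- entropy2(as.vector(pxy))
  out["Imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  out["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  off <- adiff > 0
  out["InverseVariance"] <- sum(p[off] / adiff[off]^2)
  out["JointAverage"] <- mu
  out["JointEnergy"] <- sum(p^2)
  out["JointEntropy"] <- hxy
  Qm <- sweep(p, 1, px, "/") %*% sweep(t(p), 1, px, "/")
  ev <- sort(Re(eigen(Qm, only.values = TRUE)$values), decreasing = TRUE)
  out["MCC"] <- sqrt(min(max(ev[2], 0), 1))
  out["MaximumProbability"] <- max(p)
  ps <- as.vector(rowsum(as.vector(p), as.vector(vsum)))
  ks <- sort(unique(as.vector(vsum)))
  out["SumAverage"] <- sum(ks * ps)
  out["SumEntropy"] <- entropy2(ps)
  out["SumSquares"] <- sig2
  out
}

# 16 GLRLM features from one direction's run-length count matrix.
glrlm_features_dir <- function(P, v, n_voxels) {
  out <- stats::setNames(numeric(16), glrlm_feature_names)
  nr <- sum(P)
  rl <- seq_len(ncol(P))
  gi <- matrix(v, nrow(P), ncol(P))
  rj <- matrix(rl, nrow(P), ncol(P), byrow = TRUE)
  pg <- rowSums(P)      # runs per gray level
  pr <- colSums(P)      # runs per length
  out["GrayLevelNonUniformity"] <- sum(pg^2) / nr
  out["GrayLevelNonUniformityNormalized"] <- sum(pg^2) / nr^2
  pnorm <- P / nr
  mu_g <- sum(pnorm * gi)
  out["GrayLevelVariance"] <- sum(pnorm * (gi - mu_g)^2)
  out["HighGrayLevelRunEmphasis"] <- sum(P * gi^2) / nr
  out["LongRunEmphasis"] <- sum(P * rj^2) / nr
  out["LongRunHighGrayLevelEmphasis"] <- sum(P * gi^2 * rj^2) / nr
  out["LongRunLowGrayLevelEmphasis"] <- sum(P * rj^2 / gi^2) / nr
  out["LowGrayLevelRunEmphasis"] <- sum(P / gi^2) / nr
  out["RunEntropy"] <- entropy2(as.vector(pnorm))
  out["RunLengthNonUniformity"] <- sum(pr^2) / nr
  out["RunLengthNonUniformityNormalized"] <- sum(pr^2) / nr^2
  out["RunPercentage"] <- nr / n_voxels
  mu_r <- sum(pnorm * rj)
  out["RunVariance"] <- sum(pnorm * (rj - mu_r)^2)
  out["ShortRunEmphasis"] <- sum(P / rj^2) / nr
  out["ShortRunHighGrayLevelEmphasis"] <- sum(P * gi^2 / rj^2) / nr
  out["ShortRunLowGrayLevelEmphasis"] <- sum(P / (gi^2 * rj^2)) / nr
  out
}

# 14 GLDM features.
gldm_features <- function(P, v) {
  out <- stats::setNames(numeric(14), gldm_feature_names)
  nz <- sum(P)
  jv <- seq_len(ncol(P))
  gi <- matrix(v, nrow(P), ncol(P))
  jm <- matrix(jv, nrow(P), ncol(P), byrow = TRUE)
  pnorm <- P / nz
  out["DependenceEntropy"] <- entropy2(as.vector(pnorm))
  pj <- colSums(P)
  out["DependenceNonUniformity"] <- sum(pj^2) / nz
  out["DependenceNonUniformityNormalized"] <- sum(pj^2) / nz^2
  mu_j <- sum(pnorm * jm)
  out["DependenceVariance"] <- sum(pnorm * (jm - mu_j)^2)
  pg <- rowSums(P)
  out["GrayLevelNonUniformity"] <- sum(pg^2) / nz
  mu_g <- sum(pnorm * gi)
  out["GrayLevelVariance"] <- sum(pnorm * (gi - mu_g)^2)
  out["HighGrayLevelEmphasis"] <- sum(P * gi^2) / nz
  out["LargeDependenceEmphasis"] <- sum(P * jm^2) / nz
  out["LargeDependenceHighGrayLevelEmphasis"] <- sum(P * gi^2 * jm^2) / nz
  out["LargeDependenceLowGrayLevelEmphasis"] <- sum(P * jm^2 / gi^2) / nz
  out["LowGrayLevelEmphasis"] <- sum(P / gi^2) / nz
  out["SmallDependenceEmphasis"] <- sum(P / jm^2) / nz
  out["SmallDependenceHighGrayLevelEmphasis"] <- sum(P * gi^2 / jm^2) / nz
  out["SmallDependenceLowGrayLevelEmphasis"] <- sum(P / (gi^2 * jm^2)) / nz
  out
}

# 5 NGTDM features.
ngtdm_features <- function(comp) {
  out <- stats::setNames(numeric(5), ngtdm_feature_names)
  keep <- comp$p > 0
  v <- comp$levels[keep]; p <- comp$p[keep]; s <- comp$s[keep]
  nvp <- sum(comp$n)
  ngp <- length(v)
  ps <- sum(p * s)
  out["Coarseness"] <- if (ps > 0) 1 / ps else 1e6
  if (ngp > 1) {
    vd2 <- outer(v, v, "-")^2
    out["Contrast"] <- sum(outer(p, p) * vd2) / (ngp * (ngp - 1)) *
      sum(s) / nvp
    bdenom <- sum(abs(outer(v * p, v * p, "-")))
    out["Busyness"] <- if (bdenom > 0) ps / bdenom else 0
    pi_ <- matrix(p, ngp, ngp); pj_ <- t(pi_)
    si_ <- matrix(s, ngp, ngp); sj_ <- t(si_)
    avd <- abs(outer(v, v, "-"))
    out["Complexity"] <- sum(avd * (pi_ * si_ + pj_ * sj_) / (pi_ + pj_)) / nvp
    ssum <- sum(s)
    out["Strength"] <- if (ssum > 0) sum((pi_ + pj_) * vd2) / ssum else 0
  }
  out
}

#' All 59 texture features of one window
#'
#' Computes the four texture-matrix classes on a single 2D integer-label
#' window and evaluates every feature. GLCM and GLRLM features are averaged
#' over the four in-plane directions (distance 1, symmetric matrices).
#'
#' @param window Integer matrix of gray labels (at least 3x3 for a full
#'   neighbourhood; smaller cropped edge windows are accepted).
#' @return Named numeric vector of length 59; names are
#'   `"<class>_<feature>"` in the order of [feature_catalog()].
#' @export
window_texture_features <- function(window) {
  window <- as.matrix(window)
  storage.mode(window) <- "integer"
  lv <- sort(unique(as.vector(window)))
  np <- length(window)
  glcm <- rowMeans(vapply(glcm_directions, function(dir) {
    glcm_features_dir(glcm_matrix(window, dir), lv)
  }, numeric(24)))
  glrlm <- rowMeans(vapply(glcm_directions, function(dir) {
    glrlm_features_dir(glrlm_matrix(window, dir), lv, np)
  }, numeric(16)))
  gldm <- gldm_features(gldm_matrix(window), lv)
  ngtdm <- ngtdm_features(ngtdm_components(window))
  cat_ <- feature_catalog()
  stats::setNames(c(glcm, glrlm, gldm, ngtdm),
                  paste(cat_$class, cat_$name, sep = "_"))
}
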