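#' Region sets for zonal analysis
#'
#' A `region_set` holds the five boolean masks used throughout the repeatability
#' analysis: whole gland (WG, after erosion), peripheral zone (PZ),
#' non-peripheral zone (nPZ = WG minus PZ), tumor and benign (WG minus tumor).
#' Construction enforces the set algebra: `npz = wg & !pz`,
#' `benign = wg & !tumor`, `tumor` a subset of `wg`, `pz` and `npz` disjoint.
#'
#' @param wg,pz,tumor Logical 3D arrays on a common grid. `pz` and `tumor` are
#'   clipped to `wg` (with a message when voxels are clipped).
#' @param spacing Voxel spacing in mm.
#' @return An object of class `region_set`: a named list of logical arrays
#'   `wg`, `pz`, `npz`, `tumor`, `benign` plus `spacing`.
#' @export
region_set <- function(wg, pz, tumor, spacing = c(1, 1, 1)) {
  stopifnot(is.logical(wg), is.logical(pz), is.logical(tumor),
            identical(dim(wg), dim(pz)), identical(dim(wg), dim(tumor)))
  n_clip <- sum(pz & !wg) + sum(tumor & !wg)
  if (n_clip > 0) {
    message("region_set: clipped ", n_clip, " voxel(s) outside WG from PZ/tumor")
  }
  pz <- pz & wg
  tumor <- tumor & wg
  rs <- structure(
    list(wg = wg, pz = pz, npz = wg & !pz, tumor = tumor, benign = wg & !tumor,
         spacing = as.numeric(spacing)),
    class = "region_set"
  )
  for (nm in c("pz", "npz")) {
    if (!any(rs[[nm]])) warning("region '", toupper(nm), "' is empty", call. = FALSE)
  }
  rs
}

#' @export
print.region_set <- function(x, ...) {
  n <- vapply(x[c("wg", "pz", "npz", "tumor", "benign")], sum, integer(1))
  cat("<region_set> voxels:", paste(names(n), n, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Morphological erosion by a physical radius
#'
#' Erodes a boolean mask by a discretised ball: a voxel offset belongs to the
#' structuring element iff the Euclidean distance between voxel centres,
#' measured in mm using the grid spacing, is at most `radius`. Voxels outside
#' the grid count as background, so the mask also retreats from the array
#' boundary. Radius 0 is the identity.
#'
#' @param mask Logical 3D array.
#' @param radius Erosion radius in mm (>= 0).
#' @param spacing Voxel spacing in mm.
#' @return Logical array of the same shape, a subset of `mask`.
#' @export
erode_region <- function(mask, radius, spacing = c(1, 1, 1)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, radius >= 0)
  if (radius == 0) return(mask)
  sp <- as.numeric(spacing)
  rv <- floor(radius / sp)
  off <- expand.grid(di = -rv[1]:rv[1], dj = -rv[2]:rv[2], dk = -rv[3]:rv[3])
  dist <- sqrt((off$di * sp[1])^2 + (off$dj * sp[2])^2 + (off$dk * sp[3])^2)
  off <- off[dist <= radius, , drop = FALSE]
  out <- mask
  for (r in seq_len(nrow(off))) {
    out <- out & shift_mask(mask, off$di[r], off$dj[r], off$dk[r])
    if (!any(out)) break
  }
  if (!any(out)) warning("erosion emptied the mask", call. = FALSE)
  out
}

# Shift a logical array by (di, dj, dk), padding with FALSE: the result at v
# is mask[v + (di,dj,dk)] when inside the grid.
shift_mask <- function(mask, di, dj, dk) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- list(seq_len(d[1]) + di, seq_len(d[2]) + dj, seq_len(d[3]) + dk)
  keep <- lapply(seq_len(3), function(a) which(src[[a]] >= 1 & src[[a]] <= d[a]))
  if (any(vapply(keep, length, integer(1)) == 0)) return(out)
  out[keep[[1]], keep[[2]], keep[[3]]] <-
    mask[src[[1]][keep[[1]]], src[[2]][keep[[2]]], src[[3]][keep[[3]]]]
  out
}

#' Yen's automatic threshold
#'
#' Selects the threshold maximising Yen's maximum-correlation criterion over a
#' histogram of the probabilities inside `mask` (256 bins over the masked
#' min-max range by default), and returns the voxels whose value strictly
#' exceeds it. A constant map admits no separating threshold and yields an
#' empty mask with a warning.
#'
#' @param prob An `image_volume` (or numeric array) of tumor probabilities.
#' @param mask Logical array restricting the histogram and the output.
#' @param n_bins Number of histogram bins.
#' @return Logical array: voxels in `mask` above the Yen threshold.
#' @export
yen_threshold <- function(prob, mask = NULL, n_bins = 256L) {
  v <- if (inherits(prob, "image_volume")) prob$values else as.array(prob)
  if (is.null(mask)) mask <- array(TRUE, dim(v))
  stopifnot(identical(dim(mask), dim(v)), any(mask))
  x <- v[mask]
  if (any(!is.finite(x))) stop("non-finite probabilities inside mask", call. = FALSE)
  if (max(x) == min(x)) {
    warning("constant probability map: no threshold separates classes; ",
            "returning an empty mask", call. = FALSE)
    return(array(FALSE, dim(v)))
  }
  h <- bin_histogram(x, n_bins)
  thr <- h$centers[yen_argmax(h$counts)]
  mask & (v > thr)
}

# Equal-width histogram over [min, max] with the top edge inclusive.
bin_histogram <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / n_bins
  idx <- pmin(floor((x - lo) / w), n_bins - 1) + 1
  list(counts = tabulate(idx, n_bins),
       centers = lo + (seq_len(n_bins) - 0.5) * w,
       edges = lo + (0:n_bins) * w)
}

# Index (into bin centres) maximising Yen's criterion
#   crit(t) = 2 log(P1 (1 - P1)) - log(P1_sq * P2_sq)
# where P1 is the cumulative mass up to bin t and P1_sq/P2_sq the cumulative
# sums of squared normalised counts below/above t.
yen_argmax <- function(counts) {
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  P1_sq <- cumsum(p^2)
  P2_sq <- sum(p^2) - P1_sq
  n <- length(p)
  t <- seq_len(n - 1)
  crit <- 2 * log(pmax(P1[t] * (1 - P1[t]), .Machine$double.xmin)) -
    log(pmax(P1_sq[t] * P2_sq[t], .Machine$double.xmin))
  which.max(crit)
}

#' Derive the analysis regions from raw segmentations
#'
#' Applies the delineation rules used throughout the package: the whole gland
#' is eroded by `erosion_mm` (default 1 mm) in 3D to guard against contouring
#' errors at the gland periphery; the non-peripheral zone is the eroded gland
#' minus the PZ; the tumor mask is obtained by Yen thresholding of the tumor
#' probability map (restricted to the eroded gland); benign is the eroded gland
#' minus tumor.
#'
#' @param wg,pz Logical 3D arrays: raw whole-gland and peripheral-zone masks.
#' @param tumor_prob An `image_volume` or array of tumor probabilities in
#'   \[0, 1\]; `NULL` for a tumor-free subject.
#' @param spacing Voxel spacing in mm.
#' @param erosion_mm Whole-gland erosion radius in mm.
#' @return A [region_set()].
#' @export
derive_regions <- function(wg, pz, tumor_prob = NULL, spacing = c(1, 1, 1),
                           erosion_mm = 1) {
  stopifnot(is.logical(wg), is.logical(pz), identical(dim(wg), dim(pz)))
  if (!is.null(tumor_prob)) {
    tv <- if (inherits(tumor_prob, "image_volume")) tumor_prob$values else tumor_prob
    stopifnot(identical(dim(tv), dim(wg)))
    rng <- range(tv[is.finite(tv)])
    if (rng[1] < 0 || rng[2] > 1) {
      stop("tumor probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  wg_er <- erode_region(wg, erosion_mm, spacing)
  tumor <- if (is.null(tumor_prob)) {
    array(FALSE, dim(wg))
  } else {
    yen_threshold(tv, mask = wg_er)
  }
  region_set(wg = wg_er, pz = pz, tumor = tumor, spacing = spacing)
}
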