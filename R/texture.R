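#' Resample a volume to isotropic resolution
#'
#' Resamples onto a grid of spacing `target` mm covering the same physical
#' extent, using trilinear interpolation for intensity volumes and
#' nearest-neighbour for masks/labels. A volume already at the target spacing
#' is returned unchanged.
#'
#' @param volume An [image_volume()], or a logical array with
#'   `method = "nearest"` and an explicit `spacing`.
#' @param target Isotropic voxel size in mm (> 0), default 1.
#' @param method `"linear"` or `"nearest"`.
#' @param spacing Required when `volume` is a plain array.
#' @return An `image_volume` with spacing `c(target, target, target)` (for
#'   logical input with `method = "nearest"`, a logical array attribute-free
#'   result is returned inside the volume's `values`).
#' @export
resample_isotropic <- function(volume, target = 1, method = c("linear", "nearest"),
                               spacing = NULL) {
  method <- match.arg(method)
  stopifnot(target > 0)
  if (!inherits(volume, "image_volume")) {
    stopifnot(!is.null(spacing))
    volume <- image_volume(volume * 1, spacing = spacing)
  }
  sp <- volume$spacing
  d <- dim(volume$values)
  if (max(abs(sp - target)) < 1e-9) return(volume)
  d_out <- pmax(2L, as.integer(round(d * sp / target)))
  g <- index_grid(d_out)
  # align physical corners: input voxel i centre at i*sp, extent [-sp/2, ...]
  src_i <- ((g$i + 0.5) * target - sp[1] / 2) / sp[1]
  src_j <- ((g$j + 0.5) * target - sp[2] / 2) / sp[2]
  src_k <- ((g$k + 0.5) * target - sp[3] / 2) / sp[3]
  out <- if (method == "linear") {
    trilinear_sample(volume$values, src_i, src_j, src_k)
  } else {
    nearest_sample(volume$values, src_i, src_j, src_k)
  }
  image_volume(array(out, d_out), spacing = rep(target, 3),
               origin = volume$origin, orientation = volume$orientation)
}

# Resample a logical mask to the isotropic grid (nearest neighbour).
resample_mask_isotropic <- function(mask, spacing, target = 1) {
  v <- resample_isotropic(image_volume(mask * 1, spacing = spacing),
                          target = target, method = "nearest")
  array(v$values > 0.5, dim(v$values))
}

#' Normalise image intensities
#'
#' Z-scores the volume (mean 0, population standard deviation 1 over finite
#' voxels), multiplies by `scale` (default 100) and clips to
#' `[-3 * scale, 3 * scale]`, so outputs lie in \[-300, 300\] at the default
#' scale. A volume with zero intensity spread has no defined normalisation and
#' raises an error.
#'
#' @param volume An [image_volume()].
#' @param scale Scaling factor.
#' @return An `image_volume` of normalised intensities.
#' @export
normalize_image <- function(volume, scale = 100) {
  stopifnot(inherits(volume, "image_volume"))
  x <- volume$values
  fin <- is.finite(x)
  mu <- mean(x[fin])
  sd_pop <- sqrt(mean((x[fin] - mu)^2))
  if (!is.finite(sd_pop) || sd_pop == 0) {
    stop("zero intensity spread: normalization undefined", call. = FALSE)
  }
  y <- (x - mu) / sd_pop * scale
  y <- pmin(pmax(y, -3 * scale), 3 * scale)
  image_volume(array(y, dim(x)), volume$spacing, volume$origin,
               volume$orientation)
}

#' Fixed-bin-width discretisation
#'
#' Assigns gray labels `floor((x - anchor) / bin_width) + 1` with the anchor
#' the minimum finite value inside `mask` (volume-global binning: labels are
#' comparable across sliding windows). Labels are contiguous from 1.
#'
#' @param volume An [image_volume()] or numeric array.
#' @param bin_width Width of each gray-level bin (> 0), default 20.
#' @param mask Optional logical array; the anchor is the masked minimum.
#' @return Integer array of gray labels (NA where the input is not finite).
#' @export
discretize <- function(volume, bin_width = 20, mask = NULL) {
  stopifnot(bin_width > 0)
  x <- if (inherits(volume, "image_volume")) volume$values else as.array(volume)
  sel <- if (is.null(mask)) is.finite(x) else mask & is.finite(x)
  anchor <- min(x[sel])
  lab <- array(NA_integer_, dim(x))
  fin <- is.finite(x)
  lab[fin] <- as.integer(floor((x[fin] - anchor) / bin_width)) + 1L
  lab
}

#' Voxel-wise texture-feature maps of one image
#'
#' Slides an in-plane window (default 5 x 5 mm, i.e. 5 x 5 voxels on the 1 mm
#' isotropic grid) across every masked voxel of a resampled, normalised
#' volume, discretises the volume once with a global anchor, and evaluates
#' all 59 texture features (24 GLCM + 16 GLRLM + 14 GLDM + 5 NGTDM) on each
#' voxel's window. Windows are cropped (not padded) at slice edges. Windows
#' containing a single gray level are evaluated under the degenerate-window
#' conventions and counted.
#'
#' @param volume An [image_volume()], already resampled and normalised.
#' @param mask Logical array selecting the window centres.
#' @param kernel_mm In-plane window size in mm (default 5).
#' @param bin_width Discretisation bin width (default 20).
#' @param source Label for the source image (e.g. `"ADC"`, `"T2w"`).
#' @return A `feature_map_set`: list with `values` (matrix, masked voxels x
#'   59 features), `index` (linear voxel indices of the rows), `dim`,
#'   `spacing`, `source`, `catalog` (the 59-row feature tibble) and
#'   `n_degenerate`.
#' @export
extract_voxel_features <- function(volume, mask, kernel_mm = 5, bin_width = 20,
                                   source = "image") {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$values)
  stopifnot(identical(dim(mask), d), any(mask))
  k_vox <- round(kernel_mm / volume$spacing[1])
  if (k_vox < 3) stop("window kernel smaller than 3 voxels", call. = FALSE)
  half <- k_vox %/% 2
  labels <- discretize(volume, bin_width = bin_width)
  idx <- which(mask)
  res <- .cpp_extract_features(as.integer(labels), as.integer(d),
                               as.integer(idx), as.integer(half))
  vals <- res$values
  n_degenerate <- res$n_degenerate
  cat_ <- feature_catalog()
  colnames(vals) <- paste(cat_$class, cat_$name, sep = "_")
  structure(
    list(values = vals, index = idx, dim = d, spacing = volume$spacing,
         source = source, catalog = cat_, n_degenerate = n_degenerate),
    class = "feature_map_set"
  )
}

#' @export
print.feature_map_set <- function(x, ...) {
  cat("<feature_map_set> source ", x$source, ": ", ncol(x$values),
      " feature maps over ", nrow(x$values), " voxels (",
      x$n_degenerate, " degenerate windows)\n", sep = "")
  invisible(x)
}

#' Materialise one feature map as a volume
#'
#' @param fms A `feature_map_set`.
#' @param feature Column name (`"<class>_<name>"`) or index.
#' @return An [image_volume()], `NaN` outside the extraction mask.
#' @export
as_feature_volume <- function(fms, feature) {
  stopifnot(inherits(fms, "feature_map_set"))
  v <- array(NaN, fms$dim)
  v[fms$index] <- fms$values[, feature]
  image_volume(v, fms$spacing)
}

#' Texture-feature maps for a whole session
#'
#' Runs the full preprocessing and extraction chain for every image of a
#' fitted session (the T2w image and the six parameter maps): resample to the
#' isotropic reference grid, z-score normalise, then extract the 59 feature
#' maps per image — 7 x 59 = 413 feature maps per session.
#'
#' @param maps Named list of [parametric_map()]s as returned by [fit_qmaps()].
#' @param mask Logical array on the *acquisition* grid selecting window
#'   centres (e.g. the whole-gland mask); it is resampled to the isotropic
#'   grid with nearest-neighbour interpolation.
#' @param mask_spacing Spacing of `mask` (defaults to the spacing of the first
#'   map).
#' @param target Isotropic resolution in mm.
#' @param kernel_mm,bin_width See [extract_voxel_features()].
#' @return A list of class `session_features`: `sets` (named list of
#'   `feature_map_set`), `meta` (tibble: source, class, name — one row per
#'   feature map), `mask` (the isotropic-grid mask).
#' @export
extract_session_features <- function(maps, mask, mask_spacing = NULL,
                                     target = 1, kernel_mm = 5,
                                     bin_width = 20) {
  stopifnot(is.list(maps), length(maps) >= 1)
  if (is.null(mask_spacing)) mask_spacing <- maps[[1]]$spacing
  mask_iso <- resample_mask_isotropic(mask, mask_spacing, target)
  sets <- lapply(names(maps), function(nm) {
    m <- maps[[nm]]
    iso <- resample_isotropic(image_volume(m$values, m$spacing, m$origin,
                                           m$orientation), target)
    norm <- normalize_image(iso)
    extract_voxel_features(norm, mask_iso, kernel_mm = kernel_mm,
                           bin_width = bin_width, source = nm)
  })
  names(sets) <- names(maps)
  meta <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    dplyr::mutate(sets[[nm]]$catalog, source = nm, .before = 1)
  }))
  structure(list(sets = sets, meta = meta, mask = mask_iso, target = target),
            class = "session_features")
}

#' @export
print.session_features <- function(x, ...) {
  cat("<session_features> ", length(x$sets), " source images x ",
      nrow(x$sets[[1]]$catalog), " features = ", nrow(x$meta),
      " feature maps\n", sep = "")
  invisible(x)
}
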