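#' Image volumes
#'
#' An `image_volume` is the unit of all I/O in qmrirep: a 3D scalar grid with a
#' physical voxel size (mm), an origin and an orientation. Voxel indices are
#' 0-based in physical-coordinate formulas: the centre of voxel `(i, j, k)` sits
#' at `origin + orientation %*% (c(i, j, k) * spacing)`.
#'
#' @param values A numeric 3D array.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly positive.
#' @param origin Numeric length-3, physical position (mm) of voxel (0,0,0).
#' @param orientation 3x3 direction-cosine matrix (columns are the physical
#'   directions of the grid axes). Defaults to the identity.
#'
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("image_volume requires a 3D array, got ", length(dim(values)),
         " dimension(s)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three finite, strictly positive values", call. = FALSE)
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, is.matrix(orientation),
            all(dim(orientation) == c(3L, 3L)))
  structure(
    list(values = values, spacing = spacing, origin = origin,
         orientation = orientation),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat("  finite range: [", signif(min(v), 5), ", ", signif(max(v), 5), "]",
        if (anyNA(x$values)) "  (contains NA/NaN)", "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Test whether two volumes share a grid
#'
#' Two volumes are aligned iff their grid shape, spacing and orientation match
#' (spacing and orientation to a small numeric tolerance).
#'
#' @param a,b `image_volume` objects (a plain logical/numeric array is accepted
#'   for `b` and compared on shape only).
#' @param tol Relative tolerance for spacing and orientation comparisons.
#' @return `TRUE` or `FALSE`.
#' @export
volumes_aligned <- function(a, b, tol = 1e-6) {
  if (!inherits(a, "image_volume")) stop("`a` must be an image_volume")
  if (!inherits(b, "image_volume")) return(identical(dim(a$values), dim(b)))
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) <= tol * max(a$spacing) &&
    max(abs(a$orientation - b$orientation)) <= tol
}

stop_if_unaligned <- function(a, b, what = "volumes") {
  if (!volumes_aligned(a, b)) {
    stop(what, " are not aligned (shape/spacing/orientation mismatch)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write a NIfTI-1 volume
#'
#' Thin wrappers over \pkg{RNifti}. Volumes are written with a double-precision
#' payload so that finite values, spacing and orientation survive a round trip
#' bit-exactly; `NaN` voxels pass through unchanged and are treated as invalid
#' by all downstream statistics.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an `image_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  v <- as.array(img)
  if (length(dim(v)) == 4L && dim(v)[4] == 1L) dim(v) <- dim(v)[1:3]
  if (length(dim(v)) != 3L) {
    stop("NIfTI payload in ", path, " is ", length(dim(v)),
         "-dimensional; a 3D volume is required", call. = FALSE)
  }
  xf <- RNifti::xform(img)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("non-finite or non-positive voxel spacing in ", path, call. = FALSE)
  }
  attributes(v) <- list(dim = dim(v))
  image_volume(v, spacing = sp, origin = xf[1:3, 4],
               orientation = sweep(xf[1:3, 1:3], 2, sp, "/"))
}

#' @rdname read_volume
#' @param volume An `image_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$values
  storage.mode(v) <- "double"
  img <- RNifti::asNifti(v)
  xf <- rbind(cbind(sweep(volume$orientation, 2, volume$spacing, "*"),
                    volume$origin),
              c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Acquisition series
#'
#' An ordered stack of aligned [image_volume()]s along an acquisition axis:
#' b-values (s/mm^2) for diffusion, echo times (ms) for multi-echo gradient
#' echo, or flip angles (degrees, with a repetition time) for variable-flip-angle
#' SPGR.
#'
#' @param volumes List of aligned `image_volume`s, in axis order.
#' @param axis_kind One of `"b-value"`, `"echo-time"`, `"flip-angle"`.
#' @param axis_values Numeric vector, one per volume, strictly increasing.
#'   b-values must be >= 0, echo times > 0, flip angles in (0, 90].
#' @param repetition_time TR in ms; required for (and only for) the
#'   `"flip-angle"` kind.
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(volumes, axis_kind, axis_values,
                               repetition_time = NULL) {
  axis_kind <- match.arg(axis_kind, c("b-value", "echo-time", "flip-angle"))
  if (length(volumes) != length(axis_values)) {
    stop("axis_values must have one entry per volume", call. = FALSE)
  }
  if (length(axis_values) && any(diff(axis_values) <= 0)) {
    stop("axis_values must be strictly increasing", call. = FALSE)
  }
  ok <- switch(axis_kind,
    "b-value"    = all(axis_values >= 0),
    "echo-time"  = all(axis_values > 0),
    "flip-angle" = all(axis_values > 0 & axis_values <= 90))
  if (!ok) stop("axis_values out of range for kind '", axis_kind, "'", call. = FALSE)
  if (axis_kind == "flip-angle") {
    if (is.null(repetition_time) || repetition_time <= 0) {
      stop("flip-angle series require a positive repetition_time (ms)",
           call. = FALSE)
    }
  }
  ref <- volumes[[1]]
  for (v in volumes) stop_if_unaligned(ref, v, "series volumes")
  structure(
    list(volumes = volumes, axis_kind = axis_kind,
         axis_values = as.numeric(axis_values),
         repetition_time = repetition_time),
    class = "acquisition_series"
  )
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat("<acquisition_series> ", length(x$volumes), " volumes along ",
      x$axis_kind, ": ", paste(signif(x$axis_values, 4), collapse = ", "),
      if (!is.null(x$repetition_time)) paste0(" (TR ", x$repetition_time, " ms)"),
      "\n", sep = "")
  invisible(x)
}

# Stack the series into a (n_voxels x n_points) matrix for vectorised fitting.
series_matrix <- function(series) {
  n <- length(series$volumes[[1]]$values)
  matrix(vapply(series$volumes, function(v) as.vector(v$values), numeric(n)),
         nrow = n)
}

#' Parametric maps
#'
#' A fitted quantity per voxel with units and a validity mask. Invalid voxels
#' carry `NaN` in `values`; the logical `valid` grid is the authoritative
#' record and is honoured by every statistic in the package.
#'
#' @param values Numeric 3D array (NaN at invalid voxels).
#' @param quantity One of `"ADC"`, `"D"`, `"f"`, `"HS"`, `"R2*"`, `"T1"`, `"T2w"`.
#' @param spacing,origin,orientation Grid geometry, as for [image_volume()].
#' @param valid Logical array of the same shape; defaults to finite voxels.
#' @return An object of class `parametric_map` (also an `image_volume`).
#' @export
parametric_map <- function(values, quantity, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0), orientation = diag(3),
                           valid = NULL) {
  quantity <- match.arg(quantity, c("ADC", "D", "f", "HS", "R2*", "T1", "T2w"))
  vol <- image_volume(values, spacing, origin, orientation)
  if (is.null(valid)) valid <- is.finite(vol$values)
  stopifnot(is.logical(valid), identical(dim(valid), dim(vol$values)))
  vol$values[!valid] <- NaN
  vol$quantity <- quantity
  vol$units <- switch(quantity,
    ADC = "mm^2/s", D = "mm^2/s", f = "", HS = "",
    `R2*` = "1/s", T1 = "ms", T2w = "a.u.")
  vol$valid <- valid
  class(vol) <- c("parametric_map", "image_volume")
  vol
}

#' @export
print.parametric_map <- function(x, ...) {
  cat("<parametric_map> ", x$quantity,
      if (nzchar(x$units)) paste0(" [", x$units, "]"), ", ",
      paste(dim(x$values), collapse = " x "), " voxels, ",
      sum(x$valid), " valid\n", sep = "")
  invisible(x)
}

# --- interpolation -----------------------------------------------------------

# Trilinear sampling of `values` at fractional 0-based voxel coordinates.
# Coordinates are clamped to the grid; NaN in the input propagates.
trilinear_sample <- function(values, i, j, k) {
  d <- dim(values)
  i <- pmin(pmax(i, 0), d[1] - 1)
  j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  i0 <- pmin(floor(i), d[1] - 2 + (d[1] == 1)); fi <- i - i0
  j0 <- pmin(floor(j), d[2] - 2 + (d[2] == 1)); fj <- j - j0
  k0 <- pmin(floor(k), d[3] - 2 + (d[3] == 1)); fk <- k - k0
  at <- function(di, dj, dk) {
    values[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  i1 <- as.integer(d[1] > 1); j1 <- as.integer(d[2] > 1); k1 <- as.integer(d[3] > 1)
  (1 - fi) * ((1 - fj) * ((1 - fk) * at(0, 0, 0) + fk * at(0, 0, k1)) +
                fj * ((1 - fk) * at(0, j1, 0) + fk * at(0, j1, k1))) +
    fi * ((1 - fj) * ((1 - fk) * at(i1, 0, 0) + fk * at(i1, 0, k1)) +
            fj * ((1 - fk) * at(i1, j1, 0) + fk * at(i1, j1, k1)))
}

# Nearest-neighbour sampling (used for masks / label grids).
nearest_sample <- function(values, i, j, k) {
  d <- dim(values)
  i <- pmin(pmax(round(i), 0), d[1] - 1)
  j <- pmin(pmax(round(j), 0), d[2] - 1)
  k <- pmin(pmax(round(k), 0), d[3] - 1)
  values[cbind(i + 1, j + 1, k + 1)]
}

# 0-based index grids for every voxel of a dim-`d` array, as long vectors.
index_grid <- function(d) {
  list(i = rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
       j = rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
       k = rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# Resample a volume after a rigid perturbation (rotation in degrees about the
# grid centre, then translation in mm), back onto its own grid. Emulates a
# residual test-retest registration error. Linear interpolation.
apply_rigid_jitter <- function(volume, translation_mm = c(0, 0, 0),
                               rotation_deg = c(0, 0, 0)) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$values)
  g <- index_grid(d)
  sp <- volume$spacing
  ctr <- (d - 1) / 2 * sp
  # physical coords of output voxels (grid-aligned frame)
  x <- g$i * sp[1] - ctr[1]; y <- g$j * sp[2] - ctr[2]; z <- g$k * sp[3] - ctr[3]
  r <- rotation_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3)
  Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3)
  Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  # pull-back: source position = R^-1 (x - t)
  src <- t(R) %*% rbind(x - translation_mm[1], y - translation_mm[2],
                        z - translation_mm[3])
  out <- trilinear_sample(volume$values,
                          (src[1, ] + ctr[1]) / sp[1],
                          (src[2, ] + ctr[2]) / sp[2],
                          (src[3, ] + ctr[3]) / sp[3])
  image_volume(array(out, d), volume$spacing, volume$origin, volume$orientation)
}
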