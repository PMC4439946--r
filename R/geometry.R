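#' Construct a density volume
#'
#' A density volume is the voxelized patient or phantom model: a 3D array of
#' mass density (g/cm^3) with per-axis voxel spacing and the physical
#' position of the first voxel center. Axis convention: x lateral,
#' y anterior-posterior, z superior-inferior.
#'
#' @param data 3D numeric array of mass densities (g/cm^3), all >= 0.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param origin numeric length-3, physical coordinate (mm) of the center of
#'   voxel `[1,1,1]`. Defaults to a grid centered on the physical origin.
#' @return object of class `density_volume`.
#' @export
density_volume <- function(data, spacing = c(2, 2, 2), origin = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (any(dim(data) < 8L)) stop("grid must be at least 8 voxels per axis")
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("densities must be finite and nonnegative")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel sizes (mm)")
  }
  if (is.null(origin)) {
    origin <- -(dim(data) - 1) * spacing / 2
  }
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "density_volume")
}

#' @method print density_volume
#' @export
print.density_volume <- function(x, ...) {
  cat("density_volume:", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(x$spacing, collapse = " x "), "mm spacing\n")
  cat("  density range:", paste(signif(range(x$data), 4), collapse = " - "),
      "g/cm^3\n")
  invisible(x)
}

#' Dose grid on the geometry of a density volume
#'
#' @param data 3D array of dose-to-water (Gy), nonnegative and finite.
#' @param spacing,origin grid geometry, as in [density_volume()].
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(data, spacing, origin) {
  data <- as.array(data)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("dose values must be finite and nonnegative")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @method print dose_grid
#' @export
print.dose_grid <- function(x, ...) {
  cat("dose_grid:", paste(dim(x$data), collapse = " x "), "voxels, max",
      signif(max(x$data), 4), "Gy\n")
  invisible(x)
}

# physical center positions of a set of voxels (linear indices), n x 3
voxel_centers <- function(dims, spacing, origin, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(prod(dims))
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(origin[1] + i * spacing[1],
        origin[2] + j * spacing[2],
        origin[3] + k * spacing[3])
}

# physical center of the grid
grid_center <- function(dv) {
  dv$origin + (dim(dv$data) - 1) * dv$spacing / 2
}

# beam frame for a gantry angle (degrees): direction of travel, BEV u axis
# (axial plane, right-handed with v = +z), BEV v axis
beam_frame <- function(angle_deg) {
  a <- angle_deg * pi / 180
  list(dir = c(-sin(a), cos(a), 0),
       u = c(cos(a), sin(a), 0),
       v = c(0, 0, 1))
}

# centroid (mm) of a boolean mask on a grid
mask_centroid <- function(mask, spacing, origin) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  colMeans(voxel_centers(dim(mask), spacing, origin, idx))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}
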