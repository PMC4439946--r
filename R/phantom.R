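#' Specify a synthetic phantom
#'
#' The default phantom emulates a challenging head-and-neck geometry: a
#' water-density cylindrical body with a spherical clinical target volume
#' (CTV) and an air cavity directly abutting the CTV laterally, so that
#' pencil beams from many directions traverse a sharp density interface
#' right next to the target.
#'
#' @param body list with `radius` (mm, cylinder about the z axis) and
#'   `height` (mm, cylinder extent along z; also the grid z extent).
#' @param ctv list with `center` (mm, length 3) and `radius` (mm).
#' @param cavity list with `radius` (mm), `direction` (unit-ish vector from
#'   the CTV center towards the cavity) and `gap` (mm between the CTV and
#'   cavity surfaces; 0 = abutting), or `NULL` for a homogeneous body.
#' @param spacing voxel size in mm (length 3).
#' @param ptv_margin isotropic CTV-to-PTV margin in mm.
#' @param ring_thickness thickness in mm of the normal-tissue ring
#'   surrounding the PTV.
#' @param air_border air padding around the body in mm.
#' @param densities mass densities (g/cm^3) used for body water and air.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(body = list(radius = 80, height = 112),
                         ctv = list(center = c(0, 0, 0), radius = 25),
                         cavity = list(radius = 20,
                                       direction = c(-1, 0, 0),
                                       gap = 0),
                         spacing = c(2, 2, 2),
                         ptv_margin = 5,
                         ring_thickness = 10,
                         air_border = 8,
                         densities = c(water = 1.0, air = 0.0012)) {
  spec <- list(body = body, ctv = ctv, cavity = cavity,
               spacing = as.numeric(spacing), ptv_margin = ptv_margin,
               ring_thickness = ring_thickness, air_border = air_border,
               densities = densities)
  class(spec) <- "phantom_spec"
  spec
}

#' Generate a voxel phantom with target and ring structures
#'
#' Builds the density volume (body = water, cavity and exterior = air) and
#' the structure set: CTV, PTV (CTV expanded by the isotropic margin), ring
#' (shell around the PTV, clipped to the body) and body.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([density_volume]) and `structures`
#'   ([structure_set]).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  sp <- spec$spacing
  half_xy <- spec$body$radius + spec$air_border
  nx <- 2L * ceiling(half_xy / sp[1])
  ny <- 2L * ceiling(half_xy / sp[2])
  nz <- 2L * ceiling(spec$body$height / 2 / sp[3])
  dims <- c(nx, ny, nz)
  origin <- -(dims - 1) * sp / 2
  pts <- voxel_centers(dims, sp, origin)

  body <- array(pts[, 1]^2 + pts[, 2]^2 <= spec$body$radius^2, dims)
  ctv_c <- spec$ctv$center
  d2ctv <- (pts[, 1] - ctv_c[1])^2 + (pts[, 2] - ctv_c[2])^2 +
    (pts[, 3] - ctv_c[3])^2
  ctv <- array(d2ctv <= spec$ctv$radius^2, dims)
  if (!any(ctv)) stop("CTV mask is empty; check radius vs voxel spacing")
  if (any(ctv & !body)) stop("CTV is not fully inside the body")

  dens <- array(spec$densities[["air"]], dims)
  dens[body] <- spec$densities[["water"]]

  if (!is.null(spec$cavity)) {
    dirv <- spec$cavity$direction / sqrt(sum(spec$cavity$direction^2))
    cav_c <- ctv_c + dirv *
      (spec$ctv$radius + spec$cavity$radius + spec$cavity$gap)
    d2cav <- (pts[, 1] - cav_c[1])^2 + (pts[, 2] - cav_c[2])^2 +
      (pts[, 3] - cav_c[3])^2
    cav <- array(d2cav <= spec$cavity$radius^2, dims)
    if (any(cav & ctv)) {
      stop("air cavity overlaps the CTV; it must abut, not intrude")
    }
    dens[cav] <- spec$densities[["air"]]
  }

  ptv <- expand_margin(ctv, spec$ptv_margin, sp) & body
  if (any(ctv & !ptv)) stop("PTV clipped inside the CTV; enlarge the body")
  ring <- make_ring(ptv, spec$ring_thickness, sp, body = body)

  dv <- density_volume(dens, sp, origin)
  ss <- structure_set(list(CTV = ctv, PTV = ptv, ring = ring, body = body),
                      spacing = sp, origin = origin)
  list(volume = dv, structures = ss)
}

#' Structure set: named boolean masks on a common grid
#'
#' Validates the construction invariants: CTV, PTV, ring and body are
#' present and nonempty, CTV is a subset of PTV, PTV a subset of body, and
#' the ring is disjoint from the PTV.
#'
#' @param masks named list of 3D logical arrays of identical dimension.
#' @param spacing,origin grid geometry (mm).
#' @return object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing, origin) {
  required <- c("CTV", "PTV", "ring", "body")
  if (!all(required %in% names(masks))) {
    stop("masks must include: ", paste(required, collapse = ", "))
  }
  dims <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dims)) stop("mask grids differ: ", nm)
    if (nm %in% required && !any(masks[[nm]])) stop("empty mask: ", nm)
  }
  if (any(masks$CTV & !masks$PTV)) stop("CTV must be a subset of the PTV")
  if (any(masks$PTV & !masks$body)) stop("PTV must be a subset of the body")
  if (any(masks$ring & masks$PTV)) stop("ring must be disjoint from the PTV")
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' @method print structure_set
#' @export
print.structure_set <- function(x, ...) {
  vol <- prod(x$spacing)
  for (nm in names(x$masks)) {
    cat(sprintf("  %-6s %7d voxels  %9.1f mm^3\n", nm, sum(x$masks[[nm]]),
                sum(x$masks[[nm]]) * vol))
  }
  invisible(x)
}

# FFT-based binary convolution; returns mask dilated by `kernel`
conv3d_dilate <- function(mask, kernel) {
  dm <- dim(mask)
  dk <- dim(kernel)
  dp <- vapply(dm + dk - 1L, function(n) stats::nextn(n, c(2, 3, 5)), 0)
  A <- array(0, dp)
  A[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- mask
  K <- array(0, dp)
  K[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  C <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(dp)
  o <- (dk - 1L) / 2L
  array(C[o[1] + seq_len(dm[1]), o[2] + seq_len(dm[2]),
          o[3] + seq_len(dm[3])] > 0.5, dm)
}

#' Expand a mask by an isotropic physical margin
#'
#' A voxel belongs to the expanded mask when the Euclidean distance between
#' its center and the center of any input-mask voxel is at most `margin_mm`,
#' with anisotropic voxel spacing respected. Equivalent to binary dilation
#' with an ellipsoidal structuring element.
#'
#' @param mask 3D logical array (nonempty).
#' @param margin_mm margin in mm, >= 0.
#' @param spacing voxel size in mm (length 3).
#' @return 3D logical array, superset of `mask`.
#' @export
expand_margin <- function(mask, margin_mm, spacing) {
  if (margin_mm < 0) stop("margin must be nonnegative")
  if (!any(mask)) stop("mask is empty")
  if (margin_mm == 0) return(mask)
  spacing <- rep_len(as.numeric(spacing), 3L)
  r <- floor(margin_mm / spacing)
  if (all(r == 0)) return(mask)
  off <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d2 <- (off$i * spacing[1])^2 + (off$j * spacing[2])^2 +
    (off$k * spacing[3])^2
  kernel <- array(as.numeric(d2 <= margin_mm^2 + 1e-9),
                  dim = 2 * r + 1)
  conv3d_dilate(mask, kernel)
}

#' Ring structure surrounding a PTV
#'
#' The ring is the PTV expanded by `thickness_mm` minus the PTV itself,
#' optionally clipped to the body; it is disjoint from the PTV by
#' construction and starts at the PTV surface (no gap).
#'
#' @param ptv 3D logical PTV mask (nonempty).
#' @param thickness_mm ring thickness in mm, > 0.
#' @param spacing voxel size in mm.
#' @param body optional body mask to clip against.
#' @return 3D logical ring mask.
#' @export
make_ring <- function(ptv, thickness_mm, spacing, body = NULL) {
  if (thickness_mm <= 0) stop("ring thickness must be positive")
  ring <- expand_margin(ptv, thickness_mm, spacing) & !ptv
  if (!is.null(body)) ring <- ring & body
  ring
}
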