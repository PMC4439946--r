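#' Beam arrangements
#'
#' Static gantry-angle sets: `full_arc` = 24 equally spaced angles over 360
#' degrees, `half_arc` = 12 equally spaced angles spanning 180 degrees from
#' `start_angle`, `two_fan` = 12 angles over two opposing 90-degree spans
#' starting at `start_angle` and `start_angle + 180`.
#'
#' @param kind one of `"full_arc"`, `"half_arc"`, `"two_fan"`.
#' @param start_angle first gantry angle in degrees.
#' @return list of class `beam_arrangement` with `angles` (degrees, in
#'   `[0, 360)`) and `label`.
#' @export
make_arrangement <- function(kind = c("full_arc", "half_arc", "two_fan"),
                             start_angle = 0) {
  kind <- match.arg(kind)
  angles <- switch(kind,
    full_arc = start_angle + seq(0, 345, by = 15),
    half_arc = start_angle + seq(0, 165, by = 15),
    two_fan = c(start_angle + seq(0, 75, by = 15),
                start_angle + 180 + seq(0, 75, by = 15))
  )
  angles <- angles %% 360
  if (anyDuplicated(angles)) stop("beam angles must be unique")
  structure(list(angles = angles, label = kind),
            class = "beam_arrangement")
}

#' Place distal-edge-tracking spots for one beam angle
#'
#' Casts rays on a regular beam's-eye-view (BEV) lattice covering the PTV
#' footprint. For each lattice ray that intersects the PTV, the cumulative
#' water-equivalent path length (WEPL) from phantom entry to the ray's
#' distal PTV exit determines the nominal energy: E0 is the energy whose
#' range equals that WEPL, quantized up to the next whole MeV so that
#' quantization never causes undershoot. Rays that miss the PTV produce no
#' spot.
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param ptv 3D logical PTV mask (nonempty).
#' @param angle gantry angle in degrees.
#' @param spacing BEV lattice spacing in mm (default 3).
#' @param iso isocenter (mm); defaults to the PTV centroid.
#' @param model a [beam_model()].
#' @return data.frame with one row per spot: `beam_angle`, `u`, `v` (BEV
#'   lattice position, mm), `E0` (MeV, integer-valued), `wepl` (mm).
#' @export
place_det_spots <- function(dv, mm, ptv, angle, spacing = 3, iso = NULL,
                            model = beam_model()) {
  if (!any(ptv)) stop("PTV mask is empty")
  if (spacing <= 0) stop("spot spacing must be positive")
  if (is.null(iso)) iso <- mask_centroid(ptv, dv$spacing, dv$origin)
  fr <- beam_frame(angle)
  idx <- which(ptv)
  ctr <- voxel_centers(dim(dv$data), dv$spacing, dv$origin, idx)
  rel <- sweep(ctr, 2, iso)
  pu <- rel %*% fr$u
  pv <- rel[, 3]
  uk <- seq(floor(min(pu) / spacing), ceiling(max(pu) / spacing)) * spacing
  vk <- seq(floor(min(pv) / spacing), ceiling(max(pv) / spacing)) * spacing
  lat <- expand.grid(u = uk, v = vk)
  # ray start well outside the grid, marching along the beam direction
  tback <- sqrt(sum(((dim(dv$data) - 1) * dv$spacing)^2)) + 20
  p0 <- cbind(iso[1] + fr$u[1] * lat$u - fr$dir[1] * tback,
              iso[2] + fr$u[2] * lat$u - fr$dir[2] * tback,
              iso[3] + lat$v - fr$dir[3] * tback)
  rsp <- rsp_volume(dv, mm)
  hit <- cpp_det_rays(as.numeric(rsp), as.logical(ptv), dim(dv$data),
                      dv$spacing, dv$origin, p0, fr$dir)
  keep <- !is.na(hit[, "wepl_exit"]) & hit[, "chord"] > 0
  if (!any(keep)) stop("no lattice ray intersects the PTV")
  wepl <- hit[keep, "wepl_exit"]
  data.frame(beam_angle = angle, u = lat$u[keep], v = lat$v[keep],
             E0 = ceiling(energy_from_range(wepl, model)), wepl = wepl)
}

#' Apply the energy margin to a spot set
#'
#' For each spot at BEV position x0, the margined energy E1 is the maximum
#' nominal energy E0 over all existing spots of the same beam whose BEV
#' position lies within the setup-uncertainty neighborhood of x0: an
#' axis-aligned box of half-width `d` on each BEV axis (the component-wise
#' inequality form), or optionally a disc of radius `d`. The spot itself is
#' always in its own neighborhood, so E1 >= E0; lateral positions are
#' unchanged. `d` is the maximum setup uncertainty projected on the plane
#' perpendicular to the beam; shifts parallel to the beam axis do not change
#' the range and play no role.
#'
#' @param spots data.frame from [place_det_spots()] (or several beams bound
#'   together), with columns `beam_angle`, `u`, `v`, `E0`.
#' @param d maximum projected setup uncertainty in mm (default 6, >= 0).
#' @param shape `"box"` (default, component-wise inequality) or `"disc"`.
#' @return `spots` with an added integer column `E1 >= E0`.
#' @export
apply_energy_margin <- function(spots, d = 6, shape = c("box", "disc")) {
  shape <- match.arg(shape)
  if (d < 0) stop("d must be nonnegative")
  spots$E1 <- spots$E0
  if (d == 0) return(spots)
  for (ang in unique(spots$beam_angle)) {
    sel <- which(spots$beam_angle == ang)
    u <- spots$u[sel]; v <- spots$v[sel]; e0 <- spots$E0[sel]
    du <- abs(outer(u, u, "-"))
    dvv <- abs(outer(v, v, "-"))
    nb <- if (shape == "box") du <= d & dvv <= d
          else du^2 + dvv^2 <= d^2
    spots$E1[sel] <- apply(nb, 1L, function(m) max(e0[m]))
  }
  spots
}

#' Build a DET spot plan for a beam arrangement
#'
#' Places distal-edge spots for every gantry angle and assigns the energy
#' margin. The returned plan carries both the nominal (`E0`) and margined
#' (`E1`) energies; which one is delivered is selected by the `energy`
#' argument of [build_influence()], [plan_dose()] and [deliver_fraction()]
#' (ORG plan = `"E0"`, EM plan = `"E1"`).
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param structures a [structure_set()].
#' @param arrangement a [make_arrangement()].
#' @param spacing BEV spot lattice spacing in mm.
#' @param d energy-margin setup uncertainty in mm (see
#'   [apply_energy_margin()]).
#' @param shape neighborhood shape, `"box"` or `"disc"`.
#' @param iso isocenter; defaults to the CTV centroid.
#' @param model a [beam_model()].
#' @return data.frame of class `spot_plan` with columns `beam_angle`, `u`,
#'   `v`, `E0`, `E1`, `wepl`, `weight` (NA until optimized) and attributes
#'   `iso`, `spacing`, `d`, `arrangement`, `model`.
#' @export
build_det_plan <- function(dv, mm, structures, arrangement,
                           spacing = 3, d = 6, shape = c("box", "disc"),
                           iso = NULL, model = beam_model()) {
  shape <- match.arg(shape)
  if (is.null(iso)) {
    iso <- mask_centroid(structures$masks$CTV, dv$spacing, dv$origin)
  }
  ptv <- structures$masks$PTV
  spots <- do.call(rbind, lapply(arrangement$angles, function(a) {
    place_det_spots(dv, mm, ptv, a, spacing = spacing, iso = iso,
                    model = model)
  }))
  spots <- apply_energy_margin(spots, d = d, shape = shape)
  spots$weight <- NA_real_
  attr(spots, "iso") <- iso
  attr(spots, "spacing") <- spacing
  attr(spots, "d") <- d
  attr(spots, "arrangement") <- arrangement$label
  attr(spots, "model") <- model
  class(spots) <- c("spot_plan", "data.frame")
  spots
}

#' Summarize a spot plan
#'
#' @param plan a `spot_plan` (or any data.frame with `beam_angle`, `E0`,
#'   `E1`).
#' @return list with `n_spots`, `n_beams`, `mean_E0`, `mean_E1` (unweighted
#'   mean energies, MeV).
#' @export
plan_info <- function(plan) {
  if (!nrow(plan)) stop("plan is empty")
  list(n_spots = nrow(plan),
       n_beams = length(unique(plan$beam_angle)),
       mean_E0 = mean(plan$E0),
       mean_E1 = mean(plan$E1))
}
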