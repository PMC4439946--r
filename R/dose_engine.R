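#' Analytic pencil-beam model parameters
#'
#' Collects the parameters of the analytic proton pencil-beam engine:
#' the Bragg-Kleeman range-energy power law `R(E) = 10 * alpha * E^p` (mm),
#' the fractional Gaussian energy spread (1% of the nominal energy), the
#' in-air lateral spot sigma at isocenter (3 mm), the end-of-range multiple
#' Coulomb scattering fraction (lateral sigma grows to `mcs_frac * R(E)` at
#' the end of range), the lateral Gaussian evaluation cutoff in sigmas, and
#' the depth sampling step of the tabulated depth-dose curves.
#'
#' @param alpha Bragg-Kleeman coefficient (cm/MeV^p).
#' @param p Bragg-Kleeman exponent, 1 < p < 2.
#' @param sigma_air lateral Gaussian sigma in air at isocenter (mm).
#' @param energy_spread fractional energy sigma (dimensionless).
#' @param mcs_frac end-of-range scattering sigma as a fraction of range.
#' @param cutoff_sigma lateral kernel evaluation cutoff (sigmas).
#' @param idd_step depth-dose table sampling step (mm).
#' @return list of class `beam_model`.
#' @export
beam_model <- function(alpha = 0.0022, p = 1.77, sigma_air = 3.0,
                       energy_spread = 0.01, mcs_frac = 0.02,
                       cutoff_sigma = 3.5, idd_step = 0.25) {
  if (alpha <= 0) stop("alpha must be positive")
  if (p <= 1 || p >= 2) stop("p must lie in (1, 2)")
  structure(list(alpha = alpha, p = p, sigma_air = sigma_air,
                 energy_spread = energy_spread, mcs_frac = mcs_frac,
                 cutoff_sigma = cutoff_sigma, idd_step = idd_step),
            class = "beam_model")
}

#' Water-equivalent range of a proton beam
#'
#' Bragg-Kleeman power law: `R(E) = 10 * alpha * E^p` millimetres of water.
#' Strictly increasing in energy, exactly invertible by
#' [energy_from_range()].
#'
#' @param E kinetic energy in MeV (> 0), vectorized.
#' @param model a [beam_model()].
#' @return range in mm water.
#' @export
range_from_energy <- function(E, model = beam_model()) {
  if (any(E <= 0)) stop("energy must be positive")
  10 * model$alpha * E^model$p
}

#' Energy required for a given water-equivalent range
#'
#' Exact analytic inverse of [range_from_energy()].
#'
#' @param R range in mm water (> 0), vectorized.
#' @param model a [beam_model()].
#' @return kinetic energy in MeV.
#' @export
energy_from_range <- function(R, model = beam_model()) {
  if (any(R <= 0)) stop("range must be positive")
  (R / (10 * model$alpha))^(1 / model$p)
}

#' Pristine Bragg curve with Gaussian range spread
#'
#' Depth dose per unit fluence at water-equivalent depth `wed` for a beam of
#' nominal energy `E` and absolute energy spread `energy_sigma`. The pristine
#' peak follows the Bragg-Kleeman stopping-power term
#' `(R - w)^(1/p - 1)`, which is convolved with a Gaussian range spread
#' `sigma_R = p * R * energy_sigma / E` (the first-order propagation of the
#' energy spread through the range-energy power law). The convolution
#' integral uses exact per-cell weights for the integrable end-of-range
#' singularity. Dose is identically zero beyond `R + 4 * sigma_R`.
#'
#' @param E nominal energy (MeV).
#' @param energy_sigma absolute energy sigma (MeV); default 1% of `E`.
#' @param wed water-equivalent depth(s) in mm, >= 0.
#' @param model a [beam_model()].
#' @return relative dose (arbitrary units), same length as `wed`.
#' @export
depth_dose <- function(E, energy_sigma = 0.01 * E, wed,
                       model = beam_model()) {
  if (E <= 0) stop("energy must be positive")
  if (any(wed < 0)) stop("depth must be nonnegative")
  R <- range_from_energy(E, model)
  sigma_r <- max(model$p * R * energy_sigma / E, 1e-3)
  nu <- 1 / model$p
  h <- min(0.1, sigma_r / 5)
  edges <- seq(0, R, by = h)
  if (edges[length(edges)] < R) edges <- c(edges, R)
  # exact integral of (R - x)^(nu - 1) over each cell
  wts <- ((R - edges[-length(edges)])^nu - (R - edges[-1])^nu) / nu
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  out <- numeric(length(wed))
  live <- wed <= R + 4 * sigma_r
  if (any(live)) {
    # D(w) = sum_cells w_cell * phi(w - mid; sigma_r)
    out[live] <- as.numeric(
      dnorm(outer(wed[live], mids, "-"), sd = sigma_r) %*% wts
    )
  }
  out
}

#' Lateral Gaussian sigma of a pencil beam at depth
#'
#' `sigma(w)^2 = sigma_air^2 + sigma_mcs(w)^2` with the multiple-scattering
#' term `sigma_mcs(w) = mcs_frac * R * (w/R)^1.5`, a monotone-increasing
#' model that reaches `mcs_frac * R(E)` at the end of range and vanishes at
#' the surface.
#'
#' @param E nominal energy (MeV).
#' @param wed water-equivalent depth(s) in mm, >= 0.
#' @param model a [beam_model()].
#' @return lateral sigma in mm, same length as `wed`.
#' @export
lateral_sigma <- function(E, wed, model = beam_model()) {
  if (any(wed < 0)) stop("depth must be nonnegative")
  R <- range_from_energy(E, model)
  sqrt(model$sigma_air^2 + model$mcs_frac^2 * wed^3 / R)
}

# Per-energy depth-dose table used by the C++ deposition kernel:
# relative dose sampled every `idd_step` mm of WEPL, the range, the support
# cutoff, and the normalization constant making a unit-weight spot deposit
# 1 Gy at its Bragg-peak position in uniform water.
energy_table <- function(E, model) {
  key <- paste(signif(E, 10), model$alpha, model$p, model$energy_spread,
               model$sigma_air, model$mcs_frac, model$idd_step, sep = "|")
  hit <- .detem_cache[[key]]
  if (!is.null(hit)) return(hit)
  R <- range_from_energy(E, model)
  sigma_r <- max(model$p * R * model$energy_spread, 1e-3)
  wcut <- R + 4 * sigma_r
  w <- seq(0, wcut + model$idd_step, by = model$idd_step)
  vals <- depth_dose(E, model$energy_spread * E, w, model)
  sig <- lateral_sigma(E, w, model)
  norm <- max(vals / (2 * pi * sig^2))
  tab <- list(energy = E, step = model$idd_step, vals = vals, range = R,
              wcut = wcut, norm = norm)
  assign(key, tab, envir = .detem_cache)
  tab
}

energy_tables <- function(energies, model) {
  uE <- sort(unique(energies))
  tabs <- lapply(uE, energy_table, model = model)
  list(tabs = tabs, eid = match(energies, uE))
}

#' Water-equivalent path length along a ray
#'
#' Traces a ray through the voxel grid with exact voxel-boundary ray
#' marching and integrates relative stopping power, giving the cumulative
#' WEPL at each voxel exit. A ray that misses the grid yields a zero-row
#' result (not an error).
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param origin ray origin (mm, length 3).
#' @param direction ray direction (length 3; normalized internally).
#' @return data.frame with columns `idx` (1-based linear voxel index),
#'   `t_in`, `t_out` (mm along the ray) and `wepl` (cumulative mm water at
#'   `t_out`), ordered along the ray.
#' @export
wepl_trace <- function(dv, mm, origin, direction) {
  direction <- direction / sqrt(sum(direction^2))
  rsp <- rsp_volume(dv, mm)
  m <- cpp_trace_ray(as.numeric(rsp), dim(dv$data), dv$spacing, dv$origin,
                     as.numeric(origin), as.numeric(direction))
  as.data.frame(m)
}

#' Single pencil-beam spot
#'
#' @param beam_angle gantry angle in degrees (0 = travelling +y,
#'   counterclockwise in the axial plane).
#' @param bev_pos lateral offset in the beam's-eye view, mm (length 2).
#' @param energy nominal kinetic energy (MeV, > 0).
#' @param energy_sigma absolute energy spread (MeV); default 1% of energy.
#' @param sigma_air lateral sigma in air at isocenter (mm).
#' @return list of class `pencil_beam`.
#' @export
pencil_beam <- function(beam_angle, bev_pos = c(0, 0), energy,
                        energy_sigma = 0.01 * energy, sigma_air = 3.0) {
  if (energy <= 0) stop("energy must be positive")
  structure(list(beam_angle = beam_angle, bev_pos = bev_pos,
                 energy = energy, energy_sigma = energy_sigma,
                 sigma_air = sigma_air),
            class = "pencil_beam")
}

# internal: dose from a set of spots at evaluation points.
# spots: data.frame(beam_angle, u, v, energy); weights aligned with rows.
dose_at_points <- function(rsp, dims, spacing, grid_origin, pts, iso, spots,
                          weights, model) {
  et <- energy_tables(spots$energy, model)
  dose <- numeric(nrow(pts))
  for (ang in unique(spots$beam_angle)) {
    sel <- spots$beam_angle == ang
    dose <- dose + cpp_dose_points_angle(
      as.numeric(rsp), dims, spacing, grid_origin, pts, as.numeric(iso),
      ang, spots$u[sel], spots$v[sel], et$eid[sel], weights[sel], et$tabs,
      model$sigma_air, model$mcs_frac, model$cutoff_sigma)
  }
  dose
}

#' Dose grid of a single pencil-beam spot
#'
#' Deposits the dose of one spot on the phantom grid. Each voxel is mapped
#' to the beam frame; its depth coordinate is converted to water-equivalent
#' depth using the WEPL of the spot's central axis at equal geometric depth
#' (central-axis approximation), and the dose is the tabulated depth dose
#' times a normalized 2D lateral Gaussian. A unit-weight spot deposits 1 Gy
#' at its Bragg-peak position in uniform water.
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param beam a [pencil_beam()].
#' @param grid_mask optional logical array restricting evaluated voxels.
#' @param iso isocenter (mm); defaults to the grid center.
#' @param weight spot weight (1 = unit weight).
#' @param model a [beam_model()]; `sigma_air` is taken from the beam.
#' @return a [dose_grid()].
#' @export
compute_spot_dose <- function(dv, mm, beam, grid_mask = NULL, iso = NULL,
                              weight = 1, model = beam_model()) {
  stopifnot(inherits(beam, "pencil_beam"))
  model$sigma_air <- beam$sigma_air
  model$energy_spread <- beam$energy_sigma / beam$energy
  if (is.null(iso)) iso <- grid_center(dv)
  dims <- dim(dv$data)
  idx <- if (is.null(grid_mask)) NULL else which(grid_mask)
  pts <- voxel_centers(dims, dv$spacing, dv$origin, idx)
  rsp <- rsp_volume(dv, mm)
  spots <- data.frame(beam_angle = beam$beam_angle, u = beam$bev_pos[1],
                      v = beam$bev_pos[2], energy = beam$energy)
  d <- dose_at_points(rsp, dims, dv$spacing, dv$origin, pts, iso, spots,
                      weight, model)
  out <- array(0, dims)
  if (is.null(idx)) out[] <- d else out[idx] <- d
  dose_grid(out, dv$spacing, dv$origin)
}
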