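#' Sample per-fraction rigid setup shifts
#'
#' Each translation component (lateral, anterior-posterior,
#' superior-inferior) is drawn from a zero-mean Gaussian with the given
#' sigma and rejection-resampled while it exceeds the per-axis cutoff
#' (truncation by rejection, not clipping, so no probability mass piles up
#' at the cutoff). By default a sample whose 3D norm exceeds `max_3d` is
#' also redrawn, so both the per-axis +/-4 mm bound and the 6 mm maximum 3D
#' shift hold simultaneously.
#'
#' @param n number of fractions (default 30).
#' @param sigma per-axis Gaussian sigma in mm (default 2).
#' @param cutoff per-axis absolute cutoff in mm (default 4).
#' @param seed optional integer seed for reproducibility.
#' @param max_3d maximum 3D shift norm in mm (default 6; `Inf` disables).
#' @return `n x 3` matrix of class `shift_set` (columns `dx`, `dy`, `dz`)
#'   with attributes `sigma`, `cutoff`, `max_3d`, `seed`.
#' @export
sample_shifts <- function(n = 30, sigma = 2, cutoff = 4, seed = NULL,
                          max_3d = 6) {
  if (sigma <= 0) stop("sigma must be positive")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!is.null(seed)) set.seed(seed)
  draw_axis <- function(m) {
    x <- rnorm(m, 0, sigma)
    bad <- abs(x) > cutoff
    while (any(bad)) {
      x[bad] <- rnorm(sum(bad), 0, sigma)
      bad <- abs(x) > cutoff
    }
    x
  }
  draw <- function(m) cbind(draw_axis(m), draw_axis(m), draw_axis(m))
  s <- draw(n)
  if (is.finite(max_3d)) {
    bad <- sqrt(rowSums(s^2)) > max_3d
    while (any(bad)) {
      s[bad, ] <- draw(sum(bad))
      bad <- sqrt(rowSums(s^2)) > max_3d
    }
  }
  colnames(s) <- c("dx", "dy", "dz")
  structure(s, class = c("shift_set", "matrix"), sigma = sigma,
            cutoff = cutoff, max_3d = max_3d,
            seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Deliver one fraction of a plan under a rigid setup shift
#'
#' The patient translation is applied as a translation of every beam's
#' isocenter by minus the shift (exact rigid equivalence, no resampling),
#' and the full spot dose is recomputed through the shifted geometry: every
#' spot's central-axis WEPL is retraced, so range undershoot and overshoot
#' through heterogeneities emerge naturally. The result is scaled to
#' `1/n_fractions` of the plan weights.
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param plan a weighted `spot_plan` (see [set_weights()]).
#' @param shift length-3 translation in mm.
#' @param n_fractions number of fractions the plan is divided into.
#' @param mask optional logical array restricting evaluated voxels.
#' @param model a [beam_model()]; defaults to the plan's model.
#' @return a [dose_grid()] of the fraction dose.
#' @export
deliver_fraction <- function(dv, mm, plan, shift, n_fractions = 30,
                             mask = NULL, model = NULL) {
  if (anyNA(plan$weight)) stop("plan has no optimized weights")
  if (is.null(model)) model <- attr(plan, "model")
  if (is.null(model)) model <- beam_model()
  energy <- attr(plan, "energy")
  if (is.null(energy)) energy <- "E0"
  iso <- attr(plan, "iso")
  if (is.null(iso)) iso <- grid_center(dv)
  iso_eff <- iso - as.numeric(shift)
  dims <- dim(dv$data)
  idx <- if (is.null(mask)) NULL else which(mask)
  pts <- voxel_centers(dims, dv$spacing, dv$origin, idx)
  rsp <- rsp_volume(dv, mm)
  spots <- data.frame(beam_angle = plan$beam_angle, u = plan$u, v = plan$v,
                      energy = plan[[energy]])
  d <- dose_at_points(rsp, dims, dv$spacing, dv$origin, pts, iso_eff, spots,
                      plan$weight / n_fractions, model)
  out <- array(0, dims)
  if (is.null(idx)) out[] <- d else out[idx] <- d
  dose_grid(out, dv$spacing, dv$origin)
}

# internal: deliver a whole course at masked voxels, returning a
# fraction_dose_set (points x fractions matrix)
deliver_course <- function(dv, mm, plan, shifts, mask, model = NULL) {
  if (anyNA(plan$weight)) stop("plan has no optimized weights")
  if (is.null(model)) model <- attr(plan, "model")
  if (is.null(model)) model <- beam_model()
  energy <- attr(plan, "energy")
  if (is.null(energy)) energy <- "E0"
  iso <- attr(plan, "iso")
  if (is.null(iso)) iso <- grid_center(dv)
  n <- nrow(shifts)
  dims <- dim(dv$data)
  idx <- if (is.null(mask)) seq_len(prod(dims)) else which(mask)
  pts <- voxel_centers(dims, dv$spacing, dv$origin, idx)
  rsp <- rsp_volume(dv, mm)
  spots <- data.frame(beam_angle = plan$beam_angle, u = plan$u, v = plan$v,
                      energy = plan[[energy]])
  doses <- matrix(0, length(idx), n)
  for (i in seq_len(n)) {
    doses[, i] <- dose_at_points(rsp, dims, dv$spacing, dv$origin, pts,
                                 iso - shifts[i, ], spots,
                                 plan$weight / n, model)
  }
  structure(list(doses = doses, idx = idx, dims = dims,
                 spacing = dv$spacing, origin = dv$origin,
                 n_fractions = n),
            class = "fraction_dose_set")
}

#' Simulate a fractionated course for the ORG and EM plans
#'
#' Both plans are delivered against the *same* shift set, fraction by
#' fraction, so the ORG/EM comparison is paired by construction.
#'
#' @param dv a [density_volume()].
#' @param mm matching [assign_materials()] map.
#' @param org_plan,em_plan weighted `spot_plan`s (ORG delivering `E0`, EM
#'   delivering `E1`; see [set_weights()]).
#' @param shifts a [sample_shifts()] matrix; its row count sets the number
#'   of fractions.
#' @param mask optional logical array restricting evaluated voxels (e.g.
#'   CTV union ring for evaluation-only courses); `NULL` evaluates the full
#'   grid.
#' @param model a [beam_model()].
#' @return list with elements `org` and `em`, each a `fraction_dose_set`:
#'   a voxels-by-fractions dose matrix plus grid bookkeeping.
#' @export
simulate_course <- function(dv, mm, org_plan, em_plan, shifts, mask = NULL,
                            model = NULL) {
  list(org = deliver_course(dv, mm, org_plan, shifts, mask, model),
       em = deliver_course(dv, mm, em_plan, shifts, mask, model))
}
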