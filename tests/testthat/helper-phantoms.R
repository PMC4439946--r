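# uniform box of a given density (1.0 -> relative stopping power exactly 1)
water_box <- function(dims = c(31, 101, 31), spacing = c(2, 2, 2),
                      density = 1.0) {
  dv <- density_volume(array(density, dims), spacing)
  list(dv = dv, mm = assign_materials(dv))
}

# scaled-down heterogeneous phantom for fast end-to-end tests
small_phantom <- function(cavity = list(radius = 6, direction = c(-1, 0, 0),
                                        gap = 0)) {
  make_phantom(phantom_spec(
    body = list(radius = 30, height = 64),
    ctv = list(center = c(0, 0, 0), radius = 8),
    cavity = cavity,
    air_border = 6
  ))
}

# single-spot plan data.frame with the attributes build_det_plan would set
single_spot_plan <- function(angle, u, v, energy, iso,
                             model = beam_model()) {
  plan <- data.frame(beam_angle = angle, u = u, v = v,
                     E0 = energy, E1 = energy, weight = NA_real_)
  attr(plan, "iso") <- iso
  attr(plan, "spacing") <- 3
  attr(plan, "d") <- 0
  attr(plan, "arrangement") <- "custom"
  attr(plan, "model") <- model
  class(plan) <- c("spot_plan", "data.frame")
  plan
}

# brute-force energy-margin oracle: exhaustive pairwise neighborhood scan
em_oracle <- function(u, v, e0, d, shape = "box") {
  vapply(seq_along(u), function(i) {
    du <- abs(u - u[i])
    dv <- abs(v - v[i])
    nb <- if (shape == "box") du <= d & dv <= d else du^2 + dv^2 <= d^2
    max(e0[nb])
  }, 0)
}

# midpoint-rule WEPL quadrature along a clipped ray segment, including the
# partial final step so the integration interval matches exactly
wepl_quadrature <- function(rsp, dims, spacing, lo, p0, u, t0, t1,
                            step = 0.02) {
  len <- t1 - t0
  n <- floor(len / step)
  tt <- t0 + (seq_len(n) - 0.5) * step
  wt <- rep(step, n)
  rem <- len - n * step
  if (rem > 1e-12) {
    tt <- c(tt, t0 + n * step + rem / 2)
    wt <- c(wt, rem)
  }
  pts <- outer(tt, u) + rep(p0, each = length(tt))
  ijk <- sweep(pts, 2, lo)
  ijk <- pmin(pmax(floor(sweep(ijk, 2, spacing, "/")), 0),
              rep(dims - 1, each = nrow(ijk)))
  sum(wt * rsp[1 + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])])
}

# sort-based DVH percentile oracle: minimum dose of the hottest x% voxels
dx_oracle <- function(doses, volume_pct) {
  sort(doses, decreasing = TRUE)[ceiling(volume_pct / 100 * length(doses))]
}
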