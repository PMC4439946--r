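test_that("range-energy power law evaluates and inverts exactly", {
  expect_equal(range_from_energy(100), 10 * 0.0022 * 100^1.77)
  E <- energy_from_range(100)
  expect_equal(energy_from_range(range_from_energy(E)), E,
               tolerance = 1e-9)
  for (E in c(30, 70, 150)) expect_gt(range_from_energy(2 * E),
                                      range_from_energy(E))
  expect_error(range_from_energy(-1), "positive")
  expect_error(energy_from_range(0), "positive")
})

test_that("depth dose peaks near the range with a hard distal cutoff", {
  E <- energy_from_range(100)
  w <- seq(0, 120, by = 0.05)
  dd <- depth_dose(E, 0.01 * E, w)
  expect_true(all(dd >= 0))
  expect_lt(abs(w[which.max(dd)] - 100), 2)
  sigma_r <- 1.77 * 100 * 0.01
  expect_true(all(dd[w > 100 + 4 * sigma_r] == 0))
  # a wider energy spread lowers and widens the peak
  dd2 <- depth_dose(E, 0.02 * E, w)
  expect_lt(max(dd2), max(dd))
  expect_gt(sum(dd2 > max(dd2) / 2) , sum(dd > max(dd) / 2))
})

test_that("lateral sigma starts at the in-air value and grows with depth", {
  E <- energy_from_range(100)
  expect_equal(lateral_sigma(E, 0), 3.0)
  w <- seq(0, 110, by = 1)
  s <- lateral_sigma(E, w)
  expect_true(all(diff(s) >= 0))
  expect_equal(lateral_sigma(E, 100)^2 - 9, (0.02 * 100)^2,
               tolerance = 1e-9)
})

test_that("WEPL tracing is exact in uniform water and through air", {
  bx <- water_box(c(31, 31, 31))
  tr <- wepl_trace(bx$dv, bx$mm, origin = c(-200, 0, 0),
                   direction = c(1, 0, 0))
  expect_true(all(diff(tr$wepl) >= 0))
  # 50 mm of geometric path in water = 50 mm WEPL
  t0 <- tr$t_in[1]
  w50 <- approx(tr$t_out, tr$wepl, t0 + 50)$y
  expect_equal(w50, 50, tolerance = 1e-6)

  # 20 mm air gap contributes at most 20 * 0.0012 mm of WEPL
  dens <- array(1.0, c(31, 31, 31))
  dens[, 11:20, ] <- 0.0012
  dv <- density_volume(dens, c(2, 2, 2))
  mm <- assign_materials(dv)
  tr2 <- wepl_trace(dv, mm, c(0, -200, 0), c(0, 1, 0))
  expect_equal(max(tr2$wepl), (62 - 20) * 1 + 20 * 0.0012,
               tolerance = 1e-6)
  # a missed ray yields an empty trace, not an error
  tr3 <- wepl_trace(bx$dv, bx$mm, c(500, 500, 0), c(0, 1, 0))
  expect_equal(nrow(tr3), 0)
})

test_that("Siddon trace agrees with midpoint quadrature on random rays", {
  set.seed(7)
  dims <- c(24, 24, 24)
  dv <- density_volume(array(runif(prod(dims), 0, 1.6), dims), c(2, 2, 2))
  mm <- assign_materials(dv)
  rsp <- rsp_volume(dv, mm)
  lo <- dv$origin - dv$spacing / 2
  for (i in 1:100) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    target <- runif(3, -10, 10)
    p0 <- target - 150 * u
    tr <- wepl_trace(dv, mm, p0, u)
    if (!nrow(tr)) next
    q <- wepl_quadrature(rsp, dims, dv$spacing, lo, p0, u,
                         tr$t_in[1], tr$t_out[nrow(tr)])
    expect_lt(abs(q - max(tr$wepl)) / max(tr$wepl), 0.005)
  }
})

test_that("a spot's Bragg peak sits at the beam range in uniform water", {
  bx <- water_box(c(31, 101, 31))
  E <- energy_from_range(100)
  b <- pencil_beam(0, c(0, 0), energy = E)
  dg <- compute_spot_dose(bx$dv, bx$mm, b)
  pk <- which(dg$data == max(dg$data), arr.ind = TRUE)[1, ]
  entry_y <- bx$dv$origin[2] - bx$dv$spacing[2] / 2
  depth <- bx$dv$origin[2] + (pk[2] - 1) * bx$dv$spacing[2] - entry_y
  expect_lt(abs(depth - 100), 2)
  # the on-axis peak voxel receives close to the normalized 1 Gy (it sits
  # within half a voxel of the continuous Bragg-peak position)
  expect_equal(max(dg$data), 1.0, tolerance = 0.05)
  # lateral falloff: dose at >= 3 sigma off-axis under 1.2% of axis dose
  sig <- lateral_sigma(E, depth)
  off <- ceiling(3 * sig / 2)  # voxel offset placing the center past 3 sigma
  ratio <- dg$data[pk[1] + off, pk[2], pk[3]] / dg$data[pk[1], pk[2], pk[3]]
  expect_lt(ratio, 0.012)
})

test_that("spot dose is linear in weights and zero off the grid", {
  bx <- water_box(c(21, 61, 21))
  E <- energy_from_range(60)
  b1 <- pencil_beam(0, c(0, 0), energy = E)
  b2 <- pencil_beam(0, c(6, 3), energy = E)
  d1 <- compute_spot_dose(bx$dv, bx$mm, b1)
  d2 <- compute_spot_dose(bx$dv, bx$mm, b2)
  plan <- rbind(single_spot_plan(0, 0, 0, E, c(0, 0, 0)),
                single_spot_plan(0, 6, 3, E, c(0, 0, 0)))
  attr(plan, "iso") <- c(0, 0, 0)
  attr(plan, "model") <- beam_model()
  class(plan) <- c("spot_plan", "data.frame")
  both <- plan_dose(bx$dv, bx$mm, plan, weights = c(2, 0.5), energy = "E0")
  expect_equal(both$data, 2 * d1$data + 0.5 * d2$data, tolerance = 1e-12)
  # beam missing the grid deposits nothing
  miss <- pencil_beam(0, c(500, 0), energy = E)
  expect_equal(max(compute_spot_dose(bx$dv, bx$mm, miss)$data), 0)
})

test_that("an upstream air slab deepens the Bragg peak by its thickness", {
  dims <- c(31, 101, 31)
  E <- energy_from_range(100)
  peak_depth <- function(dv) {
    mm <- assign_materials(dv)
    dg <- compute_spot_dose(dv, mm, pencil_beam(0, c(0, 0), energy = E))
    pk <- which(dg$data == max(dg$data), arr.ind = TRUE)[1, ]
    dv$origin[2] + (pk[2] - 1) * dv$spacing[2]
  }
  uni <- water_box(dims)
  dens <- array(1.0, dims)
  dens[, 11:20, ] <- 0.0012  # 20 mm air slab, upstream of the peak
  slab <- density_volume(dens, c(2, 2, 2))
  shift <- peak_depth(slab) - peak_depth(uni$dv)
  expect_lt(abs(shift - 20), 2)
})

test_that("higher energies have deeper distal falloff", {
  bx <- water_box(c(21, 101, 21))
  d80 <- function(E) {
    dg <- compute_spot_dose(bx$dv, bx$mm, pencil_beam(0, c(0, 0), E))
    ax <- dg$data[11, , 11]
    y <- which(ax > 0.8 * max(ax))
    max(y)
  }
  E1 <- energy_from_range(60)
  E2 <- energy_from_range(90)
  expect_lt(d80(E1), d80(E2))
})
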