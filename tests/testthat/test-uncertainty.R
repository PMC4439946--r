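test_that("shift sampling honors the truncation bounds", {
  s <- sample_shifts(n = 1e5, seed = 2)
  expect_true(all(abs(s) <= 4))
  expect_true(all(sqrt(rowSums(s^2)) <= 6))
  # truncation shrinks the nominal 2 mm sigma to about 1.88 mm
  sds <- apply(s, 2, sd)
  expect_true(all(sds > 1.75 & sds < 2.0))
  expect_true(all(abs(colMeans(s)) < 0.05))
  # without the 3D bound, per-axis truncation alone still holds
  s2 <- sample_shifts(n = 1e4, seed = 3, max_3d = Inf)
  expect_true(all(abs(s2) <= 4))
})

test_that("shift sampling is reproducible under a fixed seed", {
  a <- sample_shifts(seed = 9)
  b <- sample_shifts(seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(sample_shifts(seed = 10))))
})

test_that("a zero shift delivers exactly the planned fraction dose", {
  ph <- small_phantom()
  dv <- ph$volume
  mm <- assign_materials(dv)
  plan <- build_det_plan(dv, mm, ph$structures,
                         make_arrangement("half_arc", 45))
  plan <- set_weights(plan, rep(0.02, nrow(plan)), "E0")
  planned <- plan_dose(dv, mm, plan)
  fr <- deliver_fraction(dv, mm, plan, shift = c(0, 0, 0), n_fractions = 30)
  expect_equal(30 * fr$data, planned$data, tolerance = 1e-12)
})

test_that("shifts along a beam's axis leave its dose unchanged in water", {
  # axial motion does not change the water-equivalent depth of any voxel,
  # so the range (and the whole dose pattern) is invariant
  bx <- water_box(c(25, 61, 25))
  E <- energy_from_range(60)
  plan <- single_spot_plan(0, 0, 0, E, iso = c(0, 0, 0))
  plan <- set_weights(plan, 1, "E0")
  planned <- deliver_fraction(bx$dv, bx$mm, plan, c(0, 0, 0),
                              n_fractions = 1)
  shifted <- deliver_fraction(bx$dv, bx$mm, plan, c(0, 3.5, 0),
                              n_fractions = 1)
  expect_equal(shifted$data, planned$data, tolerance = 1e-9)
  # whereas a lateral shift moves the spot
  lat <- deliver_fraction(bx$dv, bx$mm, plan, c(3.5, 0, 0),
                          n_fractions = 1)
  expect_gt(max(abs(lat$data - planned$data)), 0.1)
})

test_that("a lateral shift into the air cavity deepens the Bragg peak", {
  ph <- make_phantom()
  dv <- ph$volume
  mm <- assign_materials(dv)
  E <- energy_from_range(100)
  # beam travelling +x passes the cavity before the target; the spot axis
  # at u = -22 (patient y = +22) just misses the 20 mm cavity silhouette
  plan <- single_spot_plan(270, u = -22, v = 0, energy = E,
                           iso = c(0, 0, 0))
  plan <- set_weights(plan, 1, "E0")
  peak_x <- function(shift) {
    fr <- deliver_fraction(dv, mm, plan, shift, n_fractions = 1)
    pk <- which(fr$data == max(fr$data), arr.ind = TRUE)[1, ]
    dv$origin[1] + (pk[1] - 1) * dv$spacing[1]
  }
  # a 4 mm lateral patient shift moves the axis across the silhouette;
  # the lost water path deepens the peak by >= 10 mm
  x0 <- peak_x(c(0, 0, 0))
  x1 <- peak_x(c(0, 4, 0))
  expect_gte(x1 - x0, 10)
})

test_that("course simulation shares one shift set and reproduces exactly", {
  ph <- small_phantom()
  dv <- ph$volume
  mm <- assign_materials(dv)
  plan <- build_det_plan(dv, mm, ph$structures,
                         make_arrangement("half_arc", 45))
  org <- set_weights(plan, rep(0.02, nrow(plan)), "E0")
  em <- set_weights(plan, rep(0.02, nrow(plan)), "E1")
  mask <- ph$structures$masks$CTV | ph$structures$masks$ring
  shifts <- sample_shifts(n = 4, seed = 5)
  c1 <- simulate_course(dv, mm, org, em, shifts, mask = mask)
  c2 <- simulate_course(dv, mm, org, em, sample_shifts(n = 4, seed = 5),
                        mask = mask)
  expect_identical(c1$org$doses, c2$org$doses)
  expect_identical(c1$em$doses, c2$em$doses)
  expect_equal(c1$org$n_fractions, 4)
  # zero shifts: the fraction sum equals the planned dose
  zero <- sample_shifts(n = 4, seed = 5)
  zero[] <- 0
  c0 <- simulate_course(dv, mm, org, em, zero, mask = mask)
  planned <- plan_dose(dv, mm, org, mask = mask)
  expect_equal(rowSums(c0$org$doses), planned$data[mask],
               tolerance = 1e-9)
  expect_error(simulate_course(dv, mm, plan, em, shifts, mask = mask),
               "weights")
})
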