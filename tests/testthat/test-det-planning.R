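test_that("beam arrangements have the stated angle structure", {
  fa <- make_arrangement("full_arc")
  expect_length(fa$angles, 24)
  expect_equal(sort(diff(sort(fa$angles))), rep(15, 23))

  ha <- make_arrangement("half_arc", start_angle = 45)
  expect_length(ha$angles, 12)
  expect_true(all(ha$angles >= 45 & ha$angles < 225))

  tf <- make_arrangement("two_fan", start_angle = 0)
  expect_length(tf$angles, 12)
  expect_true(all((tf$angles >= 0 & tf$angles < 90) |
                    (tf$angles >= 180 & tf$angles < 270)))

  expect_error(make_arrangement("spiral"))
})

test_that("energy margin reproduces the worked 1D profile", {
  spots <- data.frame(beam_angle = 0, u = c(0, 3, 6, 9), v = 0,
                      E0 = c(100, 110, 105, 120))
  out <- apply_energy_margin(spots, d = 6)
  expect_equal(out$E1, c(110, 120, 120, 120))
  expect_equal(out$u, spots$u)
  expect_equal(out$v, spots$v)
  # d = 0 is the identity
  expect_equal(apply_energy_margin(spots, d = 0)$E1, spots$E0)
  expect_error(apply_energy_margin(spots, d = -1), "nonnegative")
})

test_that("energy margin matches the exhaustive oracle on random spot sets", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    u <- sample(seq(-30, 30, by = 3), n, replace = TRUE)
    v <- sample(seq(-15, 15, by = 3), n, replace = TRUE)
    keep <- !duplicated(cbind(u, v))
    u <- u[keep]; v <- v[keep]
    e0 <- sample(60:140, length(u), replace = TRUE)
    spots <- data.frame(beam_angle = 0, u = u, v = v, E0 = e0)
    d <- sample(c(0, 3, 6, 9), 1)
    for (shape in c("box", "disc")) {
      out <- apply_energy_margin(spots, d = d, shape = shape)
      expect_equal(out$E1, em_oracle(u, v, e0, d, shape),
                   ignore_attr = TRUE)
      expect_true(all(out$E1 >= e0))
    }
    # monotone in d: larger uncertainty never lowers the margined energy
    e_small <- apply_energy_margin(spots, d = 3)$E1
    e_large <- apply_energy_margin(spots, d = 6)$E1
    expect_true(all(e_small <= e_large))
  }
})

test_that("margins are computed per beam, not across beams", {
  spots <- data.frame(beam_angle = c(0, 0, 90, 90), u = c(0, 3, 0, 3),
                      v = 0, E0 = c(100, 120, 80, 90))
  out <- apply_energy_margin(spots, d = 6)
  expect_equal(out$E1, c(120, 120, 90, 90))
})

test_that("plan_info summarizes the toy profile", {
  spots <- data.frame(beam_angle = 0, u = c(0, 3, 6, 9), v = 0,
                      E0 = c(100, 110, 105, 120))
  spots <- apply_energy_margin(spots, d = 6)
  info <- plan_info(spots)
  expect_equal(info$n_spots, 4)
  expect_equal(info$mean_E0, 108.75)
  expect_equal(info$mean_E1, 117.5)
  expect_gte(info$mean_E1, info$mean_E0)
  expect_error(plan_info(spots[0, ]), "empty")
})

test_that("DET spots stop at the distal PTV edge with upward quantization", {
  ph <- small_phantom(cavity = NULL)
  dv <- ph$volume
  mm <- assign_materials(dv)
  ptv <- ph$structures$masks$PTV
  spots <- place_det_spots(dv, mm, ptv, angle = 0, iso = c(0, 0, 0))
  expect_false(any(duplicated(spots[, c("u", "v")])))
  expect_true(all(spots$E0 == round(spots$E0)))
  central <- spots[spots$u == 0 & spots$v == 0, ]
  expect_equal(nrow(central), 1)
  # E0 brackets the distal WEPL: R(E0) reaches it, R(E0 - 1 MeV) does not
  expect_gte(range_from_energy(central$E0), central$wepl - 1e-9)
  expect_lt(range_from_energy(central$E0 - 1), central$wepl)
  # spots exist exactly for lattice rays whose PTV chord is positive
  expect_true(all(!is.na(spots$wepl)))
  expect_error(place_det_spots(dv, mm, array(FALSE, dim(dv$data)), 0),
               "empty")
})

test_that("half-arc plans carry about half the spots of a full arc", {
  ph <- small_phantom()
  dv <- ph$volume
  mm <- assign_materials(dv)
  full <- build_det_plan(dv, mm, ph$structures, make_arrangement("full_arc"))
  half <- build_det_plan(dv, mm, ph$structures,
                         make_arrangement("half_arc", 45))
  expect_lt(abs(nrow(half) / nrow(full) - 0.5), 0.1)
  expect_true(all(full$E1 >= full$E0))
  info <- plan_info(full)
  expect_gte(info$mean_E1, info$mean_E0)
  expect_equal(info$n_beams, 24)
})
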