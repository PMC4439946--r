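test_that("generated CTV volume matches the analytic sphere volume", {
  ph <- make_phantom(phantom_spec(
    body = list(radius = 40, height = 80),
    ctv = list(center = c(0, 0, 0), radius = 15),
    cavity = NULL, air_border = 6
  ))
  vox <- sum(ph$structures$masks$CTV) * prod(ph$volume$spacing)
  expect_lt(abs(vox - 4 / 3 * pi * 15^3) / (4 / 3 * pi * 15^3), 0.2)
})

test_that("default phantom has valid structures and an air-bearing PTV", {
  ph <- make_phantom()
  m <- ph$structures$masks
  expect_true(all(c("CTV", "PTV", "ring", "body") %in% names(m)))
  expect_true(all(vapply(m, any, TRUE)))
  expect_false(any(m$CTV & !m$PTV))
  expect_false(any(m$PTV & !m$body))
  expect_false(any(m$ring & m$PTV))
  # the abutting cavity carves air voxels into the PTV margin
  expect_gt(sum(m$PTV & ph$volume$data < 0.207), 0)
  # body water has relative stopping power exactly 1
  rsp <- rsp_volume(ph$volume, assign_materials(ph$volume))
  expect_equal(unique(rsp[m$CTV]), 1.0)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(
    make_phantom(phantom_spec(
      body = list(radius = 20, height = 60),
      ctv = list(center = c(15, 0, 0), radius = 10),
      cavity = NULL
    )),
    "inside the body"
  )
  expect_error(
    make_phantom(phantom_spec(
      body = list(radius = 40, height = 80),
      ctv = list(center = c(0, 0, 0), radius = 12),
      cavity = list(radius = 8, direction = c(-1, 0, 0), gap = -6)
    )),
    "overlaps"
  )
})

test_that("expand_margin matches a brute-force distance computation", {
  dims <- c(13, 11, 9)
  spacing <- c(2, 2, 2)
  mask <- array(FALSE, dims)
  mask[7, 6, 5] <- TRUE
  out <- expand_margin(mask, 5, spacing)
  # exhaustive check: voxel center distance to the seed voxel center
  idx <- which(array(TRUE, dims))
  ctr <- detem:::voxel_centers(dims, spacing, -(dims - 1) * spacing / 2, idx)
  seed <- ctr[which(mask[idx]), ]
  d <- sqrt(colSums((t(ctr) - seed)^2))
  expect_identical(as.vector(out), d <= 5)

  # anisotropic spacing respected
  out2 <- expand_margin(mask, 5, c(1, 2, 4))
  ctr2 <- detem:::voxel_centers(dims, c(1, 2, 4),
                                -(dims - 1) * c(1, 2, 4) / 2, idx)
  seed2 <- ctr2[which(mask[idx]), ]
  d2 <- sqrt(colSums((t(ctr2) - seed2)^2))
  expect_identical(as.vector(out2), d2 <= 5)
})

test_that("expand_margin is the identity at zero and monotone in margin", {
  ph <- small_phantom()
  ctv <- ph$structures$masks$CTV
  sp <- ph$volume$spacing
  expect_identical(expand_margin(ctv, 0, sp), ctv)
  prev <- ctv
  for (m in c(2, 4, 7)) {
    cur <- expand_margin(ctv, m, sp)
    expect_false(any(prev & !cur))
    prev <- cur
  }
  expect_error(expand_margin(ctv, -1, sp), "nonnegative")
  expect_error(expand_margin(array(FALSE, c(8, 8, 8)), 1, sp), "empty")
})

test_that("ring is a disjoint shell of the requested thickness", {
  bx <- water_box(c(41, 41, 41))
  dims <- dim(bx$dv$data)
  ctr <- detem:::voxel_centers(dims, bx$dv$spacing, bx$dv$origin)
  r2 <- rowSums(ctr^2)
  ptv <- array(r2 <= 12^2, dims)
  ring <- make_ring(ptv, 10, bx$dv$spacing)
  expect_false(any(ring & ptv))
  # shell volume close to the analytic (r+10)^3 - r^3 sphere shell
  shell <- 4 / 3 * pi * (22^3 - 12^3)
  expect_lt(abs(sum(ring) * 8 - shell) / shell, 0.2)
  # thickness along +x through the centroid: 10 mm = 5 voxels
  mid <- (dims + 1) / 2
  profile <- ring[, mid[2], mid[3]]
  expect_equal(sum(profile & seq_along(profile) > mid[1]), 5)
})

test_that("material assignment follows the density thresholds", {
  dens <- array(1.0, c(8, 8, 8))
  dens[1:8] <- c(0.10, 1.05, 0.207, 0.5, 0.99, 1.0, 1.2, 0.0012)
  dv <- density_volume(dens, c(2, 2, 2))
  mm <- assign_materials(dv)
  lab <- mm$materials[mm$labels]
  expect_equal(lab[1], "Air")       # 0.10
  expect_equal(lab[2], "Muscle")    # 1.05
  expect_equal(lab[3], "Adipose")   # 0.207 exactly, lower-closed interval
  expect_equal(lab[4], "Adipose")   # 0.5
  expect_equal(lab[5], "Water")     # 0.99
  expect_equal(lab[6], "Muscle")    # 1.0 exactly, lower-closed interval
  expect_equal(lab[7], "DenseBone") # 1.2
  expect_equal(lab[8], "Air")
})

test_that("material labels partition the density axis", {
  set.seed(42)
  rho <- array(runif(8 * 8 * 8, 0, 2.5), c(8, 8, 8))
  mm <- assign_materials(density_volume(rho, c(2, 2, 2)))
  # brute-force per-voxel threshold check
  expected <- ifelse(rho < 0.207, 1L,
              ifelse(rho < 0.979, 2L,
              ifelse(rho < 1.0, 3L,
              ifelse(rho < 1.109, 4L, 5L))))
  expect_identical(as.vector(mm$labels), as.vector(expected))
})
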