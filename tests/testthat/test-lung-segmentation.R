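make_two_lung_volume <- function() {
  dm <- c(12, 40, 60)
  g <- pqct:::coord_grids(dm)
  e1 <- pqct:::ellipsoid_bits(g, c(6.5, 20.5, 15), c(4, 12, 8))
  e2 <- pqct:::ellipsoid_bits(g, c(6.5, 20.5, 45), c(4, 12, 8))
  vox <- array(0, dim = dm)           # body everywhere
  vox[e1 | e2] <- -850
  list(volume = ct_volume(vox, c(1.25, 0.7, 0.7)), e1 = e1, e2 = e2)
}

test_that("criterion derives window extremes and rejects degenerate windows", {
  dm <- c(3, 60, 60)
  vox <- array(-850, dim = dm)
  vox[2, 10, 10] <- -1000
  vox[2, 30, 30] <- 50
  vol <- ct_volume(vox, c(1.25, 0.7, 0.7))
  seed <- seed_point(vol, 2, 25, 25)
  crit <- derive_criterion(vol, seed)   # 40x40 window spans both extremes
  expect_equal(crit$ct_min, -1000)
  expect_equal(crit$ct_max, 50)
  expect_equal(crit$threshold_hu, 0.3 * 1050)

  # clipped at the corner: window sees only the constant corner region
  vox2 <- array(-850, dim = dm)
  vox2[1, 1:10, 1:10] <- -900
  vol2 <- ct_volume(vox2, c(1.25, 0.7, 0.7))
  crit2 <- derive_criterion(vol2, seed_point(vol2, 1, 2, 2))
  expect_equal(crit2$ct_min, -900)
  expect_equal(crit2$ct_max, -850)

  const <- ct_volume(array(-850, dm), c(1.25, 0.7, 0.7))
  expect_error(derive_criterion(const, seed_point(const, 2, 30, 30)),
               "degenerate")
  expect_error(seed_point(vol, 2, 30, 30), "aerated")  # +50 HU voxel
})

test_that("region growing recovers a uniform ellipsoid exactly", {
  tw <- make_two_lung_volume()
  seed <- seed_point(tw$volume, 6, 20, 15)
  crit <- derive_criterion(tw$volume, seed)  # range 850 -> threshold 255
  mask <- region_grow(tw$volume, seed, crit)
  expect_identical(mask$bits, tw$e1)   # body differs by 850 > threshold
  expect_identical(mask$role, "lung")

  # zero threshold limit: only voxels equal to the seed value, connected
  crit0 <- crit
  crit0$threshold_hu <- 0
  m0 <- region_grow(tw$volume, seed, crit0)
  expect_identical(m0$bits, tw$e1)     # ellipsoid is constant-valued

  # one seed yields only the seeded lung; the union covers both
  expect_equal(sum(mask$bits & tw$e2), 0)
  both <- segment_lungs(tw$volume,
                        list(seed, seed_point(tw$volume, 6, 20, 45)))
  expect_identical(both$bits, tw$e1 | tw$e2)
  dup <- segment_lungs(tw$volume, list(seed, seed))
  expect_identical(dup$bits, segment_lungs(tw$volume, seed)$bits)
  expect_error(segment_lungs(tw$volume, list()), "seed")
})

test_that("mask grows monotonically with the criterion coefficient", {
  ph <- default_phantom()
  seed <- auto_seed_points(ph$smoothed)[[1]]
  prev <- NULL
  for (coef in c(0.1, 0.2, 0.3, 0.45)) {
    crit <- derive_criterion(ph$smoothed, seed, coefficient = coef)
    cur <- region_grow(ph$smoothed, seed, crit)$bits
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("hole filling restores injured tissue and vessels inside the lung", {
  ph <- default_phantom()
  seeds <- auto_seed_points(ph$smoothed)
  lung <- segment_lungs(ph$smoothed, seeds)
  expect_gt(dice(lung, ph$truth$lung), 0.99)
  # without filling, the dense injured core is left out of the mask
  open <- segment_lungs(ph$smoothed, seeds, fill_holes = FALSE)
  expect_lt(sum(open$bits), sum(lung$bits))
  expect_gt(sum(lung$bits & ph$truth$injured$bits),
            0.95 * sum(ph$truth$injured$bits))
})

test_that("a leaking grow is flagged", {
  vox <- array(-850, c(4, 10, 10))
  vox[1, 1, 1] <- -849  # near-constant volume: everything joins the region
  vol <- ct_volume(vox, c(1, 1, 1))
  seed <- seed_point(vol, 2, 5, 5)
  crit <- structure(list(ct_max = 0, ct_min = -1000, coefficient = 0.3,
                         window_edge = 40, threshold_hu = 300),
                    class = "pq_grow_criterion")
  expect_warning(m <- region_grow(vol, seed, crit), "leak")
  expect_true(attr(m, "leak_flag"))
})
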