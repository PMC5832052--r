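# plain reference labelling by repeated seed fill (oracle for component
# counting; intentionally naive)
reference_component_sizes <- function(bits) {
  sizes <- integer()
  left <- bits
  while (any(left)) {
    seedv <- which(left)[1]
    comp <- pqct:::flood_from(left, arrayInd(seedv, dim(left))[1, ])
    sizes <- c(sizes, sum(comp))
    left <- left & !comp
  }
  sort(sizes)
}

test_that("small-region removal matches brute-force component filtering", {
  dm <- c(10, 20, 20)
  set.seed(17)
  bits <- array(runif(prod(dm)) < 0.12, dm)
  m <- binary_mask(bits, "injured_candidate", c(1, 1, 1))
  expect_identical(remove_small_regions(m, 0)$bits, bits)   # identity

  out <- remove_small_regions(m, min_voxels = 5)
  expect_identical(out$role, "injured_final")
  ref <- reference_component_sizes(bits)
  kept <- reference_component_sizes(out$bits)
  expect_identical(kept, ref[ref >= 5])

  blob <- array(FALSE, dm)
  blob[5, 10, 10:14] <- TRUE   # a single 5-voxel component
  mb <- binary_mask(blob, "injured_candidate", c(1, 1, 1))
  expect_equal(sum(remove_small_regions(mb, 10)$bits), 0)
  expect_equal(sum(remove_small_regions(mb, 5)$bits), 5)
})

test_that("mask volumes follow the voxel-count arithmetic", {
  dm <- c(10, 10, 10)
  bits <- array(TRUE, dm)
  expect_equal(mask_volume_ml(binary_mask(bits, "lung", c(1, 1, 1))), 1)
  expect_equal(
    mask_volume_ml(binary_mask(bits, "lung", c(1.25, 0.7, 0.7))),
    1000 * 1.25 * 0.7 * 0.7 / 1000)
  empty <- binary_mask(array(FALSE, dm), "lung", c(1, 1, 1))
  expect_equal(mask_volume_ml(empty), 0)
})

test_that("injured fractions are exact count ratios on phantoms", {
  ph <- default_phantom()
  vr <- injured_fraction(ph$truth$injured, ph$truth$lung)
  expect_equal(vr$injured_fraction,
               sum(ph$truth$injured$bits) / sum(ph$truth$lung$bits))
  expect_equal(vr$injured_ml / vr$whole_lung_ml, vr$injured_fraction)

  full <- injured_fraction(ph$truth$lung, ph$truth$lung)
  expect_equal(full$injured_fraction, 1)
  empty <- binary_mask(array(FALSE, dim(ph$volume$voxels)), "injured_final",
                       ph$volume$spacing_mm)
  expect_equal(injured_fraction(empty, ph$truth$lung)$injured_fraction, 0)
  expect_error(injured_fraction(ph$truth$injured, empty), "empty lung")
})

test_that("the prognostic ratio follows the worked arithmetic", {
  r <- fraction_ratio(0.354, 0.781)
  expect_equal(round(r$ratio, 2), 0.45)
  expect_equal(fraction_ratio(0.5, 0.5)$ratio, 1)
  expect_equal(fraction_ratio(0.2, 0.4)$ratio, 0.5)
  expect_error(fraction_ratio(0.2, 0), "undefined")
  # enlarging the follow-up injury never increases the ratio
  f2 <- seq(0.3, 0.9, 0.1)
  ratios <- vapply(f2, function(f) fraction_ratio(0.25, f)$ratio, 0)
  expect_true(all(diff(ratios) <= 0))
})

test_that("surface meshes enclose the voxel volume and re-voxelise exactly", {
  dm <- c(25, 25, 25)
  g <- pqct:::coord_grids(dm)
  sphere <- ((g$z - 13)^2 + (g$y - 13)^2 + (g$x - 13)^2) <= 100  # r = 10 mm
  m <- binary_mask(sphere, "injured_final", c(1, 1, 1))
  stl <- withr::local_tempfile(fileext = ".stl")
  mesh <- export_mesh(m, stl)
  expect_true(file.exists(stl))
  # closed orientable surface: every edge is shared by exactly two faces
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(ekey) == 2))
  # enclosed volume: exact vs voxel count, within 5% of the smooth sphere
  expect_equal(mesh$volume_mm3, sum(sphere))
  expect_lt(abs(mesh$volume_mm3 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
  expect_identical(voxelize_mesh(mesh, dm, c(1, 1, 1)), sphere)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  ply <- withr::local_tempfile(fileext = ".ply")
  mesh1 <- export_mesh(binary_mask(single, "lung", c(1, 1, 1)), ply)
  expect_equal(nrow(mesh1$faces), 12)
  expect_equal(mesh1$volume_mm3, 1)
  empty <- binary_mask(array(FALSE, c(3, 3, 3)), "lung", c(1, 1, 1))
  expect_error(export_mesh(empty, stl), "empty")
})
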