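test_that("rendering is deterministic and truth fractions are exact", {
  spec <- phantom_spec(seed = 3)
  a <- render_phantom(spec)
  b <- render_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$lung$bits, b$truth$lung$bits)
  expect_equal(a$fraction,
               sum(a$truth$injured$bits) / sum(a$truth$lung$bits))
  # different seed: different noise, identical geometry
  c2 <- render_phantom(phantom_spec(seed = 4))
  expect_false(identical(a$volume$voxels, c2$volume$voxels))
  expect_identical(a$truth$lung$bits, c2$truth$lung$bits)
  expect_identical(a$truth$injured$bits, c2$truth$injured$bits)
})

test_that("phantom tissue levels sit near their nominal HU", {
  ph <- render_phantom(phantom_spec(seed = 3))
  vox <- ph$volume$voxels
  lungonly <- ph$truth$lung$bits & !ph$truth$injured$bits &
    !ph$truth$vessel$bits & !pqct:::dilate3(ph$truth$injured$bits, 26L)
  interior <- pqct:::erode3(lungonly, 6L)   # away from partial-volume rims
  expect_lt(abs(mean(vox[interior]) + 850), 10)
  expect_lt(abs(mean(vox[ph$truth$injured$bits]) + 450), 25)
  expect_equal(unique(as.vector(vox[ph$truth$vessel$bits])), 50)
  expect_equal(min(vox), -1000)
})

test_that("a no-injury spec yields an empty injured truth", {
  spec <- phantom_spec(seed = 3, injured_blobs = list())
  ph <- render_phantom(spec)
  expect_equal(sum(ph$truth$injured$bits), 0)
  expect_equal(ph$fraction, 0)
})

test_that("scan pairs grow to target fractions with nested truths", {
  spec <- phantom_spec(seed = 9)
  pair <- render_scan_pair(spec, target_fractions = c(0.20, 0.50))
  expect_gte(pair$scan1$fraction, 0.20)
  expect_lt(pair$scan1$fraction, 0.21)
  expect_gte(pair$scan2$fraction, 0.50)
  expect_lt(pair$scan2$fraction, 0.51)
  expect_equal(pair$truth_ratio, pair$scan1$fraction / pair$scan2$fraction)
  # follow-up injury contains the admission injury
  expect_true(all(pair$scan2$truth$injured$bits[
    pair$scan1$truth$injured$bits]))
  # identical injury at growth factor one
  same <- render_scan_pair(spec, growth_factor = 1)
  expect_identical(same$scan1$truth$injured$bits,
                   same$scan2$truth$injured$bits)
  expect_equal(same$truth_ratio, 1)
  # unreachable targets fail loudly
  expect_error(render_scan_pair(spec, target_fractions = c(0.2, 0.95)),
               "exceeds")
})

test_that("scan pairs with different seeds share truth but not noise", {
  p1 <- render_scan_pair(phantom_spec(seed = 1),
                         target_fractions = c(0.1, 0.3))
  p2 <- render_scan_pair(phantom_spec(seed = 2),
                         target_fractions = c(0.1, 0.3))
  expect_identical(p1$scan1$truth$injured$bits, p2$scan1$truth$injured$bits)
  expect_false(identical(p1$scan1$volume$voxels, p2$scan1$volume$voxels))
})

test_that("synthetic cohorts are deterministic with faithful moments", {
  a <- sample_cohort(seed = 8)
  b <- sample_cohort(seed = 8)
  expect_identical(a, b)
  expect_equal(nrow(a), 58)
  expect_equal(as.vector(table(a$outcome)), c(21, 37))
  expect_true(all(a$ratio >= 0))
  big <- sample_cohort(n_survivor = 10000, n_nonsurvivor = 10000, seed = 8)
  # sample means within 3 standard errors of the generating means
  expect_lt(abs(mean(big$ratio[big$outcome == "survivor"]) - 0.73),
            3 * 0.17 / sqrt(10000) + 0.01)
  expect_lt(abs(mean(big$ratio[big$outcome == "nonsurvivor"]) - 0.40),
            3 * 0.14 / sqrt(10000) + 0.01)
  expect_error(sample_cohort(n_survivor = 0), "positive")
  bad <- tibble::tibble(parameter = "x", mean_survivor = 1, sd_survivor = 0,
                        mean_nonsurvivor = 1, sd_nonsurvivor = 1,
                        lower = -Inf, upper = Inf)
  expect_error(sample_cohort(param_specs = bad), "sd")
})

test_that("phantoms render quickly at the default grid", {
  t0 <- Sys.time()
  render_phantom(phantom_spec(seed = 99))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
})
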