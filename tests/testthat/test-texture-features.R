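full_window <- function(values) list(values = values,
                                     n_valid = length(values),
                                     center = c(2L, 4L, 4L))

test_that("window means use the valid-pixel divisor", {
  expect_equal(roi_mean(full_window(rep(-850, 49))), -850)
  expect_equal(roi_mean(full_window(c(rep(-1000, 48), -20))), -980)
  expect_equal(roi_mean(full_window(rep(-700, 30))), -700)  # boundary window
  expect_error(roi_mean(list(values = numeric(), n_valid = 0)), "empty")
})

test_that("slice correlation flags single-slice structures", {
  expect_equal(slice_correlation(-700, -700, -700), 0)
  # isolated bright slice: both differences +100 -> strongly positive
  expect_equal(slice_correlation(-800, -700, -800), 10000)
  # monotone ramp: differences of opposite sign -> negative
  expect_equal(slice_correlation(-800, -700, -600), -10000)
  # sign flips under neighbour swap only when the factors differ
  expect_equal(slice_correlation(-800, -700, -600),
               slice_correlation(-600, -700, -800))
  expect_equal(slice_correlation(-650, -700, -600, method = "quotient"),
               (-700 + 650) / (-700 + 600))
})

test_that("air fraction counts sub-threshold pixels", {
  expect_equal(air_fraction(full_window(rep(-1000, 49))), 1)
  expect_equal(air_fraction(full_window(rep(-300, 49))), 0)
  expect_equal(air_fraction(full_window(c(rep(-900, 10), rep(-500, 39)))),
               10 / 49)
  # permutation invariance and monotonicity in the threshold
  set.seed(9)
  v <- runif(49, -1000, 0)
  w1 <- full_window(v)
  w2 <- full_window(sample(v))
  expect_equal(air_fraction(w1), air_fraction(w2))
  fr <- sapply(c(-900, -825, -700, -500), function(t) air_fraction(w1, t))
  expect_true(all(diff(fr) >= 0))
})

test_that("vectorised features equal the direct-formula oracle", {
  rf <- random_feature_volume(seed = 42)
  tab <- extract_feature_table(rf$volume, rf$lung)
  set.seed(10)
  pick <- tab[sample(nrow(tab), 300), ]
  for (k in seq_len(nrow(pick))) {
    row <- pick[k, ]
    o <- oracle_features(rf$volume$voxels, rf$lung$bits,
                         c(row$slice, row$row, row$col))
    for (f in c("center_hu", "mean", "sd", "max", "min", "skewness",
                "kurtosis", "rco")) {
      expect_equal(row[[f]], o[[f]], tolerance = 1e-9,
                   label = sprintf("%s at (%d,%d,%d)", f, row$slice,
                                   row$row, row$col))
    }
    expect_identical(row$air_fraction, o$air_fraction)
  }
})

test_that("single-pixel extraction matches the table and handles boundaries", {
  ph <- default_phantom()
  tab <- extract_feature_table(ph$smoothed, ph$truth$lung)
  set.seed(11)
  pick <- tab[sample(nrow(tab), 25), ]
  for (k in seq_len(nrow(pick))) {
    row <- pick[k, ]
    one <- extract_features(ph$smoothed, ph$truth$lung,
                            c(row$slice, row$row, row$col))
    expect_equal(as.numeric(one[1, pqct:::FEATURE_NAMES]),
                 as.numeric(row[1, pqct:::FEATURE_NAMES]),
                 tolerance = 1e-8)
  }
  # windows at the lung edge exclude out-of-lung pixels
  edge_ix <- which(ph$truth$lung$bits &
                     !pqct:::erode3(ph$truth$lung$bits, 26L))[1]
  ctr <- arrayInd(edge_ix, dim(ph$truth$lung$bits))[1, ]
  w <- roi_window(ph$smoothed, ph$truth$lung, ctr)
  expect_lt(w$n_valid, 49)
  expect_gte(w$n_valid, 1)
  expect_error(roi_window(ph$smoothed, ph$truth$lung, c(1, 1, 1)),
               "outside the lung")
})

test_that("constant regions give degenerate statistics by convention", {
  vox <- array(-850, c(3, 20, 20))
  vol <- ct_volume(vox, c(1.25, 0.7, 0.7))
  lung <- binary_mask(array(TRUE, dim(vox)), "lung", vol$spacing_mm)
  fv <- extract_features(vol, lung, c(2, 10, 10))
  expect_equal(fv$sd, 0)
  expect_equal(fv$skewness, 0)
  expect_equal(fv$kurtosis, 0)
  expect_equal(fv$mean, -850)
  expect_equal(fv$max, fv$min)
  expect_equal(fv$rco, 0)
  expect_false(fv$rco_one_sided)
  # first slice uses the one-sided convention and is flagged
  fv1 <- extract_features(vol, lung, c(1, 10, 10))
  expect_true(fv1$rco_one_sided)
})

test_that("labelled datasets follow the truth mask and need both classes", {
  ph <- default_phantom()
  ds <- training_dataset()
  expect_setequal(levels(ds$label), c("noninjured", "injured"))
  expect_equal(as.vector(table(ds$label)), c(1000, 1000))
  lab_truth <- ph$truth$injured$bits[cbind(ds$slice, ds$row, ds$col)]
  expect_identical(ds$label == "injured", lab_truth)

  out <- binary_mask(!ph$truth$lung$bits, "injured_final",
                     ph$volume$spacing_mm)
  expect_error(build_dataset(ph$smoothed, ph$truth$lung, out),
               "outside the lung")
  empty <- binary_mask(array(FALSE, dim(ph$volume$voxels)), "injured_final",
                       ph$volume$spacing_mm)
  expect_warning(build_dataset(ph$smoothed, ph$truth$lung, empty,
                               n_per_class = 5, seed = 1),
                 "single-class")
})
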