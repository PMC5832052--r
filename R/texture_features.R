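#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

FEATURE_NAMES <- c("center_hu", "mean", "sd", "max", "min",
                   "skewness", "kurtosis", "rco", "air_fraction")

#' Extract the 7x7 texture window at a pixel
#'
#' Collects the HU values of the 7 × 7 in-plane window centred at a pixel,
#' intersected with the lung mask: window positions outside the lung (or
#' outside the image) are ignored, so boundary windows carry fewer than 49
#' values and every statistic divides by the number of valid pixels.
#'
#' @param volume A [ct_volume()].
#' @param lung A [binary_mask()] restricting the window to lung tissue.
#' @param center Length-3 integer `(slice, row, col)` of the window centre;
#'   must lie inside the lung mask.
#' @param edge Window edge in pixels (default 7, i.e. up to 49 values).
#' @return A list with `values` (HU), `n_valid`, and `center`.
#' @export
roi_window <- function(volume, lung, center, edge = 7) {
  stopifnot(inherits(volume, "ct_volume"))
  bits <- mask_bits(lung)
  dm <- dim(volume$voxels)
  s <- center[1]; r <- center[2]; cc <- center[3]
  if (any(center < 1) || s > dm[1] || r > dm[2] || cc > dm[3]) {
    stop("window centre outside the volume", call. = FALSE)
  }
  if (!bits[s, r, cc]) stop("window centre outside the lung mask",
                            call. = FALSE)
  window_values(volume, bits, center, edge)
}

# window collection without the centre-in-lung requirement (used for the
# slice-neighbour means of rco, whose co-located centre may fall outside lung)
window_values <- function(volume, bits, center, edge) {
  dm <- dim(volume$voxels)
  s <- center[1]; r <- center[2]; cc <- center[3]
  h <- (edge - 1) / 2
  rows <- max(1, r - h):min(dm[2], r + h)
  cols <- max(1, cc - h):min(dm[3], cc + h)
  vals <- volume$voxels[s, rows, cols]
  ok <- bits[s, rows, cols]
  list(values = as.numeric(vals[ok]), n_valid = sum(ok),
       center = as.integer(center))
}

#' Mean CT value of a texture window
#'
#' Arithmetic mean over the window's valid (in-lung) pixels; the divisor is
#' the valid-pixel count — 49 for a full interior window, fewer at the lung
#' boundary where external area is ignored.
#'
#' @param window A window from [roi_window()].
#' @return Mean HU.
#' @export
roi_mean <- function(window) {
  if (window$n_valid < 1) stop("empty window", call. = FALSE)
  sum(window$values) / window$n_valid
}

#' 3-D mean CT value correlation across adjacent slices
#'
#' Combines the co-located window means on slices `n - 1`, `n`, `n + 1` into
#' `rco = (mean_cur - mean_prev) * (mean_cur - mean_next)` (units HU^2).
#' A structure present on a single slice only — the signature of the partial
#' volume effect at lung boundaries — makes both differences large with the
#' same sign, giving a large positive product, whereas tissue continuing
#' across slices (true injury) gives a small or negative value. The published
#' definition's typography admits a quotient reading, available via
#' `method = "quotient"` (undefined when the lower difference is zero).
#'
#' @param mean_prev,mean_cur,mean_next Window means (HU) on slices `n - 1`,
#'   `n`, `n + 1`.
#' @param method `"product"` (default) or `"quotient"`.
#' @return `rco` (HU^2 for the product form).
#' @export
slice_correlation <- function(mean_prev, mean_cur, mean_next,
                              method = c("product", "quotient")) {
  method <- match.arg(method)
  a <- mean_cur - mean_prev
  b <- mean_cur - mean_next
  if (method == "product") a * b else a / b
}

#' Air-density area fraction of a texture window
#'
#' Fraction of window pixels with CT value below the air-density threshold
#' (−825 HU): `count(values < threshold) / n_valid` (divisor 49 for full
#' windows). Near 1 in well-aerated parenchyma, near 0 in ground-glass or
#' consolidated tissue.
#'
#' @inheritParams roi_mean
#' @param threshold HU cutoff (default −825).
#' @return Fraction in `[0, 1]`.
#' @export
air_fraction <- function(window, threshold = -825) {
  if (window$n_valid < 1) stop("empty window", call. = FALSE)
  sum(window$values < threshold) / window$n_valid
}

# moment statistics over a value vector; skewness is Fisher (moment) skewness
# m3/m2^1.5, kurtosis is excess m4/m2^2 - 3; both 0 by convention when sd = 0.
window_moments <- function(values) {
  n <- length(values)
  m <- mean(values)
  if (n < 2) {
    return(list(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  }
  d <- values - m
  m2 <- mean(d^2)
  s <- stats::sd(values)
  if (m2 <= 1e-6) {  # degenerate (constant) window convention
    return(list(mean = m, sd = s, skewness = 0, kurtosis = 0))
  }
  list(mean = m, sd = s,
       skewness = mean(d^3) / m2^1.5,
       kurtosis = mean(d^4) / m2^2 - 3)
}

#' Texture features at one pixel
#'
#' Computes the nine-feature vector used by the injury classifier at a single
#' in-lung pixel: the centre-pixel HU, the window mean, standard deviation,
#' maximum, minimum, Fisher skewness and excess kurtosis of the 7 × 7 window
#' (lung-restricted; sd uses the n−1 denominator, skewness/kurtosis the
#' moment definitions, all three defined as 0 for constant windows), the 3-D
#' mean CT value correlation `rco` across the neighbouring slices, and the
#' air-density area fraction at −825 HU. On the first/last slice the missing
#' slice neighbour is replaced by the only available one (one-sided `rco`,
#' flagged in the output).
#'
#' @inheritParams roi_window
#' @param air_threshold HU cutoff for the air-density fraction.
#' @param rco_method See [slice_correlation()].
#' @return A one-row [tibble::tibble()] with `slice`, `row`, `col`, the nine
#'   features, and `rco_one_sided`.
#' @export
extract_features <- function(volume, lung, center, edge = 7,
                             air_threshold = -825,
                             rco_method = c("product", "quotient")) {
  rco_method <- match.arg(rco_method)
  bits <- mask_bits(lung)
  nz <- dim(volume$voxels)[1]
  w <- roi_window(volume, lung, center, edge = edge)
  mom <- window_moments(w$values)
  s <- center[1]
  sl_prev <- if (s > 1) s - 1L else s + 1L
  sl_next <- if (s < nz) s + 1L else s - 1L
  nb_mean <- function(sl) {
    wn <- window_values(volume, bits, c(sl, center[2], center[3]), edge)
    # no lung pixels in the neighbour window: contribute a zero difference
    if (wn$n_valid == 0) mom$mean else roi_mean(wn)
  }
  rco <- slice_correlation(nb_mean(sl_prev), mom$mean, nb_mean(sl_next),
                           method = rco_method)
  tibble(
    slice = center[1], row = center[2], col = center[3],
    center_hu = volume$voxels[center[1], center[2], center[3]],
    mean = mom$mean, sd = mom$sd, max = max(w$values), min = min(w$values),
    skewness = mom$skewness, kurtosis = mom$kurtosis, rco = rco,
    air_fraction = air_fraction(w, threshold = air_threshold),
    rco_one_sided = (s == 1L || s == nz)
  )
}

#' Texture features for every in-lung pixel
#'
#' Vectorised evaluation of [extract_features()] over the whole lung mask via
#' shifted-array accumulation of windowed power sums; identical definitions
#' (the equivalence is exercised by the test suite against the direct
#' per-pixel formulas). Power sums are accumulated on values centred by the
#' in-lung mean HU, which is algebraically neutral for every moment and keeps
#' the higher-order sums well conditioned.
#'
#' @inheritParams extract_features
#' @return A tibble with one row per in-lung pixel: coordinates, the nine
#'   features, and `rco_one_sided`.
#' @export
extract_feature_table <- function(volume, lung, edge = 7,
                                  air_threshold = -825,
                                  rco_method = c("product", "quotient")) {
  rco_method <- match.arg(rco_method)
  stopifnot(inherits(volume, "ct_volume"))
  bits <- mask_bits(lung)
  dm <- dim(volume$voxels)
  stopifnot(identical(dim(bits), dm))
  if (!any(bits)) stop("empty lung mask", call. = FALSE)
  h <- (edge - 1) / 2
  c0 <- mean(volume$voxels[bits])
  v <- (volume$voxels - c0) * bits
  mnum <- bits * 1.0
  air <- (volume$voxels < air_threshold & bits) * 1.0

  S1 <- S2 <- S3 <- S4 <- N <- A <- array(0, dim = dm)
  MX <- array(-Inf, dim = dm)
  MN <- array(Inf, dim = dm)
  vmax <- ifelse(bits, v, -Inf)
  vmin <- ifelse(bits, v, Inf)
  for (dy in -h:h) for (dx in -h:h) {
    d <- c(0L, dy, dx)
    sv <- shift3(v, d, pad = "constant", fill = 0)
    sm <- shift3(mnum, d, pad = "constant", fill = 0)
    S1 <- S1 + sv
    S2 <- S2 + sv * sv
    S3 <- S3 + sv * sv * sv
    S4 <- S4 + (sv * sv) * (sv * sv)
    N <- N + sm
    A <- A + shift3(air, d, pad = "constant", fill = 0)
    MX <- pmax(MX, shift3(vmax, d, pad = "constant", fill = -Inf))
    MN <- pmin(MN, shift3(vmin, d, pad = "constant", fill = Inf))
  }

  mu <- S1 / N                       # centred window mean
  m2 <- S2 / N - mu^2
  m3 <- S3 / N - 3 * mu * S2 / N + 2 * mu^3
  m4 <- S4 / N - 4 * mu * S3 / N + 6 * mu^2 * S2 / N - 3 * mu^4
  m2 <- pmax(m2, 0)
  sdv <- sqrt(pmax(N / pmax(N - 1, 1), 0) * m2) * (N > 1)
  skew <- ifelse(m2 > 1e-6, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 1e-6, m4 / m2^2 - 3, 0)

  # slice-neighbour window means for rco, one-sided at the volume ends
  nz <- dm[1]
  prev_ix <- c(if (nz > 1) 2L else 1L, seq_len(nz - 1L))
  next_ix <- c(seq_len(nz)[-1], if (nz > 1) nz - 1L else 1L)
  mu_prev <- mu[prev_ix, , , drop = FALSE]
  mu_next <- mu[next_ix, , , drop = FALSE]
  # neighbour windows with no lung pixels contribute a zero difference
  mu_prev[!is.finite(mu_prev)] <- mu[!is.finite(mu_prev)]
  mu_next[!is.finite(mu_next)] <- mu[!is.finite(mu_next)]
  dprev <- mu - mu_prev
  dnext <- mu - mu_next
  rco <- if (rco_method == "product") dprev * dnext else dprev / dnext

  idx <- which(bits)
  ai <- arrayInd(idx, dm)
  tibble(
    slice = ai[, 1], row = ai[, 2], col = ai[, 3],
    center_hu = volume$voxels[idx],
    mean = mu[idx] + c0,
    sd = sdv[idx],
    max = MX[idx] + c0,
    min = MN[idx] + c0,
    skewness = skew[idx],
    kurtosis = kurt[idx],
    rco = rco[idx],
    air_fraction = A[idx] / N[idx],
    rco_one_sided = ai[, 1] == 1L | ai[, 1] == nz
  )
}

#' Build a labelled feature dataset from truth regions
#'
#' Pairs per-pixel feature vectors with injured/noninjured labels taken from a
#' reference region mask (per-pixel labelling), emulating radiologist-labelled
#' training data. Optionally subsamples a fixed number of pixels per class.
#'
#' @inheritParams extract_feature_table
#' @param injured A [binary_mask()] (or logical array) of injured pixels; must
#'   lie inside the lung mask.
#' @param n_per_class Optional subsample size per class (without replacement,
#'   capped at the class size).
#' @param seed Optional RNG seed for the subsample.
#' @return A tibble of features plus a `label` factor with levels
#'   `noninjured`, `injured`. A single-class result is flagged with a warning.
#' @export
build_dataset <- function(volume, lung, injured, n_per_class = NULL,
                          seed = NULL, edge = 7, air_threshold = -825,
                          rco_method = "product") {
  lung_bits <- mask_bits(lung)
  inj_bits <- mask_bits(injured)
  if (!any(lung_bits)) stop("empty lung mask", call. = FALSE)
  if (any(inj_bits & !lung_bits)) {
    stop("labelled injured pixels fall outside the lung mask", call. = FALSE)
  }
  feats <- extract_feature_table(volume, lung, edge = edge,
                                 air_threshold = air_threshold,
                                 rco_method = rco_method)
  lab <- inj_bits[cbind(feats$slice, feats$row, feats$col)]
  feats$label <- factor(ifelse(lab, "injured", "noninjured"),
                        levels = c("noninjured", "injured"))
  if (nlevels(droplevels(feats$label)) < 2) {
    warning("single-class dataset: both classes are needed for training",
            call. = FALSE)
  }
  if (!is.null(n_per_class)) {
    if (!is.null(seed)) set.seed(seed)
    feats <- dplyr::slice_sample(dplyr::group_by(feats, .data$label),
                                 n = n_per_class) |>
      dplyr::ungroup()
  }
  feats
}
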