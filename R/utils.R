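# Internal array helpers shared by the imaging modules. All volumes follow the
# (slice, row, col) index convention with the slice axis as the axial (z)
# direction.

# Shift a 3-D array by `d = c(dz, dy, dx)`; out-of-range source positions are
# either clamped to the edge ("edge", replicate padding) or filled with `fill`
# ("constant"). shift3(a, c(1,0,0)) places a[i+1,,] at position i.
shift3 <- function(a, d, pad = c("edge", "constant"), fill = 0) {
  pad <- match.arg(pad)
  dm <- dim(a)
  ix <- lapply(1:3, function(k) seq_len(dm[k]) + d[k])
  if (pad == "edge") {
    ix <- lapply(1:3, function(k) pmin(pmax(ix[[k]], 1L), dm[k]))
    return(a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
  }
  out <- array(fill, dim = dm)
  src <- lapply(1:3, function(k) ix[[k]][ix[[k]] >= 1L & ix[[k]] <= dm[k]])
  dst <- lapply(1:3, function(k) which(ix[[k]] >= 1L & ix[[k]] <= dm[k]))
  if (all(lengths(src) > 0)) {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]],
                                           drop = FALSE]
  }
  out
}

# Separable Gaussian smoothing with replicate-edge padding. `sigma_mm` is a
# physical scale; the per-axis kernel width adapts to the voxel spacing.
gaussian_smooth3 <- function(a, sigma_mm, spacing_mm) {
  out <- a
  for (axis in 1:3) {
    sig_vox <- sigma_mm / spacing_mm[axis]
    if (sig_vox < 1e-8) next
    r <- max(1L, ceiling(3 * sig_vox))
    w <- stats::dnorm(-r:r, sd = sig_vox)
    w <- w / sum(w)
    acc <- array(0, dim = dim(a))
    for (t in -r:r) {
      d <- c(0L, 0L, 0L)
      d[axis] <- t
      acc <- acc + w[t + r + 1L] * shift3(out, d, pad = "edge")
    }
    out <- acc
  }
  out
}

as_dim3 <- function(x) {
  dm <- dim(x)
  if (is.null(dm) || length(dm) != 3L) {
    stop("expected a 3-D array (slice, row, col)", call. = FALSE)
  }
  dm
}

# Rcpp kernel wrappers -------------------------------------------------------

label_components <- function(bits, connectivity = 26L) {
  dm <- as_dim3(bits)
  .cc_label_3d(as.logical(bits), as.integer(dm), as.integer(connectivity))
}

flood_from <- function(bits, seed_idx, connectivity = 26L) {
  dm <- as_dim3(bits)
  seed0 <- (seed_idx[1] - 1L) +
    dm[1] * ((seed_idx[2] - 1L) + dm[2] * (seed_idx[3] - 1L))
  out <- .flood_fill_3d(as.logical(bits), as.integer(dm), as.integer(seed0),
                        as.integer(connectivity))
  array(out, dim = dm)
}

dilate3 <- function(bits, connectivity = 26L, iterations = 1L) {
  dm <- as_dim3(bits)
  out <- as.logical(bits)
  for (i in seq_len(iterations)) {
    out <- .binary_dilate_3d(out, as.integer(dm), as.integer(connectivity))
  }
  array(out, dim = dm)
}

erode3 <- function(bits, connectivity = 26L, iterations = 1L) {
  dm <- as_dim3(bits)
  out <- as.logical(bits)
  for (i in seq_len(iterations)) {
    out <- .binary_erode_3d(out, as.integer(dm), as.integer(connectivity))
  }
  array(out, dim = dm)
}

# Fill cavities: complement components (6-connected, the dual of a
# 26-connected foreground) that do not touch the volume border.
fill_holes3 <- function(bits) {
  dm <- as_dim3(bits)
  lab <- label_components(!bits, connectivity = 6L)
  border <- array(FALSE, dim = dm)
  border[c(1L, dm[1]), , ] <- TRUE
  border[, c(1L, dm[2]), ] <- TRUE
  border[, , c(1L, dm[3])] <- TRUE
  outside <- unique(lab[border & !bits])
  holes <- !bits & !(lab %in% outside)
  array(bits | holes, dim = dm)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A∩B| / (|A| + |B|)`, the standard agreement score between a segmentation
#' and a reference. Returns `NA` when both masks are empty.
#'
#' @param a,b Binary masks (see [binary_mask()]) or logical arrays of equal
#'   shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- mask_bits(a)
  b <- mask_bits(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

mask_bits <- function(x) {
  if (inherits(x, "pq_mask")) x$bits else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
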