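#' Seed point for lung region growing
#'
#' Seeds are voxel indices chosen inside aerated lung (in practice close to
#' the pleura). The HU value at the seed must be below −500, i.e. clearly
#' air-like, which guards against seeds dropped in soft tissue.
#'
#' @param volume A [ct_volume()].
#' @param slice,row,col 1-based voxel indices of the seed.
#' @return An object of class `pq_seed` with fields `slice`, `row`, `col`,
#'   `value` (HU at the seed).
#' @export
seed_point <- function(volume, slice, row, col) {
  stopifnot(inherits(volume, "ct_volume"))
  dm <- dim(volume$voxels)
  idx <- c(slice, row, col)
  if (any(idx < 1) || any(idx > dm)) {
    stop("seed point outside volume bounds", call. = FALSE)
  }
  value <- volume$voxels[slice, row, col]
  if (value >= -500) {
    stop(sprintf(
      "seed value %.0f HU is not aerated lung (must be < -500 HU)", value),
      call. = FALSE)
  }
  structure(list(slice = slice, row = row, col = col, value = value),
            class = "pq_seed")
}

#' Derive the region-growing criterion from a window around the seed
#'
#' A square window (default 40 × 40 pixels) centred at the seed on the seed's
#' slice — chosen to include both lung and surrounding non-lung tissue — gives
#' the local CT extremes `CTmax` and `CTmin`; a voxel joins the lung when
#' `|CT(p) - CT(seed)| < coefficient * (CTmax - CTmin)` (strict inequality),
#' with `coefficient = 0.3` by default. The window is clipped at the slice
#' bounds.
#'
#' @inheritParams seed_point
#' @param seed A [seed_point()].
#' @param coefficient Unitless multiplier of the window range (default 0.3).
#' @param window_edge Window edge length in pixels (default 40).
#' @return An object of class `pq_grow_criterion` with fields `ct_max`,
#'   `ct_min`, `coefficient`, `window_edge` and the derived `threshold_hu`.
#' @export
derive_criterion <- function(volume, seed, coefficient = 0.3,
                             window_edge = 40) {
  stopifnot(inherits(volume, "ct_volume"), inherits(seed, "pq_seed"))
  if (coefficient <= 0 || coefficient >= 1) {
    stop("coefficient must lie in (0, 1)", call. = FALSE)
  }
  dm <- dim(volume$voxels)
  h <- floor(window_edge / 2)
  rows <- max(1, seed$row - h):min(dm[2], seed$row + h - 1 + window_edge %% 2)
  cols <- max(1, seed$col - h):min(dm[3], seed$col + h - 1 + window_edge %% 2)
  win <- volume$voxels[seed$slice, rows, cols]
  ct_max <- max(win)
  ct_min <- min(win)
  if (ct_max == ct_min) {
    stop("degenerate criterion window: all values identical", call. = FALSE)
  }
  structure(
    list(ct_max = ct_max, ct_min = ct_min, coefficient = coefficient,
         window_edge = window_edge,
         threshold_hu = coefficient * (ct_max - ct_min)),
    class = "pq_grow_criterion"
  )
}

#' Grow a lung mask from a seed
#'
#' Returns the connected component, containing the seed, of voxels `p` with
#' `|CT(p) - CT(seed)| < coefficient * (CTmax - CTmin)`. Growth is volumetric
#' (26-connected by default) even though the criterion window lives on the
#' seed's slice, because volumes are the analysis target. A mask covering more
#' than 90% of the volume is a suspected leak and is flagged with a warning
#' (and a `leak_flag` attribute).
#'
#' @inheritParams derive_criterion
#' @param criterion A `pq_grow_criterion`, usually from [derive_criterion()].
#' @param connectivity 26 (default) or 6.
#' @return A [binary_mask()] with role `"lung"`.
#' @export
region_grow <- function(volume, seed, criterion, connectivity = 26) {
  stopifnot(inherits(volume, "ct_volume"), inherits(seed, "pq_seed"),
            inherits(criterion, "pq_grow_criterion"))
  # strict inequality, except that exact seed-value matches always qualify
  # (the threshold -> 0 limit then selects the seed's iso-value component)
  d <- volume$voxels - seed$value
  eligible <- abs(d) < criterion$threshold_hu | d == 0
  bits <- flood_from(eligible, c(seed$slice, seed$row, seed$col),
                     connectivity = connectivity)
  leak <- mean(bits) > 0.9
  if (leak) {
    warning("region growing covered >90% of the volume: suspected leak",
            call. = FALSE)
  }
  m <- binary_mask(bits, role = "lung", spacing_mm = volume$spacing_mm,
                   source_scan_id = volume$scan_id)
  attr(m, "leak_flag") <- leak
  m
}

#' Segment both lungs from one or more seeds
#'
#' Unions the per-seed region growths (one seed per lung for disconnected
#' lungs; duplicate seeds are idempotent). An optional cavity-filling
#' post-step completes the lung extent: the growing criterion is derived from
#' aerated parenchyma, so dense injured tissue (ground-glass/consolidation)
#' and intrapulmonary vessels fail it and appear as cavities in the grown
#' mask; filling them is what makes the mask the *whole* lung, the
#' denominator of the injured volume fraction. Because vessels run from the
#' hilum to the pleura, they drill thin tunnels through the aerated shell
#' that would let the cavity "leak" to the outside; holes are therefore
#' filled on a mask dilated by `seal_radius` voxels and eroded back, which
#' plugs tunnels up to about `2 * seal_radius` voxels wide while leaving the
#' outer boundary and the mediastinal gap untouched.
#'
#' @inheritParams region_grow
#' @param seeds A list of [seed_point()]s (or a single seed).
#' @param coefficient,window_edge Criterion parameters, per
#'   [derive_criterion()]; a criterion is derived per seed from the
#'   (smoothed) input volume.
#' @param fill_holes Fill enclosed cavities of the union mask (default TRUE).
#' @param seal_radius Dilation radius (voxels) used while filling, to plug
#'   vessel-calibre tunnels (default 1; 0 fills only fully enclosed
#'   cavities).
#' @return A [binary_mask()] with role `"lung"`.
#' @export
segment_lungs <- function(volume, seeds, coefficient = 0.3, window_edge = 40,
                          connectivity = 26, fill_holes = TRUE,
                          seal_radius = 1) {
  if (inherits(seeds, "pq_seed")) seeds <- list(seeds)
  if (length(seeds) == 0) stop("at least one seed is required", call. = FALSE)
  bits <- array(FALSE, dim = dim(volume$voxels))
  for (s in seeds) {
    crit <- derive_criterion(volume, s, coefficient = coefficient,
                             window_edge = window_edge)
    bits <- bits | region_grow(volume, s, crit,
                               connectivity = connectivity)$bits
  }
  if (fill_holes) {
    if (seal_radius > 0) {
      filled <- erode3(fill_holes3(dilate3(bits, 26L, seal_radius)), 26L,
                       seal_radius)
      bits <- bits | filled
    } else {
      bits <- fill_holes3(bits)
    }
  }
  binary_mask(bits, role = "lung", spacing_mm = volume$spacing_mm,
              source_scan_id = volume$scan_id)
}

#' Automatic seed proposal
#'
#' Fallback for non-interactive runs: finds air-density connected components
#' (HU below `air_hu`) that do not touch the volume border (which excludes the
#' air surrounding the body) and proposes one interior voxel per component,
#' largest components first. Radiologist-chosen seeds remain the reference
#' workflow.
#'
#' @inheritParams seed_point
#' @param n Maximum number of seeds to return (default 2, one per lung).
#' @param air_hu HU cutoff defining aerated tissue (default −700).
#' @return A list of [seed_point()]s.
#' @export
auto_seed_points <- function(volume, n = 2, air_hu = -700) {
  stopifnot(inherits(volume, "ct_volume"))
  dm <- dim(volume$voxels)
  air <- volume$voxels < air_hu
  lab <- label_components(air, connectivity = 26L)
  border <- array(FALSE, dim = dm)
  border[c(1L, dm[1]), , ] <- TRUE
  border[, c(1L, dm[2]), ] <- TRUE
  border[, , c(1L, dm[3])] <- TRUE
  bad <- unique(lab[border & air])
  tab <- tabulate(lab[air & !(lab %in% bad)])
  keep <- order(tab, decreasing = TRUE)
  keep <- keep[tab[keep] > 0]
  keep <- utils::head(keep, n)
  lapply(keep, function(lb) {
    idx <- which(lab == lb, arr.ind = TRUE)
    ctr <- colMeans(idx)
    best <- idx[which.min(rowSums(sweep(idx, 2, ctr)^2)), ]
    seed_point(volume, best[1], best[2], best[3])
  })
}
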