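#' Specification of a digital chest phantom
#'
#' Describes a synthetic CT volume with known ground truth: a soft-tissue
#' torso (an elliptical cylinder, 0 HU) in surrounding air (−1000 HU), two
#' lung ellipsoids
#' of aerated parenchyma (−850 HU plus Gaussian noise), injured regions
#' rendered as a correlated Gaussian random field around −450 HU (a learnable
#' ground-glass-like texture — a pure offset would leave the dispersion
#' features uninformative), and bright tubular vessels (+50 HU) crossing the
#' lungs. Partial-volume slices at the lung boundaries can be emulated by
#' linear mixing along the slice axis. Rendering is deterministic given the
#' seed; geometry (and hence every truth mask) does not depend on the seed at
#' all.
#'
#' @param dim Grid dimension `(slice, row, col)`; default `c(24, 64, 64)`.
#' @param spacing_mm Voxel spacing; default `c(1.25, 0.7, 0.7)` mm, the
#'   acquisition geometry scaled to a research grid.
#' @param hu Named list of tissue HU levels (`air`, `parenchyma`, `injured`,
#'   `vessel`, `body`); must satisfy `air < parenchyma < injured < vessel`.
#' @param noise_sd Parenchymal noise SD in HU (default 20).
#' @param texture_sd Injured-texture SD in HU (default 50).
#' @param texture_corr_mm Correlation length of the injured texture (default
#'   1.8 mm).
#' @param partial_volume Mix lung-boundary voxels along the slice axis
#'   (default TRUE).
#' @param seed RNG seed (default 1).
#' @param lungs,injured_blobs,vessels Optional geometry overrides: lists of
#'   `list(center=, radii=)` ellipsoids (voxel units) for lungs/blobs and of
#'   `list(from=, to=, radius_mm=)` segments for vessels. Defaults scale with
#'   the grid.
#' @return An object of class `pq_phantom_spec`.
#' @export
phantom_spec <- function(dim = c(24, 64, 64),
                         spacing_mm = c(1.25, 0.7, 0.7),
                         hu = list(air = -1000, parenchyma = -850,
                                   injured = -450, vessel = 50, body = 0),
                         noise_sd = 20, texture_sd = 50,
                         texture_corr_mm = 1.8, partial_volume = TRUE,
                         seed = 1L, lungs = NULL, injured_blobs = NULL,
                         vessels = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 8), all(spacing_mm > 0))
  if (!(hu$air < hu$parenchyma && hu$parenchyma < hu$injured &&
        hu$injured < hu$vessel)) {
    stop("HU levels must be ordered air < parenchyma < injured < vessel",
         call. = FALSE)
  }
  if (noise_sd < 0 || texture_sd < 0) stop("noise sd must be >= 0",
                                           call. = FALSE)
  ctr <- (dim + 1) / 2
  if (is.null(lungs)) {
    radii <- c(0.38 * dim[1], 0.32 * dim[2], 0.18 * dim[3])
    lungs <- list(
      list(center = c(ctr[1], ctr[2], 0.27 * dim[3]), radii = radii),
      list(center = c(ctr[1], ctr[2], 0.73 * dim[3]), radii = radii))
  }
  if (is.null(injured_blobs)) {
    injured_blobs <- lapply(lungs, function(lg) {
      list(center = lg$center, radii = lg$radii * 0.45)
    })
  }
  if (is.null(vessels)) {
    vessels <- unlist(lapply(lungs, function(lg) {
      cz <- lg$center[1]; cy <- lg$center[2]; cx <- lg$center[3]
      ry <- lg$radii[2]; rz <- lg$radii[1]; rx <- lg$radii[3]
      list(
        list(from = c(cz, cy - ry - 2, cx), to = c(cz, cy + ry + 2, cx),
             radius_mm = 0.8),
        list(from = c(cz - 0.7 * rz, cy - 0.9 * ry, cx - 0.3 * rx),
             to = c(cz + 0.7 * rz, cy + 0.9 * ry, cx + 0.3 * rx),
             radius_mm = 0.6))
    }), recursive = FALSE)
  }
  for (lg in c(lungs, injured_blobs)) {
    if (any(lg$center < 1) || any(lg$center > dim)) {
      stop("phantom region centre outside the grid", call. = FALSE)
    }
  }
  structure(
    list(dim = dim, spacing_mm = spacing_mm, hu = hu, noise_sd = noise_sd,
         texture_sd = texture_sd, texture_corr_mm = texture_corr_mm,
         partial_volume = partial_volume, seed = as.integer(seed),
         lungs = lungs, injured_blobs = injured_blobs, vessels = vessels,
         # torso as an elliptical cylinder: the axial cross-section of a
         # chest is nearly constant over the scanned range, and a full-height
         # body guarantees soft tissue (not outside air) above and below the
         # lung apices on every slice
         body = list(center = ctr,
                     radii_yx = c(0.46 * dim[2], 0.48 * dim[3]))),
    class = "pq_phantom_spec")
}

# geometry rasterisers --------------------------------------------------------

coord_grids <- function(dim) {
  list(z = array(rep(seq_len(dim[1]), times = dim[2] * dim[3]), dim = dim),
       y = array(rep(rep(seq_len(dim[2]), each = dim[1]), times = dim[3]),
                 dim = dim),
       x = array(rep(seq_len(dim[3]), each = dim[1] * dim[2]), dim = dim))
}

ellipsoid_bits <- function(g, center, radii) {
  ((g$z - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
    ((g$x - center[3]) / radii[3])^2 <= 1
}

cylinder_bits <- function(g, from, to, radius_mm, spacing_mm) {
  p1 <- from * spacing_mm
  p2 <- to * spacing_mm
  vz <- g$z * spacing_mm[1]; vy <- g$y * spacing_mm[2]
  vx <- g$x * spacing_mm[3]
  d <- p2 - p1
  len2 <- sum(d^2)
  t <- ((vz - p1[1]) * d[1] + (vy - p1[2]) * d[2] + (vx - p1[3]) * d[3]) /
    len2
  t <- pmin(pmax(t, 0), 1)
  dist2 <- (vz - (p1[1] + t * d[1]))^2 + (vy - (p1[2] + t * d[2]))^2 +
    (vx - (p1[3] + t * d[3]))^2
  dist2 <= radius_mm^2
}

phantom_geometry <- function(spec) {
  g <- coord_grids(spec$dim)
  body <- (((g$y - spec$body$center[2]) / spec$body$radii_yx[1])^2 +
             ((g$x - spec$body$center[3]) / spec$body$radii_yx[2])^2) <= 1
  lung <- array(FALSE, dim = spec$dim)
  for (lg in spec$lungs) lung <- lung | ellipsoid_bits(g, lg$center, lg$radii)
  lung <- lung & body
  injured <- array(FALSE, dim = spec$dim)
  for (bl in spec$injured_blobs) {
    injured <- injured | ellipsoid_bits(g, bl$center, bl$radii)
  }
  injured <- injured & lung
  vessel <- array(FALSE, dim = spec$dim)
  for (vs in spec$vessels) {
    vessel <- vessel | cylinder_bits(g, vs$from, vs$to, vs$radius_mm,
                                     spec$spacing_mm)
  }
  vessel <- vessel & body
  list(body = body, lung = lung, injured = injured, vessel = vessel)
}

# correlated Gaussian random field with unit variance
grf_texture <- function(dim, corr_mm, spacing_mm) {
  w <- array(stats::rnorm(prod(dim)), dim = dim)
  if (corr_mm > 0) {
    w <- gaussian_smooth3(w, corr_mm, spacing_mm)
    w <- w / stats::sd(w)
  }
  w
}

render_volume <- function(spec, injured_bits, geo, seed, scan_id) {
  set.seed(seed)
  hu <- spec$hu
  vox <- array(hu$air, dim = spec$dim)
  vox[geo$body] <- hu$body
  n_lung <- sum(geo$lung)
  vox[geo$lung] <- hu$parenchyma +
    if (spec$noise_sd > 0) stats::rnorm(n_lung, 0, spec$noise_sd) else 0
  tex <- grf_texture(spec$dim, spec$texture_corr_mm, spec$spacing_mm)
  inj <- injured_bits & geo$lung
  vox[inj] <- hu$injured + spec$texture_sd * tex[inj]
  vox[geo$vessel] <- hu$vessel
  if (spec$partial_volume) {
    # linear mixing at axial lung boundaries: the partial-volume signature
    # the 3-D mean-CT-correlation feature is designed to catch
    lungf <- geo$lung * 1.0
    f <- 0.25 * shift3(lungf, c(1L, 0L, 0L), "edge") + 0.5 * lungf +
      0.25 * shift3(lungf, c(-1L, 0L, 0L), "edge")
    mixv <- geo$lung & f < 1 & !geo$vessel
    vox[mixv] <- f[mixv] * vox[mixv] + (1 - f[mixv]) * hu$body
  }
  ct_volume(vox, spacing_mm = spec$spacing_mm, scan_id = scan_id)
}

truth_masks <- function(spec, injured_bits, geo, scan_id) {
  mk <- function(bits, role) {
    binary_mask(bits, role = role, spacing_mm = spec$spacing_mm,
                source_scan_id = scan_id)
  }
  list(lung = mk(geo$lung, "lung"),
       injured = mk(injured_bits & geo$lung & !geo$vessel, "injured_final"),
       vessel = mk(geo$vessel & geo$lung, "vessel"))
}

#' Render a phantom CT volume with ground-truth masks
#'
#' @param spec A [phantom_spec()].
#' @param scan_id Identifier for the rendered scan.
#' @return A list with `volume` (a [ct_volume()]), `truth` (list of `lung`,
#'   `injured`, `vessel` [binary_mask()]s, exact by construction; the injured
#'   truth excludes vessel voxels, matching the pipeline's vessel-removal
#'   step), and `fraction` (the exact ground-truth injured lung volume
#'   fraction).
#' @export
render_phantom <- function(spec, scan_id = "phantom") {
  stopifnot(inherits(spec, "pq_phantom_spec"))
  geo <- phantom_geometry(spec)
  vol <- render_volume(spec, geo$injured, geo, spec$seed, scan_id)
  truth <- truth_masks(spec, geo$injured, geo, scan_id)
  list(volume = vol, truth = truth,
       fraction = sum(truth$injured$bits) / sum(truth$lung$bits))
}

#' Render a serial scan pair with growing injury
#'
#' Emulates rapid disease evolution between the admission and follow-up
#' scans: the follow-up injured region is the admission region dilated inside
#' the lung until a target ground-truth fraction is reached. Growth is
#' confined to the lung eroded by one voxel, so a shell of aerated parenchyma
#' always separates the injury from the pleura; the two scans share geometry
#' but draw independent noise.
#'
#' @param spec A [phantom_spec()].
#' @param growth_factor Ratio of follow-up to admission fraction (used when
#'   `target_fractions` is `NULL`; the admission fraction is then the blob
#'   fraction of `spec`). `1` reproduces the same injury on both scans.
#' @param target_fractions Length-2 numeric: exact target fractions
#'   `(f1, f2)` grown from the spec's initial blobs.
#' @return A list with `scan1`, `scan2` (each as in [render_phantom()]) and
#'   `truth_ratio` (= `fraction1 / fraction2`, an exact rational number).
#' @export
render_scan_pair <- function(spec, growth_factor = NULL,
                             target_fractions = NULL) {
  stopifnot(inherits(spec, "pq_phantom_spec"))
  geo <- phantom_geometry(spec)
  room <- erode3(geo$lung, 6L)
  lung_n <- sum(geo$lung)
  frac_of <- function(bits) sum(bits & geo$lung & !geo$vessel) / lung_n
  # dilate towards the target fraction; the final shell is added only
  # partially (innermost frontier voxels first, deterministic order) so the
  # realised fraction overshoots the target by at most one voxel
  grow_to <- function(bits, target) {
    repeat {
      frac <- frac_of(bits)
      if (frac >= target) return(bits)
      nxt <- dilate3(bits, 26L) & room
      newv <- which(nxt & !bits)
      if (length(newv) == 0) {
        stop(sprintf(
          "target fraction %.3f exceeds the growable lung (max %.3f)",
          target, frac), call. = FALSE)
      }
      need <- ceiling((target - frac) * lung_n - 1e-9)
      counts <- !geo$vessel[newv]
      if (sum(counts) <= need) {
        bits <- nxt
        next
      }
      ai <- arrayInd(newv, spec$dim)
      ctr <- colMeans(arrayInd(which(bits), spec$dim))
      d2 <- rowSums(sweep(ai, 2, ctr)^2)
      ord <- order(d2, newv)
      take <- which(cumsum(counts[ord]) >= need)[1]
      bits[newv[ord[seq_len(take)]]] <- TRUE
      return(bits)
    }
  }
  base <- geo$injured & room
  if (!any(base)) stop("initial injured blobs are empty", call. = FALSE)
  if (is.null(target_fractions)) {
    gf <- growth_factor %||% 1
    if (gf <= 0) stop("growth_factor must be > 0", call. = FALSE)
    f1 <- frac_of(base)
    target_fractions <- c(f1, min(gf * f1, 1))
    inj1 <- base
  } else {
    stopifnot(length(target_fractions) == 2,
              target_fractions[2] >= target_fractions[1])
    inj1 <- grow_to(base, target_fractions[1])
  }
  inj2 <- grow_to(inj1, target_fractions[2])
  make_scan <- function(inj, seed, scan_id) {
    vol <- render_volume(spec, inj, geo, seed, scan_id)
    truth <- truth_masks(spec, inj, geo, scan_id)
    list(volume = vol, truth = truth,
         fraction = sum(truth$injured$bits) / sum(truth$lung$bits))
  }
  scan1 <- make_scan(inj1, spec$seed, "scan1")
  scan2 <- make_scan(inj2, spec$seed + 1L, "scan2")
  list(scan1 = scan1, scan2 = scan2,
       truth_ratio = scan1$fraction / scan2$fraction)
}

#' Sample a synthetic cohort
#'
#' Draws independent truncated-Gaussian clinical parameters per outcome
#' group. The default generating moments are the published cohort's ratio
#' row (survivors 0.73 ± 0.17, nonsurvivors 0.40 ± 0.14) plus age and white
#' blood cell count, with group sizes 21 and 37; gender is Bernoulli with
#' the published male:female proportions (13:8 and 19:18).
#'
#' @param n_survivor,n_nonsurvivor Group sizes (both must be positive).
#' @param param_specs Data frame with columns `parameter`, `mean_survivor`,
#'   `sd_survivor`, `mean_nonsurvivor`, `sd_nonsurvivor`, `lower`, `upper`.
#' @param male_prob Length-2 male probability (survivor, nonsurvivor).
#' @param seed RNG seed.
#' @return A tibble with `patient_id`, `outcome`, `gender`, one column per
#'   parameter.
#' @export
sample_cohort <- function(n_survivor = 21, n_nonsurvivor = 37,
                          param_specs = NULL,
                          male_prob = c(13 / 21, 19 / 37), seed = 1L) {
  if (n_survivor <= 0 || n_nonsurvivor <= 0) {
    stop("both group sizes must be positive", call. = FALSE)
  }
  if (is.null(param_specs)) {
    param_specs <- tibble(
      parameter = c("ratio", "age", "wbc"),
      mean_survivor = c(0.73, 38.5, 12.74),
      sd_survivor = c(0.17, 17.0, 5.50),
      mean_nonsurvivor = c(0.40, 39.9, 20.41),
      sd_nonsurvivor = c(0.14, 16.6, 10.61),
      lower = c(0, 0, 0), upper = c(Inf, Inf, Inf))
  }
  if (any(param_specs$sd_survivor <= 0 | param_specs$sd_nonsurvivor <= 0)) {
    stop("parameter sd must be > 0", call. = FALSE)
  }
  set.seed(seed)
  rtrunc <- function(n, mean, sd, lower, upper) {
    out <- stats::rnorm(n, mean, sd)
    bad <- out < lower | out > upper
    while (any(bad)) {
      out[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- out < lower | out > upper
    }
    out
  }
  n <- n_survivor + n_nonsurvivor
  out <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    outcome = factor(rep(c("survivor", "nonsurvivor"),
                         c(n_survivor, n_nonsurvivor)),
                     levels = c("survivor", "nonsurvivor")),
    gender = ifelse(stats::runif(n) < rep(male_prob,
                                          c(n_survivor, n_nonsurvivor)),
                    "M", "F"))
  for (i in seq_len(nrow(param_specs))) {
    ps <- param_specs[i, ]
    out[[ps$parameter]] <- c(
      rtrunc(n_survivor, ps$mean_survivor, ps$sd_survivor, ps$lower,
             ps$upper),
      rtrunc(n_nonsurvivor, ps$mean_nonsurvivor, ps$sd_nonsurvivor,
             ps$lower, ps$upper))
  }
  out
}
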