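#' Hessian-based multiscale vesselness
#'
#' Frangi-type tubularity response: at each Gaussian scale the volume is
#' smoothed, the scale-normalised Hessian (second derivatives multiplied by
#' sigma^2, computed in physical mm units) is assembled, and its eigenvalues
#' `|l1| <= |l2| <= |l3|` feed the three-ratio response
#' \deqn{V = (1 - e^{-R_A^2 / 2\alpha^2})\; e^{-R_B^2 / 2\beta^2}\;
#'       (1 - e^{-S^2 / 2 c^2})}
#' with `RA = |l2|/|l3|` (plate vs tube), `RB = |l1|/sqrt(|l2 l3|)`
#' (blob rejection) and `S` the Frobenius norm (noise rejection). Bright
#' tubes on a dark background are assumed (vessels are denser than aerated
#' lung), so the response is 0 wherever `l2 > 0` or `l3 > 0`. The final map
#' is the per-voxel maximum over scales, in `[0, 1]`.
#'
#' @param volume A [ct_volume()].
#' @param scales_mm Gaussian scales in mm (default `c(1, 2, 3, 4)`, spanning
#'   typical intrapulmonary vessel radii).
#' @param alpha,beta Frangi sensitivity parameters (defaults 0.5).
#' @param c_param Structureness parameter `c`; default `NULL` uses half the maximum
#'   Hessian norm at each scale.
#' @param mask Optional [binary_mask()]/logical array restricting where the
#'   response is computed (e.g. a dilated lung mask, for speed); outside it
#'   the map is 0.
#' @return A `pq_vesselness` object with `values` (array in `[0, 1]`),
#'   `scales_mm`, and `best_scale` (array of the argmax scale).
#' @export
vesselness <- function(volume, scales_mm = c(1, 2, 3, 4), alpha = 0.5,
                       beta = 0.5, c_param = NULL, mask = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (length(scales_mm) < 1 || any(scales_mm <= 0)) {
    stop("at least one positive scale is required", call. = FALSE)
  }
  dm <- dim(volume$voxels)
  sp <- volume$spacing_mm
  if (any(dm * sp < 2 * max(scales_mm))) {
    stop("volume thinner than the largest scale support", call. = FALSE)
  }
  sel <- if (is.null(mask)) NULL else which(mask_bits(mask))
  best <- array(0, dim = dm)
  best_scale <- array(NA_real_, dim = dm)
  for (sig in scales_mm) {
    sm <- gaussian_smooth3(volume$voxels, sig, sp)
    d2 <- function(axis) {
      e <- c(0L, 0L, 0L); e[axis] <- 1L
      (shift3(sm, e, "edge") - 2 * sm + shift3(sm, -e, "edge")) / sp[axis]^2
    }
    dcross <- function(a1, a2) {
      e1 <- c(0L, 0L, 0L); e1[a1] <- 1L
      e2 <- c(0L, 0L, 0L); e2[a2] <- 1L
      (shift3(sm, e1 + e2, "edge") + shift3(sm, -e1 - e2, "edge") -
         shift3(sm, e1 - e2, "edge") - shift3(sm, e2 - e1, "edge")) /
        (4 * sp[a1] * sp[a2])
    }
    s2 <- sig^2  # gamma-normalisation across scales
    h11 <- d2(1) * s2; h22 <- d2(2) * s2; h33 <- d2(3) * s2
    h12 <- dcross(1, 2) * s2; h13 <- dcross(1, 3) * s2
    h23 <- dcross(2, 3) * s2
    ix <- sel %||% seq_along(h11)
    ev <- .hessian_eigvals(h11[ix], h22[ix], h33[ix],
                           h12[ix], h13[ix], h23[ix])
    l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cval <- c_param %||% (max(S) / 2)
    if (cval <= 0) cval <- 1
    ra <- abs(l2) / pmax(abs(l3), 1e-12)
    rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-12)
    v <- (1 - exp(-ra^2 / (2 * alpha^2))) *
      exp(-rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * cval^2)))
    v[l2 > 0 | l3 > 0 | abs(l3) < 1e-12] <- 0
    resp <- array(0, dim = dm)
    resp[ix] <- v
    upd <- resp > best
    best[upd] <- resp[upd]
    best_scale[upd] <- sig
  }
  structure(list(values = best, scales_mm = scales_mm,
                 best_scale = best_scale, spacing_mm = sp,
                 source_scan_id = volume$scan_id),
            class = "pq_vesselness")
}

#' @export
print.pq_vesselness <- function(x, ...) {
  cat(sprintf("<pq_vesselness> scales %s mm, max response %.3f\n",
              paste(x$scales_mm, collapse = "/"), max(x$values)))
  invisible(x)
}

#' Threshold a vesselness map into a vessel mask
#'
#' @param map A `pq_vesselness` from [vesselness()].
#' @param threshold Response cutoff in `[0, 1]`; the mask is
#'   `{vesselness >= threshold}` (threshold 0 keeps every voxel with a
#'   defined response, a value above 1 keeps none).
#' @return A [binary_mask()] with role `"vessel"`.
#' @export
segment_vessels <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "pq_vesselness"))
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  bits <- if (threshold == 0) map$values > 0 else map$values >= threshold
  binary_mask(bits, role = "vessel", spacing_mm = map$spacing_mm,
              source_scan_id = map$source_scan_id)
}

#' Remove vessels from the injured-candidate mask
#'
#' Set difference `candidate \ vessels`: blood vessels share CT values with
#' injured tissue and are indistinguishable by the texture features alone, so
#' the vessel segmentation is subtracted from the network's candidate mask.
#' Idempotent; the output is always a subset of the candidate and
#' `|out| = |candidate| - |candidate ∩ vessels|`.
#'
#' @param candidate A [binary_mask()] (role `"injured_candidate"`).
#' @param vessels A [binary_mask()] (role `"vessel"`) of identical shape.
#' @return A [binary_mask()] with the candidate's role, vessels removed.
#' @export
remove_vessels <- function(candidate, vessels) {
  cb <- mask_bits(candidate)
  vb <- mask_bits(vessels)
  if (!identical(dim(cb), dim(vb))) {
    stop("candidate and vessel masks differ in shape", call. = FALSE)
  }
  binary_mask(cb & !vb, role = candidate$role,
              spacing_mm = candidate$spacing_mm,
              source_scan_id = candidate$source_scan_id)
}

#' Write a vesselness map to NIfTI
#'
#' @param map A `pq_vesselness`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_vesselness <- function(map, path) {
  img <- RNifti::asNifti(aperm(map$values, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(map$spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
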