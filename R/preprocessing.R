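#' Edge-preserving anisotropic diffusion
#'
#' Perona–Malik diffusion applied slice-wise (the segmentation that follows is
#' seeded per slice), with the exponential conduction function
#' `g(d) = exp(-(d / kappa)^2)` on the 4-neighbourhood and reflective
#' boundaries. Noise in flat lung parenchyma is attenuated while strong HU
#' boundaries (lung/body, lung/vessel) conduct almost nothing and are
#' preserved.
#'
#' @param volume A [ct_volume()].
#' @param n_iter Number of iterations (default 10); 0 returns the input
#'   unchanged.
#' @param kappa Conduction threshold in HU (default 50): gradients well below
#'   `kappa` are smoothed, gradients well above it are kept.
#' @param step Explicit time step (default 0.15); must be below 0.25 for
#'   stability of the 4-neighbour scheme.
#' @return A smoothed [ct_volume()] with identical shape and spacing.
#' @examples
#' vol <- ct_volume(array(-850, c(3, 8, 8)), c(1.25, 0.7, 0.7))
#' sm <- anisotropic_diffusion(vol, n_iter = 5)
#' max(abs(sm$voxels - vol$voxels))  # constant volume is a fixed point
#' @export
anisotropic_diffusion <- function(volume, n_iter = 10, kappa = 50,
                                  step = 0.15) {
  stopifnot(inherits(volume, "ct_volume"))
  if (n_iter < 0) stop("n_iter must be >= 0", call. = FALSE)
  if (step <= 0 || step > 0.25) {
    stop("step must lie in (0, 0.25] for the 4-neighbour scheme",
         call. = FALSE)
  }
  if (!all(is.finite(volume$voxels))) {
    stop("non-finite voxel values", call. = FALSE)
  }
  if (n_iter == 0) return(volume)
  u <- volume$voxels
  offs <- list(c(0L, 1L, 0L), c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  for (it in seq_len(n_iter)) {
    flux <- 0
    for (d in offs) {
      g <- shift3(u, d, pad = "edge") - u  # reflective: edge gradient = 0
      flux <- flux + exp(-(g / kappa)^2) * g
    }
    u <- u + step * flux
  }
  out <- volume
  out$voxels <- u
  out
}
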