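#' Remove very small regions from a mask
#'
#' Deletes every connected component (26-connected by default) with fewer
#' than `min_voxels` voxels — the final post-processing step that cleans
#' isolated speckle from the injury segmentation. `min_voxels = 0` is the
#' identity.
#'
#' @param mask A [binary_mask()].
#' @param min_voxels Minimum surviving component size (default 30).
#' @param connectivity 26 (default) or 6.
#' @return A [binary_mask()]; injured-candidate input is promoted to role
#'   `"injured_final"`.
#' @export
remove_small_regions <- function(mask, min_voxels = 30, connectivity = 26) {
  stopifnot(inherits(mask, "pq_mask"), min_voxels >= 0)
  bits <- mask$bits
  if (min_voxels > 0 && any(bits)) {
    lab <- label_components(bits, connectivity = connectivity)
    sizes <- tabulate(lab[bits])
    small <- which(sizes < min_voxels)
    bits <- bits & !(lab %in% small)
    bits <- array(bits, dim = dim(mask$bits))
  }
  role <- if (mask$role %in% c("injured_candidate", "injured_final")) {
    "injured_final"
  } else {
    mask$role
  }
  binary_mask(bits, role = role, spacing_mm = mask$spacing_mm,
              source_scan_id = mask$source_scan_id)
}

#' Volume of a mask in millilitres
#'
#' Voxel counting: `count(true) * slice_spacing * row_spacing * col_spacing`
#' in mm^3, reported in ml (1 ml = 1000 mm^3). Voxel counting is exact on the
#' mask, so it is the volumetric backbone of the pipeline; surface meshes
#' ([export_mesh()]) are for visualisation only.
#'
#' @param mask A [binary_mask()] or logical array.
#' @param spacing_mm Length-3 voxel spacing; defaults to the mask's own.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask, spacing_mm = NULL) {
  bits <- mask_bits(mask)
  spacing_mm <- spacing_mm %||%
    (if (inherits(mask, "pq_mask")) mask$spacing_mm else NULL)
  if (is.null(spacing_mm)) stop("spacing_mm required", call. = FALSE)
  sum(bits) * voxel_volume_mm3(spacing_mm) / 1000
}

#' Injured lung volume fraction of one scan
#'
#' The quotient of the injured lung volume and the whole lung volume. The
#' injured mask is intersected with the lung mask first (the denominator is
#' the whole lung, injured tissue included), so the fraction lies in
#' `[0, 1]`.
#'
#' @param injured A [binary_mask()] of final injured tissue.
#' @param lung A [binary_mask()] of the whole lung; must be nonempty.
#' @param spacing_mm Voxel spacing; defaults to the lung mask's.
#' @param scan_id Scan identifier for the result row.
#' @return A one-row tibble of class `pq_volumetrics`: `scan_id`,
#'   `whole_lung_ml`, `injured_ml`, `injured_fraction`.
#' @export
injured_fraction <- function(injured, lung, spacing_mm = NULL,
                             scan_id = NULL) {
  ib <- mask_bits(injured)
  lb <- mask_bits(lung)
  stopifnot(identical(dim(ib), dim(lb)))
  if (!any(lb)) stop("empty lung mask: fraction undefined", call. = FALSE)
  spacing_mm <- spacing_mm %||%
    (if (inherits(lung, "pq_mask")) lung$spacing_mm else NULL)
  if (is.null(spacing_mm)) stop("spacing_mm required", call. = FALSE)
  scan_id <- scan_id %||%
    (if (inherits(lung, "pq_mask")) lung$source_scan_id else "scan")
  vv <- voxel_volume_mm3(spacing_mm) / 1000
  out <- tibble(
    scan_id = scan_id,
    whole_lung_ml = sum(lb) * vv,
    injured_ml = sum(ib & lb) * vv,
    injured_fraction = sum(ib & lb) / sum(lb)
  )
  class(out) <- c("pq_volumetrics", class(out))
  out
}

#' Prognostic ratio of injured lung volume fractions
#'
#' The ratio of the injured lung volume fraction in the first (admission) CT
#' scan to that in the second (follow-up) scan. A low ratio means the injured
#' area grew quickly between the scans — rapid disease evolution and poor
#' prognosis. The ratio is kept at full precision; reports round it to two
#' decimals (e.g. fractions of 35.4% and 78.1% give 0.45).
#'
#' @param scan1,scan2 Either `pq_volumetrics` rows from [injured_fraction()]
#'   or bare numeric fractions in `[0, 1]`.
#' @return A one-row tibble of class `pq_ratio`: `scan_id_1`, `scan_id_2`,
#'   `fraction_scan1`, `fraction_scan2`, `ratio`.
#' @examples
#' fraction_ratio(0.354, 0.781)$ratio  # ~0.45
#' @export
fraction_ratio <- function(scan1, scan2) {
  as_frac <- function(x, default_id) {
    if (inherits(x, "pq_volumetrics")) {
      list(f = x$injured_fraction, id = x$scan_id)
    } else {
      stopifnot(is.numeric(x), length(x) == 1, x >= 0, x <= 1)
      list(f = as.numeric(x), id = default_id)
    }
  }
  s1 <- as_frac(scan1, "scan1")
  s2 <- as_frac(scan2, "scan2")
  if (s2$f <= 0) {
    stop("second-scan injured fraction is 0: ratio undefined ",
         "(resolved disease or misdetection; review the segmentation)",
         call. = FALSE)
  }
  out <- tibble(
    scan_id_1 = s1$id, scan_id_2 = s2$id,
    fraction_scan1 = s1$f, fraction_scan2 = s2$f,
    ratio = s1$f / s2$f
  )
  class(out) <- c("pq_ratio", class(out))
  out
}

#' @export
print.pq_ratio <- function(x, ...) {
  cat(sprintf(
    "<pq_ratio> fractions %.1f%% (scan 1) / %.1f%% (scan 2); ratio %.2f\n",
    100 * x$fraction_scan1, 100 * x$fraction_scan2, round(x$ratio, 2)))
  invisible(x)
}

# --- surface export ---------------------------------------------------------

# Build the boundary surface of a mask as axis-aligned quads (two triangles
# per exposed voxel face), vertices at voxel corners in physical mm. The mesh
# is closed and the enclosed volume equals the voxel-count volume exactly.
mask_surface_mesh <- function(bits, spacing_mm) {
  dm <- as_dim3(bits)
  verts <- list()
  faces <- list()
  nv <- 0L
  # exposed faces along each axis: voxel true, neighbour (constant-pad) false
  for (axis in 1:3) {
    e <- c(0L, 0L, 0L); e[axis] <- 1L
    for (side in c(-1L, 1L)) {
      nb <- shift3(bits, side * e, pad = "constant", fill = FALSE)
      expo <- which(bits & !nb)
      if (length(expo) == 0) next
      ai <- arrayInd(expo, dm) - 1L  # 0-based voxel corner
      # face plane offset along `axis`: +1 when the exposed side is +
      off <- if (side == 1L) 1L else 0L
      u <- (axis %% 3) + 1L
      v <- (u %% 3) + 1L
      base <- ai
      base[, axis] <- base[, axis] + off
      corner <- function(du, dv) {
        p <- base
        p[, u] <- p[, u] + du
        p[, v] <- p[, v] + dv
        sweep(p, 2, spacing_mm, "*")
      }
      p00 <- corner(0L, 0L); p10 <- corner(1L, 0L)
      p11 <- corner(1L, 1L); p01 <- corner(0L, 1L)
      # wind the quad so the normal points away from the voxel: the in-plane
      # axes (u, v, axis) are a right-handed cycle, so e_u x e_v = +e_axis
      n <- nrow(base)
      vs <- rbind(p00, p10, p11, p01)
      i00 <- nv + seq_len(n)
      i10 <- i00 + n; i11 <- i10 + n; i01 <- i11 + n
      tri <- if (side == 1L) {
        rbind(cbind(i00, i10, i11), cbind(i00, i11, i01))
      } else {
        rbind(cbind(i00, i11, i10), cbind(i00, i01, i11))
      }
      verts[[length(verts) + 1L]] <- vs
      faces[[length(faces) + 1L]] <- tri
      nv <- nv + 4L * n
    }
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  # merge duplicated corner vertices
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "/")
  uk <- !duplicated(key)
  remap <- match(key, key[uk])
  list(vertices = v[uk, , drop = FALSE],
       faces = matrix(remap[f], ncol = 3))
}

# signed volume via the divergence theorem (sum of tetrahedra to the origin)
mesh_volume_mm3 <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det)) / 6
}

#' Export a mask surface for 3-D visualisation
#'
#' Extracts the closed boundary surface of a mask (two triangles per exposed
#' voxel face, vertices in physical mm) and writes it as ASCII STL or PLY.
#' The enclosed volume equals the voxel-count volume exactly; meshes are for
#' visualisation, volumes are always computed by [mask_volume_ml()].
#'
#' @param mask A nonempty [binary_mask()].
#' @param path Output path ending in `.stl` or `.ply`.
#' @param spacing_mm Voxel spacing; defaults to the mask's.
#' @return Invisibly, the mesh (list of `vertices`, `faces`, `volume_mm3`).
#' @export
export_mesh <- function(mask, path, spacing_mm = NULL) {
  bits <- mask_bits(mask)
  if (!any(bits)) stop("empty mask: nothing to export", call. = FALSE)
  spacing_mm <- spacing_mm %||%
    (if (inherits(mask, "pq_mask")) mask$spacing_mm else NULL)
  if (is.null(spacing_mm)) stop("spacing_mm required", call. = FALSE)
  mesh <- mask_surface_mesh(bits, spacing_mm)
  mesh$volume_mm3 <- mesh_volume_mm3(mesh)
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    write_stl_ascii(mesh, path)
  } else if (ext == "ply") {
    write_ply_ascii(mesh, path)
  } else {
    stop("unsupported mesh format '", ext, "' (use .stl or .ply)",
         call. = FALSE)
  }
  invisible(mesh)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mask", con)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  n1 <- (b - a); n2 <- (cc - a)
  nx <- n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2]
  ny <- n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3]
  nz <- n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1]
  nrm <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-12)
  txt <- sprintf(
    paste0("facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n",
           "  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet"),
    nx / nrm, ny / nrm, nz / nrm,
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
    cc[, 1], cc[, 2], cc[, 3])
  writeLines(txt, con)
  writeLines("endsolid mask", con)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

#' Rasterise a closed axis-aligned mesh back onto a voxel grid
#'
#' Utility for consistency checks of [export_mesh()]: voxel centres are
#' classified inside/outside by parity counting of mesh faces perpendicular
#' to the column axis along each (slice, row) ray.
#'
#' @param mesh A mesh from [export_mesh()].
#' @param dim Target grid dimension `(slice, row, col)`.
#' @param spacing_mm Voxel spacing of the target grid.
#' @return A logical array.
#' @export
voxelize_mesh <- function(mesh, dim, spacing_mm) {
  v <- mesh$vertices
  f <- mesh$faces
  out <- array(FALSE, dim = dim)
  # faces perpendicular to the col axis have constant 3rd coordinate
  x3 <- matrix(v[f, 3], ncol = 3)
  perp <- x3[, 1] == x3[, 2] & x3[, 2] == x3[, 3]
  if (!any(perp)) return(out)
  fs <- f[perp, , drop = FALSE]
  plane <- x3[perp, 1]
  # bounding box of each perpendicular face in (slice, row)
  r1 <- matrix(v[fs, 1], ncol = 3)
  r2 <- matrix(v[fs, 2], ncol = 3)
  lo1 <- apply(r1, 1, min); hi1 <- apply(r1, 1, max)
  lo2 <- apply(r2, 1, min); hi2 <- apply(r2, 1, max)
  for (i in seq_len(dim[1])) {
    c1 <- (i - 0.5) * spacing_mm[1]
    for (j in seq_len(dim[2])) {
      c2 <- (j - 0.5) * spacing_mm[2]
      hit <- lo1 <= c1 & c1 < hi1 & lo2 <= c2 & c2 < hi2
      if (!any(hit)) next
      xs <- sort(plane[hit])
      # triangle pairs duplicate each crossing plane; collapse to quads
      xs <- unique(xs)
      ctrs <- (seq_len(dim[3]) - 0.5) * spacing_mm[3]
      inside <- (findInterval(ctrs, xs) %% 2) == 1
      out[i, j, ] <- inside
    }
  }
  out
}
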