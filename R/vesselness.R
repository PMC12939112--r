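#' Multiscale tubular-structure enhancement (Frangi-type)
#'
#' Computes a Hessian-eigenvalue vesselness response for bright tubes on a
#' dark background over a set of scales covering the analysed 2-10 mm
#' diameter range, with spacing-aware Gaussian derivatives (no isotropic
#' resampling, preserving anisotropic reconstructions). At each voxel the
#' response is the maximum over scales, `best_scale` is the winning scale
#' interpreted as the local tube radius (matched-scale convention: the
#' Gaussian sigma equals the tube radius), and the orientation is the
#' Hessian eigenvector of the smallest-magnitude eigenvalue at that scale.
#'
#' @param volume A [ct_volume()].
#' @param lungs A `lung_model` from [segment_lungs()]; the response is zeroed
#'   outside the lung mask.
#' @param scales Radii in mm to probe; must lie within \[1, 5\] mm
#'   (diameters 2-10 mm).
#' @param config Parameter list, see [default_config()].
#' @return A `vesselness_field`: list with `response` (in \[0,1\]),
#'   `best_scale` (mm), `orientation` (list of 3 arrays, unit tube axis),
#'   plus geometry.
#' @export
compute_vesselness <- function(volume, lungs, scales = NULL,
                               config = default_config()) {
  if (is.null(scales)) scales <- config$scales_mm
  if (any(scales < 1 - 1e-9 | scales > 5 + 1e-9))
    stop("config error: scales must lie within [1, 5] mm (diameters 2-10 mm)",
         call. = FALSE)
  dm <- dim(volume$data)
  in_lung <- lungs$lung_mask$labels != 0L
  # suppress responses at the lung boundary, where the body/lung intensity
  # step mimics large-scale structure
  erode_vox <- config$mask_margin_vox %||% 2
  if (erode_vox > 0 && any(in_lung))
    in_lung <- !cpp_binary_dilate(!in_lung, dm, rep(erode_vox, 3))
  if (!any(in_lung)) {
    z <- array(0, dm)
    return(structure(list(response = z, best_scale = z,
                          orientation = list(z, z, z),
                          spacing = volume$spacing, origin = volume$origin),
                     class = "vesselness_field"))
  }
  # crop to the lung bounding box (plus margin) for speed
  margin <- ceiling(max(scales) * 3 / volume$spacing)
  rng <- lapply(1:3, function(a) {
    pres <- which(apply(in_lung, a, any))
    c(max(1, min(pres) - margin[a]), min(dm[a], max(pres) + margin[a]))
  })
  sub <- volume$data[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
                     rng[[3]][1]:rng[[3]][2], drop = FALSE]
  sub_mask <- in_lung[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
                      rng[[3]][1]:rng[[3]][2], drop = FALSE]
  sdm <- dim(sub)
  sp <- volume$spacing

  best_resp <- array(0, sdm)
  best_scale <- array(0, sdm)
  best_o <- list(array(0, sdm), array(0, sdm), array(0, sdm))
  # first pass: global structure-strength normalizer c (half the maximum
  # scale-normalized Hessian norm across ALL scales, so that the S-term
  # penalizes mismatched scales and argmax over scale is meaningful)
  scale_H <- function(s) {
    H <- hessian3(cpp_gauss_blur3(sub, sdm, s / sp), sp)
    for (nm in names(H)) H[[nm]] <- H[[nm]] * s^2
    H
  }
  smax <- 0
  for (s in scales) {
    H <- scale_H(s)
    S2 <- H$xx^2 + H$yy^2 + H$zz^2 + 2 * (H$xy^2 + H$xz^2 + H$yz^2)
    smax <- max(smax, max(S2[sub_mask], 0))
  }
  cpar <- 0.5 * sqrt(smax)
  if (cpar <= 0) cpar <- 1
  for (s in scales) {
    H <- scale_H(s)
    fr <- cpp_frangi(H$xx, H$yy, H$zz, H$xy, H$xz, H$yz,
                     config$frangi_alpha, config$frangi_beta, cpar)
    resp <- array(fr$response, sdm)
    resp[!sub_mask] <- 0
    upd <- resp > best_resp
    best_resp[upd] <- resp[upd]
    best_scale[upd] <- s
    best_o[[1]][upd] <- fr$ox[upd]
    best_o[[2]][upd] <- fr$oy[upd]
    best_o[[3]][upd] <- fr$oz[upd]
  }
  # paste back into the full grid
  full <- function(subarr) {
    a <- array(0, dm)
    a[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
      rng[[3]][1]:rng[[3]][2]] <- subarr
    a
  }
  structure(list(response = full(best_resp), best_scale = full(best_scale),
                 orientation = lapply(best_o, full),
                 spacing = volume$spacing, origin = volume$origin),
            class = "vesselness_field")
}

# Hessian by central second differences of a (blurred) array, spacing-aware.
hessian3 <- function(f, sp) {
  sh <- function(di, dj, dk) shift3(f, di, dj, dk)
  list(
    xx = (sh(1, 0, 0) - 2 * f + sh(-1, 0, 0)) / sp[1]^2,
    yy = (sh(0, 1, 0) - 2 * f + sh(0, -1, 0)) / sp[2]^2,
    zz = (sh(0, 0, 1) - 2 * f + sh(0, 0, -1)) / sp[3]^2,
    xy = (sh(1, 1, 0) - sh(1, -1, 0) - sh(-1, 1, 0) + sh(-1, -1, 0)) /
      (4 * sp[1] * sp[2]),
    xz = (sh(1, 0, 1) - sh(1, 0, -1) - sh(-1, 0, 1) + sh(-1, 0, -1)) /
      (4 * sp[1] * sp[3]),
    yz = (sh(0, 1, 1) - sh(0, 1, -1) - sh(0, -1, 1) + sh(0, -1, -1)) /
      (4 * sp[2] * sp[3])
  )
}

# shift a 3D array by (di, dj, dk) with edge replication
shift3 <- function(a, di, dj, dk) {
  dm <- dim(a)
  ix <- pmin(pmax(seq_len(dm[1]) + di, 1L), dm[1])
  iy <- pmin(pmax(seq_len(dm[2]) + dj, 1L), dm[2])
  iz <- pmin(pmax(seq_len(dm[3]) + dk, 1L), dm[3])
  a[ix, iy, iz, drop = FALSE]
}

#' @export
print.vesselness_field <- function(x, ...) {
  cat("<vesselness_field> ", paste(dim(x$response), collapse = " x "),
      ", peak response ", signif(max(x$response), 3), "\n", sep = "")
  invisible(x)
}
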