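#' Representative diameter of a vessel segment
#'
#' Twice the median of the per-point radii: robust against end effects at
#' bifurcations where the local radius estimate is inflated.
#'
#' @param segment A [vessel_segment()].
#' @return Diameter in mm.
#' @export
segment_diameter <- function(segment) {
  2 * stats::median(segment$radii)
}

#' Sum-of-angles metric (SOAM) tortuosity of a centerline
#'
#' For points p0..pn with sections s_i = p_{i+1} - p_i, sums the angles
#' between adjacent sections (radians) and divides by the total polyline
#' length: `SOAM = sum_i angle(s_{i-1}, s_i) / sum_i |s_i|` in rad/mm. A
#' straight polyline gives exactly 0; a densely sampled circular arc tends to
#' its curvature 1/R. Segments with only two points (no interior angle)
#' return 0.
#'
#' @param segment A [vessel_segment()] (or an m x 3 point matrix).
#' @return Tortuosity in rad/mm.
#' @export
soam <- function(segment) {
  pts <- if (inherits(segment, "vessel_segment")) segment$points else
    as.matrix(segment)
  if (nrow(pts) < 2) stop("need at least 2 points", call. = FALSE)
  secs <- diff(pts)
  lens <- sqrt(rowSums(secs^2))
  if (any(lens == 0)) stop("duplicate consecutive points", call. = FALSE)
  if (nrow(secs) < 2) return(0)
  u <- secs / lens
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  angles <- acos(pmin(1, pmax(-1, dots)))
  sum(angles) / sum(lens)
}

# vessel volume of one segment: frustum sum pi * r_mid^2 * section length
segment_volume_mm3 <- function(seg) {
  secs <- diff(seg$points)
  lens <- sqrt(rowSums(secs^2))
  rmid <- (seg$radii[-length(seg$radii)] + seg$radii[-1]) / 2
  sum(pi * rmid^2 * lens)
}

#' Per-scan morphometry report
#'
#' Computes every scan-level readout from a labelled vessel graph and the
#' lung model: total segment count, vessel volume (frustum sum over the
#' centerline radii), vessel density (segments per litre of lung),
#' normalized vessel volume (vessel volume / lung volume, dimensionless),
#' median SOAM tortuosity, and, per label (artery/vein) and diameter bin
#' (2-4, 4-6, 6-10 mm, all), segment counts and densities together with the
#' artery-minus-vein density differences and artery-to-vein count ratios.
#' Unknown-labelled segments count toward totals but are excluded from the
#' artery/vein metrics; an artery/vein ratio with a zero vein count is NA.
#'
#' @param graph A labelled [vessel_graph()].
#' @param lungs A `lung_model` (or a scalar lung volume in litres).
#' @return A one-row tibble with the columns of [morphometry_columns()] plus
#'   `lung_volume_L`.
#' @export
compute_report <- function(graph, lungs) {
  vol_L <- if (inherits(lungs, "lung_model")) lungs$lung_volume_L else
    as.numeric(lungs)
  if (!is.finite(vol_L) || vol_L <= 0)
    stop("lung volume must be positive (litres)", call. = FALSE)
  st <- as_tibble(graph)
  st$bin <- as.character(diameter_bin(st$diameter_mm))
  vessel_vol <- sum(vapply(graph$segments, segment_volume_mm3, numeric(1)))

  cnt <- function(lab, bin) {
    if (bin == "all") sum(st$label == lab, na.rm = TRUE)
    else sum(st$label == lab & !is.na(st$bin) & st$bin == bin)
  }
  bins <- c("2_4", "4_6", "6_10", "all")
  out <- tibble::tibble(
    n_segments_total = nrow(st),
    vessel_volume_mm3 = vessel_vol,
    lung_volume_L = vol_L,
    density_total = nrow(st) / vol_L,
    normalized_vessel_volume = vessel_vol * 1e-6 / vol_L
  )
  for (lab in c("artery", "vein")) for (b in bins) {
    out[[paste0("count_", lab, "_", b)]] <- cnt(lab, b)
    out[[paste0("density_", lab, "_", b)]] <- cnt(lab, b) / vol_L
  }
  med_soam <- function(mask) if (any(mask)) stats::median(st$soam[mask]) else NA_real_
  out$soam_median_artery <- med_soam(st$label == "artery")
  out$soam_median_vein <- med_soam(st$label == "vein")
  out$soam_median_all <- med_soam(rep(TRUE, nrow(st)))
  for (b in bins[1:3]) {
    ca <- cnt("artery", b); cv <- cnt("vein", b)
    out[[paste0("density_diff_av_", b)]] <- (ca - cv) / vol_L
    out[[paste0("ratio_av_", b)]] <- if (cv > 0) ca / cv else NA_real_
  }
  out
}
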