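#' Signal a segmentation failure
#'
#' Raised when a stage cannot produce a usable segmentation (e.g. no airway
#' found). The batch pipeline catches this classed condition and flags the
#' scan instead of aborting the run.
#'
#' @param msg Human-readable reason.
#' @keywords internal
segmentation_failure <- function(msg) {
  stop(structure(class = c("pulmovasc_segmentation_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Default pipeline configuration
#'
#' All numeric defaults of the scan-level pipeline in one place. Thresholds
#' are in HU, distances in mm, angles in degrees.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    # lung / airway
    airway_hu_max = -950,      # airway lumen attenuation threshold
    lung_hu_max = -400,        # lung parenchyma attenuation threshold
    airway_leak_factor = 2.0,  # abort growth if one wave doubles the volume
    airway_leak_burn_in = 12,  # waves before the leak guard engages
    lung_closing_radius_mm = 3,# morphological closing to keep vessels inside
    min_lung_voxels = 1000,
    # vesselness
    scales_mm = seq(1, 5, by = 0.5),
    frangi_alpha = 0.5,
    frangi_beta = 0.5,
    response_threshold = 0.08,
    # tree building
    min_spacing_mm = 3,
    nms_radius_factor = 1.5,
    knn = 5,
    max_edge_mm = 12,
    w_par = 1, w_dir = 0.5, w_dia = 0.5, w_len = 0.1,
    max_direction_change_deg = 45,
    max_diameter_jump = 0.5,
    edge_cost_threshold = 0.8,
    min_component_mm = 12,
    prune_twig_mm = 15,
    # artery/vein separation
    parallel_tol_deg = 30,
    bronchus_dist_max_mm = 10,
    neighbor_radius_mm = 10,
    lambda_bronchus = NULL,    # NULL: 2 x mean positive pairwise weight
    av_exact_max_units = 24,
    # exclusion rule
    min_av_accuracy = 0.80
  )
}

#' Segment the airways by attenuation region growing
#'
#' Thresholds the volume at the airway lumen attenuation, seeds the growth in
#' the most superior connected air component (the trachea) unless a seed
#' voxel is given, and grows a 6-connected region with a leakage guard: if a
#' single growth wave multiplies the accumulated volume by more than
#' `airway_leak_factor`, the growth is stopped at the previous wave.
#'
#' @param volume A [ct_volume()].
#' @param seed Optional voxel index (length-3 integer) inside the trachea.
#' @param config Parameter list, see [default_config()].
#' @return A [mask_volume()] with code `airway`.
#' @export
segment_airways <- function(volume, seed = NULL, config = default_config()) {
  mask <- volume$data < config$airway_hu_max
  if (!any(mask))
    segmentation_failure("no voxels below the airway attenuation threshold")
  dm <- dim(volume$data)
  if (is.null(seed)) {
    # most superior slice (largest axis-3 index) that contains air
    kz <- max(which(apply(mask, 3, any)))
    sl <- which(mask[, , kz], arr.ind = TRUE)
    ctr <- colMeans(sl)
    pick <- sl[which.min((sl[, 1] - ctr[1])^2 + (sl[, 2] - ctr[2])^2), ]
    seed <- c(pick[1], pick[2], kz)
  }
  seed0 <- (seed[1] - 1L) + dm[1] * ((seed[2] - 1L) + dm[2] * (seed[3] - 1L))
  grown <- cpp_region_grow(mask, dim(volume$data), as.integer(seed0),
                           config$airway_leak_factor,
                           as.integer(config$airway_leak_burn_in))
  if (grown$n_voxels < 10)
    segmentation_failure("airway seed component too small")
  labels <- array(0L, dm)
  labels[grown$region] <- 3L
  mask_volume(labels, spacing = volume$spacing, origin = volume$origin)
}

#' Segment the lungs by attenuation
#'
#' Low-attenuation voxels (below the parenchyma threshold) excluding the
#' airway are labelled; components touching the lateral image boundary
#' (outside air) are discarded; the two largest remaining components become
#' the lungs, assigned left/right by centroid laterality along axis 1.
#' Morphological closing followed by 3D hole filling pulls the
#' higher-attenuation vessels into the lung mask so that they count toward
#' the lung volume, which is returned in litres.
#'
#' @param volume A [ct_volume()].
#' @param airways Airway [mask_volume()] from [segment_airways()].
#' @param config Parameter list, see [default_config()].
#' @return A `lung_model`: list with `lung_mask`, `airway_mask`,
#'   `lung_volume_L`.
#' @export
segment_lungs <- function(volume, airways, config = default_config()) {
  dm <- dim(volume$data)
  low <- volume$data < config$lung_hu_max & airways$labels == 0L
  if (!any(low))
    segmentation_failure("no voxels below the lung attenuation threshold")
  comp <- cpp_label_components(low, dm, 26L)
  # drop components touching the x/y boundary (air outside the body)
  border_labs <- unique(c(comp[1, , ], comp[dm[1], , ],
                          comp[, 1, ], comp[, dm[2], ]))
  border_labs <- setdiff(border_labs, 0L)
  sizes <- tabulate(comp)
  if (length(border_labs) > 0) sizes[border_labs] <- 0L
  keep <- which(sizes >= config$min_lung_voxels)
  if (length(keep) < 1)
    segmentation_failure("no lung-like low-attenuation component found")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- utils::head(keep, 2)
  if (length(keep) == 1)
    warning("only one lung-like component found", call. = FALSE)

  labels <- array(0L, dm)
  close_r <- pmax(1, round(config$lung_closing_radius_mm / volume$spacing))
  for (lab in keep) {
    m <- comp == lab
    # closing: dilate then erode with an ellipsoidal element, then fill holes
    d <- cpp_binary_dilate(m, dm, as.numeric(close_r))
    er <- !cpp_binary_dilate(!d, dm, as.numeric(close_r))
    filled <- fill_holes3(er | m, dm)
    filled <- filled & airways$labels == 0L
    labels[filled & labels == 0L] <- lab  # temporary component code
  }
  # left/right by world-x centroid (axis 1 = lateral)
  cents <- vapply(keep, function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    mean(volume$origin[1] + (idx[, 1] - 1) * volume$spacing[1])
  }, numeric(1))
  out <- array(0L, dm)
  if (length(keep) == 2) {
    left_lab <- keep[which.min(cents)]
    right_lab <- keep[which.max(cents)]
    out[labels == left_lab] <- 1L
    out[labels == right_lab] <- 2L
  } else {
    mid <- volume$origin[1] + (dm[1] - 1) / 2 * volume$spacing[1]
    out[labels == keep[1]] <- if (cents[1] <= mid) 1L else 2L
  }
  lung_mask <- mask_volume(out, spacing = volume$spacing, origin = volume$origin)
  model <- structure(list(lung_mask = lung_mask, airway_mask = airways,
                          lung_volume_L = NA_real_),
                     class = "lung_model")
  model$lung_volume_L <- lung_volume_litres(model)
  model
}

# fill 3D holes: complement components not touching the volume boundary
fill_holes3 <- function(mask, dm) {
  comp <- cpp_label_components(!mask, dm, 6L)
  border <- unique(c(comp[1, , ], comp[dm[1], , ], comp[, 1, ], comp[, dm[2], ],
                     comp[, , 1], comp[, , dm[3]]))
  border <- setdiff(border, 0L)
  holes <- comp != 0L
  for (b in border) holes[comp == b] <- FALSE
  mask | holes
}

#' Lung volume in litres
#'
#' Combined volume of both lungs: voxel count times voxel volume (mm^3)
#' times 1e-6.
#'
#' @param model A `lung_model` (or a lung [mask_volume()]).
#' @return Scalar lung volume in litres; 0 with a warning for an empty mask.
#' @export
lung_volume_litres <- function(model) {
  mask <- if (inherits(model, "lung_model")) model$lung_mask else model
  n <- sum(mask$labels == 1L | mask$labels == 2L)
  if (n == 0) {
    warning("empty lung mask; volume is 0 L", call. = FALSE)
    return(0)
  }
  n * prod(mask$spacing) * 1e-6
}

#' @export
print.lung_model <- function(x, ...) {
  cat("<lung_model> lung volume ", round(x$lung_volume_L, 2), " L, ",
      sum(x$airway_mask$labels == 3L), " airway voxels\n", sep = "")
  invisible(x)
}
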