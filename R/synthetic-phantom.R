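#' Phantom specification
#'
#' Describes a CT-like phantom: volume geometry, lung ellipsoids, a list of
#' tube descriptors and an intensity model. The seed fully determines the
#' generated volume. Tube identities: `artery`, `vein` (contrast-filled
#' vessels, radii 1-5 mm), `bronchus`/`airway` (air-filled). An artery with
#' `paired_bronchus = TRUE` receives a companion bronchus: the same
#' centerline offset laterally by `bronchus_gap` mm, emulating the
#' characteristic parallel course of arteries alongside bronchi.
#'
#' @param shape Volume dimensions (voxels).
#' @param spacing Voxel spacing in mm.
#' @param lungs List of ellipsoids, each `list(center, semi)` in mm (world
#'   coordinates; the origin is placed so the volume is centred on 0).
#' @param tubes List of tube descriptors:
#'   `list(control_points, radius, identity, paired_bronchus, bronchus_gap)`;
#'   `radius` may be a scalar or one value per control point (tapering).
#' @param hu Intensity model in HU: `parenchyma`, `vessel`, `airway`,
#'   `body`, `noise_sd`.
#' @param seed Integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing = c(1.5, 1.5, 1.5),
                         lungs = list(), tubes = list(),
                         hu = list(parenchyma = -850, vessel = 300,
                                   airway = -1000, body = 0, noise_sd = 20),
                         seed = 1L) {
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 lungs = lungs, tubes = tubes, hu = hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# natural-spline resample of control points to a fine polyline (step mm)
sample_centerline <- function(control_points, radius, step) {
  cp <- as.matrix(control_points)
  if (nrow(cp) == 1) stop("tube needs at least 2 control points", call. = FALSE)
  tt <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  total <- tt[length(tt)]
  ts <- seq(0, total, by = step)
  if (ts[length(ts)] < total) ts <- c(ts, total)
  pts <- vapply(1:3, function(a) {
    if (nrow(cp) == 2) stats::approx(tt, cp[, a], xout = ts)$y
    else stats::spline(tt, cp[, a], xout = ts, method = "natural")$y
  }, numeric(length(ts)))
  radii <- if (length(radius) == 1) rep(radius, length(ts))
  else stats::approx(tt, radius, xout = ts)$y
  list(points = pts, radii = radii)
}

in_any_ellipsoid <- function(pts, lungs) {
  if (length(lungs) == 0) return(rep(TRUE, nrow(pts)))
  inside <- rep(FALSE, nrow(pts))
  for (el in lungs) {
    q <- sweep(sweep(pts, 2, el$center, "-"), 2, el$semi, "/")
    inside <- inside | rowSums(q^2) <= 1
  }
  inside
}

#' Generate a CT-like phantom with ground truth
#'
#' Rasterizes lung ellipsoids and tubes into a HU volume (body, parenchyma,
#' air-filled airways, contrast-filled vessels, in that painting order, so
#' vessels override crossing structures), adds Gaussian noise, and returns
#' the volume together with the exact ground truth: the lung model (lung
#' mask = ellipsoids including embedded vessels, minus airway voxels), the
#' vessel graph (centerline polylines, per-point radii, artery/vein labels)
#' and the airway/bronchus mask. Vessel tubes whose centerline exits every
#' lung ellipsoid raise a spec error.
#'
#' @param spec A [phantom_spec()].
#' @return List: `volume` ([ct_volume()]), `lungs` (`lung_model` ground
#'   truth), `truth` ([vessel_graph()]), `airway_mask` ([mask_volume()]).
#' @export
make_phantom <- function(spec) {
  dm <- spec$shape
  sp <- spec$spacing
  origin <- -(dm - 1) * sp / 2
  vol <- array(spec$hu$body, dm)

  # lungs: analytic ellipsoid membership over the grid
  xs <- origin[1] + (seq_len(dm[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dm[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dm[3]) - 1) * sp[3]
  lung_mask <- array(FALSE, dm)
  for (el in spec$lungs) {
    qx <- ((xs - el$center[1]) / el$semi[1])^2
    qy <- ((ys - el$center[2]) / el$semi[2])^2
    qz <- ((zs - el$center[3]) / el$semi[3])^2
    inside <- outer(outer(qx, qy, "+"), qz, "+") <= 1
    lung_mask <- lung_mask | inside
  }
  vol[lung_mask] <- spec$hu$parenchyma

  step <- 0.5 * min(sp)
  # expand paired bronchi into explicit tubes
  tubes <- list()
  for (tb in spec$tubes) {
    tubes[[length(tubes) + 1]] <- tb
    if (isTRUE(tb$paired_bronchus)) {
      gap <- tb$bronchus_gap %||% 7
      cp <- as.matrix(tb$control_points)
      tubes[[length(tubes) + 1]] <- list(
        control_points = cp + matrix(c(gap, 0, 0), nrow(cp), 3, byrow = TRUE),
        radius = 1.5, identity = "bronchus")
    }
  }
  sampled <- lapply(tubes, function(tb)
    c(tb, sample_centerline(tb$control_points, tb$radius, step)))

  # vessel centerlines must stay inside the lungs
  for (tb in sampled) {
    if (tb$identity %in% c("artery", "vein") && length(spec$lungs) > 0 &&
        !all(in_any_ellipsoid(tb$points, spec$lungs)))
      stop("spec error: vessel tube exits the lung ellipsoid", call. = FALSE)
  }

  airway_arr <- array(0L, dm)
  for (tb in sampled) {
    if (!tb$identity %in% c("bronchus", "airway")) next
    cpp_paint_tube(vol, dm, sp, origin, tb$points, tb$radii, spec$hu$airway)
    tmp <- array(0, dm)
    cpp_paint_tube(tmp, dm, sp, origin, tb$points, tb$radii, 1)
    airway_arr[tmp > 0] <- 3L
  }
  for (tb in sampled) {
    if (!tb$identity %in% c("artery", "vein")) next
    cpp_paint_tube(vol, dm, sp, origin, tb$points, tb$radii, spec$hu$vessel)
  }

  if (spec$hu$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$hu$noise_sd), dm)
  }

  segs <- list()
  sid <- 0L
  for (tb in sampled) {
    if (!tb$identity %in% c("artery", "vein")) next
    sid <- sid + 1L
    segs[[sid]] <- vessel_segment(tb$points, tb$radii, label = tb$identity,
                                  id = sid)
  }
  truth <- vessel_graph(segs, metadata = list(source = "phantom",
                                              seed = spec$seed))

  lung_lab <- array(0L, dm)
  mid <- (min(xs) + max(xs)) / 2
  for (el in spec$lungs) {
    qx <- ((xs - el$center[1]) / el$semi[1])^2
    qy <- ((ys - el$center[2]) / el$semi[2])^2
    qz <- ((zs - el$center[3]) / el$semi[3])^2
    inside <- outer(outer(qx, qy, "+"), qz, "+") <= 1
    code <- if (el$center[1] <= mid) 1L else 2L
    lung_lab[inside & airway_arr == 0L] <- code
  }
  airway_mask <- mask_volume(airway_arr, spacing = sp, origin = origin)
  lmask <- mask_volume(lung_lab, spacing = sp, origin = origin)
  lmodel <- structure(list(lung_mask = lmask, airway_mask = airway_mask,
                           lung_volume_L = 0), class = "lung_model")
  if (length(spec$lungs) > 0)
    lmodel$lung_volume_L <- lung_volume_litres(lmodel)

  list(volume = ct_volume(vol, spacing = sp, origin = origin),
       lungs = lmodel, truth = truth, airway_mask = airway_mask)
}

#' Standard benchmark phantom
#'
#' Fixed-geometry, fixed-seed phantom used throughout validation: two lung
#' ellipsoids, 16 gently curved vessels (8 arteries, 8 veins) arranged as
#' interdigitated artery/vein pairs 9 mm apart and spanning all three
#' diameter bins (2-4, 4-6, 6-10 mm), companion bronchi parallel to every
#' artery, and a connected airway tree (trachea plus connectors) so that
#' attenuation-based airway segmentation reaches every bronchus.
#'
#' @param seed RNG seed for the additive noise.
#' @param noise_sd Noise standard deviation in HU.
#' @return The [make_phantom()] bundle plus `$spec` and `$truth_bin_counts`
#'   (named artery/vein x bin count table of the ground truth).
#' @export
standard_benchmark_phantom <- function(seed = 20260101L, noise_sd = 20) {
  lungs <- list(list(center = c(-45, 0, 0), semi = c(36, 50, 78)),
                list(center = c(45, 0, 0), semi = c(36, 50, 78)))
  # per-lung artery/vein pair layout: (y position, artery radius, vein radius)
  layout <- list(list(y = -28, ra = 1.2, rv = 1.3),
                 list(y = -10, ra = 2.2, rv = 2.4),
                 list(y = 10, ra = 3.5, rv = 3.3),
                 list(y = 28, ra = 1.6, rv = 1.4))
  tubes <- list()
  zs <- seq(-55, 55, length.out = 7)
  for (side in c(-1, 1)) {
    cx <- 45 * side
    for (p in seq_along(layout)) {
      ly <- layout[[p]]
      phase <- p + (side + 1)
      bend <- function(amp, ph) amp * sin(seq_along(zs) / length(zs) * pi + ph)
      # artery and vein of a pair run as parallel curves at a constant
      # 9 mm separation: intertwined within the copula radius yet never
      # merging, as for real artery/vein pairs accompanying an airway
      acp <- cbind(cx - 4.5 * side + bend(3, phase), ly$y + bend(2, phase + 1), zs)
      vcp <- cbind(cx + 4.5 * side + bend(3, phase), ly$y + bend(2, phase + 1), zs)
      tubes[[length(tubes) + 1]] <- list(control_points = acp, radius = ly$ra,
                                         identity = "artery",
                                         paired_bronchus = TRUE,
                                         bronchus_gap = -7 * side)
      tubes[[length(tubes) + 1]] <- list(control_points = vcp, radius = ly$rv,
                                         identity = "vein")
    }
  }
  # trachea + connectors reaching the top of every companion bronchus
  tubes[[length(tubes) + 1]] <- list(
    control_points = cbind(0, 0, c(70, 66)), radius = 4, identity = "airway")
  for (side in c(-1, 1)) {
    cx <- 45 * side
    for (p in seq_along(layout)) {
      ly <- layout[[p]]
      phase <- p + (side + 1)
      top_x <- cx - 4.5 * side - 7 * side + 3 * sin(pi + phase)
      top_y <- ly$y + 2 * sin(pi + phase + 1)
      tubes[[length(tubes) + 1]] <- list(
        control_points = rbind(c(0, 0, 68), c(top_x, top_y, 55)),
        radius = 2, identity = "airway")
    }
  }
  spec <- phantom_spec(shape = c(128, 128, 128), spacing = c(1.5, 1.5, 1.5),
                       lungs = lungs, tubes = tubes,
                       hu = list(parenchyma = -850, vessel = 300,
                                 airway = -1000, body = 0,
                                 noise_sd = noise_sd),
                       seed = seed)
  bundle <- make_phantom(spec)
  tb <- as_tibble(bundle$truth)
  tb$bin <- diameter_bin(tb$diameter_mm)
  bundle$spec <- spec
  bundle$truth_bin_counts <- table(label = tb$label, bin = tb$bin)
  bundle
}

#' Helical test tube phantom
#'
#' A single vessel following a circular helix of radius `R` and pitch
#' parameter `c` (z advances by `2*pi*c` per turn). The curvature of the
#' helix, `R / (R^2 + c^2)`, is the continuum limit of the polyline SOAM,
#' making this a closed-form oracle for the tortuosity metric.
#'
#' @param R Helix radius (mm).
#' @param c_pitch Pitch parameter (mm).
#' @param turns Number of turns.
#' @param step Arc-length sampling step (mm).
#' @return List with `points` (polyline), `kappa` (analytic curvature).
#' @export
helix_centerline <- function(R = 10, c_pitch = 4, turns = 2, step = 0.5) {
  speed <- sqrt(R^2 + c_pitch^2)
  s <- seq(0, 2 * pi * turns * speed, by = step)
  t <- s / speed
  list(points = cbind(R * cos(t), R * sin(t), c_pitch * t),
       kappa = R / (R^2 + c_pitch^2))
}
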