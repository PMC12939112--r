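#' Detect regularly spaced vesselness maxima
#'
#' Finds centerline candidates as transverse local maxima of the vesselness
#' response: a voxel above the detection threshold is kept when its response
#' is at least as large as the (interpolated) response one voxel away along
#' both directions perpendicular to the local tube orientation — ridge
#' points along the vessel axis. Non-maximum suppression then enforces
#' regular spacing: candidates are visited in decreasing response order and
#' accepted only if at least `min_spacing` mm (world distance) from every
#' already accepted node. Each node carries the scale estimate and tube
#' orientation at its voxel; if the CT volume is supplied, the radius is
#' refined by half-maximum edge detection on rays perpendicular to the tube
#' axis (the scale argmax alone systematically under-sizes solid tubes).
#'
#' @param field A `vesselness_field` from [compute_vesselness()].
#' @param min_spacing Minimum node spacing in mm.
#' @param config Parameter list (detection threshold).
#' @param volume Optional [ct_volume()] for half-maximum radius refinement.
#' @return A tibble of candidate nodes: world position (mm), `radius` (mm),
#'   `response`, orientation components `ox`,`oy`,`oz`.
#' @export
detect_maxima <- function(field, min_spacing = NULL, config = default_config(),
                          volume = NULL) {
  if (is.null(min_spacing)) min_spacing <- config$min_spacing_mm
  stopifnot(min_spacing > 0)
  dm <- dim(field$response)
  lin <- which(field$response >= config$response_threshold)
  empty <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          radius = numeric(), response = numeric(),
                          ox = numeric(), oy = numeric(), oz = numeric())
  if (length(lin) == 0) return(empty)
  idx <- arrayInd(lin, dm)
  pos <- sweep(sweep(idx - 1, 2, field$spacing, "*"), 2, field$origin, "+")
  axes <- cbind(field$orientation[[1]][lin], field$orientation[[2]][lin],
                field$orientation[[3]][lin])
  perp <- perp_basis(axes)
  h <- max(field$spacing)
  resp <- field$response[lin]
  # transverse NMS: for each perpendicular direction, the response must not
  # be below both neighbours at +-h; comparing against the smaller of the
  # two sides keeps ridge points even where an axial response gradient
  # leaks into a slightly misestimated orientation
  ok <- rep(TRUE, length(lin))
  for (u in perp) {
    rp <- interp3(field$response, field$spacing, field$origin, pos + h * u)
    rn <- interp3(field$response, field$spacing, field$origin, pos - h * u)
    ok <- ok & (resp + 1e-9 >= pmin(rp, rn))
  }
  lin <- lin[ok]; pos <- pos[ok, , drop = FALSE]; resp <- resp[ok]
  axes <- axes[ok, , drop = FALSE]
  if (length(lin) == 0) return(empty)
  ord <- order(resp, decreasing = TRUE)
  lin <- lin[ord]; pos <- pos[ord, , drop = FALSE]; resp <- resp[ord]
  axes <- axes[ord, , drop = FALSE]
  # adaptive cylindrical suppression: an accepted node shadows later
  # (weaker) candidates within min_spacing along its own axis and within
  # max(min_spacing, nms_radius_factor * scale) laterally — removing
  # shoulder responses around thick vessels without thinning the chain of
  # nodes along the centerline
  supp <- pmax(min_spacing,
               (config$nms_radius_factor %||% 1.5) * field$best_scale[lin])
  keep <- integer(0)
  for (i in seq_along(lin)) {
    ok1 <- TRUE
    if (length(keep) > 0) {
      delta <- pos[keep, , drop = FALSE] -
        matrix(pos[i, ], length(keep), 3, byrow = TRUE)
      d2 <- rowSums(delta^2)
      along <- abs(rowSums(delta * axes[keep, , drop = FALSE]))
      lat2 <- pmax(d2 - along^2, 0)
      ok1 <- all(d2 >= min_spacing^2 &
                   !(along < min_spacing & lat2 < supp[keep]^2))
    }
    if (ok1) keep <- c(keep, i)
  }
  nodes <- tibble::tibble(
    x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
    radius = field$best_scale[lin[keep]], response = resp[keep],
    ox = axes[keep, 1], oy = axes[keep, 2], oz = axes[keep, 3])
  if (!is.null(volume)) {
    nodes <- recenter_nodes(nodes, volume)
    nodes <- dedupe_nodes(nodes, min_spacing)
    nodes$radius <- refine_radii(nodes, volume, config)
    nodes <- reorient_nodes(nodes, radius_mm = 2.5 * min_spacing)
    nodes <- dedupe_lateral(nodes, min_spacing)
  }
  nodes
}

# re-estimate node orientations from the principal axis of neighbouring
# node positions: after recentering the nodes lie on the centerline, so the
# local point cloud is far less noisy than the per-voxel Hessian eigenvector
reorient_nodes <- function(nodes, radius_mm = 7) {
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  n <- nrow(pos)
  if (n < 3) return(nodes)
  for (i in seq_len(n)) {
    d2 <- colSums((t(pos) - pos[i, ])^2)
    nb <- which(d2 <= radius_mm^2)
    if (length(nb) < 3) next
    ax <- svd(sweep(pos[nb, , drop = FALSE], 2, colMeans(pos[nb, , drop = FALSE])))$v[, 1]
    nodes$ox[i] <- ax[1]; nodes$oy[i] <- ax[2]; nodes$oz[i] <- ax[3]
  }
  nodes
}

# second suppression pass with the refined radii: a stronger node shadows
# weaker ones lying alongside it (within its own cross-section) — residual
# shoulder duplicates around thick vessels
dedupe_lateral <- function(nodes, min_spacing, factor = 1.2) {
  ord <- order(nodes$response, decreasing = TRUE)
  nodes <- nodes[ord, ]
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  axes <- as.matrix(nodes[, c("ox", "oy", "oz")])
  rad <- nodes$radius
  keep <- integer(0)
  for (i in seq_len(nrow(pos))) {
    ok <- TRUE
    if (length(keep) > 0) {
      delta <- pos[keep, , drop = FALSE] -
        matrix(pos[i, ], length(keep), 3, byrow = TRUE)
      d2 <- rowSums(delta^2)
      along <- abs(rowSums(delta * axes[keep, , drop = FALSE]))
      lat2 <- pmax(d2 - along^2, 0)
      # genuine chain neighbours (small lateral offset) are kept as long as
      # they respect min_spacing; laterally offset duplicates inside the
      # stronger node's cross-section are shadowed over a longer window so
      # that shoulder chains cannot thread between chain nodes
      lat_cap2 <- pmax(factor * rad[keep], min_spacing / 2)^2
      shadow <- (along < min_spacing & lat2 < lat_cap2) |
        (along < 1.75 * min_spacing & lat2 >= (min_spacing / 2)^2 &
           lat2 < lat_cap2)
      ok <- !any(shadow)
    }
    if (ok) keep <- c(keep, i)
  }
  nodes[keep, ]
}

# snap each node to the intensity centroid of the vessel cross-section in
# its perpendicular plane (two iterations); off-axis shoulder responses
# collapse onto the centerline and are then merged by dedupe_nodes
recenter_nodes <- function(nodes, volume, window_mm = 5, step_mm = 0.5) {
  n <- nrow(nodes)
  if (n == 0) return(nodes)
  axes <- as.matrix(nodes[, c("ox", "oy", "oz")])
  perp <- perp_basis(axes)
  gs <- seq(-window_mm, window_mm, by = step_mm)
  grid <- expand.grid(a = gs, b = gs)
  grid <- grid[grid$a^2 + grid$b^2 <= window_mm^2, ]
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  for (iter in 1:2) {
    for (i in seq_len(n)) {
      u1 <- perp[[1]][i, ]; u2 <- perp[[2]][i, ]
      pts <- cbind(pos[i, 1] + grid$a * u1[1] + grid$b * u2[1],
                   pos[i, 2] + grid$a * u1[2] + grid$b * u2[2],
                   pos[i, 3] + grid$a * u1[3] + grid$b * u2[3])
      hu <- interp3(volume$data, volume$spacing, volume$origin, pts)
      bg <- stats::quantile(hu, 0.25, names = FALSE)
      w <- pmax(hu - bg, 0)
      # retain only the mass connected to the centre in radius: keep weights
      # within the contiguous high-intensity core by damping far samples
      w <- w * exp(-(grid$a^2 + grid$b^2) / (2 * (window_mm / 2)^2))
      if (sum(w) <= 0) next
      da <- sum(w * grid$a) / sum(w)
      db <- sum(w * grid$b) / sum(w)
      pos[i, ] <- pos[i, ] + da * u1 + db * u2
    }
  }
  nodes$x <- pos[, 1]; nodes$y <- pos[, 2]; nodes$z <- pos[, 3]
  nodes
}

# merge nodes closer than min_spacing (keep the stronger response)
dedupe_nodes <- function(nodes, min_spacing) {
  ord <- order(nodes$response, decreasing = TRUE)
  nodes <- nodes[ord, ]
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  keep <- integer(0)
  for (i in seq_len(nrow(pos))) {
    ok <- TRUE
    if (length(keep) > 0) {
      d2 <- colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2)
      ok <- all(d2 >= min_spacing^2)
    }
    if (ok) keep <- c(keep, i)
  }
  nodes[keep, ]
}

# two unit vectors perpendicular to each row of `axes`
perp_basis <- function(axes) {
  n <- nrow(axes)
  ref <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  swap <- abs(axes[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), sum(swap), 3)
  u1 <- cbind(axes[, 2] * ref[, 3] - axes[, 3] * ref[, 2],
              axes[, 3] * ref[, 1] - axes[, 1] * ref[, 3],
              axes[, 1] * ref[, 2] - axes[, 2] * ref[, 1])
  u1 <- u1 / pmax(sqrt(rowSums(u1^2)), 1e-12)
  u2 <- cbind(axes[, 2] * u1[, 3] - axes[, 3] * u1[, 2],
              axes[, 3] * u1[, 1] - axes[, 1] * u1[, 3],
              axes[, 1] * u1[, 2] - axes[, 2] * u1[, 1])
  list(u1, u2)
}

#' Refine node radii by half-maximum edge detection
#'
#' For each candidate node, HU profiles are sampled along rays
#' perpendicular to the tube axis; the radius is the median distance at
#' which the profile first drops below the half-maximum between the
#' centre intensity and the local background (estimated from the outer end
#' of the rays). Clamped to the analysed 1-5 mm radius range.
#'
#' @param nodes Candidate tibble from [detect_maxima()].
#' @param volume The [ct_volume()].
#' @param config Parameter list.
#' @return Numeric vector of refined radii (mm).
#' @export
refine_radii <- function(nodes, volume, config = default_config()) {
  n <- nrow(nodes)
  if (n == 0) return(numeric(0))
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  axes <- as.matrix(nodes[, c("ox", "oy", "oz")])
  perp <- perp_basis(axes)
  nray <- 8
  tmax <- 7; tstep <- 0.25
  ts <- seq(tstep, tmax, by = tstep)
  ic <- interp3(volume$data, volume$spacing, volume$origin, pos)
  rad <- vapply(seq_len(n), function(i) {
    u1 <- perp[[1]][i, ]; u2 <- perp[[2]][i, ]
    rs <- numeric(0)
    bgs <- numeric(0)
    profs <- vector("list", nray)
    for (j in seq_len(nray)) {
      th <- 2 * pi * (j - 1) / nray
      d <- cos(th) * u1 + sin(th) * u2
      pts <- sweep(outer(ts, d), c(2), pos[i, ], "+")
      prof <- interp3(volume$data, volume$spacing, volume$origin, pts)
      profs[[j]] <- prof
      bgs <- c(bgs, prof[ts >= tmax - 1.5])
    }
    bg <- stats::quantile(bgs, 0.25, names = FALSE)
    half <- (ic[i] + bg) / 2
    for (j in seq_len(nray)) {
      prof <- profs[[j]]
      below <- which(prof < half)
      if (length(below) == 0) next
      k <- below[1]
      if (k == 1) { rs <- c(rs, ts[1]); next }
      frac <- (prof[k - 1] - half) / (prof[k - 1] - prof[k])
      rs <- c(rs, ts[k - 1] + frac * tstep)
    }
    if (length(rs) == 0) return(NA_real_)
    stats::median(rs)
  }, numeric(1))
  rad[is.na(rad)] <- nodes$radius[is.na(rad)]
  pmin(5, pmax(1, rad))
}

# trilinear interpolation of a 3D array at world positions (n x 3)
interp3 <- function(arr, spacing, origin, pts) {
  dm <- dim(arr)
  g <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") # 0-based voxel coords
  g <- pmin(pmax(g, 0), matrix(rep(dm - 1, each = nrow(g)), ncol = 3) - 1e-9)
  i0 <- floor(g); f <- g - i0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    ii <- pmin(i0[, 1] + dx + 1, dm[1])
    jj <- pmin(i0[, 2] + dy + 1, dm[2])
    kk <- pmin(i0[, 3] + dz + 1, dm[3])
    out <- out + w * arr[cbind(ii, jj, kk)]
  }
  out
}

#' Link candidate nodes into an optimized vessel forest
#'
#' Builds a k-nearest-neighbour candidate edge set over the detected maxima
#' and assigns each edge a cost combining four penalties: crossing lung
#' parenchyma (one minus the mean vesselness sampled along the straight
#' connection), direction change (angle between the edge and the node
#' orientations), relative diameter change, and length. Edges whose direction
#' change or diameter jump exceed the hard caps are inadmissible. A
#' minimum-cost spanning forest is extracted; tree edges costlier than
#' `edge_cost_threshold` are cut; the forest is decomposed into maximal
#' segments between branch points and leaves. Ties in edge cost are broken
#' deterministically by node-id pair.
#'
#' @param nodes Candidate tibble from [detect_maxima()].
#' @param field The `vesselness_field` (for the parenchyma term).
#' @param lungs Unused placeholder kept for interface symmetry (the response
#'   is already zero outside the lungs).
#' @param config Parameter list, see [default_config()].
#' @return A [vessel_graph()] with all segments labelled `"unknown"`.
#' @export
link_candidates <- function(nodes, field, lungs = NULL,
                            config = default_config()) {
  n <- nrow(nodes)
  if (n == 0) return(vessel_graph())
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  ori <- as.matrix(nodes[, c("ox", "oy", "oz")])
  rad <- nodes$radius

  # candidate edges: k nearest neighbours within max_edge_mm
  edges <- NULL
  if (n > 1) {
    d2 <- as.matrix(stats::dist(pos))^2
    diag(d2) <- Inf
    k <- min(config$knn, n - 1)
    cand <- lapply(seq_len(n), function(i) {
      nb <- order(d2[i, ])[seq_len(k)]
      nb <- nb[d2[i, nb] <= config$max_edge_mm^2]
      if (length(nb) == 0) return(NULL)
      cbind(pmin(i, nb), pmax(i, nb))
    })
    edges <- unique(do.call(rbind, cand))
  }
  if (is.null(edges) || nrow(edges) == 0) return(vessel_graph())

  a <- edges[, 1]; b <- edges[, 2]
  dvec <- pos[b, , drop = FALSE] - pos[a, , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  e <- dvec / len
  ang <- function(u, v) { # angle in degrees between an edge and an (axial) orientation
    d <- abs(rowSums(u * v))
    acos(pmin(1, d)) * 180 / pi
  }
  ang_a <- ang(e, ori[a, , drop = FALSE])
  ang_b <- ang(e, ori[b, , drop = FALSE])
  dir_change <- pmax(ang_a, ang_b)
  dia_jump <- abs(rad[a] - rad[b]) / pmax(rad[a], rad[b])
  # parenchyma term: mean response at interior sample points of the chord,
  # normalized by the endpoint node responses — a chord that stays on the
  # vessel keeps the local response level (term near 0), one that crosses
  # parenchyma drops to the background (term near 1)
  ts <- seq(0.15, 0.85, length.out = 5)
  resp_mean <- rowMeans(vapply(ts, function(t) {
    interp3(field$response, field$spacing, field$origin,
            pos[a, , drop = FALSE] + t * dvec)
  }, numeric(length(a))))
  node_resp <- (nodes$response[a] + nodes$response[b]) / 2
  par_term <- pmin(1, pmax(0, 1 - resp_mean / pmax(node_resp, 1e-9)))
  cost <- config$w_par * par_term +
    config$w_dir * ((ang_a + ang_b) / 2) / 90 +
    config$w_dia * dia_jump +
    config$w_len * len / 10
  admissible <- dir_change <= config$max_direction_change_deg &
    dia_jump <= config$max_diameter_jump
  keep <- which(admissible)
  if (length(keep) == 0) return(vessel_graph())
  a <- a[keep]; b <- b[keep]; cost <- cost[keep]

  mst <- min_spanning_forest(a, b, cost, n)
  ecost <- igraph::E(mst)$weight
  mst <- igraph::delete_edges(mst, which(ecost > config$edge_cost_threshold))
  mst <- prune_twigs(mst, pos, config$prune_twig_mm %||% 15)
  g <- forest_to_graph(mst, pos, rad)
  drop_short_components(g, config$min_component_mm %||% 12)
}

#' Minimum-cost spanning forest of a candidate edge set
#'
#' One minimum spanning tree per connected component of the candidate
#' graph; equal-cost edges are ordered deterministically by their node-id
#' pair (a tiny lexicographic perturbation far below any meaningful cost
#' difference). For small inputs an exhaustive search over spanning forests
#' serves as an oracle for this routine.
#'
#' @param a,b Integer endpoints of each candidate edge (1-based node ids).
#' @param cost Numeric edge costs.
#' @param n Number of nodes.
#' @return An igraph forest whose vertex names are the node ids.
#' @export
min_spanning_forest <- function(a, b, cost, n) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b,
               weight = cost + 1e-12 * (a * (n + 1) + b)),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  igraph::mst(ig, algorithm = "prim")
}

# iteratively remove short leaf twigs hanging off branch points: spurious
# side responses otherwise split a straight vessel into many segments
prune_twigs <- function(tree, pos, prune_mm) {
  repeat {
    deg <- igraph::degree(tree)
    leaves <- which(deg == 1)
    if (length(leaves) == 0) break
    drop <- integer(0)
    for (lf in leaves) {
      path <- lf
      v <- lf
      len <- 0
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(tree, v)), path)
        if (length(nb) == 0) { v <- NA; break }
        nxt <- nb[1]
        len <- len + sqrt(sum((pos[as.integer(igraph::V(tree)$name)[nxt], ] -
                               pos[as.integer(igraph::V(tree)$name)[v], ])^2))
        if (deg[nxt] >= 3) { v <- nxt; break }
        path <- c(path, nxt)
        v <- nxt
        if (len > prune_mm) break
      }
      if (!is.na(v) && deg[v] >= 3 && len <= prune_mm)
        drop <- union(drop, path)
    }
    if (length(drop) == 0) break
    tree <- igraph::delete_vertices(tree, drop)
  }
  tree
}

# Decompose a forest (igraph over node indices) into maximal segments
# between branch points (degree >= 3) and leaves; isolated nodes dropped.
forest_to_graph <- function(tree, pos, rad) {
  deg <- igraph::degree(tree)
  nm <- as.integer(igraph::V(tree)$name)
  segments <- list()
  adjacency <- data.frame(branch_id = integer(), seg_id = integer())
  visited_edge <- rep(FALSE, igraph::ecount(tree))
  seg_id <- 0L
  endpoints <- which(deg != 2)
  inc <- igraph::incident_edges(tree, igraph::V(tree))
  walk_from <- function(v_start, e_first) {
    # walk along degree-2 nodes until hitting a non-degree-2 node
    path_v <- c(v_start)
    e <- e_first
    v <- v_start
    repeat {
      visited_edge[e] <<- TRUE
      ends <- igraph::ends(tree, e, names = FALSE)
      v_next <- if (ends[1] == v) ends[2] else ends[1]
      path_v <- c(path_v, v_next)
      if (deg[v_next] != 2) break
      es <- as.integer(inc[[v_next]])
      e_next <- es[!visited_edge[es]]
      if (length(e_next) == 0) break
      e <- e_next[1]
      v <- v_next
    }
    path_v
  }
  for (v0 in endpoints) {
    es <- as.integer(inc[[v0]])
    for (e0 in es) {
      if (visited_edge[e0]) next
      path_v <- walk_from(v0, e0)
      seg_id <- seg_id + 1L
      pts <- pos[nm[path_v], , drop = FALSE]
      segments[[seg_id]] <- vessel_segment(pts, rad[nm[path_v]],
                                           label = "unknown", id = seg_id)
      for (endv in c(path_v[1], path_v[length(path_v)]))
        if (deg[endv] >= 3)
          adjacency <- rbind(adjacency,
                             data.frame(branch_id = nm[endv], seg_id = seg_id))
    }
  }
  # pure cycles cannot occur in a spanning forest; isolated nodes dropped
  # branch points that ended up with a single segment row (other edges cut)
  # are no longer branch points
  if (nrow(adjacency) > 0) {
    cnt <- table(adjacency$branch_id)
    adjacency <- adjacency[adjacency$branch_id %in%
                             as.integer(names(cnt)[cnt >= 2]), , drop = FALSE]
    rownames(adjacency) <- NULL
  }
  vessel_graph(segments, adjacency)
}

# remove connected components whose total centerline length is below
# min_mm: isolated chainlets from residual off-axis detections
drop_short_components <- function(g, min_mm) {
  if (length(g$segments) == 0 || min_mm <= 0) return(g)
  units <- group_subtrees(g)
  keep_ids <- integer(0)
  for (u in units) {
    segs <- g$segments[match(u$segment_ids,
                             vapply(g$segments, function(s) s$id, integer(1)))]
    total <- sum(vapply(segs, segment_length, numeric(1)))
    if (total >= min_mm) keep_ids <- c(keep_ids, u$segment_ids)
  }
  segs <- g$segments[vapply(g$segments, function(s) s$id, integer(1)) %in% keep_ids]
  adj <- g$adjacency[g$adjacency$seg_id %in% keep_ids, , drop = FALSE]
  vessel_graph(segs, adj, g$metadata)
}

#' Count vessel segments, in total and per diameter bin
#'
#' Bin membership uses the segment representative diameter
#' ([segment_diameter()]) against the half-open bins \[2,4), \[4,6) and
#' \[6,10\] mm (top edge closed).
#'
#' @param graph A [vessel_graph()].
#' @param by_bin If `TRUE`, return the per-bin counts as well.
#' @return Integer count, or a named vector `c(total, d2_4, d4_6, d6_10)`.
#' @export
count_segments <- function(graph, by_bin = FALSE) {
  n <- length(graph$segments)
  if (!by_bin) return(n)
  dia <- vapply(graph$segments, segment_diameter, numeric(1))
  c(total = n,
    d2_4 = sum(dia >= 2 & dia < 4),
    d4_6 = sum(dia >= 4 & dia < 6),
    d6_10 = sum(dia >= 6 & dia <= 10))
}

#' Diameter bin of a vessel diameter
#' @param diameter_mm Numeric vector of diameters (mm).
#' @return Factor with levels `2_4`, `4_6`, `6_10` (NA outside 2-10 mm).
#' @export
diameter_bin <- function(diameter_mm) {
  cut(diameter_mm, breaks = c(2, 4, 6, 10), labels = c("2_4", "4_6", "6_10"),
      right = FALSE, include.lowest = FALSE) -> f
  # top edge closed: diameter exactly 10 belongs to 6_10
  f[diameter_mm == 10] <- "6_10"
  f
}
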