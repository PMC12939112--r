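#' Vessel centerline segment
#'
#' An ordered polyline through a vessel in world coordinates (mm), with a
#' radius estimate at every point and an artery/vein/unknown label. Segments
#' are the unit of all counting and tortuosity statistics: a segment is a
#' maximal centerline path between branch points and/or endpoints.
#'
#' @param points m x 3 numeric matrix of positions (mm, world coordinates).
#' @param radii Numeric length m, per-point radius (mm). Vessels analysed by
#'   the pipeline lie in the 2-10 mm diameter range, i.e. radii in 1-5 mm.
#' @param label One of `"artery"`, `"vein"`, `"unknown"`.
#' @param id Integer segment id, unique within a graph.
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(points, radii, label = "unknown", id = 1L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("`points` must be an m x 3 matrix with m >= 2", call. = FALSE)
  radii <- as.numeric(radii)
  if (length(radii) != nrow(points))
    stop("`radii` must match the number of points", call. = FALSE)
  steps <- diff(points)
  if (any(rowSums(steps^2) == 0))
    stop("consecutive points must be distinct", call. = FALSE)
  if (!label %in% c("artery", "vein", "unknown"))
    stop("label must be artery, vein or unknown", call. = FALSE)
  structure(list(id = as.integer(id), points = unname(points),
                 radii = radii, label = label),
            class = "vessel_segment")
}

#' Total centerline length of a segment (mm)
#' @param seg A [vessel_segment()].
#' @return Scalar length in mm.
#' @export
segment_length <- function(seg) {
  sum(sqrt(rowSums(diff(seg$points)^2)))
}

#' Vessel graph (forest of centerline segments)
#'
#' @param segments List of [vessel_segment()]s with unique ids.
#' @param adjacency Data frame with columns `branch_id`, `seg_id`: each row
#'   records that a segment touches a branch point (a segment touches at most
#'   two branch points, one per end; a branch point joins at least two
#'   segments). The underlying centerline network must be a forest.
#' @param metadata Named list of provenance (scan id, parameters).
#' @return An object of class `vessel_graph`.
#' @export
vessel_graph <- function(segments = list(), adjacency = NULL, metadata = list()) {
  if (is.null(adjacency))
    adjacency <- data.frame(branch_id = integer(), seg_id = integer())
  g <- structure(list(segments = segments, adjacency = adjacency,
                      metadata = metadata),
                 class = "vessel_graph")
  validate_vessel_graph(g)
  g
}

#' Validate vessel-graph invariants
#'
#' Checks unique segment ids, per-segment invariants (>= 2 distinct points,
#' radii within the analysed 1-5 mm range), and that segment connectivity
#' forms a forest (no cycles).
#'
#' @param g A [vessel_graph()].
#' @param radius_range Allowed radius range in mm.
#' @return `g`, invisibly; errors describe the violated field.
#' @export
validate_vessel_graph <- function(g, radius_range = c(1, 5)) {
  ids <- vapply(g$segments, function(s) s$id, integer(1))
  if (anyDuplicated(ids)) stop("validation error: duplicate segment ids", call. = FALSE)
  for (s in g$segments) {
    if (nrow(s$points) < 2L)
      stop("validation error: segment ", s$id, ": fewer than 2 points", call. = FALSE)
    if (any(rowSums(diff(s$points)^2) == 0))
      stop("validation error: segment ", s$id, ": duplicate consecutive points",
           call. = FALSE)
    if (any(s$radii < radius_range[1] - 1e-6 | s$radii > radius_range[2] + 1e-6))
      stop("validation error: segment ", s$id, ": radii outside [",
           radius_range[1], ", ", radius_range[2], "] mm", call. = FALSE)
    if (!s$label %in% c("artery", "vein", "unknown"))
      stop("validation error: segment ", s$id, ": bad label", call. = FALSE)
  }
  adj <- g$adjacency
  if (nrow(adj) > 0) {
    if (!all(adj$seg_id %in% ids))
      stop("validation error: adjacency references unknown segment id", call. = FALSE)
    per_branch <- table(adj$branch_id)
    if (any(per_branch < 2))
      stop("validation error: branch point with fewer than 2 segments", call. = FALSE)
    per_seg <- table(adj$seg_id)
    if (any(per_seg > 2))
      stop("validation error: segment attached to more than 2 branch points",
           call. = FALSE)
    # underlying network: vertices are branch points plus one synthetic leaf
    # per unattached segment end; each segment is one edge -> must be acyclic
    edges <- character(0)
    leaf <- 0L
    for (sid in ids) {
      bs <- adj$branch_id[adj$seg_id == sid]
      ends <- as.character(bs)
      while (length(ends) < 2) {
        leaf <- leaf + 1L
        ends <- c(ends, paste0("leaf", leaf))
      }
      edges <- c(edges, paste0("b", ends[1]), paste0("b", ends[2]))
    }
    ig <- igraph::make_graph(edges, directed = FALSE)
    is_forest <- igraph::ecount(ig) ==
      igraph::vcount(ig) - igraph::count_components(ig)
    if (!is_forest)
      stop("validation error: connectivity contains a cycle (not a forest)",
           call. = FALSE)
  }
  invisible(g)
}

#' @export
print.vessel_graph <- function(x, ...) {
  labs <- vapply(x$segments, function(s) s$label, character(1))
  cat("<vessel_graph> ", length(x$segments), " segments (",
      sum(labs == "artery"), " artery / ", sum(labs == "vein"), " vein / ",
      sum(labs == "unknown"), " unknown), ",
      nrow(x$adjacency), " branch adjacencies\n", sep = "")
  invisible(x)
}

#' Per-segment summary of a vessel graph as a tibble
#'
#' @param x A [vessel_graph()].
#' @param ... Unused.
#' @return A tibble with one row per segment: id, label, number of points,
#'   centerline length (mm), representative diameter (mm) and SOAM
#'   tortuosity (rad/mm).
#' @export
as_tibble.vessel_graph <- function(x, ...) {
  tibble::tibble(
    id = vapply(x$segments, function(s) s$id, integer(1)),
    label = vapply(x$segments, function(s) s$label, character(1)),
    n_points = vapply(x$segments, function(s) nrow(s$points), integer(1)),
    length_mm = vapply(x$segments, segment_length, numeric(1)),
    diameter_mm = vapply(x$segments, segment_diameter, numeric(1)),
    soam = vapply(x$segments, soam, numeric(1))
  )
}

# ---- JSON serialization (versioned schema) ----

#' Write a vessel graph to JSON
#'
#' Versioned JSON schema (`pulmovasc-vessel-graph` v1) with full
#' double-precision coordinates so graphs round-trip losslessly.
#'
#' @param g A [vessel_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vessel_graph <- function(g, path) {
  validate_vessel_graph(g)
  doc <- list(
    format = "pulmovasc-vessel-graph",
    version = 1L,
    metadata = g$metadata,
    segments = lapply(g$segments, function(s) list(
      id = s$id, label = s$label,
      points = unname(apply(s$points, 1, function(p) as.list(p), simplify = FALSE)),
      radii = as.list(s$radii))),
    adjacency = if (nrow(g$adjacency) == 0) list() else
      lapply(seq_len(nrow(g$adjacency)), function(i) list(
        branch_id = g$adjacency$branch_id[i],
        seg_id = g$adjacency$seg_id[i]))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a vessel graph from JSON
#'
#' @param path Path to a graph written by [write_vessel_graph()].
#' @return A [vessel_graph()]; schema violations raise a validation error
#'   naming the offending field.
#' @export
read_vessel_graph <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "pulmovasc-vessel-graph")
    stop("validation error: field 'format' missing or wrong", call. = FALSE)
  segs <- lapply(doc$segments, function(s) {
    for (f in c("id", "label", "points", "radii"))
      if (is.null(s[[f]]))
        stop("validation error: segment missing field '", f, "'", call. = FALSE)
    pts <- do.call(rbind, lapply(s$points, function(p) unlist(p)))
    vessel_segment(pts, unlist(s$radii), label = s$label, id = s$id)
  })
  adj <- if (length(doc$adjacency) == 0)
    data.frame(branch_id = integer(), seg_id = integer())
  else do.call(rbind, lapply(doc$adjacency, function(a) {
    for (f in c("branch_id", "seg_id"))
      if (is.null(a[[f]]))
        stop("validation error: adjacency missing field '", f, "'", call. = FALSE)
    data.frame(branch_id = as.integer(a$branch_id),
               seg_id = as.integer(a$seg_id))
  }))
  md <- doc$metadata
  if (length(md) == 0) md <- list()
  vessel_graph(segs, adj, md)
}
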