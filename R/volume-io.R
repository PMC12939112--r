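#' CT volume container
#'
#' A minimal in-memory representation of a 3D CT scan: a numeric array of
#' Hounsfield units plus the voxel spacing and origin that map voxel indices
#' to world coordinates. All geometry in the package (lengths, radii, angles,
#' volumes) is computed in world millimetres via
#' `world = origin + (index - 1) * spacing`, never in voxel units, so that
#' anisotropic reconstructions (e.g. 0.5 mm in-plane increment with 1 mm
#' slices) are handled correctly.
#'
#' @param data 3D numeric array of attenuation values (HU).
#' @param spacing Numeric length-3, voxel spacing in mm along each array axis.
#' @param origin Numeric length-3, world position (mm) of the first voxel.
#' @param axis_order Tag recording the axis convention; the package uses
#'   `"xyz"` with axis 1 = left-right (lateral), axis 3 = inferior-superior.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      axis_order = "xyz") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L)) stop("each axis needs at least 2 voxels", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (any(!is.finite(data))) stop("`data` must be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_order = axis_order),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, HU range [", round(min(x$data)), ", ", round(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' Labelled mask volume aligned with a CT volume
#'
#' Integer labels over the same grid as a [ct_volume()]: 0 = background, with
#' the code meanings declared in `label_codes` (by default left lung, right
#' lung, airway).
#'
#' @param labels 3D integer array.
#' @param spacing,origin Geometry inherited from the companion CT volume.
#' @param label_codes Named integer vector declaring the legal codes.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        label_codes = c(background = 0L, lung_left = 1L,
                                        lung_right = 2L, airway = 3L)) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array", call. = FALSE)
  bad <- setdiff(unique(as.vector(labels)), unname(label_codes))
  if (length(bad) > 0)
    stop("mask contains undeclared label codes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label_codes = label_codes),
            class = "mask_volume")
}

#' Voxel volume in mm^3
#' @param x A `ct_volume` or `mask_volume`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

# ---- MetaImage (.mha/.mhd) ----

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0)
      stop("format error: no ElementDataFile key in MetaImage header", call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("format error: malformed header line: ", line, call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("format error: compressed MetaImage data not supported", call. = FALSE)
  if (is.null(hdr$DimSize)) stop("metadata error: DimSize missing", call. = FALSE)
  if (is.null(hdr$ElementSpacing))
    stop("metadata error: ElementSpacing missing", call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, length(dims))
  type <- hdr$ElementType %||% "MET_FLOAT"
  tinfo <- .met_types[[type]]
  if (is.null(tinfo)) stop("format error: unsupported ElementType ", type, call. = FALSE)
  n <- prod(dims)
  msb <- !is.null(hdr$BinaryDataByteOrderMSB) &&
    toupper(hdr$BinaryDataByteOrderMSB) == "TRUE"
  data_con <- con
  if (hdr$ElementDataFile != "LOCAL") {
    data_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(data_path))
      stop("format error: ElementDataFile not found: ", data_path, call. = FALSE)
    data_con <- file(data_path, "rb")
    on.exit(close(data_con), add = TRUE)
  }
  vals <- readBin(data_con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed,
                  endian = if (msb) "big" else "little")
  if (length(vals) < n)
    stop("format error: truncated MetaImage data (expected ", n,
         " elements, got ", length(vals), ")", call. = FALSE)
  ct_volume(array(as.numeric(vals), dim = dims), spacing = spacing,
            origin = origin)
}

write_mha <- function(vol, path, element_type = "MET_FLOAT") {
  tinfo <- .met_types[[element_type]]
  if (is.null(tinfo)) stop("unsupported ElementType ", element_type, call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(vol$origin, trim = TRUE), collapse = " ")),
           paste("ElementSpacing =",
                 paste(format(vol$spacing, trim = TRUE), collapse = " ")),
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementType =", element_type),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  vals <- as.vector(vol$data)
  if (tinfo$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = tinfo$size, endian = "little")
  invisible(path)
}

# ---- NIfTI via RNifti ----

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[1:3, 4])
  ct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = spacing,
            origin = origin)
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(img, reference = list(pixdim = c(-1, vol$spacing, rep(1, 4))))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT (or mask) volume from MetaImage or NIfTI
#'
#' Supports uncompressed MetaImage (`.mha`, `.mhd` + raw) and NIfTI
#' (`.nii`, `.nii.gz`). Spacing and origin are taken from the file's own
#' metadata and preserved exactly; voxel values are not rescaled.
#'
#' @param path Path to the volume file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(path)
  if (grepl("\\.(mha|mhd)$", ext)) read_mha(path)
  else if (grepl("\\.(nii|nii\\.gz)$", ext)) read_nifti_volume(path)
  else stop("format error: unrecognised volume extension for ", path, call. = FALSE)
}

#' Write a CT (or mask) volume
#'
#' @param vol A [ct_volume()] (a [mask_volume()] is converted on the fly).
#' @param path Destination: `.mha` (uncompressed MetaImage) or
#'   `.nii`/`.nii.gz`.
#' @param element_type MetaImage element type; the default `MET_DOUBLE`
#'   round-trips HU values losslessly (use `MET_SHORT` for compact masks).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, element_type = "MET_DOUBLE") {
  if (inherits(vol, "mask_volume"))
    vol <- ct_volume(array(as.numeric(vol$labels), dim = dim(vol$labels)),
                     spacing = vol$spacing, origin = vol$origin)
  ext <- tolower(path)
  if (grepl("\\.mha$", ext)) write_mha(vol, path, element_type)
  else if (grepl("\\.(nii|nii\\.gz)$", ext)) write_nifti_volume(vol, path)
  else stop("format error: unrecognised volume extension for ", path, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
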