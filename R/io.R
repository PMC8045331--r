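# NIfTI stores affines in RAS+ patient coordinates; the package convention
# is LPS (+x Left, +y Posterior, +z Superior), so the first two affine rows
# are negated on read and write.
.rasToLps <- diag(c(-1, -1, 1))

# Decompose a 4x4 LPS affine (0-based voxel indices -> mm) into
# spacing/origin/directions, snapping near-orthonormal direction matrices
# (float32 headers) to exact orthonormality via SVD.
.affineToGeometry <- function(aff, what) {
  A <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0))
    ctvStop("ctv_io_error", sprintf("%s: degenerate voxel spacing", what))
  R <- sweep(A, 2L, spacing, `/`)
  if (max(abs(crossprod(R) - diag(3))) > 1e-4)
    ctvStop("ctv_io_error",
            sprintf("%s: non-orthogonal axis directions are not supported", what))
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  list(spacing = spacing, origin = aff[1:3, 4], axisDirections = R)
}

.readNifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (RNifti::ndim(img) != 3L)
    ctvStop("ctv_io_error", sprintf("%s: expected a 3D volume", path))
  aff <- .rasToLps %*% structure(RNifti::xform(img), imagedim = NULL)[1:3, ]
  aff <- rbind(aff, c(0, 0, 0, 1))
  g <- .affineToGeometry(aff, path)
  arr <- array(as.vector(img) != 0, dim = dim(img))
  BinaryVolume(arr, g$spacing, g$origin, g$axisDirections)
}

# datatype 2 = uint8, 16 = float32 (NIfTI-1 codes)
.writeNifti <- function(arr, spacing, origin, axisDirections, path,
                        datatype) {
  img <- oro.nifti::nifti(arr, datatype = datatype)
  oro.nifti::pixdim(img)[2:4] <- spacing
  aff <- .rasToLps %*% cbind(axisDirections %*% diag(spacing), origin)
  img@sform_code <- 2L
  img@qform_code <- 0L
  img@srow_x <- aff[1, ]
  img@srow_y <- aff[2, ]
  img@srow_z <- aff[3, ]
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  oro.nifti::writeNIfTI(img, stem, gzipped = grepl("\\.gz$", path),
                        verbose = FALSE)
  invisible(path)
}

# ---- minimal NRRD codec (3D scalar volumes, raw/gzip encodings) ------------

.nrrdTypes <- list(
  uint8 = list(what = "integer", size = 1L, signed = FALSE),
  int8 = list(what = "integer", size = 1L, signed = TRUE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int16 = list(what = "integer", size = 2L, signed = TRUE),
  int32 = list(what = "integer", size = 4L, signed = TRUE),
  float = list(what = "double", size = 4L, signed = TRUE),
  double = list(what = "double", size = 8L, signed = TRUE)
)
.nrrdTypeAliases <- c(
  "unsigned char" = "uint8", uchar = "uint8", "signed char" = "int8",
  "unsigned short" = "uint16", short = "int16", "short int" = "int16",
  int = "int32", "signed int" = "int32", float = "float", double = "double",
  uint8 = "uint8", int8 = "int8", uint16 = "uint16", int16 = "int16",
  int32 = "int32", uint8_t = "uint8", int16_t = "int16", int32_t = "int32"
)

.parseNrrdVectors <- function(value) {
  m <- regmatches(value, gregexpr("\\(([^)]*)\\)", value))[[1]]
  vecs <- lapply(m, function(s)
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
  do.call(cbind, vecs)
}

.readNrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header and data are separated by the first blank line
  nl <- which(bytes == as.raw(10L))
  split <- NA_integer_
  for (i in seq_along(nl)[-1]) {
    if (nl[i] == nl[i - 1] + 1L ||
        (nl[i] == nl[i - 1] + 2L && bytes[nl[i] - 1L] == as.raw(13L))) {
      split <- nl[i]; break
    }
  }
  if (is.na(split))
    ctvStop("ctv_io_error", sprintf("%s: truncated NRRD header", path))
  lines <- strsplit(rawToChar(bytes[seq_len(split)]), "\r?\n")[[1]]
  raw <- bytes[seq.int(split + 1L, length(bytes))]
  if (!grepl("^NRRD000[1-5]$", lines[1]))
    ctvStop("ctv_io_error", sprintf("%s: not an NRRD file", path))
  fields <- list()
  for (line in lines[-1]) {
    if (!nzchar(line) || startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ?", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(fields$dimension) || as.integer(fields$dimension) != 3L)
    ctvStop("ctv_io_error", sprintf("%s: only 3D NRRD volumes are supported", path))
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  typeKey <- .nrrdTypeAliases[[tolower(fields$type)]]
  if (is.null(typeKey))
    ctvStop("ctv_io_error",
            sprintf("%s: unsupported NRRD type \"%s\"", path, fields$type))
  tp <- .nrrdTypes[[typeKey]]
  enc <- tolower(fields$encoding %||% "raw")
  if (enc %in% c("gzip", "gz")) raw <- memDecompress(raw, type = "gzip")
  else if (enc != "raw")
    ctvStop("ctv_io_error",
            sprintf("%s: unsupported NRRD encoding \"%s\"", path, enc))
  endian <- if (identical(fields$endian, "big")) "big" else "little"
  vals <- readBin(raw, tp$what, n = prod(sizes), size = tp$size,
                  signed = tp$signed, endian = endian)
  if (length(vals) < prod(sizes))
    ctvStop("ctv_io_error", sprintf("%s: NRRD data shorter than sizes", path))

  space <- tolower(fields$space %||% "left-posterior-superior")
  flip <- switch(space,
    "left-posterior-superior" = , lps = c(1, 1, 1),
    "right-anterior-superior" = , ras = c(-1, -1, 1),
    ctvStop("ctv_io_error",
            sprintf("%s: unsupported NRRD space \"%s\"", path, space)))
  A <- if (!is.null(fields$`space directions`))
    .parseNrrdVectors(fields$`space directions`) * flip else diag(3)
  origin <- if (!is.null(fields$`space origin`))
    as.numeric(.parseNrrdVectors(fields$`space origin`)) * flip else c(0, 0, 0)
  g <- .affineToGeometry(rbind(cbind(A, origin), c(0, 0, 0, 1)), path)
  BinaryVolume(array(vals != 0, dim = sizes), g$spacing, g$origin,
               g$axisDirections)
}

.writeNrrd <- function(arr, spacing, origin, axisDirections, path,
                       type = c("uint8", "float")) {
  type <- match.arg(type)
  A <- axisDirections %*% diag(spacing)
  vec <- function(v) sprintf("(%s)", paste(format(v, digits = 17),
                                           collapse = ","))
  header <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(arr), collapse = " ")),
    "space: left-posterior-superior",
    sprintf("space directions: %s %s %s", vec(A[, 1]), vec(A[, 2]),
            vec(A[, 3])),
    sprintf("space origin: %s", vec(origin)),
    "kinds: domain domain domain",
    "encoding: gzip",
    "endian: little",
    ""
  )
  payload <- if (type == "uint8")
    writeBin(as.integer(arr), raw(), size = 1L, endian = "little")
  else
    writeBin(as.double(arr), raw(), size = 4L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a binary mask volume
#'
#' Reads a NIfTI (\code{.nii}, \code{.nii.gz}) or NRRD (\code{.nrrd},
#' \code{.nhdr} with attached data) volume as a [BinaryVolume-class]. Any
#' nonzero voxel is foreground. Affines are converted from the file's
#' stored convention (RAS for NIfTI, declared \code{space} for NRRD) to the
#' package's LPS patient coordinates.
#'
#' @param path file path.
#' @return a [BinaryVolume-class].
#' @seealso [writeMask()]
#' @export
readMask <- function(path) {
  if (!file.exists(path))
    ctvStop("ctv_io_error", sprintf("file not found: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) .readNifti(path)
  else if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) .readNrrd(path)
  else ctvStop("ctv_io_error",
               sprintf("unrecognized volume format: %s (use .nii/.nii.gz/.nrrd)", path))
}

#' Write a binary mask volume
#'
#' Writes a [BinaryVolume-class] as unsigned 8-bit 0/1 voxels to NIfTI
#' (\code{.nii}, \code{.nii.gz}) or NRRD (\code{.nrrd}), with the LPS
#' geometry converted to the format's native convention.
#'
#' @param vol a [BinaryVolume-class].
#' @param path destination path; the extension selects the format.
#' @return the path, invisibly.
#' @seealso [readMask()]
#' @export
writeMask <- function(vol, path) {
  arr <- array(as.integer(vol@occupancy), dim = dim(vol@occupancy))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    .writeNifti(arr, vol@spacing, vol@origin, vol@axisDirections, path,
                datatype = 2L)
  else if (grepl("\\.nrrd$", path, ignore.case = TRUE))
    .writeNrrd(arr, vol@spacing, vol@origin, vol@axisDirections, path,
               type = "uint8")
  else ctvStop("ctv_io_error",
               sprintf("unrecognized volume format: %s (use .nii/.nii.gz/.nrrd)", path))
  invisible(path)
}

#' Write a STAPLE probability map
#'
#' Writes the voxel-wise posterior probabilities as a floating-point NIfTI
#' or NRRD volume on the consensus mask's grid.
#'
#' @param result a [StapleResult-class].
#' @param path destination path (\code{.nii}, \code{.nii.gz} or
#'   \code{.nrrd}).
#' @return the path, invisibly.
#' @export
writeProbabilityMap <- function(result, path) {
  vol <- result@consensusMask
  arr <- result@probabilityMap
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    .writeNifti(arr, vol@spacing, vol@origin, vol@axisDirections, path,
                datatype = 16L)
  else if (grepl("\\.nrrd$", path, ignore.case = TRUE))
    .writeNrrd(arr, vol@spacing, vol@origin, vol@axisDirections, path,
               type = "float")
  else ctvStop("ctv_io_error",
               sprintf("unrecognized volume format: %s", path))
  invisible(path)
}

#' Read planar contours
#'
#' Reads the package's plain-text planar-contour interchange format: a JSON
#' object \code{{"slices": [{"position": <mm>, "polygons": [[[x, y], ...],
#' ...]}, ...]}} with closed in-plane polygons in physical mm (LPS x/y) and
#' the slice position in mm along the slice axis. Any RT-STRUCT converter
#' can produce this neutral format.
#'
#' @param path JSON file path.
#' @return a list of slices suitable for [rasterizeContours()].
#' @export
readContours <- function(path) {
  if (!file.exists(path))
    ctvStop("ctv_io_error", sprintf("file not found: %s", path))
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  slices <- parsed$slices %||% parsed
  lapply(slices, function(s) list(
    position = as.numeric(s$position),
    polygons = lapply(s$polygons, function(p)
      do.call(rbind, lapply(p, as.numeric)))
  ))
}
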