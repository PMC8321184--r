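# File I/O: volumes and projection stacks travel as multi-page 32-bit float
# TIFF (one page per z-slice or per angle), geometry and parameters as JSON.
# No TIFF package is available in this stack, so a minimal reader/writer for
# uncompressed little-endian float TIFF (single strip per page) lives here.

#' Write a 3D array as a multi-page float32 TIFF
#'
#' One page per slice along the third axis; within a page the first array
#' axis runs along TIFF rows (width), the second along image length.
#' Uncompressed, little-endian, 32-bit IEEE float.
#'
#' @param x 3D numeric array, or a \linkS4class{VoxelVolume} /
#'   \linkS4class{ProjectionStack}.
#' @param path output file.
#' @export
writeTiffStack <- function(x, path) {
  if (is(x, "VoxelVolume") || is(x, "ProjectionStack")) x <- x@values
  d <- dim(x)
  if (length(d) != 3L) stop("need a 3D array")
  nu <- d[1]; nv <- d[2]; np <- d[3]
  stripSize <- nu * nv * 4L
  nEntry <- 10L
  ifdSize <- 2L + nEntry * 12L + 4L
  blockSize <- ifdSize + stripSize
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_len(np)) {
    ifdOff <- 8L + (p - 1L) * blockSize
    stripOff <- ifdOff + ifdSize
    writeBin(nEntry, con, size = 2, endian = "little")
    entry(256, 4, 1, nu)                 # ImageWidth
    entry(257, 4, 1, nv)                 # ImageLength
    entry(258, 3, 1, 32)                 # BitsPerSample
    entry(259, 3, 1, 1)                  # Compression: none
    entry(262, 3, 1, 1)                  # Photometric: BlackIsZero
    entry(273, 4, 1, stripOff)           # StripOffsets
    entry(277, 3, 1, 1)                  # SamplesPerPixel
    entry(278, 4, 1, nv)                 # RowsPerStrip
    entry(279, 4, 1, stripSize)          # StripByteCounts
    entry(339, 3, 1, 3)                  # SampleFormat: IEEE float
    nextIFD <- if (p < np) ifdOff + blockSize else 0L
    writeBin(as.integer(nextIFD), con, size = 4, endian = "little")
    writeBin(as.numeric(x[, , p]), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page float32 TIFF into a 3D array
#'
#' Supports the subset written by \code{\link{writeTiffStack}}: uncompressed
#' little-endian 32-bit float pages of equal size (one or more strips).
#'
#' @param path TIFF file.
#' @return 3D numeric array (width, length, pages).
#' @export
readTiffStack <- function(path) {
  if (!file.exists(path)) stop("no such TIFF file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF file: ", path)
  ifdOff <- u32(4)
  pages <- list()
  while (ifdOff != 0) {
    n <- u16(ifdOff)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifdOff + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      val <- if (type == 3L) u16(e + 8) else u32(e + 8)
      # multi-valued offsets: record position for indirect reads
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, pos = e + 8)
    }
    gv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      t$value
    }
    if (gv(259, 1L) != 1L) stop("compressed TIFF not supported: ", path)
    if (gv(258, 1L) != 32L || gv(339, 1L) != 3L)
      stop("non-float pixel data (need 32-bit IEEE float): ", path)
    w <- gv(256); h <- gv(257)
    so <- tags[["273"]]; sc <- tags[["279"]]
    if (is.null(so)) stop("malformed TIFF: no strip offsets")
    readVals <- function(t) {
      if (t$count == 1L) return(t$value)
      sz <- if (t$type == 3L) 2L else 4L
      vapply(seq_len(t$count) - 1L, function(k)
        if (sz == 2L) u16(t$value + 2L * k) else u32(t$value + 4L * k),
        numeric(1))
    }
    offs <- readVals(so)
    cnts <- if (is.null(sc)) w * h * 4 / length(offs) else readVals(sc)
    vals <- unlist(lapply(seq_along(offs), function(k)
      readBin(raw[(offs[k] + 1):(offs[k] + cnts[k])], "numeric",
              n = cnts[k] / 4, size = 4, endian = "little")))
    if (length(vals) != w * h) stop("malformed TIFF: wrong strip size")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = w)
    ifdOff <- u32(ifdOff + 2 + 12 * n)
  }
  d1 <- dim(pages[[1]])
  array(unlist(pages), dim = c(d1[1], d1[2], length(pages)))
}

#' Geometry JSON serialization
#'
#' Keys: source_to_center_mm, center_to_detector_mm, detector_pixel_size_mm,
#' n_voxels, voxel_size_mm, angles_rad. Detector pixel counts live in the
#' TIFF pages and are supplied separately when reading.
#'
#' @param geometry a \linkS4class{ConeBeamGeometry}.
#' @param path output file.
#' @export
writeGeometryJSON <- function(geometry, path) {
  x <- list(source_to_center_mm = geometry@sourceToCenter,
            center_to_detector_mm = geometry@centerToDetector,
            detector_pixel_size_mm = geometry@detectorPixelSize,
            n_voxels = geometry@nVoxels,
            voxel_size_mm = geometry@voxelSize,
            angles_rad = geometry@angles)
  writeLines(jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname writeGeometryJSON
#' @param detectorPixels \code{c(rows, cols)} from the projection pages.
#' @export
readGeometryJSON <- function(path, detectorPixels = NULL) {
  if (!file.exists(path)) stop("missing geometry sidecar: ", path)
  x <- jsonlite::fromJSON(path)
  need <- c("source_to_center_mm", "center_to_detector_mm",
            "detector_pixel_size_mm", "n_voxels", "voxel_size_mm",
            "angles_rad")
  if (!all(need %in% names(x)))
    stop("geometry JSON lacks keys: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (is.null(detectorPixels)) detectorPixels <- rep(x$n_voxels, 2L)
  coneBeamGeometry(x$source_to_center_mm, x$center_to_detector_mm,
                   detectorPixels, x$detector_pixel_size_mm, x$n_voxels,
                   x$voxel_size_mm, angles = x$angles_rad)
}

#' Write / read a projection stack with its geometry sidecar
#'
#' The stack goes to \code{<path>} as multi-page float TIFF (one page per
#' angle) and the geometry to \code{<path minus extension>.json}. Reading
#' validates that the page count matches the sidecar's angle list.
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param path TIFF path.
#' @export
writeProjectionStack <- function(proj, path) {
  writeTiffStack(proj@values, path)
  writeGeometryJSON(proj@geometry, .sidecarPath(path))
  invisible(path)
}

#' @rdname writeProjectionStack
#' @return \code{readProjectionStack}: a \linkS4class{ProjectionStack} (the
#'   geometry is in \code{geometry(x)}).
#' @export
readProjectionStack <- function(path) {
  vals <- readTiffStack(path)
  g <- readGeometryJSON(.sidecarPath(path),
                        detectorPixels = c(dim(vals)[2], dim(vals)[1]))
  if (dim(vals)[3] != length(g@angles))
    stop("TIFF has ", dim(vals)[3], " pages but the sidecar lists ",
         length(g@angles), " angles")
  projectionStack(vals, g)
}

.sidecarPath <- function(path) sub("\\.[^.]+$", ".json", path)

#' Generate a self-consistent experiment fixture
#'
#' Writes a complete small scene into a directory: ground-truth phantom
#' (TIFF), noisy projections (TIFF + geometry JSON), the phantom description
#' and the resolved configuration (JSON). Deterministic given the seed.
#'
#' @param dir output directory (created if needed).
#' @param scale "tiny" (N = 32) or "small" (N = 64).
#' @param seed RNG seed (phantom and noise).
#' @param nAngles,I0 acquisition settings.
#' @return the directory, invisibly.
#' @export
makeFixture <- function(dir, scale = c("tiny", "small"), seed = 1L,
                        nAngles = 32L, I0 = 1024) {
  scale <- match.arg(scale)
  N <- if (scale == "tiny") 32L else 64L
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- fourshapeRandom(seed)
  vol <- voxelize(spec, N)
  g <- simGeometry(N, nAngles)
  proj <- simulateProjections(vol, g, I0 = I0, seed = seed + 1L)
  writeTiffStack(vol@values, file.path(dir, "phantom.tif"))
  writeProjectionStack(proj, file.path(dir, "projections.tif"))
  cfg <- list(scale = scale, n = N, n_angles = nAngles, i0 = I0, seed = seed,
              family = "fourshape", mu_base = .MU_PLASTIC,
              cube_mm = .CUBE_MM)
  writeLines(jsonlite::toJSON(cfg, digits = I(17), auto_unbox = TRUE),
             file.path(dir, "config.json"))
  writeLines(.specToJSON(spec), file.path(dir, "phantom_spec.json"))
  invisible(dir)
}

.specToJSON <- function(spec) {
  jsonlite::toJSON(list(family = spec@family, primitives = spec@primitives),
                   digits = I(17), auto_unbox = TRUE)
}
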