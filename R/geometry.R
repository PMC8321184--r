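#' Construct a circular cone-beam geometry
#'
#' @param sourceToCenter source to rotation-centre distance (mm).
#' @param centerToDetector rotation-centre to detector distance (mm).
#' @param detectorPixels detector grid \code{c(rows, cols)}.
#' @param detectorPixelSize pixel pitch (mm).
#' @param nVoxels N; the reconstruction volume is N x N x N.
#' @param voxelSize voxel pitch (mm).
#' @param angles rotation angles (radians, strictly increasing in
#'   \code{[0, 2*pi)}); if \code{NULL}, \code{nAngles} equidistant angles over
#'   a full circle.
#' @param nAngles number of equidistant angles when \code{angles} is NULL.
#' @return a \linkS4class{ConeBeamGeometry}.
#' @examples
#' g <- coneBeamGeometry(1000, 500, c(32, 32), 6, 32, 3, nAngles = 24)
#' magnification(g)
#' @export
coneBeamGeometry <- function(sourceToCenter, centerToDetector, detectorPixels,
                             detectorPixelSize, nVoxels, voxelSize,
                             angles = NULL, nAngles = 360L) {
  if (is.null(angles))
    angles <- seq(0, 2 * pi, length.out = nAngles + 1L)[seq_len(nAngles)]
  new("ConeBeamGeometry",
      sourceToCenter = as.numeric(sourceToCenter),
      centerToDetector = as.numeric(centerToDetector),
      detectorPixels = as.integer(rep_len(detectorPixels, 2L)),
      detectorPixelSize = as.numeric(detectorPixelSize),
      nVoxels = as.integer(nVoxels),
      voxelSize = as.numeric(voxelSize),
      angles = as.numeric(angles))
}

#' Default desk-scale simulation geometry
#'
#' Geometry used by the phantom simulations: the phantom cube is 10 cm wide
#' (voxel pitch 100/N mm), the source sits at ten object widths (1 m) from the
#' rotation centre and the detector 0.5 m behind it (magnification 1.5). The
#' detector is N x N with a pitch of 1.25 x magnification x voxelSize, which
#' covers the magnified cube with margin for every primitive inside the
#' field-of-view sphere. The half cone angle is about 3 degrees.
#'
#' @param N volume and detector size.
#' @param nAngles number of equidistant projection angles.
#' @param sourceToCenter,centerToDetector override distances (mm).
#' @return a \linkS4class{ConeBeamGeometry}.
#' @export
simGeometry <- function(N, nAngles = 360L, sourceToCenter = 1000,
                        centerToDetector = 500) {
  vs <- 100 / N
  mag <- (sourceToCenter + centerToDetector) / sourceToCenter
  coneBeamGeometry(sourceToCenter, centerToDetector, c(N, N),
                   1.25 * mag * vs, N, vs, nAngles = nAngles)
}

#' @describeIn coneBeamGeometry geometric magnification D / sourceToCenter.
#' @param geometry a \linkS4class{ConeBeamGeometry}.
#' @export
magnification <- function(geometry) {
  (geometry@sourceToCenter + geometry@centerToDetector) / geometry@sourceToCenter
}

#' Wrap an array as a VoxelVolume
#' @param values cubic 3D array of attenuation values (1/cm).
#' @param voxelSize voxel pitch (mm).
#' @export
voxelVolume <- function(values, voxelSize) {
  if (is.null(dim(values))) {
    n <- round(length(values)^(1 / 3))
    dim(values) <- c(n, n, n)
  }
  new("VoxelVolume", values = values, voxelSize = as.numeric(voxelSize))
}

#' Wrap an array as a ProjectionStack
#' @param values array, dim \code{c(nu, nv, nAngles)}.
#' @param geometry matching \linkS4class{ConeBeamGeometry}.
#' @export
projectionStack <- function(values, geometry) {
  new("ProjectionStack", values = values, geometry = geometry)
}

#' @rdname values
#' @aliases values,VoxelVolume-method
setMethod("values", "VoxelVolume", function(x) x@values)
#' Extract raw values from volumes and projection stacks
#' @param x a \linkS4class{VoxelVolume} or \linkS4class{ProjectionStack}.
#' @rdname values
#' @export
setMethod("values", "ProjectionStack", function(x) x@values)

#' @export
setMethod("geometry", "ProjectionStack", function(x) x@geometry)
#' @export
setMethod("angles", "ConeBeamGeometry", function(x) x@angles)
#' @export
setMethod("angles", "ProjectionStack", function(x) x@geometry@angles)
#' @export
setMethod("nVoxels", "ConeBeamGeometry", function(x) x@nVoxels)
#' @export
setMethod("nVoxels", "VoxelVolume", function(x) dim(x@values)[1])
#' @export
setMethod("voxelSize", "ConeBeamGeometry", function(x) x@voxelSize)
#' @export
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)

setMethod("show", "ConeBeamGeometry", function(object) {
  cat("ConeBeamGeometry\n",
      sprintf("  source-centre %.1f mm, centre-detector %.1f mm (mag %.2f)\n",
              object@sourceToCenter, object@centerToDetector,
              magnification(object)),
      sprintf("  detector %d x %d px @ %.3f mm; volume %d^3 @ %.3f mm\n",
              object@detectorPixels[1], object@detectorPixels[2],
              object@detectorPixelSize, object@nVoxels, object@voxelSize),
      sprintf("  %d angles in [%.3f, %.3f] rad\n", length(object@angles),
              min(object@angles), max(object@angles)), sep = "")
})

setMethod("show", "VoxelVolume", function(object) {
  v <- object@values
  cat(sprintf("VoxelVolume %d^3 @ %.3f mm, range [%.4g, %.4g] 1/cm\n",
              dim(v)[1], object@voxelSize, min(v), max(v)))
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProjectionStack %d x %d px, %d angles, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(object@values), max(object@values)))
})

# shared shape checks -------------------------------------------------------

.checkVolGeom <- function(vol, geometry) {
  if (!is(vol, "VoxelVolume")) stop("expected a VoxelVolume")
  if (dim(vol@values)[1] != geometry@nVoxels)
    stop("volume shape does not match geometry: N = ", dim(vol@values)[1],
         " vs ", geometry@nVoxels)
  if (abs(vol@voxelSize - geometry@voxelSize) > 1e-9)
    stop("volume voxel size does not match geometry")
  invisible(TRUE)
}

.checkProjGeom <- function(proj, geometry) {
  if (!is(proj, "ProjectionStack")) stop("expected a ProjectionStack")
  d <- dim(proj@values)
  if (d[1] != geometry@detectorPixels[2] || d[2] != geometry@detectorPixels[1] ||
      d[3] != length(geometry@angles))
    stop("projection stack shape does not match geometry")
  invisible(TRUE)
}
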