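#' Circular cone-beam scan geometry
#'
#' Describes a circular cone-beam acquisition: a point source and a flat
#' detector rotating around the reconstruction volume. The volume is an
#' \code{N x N x N} voxel cube centred on the rotation axis; world coordinates
#' place sample points at cell centres and the rotation centre at the origin.
#' Detector rows are axial (v), columns transaxial (u), with u = v = 0 at the
#' detector centre. All lengths are millimetres.
#'
#' @slot sourceToCenter distance from the source to the rotation centre (mm).
#' @slot centerToDetector distance from the rotation centre to the detector (mm).
#' @slot detectorPixels integer vector \code{c(rows, cols)}.
#' @slot detectorPixelSize detector pixel pitch (mm), square pixels.
#' @slot nVoxels N, the volume is N x N x N.
#' @slot voxelSize voxel pitch (mm).
#' @slot angles rotation angles in radians, strictly increasing in [0, 2*pi).
#'
#' @section Validity:
#' Construction fails unless the detector covers the magnified volume
#' footprint, i.e. \code{magnification * N * voxelSize} fits inside the
#' detector extent in both directions, where magnification is
#' (sourceToCenter + centerToDetector) / sourceToCenter.
#'
#' @export
setClass("ConeBeamGeometry",
  representation(
    sourceToCenter = "numeric",
    centerToDetector = "numeric",
    detectorPixels = "integer",
    detectorPixelSize = "numeric",
    nVoxels = "integer",
    voxelSize = "numeric",
    angles = "numeric"
  )
)

setValidity("ConeBeamGeometry", function(object) {
  msg <- character(0)
  if (object@sourceToCenter <= 0)
    msg <- c(msg, "sourceToCenter must be > 0")
  if (object@centerToDetector < 0)
    msg <- c(msg, "centerToDetector must be >= 0")
  if (length(object@detectorPixels) != 2L || any(object@detectorPixels < 1L))
    msg <- c(msg, "detectorPixels must be two positive counts (rows, cols)")
  if (object@detectorPixelSize <= 0) msg <- c(msg, "detectorPixelSize must be > 0")
  if (object@nVoxels < 2L) msg <- c(msg, "nVoxels must be >= 2")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  a <- object@angles
  if (length(a) < 1L) msg <- c(msg, "need at least one angle")
  if (any(a < 0) || any(a >= 2 * pi))
    msg <- c(msg, "angles must lie in [0, 2*pi)")
  if (length(a) > 1L && any(diff(a) <= 0))
    msg <- c(msg, "angles must be strictly increasing")
  mag <- (object@sourceToCenter + object@centerToDetector) / object@sourceToCenter
  footprint <- mag * object@nVoxels * object@voxelSize
  extent <- object@detectorPixels * object@detectorPixelSize
  if (any(footprint > extent + 1e-9))
    msg <- c(msg, sprintf(
      "detector does not cover the projected volume (need %.1f mm, have %.1f x %.1f mm)",
      footprint, extent[1], extent[2]))
  if (length(msg)) msg else TRUE
})

#' Reconstruction volume
#'
#' An \code{N x N x N} array of attenuation values (1/cm) with its voxel pitch
#' (mm). The cube is centred on the rotation axis.
#'
#' @slot values numeric array, dim \code{c(N, N, N)}, indexed (x, y, z).
#' @slot voxelSize voxel pitch (mm).
#' @export
setClass("VoxelVolume",
  representation(values = "array", voxelSize = "numeric")
)

setValidity("VoxelVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || length(unique(d)) != 1L)
    return("values must be a cubic 3D array")
  if (!all(is.finite(object@values))) return("values must be finite")
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  TRUE
})

#' Cone-beam projection stack
#'
#' Line integrals (dimensionless, i.e. -ln(I/I0)) for every angle of a
#' \linkS4class{ConeBeamGeometry}, stored as an array with dim
#' \code{c(cols, rows, nAngles)} (u fastest).
#'
#' @slot values numeric array, dim \code{c(nu, nv, Na)}.
#' @slot geometry the \linkS4class{ConeBeamGeometry} the data belong to.
#' @export
setClass("ProjectionStack",
  representation(values = "array", geometry = "ConeBeamGeometry")
)

setValidity("ProjectionStack", function(object) {
  d <- dim(object@values)
  g <- object@geometry
  if (length(d) != 3L) return("values must be a 3D array (u, v, angle)")
  if (d[1] != g@detectorPixels[2] || d[2] != g@detectorPixels[1])
    return("detector dimensions do not match the geometry")
  if (d[3] != length(g@angles))
    return("first... angle axis length must equal the number of angles")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' Spatial-domain FDK filter
#'
#' A one-dimensional reconstruction filter h of length 2N (N = detector
#' columns), stored as spatial-domain taps centred at index N + 1.
#'
#' @slot taps numeric vector of length 2N.
#' @slot name label, e.g. "ram-lak", "hann", "binned".
#' @export
setClass("Filter1D", representation(taps = "numeric", name = "character"))

setValidity("Filter1D", function(object) {
  if (!all(is.finite(object@taps))) return("taps must be finite")
  if (length(object@taps) %% 2L != 0L) return("taps must have even length 2N")
  TRUE
})

#' Exponential binning operator
#'
#' Maps Ne coefficients to a length-2N spatial filter by piecewise-constant
#' expansion. Bins are symmetric about the filter centre; radial widths grow
#' as 1, 1, 1, 1, 2, 4, 8, ... (doubling), truncated at radius N, and the two
#' mirror-image bins at equal distance are merged, so Ne grows like log2(N).
#'
#' @slot n N (filter length is 2N).
#' @slot ne number of bins Ne.
#' @slot binIndex integer vector of length 2N assigning each tap to a bin.
#' @export
setClass("BinningOperator",
  representation(n = "integer", ne = "integer", binIndex = "integer")
)

setValidity("BinningOperator", function(object) {
  if (length(object@binIndex) != 2L * object@n)
    return("binIndex must have length 2N")
  if (!identical(sort(unique(object@binIndex)), seq_len(object@ne)))
    return("binIndex must use every bin 1..Ne")
  TRUE
})

#' Binned filter coefficients
#'
#' The Ne coefficients h_e of an exponentially binned filter; the full filter
#' is recovered with \code{\link{expandFilter}}.
#'
#' @slot coefficients numeric vector of length Ne.
#' @export
setClass("BinnedFilter", representation(coefficients = "numeric"))

setValidity("BinnedFilter", function(object) {
  if (!all(is.finite(object@coefficients))) return("coefficients must be finite")
  TRUE
})

#' NN-FDK parameter set
#'
#' All trainable parameters of the NN-FDK network together with the input and
#' target scalings needed to apply it to raw feature values and to map the
#' sigmoid output back to grey values. The hidden layer has Nh nodes, each a
#' binned filter plus bias; the output perceptron has Nh weights and a bias.
#' The parameter count is (Ne + 2) * Nh + 1.
#'
#' @slot binning the shared \linkS4class{BinningOperator}.
#' @slot hiddenFilters Ne x Nh matrix, column k the binned filter of node k.
#' @slot hiddenBiases numeric length Nh.
#' @slot outputWeights numeric length Nh.
#' @slot outputBias numeric scalar.
#' @slot inputScale,inputOffset per-feature affine scaling applied to network
#'   inputs: scaled = (raw - inputOffset) * inputScale.
#' @slot targetScale,targetOffset affine map taking grey values into (0, 1):
#'   scaled = grey * targetScale + targetOffset; inverted after reconstruction.
#' @export
setClass("NNFDKParams",
  representation(
    binning = "BinningOperator",
    hiddenFilters = "matrix",
    hiddenBiases = "numeric",
    outputWeights = "numeric",
    outputBias = "numeric",
    inputScale = "numeric",
    inputOffset = "numeric",
    targetScale = "numeric",
    targetOffset = "numeric"
  )
)

setValidity("NNFDKParams", function(object) {
  ne <- object@binning@ne
  nh <- ncol(object@hiddenFilters)
  msg <- character(0)
  if (nh < 1L) msg <- c(msg, "need at least one hidden node")
  if (nrow(object@hiddenFilters) != ne)
    msg <- c(msg, "hiddenFilters must have Ne rows")
  if (length(object@hiddenBiases) != nh || length(object@outputWeights) != nh)
    msg <- c(msg, "biases/output weights must have length Nh")
  if (length(object@outputBias) != 1L) msg <- c(msg, "outputBias must be scalar")
  if (length(object@inputScale) != ne || length(object@inputOffset) != ne)
    msg <- c(msg, "input scaling must have length Ne")
  if (length(object@targetScale) != 1L || object@targetScale == 0)
    msg <- c(msg, "targetScale must be a nonzero scalar")
  if (length(msg)) msg else TRUE
})

#' Training or validation pair set
#'
#' Rows of the feature matrix (raw, unscaled FDK feature values) with their
#' scaled high-quality target voxel values and provenance.
#'
#' @slot inputs n x Ne matrix of raw feature vectors Z.
#' @slot targets numeric length n, target voxel values O (already scaled into
#'   (0, 1) by the caller's target scaling).
#' @slot provenance data.frame with columns \code{dataset} and \code{voxel}.
#' @export
setClass("TrainingSet",
  representation(inputs = "matrix", targets = "numeric", provenance = "data.frame")
)

setValidity("TrainingSet", function(object) {
  n <- nrow(object@inputs)
  if (length(object@targets) != n) return("targets length must match inputs rows")
  if (nrow(object@provenance) != n) return("provenance must have one row per pair")
  if (anyDuplicated(object@provenance)) return("pairs must be unique")
  TRUE
})

#' Phantom description
#'
#' A list of geometric primitives (ellipsoid, cuboid, gaussian_blob,
#' siemens_star, disk) in a unit cube centred at the origin; intensities are
#' relative and additive, and are mapped to attenuation by
#' \code{\link{voxelize}}.
#'
#' @slot primitives list; each element has fields kind, center, size, orient
#'   (3 x 3 rotation), intensity.
#' @slot family label ("fourshape", "defrise", ...).
#' @export
setClass("PhantomSpec", representation(primitives = "list", family = "character"))
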