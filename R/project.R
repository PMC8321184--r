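# Projection operators. The forward projector is ray-driven (Joseph-style
# trilinear sampling along each source-pixel ray); backProject() is its exact
# transpose, so the pair passes adjoint dot-product tests to machine precision
# and is the pair used by SIRT. The FDK backprojector is voxel-driven with
# bilinear detector interpolation, which is the standard choice for filtered
# backprojection and much faster, but is not the exact transpose.

.STEP_FRAC <- 0.5  # ray sampling step as a fraction of the voxel size

#' Cone-beam forward projection
#'
#' Computes line integrals W x of a volume along every source-to-pixel ray.
#' Lengths are integrated in cm so that a phantom in 1/cm gives dimensionless
#' -ln(I/I0) values.
#'
#' @param vol a \linkS4class{VoxelVolume}.
#' @param geometry a \linkS4class{ConeBeamGeometry} consistent with \code{vol}.
#' @param stepFrac ray sampling step, as a fraction of the voxel size.
#' @return a \linkS4class{ProjectionStack}.
#' @export
setMethod("forwardProject", signature("VoxelVolume", "ConeBeamGeometry"),
  function(vol, geometry, stepFrac = .STEP_FRAC) {
    .checkVolGeom(vol, geometry)
    g <- geometry
    p <- cpp_forward_project(as.numeric(vol@values), g@nVoxels, g@voxelSize,
                             g@angles, g@detectorPixels[2], g@detectorPixels[1],
                             g@detectorPixelSize, g@sourceToCenter,
                             g@centerToDetector, stepFrac)
    projectionStack(p, g)
  })

#' Plain backprojection (exact transpose of the forward projector)
#'
#' Computes W^T y for the matched discretization: the same rays and sample
#' weights as \code{\link{forwardProject}}, applied in scatter form. Used by
#' the SIRT baseline and adjoint tests. \code{method = "voxel"} instead gives
#' an unweighted voxel-driven backprojection with bilinear detector
#' interpolation (the FDK discretization without the distance weight).
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param geometry geometry; defaults to the stack's own.
#' @param method "matched" (transpose of forwardProject) or "voxel".
#' @param stepFrac ray sampling step for the matched method.
#' @return a \linkS4class{VoxelVolume}.
#' @export
setMethod("backProject", "ProjectionStack",
  function(proj, geometry = NULL, method = c("matched", "voxel"),
           stepFrac = .STEP_FRAC) {
    method <- match.arg(method)
    if (is.null(geometry)) geometry <- proj@geometry
    .checkProjGeom(proj, geometry)
    g <- geometry
    v <- if (method == "matched") {
      cpp_backproject_matched(as.numeric(proj@values), g@nVoxels, g@voxelSize,
                              g@angles, g@detectorPixels[2], g@detectorPixels[1],
                              g@detectorPixelSize, g@sourceToCenter,
                              g@centerToDetector, stepFrac)
    } else {
      cpp_backproject_voxel(as.numeric(proj@values), g@nVoxels, g@voxelSize,
                            g@angles, g@detectorPixels[2], g@detectorPixels[1],
                            g@detectorPixelSize, g@sourceToCenter,
                            g@centerToDetector, FALSE)
    }
    voxelVolume(v, g@voxelSize)
  })

#' FDK-weighted backprojection
#'
#' Voxel-driven backprojection with bilinear detector interpolation and the
#' Feldkamp distance weight (D / (D + s))^2, where s is the voxel coordinate
#' along the source-to-centre axis (weight 1 on the rotation axis). The FDK
#' normalization constants (angular step and virtual detector pitch) are
#' folded into this step so that learned filters stay comparable across
#' angle counts; pass \code{normalize = FALSE} for the raw weighted sum.
#'
#' @param proj a \linkS4class{ProjectionStack} (normally already reweighted
#'   and filtered).
#' @param geometry geometry; defaults to the stack's own.
#' @param normalize multiply by pi / Na times the virtual detector pitch (cm).
#' @return a \linkS4class{VoxelVolume}.
#' @export
setMethod("fdkWeightedBackproject", "ProjectionStack",
  function(proj, geometry = NULL, normalize = TRUE) {
    if (is.null(geometry)) geometry <- proj@geometry
    .checkProjGeom(proj, geometry)
    g <- geometry
    v <- cpp_backproject_voxel(as.numeric(proj@values), g@nVoxels, g@voxelSize,
                               g@angles, g@detectorPixels[2],
                               g@detectorPixels[1], g@detectorPixelSize,
                               g@sourceToCenter, g@centerToDetector, TRUE)
    if (normalize) v <- v * .fdkNorm(g)
    voxelVolume(v, g@voxelSize)
  })

# angular step over the half-scan redundancy of the full circle. The virtual
# detector pitch does not appear here: the standard filters are constructed on
# the DFT frequency grid in physical units (cycles/cm of the isocentre pitch),
# which already carries the 1/pitch of the convolution-integral discretization.
.fdkNorm <- function(g) {
  pi / length(g@angles)
}
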