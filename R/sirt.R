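# SIRT with a nonnegativity constraint: the classical simultaneous iterative
# scheme x <- max(0, x + C W' R (y - W x)) with R and C the inverse row and
# column sums of the system matrix. Uses the matched (adjoint-consistent)
# projector pair, as SIRT convergence theory assumes the true transpose.

#' SIRT reconstruction with nonnegativity constraint
#'
#' Runs \code{nIter} SIRT iterations from x0 = 0, projecting onto the
#' nonnegative orthant after every update (disable with
#' \code{nonneg = FALSE}). Row/column sums are computed by projecting
#' all-ones volumes/data; their inverses are zeroed where a ray or voxel is
#' never touched. The per-iteration data residual norms ||y - W x|| are
#' attached as attribute \code{"residuals"} of the returned volume's values.
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param geometry geometry; defaults to the stack's own.
#' @param nIter number of iterations (paper-style defaults: 200 for
#'   low-angle/high-dose problems, 20 for low-dose).
#' @param nonneg apply the nonnegativity projection each iteration.
#' @return a \linkS4class{VoxelVolume} with attribute \code{"residuals"}.
#' @export
sirtPlus <- function(proj, geometry = NULL, nIter = 200L,
                     nonneg = TRUE) {
  if (nIter < 1L) stop("nIter must be >= 1")
  if (is.null(geometry)) geometry <- proj@geometry
  .checkProjGeom(proj, geometry)
  g <- geometry
  Wfun <- function(x) forwardProject(voxelVolume(x, g@voxelSize), g)@values
  Wtfun <- function(y) backProject(projectionStack(y, g), g,
                                   method = "matched")@values
  fit <- .sirtCore(Wfun, Wtfun, proj@values,
                   dim = rep(g@nVoxels, 3L), nIter = nIter, nonneg = nonneg)
  out <- voxelVolume(fit$x, g@voxelSize)
  attr(out@values, "residuals") <- fit$residuals
  out
}

# operator-level core, also exercised directly on tiny abstract systems
.sirtCore <- function(Wfun, Wtfun, y, dim, nIter, nonneg = TRUE) {
  ones_x <- array(1, dim)
  rowsum <- Wfun(ones_x)
  R <- ifelse(rowsum > 1e-12, 1 / rowsum, 0)
  ones_y <- array(1, dim(y))
  colsum <- Wtfun(ones_y)
  C <- ifelse(colsum > 1e-12, 1 / colsum, 0)
  x <- array(0, dim)
  residuals <- numeric(nIter)
  for (it in seq_len(nIter)) {
    r <- y - Wfun(x)
    residuals[it] <- sqrt(sum(r^2))
    x <- x + C * Wtfun(R * r)
    if (nonneg) x[x < 0] <- 0
  }
  list(x = x, residuals = residuals)
}
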