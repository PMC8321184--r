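# The FDK algorithm: cosine reweighting, row-wise 1D filtering, weighted
# backprojection. Filters are kept in the spatial domain (length 2N) because
# the exponential binning is defined on spatial taps.

#' Cosine reweighting of cone-beam data
#'
#' Multiplies each detector sample at physical position (u, v) from the
#' detector centre by D / sqrt(D^2 + u^2 + v^2), D the source-to-detector
#' distance. This makes the cone-beam rows approximately behave like fan-beam
#' data before 1D filtering.
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param geometry geometry; defaults to the stack's own.
#' @return the reweighted \linkS4class{ProjectionStack}.
#' @export
reweight <- function(proj, geometry = NULL) {
  if (is.null(geometry)) geometry <- proj@geometry
  .checkProjGeom(proj, geometry)
  g <- geometry
  nu <- g@detectorPixels[2]; nv <- g@detectorPixels[1]
  u <- (seq_len(nu) - (nu + 1) / 2) * g@detectorPixelSize
  v <- (seq_len(nv) - (nv + 1) / 2) * g@detectorPixelSize
  D <- g@sourceToCenter + g@centerToDetector
  w <- D / sqrt(D^2 + outer(u^2, v^2, `+`))
  projectionStack(proj@values * as.numeric(w), g)
}

#' Row-wise 1D filtering of projection data
#'
#' Convolves every detector row (fixed angle, fixed v) with the spatial-domain
#' filter taps, by FFT multiplication with zero padding (linear convolution,
#' zero boundary). The filter centre tap is at index N + 1 of the length-2N
#' tap vector, so a centred unit impulse reproduces the input.
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param filter a \linkS4class{Filter1D} with 2N taps, N = detector columns.
#' @param geometry geometry; defaults to the stack's own.
#' @return the filtered \linkS4class{ProjectionStack}.
#' @export
applyFilter1D <- function(proj, filter, geometry = NULL) {
  if (is.null(geometry)) geometry <- proj@geometry
  .checkProjGeom(proj, geometry)
  h <- if (is(filter, "Filter1D")) filter@taps else as.numeric(filter)
  d <- dim(proj@values)
  nu <- d[1]
  if (length(h) != 2L * nu)
    stop("filter length must be 2N = ", 2L * nu, ", got ", length(h))
  P <- nextn(3L * nu - 1L, 2L)
  H <- fft(c(h, numeric(P - length(h))))
  ncols <- d[2] * d[3]
  mat <- matrix(proj@values, nrow = nu)
  out <- matrix(0, nrow = nu, ncol = ncols)
  # chunk columns to bound FFT workspace for large angle counts
  chunk <- max(1L, floor(2^22 / P))
  for (s in seq(1L, ncols, by = chunk)) {
    e <- min(s + chunk - 1L, ncols)
    y <- rbind(mat[, s:e, drop = FALSE],
               matrix(0, nrow = P - nu, ncol = e - s + 1L))
    cf <- mvfft(mvfft(y) * H, inverse = TRUE) / P
    out[, s:e] <- Re(cf[(nu + 1L):(2L * nu), , drop = FALSE])
  }
  dim(out) <- d
  projectionStack(out, proj@geometry)
}

#' Standard FDK filters
#'
#' Constructs Ram-Lak (band-limited ramp) or Hann-apodized ramp filter taps in
#' the spatial domain. The frequency response is sampled on the 2N-point DFT
#' grid in cycles per cm of the virtual (isocentre) detector pitch, so
#' \code{fdk} of noiseless data approximates the attenuation in 1/cm; the
#' angular-step and pitch normalization itself lives in the backprojection.
#' The DC response is exactly zero, and for Hann so is the Nyquist response.
#'
#' @param name "ram-lak" or "hann".
#' @param geometry a \linkS4class{ConeBeamGeometry} (fixes N and the pitch).
#' @return a \linkS4class{Filter1D} of length 2N.
#' @export
standardFilter <- function(name = c("ram-lak", "hann"), geometry) {
  name <- match.arg(name)
  nu <- geometry@detectorPixels[2]
  L <- 2L * nu
  dv <- geometry@detectorPixelSize / magnification(geometry) * 0.1  # cm
  k <- c(0:nu, (nu - 1):1)                      # DFT frequency index magnitudes
  resp <- k / (L * dv)                          # |f|, f_Nyquist = 1 / (2 dv)
  if (name == "hann")
    resp <- resp * (0.5 * (1 + cos(pi * k / nu)))
  h <- Re(fft(resp, inverse = TRUE)) / L
  taps <- h[(c(0:(L - 1)) - nu) %% L + 1L]      # centre tap at index N + 1
  new("Filter1D", taps = taps, name = name)
}

#' @export
setMethod("taps", "Filter1D", function(x) x@taps)

setMethod("show", "Filter1D", function(object) {
  cat(sprintf("Filter1D '%s', %d taps, centre %.4g\n", object@name,
              length(object@taps), object@taps[length(object@taps) / 2 + 1]))
})

#' FDK reconstruction
#'
#' The Feldkamp-Davis-Kress algorithm: cosine reweighting, row-wise 1D
#' filtering with \code{filter}, and distance-weighted backprojection. The
#' map is bilinear in (projections, filter).
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param filter a \linkS4class{Filter1D} (2N taps) or a name accepted by
#'   \code{\link{standardFilter}}.
#' @param geometry geometry; defaults to the stack's own.
#' @return a \linkS4class{VoxelVolume}.
#' @examples
#' g <- simGeometry(32, 24)
#' ph <- voxelize(fourshapeRandom(1), 32)
#' rec <- fdk(forwardProject(ph, g), "hann")
#' @export
setMethod("fdk", signature("ProjectionStack", "ANY"),
  function(proj, filter, geometry = NULL) {
    if (is.null(geometry)) geometry <- proj@geometry
    if (is.character(filter)) filter <- standardFilter(filter, geometry)
    fdkWeightedBackproject(applyFilter1D(reweight(proj, geometry), filter,
                                         geometry), geometry)
  })
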