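# The NN-FDK network: a two-layer perceptron over the Ne feature values of a
# voxel (the voxel's row of the feature matrix). Applying it voxelwise over
# the whole volume is algebraically identical to running one FDK per hidden
# node with the node's expanded binned filter and combining the sigmoid
# outputs -- which is how nnfdkReconstruct evaluates it.

#' Numerically stable sigmoid
#'
#' 1 / (1 + exp(-t)) without overflow for large |t|.
#' @param t numeric.
#' @export
sigmoid <- function(t) {
  out <- t
  pos <- !is.na(t) & t >= 0
  out[pos] <- 1 / (1 + exp(-t[pos]))
  e <- exp(t[!pos])
  out[!pos] <- e / (1 + e)
  out
}

#' Single perceptron
#'
#' sigmoid(eta . xi - b).
#' @param eta input vector.
#' @param xi weight vector, same length as \code{eta}.
#' @param b bias.
#' @export
perceptron <- function(eta, xi, b) {
  if (length(eta) != length(xi)) stop("eta and xi must have equal length")
  sigmoid(sum(eta * xi) - b)
}

#' Evaluate the NN-FDK network on feature vectors
#'
#' Applies the stored input scaling to the raw feature values, the Nh hidden
#' perceptrons and the output perceptron. The raw network output lies in
#' (0, 1); with \code{rescale = TRUE} the inverse target scaling maps it back
#' to grey values.
#'
#' @param q numeric vector of length Ne, or an n x Ne matrix of feature rows.
#' @param params an \linkS4class{NNFDKParams}.
#' @param rescale apply the inverse target scaling.
#' @return numeric vector of network outputs (one per input row).
#' @export
networkForward <- function(q, params, rescale = FALSE) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (ncol(q) != params@binning@ne)
    stop("feature vectors must have Ne = ", params@binning@ne, " columns")
  zs <- sweep(sweep(q, 2, params@inputOffset), 2, params@inputScale, `*`)
  a <- sweep(zs %*% params@hiddenFilters, 2, params@hiddenBiases)
  h <- sigmoid(a)
  out <- sigmoid(as.numeric(h %*% params@outputWeights) - params@outputBias)
  if (rescale) (out - params@targetOffset) / params@targetScale else out
}

#' Random initialization of NN-FDK parameters
#'
#' Hidden filter coefficients, hidden biases and output weights uniform in
#' [-1, 1]; output bias 0; identity scalings. Deterministic given the seed.
#'
#' @param nHidden number of hidden nodes Nh (default 4).
#' @param binning the shared \linkS4class{BinningOperator}.
#' @param seed RNG seed.
#' @return an \linkS4class{NNFDKParams}.
#' @export
initParams <- function(nHidden = 4L, binning, seed = 1L) {
  ne <- binning@ne
  rng <- .seededRNG(seed)
  new("NNFDKParams",
      binning = binning,
      hiddenFilters = matrix(rng(ne * nHidden) * 2 - 1, ne, nHidden),
      hiddenBiases = rng(nHidden) * 2 - 1,
      outputWeights = rng(nHidden) * 2 - 1,
      outputBias = 0,
      inputScale = rep(1, ne), inputOffset = rep(0, ne),
      targetScale = 1, targetOffset = 0)
}

#' @export
setMethod("nHidden", "NNFDKParams", function(x) ncol(x@hiddenFilters))

setMethod("show", "NNFDKParams", function(object) {
  cat(sprintf("NNFDKParams: Nh = %d, Ne = %d, |theta| = %d\n",
              ncol(object@hiddenFilters), object@binning@ne,
              countParams(ncol(object@hiddenFilters), object@binning)))
})

#' NN-FDK reconstruction
#'
#' Runs exactly Nh FDK reconstructions, one per hidden node, using the node's
#' expanded binned filter with the input scaling fused into the filter
#' coefficients and bias (so the result is voxelwise identical to evaluating
#' \code{\link{networkForward}} on the rows of the feature matrix). Outputs
#' are mapped back to grey values through the inverse target scaling unless
#' \code{greyValues = FALSE}.
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param params an \linkS4class{NNFDKParams} whose binning matches the
#'   geometry's detector width.
#' @param geometry geometry; defaults to the stack's own.
#' @param greyValues apply the inverse target scaling.
#' @return a \linkS4class{VoxelVolume}.
#' @export
nnfdkReconstruct <- function(proj, params, geometry = NULL,
                             greyValues = TRUE) {
  if (is.null(geometry)) geometry <- proj@geometry
  .checkProjGeom(proj, geometry)
  if (params@binning@n != geometry@detectorPixels[2])
    stop("params binning is for N = ", params@binning@n,
         ", geometry has ", geometry@detectorPixels[2], " detector columns")
  nh <- ncol(params@hiddenFilters)
  pr <- reweight(proj, geometry)
  acc <- 0
  for (k in seq_len(nh)) {
    hek <- params@hiddenFilters[, k]
    fused <- expandFilter(params@binning, params@inputScale * hek)
    vol <- fdkWeightedBackproject(applyFilter1D(pr, fused, geometry), geometry)
    bk <- params@hiddenBiases[k] +
      sum(params@inputOffset * params@inputScale * hek)
    acc <- acc + params@outputWeights[k] * sigmoid(vol@values - bk)
  }
  out <- sigmoid(acc - params@outputBias)
  if (greyValues) out <- (out - params@targetOffset) / params@targetScale
  voxelVolume(out, geometry@voxelSize)
}

#' Serialize NN-FDK parameters to JSON
#'
#' Full-precision JSON round trip, including the binning description and the
#' input/target scalings.
#'
#' @param params an \linkS4class{NNFDKParams}.
#' @param path file to write; if NULL, the JSON string is returned.
#' @export
paramsToJSON <- function(params, path = NULL) {
  x <- list(
    n = params@binning@n, ne = params@binning@ne,
    hidden_filters = params@hiddenFilters,
    hidden_biases = params@hiddenBiases,
    output_weights = params@outputWeights,
    output_bias = params@outputBias,
    input_scale = params@inputScale, input_offset = params@inputOffset,
    target_scale = params@targetScale, target_offset = params@targetOffset)
  js <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) js else writeLines(js, path)
}

#' @rdname paramsToJSON
#' @param json JSON string or path to a JSON file.
#' @export
paramsFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  b <- makeBinning(x$n)
  if (b@ne != x$ne) stop("stored Ne does not match the binning scheme")
  new("NNFDKParams", binning = b,
      hiddenFilters = matrix(x$hidden_filters, nrow = x$ne),
      hiddenBiases = as.numeric(x$hidden_biases),
      outputWeights = as.numeric(x$output_weights),
      outputBias = as.numeric(x$output_bias),
      inputScale = as.numeric(x$input_scale),
      inputOffset = as.numeric(x$input_offset),
      targetScale = as.numeric(x$target_scale),
      targetOffset = as.numeric(x$target_offset))
}
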