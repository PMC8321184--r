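# Exponential filter binning: a length-2N spatial filter is represented by
# Ne ~ log2(N) piecewise-constant coefficients. Radial bin widths from the
# filter centre are 1, 1, 1, 1, 2, 4, 8, ..., truncated at radius N, and the
# mirror-image bins at equal distance are merged (learned FDK filters are
# treated as symmetric). This puts Ne = 13 at N = 1024, so an Nh = 4 network
# has (13 + 2) * 4 + 1 = 61 trainable parameters.

#' Construct the exponential binning operator
#'
#' @param n N (the filter has 2N taps), or a \linkS4class{ConeBeamGeometry}
#'   from which N is taken (detector columns).
#' @return a \linkS4class{BinningOperator}.
#' @examples
#' nBins(makeBinning(1024))  # 13
#' @export
makeBinning <- function(n) {
  if (is(n, "ConeBeamGeometry")) n <- n@detectorPixels[2]
  n <- as.integer(n)
  if (n < 4L) stop("N must be >= 4 for exponential binning")
  starts <- .binStarts(n)
  # tap j (1-based) sits at offset j - (n + 1); radius = |offset|, max n
  offs <- seq_len(2L * n) - (n + 1L)
  idx <- findInterval(abs(offs), starts)
  new("BinningOperator", n = n, ne = length(starts), binIndex = as.integer(idx))
}

# radial bin start positions: unit bins at 0,1,2,3 then doubling widths
.binStarts <- function(n) {
  starts <- 0:3
  nxt <- 4L
  w <- 2L
  while (nxt <= n) {
    starts <- c(starts, nxt)
    nxt <- nxt + w
    w <- w * 2L
  }
  starts
}

#' @export
setMethod("nBins", "BinningOperator", function(x) x@ne)

setMethod("show", "BinningOperator", function(object) {
  cat(sprintf("BinningOperator: N = %d, Ne = %d bins over 2N = %d taps\n",
              object@n, object@ne, 2L * object@n))
})

#' Binned filter coefficients
#' @param coefficients numeric vector of length Ne.
#' @export
binnedFilter <- function(coefficients) {
  new("BinnedFilter", coefficients = as.numeric(coefficients))
}

#' @export
setMethod("binCoefficients", "BinnedFilter", function(x) x@coefficients)

#' Expand binned coefficients to a full spatial filter
#'
#' Piecewise-constant expansion h = E h_e: tap t receives the coefficient of
#' its bin. Linear in the coefficients.
#'
#' @param binning a \linkS4class{BinningOperator}.
#' @param he a \linkS4class{BinnedFilter} or numeric vector of length Ne.
#' @param name label for the resulting filter.
#' @return a \linkS4class{Filter1D} with 2N taps.
#' @export
expandFilter <- function(binning, he, name = "binned") {
  co <- if (is(he, "BinnedFilter")) he@coefficients else as.numeric(he)
  if (length(co) != binning@ne)
    stop("expected ", binning@ne, " coefficients, got ", length(co))
  new("Filter1D", taps = co[binning@binIndex], name = name)
}

#' Bin-wise means of a full filter (left inverse of expandFilter)
#'
#' @param binning a \linkS4class{BinningOperator}.
#' @param filter a \linkS4class{Filter1D} or numeric vector of 2N taps.
#' @return numeric vector of length Ne.
#' @export
binMeans <- function(binning, filter) {
  t <- if (is(filter, "Filter1D")) filter@taps else as.numeric(filter)
  if (length(t) != 2L * binning@n) stop("filter length must be 2N")
  as.numeric(tapply(t, binning@binIndex, mean))
}

#' Export the binning as bin boundaries
#'
#' @param binning a \linkS4class{BinningOperator}.
#' @return list with N, Ne and the radial start offset of every bin.
#' @export
binningDescription <- function(binning) {
  list(n = binning@n, ne = binning@ne, radial_starts = .binStarts(binning@n))
}

#' Number of trainable NN-FDK parameters
#'
#' (Ne + 2) * Nh + 1: per hidden node Ne filter coefficients plus a bias and
#' an output weight, plus the output bias.
#'
#' @param nHidden number of hidden nodes Nh.
#' @param binning a \linkS4class{BinningOperator} (or Ne directly).
#' @return integer parameter count.
#' @examples
#' countParams(4, makeBinning(1024))  # 61
#' @export
countParams <- function(nHidden, binning) {
  ne <- if (is(binning, "BinningOperator")) binning@ne else as.integer(binning)
  if (nHidden < 1L) stop("need at least one hidden node")
  as.integer((ne + 2L) * nHidden + 1L)
}
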