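# Quantitative evaluation: test set error (half mean squared difference over
# the ROI), structural similarity with a 19-pixel uniform window computed
# slice-by-slice, and segmentation overlap metrics.

#' Test set error
#'
#' TSE(x_r, x_hq) = 1 / (2 N_ROI) * || mask * (x_hq - x_r) ||^2 -- the average
#' of the half-squared-error training loss over the ROI voxels.
#'
#' @param xr reconstruction (\linkS4class{VoxelVolume} or array).
#' @param xhq reference (same shape).
#' @param mask logical array of ROI voxels; default: all voxels.
#' @return scalar TSE.
#' @export
tse <- function(xr, xhq, mask = NULL) {
  a <- if (is(xr, "VoxelVolume")) xr@values else xr
  b <- if (is(xhq, "VoxelVolume")) xhq@values else xhq
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  if (!identical(dim(mask), dim(a))) stop("mask shape differs")
  n <- sum(mask)
  if (n == 0) stop("empty ROI mask")
  sum((b[mask] - a[mask])^2) / (2 * n)
}

#' Structural similarity of two volumes
#'
#' Mean SSIM with a uniform (boxcar) window of odd width (default 19) and the
#' standard stabilization constants C1 = (0.01 L)^2, C2 = (0.03 L)^2, where L
#' is the value range of the reference. Computed in 2D per z-slice over the
#' bounding box of the ROI (whole volume when no ROI is given) and averaged;
#' when an ROI is given, the per-window SSIM map is averaged over ROI voxels
#' only. Windows are "valid" (no padding), as in the common scikit-image
#' implementation, with sample (n - 1) covariance normalization.
#'
#' @param xr reconstruction (\linkS4class{VoxelVolume} or array).
#' @param xhq reference (same shape; also sets the data range).
#' @param roi optional logical array restricting evaluation.
#' @param windowWidth odd uniform filter width (default 19).
#' @return scalar mean SSIM.
#' @export
ssimVolume <- function(xr, xhq, roi = NULL, windowWidth = 19L) {
  a <- if (is(xr, "VoxelVolume")) xr@values else xr
  b <- if (is(xhq, "VoxelVolume")) xhq@values else xhq
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  w <- as.integer(windowWidth)
  if (w %% 2L == 0L) stop("windowWidth must be odd")
  if (!is.null(roi)) {
    bb <- lapply(1:3, function(ax) range(which(apply(roi, ax, any))))
    a <- a[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2], bb[[3]][1]:bb[[3]][2]]
    b <- b[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2], bb[[3]][1]:bb[[3]][2]]
    roi <- roi[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
               bb[[3]][1]:bb[[3]][2]]
  }
  d <- dim(a)
  if (d[1] < w || d[2] < w)
    stop("slices smaller than the SSIM window (", w, ")")
  L <- max(b) - min(b)
  if (L == 0) L <- 1        # constant reference: stabilized formula only
  acc <- 0; nacc <- 0
  pad <- (w - 1L) %/% 2L
  for (z in seq_len(d[3])) {
    s <- .ssimMap2D(a[, , z], b[, , z], w, L)
    if (is.null(roi)) { acc <- acc + sum(s); nacc <- nacc + length(s) }
    else {
      rz <- roi[(pad + 1):(d[1] - pad), (pad + 1):(d[2] - pad), z]
      acc <- acc + sum(s[rz]); nacc <- nacc + sum(rz)
    }
  }
  if (nacc == 0) stop("ROI contains no valid SSIM windows")
  acc / nacc
}

# valid-window uniform-filter SSIM map of two 2D slices
.ssimMap2D <- function(x, y, w, L) {
  np <- w * w
  covNorm <- np / (np - 1)
  ux <- .boxMean2D(x, w); uy <- .boxMean2D(y, w)
  uxx <- .boxMean2D(x * x, w); uyy <- .boxMean2D(y * y, w)
  uxy <- .boxMean2D(x * y, w)
  vx <- covNorm * (uxx - ux * ux)
  vy <- covNorm * (uyy - uy * uy)
  vxy <- covNorm * (uxy - ux * uy)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
}

# exact valid-region moving average via cumulative sums
.boxMean2D <- function(m, w) {
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  colsum <- cs[(w + 1):nrow(cs), , drop = FALSE] -
            cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- t(apply(colsum, 1, cumsum))
  cs2 <- cbind(0, cs2)
  (cs2[, (w + 1):ncol(cs2), drop = FALSE] -
   cs2[, 1:(ncol(cs2) - w), drop = FALSE]) / (w * w)
}

#' Segmentation accuracy metrics
#'
#' Compares a binary segmentation to a gold standard: signed volume error
#' Verr = (|S_rec| - |S_gs|) / |S_gs|, mislabelled-voxel fraction
#' MLerr = |S_rec - S_gs| / |S_gs| (voxelwise absolute differences), and the
#' Dice coefficient DC = 2 |S_rec & S_gs| / (|S_rec| + |S_gs|). Verr is kept
#' signed; take its absolute value for table-style reporting.
#'
#' @param sRec,sGs logical or 0/1 arrays of equal shape; \code{sGs} nonempty.
#' @return named list (verr, mlerr, dice).
#' @export
segmentationMetrics <- function(sRec, sGs) {
  a <- as.numeric(sRec) != 0
  b <- as.numeric(sGs) != 0
  if (length(a) != length(b)) stop("shapes differ")
  nb <- sum(b)
  if (nb == 0) stop("empty gold standard segmentation")
  na <- sum(a)
  list(verr = (na - nb) / nb,
       mlerr = sum(a != b) / nb,
       dice = 2 * sum(a & b) / (na + nb))
}
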