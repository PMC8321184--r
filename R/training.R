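# Training machinery: feature volumes (one FDK per binned unit filter), ROI
# masking, training-pair sampling, and full-batch Levenberg-Marquardt with
# validation gating. The parameter vector is laid out as
# [he_1, b_1, ..., he_Nh, b_Nh, xi_1..xi_Nh, b_o].

#' Compute the Ne feature volumes
#'
#' Feature volume j is the FDK reconstruction with the expanded j-th binned
#' unit filter; the linear span of the feature volumes reproduces FDK with
#' any binned filter, and row v across them is the network input for voxel v.
#'
#' @param proj a \linkS4class{ProjectionStack}.
#' @param geometry geometry; defaults to the stack's own.
#' @param binning a \linkS4class{BinningOperator}; default from the geometry.
#' @return list with elements \code{volumes} (list of Ne
#'   \linkS4class{VoxelVolume}s) and \code{binning}.
#' @export
computeFeatureVolumes <- function(proj, geometry = NULL,
                                  binning = NULL) {
  if (is.null(geometry)) geometry <- proj@geometry
  if (is.null(binning)) binning <- makeBinning(geometry)
  vols <- lapply(seq_len(binning@ne), function(j) {
    ej <- numeric(binning@ne); ej[j] <- 1
    fdk(proj, expandFilter(binning, ej), geometry)
  })
  list(volumes = vols, binning = binning)
}

#' Feature matrix rows for selected voxels
#'
#' @param features result of \code{\link{computeFeatureVolumes}}.
#' @param voxels integer voxel indices (into the flattened volume).
#' @return length(voxels) x Ne matrix.
#' @export
featureMatrix <- function(features, voxels) {
  vapply(features$volumes, function(v) v@values[voxels],
         numeric(length(voxels)))
}

#' Region-of-interest mask around the scanned object
#'
#' Thresholds the high-quality volume (Otsu's method on a 256-bin histogram)
#' to find the object support, then dilates it with a cubic structuring
#' element of radius \code{round(bufferFrac * N)} voxels, clipped to the
#' volume.
#'
#' @param volume a \linkS4class{VoxelVolume} (typically the HQ target).
#' @param bufferFrac buffer radius as a fraction of N (default 0.2).
#' @return logical array of the volume's shape.
#' @export
roiMask <- function(volume, bufferFrac = 0.2) {
  v <- volume@values
  if (max(v) - min(v) <= 0) stop("constant volume: no object to mask")
  mask <- v > .otsu(v)
  if (!any(mask)) stop("threshold removed everything: no object found")
  b <- round(bufferFrac * dim(v)[1])
  .dilateBox(mask, b)
}

.otsu <- function(v, nbins = 256L) {
  r <- range(v)
  h <- tabulate(pmin(nbins, 1L + floor((v - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) * diff(r) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# binary dilation with a (2b+1)^3 box, separably along each axis
.dilateBox <- function(mask, b) {
  if (b <= 0) return(mask)
  n <- dim(mask)
  for (ax in 1:3) {
    out <- mask
    for (s in seq_len(b)) {
      idx <- seq_len(n[ax] - s)
      lo <- vector("list", 3); hi <- lo
      for (d in 1:3) { lo[[d]] <- TRUE; hi[[d]] <- TRUE }
      lo[[ax]] <- idx; hi[[ax]] <- idx + s
      out[lo[[1]], lo[[2]], lo[[3]]] <-
        out[lo[[1]], lo[[2]], lo[[3]]] | mask[hi[[1]], hi[[2]], hi[[3]]]
      out[hi[[1]], hi[[2]], hi[[3]]] <-
        out[hi[[1]], hi[[2]], hi[[3]]] | mask[lo[[1]], lo[[2]], lo[[3]]]
    }
    mask <- out
  }
  mask
}

#' Draw unique training and validation pairs from the ROI
#'
#' Draws voxels uniformly without replacement from each dataset's ROI mask,
#' an equal number from every dataset, with training and validation pairs
#' disjoint. Inputs are raw feature rows; targets are taken from the supplied
#' (already scaled) target volumes.
#'
#' @param datasets list; each element a list with \code{features} (from
#'   \code{\link{computeFeatureVolumes}}), \code{target} (numeric array of
#'   scaled HQ values), \code{mask} (logical array) and optional \code{id}.
#' @param nTrain,nVal total numbers of training and validation pairs (split
#'   equally over datasets; must be divisible by the number of datasets).
#' @param seed RNG seed.
#' @return list of two \linkS4class{TrainingSet}s: \code{train}, \code{val}.
#' @export
samplePairs <- function(datasets, nTrain, nVal, seed = 1L) {
  nd <- length(datasets)
  if (nTrain %% nd || nVal %% nd)
    stop("nTrain and nVal must be divisible by the number of datasets")
  ntd <- nTrain %/% nd; nvd <- nVal %/% nd
  rng <- .seededRNG(seed)
  tr <- list(); va <- list()
  for (i in seq_len(nd)) {
    d <- datasets[[i]]
    idx <- which(d$mask)
    if (length(idx) < ntd + nvd)
      stop("dataset ", i, ": ROI has ", length(idx),
           " voxels, need ", ntd + nvd)
    pick <- idx[order(rng(length(idx)))[seq_len(ntd + nvd)]]
    id <- if (is.null(d$id)) i else d$id
    Z <- featureMatrix(d$features, pick)
    O <- as.numeric(d$target)[pick]
    tr[[i]] <- list(Z = Z[seq_len(ntd), , drop = FALSE],
                    O = O[seq_len(ntd)],
                    pv = data.frame(dataset = id, voxel = pick[seq_len(ntd)]))
    va[[i]] <- list(Z = Z[ntd + seq_len(nvd), , drop = FALSE],
                    O = O[ntd + seq_len(nvd)],
                    pv = data.frame(dataset = id, voxel = pick[ntd + seq_len(nvd)]))
  }
  mk <- function(parts) new("TrainingSet",
    inputs = do.call(rbind, lapply(parts, `[[`, "Z")),
    targets = unlist(lapply(parts, `[[`, "O")),
    provenance = do.call(rbind, lapply(parts, `[[`, "pv")))
  list(train = mk(tr), val = mk(va))
}

#' Training set accessors
#' @param x a \linkS4class{TrainingSet}.
#' @export
trainingInputs <- function(x) x@inputs
#' @rdname trainingInputs
#' @export
trainingTargets <- function(x) x@targets

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d pairs, Ne = %d, %d dataset(s)\n",
              nrow(object@inputs), ncol(object@inputs),
              length(unique(object@provenance$dataset))))
})

# ---- parameter vector packing --------------------------------------------

.packTheta <- function(p) {
  nh <- ncol(p@hiddenFilters)
  c(as.numeric(rbind(p@hiddenFilters, p@hiddenBiases)),
    p@outputWeights, p@outputBias)
}

.unpackTheta <- function(theta, template) {
  ne <- template@binning@ne
  nh <- ncol(template@hiddenFilters)
  m <- matrix(theta[seq_len((ne + 1) * nh)], ne + 1, nh)
  p <- template
  p@hiddenFilters <- m[seq_len(ne), , drop = FALSE]
  p@hiddenBiases <- m[ne + 1, ]
  p@outputWeights <- theta[(ne + 1) * nh + seq_len(nh)]
  p@outputBias <- theta[length(theta)]
  p
}

# forward pass + residual Jacobian on pre-scaled inputs Zs.
# residual r = O - out; J[i, l] = d r_i / d theta_l = -d out_i / d theta_l.
.lmaResidJac <- function(theta, Zs, O, ne, nh, jacobian = TRUE) {
  m <- matrix(theta[seq_len((ne + 1) * nh)], ne + 1, nh)
  Wh <- m[seq_len(ne), , drop = FALSE]
  bh <- m[ne + 1, ]
  xi <- theta[(ne + 1) * nh + seq_len(nh)]
  bo <- theta[length(theta)]
  H <- sigmoid(sweep(Zs %*% Wh, 2, bh))            # n x nh
  out <- sigmoid(as.numeric(H %*% xi) - bo)        # n
  r <- O - out
  if (!jacobian) return(list(r = r, out = out))
  dout <- out * (1 - out)                          # n
  dH <- H * (1 - H)                                # n x nh
  n <- length(out)
  J <- matrix(0, n, (ne + 2) * nh + 1)
  for (k in seq_len(nh)) {
    gk <- dout * xi[k] * dH[, k]                   # d out / d a_k
    cols <- (k - 1) * (ne + 1) + seq_len(ne)
    J[, cols] <- -gk * Zs
    J[, (k - 1) * (ne + 1) + ne + 1] <- gk         # d r / d b_k = +gk
    J[, (ne + 1) * nh + k] <- -dout * H[, k]
  }
  J[, ncol(J)] <- dout                              # d r / d b_o
  list(r = r, out = out, J = J)
}

#' Default LMA training configuration
#'
#' Classical Marquardt schedule: initial damping 1e-2, multiplied by 10 on a
#' rejected step and divided by 10 on acceptance; at most 500 epochs (one
#' full-batch LMA iteration each) and early stopping after 100 epochs without
#' improvement of the validation loss. \code{damping} selects identity
#' damping (default) or scaling by diag(J'J).
#'
#' @param lambda0,factor,maxEpochs,patience,damping,restarts see description.
#' @export
lmaConfig <- function(lambda0 = 1e-2, factor = 10, maxEpochs = 500L,
                      patience = 100L, damping = c("identity", "diag"),
                      restarts = 1L) {
  list(lambda0 = lambda0, factor = factor, maxEpochs = as.integer(maxEpochs),
       patience = as.integer(patience), damping = match.arg(damping),
       restarts = as.integer(restarts))
}

#' Levenberg-Marquardt training of an NN-FDK network
#'
#' Minimizes the l2 loss 0.5 * sum (O - N_theta(Z))^2 over the training set
#' with full-batch LMA using the analytic Jacobian: each step solves
#' (J'J + lambda I) delta = J'r and is accepted only if it reduces the
#' training loss. The validation loss is tracked every epoch and the
#' parameters with the lowest validation loss seen (starting from theta0) are
#' returned; training stops after \code{patience} epochs without validation
#' improvement. Ties keep the earliest best parameters.
#'
#' @param theta0 starting \linkS4class{NNFDKParams} (its input scaling is
#'   applied to the raw inputs once, up front; scaling slots are not trained).
#' @param train,val \linkS4class{TrainingSet}s.
#' @param config list from \code{\link{lmaConfig}}.
#' @param trace if TRUE, attach a per-epoch train/val loss log as attribute
#'   \code{"log"} (data.frame epoch, lambda, train, val, accepted).
#' @return the trained \linkS4class{NNFDKParams}.
#' @export
trainLMA <- function(theta0, train, val, config = lmaConfig(), trace = FALSE) {
  ne <- theta0@binning@ne
  nh <- ncol(theta0@hiddenFilters)
  scale <- function(Z) sweep(sweep(Z, 2, theta0@inputOffset), 2,
                             theta0@inputScale, `*`)
  Zt <- scale(train@inputs); Ot <- train@targets
  Zv <- scale(val@inputs); Ov <- val@targets
  loss <- function(r) 0.5 * sum(r^2)

  theta <- .packTheta(theta0)
  cur <- .lmaResidJac(theta, Zt, Ot, ne, nh)
  trLoss <- loss(cur$r)
  vaLoss <- loss(.lmaResidJac(theta, Zv, Ov, ne, nh, jacobian = FALSE)$r)
  if (!is.finite(trLoss) || !is.finite(vaLoss))
    stop("non-finite loss at the starting parameters")
  best <- theta; bestVal <- vaLoss; sinceBest <- 0L
  lambda <- config$lambda0
  log <- list()

  for (epoch in seq_len(config$maxEpochs)) {
    JtJ <- crossprod(cur$J)
    Jtr <- crossprod(cur$J, cur$r)
    Dmp <- if (config$damping == "identity") diag(nrow(JtJ))
           else diag(pmax(diag(JtJ), 1e-12))
    delta <- tryCatch(solve(JtJ + lambda * Dmp, -Jtr),
                      error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta)) {
      cand <- theta + as.numeric(delta)
      candFit <- .lmaResidJac(cand, Zt, Ot, ne, nh, jacobian = FALSE)
      if (is.finite(loss(candFit$r)) && loss(candFit$r) < trLoss) {
        theta <- cand
        trLoss <- loss(candFit$r)
        cur <- .lmaResidJac(theta, Zt, Ot, ne, nh)
        lambda <- lambda / config$factor
        accepted <- TRUE
      }
    }
    if (!accepted) lambda <- lambda * config$factor
    vaLoss <- loss(.lmaResidJac(theta, Zv, Ov, ne, nh, jacobian = FALSE)$r)
    if (!is.finite(vaLoss)) stop("non-finite validation loss")
    if (vaLoss < bestVal) { bestVal <- vaLoss; best <- theta; sinceBest <- 0L }
    else sinceBest <- sinceBest + 1L
    if (trace)
      log[[epoch]] <- data.frame(epoch = epoch, lambda = lambda,
                                 train = trLoss, val = vaLoss,
                                 accepted = accepted)
    if (sinceBest >= config$patience) break
    if (lambda > 1e12 && !accepted && sinceBest > 10L) break
  }
  out <- .unpackTheta(best, theta0)
  if (trace) attr(out, "log") <- do.call(rbind, log)
  out
}

#' End-to-end NN-FDK training from simulated or loaded datasets
#'
#' For every dataset: computes the Ne feature volumes from the low-quality
#' projections and the ROI mask of its high-quality target; fixes the target
#' scaling (affine map of the pooled ROI value range onto [0.05, 0.95], as
#' required by the sigmoid output) and the per-feature input scaling (zero
#' mean, unit deviation over the training pairs); then runs
#' \code{\link{trainLMA}}, optionally from several random restarts, keeping
#' the parameters with the lowest validation loss.
#'
#' @param datasets list; each element a list with \code{proj}
#'   (\linkS4class{ProjectionStack}) and \code{hq} (\linkS4class{VoxelVolume}),
#'   or pre-computed \code{features} and \code{mask}.
#' @param nHidden number of hidden nodes (default 4).
#' @param nTrain,nVal total training/validation pairs.
#' @param seed RNG seed (pair sampling and initialization).
#' @param config list from \code{\link{lmaConfig}}.
#' @param bufferFrac ROI buffer fraction (default 0.2).
#' @return trained \linkS4class{NNFDKParams} (attribute \code{"valLoss"}
#'   holds the achieved validation loss).
#' @export
trainNNFDK <- function(datasets, nHidden = 4L, nTrain = 1e6, nVal = 1e6,
                       seed = 1L, config = lmaConfig(), bufferFrac = 0.2) {
  prep <- lapply(datasets, function(d) {
    if (is.null(d$features))
      d$features <- computeFeatureVolumes(d$proj)
    if (is.null(d$mask)) d$mask <- roiMask(d$hq, bufferFrac)
    d
  })
  binning <- prep[[1]]$features$binning
  # target scaling from the pooled ROI value range -> [0.05, 0.95]
  rng <- range(unlist(lapply(prep, function(d) range(d$hq@values[d$mask]))))
  tScale <- 0.9 / diff(rng)
  tOffset <- 0.05 - rng[1] * tScale
  for (i in seq_along(prep))
    prep[[i]]$target <- prep[[i]]$hq@values * tScale + tOffset
  # auto-scale the pair counts down if the ROIs are small
  nd <- length(prep)
  avail <- min(vapply(prep, function(d) sum(d$mask), numeric(1)))
  cap <- floor(0.8 * avail) * nd
  if (nTrain + nVal > cap) {
    f <- cap / (nTrain + nVal)
    nTrain <- max(nd, (floor(nTrain * f) %/% nd) * nd)
    nVal <- max(nd, (floor(nVal * f) %/% nd) * nd)
    message("ROI smaller than requested pairs; using nTrain = ", nTrain,
            ", nVal = ", nVal)
  }
  pairs <- samplePairs(prep, nTrain, nVal, seed = seed)
  # input scaling: zero mean, unit deviation per feature over training pairs
  mu <- colMeans(pairs$train@inputs)
  sdv <- apply(pairs$train@inputs, 2, sd)
  sdv[sdv < 1e-12] <- 1
  best <- NULL; bestVal <- Inf
  for (r in seq_len(max(1L, config$restarts))) {
    th0 <- initParams(nHidden, binning, seed = seed + 1000L * r)
    th0@inputScale <- 1 / sdv; th0@inputOffset <- mu
    th0@targetScale <- tScale; th0@targetOffset <- tOffset
    fit <- trainLMA(th0, pairs$train, pairs$val, config)
    v <- .valLoss(fit, pairs$val)
    if (v < bestVal) { bestVal <- v; best <- fit }
  }
  attr(best, "valLoss") <- bestVal
  best
}

.valLoss <- function(params, val) {
  0.5 * sum((val@targets - networkForward(val@inputs, params))^2)
}
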