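test_that("feature volumes are FDK reconstructions with binned unit filters", {
  N <- 16
  g <- simGeometry(N, 8)
  proj <- forwardProject(voxelize(fourshapeRandom(2), N), g)
  fv <- computeFeatureVolumes(proj)
  b <- fv$binning
  expect_identical(length(fv$volumes), as.integer(nBins(b)))
  # column j is bit-for-bit the direct FDK call with expand(e_j)
  e3 <- numeric(nBins(b)); e3[3] <- 1
  expect_identical(values(fv$volumes[[3]]),
                   values(fdk(proj, expandFilter(b, e3), g)))
  # the linear span reproduces FDK with any binned filter
  set.seed(5)
  he <- rnorm(nBins(b))
  comb <- Reduce(`+`, Map(function(c, v) c * values(v), he, fv$volumes))
  direct <- values(fdk(proj, expandFilter(b, he), g))
  expect_lt(max(abs(comb - direct)), 1e-6 * max(abs(direct)))
  # zero projections give all-zero features
  z <- projectionStack(array(0, dim(values(proj))), g)
  fz <- computeFeatureVolumes(z)
  expect_true(all(vapply(fz$volumes, function(v) all(values(v) == 0),
                         logical(1))))
})

test_that("ROI mask is the thresholded object dilated by the buffer", {
  N <- 32
  vol <- voxelize(cubeSpec(0.25), N)
  mask <- roiMask(vol, bufferFrac = 0.2)
  obj <- values(vol) > 0.11
  # brute-force box dilation oracle with radius round(0.2 * 32) = 6
  b <- 6L
  oracle <- array(FALSE, dim(obj))
  idx <- which(obj, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    oracle[max(1, i[1] - b):min(N, i[1] + b),
           max(1, i[2] - b):min(N, i[2] + b),
           max(1, i[3] - b):min(N, i[3] + b)] <- TRUE
  }
  expect_identical(mask, oracle)
  # dilation is extensive; zero buffer reduces to the thresholded object
  expect_true(all(mask[obj]))
  expect_identical(roiMask(vol, bufferFrac = 0), obj)
  expect_error(roiMask(voxelVolume(array(1, c(16, 16, 16)), 1)), "constant")
})

test_that("pair sampling is unique, masked, balanced and reproducible", {
  N <- 16
  g <- simGeometry(N, 6)
  mkd <- function(seed) {
    proj <- forwardProject(voxelize(fourshapeRandom(seed), N), g)
    fv <- computeFeatureVolumes(proj)
    list(features = fv, target = values(fv$volumes[[1]]),
         mask = array(rep(c(TRUE, FALSE), length.out = N^3), rep(N, 3)),
         id = seed)
  }
  ds <- list(mkd(1), mkd(2))
  ps <- samplePairs(ds, 100, 40, seed = 5)
  expect_identical(nrow(trainingInputs(ps$train)), 100L)
  expect_identical(length(trainingTargets(ps$val)), 40L)
  expect_identical(as.integer(table(ps$train@provenance$dataset)), c(50L, 50L))
  # no duplicate pairs, train and val disjoint, all inside the masks
  key <- function(x) paste(x@provenance$dataset, x@provenance$voxel)
  expect_identical(anyDuplicated(c(key(ps$train), key(ps$val))), 0L)
  for (i in 1:2) {
    vox <- ps$train@provenance$voxel[ps$train@provenance$dataset == ds[[i]]$id]
    expect_true(all(ds[[i]]$mask[vox]))
  }
  # determinism and divisibility contract
  ps2 <- samplePairs(ds, 100, 40, seed = 5)
  expect_identical(ps$train@provenance, ps2$train@provenance)
  expect_error(samplePairs(ds, 101, 40, seed = 1), "divisible")
  expect_error(samplePairs(ds, 2 * sum(ds[[1]]$mask) + 2, 2, seed = 1), "ROI")
})

test_that("analytic LMA Jacobian matches central finite differences", {
  set.seed(3)
  ne <- 4L; nh <- 3L
  Zs <- matrix(rnorm(25 * ne), 25, ne)
  O <- runif(25)
  theta <- rnorm((ne + 2) * nh + 1, sd = 0.6)
  got <- nnfdk:::.lmaResidJac(theta, Zs, O, ne, nh)$J
  eps <- 1e-6
  want <- vapply(seq_along(theta), function(l) {
    tp <- theta; tp[l] <- tp[l] + eps
    tm <- theta; tm[l] <- tm[l] - eps
    (nnfdk:::.lmaResidJac(tp, Zs, O, ne, nh, FALSE)$r -
     nnfdk:::.lmaResidJac(tm, Zs, O, ne, nh, FALSE)$r) / (2 * eps)
  }, numeric(25))
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-5)
})

test_that("LMA recovers a planted network and never worsens validation", {
  bn <- new("BinningOperator", n = 5L, ne = 5L, binIndex = rep(1:5, each = 2L))
  planted <- initParams(2, bn, seed = 11)
  set.seed(21)
  Z <- matrix(rnorm(4000 * 5), ncol = 5)
  O <- networkForward(Z, planted)
  mkset <- function(i) new("TrainingSet", inputs = Z[i, ], targets = O[i],
                           provenance = data.frame(dataset = 1, voxel = i))
  tr <- mkset(1:3200); va <- mkset(3201:4000)
  th0 <- initParams(2, bn, seed = 99)
  fit <- trainLMA(th0, tr, va, lmaConfig(), trace = TRUE)
  expect_lt(mean((networkForward(Z, fit) - O)^2), 1e-6)
  # training loss over accepted steps is non-increasing
  log <- attr(fit, "log")
  expect_true(all(diff(log$train) <= 1e-12))
  # returned parameters never validate worse than the starting point
  vloss <- function(p) 0.5 * sum((trainingTargets(va) -
                                  networkForward(trainingInputs(va), p))^2)
  expect_lte(vloss(fit), vloss(th0))
})

test_that("a degenerate one-parameter problem reaches the analytic optimum", {
  # constant-input network: the only attainable predictions are constants,
  # so the l2-optimal prediction is the target mean (grid-search oracle)
  bn <- new("BinningOperator", n = 1L, ne = 1L, binIndex = c(1L, 1L))
  Z <- matrix(0, 500, 1)
  O <- rep(0.7, 500)
  mkset <- function(i) new("TrainingSet",
                           inputs = Z[i, , drop = FALSE], targets = O[i],
                           provenance = data.frame(dataset = 1, voxel = i))
  fit <- trainLMA(initParams(1, bn, seed = 2), mkset(1:400), mkset(401:500),
                  lmaConfig())
  pred <- networkForward(Z[1, , drop = FALSE], fit)
  grid <- seq(0, 1, by = 1e-4)
  opt <- grid[which.min(vapply(grid, function(p) sum((O - p)^2), numeric(1)))]
  expect_lt(abs(pred - opt), 1e-4 + 1e-6)
  expect_lt(mean((pred - O)^2), 1e-6)
})

test_that("trainNNFDK scales pair counts down to small ROIs and stores scalings", {
  N <- 16
  g <- simGeometry(N, 8)
  mkd <- function(seed) {
    spec <- ballSpec(0.2, intensity = seed)
    vol <- voxelize(spec, N)
    proj <- simulateProjections(vol, g, I0 = 4096, seed = seed)
    list(proj = proj, hq = fdk(forwardProject(vol, g), "hann", g))
  }
  ds <- list(mkd(1), mkd(2))
  expect_message(
    fit <- trainNNFDK(ds, nHidden = 2, nTrain = 1e6, nVal = 1e6, seed = 3,
                      config = lmaConfig(maxEpochs = 30, patience = 10)),
    "using nTrain")
  expect_s4_class(fit, "NNFDKParams")
  expect_identical(nHidden(fit), 2L)
  # target scaling maps the pooled ROI range into [0.05, 0.95]
  rng <- range(unlist(lapply(ds, function(d)
    range(values(d$hq)[roiMask(d$hq)]))))
  expect_equal(rng[1] * fit@targetScale + fit@targetOffset, 0.05)
  expect_equal(rng[2] * fit@targetScale + fit@targetOffset, 0.95)
  expect_true(is.finite(attr(fit, "valLoss")))
})
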