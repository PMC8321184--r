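test_that("sigmoid is stable, symmetric and saturating", {
  expect_identical(sigmoid(0), 0.5)
  t <- c(-3.2, -0.5, 0.1, 7)
  expect_equal(sigmoid(-t), 1 - sigmoid(t))
  expect_equal(sigmoid(50), 1, tolerance = 1e-12)
  expect_equal(sigmoid(-50), 0, tolerance = 1e-12)
  expect_true(all(is.finite(sigmoid(c(-750, 750)))))
})

test_that("perceptron evaluates sigmoid(eta . xi - b)", {
  expect_identical(perceptron(c(1, 2), c(0, 0), 0.3), sigmoid(-0.3))
  expect_identical(perceptron(c(2, 1, 3), c(0.5, 1, -1), -3), sigmoid(2))
  # eta . xi == b lands exactly on 0.5
  expect_identical(perceptron(c(1, 1), c(0.4, 0.6), 1), 0.5)
  # hand evaluation of a random 3-vector case
  eta <- c(0.3, -1.2, 2.0); xi <- c(1.5, 0.4, -0.7); b <- 0.25
  expect_equal(perceptron(eta, xi, b),
               1 / (1 + exp(-(0.3 * 1.5 - 1.2 * 0.4 + 2.0 * -0.7 - 0.25))))
  expect_error(perceptron(1:3, 1:2, 0), "length")
})

test_that("networkForward matches a spelled-out nested evaluation", {
  bn <- new("BinningOperator", n = 3L, ne = 3L, binIndex = rep(1:3, each = 2L))
  th <- new("NNFDKParams", binning = bn,
            hiddenFilters = matrix(c(0.2, -0.4, 1.0, -1.1, 0.6, 0.3), 3, 2),
            hiddenBiases = c(0.1, -0.2), outputWeights = c(1.4, -0.9),
            outputBias = 0.35, inputScale = c(1, 2, 0.5),
            inputOffset = c(0.1, 0, -0.3), targetScale = 2, targetOffset = 0.1)
  q <- c(0.7, -0.2, 0.9)
  zs <- (q - th@inputOffset) * th@inputScale
  h1 <- sigmoid(sum(zs * th@hiddenFilters[, 1]) - 0.1)
  h2 <- sigmoid(sum(zs * th@hiddenFilters[, 2]) + 0.2)
  want <- sigmoid(1.4 * h1 - 0.9 * h2 - 0.35)
  expect_equal(networkForward(q, th), want)
  expect_equal(networkForward(q, th, rescale = TRUE), (want - 0.1) / 2)
  # zero output weights ignore the input entirely
  th0 <- th; th0@outputWeights <- c(0, 0)
  expect_equal(networkForward(matrix(rnorm(9), 3, 3), th0),
               rep(sigmoid(-0.35), 3))
  expect_error(networkForward(c(1, 2), th), "Ne")
})

test_that("initParams is reproducible and sized by the parameter formula", {
  b <- makeBinning(64)
  p1 <- initParams(4, b, seed = 3)
  p2 <- initParams(4, b, seed = 3)
  p3 <- initParams(4, b, seed = 4)
  expect_identical(p1@hiddenFilters, p2@hiddenFilters)
  expect_false(identical(p1@hiddenFilters, p3@hiddenFilters))
  expect_identical(p1@outputBias, 0)
  expect_true(all(abs(p1@hiddenFilters) <= 1))
  expect_identical(length(nnfdk:::.packTheta(p1)), countParams(4L, b))
  expect_identical(nHidden(p1), 4L)
})

test_that("parameters survive a JSON round trip bit-exactly", {
  b <- makeBinning(32)
  th <- initParams(3, b, seed = 17)
  th@inputScale <- runif(nBins(b)); th@inputOffset <- rnorm(nBins(b))
  th@targetScale <- pi; th@targetOffset <- exp(-2)
  f <- withr::local_tempfile(fileext = ".json")
  paramsToJSON(th, f)
  th2 <- paramsFromJSON(f)
  for (s in c("hiddenFilters", "hiddenBiases", "outputWeights", "outputBias",
              "inputScale", "inputOffset", "targetScale", "targetOffset"))
    expect_identical(slot(th, s), slot(th2, s), label = s)
  expect_identical(th2@binning@binIndex, th@binning@binIndex)
})

test_that("full-volume reconstruction equals the voxelwise network (Eq-style)", {
  N <- 16
  g <- simGeometry(N, 8)
  proj <- forwardProject(voxelize(fourshapeRandom(3), N), g)
  bn <- makeBinning(g)
  th <- initParams(3, bn, seed = 7)
  set.seed(7)
  th@inputScale <- runif(nBins(bn), 0.5, 2)
  th@inputOffset <- rnorm(nBins(bn), 0, 0.1)
  th@targetScale <- 2; th@targetOffset <- 0.1
  rec <- nnfdkReconstruct(proj, th)
  Z <- featureMatrix(computeFeatureVolumes(proj), seq_len(N^3))
  net <- networkForward(Z, th, rescale = TRUE)
  expect_lt(max(abs(values(rec) - net) / pmax(abs(net), 1e-8)), 1e-5)

  # permuting hidden nodes together with their weights leaves the output fixed
  pm <- c(3, 1, 2)
  thp <- th
  thp@hiddenFilters <- th@hiddenFilters[, pm]
  thp@hiddenBiases <- th@hiddenBiases[pm]
  thp@outputWeights <- th@outputWeights[pm]
  expect_equal(values(nnfdkReconstruct(proj, thp)), values(rec))

  # zero projections give the constant no-signal response everywhere
  z <- projectionStack(array(0, dim(values(proj))), g)
  recz <- nnfdkReconstruct(z, th, greyValues = FALSE)
  b_eff <- th@hiddenBiases + colSums(th@inputOffset * th@inputScale *
                                     th@hiddenFilters)
  want <- sigmoid(sum(th@outputWeights * sigmoid(-b_eff)) - th@outputBias)
  expect_equal(as.numeric(values(recz)), rep(want, N^3))
  # raw network outputs stay strictly inside (0, 1)
  raw <- values(nnfdkReconstruct(proj, th, greyValues = FALSE))
  expect_true(all(raw > 0 & raw < 1))
})
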