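test_that("geometry construction validates its invariants", {
  g <- simGeometry(16, 8)
  expect_s4_class(g, "ConeBeamGeometry")
  expect_equal(length(angles(g)), 8)
  expect_true(all(diff(angles(g)) > 0))
  # detector too small to cover the magnified volume
  expect_error(coneBeamGeometry(100, 100, c(16, 16), 0.5, 16, 1, nAngles = 4),
               "cover")
  # bad angle lists
  expect_error(coneBeamGeometry(100, 50, c(16, 16), 2, 16, 1,
                                angles = c(0.5, 0.2)), "increasing")
  expect_error(coneBeamGeometry(100, 50, c(16, 16), 2, 16, 1,
                                angles = c(0, 7)), "2\\*pi")
  expect_error(coneBeamGeometry(-1, 50, c(16, 16), 2, 16, 1, nAngles = 4),
               "sourceToCenter")
})

test_that("projectors are linear and vanish on zero input", {
  g <- simGeometry(8, 6)
  zero <- voxelVolume(array(0, c(8, 8, 8)), voxelSize(g))
  expect_true(all(values(forwardProject(zero, g)) == 0))
  zstack <- projectionStack(array(0, c(8, 8, 6)), g)
  expect_true(all(values(backProject(zstack, g)) == 0))
  expect_true(all(values(fdkWeightedBackproject(zstack, g)) == 0))

  x1 <- randomVolume(g, 1); x2 <- randomVolume(g, 2)
  a <- 0.7; b <- -1.3
  comb <- voxelVolume(a * values(x1) + b * values(x2), voxelSize(g))
  lhs <- values(forwardProject(comb, g))
  rhs <- a * values(forwardProject(x1, g)) + b * values(forwardProject(x2, g))
  expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(rhs)))

  y1 <- randomStack(g, 3); y2 <- randomStack(g, 4)
  comby <- projectionStack(a * values(y1) + b * values(y2), g)
  for (meth in c("matched", "voxel")) {
    lhs <- values(backProject(comby, g, method = meth))
    rhs <- a * values(backProject(y1, g, method = meth)) +
           b * values(backProject(y2, g, method = meth))
    expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(rhs)))
  }
})

test_that("central ray through a homogeneous cube gives mu * chord length", {
  # cube with half-width 0.25 of a 10 cm cube: central chord 5 cm at 0.22/cm
  N <- 64
  vol <- cached("cube64", function() voxelize(cubeSpec(0.25), N))
  g <- simGeometry(N, 2)
  p <- values(forwardProject(vol, g))
  central <- mean(p[N / 2 + 0:1, N / 2 + 0:1, 1])
  expect_lt(abs(central - 0.22 * 5) / (0.22 * 5), 0.02)
})

test_that("forward projection matches an independent fine-step ray oracle", {
  g <- simGeometry(8, 3)
  vol <- randomVolume(g, 5)
  vol@values <- abs(vol@values)
  p <- values(forwardProject(vol, g))
  for (case in list(c(4, 4, 1), c(5, 4, 2), c(3, 6, 3), c(4, 5, 2))) {
    want <- oracleRayIntegral(vol, g, case[1], case[2], case[3])
    got <- p[case[1], case[2], case[3]]
    expect_lt(abs(got - want), 0.02 * max(abs(p)))
  }
})

test_that("matched backprojector is the exact transpose (explicit W oracle)", {
  g <- cached("g8w", function() simGeometry(8, 4))
  W <- cached("W8", function() explicitW(g))
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(8^3); y <- rnorm(nrow(W))
    Wx <- values(forwardProject(voxelVolume(array(x, c(8, 8, 8)),
                                            voxelSize(g)), g))
    expect_lt(max(abs(as.numeric(Wx) - W %*% x)), 1e-10)
    Wty <- values(backProject(projectionStack(array(y, dim(Wx)), g), g))
    expect_lt(max(abs(as.numeric(Wty) - crossprod(W, y))), 1e-10)
    err <- abs(sum(Wx * y) - sum(x * Wty)) /
      (sqrt(sum(Wx^2)) * sqrt(sum(y^2)))
    expect_lt(err, 1e-3)
  }
})

test_that("a single detector pixel backprojects only along its ray", {
  g <- simGeometry(8, 4)
  y <- array(0, c(8, 8, 4))
  y[3, 5, 2] <- 1
  bp <- values(backProject(projectionStack(y, g), g))
  hits <- which(bp != 0, arr.ind = TRUE)
  expect_gt(nrow(hits), 0)
  # geometric oracle: distance from voxel centre to the source-pixel line
  beta <- angles(g)[2]
  S <- c(-g@sourceToCenter * cos(beta), -g@sourceToCenter * sin(beta), 0)
  eu <- c(-sin(beta), cos(beta), 0)
  Cd <- c(g@centerToDetector * cos(beta), g@centerToDetector * sin(beta), 0)
  u <- (3 - 4.5) * g@detectorPixelSize
  v <- (5 - 4.5) * g@detectorPixelSize
  P <- Cd + u * eu + c(0, 0, v)
  d <- (P - S) / sqrt(sum((P - S)^2))
  for (r in seq_len(nrow(hits))) {
    pos <- (hits[r, ] - (8 + 1) / 2) * voxelSize(g)
    perp <- (pos - S) - sum((pos - S) * d) * d
    # within the interpolation footprint of the ray (~1 voxel diagonal)
    expect_lt(sqrt(sum(perp^2)), sqrt(3) * voxelSize(g))
  }
})

test_that("rotating the phantom one angular step equals shifting the angle list", {
  # Na = 4: one step is 90 degrees, so the rotated phantom is an exact array
  # permutation and the circular symmetry of the trajectory must be exact
  g <- simGeometry(16, 4)
  v <- values(voxelize(fourshapeRandom(5), 16))
  vr90 <- aperm(v, c(2, 1, 3))[, dim(v)[1]:1, ]   # +90 deg about z
  p0 <- values(forwardProject(voxelVolume(v, voxelSize(g)), g))
  p1 <- values(forwardProject(voxelVolume(vr90, voxelSize(g)), g))
  for (a in 1:4) {
    b <- a %% 4 + 1  # angle shifted by one step
    expect_lt(max(abs(p1[, , a] - p0[, , b])), 1e-3 * max(abs(p0)))
  }
})

test_that("FDK weight field matches the analytic distance weight", {
  g <- simGeometry(16, 5)
  y <- randomStack(g, 7)
  # single-angle stacks: the ratio must equal (Rs / (Rs + s))^2 per voxel
  g1 <- coneBeamGeometry(g@sourceToCenter, g@centerToDetector,
                         g@detectorPixels, g@detectorPixelSize, g@nVoxels,
                         g@voxelSize, angles = angles(g)[2])
  y1 <- projectionStack(values(y)[, , 2, drop = FALSE], g1)
  unw1 <- values(backProject(y1, g1, method = "voxel"))
  w1 <- values(fdkWeightedBackproject(y1, g1, normalize = FALSE))
  beta <- angles(g)[2]
  idx <- which(abs(unw1) > 1e-8, arr.ind = TRUE)
  pos <- (idx - (16 + 1) / 2) * voxelSize(g)
  tax <- pos[, 1] * cos(beta) + pos[, 2] * sin(beta) + g@sourceToCenter
  expect_lt(max(abs(w1[idx] / unw1[idx] - (g@sourceToCenter / tax)^2)), 1e-9)
  # voxels on the rotation axis carry weight ~ 1 (s = 0)
  ctr <- idx[abs(tax - g@sourceToCenter) < voxelSize(g), , drop = FALSE]
  expect_gt(nrow(ctr), 0)
  expect_lt(max(abs(w1[ctr] / unw1[ctr] - 1)), 0.02)
})

test_that("shape mismatches raise contract errors", {
  g <- simGeometry(8, 4)
  g2 <- simGeometry(16, 4)
  vol <- randomVolume(g2, 1)
  expect_error(forwardProject(vol, g), "does not match")
  y <- randomStack(g, 2)
  expect_error(backProject(y, g2), "does not match")
})
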