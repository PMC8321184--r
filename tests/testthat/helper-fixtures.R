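# Shared builders for small test scenes, with a per-session cache so that
# expensive objects (projections, feature volumes) are built once.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# a single centred ball, radius as fraction of the cube width
ballSpec <- function(radius = 0.25, intensity = 1) {
  new("PhantomSpec", primitives = list(list(
    kind = "ellipsoid", center = c(0, 0, 0),
    size = list(semi = rep(radius, 3)), orient = diag(3),
    intensity = intensity)), family = "test")
}

# axis-aligned centred cuboid
cubeSpec <- function(half = 0.25, intensity = 1) {
  new("PhantomSpec", primitives = list(list(
    kind = "cuboid", center = c(0, 0, 0),
    size = list(half = rep(half, 3)), orient = diag(3),
    intensity = intensity)), family = "test")
}

# random volume / projection stack with reproducible content
randomVolume <- function(g, seed = 1) {
  set.seed(seed)
  voxelVolume(array(rnorm(g@nVoxels^3), rep(g@nVoxels, 3)), g@voxelSize)
}

randomStack <- function(g, seed = 1) {
  set.seed(seed)
  d <- c(g@detectorPixels[2], g@detectorPixels[1], length(g@angles))
  projectionStack(array(rnorm(prod(d)), d), g)
}

# explicit system matrix W (rows = detector samples, cols = voxels) built by
# forward-projecting every unit voxel; only for tiny grids
explicitW <- function(g) {
  n <- g@nVoxels^3
  m <- prod(g@detectorPixels) * length(g@angles)
  W <- matrix(0, m, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    W[, j] <- as.numeric(values(forwardProject(
      voxelVolume(array(e, rep(g@nVoxels, 3)), g@voxelSize), g)))
  }
  W
}

# independent slow ray-marching line integral, R implementation: fine-step
# trilinear sampling from detector pixel (ju, jv) at angle index a (1-based)
oracleRayIntegral <- function(vol, g, ju, jv, a, nSteps = 4000) {
  N <- g@nVoxels; vs <- g@voxelSize
  beta <- g@angles[a]
  S <- c(-g@sourceToCenter * cos(beta), -g@sourceToCenter * sin(beta), 0)
  Cd <- c(g@centerToDetector * cos(beta), g@centerToDetector * sin(beta), 0)
  eu <- c(-sin(beta), cos(beta), 0)
  u <- (ju - (g@detectorPixels[2] + 1) / 2) * g@detectorPixelSize
  v <- (jv - (g@detectorPixels[1] + 1) / 2) * g@detectorPixelSize
  P <- Cd + u * eu + c(0, 0, v)
  d <- (P - S) / sqrt(sum((P - S)^2))
  # cube [-h, h]^3 entry/exit
  h <- N * vs / 2
  t0 <- -Inf; t1 <- Inf
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) next
    tt <- sort(c((-h - S[ax]) / d[ax], (h - S[ax]) / d[ax]))
    t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
  }
  if (t1 <= t0) return(0)
  ts <- t0 + (seq_len(nSteps) - 0.5) * (t1 - t0) / nSteps
  trilin <- function(p) {
    gx <- p[1] / vs + (N - 1) / 2
    gy <- p[2] / vs + (N - 1) / 2
    gz <- p[3] / vs + (N - 1) / 2
    i0 <- floor(gx); j0 <- floor(gy); k0 <- floor(gz)
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      i <- i0 + di; j <- j0 + dj; k <- k0 + dk
      if (i < 0 || i >= N || j < 0 || j >= N || k < 0 || k >= N) next
      w <- (if (di) gx - i0 else 1 - gx + i0) *
           (if (dj) gy - j0 else 1 - gy + j0) *
           (if (dk) gz - k0 else 1 - gz + k0)
      acc <- acc + w * values(vol)[i + 1, j + 1, k + 1]
    }
    acc
  }
  sum(vapply(ts, function(t) trilin(S + t * d), numeric(1))) *
    (t1 - t0) / nSteps * 0.1
}
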