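# Synthetic phantom families and the cone-beam data simulator. Phantoms are
# described analytically in a unit cube centred at the origin and voxelized
# on demand at any N; intensities are relative and additive and are mapped
# to attenuation 0.22 1/cm (common plastics at ~40 keV) when the cube is
# scaled to a 10 cm physical width. Primitives are kept inside the inscribed
# field-of-view sphere (radius 0.475 of the cube width) so that every
# projection in the default geometry is untruncated.

.MU_PLASTIC <- 0.22   # 1/cm, base attenuation for intensity 1
.CUBE_MM <- 100       # physical cube width
.FOV_RADIUS <- 0.475  # primitives stay inside this sphere (cube units)

#' Random Fourshape phantom
#'
#' Three random occurrences of each of four primitive types (ellipsoid,
#' cuboid, Gaussian blob, Siemens star): 12 primitives with randomized
#' centres, sizes, orientations and intensities. Deterministic given the
#' seed.
#'
#' @param seed RNG seed.
#' @param sizeRange half-extent range, as a fraction of the cube width.
#' @param intensityRange relative intensity range.
#' @param nSpokes bright wedges of the Siemens star.
#' @return a \linkS4class{PhantomSpec} with 12 primitives.
#' @export
fourshapeRandom <- function(seed = 1L, sizeRange = c(0.025, 0.15),
                            intensityRange = c(0.5, 1.5), nSpokes = 8L) {
  rng <- .seededRNG(seed)
  u <- function(lo, hi, n = 1L) lo + (hi - lo) * rng(n)
  prims <- list()
  for (kind in c("ellipsoid", "cuboid", "gaussian_blob", "siemens_star")) {
    for (i in 1:3) {
      orient <- .randRotation(rng)
      size <- switch(kind,
        ellipsoid = list(semi = u(sizeRange[1], sizeRange[2], 3)),
        cuboid = list(half = u(sizeRange[1], sizeRange[2], 3)),
        gaussian_blob = list(sigma = u(sizeRange[1] / 2, sizeRange[2] / 3, 3)),
        siemens_star = list(radius = u(2 * sizeRange[1], sizeRange[2]),
                            halfHeight = u(sizeRange[1] / 2, sizeRange[2] / 2),
                            nSpokes = nSpokes))
      rmax <- .boundRadius(kind, size)
      prims[[length(prims) + 1L]] <- list(
        kind = kind,
        center = .randInBall(rng, max(.FOV_RADIUS - rmax, 0)),
        size = size, orient = orient,
        intensity = u(intensityRange[1], intensityRange[2]))
    }
  }
  new("PhantomSpec", primitives = prims, family = "fourshape")
}

.boundRadius <- function(kind, size) {
  switch(kind,
    ellipsoid = max(size$semi),
    cuboid = sqrt(sum(size$half^2)),
    gaussian_blob = 3 * max(size$sigma),
    siemens_star = ,
    disk = sqrt(size$radius^2 + size$halfHeight^2))
}

.randRotation <- function(rng) {
  m <- matrix(stats::qnorm(rng(9L)), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.randInBall <- function(rng, radius) {
  repeat {
    p <- rng(3L) * 2 - 1
    if (sum(p^2) <= 1) return(p * radius)
  }
}

#' Standard Defrise phantom
#'
#' A stack of equally spaced flat disks of equal intensity, symmetric about
#' the axial midplane; the classic phantom for exposing cone-angle artifacts
#' of circular trajectories.
#'
#' @param nDisks number of disks.
#' @param radius disk radius (cube units).
#' @param halfThickness half of the disk thickness (cube units).
#' @return a \linkS4class{PhantomSpec}.
#' @export
defriseStandard <- function(nDisks = 7L, radius = 0.4, halfThickness = 0.022) {
  zc <- (seq_len(nDisks) - (nDisks + 1) / 2) * (0.85 / nDisks)
  prims <- lapply(zc, function(z) list(
    kind = "disk", center = c(0, 0, z),
    size = list(radius = radius, halfHeight = halfThickness),
    orient = diag(3), intensity = 1))
  new("PhantomSpec", primitives = prims, family = "defrise")
}

#' Random Defrise phantom
#'
#' Disks with randomized radii, thicknesses, tilts and intensities, placed
#' along the axis without overlap. Errors out if a non-overlapping placement
#' is not found within a bounded number of retries.
#'
#' @param seed RNG seed.
#' @param nDisks number of disks.
#' @param maxTiltDeg maximum tilt of a disk from the transaxial plane.
#' @param maxTries placement retries before giving up.
#' @return a \linkS4class{PhantomSpec}.
#' @export
defriseRandom <- function(seed = 1L, nDisks = 6L, maxTiltDeg = 5,
                          maxTries = 200L) {
  rng <- .seededRNG(seed)
  u <- function(lo, hi, n = 1L) lo + (hi - lo) * rng(n)
  for (try in seq_len(maxTries)) {
    prims <- list(); top <- -0.45; ok <- TRUE
    for (i in seq_len(nDisks)) {
      radius <- u(0.25, 0.4)
      ht <- u(0.012, 0.03)
      tilt <- u(0, maxTiltDeg * pi / 180)
      axis <- u(0, 2 * pi)
      # rotation by `tilt` about a random axis in the xy-plane
      R <- .axisRotation(c(cos(axis), sin(axis), 0), tilt)
      zext <- ht * cos(tilt) + radius * sin(tilt)
      zc <- top + u(0.01, 0.05) + zext
      if (zc + zext > 0.45) { ok <- FALSE; break }
      prims[[i]] <- list(kind = "disk", center = c(0, 0, zc),
                         size = list(radius = radius, halfHeight = ht),
                         orient = R, intensity = u(0.5, 1.5))
      top <- zc + zext
    }
    if (ok) return(new("PhantomSpec", primitives = prims, family = "defrise"))
  }
  stop("could not place ", nDisks, " non-overlapping disks after ",
       maxTries, " retries")
}

.axisRotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

setMethod("show", "PhantomSpec", function(object) {
  kinds <- vapply(object@primitives, `[[`, character(1), "kind")
  cat(sprintf("PhantomSpec '%s': %d primitives (%s)\n", object@family,
              length(kinds), paste(names(table(kinds)), table(kinds),
                                   sep = ":", collapse = ", ")))
})

#' Voxelize a phantom
#'
#' Samples the analytic phantom on a supersampled grid (2x per axis by
#' default) and block-averages, which handles partial-volume voxels. Base
#' intensity 1 maps to 0.22 1/cm; the cube is 10 cm wide, so the voxel pitch
#' is 100 / N mm.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param N output volume size.
#' @param supersample linear supersampling factor.
#' @return a \linkS4class{VoxelVolume}.
#' @export
voxelize <- function(spec, N, supersample = 2L) {
  N <- as.integer(N)
  if (N < 16L) stop("N must be >= 16")
  s <- as.integer(supersample)
  sn <- s * N
  g <- (seq_len(sn) - 0.5) / sn - 0.5
  px <- rep(g, times = sn * sn)
  py <- rep(rep(g, each = sn), times = sn)
  pz <- rep(g, each = sn * sn)
  vals <- numeric(sn^3)
  for (pr in spec@primitives)
    vals <- vals + .primitiveValues(pr, px, py, pz)
  vals <- vals * .MU_PLASTIC
  dim(vals) <- c(sn, sn, sn)
  if (s > 1L) {
    out <- 0
    for (dx in seq_len(s)) for (dy in seq_len(s)) for (dz in seq_len(s))
      out <- out + vals[seq(dx, sn, s), seq(dy, sn, s), seq(dz, sn, s)]
    vals <- out / s^3
  }
  voxelVolume(vals, .CUBE_MM / N)
}

.primitiveValues <- function(pr, px, py, pz) {
  R <- pr$orient; c0 <- pr$center
  dx <- px - c0[1]; dy <- py - c0[2]; dz <- pz - c0[3]
  qx <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
  qy <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
  qz <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz
  s <- pr$size
  inside <- switch(pr$kind,
    ellipsoid = (qx / s$semi[1])^2 + (qy / s$semi[2])^2 +
                (qz / s$semi[3])^2 <= 1,
    cuboid = abs(qx) <= s$half[1] & abs(qy) <= s$half[2] &
             abs(qz) <= s$half[3],
    gaussian_blob = return(pr$intensity *
      exp(-0.5 * ((qx / s$sigma[1])^2 + (qy / s$sigma[2])^2 +
                  (qz / s$sigma[3])^2))),
    disk = qx^2 + qy^2 <= s$radius^2 & abs(qz) <= s$halfHeight,
    siemens_star = {
      base <- qx^2 + qy^2 <= s$radius^2 & abs(qz) <= s$halfHeight
      sector <- floor((atan2(qy, qx) + pi) / (pi / s$nSpokes))
      base & (sector %% 2 == 0)
    },
    stop("unknown primitive kind: ", pr$kind))
  pr$intensity * inside
}

#' Simulate cone-beam projections with Beer-Lambert Poisson noise
#'
#' Computes clean line integrals by forward projection; if an emitted photon
#' count I0 is given, detected counts are drawn as Poisson(I0 * exp(-y)) and
#' converted back to line integrals with -ln(max(c, 1) / I0) (the clamp keeps
#' fully absorbed rays finite). \code{I0 = NULL} returns the noiseless data.
#'
#' @param vol a \linkS4class{VoxelVolume}.
#' @param geometry a matching \linkS4class{ConeBeamGeometry}.
#' @param I0 emitted photon count per detector pixel, or NULL for no noise.
#' @param seed RNG seed for the Poisson draw.
#' @return a \linkS4class{ProjectionStack}.
#' @export
simulateProjections <- function(vol, geometry, I0 = NULL, seed = 1L) {
  proj <- forwardProject(vol, geometry)
  if (is.null(I0)) return(proj)
  y <- proj@values
  counts <- .withSeed(seed, rpois(length(y), I0 * exp(-y)))
  ynoisy <- -log(pmax(counts, 1) / I0)
  dim(ynoisy) <- dim(y)
  projectionStack(ynoisy, geometry)
}

#' High-quality training target
#'
#' The supervised-learning target: a dense, low-noise acquisition (1500
#' angles, emitted photon count 2^20) of the same phantom, reconstructed
#' with FDK and a Hann filter.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param N volume size.
#' @param seed RNG seed for the (weak) Poisson noise.
#' @param geometry template geometry for distances; the angle list is
#'   replaced by \code{nAngles} equidistant angles. Default
#'   \code{simGeometry(N, nAngles)}.
#' @param nAngles number of projection angles for the dense scan.
#' @param I0 emitted photon count of the dense scan.
#' @param vol optional pre-voxelized ground truth of \code{spec} at \code{N}
#'   (avoids re-voxelizing when the caller already has it).
#' @return a \linkS4class{VoxelVolume}.
#' @export
makeHQTarget <- function(spec, N, seed = 1L, geometry = NULL,
                         nAngles = 1500L, I0 = 2^20, vol = NULL) {
  g <- if (is.null(geometry)) simGeometry(N, nAngles)
       else coneBeamGeometry(geometry@sourceToCenter, geometry@centerToDetector,
                             geometry@detectorPixels, geometry@detectorPixelSize,
                             geometry@nVoxels, geometry@voxelSize,
                             nAngles = nAngles)
  if (is.null(vol)) vol <- voxelize(spec, N)
  proj <- simulateProjections(vol, g, I0 = I0, seed = seed)
  out <- fdk(proj, "hann", g)
  attr(out, "nAngles") <- length(g@angles)
  out
}
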