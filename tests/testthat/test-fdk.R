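test_that("reweighting applies the cosine weight field", {
  g <- simGeometry(16, 3)
  y <- projectionStack(array(1, c(16, 16, 3)), g)
  w <- values(reweight(y, g))
  D <- g@sourceToCenter + g@centerToDetector
  # centre 2x2 block sits half a pixel off-axis; weight just below 1
  expect_lt(max(abs(w[8:9, 8:9, 1] -
    D / sqrt(D^2 + 2 * (g@detectorPixelSize / 2)^2))), 1e-12)
  # radially symmetric and strictly decreasing from the centre
  expect_equal(w[, , 1], w[16:1, , 1])
  expect_equal(w[, , 1], w[, 16:1, 1])
  mid <- w[9:16, 9, 1]
  expect_true(all(diff(mid) < 0))
  # analytic point: u^2 + v^2 = 3 D^2 gives weight exactly 1/2
  expect_equal(D / sqrt(D^2 + 3 * D^2), 0.5)
})

test_that("1D filtering matches a direct convolution oracle", {
  g <- simGeometry(8, 2)
  set.seed(4)
  y <- randomStack(g, 4)
  h <- rnorm(16)
  out <- values(applyFilter1D(y, new("Filter1D", taps = h, name = "t"), g))
  # direct O(N^2) sum: out[i] = sum_j h[j] y[i - j + N + 1]
  for (a in 1:2) for (v in c(1, 5)) {
    row <- values(y)[, v, a]
    want <- vapply(1:8, function(i) {
      s <- 0
      for (j in 1:16) {
        k <- i - j + 8 + 1
        if (k >= 1 && k <= 8) s <- s + h[j] * row[k]
      }
      s
    }, numeric(1))
    expect_lt(max(abs(out[, v, a] - want)), 1e-10)
  }
  # centred unit impulse reproduces the input
  imp <- numeric(16); imp[9] <- 1
  same <- values(applyFilter1D(y, new("Filter1D", taps = imp, name = "i"), g))
  expect_lt(max(abs(same - values(y))), 1e-12)
  # wrong length errors
  expect_error(applyFilter1D(y, new("Filter1D", taps = numeric(8), name = "x"),
                             g), "length")
})

test_that("standard filters have the closed-form ramp structure", {
  g <- simGeometry(32, 8)
  rl <- standardFilter("ram-lak", g)
  h <- taps(rl)
  ctr <- 33
  dv <- g@detectorPixelSize / magnification(g) * 0.1
  # centre tap positive and equal to the closed-form value; the DFT-sampled
  # taps equal pitch times the continuous ramp coefficients, so h[0] = 1/(4 d)
  expect_gt(h[ctr], 0)
  expect_lt(abs(h[ctr] - 1 / (4 * dv)) / h[ctr], 0.01)
  offs <- seq_along(h) - ctr
  # even-offset taps vanish, odd-offset taps are negative
  expect_lt(max(abs(h[offs != 0 & offs %% 2 == 0])), 1e-9 * h[ctr])
  expect_true(all(h[offs %% 2 != 0] < 0))
  # odd taps follow -1 / (pi^2 n^2 d) closely away from the truncation edge
  n <- c(1, 3, 5)
  expect_lt(max(abs(h[ctr + n] + 1 / (pi^2 * n^2 * dv)) /
                abs(h[ctr + n])), 0.02)

  # frequency responses: zero DC for both; Hann also zero at Nyquist
  Hrl <- Re(fft(h[c(ctr:64, 1:(ctr - 1))]))
  expect_lt(abs(Hrl[1]), 1e-9 * max(abs(Hrl)))
  hn <- taps(standardFilter("hann", g))
  Hhn <- Re(fft(hn[c(ctr:64, 1:(ctr - 1))]))
  expect_lt(abs(Hhn[1]), 1e-9 * max(abs(Hhn)))
  expect_lt(abs(Hhn[33]), 1e-9 * max(abs(Hhn)))     # Nyquist bin
  expect_true(all(abs(Hhn) <= abs(Hrl) + 1e-9))
  expect_error(standardFilter("cosine", g))

  # Ram-Lak has zero DC gain: constant rows filter to ~0 away from the row
  # ends (linear convolution truncates the tap tails, leaving ~2% residue)
  const <- projectionStack(array(1, c(32, 32, 8)), g)
  out <- values(applyFilter1D(const, rl, g))
  expect_lt(max(abs(out[8:24, , ])), 0.04 * h[ctr])
})

test_that("fdk is bilinear and homogeneous in its inputs", {
  g <- simGeometry(32, 12)
  y <- randomStack(g, 9)
  h1 <- standardFilter("ram-lak", g)
  h2 <- standardFilter("hann", g)
  a <- 0.6; b <- -2.1
  comb <- new("Filter1D", taps = a * taps(h1) + b * taps(h2), name = "c")
  lhs <- values(fdk(y, comb, g))
  rhs <- a * values(fdk(y, h1, g)) + b * values(fdk(y, h2, g))
  expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(rhs)))
  # homogeneity in the projections
  y3 <- projectionStack(3 * values(y), g)
  expect_lt(max(abs(values(fdk(y3, h2, g)) - 3 * values(fdk(y, h2, g)))),
            1e-9 * max(abs(values(fdk(y, h2, g)))))
  # zero data reconstruct to zero
  z <- projectionStack(array(0, dim(values(y))), g)
  expect_true(all(values(fdk(z, h1, g)) == 0))
})

test_that("fdk recovers the attenuation value of a homogeneous ellipsoid", {
  N <- 64
  vol <- cached("ball64", function() voxelize(ballSpec(0.25), N))
  g <- simGeometry(N, 128)
  proj <- cached("ballproj64", function() forwardProject(vol, g))
  rec <- fdk(proj, "hann", g)
  inside <- values(vol) > 0.21
  expect_lt(abs(mean(values(rec)[inside]) - 0.22) / 0.22, 0.10)
})

test_that("Hann amplifies high-frequency noise less than Ram-Lak", {
  g <- simGeometry(32, 16)
  set.seed(12)
  noise <- projectionStack(array(rnorm(32 * 32 * 16), c(32, 32, 16)), g)
  vh <- var(as.numeric(values(fdk(noise, "hann", g))))
  vr <- var(as.numeric(values(fdk(noise, "ram-lak", g))))
  expect_lt(vh, vr)
})
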