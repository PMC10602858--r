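# PMF feature extraction: minima, barriers, crossover, plateaus, gaps and
# the derived energetic constructs

grid <- function(lo, hi, bw = 0.1) seq(lo + bw / 2, hi, by = bw)

test_that("a discretized parabola has a single minimum at its vertex", {
  xs <- grid(1, 9)
  p <- pmfProfile(xs, 0.5 * 8 * (xs - 4.57)^2)
  m <- findMinima(p)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$x - 4.57), 0.1)
  expect_true(m$global)
})

test_that("the planted double well is read back feature-for-feature", {
  ls <- makeDoubleWell(10.4, 14.2, barrier = 3.19, asymmetry = -1.1)
  p <- landscapeToProfile(ls)
  m <- findMinima(p)
  expect_equal(nrow(m), 2L)
  expect_lt(max(abs(m$x - c(10.4, 14.2))), 0.1)
  expect_equal(m$F[1] - m$F[2], 1.1, tolerance = 0.02)
  b <- barrierBetween(p, m$x[1], m$x[2])
  expect_true(b$found)
  reg <- landscapeFeatures(ls)
  expect_lt(abs(b$x - reg$barrier$x), 0.1)
  expect_equal(b$height, 3.19, tolerance = 0.02)
  expect_equal(b$height_from_global, b$height + 1.1, tolerance = 0.03)
})

test_that("sub-prominence noise does not create spurious minima", {
  xs <- grid(1, 9)
  set.seed(12)
  noisy <- 0.5 * 8 * (xs - 4.57)^2 + runif(length(xs), -0.05, 0.05)
  m <- findMinima(pmfProfile(xs, noisy), prominence = 0.25)
  expect_equal(nrow(m), 1L)
})

test_that("findMinima input guards fire", {
  xs <- grid(1, 9)
  p <- pmfProfile(xs, rep(NA_real_, length(xs)))
  expect_error(findMinima(p), "all bins are masked")
  expect_error(findMinima(pmfProfile(c(1, 1.1), c(0, 1))), "3 unmasked")
})

test_that("a monotone segment yields a no-barrier result", {
  xs <- grid(0, 10)
  p <- pmfProfile(xs, 2 * xs)
  b <- barrierBetween(p, 2, 8)
  expect_false(b$found)
})

test_that("barrierBetween agrees with a dense-grid argmax oracle", {
  set.seed(31)
  for (i in 1:10) {
    x1 <- runif(1, 4, 8); x2 <- x1 + runif(1, 2.5, 5)
    ls <- makeDoubleWell(x1, x2, runif(1, 1, 5),
                         runif(1, -0.5, 0.5))
    p <- landscapeToProfile(ls, binWidth = 0.05)
    m <- findMinima(p)
    b <- barrierBetween(p, m$x[1], m$x[nrow(m)])
    idx <- which(binCenters(p) > m$x[1] & binCenters(p) < m$x[nrow(m)])
    oracle <- idx[which.max(pmfValues(p)[idx])]
    nearest <- function(x) which.min(abs(binCenters(p) - x))
    expect_equal(b$x, binCenters(p)[oracle])
    expect_equal(b$height,
                 pmfValues(p)[oracle] -
                   max(pmfValues(p)[nearest(m$x[1])],
                       pmfValues(p)[nearest(m$x[nrow(m)])]))
  }
})

test_that("crossoverPoint: harmonic profiles have none, planted kinks are found", {
  xs <- grid(1, 9, 0.05)
  harm <- pmfProfile(xs, 0.5 * 13.3 * (xs - 3.1)^2)
  expect_null(crossoverPoint(harm, 3.1))

  # harmonic well switching to a shallow line at xc: the epsilon band is
  # crossed where 0.5 c (x - x0)^2 - [F(xc) + s (x - xc)] = epsilon
  x0 <- 3.1; cc <- 13.3; xc <- 4.5; s <- 2
  Fc <- 0.5 * cc * (xc - x0)^2
  Fx <- ifelse(xs <= xc, 0.5 * cc * (xs - x0)^2, Fc + s * (xs - xc))
  p <- pmfProfile(xs, Fx)
  got <- crossoverPoint(p, x0, fitHalfwidth = 1.4, epsilon = 1.0)
  expect_false(is.null(got))
  analytic <- uniroot(function(x) {
    0.5 * cc * (x - x0)^2 - (Fc + s * (x - xc)) - 1.0
  }, c(xc, 9))$root
  expect_lt(abs(got$x - analytic), 0.1)
})

test_that("a hairpin-like profile leaves its elastic cage near 13 kcal/mol", {
  # harmonic basin around 3.1 A; softer rise past ~4.5 A, as read off the
  # inserted-state insertion profile
  xs <- grid(1.5, 10, 0.05)
  x0 <- 3.1; cc <- 13.3; xc <- 4.5; s <- 3.5
  Fc <- 0.5 * cc * (xc - x0)^2   # ~13 kcal/mol at the slope change
  Fx <- ifelse(xs <= xc, 0.5 * cc * (xs - x0)^2, Fc + s * (xs - xc))
  got <- crossoverPoint(pmfProfile(xs, Fx), x0, fitHalfwidth = 1.4,
                        epsilon = 1.0)
  expect_equal(got$F, 13, tolerance = 0.15)
})

test_that("plateau detection matches planted bounds and level", {
  xs <- grid(0, 10)
  flat <- pmfProfile(xs, rep(2, length(xs)))
  pl <- plateauRegions(flat)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$lo, min(xs))
  expect_equal(pl$hi, max(xs))

  ls <- makeWellPlusPlateau(4.57, 4.0, domain = c(2.5, 17))
  p <- landscapeToProfile(ls)
  reg <- landscapeFeatures(ls)$plateaus
  got <- plateauRegions(p)
  expect_gte(nrow(got), 1L)
  main <- got[which.max(got$hi - got$lo), ]
  expect_equal(main$mean_F, 4.0, tolerance = 0.05)
  expect_lt(abs(main$lo - reg$lo[which.max(reg$hi - reg$lo)]), 0.3)

  # a strict parabola is flat only near the vertex
  par <- pmfProfile(xs, 0.5 * 2 * (xs - 5)^2)
  gotPar <- plateauRegions(par, slopeTol = 0.2, minSpan = 0.3)
  expect_true(all(abs((gotPar$lo + gotPar$hi) / 2 - 5) < 0.5))
})

test_that("energyGap is a nearest-bin antisymmetric lookup", {
  ls <- makeDoubleWell(10.4, 14.2, barrier = 3.19, asymmetry = -1.1)
  p <- landscapeToProfile(ls)
  expect_equal(energyGap(p, 12, 12), 0)
  expect_equal(energyGap(p, 10.4, 14.2), -energyGap(p, 14.2, 10.4))
  expect_equal(energyGap(p, 14.2, 10.4), 1.1, tolerance = 0.02)
  expect_error(energyGap(p, 50, 12), "outside")
})

test_that("deinsertion energy reproduces the worked example", {
  expect_equal(deinsertionEnergy(41.81, 46.77), 4.96, tolerance = 1e-12)
  expect_equal(deinsertionEnergy(5, 5), 0)
  expect_equal(deinsertionEnergy(46.77, 41.81),
               deinsertionEnergy(41.81, 46.77))
  expect_error(deinsertionEnergy(-1, 2), "non-negative")
})

test_that("deinsertion energy from two profiles matches the magnitudes", {
  xs <- grid(2, 12, 0.05)
  # downhill insertion (bases out): F falls by 41.81 from deinserted to
  # inserted; uphill (bases in): F rises by 46.77
  downF <- (41.81 / 8) * (xs - 3)
  upF <- 46.77 - (46.77 / 8) * (xs - 3)
  down <- pmfProfile(xs, downF)
  up <- pmfProfile(xs, upF)
  expect_equal(deinsertionEnergy(down, up, xInserted = 3, xDeinserted = 11),
               4.96, tolerance = 0.02)
})

test_that("flipping cost from the association hump matches its energy gap", {
  xs <- grid(10, 30)
  ls <- makePiecewiseLandscape(c(10, 11.5, 13.5, 16.9, 19, 30),
                               c(30, 23.9, 9, 0, 2.5, 13))
  p <- landscapeToProfile(ls)
  cost <- flippingCostFromHump(p, xHump = 11.5, xMin = 16.9)
  expect_equal(cost, 23.9, tolerance = 0.05)
  expect_equal(cost, energyGap(p, 16.9, 11.5))
  expect_equal(flippingCostFromHump(p, 16.9, 16.9), 0)
})

test_that("feature outputs are invariant to a constant shift before anchoring", {
  ls <- makeDoubleWell(10.4, 14.2, barrier = 3.19, asymmetry = -1.1)
  xs <- grid(8, 16.5, 0.05)
  Fx <- landscapeEnergy(ls, xs)
  a <- pmfFeatures(pmfProfile(xs, Fx))
  b <- pmfFeatures(pmfProfile(xs, Fx + 57.3))
  expect_equal(a$minima, b$minima)
  expect_equal(a$barriers, b$barriers)
  expect_equal(a$plateaus, b$plateaus)
})

test_that("feature reports serialize to JSON", {
  ls <- makeDoubleWell(10.4, 14.2, barrier = 3.19, asymmetry = -1.1)
  feats <- pmfFeatures(landscapeToProfile(ls))
  f <- withr::local_tempfile(fileext = ".json")
  writeFeatures(feats, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(back$minima), 2L)
})
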