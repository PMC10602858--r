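# WHAM estimator: harmonic-limit oracle, parameter recovery, invariances,
# bootstrap uncertainties

mkSeries <- function(samples, center, k) {
  new("BiasedTimeSeries",
      window = new("UmbrellaWindow", center = center, kEq = k, kProd = k,
                   nEq = 0L, nProd = length(samples)),
      samples = samples, provenance = "test")
}

# draw samples exactly from the Boltzmann law of landscape + bias on a fine
# grid (independent of the Langevin engine)
boltzmannSeries <- function(landscape, center, k, n, kT = KB_KCAL * 300) {
  xs <- seq(landscape@domain[1], landscape@domain[2], by = 0.01)
  w <- landscapeEnergy(landscape, xs) + 0.5 * k * (xs - center)^2
  p <- exp(-(w - min(w)) / kT)
  idx <- sample.int(length(xs), n, replace = TRUE, prob = p)
  mkSeries(xs[idx] + runif(n, -0.005, 0.005), center, k)
}

test_that("the bias divides out exactly on a flat landscape", {
  flat <- makeFlatLandscape(c(2, 14))
  cfg <- engineConfig(dt = 0.002, sampleStride = 5, seed = 19)
  s <- simulateBiased(flat, harmonicBias(8, 10), nSteps = 1.2e6, cfg)
  p <- wham(list(mkSeries(as.numeric(s), 8, 10)), whamConfig())
  sigma <- sqrt(engineKT(cfg) / 10)
  central <- abs(binCenters(p) - 8) <= 2 * sigma
  expect_gte(sum(central), 8)
  expect_lt(max(pmfValues(p)[central]) - min(pmfValues(p)[central]), 0.15)
  expect_identical(min(pmfValues(p)), 0)
})

test_that("WHAM recovers a planted double well from umbrella sampling", {
  ls <- makeDoubleWell(10.4, 14.2, barrier = 4.0, asymmetry = -1.1)
  reg <- landscapeFeatures(ls)
  sched <- buildSchedule(8.5, 16.5, 0.4, 100, 10, nEq = 300L,
                         nProd = 20000L)
  expect_equal(nWindows(sched), 21L)
  cfg <- engineConfig(dt = 0.001, sampleStride = 10, seed = 23)
  ser <- runUmbrella(ls, sched, cfg)
  p <- wham(ser, whamConfig())
  m <- findMinima(p)
  expect_equal(nrow(m), 2L)
  expect_lt(max(abs(m$x - reg$minima$x)), 0.2)
  b <- barrierBetween(p, m$x[1], m$x[2])
  expect_true(b$found)
  expect_equal(b$height, reg$barrier$height_metastable, tolerance = 0.1)
})

test_that("exact Boltzmann samples reproduce the landscape within 0.3 kcal/mol RMS", {
  ls <- makeDoubleWell(9, 13, barrier = 3, asymmetry = 1.2)
  set.seed(101)
  ser <- lapply(seq(8, 14, by = 0.5), function(c0) {
    boltzmannSeries(ls, c0, 10, 8000)
  })
  p <- wham(ser, whamConfig())
  truth <- landscapeEnergy(ls, binCenters(p))
  truth <- truth - min(truth)
  band <- pmfValues(p) <= 6 & truth <= 6
  rms <- sqrt(mean((pmfValues(p)[band] - truth[band])^2))
  expect_lt(rms, 0.3)
})

test_that("anchoring, window order and window splitting leave the profile unchanged", {
  ls <- makeDoubleWell(9, 12, barrier = 2.5, asymmetry = -0.8)
  set.seed(55)
  ser <- lapply(seq(8, 13, by = 0.5), function(c0) {
    boltzmannSeries(ls, c0, 10, 3000)
  })
  p <- wham(ser, whamConfig())
  expect_identical(min(pmfValues(p)), 0)

  pShuffled <- wham(rev(ser), whamConfig())
  expect_equal(pmfValues(pShuffled), pmfValues(p), tolerance = 1e-5)

  # split one window's samples into two windows with the identical bias
  s1 <- ser[[5]]
  h <- length(s1@samples) %/% 2
  serSplit <- c(ser[-5],
                list(mkSeries(s1@samples[1:h], s1@window@center, 10),
                     mkSeries(s1@samples[(h + 1):length(s1@samples)],
                              s1@window@center, 10)))
  pSplit <- wham(serSplit, whamConfig())
  common <- match(round(binCenters(p), 6), round(binCenters(pSplit), 6))
  expect_equal(pmfValues(pSplit)[common], pmfValues(p), tolerance = 1e-4)
})

test_that("WHAM error handling: empty input, gaps, non-convergence", {
  expect_error(wham(list()), "non-empty")
  a <- mkSeries(rnorm(2000, 2, 0.2), 2, 10)
  b <- mkSeries(rnorm(2000, 12, 0.2), 12, 10)
  expect_error(wham(list(a, b)), "disconnected")
  c1 <- mkSeries(rnorm(2000, 7.9, 0.25), 7.9, 10)
  c2 <- mkSeries(rnorm(2000, 8.3, 0.25), 8.3, 10)
  expect_error(wham(list(c1, c2), whamConfig(maxIterations = 1)),
               "did not converge")
})

test_that("duplicate samples give near-zero bootstrap uncertainty", {
  # every window holds one repeated value: resampling cannot change anything
  centers <- seq(7.55, 8.35, by = 0.1)  # bin midpoints of the 0.1 A grid
  ser <- lapply(centers, function(c0) mkSeries(rep(c0, 300), c0, 10))
  p <- bootstrapUncertainty(ser, whamConfig(nBootstrap = 8), seed = 3)
  expect_lt(max(pmfUncertainty(p), na.rm = TRUE), 1e-8)
})

test_that("bootstrap uncertainty scales like one over sqrt(samples)", {
  ls <- makeDoubleWell(9, 12, barrier = 2, asymmetry = 0)
  centers <- seq(8.25, 12.75, by = 0.25)
  mkSet <- function(n, seed) {
    set.seed(seed)
    lapply(centers, function(c0) boltzmannSeries(ls, c0, 10, n))
  }
  cfg <- whamConfig(nBootstrap = 30L)
  pSmall <- bootstrapUncertainty(mkSet(1500, 1), cfg, seed = 11)
  pBig <- bootstrapUncertainty(mkSet(6000, 2), cfg, seed = 12)
  common <- intersect(round(binCenters(pSmall), 6),
                      round(binCenters(pBig), 6))
  uS <- pmfUncertainty(pSmall)[match(common, round(binCenters(pSmall), 6))]
  uB <- pmfUncertainty(pBig)[match(common, round(binCenters(pBig), 6))]
  ok <- is.finite(uS) & is.finite(uB) & uS > 0
  ratio <- median(uB[ok] / uS[ok])
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("bootstrap replicates are self-consistent with the point estimate", {
  ls <- makeDoubleWell(9, 12, barrier = 2, asymmetry = -0.5)
  set.seed(77)
  ser <- lapply(seq(8.5, 12.5, by = 0.5), function(c0) {
    boltzmannSeries(ls, c0, 10, 3000)
  })
  p <- bootstrapUncertainty(ser, whamConfig(nBootstrap = 12L), seed = 5)
  u <- pmfUncertainty(p)
  ok <- is.finite(u) & u > 0
  # pooled deviation between truth and estimate stays of the order of the
  # reported uncertainty over the sampled range
  truth <- landscapeEnergy(ls, binCenters(p))
  truth <- truth - min(truth)
  dev <- abs(pmfValues(p) - truth)[ok]
  expect_lt(median(dev / u[ok]), 3)
})

test_that("PMF TSV round trip preserves the profile", {
  flat <- makeFlatLandscape(c(2, 14))
  set.seed(2)
  p <- wham(list(mkSeries(rnorm(5000, 8, 0.3), 8, 10)), whamConfig(),
            cvName = "eta")
  f <- withr::local_tempfile(fileext = ".tsv")
  writePMF(p, f)
  p2 <- readPMF(f)
  expect_equal(binCenters(p2), binCenters(p))
  expect_equal(pmfValues(p2), pmfValues(p), tolerance = 1e-9)
  expect_equal(p2@cvName, "eta")
})
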