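# Kabsch superposition, RMSD, GROMOS clustering and metastable-state
# selection

test_that("superposition RMSD: identity, rigid invariance, reflection guard", {
  s <- makeToyComplex(c(eta = 5), nDecorationAtoms = 5L, seed = 1)
  fit <- superposeRmsd(s, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  set.seed(6)
  for (i in 1:5) {
    b <- rigidTransform(s)
    fit <- superposeRmsd(s, b)
    expect_equal(fit$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
})

test_that("rmsd of one displaced atom among ten follows the explicit formula", {
  xyz <- matrix(rnorm(30), ncol = 3)
  a <- simpleStructure(xyz)
  xyz2 <- xyz
  xyz2[4, 1] <- xyz2[4, 1] + 1
  b <- simpleStructure(xyz2)
  expect_equal(structureRmsd(a, b, superpose = FALSE), sqrt(1 / 10),
               tolerance = 1e-12)
})

test_that("superposed RMSD is symmetric and matches the bio3d oracle", {
  set.seed(8)
  a <- simpleStructure(matrix(rnorm(36, sd = 3), ncol = 3))
  b <- a
  b@atoms$x <- b@atoms$x + rnorm(12, sd = 0.6)
  b@atoms$y <- b@atoms$y + rnorm(12, sd = 0.6)
  b@atoms$z <- b@atoms$z + rnorm(12, sd = 0.6)
  b <- rigidTransform(b)
  r1 <- superposeRmsd(a, b)$rmsd
  r2 <- superposeRmsd(b, a)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  oracle <- bio3d::rmsd(
    as.vector(t(as.matrix(a@atoms[, c("x", "y", "z")]))),
    as.vector(t(as.matrix(b@atoms[, c("x", "y", "z")]))),
    fit = TRUE)
  expect_equal(r1, oracle, tolerance = 1e-3)
})

test_that("selection mismatch raises a correspondence error", {
  a <- makeToyComplex(c(eta = 5), nDecorationAtoms = 0L, seed = 1)
  b <- makeToyComplex(c(eta = 5, xi = 7), nDecorationAtoms = 0L, seed = 1)
  expect_error(superposeRmsd(a, b), "correspondence")
})

test_that("GROMOS clustering recovers a planted 50 + 30 partition", {
  c1 <- makeToyComplex(c(eta = 5), nDecorationAtoms = 0L, seed = 2)
  c2 <- conformerStructure(c1, 4, seed = 99, label = "c2")
  ens <- makePlantedEnsemble(list(c1, c2), nPerCluster = 50L,
                             jitterRmsd = 0.5, seed = 9)
  structures <- c(ens@structures[ens@clusterAssignment == 1L],
                  ens@structures[ens@clusterAssignment == 2L][1:30])
  cfg <- rmsdConfig(selection = atomSelection(), cutoff = 1.5)
  cl <- clusterEnsemble(structures, cfg)
  expect_length(cl, 2L)
  expect_equal(vapply(cl, `[[`, integer(1), "size"), c(50L, 30L))
  d <- structureRmsd(cl[[1]]$structure, c1, atomSelection())
  expect_lt(d, 0.5)
})

test_that("clustering edge cases and order invariance", {
  c1 <- makeToyComplex(c(eta = 5), nDecorationAtoms = 0L, seed = 2)
  one <- clusterEnsemble(list(c1))
  expect_length(one, 1L)
  expect_equal(one[[1]]$center, 1L)

  c2 <- conformerStructure(c1, 4, seed = 99, label = "c2")
  ens <- makePlantedEnsemble(list(c1, c2), nPerCluster = 8L,
                             jitterRmsd = 0.4, seed = 3)
  big <- clusterEnsemble(ens@structures,
                         rmsdConfig(selection = atomSelection(),
                                    cutoff = 50))
  expect_length(big, 1L)
  expect_equal(big[[1]]$size, 16L)

  cfg <- rmsdConfig(selection = atomSelection(), cutoff = 1.5)
  cl <- clusterEnsemble(ens@structures, cfg)
  set.seed(14)
  perm <- sample(seq_along(ens@structures))
  clP <- clusterEnsemble(ens@structures[perm], cfg)
  partition <- function(cl, labels) {
    lapply(cl, function(x) sort(labels[x$members]))
  }
  expect_setequal(
    partition(cl, vapply(ens@structures, structureLabel, character(1))),
    partition(clP, vapply(ens@structures[perm], structureLabel,
                          character(1))))
})

test_that("shoulder-point selection returns the dominant metastable state", {
  # profile with F(11.46) = 40 relative to its global minimum
  ls <- makePiecewiseLandscape(c(1, 3.1, 4.5, 8, 11.46, 13.5, 15),
                               c(18, 0, 13, 28, 40, 44, 46))
  p <- landscapeToProfile(ls, binWidth = 0.02)
  c1 <- makeToyComplex(c(eta = 5), nDecorationAtoms = 0L, seed = 4)
  c2 <- conformerStructure(c1, 5, seed = 99, label = "minor")
  ens <- makePlantedEnsemble(list(c1, c2), nPerCluster = 15L,
                             jitterRmsd = 0.4, seed = 6)
  cvs <- c(rep(11.46, 15), rep(12.3, 15))    # all inside the shoulder range
  cfg <- rmsdConfig(selection = atomSelection(), cutoff = 1.5)
  # make the first cluster dominant by dropping some minor members
  keep <- c(1:15, 16:25)
  got <- selectMetastable(p, c(8, 13.5), ens@structures[keep], cvs[keep],
                          cfg)
  expect_equal(got$cv, 11.46)
  expect_equal(got$F_rel, 40, tolerance = 0.05)
  expect_equal(got$cluster_size, 15L)
  expect_lt(structureRmsd(got$structure, c1, atomSelection()), 0.4)

  single <- selectMetastable(p, c(12.2, 12.4), ens@structures[16:16],
                             cvs[16:16], cfg)
  expect_equal(single$cv, 12.3)
  expect_error(selectMetastable(p, c(2, 3), ens@structures[keep],
                                cvs[keep], cfg),
               "no ensemble member")
})

test_that("dominant-cluster recovery is stable across seeded regenerations", {
  c1 <- makeToyComplex(c(eta = 5), nDecorationAtoms = 0L, seed = 4)
  c2 <- conformerStructure(c1, 4, seed = 99, label = "minor")
  cfg <- rmsdConfig(selection = atomSelection(), cutoff = 1.5)
  hits <- 0L
  for (seed in 1:20) {
    ens <- makePlantedEnsemble(list(c1, c2), nPerCluster = 12L,
                               jitterRmsd = 0.5, seed = seed)
    structures <- c(ens@structures[ens@clusterAssignment == 1L],
                    ens@structures[ens@clusterAssignment == 2L][1:6])
    cl <- clusterEnsemble(structures, cfg)
    if (cl[[1]]$size == 12L &&
        structureRmsd(cl[[1]]$structure, c1, atomSelection()) < 0.5) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, 20L)
})

test_that("metastable summaries are written as PDB + JSON", {
  c1 <- makeToyComplex(c(eta = 5), nDecorationAtoms = 0L, seed = 4)
  xs <- seq(8.05, 13.5, by = 0.1)
  p <- pmfProfile(xs, xs)  # any anchored profile covering the range
  sel <- selectMetastable(p, c(8, 13.5), list(c1), 11.5,
                          rmsdConfig(selection = atomSelection()))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  js <- withr::local_tempfile(fileext = ".json")
  writeMetastable(sel, pdb, js)
  expect_true(file.exists(pdb) && file.exists(js))
  back <- jsonlite::read_json(js)
  expect_equal(back$cv_A, 11.5)
})
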