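# PDB parsing, selections, centers of mass and collective variables

test_that("parseStructure reads records and applies the altLoc rule", {
  txt <- c(pdbLine(1, "CA", "ALA", "A", 1, 1, 2, 3, "C"),
           pdbLine(2, "N", "ALA", "A", 2, 4, 5, 6, "N"))
  s <- parseStructure(txt)
  expect_s4_class(s, "Structure")
  expect_equal(nAtoms(s), 2L)
  expect_equal(atomTable(s)$element, c("C", "N"))

  withAlt <- c(pdbLine(1, "CA", "ALA", "A", 1, 1, 2, 3, "C", alt = "A"),
               pdbLine(2, "CA", "ALA", "A", 2, 1.5, 2, 3, "C", alt = "B"),
               pdbLine(3, "N", "ALA", "A", 3, 4, 5, 6, "N"))
  expect_equal(nAtoms(parseStructure(withAlt)), 2L)
})

test_that("parseStructure errors are informative", {
  expect_error(parseStructure("REMARK nothing here"), "no parsable")
  bad <- pdbLine(1, "XQ1", "LIG", "A", 1, 0, 0, 0, "Xq")
  expect_error(parseStructure(bad), "unknown element")
})

test_that("toy-complex fixture round-trips through PDB at 3-decimal precision", {
  s <- makeToyComplex(c(eta = 4.95, gamma = 7.73, delta = 4.57, xi = 13.81),
                      nDecorationAtoms = 200L, seed = 5)
  expect_equal(nAtoms(s), 240L)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(nAtoms(s2), 240L)
  expect_equal(atomTable(s2)$x, round(atomTable(s)$x, 3))
  expect_equal(atomTable(s2)$y, round(atomTable(s)$y, 3))
  expect_equal(atomTable(s2)$z, round(atomTable(s)$z, 3))
})

test_that("centerOfMass matches midpoint, identity and a brute-force oracle", {
  two <- simpleStructure(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(centerOfMass(two, atomSelection()), c(1, 0, 0))

  one <- simpleStructure(rbind(c(3.2, -1.5, 7.9)))
  expect_equal(centerOfMass(one, atomSelection()), c(3.2, -1.5, 7.9))

  set.seed(1)
  xyz <- matrix(runif(15, -5, 5), ncol = 3)
  s <- simpleStructure(xyz, element = c("C", "N", "O", "C", "N"))
  com <- centerOfMass(s, atomSelection())
  # explicit-loop oracle
  m <- atomTable(s)$mass
  oracle <- c(0, 0, 0)
  for (i in 1:5) oracle <- oracle + m[i] * xyz[i, ]
  oracle <- oracle / sum(m)
  expect_equal(com, oracle, tolerance = 1e-12)

  expect_error(centerOfMass(s, atomSelection(chain = "Q")),
               "matched no atoms")
})

test_that("COM of a union is the mass-weighted mean of group COMs", {
  s <- makeToyComplex(c(eta = 6), nDecorationAtoms = 0L, seed = 2)
  a <- atomSelection(chain = "A")
  b <- atomSelection(chain = "B")
  u <- atomSelection()  # both groups
  ta <- atomTable(s)
  ma <- sum(ta$mass[ta$chain == "A"])
  mb <- sum(ta$mass[ta$chain == "B"])
  expect_equal(
    centerOfMass(s, u),
    (ma * centerOfMass(s, a) + mb * centerOfMass(s, b)) / (ma + mb),
    tolerance = 1e-12)
})

test_that("evaluateCV recovers planted separations and is rigid-invariant", {
  s <- makeToyComplex(c(custom = 5.0), nDecorationAtoms = 10L, seed = 3)
  expect_equal(evaluateCV(s, "custom"), 5.0, tolerance = 1e-9)

  set.seed(42)
  for (i in 1:8) {
    st <- rigidTransform(s)
    expect_equal(evaluateCV(st, "custom"), 5.0, tolerance = 1e-6)
  }
})

test_that("evaluateCV equals an independent two-pass computation", {
  set.seed(9)
  xyz <- matrix(runif(120, -10, 10), ncol = 3)
  s <- simpleStructure(xyz,
                       element = sample(c("C", "N", "O"), 40, replace = TRUE),
                       chain = rep(c("A", "B"), each = 20),
                       resno = rep(1:2, each = 20),
                       elety = paste0("C", rep(1:20, 2)))
  cv <- cvSpec("custom", atomSelection(chain = "A"),
               atomSelection(chain = "B"))
  m <- atomTable(s)$mass
  comA <- colSums(xyz[1:20, ] * m[1:20]) / sum(m[1:20])
  comB <- colSums(xyz[21:40, ] * m[21:40]) / sum(m[21:40])
  expect_equal(evaluateCV(s, cv), sqrt(sum((comA - comB)^2)),
               tolerance = 1e-9)
})

test_that("CV groups must be disjoint", {
  s <- makeToyComplex(c(eta = 3), nDecorationAtoms = 0L, seed = 1)
  cv <- cvSpec("bad", atomSelection(chain = "A"), atomSelection())
  expect_error(evaluateCV(s, cv), "disjoint")
})

test_that("selection filters follow the backbone/sugar conventions", {
  rows <- data.frame(
    chain = "U", resno = 18L, resid = "DA",
    elety = c("P", "OP1", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'", "C2'",
              "O4'", "N9", "C8", "H8"),
    element = c("P", "O", "O", "C", "C", "C", "O", "C", "C", "O", "N", "C",
                "H"),
    x = 1:13, y = 0, z = 0, stringsAsFactors = FALSE)
  s <- newStructure(rows)
  expect_equal(length(resolveSelection(s, atomSelection(filter = "sugar_ring"))), 5L)
  expect_equal(length(resolveSelection(s, atomSelection(filter = "backbone_heavy"))), 7L)
  expect_equal(length(resolveSelection(s, atomSelection(filter = "base_heavy"))), 2L)
  expect_equal(length(resolveSelection(s, atomSelection(filter = "all_heavy"))), 12L)
  expect_equal(length(resolveSelection(s, atomSelection(filter = "all"))), 13L)
})

test_that("restraintDistance recovers the study's planted base-pair separations", {
  s <- makeToyComplex(c(pair_a18_t18 = 6.06, pair_g21_c21 = 5.85),
                      nDecorationAtoms = 0L, seed = 4)
  specs <- s@metadata$cvSpecs
  r1 <- restraintSpec(specs$pair_a18_t18@groupA, specs$pair_a18_t18@groupB,
                      target = 6.06, k = 25)
  r2 <- restraintSpec(specs$pair_g21_c21@groupA, specs$pair_g21_c21@groupB,
                      target = 5.85, k = 25)
  expect_equal(restraintDistance(s, r1), 6.06, tolerance = 1e-9)
  expect_equal(restraintDistance(s, r2), 5.85, tolerance = 1e-9)

  # coincident COMs
  xyz <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  s0 <- simpleStructure(xyz, chain = c("A", "A", "B", "B"),
                        resno = rep(1L, 4), elety = paste0("C", 1:4))
  r0 <- restraintSpec(atomSelection(chain = "A"), atomSelection(chain = "B"),
                      target = 1, k = 25)
  expect_equal(restraintDistance(s0, r0), 0)
})

test_that("geometric-center option drops the mass weighting", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  s <- simpleStructure(xyz, element = c("C", "O"))
  com <- centerOfMass(s, atomSelection())
  geo <- centerOfMass(s, atomSelection(), weighted = FALSE)
  expect_gt(com[1], 0.5)   # pulled towards the heavier oxygen
  expect_equal(geo[1], 0.5)
})

test_that("CV table export is well formed", {
  s <- makeToyComplex(c(eta = 3.1), nDecorationAtoms = 0L, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- writeCVTable(list(s), list(s@metadata$cvSpecs$eta), f)
  back <- read.delim(f)
  expect_equal(names(back), c("structure_label", "cv_name", "value_A"))
  expect_equal(back$value_A, 3.1, tolerance = 1e-9)
})
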