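# Synthetic structures: toy complexes with planted CV values and ensembles
# with planted conformational clusters. These are geometric scaffolds for
# testing selections, CVs, RMSD and clustering - not physical molecules.

# a 5-carbon cross whose COM is exactly at `at`, rigidly rotated at random
.atomCross <- function(at, chain, resno, arm = 0.8) {
  local <- rbind(c(0, 0, 0),
                 c(arm, 0, 0), c(-arm, 0, 0),
                 c(0, arm, 0), c(0, -arm, 0))
  # random proper rotation (QR of a Gaussian matrix, det fixed to +1)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  xyz <- local %*% t(R) + rep(at, each = nrow(local))
  data.frame(chain = chain, resno = resno, resid = "TOY",
             elety = paste0("C", seq_len(nrow(local))), element = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Build a toy complex with planted collective-variable values
#'
#' For each named CV, two disjoint 5-atom groups (chains "A" and "B",
#' residue number = CV index) are placed so that the distance between their
#' mass-weighted COMs equals the planted value exactly; symmetric atom
#' placement makes the COM exact to machine precision. Decoration atoms go
#' on chain "Z" and enter no named selection. The matching
#' \linkS4class{CVSpec} objects are stored in the structure's
#' \code{metadata$cvSpecs}, so \code{evaluateCV(s, "eta")} recovers the
#' planted value.
#'
#' @param plantedCVs named numeric vector/list, CV name -> planted value
#'   (Angstrom, > 0).
#' @param nDecorationAtoms count of inert extra atoms.
#' @param seed integer; same seed gives identical coordinates.
#' @return A \linkS4class{Structure} with planted \code{metadata$cvSpecs}.
#' @examples
#' s <- makeToyComplex(c(eta = 3.1, gamma = 14.2), seed = 7)
#' evaluateCV(s, "eta")
#' @export
makeToyComplex <- function(plantedCVs, nDecorationAtoms = 20L, seed = 1L) {
  vals <- unlist(plantedCVs)
  if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
    stop("plantedCVs must be named")
  }
  if (anyDuplicated(names(vals))) stop("duplicate CV names")
  if (any(vals <= 0)) stop("planted CV values must be > 0")
  .withSeed(seed, {
    rows <- list()
    specs <- list()
    for (i in seq_along(vals)) {
      nm <- names(vals)[i]
      origin <- c(0, 20 * i, 0)
      rows[[length(rows) + 1L]] <- .atomCross(origin, "A", i)
      rows[[length(rows) + 1L]] <- .atomCross(origin + c(vals[[i]], 0, 0),
                                              "B", i)
      specs[[nm]] <- cvSpec(nm,
                            atomSelection(chain = "A", resno = i),
                            atomSelection(chain = "B", resno = i))
    }
    if (nDecorationAtoms > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "Z", resno = 1000L + seq_len(nDecorationAtoms),
        resid = "DEC", elety = "C1", element = "C",
        x = stats::runif(nDecorationAtoms, -30, 30),
        y = stats::runif(nDecorationAtoms, -30, 30),
        z = stats::runif(nDecorationAtoms, 5, 35),
        stringsAsFactors = FALSE)
    }
    newStructure(do.call(rbind, rows), label = "toy_complex",
                 metadata = list(cvSpecs = specs))
  })
}

# plain coordinate RMSD (no superposition) over the full atom table
.plainRmsd <- function(a, b) {
  da <- a@atoms; db <- b@atoms
  sqrt(mean((da$x - db$x)^2 + (da$y - db$y)^2 + (da$z - db$z)^2))
}

#' Build an ensemble with planted conformational clusters
#'
#' Each center is copied \code{nPerCluster} times with iid Gaussian
#' coordinate noise of standard deviation jitterRmsd/sqrt(3) per component,
#' so the expected RMSD of a copy to its center is \code{jitterRmsd}. The
#' planted labels are the ground truth for clustering tests. Centers must
#' be separated by more than twice the jitter (in plain coordinate RMSD over
#' all atoms).
#'
#' @param centers list of \linkS4class{Structure} with identical atom tables
#'   (same chains/residues/atom names in the same order).
#' @param nPerCluster copies per center.
#' @param jitterRmsd target RMSD of a copy to its center, Angstrom.
#' @param seed integer seed.
#' @return A \linkS4class{PlantedEnsemble}.
#' @export
makePlantedEnsemble <- function(centers, nPerCluster = 50L,
                                jitterRmsd = 0.5, seed = 1L) {
  k <- length(centers)
  if (k < 1L) stop("need at least one center")
  if (k > 1L) {
    sep <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      if (i >= j) Inf else .plainRmsd(centers[[i]], centers[[j]])
    }))
    if (jitterRmsd >= min(sep) / 2) {
      stop(sprintf(
        "overlap error: jitterRmsd (%.3g A) must be < half the minimum center separation (%.3g A)",
        jitterRmsd, min(sep)))
    }
  }
  sigma <- jitterRmsd / sqrt(3)
  .withSeed(seed, {
    structures <- list()
    labels <- integer()
    for (ci in seq_len(k)) {
      for (m in seq_len(nPerCluster)) {
        s <- centers[[ci]]
        n <- nrow(s@atoms)
        s@atoms$x <- s@atoms$x + stats::rnorm(n, 0, sigma)
        s@atoms$y <- s@atoms$y + stats::rnorm(n, 0, sigma)
        s@atoms$z <- s@atoms$z + stats::rnorm(n, 0, sigma)
        s@label <- sprintf("c%d_m%d", ci, m)
        structures[[length(structures) + 1L]] <- s
        labels <- c(labels, ci)
      }
    }
    new("PlantedEnsemble", structures = structures,
        clusterAssignment = labels, plantedCenters = centers)
  })
}
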