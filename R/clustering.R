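# Metastable-state identification: Kabsch superposition, pairwise RMSD over
# a chosen atom set, GROMOS neighbour-counting clustering, and shoulder-point
# selection against a PMF.

# ordered selected coordinates plus a correspondence key
.selCoords <- function(structure, sel) {
  idx <- resolveSelection(structure, sel)
  a <- structure@atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$elety, sep = "|")
  o <- order(key)
  list(xyz = cbind(a$x, a$y, a$z)[o, , drop = FALSE], key = key[o])
}

.pairCoords <- function(a, b, sel) {
  ca <- .selCoords(a, sel)
  cb <- .selCoords(b, sel)
  if (length(ca$key) != length(cb$key) || !all(ca$key == cb$key)) {
    stop("correspondence error: selection resolves to different atom sets ",
         "on the two structures (", length(ca$key), " vs ",
         length(cb$key), " atoms)")
  }
  list(P = ca$xyz, Q = cb$xyz)
}

# Kabsch on raw coordinate matrices (rows in correspondence)
.kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  sv <- svd(crossprod(Q0, P0))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rmsd = sqrt(mean(rowSums((P0 - Q0 %*% t(R))^2))),
       rotation = R, translation = as.numeric(pc - R %*% qc))
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of the selected atoms of \code{b} onto those
#' of \code{a}; the rotation is constrained to be proper (determinant +1),
#' so mirror solutions are excluded. Atoms are put in correspondence by
#' (chain, residue number, atom name).
#'
#' @param a,b \linkS4class{Structure} objects.
#' @param sel \linkS4class{Selection} of the atoms entering the fit.
#' @return list(rmsd, rotation (3x3), translation (length 3)): the selected
#'   coordinates of \code{b} map onto \code{a} as \code{R x + t}.
#' @export
superposeRmsd <- function(a, b, sel = atomSelection()) {
  pq <- .pairCoords(a, b, sel)
  .kabsch(pq$P, pq$Q)
}

#' Pairwise RMSD between two structures
#'
#' @param a,b \linkS4class{Structure} objects.
#' @param sel \linkS4class{Selection}.
#' @param superpose optimal superposition first (default TRUE); with FALSE
#'   the raw coordinate RMSD is returned.
#' @return RMSD in Angstrom.
#' @export
structureRmsd <- function(a, b, sel = atomSelection(), superpose = TRUE) {
  if (superpose) return(superposeRmsd(a, b, sel)$rmsd)
  pq <- .pairCoords(a, b, sel)
  sqrt(mean(rowSums((pq$P - pq$Q)^2)))
}

#' RMSD clustering configuration
#'
#' @param selection atoms entering the RMSD; the study clusters over the
#'   heavy atoms of the lesion-flanking nucleotides (C17u-C22u and
#'   G17d-G22d), i.e. residues 17-22 of both strands in its numbering.
#' @param superpose Kabsch superposition before each RMSD (default TRUE).
#' @param cutoff GROMOS neighbour cutoff, Angstrom.
#' @return An \linkS4class{RMSDConfig}.
#' @export
rmsdConfig <- function(selection = atomSelection(resno = 17:22,
                                                 filter = "all_heavy"),
                       superpose = TRUE, cutoff = 1.5) {
  new("RMSDConfig", selection = selection, superpose = superpose,
      cutoff = cutoff)
}

#' Cluster an ensemble by the GROMOS neighbour-counting scheme
#'
#' Iteratively takes the structure with the most neighbours within
#' \code{cutoff} RMSD as a cluster center (ties broken by the earlier
#' index), removes the cluster, and repeats. Clusters are ranked by size,
#' ties by earlier center index. The center is the neighbour-richest member
#' (a medoid), not an averaged structure.
#'
#' @param structures list of \linkS4class{Structure}.
#' @param cfg an \linkS4class{RMSDConfig}.
#' @return list of clusters, each list(center, members, size, structure):
#'   \code{center}/\code{members} are indices into \code{structures}.
#' @export
clusterEnsemble <- function(structures, cfg = rmsdConfig()) {
  n <- length(structures)
  if (n == 0L) stop("need at least one structure")
  if (n == 1L) {
    return(list(list(center = 1L, members = 1L, size = 1L,
                     structure = structures[[1]])))
  }
  coords <- lapply(structures, .selCoords, sel = cfg@selection)
  key <- coords[[1]]$key
  for (i in seq_len(n)) {
    if (length(coords[[i]]$key) != length(key) ||
        !all(coords[[i]]$key == key)) {
      stop("correspondence error: selection resolves differently on ",
           "structure ", i)
    }
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- if (cfg@superpose) {
        .kabsch(coords[[i]]$xyz, coords[[j]]$xyz)$rmsd
      } else {
        sqrt(mean(rowSums((coords[[i]]$xyz - coords[[j]]$xyz)^2)))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  adj <- D <= cfg@cutoff
  remaining <- rep(TRUE, n)
  clusters <- list()
  while (any(remaining)) {
    counts <- colSums(adj[remaining, , drop = FALSE]) * remaining
    best <- which(counts == max(counts) & remaining)
    if (length(best) > 1L) {
      # neighbour-count ties: take the medoid (least summed RMSD to its
      # neighbours), then the earliest index
      score <- vapply(best, function(c0) {
        sum(D[c0, adj[c0, ] & remaining])
      }, numeric(1))
      best <- best[which.min(score)]
    }
    center <- best[1]
    members <- which(adj[center, ] & remaining)
    clusters[[length(clusters) + 1L]] <- list(
      center = as.integer(center), members = as.integer(members),
      size = length(members), structure = structures[[center]])
    remaining[members] <- FALSE
  }
  sizes <- vapply(clusters, `[[`, integer(1), "size")
  centers <- vapply(clusters, `[[`, integer(1), "center")
  clusters[order(-sizes, centers)]
}

#' Select the metastable state from shoulder-region snapshots
#'
#' Implements the study's deinserted-state identification: restrict the
#' ensemble to snapshots whose CV value lies in the shoulder range (8 A <=
#' eta <= 13.5 A in the study), cluster them by RMSD, and return the center
#' of the top-ranked cluster together with its CV value and its free energy
#' relative to the profile's global minimum (11.46 A and ~40 kcal/mol in
#' the study).
#'
#' @param profile a \linkS4class{PMFProfile} for the same CV.
#' @param shoulder numeric(2): CV range (lo, hi), Angstrom.
#' @param structures list of \linkS4class{Structure} snapshots.
#' @param cvValues numeric vector of CV values, one per snapshot.
#' @param cfg an \linkS4class{RMSDConfig}.
#' @return list(structure, cv, F_rel, cluster_size, n_in_range).
#' @export
selectMetastable <- function(profile, shoulder, structures, cvValues,
                             cfg = rmsdConfig()) {
  stopifnot(length(structures) == length(cvValues), length(shoulder) == 2L)
  inRange <- which(cvValues >= shoulder[1] & cvValues <= shoulder[2])
  if (!length(inRange)) {
    stop(sprintf("no ensemble member with CV in [%g, %g] A",
                 shoulder[1], shoulder[2]))
  }
  clusters <- clusterEnsemble(structures[inRange], cfg)
  top <- clusters[[1]]
  cv <- cvValues[inRange[top$center]]
  list(structure = top$structure, cv = cv,
       F_rel = .binF(profile, cv),
       cluster_size = top$size, n_in_range = length(inRange))
}

#' Write a clustering/metastable-state summary
#'
#' Writes the chosen center as PDB and a JSON summary (model index, CV
#' value, relative free energy, cluster size).
#'
#' @param selection result of [selectMetastable()].
#' @param pdbFile,jsonFile output paths (NULL to skip either).
#' @return \code{selection}, invisibly.
#' @export
writeMetastable <- function(selection, pdbFile = NULL, jsonFile = NULL) {
  if (!is.null(pdbFile)) writeStructure(selection$structure, pdbFile)
  if (!is.null(jsonFile)) {
    jsonlite::write_json(
      list(label = selection$structure@label, cv_A = selection$cv,
           F_rel_kcal_mol = selection$F_rel,
           cluster_size = selection$cluster_size,
           n_in_range = selection$n_in_range),
      jsonFile, auto_unbox = TRUE, digits = NA)
  }
  invisible(selection)
}
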