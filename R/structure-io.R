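# Structure parsing, atom selections, centers of mass and collective
# variables.

# Atomic masses (u) for elements seen in protein/DNA work; D kept distinct
# so "heavy" can exclude it.
.ELEMENT_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  P = 30.973762, S = 32.06, F = 18.998403, CL = 35.45, BR = 79.904,
  I = 126.90447, NA. = 22.98977, MG = 24.305, K = 39.0983, CA = 40.078,
  ZN = 65.38, FE = 55.845, MN = 54.938, SE = 78.971
)

.elementMass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  unname(.ELEMENT_MASS[key])
}

# normalize old-style primes and whitespace in atom names
.normName <- function(x) {
  x <- gsub("\\*", "'", trimws(x))
  x[x == "O1P"] <- "OP1"
  x[x == "O2P"] <- "OP2"
  x
}

# first alphabetic character of an atom name, the PDB fallback element rule
.elementFromName <- function(name) {
  m <- regmatches(name, regexpr("[A-Za-z]", name))
  ifelse(lengths(regmatches(name, gregexpr("[A-Za-z]", name))) > 0,
         toupper(m), "")
}

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resid, elety, element,
#'   x, y, z (mass is derived from element if absent).
#' @param label character label.
#' @param metadata optional list.
#' @return A \linkS4class{Structure}.
#' @export
newStructure <- function(atoms, label = "structure", metadata = list()) {
  atoms$elety <- .normName(atoms$elety)
  if (is.null(atoms$mass)) {
    atoms$mass <- .elementMass(atoms$element)
    if (any(is.na(atoms$mass))) {
      bad <- unique(atoms$element[is.na(atoms$mass)])
      stop("unknown element(s): ", paste(bad, collapse = ", "))
    }
  }
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, label = label, metadata = metadata)
}

#' Parse a PDB structure
#'
#' Reads fixed-column ATOM/HETATM records (via bio3d). Alternate locations
#' other than blank or 'A' are dropped; masses are assigned from the element
#' column, falling back to the first alphabetic character of the atom name.
#'
#' @param pdb_text character: PDB file content (single string or vector of
#'   lines).
#' @param label label for the structure; default "structure".
#' @return A \linkS4class{Structure}.
#' @seealso [readStructure()] to read from a file path.
#' @export
parseStructure <- function(pdb_text, label = "structure") {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste(pdb_text, collapse = "\n"), tf)
  readStructure(tf, label = label)
}

#' @rdname parseStructure
#' @param file path to a PDB file.
#' @export
readStructure <- function(file, label = basename(file)) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("no parsable ATOM/HETATM records in input: ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) {
    stop("no parsable ATOM/HETATM records in input")
  }
  keep <- is.na(a$alt) | a$alt %in% c("", " ", "A")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms left after alternate-location filtering")
  element <- toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy)))
  fall <- element == ""
  element[fall] <- .elementFromName(.normName(a$elety[fall]))
  mass <- .elementMass(element)
  if (any(is.na(mass) | element == "")) {
    i <- which(is.na(mass) | element == "")[1]
    stop(sprintf(
      "unknown element for record %d (%s %s%d atom '%s', element '%s')",
      i, a$resid[i], a$chain[i], a$resno[i], a$elety[i], element[i]))
  }
  chain <- ifelse(is.na(a$chain), "", a$chain)
  newStructure(
    data.frame(chain = chain, resno = a$resno, resid = trimws(a$resid),
               elety = a$elety, element = element,
               x = a$x, y = a$y, z = a$z, mass = mass,
               stringsAsFactors = FALSE),
    label = label)
}

#' Write a Structure (or list of Structures) as (multi-model) PDB
#'
#' Coordinates are written with the standard 3-decimal PDB precision.
#'
#' @param x a \linkS4class{Structure} or a list of them (written as
#'   MODEL/ENDMDL blocks).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeStructure <- function(x, file) {
  structures <- if (is(x, "Structure")) list(x) else x
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  multi <- length(structures) > 1L
  for (m in seq_along(structures)) {
    a <- structures[[m]]@atoms
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L,
      ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
      substr(a$resid, 1, 3), substr(paste0(a$chain, " "), 1, 1),
      a$resno, a$x, a$y, a$z, 1, 0, a$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB file as a list of Structures
#'
#' @param file path to a (possibly multi-model) PDB file.
#' @return list of \linkS4class{Structure}, one per MODEL.
#' @export
readEnsemble <- function(file) {
  txt <- readLines(file)
  starts <- grep("^MODEL", txt)
  if (length(starts) == 0L) return(list(readStructure(file)))
  ends <- grep("^ENDMDL", txt)
  lapply(seq_along(starts), function(i) {
    parseStructure(txt[(starts[i] + 1L):(ends[i] - 1L)],
                   label = sprintf("model_%d", i))
  })
}

# ---- selections ------------------------------------------------------------

.BACKBONE_PROT <- c("N", "CA", "C", "O")
.BACKBONE_DNA <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")
.SUGAR_RING <- c("C1'", "C2'", "C3'", "C4'", "O4'")

#' Create an atom Selection
#'
#' @param chain chain identifier, or NA for any chain.
#' @param resno residue numbers (source-file numbering); empty for any.
#' @param filter one of "all", "all_heavy", "backbone_heavy", "sugar_ring",
#'   "base_heavy", "explicit". Conventions: protein backbone = N, CA, C, O;
#'   DNA backbone = P, OP1, OP2, O5', C5', C4', C3', O3'; sugar ring = C1',
#'   C2', C3', C4', O4'; base_heavy = heavy atoms of a nucleotide that are
#'   neither backbone nor sugar (nor O2'). "Heavy" excludes H and D.
#' @param atomNames explicit atom names when \code{filter = "explicit"}.
#' @return A \linkS4class{Selection}.
#' @export
atomSelection <- function(chain = NA_character_, resno = integer(),
                          filter = "all_heavy", atomNames = character()) {
  new("Selection", chain = as.character(chain), resno = as.integer(resno),
      filter = filter, atomNames = .normName(atomNames))
}

#' Resolve a Selection to atom row indices
#'
#' @param structure a \linkS4class{Structure}.
#' @param selection a \linkS4class{Selection}.
#' @return integer vector of row indices into \code{atomTable(structure)}.
#'   Errors if the selection matches no atom, listing the unmatched criteria.
#' @export
resolveSelection <- function(structure, selection) {
  a <- structure@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.na(selection@chain)) keep <- keep & a$chain == selection@chain
  if (length(selection@resno)) keep <- keep & a$resno %in% selection@resno
  heavy <- !(a$element %in% c("H", "D"))
  keep <- keep & switch(
    selection@filter,
    all = TRUE,
    all_heavy = heavy,
    backbone_heavy = heavy & a$elety %in% c(.BACKBONE_PROT, .BACKBONE_DNA),
    sugar_ring = a$elety %in% .SUGAR_RING,
    base_heavy = heavy &
      !(a$elety %in% c(.BACKBONE_DNA, .SUGAR_RING, "O2'")),
    explicit = a$elety %in% selection@atomNames)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop(sprintf(
      "selection matched no atoms (chain=%s, resno=[%s], filter=%s%s)",
      selection@chain, paste(selection@resno, collapse = ","),
      selection@filter,
      if (selection@filter == "explicit")
        paste0(", atoms=", paste(selection@atomNames, collapse = ","))
      else ""))
  }
  idx
}

#' Mass-weighted center of mass of a selection
#'
#' @param x a \linkS4class{Structure}.
#' @param selection a \linkS4class{Selection}.
#' @param weighted logical; mass weighting (default). With \code{FALSE} the
#'   geometric center is returned instead.
#' @return numeric(3) position in Angstrom.
#' @export
setMethod("centerOfMass", "Structure", function(x, selection,
                                                weighted = TRUE) {
  idx <- resolveSelection(x, selection)
  a <- x@atoms[idx, , drop = FALSE]
  w <- if (weighted) a$mass else rep(1, nrow(a))
  c(sum(w * a$x), sum(w * a$y), sum(w * a$z)) / sum(w)
})

#' Create a collective-variable specification
#'
#' @param name CV name; the study's canonical names are "eta", "gamma",
#'   "gamma_prime", "delta", "xi" (any other name is treated as custom).
#' @param groupA,groupB \linkS4class{Selection} objects; must resolve to
#'   disjoint atom sets on the target structure.
#' @return A \linkS4class{CVSpec}.
#' @export
cvSpec <- function(name, groupA, groupB) {
  new("CVSpec", name = name, groupA = groupA, groupB = groupB)
}

#' Evaluate a collective variable on a structure
#'
#' The CV value is the Euclidean distance between the mass-weighted centers
#' of mass of the two atom groups (Angstrom). It is invariant under rigid
#' rotation and translation of the whole structure.
#'
#' @param x a \linkS4class{Structure}.
#' @param cv a \linkS4class{CVSpec}, or a character CV name looked up in the
#'   structure's \code{metadata$cvSpecs} (as planted by [makeToyComplex()]).
#' @param weighted logical, mass-weighted COM (default TRUE).
#' @return CV value in Angstrom.
#' @export
setMethod("evaluateCV", signature("Structure", "CVSpec"),
          function(x, cv, weighted = TRUE) {
  ia <- resolveSelection(x, cv@groupA)
  ib <- resolveSelection(x, cv@groupB)
  if (length(intersect(ia, ib))) {
    stop("CV groups must be disjoint: ", length(intersect(ia, ib)),
         " shared atom(s) for CV '", cv@name, "'")
  }
  ca <- centerOfMass(x, cv@groupA, weighted = weighted)
  cb <- centerOfMass(x, cv@groupB, weighted = weighted)
  sqrt(sum((ca - cb)^2))
})

#' @rdname evaluateCV
#' @export
setMethod("evaluateCV", signature("Structure", "character"),
          function(x, cv, weighted = TRUE) {
  specs <- x@metadata$cvSpecs
  if (is.null(specs) || is.null(specs[[cv]])) {
    stop("structure carries no CV specification named '", cv, "'")
  }
  evaluateCV(x, specs[[cv]], weighted = weighted)
})

#' Create a harmonic COM-distance restraint specification
#'
#' In the study, the lesion-flanking base pairs are held at their
#' crystalline COM separations (6.06 A and 5.85 A) with k = 25
#' kcal mol^-1 A^-2 during all umbrella runs.
#'
#' @param groupA,groupB \linkS4class{Selection} objects for the COM pair.
#' @param target target distance, Angstrom.
#' @param k spring constant, kcal mol^-1 A^-2.
#' @return A \linkS4class{RestraintSpec}.
#' @export
restraintSpec <- function(groupA, groupB, target, k = 25) {
  new("RestraintSpec", groupA = groupA, groupB = groupB,
      target = target, k = k)
}

#' Distance between the COMs of a restraint's atom pair
#'
#' @param structure a \linkS4class{Structure}.
#' @param restraint a \linkS4class{RestraintSpec}.
#' @param weighted mass-weighted COM (default).
#' @return distance in Angstrom.
#' @export
restraintDistance <- function(structure, restraint, weighted = TRUE) {
  evaluateCV(structure,
             cvSpec("restraint", restraint@groupA, restraint@groupB),
             weighted = weighted)
}

#' Write CV values for a set of structures as TSV
#'
#' Columns: structure_label, cv_name, value_A.
#'
#' @param structures list of \linkS4class{Structure}.
#' @param cvs list of \linkS4class{CVSpec}.
#' @param file output path.
#' @return the table, invisibly.
#' @export
writeCVTable <- function(structures, cvs, file) {
  rows <- do.call(rbind, lapply(structures, function(s) {
    data.frame(structure_label = s@label,
               cv_name = vapply(cvs, function(cv) cv@name, character(1)),
               value_A = vapply(cvs, function(cv) evaluateCV(s, cv),
                                numeric(1)),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
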