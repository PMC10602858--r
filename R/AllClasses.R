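# Central S4 containers. Coordinates are in Angstrom, energies in kcal/mol,
# times in ps, spring constants in kcal mol^-1 A^-2 throughout.

#' Molecular structure
#'
#' An ordered atom table (one row per ATOM/HETATM record) plus a label and a
#' free-form metadata list. Atom fields: \code{chain}, \code{resno},
#' \code{resid}, \code{elety} (atom name), \code{element}, \code{x},
#' \code{y}, \code{z}, \code{mass}.
#'
#' @slot atoms data.frame of atoms as described above.
#' @slot label character scalar identifying the structure.
#' @slot metadata list; e.g. planted CV specifications for toy complexes.
#' @export
setClass("Structure", representation(
  atoms = "data.frame", label = "character", metadata = "list"
))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z", "mass")
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(need %in% names(a))) {
    return(paste("atom table missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  }
  if (anyDuplicated(a[c("chain", "resno", "elety")])) {
    return("(chain, resno, atom name) must be unique")
  }
  if (any(!is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0)) return("masses must be > 0")
  TRUE
})

#' Atom selection
#'
#' Selects atoms by optional chain, optional residue numbers, and an atom
#' name filter: one of \code{"all"}, \code{"all_heavy"},
#' \code{"backbone_heavy"}, \code{"sugar_ring"}, \code{"base_heavy"} or
#' \code{"explicit"} (with \code{atomNames}). "Heavy" excludes H/D.
#'
#' @slot chain character scalar or NA (any chain).
#' @slot resno integer vector; empty means any residue.
#' @slot filter character scalar, one of the filters above.
#' @slot atomNames character vector used when \code{filter == "explicit"}.
#' @export
setClass("Selection", representation(
  chain = "character", resno = "integer", filter = "character",
  atomNames = "character"
))

setValidity("Selection", function(object) {
  ok <- c("all", "all_heavy", "backbone_heavy", "sugar_ring", "base_heavy",
          "explicit")
  if (length(object@filter) != 1L || !object@filter %in% ok) {
    return(paste("filter must be one of:", paste(ok, collapse = ", ")))
  }
  if (object@filter == "explicit" && length(object@atomNames) == 0L) {
    return("explicit filter requires atomNames")
  }
  TRUE
})

#' Collective variable specification
#'
#' A named COM--COM distance observable: the CV value on a structure is the
#' Euclidean distance between the mass-weighted centers of mass of the two
#' atom groups, in Angstrom. Canonical names follow the Rad4--DNA study:
#' eta (hairpin insertion), gamma / gamma_prime (5'-dA flipping), delta
#' (3'-dA flipping), xi (Rad4--DNA association).
#'
#' @slot name character scalar.
#' @slot groupA,groupB \linkS4class{Selection} objects (must be disjoint on
#'   the target structure).
#' @export
setClass("CVSpec", representation(
  name = "character", groupA = "Selection", groupB = "Selection"
))

#' Harmonic distance restraint
#'
#' @slot groupA,groupB \linkS4class{Selection} objects defining the COM pair.
#' @slot target numeric, target distance in Angstrom (> 0).
#' @slot k numeric, spring constant in kcal mol^-1 A^-2 (>= 0).
#' @export
setClass("RestraintSpec", representation(
  groupA = "Selection", groupB = "Selection", target = "numeric",
  k = "numeric"
))

setValidity("RestraintSpec", function(object) {
  if (object@target <= 0) return("target distance must be > 0")
  if (object@k < 0) return("spring constant must be >= 0")
  TRUE
})

#' Analytic toy free-energy landscape
#'
#' A 1-D free-energy surface F(x) (kcal/mol against Angstrom) with known,
#' registered features, used as ground truth for the sampling/WHAM stack.
#' Landscapes are anchored so that min F over the domain is 0.
#'
#' @slot kind one of \code{"harmonic"}, \code{"double_well"},
#'   \code{"well_plus_plateau"}, \code{"piecewise"}.
#' @slot parameters kind-specific parameter list.
#' @slot domain numeric(2), evaluation interval in Angstrom.
#' @slot registry list of scan-verified features: \code{minima} (data.frame
#'   x, F, global), \code{barrier} (list x, height_metastable, height_global,
#'   or NULL), \code{plateaus} (data.frame lo, hi, F).
#' @slot offset numeric anchoring constant added to the raw functional form.
#' @export
setClass("ToyLandscape", representation(
  kind = "character", parameters = "list", domain = "numeric",
  registry = "list", offset = "numeric"
))

setValidity("ToyLandscape", function(object) {
  if (length(object@domain) != 2L || diff(object@domain) <= 0) {
    return("domain must be an increasing interval")
  }
  ok <- c("harmonic", "double_well", "well_plus_plateau", "piecewise")
  if (!object@kind %in% ok) return(paste("unknown landscape kind:", object@kind))
  TRUE
})

#' Langevin engine configuration
#'
#' Parameters of the overdamped (Brownian) propagator
#' x <- x - (D/kBT) (F'(x) + w'(x)) dt + sqrt(2 D dt) N(0,1).
#' Stability requires dt * k_max * D / kBT < 0.2 for the strongest harmonic
#' bias k_max used with the configuration.
#'
#' @slot dt time step, ps.
#' @slot diffusion D, A^2/ps.
#' @slot temperature K.
#' @slot sampleStride integer, steps between retained samples.
#' @slot seed integer master seed.
#' @export
setClass("EngineConfig", representation(
  dt = "numeric", diffusion = "numeric", temperature = "numeric",
  sampleStride = "integer", seed = "integer"
))

setValidity("EngineConfig", function(object) {
  if (object@dt <= 0) return("dt must be > 0")
  if (object@diffusion <= 0) return("diffusion must be > 0")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@sampleStride < 1L) return("sampleStride must be >= 1")
  TRUE
})

#' Harmonic umbrella bias w(x) = k/2 (x - center)^2
#' @slot center Angstrom.
#' @slot k kcal mol^-1 A^-2 (>= 0).
#' @export
setClass("HarmonicBias", representation(center = "numeric", k = "numeric"))

setValidity("HarmonicBias", function(object) {
  if (object@k < 0) return("bias k must be >= 0")
  TRUE
})

#' One umbrella window of the two-stage protocol
#'
#' Equilibration under the strong constant \code{kEq} positions the system at
#' the window center; production under the weaker \code{kProd} supplies the
#' samples that enter WHAM.
#'
#' @slot center Angstrom.
#' @slot kEq,kProd spring constants, kcal mol^-1 A^-2, kEq >= kProd > 0.
#' @slot nEq,nProd sample counts for the two stages.
#' @export
setClass("UmbrellaWindow", representation(
  center = "numeric", kEq = "numeric", kProd = "numeric",
  nEq = "integer", nProd = "integer"
))

setValidity("UmbrellaWindow", function(object) {
  if (!(object@kEq >= object@kProd && object@kProd > 0)) {
    return("require kEq >= kProd > 0")
  }
  if (object@nEq < 0L || object@nProd < 0L) return("sample counts must be >= 0")
  TRUE
})

#' Window schedule along one collective variable
#'
#' Centers run inclusively from xMin to xMax in steps of \code{spacing};
#' the count is round((xMax - xMin)/spacing) + 1.
#'
#' @slot cvName character.
#' @slot xMin,xMax,spacing Angstrom.
#' @slot windows list of \linkS4class{UmbrellaWindow}.
#' @export
setClass("WindowSchedule", representation(
  cvName = "character", xMin = "numeric", xMax = "numeric",
  spacing = "numeric", windows = "list"
))

setValidity("WindowSchedule", function(object) {
  n <- round((object@xMax - object@xMin) / object@spacing) + 1L
  if (length(object@windows) != n) {
    return("window count inconsistent with range/spacing")
  }
  cen <- vapply(object@windows, function(w) w@center, numeric(1))
  want <- object@xMin + object@spacing * (seq_len(n) - 1L)
  if (max(abs(cen - want)) > 1e-9) return("window centers not evenly spaced")
  TRUE
})

#' Biased CV time series from one umbrella window
#'
#' @slot window \linkS4class{UmbrellaWindow} (production bias kProd applies
#'   to \code{samples}).
#' @slot samples numeric vector of production CV samples, Angstrom.
#' @slot provenance character.
#' @export
setClass("BiasedTimeSeries", representation(
  window = "UmbrellaWindow", samples = "numeric", provenance = "character"
))

setValidity("BiasedTimeSeries", function(object) {
  if (length(object@samples) && any(!is.finite(object@samples))) {
    return("samples must be finite")
  }
  TRUE
})

#' WHAM configuration
#'
#' @slot binWidth Angstrom.
#' @slot kT kcal/mol.
#' @slot tolerance convergence tolerance on window free-energy shifts,
#'   kcal/mol.
#' @slot maxIterations integer.
#' @slot nBootstrap integer, replicates for \code{bootstrapUncertainty}.
#' @export
setClass("WhamConfig", representation(
  binWidth = "numeric", kT = "numeric", tolerance = "numeric",
  maxIterations = "integer", nBootstrap = "integer"
))

setValidity("WhamConfig", function(object) {
  if (object@binWidth <= 0) return("binWidth must be > 0")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@kT <= 0) return("kT must be > 0")
  TRUE
})

#' Potential of mean force profile
#'
#' Binned free-energy profile anchored to zero at its global minimum over
#' the unmasked (sampled) bins.
#'
#' @slot binCenters strictly increasing, evenly spaced grid, Angstrom.
#' @slot F kcal/mol per bin (NA where masked).
#' @slot uncertainty kcal/mol per bin (NA until bootstrapped).
#' @slot mask logical, TRUE where the bin has data.
#' @slot nSamples integer counts per bin.
#' @slot cvName character.
#' @slot kT kcal/mol used in the estimate.
#' @export
setClass("PMFProfile", representation(
  binCenters = "numeric", F = "numeric", uncertainty = "numeric",
  mask = "logical", nSamples = "integer", cvName = "character",
  kT = "numeric"
))

setValidity("PMFProfile", function(object) {
  n <- length(object@binCenters)
  if (n < 1L) return("empty grid")
  if (length(object@F) != n || length(object@mask) != n) {
    return("F/mask length must match grid")
  }
  if (n > 1L) {
    d <- diff(object@binCenters)
    if (any(d <= 0)) return("grid must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-6 * d[1]) return("grid must be evenly spaced")
  }
  if (any(object@mask)) {
    Fm <- object@F[object@mask]
    if (any(!is.finite(Fm))) return("F must be finite on the mask")
    if (abs(min(Fm)) > 1e-8) return("profile must be anchored: min F = 0")
  }
  TRUE
})

#' Planted structural ensemble with known cluster labels
#'
#' @slot structures list of \linkS4class{Structure}.
#' @slot clusterAssignment integer labels, one per structure.
#' @slot plantedCenters list of \linkS4class{Structure} cluster centers.
#' @export
setClass("PlantedEnsemble", representation(
  structures = "list", clusterAssignment = "integer",
  plantedCenters = "list"
))

setValidity("PlantedEnsemble", function(object) {
  if (length(object@structures) != length(object@clusterAssignment)) {
    return("one cluster label per structure required")
  }
  k <- length(object@plantedCenters)
  if (length(object@clusterAssignment) &&
      (min(object@clusterAssignment) < 1L ||
       max(object@clusterAssignment) > k)) {
    return("cluster labels out of range")
  }
  TRUE
})

#' RMSD clustering configuration
#'
#' @slot selection \linkS4class{Selection} of the atoms entering the RMSD
#'   (default in the study: heavy atoms of the lesion-flanking nucleotides).
#' @slot superpose logical; optimal (Kabsch) superposition before the RMSD.
#' @slot cutoff neighbour cutoff in Angstrom for GROMOS clustering.
#' @export
setClass("RMSDConfig", representation(
  selection = "Selection", superpose = "logical", cutoff = "numeric"
))

setValidity("RMSDConfig", function(object) {
  if (object@cutoff <= 0) return("cutoff must be > 0")
  TRUE
})

#' Conformational model state of the Rad4--DNA complex
#'
#' Flag combinations follow the study's model alphabet A--J (A: hairpin
#' inserted, CPD and partner bases extrahelical, Rad4 associated; F: hairpin
#' deinserted, everything intrahelical, associated; ...).
#'
#' @slot id single letter A--J.
#' @slot hairpinInserted,base5Intrahelical,base3Intrahelical,cpdIntrahelical,rad4Associated logical flags.
#' @export
setClass("ModelState", representation(
  id = "character", hairpinInserted = "logical",
  base5Intrahelical = "logical", base3Intrahelical = "logical",
  cpdIntrahelical = "logical", rad4Associated = "logical"
))

#' Pairwise event-ordering decision
#'
#' The outcome of comparing two PMFs that encode rival hypotheses about
#' which of two events happens first; the energetically cheaper arrangement
#' wins unless the margin is below the indeterminacy threshold.
#'
#' @slot eventPair character(2): the two events compared.
#' @slot preferredFirst character: one of the pair, or NA when indeterminate.
#' @slot evidence data.frame with columns profile, probe_x, F, dF, rule.
#' @export
setClass("OrderingDecision", representation(
  eventPair = "character", preferredFirst = "character",
  evidence = "data.frame"
))

setValidity("OrderingDecision", function(object) {
  if (length(object@eventPair) != 2L) return("eventPair must have length 2")
  if (!is.na(object@preferredFirst) &&
      !object@preferredFirst %in% object@eventPair) {
    return("preferredFirst must be one of eventPair (or NA)")
  }
  TRUE
})
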