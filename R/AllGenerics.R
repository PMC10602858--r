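#' @rdname centerOfMass
#' @export
setGeneric("centerOfMass", function(x, selection, ...)
  standardGeneric("centerOfMass"))

#' @rdname evaluateCV
#' @export
setGeneric("evaluateCV", function(x, cv, ...) standardGeneric("evaluateCV"))

#' @rdname landscapeEnergy
#' @export
setGeneric("landscapeEnergy", function(landscape, x)
  standardGeneric("landscapeEnergy"))

#' @rdname landscapeEnergy
#' @export
setGeneric("landscapeForce", function(landscape, x)
  standardGeneric("landscapeForce"))

#' @rdname deinsertionEnergy
#' @export
setGeneric("deinsertionEnergy", function(downhill, uphill, ...)
  standardGeneric("deinsertionEnergy"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure \"", object@label, "\": ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resno))), " residues, chains: ",
      paste(unique(a$chain), collapse = " "), "\n", sep = "")
})

setMethod("show", "ToyLandscape", function(object) {
  cat("ToyLandscape <", object@kind, "> on [",
      object@domain[1], ", ", object@domain[2], "] A\n", sep = "")
  m <- object@registry$minima
  if (!is.null(m) && nrow(m)) {
    cat("  minima (A, kcal/mol):",
        paste(sprintf("%.3f/%.3f%s", m$x, m$F,
                      ifelse(m$global, "*", "")), collapse = "  "), "\n")
  }
  b <- object@registry$barrier
  if (!is.null(b)) {
    cat(sprintf("  barrier: %.3f kcal/mol at %.3f A (metastable side)\n",
                b$height_metastable, b$x))
  }
})

setMethod("show", "WindowSchedule", function(object) {
  w1 <- object@windows[[1]]
  cat("WindowSchedule for ", object@cvName, ": ", length(object@windows),
      " windows, ", object@xMin, " to ", object@xMax, " A by ",
      object@spacing, " A; k_eq=", w1@kEq, ", k_prod=", w1@kProd,
      " kcal/mol/A^2\n", sep = "")
})

setMethod("show", "BiasedTimeSeries", function(object) {
  cat(sprintf(
    "BiasedTimeSeries: %d samples, window center %.3f A (k_prod=%g)\n",
    length(object@samples), object@window@center, object@window@kProd))
})

setMethod("show", "PMFProfile", function(object) {
  cat(sprintf(
    "PMFProfile [%s]: %d bins (%d sampled), %.2f-%.2f A, kT=%.5f kcal/mol\n",
    object@cvName, length(object@binCenters), sum(object@mask),
    min(object@binCenters), max(object@binCenters), object@kT))
})

setMethod("show", "OrderingDecision", function(object) {
  if (is.na(object@preferredFirst)) {
    cat("OrderingDecision [", paste(object@eventPair, collapse = " vs "),
        "]: indeterminate\n", sep = "")
  } else {
    cat("OrderingDecision [", paste(object@eventPair, collapse = " vs "),
        "]: ", object@preferredFirst, " first (|dF| = ",
        sprintf("%.3f", abs(object@evidence$dF[1])), " kcal/mol)\n",
        sep = "")
  }
})

# ---- simple accessors ------------------------------------------------------

#' Accessors for the core containers
#'
#' @param x object to access.
#' @return \code{atomTable}: the atom data.frame; \code{structureLabel}: the
#'   label; \code{nAtoms}: atom count; \code{windowCenters}: numeric vector
#'   of umbrella centers; \code{nWindows}: window count; \code{cvSamples}:
#'   production samples of a \linkS4class{BiasedTimeSeries};
#'   \code{binCenters}/\code{pmfValues}/\code{pmfUncertainty}/\code{pmfMask}:
#'   the corresponding \linkS4class{PMFProfile} slots;
#'   \code{landscapeFeatures}: the scan-verified feature registry of a
#'   \linkS4class{ToyLandscape}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
atomTable <- function(x) x@atoms

#' @rdname accessors
#' @export
structureLabel <- function(x) x@label

#' @rdname accessors
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @rdname accessors
#' @export
windowCenters <- function(x) vapply(x@windows, function(w) w@center, numeric(1))

#' @rdname accessors
#' @export
nWindows <- function(x) length(x@windows)

#' @rdname accessors
#' @export
cvSamples <- function(x) x@samples

#' @rdname accessors
#' @export
binCenters <- function(x) x@binCenters

#' @rdname accessors
#' @export
pmfValues <- function(x) x@F

#' @rdname accessors
#' @export
pmfUncertainty <- function(x) x@uncertainty

#' @rdname accessors
#' @export
pmfMask <- function(x) x@mask

#' @rdname accessors
#' @export
landscapeFeatures <- function(x) x@registry
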