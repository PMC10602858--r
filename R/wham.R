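# Self-consistent WHAM: combine per-window biased histograms into one
# unbiased potential of mean force, with block-bootstrap uncertainties.

#' WHAM configuration
#'
#' @param binWidth histogram bin width, Angstrom.
#' @param kT thermal energy, kcal/mol; the default corresponds to 300 K with
#'   kB = 0.0019872041 kcal mol^-1 K^-1, i.e. 0.59616 kcal/mol.
#' @param tolerance convergence threshold on the maximum change of the
#'   window free-energy shifts f_i, kcal/mol.
#' @param maxIterations iteration cap.
#' @param nBootstrap replicates for [bootstrapUncertainty()].
#' @return A \linkS4class{WhamConfig}.
#' @export
whamConfig <- function(binWidth = 0.1, kT = KB_KCAL * 300,
                       tolerance = 1e-7, maxIterations = 100000L,
                       nBootstrap = 20L) {
  new("WhamConfig", binWidth = binWidth, kT = kT, tolerance = tolerance,
      maxIterations = as.integer(maxIterations),
      nBootstrap = as.integer(nBootstrap))
}

# histogram all series on a common grid aligned to multiples of binWidth
.whamGrid <- function(samples, bw) {
  lo <- floor(min(samples) / bw) * bw
  hi <- ceiling(max(samples) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  breaks <- seq(lo, hi, by = bw)
  list(breaks = breaks, centers = breaks[-length(breaks)] + bw / 2)
}

#' Estimate a potential of mean force by self-consistent WHAM
#'
#' Iterates the coupled equations
#' rho(x_b) = sum_i n_i(x_b) / sum_i N_i exp[(f_i - w_i(x_b)) / kT] and
#' f_i = -kT ln sum_b rho(x_b) exp(-w_i(x_b) / kT)
#' to convergence (max |delta f_i| < tolerance), then F = -kT ln rho,
#' anchored to zero at its minimum. Only production samples should be
#' supplied (the protocol's equilibration stage is burn-in). Bins with zero
#' total count are masked; stray outlier bins holding less than 0.1% of the
#' samples are trimmed from the support edges, and a zero-count gap that
#' splits the remaining support raises a support error.
#'
#' @param series list of \linkS4class{BiasedTimeSeries} with harmonic
#'   production biases (center, kProd).
#' @param cfg a \linkS4class{WhamConfig}.
#' @param cvName label stored in the profile.
#' @param warmStart optional numeric vector of initial window free energies.
#' @return A \linkS4class{PMFProfile} (uncertainty slot NA; see
#'   [bootstrapUncertainty()]).
#' @export
wham <- function(series, cfg = whamConfig(), cvName = "cv",
                 warmStart = NULL) {
  series <- Filter(function(s) length(s@samples) > 0L, series)
  if (!length(series)) stop("need at least one non-empty series")
  bw <- cfg@binWidth
  kT <- cfg@kT
  allSamples <- unlist(lapply(series, function(s) s@samples))
  grid <- .whamGrid(allSamples, bw)
  centers <- grid$centers
  nb <- length(centers)

  counts <- vapply(series, function(s) {
    tabulate(findInterval(s@samples, grid$breaks, rightmost.closed = TRUE),
             nb)
  }, integer(nb))
  counts <- matrix(counts, nrow = nb)
  H <- rowSums(counts)
  N <- colSums(counts)

  # trim negligible outlier components at the support edges, then require a
  # single connected support
  occ <- H > 0L
  comp <- cumsum(c(TRUE, diff(occ) != 0))
  occComps <- unique(comp[occ])
  sizes <- vapply(occComps, function(cid) sum(H[comp == cid]), numeric(1))
  keep <- occComps[sizes >= 1e-3 * sum(H)]
  if (length(keep) > 1L) {
    gapAt <- centers[which(comp == keep[1])[sum(comp == keep[1])] + 1L]
    stop(sprintf(
      "disconnected histogram support: zero-count gap near %.3f A splits the range",
      gapAt))
  }
  sel <- comp == keep
  centers <- centers[sel]
  H <- H[sel]
  nb <- length(centers)

  # bias Boltzmann factors, windows x bins
  kProd <- vapply(series, function(s) s@window@kProd, numeric(1))
  cen <- vapply(series, function(s) s@window@center, numeric(1))
  W <- 0.5 * outer(kProd, rep(1, nb)) *
    (outer(rep(1, length(series)), centers) - outer(cen, rep(1, nb)))^2
  B <- exp(-W / kT)

  f <- if (is.null(warmStart)) rep(0, length(series)) else warmStart
  converged <- FALSE
  lastResid <- NA_real_
  for (it in seq_len(cfg@maxIterations)) {
    z <- N * exp(f / kT)
    denom <- as.vector(crossprod(B, z))
    rho <- H / denom
    fnew <- -kT * log(as.vector(B %*% rho))
    fnew <- fnew - fnew[1]
    lastResid <- max(abs(fnew - f))
    f <- fnew
    if (lastResid < cfg@tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(
      "WHAM did not converge in %d iterations (last residual %.3g kcal/mol)",
      cfg@maxIterations, lastResid))
  }

  Fv <- -kT * log(rho)
  Fv <- Fv - min(Fv)
  new("PMFProfile", binCenters = centers, F = Fv,
      uncertainty = rep(NA_real_, nb), mask = rep(TRUE, nb),
      nSamples = as.integer(H), cvName = cvName, kT = kT)
}

# integrated autocorrelation time (samples); block length for the
# moving-block bootstrap
.blockLength <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(1L)
  a <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(a <= 0)
  upto <- if (length(pos)) pos[1] - 1L else length(a)
  tau <- 1 + 2 * sum(a[seq_len(upto)])
  max(1L, min(as.integer(ceiling(2 * tau)), n %/% 2L))
}

.blockResample <- function(x, blk) {
  n <- length(x)
  if (blk >= n) return(x[sample.int(n, n, replace = TRUE)])
  nblocks <- ceiling(n / blk)
  starts <- sample.int(n - blk + 1L, nblocks, replace = TRUE)
  idx <- as.vector(outer(0:(blk - 1L), starts, "+"))[1:n]
  x[idx]
}

#' Block-bootstrap uncertainties for a WHAM profile
#'
#' Within-window moving-block resampling (block length set by an
#' autocorrelation-time estimate) followed by a WHAM re-estimate per
#' replicate; the per-bin standard deviation across replicates fills the
#' profile's uncertainty slot.
#'
#' @param series list of \linkS4class{BiasedTimeSeries}.
#' @param cfg a \linkS4class{WhamConfig} (\code{nBootstrap} >= 2).
#' @param cvName label stored in the profile.
#' @param seed integer seed for the resampling.
#' @return the point-estimate \linkS4class{PMFProfile} with uncertainties
#'   filled (NA in bins absent from some replicate).
#' @export
bootstrapUncertainty <- function(series, cfg = whamConfig(), cvName = "cv",
                                 seed = 1L) {
  if (cfg@nBootstrap < 2L) stop("need nBootstrap >= 2")
  point <- wham(series, cfg, cvName = cvName)
  series <- Filter(function(s) length(s@samples) > 0L, series)
  blks <- vapply(series, function(s) .blockLength(s@samples), integer(1))
  reps <- .withSeed(seed, {
    lapply(seq_len(cfg@nBootstrap), function(r) {
      resampled <- lapply(seq_along(series), function(i) {
        s <- series[[i]]
        new("BiasedTimeSeries", window = s@window,
            samples = .blockResample(s@samples, blks[i]),
            provenance = s@provenance)
      })
      tryCatch(wham(resampled, cfg, cvName = cvName),
               error = function(e) NULL)
    })
  })
  reps <- Filter(Negate(is.null), reps)
  if (!length(reps)) stop("all bootstrap replicates failed")
  key <- round(point@binCenters / cfg@binWidth)
  Fmat <- vapply(reps, function(p) {
    m <- match(key, round(p@binCenters / cfg@binWidth))
    p@F[m]
  }, numeric(length(key)))
  Fmat <- matrix(Fmat, nrow = length(key))
  sds <- apply(Fmat, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2L) sd(v) else NA_real_
  })
  point@uncertainty <- sds
  point
}

#' Write / read a PMF profile as TSV
#'
#' Columns: bin_center_A, F_kcal_mol, sd_kcal_mol, n_samples.
#'
#' @param profile a \linkS4class{PMFProfile}.
#' @param file path.
#' @return \code{readPMF} returns a \linkS4class{PMFProfile}.
#' @export
writePMF <- function(profile, file) {
  df <- data.frame(bin_center_A = profile@binCenters,
                   F_kcal_mol = profile@F,
                   sd_kcal_mol = profile@uncertainty,
                   n_samples = profile@nSamples)
  hdr <- sprintf("# cv=%s kT=%.10g", profile@cvName, profile@kT)
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(file)
}

#' @rdname writePMF
#' @export
readPMF <- function(file) {
  txt <- readLines(file, n = 1L)
  cvName <- sub(".*cv=(\\S+).*", "\\1", txt)
  kT <- as.numeric(sub(".*kT=(\\S+).*", "\\1", txt))
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  new("PMFProfile", binCenters = df$bin_center_A,
      F = df$F_kcal_mol - min(df$F_kcal_mol, na.rm = TRUE),
      uncertainty = as.numeric(df$sd_kcal_mol),
      mask = is.finite(df$F_kcal_mol),
      nSamples = as.integer(df$n_samples), cvName = cvName, kT = kT)
}
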