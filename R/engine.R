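# Overdamped Langevin engine: the desk-scale stand-in for biased all-atom
# MD. Only the stationary (Boltzmann) distribution matters for WHAM, so the
# simplest propagator with the correct stationary law is used.

# run expr with a private RNG stream, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Langevin engine configuration
#'
#' @param dt time step, ps. The default 0.01 ps is stable for bias constants
#'   up to about 11 kcal mol^-1 A^-2 at the default diffusion/temperature;
#'   protocols that carry the study's strong equilibration constants
#'   (75-100 kcal mol^-1 A^-2) need dt around 0.001 ps (the stability
#'   invariant dt k D / kBT < 0.2 is checked at run time).
#' @param diffusion D, A^2/ps.
#' @param temperature K (the study's simulations run at 300 K).
#' @param sampleStride steps between retained samples.
#' @param seed integer master seed; all randomness flows from it.
#' @return An \linkS4class{EngineConfig}.
#' @export
engineConfig <- function(dt = 0.01, diffusion = 1, temperature = 300,
                         sampleStride = 10L, seed = 1L) {
  new("EngineConfig", dt = dt, diffusion = diffusion,
      temperature = temperature, sampleStride = as.integer(sampleStride),
      seed = as.integer(seed))
}

#' @rdname engineConfig
#' @param cfg an \linkS4class{EngineConfig}.
#' @return \code{engineKT}: kT in kcal/mol.
#' @export
engineKT <- function(cfg) KB_KCAL * cfg@temperature

#' Harmonic umbrella bias
#' @param center bias center, Angstrom.
#' @param k spring constant, kcal mol^-1 A^-2.
#' @return A \linkS4class{HarmonicBias}.
#' @export
harmonicBias <- function(center, k) new("HarmonicBias", center = center, k = k)

.checkStability <- function(cfg, kmax) {
  crit <- cfg@dt * kmax * cfg@diffusion / engineKT(cfg)
  if (crit >= 0.2) {
    stop(sprintf(
      "unstable engine configuration: dt*k*D/kBT = %.3f >= 0.2 for k = %g; reduce dt",
      crit, kmax))
  }
  invisible(crit)
}

# tabulate the landscape force once per simulation for the C++ kernel
.forceTable <- function(landscape, pad = 6, dx = 0.002) {
  xs <- seq(landscape@domain[1] - pad, landscape@domain[2] + pad, by = dx)
  list(x0 = xs[1], dx = dx, f = landscapeForce(landscape, xs))
}

.runKernel <- function(landscape, bias, nSamples, cfg, x0, ft = NULL) {
  if (is.null(ft)) ft <- .forceTable(landscape)
  .langevin_kernel(
    x0, as.integer(nSamples), cfg@sampleStride, cfg@dt, cfg@diffusion,
    engineKT(cfg), bias@center, bias@k, ft$f, ft$x0, ft$dx,
    landscape@domain[1] - 5, landscape@domain[2] + 5)
}

#' Generate biased CV samples by overdamped Langevin dynamics
#'
#' Euler-Maruyama propagation on a \linkS4class{ToyLandscape} under a
#' harmonic umbrella bias; returns every \code{sampleStride}-th position.
#' The trajectory starts at the bias center (mirroring the umbrella
#' protocol's displacement step) unless \code{x0} is given. A trajectory
#' escaping the landscape domain by more than 5 A signals an unstable time
#' step and raises a divergence error.
#'
#' @param landscape a \linkS4class{ToyLandscape}.
#' @param bias a \linkS4class{HarmonicBias}.
#' @param nSteps total number of propagation steps; floor(nSteps /
#'   sampleStride) samples are returned.
#' @param cfg an \linkS4class{EngineConfig}; \code{cfg@seed} makes the run
#'   reproducible.
#' @param x0 starting position (default: the bias center).
#' @return numeric vector of CV samples (Angstrom), with the final position
#'   in attribute \code{"xfinal"}.
#' @export
simulateBiased <- function(landscape, bias, nSteps, cfg = engineConfig(),
                           x0 = bias@center) {
  .checkStability(cfg, bias@k)
  n <- as.integer(nSteps %/% cfg@sampleStride)
  res <- .withSeed(cfg@seed, .runKernel(landscape, bias, n, cfg, x0))
  out <- res$samples
  attr(out, "xfinal") <- res$xfinal
  out
}
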