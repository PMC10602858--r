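# Analytic toy free-energy landscapes with scan-verified feature registries.
# These stand in for the unknown true F(eta), F(gamma), F(delta), F(xi) so
# that the sampling/WHAM stack can be validated against known ground truth.

.SCAN_DX <- 1e-3

# raw (un-anchored) energy of each functional form
.rawEnergy <- function(kind, p, x) {
  switch(kind,
    harmonic = 0.5 * p$curvature * (x - p$center)^2,
    double_well = {
      wall <- ifelse(x < p$x1, p$wallK * (p$x1 - x)^4,
                     ifelse(x > p$x2, p$wallK * (x - p$x2)^4, 0))
      p$C + wall -
        p$a1 * exp(-(x - p$x1)^2 / (2 * p$width^2)) -
        p$a2 * exp(-(x - p$x2)^2 / (2 * p$width^2))
    },
    well_plus_plateau = {
      wall <- ifelse(x < p$center, p$wallK * (p$center - x)^4, 0)
      p$plateau * (1 - exp(-(x - p$center)^2 / (2 * p$riseWidth^2))) + wall
    },
    piecewise = .piecewiseFun(p)(x),
    stop("unknown landscape kind: ", kind))
}

.rawDeriv <- function(kind, p, x) {
  switch(kind,
    harmonic = p$curvature * (x - p$center),
    double_well = {
      dwall <- ifelse(x < p$x1, -4 * p$wallK * (p$x1 - x)^3,
                      ifelse(x > p$x2, 4 * p$wallK * (x - p$x2)^3, 0))
      s2 <- p$width^2
      dwall +
        p$a1 * (x - p$x1) / s2 * exp(-(x - p$x1)^2 / (2 * s2)) +
        p$a2 * (x - p$x2) / s2 * exp(-(x - p$x2)^2 / (2 * s2))
    },
    well_plus_plateau = {
      dwall <- ifelse(x < p$center, -4 * p$wallK * (p$center - x)^3, 0)
      s2 <- p$riseWidth^2
      p$plateau * (x - p$center) / s2 *
        exp(-(x - p$center)^2 / (2 * s2)) + dwall
    },
    piecewise = .piecewiseFun(p, deriv = 1L)(x),
    stop("unknown landscape kind: ", kind))
}

.piecewiseFun <- function(p, deriv = 0L) {
  if (identical(p$method, "linear")) {
    # linear interpolation with linear extrapolation from the end segments
    kx <- p$x; ky <- p$y
    slopes <- diff(ky) / diff(kx)
    if (deriv == 0L) {
      function(x) {
        i <- pmin(pmax(findInterval(x, kx), 1L), length(kx) - 1L)
        ky[i] + slopes[i] * (x - kx[i])
      }
    } else {
      function(x) {
        i <- pmin(pmax(findInterval(x, kx), 1L), length(kx) - 1L)
        slopes[i]
      }
    }
  } else {
    sf <- splinefun(p$x, p$y, method = "natural")
    function(x) sf(x, deriv = deriv)
  }
}

# scan the anchored energy for minima, the main barrier and plateaus,
# refining locations with optimize(); this registry is the oracle the
# sampling and feature-extraction stages are tested against
.buildRegistry <- function(kind, p, domain, offset,
                           slopeTol = 0.2, minSpan = 3) {
  xs <- seq(domain[1], domain[2], by = .SCAN_DX)
  Fx <- .rawEnergy(kind, p, xs) + offset
  n <- length(Fx)
  isMin <- c(FALSE, Fx[2:(n - 1)] < Fx[1:(n - 2)] &
               Fx[2:(n - 1)] <= Fx[3:n], FALSE)
  mins <- lapply(which(isMin), function(i) {
    lo <- xs[max(1L, i - 5L)]; hi <- xs[min(n, i + 5L)]
    opt <- optimize(function(x) .rawEnergy(kind, p, x) + offset,
                    c(lo, hi))
    c(x = opt$minimum, F = opt$objective)
  })
  minima <- if (length(mins)) {
    m <- as.data.frame(do.call(rbind, mins))
    m <- m[order(m$x), , drop = FALSE]
    m$global <- abs(m$F - min(m$F)) < 1e-9
    rownames(m) <- NULL
    m
  } else data.frame(x = numeric(), F = numeric(), global = logical())

  barrier <- NULL
  if (nrow(minima) >= 2L) {
    i <- order(minima$F)[1:2]
    lo <- min(minima$x[i]); hi <- max(minima$x[i])
    opt <- optimize(function(x) .rawEnergy(kind, p, x) + offset,
                    c(lo, hi), maximum = TRUE)
    metaF <- max(minima$F[i])
    if (opt$objective > metaF + 1e-9) {
      barrier <- list(x = opt$maximum,
                      height_metastable = opt$objective - metaF,
                      height_global = opt$objective - min(minima$F[i]))
    }
  }

  slope <- .rawDeriv(kind, p, xs)
  flat <- abs(slope) < slopeTol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (xs[ends] - xs[starts]) >= minSpan
  plateaus <- data.frame(lo = xs[starts[keep]], hi = xs[ends[keep]],
                         F = vapply(which(keep), function(j) {
                           mean(Fx[starts[j]:ends[j]])
                         }, numeric(1)))

  list(minima = minima, barrier = barrier, plateaus = plateaus)
}

.newLandscape <- function(kind, p, domain) {
  xs <- seq(domain[1], domain[2], by = .SCAN_DX)
  offset <- -min(.rawEnergy(kind, p, xs))
  new("ToyLandscape", kind = kind, parameters = p, domain = domain,
      registry = .buildRegistry(kind, p, domain, offset), offset = offset)
}

#' Harmonic toy landscape F(x) = c/2 (x - x0)^2
#'
#' @param center x0, Angstrom.
#' @param curvature c, kcal mol^-1 A^-2.
#' @param domain numeric(2) evaluation interval.
#' @return A \linkS4class{ToyLandscape}.
#' @export
makeHarmonicWell <- function(center, curvature, domain = center + c(-5, 5)) {
  .newLandscape("harmonic",
                list(center = center, curvature = curvature), domain)
}

#' Flat toy landscape (zero curvature harmonic)
#' @param domain numeric(2) evaluation interval.
#' @return A \linkS4class{ToyLandscape}.
#' @export
makeFlatLandscape <- function(domain = c(0, 20)) {
  .newLandscape("harmonic",
                list(center = mean(domain), curvature = 0), domain)
}

#' Two-minimum toy landscape with planted well positions, barrier and
#' asymmetry
#'
#' Built as the sum of two negative Gaussian wells plus quartic confining
#' walls outside the wells, with depths solved so that F(x1) = 0,
#' F(x2) = asymmetry and the maximum of F on (x1, x2) equals \code{barrier}
#' (measured from the x1 well, i.e. the metastable side when asymmetry < 0).
#' The returned landscape is anchored so its global minimum is 0; the
#' feature registry stores the scan-verified minima and barrier.
#'
#' @param x1,x2 well positions, Angstrom (x1 < x2).
#' @param barrier interior barrier height from the x1 well, kcal/mol (> 0).
#' @param asymmetry F(x2) - F(x1), kcal/mol; |asymmetry| < barrier.
#' @param width Gaussian well width, Angstrom.
#' @param wallK quartic wall constant, kcal mol^-1 A^-4.
#' @param domain evaluation interval.
#' @return A \linkS4class{ToyLandscape}.
#' @examples
#' ls <- makeDoubleWell(10.4, 14.2, barrier = 3.19, asymmetry = -1.1)
#' landscapeFeatures(ls)$barrier
#' @export
makeDoubleWell <- function(x1, x2, barrier, asymmetry = 0,
                           width = (x2 - x1) / 5, wallK = 1,
                           domain = c(x1 - 2.5, x2 + 2.5)) {
  if (!(x1 < x2)) stop("require x1 < x2")
  if (!(barrier > 0)) stop("require barrier > 0")
  if (!(abs(asymmetry) < barrier)) {
    stop("infeasible parameters: |asymmetry| must be < barrier")
  }
  g <- function(x, xi) exp(-(x - xi)^2 / (2 * width^2))
  wall <- function(x) {
    ifelse(x < x1, wallK * (x1 - x)^4,
           ifelse(x > x2, wallK * (x - x2)^4, 0))
  }
  xb <- (x1 + x2) / 2
  u <- NULL
  for (iter in 1:50) {
    pts <- c(x1, x2, xb)
    A <- cbind(1, -g(pts, x1), -g(pts, x2))
    b <- c(0, asymmetry, barrier) - wall(pts)
    u <- solve(A, b)
    raw <- function(x) {
      u[1] + wall(x) - u[2] * g(x, x1) - u[3] * g(x, x2)
    }
    opt <- optimize(raw, c(x1, x2), maximum = TRUE)
    if (abs(opt$maximum - xb) < 1e-7) { xb <- opt$maximum; break }
    xb <- opt$maximum
  }
  if (u[2] <= 0 || u[3] <= 0) {
    stop("infeasible parameters: solved well depths are not positive")
  }
  p <- list(x1 = x1, x2 = x2, barrier = barrier, asymmetry = asymmetry,
            width = width, wallK = wallK, C = u[1], a1 = u[2], a2 = u[3])
  ls <- .newLandscape("double_well", p, domain)
  if (nrow(ls@registry$minima) != 2L || is.null(ls@registry$barrier)) {
    stop("infeasible parameters: landscape does not realize two wells ",
         "with an interior barrier")
  }
  ls
}

#' Single well rising to a flat plateau
#'
#' Emulates the 3'-dA flipping profile: a well at \code{center} (the
#' extrahelical, stacked state), a Gaussian-saturating rise of height
#' \code{plateau} towards large x (the intrahelical state), and a steep
#' quartic wall on the small-x side (steric clash with the binding pocket).
#'
#' @param center well position, Angstrom.
#' @param plateau plateau height, kcal/mol.
#' @param riseWidth Gaussian rise width, Angstrom.
#' @param wallK left-wall quartic constant.
#' @param domain evaluation interval.
#' @return A \linkS4class{ToyLandscape}.
#' @export
makeWellPlusPlateau <- function(center, plateau, riseWidth = 2.3,
                                wallK = 2, domain = c(center - 2.5,
                                                      center + 12.5)) {
  if (plateau <= 0) stop("plateau height must be > 0")
  .newLandscape("well_plus_plateau",
                list(center = center, plateau = plateau,
                     riseWidth = riseWidth, wallK = wallK), domain)
}

#' Piecewise toy landscape through knot points
#'
#' @param x,y knot coordinates (Angstrom, kcal/mol); interpolated with a
#'   natural cubic spline (\code{method = "spline"}) or linearly
#'   (\code{method = "linear"}).
#' @param method "spline" or "linear".
#' @param domain evaluation interval; defaults to the knot range.
#' @return A \linkS4class{ToyLandscape}.
#' @export
makePiecewiseLandscape <- function(x, y, method = "spline",
                                   domain = range(x)) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !is.unsorted(x))
  .newLandscape("piecewise",
                list(x = as.numeric(x), y = as.numeric(y), method = method),
                domain)
}

#' Evaluate a toy landscape (anchored: min F over domain = 0)
#'
#' @param landscape a \linkS4class{ToyLandscape}.
#' @param x positions, Angstrom (vectorized).
#' @return \code{landscapeEnergy}: F(x) in kcal/mol;
#'   \code{landscapeForce}: -dF/dx in kcal mol^-1 A^-1.
#' @export
setMethod("landscapeEnergy", "ToyLandscape", function(landscape, x) {
  .rawEnergy(landscape@kind, landscape@parameters, x) + landscape@offset
})

#' @rdname landscapeEnergy
#' @export
setMethod("landscapeForce", "ToyLandscape", function(landscape, x) {
  -.rawDeriv(landscape@kind, landscape@parameters, x)
})

#' Serialize / deserialize toy landscapes as YAML
#'
#' Only the defining parameters are stored; the feature registry is rebuilt
#' on read, so a round trip re-verifies the features.
#'
#' @param landscape a \linkS4class{ToyLandscape}.
#' @param file path.
#' @return \code{readLandscape} returns a \linkS4class{ToyLandscape}.
#' @export
writeLandscape <- function(landscape, file) {
  p <- landscape@parameters
  spec <- switch(landscape@kind,
    harmonic = p[c("center", "curvature")],
    double_well = p[c("x1", "x2", "barrier", "asymmetry", "width", "wallK")],
    well_plus_plateau = p[c("center", "plateau", "riseWidth", "wallK")],
    piecewise = p[c("x", "y", "method")])
  yaml::write_yaml(c(list(kind = landscape@kind),
                     spec, list(domain = landscape@domain)), file)
  invisible(file)
}

#' @rdname writeLandscape
#' @export
readLandscape <- function(file) {
  landscapeFromSpec(yaml::read_yaml(file))
}

#' Build a landscape from a parameter list (as in run configs / YAML)
#'
#' @param spec named list with \code{kind} and the constructor arguments of
#'   the corresponding \code{make*} function.
#' @return A \linkS4class{ToyLandscape}.
#' @export
landscapeFromSpec <- function(spec) {
  kind <- spec$kind
  spec$kind <- NULL
  if (!is.null(spec$domain)) spec$domain <- as.numeric(spec$domain)
  fn <- switch(kind,
    harmonic = makeHarmonicWell,
    double_well = makeDoubleWell,
    well_plus_plateau = makeWellPlusPlateau,
    piecewise = makePiecewiseLandscape,
    stop("unknown landscape kind: ", kind))
  do.call(fn, spec)
}
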