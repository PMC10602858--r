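# Umbrella-sampling orchestration: window schedules, the two-stage
# (strong-equilibration / weak-production) protocol, overlap diagnostics and
# bias-engine config export.

#' Build an umbrella window schedule
#'
#' Centers run inclusively from \code{xMin} to \code{xMax} in steps of
#' \code{spacing}; the count is round((xMax - xMin)/spacing) + 1. The
#' study's four schedules are: eta 1-22.5 A (44 windows, k 75/5), gamma
#' 4-19.5 A (32 windows, k 100/10), delta 2-16.5 A (30 windows, k 100/10),
#' xi 10-30 A (41 windows, k 100/10), all with 0.5 A spacing.
#'
#' @param xMin,xMax,spacing Angstrom; (xMax - xMin)/spacing must be an
#'   integer to within 1e-9.
#' @param kEq,kProd equilibration/production spring constants,
#'   kcal mol^-1 A^-2 (kEq >= kProd > 0).
#' @param nEq,nProd samples per stage. The default 1:30 ratio mirrors the
#'   study's 200 ps equilibration against 6 ns production.
#' @param cvName label for the collective variable.
#' @return A \linkS4class{WindowSchedule}.
#' @examples
#' nWindows(buildSchedule(1, 22.5, 0.5, 75, 5))  # 44
#' @export
buildSchedule <- function(xMin, xMax, spacing, kEq, kProd,
                          nEq = 2000L, nProd = 60000L, cvName = "cv") {
  if (!(xMax > xMin)) stop("require xMax > xMin")
  if (!(spacing > 0)) stop("require spacing > 0")
  r <- (xMax - xMin) / spacing
  if (abs(r - round(r)) > 1e-9 * max(1, abs(r))) {
    stop(sprintf("range %g..%g is not commensurate with spacing %g",
                 xMin, xMax, spacing))
  }
  n <- as.integer(round(r)) + 1L
  windows <- lapply(seq_len(n) - 1L, function(i) {
    new("UmbrellaWindow", center = xMin + i * spacing, kEq = kEq,
        kProd = kProd, nEq = as.integer(nEq), nProd = as.integer(nProd))
  })
  new("WindowSchedule", cvName = cvName, xMin = xMin, xMax = xMax,
      spacing = spacing, windows = windows)
}

#' The study's four canonical umbrella schedules
#'
#' @param nEq,nProd desk-scale samples per stage.
#' @return named list of \linkS4class{WindowSchedule}: eta (44 windows),
#'   gamma (32), delta (30), xi (41).
#' @export
canonicalSchedules <- function(nEq = 2000L, nProd = 60000L) {
  list(
    eta = buildSchedule(1, 22.5, 0.5, 75, 5, nEq, nProd, "eta"),
    gamma = buildSchedule(4, 19.5, 0.5, 100, 10, nEq, nProd, "gamma"),
    delta = buildSchedule(2, 16.5, 0.5, 100, 10, nEq, nProd, "delta"),
    xi = buildSchedule(10, 30, 0.5, 100, 10, nEq, nProd, "xi"))
}

# deterministic per-window seed derived from the master seed (kept < 2^31)
.windowSeed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 7919) %% 2147483629)
}

#' Run the two-stage umbrella protocol over the Langevin engine
#'
#' Per window: \code{nEq} samples are generated under the strong constant
#' \code{kEq} starting at the window center and discarded; production then
#' resumes from the equilibration endpoint under \code{kProd} and retains
#' \code{nProd} samples. Window seeds are derived deterministically from
#' \code{cfg@seed} and the window index.
#'
#' @param landscape a \linkS4class{ToyLandscape}.
#' @param schedule a \linkS4class{WindowSchedule}.
#' @param cfg an \linkS4class{EngineConfig}.
#' @return list of \linkS4class{BiasedTimeSeries}, one per window.
#' @export
runUmbrella <- function(landscape, schedule, cfg = engineConfig()) {
  kmax <- max(vapply(schedule@windows, function(w) w@kEq, numeric(1)))
  .checkStability(cfg, kmax)
  ft <- .forceTable(landscape)
  lapply(seq_along(schedule@windows), function(i) {
    w <- schedule@windows[[i]]
    seed <- .windowSeed(cfg@seed, i)
    res <- tryCatch(
      .withSeed(seed, {
        x0 <- w@center
        if (w@nEq > 0L) {
          eq <- .runKernel(landscape, harmonicBias(w@center, w@kEq),
                           w@nEq, cfg, x0, ft)
          x0 <- eq$xfinal
        }
        .runKernel(landscape, harmonicBias(w@center, w@kProd),
                   w@nProd, cfg, x0, ft)
      }),
      error = function(e) {
        stop(sprintf("window %d (center %.3f A): %s", i, w@center,
                     conditionMessage(e)), call. = FALSE)
      })
    new("BiasedTimeSeries", window = w, samples = res$samples,
        provenance = sprintf("%s window %d center=%g seed=%d",
                             schedule@cvName, i, w@center, seed))
  })
}

#' Histogram overlap between two biased series
#'
#' Sum over shared histogram bins of min(p_a, p_b), a WHAM solvability
#' diagnostic; adjacent-window overlaps should stay above roughly 0.05.
#'
#' @param a,b \linkS4class{BiasedTimeSeries} (non-empty).
#' @param binWidth histogram bin width, Angstrom.
#' @param breaks optional explicit break points (overrides binWidth).
#' @return overlap fraction in [0, 1].
#' @export
overlapFraction <- function(a, b, binWidth = 0.1, breaks = NULL) {
  sa <- a@samples; sb <- b@samples
  if (!length(sa) || !length(sb)) stop("both series must be non-empty")
  if (is.null(breaks)) {
    lo <- floor(min(sa, sb) / binWidth) * binWidth
    hi <- ceiling(max(sa, sb) / binWidth) * binWidth
    breaks <- seq(lo - binWidth / 2, hi + binWidth / 2, by = binWidth)
  }
  pa <- tabulate(findInterval(sa, breaks), length(breaks) - 1L) / length(sa)
  pb <- tabulate(findInterval(sb, breaks), length(breaks) - 1L) / length(sb)
  sum(pmin(pa, pb))
}

#' Check all adjacent-window overlaps of an umbrella run
#'
#' @param series list of \linkS4class{BiasedTimeSeries} in window order.
#' @param binWidth histogram bin width.
#' @return numeric vector of length (n - 1) with adjacent overlaps.
#' @export
adjacentOverlaps <- function(series, binWidth = 0.1) {
  if (length(series) < 2L) return(numeric())
  vapply(seq_len(length(series) - 1L), function(i) {
    overlapFraction(series[[i]], series[[i + 1L]], binWidth = binWidth)
  }, numeric(1))
}

# ---- plain-text series exchange -------------------------------------------

#' Write / read per-window CV series as plain text
#'
#' One CV value (Angstrom) per line, preceded by header lines of the form
#' \code{# key=value} recording the window parameters. The format is the
#' exchange medium between a real biased-MD engine and the WHAM stage.
#'
#' @param ts a \linkS4class{BiasedTimeSeries}.
#' @param file path.
#' @return \code{readSeries} returns a \linkS4class{BiasedTimeSeries}.
#' @export
writeSeries <- function(ts, file) {
  w <- ts@window
  hdr <- sprintf("# %s=%s",
                 c("center", "k_prod", "k_eq", "n_eq", "provenance"),
                 c(sprintf("%.10g", c(w@center, w@kProd, w@kEq)),
                   w@nEq, ts@provenance))
  writeLines(c(hdr, sprintf("%.10g", ts@samples)), file)
  invisible(file)
}

#' @rdname writeSeries
#' @export
readSeries <- function(file) {
  txt <- readLines(file)
  hdr <- grep("^#", txt, value = TRUE)
  body <- txt[!grepl("^#", txt) & nzchar(txt)]
  getv <- function(key, default = NA) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    m <- unlist(m)
    if (!length(m)) return(default)
    sub(paste0(key, "="), "", m[1])
  }
  samples <- as.numeric(body)
  w <- new("UmbrellaWindow",
           center = as.numeric(getv("center")),
           kEq = as.numeric(getv("k_eq", getv("k_prod"))),
           kProd = as.numeric(getv("k_prod")),
           nEq = as.integer(as.numeric(getv("n_eq", 0))),
           nProd = length(samples))
  new("BiasedTimeSeries", window = w, samples = samples,
      provenance = as.character(getv("provenance", basename(file))))
}

#' @rdname writeSeries
#' @param series list of \linkS4class{BiasedTimeSeries}.
#' @param dir directory for per-window files \code{window_###.dat}.
#' @export
writeUmbrellaRun <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(series)) {
    writeSeries(series[[i]], file.path(dir, sprintf("window_%03d.dat", i)))
  }
  invisible(dir)
}

#' @rdname writeSeries
#' @export
readUmbrellaRun <- function(dir) {
  files <- sort(list.files(dir, pattern = "^window_\\d+\\.dat$",
                           full.names = TRUE))
  if (!length(files)) stop("no window_###.dat files in ", dir)
  lapply(files, readSeries)
}

# ---- bias-engine export ----------------------------------------------------

.comIndices <- function(structure, sel) {
  paste(resolveSelection(structure, sel), collapse = ",")
}

#' Export a bias-engine configuration for real-MD use
#'
#' Emits deterministic PLUMED-style text: one COM pair and DISTANCE
#' definition per collective variable, one RESTRAINT line per distance
#' restraint (the study holds the lesion-flanking base pairs at 6.06 A and
#' 5.85 A with k = 25 kcal mol^-1 A^-2), and one umbrella RESTRAINT line
#' per window with its center and production constant. Atom indices are
#' resolved against \code{structure}; an unresolvable selection raises a
#' mapping error.
#'
#' @param schedule a \linkS4class{WindowSchedule} (may have zero windows).
#' @param cvs list of \linkS4class{CVSpec}.
#' @param restraints list of \linkS4class{RestraintSpec}.
#' @param structure the \linkS4class{Structure} providing atom numbering.
#' @return single character string (the config text).
#' @export
exportBiasConfig <- function(schedule, cvs, restraints, structure) {
  lines <- c(
    sprintf("# bias-engine export: %s schedule, %d windows",
            schedule@cvName, length(schedule@windows)),
    "# units: kcal/mol, Angstrom")
  for (cv in cvs) {
    lines <- c(lines,
      sprintf("%s_a: COM ATOMS=%s", cv@name,
              .comIndices(structure, cv@groupA)),
      sprintf("%s_b: COM ATOMS=%s", cv@name,
              .comIndices(structure, cv@groupB)),
      sprintf("%s: DISTANCE ATOMS=%s_a,%s_b", cv@name, cv@name, cv@name))
  }
  for (i in seq_along(restraints)) {
    r <- restraints[[i]]
    nm <- sprintf("rest%d", i)
    lines <- c(lines,
      sprintf("%s_a: COM ATOMS=%s", nm, .comIndices(structure, r@groupA)),
      sprintf("%s_b: COM ATOMS=%s", nm, .comIndices(structure, r@groupB)),
      sprintf("%s: DISTANCE ATOMS=%s_a,%s_b", nm, nm, nm),
      sprintf("RESTRAINT ARG=%s AT=%.10g KAPPA=%.10g", nm, r@target, r@k))
  }
  if (length(schedule@windows)) {
    lines <- c(lines, sprintf("# umbrella windows for %s", schedule@cvName))
    for (i in seq_along(schedule@windows)) {
      w <- schedule@windows[[i]]
      lines <- c(lines, sprintf(
        "RESTRAINT ARG=%s AT=%.10g KAPPA=%.10g LABEL=window_%03d",
        schedule@cvName, w@center, w@kProd, i))
    }
  }
  paste(lines, collapse = "\n")
}
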