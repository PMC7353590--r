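# Synthetic PRM runs and whole digestion studies with known ground truth.
# The generator emulates the signal structure of the real acquisitions:
# co-eluting light/heavy peptide peaks around 14.4 min, a later-eluting
# PEG peak at 18.5 min, Gaussian elution profiles, peptide peak areas
# proportional to concentration, a saturating (log-linear) PEG response,
# and additive Gaussian point noise.

# evaluate expr with a temporary RNG state seeded from 'seed'
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# derive a per-run seed from a study seed; kept within 32-bit integer range
.deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 9973) %% 2147483647)
}

#' Signal model for synthetic PRM runs
#'
#' Describes how analyte concentrations turn into chromatographic traces:
#' each analyte elutes as a Gaussian peak at a fixed retention time, its
#' total response (integrated area at unit fragment factor) is either
#' linear (peptides, \code{area = slope * conc}) or saturating
#' (PEG, \code{area = a * ln(conc) + b}), and the response is split across
#' the analyte's transitions by relative fragment factors that sum to 1.
#' Additive Gaussian noise (sd \code{noiseSd}) and a constant baseline are
#' applied per trace point; negative values are clamped to zero.
#'
#' @slot rt Named numeric, retention-time center per analyte (min).
#' @slot width Named numeric, Gaussian peak sd per analyte (min).
#' @slot fragmentFactors Named list: per analyte, a named numeric vector of
#'   relative per-fragment response factors (non-negative, normalized to
#'   sum 1 by the constructor).
#' @slot response Named list: per analyte, \code{list(kind = "linear",
#'   slope = ...)} or \code{list(kind = "log", a = ..., b = ...)}.
#' @slot noiseSd Additive noise sd (intensity units).
#' @slot baseline Constant baseline level (intensity units).
#' @seealso \code{\link{signalModel}}, \code{\link{simulateRun}}
#' @export
setClass("SignalModel",
  representation(rt = "numeric", width = "numeric",
                 fragmentFactors = "list", response = "list",
                 noiseSd = "numeric", baseline = "numeric"))

setValidity("SignalModel", function(object) {
  msg <- character()
  ids <- names(object@rt)
  if (is.null(ids) || !identical(sort(ids), sort(names(object@width))) ||
      !identical(sort(ids), sort(names(object@fragmentFactors))) ||
      !identical(sort(ids), sort(names(object@response))))
    return("rt, width, fragmentFactors and response must share analyte names")
  if (any(object@width <= 0)) msg <- c(msg, "peak widths must be > 0")
  for (id in ids) {
    f <- object@fragmentFactors[[id]]
    if (any(f < 0)) msg <- c(msg, sprintf("negative fragment factor (%s)", id))
    if (abs(sum(f) - 1) > 1e-8)
      msg <- c(msg, sprintf("fragment factors of '%s' must sum to 1", id))
    r <- object@response[[id]]
    if (!r$kind %in% c("linear", "log"))
      msg <- c(msg, sprintf("response kind of '%s' must be linear or log", id))
    if (r$kind == "linear" && r$slope <= 0)
      msg <- c(msg, sprintf("response slope of '%s' must be > 0", id))
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalModel
#'
#' @param rt Named numeric retention-time centers (min).
#' @param width Named numeric Gaussian peak sds (min), or a single value
#'   recycled to all analytes.
#' @param fragmentFactors Named list of per-fragment relative factors per
#'   analyte; normalized to sum 1.
#' @param response Named list of response descriptions per analyte (see
#'   \code{\linkS4class{SignalModel}}).
#' @param noiseSd Additive Gaussian noise sd (default 0: deterministic).
#' @param baseline Constant baseline (default 0).
#' @return A \code{\linkS4class{SignalModel}}.
#' @export
signalModel <- function(rt, width, fragmentFactors, response,
                        noiseSd = 0, baseline = 0) {
  if (length(width) == 1L && is.null(names(width)))
    width <- setNames(rep(width, length(rt)), names(rt))
  fragmentFactors <- lapply(fragmentFactors, function(f) f / sum(f))
  new("SignalModel", rt = rt, width = width[names(rt)],
      fragmentFactors = fragmentFactors[names(rt)],
      response = response[names(rt)],
      noiseSd = as.numeric(noiseSd), baseline = as.numeric(baseline))
}

setMethod("show", "SignalModel", function(object) {
  cat(sprintf("SignalModel for %d analytes (noise sd %.3g, baseline %.3g)\n",
              length(object@rt), object@noiseSd, object@baseline))
  for (id in names(object@rt)) {
    r <- object@response[[id]]
    desc <- if (r$kind == "linear") sprintf("linear slope %.4g", r$slope)
            else sprintf("log a %.4g b %.4g", r$a, r$b)
    cat(sprintf("  %s: RT %.2f min (sd %.3f), %s, %d fragments\n", id,
                object@rt[[id]], object@width[[id]], desc,
                length(object@fragmentFactors[[id]])))
  }
  invisible(NULL)
})

# total response (area units) of one analyte at a concentration
.analyteResponse <- function(model, id, conc) {
  r <- model@response[[id]]
  if (conc < 0) stop("negative concentration", call. = FALSE)
  if (conc == 0) return(0)
  switch(r$kind,
         linear = r$slope * conc,
         log = max(0, r$a * log(conc) + r$b))
}

#' Simulate one PRM injection
#'
#' Each transition's trace is
#' \code{baseline + factor * response(conc) * dnorm(t, rt, width) + noise},
#' sampled on a regular time grid and clamped at zero, so the integrated
#' (noise-free, baseline-free) peak area of an analyte equals its total
#' response and splits across transitions by the fragment factors.
#' Identical seeds give identical runs.
#'
#' @param concentrations Named numeric, concentration (ng/uL) per analyte;
#'   analytes of \code{tl} missing from the vector are simulated at 0.
#' @param model A \code{\linkS4class{SignalModel}}.
#' @param tl \code{\linkS4class{TransitionList}} defining the monitored
#'   traces.
#' @param duration Run length in minutes; must cover all transition RT
#'   windows.
#' @param interval Sampling interval in minutes (default 0.005, about 3 Hz).
#' @param seed Integer seed for the noise; ignored when \code{noiseSd} is 0.
#' @param sampleId Sample identifier for the run.
#' @return A \code{\linkS4class{PrmRun}}.
#' @export
simulateRun <- function(concentrations, model, tl, duration = 20,
                        interval = 0.005, seed = 1L, sampleId = "run") {
  stopifnot(is(model, "SignalModel"), is(tl, "TransitionList"))
  validObject(model)
  if (any(concentrations < 0))
    stop("negative concentration", call. = FALSE)
  tr <- transitions(tl)
  if (duration < max(tr$rt_end))
    stop("'duration' does not cover all transition RT windows", call. = FALSE)
  tgrid <- seq(0, duration, by = interval)
  ids <- transitionIds(tl)

  .withSeed(seed, {
    chroms <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
      id <- tr$analyte_id[i]
      conc <- if (id %in% names(concentrations)) concentrations[[id]] else 0
      resp <- .analyteResponse(model, id, conc)
      factor <- model@fragmentFactors[[id]][[tr$fragment_label[i]]]
      trace <- model@baseline +
        factor * resp * dnorm(tgrid, model@rt[[id]], model@width[[id]])
      if (model@noiseSd > 0)
        trace <- trace + rnorm(length(tgrid), 0, model@noiseSd)
      chroms[[i]] <- chromatogram(ids[i], tgrid, pmax(trace, 0))
    }
    prmRun(sampleId, chroms)
  })
}

#' Simulate a calibration standard series
#'
#' One run per standard level, every analyte present at its level-specific
#' concentration, plus optional blank (all-zero) runs used downstream for
#' LOD/LOQ estimation.
#'
#' @param model A \code{\linkS4class{SignalModel}}.
#' @param tl \code{\linkS4class{TransitionList}}.
#' @param series Named list: per analyte, the numeric vector of standard
#'   concentrations (all vectors the same length; level i of the series
#'   mixes the i-th concentration of every analyte, as in a serially
#'   diluted standard mixture).
#' @param nBlanks Number of blank runs appended (default 3).
#' @param seed Study seed; per-run seeds are derived deterministically.
#' @param duration,interval Passed to \code{\link{simulateRun}}.
#' @return List with \code{standards} (list of
#'   \code{list(concentrations, run)}) and \code{blanks} (list of
#'   \code{\linkS4class{PrmRun}}).
#' @export
simulateStandardSeries <- function(model, tl, series, nBlanks = 3L,
                                   seed = 1L, duration = 20,
                                   interval = 0.005) {
  lens <- lengths(series)
  if (!length(series) || any(lens == 0L))
    stop("'series' must give a non-empty level vector per analyte",
         call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("all analytes need the same number of standard levels",
         call. = FALSE)
  nLevels <- lens[[1L]]
  standards <- vector("list", nLevels)
  for (i in seq_len(nLevels)) {
    conc <- vapply(series, `[[`, numeric(1L), i)
    run <- simulateRun(conc, model, tl, duration, interval,
                       seed = .deriveSeed(seed, i),
                       sampleId = sprintf("standard_L%02d", i))
    standards[[i]] <- list(concentrations = conc, run = run)
  }
  blanks <- lapply(seq_len(nBlanks), function(j)
    simulateRun(setNames(numeric(length(series)), names(series)),
                model, tl, duration, interval,
                seed = .deriveSeed(seed, 1000L + j),
                sampleId = sprintf("blank_%02d", j)))
  list(standards = standards, blanks = blanks)
}

#' Ground truth for a synthetic digestion study
#'
#' Builds the per subject x compartment truth table from survival fractions
#' and dilution factors. The marker logic mirrors the study design: the
#' compartment's PEG concentration is the feed PEG divided by the true
#' dilution factor; the intact-target concentration is feed target times
#' survival fraction divided by dilution factor; the SIS spike is constant
#' because it is added after trypsin digestion, post-collection.
#'
#' @param subjects Character vector of subject ids.
#' @param survival Matrix (subjects x compartments gastric/intestinal/stool)
#'   of true survival fractions in [0, 1].
#' @param dilution Matrix of true dilution factors (> 0), same shape.
#' @param feedTarget Feed intact-target concentration(s), ng/uL (recycled
#'   over subjects).
#' @param feedPeg Feed PEG concentration(s), ng/uL.
#' @param sisSpike SIS spike concentration, ng/uL (constant).
#' @return \code{data.frame} with one row per subject x compartment:
#'   \code{subject}, \code{compartment}, \code{survival_fraction},
#'   \code{dilution_factor}, \code{target_conc}, \code{peg_conc},
#'   \code{sis_conc}. Feed rows have survival 1 and dilution 1.
#' @export
studyTruth <- function(subjects, survival, dilution, feedTarget = 18,
                       feedPeg = 0.1, sisSpike = 0.5) {
  comps <- c("gastric", "intestinal", "stool")
  survival <- as.matrix(survival); dilution <- as.matrix(dilution)
  stopifnot(nrow(survival) == length(subjects),
            ncol(survival) == 3L, all(dim(survival) == dim(dilution)))
  if (any(survival < 0 | survival > 1))
    stop("survival fractions must lie in [0, 1]", call. = FALSE)
  if (any(dilution <= 0))
    stop("dilution factors must be > 0", call. = FALSE)
  feedTarget <- rep_len(feedTarget, length(subjects))
  feedPeg <- rep_len(feedPeg, length(subjects))
  rows <- list()
  for (s in seq_along(subjects)) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subjects[s], compartment = "feed", survival_fraction = 1,
      dilution_factor = 1, target_conc = feedTarget[s],
      peg_conc = feedPeg[s], sis_conc = sisSpike, stringsAsFactors = FALSE)
    for (k in seq_along(comps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[s], compartment = comps[k],
        survival_fraction = survival[s, k], dilution_factor = dilution[s, k],
        target_conc = feedTarget[s] * survival[s, k] / dilution[s, k],
        peg_conc = feedPeg[s] / dilution[s, k], sis_conc = sisSpike,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default study truth: four subjects, Table-like digestion pattern
#'
#' Emulates the observed study conditions: four subjects, high gastric
#' survival, roughly one-third intestinal survival, near-complete stool
#' degradation with one non-detect, gastric/intestinal dilution factors
#' slightly above 1, and stool factors straddling 1 (variable transit).
#' Feed concentrations sit inside the default calibrated standard ranges.
#'
#' @return A truth \code{data.frame} (see \code{\link{studyTruth}}).
#' @export
defaultStudyTruth <- function() {
  studyTruth(
    subjects = paste0("infant", 1:4),
    survival = rbind(c(0.85, 0.30, 0.00),
                     c(0.79, 0.13, 0.12),
                     c(1.00, 0.39, 0.05),
                     c(0.90, 0.38, 0.05)),
    dilution = rbind(c(1.004, 1.14, 0.45),
                     c(1.25,  1.51, 1.14),
                     c(1.14,  1.30, 0.76),
                     c(1.01,  1.14, 1.23)),
    feedTarget = 18, feedPeg = 0.1, sisSpike = 0.5)
}

#' Simulate a whole digestion study
#'
#' Generates the replicate injection runs for every subject x compartment
#' cell of a truth table, writes them as run TSVs together with a sample
#' metadata CSV and a truth JSON, and returns the file manifest.
#'
#' @param truth Truth table from \code{\link{studyTruth}}.
#' @param model A \code{\linkS4class{SignalModel}}.
#' @param tl \code{\linkS4class{TransitionList}}.
#' @param dir Output directory (created if needed).
#' @param targetId,sisId,pegId Analyte ids in \code{tl} for the surrogate
#'   peptide, the SIS peptide and the PEG marker.
#' @param nInjections Replicate injections per sample (default 4).
#' @param seed Study seed; all per-run seeds derive from it.
#' @param duration,interval Passed to \code{\link{simulateRun}}.
#' @return List with \code{samples} (the metadata \code{data.frame}),
#'   \code{metadata} (CSV path) and \code{truth} (JSON path).
#' @export
simulateDigestionStudy <- function(truth, model, tl, dir,
                                   targetId = "palivizumab",
                                   sisId = "sis", pegId = "peg28",
                                   nInjections = 4L, seed = 1L,
                                   duration = 20, interval = 0.005) {
  need <- c("subject", "compartment", "target_conc", "peg_conc", "sis_conc")
  missing <- setdiff(need, names(truth))
  if (length(missing))
    stop(sprintf("truth is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (s in unique(truth$subject))
    if (sum(truth$compartment == "feed" & truth$subject == s) != 1L)
      stop(sprintf("missing (or duplicated) feed row for subject '%s'", s),
           call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  runIndex <- 0L
  for (i in seq_len(nrow(truth))) {
    cell <- truth[i, ]
    conc <- setNames(c(cell$target_conc, cell$sis_conc, cell$peg_conc),
                     c(targetId, sisId, pegId))
    paths <- character(nInjections)
    for (j in seq_len(nInjections)) {
      runIndex <- runIndex + 1L
      sid <- sprintf("%s_%s_inj%d", cell$subject, cell$compartment, j)
      run <- simulateRun(conc, model, tl, duration, interval,
                         seed = .deriveSeed(seed, runIndex), sampleId = sid)
      paths[j] <- file.path(dir, paste0(sid, ".tsv"))
      writeRun(run, paths[j])
    }
    rows[[i]] <- data.frame(
      subject_id = cell$subject, compartment = cell$compartment,
      run_path = paste(paths, collapse = ";"),
      spiked_target = cell$target_conc, spiked_sis = cell$sis_conc,
      spiked_peg = cell$peg_conc, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  metaPath <- file.path(dir, "samples.csv")
  writeSampleSheet(samples, metaPath)
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truthPath, digits = NA)
  list(samples = samples, metadata = metaPath, truth = truthPath)
}
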