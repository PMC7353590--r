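# Workflow orchestration: a single study configuration drives transition
# building, simulation, calibration, per-sample quantitation and the
# survival report. Every stage reads and writes plain-text artifacts in
# the study output directory, so the stages compose stepwise (as the CLI
# subcommands) or all at once via runStudy(). All outputs are
# deterministic given the config and seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default study configuration
#'
#' The configuration of the reference workflow: a doubly charged surrogate
#' peptide LLIYDTSK monitored by its y2-y7 ions under HCD, its SIS
#' counterpart (13C6,15N2 lysine label) with the same fragment set, and the
#' PEG 28-mer monitored at z = 3 by the DP 7-17 CID ladder (DP 9 excluded),
#' plus the standard dilution series, m/z match tolerance (0.01), Gaussian
#' signal-model parameters and simulation settings.
#'
#' @param seed Study seed recorded in the config (default 1).
#' @return Nested list; see the package vignette for the schema.
#' @export
defaultStudyConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    analytes = list(
      palivizumab = list(
        kind = "peptide", sequence = "LLIYDTSK", charge = 2L,
        fragments = paste0("y", 2:7), activation = "HCD",
        rt_center = 14.4, rt_window = c(14.1, 14.7),
        calibration = "linear", role = "target"),
      sis = list(
        kind = "peptide", sequence = "LLIYDTSK",
        modifications = list(list(position = 8L,
                                  name = "label_13C6_15N2_K")),
        charge = 2L, fragments = paste0("y", 2:7), activation = "HCD",
        rt_center = 14.4, rt_window = c(14.1, 14.7),
        calibration = "linear", role = "sis", expected_conc = 0.5),
      peg28 = list(
        kind = "peg", n_units = 28L, charge = 3L,
        fragments = paste0("DP", setdiff(7:17, 9L)), activation = "CID",
        rt_center = 18.5, rt_window = c(18.2, 18.8),
        calibration = "log", role = "dilution_marker")),
    standards = list(
      palivizumab = c(0.5, 1, 2, 5, 10, 20),
      sis = c(0.01, 0.05, 0.1, 0.2, 0.5, 1),
      peg28 = c(0.005, 0.01, 0.05, 0.1, 0.5, 1)),
    n_blanks = 3L,
    tolerance_mz = 0.01,
    integration = list(baseline = "flanking_median"),
    signal = list(width = 0.05, noise_sd = 0, baseline = 0,
                  peptide_slope = 1000, peg_a = 300, peg_b = 2000),
    simulation = list(duration = 20, interval = 0.005, n_injections = 4L))
}

#' Read / write a study configuration (YAML)
#'
#' @param path Path to the YAML file.
#' @return \code{readStudyConfig}: the config list.
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$analytes) || !length(cfg$analytes))
    stop("config must define at least one analyte", call. = FALSE)
  if (!is.null(cfg$tolerance_mz) && cfg$tolerance_mz <= 0)
    stop("tolerance_mz must be > 0", call. = FALSE)
  cfg
}

#' @rdname readStudyConfig
#' @param config Config list.
#' @export
writeStudyConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# parse a fragment label into (series, index): "y5" or "DP12"
.parseFragment <- function(label) {
  if (grepl("^y[0-9]+$", label))
    list(series = "y", index = as.integer(sub("^y", "", label)))
  else if (grepl("^DP[0-9]+$", label))
    list(series = "DP", index = as.integer(sub("^DP", "", label)))
  else stop(sprintf("unrecognized fragment label '%s'", label),
            call. = FALSE)
}

.peptideFromConfig <- function(a) {
  mods <- NULL
  if (!is.null(a$modifications) && length(a$modifications)) {
    mods <- data.frame(
      position = vapply(a$modifications, function(m)
        as.integer(m$position), integer(1L)),
      name = vapply(a$modifications, function(m)
        as.character(m$name), character(1L)),
      stringsAsFactors = FALSE)
  }
  modifiedPeptide(a$sequence, mods, a$charge)
}

#' Build the transition list from a study configuration
#'
#' Computes precursor and fragment m/z for every configured analyte:
#' y-ion m/z for peptides (with any isotope label applied), DP-ladder m/z
#' for PEG. The default configuration yields 22 fragment transitions
#' (6 light y-ions, 6 heavy y-ions, 10 PEG DP ions).
#'
#' @param config Study configuration (see \code{\link{defaultStudyConfig}}).
#' @return A \code{\linkS4class{TransitionList}}.
#' @examples
#' length(buildTransitions(defaultStudyConfig()))  # 22
#' @export
buildTransitions <- function(config) {
  analytes <- config$analytes
  if (is.null(analytes) || !length(analytes))
    stop("config defines no analytes", call. = FALSE)
  rows <- list()
  for (id in names(analytes)) {
    a <- analytes[[id]]
    if (a$kind == "peptide") {
      p <- .peptideFromConfig(a)
      prec <- precursorMz(p)
      activation <- a$activation %||% "HCD"
      fragMz <- vapply(a$fragments, function(lab) {
        f <- .parseFragment(lab)
        if (f$series != "y")
          stop(sprintf("peptide analyte '%s' supports y-ion fragments only",
                       id), call. = FALSE)
        yIonMz(p, f$index)
      }, numeric(1L))
      charge <- a$charge
    } else if (a$kind == "peg") {
      prec <- pegMz(pegOligomer(a$n_units, a$charge))
      activation <- a$activation %||% "CID"
      fragMz <- vapply(a$fragments, function(lab) {
        f <- .parseFragment(lab)
        if (f$series != "DP")
          stop(sprintf("peg analyte '%s' supports DP fragments only", id),
               call. = FALSE)
        pegMz(pegOligomer(f$index, 1L))
      }, numeric(1L))
      charge <- a$charge
    } else stop(sprintf("unknown analyte kind '%s'", a$kind), call. = FALSE)
    rows[[id]] <- data.frame(
      analyte_id = id, analyte_kind = a$kind, precursor_mz = prec,
      precursor_charge = as.integer(charge),
      fragment_label = unname(a$fragments), fragment_mz = unname(fragMz),
      activation = activation, rt_start = a$rt_window[[1L]],
      rt_end = a$rt_window[[2L]], stringsAsFactors = FALSE)
  }
  transitionList(do.call(rbind, rows))
}

#' Signal model implied by a study configuration
#'
#' Retention times and windows come from the analyte definitions; fragment
#' factors are uniform across each analyte's transitions; peptides get the
#' configured linear response slope, the PEG marker the configured
#' log-linear coefficients.
#'
#' @param config Study configuration.
#' @return A \code{\linkS4class{SignalModel}}.
#' @export
signalModelFromConfig <- function(config) {
  analytes <- config$analytes
  sig <- config$signal
  rt <- vapply(analytes, function(a) a$rt_center, numeric(1L))
  width <- setNames(rep(sig$width, length(analytes)), names(analytes))
  ff <- lapply(analytes, function(a)
    setNames(rep(1 / length(a$fragments), length(a$fragments)),
             a$fragments))
  resp <- lapply(analytes, function(a) {
    if (a$kind == "peg") list(kind = "log", a = sig$peg_a, b = sig$peg_b)
    else list(kind = "linear", slope = sig$peptide_slope)
  })
  signalModel(rt, width, ff, resp, noiseSd = sig$noise_sd,
              baseline = sig$baseline)
}

.logLine <- function(logPath, stage, detail) {
  cat(sprintf("[%s] %s\n", stage, detail), file = logPath, append = TRUE)
}

#' Pipeline stage: write the transition list
#'
#' @param config Study configuration.
#' @param outDir Study output directory (created if needed).
#' @return The \code{\linkS4class{TransitionList}}, invisibly; writes
#'   \code{transitions.tsv}.
#' @export
stageTransitions <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tl <- buildTransitions(config)
  writeTransitions(tl, file.path(outDir, "transitions.tsv"))
  .logLine(file.path(outDir, "run.log"), "transitions",
           sprintf("%d transitions for %d analytes", length(tl),
                   length(config$analytes)))
  invisible(tl)
}

#' Pipeline stage: simulate standards, blanks and study runs
#'
#' Writes standard-series and blank runs plus a \code{standards.csv}
#' manifest, and the study's sample runs, metadata and truth JSON, all
#' under \code{outDir/runs}.
#'
#' @param config Study configuration.
#' @param outDir Study output directory.
#' @param truth Truth table (default \code{\link{defaultStudyTruth}()}).
#' @return List with the standards manifest and sample metadata, invisibly.
#' @export
stageSimulate <- function(config, outDir, truth = defaultStudyTruth()) {
  runsDir <- file.path(outDir, "runs")
  dir.create(runsDir, showWarnings = FALSE, recursive = TRUE)
  tl <- buildTransitions(config)
  model <- signalModelFromConfig(config)
  sim <- config$simulation
  seed <- config$seed %||% 1L

  series <- simulateStandardSeries(
    model, tl, config$standards, nBlanks = config$n_blanks %||% 3L,
    seed = seed, duration = sim$duration, interval = sim$interval)
  manifest <- list()
  for (lvl in series$standards) {
    path <- file.path(runsDir, paste0(lvl$run@sampleId, ".tsv"))
    writeRun(lvl$run, path)
    manifest[[length(manifest) + 1L]] <- data.frame(
      run_path = path, type = "standard",
      analyte_id = names(lvl$concentrations),
      conc = unname(lvl$concentrations), stringsAsFactors = FALSE)
  }
  for (bl in series$blanks) {
    path <- file.path(runsDir, paste0(bl@sampleId, ".tsv"))
    writeRun(bl, path)
    manifest[[length(manifest) + 1L]] <- data.frame(
      run_path = path, type = "blank",
      analyte_id = names(config$standards), conc = 0,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(outDir, "standards.csv"),
                   row.names = FALSE, quote = FALSE)

  roles <- vapply(config$analytes, function(a) a$role %||% "", character(1L))
  study <- simulateDigestionStudy(
    truth, model, tl, runsDir,
    targetId = names(roles)[roles == "target"][1L],
    sisId = names(roles)[roles == "sis"][1L],
    pegId = names(roles)[roles == "dilution_marker"][1L],
    nInjections = sim$n_injections, seed = seed + 500000L,
    duration = sim$duration, interval = sim$interval)
  file.rename(study$metadata, file.path(outDir, "samples.csv"))
  file.rename(study$truth, file.path(outDir, "truth.json"))
  .logLine(file.path(outDir, "run.log"), "simulate",
           sprintf("%d standard levels, %d blanks, %d samples, seed %d",
                   length(series$standards), length(series$blanks),
                   nrow(study$samples), seed))
  invisible(list(standards = manifest, samples = study$samples))
}

#' Pipeline stage: fit calibration curves and detection limits
#'
#' Reads the standard/blank manifest, integrates each run, fits the
#' per-analyte calibration model from the config, estimates LOD/LOQ from
#' the blank runs (quantified through the fitted curve), and writes
#' \code{calibration.json}.
#'
#' @param config Study configuration.
#' @param outDir Study output directory containing \code{transitions.tsv}
#'   and \code{standards.csv}.
#' @return Named list of \code{\linkS4class{CalibrationCurve}}, invisibly.
#' @export
stageCalibrate <- function(config, outDir) {
  tl <- readTransitions(file.path(outDir, "transitions.tsv"))
  manifest <- read.csv(file.path(outDir, "standards.csv"),
                       stringsAsFactors = FALSE)
  baseline <- config$integration$baseline %||% "flanking_median"

  paths <- unique(manifest$run_path)
  areas <- list()
  for (p in paths) {
    run <- readRun(p)
    resp <- analyteResponses(run, tl, baseline)
    resp$run_path <- p
    areas[[p]] <- resp
  }
  areas <- do.call(rbind, areas)
  merged <- merge(manifest, areas, by = c("run_path", "analyte_id"))

  curves <- list()
  for (aid in names(config$analytes)) {
    std <- merged[merged$type == "standard" & merged$analyte_id == aid, ]
    curve <- fitCalibration(std$conc, std$area,
                            config$analytes[[aid]]$calibration %||% "linear",
                            analyteId = aid)
    blank <- merged[merged$type == "blank" & merged$analyte_id == aid, ]
    if (nrow(blank) >= 2L) {
      blankConc <- as.numeric(invertCalibration(curve, blank$area))
      curve <- setDetectionLimits(curve, lodLoq(blankConc))
    }
    curves[[aid]] <- curve
  }
  json <- lapply(curves, function(cu) list(
    analyte_id = cu@analyteId, model = cu@modelKind,
    coefficients = as.list(cu@coefficients), r2 = cu@r2,
    conc_range = cu@concRange, response_range = cu@responseRange,
    lod = cu@lod, loq = cu@loq))
  jsonlite::write_json(json, file.path(outDir, "calibration.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  .logLine(file.path(outDir, "run.log"), "calibrate",
           paste(vapply(curves, function(cu)
             sprintf("%s %s R2=%.4f", cu@analyteId, cu@modelKind, cu@r2),
             character(1L)), collapse = "; "))
  invisible(curves)
}

#' Read calibration curves back from calibration.json
#'
#' @param path Path to the JSON written by \code{\link{stageCalibrate}}.
#' @return Named list of \code{\linkS4class{CalibrationCurve}}.
#' @export
readCalibration <- function(path) {
  json <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  curves <- lapply(json, function(j)
    new("CalibrationCurve", analyteId = j$analyte_id, modelKind = j$model,
        coefficients = unlist(j$coefficients), r2 = j$r2,
        concRange = j$conc_range, responseRange = j$response_range,
        lod = j$lod %||% NA_real_, loq = j$loq %||% NA_real_))
  setNames(curves, vapply(curves, function(cu) cu@analyteId, character(1L)))
}

#' Pipeline stage: quantify every sample injection
#'
#' Reads each replicate run of every sample, integrates and inverts the
#' calibration curves, and writes the long-format \code{quant.csv} (one row
#' per sample x injection x analyte).
#'
#' @param config Study configuration.
#' @param outDir Study output directory containing \code{transitions.tsv},
#'   \code{calibration.json} and \code{samples.csv}.
#' @return The quant \code{data.frame}, invisibly.
#' @export
stageQuantify <- function(config, outDir) {
  tl <- readTransitions(file.path(outDir, "transitions.tsv"))
  curves <- readCalibration(file.path(outDir, "calibration.json"))
  samples <- readSampleSheet(file.path(outDir, "samples.csv"))
  baseline <- config$integration$baseline %||% "flanking_median"

  rows <- list()
  for (i in seq_len(nrow(samples))) {
    paths <- strsplit(samples$run_path[i], ";", fixed = TRUE)[[1L]]
    for (j in seq_along(paths)) {
      q <- quantifyRun(readRun(paths[j]), tl, curves, baseline)
      q$subject <- samples$subject_id[i]
      q$compartment <- samples$compartment[i]
      q$injection <- j
      rows[[length(rows) + 1L]] <- q
    }
  }
  quant <- do.call(rbind, rows)
  quant <- quant[, c("subject", "compartment", "injection", "analyte_id",
                     "area", "conc", "flags")]
  out <- quant
  out$area <- sprintf("%.10g", out$area)
  out$conc <- sprintf("%.10g", out$conc)
  write.table(out, file.path(outDir, "quant.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  .logLine(file.path(outDir, "run.log"), "quantify",
           sprintf("%d sample rows, %d flagged", nrow(quant),
                   sum(nzchar(quant$flags))))
  invisible(quant)
}

#' Pipeline stage: normalization chain and survival report
#'
#' Pivots the per-injection quant table to the wide per-analyte layout,
#' applies the SIS correction and the PEG dilution-factor normalization,
#' and writes \code{survival.csv} / \code{survival.json}.
#'
#' @param config Study configuration.
#' @param outDir Study output directory containing \code{quant.csv} and
#'   \code{calibration.json}.
#' @return The \code{\linkS4class{SurvivalReport}}, invisibly.
#' @export
stageSurvive <- function(config, outDir) {
  quant <- read.csv(file.path(outDir, "quant.csv"),
                    stringsAsFactors = FALSE)
  curves <- readCalibration(file.path(outDir, "calibration.json"))
  roles <- vapply(config$analytes, function(a) a$role %||% "", character(1L))
  targetId <- names(roles)[roles == "target"][1L]
  sisId <- names(roles)[roles == "sis"][1L]
  pegId <- names(roles)[roles == "dilution_marker"][1L]

  wide <- NULL
  for (aid in c(targetId, sisId, pegId)) {
    sub <- quant[quant$analyte_id == aid,
                 c("subject", "compartment", "injection", "conc")]
    names(sub)[4L] <- paste0(aid, "_conc")
    wide <- if (is.null(wide)) sub else
      merge(wide, sub, by = c("subject", "compartment", "injection"))
  }
  names(wide)[match(paste0(c(targetId, sisId, pegId), "_conc"),
                    names(wide))] <-
    c("target_conc", "sis_conc", "peg_conc")

  report <- buildSurvivalReport(
    wide, expectedSis = config$analytes[[sisId]]$expected_conc %||% 0.5,
    targetLod = curves[[targetId]]@lod %||% NA_real_)
  writeSurvivalReport(report, file.path(outDir, "survival.csv"),
                      file.path(outDir, "survival.json"))
  .logLine(file.path(outDir, "run.log"), "survive",
           paste(vapply(seq_len(nrow(report@summary)), function(i)
             sprintf("%s %.1f%%", report@summary$compartment[i],
                     report@summary$mean_survival[i]), character(1L)),
             collapse = "; "))
  invisible(report)
}

#' Run the whole study pipeline
#'
#' Composes the stages: transitions, simulate (unless \code{simulate =
#' FALSE}, in which case \code{samples.csv} and \code{standards.csv} must
#' already exist in \code{outDir}), calibrate, quantify, survive. All
#' artifacts land in \code{outDir}; re-running with the same config and
#' seed reproduces them byte-identically.
#'
#' @param config Study configuration (see \code{\link{defaultStudyConfig}}).
#' @param outDir Study output directory.
#' @param truth Truth table for simulation (default
#'   \code{\link{defaultStudyTruth}()}).
#' @param simulate Generate synthetic inputs (default TRUE).
#' @return List with \code{transitions}, \code{curves}, \code{quant} and
#'   \code{report}.
#' @export
runStudy <- function(config, outDir, truth = defaultStudyTruth(),
                     simulate = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  if (file.exists(logPath)) file.remove(logPath)
  .logLine(logPath, "config",
           sprintf("seed %d, %d analytes, tolerance %.3g",
                   config$seed %||% 1L, length(config$analytes),
                   config$tolerance_mz %||% 0.01))
  tl <- stageTransitions(config, outDir)
  if (simulate) stageSimulate(config, outDir, truth)
  curves <- stageCalibrate(config, outDir)
  quant <- stageQuantify(config, outDir)
  report <- stageSurvive(config, outDir)
  list(transitions = tl, curves = curves, quant = quant, report = report)
}
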