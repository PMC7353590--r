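#' @include prmQuant-package.R
NULL

#' Peptide with modifications and charge
#'
#' An amino-acid sequence (one-letter codes) carrying zero or more named
#' modifications at specific residues and an ionization charge. This is the
#' unit the mass arithmetic operates on: the light surrogate peptide, its
#' stable-isotope-labeled (SIS) counterpart, or any tryptic candidate.
#'
#' @slot sequence Single string of one-letter residue codes.
#' @slot modifications \code{data.frame} with columns \code{position}
#'   (1-based residue index) and \code{name} (a key of the modification
#'   table in \code{\link{massConstants}}). Zero rows means unmodified.
#' @slot charge Positive integer charge state.
#' @seealso \code{\link{modifiedPeptide}}, \code{\link{peptideMass}},
#'   \code{\link{precursorMz}}, \code{\link{yIonMz}}
#' @export
setClass("ModifiedPeptide",
  representation(sequence = "character", modifications = "data.frame",
                 charge = "integer"))

setValidity("ModifiedPeptide", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || is.na(object@sequence) ||
      !nzchar(object@sequence))
    return("'sequence' must be a single non-empty string")
  res <- strsplit(object@sequence, "")[[1L]]
  known <- names(massConstants()$residue_masses)
  bad <- setdiff(res, known)
  if (length(bad))
    msg <- c(msg, sprintf("unknown residue(s): %s",
                          paste(unique(bad), collapse = ", ")))
  mods <- object@modifications
  if (!all(c("position", "name") %in% names(mods)))
    msg <- c(msg, "'modifications' needs columns 'position' and 'name'")
  else if (nrow(mods)) {
    if (any(mods$position < 1L | mods$position > length(res)))
      msg <- c(msg, "modification position outside sequence bounds")
    badmod <- setdiff(mods$name, names(massConstants()$modifications))
    if (length(badmod))
      msg <- c(msg, sprintf("unknown modification(s): %s",
                            paste(unique(badmod), collapse = ", ")))
  }
  if (length(object@charge) != 1L || is.na(object@charge) ||
      object@charge < 1L)
    msg <- c(msg, "'charge' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a ModifiedPeptide
#'
#' @param sequence One-letter amino-acid string, e.g. \code{"LLIYDTSK"}.
#' @param modifications \code{NULL} for an unmodified peptide, or a
#'   \code{data.frame}/list with elements \code{position} (1-based) and
#'   \code{name}. The SIS label used throughout the package is
#'   \code{"label_13C6_15N2_K"} on the C-terminal lysine.
#' @param charge Integer charge state (default 1).
#' @return A \code{\linkS4class{ModifiedPeptide}}.
#' @examples
#' modifiedPeptide("LLIYDTSK", charge = 2)
#' modifiedPeptide("LLIYDTSK",
#'   modifications = list(position = 8, name = "label_13C6_15N2_K"),
#'   charge = 2)
#' @export
modifiedPeptide <- function(sequence, modifications = NULL, charge = 1L) {
  if (is.null(modifications)) {
    mods <- data.frame(position = integer(), name = character(),
                       stringsAsFactors = FALSE)
  } else {
    mods <- as.data.frame(modifications, stringsAsFactors = FALSE)
    mods$position <- as.integer(mods$position)
    mods$name <- as.character(mods$name)
  }
  new("ModifiedPeptide", sequence = as.character(sequence),
      modifications = mods, charge = as.integer(charge))
}

#' PEG oligomer
#'
#' A polyethylene-glycol chain of \code{nUnits} ethylene-oxide repeat units
#' (the degree of polymerization, DP) at a given charge. The same formula
#' describes the intact co-fed marker (e.g. the 28-mer at z = 3) and its
#' collision-induced fragments (DP 7-17 at z = 1).
#'
#' @slot nUnits Non-negative integer degree of polymerization.
#' @slot charge Positive integer charge state.
#' @seealso \code{\link{pegOligomer}}, \code{\link{pegMz}}
#' @export
setClass("PegOligomer",
  representation(nUnits = "integer", charge = "integer"))

setValidity("PegOligomer", function(object) {
  msg <- character()
  if (length(object@nUnits) != 1L || is.na(object@nUnits) ||
      object@nUnits < 0L)
    msg <- c(msg, "'nUnits' must be a non-negative integer")
  if (length(object@charge) != 1L || is.na(object@charge) ||
      object@charge < 1L)
    msg <- c(msg, "'charge' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a PegOligomer
#'
#' @param nUnits Degree of polymerization (number of ethylene-oxide units).
#' @param charge Integer charge state (default 1).
#' @return A \code{\linkS4class{PegOligomer}}.
#' @examples
#' pegMz(pegOligomer(28, charge = 3))  # intact marker precursor
#' pegMz(pegOligomer(7))               # DP 7 fragment
#' @export
pegOligomer <- function(nUnits, charge = 1L) {
  new("PegOligomer", nUnits = as.integer(nUnits), charge = as.integer(charge))
}

#' Transition list for PRM acquisition
#'
#' A table of (precursor m/z, fragment m/z) pairs with activation type and
#' retention-time window, one row per monitored fragment ion. Peptide rows
#' use the y-ion series under HCD; PEG rows use the DP ladder under CID.
#'
#' @slot transitions \code{data.frame} with columns \code{analyte_id},
#'   \code{analyte_kind} ("peptide" or "peg"), \code{precursor_mz},
#'   \code{precursor_charge}, \code{fragment_label}, \code{fragment_mz},
#'   \code{activation} ("HCD" or "CID"), \code{rt_start}, \code{rt_end}
#'   (minutes).
#' @seealso \code{\link{transitionList}}, \code{\link{buildTransitions}},
#'   \code{\link{readTransitions}}
#' @export
setClass("TransitionList", representation(transitions = "data.frame"))

.TRANSITION_COLS <- c("analyte_id", "analyte_kind", "precursor_mz",
                      "precursor_charge", "fragment_label", "fragment_mz",
                      "activation", "rt_start", "rt_end")

setValidity("TransitionList", function(object) {
  tr <- object@transitions
  msg <- character()
  missing <- setdiff(.TRANSITION_COLS, names(tr))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (nrow(tr)) {
    if (!all(tr$analyte_kind %in% c("peptide", "peg")))
      msg <- c(msg, "analyte_kind must be 'peptide' or 'peg'")
    if (!all(tr$activation %in% c("HCD", "CID")))
      msg <- c(msg, "activation must be 'HCD' or 'CID'")
    if (any(tr$fragment_mz <= 0))
      msg <- c(msg, "fragment_mz must be positive")
    if (any(tr$rt_start >= tr$rt_end))
      msg <- c(msg, "rt_start must be < rt_end")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TransitionList from a data.frame
#'
#' @param transitions \code{data.frame} with the columns documented in
#'   \code{\linkS4class{TransitionList}}.
#' @return A \code{\linkS4class{TransitionList}}.
#' @export
transitionList <- function(transitions) {
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  rownames(transitions) <- NULL
  new("TransitionList", transitions = transitions)
}

#' Extract the transition table
#'
#' @param x A \code{\linkS4class{TransitionList}}.
#' @return The underlying \code{data.frame}.
#' @export
transitions <- function(x) {
  stopifnot(is(x, "TransitionList"))
  x@transitions
}

#' Transition identifiers
#'
#' Identifier of each monitored trace, \code{"<analyte_id>.<fragment_label>"}.
#'
#' @param x A \code{\linkS4class{TransitionList}}.
#' @return Character vector, one id per transition row.
#' @export
transitionIds <- function(x) {
  tr <- transitions(x)
  paste(tr$analyte_id, tr$fragment_label, sep = ".")
}

setMethod("show", "TransitionList", function(object) {
  tr <- object@transitions
  cat(sprintf("TransitionList with %d transitions (%d analytes)\n",
              nrow(tr), length(unique(tr$analyte_id))))
  for (id in unique(tr$analyte_id)) {
    sub <- tr[tr$analyte_id == id, ]
    cat(sprintf("  %s [%s, %s]: precursor %.4f (z=%d), fragments %s\n",
                id, sub$analyte_kind[1L], sub$activation[1L],
                sub$precursor_mz[1L], sub$precursor_charge[1L],
                paste(sub$fragment_label, collapse = " ")))
  }
  invisible(NULL)
})

setMethod("length", "TransitionList", function(x) nrow(x@transitions))

#' Single extracted-ion chromatogram
#'
#' The time/intensity trace for one transition in one injection.
#'
#' @slot transitionId Identifier, \code{"<analyte_id>.<fragment_label>"}.
#' @slot time Numeric vector of retention times (minutes), strictly
#'   increasing.
#' @slot intensity Numeric vector of non-negative intensities, same length.
#' @export
setClass("Chromatogram",
  representation(transitionId = "character", time = "numeric",
                 intensity = "numeric"))

setValidity("Chromatogram", function(object) {
  msg <- character()
  if (length(object@time) != length(object@intensity))
    msg <- c(msg, "'time' and 'intensity' lengths differ")
  if (length(object@time) && any(diff(object@time) <= 0))
    msg <- c(msg, "'time' must be strictly increasing")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "'intensity' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a Chromatogram
#'
#' @param transitionId Trace identifier.
#' @param time Retention times in minutes, strictly increasing.
#' @param intensity Non-negative intensities, same length as \code{time}.
#' @return A \code{\linkS4class{Chromatogram}}.
#' @export
chromatogram <- function(transitionId, time, intensity) {
  new("Chromatogram", transitionId = as.character(transitionId),
      time = as.numeric(time), intensity = as.numeric(intensity))
}

#' One PRM injection: a set of per-transition chromatograms
#'
#' @slot sampleId Identifier of the injected sample.
#' @slot chromatograms Named list of \code{\linkS4class{Chromatogram}},
#'   keyed by transition id.
#' @seealso \code{\link{readRun}}, \code{\link{simulateRun}}
#' @export
setClass("PrmRun",
  representation(sampleId = "character", chromatograms = "list"))

setValidity("PrmRun", function(object) {
  ok <- vapply(object@chromatograms, function(x) is(x, "Chromatogram"),
               logical(1L))
  if (!all(ok)) return("all elements must be Chromatogram objects")
  ids <- vapply(object@chromatograms, function(x) x@transitionId,
                character(1L))
  if (!identical(unname(ids), names(object@chromatograms)))
    return("list names must equal the chromatogram transition ids")
  TRUE
})

#' Construct a PrmRun
#'
#' @param sampleId Sample identifier.
#' @param chromatograms List of \code{\linkS4class{Chromatogram}}; names are
#'   taken from each trace's transition id.
#' @return A \code{\linkS4class{PrmRun}}.
#' @export
prmRun <- function(sampleId, chromatograms) {
  names(chromatograms) <- vapply(chromatograms,
                                 function(x) x@transitionId, character(1L))
  new("PrmRun", sampleId = as.character(sampleId),
      chromatograms = chromatograms)
}

setMethod("show", "PrmRun", function(object) {
  npts <- if (length(object@chromatograms))
    length(object@chromatograms[[1L]]@time) else 0L
  cat(sprintf("PrmRun '%s': %d chromatograms, %d points each\n",
              object@sampleId, length(object@chromatograms), npts))
  invisible(NULL)
})

setMethod("length", "PrmRun", function(x) length(x@chromatograms))

#' Fitted calibration curve
#'
#' Response model mapping analyte concentration to summed transition peak
#' area. Peptides follow a linear model (response = m*conc + b); the PEG
#' marker saturates and follows a logarithmic model
#' (response = a*ln(conc) + b).
#'
#' @slot analyteId Analyte identifier.
#' @slot modelKind \code{"linear"} or \code{"log"}.
#' @slot coefficients Named numeric: \code{slope}/\code{intercept} (linear)
#'   or \code{a}/\code{b} (log).
#' @slot r2 Coefficient of determination of the fit.
#' @slot concRange Range of calibrated concentrations (min, max).
#' @slot responseRange Range of fitted responses (min, max).
#' @slot lod,loq Limit of detection / quantitation in concentration units
#'   (blank mean + 3 or + 10 blank standard deviations); \code{NA} until
#'   blanks are supplied.
#' @seealso \code{\link{fitCalibration}}, \code{\link{invertCalibration}},
#'   \code{\link{lodLoq}}
#' @export
setClass("CalibrationCurve",
  representation(analyteId = "character", modelKind = "character",
                 coefficients = "numeric", r2 = "numeric",
                 concRange = "numeric", responseRange = "numeric",
                 lod = "numeric", loq = "numeric"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (!object@modelKind %in% c("linear", "log"))
    msg <- c(msg, "modelKind must be 'linear' or 'log'")
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (!is.na(object@lod) && !is.na(object@loq) && object@lod > object@loq)
    msg <- c(msg, "LOD must be <= LOQ")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve '%s' (%s): %s, R2 = %.4f\n",
              object@analyteId, object@modelKind,
              paste(sprintf("%s = %.6g", names(object@coefficients),
                            object@coefficients), collapse = ", "),
              object@r2))
  cat(sprintf("  calibrated range: %.4g - %.4g; LOD = %.4g, LOQ = %.4g\n",
              object@concRange[1L], object@concRange[2L],
              object@lod, object@loq))
  invisible(NULL)
})

#' Survival report for a digestion study
#'
#' Per subject x compartment: SIS-normalized concentration, dilution factor
#' from the co-fed PEG marker, dilution-normalized concentration, replicate
#' error (sd/sqrt(n)) and CV, and percent survival relative to the feed;
#' plus study-level per-compartment summaries and paired-test statistics.
#'
#' @slot samples Per-sample \code{data.frame} (one row per subject x
#'   compartment).
#' @slot summary Per-compartment \code{data.frame} with mean survival, SE
#'   over subjects, and n.
#' @slot tests Paired feed-vs-compartment t-test results.
#' @seealso \code{\link{buildSurvivalReport}}
#' @export
setClass("SurvivalReport",
  representation(samples = "data.frame", summary = "data.frame",
                 tests = "data.frame"))

setMethod("show", "SurvivalReport", function(object) {
  cat("SurvivalReport\n")
  cat(sprintf("  %d samples, %d subjects\n", nrow(object@samples),
              length(unique(object@samples$subject))))
  for (i in seq_len(nrow(object@summary))) {
    s <- object@summary[i, ]
    cat(sprintf("  %-10s mean survival %5.1f%% (SE %.1f%%, n = %d)\n",
                s$compartment, s$mean_survival, s$se, s$n))
  }
  invisible(NULL)
})

#' Per-sample rows of a survival report
#' @param x A \code{\linkS4class{SurvivalReport}}.
#' @return \code{data.frame} with one row per subject x compartment.
#' @export
reportSamples <- function(x) {
  stopifnot(is(x, "SurvivalReport"))
  x@samples
}

#' Study-level per-compartment summary of a survival report
#' @param x A \code{\linkS4class{SurvivalReport}}.
#' @return \code{data.frame} with mean survival, SE and n per compartment.
#' @export
reportSummary <- function(x) {
  stopifnot(is(x, "SurvivalReport"))
  x@summary
}

#' Paired-test table of a survival report
#' @param x A \code{\linkS4class{SurvivalReport}}.
#' @return \code{data.frame} of feed-vs-compartment paired t results.
#' @export
reportTests <- function(x) {
  stopifnot(is(x, "SurvivalReport"))
  x@tests
}
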