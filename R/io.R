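# Readers/writers for on-disk artifacts: FASTA databases, transition-list
# TSVs, chromatogram run stores (long TSV or a minimal spectrum-list XML),
# and sample metadata. Writers are deterministic (fixed column order and
# float formatting, no timestamps); readers reject malformed input rather
# than repairing it.

.COMPARTMENTS <- c("feed", "gastric", "intestinal", "stool")

#' Read a protein FASTA database
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-cased protein sequences, names
#'   taken from the record headers (first whitespace-delimited token).
#' @export
readFastaDb <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop(sprintf("empty sequence for record(s): %s",
                 paste(ids[empty], collapse = ", ")), call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write a protein FASTA database
#'
#' @param sequences Named character vector of protein sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFastaDb <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::AAStringSet(toupper(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a transition-list TSV
#'
#' Fixed column order: analyte_id, analyte_kind, precursor_mz,
#' precursor_charge, fragment_label, fragment_mz, activation, rt_start,
#' rt_end. m/z values are serialized at 4 decimal places.
#'
#' @param path Path to the TSV written by \code{\link{writeTransitions}}.
#' @return A \code{\linkS4class{TransitionList}}.
#' @export
readTransitions <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  tr <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRANSITION_COLS, names(tr))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  for (col in c("precursor_mz", "fragment_mz", "rt_start", "rt_end")) {
    v <- suppressWarnings(as.numeric(tr[[col]]))
    badLine <- which(is.na(v) & !is.na(tr[[col]]))
    if (length(badLine))
      stop(sprintf("non-numeric %s at line %d", col, badLine[1L] + 1L),
           call. = FALSE)
    tr[[col]] <- v
  }
  transitionList(tr[, .TRANSITION_COLS])
}

#' Write a transition-list TSV
#'
#' @param tl A \code{\linkS4class{TransitionList}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTransitions <- function(tl, path) {
  stopifnot(is(tl, "TransitionList"))
  tr <- transitions(tl)[, .TRANSITION_COLS, drop = FALSE]
  out <- tr
  out$precursor_mz <- sprintf("%.4f", tr$precursor_mz)
  out$fragment_mz <- sprintf("%.4f", tr$fragment_mz)
  out$rt_start <- sprintf("%.3f", tr$rt_start)
  out$rt_end <- sprintf("%.3f", tr$rt_end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PRM run from a long-format TSV
#'
#' Columns: \code{transition_id}, \code{time_min}, \code{intensity}. Each
#' transition's trace must be strictly time-sorted with no duplicate time
#' points; intensities must be non-negative.
#'
#' @param path Path to the run TSV.
#' @param sampleId Sample identifier (default: file name without extension).
#' @return A \code{\linkS4class{PrmRun}}.
#' @export
readRun <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transition_id", "time_min", "intensity")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  chroms <- lapply(split(d, d$transition_id), function(sub) {
    if (any(diff(sub$time_min) <= 0))
      stop(sprintf("unsorted or duplicate time points in transition '%s'",
                   sub$transition_id[1L]), call. = FALSE)
    if (any(sub$intensity < 0))
      stop(sprintf("negative intensity in transition '%s'",
                   sub$transition_id[1L]), call. = FALSE)
    chromatogram(sub$transition_id[1L], sub$time_min, sub$intensity)
  })
  # preserve first-appearance order of transitions in the file
  chroms <- chroms[unique(d$transition_id)]
  prmRun(sampleId, chroms)
}

#' Write a PRM run to a long-format TSV
#'
#' @param run A \code{\linkS4class{PrmRun}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRun <- function(run, path) {
  stopifnot(is(run, "PrmRun"))
  parts <- lapply(run@chromatograms, function(ch)
    data.frame(transition_id = ch@transitionId,
               time_min = sprintf("%.10g", ch@time),
               intensity = sprintf("%.10g", ch@intensity),
               stringsAsFactors = FALSE))
  d <- do.call(rbind, parts)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a PRM run from a minimal spectrum-list XML store
#'
#' The dialect is a flat list of centroided MS/MS spectra:
#' \preformatted{
#' <spectrumList sample="s1">
#'   <spectrum rt_min="14.40">
#'     <peak mz="234.1448" intensity="1200"/>
#'   </spectrum>
#' </spectrumList>
#' }
#' Each peak is assigned to the transition whose fragment m/z is nearest
#' within \code{tolerance} (absolute m/z units; nearest target wins ties);
#' peaks outside the tolerance of every target are dropped. Spectra missing
#' a target's peak contribute intensity 0 at that retention time, so every
#' trace shares the spectrum time grid.
#'
#' @param path Path to the XML file.
#' @param tl \code{\linkS4class{TransitionList}} of targets.
#' @param tolerance Absolute m/z match tolerance (default 0.01, the usual
#'   method match tolerance for Orbitrap PRM extraction).
#' @param sampleId Sample identifier; default the \code{sample} attribute
#'   or the file name.
#' @return A \code{\linkS4class{PrmRun}} with one chromatogram per
#'   transition.
#' @export
readSpectrumList <- function(path, tl, tolerance = 0.01, sampleId = NULL) {
  stopifnot(is(tl, "TransitionList"), tolerance > 0)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  doc <- xml2::read_xml(path)
  if (is.null(sampleId)) {
    sampleId <- xml2::xml_attr(doc, "sample")
    if (is.na(sampleId)) sampleId <- sub("\\.[^.]*$", "", basename(path))
  }
  targets <- transitions(tl)$fragment_mz
  ids <- transitionIds(tl)

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  rts <- as.numeric(xml2::xml_attr(spectra, "rt_min"))
  if (any(is.na(rts)))
    stop("spectrum without a numeric rt_min attribute", call. = FALSE)
  ord <- order(rts)
  if (anyDuplicated(rts))
    stop("duplicate spectrum retention times", call. = FALSE)
  inten <- matrix(0, nrow = length(spectra), ncol = length(ids),
                  dimnames = list(NULL, ids))
  for (i in seq_along(spectra)) {
    peaks <- xml2::xml_find_all(spectra[[i]], ".//peak")
    if (!length(peaks)) next
    mz <- as.numeric(xml2::xml_attr(peaks, "mz"))
    ab <- as.numeric(xml2::xml_attr(peaks, "intensity"))
    if (any(is.na(mz)) || any(is.na(ab)))
      stop("peak without numeric mz/intensity attributes", call. = FALSE)
    for (j in seq_along(mz)) {
      dist <- abs(targets - mz[j])
      best <- which.min(dist)
      if (dist[best] <= tolerance)
        inten[i, best] <- inten[i, best] + ab[j]
    }
  }
  chroms <- lapply(seq_along(ids), function(k)
    chromatogram(ids[k], rts[ord], inten[ord, k]))
  prmRun(sampleId, chroms)
}

#' Read a sample-metadata CSV
#'
#' Columns: \code{subject_id}, \code{compartment} (feed, gastric,
#' intestinal or stool), \code{run_path} (semicolon-separated paths of the
#' replicate injection runs for that sample), optional
#' \code{spiked_target}, \code{spiked_sis}, \code{spiked_peg} (ng/uL) and
#' \code{note}. One row per sample; exactly one feed row per subject.
#'
#' @param path Path to the CSV.
#' @return \code{data.frame} of sample records.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "compartment", "run_path")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  bad <- setdiff(unique(d$compartment), .COMPARTMENTS)
  if (length(bad))
    stop(sprintf("unknown compartment(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  feeds <- table(d$subject_id[d$compartment == "feed"])
  subjects <- unique(d$subject_id)
  if (!all(subjects %in% names(feeds)) || any(feeds != 1L))
    stop("each subject needs exactly one feed sample", call. = FALSE)
  d
}

#' Write a sample-metadata CSV
#'
#' @param samples \code{data.frame} of sample records (see
#'   \code{\link{readSampleSheet}}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSampleSheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
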