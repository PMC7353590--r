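# The normalization chain and study-level statistics: SIS correction,
# PEG dilution factors, dilution normalization, recovery, SE/CV, percent
# survival and paired comparisons. Corrections apply in order: SIS first
# (per-sample analytical recovery), then the dilution factor
# (physiological); both are multiplicative, so the order only matters for
# bookkeeping.

#' SIS-correct a measured concentration
#'
#' Rescales a measured target concentration by the recovery of the
#' stable-isotope-labeled internal standard spiked at a known amount:
#' \code{measured * expectedSis / measuredSis}.
#'
#' @param measured Measured target concentration (ng/uL).
#' @param measuredSis Measured SIS concentration (ng/uL, > 0).
#' @param expectedSis Spiked (expected) SIS concentration (ng/uL).
#' @return SIS-normalized concentration (ng/uL).
#' @examples
#' sisNormalize(15.16, 0.39, 0.5)  # ~19.4
#' @export
sisNormalize <- function(measured, measuredSis, expectedSis) {
  if (any(measuredSis <= 0))
    stop("'measuredSis' must be > 0", call. = FALSE)
  measured * expectedSis / measuredSis
}

#' Recovery of a spiked analyte
#'
#' \code{measured / spiked * 100}.
#'
#' @param measured Measured concentration.
#' @param spiked Spiked (true) concentration (> 0).
#' @return Recovery in percent.
#' @examples
#' recoveryPercent(19.43, 50)  # 38.86
#' @export
recoveryPercent <- function(measured, spiked) {
  if (any(spiked <= 0)) stop("'spiked' must be > 0", call. = FALSE)
  measured / spiked * 100
}

#' Dilution factor from the non-digestible marker
#'
#' Ratio of the marker (PEG) concentration measured in the feed to that
#' measured in the digestion sample. Values above 1 signify dilution by
#' secreted digestive fluids; below 1, concentration by water absorption
#' or transit-time effects.
#'
#' @param pegFeed Marker concentration in the feed (> 0).
#' @param pegSample Marker concentration in the digestion sample (> 0).
#' @return Unitless dilution factor.
#' @examples
#' dilutionFactor(0.1, 0.074)  # ~1.35
#' @export
dilutionFactor <- function(pegFeed, pegSample) {
  if (any(pegFeed <= 0) || any(pegSample <= 0))
    stop("marker concentrations must be > 0", call. = FALSE)
  pegFeed / pegSample
}

#' Apply a dilution factor
#'
#' @param conc Concentration (ng/uL).
#' @param factor Dilution factor (> 0).
#' @return \code{conc * factor}.
#' @examples
#' dilutionNormalize(10.04, 1.14)  # 11.45
#' @export
dilutionNormalize <- function(conc, factor) {
  if (any(factor <= 0)) stop("'factor' must be > 0", call. = FALSE)
  conc * factor
}

#' Percent survival relative to the feed
#'
#' \code{normalizedConc / feedConc * 100}. A non-detected target is
#' reported as 0\% and flagged distinctly.
#'
#' @param normalizedConc Dilution-normalized concentration in the
#'   compartment (ng/uL).
#' @param feedConc Concentration in the feed (ng/uL, > 0).
#' @param detected Logical; \code{FALSE} marks a non-detect (N/D).
#' @return Percent survival, with attribute \code{"nd"} (logical) marking
#'   non-detects.
#' @examples
#' survivalPercent(32.41, 38.10)
#' @export
survivalPercent <- function(normalizedConc, feedConc, detected = TRUE) {
  if (any(feedConc <= 0)) stop("'feedConc' must be > 0", call. = FALSE)
  pct <- normalizedConc / feedConc * 100
  detected <- rep_len(detected, length(pct))
  pct[!detected] <- 0
  structure(pct, nd = !detected)
}

#' Replicate summary: mean, standard error and CV
#'
#' Error is \code{sd / sqrt(n)} and CV is \code{sd / mean * 100}, both with
#' the sample standard deviation (n - 1). CV is \code{NA} (flagged) when
#' the mean is zero.
#'
#' @param values Numeric vector of replicate measurements (>= 1; >= 2 for
#'   error and CV).
#' @return Named numeric \code{c(mean = , error = , cv = )}.
#' @examples
#' summarizeReplicates(c(5, 5, 5, 5))
#' @export
summarizeReplicates <- function(values) {
  if (!length(values)) stop("empty replicate vector", call. = FALSE)
  m <- mean(values)
  if (length(values) < 2L)
    return(c(mean = m, error = NA_real_, cv = NA_real_))
  s <- sd(values)
  cv <- if (m == 0) NA_real_ else s / m * 100
  c(mean = m, error = s / sqrt(length(values)), cv = cv)
}

#' Paired Student's t-test
#'
#' Classical paired t on within-subject differences (df = n - 1). When the
#' differences have zero spread, the result is degenerate: t = 0 and p = 1
#' for identical vectors, infinite t and p = 0 for a constant nonzero
#' shift; both are flagged.
#'
#' @param reference Numeric vector (e.g. feed values, one per subject).
#' @param compartment Numeric vector of the matched compartment values.
#' @return List with \code{t}, \code{df}, \code{p} and \code{degenerate}.
#' @examples
#' pairedT(c(10, 12, 9, 11), c(5, 7, 4, 8))
#' @export
pairedT <- function(reference, compartment) {
  if (length(reference) != length(compartment))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(reference)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- compartment - reference
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1L, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                degenerate = TRUE))
  }
  tt <- t.test(compartment, reference, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Build a survival report from per-injection quantities
#'
#' Implements the full normalization chain per subject x compartment:
#' (1) SIS-normalize each replicate target concentration using the sample's
#' mean measured SIS concentration; (2) average the replicates; (3) compute
#' the dilution factor from the feed-to-sample PEG ratio; (4) multiply by
#' it; (5) express as percent of the subject's feed. Per-sample error
#' (sd/sqrt(n injections)) and CV are computed on the dilution-normalized
#' replicate values; study-level summaries use n = number of subjects.
#' Non-detects (all replicates at or below \code{ndThreshold}, or below the
#' target LOD when given) get survival 0 and an N/D flag, and are included
#' in compartment means.
#'
#' @param quant \code{data.frame} with one row per subject x compartment x
#'   injection: \code{subject}, \code{compartment}, \code{target_conc},
#'   \code{sis_conc}, \code{peg_conc}.
#' @param expectedSis Spiked SIS concentration (ng/uL).
#' @param targetLod Optional LOD for the target (ng/uL) used to call
#'   non-detects.
#' @param ndThreshold Fallback non-detect threshold when no LOD is given
#'   (default 0: only exact zero/negative mean replicate signal is N/D).
#' @return A \code{\linkS4class{SurvivalReport}}.
#' @export
buildSurvivalReport <- function(quant, expectedSis, targetLod = NA_real_,
                                ndThreshold = 0) {
  need <- c("subject", "compartment", "target_conc", "sis_conc", "peg_conc")
  missing <- setdiff(need, names(quant))
  if (length(missing))
    stop(sprintf("quant is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  samples <- list()
  for (s in unique(quant$subject)) {
    sub <- quant[quant$subject == s, ]
    feed <- sub[sub$compartment == "feed", ]
    if (!nrow(feed))
      stop(sprintf("missing feed sample for subject '%s'", s), call. = FALSE)
    pegFeed <- mean(feed$peg_conc)
    for (comp in intersect(.COMPARTMENTS, unique(sub$compartment))) {
      cell <- sub[sub$compartment == comp, ]
      sisMean <- mean(cell$sis_conc)
      normTarget <- sisNormalize(cell$target_conc, sisMean, expectedSis)
      fac <- if (comp == "feed") 1 else dilutionFactor(pegFeed,
                                                       mean(cell$peg_conc))
      normed <- dilutionNormalize(normTarget, fac)
      stats <- summarizeReplicates(normed)
      nd <- if (!is.na(targetLod)) mean(cell$target_conc) < targetLod
            else mean(cell$target_conc) <= ndThreshold
      samples[[length(samples) + 1L]] <- data.frame(
        subject = s, compartment = comp,
        conc = mean(normTarget), dilution_factor = fac,
        normalized_conc = if (nd) NA_real_ else stats[["mean"]],
        error = stats[["error"]], cv = stats[["cv"]],
        n_injections = nrow(cell), nd = nd, stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samples)

  # percent survival per subject x compartment, N/D -> 0 flagged
  feedConc <- setNames(
    samples$normalized_conc[samples$compartment == "feed"],
    samples$subject[samples$compartment == "feed"])
  samples$survival_pct <- NA_real_
  for (i in seq_len(nrow(samples))) {
    fc <- feedConc[[samples$subject[i]]]
    samples$survival_pct[i] <- if (samples$nd[i]) 0 else
      as.numeric(survivalPercent(samples$normalized_conc[i], fc))
  }

  comps <- setdiff(intersect(.COMPARTMENTS, unique(samples$compartment)),
                   character())
  summaryRows <- list(); testRows <- list()
  for (comp in comps) {
    v <- samples$survival_pct[samples$compartment == comp]
    st <- summarizeReplicates(v)
    summaryRows[[comp]] <- data.frame(
      compartment = comp, mean_survival = st[["mean"]], se = st[["error"]],
      n = length(v), stringsAsFactors = FALSE)
    if (comp != "feed") {
      subs <- samples$subject[samples$compartment == comp]
      ref <- feedConc[subs]
      obs <- samples$normalized_conc[samples$compartment == comp]
      obs[is.na(obs)] <- 0   # non-detects enter the test as zero
      if (length(obs) >= 2L) {
        tt <- pairedT(ref, obs)
        testRows[[comp]] <- data.frame(
          compartment = comp, t = tt$t, df = tt$df, p = tt$p,
          degenerate = tt$degenerate, stringsAsFactors = FALSE)
      }
    }
  }
  summary <- do.call(rbind, summaryRows); rownames(summary) <- NULL
  tests <- if (length(testRows)) do.call(rbind, testRows) else
    data.frame(compartment = character(), t = numeric(), df = numeric(),
               p = numeric(), degenerate = logical())
  rownames(tests) <- NULL
  new("SurvivalReport", samples = samples, summary = summary, tests = tests)
}

#' Write a survival report to CSV and JSON
#'
#' The CSV mirrors the per-sample table layout (concentration, dilution
#' factor, normalized concentration, error, CV, survival); the JSON also
#' carries the per-compartment summary and test table. Concentrations are
#' printed at 2 decimals, factors at 3, percentages at 1 (half-up).
#'
#' @param report A \code{\linkS4class{SurvivalReport}}.
#' @param csvPath,jsonPath Output paths (\code{NULL} to skip either).
#' @return Invisibly, the report.
#' @export
writeSurvivalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  stopifnot(is(report, "SurvivalReport"))
  if (!is.null(csvPath)) {
    s <- report@samples
    out <- data.frame(
      subject = s$subject, compartment = s$compartment,
      conc = sprintf("%.2f", roundHalfUp(s$conc, 2L)),
      dilution_factor = sprintf("%.3f", roundHalfUp(s$dilution_factor, 3L)),
      normalized_conc = ifelse(s$nd, "N/D",
        sprintf("%.2f", roundHalfUp(s$normalized_conc, 2L))),
      error = ifelse(is.na(s$error), "",
                     sprintf("%.3f", roundHalfUp(s$error, 3L))),
      cv = ifelse(is.na(s$cv), "", sprintf("%.2f", roundHalfUp(s$cv, 2L))),
      survival_pct = sprintf("%.1f", roundHalfUp(s$survival_pct, 1L)),
      stringsAsFactors = FALSE)
    write.table(out, csvPath, sep = ",", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(samples = report@samples, summary = report@summary,
           tests = report@tests),
      jsonPath, digits = NA, na = "null")
  }
  invisible(report)
}
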