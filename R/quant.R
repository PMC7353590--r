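# Chromatograms to concentrations: XIC peak integration, calibration
# fitting (linear and logarithmic), inversion, and LOD/LOQ.

#' Integrate a chromatographic peak
#'
#' Trapezoidal area under the trace inside the retention-time window,
#' minus a baseline. The default baseline is a straight line through the
#' median intensity of up to five points flanking each window edge (the
#' points just outside the window, falling back to the edge points at the
#' trace extremes); \code{"none"} integrates the raw trace. A negative
#' corrected area is clipped to zero and flagged.
#'
#' @param chrom A \code{\linkS4class{Chromatogram}}.
#' @param window Numeric \code{c(start, end)} in minutes; must lie within
#'   the trace extent and contain at least three points.
#' @param baselineMode \code{"flanking_median"} (default) or \code{"none"}.
#' @return List with \code{area} (intensity x min), \code{apex_rt}
#'   (retention time of the maximum corrected intensity) and \code{flag}
#'   (\code{""} or \code{"negative_area_clipped"}).
#' @examples
#' t <- seq(13, 16, by = 0.005)
#' ch <- chromatogram("x", t, dnorm(t, 14.4, 0.05))
#' integratePeak(ch, c(14.1, 14.7), "none")$area  # ~1
#' @export
integratePeak <- function(chrom, window,
                          baselineMode = c("flanking_median", "none")) {
  stopifnot(is(chrom, "Chromatogram"), length(window) == 2L)
  baselineMode <- match.arg(baselineMode)
  t <- chrom@time; y <- chrom@intensity
  if (window[1L] >= window[2L])
    stop("window start must be before window end", call. = FALSE)
  if (window[1L] < t[1L] || window[2L] > t[length(t)])
    stop("integration window outside trace extent", call. = FALSE)
  inside <- which(t >= window[1L] & t <= window[2L])
  if (length(inside) < 3L)
    stop("fewer than 3 trace points inside the integration window",
         call. = FALSE)

  ti <- t[inside]; yi <- y[inside]
  if (baselineMode == "flanking_median") {
    left <- tail(which(t < window[1L]), 5L)
    if (!length(left)) left <- inside[1L]
    right <- head(which(t > window[2L]), 5L)
    if (!length(right)) right <- inside[length(inside)]
    bl <- median(y[left]); br <- median(y[right])
    baseline <- bl + (br - bl) * (ti - ti[1L]) / (ti[length(ti)] - ti[1L])
    yi <- yi - baseline
  }
  area <- sum(diff(ti) * (head(yi, -1L) + tail(yi, -1L)) / 2)
  flag <- ""
  if (area < 0) {
    area <- 0
    flag <- "negative_area_clipped"
  }
  list(area = area, apex_rt = ti[which.max(yi)], flag = flag)
}

#' Fit a calibration curve
#'
#' Unweighted least-squares fit of response against concentration:
#' \code{response = slope * conc + intercept} (linear, peptides) or
#' \code{response = a * ln(conc) + b} (log, the saturating PEG marker).
#' R-squared is \code{1 - SS_res / SS_tot}.
#'
#' @param conc Numeric standard concentrations (>= 3 distinct levels; all
#'   positive for the log model).
#' @param response Numeric responses (summed transition peak areas), same
#'   length.
#' @param modelKind \code{"linear"} or \code{"log"}.
#' @param analyteId Identifier stored on the curve.
#' @return A \code{\linkS4class{CalibrationCurve}} (LOD/LOQ set via
#'   \code{\link{lodLoq}} and \code{\link{setDetectionLimits}}).
#' @examples
#' fitCalibration(1:5, 2 * (1:5) + 1, "linear")
#' @export
fitCalibration <- function(conc, response,
                           modelKind = c("linear", "log"),
                           analyteId = "analyte") {
  modelKind <- match.arg(modelKind)
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 3L)
    stop("calibration needs at least 3 distinct concentrations",
         call. = FALSE)
  if (modelKind == "log" && any(conc <= 0))
    stop("log calibration requires strictly positive concentrations",
         call. = FALSE)
  x <- if (modelKind == "log") log(conc) else conc
  fit <- lm(response ~ x)
  co <- coef(fit)
  ssRes <- sum(residuals(fit)^2)
  ssTot <- sum((response - mean(response))^2)
  r2 <- if (ssTot == 0) 1 else 1 - ssRes / ssTot
  coefs <- if (modelKind == "linear")
    c(slope = unname(co[2L]), intercept = unname(co[1L]))
  else c(a = unname(co[2L]), b = unname(co[1L]))
  fitted <- co[1L] + co[2L] * x
  new("CalibrationCurve", analyteId = analyteId, modelKind = modelKind,
      coefficients = coefs, r2 = max(0, min(1, r2)),
      concRange = range(conc), responseRange = range(fitted),
      lod = NA_real_, loq = NA_real_)
}

#' Invert a calibration curve
#'
#' Maps responses back to concentrations: \code{(response - intercept) /
#' slope} for the linear model, \code{exp((response - b) / a)} for the log
#' model. Responses outside the fitted response range are still inverted
#' but flagged as extrapolated.
#'
#' @param curve A \code{\linkS4class{CalibrationCurve}}.
#' @param response Numeric vector of responses.
#' @return Numeric concentrations with a logical attribute
#'   \code{"extrapolated"} (one element per response).
#' @examples
#' cc <- fitCalibration(1:5, 2 * (1:5) + 1, "linear")
#' invertCalibration(cc, 5)  # 2
#' @export
invertCalibration <- function(curve, response) {
  stopifnot(is(curve, "CalibrationCurve"))
  co <- curve@coefficients
  conc <- if (curve@modelKind == "linear") {
    if (co[["slope"]] == 0) stop("zero slope: cannot invert", call. = FALSE)
    (response - co[["intercept"]]) / co[["slope"]]
  } else {
    if (co[["a"]] == 0) stop("zero 'a': cannot invert", call. = FALSE)
    exp((response - co[["b"]]) / co[["a"]])
  }
  lo <- min(curve@responseRange); hi <- max(curve@responseRange)
  structure(conc, extrapolated = response < lo | response > hi)
}

#' Limits of detection and quantitation from blank measurements
#'
#' LOD is the blank mean plus three blank standard deviations; LOQ is the
#' blank mean plus ten. Sample standard deviation (n - 1 denominator).
#'
#' @param blankConcentrations Numeric vector of blank concentration
#'   measurements (>= 2).
#' @return Named numeric \code{c(lod = , loq = )} in concentration units.
#' @examples
#' lodLoq(c(8, 10, 12))
#' @export
lodLoq <- function(blankConcentrations) {
  if (length(blankConcentrations) < 2L)
    stop("need at least 2 blank measurements", call. = FALSE)
  m <- mean(blankConcentrations)
  s <- sd(blankConcentrations)
  c(lod = m + 3 * s, loq = m + 10 * s)
}

#' Attach detection limits to a calibration curve
#'
#' @param curve A \code{\linkS4class{CalibrationCurve}}.
#' @param limits Named numeric \code{c(lod = , loq = )} from
#'   \code{\link{lodLoq}}.
#' @return The curve with LOD/LOQ slots filled.
#' @export
setDetectionLimits <- function(curve, limits) {
  stopifnot(is(curve, "CalibrationCurve"),
            all(c("lod", "loq") %in% names(limits)))
  curve@lod <- unname(limits[["lod"]])
  curve@loq <- unname(limits[["loq"]])
  validObject(curve)
  curve
}

#' Summed-transition response of each analyte in a run
#'
#' Integrates every transition trace of each analyte over its
#' retention-time window and sums the areas (the standard PRM response:
#' the full fragment set per analyte).
#'
#' @param run A \code{\linkS4class{PrmRun}}.
#' @param tl \code{\linkS4class{TransitionList}}; every transition id must
#'   have a trace in the run.
#' @param baselineMode Passed to \code{\link{integratePeak}}.
#' @return \code{data.frame} with one row per analyte: \code{analyte_id},
#'   \code{area} (summed), \code{apex_rt} (of the most intense transition),
#'   \code{flag}.
#' @export
analyteResponses <- function(run, tl,
                             baselineMode = c("flanking_median", "none")) {
  stopifnot(is(run, "PrmRun"), is(tl, "TransitionList"))
  baselineMode <- match.arg(baselineMode)
  tr <- transitions(tl)
  ids <- transitionIds(tl)
  absent <- setdiff(ids, names(run@chromatograms))
  if (length(absent))
    stop(sprintf("run '%s' lacks trace(s): %s", run@sampleId,
                 paste(absent, collapse = ", ")), call. = FALSE)
  out <- list()
  for (aid in unique(tr$analyte_id)) {
    rows <- which(tr$analyte_id == aid)
    areas <- numeric(length(rows)); apexes <- numeric(length(rows))
    flags <- character(length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      pk <- integratePeak(run@chromatograms[[ids[i]]],
                          c(tr$rt_start[i], tr$rt_end[i]), baselineMode)
      areas[k] <- pk$area; apexes[k] <- pk$apex_rt; flags[k] <- pk$flag
    }
    out[[aid]] <- data.frame(
      analyte_id = aid, area = sum(areas),
      apex_rt = apexes[which.max(areas)],
      flag = paste(unique(flags[nzchar(flags)]), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify analyte concentrations in a run
#'
#' Integrates the run's analyte responses and inverts each analyte's
#' calibration curve. Values below the curve's LOQ (when set) are reported
#' but flagged; responses outside the calibrated range are flagged as
#' extrapolated.
#'
#' @param run A \code{\linkS4class{PrmRun}}.
#' @param tl \code{\linkS4class{TransitionList}}.
#' @param curves Named list of \code{\linkS4class{CalibrationCurve}}, one
#'   per analyte id.
#' @param baselineMode Passed to \code{\link{integratePeak}}.
#' @return \code{data.frame}: \code{sample_id}, \code{analyte_id},
#'   \code{area}, \code{conc}, \code{flags}.
#' @export
quantifyRun <- function(run, tl, curves,
                        baselineMode = c("flanking_median", "none")) {
  baselineMode <- match.arg(baselineMode)
  resp <- analyteResponses(run, tl, baselineMode)
  resp$sample_id <- run@sampleId
  resp$conc <- NA_real_
  resp$flags <- resp$flag
  for (i in seq_len(nrow(resp))) {
    aid <- resp$analyte_id[i]
    if (!aid %in% names(curves))
      stop(sprintf("no calibration curve for analyte '%s'", aid),
           call. = FALSE)
    curve <- curves[[aid]]
    conc <- invertCalibration(curve, resp$area[i])
    fl <- character()
    if (nzchar(resp$flag[i])) fl <- resp$flag[i]
    if (attr(conc, "extrapolated")[1L]) fl <- c(fl, "extrapolated")
    if (!is.na(curve@loq) && conc < curve@loq) fl <- c(fl, "below_loq")
    if (!is.na(curve@lod) && conc < curve@lod) fl <- c(fl, "below_lod")
    resp$conc[i] <- as.numeric(conc)
    resp$flags[i] <- paste(fl, collapse = ";")
  }
  resp[, c("sample_id", "analyte_id", "area", "conc", "flags")]
}
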