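# In-silico tryptic digestion, uniqueness checking against a protein
# database, and ranking of surrogate-peptide candidates.

#' In-silico tryptic digestion
#'
#' Cuts a protein after every C-terminal arginine (R) and lysine (K),
#' producing all fully specific peptides with up to \code{maxMissed}
#' internal missed cleavage sites. By default cleavage also occurs before
#' proline; set \code{keepKPIntact = TRUE} for the common alternative rule
#' that leaves K|P and R|P bonds intact.
#'
#' @param protein Protein sequence (one-letter codes).
#' @param maxMissed Maximum number of internal missed cleavages (default 2).
#' @param keepKPIntact If \code{TRUE}, do not cleave K/R followed by P.
#' @param parentId Identifier stored in the \code{parent_id} column.
#' @return \code{data.frame} with columns \code{sequence},
#'   \code{parent_id}, \code{start}, \code{end} (1-based, closed, so
#'   \code{substr(protein, start, end) == sequence}) and
#'   \code{missed_cleavages}, ordered by start position then length.
#' @examples
#' trypticDigest("LLIYDTSKLASGVPSR", maxMissed = 1)
#' @export
trypticDigest <- function(protein, maxMissed = 2L, keepKPIntact = FALSE,
                          parentId = "protein") {
  protein <- as.character(protein)
  if (length(protein) != 1L || !nzchar(protein))
    stop("'protein' must be a single non-empty sequence", call. = FALSE)
  residues <- strsplit(protein, "")[[1L]]
  bad <- setdiff(residues, names(massConstants()$residue_masses))
  if (length(bad))
    stop(sprintf("unknown residue(s): %s", paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  maxMissed <- as.integer(maxMissed)
  if (is.na(maxMissed) || maxMissed < 0L)
    stop("'maxMissed' must be >= 0", call. = FALSE)

  n <- length(residues)
  cutAfter <- which(residues %in% c("K", "R"))
  if (keepKPIntact)
    cutAfter <- cutAfter[!(cutAfter < n & residues[cutAfter + 1L] == "P")]
  cutAfter <- cutAfter[cutAfter < n]      # a terminal K/R is not a site
  # base peptide boundaries: starts and ends in 1-based closed coordinates
  starts <- c(1L, cutAfter + 1L)
  ends <- c(cutAfter, n)
  nbase <- length(starts)

  out <- vector("list", 0L)
  for (i in seq_len(nbase)) {
    for (m in 0:maxMissed) {
      j <- i + m
      if (j > nbase) break
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(protein, starts[i], ends[j]),
        parent_id = parentId, start = starts[i], end = ends[j],
        missed_cleavages = m, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end - res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Peptide uniqueness against a protein database
#'
#' A peptide is unique when it occurs as a substring of no protein in the
#' database -- the behavior of online peptide-uniqueness checkers, not
#' shared-tryptic-peptide identity. Peptides shorter than \code{minLength}
#' (default 6 residues) are ineligible and reported as \code{"too_short"},
#' never unique.
#'
#' @param peptide Peptide sequence.
#' @param database Named character vector of protein sequences (names are
#'   protein ids), e.g. from \code{\link{readFastaDb}}.
#' @param minLength Minimum peptide length for eligibility (default 6).
#' @param ilEquivalent If \code{TRUE}, treat isoleucine and leucine as
#'   indistinguishable (they are isobaric); off by default.
#' @return A list with \code{status} ("unique", "non_unique" or
#'   "too_short"), \code{is_unique} (logical; \code{NA} when too short) and
#'   \code{matches} (ids of database proteins containing the peptide).
#' @examples
#' db <- c(p1 = "MKLLIYDTSKR", p2 = "MAAAGGG")
#' uniquenessCheck("AAAGGG", db)$matches
#' @export
uniquenessCheck <- function(peptide, database, minLength = 6L,
                            ilEquivalent = FALSE) {
  peptide <- as.character(peptide)
  if (length(database) == 0L)
    stop("'database' must be non-empty", call. = FALSE)
  if (is.null(names(database)) || any(!nzchar(names(database))))
    stop("'database' must be a named vector of protein sequences",
         call. = FALSE)
  if (nchar(peptide) < minLength)
    return(list(status = "too_short", is_unique = NA, matches = character()))
  pep <- peptide
  db <- database
  if (ilEquivalent) {
    pep <- gsub("I", "L", pep, fixed = TRUE)
    db <- vapply(db, function(s) gsub("I", "L", s, fixed = TRUE),
                 character(1L))
  }
  hit <- vapply(db, function(s) grepl(pep, s, fixed = TRUE), logical(1L))
  matches <- names(database)[hit]
  list(status = if (length(matches)) "non_unique" else "unique",
       is_unique = length(matches) == 0L, matches = matches)
}

#' Rank surrogate-peptide candidates
#'
#' Applies the hard selection criteria for a quantotypic surrogate peptide
#' -- unique in the background proteome, unmodified, no missed cleavages,
#' and detected at every standard concentration -- then ranks passing
#' candidates by mean chromatographic peak abundance (descending).
#' Candidates failing any hard criterion rank below all passers (ordered by
#' criteria passed, then abundance). Ties break by shorter sequence, then
#' lexicographically, making the ranking a total order.
#'
#' @param candidates \code{data.frame} with columns \code{sequence},
#'   \code{modification} (\code{NA} or \code{""} when unmodified),
#'   \code{missed_cleavages}, \code{is_unique} (logical), \code{mean_abundance},
#'   and one detection-count column per standard concentration named
#'   \code{det_<conc>} (replicate detection counts, 0..replicates).
#' @param concentrations Numeric vector of standard concentrations; the
#'   columns \code{det_<conc>} must exist for each.
#' @param replicates Number of replicate injections behind each detection
#'   count (default 4); counts outside 0..replicates are rejected.
#' @return The candidate table with added columns \code{flag_unique},
#'   \code{flag_unmodified}, \code{flag_no_missed_cleavage},
#'   \code{flag_detected_all}, \code{pass} (all four), \code{reasons}
#'   (semicolon-separated failed criteria) and \code{rank}, sorted by rank.
#' @examples
#' path <- system.file("extdata", "candidate_evidence.tsv",
#'                     package = "prmQuant")
#' cand <- read.delim(path)
#' selectSurrogate(cand, c(2, 5, 10, 15, 20, 25))$sequence[1]
#' @export
selectSurrogate <- function(candidates, concentrations, replicates = 4L) {
  if (!nrow(candidates))
    stop("'candidates' must contain at least one row", call. = FALSE)
  detCols <- paste0("det_", concentrations)
  missing <- setdiff(c("sequence", "modification", "missed_cleavages",
                       "is_unique", "mean_abundance", detCols),
                     names(candidates))
  if (length(missing))
    stop(sprintf("missing candidate column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  det <- as.matrix(candidates[, detCols, drop = FALSE])
  if (any(det < 0 | det > replicates))
    stop(sprintf("detection counts must lie in 0..%d", replicates),
         call. = FALSE)

  x <- candidates
  x$flag_unique <- as.logical(x$is_unique)
  x$flag_unmodified <- is.na(x$modification) | x$modification == ""
  x$flag_no_missed_cleavage <- x$missed_cleavages == 0L
  x$flag_detected_all <- apply(det > 0, 1L, all)
  flags <- cbind(x$flag_unique, x$flag_unmodified,
                 x$flag_no_missed_cleavage, x$flag_detected_all)
  x$pass <- apply(flags, 1L, all)
  labels <- c("not_unique", "modified", "missed_cleavage",
              "not_detected_at_all_concentrations")
  x$reasons <- apply(flags, 1L, function(f)
    paste(labels[!f], collapse = ";"))
  nPassed <- rowSums(flags)
  ord <- order(-x$pass, -nPassed, -x$mean_abundance,
               nchar(x$sequence), x$sequence)
  x <- x[ord, , drop = FALSE]
  x$rank <- seq_len(nrow(x))
  rownames(x) <- NULL
  x
}
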