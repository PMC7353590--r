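# Shared helpers: random sequence generators and independent brute-force
# oracles used to cross-check the implementation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# Brute-force digestion oracle: enumerate every substring and keep those
# that are fully tryptic with at most maxMissed internal K/R cleavage
# points. Independent of the cut-point construction in trypticDigest().
bruteForceDigest <- function(protein, maxMissed) {
  res <- strsplit(protein, "")[[1L]]
  n <- length(res)
  isSite <- res %in% c("K", "R")
  out <- character()
  for (i in seq_len(n)) {
    for (j in i:n) {
      startOk <- i == 1L || isSite[i - 1L]
      endOk <- j == n || isSite[j]
      if (!startOk || !endOk) next
      internal <- if (j > i) sum(isSite[i:(j - 1L)]) else 0L
      if (internal <= maxMissed)
        out <- c(out, substr(protein, i, j))
    }
  }
  out
}

# Naive uniqueness oracle: compare the peptide against every equal-length
# substring of every database protein.
naiveUniqueness <- function(peptide, database) {
  k <- nchar(peptide)
  hits <- character()
  for (id in names(database)) {
    s <- database[[id]]
    found <- FALSE
    if (nchar(s) >= k) {
      for (i in seq_len(nchar(s) - k + 1L)) {
        if (substr(s, i, i + k - 1L) == peptide) { found <- TRUE; break }
      }
    }
    if (found) hits <- c(hits, id)
  }
  hits
}

# Exact paired-test oracle: enumerate all 2^n sign flips of the paired
# differences and report the fraction with |mean| at least as extreme.
signFlipP <- function(reference, compartment) {
  d <- compartment - reference
  n <- length(d)
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  flipped <- abs(signs %*% d) / n
  mean(flipped >= obs - 1e-12)
}

# Small two-analyte transition list for synthetic-signal tests.
tinyTransitionList <- function() {
  transitionList(data.frame(
    analyte_id = c("pep", "pep", "peg"),
    analyte_kind = c("peptide", "peptide", "peg"),
    precursor_mz = c(476.7711, 476.7711, 417.9221),
    precursor_charge = c(2L, 2L, 3L),
    fragment_label = c("y2", "y3", "DP7"),
    fragment_mz = c(234.1448, 335.1925, 327.2013),
    activation = c("HCD", "HCD", "CID"),
    rt_start = c(14.1, 14.1, 18.2), rt_end = c(14.7, 14.7, 18.8),
    stringsAsFactors = FALSE))
}

tinySignalModel <- function(noiseSd = 0, baseline = 0,
                            pegA = 300, pegB = 2000) {
  signalModel(
    rt = c(pep = 14.4, peg = 18.5), width = 0.05,
    fragmentFactors = list(pep = c(y2 = 0.6, y3 = 0.4), peg = c(DP7 = 1)),
    response = list(pep = list(kind = "linear", slope = 1000),
                    peg = list(kind = "log", a = pegA, b = pegB)),
    noiseSd = noiseSd, baseline = baseline)
}

# Reduced-size study configuration for fast pipeline tests (coarser time
# grid, two injections); the science is unchanged.
smallStudyConfig <- function(seed = 1L) {
  cfg <- defaultStudyConfig(seed)
  cfg$simulation$interval <- 0.02
  cfg$simulation$n_injections <- 2L
  cfg$n_blanks <- 2L
  cfg
}

# The published per-sample quantitation table the normalization chain is
# checked against: measured conc, dilution factor, normalized conc.
printedStudyTable <- function() {
  data.frame(
    subject = rep(paste0("infant", 1:4), each = 4L),
    compartment = rep(c("feed", "gastric", "intestinal", "stool"), 4L),
    conc = c(38.10, 32.26, 10.04, NA, 18.66, 11.70, 1.63, 1.97,
             18.51, 16.14, 5.48, 1.24, 16.17, 14.42, 5.39, 0.65),
    factor = c(1, 1.004, 1.14, 0.45, 1, 1.25, 1.51, 1.14,
               1, 1.14, 1.30, 0.76, 1, 1.01, 1.14, 1.23),
    normalized = c(38.10, 32.41, 11.45, NA, 18.66, 14.67, 2.47, 2.25,
                   18.51, 18.44, 7.14, 0.95, 16.17, 14.57, 6.16, 0.80),
    stringsAsFactors = FALSE)
}
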