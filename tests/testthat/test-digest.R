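# In-silico tryptic digestion, uniqueness checking and surrogate ranking.

test_that("tryptic digestion produces the expected peptides", {
  d0 <- trypticDigest("LLIYDTSKLASGVPSR", maxMissed = 0L)
  expect_setequal(d0$sequence, c("LLIYDTSK", "LASGVPSR"))
  expect_equal(d0$missed_cleavages, c(0L, 0L))

  d1 <- trypticDigest("LLIYDTSKLASGVPSR", maxMissed = 1L)
  expect_true("LLIYDTSKLASGVPSR" %in% d1$sequence)

  noSite <- trypticDigest("AAGGVV", maxMissed = 2L)
  expect_identical(noSite$sequence, "AAGGVV")

  expect_error(trypticDigest("LLIYDTSK", maxMissed = -1L), "maxMissed")
  expect_error(trypticDigest("LLB1"), "unknown residue")
})

test_that("digestion coordinates and missed-cleavage counts are consistent", {
  set.seed(3)
  for (rep in 1:10) {
    prot <- randomProtein(30L)
    d <- trypticDigest(prot, maxMissed = 2L)
    # coordinates address the parent
    expect_identical(substr(rep(prot, nrow(d)), d$start, d$end), d$sequence)
    # recount internal K/R positions
    recount <- vapply(d$sequence, function(s) {
      res <- strsplit(s, "")[[1L]]
      sum(res[-length(res)] %in% c("K", "R"))
    }, integer(1L), USE.NAMES = FALSE)
    expect_identical(d$missed_cleavages, recount)
    # zero-missed-cleavage peptides tile the parent exactly
    d0 <- d[d$missed_cleavages == 0L, ]
    expect_identical(paste(d0$sequence[order(d0$start)], collapse = ""),
                     prot)
  }
})

test_that("digestion agrees with brute-force substring enumeration", {
  set.seed(5)
  for (rep in 1:8) {
    prot <- randomProtein(30L)
    for (m in 0:2) {
      got <- sort(trypticDigest(prot, maxMissed = m)$sequence)
      expect_identical(got, sort(bruteForceDigest(prot, m)),
                       label = sprintf("protein %s, maxMissed %d", prot, m))
    }
    # count formula: sites c, limit m -> sum_{j=0..m} max(0, c + 1 - j)
    res <- strsplit(prot, "")[[1L]]
    c0 <- sum(res[-length(res)] %in% c("K", "R"))
    for (m in 0:2) {
      expected <- sum(pmax(0L, c0 + 1L - 0:m))
      expect_equal(nrow(trypticDigest(prot, maxMissed = m)), expected)
    }
  }
})

test_that("the keep-KP-intact option suppresses cleavage before proline", {
  d <- trypticDigest("AAKPGGR", maxMissed = 0L, keepKPIntact = TRUE)
  expect_identical(d$sequence, "AAKPGGR")
  d2 <- trypticDigest("AAKPGGR", maxMissed = 0L)
  expect_setequal(d2$sequence, c("AAK", "PGGR"))
})

test_that("uniqueness against the bundled database matches the published calls", {
  db <- readFastaDb(system.file("extdata", "synthetic_uniqueness_db.fasta",
                                package = "prmQuant"))
  expect_identical(uniquenessCheck("LLIYDTSK", db)$status, "unique")
  res <- uniquenessCheck("DIQMTQSPSTLSASVGDR", db)
  expect_identical(res$status, "non_unique")
  expect_identical(res$matches, "P01602_synthetic")
  expect_identical(uniquenessCheck("SRLTISK", db)$matches,
                   "A0A0B4J1V2_synthetic")
  expect_identical(uniquenessCheck("NQVVLK", db)$matches, "Q07020_synthetic")
  short <- uniquenessCheck("AAGGK", db)
  expect_identical(short$status, "too_short")
  expect_true(is.na(short$is_unique))
})

test_that("uniqueness checking agrees with a naive all-substring oracle", {
  set.seed(9)
  for (rep in 1:6) {
    db <- setNames(vapply(1:4, function(i) randomProtein(40L),
                          character(1L)), paste0("prot", 1:4))
    # probe with substrings actually present plus random absent peptides
    probes <- c(substr(db[[1L]], 5L, 12L), substr(db[[3L]], 1L, 7L),
                vapply(1:3, function(i) randomProtein(8L), character(1L)))
    for (pep in probes) {
      got <- uniquenessCheck(pep, db)
      expect_setequal(got$matches, naiveUniqueness(pep, db))
      expect_identical(got$is_unique, length(naiveUniqueness(pep, db)) == 0L)
    }
  }
})

test_that("I/L equivalence is an explicit opt-in", {
  db <- c(x = "AAAILLVK")
  expect_true(uniquenessCheck("AAALLL", db)$is_unique)
  expect_false(uniquenessCheck("AAALLL", db, ilEquivalent = TRUE)$is_unique)
})

test_that("surrogate ranking on the bundled evidence selects LLIYDTSK", {
  cand <- read.delim(system.file("extdata", "candidate_evidence.tsv",
                                 package = "prmQuant"),
                     stringsAsFactors = FALSE)
  ranked <- selectSurrogate(cand, c(2, 5, 10, 15, 20, 25))
  expect_identical(ranked$sequence[1L], "LLIYDTSK")
  expect_true(ranked$pass[1L])
  expect_identical(sum(ranked$pass), 1L)  # only one candidate clears all
  # the carbamidomethylated peptide fails only on modification
  vtn <- ranked[ranked$sequence == "VTNMDPADTATYYCAR", ]
  expect_identical(vtn$reasons, "modified")
  # every passer ranks above every non-passer
  expect_true(max(which(ranked$pass)) < min(which(!ranked$pass)))
})

test_that("surrogate ranking is a deterministic total order with tie-breaks", {
  base <- data.frame(
    sequence = c("AAAGGGK", "AAAK", "CCCK"),
    modification = "", missed_cleavages = 0L, is_unique = TRUE,
    mean_abundance = 100, det_1 = 4L, det_2 = 4L, stringsAsFactors = FALSE)
  ranked <- selectSurrogate(base, c(1, 2))
  # equal abundance: shorter sequence first, then lexicographic
  expect_identical(ranked$sequence, c("AAAK", "CCCK", "AAAGGGK"))
  # antisymmetry/transitivity: the rank is a strict permutation and stable
  again <- selectSurrogate(base[c(3, 1, 2), ], c(1, 2))
  expect_identical(again$sequence, ranked$sequence)
  expect_identical(ranked$rank, 1:3)

  expect_error(selectSurrogate(base[0, ], c(1, 2)), "at least one")
  bad <- base; bad$det_1[1L] <- 9L
  expect_error(selectSurrogate(bad, c(1, 2)), "0..4")
})
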