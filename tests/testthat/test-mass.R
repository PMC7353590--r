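# Monoisotopic mass and m/z arithmetic for peptides, isotope labels and
# PEG oligomer ladders.

lightPeptide <- modifiedPeptide("LLIYDTSK", charge = 2L)
heavyPeptide <- modifiedPeptide("LLIYDTSK",
  modifications = list(position = 8L, name = "label_13C6_15N2_K"),
  charge = 2L)

test_that("mass constants table is complete and positive", {
  mc <- massConstants()
  expect_length(mc$residue_masses, 20L)
  expect_true(all(mc$residue_masses > 0))
  expect_true(all(c("carbamidomethyl", "oxidation", "phosphorylation",
                    "acetylation", "label_13C6_15N2_K") %in%
                    names(mc$modifications)))
  expect_true(all(mc$modifications > 0))
})

test_that("peptide monoisotopic masses match hand-summed values", {
  expect_equal(peptideMass(modifiedPeptide("G")), 75.032029, tolerance = 1e-6)
  expect_equal(peptideMass(modifiedPeptide("GG")), 132.053493,
               tolerance = 1e-6)
  # twice the printed doubly charged precursor minus two protons
  expect_equal(peptideMass(lightPeptide), 2 * (476.7711 - 1.007276),
               tolerance = 2e-4)
})

test_that("published precursor and y-ion m/z values are reproduced", {
  expect_identical(roundHalfUp(precursorMz(lightPeptide), 4L), 476.7711)
  expect_identical(roundHalfUp(precursorMz(heavyPeptide), 4L), 480.7782)

  lightY <- c(y2 = 234.1448, y3 = 335.1925, y4 = 450.2195,
              y5 = 613.2828, y6 = 726.3668, y7 = 839.4509)
  heavyY <- c(y2 = 242.1590, y3 = 343.2067, y4 = 458.2337,
              y5 = 621.2970, y6 = 734.3810, y7 = 847.4651)
  # the printed heavy column is the light column shifted by the label
  expect_equal(unname(heavyY - lightY), rep(8.0142, 6L), tolerance = 1e-8)
  for (k in 2:7) {
    expect_identical(roundHalfUp(yIonMz(lightPeptide, k), 4L),
                     unname(lightY[paste0("y", k)]),
                     label = sprintf("light y%d", k))
    expect_identical(roundHalfUp(yIonMz(heavyPeptide, k), 4L),
                     unname(heavyY[paste0("y", k)]),
                     label = sprintf("heavy y%d", k))
  }
})

test_that("published PEG oligomer m/z values are reproduced", {
  expect_identical(roundHalfUp(pegMz(pegOligomer(28L, 3L)), 3L), 417.922)
  dpLadder <- c("7" = 327.2013, "8" = 371.2276, "10" = 459.2800,
                "11" = 503.3062, "12" = 547.3324, "13" = 591.3586,
                "14" = 635.3848, "15" = 679.4111, "16" = 723.4373,
                "17" = 767.4635)
  for (dp in names(dpLadder))
    expect_identical(roundHalfUp(pegMz(pegOligomer(as.integer(dp))), 4L),
                     unname(dpLadder[dp]), label = sprintf("DP %s", dp))
  # protonated water at DP 0
  expect_equal(pegMz(pegOligomer(0L)), 19.017841, tolerance = 1e-6)
})

test_that("y-ion series telescopes by residue masses", {
  set.seed(7)
  masses <- massConstants()$residue_masses
  for (rep in 1:10) {
    seqStr <- randomProtein(sample(4:15, 1L))
    p <- modifiedPeptide(seqStr, charge = 1L)
    res <- rev(strsplit(seqStr, "")[[1L]])   # C-terminal first
    for (k in seq_len(nchar(seqStr) - 1L)) {
      expect_equal(yIonMz(p, k + 1L) - yIonMz(p, k),
                   unname(masses[res[k + 1L]]), tolerance = 1e-9)
    }
    # the full-length y-ion at z = 1 is the singly protonated precursor
    expect_equal(yIonMz(p, nchar(seqStr)), precursorMz(p), tolerance = 1e-9)
  }
})

test_that("isotope label shifts precursor and K-containing y-ions by delta/z", {
  delta <- massConstants()$modifications[["label_13C6_15N2_K"]]
  set.seed(11)
  for (rep in 1:5) {
    seqStr <- paste0(randomProtein(sample(3:10, 1L)), "K")
    n <- nchar(seqStr)
    for (z in 1:3) {
      light <- modifiedPeptide(seqStr, charge = z)
      heavy <- modifiedPeptide(seqStr,
        modifications = list(position = n, name = "label_13C6_15N2_K"),
        charge = z)
      expect_equal(precursorMz(heavy) - precursorMz(light), delta / z,
                   tolerance = 1e-9)
      for (k in seq_len(n))   # every y-ion contains the C-terminal K
        expect_equal(yIonMz(heavy, k, 2L) - yIonMz(light, k, 2L), delta / 2,
                     tolerance = 1e-9)
    }
  }
  # a label outside the fragment does not shift it
  labN <- modifiedPeptide("KAAAR",
    modifications = list(position = 1L, name = "label_13C6_15N2_K"))
  expect_equal(yIonMz(labN, 3L), yIonMz(modifiedPeptide("KAAAR"), 3L),
               tolerance = 1e-12)
})

test_that("PEG ladder spacing is one ethylene-oxide unit per charge", {
  eo <- massConstants()$ethylene_oxide_mass
  for (z in 1:3)
    for (n in c(0L, 5L, 17L, 27L))
      expect_equal(pegMz(pegOligomer(n + 1L, z)) - pegMz(pegOligomer(n, z)),
                   eo / z, tolerance = 1e-9)
})

test_that("invalid peptides and fragments are rejected with diagnostics", {
  expect_error(peptideMass(modifiedPeptide("LLBZK")), "B")
  expect_error(modifiedPeptide("LLK",
    modifications = list(position = 2L, name = "no_such_mod")),
    "no_such_mod")
  expect_error(modifiedPeptide("LLK",
    modifications = list(position = 9L, name = "oxidation")), "bounds")
  expect_error(modifiedPeptide("LLK", charge = 0L), "charge")
  p <- modifiedPeptide("LLIYDTSK")
  expect_error(yIonMz(p, 0L), "outside")
  expect_error(yIonMz(p, 9L), "outside")
  expect_error(pegOligomer(-1L), "nUnits")
})

test_that("reported rounding is half-up, not half-to-even", {
  expect_identical(roundHalfUp(234.14485, 4L), 234.1449)
  expect_identical(roundHalfUp(1.25, 1L), 1.3)
  expect_identical(roundHalfUp(1.35, 1L), 1.4)
  expect_identical(roundHalfUp(417.92250, 3L), 417.923)
})
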