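# The normalization chain: SIS correction, dilution factors, percent
# survival, replicate summaries and paired comparisons.

test_that("SIS normalization rescales by internal-standard recovery", {
  # published worked example: 15.16 measured, SIS 0.39 of 0.5 expected
  expect_equal(sisNormalize(15.16, 0.39, 0.5), 19.43,
               tolerance = 0.001)          # prints 19.43 from unrounded inputs
  expect_equal(sisNormalize(7.3, 0.4, 0.4), 7.3)    # full recovery: identity
  expect_equal(sisNormalize(10, 0.25, 0.5), 20)     # factor-2 correction
  expect_error(sisNormalize(10, 0, 0.5), "measuredSis")
})

test_that("recovery percent is the measured-to-spiked ratio", {
  expect_equal(recoveryPercent(19.43, 50), 38.86)
  expect_equal(recoveryPercent(50, 50), 100)
  expect_equal(recoveryPercent(0, 50), 0)
  expect_error(recoveryPercent(10, 0), "spiked")
})

test_that("dilution factors come from the feed-to-sample marker ratio", {
  expect_equal(dilutionFactor(0.1, 0.074), 1.3514, tolerance = 1e-4)
  expect_equal(dilutionFactor(0.2, 0.2), 1)
  expect_equal(dilutionFactor(0.1, 0.2), 0.5)  # concentration, factor < 1
  expect_error(dilutionFactor(0, 0.1), "> 0")
  # chain identity: normalizing the marker by its own factor returns feed
  for (feed in c(0.08, 0.1, 0.15))
    for (samp in c(0.03, 0.074, 0.2))
      expect_equal(dilutionNormalize(samp, dilutionFactor(feed, samp)),
                   feed, tolerance = 1e-12)
})

test_that("printed dilution normalization is reproduced across the study table", {
  tab <- printedStudyTable()
  nonfeed <- tab[tab$compartment != "feed" & !is.na(tab$conc), ]
  for (i in seq_len(nrow(nonfeed))) {
    got <- dilutionNormalize(nonfeed$conc[i], nonfeed$factor[i])
    # both inputs are printed rounded (conc 2 dp, factor 2-3 dp), so the
    # product can differ from the printed result by the propagated
    # half-ulps plus the output's own rounding
    ulpFactor <- 10^(-nchar(sub("^[0-9]*\\.", "",
                                format(nonfeed$factor[i]))))
    bound <- 0.005 + nonfeed$conc[i] * ulpFactor / 2 +
      nonfeed$factor[i] * 0.005
    expect_lt(abs(got - nonfeed$normalized[i]), bound,
              label = sprintf("%s %s", nonfeed$subject[i],
                              nonfeed$compartment[i]))
  }
  # two cells round exactly at 2 dp
  expect_identical(roundHalfUp(dilutionNormalize(10.04, 1.14), 2L), 11.45)
  expect_identical(roundHalfUp(dilutionNormalize(0.65, 1.23), 2L), 0.80)
  expect_equal(dilutionNormalize(5, 1), 5)
  expect_error(dilutionNormalize(5, 0), "factor")
})

test_that("percent survival is homogeneous and flags non-detects", {
  expect_equal(as.numeric(survivalPercent(32.41, 38.10)), 85.0656,
               tolerance = 1e-4)
  expect_equal(as.numeric(survivalPercent(7.7, 7.7)), 100)
  nd <- survivalPercent(0, 38.10, detected = FALSE)
  expect_equal(as.numeric(nd), 0)
  expect_true(attr(nd, "nd"))
  for (k in c(0.1, 3, 100))
    expect_equal(as.numeric(survivalPercent(5 * k, 20 * k)),
                 as.numeric(survivalPercent(5, 20)))
  expect_error(survivalPercent(5, 0), "feedConc")
})

test_that("replicate summaries use sample sd, sd/sqrt(n) and CV", {
  expect_equal(summarizeReplicates(c(5, 5, 5, 5)),
               c(mean = 5, error = 0, cv = 0))
  v <- c(2, 4, 6, 8)
  got <- summarizeReplicates(v)
  expect_equal(got[["mean"]], 5)
  expect_equal(got[["error"]], sd(v) / 2)
  expect_equal(got[["cv"]], sd(v) / 5 * 100)
  # scaling all values leaves the CV unchanged, scales mean and error
  g2 <- summarizeReplicates(v * 7)
  expect_equal(g2[["mean"]], 35)
  expect_equal(g2[["cv"]], got[["cv"]])
  expect_true(is.na(summarizeReplicates(c(-1, 1))[["cv"]]))  # mean 0 flagged
  expect_error(summarizeReplicates(numeric()), "empty")
})

test_that("per-compartment survival summaries match the published averages", {
  tab <- printedStudyTable()
  feed <- tab$normalized[tab$compartment == "feed"]
  gastric <- 100 * tab$normalized[tab$compartment == "gastric"] / feed
  got <- summarizeReplicates(gastric)
  expect_equal(roundHalfUp(got[["mean"]], 1L), 88.4)
  expect_equal(roundHalfUp(got[["error"]], 1L), 4.4)
  intestinal <- 100 * tab$normalized[tab$compartment == "intestinal"] / feed
  expect_equal(roundHalfUp(summarizeReplicates(intestinal)[["mean"]], 1L),
               30.0)
})

test_that("paired t handles regular and degenerate designs", {
  same <- c(3, 5, 9, 2)
  got <- pairedT(same, same)
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
  expect_true(got$degenerate)

  shifted <- pairedT(c(1, 2, 3, 4), c(2, 3, 4, 5))  # constant +1 shift
  expect_true(is.infinite(shifted$t))
  expect_equal(shifted$p, 0)
  expect_true(shifted$degenerate)

  reg <- pairedT(c(10, 12, 9, 11), c(5, 7, 4, 8))
  expect_false(reg$degenerate)
  expect_equal(reg$df, 3)
  # agrees with the textbook statistic
  d <- c(5, 7, 4, 8) - c(10, 12, 9, 11)
  expect_equal(reg$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("paired t significance ordering matches sign-flip enumeration", {
  set.seed(17)
  datasets <- lapply(1:8, function(i) {
    ref <- rnorm(7, 10, 1)
    list(ref = ref, comp = ref - runif(1, 0, 2) + rnorm(7, 0, 1))
  })
  pT <- vapply(datasets, function(d) pairedT(d$ref, d$comp)$p, numeric(1L))
  pExact <- vapply(datasets, function(d) signFlipP(d$ref, d$comp),
                   numeric(1L))
  # wherever the exact permutation p clearly separates two datasets, the
  # t-based p orders them the same way
  for (i in 1:7) for (j in (i + 1):8) {
    if (abs(pExact[i] - pExact[j]) > 0.1)
      expect_identical(pT[i] < pT[j], pExact[i] < pExact[j],
                       label = sprintf("datasets %d vs %d", i, j))
  }
})

test_that("the report builder runs the whole chain on replicate quant rows", {
  # two subjects, feed + gastric, two injections; SIS at half recovery
  quant <- data.frame(
    subject = rep(c("s1", "s2"), each = 4L),
    compartment = rep(rep(c("feed", "gastric"), each = 2L), 2L),
    target_conc = c(10, 10, 4, 4, 8, 8, 4, 4) / 2,  # measured at 50% recovery
    sis_conc = 0.25, peg_conc = rep(c(0.1, 0.1, 0.05, 0.05), 2L),
    stringsAsFactors = FALSE)
  rep <- buildSurvivalReport(quant, expectedSis = 0.5)
  s <- reportSamples(rep)
  g1 <- s[s$subject == "s1" & s$compartment == "gastric", ]
  expect_equal(g1$dilution_factor, 2)          # 0.1 / 0.05
  expect_equal(g1$normalized_conc, 8)          # 4 SIS-corrected, x2 dilution
  expect_equal(g1$survival_pct, 80)            # feed corrected to 10
  g2 <- s[s$subject == "s2" & s$compartment == "gastric", ]
  expect_equal(g2$survival_pct, 100)
  expect_equal(reportSummary(rep)$mean_survival[
    reportSummary(rep)$compartment == "gastric"], 90)
  expect_error(buildSurvivalReport(quant[quant$compartment != "feed", ],
                                   0.5), "feed")
})
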