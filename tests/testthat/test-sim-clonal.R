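test_that("ccfToVaf follows the diploid-heterozygous model and rejects bad input", {
  expect_equal(ccfToVaf(1, 1), 0.5)
  expect_equal(ccfToVaf(0, 0.7), 0)
  expect_equal(ccfToVaf(0.4, 0.6), 0.12)  # 0.5 * 0.6 * 0.4 by hand
  expect_error(ccfToVaf(1.2, 0.5), "ccf")
  expect_error(ccfToVaf(0.5, -0.1), "purity")
})

test_that("sampleReads noiseless mode returns rounded expectations", {
  expect_equal(sampleReads(0, 1000, errorRate = 0, noiseless = TRUE),
               data.frame(alt = 0L, depth = 1000L))
  expect_equal(sampleReads(0.25, 1000, errorRate = 0, noiseless = TRUE),
               data.frame(alt = 250L, depth = 1000L))
  expect_error(sampleReads(0.7, 100), "vaf")
  expect_error(sampleReads(0.2, 0), "depth")
})

test_that("sampleReads stochastic mean matches the binomial-model expectation", {
  # oracle: E[alt] = E[depth] * (vaf(1-e) + (1-vaf)e/3) = 1000 * 0.25 = 250
  # for vaf 0.25, e = 1e-3; s.e. of the mean over B draws from var <= depth/4
  set.seed(42)
  B <- 10000
  r <- sampleReads(rep(0.25, B), 1000, errorRate = 1e-3)
  expect_true(all(r$alt <= r$depth))
  se <- sd(r$alt) / sqrt(B)
  expect_lt(abs(mean(r$alt) - 250), 3 * se)
})

test_that("a trunk-only spec yields only SVZ-Tumor-shared truth", {
  ds <- simulatePatient(trunkOnlySpec(nMut = 3L), "PT")
  expect_equal(unname(truthCategories(ds)),
               rep("SVZ_TUMOR_SHARED", 3))
  expect_equal(truthPattern(ds), "UNKNOWN")  # no private variant to weigh
})

test_that("the gbm244 preset encodes the worked-example architecture", {
  spec <- gbm244Preset(noiseless = TRUE)
  expect_length(spec@tree@parent, 3)               # trunk + two branches
  expect_equal(nrow(spec@catalog), 12)             # 2 drivers + 10 passengers
  expect_equal(sum(spec@catalog$driver), 2)
  expect_equal(spec@samples$purity[spec@samples$role == "BLOOD"], 0)
  ds <- simulatePatient(spec, "GBM-244")
  expect_equal(as.vector(table(truthCategories(ds))[
    c("SVZ_TUMOR_SHARED", "PRIMARY_PRIVATE", "RECURRENT_PRIVATE")]),
    c(2, 5, 5))
  expect_equal(truthPattern(ds), "SVZ_ASSOCIATED")
})

test_that("simulation is deterministic given the seed and seed-free when noiseless", {
  s1 <- simulatePatient(gbm244Preset(seed = 5L), "A")
  s2 <- simulatePatient(gbm244Preset(seed = 5L), "A")
  expect_identical(variantTable(s1), variantTable(s2))
  s3 <- simulatePatient(gbm244Preset(seed = 6L), "A")
  expect_false(identical(variantTable(s1), variantTable(s3)))
  n1 <- simulatePatient(gbm244Preset(noiseless = TRUE, seed = 5L), "A")
  n2 <- simulatePatient(gbm244Preset(noiseless = TRUE, seed = 99L), "A")
  expect_identical(variantTable(n1), variantTable(n2))
})

test_that("simulatePatient does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulatePatient(gbm244Preset(seed = 5L), "A"))
  expect_identical(runif(1), before)
})

test_that("expected VAF equals 0.5 * purity * summed carrying-clone fractions", {
  for (seed in c(2L, 3L, 4L)) {
    for (sc in c("SVZ_ASSOCIATED", "PRIMARY_ASSOCIATED")) {
      spec <- randomPatientSpec(seed, scenario = sc, noiseless = TRUE)
      ds <- simulatePatient(spec, "PT")
      evaf <- ds@truth$expectedVAF
      v <- variantTable(ds)
      key <- variantKey(v)
      for (j in seq_len(nrow(spec@samples))) {
        nm <- spec@samples$name[j]
        got <- v[[paste0(nm, ".alt")]] / v[[paste0(nm, ".depth")]]
        expect_equal(got, unname(round(1063 * evaf[key, nm]) / 1063),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("truth categories equal categorization of noiseless deep data", {
  # oracle equivalence between clone-membership truth and the
  # observational presence-calling path
  for (seed in 21:25) {
    sc <- if (seed %% 2) "SVZ_ASSOCIATED" else "PRIMARY_ASSOCIATED"
    ds <- simulatePatient(randomPatientSpec(seed, scenario = sc,
                                            noiseless = TRUE), "PT")
    calls <- callPatient(variantTable(ds), ds@manifest)
    cats <- categorizePatient(calls)
    truth <- truthCategories(ds)
    got <- setNames(cats$category, cats$variant)[names(truth)]
    expect_equal(unname(got), unname(truth))
    expect_equal(patternLabel(
      classifyRecurrencePattern(cats, calls, "PT")), truthPattern(ds))
  }
})

test_that("spec validity rejects broken phylogenies and mixtures", {
  spec <- trunkOnlySpec()
  bad <- spec; bad@cloneFractions$svz <- c(trunk = 0.9)
  expect_error(validObject(bad), "sum to 1")
  bad <- spec; bad@samples$purity[1] <- 0.2  # blood must stay pure normal
  expect_error(validObject(bad), "BLOOD")
  bad <- spec; bad@errorRate <- 0.5
  expect_error(validObject(bad), "errorRate")
  expect_error(ClonalTree(c(a = "b", b = "a")) |> validObject(), "cycle")
})
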