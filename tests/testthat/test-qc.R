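# A 4-sample fixture with controlled coverage for the boundary checks.
qcFixture <- function() {
  total <- matrix(20L, 4, 4)
  meth <- matrix(10L, 4, 4)
  makeME(meth, total, ages = c("E18.5", "E18.5", "9wk", "9wk"))
}

test_that("coverage masking uses the strict fewer-than-10 boundary", {
  me <- qcFixture()
  tt <- totalCounts(me)
  tt[1, 1] <- 9L   # masked
  tt[2, 1] <- 10L  # retained
  mm <- methCounts(me)
  mm[mm > tt] <- 0L
  me <- makeME(pmin(mm, tt), tt, ages = as.character(ageGroups(me)))
  me <- maskLowCoverage(me, 10)
  expect_true(covMask(me)[1, 1])
  expect_false(covMask(me)[2, 1])

  # idempotence and monotonicity in the threshold
  me2 <- maskLowCoverage(me, 10)
  expect_identical(covMask(me2), covMask(me))
  me15 <- maskLowCoverage(me, 15)
  expect_true(all(covMask(me15)[covMask(me)]))
  expect_gte(sum(covMask(me15)), sum(covMask(me)))

  # a sample with all-zero coverage is fully masked
  tt0 <- totalCounts(qcFixture()); tt0[, 2] <- 0L
  me0 <- makeME(matrix(0L, 4, 4), tt0, ages = c("E18.5", "E18.5", "9wk", "9wk"))
  me0 <- maskLowCoverage(me0)
  expect_true(all(covMask(me0)[, 2]))
})

test_that("missingness filter removes CpGs strictly above the bound", {
  # 15 samples; site 1 has exactly 3 missing (20%, retained), site 2 has 4
  # missing (26.7%, removed), site 3 complete
  total <- matrix(20L, 3, 15)
  total[1, 1:3] <- 0L
  total[2, 1:4] <- 0L
  meth <- matrix(5L, 3, 15); meth[total == 0L] <- 0L
  me <- makeME(meth, total, ages = rep(c("E18.5", "9wk"), length.out = 15))
  me <- maskLowCoverage(me)
  out <- filterHighMissingness(me, 0.20)
  expect_equal(nrow(out), 2L)
  expect_false("chr1:200" %in% rownames(out))
  lg <- qcLog(out)
  expect_equal(lg$id, "chr1:200")
  expect_equal(lg$reason, "missing_fraction_above_threshold")

  # no missing data: identity and idempotence
  full <- makeME(matrix(5L, 3, 15), matrix(20L, 3, 15),
                 ages = rep(c("E18.5", "9wk"), length.out = 15))
  full <- maskLowCoverage(full)
  expect_equal(nrow(filterHighMissingness(full)), 3L)
  again <- filterHighMissingness(filterHighMissingness(me))
  expect_identical(rownames(again), rownames(out))
})

test_that("never-methylated filter needs every sample strictly below 10%", {
  total <- matrix(100L, 4, 5)
  meth <- rbind(rep(5L, 5),            # all at 5%: removed
                c(12L, 5L, 5L, 5L, 5L), # one at 12%: retained
                c(10L, 5L, 5L, 5L, 5L), # one at exactly 10%: retained
                rep(50L, 5))            # clearly methylated
  me <- maskLowCoverage(makeME(meth, total,
                               ages = rep(c("E18.5", "9wk"), length.out = 5)))
  out <- filterNeverMethylated(me, 10)
  expect_equal(rownames(out), c("chr1:200", "chr1:300", "chr1:400"))
  expect_equal(qcLog(out)$reason, "unmethylated_in_all_samples")

  # a site with no unmasked cell is removed with its own reason
  total2 <- total; total2[4, ] <- 0L
  meth2 <- meth; meth2[4, ] <- 0L
  me2 <- maskLowCoverage(makeME(meth2, total2,
                                ages = rep(c("E18.5", "9wk"),
                                           length.out = 5)))
  out2 <- filterNeverMethylated(me2, 10)
  expect_false("chr1:400" %in% rownames(out2))
  expect_true("no_data" %in% qcLog(out2)$reason)
})

test_that("rarely does the never-methylated filter hit a methylated CpG", {
  nm <- noiseModel(coverage_mean = 40)
  cnt <- lapply(1:5, function(j) simulateCounts(rep(0.2, 500), nm,
                                                seed = 100 + j))
  meth <- do.call(cbind, lapply(cnt, `[[`, "meth"))
  total <- do.call(cbind, lapply(cnt, `[[`, "total"))
  me <- maskLowCoverage(makeME(meth, total,
                               ages = rep("E18.5", 5)))
  out <- filterNeverMethylated(me, 10)
  expect_lt((nrow(me) - nrow(out)) / nrow(me), 0.01)
})

test_that("sample completeness scores match the hand-computed example", {
  # data pattern over 3 samples x 4 CpGs (rows CpGs, columns samples)
  covered <- cbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(1, 0, 0, 0))
  total <- matrix(0L, 4, 3); total[covered == 1] <- 20L
  meth <- matrix(0L, 4, 3); meth[covered == 1] <- 10L
  me <- maskLowCoverage(makeME(meth, total,
                               ages = c("E18.5", "P10", "9wk")))
  sc <- scoreSamples(me, cutoff = 0)
  expect_equal(sc$score, c(1 + 2 / 3 + 1 / 3 + 1 / 3, 1 + 2 / 3, 1),
               tolerance = 1e-12)
  # a sample covering every CpG attains the maximum score sum(w)
  expect_equal(sc$score[1], sc$max_score[1])

  # cutoff above the attainable maximum removes every sample
  sc_all <- scoreSamples(me, cutoff = 10)
  expect_false(any(sc_all$retained))
  # relative cutoff scales with the panel
  sc_rel <- scoreSamples(me, relative_cutoff = 0.5)
  expect_equal(sc_rel$cutoff[1], 0.5 * sc_rel$max_score[1])
  expect_equal(sc_rel$retained, c(TRUE, TRUE, FALSE))

  me_f <- filterSamplesByScore(me, sc_rel)
  expect_equal(ncol(me_f), 2L)
  expect_equal(qcLog(me_f)$entity, "sample")
})

test_that("CpH screen flags sites methylated across one whole group", {
  total <- matrix(100L, 3, 6)
  meth <- rbind(c(6L, 6L, 6L, 1L, 1L, 1L),   # all of group A above 5%
                c(4L, 1L, 1L, 4L, 1L, 1L),   # one sample high per group
                c(6L, 4L, 6L, 6L, 6L, 6L))   # group B all above
  me <- makeME(meth, total, ages = c("E18.5", "E18.5", "E18.5",
                                     "9wk", "9wk", "9wk"))
  me <- maskLowCoverage(me)
  scr <- screenCpH(me, threshold = 5)
  expect_equal(scr$flagged, c(TRUE, FALSE, TRUE))
  expect_equal(scr$group[1], "E18.5")
  expect_equal(scr$group[3], "9wk")

  # exactly 5% does not flag (strict >)
  meth2 <- matrix(5L, 1, 6)
  me2 <- maskLowCoverage(makeME(meth2, matrix(100L, 1, 6),
                                ages = c("E18.5", "E18.5", "E18.5",
                                         "9wk", "9wk", "9wk")))
  expect_false(screenCpH(me2, threshold = 5)$flagged)

  # empty input
  expect_equal(nrow(screenCpH(me[0, ])), 0L)
})

test_that("the QC cascade runs in its documented order and logs removals", {
  sim <- simulateRRBS(n_sites = 300, ages = c("E18.5", "9wk"),
                      n_replicates = 4, seed = 31)
  res <- runQC(sim$experiment, qcConfig())
  me <- res$experiment
  expect_s4_class(me, "MethylationExperiment")
  expect_true(all(qcLog(me)$step %in%
                    c("sample_score", "missingness", "never_methylated")))
  # every removed CpG appears exactly once in the log
  removed <- setdiff(rownames(sim$experiment), rownames(me))
  lg <- qcLog(me)
  expect_setequal(lg$id[lg$entity == "cpg"], removed)
  expect_false(any(duplicated(lg$id)))
  # re-running the CpG filters changes nothing
  again <- filterNeverMethylated(filterHighMissingness(me))
  expect_identical(rownames(again), rownames(me))
})
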