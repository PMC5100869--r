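test_that("consecutive changes subtract adjacent observed ages", {
  tr <- c(E18.5 = 10, P1 = 15, P5 = 25, P10 = 55, P15 = 80, P20 = 85)
  d <- consecutiveChanges(tr)
  expect_equal(unname(d), c(5, 10, 30, 25, 5))
  expect_equal(names(d)[3], "P5->P10")

  flat <- consecutiveChanges(rep(10, 6))
  expect_true(all(flat == 0))

  # gaps are bridged and the deltas always telescope
  set.seed(23)
  for (i in 1:20) {
    tr <- runif(7, 0, 100)
    names(tr) <- defaultAgeGroups()
    tr[sample(2:6, sample(0:3, 1))] <- NA
    d <- consecutiveChanges(tr)
    obs <- tr[!is.na(tr)]
    expect_equal(sum(d), unname(obs[length(obs)] - obs[1]))
  }

  expect_error(consecutiveChanges(c(a = 10, b = NA)), "two ages")
})

test_that("interval change counts use the inclusive 30-point rule", {
  ages <- c("P5", "P10", "P15", "P20")
  m <- rbind(c(10, 10, 45, 45),   # +35 in P10->P15
             c(80, 80, 49, 49),   # -31 in P10->P15
             c(10, 10, 20, 20))   # +10: below threshold
  rownames(m) <- sprintf("s%d", 1:3); colnames(m) <- ages
  cnt <- countIntervalChanges(m, threshold = 30)
  expect_equal(cnt$interval, c("P5->P10", "P10->P15", "P15->P20"))
  expect_equal(cnt$gain, c(0, 1, 0))
  expect_equal(cnt$loss, c(0, 1, 0))

  # exactly 30 points counts ("30% or more")
  m30 <- rbind(c(10, 40, 40, 40))
  colnames(m30) <- ages
  expect_equal(countIntervalChanges(m30, 30)$gain, c(1, 0, 0))

  # flat input: all zero; threshold 0 counts every strict change
  flat <- matrix(50, 2, 4, dimnames = list(NULL, ages))
  expect_true(all(countIntervalChanges(flat, 30)[, c("gain", "loss")] == 0))
  expect_equal(countIntervalChanges(m, 0)$gain, c(0, 2, 0))

  # permutation invariance over sites
  cnt_p <- countIntervalChanges(m[c(3, 1, 2), ], 30)
  expect_equal(cnt_p$gain, cnt$gain)
  expect_equal(cnt_p$loss, cnt$loss)
})

test_that("sustained-change cross-tabulation equals exhaustive enumeration", {
  ages <- c("a1", "a2", "a3", "a4")
  m <- rbind(t1 = c(0, 40, 80, 80),
             t2 = c(0, 0, 50, 50),
             t3 = c(80, 40, 40, 0),
             t4 = c(10, 20, 30, 40),
             t5 = c(0, 50, 0, 50))
  colnames(m) <- ages
  ct <- sustainedCrosstab(m, threshold = 30)

  # oracle: per-interval membership sets, intersected pairwise
  members <- lapply(1:3, function(j) {
    rownames(m)[abs(m[, j + 1] - m[, j]) >= 30]
  })
  oracle <- sapply(1:3, function(i) sapply(1:3, function(j) {
    length(intersect(members[[i]], members[[j]]))
  }))
  expect_equal(unname(ct), oracle)
  expect_true(isSymmetric(ct))
  expect_equal(diag(ct),
               setNames(lengths(members), colnames(ct)))

  # single site changing in exactly two intervals
  one <- matrix(c(0, 40, 80, 80), 1, dimnames = list("x", ages))
  ct1 <- sustainedCrosstab(one, 30)
  expect_equal(ct1["a1->a2", "a2->a3"], 1L)
  expect_equal(ct1["a1->a2", "a3->a4"], 0L)

  # disjoint change sets: zero off-diagonals
  disj <- rbind(c(0, 40, 40, 40), c(40, 40, 0, 0))
  colnames(disj) <- ages
  ctd <- sustainedCrosstab(disj, 30)
  expect_true(all(ctd[upper.tri(ctd)] == 0))
})

test_that("trajectories classify by the 50% single-step rule", {
  disc <- classifyPattern(c(10, 10, 10, 60, 60, 60))
  expect_equal(disc$pattern, "discrete")
  expect_equal(disc$direction, "increase")
  expect_equal(disc$dominant_interval, "t3->t4")
  expect_equal(disc$total_change, 50)

  cont <- classifyPattern(c(10, 20, 30, 40, 50, 60))
  expect_equal(cont$pattern, "continuous")
  expect_equal(cont$direction, "increase")

  oth <- classifyPattern(c(10, 40, 20, 50, 30, 60))
  expect_equal(oth$pattern, "other")
  expect_equal(oth$direction, "increase")

  # a tie at exactly 50% of the change is discrete
  tie <- classifyPattern(c(0, 25, 50, 50))
  expect_equal(tie$pattern, "discrete")

  # small net change is unchanged; short trajectories unclassifiable
  expect_equal(classifyPattern(c(10, 12, 14, 15))$pattern, "unchanged")
  expect_equal(classifyPattern(c(10, 60))$pattern, "unclassifiable")
  # NA ages are bridged before classification
  gap <- classifyPattern(c(10, NA, 10, 60, NA, 60))
  expect_equal(gap$pattern, "discrete")
})

test_that("classification is exhaustive, exclusive and reversal-stable", {
  set.seed(29)
  for (i in 1:50) {
    tr <- runif(7, 0, 100)
    cl <- classifyPattern(tr)
    expect_true(cl$pattern %in% c("discrete", "continuous", "other",
                                  "unchanged"))
    rev_cl <- classifyPattern(rev(tr))
    expect_equal(rev_cl$pattern, cl$pattern)
    if (cl$pattern %in% c("discrete", "continuous", "other")) {
      expect_false(rev_cl$direction == cl$direction)
      expect_equal(rev_cl$total_change, -cl$total_change)
    }
  }
})

test_that("noisy simulator output recovers discrete and continuous truth", {
  ages <- defaultAgeGroups()
  cfg <- trajectoryConfig(change_fraction = 1, magnitude_range = c(30, 60),
                          pattern_mix = c(discrete = 0.45, continuous = 0.45,
                                          other = 0.10))
  sim <- simulateRRBS(n_sites = 400, ages = ages, n_replicates = 4,
                      trajectory = cfg,
                      schedule = cellCompositionSchedule(ages, 0, 0),
                      noise = noiseModel(coverage_mean = 500,
                                         coverage_dispersion = Inf),
                      seed = 37)
  means <- trajectoryMeans(maskLowCoverage(sim$experiment))
  called <- classifyPatterns(means)
  truth <- sim$truth
  for (pat in c("discrete", "continuous")) {
    idx <- truth$pattern == pat
    acc <- mean(called$pattern[idx] == pat)
    expect_gte(acc, 0.9)
  }
  # directions are essentially always right at these magnitudes
  expect_gte(mean(called$direction == truth$direction, na.rm = TRUE), 0.99)
})

test_that("trajectory means respect masks and an optional site whitelist", {
  total <- matrix(50L, 2, 6)
  total[1, 3] <- 0L  # the only P10 observation for site 1 is missing
  meth <- matrix(c(10L, 25L), 2, 6)
  meth[total == 0L] <- 0L
  me <- maskLowCoverage(makeME(meth, total,
                               ages = c("E18.5", "P1", "P10",
                                        "P15", "P20", "9wk")))
  mm <- trajectoryMeans(me)
  expect_true(is.na(mm["chr1:100", "P10"]))
  expect_equal(mm["chr1:200", "P10"], 50)
  expect_equal(attr(mm, "n")["chr1:100", "P10"], 0L)

  sub <- trajectoryMeans(me, sites = "chr1:200")
  expect_equal(rownames(sub), "chr1:200")
  expect_error(trajectoryMeans(me, sites = "chr9:1"), "absent")
})
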