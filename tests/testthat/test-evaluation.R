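test_that("R^2 follows its definition", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rSquared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(rSquared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(rSquared(1:3, 1:4), "align")
})

test_that("variance decomposition is additive and matches hand sums", {
  d <- variationDecomposition(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(d@sTotal, 5)
  expect_equal(d@sBetween, 4)
  expect_equal(d@sWithin, 1)
  expect_identical(d@kClasses, 2L)
  # one class: everything is within-class
  one <- variationDecomposition(c(1, 3, 7), rep("x", 3))
  expect_equal(one@sBetween, 0)
  expect_equal(one@sWithin, one@sTotal)
  # singleton classes: everything is between-class
  own <- variationDecomposition(c(1, 3, 7), c("a", "b", "c"))
  expect_equal(own@sWithin, 0)
  expect_equal(own@sBetween, own@sTotal)
  expect_error(variationDecomposition(numeric(0), character(0)), "no responses")
})

test_that("the decomposition ignores joint permutations of the data", {
  set.seed(41)
  r <- rnorm(30)
  lab <- sample(letters[1:4], 30, replace = TRUE)
  perm <- sample(30)
  a <- variationDecomposition(r, lab)
  b <- variationDecomposition(r[perm], lab[perm])
  expect_equal(a@sBetween, b@sBetween, tolerance = 1e-12)
  expect_equal(a@sWithin, b@sWithin, tolerance = 1e-12)
})

test_that("between-class ratios compare two labelings", {
  r <- c(1, 2, 3, 4)
  expect_equal(betweenClassRatio(r, c("A", "A", "B", "B"),
                                 c("A", "A", "B", "B")), 1)
  expect_error(betweenClassRatio(r, c("A", "A", "B", "B"), rep("x", 4)),
               "is 0")
})

test_that("PIP measures improvement over the baseline's pure contribution", {
  expect_equal(performanceImprovement(0.7, 0.7, 0.5), 0)
  expect_equal(performanceImprovement(0.7, 0.6, 0.5), 100)
  expect_equal(performanceImprovement(0.725, 0.715, 0.678),
               (0.725 - 0.715) / (0.715 - 0.678) * 100)
  expect_error(performanceImprovement(0.7, 0.6, 0.6), "undefined")
  # sign tracks the enhanced-vs-baseline difference when the baseline beats
  # the descriptors-only model
  set.seed(44)
  for (i in 1:20) {
    dd <- runif(1, 0, 0.5); base <- dd + runif(1, 0.01, 0.3)
    enh <- runif(1, 0, 1)
    expect_equal(sign(performanceImprovement(enh, base, dd)),
                 sign(enh - base))
  }
})

test_that("CV plans partition cell lines and rotate folds correctly", {
  ccls <- sprintf("c%02d", 1:20)
  plan <- makeCVPlan(ccls, nFolds = 10, nRepeats = 3, seed = 5)
  for (rep in 1:3) {
    fold <- plan@folds[[rep]]
    expect_setequal(names(fold), ccls)
    expect_true(all(table(fold) == 2L))        # 20 / 10 exactly
  }
  tr <- plan@trials
  expect_equal(nrow(tr), 30L)
  for (rep in 1:3) {
    sub <- tr[tr$rep == rep, ]
    expect_setequal(sub$testFold, 1:10)         # each fold tests once
    expect_true(all(sub$valFold != sub$testFold))
  }
  # determinism
  plan2 <- makeCVPlan(ccls, nFolds = 10, nRepeats = 3, seed = 5)
  expect_identical(plan@folds, plan2@folds)
  # uneven division still partitions
  plan3 <- makeCVPlan(sprintf("c%d", 1:23), nFolds = 5, nRepeats = 1,
                      seed = 1)
  expect_true(all(table(plan3@folds[[1]]) %in% 4:5))
  expect_error(makeCVPlan(c("a", "b"), nFolds = 10), "fewer")
})

test_that("paired tests use BH step-up over the comparison family", {
  set.seed(47)
  m <- cbind(a = rnorm(20, 0.5, 0.05))
  m <- cbind(m, b = m[, "a"] - 0.03 + rnorm(20, 0, 0.02),
             c = m[, "a"] + rnorm(20, 0, 0.02),
             d = m[, "a"])
  cmps <- list(c("a", "b"), c("a", "c"))
  adj <- pairedTTestsBH(m, cmps)
  # oracle: raw paired-t p-values pushed through the BH step-up by hand
  raw <- vapply(cmps, function(cm) t.test(m[, cm[1]], m[, cm[2]],
                                          paired = TRUE)$p.value,
                numeric(1))
  o <- order(raw)
  bh <- pmin(1, rev(cummin(rev(raw[o] * length(raw) / seq_along(raw)))))
  expect_equal(unname(adj[o]), bh, tolerance = 1e-12)
  expect_true(all(diff(adj[o]) >= -1e-15) && all(adj <= 1))
  # a single comparison is returned unadjusted
  single <- pairedTTestsBH(m, list(c("a", "b")))
  expect_equal(unname(single), raw[1], tolerance = 1e-12)
  # identical columns: zero-variance rule
  expect_warning(pz <- pairedTTestsBH(m, list(c("a", "d"))), "zero-variance")
  expect_equal(unname(pz), 1)
})

test_that("the benchmark runs end to end and reports every arm", {
  # expression-dominated signal so the ten linear-model trials cleanly
  # separate the arms
  ds <- generateSyntheticDataset(smallSynthConfig(seed = 5, nCcls1 = 100L,
                                                  effectSize = 0.5,
                                                  drugEffectSd = 0.1))
  ccls <- sampleIds(ds@expr1)
  plan <- makeCVPlan(ccls, nFolds = 5, nRepeats = 2, seed = 2)
  cfg <- coxenConfig(30, 10, seed = 2)
  rep <- runBenchmark(ds@expr1, ds@responses, ds@descriptors,
                      selectors = c("enhanced", "random-all"),
                      regressor = linearRegressor(), plan = plan,
                      config = cfg)
  expect_s4_class(rep, "BenchmarkReport")
  expect_setequal(unique(rep@trialR2$selector),
                  c("enhanced", "random-all", "descriptors-only"))
  expect_equal(nrow(rep@summary), 3L)
  expect_true(all(is.finite(rep@summary$meanR2)))
  expect_named(rep@pip, "random-all")
  expect_named(rep@adjustedP, "enhanced_vs_random-all")
  # the planted expression signal must add predictive value over descriptors
  m <- rep@summary$meanR2
  names(m) <- rep@summary$selector
  expect_gt(m[["enhanced"]], m[["descriptors-only"]])
  # report writer produces the three CSVs
  dir <- withr::local_tempdir()
  writeBenchmarkReport(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("trial_r2.csv",
                                               "summary.csv",
                                               "variation.csv")))))
})

test_that("a response driven by drug identity alone leaves genes useless", {
  cfg <- smallSynthConfig(seed = 9, effectSize = 1e-6, drugEffectSd = 0.2)
  ds <- generateSyntheticDataset(cfg)
  plan <- makeCVPlan(sampleIds(ds@expr1), nFolds = 4, nRepeats = 1, seed = 4)
  rep <- runBenchmark(ds@expr1, ds@responses, ds@descriptors,
                      selectors = "random-all",
                      regressor = linearRegressor(), plan = plan,
                      config = coxenConfig(30, 10, seed = 4))
  m <- rep@summary$meanR2
  names(m) <- rep@summary$selector
  expect_lt(abs(m[["random-all"]] - m[["descriptors-only"]]), 0.05)
})

test_that("systematic selector failure aborts instead of silently passing", {
  ds <- generateSyntheticDataset(smallSynthConfig(seed = 5))
  plan <- makeCVPlan(sampleIds(ds@expr1), nFolds = 4, nRepeats = 1, seed = 6)
  expect_error(
    suppressWarnings(
      runBenchmark(ds@expr1, ds@responses, ds@descriptors,
                   selectors = "random-list", regressor = linearRegressor(),
                   plan = plan, config = coxenConfig(30, 10, seed = 6))),
    "failed")
})
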