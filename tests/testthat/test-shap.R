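test_that("kernel SHAP is deterministic and respects the full and null subsets", {
  refs <- defaultRefs()
  fix <- uniformFixture("Good")
  ks1 <- kernelShap(fix$instance, refs)
  ks2 <- kernelShap(fix$instance, refs)
  expect_identical(phiValues(ks1), phiValues(ks2))
  expect_identical(attrMethod(ks1), "kernel_shap")
  # E[f(M)] = f(M): no feature is replaced
  expect_identical(fullValue(ks1), 1)
  # E[f(empty)]: every feature replaced, so the hybrids are the reference
  # samples themselves; a self-consistent balanced set averages to 0
  expect_identical(nullValue(ks1), mean(ifelse(selfConsistency(refs), 1, -1) *
    ifelse(refLabels(refs) == "Good", 1, -1)))
  expect_lt(
    abs(sum(phiValues(ks1)) + nullValue(ks1) - fullValue(ks1)), 1e-12
  )
})

test_that("a feature identical across instance and references gets kernel-SHAP value 0", {
  refs <- defaultRefs()
  X <- refValues(refs)
  X[, "11903"] <- 9500
  refsC <- referenceSet(X, as.character(refLabels(refs)), k = 7)
  inst <- uniformFixture("Good")$instance
  inst["11903"] <- 9500
  ks <- kernelShap(inst, refsC)
  expect_identical(phiValues(ks)[["11903"]], 0)
})

test_that("distribution fitting recovers structure and flags degeneracy", {
  refs <- defaultRefs()
  mg <- fitDistribution(refs, "multivariate_gaussian", seed = 3)
  expect_equal(
    unname(mg@location), unname(colMeans(log(refValues(refs)))),
    tolerance = 1e-12
  )
  # duplicated feature: correlation 1 up to the regularization
  X <- refValues(refs)
  X[, "12579"] <- X[, "12452"]
  refsDup <- referenceSet(X, as.character(refLabels(refs)), k = 7)
  mgDup <- fitDistribution(refsDup, "multivariate_gaussian", seed = 3)
  expect_gt(stats::cov2cor(mgDup@covariance)["12452", "12579"], 0.999)
  expect_error(
    fitDistribution(refsDup, "multivariate_gaussian", seed = 3, shrinkage = 0),
    "shrinkage"
  )
  # independent_reference carries nothing beyond the reference table
  kr <- fitDistribution(refs, "independent_reference")
  expect_length(kr@location, 0)
})

test_that("log-space covariance is recovered from a large sample", {
  spec <- cohortSpec(nGood = 10000, nPoor = 0, seed = 6, replicateNoiseSd = 0)
  coh <- makeCohort(spec, replicates = 1)
  X <- as.matrix(coh$instances[, vsFeatures()])
  bigRefs <- referenceSet(X, rep(c("Good", "Poor"), length.out = nrow(X)), k = 7)
  fit <- fitDistribution(bigRefs, "multivariate_gaussian", seed = 1)
  expect_lt(max(abs(fit@covariance - spec@logCovGood)), 0.03)
  expect_lt(max(abs(fit@location - spec@logMeanGood)), 0.03)
})

test_that("probability integral transform round-trips the reference margins", {
  refs <- defaultRefs()
  cg <- fitDistribution(refs, "gaussian_copula", seed = 5)
  L <- log(refValues(refs))
  for (i in 1:8) {
    p <- shapknn:::.marginCdf(cg@margins[[i]], L[, i])
    back <- shapknn:::.marginQuantile(cg@margins[[i]], p)
    expect_lt(max(abs(back - L[, i])), 1e-10)
    expect_true(all(diff(shapknn:::.marginQuantile(
      cg@margins[[i]], seq(0.001, 0.999, length.out = 50)
    )) > 0))
  }
})

test_that("conditional expectations honor the full subset and the seed contract", {
  refs <- defaultRefs()
  inst <- uniformFixture("Good")$instance
  for (kind in c("multivariate_gaussian", "gaussian_copula")) {
    model <- fitDistribution(refs, kind, sampleCount = 100, seed = 13)
    expect_identical(
      conditionalExpectation(inst, vsFeatures(), model, refs), 1
    )
    e1 <- conditionalExpectation(inst, c("5843", "11529"), model, refs)
    e2 <- conditionalExpectation(inst, c("5843", "11529"), model, refs)
    expect_identical(e1, e2)
    expect_true(e1 >= -1 && e1 <= 1)
    unseeded <- fitDistribution(refs, kind, sampleCount = 100)
    expect_error(
      conditionalExpectation(inst, "5843", unseeded, refs), "seed"
    )
  }
})

test_that("Gaussian conditioning matches the closed-form bivariate conditional", {
  # two features, strong correlation: draws of the unknown coordinate
  # concentrate at the regression prediction from the known one
  rho <- 0.999
  S <- matrix(c(1, rho, rho, 1), 2)
  mu <- c(8, 8)
  withr::with_seed(2, {
    L <- MASS::mvrnorm(26, mu, S)
  })
  X <- exp(L)
  colnames(X) <- c("f1", "f2")
  refs2 <- referenceSet(X, rep(c("Good", "Poor"), 13), k = 7)
  model <- fitDistribution(refs2, "multivariate_gaussian",
    sampleCount = 4000, seed = 31
  )
  x0 <- exp(c(f1 = 8.5, f2 = 8.0)) # f2 unknown, conditioned on f1
  cond <- shapknn:::.conditionalGaussian(
    model@location, model@covariance, 1L, 2L, log(x0[1])
  )
  # conditional sd collapses under near-perfect correlation
  expect_lt(sqrt(cond$cov[1, 1]), 0.1 * sqrt(model@covariance[2, 2]))
  # Monte-Carlo expectation agrees with plugging the conditional mean
  plugin <- classifySubset(
    exp(c(f1 = unname(log(x0[1])), f2 = unname(cond$mean))),
    c("f1", "f2"), refs2
  )
  mc <- conditionalExpectation(x0, "f1", model, refs2)
  expect_lt(abs(mc - plugin), 0.1)
})

test_that("empty-subset Gaussian expectation matches dense quadrature on a 2-feature toy", {
  # independent features: compare Monte-Carlo E[f] to a dense grid
  # integration of the fitted Gaussian
  withr::with_seed(8, {
    L <- cbind(rnorm(26, 8, 0.5), rnorm(26, 6, 0.4))
  })
  X <- exp(L)
  colnames(X) <- c("f1", "f2")
  refs2 <- referenceSet(X, rep(c("Good", "Poor"), length.out = 26), k = 7)
  model <- fitDistribution(refs2, "multivariate_gaussian",
    sampleCount = 4000, seed = 77
  )
  sd1 <- sqrt(model@covariance[1, 1])
  sd2 <- sqrt(model@covariance[2, 2])
  g1 <- seq(model@location[1] - 4 * sd1, model@location[1] + 4 * sd1,
    length.out = 61
  )
  g2 <- seq(model@location[2] - 4 * sd2, model@location[2] + 4 * sd2,
    length.out = 61
  )
  grid <- as.matrix(expand.grid(f1 = exp(g1), f2 = exp(g2)))
  w <- outer(
    stats::dnorm(g1, model@location[1], sd1),
    stats::dnorm(g2, model@location[2], sd2)
  )
  w <- as.numeric(w) / sum(w)
  cls <- shapknn:::.knnVote(grid, refs2, 1:2)
  quadrature <- sum(w * cls)
  mc <- conditionalExpectation(
    exp(c(f1 = 8, f2 = 6)), character(0), model, refs2
  )
  se <- sqrt(max(1 - quadrature^2, 1e-4) / model@sampleCount)
  expect_lt(abs(mc - quadrature), 4 * se + 0.02)
})

test_that("approxShapley with reference replacement reproduces kernelShap", {
  refs <- defaultRefs()
  inst <- uniformFixture("Poor")$instance
  model <- fitDistribution(refs, "independent_reference")
  a <- approxShapley(inst, refs, model)
  b <- kernelShap(inst, refs)
  expect_identical(phiValues(a), phiValues(b))
})

test_that("sampling variants are seed-deterministic and satisfy efficiency", {
  refs <- defaultRefs()
  inst <- uniformFixture("Good")$instance
  for (kind in c("multivariate_gaussian", "gaussian_copula")) {
    model <- fitDistribution(refs, kind, sampleCount = 60, seed = 19)
    a1 <- approxShapley(inst, refs, model)
    a2 <- approxShapley(inst, refs, model)
    expect_identical(phiValues(a1), phiValues(a2))
    expect_lt(
      abs(sum(phiValues(a1)) + nullValue(a1) - fullValue(a1)), 1e-12
    )
    expect_identical(fullValue(a1), 1)
  }
})

test_that("comparison summaries compute mean square differences", {
  fix <- uniformFixture("Good")
  sv <- shapleyValues(fix$table)
  idm <- compareToExact(list(sv), list(sv))
  expect_identical(idm$msd, 0)
  expect_identical(idm$msdUniform, 0)
  shifted <- sv
  shifted@phi <- sv@phi + 0.1
  shifted@fullValue <- sv@fullValue + 0.8
  off <- compareToExact(list(shifted), list(sv))
  expect_equal(off$msd, 0.01, tolerance = 1e-12)
  other <- sv
  other@instanceId <- "someone-else"
  expect_error(compareToExact(list(other), list(sv)), "differ")
})

test_that("symmetry violations of approximations are detected and reported", {
  refs <- defaultRefs()
  X <- refValues(refs)
  X[, "12579"] <- X[, "12452"]
  refsDup <- referenceSet(X, as.character(refLabels(refs)), k = 7)
  inst <- uniformFixture("Good")$instance
  inst["12579"] <- inst["12452"]
  tab <- subsetValueTable(inst, refsDup)
  sv <- shapleyValues(tab)
  approx <- sv
  approx@phi["12452"] <- approx@phi[["12452"]] + 0.05
  approx@phi["11445"] <- approx@phi[["11445"]] - 0.05
  cmp <- compareToExact(list(approx), list(sv), tables = list(tab))
  hit <- cmp$symmetryViolations
  row <- hit[hit$feature_i == "12452" & hit$feature_j == "12579", ]
  expect_identical(nrow(row), 1L)
  expect_equal(row$absDiff, 0.05, tolerance = 1e-12)
})
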