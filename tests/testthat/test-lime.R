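test_that("robust log standardization centers, scales and round-trips", {
  refs <- defaultRefs()
  params <- standardizationParams(refs, "pooled")
  atMedian <- exp(params@center)
  names(atMedian) <- vsFeatures()
  expect_equal(
    unname(standardizeInstance(atMedian, params)), rep(0, 8),
    tolerance = 1e-12
  )
  oneSigma <- exp(params@center + params@scale)
  names(oneSigma) <- vsFeatures()
  expect_equal(
    unname(standardizeInstance(oneSigma, params)), rep(1, 8),
    tolerance = 1e-12
  )
  withr::with_seed(4, x <- exp(log(10000) + rnorm(8)))
  names(x) <- vsFeatures()
  z <- standardizeInstance(x, params)
  expect_equal(unname(unstandardize(z, params)), unname(x), tolerance = 1e-12)
  expect_error(
    standardizeInstance(setNames(c(-1, rep(1, 7)), vsFeatures()), params),
    "non-positive"
  )
})

test_that("standardized coordinates are invariant to per-feature rescaling", {
  refs <- defaultRefs()
  X <- refValues(refs)
  X[, "5843"] <- X[, "5843"] * 1000
  refsScaled <- referenceSet(X, as.character(refLabels(refs)), k = 7)
  withr::with_seed(5, x <- exp(log(10000) + rnorm(8)))
  names(x) <- vsFeatures()
  xScaled <- x
  xScaled["5843"] <- x["5843"] * 1000
  z <- standardizeInstance(x, standardizationParams(refs))
  zScaled <- standardizeInstance(xScaled, standardizationParams(refsScaled))
  expect_equal(z, zScaled, tolerance = 1e-10)
})

test_that("permutation generation enforces the discard rule exactly", {
  refs <- defaultRefs()
  perms <- generatePermutations(refs, nPerClass = 400, seed = 9)
  expect_identical(nrow(perms@x), 800L)
  expect_identical(as.integer(table(perms@sourceClass)), c(400L, 400L))
  # recompute every classification independently of the stored flags
  for (i in seq(1, 800, by = 37)) {
    cls <- classifySubset(perms@x[i, ], vsFeatures(), refs)
    expect_identical(cls, perms@classification[i])
    expect_identical(
      perms@kept[i],
      cls == (if (perms@sourceClass[i] == "Good") 1 else -1)
    )
  }
  # widely separated classes: discard fraction near zero
  expect_lt(mean(!perms@kept), 0.02)
  # determinism
  perms2 <- generatePermutations(refs, nPerClass = 400, seed = 9)
  expect_identical(perms@x, perms2@x)
  expect_error(generatePermutations(refs, 400), "seed")
})

test_that("proximity weights follow the Gaussian kernel", {
  refs <- defaultRefs()
  inst <- uniformFixture("Good")$instance
  pooled <- standardizationParams(refs)
  perms <- generatePermutations(refs, nPerClass = 300, seed = 12)
  # plant one kept draw exactly at the instance: weight must be 1
  perms@x[1, ] <- inst
  perms@classification[1] <- classifySubset(inst, vsFeatures(), refs)
  perms@sourceClass[1] <- if (perms@classification[1] == 1) "Good" else "Poor"
  perms@kept[1] <- TRUE
  wLog <- weightPermutations(perms, inst, pooled, "mean_distance")
  expect_equal(wLog@weight[1], 1, tolerance = 1e-12)
  # recompute one weight by hand from the kernel formula
  z0 <- standardizeInstance(inst, pooled)
  i2 <- which(wLog@kept)[5]
  d2 <- sqrt(sum((standardizeInstance(perms@x[i2, ], pooled) - z0)^2))
  expect_equal(
    wLog@weight[i2], exp(-d2^2 / wLog@sigma^2),
    tolerance = 1e-12
  )
  # a draw at distance sigma has weight exp(-1)
  dirv <- rep(1 / sqrt(8), 8)
  atSigma <- unstandardize(z0 + wLog@sigma * dirv, pooled)
  perms@x[2, ] <- atSigma
  perms@classification[2] <- classifySubset(atSigma, vsFeatures(), refs)
  perms@sourceClass[2] <- if (perms@classification[2] == 1) "Good" else "Poor"
  perms@kept[2] <- TRUE
  wLog2 <- weightPermutations(perms, inst, pooled, "mean_distance")
  expect_equal(
    unname(wLog2@weight[2] / exp(-(wLog2@sigma^2) / wLog2@sigma^2)),
    1,
    tolerance = 0.05
  )
  # halving sigma (the SVM rule) strictly decreases every positive-distance weight
  wSvm <- weightPermutations(perms, inst, pooled, "half_mean_distance")
  expect_equal(wSvm@sigma, wLog2@sigma / 2, tolerance = 1e-12)
  pos <- wLog2@kept & wLog2@weight < 1
  expect_true(all(wSvm@weight[pos] < wLog2@weight[pos]))
})

test_that("one informative feature dominates both surrogate coefficient vectors", {
  # classes differ only in feature f1; the others share one distribution
  withr::with_seed(14, {
    m <- 4
    n <- 13
    common <- matrix(rnorm(2 * n * (m - 1), 7, 0.3), 2 * n)
    f1 <- c(rnorm(n, 10, 0.3), rnorm(n, 6, 0.3)) # Good high, Poor low
    X <- exp(cbind(f1, common))
  })
  colnames(X) <- c("f1", "f2", "f3", "f4")
  refs <- referenceSet(X, rep(c("Good", "Poor"), each = 13), k = 7)
  inst <- exp(c(f1 = 10, f2 = 7, f3 = 7, f4 = 7))
  for (kind in c("logistic", "linear_svm")) {
    attr <- limeExplain(inst, refs,
      nPerClass = 3000, seed = 23, modelKind = kind
    )
    phi <- phiValues(attr)
    expect_gt(phi[["f1"]], 0) # higher f1 pushes toward Good
    expect_gt(abs(phi[["f1"]]), 5 * max(abs(phi[c("f2", "f3", "f4")])))
  }
})

test_that("surrogate coefficients are label-antisymmetric and duplication-invariant", {
  refs <- defaultRefs()
  inst <- uniformFixture("Good")$instance
  pooled <- standardizationParams(refs)
  perms <- generatePermutations(refs, nPerClass = 800, seed = 3)
  perms <- weightPermutations(perms, inst, pooled, "mean_distance")
  fit <- fitSurrogate(perms, pooled, "logistic")

  flipped <- perms
  flipped@classification <- -perms@classification
  flipped@sourceClass <- factor(
    ifelse(perms@sourceClass == "Good", "Poor", "Good"),
    levels = c("Poor", "Good")
  )
  fitF <- fitSurrogate(flipped, pooled, "logistic")
  expect_equal(phiValues(fitF), -phiValues(fit), tolerance = 1e-4)

  doubled <- new("PermutationSet",
    features = perms@features, x = rbind(perms@x, perms@x),
    sourceClass = factor(rep(as.character(perms@sourceClass), 2),
      levels = c("Poor", "Good")
    ),
    classification = rep(perms@classification, 2),
    kept = rep(perms@kept, 2), weight = rep(perms@weight, 2),
    sigma = perms@sigma, seed = perms@seed
  )
  for (kind in c("logistic", "linear_svm")) {
    expect_equal(
      phiValues(fitSurrogate(doubled, pooled, kind)),
      phiValues(fitSurrogate(perms, pooled, kind)),
      tolerance = 1e-3
    )
  }
})

test_that("single-class permutation sets are rejected with a locality message", {
  refs <- defaultRefs()
  inst <- uniformFixture("Good")$instance
  pooled <- standardizationParams(refs)
  perms <- generatePermutations(refs, nPerClass = 200, seed = 6)
  onlyGood <- perms@sourceClass == "Good" & perms@kept
  sub <- new("PermutationSet",
    features = perms@features, x = perms@x[onlyGood, ],
    sourceClass = droplevels(perms@sourceClass[onlyGood], exclude = NULL),
    classification = perms@classification[onlyGood],
    kept = perms@kept[onlyGood], weight = perms@weight[onlyGood],
    sigma = NA_real_, seed = perms@seed
  )
  sub@sourceClass <- factor(as.character(sub@sourceClass), levels = c("Poor", "Good"))
  sub <- weightPermutations(sub, inst, pooled, "mean_distance")
  expect_error(fitSurrogate(sub, pooled, "logistic"), "single class|both")
})

test_that("coefficient signs are stable across permutation seeds", {
  refs <- defaultRefs()
  inst <- uniformFixture("Good")$instance
  signs <- sapply(1:3, function(s) {
    sign(phiValues(limeExplain(inst, refs, nPerClass = 2000, seed = s)))
  })
  expect_true(all(signs == signs[, 1]))
})
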