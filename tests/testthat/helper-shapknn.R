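# Shared fixtures, all generated in code at test time.

# memoised default reference set and uniform fixtures
.fixtureCache <- new.env(parent = emptyenv())

defaultRefs <- function(seed = 1) {
  key <- paste0("refs", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- suppressWarnings(
      makeReferenceSet(cohortSpec(seed = seed))
    )
  .fixtureCache[[key]]
}

uniformFixture <- function(label = "Good", seed = 1) {
  key <- paste0("uni", label, seed)
  if (is.null(.fixtureCache[[key]])) {
    refs <- defaultRefs(seed)
    inst <- makeUniformInstance(refs, label)
    .fixtureCache[[key]] <- list(
      refs = refs, instance = inst,
      table = subsetValueTable(inst, refs)
    )
  }
  .fixtureCache[[key]]
}

# random exact-mode +/-1 table (empty subset = 0)
randomExactTable <- function(m, seed, features = letters[seq_len(m)]) {
  withr::with_seed(seed, {
    vals <- c(0, sample(c(-1, 1), 2^m - 1, replace = TRUE))
  })
  new("SubsetValueTable",
    instanceId = paste0("rand", seed), features = features,
    values = vals, mode = "exact"
  )
}

# additive value function f(S) = sum of per-feature contributions
additiveTable <- function(contrib, features = names(contrib)) {
  m <- length(contrib)
  vals <- vapply(0:(2^m - 1), function(mask) {
    sum(contrib[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L])
  }, numeric(1))
  new("SubsetValueTable",
    instanceId = "additive", features = features,
    values = vals, mode = "expectation"
  )
}

expectationTable <- function(values, features) {
  new("SubsetValueTable",
    instanceId = "toy", features = features,
    values = values, mode = "expectation"
  )
}

# tiny hand-built reference set on a reduced panel
toyRefs <- function(values, labels, k = 3L, distance = "log-euclidean") {
  referenceSet(values, labels, k = k, distance = distance)
}

# independent brute-force restricted-kNN classifier used as an oracle:
# plain sort of the per-reference distances with the same lowest-index
# tie rule, implemented without touching the package internals
bruteKnn <- function(instance, subset, refs) {
  if (length(subset) == 0L) return(0)
  X <- refValues(refs)
  tr <- function(v) if (refs@distance == "log-euclidean") log(v) else v
  d <- apply(X[, subset, drop = FALSE], 1L, function(r) {
    sum((tr(instance[subset]) - tr(r))^2)
  })
  nearest <- order(d)[seq_len(refK(refs))]
  votes <- ifelse(refLabels(refs)[nearest] == "Good", 1, -1)
  if (sum(votes) > 0) 1 else -1
}
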