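test_that("explainCohort runs the requested methods and tags patterns", {
  refs <- defaultRefs()
  spec <- cohortSpec(nGood = 3, nPoor = 2, seed = 5)
  coh <- makeCohort(spec)
  out <- explainCohort(coh$instances, refs,
    methods = c("exact", "kernel"), seed = 2
  )
  expect_named(out$attributions, c("exact", "kernel"))
  expect_length(out$attributions$exact, 5)
  expect_length(out$tables, 5)
  expect_true(all(out$patterns %in% c("uniform", "boundary", "other")))
  expect_identical(sum(out$summary), 5L)
  expect_error(explainCohort(coh$instances, refs, methods = "magic"), "unknown method")
})

test_that("compareReport summarizes approximation error per method", {
  refs <- defaultRefs()
  spec <- cohortSpec(nGood = 3, nPoor = 2, seed = 5)
  coh <- makeCohort(spec)
  out <- explainCohort(coh$instances, refs,
    methods = c("exact", "kernel"), seed = 2
  )
  rep <- compareReport(out)
  expect_identical(rep$method, "kernel")
  expect_true(rep$msd >= 0)
  expect_error(
    compareReport(list(attributions = list(kernel = out$attributions$kernel))),
    "exact"
  )
})

test_that("reproducibility reports cover concordant samples only", {
  refs <- defaultRefs()
  specZero <- cohortSpec(nGood = 3, nPoor = 2, replicateNoiseSd = 0, seed = 7)
  cohZero <- makeCohort(specZero)
  rep0 <- reproducibilityReport(cohZero$instances, refs)
  expect_identical(rep0$nConcordant, 5L)
  expect_true(all(rep0$scatter$distance == 0))
  expect_equal(sum(rep0$histogram$normalized), 1)
  # heavy noise on overlapping classes produces discordant samples that
  # must be absent from the scatter
  specNoisy <- cohortSpec(
    nGood = 8, nPoor = 8, separation = 0.5,
    replicateNoiseSd = 0.6, seed = 21
  )
  refsNoisy <- suppressWarnings(makeReferenceSet(specNoisy))
  cohNoisy <- makeCohort(specNoisy)
  repN <- reproducibilityReport(cohNoisy$instances, refsNoisy)
  expect_gt(repN$nDiscordant, 0)
  expect_identical(
    length(unique(repN$scatter$instance_id)), repN$nConcordant
  )
  noReps <- cohZero$instances[cohZero$instances$replicate_id == 1, ]
  expect_error(reproducibilityReport(noReps, refs), "two replicates")
})

test_that("tabular exports round-trip through CSV and JSON", {
  refs <- defaultRefs()
  # reference set CSV
  f <- tempfile(fileext = ".csv")
  writeReferenceSetCSV(refs, f)
  back <- readReferenceSetCSV(f)
  expect_equal(refValues(back), refValues(refs), tolerance = 1e-12)
  expect_identical(refLabels(back), refLabels(refs))

  # instance CSV
  coh <- makeCohort(cohortSpec(nGood = 2, nPoor = 2, seed = 3))
  fi <- tempfile(fileext = ".csv")
  writeInstancesCSV(coh$instances, fi)
  backI <- readInstancesCSV(fi)
  expect_identical(backI$instance_id, coh$instances$instance_id)
  expect_equal(
    as.matrix(backI[, vsFeatures()]),
    as.matrix(coh$instances[, vsFeatures()]),
    tolerance = 1e-12
  )

  # subset table: bitmask CSV and JSON mirror
  tab <- uniformFixture("Good")$table
  fc <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  writeSubsetValueTable(tab, fc)
  writeSubsetValueTable(tab, fj)
  csvTab <- read.csv(fc)
  expect_identical(nrow(csvTab), 256L)
  expect_true(all(c("mask", "value") %in% names(csvTab)))
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_identical(js$subsets$value, csvTab$value)

  # attributions
  sv <- shapleyValues(tab)
  fa <- tempfile(fileext = ".csv")
  faj <- tempfile(fileext = ".json")
  writeAttributions(list(sv), fa)
  writeAttributions(list(sv), faj)
  dfa <- read.csv(fa)
  expect_identical(nrow(dfa), 8L)
  expect_equal(dfa$phi, rep(1 / 8, 8), tolerance = 1e-12)
  jsa <- jsonlite::read_json(faj, simplifyVector = TRUE)
  expect_equal(jsa$phi[["11529"]], 1 / 8, tolerance = 1e-12)

  # interactions: undefined diagonals omitted, not zero-filled
  hd <- interactionMatrix(tab, "HD")
  fh <- tempfile(fileext = ".csv")
  writeInteractionsCSV(hd, fh)
  dfh <- read.csv(fh, colClasses = c(feature_i = "character", feature_j = "character"))
  expect_identical(nrow(dfh), 56L)
  expect_false(any(dfh$feature_i == dfh$feature_j))
})

test_that("the command-line wrapper simulates and explains end to end", {
  skip_if_not(nzchar(Sys.which("Rscript")))
  cli <- system.file("scripts", "shapknn-cli.R", package = "shapknn")
  skip_if(cli == "")
  dir <- tempfile("cli")
  dir.create(dir)
  res <- system2("Rscript",
    c(cli, "simulate", "--seed", "4", "--n-good", "3", "--n-poor", "2",
      "--out", dir),
    stdout = TRUE, stderr = TRUE
  )
  expect_true(file.exists(file.path(dir, "reference_set.csv")))
  expect_true(file.exists(file.path(dir, "instances.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  res2 <- system2("Rscript",
    c(cli, "explain",
      "--input", file.path(dir, "instances.csv"),
      "--refs", file.path(dir, "reference_set.csv"),
      "--method", "exact", "--seed", "4", "--out", dir),
    stdout = TRUE, stderr = TRUE
  )
  expect_true(file.exists(file.path(dir, "attributions_exact.csv")))
  att <- read.csv(file.path(dir, "attributions_exact.csv"))
  expect_identical(nrow(att), 5L * 8L)
  unlink(dir, recursive = TRUE)
})
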