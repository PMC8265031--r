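# Cohort-level drivers: explain every instance of a cohort with the
# requested methods, compare approximations with the exact values, and
# summarize replicate reproducibility. These functions are the package's
# pipeline interface; inst/scripts/shapknn-cli.R wraps them for the shell.

#' Explain every instance of a cohort
#'
#' Runs the requested explanation methods on one replicate of each
#' instance. Exact Shapley values also yield the uniform/boundary/other
#' pattern tag; exact subset-value tables are cached and reused by the
#' interaction metrics if requested later.
#'
#' @param instances data.frame as from [makeCohort()] (or
#'   [readInstancesCSV()]).
#' @param refs a [ReferenceSet-class].
#' @param methods subset of `c("exact", "kernel", "gaussian", "copula",
#'   "lime-logistic", "lime-svm")` or `"all"`.
#' @param replicate which replicate to explain (default 1).
#' @param seed base seed for the stochastic methods.
#' @param nSamples Monte-Carlo draws per conditional expectation.
#' @param nPerClass LIME permutations per class.
#' @param probePair probe features for the pattern taxonomy.
#' @return list with `attributions` (list of lists of
#'   [Attribution-class], one inner list per method), `tables` (exact
#'   [SubsetValueTable-class]s, when `"exact"` was run), `patterns`
#'   (character vector per instance) and `summary` (pattern counts).
#' @export
explainCohort <- function(instances, refs,
                          methods = "exact", replicate = 1L,
                          seed = 1L, nSamples = 1000L, nPerClass = 10000L,
                          probePair = c("11529", "11685")) {
  all <- c("exact", "kernel", "gaussian", "copula", "lime-logistic", "lime-svm")
  if (identical(methods, "all")) methods <- all
  bad <- setdiff(methods, all)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  ids <- unique(instances$instance_id)
  insts <- lapply(ids, function(id) cohortInstance(instances, id, replicate))

  out <- list(attributions = list(), tables = NULL, patterns = NULL)
  if ("exact" %in% methods) {
    out$tables <- lapply(insts, function(x)
      subsetValueTable(x, refs, instanceId = attr(x, "instanceId")))
    exacts <- lapply(out$tables, shapleyValues)
    out$attributions$exact <- exacts
    pats <- vapply(
      exacts,
      function(a) classifySVPattern(a, probePair = probePair),
      character(1)
    )
    out$patterns <- setNames(pats, ids)
    out$summary <- table(factor(pats, levels = c("uniform", "boundary", "other")))
  }
  shapKinds <- c(
    kernel = "independent_reference",
    gaussian = "multivariate_gaussian",
    copula = "gaussian_copula"
  )
  for (mth in intersect(methods, names(shapKinds))) {
    model <- fitDistribution(refs, shapKinds[[mth]],
      sampleCount = nSamples, seed = as.integer(seed)
    )
    out$attributions[[mth]] <- lapply(insts, function(x)
      approxShapley(x, refs, model, instanceId = attr(x, "instanceId")))
  }
  limeKinds <- c(`lime-logistic` = "logistic", `lime-svm` = "linear_svm")
  if (length(intersect(methods, names(limeKinds)))) {
    perms <- generatePermutations(refs, nPerClass, seed = as.integer(seed))
    for (mth in intersect(methods, names(limeKinds))) {
      out$attributions[[mth]] <- lapply(insts, function(x)
        limeExplain(x, refs,
          seed = as.integer(seed), modelKind = limeKinds[[mth]],
          instanceId = attr(x, "instanceId"), perms = perms
        ))
    }
  }
  out
}

#' Mean-square-difference report for SHAP approximations
#'
#' Convenience wrapper around [compareToExact()] for the output of
#' [explainCohort()]: one row per approximate method with the overall
#' and uniform-only mean square differences.
#'
#' @param explained output of [explainCohort()] run with `"exact"` plus
#'   at least one approximate method.
#' @return data.frame with columns `method`, `msd`, `msd_uniform`,
#'   `n_uniform`, `n_symmetric_pairs`, `max_symmetry_violation`.
#' @export
compareReport <- function(explained) {
  if (is.null(explained$attributions$exact))
    stop("explainCohort must have been run with the exact method")
  exact <- explained$attributions$exact
  methods <- setdiff(names(explained$attributions), "exact")
  if (!length(methods)) stop("no approximate methods to compare")
  rows <- lapply(methods, function(mth) {
    cmp <- compareToExact(
      explained$attributions[[mth]], exact,
      tables = explained$tables
    )
    data.frame(
      method = mth, msd = cmp$msd, msd_uniform = cmp$msdUniform,
      n_uniform = cmp$nUniform,
      n_symmetric_pairs = nrow(cmp$symmetryViolations),
      max_symmetry_violation = if (nrow(cmp$symmetryViolations)) {
        max(cmp$symmetryViolations$absDiff)
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Replicate reproducibility of exact Shapley values
#'
#' For every sample whose replicates all concord on the full-panel
#' classification, computes exact Shapley values for two chosen
#' replicates and the per-feature perpendicular distance of the
#' (replicate-a, replicate-b) scatter points from the y = x line, plus
#' the normalized distance histogram.
#'
#' @param instances data.frame with a `replicate_id` column (see
#'   [makeCohort()]).
#' @param refs a [ReferenceSet-class].
#' @param replicates length-2 integer vector of the replicates compared.
#' @param breaks histogram bin edges.
#' @return list with `scatter` (data.frame instance_id, feature, phi_a,
#'   phi_b, distance), `histogram` (see [svReproducibilityHistogram()]),
#'   `nConcordant` and `nDiscordant`.
#' @export
reproducibilityReport <- function(instances, refs, replicates = c(1L, 2L),
                                  breaks = seq(0, 1.5, by = 0.05)) {
  if (is.null(instances$replicate_id))
    stop("instances must carry a replicate_id column")
  if (length(unique(instances$replicate_id)) < 2L)
    stop("at least two replicates are required")
  ids <- unique(instances$instance_id)
  concordant <- vapply(ids, function(id) {
    reps <- lapply(
      unique(instances$replicate_id),
      function(r) cohortInstance(instances, id, r)
    )
    classifyReplicates(reps, refs) != "Indeterminate"
  }, logical(1))
  rows <- lapply(ids[concordant], function(id) {
    a <- shapleyValues(subsetValueTable(
      cohortInstance(instances, id, replicates[1L]), refs, instanceId = id
    ))
    b <- shapleyValues(subsetValueTable(
      cohortInstance(instances, id, replicates[2L]), refs, instanceId = id
    ))
    data.frame(
      instance_id = id, feature = names(a@phi),
      phi_a = unname(a@phi), phi_b = unname(b@phi[names(a@phi)]),
      distance = unname(replicateSVReproducibility(a, b)),
      stringsAsFactors = FALSE
    )
  })
  scatter <- do.call(rbind, rows)
  list(
    scatter = scatter,
    histogram = svReproducibilityHistogram(scatter$distance, breaks),
    nConcordant = sum(concordant),
    nDiscordant = sum(!concordant)
  )
}
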