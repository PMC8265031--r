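# Synthetic cohort generator: correlated log-normal mass-spectral feature
# panels with two labeled classes, deterministic constructors for uniform
# and boundary instances, and triplicate cohorts with technical noise.

#' Specify a synthetic cohort
#'
#' Builds a [CohortSpec-class] describing two class-conditional
#' multivariate log-normal feature distributions. By default the class
#' centers sit `separation` log units apart along the equal-loading
#' direction (all features shifted together, mimicking the co-regulated
#' acute-phase protein isoforms the panel measures), with an
#' equicorrelated log covariance `sd^2 * ((1-correlation) I +
#' correlation J)` shared by both classes.
#'
#' Defaults: cohort of 189 Good / 67 Poor instances, three technical
#' replicates with 0.05 log-units noise, within-class log-sd 0.5,
#' inter-feature correlation 0.6, class separation 6 log units. The
#' correlation sits inside the range reported for real panels of this
#' kind. Note that equicorrelation concentrates within-class variance
#' along the equal-loading direction (standard deviation
#' `sd * sqrt(1 + (m-1) * correlation)`, about 1.14 log units at the
#' defaults) — the same direction the classes are separated along — so
#' the default separation corresponds to roughly 5.3 of those standard
#' deviations: cleanly separated classes whose reference sets are
#' almost always self-consistent (a rare sampling outlier triggers the
#' self-consistency warning), while the segment between the class
#' centroids still crosses a genuine decision surface for boundary
#' constructions. Smaller separations emulate overlapping cohorts.
#'
#' @param nGood,nPoor cohort class sizes.
#' @param features feature names (default [vsFeatures()]).
#' @param baseLogMean scalar or per-feature log-intensity center of the
#'   midpoint between classes (default `log(10000)`).
#' @param separation Euclidean distance between class centers in log
#'   space (>= 0).
#' @param sd within-class log-scale standard deviation per feature.
#' @param correlation common inter-feature correlation in `[0, 1)`.
#' @param logMeanGood,logMeanPoor,logCovGood,logCovPoor explicit
#'   overrides of the class parameters.
#' @param replicateNoiseSd sd of i.i.d. Gaussian log-space technical
#'   noise per replicate.
#' @param seed integer base seed.
#' @return A [CohortSpec-class].
#' @examples
#' cohortSpec(seed = 1)
#' @export
cohortSpec <- function(nGood = 189L, nPoor = 67L, features = vsFeatures(),
                       baseLogMean = log(10000), separation = 6,
                       sd = 0.5, correlation = 0.6,
                       logMeanGood = NULL, logMeanPoor = NULL,
                       logCovGood = NULL, logCovPoor = NULL,
                       replicateNoiseSd = 0.05, seed = 1L) {
  m <- length(features)
  if (separation < 0) stop("separation must be non-negative")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)")
  u <- rep(1 / sqrt(m), m)
  base <- rep(baseLogMean, length.out = m)
  if (is.null(logMeanGood)) logMeanGood <- base + separation / 2 * u
  if (is.null(logMeanPoor)) logMeanPoor <- base - separation / 2 * u
  S <- sd^2 * ((1 - correlation) * diag(m) + correlation)
  if (is.null(logCovGood)) logCovGood <- S
  if (is.null(logCovPoor)) logCovPoor <- S
  new("CohortSpec",
    nGood = as.integer(nGood), nPoor = as.integer(nPoor),
    features = features,
    logMeanGood = setNames(logMeanGood, features),
    logMeanPoor = setNames(logMeanPoor, features),
    logCovGood = logCovGood, logCovPoor = logCovPoor,
    replicateNoiseSd = replicateNoiseSd, seed = as.integer(seed)
  )
}

.drawClass <- function(spec, label, n) {
  mu <- if (label == "Good") spec@logMeanGood else spec@logMeanPoor
  S <- if (label == "Good") spec@logCovGood else spec@logCovPoor
  X <- exp(.rmvnorm(n, mu, S))
  if (!is.matrix(X)) X <- matrix(X, nrow = n)
  colnames(X) <- spec@features
  X
}

#' Generate a labeled reference set
#'
#' Draws `nGood` + `nPoor` reference samples from the spec's two class
#' distributions and wraps them as a kNN [ReferenceSet-class]. By default
#' the self-consistency of the set is checked — each reference sample
#' should classify to its own label under the full-panel kNN — and a
#' warning reports any failures (expected when the requested class
#' separation is small or zero).
#'
#' @param spec a [CohortSpec-class].
#' @param nGood,nPoor reference class sizes (default 13 each).
#' @param k neighbor count (default 7).
#' @param distance passed to [referenceSet()].
#' @param checkSelfConsistency warn when reference samples misclassify.
#' @return A [ReferenceSet-class].
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' table(refLabels(refs))
#' @export
makeReferenceSet <- function(spec, nGood = 13L, nPoor = 13L, k = 7L,
                             distance = "log-euclidean",
                             checkSelfConsistency = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  withr::with_seed(spec@seed, {
    XG <- .drawClass(spec, "Good", nGood)
    XP <- .drawClass(spec, "Poor", nPoor)
  })
  X <- rbind(XG, XP)
  rownames(X) <- sprintf("ref%02d", seq_len(nrow(X)))
  refs <- referenceSet(X, rep(c("Good", "Poor"), c(nGood, nPoor)),
    k = k, distance = distance
  )
  if (checkSelfConsistency) {
    ok <- selfConsistency(refs)
    if (!all(ok))
      warning(
        sum(!ok), " of ", length(ok),
        " reference samples do not classify to their own label ",
        "(classes may be insufficiently separated)"
      )
  }
  refs
}

#' Self-consistency of a reference set
#'
#' Classifies every reference sample with the full-panel kNN (the sample
#' itself is part of the reference set, as in the deployed classifier)
#' and compares to its label.
#'
#' @param refs a [ReferenceSet-class].
#' @return Named logical vector, TRUE where the classification matches.
#' @export
selfConsistency <- function(refs) {
  stopifnot(is(refs, "ReferenceSet"))
  cls <- .knnVote(refs@intensities, refs, seq_along(refFeatures(refs)))
  enc <- ifelse(refs@label == "Good", 1, -1)
  setNames(cls == enc, rownames(refs@intensities))
}

.classLogCentroid <- function(refs, label) {
  colMeans(log(refs@intensities[refs@label == label, , drop = FALSE]))
}

#' Construct a uniform instance
#'
#' Builds an instance that every non-empty feature subset classifies
#' identically (the *uniform* pattern, which forces all Shapley values to
#' +/- 1/m). The construction starts at the log-centroid of the target
#' class's reference samples and, if any subset disagrees, steps the
#' candidate deeper into the class region (away from the other class's
#' centroid), verifying with the exhaustive subset-value table at each
#' attempt.
#'
#' @param refs a [ReferenceSet-class] with separated classes.
#' @param label target class, `"Good"` or `"Poor"`.
#' @param maxRetries placement attempts before giving up.
#' @return Named numeric feature vector (raw positive intensities) with
#'   an `"instanceId"` attribute.
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' inst <- makeUniformInstance(refs, "Good")
#' unique(subsetTableAsDataFrame(subsetValueTable(inst, refs))$value[-1]) # +1
#' @export
makeUniformInstance <- function(refs, label = c("Good", "Poor"),
                                maxRetries = 8L) {
  stopifnot(is(refs, "ReferenceSet"))
  label <- match.arg(label)
  target <- if (label == "Good") 1 else -1
  own <- .classLogCentroid(refs, label)
  other <- .classLogCentroid(refs, setdiff(c("Good", "Poor"), label))
  for (attempt in 0:maxRetries) {
    cand <- exp(own + 0.5 * attempt * (own - other))
    tab <- subsetValueTable(cand, refs,
      instanceId = paste0("uniform", label)
    )
    if (all(tab@values[-1L] == target)) {
      attr(cand, "instanceId") <- paste0("uniform", label)
      return(cand)
    }
  }
  stop(
    "could not place a uniform ", label, " instance in ", maxRetries,
    " attempts; are the reference classes separated?"
  )
}

#' Construct a boundary instance by bisection
#'
#' Bisects the log-space segment between a Good-classified and a
#' Poor-classified point until the bracketing interval is shorter than
#' `tol`, and returns the midpoint — an instance essentially on the kNN
#' decision surface, whose exact Shapley values are typically
#' non-uniform.
#'
#' @param refs a [ReferenceSet-class].
#' @param from,to named numeric feature vectors with opposite full-panel
#'   classifications (defaults: the Good and Poor reference log
#'   centroids).
#' @param tol log-space interval length at which bisection stops.
#' @return Named numeric feature vector with attributes `"instanceId"`
#'   and `"bracket"` (the final two endpoints, one per classification).
#' @export
makeBoundaryInstance <- function(refs, from = NULL, to = NULL, tol = 1e-9) {
  stopifnot(is(refs, "ReferenceSet"))
  feats <- refFeatures(refs)
  if (is.null(from)) from <- exp(.classLogCentroid(refs, "Good"))
  if (is.null(to)) to <- exp(.classLogCentroid(refs, "Poor"))
  a <- log(.checkInstance(from, feats))
  b <- log(.checkInstance(to, feats))
  fa <- classifySubset(exp(a), feats, refs)
  fb <- classifySubset(exp(b), feats, refs)
  if (fa == fb)
    stop("endpoints classify identically; bisection needs opposite classes")
  while (sqrt(sum((a - b)^2)) > tol) {
    mid <- (a + b) / 2
    fm <- classifySubset(exp(mid), feats, refs)
    if (fm == fa) a <- mid else b <- mid
  }
  out <- exp((a + b) / 2)
  attr(out, "instanceId") <- "boundary"
  attr(out, "bracket") <- rbind(exp(a), exp(b))
  out
}

#' Generate a synthetic cohort with technical replicates
#'
#' Draws instances per class from the spec's distributions and applies
#' independent i.i.d. Gaussian log-space noise per technical replicate.
#' Feature data and truth metadata are returned as separate data frames
#' so that pipelines cannot accidentally leak generating labels.
#'
#' @param spec a [CohortSpec-class].
#' @param replicates technical replicates per instance (default 3).
#' @return list with `instances` (data.frame: `instance_id`,
#'   `replicate_id`, one column per feature) and `truth` (data.frame:
#'   `instance_id`, `true_class`).
#' @examples
#' coh <- makeCohort(cohortSpec(nGood = 5, nPoor = 3, seed = 1))
#' dim(coh$instances)
#' @export
makeCohort <- function(spec, replicates = 3L) {
  stopifnot(is(spec, "CohortSpec"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("at least one replicate required")
  withr::with_seed(spec@seed + 1L, {
    base <- rbind(
      .drawClass(spec, "Good", spec@nGood),
      .drawClass(spec, "Poor", spec@nPoor)
    )
    n <- nrow(base)
    ids <- sprintf("S%04d", seq_len(n))
    rows <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      noise <- if (spec@replicateNoiseSd > 0) {
        matrix(rnorm(n * ncol(base), sd = spec@replicateNoiseSd), n)
      } else {
        matrix(0, n, ncol(base))
      }
      X <- exp(log(base) + noise)
      rows[[r]] <- data.frame(
        instance_id = ids, replicate_id = r, X,
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }
  })
  instances <- do.call(rbind, rows)
  instances <- instances[order(instances$instance_id, instances$replicate_id), ]
  rownames(instances) <- NULL
  truth <- data.frame(
    instance_id = ids,
    true_class = rep(c("Good", "Poor"), c(spec@nGood, spec@nPoor)),
    stringsAsFactors = FALSE
  )
  list(instances = instances, truth = truth)
}

#' Extract one instance vector from a cohort data frame
#'
#' @param instances the `instances` data.frame of [makeCohort()] (or any
#'   data frame with `instance_id`, optional `replicate_id`, and feature
#'   columns).
#' @param id instance identifier.
#' @param replicate replicate number (default 1; ignored when the frame
#'   has no `replicate_id` column).
#' @return Named numeric feature vector with an `"instanceId"` attribute.
#' @export
cohortInstance <- function(instances, id, replicate = 1L) {
  row <- instances$instance_id == id
  if (!is.null(instances$replicate_id))
    row <- row & instances$replicate_id == replicate
  if (sum(row) != 1L)
    stop("instance ", id, " replicate ", replicate, " not uniquely found")
  featCols <- setdiff(names(instances), c("instance_id", "replicate_id"))
  out <- unlist(instances[row, featCols])
  attr(out, "instanceId") <- as.character(id)
  out
}
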