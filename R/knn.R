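# Value function of the diagnostic classifier: a kNN vote restricted to an
# arbitrary feature subset. Everything downstream (exact Shapley values,
# interaction metrics, SHAP expectations) consumes this.

.checkInstance <- function(instance, features, requirePositive = TRUE) {
  if (is.null(names(instance)))
    stop("instance must be a named numeric vector of feature intensities")
  missing <- setdiff(features, names(instance))
  if (length(missing))
    stop("instance is missing feature(s): ", paste(missing, collapse = ", "))
  x <- instance[features]
  if (anyNA(x) || !all(is.finite(x)))
    stop("instance intensities must be finite")
  if (requirePositive && any(x <= 0))
    stop(
      "non-positive intensity for feature(s): ",
      paste(features[x <= 0], collapse = ", "),
      " (log-space distance requires strictly positive values)"
    )
  x
}

# transform to the configured distance space
.distSpace <- function(x, refs) {
  if (refs@distance == "log-euclidean") log(x) else x
}

# classify the rows of a full-panel matrix X (raw intensity scale, columns
# = refFeatures(refs)) using only the columns in `cols`.
# Returns -1 (Poor) / +1 (Good) per row; 0 for the empty subset.
# Squared distances are accumulated coordinate-wise by explicit
# differences, so a coordinate on which the instance equals every
# reference contributes exactly zero; distance ties at the k-th neighbor
# are broken in favor of the lowest reference index (order() is stable).
.knnVote <- function(X, refs, cols) {
  n <- nrow(X)
  if (length(cols) == 0L) return(rep(0, n))
  A <- .distSpace(X[, cols, drop = FALSE], refs)
  B <- .distSpace(refs@intensities[, cols, drop = FALSE], refs)
  nr <- nrow(B)
  D <- matrix(0, n, nr)
  for (j in seq_len(nr)) {
    diff <- A - matrix(B[j, ], n, length(cols), byrow = TRUE)
    D[, j] <- rowSums(diff * diff)
  }
  enc <- ifelse(refs@label == "Good", 1, -1)
  k <- refs@k
  votes <- apply(D, 1L, function(d) sum(enc[order(d)[seq_len(k)]]))
  ifelse(votes > 0, 1, -1)
}

#' Classify an instance with the kNN restricted to a feature subset
#'
#' Computes distances from the instance to every reference sample using
#' only the subset's coordinates, takes the `k` nearest (ties at the k-th
#' neighbor broken in favor of the lowest reference-sample index), and
#' returns the majority class encoded Poor = -1, Good = +1. The empty
#' subset is defined as uninformative and returns 0.
#'
#' @param instance named numeric vector of strictly positive intensities
#'   covering the reference panel's features.
#' @param subset character vector of feature names (possibly empty,
#'   `character(0)`).
#' @param refs a [ReferenceSet-class].
#' @return -1, 0 or +1.
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' inst <- makeUniformInstance(refs, "Good")
#' classifySubset(inst, character(0), refs) # 0
#' classifySubset(inst, vsFeatures(), refs) # +1
#' @export
classifySubset <- function(instance, subset, refs) {
  stopifnot(is(refs, "ReferenceSet"))
  feats <- refFeatures(refs)
  x <- .checkInstance(instance, feats, refs@distance == "log-euclidean")
  mask <- .featuresToMask(subset, feats) # validates names
  cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(feats) - 1L)) != 0L)
  .knnVote(matrix(x, 1L, dimnames = list(NULL, feats)), refs, cols)[1L]
}

#' Evaluate the value function on every feature subset
#'
#' Runs the restricted kNN classifier for all 2^m subsets of the panel,
#' producing the complete subset-value table f(S) that the exact Shapley
#' value and the interaction metrics are computed from. With the default
#' eight-feature panel this is 256 classifier evaluations.
#'
#' @inheritParams classifySubset
#' @param instanceId identifier stored in the table (default: the
#'   instance's `"instanceId"` attribute, or `"instance"`).
#' @return A [SubsetValueTable-class] (mode `"exact"`).
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' tab <- subsetValueTable(makeUniformInstance(refs, "Good"), refs)
#' tab
#' @export
subsetValueTable <- function(instance, refs, instanceId = NULL) {
  stopifnot(is(refs, "ReferenceSet"))
  feats <- refFeatures(refs)
  x <- .checkInstance(instance, feats, refs@distance == "log-euclidean")
  if (is.null(instanceId))
    instanceId <- attr(instance, "instanceId") %||% "instance"
  m <- length(feats)
  X <- matrix(x, 1L, dimnames = list(NULL, feats))
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  values <- numeric(2^m)
  for (mask in 1:(2^m - 1)) {
    cols <- which(bitwAnd(mask, bits) != 0L)
    values[mask + 1L] <- .knnVote(X, refs, cols)
  }
  new("SubsetValueTable",
    instanceId = as.character(instanceId), features = feats,
    values = values, mode = "exact"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine technical-replicate classifications into a reported result
#'
#' The reported test result requires concordance across technical
#' replicates: `"Good"` if every replicate's full-panel classification is
#' +1, `"Poor"` if every one is -1, `"Indeterminate"` otherwise.
#'
#' @param replicates a list of named numeric instance vectors (the
#'   replicates of one sample), or a numeric matrix with one row per
#'   replicate and the panel's features as columns.
#' @param refs a [ReferenceSet-class].
#' @return `"Good"`, `"Poor"` or `"Indeterminate"`.
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' inst <- makeUniformInstance(refs, "Good")
#' classifyReplicates(list(inst, inst, inst), refs) # "Good"
#' @export
classifyReplicates <- function(replicates, refs) {
  if (is.matrix(replicates))
    replicates <- lapply(seq_len(nrow(replicates)), function(i) replicates[i, ])
  if (!is.list(replicates) || length(replicates) == 0L)
    stop("at least one replicate is required")
  cls <- vapply(
    replicates,
    function(r) classifySubset(r, refFeatures(refs), refs),
    numeric(1)
  )
  if (all(cls == 1)) "Good" else if (all(cls == -1)) "Poor" else "Indeterminate"
}
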