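#' @import methods
#' @importFrom stats approx cor cov glm IQR median pnorm qnorm
#'   quasibinomial rnorm sd optim setNames coef
#' @importFrom utils read.csv write.csv
NULL

#' Canonical mass-spectral feature panel
#'
#' The eight m/z positions (Da, rounded to the nearest integer and used as
#' feature names) of the serum proteomic test panel: 5843, 11445, 11529,
#' 11685, 11759, 11903, 12452 and 12579. The 11685 feature is variously
#' written 11686 in the literature; the panel always comprises eight
#' features even though enumerations of the mass positions sometimes list
#' only seven.
#'
#' @return Character vector of the eight canonical feature names.
#' @examples
#' vsFeatures()
#' @export
vsFeatures <- function() {
  c("5843", "11445", "11529", "11685", "11759", "11903", "12452", "12579")
}

.validPositiveMatrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) && all(x > 0)
}

#' ReferenceSet: a k-nearest-neighbor diagnostic classifier
#'
#' An S4 container holding the labeled reference samples that define a
#' k-nearest-neighbor (kNN) classifier, together with the neighbor count
#' `k` and the distance configuration. The default configuration is the
#' diagnostic test setting: 26 reference samples (13 Good, 13 Poor),
#' `k = 7`, Euclidean distance on log-transformed intensities.
#'
#' Classification is encoded numerically as Poor = -1, Good = +1. Distance
#' ties at the k-th neighbor are broken deterministically in favor of the
#' lowest reference-sample index.
#'
#' @slot intensities numeric matrix, samples x features, strictly positive;
#'   rownames are sample identifiers, colnames are feature names.
#' @slot label factor with levels `c("Poor", "Good")`, one per sample.
#' @slot k integer, odd neighbor count, at most the number of samples.
#' @slot distance character, `"log-euclidean"` (default) or `"euclidean"`.
#'
#' @aliases ReferenceSet
#' @seealso [referenceSet()], [classifySubset()], [makeReferenceSet()]
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    intensities = "matrix",
    label = "factor",
    k = "integer",
    distance = "character"
  )
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (!.validPositiveMatrix(object@intensities))
    msg <- c(msg, "intensities must be a finite, strictly positive numeric matrix")
  if (is.null(colnames(object@intensities)))
    msg <- c(msg, "intensities must have feature column names")
  if (!identical(levels(object@label), c("Poor", "Good")))
    msg <- c(msg, "label must be a factor with levels Poor, Good")
  if (length(object@label) != nrow(object@intensities))
    msg <- c(msg, "one label per reference sample required")
  if (anyNA(object@label))
    msg <- c(msg, "labels must not be missing")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  else {
    if (object@k %% 2L == 0L)
      msg <- c(msg, "k must be odd so that majority votes cannot tie")
    if (object@k > nrow(object@intensities))
      msg <- c(msg, "k cannot exceed the number of reference samples")
  }
  if (!object@distance %in% c("log-euclidean", "euclidean"))
    msg <- c(msg, "distance must be 'log-euclidean' or 'euclidean'")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param intensities samples x features matrix of strictly positive
#'   intensities with feature colnames (and, optionally, sample rownames).
#' @param label character or factor of class labels, `"Good"` or `"Poor"`,
#'   one per row of `intensities`.
#' @param k odd neighbor count (default 7).
#' @param distance `"log-euclidean"` (Euclidean on log intensities, the
#'   default) or `"euclidean"` (raw scale).
#' @return A [ReferenceSet-class] object.
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' refs
#' @export
referenceSet <- function(intensities, label, k = 7L,
                         distance = c("log-euclidean", "euclidean")) {
  distance <- match.arg(distance)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("ref%02d", seq_len(nrow(intensities)))
  label <- factor(as.character(label), levels = c("Poor", "Good"))
  new("ReferenceSet",
    intensities = intensities, label = label,
    k = as.integer(k), distance = distance
  )
}

#' @describeIn referenceSet reference intensity matrix (samples x features).
#' @param x,object a `ReferenceSet`.
#' @export
refValues <- function(x) x@intensities

#' @describeIn referenceSet class labels (factor, levels Poor/Good).
#' @export
refLabels <- function(x) x@label

#' @describeIn referenceSet neighbor count k.
#' @export
refK <- function(x) x@k

#' @describeIn referenceSet feature names of the panel.
#' @export
refFeatures <- function(x) colnames(x@intensities)

setMethod("show", "ReferenceSet", function(object) {
  cat(
    "ReferenceSet:", nrow(object@intensities), "samples (",
    sum(object@label == "Good"), "Good /", sum(object@label == "Poor"),
    "Poor ),", ncol(object@intensities), "features\n"
  )
  cat("  k =", object@k, "| distance:", object@distance, "\n")
  cat("  features:", paste(colnames(object@intensities), collapse = ", "), "\n")
})

#' SubsetValueTable: the value function over the feature-subset lattice
#'
#' Stores f(S), the restricted-classifier prediction, for every one of the
#' 2^m subsets S of an m-feature panel. For the exact (retrained-kNN) mode
#' the values are -1/+1 for non-empty subsets and 0 for the empty subset
#' (the null prediction is defined as uninformative); expectation-based
#' modes store real values in `[-1, 1]`.
#'
#' Subsets are indexed internally by bitmask: bit `i` (value `2^(i-1)`)
#' set means the `i`-th feature of `features(x)` is in the subset. The
#' canonical enumeration order used for display and export is by subset
#' size, then lexicographically by feature name.
#'
#' @slot instanceId character identifier of the explained instance.
#' @slot features character vector of feature names (defines bit order).
#' @slot values numeric vector of length 2^m; element `mask + 1` holds
#'   f(S) for the subset with that bitmask.
#' @slot mode `"exact"` or `"expectation"`.
#' @aliases SubsetValueTable
#' @seealso [subsetValueTable()], [subsetValue()], [shapleyValues()]
#' @exportClass SubsetValueTable
setClass("SubsetValueTable",
  representation(
    instanceId = "character",
    features = "character",
    values = "numeric",
    mode = "character"
  )
)

setValidity("SubsetValueTable", function(object) {
  m <- length(object@features)
  msg <- character()
  if (m < 1L) msg <- c(msg, "at least one feature required")
  if (anyDuplicated(object@features))
    msg <- c(msg, "feature names must be unique")
  if (length(object@values) != 2^m)
    msg <- c(msg, sprintf("values must have length 2^%d = %d", m, 2^m))
  if (anyNA(object@values))
    msg <- c(msg, "all subset values must be present")
  if (!object@mode %in% c("exact", "expectation"))
    msg <- c(msg, "mode must be 'exact' or 'expectation'")
  if (object@mode == "exact" && length(object@values) == 2^m && !anyNA(object@values)) {
    if (object@values[1L] != 0)
      msg <- c(msg, "exact-mode empty-subset value must be 0")
    if (m >= 1L && !all(object@values[-1L] %in% c(-1, 1)))
      msg <- c(msg, "exact-mode non-empty subset values must be -1 or +1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubsetValueTable", function(object) {
  m <- length(object@features)
  cat(
    "SubsetValueTable for instance", object@instanceId, ":",
    2^m, "subsets of", m, "features (mode:", object@mode, ")\n"
  )
  cat(
    "  f(empty) =", object@values[1L],
    "| f(full) =", object@values[2^m], "\n"
  )
})

#' Attribution: a per-feature explanation
#'
#' One explanation of one instance: a named vector `phi` of per-feature
#' values (exact Shapley values, a SHAP approximation, or LIME surrogate
#' coefficients), the null-set value `phi_0`, and the full-model value
#' f(M). For Shapley-type methods the efficiency identity
#' `sum(phi) + nullValue == fullValue` holds to numerical precision; the
#' validity method enforces it at 1e-12 for those methods. LIME
#' coefficients are not additive attributions, so `nullValue` stores the
#' surrogate intercept and `fullValue` is `NA`.
#'
#' @slot instanceId character.
#' @slot method one of `"exact"`, `"kernel_shap"`, `"gaussian_shap"`,
#'   `"copula_shap"`, `"lime_logistic"`, `"lime_svm"`.
#' @slot phi named numeric vector, one value per feature.
#' @slot nullValue numeric scalar (f(empty set), E[f(empty)], or intercept).
#' @slot fullValue numeric scalar f(M) (`NA` for LIME methods).
#' @slot seed integer RNG seed used (NA when deterministic).
#' @slot nSamples integer Monte-Carlo sample count (NA when not sampled).
#' @aliases Attribution
#' @seealso [shapleyValues()], [kernelShap()], [approxShapley()],
#'   [fitSurrogate()]
#' @exportClass Attribution
setClass("Attribution",
  representation(
    instanceId = "character",
    method = "character",
    phi = "numeric",
    nullValue = "numeric",
    fullValue = "numeric",
    seed = "integer",
    nSamples = "integer"
  ),
  prototype(seed = NA_integer_, nSamples = NA_integer_)
)

.shapleyMethods <- c("exact", "kernel_shap", "gaussian_shap", "copula_shap")
.limeMethods <- c("lime_logistic", "lime_svm")

setValidity("Attribution", function(object) {
  msg <- character()
  if (!object@method %in% c(.shapleyMethods, .limeMethods))
    msg <- c(msg, "unknown method tag")
  if (is.null(names(object@phi)) || anyDuplicated(names(object@phi)))
    msg <- c(msg, "phi must be named with unique feature names")
  if (object@method %in% .shapleyMethods) {
    gap <- abs(sum(object@phi) + object@nullValue - object@fullValue)
    if (!is.finite(gap) || gap > 1e-12)
      msg <- c(msg, sprintf(
        "efficiency violated: |sum(phi) + nullValue - fullValue| = %g > 1e-12",
        gap
      ))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Attribution", function(object) {
  cat(
    "Attribution [", object@method, "] for instance",
    object@instanceId, "\n"
  )
  print(round(object@phi, 4))
  cat(
    "  nullValue =", signif(object@nullValue, 4),
    "| fullValue =", signif(object@fullValue, 4)
  )
  if (!is.na(object@seed)) cat(" | seed =", object@seed)
  if (!is.na(object@nSamples)) cat(" | N =", object@nSamples)
  cat("\n")
})

#' @describeIn phiValues attribution values as a named numeric vector.
#' @export
phiValues <- function(x) x@phi

#' Accessors for Attribution objects
#'
#' @param x an [Attribution-class] object.
#' @return `phiValues`: named numeric vector of per-feature values;
#'   `nullValue`: the null-set value / intercept; `fullValue`: f(M);
#'   `attrMethod`: the method tag.
#' @name phiValues
#' @export
nullValue <- function(x) x@nullValue

#' @rdname phiValues
#' @export
fullValue <- function(x) x@fullValue

#' @rdname phiValues
#' @export
attrMethod <- function(x) x@method

#' InteractionMatrix: one pairwise interaction metric for one instance
#'
#' An m x m matrix of one of the four pairwise metrics. SII and STII have
#' defined main-effect diagonals; the Harsanyi dividend and the Shapley
#' partial sum do not, and their diagonals are stored as `NA` so that
#' "not defined" is distinguishable from "computed as 0". SII, STII and HD
#' are symmetric; the Shapley partial sum is generally asymmetric (row i,
#' column j holds the part of feature j's Shapley value contributed by
#' coalitions that already contain feature i).
#'
#' @slot instanceId character.
#' @slot metric one of `"SII"`, `"STII"`, `"HD"`, `"SPS"`.
#' @slot values numeric m x m matrix with feature dimnames.
#' @slot diagonalDefined logical, TRUE for SII and STII.
#' @aliases InteractionMatrix
#' @seealso [interactionMatrix()]
#' @exportClass InteractionMatrix
setClass("InteractionMatrix",
  representation(
    instanceId = "character",
    metric = "character",
    values = "matrix",
    diagonalDefined = "logical"
  )
)

setValidity("InteractionMatrix", function(object) {
  msg <- character()
  if (!object@metric %in% c("SII", "STII", "HD", "SPS"))
    msg <- c(msg, "metric must be SII, STII, HD or SPS")
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(dimnames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must have matching feature dimnames")
  if (object@diagonalDefined && anyNA(diag(v)))
    msg <- c(msg, "diagonal declared defined but contains NA")
  if (!object@diagonalDefined && !all(is.na(diag(v))))
    msg <- c(msg, "diagonal declared undefined must be NA")
  if (object@metric %in% c("SII", "STII", "HD")) {
    off <- v
    diag(off) <- 0
    if (any(abs(off - t(off)) > 1e-12, na.rm = TRUE))
      msg <- c(msg, paste(object@metric, "matrix must be symmetric"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(
    "InteractionMatrix [", object@metric, "] for instance",
    object@instanceId,
    if (object@diagonalDefined) "(diagonal = main effects)\n"
    else "(diagonal undefined)\n"
  )
  print(round(object@values, 4))
})

#' @describeIn interactionMatrix interaction values as a plain matrix.
#' @param x an `InteractionMatrix`.
#' @export
interactionValues <- function(x) x@values

#' DistributionModel: a feature-distribution model for conditional SHAP
#'
#' Parameters of the feature distribution assumed by a SHAP approximation:
#' none beyond the stored reference table (`independent_reference`, i.e.
#' kernel SHAP), a multivariate Gaussian on log intensities, or a Gaussian
#' copula with empirical log-scale margins.
#'
#' @slot kind `"independent_reference"`, `"multivariate_gaussian"` or
#'   `"gaussian_copula"`.
#' @slot features character feature names.
#' @slot location numeric per-feature center in log space (Gaussian kinds).
#' @slot covariance numeric covariance (Gaussian) or copula correlation
#'   matrix (copula), regularized to be positive definite.
#' @slot margins list of sorted per-feature log-intensity vectors (copula).
#' @slot sampleCount integer Monte-Carlo draws per conditional expectation.
#' @slot seed integer base RNG seed; required for the sampling kinds.
#' @aliases DistributionModel
#' @seealso [fitDistribution()], [conditionalExpectation()],
#'   [approxShapley()]
#' @exportClass DistributionModel
setClass("DistributionModel",
  representation(
    kind = "character",
    features = "character",
    location = "numeric",
    covariance = "matrix",
    margins = "list",
    sampleCount = "integer",
    seed = "integer"
  )
)

setValidity("DistributionModel", function(object) {
  msg <- character()
  if (!object@kind %in% c(
    "independent_reference", "multivariate_gaussian", "gaussian_copula"
  ))
    msg <- c(msg, "unknown distribution kind")
  if (object@kind != "independent_reference") {
    m <- length(object@features)
    if (length(object@location) != m)
      msg <- c(msg, "location must have one entry per feature")
    if (!all(dim(object@covariance) == c(m, m)))
      msg <- c(msg, "covariance must be m x m")
    else if (any(abs(object@covariance - t(object@covariance)) > 1e-10))
      msg <- c(msg, "covariance must be symmetric")
  }
  if (object@kind == "gaussian_copula") {
    if (length(object@margins) != length(object@features))
      msg <- c(msg, "one empirical margin per feature required")
    else if (any(!vapply(object@margins, function(v) !is.unsorted(v), logical(1))))
      msg <- c(msg, "margins must be sorted (strictly increasing order statistics)")
  }
  if (length(object@sampleCount) != 1L || object@sampleCount < 1L)
    msg <- c(msg, "sampleCount must be a positive integer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DistributionModel", function(object) {
  cat("DistributionModel:", object@kind, "\n")
  if (object@kind != "independent_reference") {
    cat("  ", length(object@features), "features, N =", object@sampleCount)
    if (!is.na(object@seed)) cat(", seed =", object@seed)
    cat("\n")
  }
})

#' StandardizationParams: robust log-scale standardization
#'
#' Per-feature center (median of log intensity) and scale (interquartile
#' range of log intensity divided by 1.35, an asymptotically consistent
#' robust estimate of the normal standard deviation) used to map raw
#' intensities to z-scores: `z_i = (log(x_i) - center_i) / scale_i`.
#'
#' @slot features character feature names.
#' @slot center numeric per-feature median log intensity.
#' @slot scale numeric per-feature IQR/1.35 of log intensity (positive).
#' @slot provenance `"pooled"`, `"Good"` or `"Poor"` — which reference
#'   samples the parameters were estimated from.
#' @aliases StandardizationParams
#' @seealso [standardizationParams()], [standardizeInstance()]
#' @exportClass StandardizationParams
setClass("StandardizationParams",
  representation(
    features = "character",
    center = "numeric",
    scale = "numeric",
    provenance = "character"
  )
)

setValidity("StandardizationParams", function(object) {
  msg <- character()
  m <- length(object@features)
  if (length(object@center) != m || length(object@scale) != m)
    msg <- c(msg, "center and scale must have one entry per feature")
  if (!all(is.finite(object@scale)) || any(object@scale <= 0))
    msg <- c(msg, "scales must be strictly positive")
  if (!object@provenance %in% c("pooled", "Good", "Poor"))
    msg <- c(msg, "provenance must be pooled, Good or Poor")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StandardizationParams", function(object) {
  cat(
    "StandardizationParams (", object@provenance, "):",
    length(object@features), "features\n"
  )
})

#' PermutationSet: perturbed instances for LIME surrogate training
#'
#' The perturbation sample used to train a local surrogate: feature
#' vectors drawn independently per feature from class-conditional
#' log-scale distributions, their full-panel kNN classifications, the
#' keep/discard flag (kept iff the classification matches the class whose
#' distribution generated the draw), and, after weighting, the Gaussian
#' proximity weights relative to an explained instance.
#'
#' @slot features character feature names.
#' @slot x numeric matrix of raw (positive) feature values, draws x features.
#' @slot sourceClass factor, the class distribution each draw came from.
#' @slot classification numeric -1/+1 full-panel kNN result per draw.
#' @slot kept logical, classification agrees with sourceClass.
#' @slot weight numeric proximity weights (NA before weighting; NA for
#'   discarded draws).
#' @slot sigma numeric kernel width used for the weights (NA before
#'   weighting).
#' @slot seed integer RNG seed used for generation.
#' @aliases PermutationSet
#' @seealso [generatePermutations()], [weightPermutations()],
#'   [fitSurrogate()]
#' @exportClass PermutationSet
setClass("PermutationSet",
  representation(
    features = "character",
    x = "matrix",
    sourceClass = "factor",
    classification = "numeric",
    kept = "logical",
    weight = "numeric",
    sigma = "numeric",
    seed = "integer"
  ),
  prototype(sigma = NA_real_)
)

setValidity("PermutationSet", function(object) {
  msg <- character()
  n <- nrow(object@x)
  if (ncol(object@x) != length(object@features))
    msg <- c(msg, "x must have one column per feature")
  if (length(object@sourceClass) != n || length(object@classification) != n ||
    length(object@kept) != n || length(object@weight) != n)
    msg <- c(msg, "per-draw slots must match nrow(x)")
  if (!all(object@classification %in% c(-1, 1)))
    msg <- c(msg, "classifications must be -1 or +1")
  enc <- ifelse(object@sourceClass == "Good", 1, -1)
  if (!identical(object@kept, unname(object@classification == enc)))
    msg <- c(msg, "kept flag must equal (classification == source class)")
  w <- object@weight[object@kept]
  if (!all(is.na(w)) && (any(is.na(w)) || any(w <= 0) || any(w > 1)))
    msg <- c(msg, "weights of kept draws must all be set and lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationSet", function(object) {
  n <- nrow(object@x)
  cat(
    "PermutationSet:", n, "draws,", sum(object@kept), "kept (",
    sprintf("%.1f%%", 100 * mean(!object@kept)), "discarded )\n"
  )
  if (!is.na(object@sigma))
    cat("  weighted, kernel width sigma =", signif(object@sigma, 4), "\n")
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Defines the two class-conditional multivariate log-normal feature
#' distributions (Gaussian in log space), the cohort composition, and the
#' technical-replicate noise level. See [cohortSpec()] for the defaults
#' and their rationale.
#'
#' @slot nGood,nPoor integer cohort sizes per class.
#' @slot features character feature names.
#' @slot logMeanGood,logMeanPoor numeric class centers in log space.
#' @slot logCovGood,logCovPoor numeric class covariances in log space.
#' @slot replicateNoiseSd numeric sd of i.i.d. log-space technical noise.
#' @slot seed integer base seed.
#' @aliases CohortSpec
#' @seealso [cohortSpec()], [makeReferenceSet()], [makeCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nGood = "integer",
    nPoor = "integer",
    features = "character",
    logMeanGood = "numeric",
    logMeanPoor = "numeric",
    logCovGood = "matrix",
    logCovPoor = "matrix",
    replicateNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  m <- length(object@features)
  if (object@nGood < 0L || object@nPoor < 0L)
    msg <- c(msg, "class sizes must be non-negative")
  if (length(object@logMeanGood) != m || length(object@logMeanPoor) != m)
    msg <- c(msg, "class log means must have one entry per feature")
  for (nm in c("logCovGood", "logCovPoor")) {
    S <- slot(object, nm)
    if (!all(dim(S) == c(m, m))) {
      msg <- c(msg, paste(nm, "must be m x m"))
    } else if (any(abs(S - t(S)) > 1e-10)) {
      msg <- c(msg, paste(nm, "must be symmetric"))
    } else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(diag(S))) {
      msg <- c(msg, paste(nm, "must be positive semidefinite"))
    }
  }
  if (object@replicateNoiseSd < 0)
    msg <- c(msg, "replicateNoiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(
    "CohortSpec:", object@nGood, "Good /", object@nPoor, "Poor,",
    length(object@features), "features\n"
  )
  sep <- sqrt(sum((object@logMeanGood - object@logMeanPoor)^2))
  cat(
    "  class separation:", signif(sep, 4), "log units | replicate noise sd:",
    object@replicateNoiseSd, "| seed:", object@seed, "\n"
  )
})
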