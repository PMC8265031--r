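# LIME local surrogate explanations: class-conditional permutation
# generation in robust-standardized log space, concordance-based
# discarding, Gaussian proximity weighting, and weighted logistic /
# linear-SVM surrogate fits whose coefficients are the explanation.

#' Estimate robust log-scale standardization parameters
#'
#' Per-feature median and IQR/1.35 of the log intensities of the
#' reference samples, estimated from all samples (`"pooled"`) or from one
#' class only (`"Good"` / `"Poor"`, used for class-conditional
#' permutation generation).
#'
#' @param refs a [ReferenceSet-class].
#' @param provenance which samples to estimate from.
#' @return A [StandardizationParams-class].
#' @export
standardizationParams <- function(refs,
                                  provenance = c("pooled", "Good", "Poor")) {
  stopifnot(is(refs, "ReferenceSet"))
  provenance <- match.arg(provenance)
  keep <- if (provenance == "pooled") rep(TRUE, nrow(refs@intensities)) else
    refs@label == provenance
  if (!any(keep)) stop("no reference samples with label ", provenance)
  L <- log(refs@intensities[keep, , drop = FALSE])
  new("StandardizationParams",
    features = refFeatures(refs),
    center = apply(L, 2L, median),
    scale = apply(L, 2L, IQR) / 1.35,
    provenance = provenance
  )
}

#' Standardize an instance to robust log z-scores
#'
#' `z_i = (log(x_i) - center_i) / scale_i`.
#'
#' @param instance named numeric vector of positive intensities (or a
#'   matrix with feature columns).
#' @param params a [StandardizationParams-class].
#' @return numeric vector (or matrix) of z-scores in feature order.
#' @seealso [unstandardize()]
#' @export
standardizeInstance <- function(instance, params) {
  stopifnot(is(params, "StandardizationParams"))
  feats <- params@features
  if (is.matrix(instance)) {
    X <- instance[, feats, drop = FALSE]
    if (any(X <= 0)) stop("intensities must be strictly positive")
    return(sweep(sweep(log(X), 2L, params@center), 2L, params@scale, "/"))
  }
  x <- .checkInstance(instance, feats)
  setNames((log(x) - params@center) / params@scale, feats)
}

#' Back-transform z-scores to raw intensities
#'
#' Inverse of [standardizeInstance()]: `x_i = exp(scale_i * z_i +
#' center_i)`.
#'
#' @param z numeric vector (or matrix) of z-scores in the parameter's
#'   feature order.
#' @param params a [StandardizationParams-class].
#' @return numeric vector (or matrix) of strictly positive intensities.
#' @export
unstandardize <- function(z, params) {
  stopifnot(is(params, "StandardizationParams"))
  if (is.matrix(z)) {
    out <- exp(sweep(sweep(z, 2L, params@scale, "*"), 2L, params@center, "+"))
    colnames(out) <- params@features
    return(out)
  }
  setNames(exp(params@scale * z + params@center), params@features)
}

#' Generate class-conditional permutations for surrogate training
#'
#' Draws `nPerClass` standard-normal z-vectors per class (feature
#' correlations deliberately ignored), back-transforms them with the
#' class-specific robust parameters (`x = exp(scale_class * z +
#' center_class)`), classifies each draw with the full-panel kNN, and
#' flags as kept exactly those whose classification matches the class
#' whose distribution generated them (the rest are discarded from
#' surrogate training).
#'
#' @param refs a [ReferenceSet-class].
#' @param nPerClass draws per class (default 1e4 for desk-scale work; the
#'   full-scale procedure uses 5e5 per class).
#' @param seed integer RNG seed (required).
#' @return A [PermutationSet-class].
#' @export
generatePermutations <- function(refs, nPerClass = 10000L, seed) {
  stopifnot(is(refs, "ReferenceSet"))
  if (missing(seed) || is.na(seed)) stop("an explicit seed is required")
  nPerClass <- as.integer(nPerClass)
  if (nPerClass < 50L)
    warning("fewer than 50 permutations per class is unlikely to support a surrogate fit")
  feats <- refFeatures(refs)
  m <- length(feats)
  pG <- standardizationParams(refs, "Good")
  pP <- standardizationParams(refs, "Poor")
  withr::with_seed(as.integer(seed), {
    zG <- matrix(rnorm(nPerClass * m), nPerClass, m)
    zP <- matrix(rnorm(nPerClass * m), nPerClass, m)
  })
  X <- rbind(unstandardize(zG, pG), unstandardize(zP, pP))
  srcClass <- factor(
    rep(c("Good", "Poor"), each = nPerClass),
    levels = c("Poor", "Good")
  )
  cls <- .knnVote(X, refs, seq_len(m))
  enc <- ifelse(srcClass == "Good", 1, -1)
  new("PermutationSet",
    features = feats, x = X, sourceClass = srcClass, classification = cls,
    kept = unname(cls == enc), weight = rep(NA_real_, nrow(X)),
    sigma = NA_real_, seed = as.integer(seed)
  )
}

#' Weight permutations by proximity to an explained instance
#'
#' Gaussian distance kernel `w = exp(-d^2 / sigma^2)` on Euclidean
#' distances in (pooled) standardized space. The kernel width is the mean
#' distance over the kept permutations (`"mean_distance"`, logistic
#' surrogate) or half of it (`"half_mean_distance"`, SVM surrogate),
#' optionally rescaled by `sigmaMultiplier` for boundary-region variants.
#'
#' @param perms a [PermutationSet-class].
#' @param instance named numeric vector, the instance being explained.
#' @param params [StandardizationParams-class] defining the standardized
#'   space (typically pooled).
#' @param sigmaRule `"mean_distance"` or `"half_mean_distance"`.
#' @param sigmaMultiplier positive rescaling of the kernel width
#'   (default 1).
#' @return The permutation set with `weight` filled in for kept draws and
#'   `sigma` recorded.
#' @export
weightPermutations <- function(perms, instance, params,
                               sigmaRule = c("mean_distance", "half_mean_distance"),
                               sigmaMultiplier = 1) {
  stopifnot(is(perms, "PermutationSet"), is(params, "StandardizationParams"))
  sigmaRule <- match.arg(sigmaRule)
  if (!any(perms@kept)) stop("no kept permutations to weight")
  if (sigmaMultiplier <= 0) stop("sigmaMultiplier must be positive")
  Z <- standardizeInstance(perms@x[perms@kept, , drop = FALSE], params)
  z0 <- standardizeInstance(instance, params)
  d <- sqrt(rowSums(sweep(Z, 2L, z0)^2))
  sigma <- mean(d) * sigmaMultiplier
  if (sigmaRule == "half_mean_distance") sigma <- sigma / 2
  if (sigma <= 0) stop("degenerate kernel width (all permutations at the instance)")
  w <- rep(NA_real_, nrow(perms@x))
  w[perms@kept] <- exp(-d^2 / sigma^2)
  perms@weight <- w
  perms@sigma <- sigma
  validObject(perms)
  perms
}

# weighted logistic surrogate; an unpenalized fit (ridge = 0) goes
# through glm, but the kept permutation clouds are separated exactly by
# the kNN decision surface and can be linearly separable, in which case
# the logistic MLE diverges — the default negligible ridge (1e-8, via
# glmnet) keeps the fit conditioned without materially shrinking the
# coefficients
.weightedLogistic <- function(Z, y01, w, ridge) {
  if (ridge > 0) {
    fit <- glmnet::glmnet(Z, y01,
      family = "binomial", alpha = 0, lambda = ridge, weights = w,
      standardize = FALSE, thresh = 1e-12, maxit = 1e6
    )
    co <- as.numeric(coef(fit))
  } else {
    df <- data.frame(y = y01, Z, check.names = FALSE)
    fit <- glm(y ~ ., data = df, family = quasibinomial(), weights = w)
    co <- unname(coef(fit))
  }
  list(coef = setNames(co[-1L], colnames(Z)), intercept = co[1L])
}

# weighted L2-regularized squared-hinge linear SVM, fitted by L-BFGS-B;
# y in {-1, +1}, objective 0.5 ||beta||^2 + C sum_i wn_i max(0, 1 - y_i s_i)^2
# with weights normalized to sum to one, so the fit is invariant to
# duplicating the sample and depends only on the weight profile
.weightedLinearSvm <- function(Z, y, w, cost = 1) {
  m <- ncol(Z)
  w <- w / sum(w)
  obj <- function(theta) {
    beta <- theta[seq_len(m)]
    b <- theta[m + 1L]
    slack <- pmax(0, 1 - y * (Z %*% beta + b))
    0.5 * sum(beta^2) + cost * sum(w * slack^2)
  }
  grad <- function(theta) {
    beta <- theta[seq_len(m)]
    b <- theta[m + 1L]
    s <- as.numeric(Z %*% beta + b)
    slack <- pmax(0, 1 - y * s)
    gcommon <- -2 * cost * w * slack * y
    c(beta + as.numeric(t(Z) %*% gcommon), sum(gcommon))
  }
  fit <- optim(rep(0, m + 1L), obj, grad,
    method = "L-BFGS-B",
    control = list(maxit = 500L, factr = 1e4)
  )
  list(coef = setNames(fit$par[seq_len(m)], colnames(Z)),
    intercept = fit$par[m + 1L], converged = fit$convergence == 0L)
}

#' Fit a local surrogate model and read off the explanation
#'
#' Fits a proximity-weighted surrogate on the standardized features of
#' the kept permutations and returns its coefficient vector as the
#' explanation:
#' * `"logistic"` — weighted logistic regression with a negligible ridge
#'   (default 1e-8) for conditioning, since the discard rule separates
#'   the kept clouds exactly along the kNN decision surface and an
#'   unpenalized MLE can diverge when that surface is linearly
#'   separable; labels Poor = 0 / Good = 1, so a positive coefficient
#'   pushes toward Good.
#' * `"linear_svm"` — weighted L2-regularized squared-hinge linear SVM
#'   (unit cost, proximity weights normalized to total one so the fit
#'   depends only on the weight profile); labels Poor = -1 / Good = +1,
#'   and the explanation is the normal vector of the fitted decision
#'   plane.
#'
#' The surrogate intercept is stored as the attribution's `nullValue`;
#' `fullValue` is `NA` (surrogate coefficients are not additive
#' attributions).
#'
#' @param perms a weighted [PermutationSet-class] (see
#'   [weightPermutations()]).
#' @param params the [StandardizationParams-class] of the surrogate's
#'   standardized space (must match the weighting).
#' @param modelKind `"logistic"` or `"linear_svm"`.
#' @param instanceId identifier stored in the attribution.
#' @param ridge ridge penalty for the logistic surrogate (default 1e-8;
#'   0 requests the unpenalized glm fit).
#' @param cost squared-hinge cost for the SVM surrogate (default 1).
#' @return An [Attribution-class] with method `"lime_logistic"` or
#'   `"lime_svm"`.
#' @export
fitSurrogate <- function(perms, params,
                         modelKind = c("logistic", "linear_svm"),
                         instanceId = "instance", ridge = 1e-8, cost = 1) {
  stopifnot(is(perms, "PermutationSet"), is(params, "StandardizationParams"))
  modelKind <- match.arg(modelKind)
  if (!any(perms@kept)) stop("no kept permutations")
  if (all(is.na(perms@weight[perms@kept])))
    stop("permutations must be weighted before fitting (see weightPermutations)")
  keep <- perms@kept
  cls <- perms@classification[keep]
  if (length(unique(cls)) < 2L)
    stop(
      "kept permutations contain a single class; a local surrogate needs ",
      "both classifications (the locality definition is too tight)"
    )
  Z <- standardizeInstance(perms@x[keep, , drop = FALSE], params)
  colnames(Z) <- params@features
  w <- perms@weight[keep]
  if (modelKind == "logistic") {
    fit <- .weightedLogistic(Z, as.numeric(cls == 1), w, ridge)
    phi <- fit$coef
    intercept <- fit$intercept
    method <- "lime_logistic"
  } else {
    fit <- .weightedLinearSvm(Z, cls, w, cost = cost)
    if (!fit$converged)
      warning("SVM surrogate optimizer did not report convergence")
    phi <- fit$coef
    intercept <- fit$intercept
    method <- "lime_svm"
  }
  new("Attribution",
    instanceId = as.character(instanceId), method = method, phi = phi,
    nullValue = intercept, fullValue = NA_real_, seed = perms@seed,
    nSamples = as.integer(sum(keep))
  )
}

#' One-call LIME explanation of an instance
#'
#' Convenience pipeline: pooled standardization parameters, permutation
#' generation, proximity weighting with the kernel-width rule matched to
#' the surrogate kind (mean distance for logistic, half for SVM), and
#' the surrogate fit.
#'
#' @inheritParams generatePermutations
#' @param instance named numeric vector of positive intensities.
#' @param modelKind `"logistic"` or `"linear_svm"`.
#' @param sigmaMultiplier kernel-width rescaling (default 1).
#' @param ridge,cost surrogate hyperparameters (see [fitSurrogate()]).
#' @param instanceId identifier stored in the attribution.
#' @param perms optionally, a pre-generated [PermutationSet-class] to
#'   reuse across instances (its weights are recomputed per instance).
#' @return An [Attribution-class].
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' inst <- makeUniformInstance(refs, "Good")
#' limeExplain(inst, refs, nPerClass = 500, seed = 7)
#' @export
limeExplain <- function(instance, refs, nPerClass = 10000L, seed,
                        modelKind = c("logistic", "linear_svm"),
                        sigmaMultiplier = 1, ridge = 1e-8, cost = 1,
                        instanceId = NULL, perms = NULL) {
  modelKind <- match.arg(modelKind)
  if (is.null(instanceId))
    instanceId <- attr(instance, "instanceId") %||% "instance"
  if (is.null(perms)) perms <- generatePermutations(refs, nPerClass, seed)
  pooled <- standardizationParams(refs, "pooled")
  rule <- if (modelKind == "logistic") "mean_distance" else "half_mean_distance"
  perms <- weightPermutations(perms, instance, pooled,
    sigmaRule = rule, sigmaMultiplier = sigmaMultiplier
  )
  fitSurrogate(perms, pooled, modelKind,
    instanceId = instanceId, ridge = ridge, cost = cost
  )
}
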