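# SHAP approximations: replace the retrained subset classifier f(S) by a
# conditional expectation of the full-panel classifier, under one of
# three feature-distribution assumptions, then push the expectations
# through the same Shapley weighted sum as the exact values.

#' Fit a feature-distribution model for conditional SHAP
#'
#' Estimates the distribution assumed by a SHAP variant from the
#' reference samples, in log-intensity space:
#' * `independent_reference` — no parameters; expectations are averages
#'   over reference-sample replacements (kernel SHAP).
#' * `multivariate_gaussian` — mean and covariance of the log
#'   intensities.
#' * `gaussian_copula` — per-feature empirical margins (probability
#'   integral transform) plus the correlation of the Gaussian scores.
#'
#' Covariance/correlation matrices are regularized by adding
#' `shrinkage * trace/m` to the diagonal so that the conditional
#' factorizations exist even for small, strongly correlated reference
#' sets; with `shrinkage = 0` a singular fit raises an error suggesting
#' shrinkage.
#'
#' @param refs a [ReferenceSet-class].
#' @param kind distribution kind (see above).
#' @param sampleCount Monte-Carlo draws per conditional expectation
#'   (default 1000).
#' @param seed integer RNG seed; required by the sampling kinds.
#' @param shrinkage diagonal regularization weight (default 1e-6).
#' @param logScale fit on log intensities (default TRUE, matching the
#'   log-space distance); set FALSE for raw-scale fitting.
#' @return A [DistributionModel-class].
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' fitDistribution(refs, "multivariate_gaussian", seed = 7)
#' @export
fitDistribution <- function(refs,
                            kind = c(
                              "independent_reference",
                              "multivariate_gaussian",
                              "gaussian_copula"
                            ),
                            sampleCount = 1000L, seed = NA_integer_,
                            shrinkage = 1e-6, logScale = TRUE) {
  stopifnot(is(refs, "ReferenceSet"))
  kind <- match.arg(kind)
  feats <- refFeatures(refs)
  m <- length(feats)
  R <- if (logScale) log(refs@intensities) else refs@intensities
  if (kind == "independent_reference") {
    return(new("DistributionModel",
      kind = kind, features = feats, location = numeric(0),
      covariance = matrix(numeric(0), 0, 0), margins = list(),
      sampleCount = as.integer(sampleCount), seed = as.integer(seed)
    ))
  }
  if (kind == "multivariate_gaussian") {
    loc <- colMeans(R)
    S <- cov(R)
    S <- .regularizeCov(S, shrinkage)
    margins <- list()
  } else {
    margins <- lapply(seq_len(m), function(i) sort(R[, i]))
    names(margins) <- feats
    Z <- vapply(
      seq_len(m),
      function(i) qnorm(.marginCdf(margins[[i]], R[, i])),
      numeric(nrow(R))
    )
    loc <- rep(0, m)
    S <- cor(Z)
    S <- .regularizeCov(S, shrinkage)
  }
  names(loc) <- feats
  dimnames(S) <- list(feats, feats)
  new("DistributionModel",
    kind = kind, features = feats, location = loc, covariance = S,
    margins = margins, sampleCount = as.integer(sampleCount),
    seed = as.integer(seed)
  )
}

.regularizeCov <- function(S, shrinkage) {
  S <- (S + t(S)) / 2
  if (shrinkage > 0) {
    S <- S + diag(shrinkage * mean(diag(S)), nrow(S))
  } else if (inherits(try(chol(S), silent = TRUE), "try-error")) {
    stop(
      "covariance estimate is singular; refit with shrinkage > 0 ",
      "(diagonal shrinkage regularization)"
    )
  }
  S
}

# --- empirical margins (probability integral transform) ----------------
# CDF at the order statistics v_(k) is k/(n+1); linear interpolation
# between order statistics; exponential tails beyond the observed range
# (scale = sd of the margin) so the transform and its inverse are defined
# on all of R / (0, 1).

.marginCdf <- function(v, x) {
  n <- length(v)
  p <- seq_len(n) / (n + 1)
  s <- max(sd(v), 1e-12)
  out <- approx(v, p, xout = x, ties = "mean", rule = 2)$y
  lo <- x < v[1L]
  hi <- x > v[n]
  out[lo] <- p[1L] * exp((x[lo] - v[1L]) / s)
  out[hi] <- 1 - (1 - p[n]) * exp(-(x[hi] - v[n]) / s)
  out
}

.marginQuantile <- function(v, p) {
  n <- length(v)
  pk <- seq_len(n) / (n + 1)
  s <- max(sd(v), 1e-12)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  out <- approx(pk, v, xout = p, rule = 2)$y
  lo <- p < pk[1L]
  hi <- p > pk[n]
  out[lo] <- v[1L] + s * log(p[lo] / pk[1L])
  out[hi] <- v[n] - s * log((1 - p[hi]) / (1 - pk[n]))
  out
}

# deterministic multivariate normal draws (shared by both Gaussian kinds)
.rmvnorm <- function(n, mu, S) {
  if (n == 0L) return(matrix(numeric(0), 0L, length(mu)))
  S <- (S + t(S)) / 2
  MASS::mvrnorm(n, mu = mu, Sigma = S, tol = 1e-6)
}

# conditional N(mu, S) of coords `u` given coords `o` equal to xo
.conditionalGaussian <- function(mu, S, o, u, xo) {
  if (length(o) == 0L)
    return(list(mean = mu[u], cov = S[u, u, drop = FALSE]))
  Soo <- S[o, o, drop = FALSE]
  Suo <- S[u, o, drop = FALSE]
  W <- Suo %*% solve(Soo)
  list(
    mean = as.numeric(mu[u] + W %*% (xo - mu[o])),
    cov = S[u, u, drop = FALSE] - W %*% t(Suo)
  )
}

# per-subset seed derived from the model's base seed so each expectation
# is reproducible independently of evaluation order
.subsetSeed <- function(seed, mask) {
  as.integer((as.numeric(seed) * 2654435L + mask) %% 2147483629)
}

#' Conditional expectation of the classifier under a distribution model
#'
#' Estimates `E[f | x_S fixed at the instance's values]` for one feature
#' subset S:
#' * `independent_reference`: average the full-panel classifications of
#'   the hybrids that keep the instance's values on S and take each
#'   reference sample's values off S (deterministic).
#' * `multivariate_gaussian`: draw the off-S log intensities from the
#'   Gaussian conditional given the in-S values, classify the completed
#'   vectors, average.
#' * `gaussian_copula`: map to Gaussian scores with the probability
#'   integral transform, condition in score space, invert the transform,
#'   classify, average.
#'
#' `subset = M` short-circuits to the instance's own classification
#' without sampling. The sampling kinds use `sampleCount` draws seeded
#' deterministically from the model's base seed and the subset, and
#' refuse to run without a seed.
#'
#' @param instance named numeric vector of positive intensities.
#' @param subset character vector of in-S feature names (possibly empty).
#' @param model a [DistributionModel-class] from [fitDistribution()].
#' @param refs the [ReferenceSet-class] defining the classifier.
#' @return numeric scalar in `[-1, 1]`.
#' @export
conditionalExpectation <- function(instance, subset, model, refs) {
  stopifnot(is(model, "DistributionModel"), is(refs, "ReferenceSet"))
  feats <- refFeatures(refs)
  x <- .checkInstance(instance, feats)
  mask <- .featuresToMask(subset, feats)
  m <- length(feats)
  full <- 2L^m - 1L
  if (mask == full)
    return(.knnVote(matrix(x, 1L, dimnames = list(NULL, feats)), refs,
      seq_len(m)))
  inS <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
  outS <- setdiff(seq_len(m), inS)

  if (model@kind == "independent_reference") {
    H <- refs@intensities
    if (length(inS))
      H[, inS] <- matrix(x[inS], nrow(H), length(inS), byrow = TRUE)
    return(mean(.knnVote(H, refs, seq_len(m))))
  }

  if (is.na(model@seed))
    stop("sampling-based expectations require a model fitted with a seed")
  n <- model@sampleCount
  withr::with_seed(.subsetSeed(model@seed, mask), {
    if (model@kind == "multivariate_gaussian") {
      cond <- .conditionalGaussian(
        model@location, model@covariance, inS, outS, log(x[inS])
      )
      draws <- .rmvnorm(n, cond$mean, cond$cov)
      logH <- matrix(log(x), n, m, byrow = TRUE)
      logH[, outS] <- draws
      H <- exp(logH)
    } else { # gaussian_copula
      zObs <- vapply(
        inS,
        function(i) qnorm(.marginCdf(model@margins[[i]], log(x[i]))),
        numeric(1)
      )
      cond <- .conditionalGaussian(
        model@location, model@covariance, inS, outS, zObs
      )
      draws <- .rmvnorm(n, cond$mean, cond$cov)
      if (!is.matrix(draws)) draws <- matrix(draws, ncol = length(outS))
      logH <- matrix(log(x), n, m, byrow = TRUE)
      for (idx in seq_along(outS)) {
        i <- outS[idx]
        logH[, i] <- .marginQuantile(model@margins[[i]], pnorm(draws[, idx]))
      }
      H <- exp(logH)
    }
    colnames(H) <- feats
    mean(.knnVote(H, refs, seq_len(m)))
  })
}

#' SHAP attribution under a fitted distribution model
#'
#' Evaluates the conditional expectation E[f(S)] for the full subset
#' lattice (all 2^m subsets, including the empty one, whose expectation
#' is computed by the same machinery with all features unknown rather
#' than forced to 0) and pushes the expectations through the exact
#' Shapley weighted sum. The efficiency identity
#' `sum(phi) + nullValue == fullValue` holds by construction.
#'
#' @inheritParams conditionalExpectation
#' @param instanceId identifier stored in the attribution.
#' @return An [Attribution-class] with method `"kernel_shap"`,
#'   `"gaussian_shap"` or `"copula_shap"`.
#' @seealso [kernelShap()], [fitDistribution()]
#' @export
approxShapley <- function(instance, refs, model, instanceId = NULL) {
  feats <- refFeatures(refs)
  m <- length(feats)
  if (is.null(instanceId))
    instanceId <- attr(instance, "instanceId") %||% "instance"
  values <- numeric(2^m)
  for (mask in 0:(2^m - 1)) {
    values[mask + 1L] <- conditionalExpectation(
      instance, .maskToFeatures(mask, feats), model, refs
    )
  }
  phi <- .shapleyFromValues(values, feats)
  method <- switch(model@kind,
    independent_reference = "kernel_shap",
    multivariate_gaussian = "gaussian_shap",
    gaussian_copula = "copula_shap"
  )
  new("Attribution",
    instanceId = as.character(instanceId), method = method, phi = phi,
    nullValue = values[1L], fullValue = values[2^m],
    seed = model@seed, nSamples = model@sampleCount
  )
}

#' Kernel SHAP by reference-sample replacement
#'
#' The independent-features SHAP approximation: for every subset S the
#' expectation E[f(S)] is the average full-panel classification of the 26
#' hybrids formed by keeping the instance's values on S and substituting
#' each reference sample's values off S. Fully deterministic.
#'
#' @inheritParams approxShapley
#' @return An [Attribution-class] with `method = "kernel_shap"`.
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' inst <- makeUniformInstance(refs, "Good")
#' kernelShap(inst, refs)
#' @export
kernelShap <- function(instance, refs, instanceId = NULL) {
  model <- fitDistribution(refs, "independent_reference")
  approxShapley(instance, refs, model, instanceId = instanceId)
}

#' Compare approximate attributions with exact Shapley values
#'
#' Mean square difference (MSD) between matched approximate and exact
#' attributions, averaged over instances and features — overall and
#' restricted to the instances whose exact pattern is uniform — plus an
#' optional symmetry-violation report: for feature pairs whose subset
#' behavior is exactly interchangeable in the exact value table
#' (`f(S+i) == f(S+j)` for all S), exact Shapley values are equal by the
#' symmetry axiom, and any difference in the approximation is an axiom
#' violation.
#'
#' @param approx list of [Attribution-class] (one method).
#' @param exact list of exact [Attribution-class] for the same instances,
#'   in the same order.
#' @param tables optional list of the exact [SubsetValueTable-class]s
#'   (same order) used to detect symmetric feature pairs.
#' @param probePair,tol passed to [classifySVPattern()].
#' @return list with elements `msd` (overall), `msdUniform` (uniform
#'   instances only, `NA` if none), `nUniform`, and `symmetryViolations`
#'   (data.frame instance_id, feature_i, feature_j, absDiff; `NULL`
#'   without `tables`).
#' @export
compareToExact <- function(approx, exact, tables = NULL,
                           probePair = c("11529", "11685"), tol = 1e-9) {
  stopifnot(length(approx) == length(exact), length(exact) > 0L)
  ids <- vapply(exact, function(a) a@instanceId, character(1))
  idsA <- vapply(approx, function(a) a@instanceId, character(1))
  if (!identical(ids, idsA))
    stop("instance sets of approximate and exact attributions differ")
  sq <- vapply(seq_along(exact), function(k) {
    e <- exact[[k]]@phi
    a <- approx[[k]]@phi[names(e)]
    mean((a - e)^2)
  }, numeric(1))
  uni <- vapply(
    exact,
    function(a) classifySVPattern(a, probePair, tol) == "uniform",
    logical(1)
  )
  viol <- NULL
  if (!is.null(tables)) {
    stopifnot(length(tables) == length(exact))
    rows <- list()
    for (k in seq_along(tables)) {
      pairs <- symmetricFeaturePairs(tables[[k]])
      if (nrow(pairs) == 0L) next
      a <- approx[[k]]@phi
      rows[[length(rows) + 1L]] <- data.frame(
        instance_id = ids[k],
        feature_i = pairs$feature_i,
        feature_j = pairs$feature_j,
        absDiff = abs(a[pairs$feature_i] - a[pairs$feature_j]),
        row.names = NULL
      )
    }
    viol <- if (length(rows)) do.call(rbind, rows) else
      data.frame(
        instance_id = character(0), feature_i = character(0),
        feature_j = character(0), absDiff = numeric(0)
      )
  }
  list(
    msd = mean(sq),
    msdUniform = if (any(uni)) mean(sq[uni]) else NA_real_,
    nUniform = sum(uni),
    symmetryViolations = viol
  )
}

#' Feature pairs with interchangeable subset behavior
#'
#' Finds the unordered pairs (i, j) with `f(S + i) == f(S + j)` for every
#' subset S excluding both — the premise of the Shapley symmetry axiom.
#'
#' @param table a complete [SubsetValueTable-class].
#' @return data.frame with columns `feature_i`, `feature_j`.
#' @export
symmetricFeaturePairs <- function(table) {
  stopifnot(is(table, "SubsetValueTable"))
  feats <- table@features
  m <- length(feats)
  out <- list()
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      ex <- .masksExcluding(table, feats[a], feats[b])
      same <- all(
        table@values[bitwOr(ex$S, ex$bi) + 1L] ==
          table@values[bitwOr(ex$S, ex$bj) + 1L]
      )
      if (same)
        out[[length(out) + 1L]] <- data.frame(
          feature_i = feats[a], feature_j = feats[b]
        )
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(feature_i = character(0), feature_j = character(0))
}
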