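# Exact Shapley values from a complete subset-value table, an independent
# permutation-averaging oracle, and the uniform/boundary instance taxonomy.

# Shapley coalition weights |S|! (m - |S| - 1)! / m! for |S| = 0 .. m-1,
# computed with exact integer factorials and divided once.
.shapleyWeights <- function(m) {
  s <- 0:(m - 1)
  factorial(s) * factorial(m - s - 1) / factorial(m)
}

# Eq.-style weighted sum over the subset lattice, shared by the exact and
# the expectation-based (SHAP) paths.
.shapleyFromValues <- function(values, features) {
  m <- length(features)
  stopifnot(length(values) == 2^m)
  w <- .shapleyWeights(m)
  sizes <- .popcountTable(m)
  phi <- numeric(m)
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  allMasks <- 0:(2^m - 1)
  for (j in seq_len(m)) {
    without <- allMasks[bitwAnd(allMasks, bits[j]) == 0L]
    phi[j] <- sum(
      w[sizes[without + 1L] + 1L] *
        (values[bitwOr(without, bits[j]) + 1L] - values[without + 1L])
    )
  }
  names(phi) <- features
  phi
}

#' Exact Shapley values of a subset-value table
#'
#' For each feature j, the weighted sum over all subsets S not containing
#' j of `|S|! (m-|S|-1)! / m! * (f(S + j) - f(S))`. The null-set value
#' f(empty) and the full-panel value f(M) are carried along; by
#' construction `sum(phi) + f(empty) == f(M)` (efficiency).
#'
#' @param table a complete [SubsetValueTable-class] (2^m entries).
#' @return An [Attribution-class] with `method = "exact"` (or the table's
#'   expectation mode tag when applied to an expectation table).
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' sv <- shapleyValues(subsetValueTable(makeUniformInstance(refs, "Good"), refs))
#' phiValues(sv) # all 1/8
#' @export
shapleyValues <- function(table) {
  stopifnot(is(table, "SubsetValueTable"))
  phi <- .shapleyFromValues(table@values, table@features)
  new("Attribution",
    instanceId = table@instanceId,
    method = "exact",
    phi = phi,
    nullValue = table@values[1L],
    fullValue = table@values[2^length(table@features)]
  )
}

# all permutations of 1..n, one per row (n! x n); recursive construction
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    block <- matrix(rest[sub], nrow(sub), n - 1L)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(first, block)
    row <- row + nrow(sub)
  }
  out
}

#' Permutation-averaging oracle for Shapley values
#'
#' Independent brute-force computation: each feature's Shapley value is
#' the average, over all m! orderings of the panel, of its marginal
#' contribution `f(predecessors + j) - f(predecessors)`. Agrees with
#' [shapleyValues()] to 1e-12 on every complete table; intended for
#' cross-validation on small panels (factorial cost, m <= 8).
#'
#' @param table a complete [SubsetValueTable-class] with at most 8 features.
#' @return An [Attribution-class] with `method = "exact"`.
#' @export
shapleyPermutationOracle <- function(table) {
  stopifnot(is(table, "SubsetValueTable"))
  m <- length(table@features)
  if (m > 8L)
    stop("permutation oracle enumerates m! orderings; refusing m > 8")
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  perms <- .permutations(m)
  phi <- numeric(m)
  for (p in seq_len(nrow(perms))) {
    mask <- 0L
    for (j in perms[p, ]) {
      withJ <- bitwOr(mask, bits[j])
      phi[j] <- phi[j] + table@values[withJ + 1L] - table@values[mask + 1L]
      mask <- withJ
    }
  }
  phi <- phi / nrow(perms)
  names(phi) <- table@features
  new("Attribution",
    instanceId = table@instanceId, method = "exact", phi = phi,
    nullValue = table@values[1L], fullValue = table@values[2^m]
  )
}

#' Classify an exact Shapley-value pattern as uniform, boundary or other
#'
#' An instance is *uniform* when all its Shapley values are equal (for the
#' exact +/-1 value function this forces the common value to +/-1/m): every
#' non-empty feature subset classifies it identically. It is *boundary*
#' when the Shapley values of the two designated probe features (by
#' default the two dominant panel features, 11529 and 11685) differ —
#' characteristic of instances near the decision surface. Anything else
#' is *other*.
#'
#' @param attr an exact [Attribution-class].
#' @param probePair length-2 character vector of probe feature names.
#' @param tol equality tolerance (default 1e-9; exact-mode tables are
#'   rational so the default is safe).
#' @return `"uniform"`, `"boundary"` or `"other"`.
#' @export
classifySVPattern <- function(attr, probePair = c("11529", "11685"),
                              tol = 1e-9) {
  stopifnot(is(attr, "Attribution"))
  if (attr@method != "exact")
    stop("pattern taxonomy is defined for exact attributions")
  phi <- attr@phi
  if (!all(probePair %in% names(phi)))
    stop(
      "probe feature(s) absent: ",
      paste(setdiff(probePair, names(phi)), collapse = ", ")
    )
  if (diff(range(phi)) <= tol) return("uniform")
  if (abs(phi[probePair[1L]] - phi[probePair[2L]]) > tol) return("boundary")
  "other"
}

#' Per-feature reproducibility of Shapley values between two replicates
#'
#' In a scatter of replicate-a versus replicate-b Shapley values, perfect
#' reproducibility puts every point on the y = x line; the per-feature
#' discrepancy is the perpendicular distance to that line,
#' `|phi_a - phi_b| / sqrt(2)`.
#'
#' @param a,b exact [Attribution-class] objects for two replicates of the
#'   same sample (same feature panel).
#' @return Named numeric vector of perpendicular distances, one per feature.
#' @seealso [svReproducibilityHistogram()]
#' @export
replicateSVReproducibility <- function(a, b) {
  stopifnot(is(a, "Attribution"), is(b, "Attribution"))
  if (!setequal(names(a@phi), names(b@phi)))
    stop("attributions have mismatched feature sets")
  abs(a@phi - b@phi[names(a@phi)]) / sqrt(2)
}

#' Normalized histogram of replicate perpendicular distances
#'
#' Bins the pooled per-feature perpendicular distances of many samples and
#' normalizes counts by the total number of points (features x samples),
#' so the bin masses sum to 1 when all distances fall within the breaks.
#'
#' @param distances numeric vector (concatenated output of
#'   [replicateSVReproducibility()] across samples).
#' @param breaks numeric vector of bin edges covering the data.
#' @return data.frame with columns `lower`, `upper`, `count`,
#'   `normalized`.
#' @export
svReproducibilityHistogram <- function(distances,
                                       breaks = seq(0, 1.5, by = 0.05)) {
  h <- hist(distances, breaks = breaks, plot = FALSE)
  data.frame(
    lower = utils::head(breaks, -1L),
    upper = breaks[-1L],
    count = h$counts,
    normalized = h$counts / length(distances)
  )
}

#' @importFrom graphics hist
NULL
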