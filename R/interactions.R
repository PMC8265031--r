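# Pairwise interaction metrics over the subset-value lattice: Shapley
# interaction indices (SII), Shapley-Taylor interaction indices (STII),
# two-feature Harsanyi dividends (HD) and the asymmetric Shapley partial
# sum (SPS). All are evaluated from a cached SubsetValueTable, so the kNN
# is run only 2^m times per instance no matter how many metrics are asked
# for. All weights use exact integer factorials.

.pairCheck <- function(table, i, j, distinct = TRUE) {
  stopifnot(is(table, "SubsetValueTable"))
  feats <- table@features
  if (!i %in% feats) stop("unknown feature: ", i)
  if (!j %in% feats) stop("unknown feature: ", j)
  if (distinct && i == j)
    stop("i and j must be distinct features (use the main-effect form for i = j)")
  invisible(feats)
}

# masks of subsets S excluding features i and j, with |S| sizes
.masksExcluding <- function(table, i, j) {
  feats <- table@features
  m <- length(feats)
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  bi <- bits[match(i, feats)]
  bj <- bits[match(j, feats)]
  allMasks <- 0:(2^m - 1)
  S <- allMasks[bitwAnd(allMasks, bitwOr(bi, bj)) == 0L]
  list(S = S, sizes = .maskSize(S, m), bi = bi, bj = bj, m = m)
}

# weighted sum of the second difference f(S+ij) - f(S+i) - f(S+j) + f(S)
.secondDifferenceSum <- function(table, i, j, weightFun) {
  ex <- .masksExcluding(table, i, j)
  v <- table@values
  d2 <- v[bitwOr(ex$S, bitwOr(ex$bi, ex$bj)) + 1L] -
    v[bitwOr(ex$S, ex$bi) + 1L] -
    v[bitwOr(ex$S, ex$bj) + 1L] +
    v[ex$S + 1L]
  sum(weightFun(ex$sizes, ex$m) * d2)
}

#' Shapley interaction index of a feature pair
#'
#' `SII_ij = sum over S excluding i,j of
#' |S|! (m-|S|-2)! / (2 (m-1)!) * [f(S+ij) - f(S+i) - f(S+j) + f(S)]`.
#' The original pair-index normalization is kept; some treatments define
#' the index for the two-feature *subset* and hence double it — set
#' `doubled = TRUE` to match those.
#'
#' @param table a complete [SubsetValueTable-class].
#' @param i,j distinct feature names.
#' @param doubled logical; multiply by 2 for the subset-form convention.
#' @return numeric scalar; symmetric in `i`, `j`.
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' tab <- subsetValueTable(makeUniformInstance(refs, "Good"), refs)
#' siiPair(tab, "5843", "11529") # -1/14
#' @export
siiPair <- function(table, i, j, doubled = FALSE) {
  .pairCheck(table, i, j)
  out <- .secondDifferenceSum(table, i, j, function(s, m) {
    factorial(s) * factorial(m - s - 2) / (2 * factorial(m - 1))
  })
  if (doubled) 2 * out else out
}

#' Shapley interaction index main effect
#'
#' `SII_ii = psi_i - sum_{j != i} SII_ij`: the feature's Shapley value
#' minus all its pairwise interaction terms.
#'
#' @inheritParams siiPair
#' @param i a feature name.
#' @return numeric scalar.
#' @export
siiMain <- function(table, i) {
  .pairCheck(table, i, i, distinct = FALSE)
  phi <- .shapleyFromValues(table@values, table@features)
  others <- setdiff(table@features, i)
  phi[[i]] - sum(vapply(others, function(j) siiPair(table, i, j), numeric(1)))
}

#' Shapley-Taylor interaction index of a feature pair
#'
#' `STII_ij = sum over S excluding i,j of
#' 2 |S|! (m-|S|-1)! / m! * [f(S+ij) - f(S+i) - f(S+j) + f(S)]`.
#'
#' @inheritParams siiPair
#' @return numeric scalar; symmetric in `i`, `j`.
#' @export
stiiPair <- function(table, i, j) {
  .pairCheck(table, i, j)
  .secondDifferenceSum(table, i, j, function(s, m) {
    2 * factorial(s) * factorial(m - s - 1) / factorial(m)
  })
}

#' Shapley-Taylor main effect
#'
#' `STII_ii = f({i}) - f(empty)`: the single-feature classifier's value
#' relative to the null prediction. Together with the pairwise terms this
#' satisfies the second-order efficiency identity
#' `sum_i STII_ii + sum_{i<j} STII_ij = f(M) - f(empty)`.
#'
#' @inheritParams siiMain
#' @return numeric scalar.
#' @export
stiiMain <- function(table, i) {
  .pairCheck(table, i, i, distinct = FALSE)
  bi <- bitwShiftL(1L, match(i, table@features) - 1L)
  table@values[bi + 1L] - table@values[1L]
}

#' Two-feature Harsanyi dividend
#'
#' `HD_ij = f({i,j}) - f({i}) - f({j}) - 2 f(empty)`: the pure pairwise
#' synergy of i and j in isolation, ignoring larger coalitions.
#'
#' @inheritParams siiPair
#' @return numeric scalar; symmetric in `i`, `j`.
#' @export
harsanyiPair <- function(table, i, j) {
  .pairCheck(table, i, j)
  ex <- .masksExcluding(table, i, j)
  v <- table@values
  v[bitwOr(ex$bi, ex$bj) + 1L] - v[ex$bi + 1L] - v[ex$bj + 1L] - 2 * v[1L]
}

#' Shapley partial sum
#'
#' The part of feature j's Shapley value contributed by coalitions that
#' already contain feature i:
#' `SPS_ij = sum over S excluding i,j of
#' (m-|S|-2)! (|S|+1)! / m! * [f(S+ij) - f(S+i)]`.
#' Unlike SII, STII and HD this is generally *asymmetric*: if feature j
#' adds nothing once i is present but i still helps after j,
#' `SPS_ij = 0` while `SPS_ji != 0`.
#'
#' @inheritParams siiPair
#' @return numeric scalar (row index `i` conditions, column index `j` is
#'   attributed).
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' tab <- subsetValueTable(makeUniformInstance(refs, "Good"), refs)
#' sps(tab, "5843", "11529") # 0 for uniform instances
#' @export
sps <- function(table, i, j) {
  .pairCheck(table, i, j)
  ex <- .masksExcluding(table, i, j)
  v <- table@values
  w <- factorial(ex$m - ex$sizes - 2) * factorial(ex$sizes + 1) /
    factorial(ex$m)
  sum(w * (
    v[bitwOr(ex$S, bitwOr(ex$bi, ex$bj)) + 1L] -
      v[bitwOr(ex$S, ex$bi) + 1L]
  ))
}

#' Split a Shapley value by the presence of another feature
#'
#' Decomposes `psi_j` into the sum over coalitions that include feature i
#' (`withI`, which equals [sps()]`(table, i, j)`) and the sum over
#' coalitions that exclude it (`withoutI`); the two parts add back to
#' `psi_j`.
#'
#' @inheritParams siiPair
#' @return named numeric vector `c(withI = ..., withoutI = ...)`.
#' @export
shapleySplit <- function(table, i, j) {
  .pairCheck(table, i, j)
  ex <- .masksExcluding(table, i, j)
  v <- table@values
  wOut <- factorial(ex$sizes) * factorial(ex$m - ex$sizes - 1) /
    factorial(ex$m)
  withoutI <- sum(wOut * (v[bitwOr(ex$S, ex$bj) + 1L] - v[ex$S + 1L]))
  c(withI = sps(table, i, j), withoutI = withoutI)
}

#' Compute a full pairwise interaction matrix
#'
#' Evaluates one metric for every feature pair of the table. SII and STII
#' matrices carry their main effects on the diagonal; HD and SPS have no
#' defined diagonal (stored as `NA`, not zero). The SPS matrix is read as
#' `values[i, j]` = contribution of feature j within coalitions already
#' containing feature i.
#'
#' @param table a complete [SubsetValueTable-class].
#' @param metric `"SII"`, `"STII"`, `"HD"` or `"SPS"`.
#' @param doubled passed to [siiPair()] when `metric = "SII"`.
#' @return An [InteractionMatrix-class].
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' tab <- subsetValueTable(makeUniformInstance(refs, "Good"), refs)
#' interactionMatrix(tab, "STII")
#' @export
interactionMatrix <- function(table, metric = c("SII", "STII", "HD", "SPS"),
                              doubled = FALSE) {
  metric <- match.arg(metric)
  feats <- table@features
  m <- length(feats)
  vals <- matrix(NA_real_, m, m, dimnames = list(feats, feats))
  pairFun <- switch(metric,
    SII = function(i, j) siiPair(table, i, j, doubled = doubled),
    STII = function(i, j) stiiPair(table, i, j),
    HD = function(i, j) harsanyiPair(table, i, j),
    SPS = function(i, j) sps(table, i, j)
  )
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      vals[a, b] <- pairFun(feats[a], feats[b])
    }
  }
  diagDefined <- metric %in% c("SII", "STII")
  if (diagDefined) {
    mainFun <- if (metric == "SII") {
      function(i) siiMain(table, i)
    } else {
      function(i) stiiMain(table, i)
    }
    diag(vals) <- vapply(feats, mainFun, numeric(1))
  }
  new("InteractionMatrix",
    instanceId = table@instanceId, metric = metric,
    values = vals, diagonalDefined = diagDefined
  )
}
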