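# Feature subsets are represented internally as bitmasks over the panel's
# feature vector: bit i-1 (value 2^(i-1)) set <=> feature i is a member.
# The canonical human-facing enumeration is by subset size, then
# lexicographically by feature name.

.popcountTable <- local({
  cache <- new.env(parent = emptyenv())
  function(m) {
    key <- as.character(m)
    if (is.null(cache[[key]])) {
      masks <- 0:(2^m - 1)
      cache[[key]] <- vapply(
        masks,
        function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:(m - 1))) != 0L),
        integer(1)
      )
    }
    cache[[key]]
  }
})

.maskSize <- function(mask, m) .popcountTable(m)[mask + 1L]

.maskToFeatures <- function(mask, features) {
  m <- length(features)
  features[bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0L]
}

.featuresToMask <- function(subset, features) {
  if (length(subset) == 0L) return(0L)
  idx <- match(subset, features)
  if (anyNA(idx))
    stop(
      "unknown feature name(s): ",
      paste(subset[is.na(idx)], collapse = ", ")
    )
  if (anyDuplicated(idx)) stop("duplicated feature names in subset")
  sum(bitwShiftL(1L, idx - 1L))
}

# masks ordered by subset size, then lexicographically by feature names
.canonicalMaskOrder <- function(features) {
  m <- length(features)
  masks <- 0:(2^m - 1)
  keys <- vapply(
    masks,
    function(mk) paste(sort(.maskToFeatures(mk, features)), collapse = "+"),
    character(1)
  )
  masks[order(.maskSize(masks, m), keys)]
}

#' Look up the value of one feature subset
#'
#' @param table a [SubsetValueTable-class].
#' @param subset character vector of feature names (possibly empty).
#' @return The stored value f(S).
#' @examples
#' refs <- makeReferenceSet(cohortSpec(seed = 1))
#' inst <- makeUniformInstance(refs, "Good")
#' tab <- subsetValueTable(inst, refs)
#' subsetValue(tab, character(0)) # f(empty) = 0
#' subsetValue(tab, c("5843", "11529"))
#' @export
subsetValue <- function(table, subset) {
  stopifnot(is(table, "SubsetValueTable"))
  table@values[.featuresToMask(subset, table@features) + 1L]
}

#' @describeIn subsetValue feature names of a table, attribution, or
#'   interaction matrix.
#' @export
featureNames <- function(table) {
  if (is(table, "SubsetValueTable")) return(table@features)
  if (is(table, "Attribution")) return(names(table@phi))
  if (is(table, "InteractionMatrix")) return(rownames(table@values))
  stop("no feature names for objects of class ", class(table))
}

#' Export a subset-value table as a data frame
#'
#' Rows are ordered canonically: by subset size, then lexicographically by
#' the sorted feature names of the subset.
#'
#' @param table a [SubsetValueTable-class].
#' @return data.frame with columns `mask` (integer bitmask), `size`,
#'   `subset` ("+"-joined feature names, "" for the empty set) and `value`.
#' @export
subsetTableAsDataFrame <- function(table) {
  stopifnot(is(table, "SubsetValueTable"))
  feats <- table@features
  m <- length(feats)
  masks <- .canonicalMaskOrder(feats)
  data.frame(
    instance_id = table@instanceId,
    mask = masks,
    size = .maskSize(masks, m),
    subset = vapply(
      masks,
      function(mk) paste(sort(.maskToFeatures(mk, feats)), collapse = "+"),
      character(1)
    ),
    value = table@values[masks + 1L],
    stringsAsFactors = FALSE
  )
}
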