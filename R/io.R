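# CSV / JSON interchange. The CSV dialect has a header row
# sample_id,label,<feature...> for reference sets and
# instance_id[,replicate_id],<feature...> for instance tables.

#' Read a reference set from CSV
#'
#' Expects columns `sample_id`, `label` and one column per feature.
#'
#' @param path CSV file path.
#' @param k,distance classifier configuration (see [referenceSet()]).
#' @return A [ReferenceSet-class].
#' @seealso [writeReferenceSetCSV()]
#' @export
readReferenceSetCSV <- function(path, k = 7L, distance = "log-euclidean") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "label")
  if (!all(need %in% names(df)))
    stop("reference CSV must have columns sample_id and label")
  feats <- setdiff(names(df), need)
  X <- as.matrix(df[, feats, drop = FALSE])
  if (!is.numeric(X)) stop("feature columns must be numeric")
  rownames(X) <- df$sample_id
  referenceSet(X, df$label, k = k, distance = distance)
}

#' Write a reference set to CSV
#'
#' @param refs a [ReferenceSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReferenceSetCSV <- function(refs, path) {
  df <- data.frame(
    sample_id = rownames(refs@intensities),
    label = as.character(refs@label),
    refs@intensities,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an instance table from CSV
#'
#' Expects `instance_id`, optionally `replicate_id`, and one column per
#' feature; any `label` column is ignored.
#'
#' @param path CSV file path.
#' @return data.frame usable with [cohortInstance()].
#' @export
readInstancesCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"instance_id" %in% names(df))
    stop("instance CSV must have an instance_id column")
  df$label <- NULL
  featCols <- setdiff(names(df), c("instance_id", "replicate_id"))
  for (fc in featCols) {
    if (!is.numeric(df[[fc]]))
      stop("feature column '", fc, "' is not numeric")
  }
  df
}

#' Write an instance table to CSV
#'
#' @param instances data.frame as produced by [makeCohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeInstancesCSV <- function(instances, path) {
  write.csv(instances, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a subset-value table to CSV or JSON
#'
#' CSV columns: `instance_id`, `mask` (bitmask over the canonical feature
#' order), `size`, `subset`, `value`; JSON mirrors the same records plus
#' the feature order.
#'
#' @param table a [SubsetValueTable-class].
#' @param path output path; format chosen by extension (`.json` vs CSV).
#' @return `path`, invisibly.
#' @export
writeSubsetValueTable <- function(table, path) {
  df <- subsetTableAsDataFrame(table)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(
        instance_id = table@instanceId, mode = table@mode,
        features = table@features, subsets = df
      ),
      path,
      auto_unbox = TRUE, digits = NA
    )
  } else {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Flatten attributions to a long data frame
#'
#' @param attrs a single [Attribution-class] or a list of them.
#' @return data.frame with columns `instance_id`, `method`, `feature`,
#'   `phi`, `null_value`, `full_value`, `seed`, `n_samples`.
#' @export
attributionsAsDataFrame <- function(attrs) {
  if (is(attrs, "Attribution")) attrs <- list(attrs)
  do.call(rbind, lapply(attrs, function(a) {
    data.frame(
      instance_id = a@instanceId, method = a@method,
      feature = names(a@phi), phi = unname(a@phi),
      null_value = a@nullValue, full_value = a@fullValue,
      seed = a@seed, n_samples = a@nSamples,
      stringsAsFactors = FALSE
    )
  }))
}

#' Export attributions to CSV or JSON
#'
#' @param attrs a single [Attribution-class] or a list of them.
#' @param path output path; format chosen by extension (`.json` vs CSV).
#' @return `path`, invisibly.
#' @export
writeAttributions <- function(attrs, path) {
  if (is(attrs, "Attribution")) attrs <- list(attrs)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      lapply(attrs, function(a) {
        list(
          instance_id = a@instanceId, method = a@method,
          phi = as.list(a@phi), null_value = a@nullValue,
          full_value = a@fullValue, seed = a@seed, n_samples = a@nSamples
        )
      }),
      path,
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    write.csv(attributionsAsDataFrame(attrs), path,
      row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Flatten interaction matrices to a long data frame
#'
#' Undefined diagonal entries (HD, SPS) are omitted rather than written
#' as zeros.
#'
#' @param mats a single [InteractionMatrix-class] or a list of them.
#' @return data.frame with columns `instance_id`, `metric`, `feature_i`,
#'   `feature_j`, `value`.
#' @export
interactionsAsDataFrame <- function(mats) {
  if (is(mats, "InteractionMatrix")) mats <- list(mats)
  do.call(rbind, lapply(mats, function(im) {
    v <- im@values
    idx <- which(!is.na(v), arr.ind = TRUE)
    data.frame(
      instance_id = im@instanceId, metric = im@metric,
      feature_i = rownames(v)[idx[, 1L]],
      feature_j = colnames(v)[idx[, 2L]],
      value = v[idx],
      stringsAsFactors = FALSE
    )
  }))
}

#' Export interaction matrices to long CSV
#'
#' @param mats a single [InteractionMatrix-class] or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeInteractionsCSV <- function(mats, path) {
  write.csv(interactionsAsDataFrame(mats), path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
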