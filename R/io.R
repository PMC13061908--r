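#' Write a study to a directory of CSV files
#'
#' Serialises a \code{\link{feature_table}} as three plain CSV files:
#' \code{matrix.csv} (rows = samples, columns = features; censored cells as
#' the literal token \code{<LOD}), \code{samples.csv} and
#' \code{features.csv}. Values are written with enough digits for an exact
#' binary round trip.
#'
#' @param table a \code{\link{feature_table}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- matrix(sprintf("%.17g", table$values), nrow(table$values),
                 dimnames = dimnames(table$values))
  vals[table$below_lod] <- "<LOD"
  df <- data.frame(sample_id = table$samples$sample_id, vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file.path(dir, "matrix.csv"), row.names = FALSE)
  utils::write.csv(table$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(table$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a study from a directory of CSV files
#'
#' Reads the \code{matrix.csv} / \code{samples.csv} / \code{features.csv}
#' triplet written by \code{\link{write_study}} (or prepared externally in
#' the same layout), parsing \code{<LOD} tokens into the censoring mask and
#' validating the schema: aligned ids, numeric cells, complete metadata.
#'
#' @param dir directory containing the three files.
#' @param expected_time_points optional vector of allowed collection-point
#'   labels (and their order); any other label is an error.
#' @return a \code{\link{feature_table}}.
#' @export
read_study <- function(dir, expected_time_points = NULL) {
  paths <- file.path(dir, c("matrix.csv", "samples.csv", "features.csv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stop("missing study file(s): ", paste(miss, collapse = ", "))
  mat <- utils::read.csv(paths[1L], check.names = FALSE,
                         colClasses = "character")
  samples <- utils::read.csv(paths[2L], stringsAsFactors = FALSE)
  features <- utils::read.csv(paths[3L], stringsAsFactors = FALSE)
  if (names(mat)[1L] != "sample_id")
    stop("matrix.csv must start with a 'sample_id' column")
  ids <- mat$sample_id
  raw <- as.matrix(mat[, -1L, drop = FALSE])
  below <- raw == "<LOD"
  vals <- suppressWarnings(array(as.numeric(raw), dim(raw), dimnames(raw)))
  bad <- is.na(vals) & !below
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell in matrix.csv at sample '", ids[w[1L]],
         "', feature '", colnames(raw)[w[2L]], "'")
  }
  vals[below] <- NA_real_
  miss_meta <- setdiff(ids, samples$sample_id)
  if (length(miss_meta))
    stop("sample metadata missing for sample '", miss_meta[1L], "'")
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!setequal(colnames(raw), features$feature_id))
    stop("features.csv ids do not match the matrix columns")
  features <- features[match(colnames(raw), features$feature_id), ,
                       drop = FALSE]
  rownames(features) <- NULL
  if (!is.null(expected_time_points)) {
    unknown <- setdiff(unique(samples$time_point), expected_time_points)
    if (length(unknown))
      stop("unknown time-point label '", unknown[1L], "'")
  }
  feature_table(vals, samples, features, below_lod = below,
                time_levels = expected_time_points)
}
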