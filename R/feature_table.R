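#' Construct a feature table
#'
#' The central container of the pipeline: a samples x features concentration
#' matrix together with per-sample and per-feature metadata and an explicit
#' below-LOD (limit of detection) censoring mask. Concentrations are stored in
#' plain (unlogged) units; censored cells hold \code{NA} in the matrix and
#' \code{TRUE} in the mask.
#'
#' @param values numeric matrix, samples in rows and features in columns.
#'   Cells must be non-negative or \code{NA}; every \code{NA} cell must be
#'   flagged in \code{below_lod}.
#' @param samples data.frame with one row per matrix row and columns
#'   \code{sample_id}, \code{participant_id}, \code{group}
#'   (\code{"control"}/\code{"high-stress"}), \code{time_point}, \code{sex},
#'   \code{age_group}.
#' @param features data.frame with one row per matrix column and columns
#'   \code{feature_id}, \code{class} (\code{"metabolite"}, \code{"steroid"} or
#'   \code{"protein"}) plus, once QC metadata are attached, \code{recovery},
#'   \code{rsd} and \code{min_quantifiable}.
#' @param below_lod logical matrix with the dimensions of \code{values};
#'   \code{TRUE} marks a censored (below-LOD) cell. Defaults to
#'   \code{is.na(values)}.
#' @param time_levels character vector giving the collection-point order;
#'   defaults to the order of first appearance in \code{samples$time_point}.
#'
#' @return an object of class \code{feature_table}.
#' @export
feature_table <- function(values, samples, features,
                          below_lod = is.na(values),
                          time_levels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.data.frame(samples) || !is.data.frame(features))
    stop("'samples' and 'features' must be data frames")
  if (nrow(samples) != nrow(values))
    stop("sample metadata rows (", nrow(samples),
         ") do not match matrix rows (", nrow(values), ")")
  if (nrow(features) != ncol(values))
    stop("feature metadata rows (", nrow(features),
         ") do not match matrix columns (", ncol(values), ")")
  req_s <- c("sample_id", "participant_id", "group", "time_point")
  miss <- setdiff(req_s, names(samples))
  if (length(miss))
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("feature_id", "class") %in% names(features)))
    stop("feature metadata must contain 'feature_id' and 'class'")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  if (anyDuplicated(features$feature_id))
    stop("duplicated feature id: ",
         features$feature_id[duplicated(features$feature_id)][1L])
  if (anyDuplicated(samples[, c("participant_id", "time_point")]))
    stop("duplicated (participant, time point) pair in sample metadata")
  below_lod <- as.matrix(below_lod)
  if (!identical(dim(below_lod), dim(values)))
    stop("'below_lod' mask dimensions do not match the value matrix")
  bad <- is.na(values) & !below_lod
  if (any(bad))
    stop("matrix has NA cells not flagged below-LOD (first at row ",
         which(bad, arr.ind = TRUE)[1L, 1L], ")")
  if (any(values < 0, na.rm = TRUE))
    stop("negative concentration values are not allowed")
  rownames(values) <- samples$sample_id
  colnames(values) <- features$feature_id
  dimnames(below_lod) <- dimnames(values)
  if (is.null(time_levels))
    time_levels <- unique(as.character(samples$time_point))
  samples$time_point <- factor(as.character(samples$time_point),
                               levels = time_levels)
  if (anyNA(samples$time_point))
    stop("unknown time-point label in sample metadata")
  # group, sex and age must be constant within participant
  for (col in intersect(c("group", "sex", "age_group"), names(samples))) {
    n_lev <- tapply(as.character(samples[[col]]), samples$participant_id,
                    function(v) length(unique(v)))
    if (any(n_lev > 1L))
      stop("'", col, "' is not constant within participant ",
           names(n_lev)[which(n_lev > 1L)[1L]])
  }
  structure(list(values = values, samples = samples, features = features,
                 below_lod = below_lod),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "samples x", ncol(x$values),
      "features\n")
  cat("  participants:", length(unique(x$samples$participant_id)),
      " groups:", paste(levels(factor(x$samples$group)), collapse = "/"),
      "\n")
  cat("  time points: ", paste(levels(x$samples$time_point), collapse = ", "),
      "\n", sep = "")
  cls <- table(x$features$class)
  cat("  feature classes:",
      paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  n_cens <- sum(x$below_lod)
  cat("  below-LOD cells:", n_cens,
      sprintf("(%.1f%%)", 100 * n_cens / length(x$below_lod)), "\n")
  if (!is.null(x$truth))
    cat("  synthetic table with planted-effect registry\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table
#'
#' @param x a \code{feature_table}.
#' @param i sample index (logical, integer or sample ids).
#' @param j feature index (logical, integer or feature ids).
#' @param ... ignored.
#' @return the subsetted \code{feature_table}.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$features$feature_id)
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  out$below_lod <- x$below_lod[i, j, drop = FALSE]
  out$samples <- x$samples[i, , drop = FALSE]
  out$features <- x$features[j, , drop = FALSE]
  rownames(out$samples) <- NULL
  rownames(out$features) <- NULL
  out
}

## internal: samples of one stratum ("Rest", ..., or "All")
stratum_samples <- function(table, stratum) {
  tp <- levels(table$samples$time_point)
  if (identical(stratum, "All")) return(seq_len(nrow(table$values)))
  if (!stratum %in% tp)
    stop("unknown stratum '", stratum, "'; expected one of: ",
         paste(c(tp, "All"), collapse = ", "))
  which(as.character(table$samples$time_point) == stratum)
}

## internal: 0/1 high-stress indicator per sample row
group_indicator <- function(samples) {
  g <- as.character(samples$group)
  ok <- g %in% c("control", "high-stress")
  if (!all(ok)) stop("unknown group label: ", g[!ok][1L])
  as.integer(g == "high-stress")
}
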