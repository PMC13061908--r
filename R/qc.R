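#' Feature-inclusion filter
#'
#' Applies the analytical-validation inclusion criteria to metabolite-class
#' features: recovery within 100 +/- 30 percent (closed interval
#' \code{[70, 130]}), relative standard deviation at most 20 percent, and
#' detection (quantified above the LOD) in at least half of the samples of at
#' least one group. Steroid and protein features bypass the recovery/RSD
#' criteria, which belong to the metabolite platform's validation, but are
#' still subject to the detection criterion. Boundaries are inclusive;
#' \code{strict_boundaries = TRUE} switches to open intervals.
#'
#' @param table a \code{\link{feature_table}} with QC metadata.
#' @param recovery_range numeric length-2, allowed recovery interval.
#' @param rsd_max maximum allowed RSD.
#' @param detection_min minimum detection rate required in at least one group.
#' @param detection_scope \code{"pooled"} (default: a group's samples pooled
#'   across time points) or \code{"per_timepoint"} (criterion met if any
#'   group x time point cell reaches the rate).
#' @param strict_boundaries use open comparison at the interval boundaries.
#' @return a list with elements \code{table} (the filtered
#'   \code{feature_table}) and \code{report} (a \code{qc_filter_report}: one
#'   row per input feature with per-criterion pass flags).
#' @export
filter_features <- function(table, recovery_range = c(70, 130), rsd_max = 20,
                            detection_min = 0.5,
                            detection_scope = c("pooled", "per_timepoint"),
                            strict_boundaries = FALSE) {
  detection_scope <- match.arg(detection_scope)
  f <- table$features
  is_met <- f$class == "metabolite"
  if (any(is_met & (is.na(f$recovery) | is.na(f$rsd))))
    stop("metabolite feature without QC metadata: ",
         f$feature_id[is_met & (is.na(f$recovery) | is.na(f$rsd))][1L])

  cmp_ge <- if (strict_boundaries) `>` else `>=`
  cmp_le <- if (strict_boundaries) `<` else `<=`
  pass_recovery <- !is_met | (cmp_ge(f$recovery, recovery_range[1L]) &
                                cmp_le(f$recovery, recovery_range[2L]))
  pass_rsd <- !is_met | cmp_le(f$rsd, rsd_max)

  detected <- !table$below_lod
  grp <- as.character(table$samples$group)
  rate_by <- function(keep) colSums(detected[keep, , drop = FALSE]) / sum(keep)
  if (detection_scope == "pooled") {
    rates <- vapply(unique(grp), function(g) rate_by(grp == g),
                    numeric(ncol(detected)))
  } else {
    tp <- as.character(table$samples$time_point)
    cells <- unique(data.frame(grp, tp, stringsAsFactors = FALSE))
    rates <- vapply(seq_len(nrow(cells)),
                    function(i) rate_by(grp == cells$grp[i] &
                                          tp == cells$tp[i]),
                    numeric(ncol(detected)))
  }
  rates <- matrix(rates, nrow = ncol(detected))
  pass_detection <- apply(rates, 1L, function(r) any(cmp_ge(r, detection_min)))

  keep <- pass_recovery & pass_rsd & pass_detection
  report <- data.frame(feature_id = f$feature_id, class = f$class,
                       recovery = f$recovery, rsd = f$rsd,
                       detection_rate_max = apply(rates, 1L, max),
                       pass_recovery = pass_recovery, pass_rsd = pass_rsd,
                       pass_detection = pass_detection, retained = keep,
                       stringsAsFactors = FALSE)
  report$reason <- ifelse(keep, "", ifelse(!pass_recovery, "recovery",
                                           ifelse(!pass_rsd, "rsd",
                                                  "detection")))
  attr(report, "counts") <- c(input = nrow(f),
                              after_recovery_rsd = sum(pass_recovery &
                                                         pass_rsd),
                              retained = sum(keep))
  class(report) <- c("qc_filter_report", "data.frame")
  list(table = table[, which(keep)], report = report)
}

#' @export
print.qc_filter_report <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("qc_filter_report:", cnt["input"], "features ->", cnt["retained"],
      "retained\n")
  drop <- table(x$reason[x$reason != ""])
  if (length(drop))
    cat("  excluded:", paste(names(drop), drop, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Substitute below-LOD cells
#'
#' Replaces every censored (below-LOD) cell by one-fifth of that feature's
#' minimum quantifiable value; quantified cells are untouched and the
#' censoring mask is cleared.
#'
#' @param table a \code{\link{feature_table}}.
#' @return the table with all cells quantified.
#' @export
impute_below_lod <- function(table) {
  mq <- table$features$min_quantifiable
  if (is.null(mq) || anyNA(mq))
    stop("minimum quantifiable value missing for feature ",
         table$features$feature_id[is.na(mq)][1L])
  all_cens <- colSums(!table$below_lod) == 0L
  if (any(all_cens))
    warning("feature(s) entirely below LOD: ",
            paste(table$features$feature_id[all_cens], collapse = ", "))
  sub <- matrix(mq / 5, nrow(table$values), ncol(table$values), byrow = TRUE)
  table$values[table$below_lod] <- sub[table$below_lod]
  table$below_lod[] <- FALSE
  table
}

#' Z-score standardisation
#'
#' Centres and scales every feature to mean 0 and unit sample SD (n - 1)
#' across all samples. Constant features are mapped to all zeros with a
#' warning. The per-feature means and SDs are stored in the \code{scaling}
#' attribute so the transform is invertible.
#'
#' @param table an imputed \code{\link{feature_table}}.
#' @return the standardised table (values may be negative; the non-negativity
#'   check is bypassed through the stored class contract).
#' @export
zscore <- function(table) {
  if (any(table$below_lod))
    stop("z-scoring requires an imputed table (below-LOD cells remain)")
  x <- table$values
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  const <- sdv == 0 | is.na(sdv)
  if (any(const)) {
    warning("constant feature(s) mapped to zeros: ",
            paste(table$features$feature_id[const], collapse = ", "))
    sdv[const] <- 1
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  table$values <- z
  attr(table, "scaling") <- list(mean = mu, sd = sdv, constant = const)
  table
}

#' Invert a z-score transform
#'
#' @param table a table returned by \code{\link{zscore}}.
#' @return the table on the original concentration scale.
#' @export
unzscore <- function(table) {
  sc <- attr(table, "scaling")
  if (is.null(sc)) stop("table carries no scaling attribute")
  table$values <- sweep(sweep(table$values, 2L, sc$sd, "*"), 2L, sc$mean, "+")
  attr(table, "scaling") <- NULL
  table
}
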