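#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The statistic is the number
#' of (x, y) pairs with \code{x > y} plus half the tied pairs. The p-value is
#' computed by exact enumeration when both samples have at most eight
#' observations and no ties are present, and by the tie-corrected normal
#' approximation with continuity correction otherwise; the approximation
#' error at the study's group sizes is below 0.01 (checked against a
#' permutation oracle in the test suite).
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact_max largest per-sample size for which the exact distribution
#'   is enumerated (given no ties).
#' @return list with \code{statistic} (U) and \code{p}.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must contain at least one value")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment producing q-values in the input
#' order: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, clipped at 1.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table (the test used for the sex split of the study
#' demographics).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with \code{odds_ratio} (conditional MLE) and \code{p}.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("'tab' must be a 2x2 matrix of non-negative integer counts")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Cross-sectional group screen
#'
#' Compares high-stress against control for every feature within one stratum:
#' a single collection point, or \code{"median"}, where each participant
#' contributes the median of their per-time-point values. p-values come from
#' \code{\link{mann_whitney}}; q-values from \code{\link{bh_adjust}} applied
#' within the stratum's feature family (or across the supplied p-values
#' pooled over strata via \code{screen_all_strata}).
#'
#' @param table a filtered, imputed \code{\link{feature_table}}.
#' @param stratum a time-point label or \code{"median"}.
#' @return data.frame with columns \code{feature_id}, \code{stratum},
#'   \code{U}, \code{p}, \code{q}, \code{direction} (sign of high-stress
#'   minus control median).
#' @export
group_screen <- function(table, stratum) {
  tp <- levels(table$samples$time_point)
  if (!stratum %in% c(tp, "median"))
    stop("unknown stratum '", stratum, "'; expected one of: ",
         paste(c(tp, "median"), collapse = ", "))
  if (stratum == "median") {
    parts <- unique(table$samples$participant_id)
    x <- t(vapply(parts, function(p) {
      apply(table$values[table$samples$participant_id == p, , drop = FALSE],
            2L, stats::median)
    }, numeric(ncol(table$values))))
    grp <- table$samples$group[match(parts, table$samples$participant_id)]
  } else {
    keep <- as.character(table$samples$time_point) == stratum
    x <- table$values[keep, , drop = FALSE]
    grp <- table$samples$group[keep]
  }
  high <- as.character(grp) == "high-stress"
  res <- lapply(seq_len(ncol(x)), function(j) {
    mw <- mann_whitney(x[high, j], x[!high, j])
    data.frame(feature_id = colnames(x)[j], stratum = stratum,
               U = mw$statistic, p = mw$p,
               direction = sign(stats::median(x[high, j]) -
                                  stats::median(x[!high, j])),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res[, c("feature_id", "stratum", "U", "p", "q", "direction")]
}

#' Screen every stratum
#'
#' Runs \code{\link{group_screen}} for each collection point and the
#' per-participant median analysis. With \code{bh_family = "stratum"}
#' (default) q-values are corrected within each stratum's feature family;
#' with \code{"pooled"} one correction is applied across all strata.
#'
#' @param table a filtered, imputed \code{\link{feature_table}}.
#' @param bh_family \code{"stratum"} or \code{"pooled"}.
#' @return row-bound data.frame of per-stratum results.
#' @export
screen_all_strata <- function(table, bh_family = c("stratum", "pooled")) {
  bh_family <- match.arg(bh_family)
  strata <- c(levels(table$samples$time_point), "median")
  out <- do.call(rbind, lapply(strata, function(s) group_screen(table, s)))
  if (bh_family == "pooled") out$q <- bh_adjust(out$p)
  out
}
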