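#' Friedman test on a complete block design
#'
#' Rank-based omnibus test of a time-point effect with participants as
#' blocks, using the tie-corrected chi-square statistic on k - 1 degrees of
#' freedom (ties arise routinely from below-LOD substitution). When every
#' participant's values are completely tied the statistic is 0 and p is 1.
#'
#' @param block_matrix numeric matrix, participants in rows, time points in
#'   columns, no missing cells.
#' @return list with \code{statistic} and \code{p}.
#' @export
friedman <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m))
    stop("missing cell in the block matrix; the design must be complete")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 participants and 2 time points")
  n <- nrow(m); k <- ncol(m)
  # the tie-correction denominator vanishes when every row is fully tied
  all_tied <- all(apply(m, 1L, function(row) length(unique(row)) == 1L))
  if (all_tied) return(list(statistic = 0, p = 1))
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), p = ft$p.value)
}

#' Nemenyi post-hoc test
#'
#' All-pairs comparison of time points following a Friedman test: for each
#' pair the statistic is the absolute difference in average within-block
#' ranks divided by \eqn{\sqrt{k(k+1)/(6n)}}, referred to the studentized
#' range distribution (k means, infinite df) after scaling by \eqn{\sqrt 2}.
#'
#' @param block_matrix numeric matrix as in \code{\link{friedman}}.
#' @return data.frame with columns \code{t1}, \code{t2}, \code{statistic},
#'   \code{p} (one row per unordered time-point pair).
#' @export
nemenyi_posthoc <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m))
    stop("missing cell in the block matrix; the design must be complete")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 participants and 2 time points")
  n <- nrow(m); k <- ncol(m)
  rbar <- colMeans(t(apply(m, 1L, rank)))
  cn <- colnames(m); if (is.null(cn)) cn <- paste0("t", seq_len(k))
  pairs <- utils::combn(k, 2L)
  se <- sqrt(k * (k + 1) / (6 * n))
  out <- data.frame(
    t1 = cn[pairs[1L, ]], t2 = cn[pairs[2L, ]],
    statistic = abs(rbar[pairs[1L, ]] - rbar[pairs[2L, ]]) / se,
    stringsAsFactors = FALSE)
  out$p <- pmin(1, stats::ptukey(out$statistic * sqrt(2), nmeans = k,
                                 df = Inf, lower.tail = FALSE))
  rownames(out) <- NULL
  out
}

#' Longitudinal screen over all features
#'
#' For each feature, builds the participants x time-points block matrix for
#' the chosen cohort, applies \code{\link{friedman}} (with Benjamini-Hochberg
#' correction across features) and \code{\link{nemenyi_posthoc}}, and records
#' per-interval cohort-median percent changes.
#'
#' @param table a filtered, imputed \code{\link{feature_table}}.
#' @param cohort \code{"all"}, \code{"control"} or \code{"high-stress"}.
#' @return list with \code{omnibus} (feature, statistic, p, q) and
#'   \code{intervals} (feature x interval rows: Nemenyi p, median percent
#'   change, direction).
#' @export
longitudinal_screen <- function(table,
                                cohort = c("all", "control", "high-stress")) {
  cohort <- match.arg(cohort)
  keep <- if (cohort == "all") rep(TRUE, nrow(table$values))
  else as.character(table$samples$group) == cohort
  s <- table$samples[keep, , drop = FALSE]
  v <- table$values[keep, , drop = FALSE]
  tp <- levels(table$samples$time_point)
  parts <- unique(s$participant_id)
  ridx <- vapply(tp, function(t)
    match(paste(parts, t), paste(s$participant_id, s$time_point)),
    integer(length(parts)))
  if (anyNA(ridx)) stop("incomplete design: a participant misses a time point")

  omni <- vector("list", ncol(v))
  ints <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    bm <- matrix(v[ridx, j], ncol = length(tp),
                 dimnames = list(NULL, tp))
    fr <- friedman(bm)
    ne <- nemenyi_posthoc(bm)
    med <- apply(bm, 2L, stats::median)
    chg <- (med[match(ne$t2, tp)] - med[match(ne$t1, tp)]) /
      med[match(ne$t1, tp)]
    omni[[j]] <- data.frame(feature_id = colnames(v)[j], cohort = cohort,
                            statistic = fr$statistic, p = fr$p,
                            stringsAsFactors = FALSE)
    ints[[j]] <- data.frame(feature_id = colnames(v)[j], cohort = cohort,
                            interval = paste(ne$t1, "->", ne$t2),
                            t1 = ne$t1, t2 = ne$t2, nemenyi_p = ne$p,
                            pct_change = 100 * chg, direction = sign(chg),
                            stringsAsFactors = FALSE)
  }
  omni <- do.call(rbind, omni)
  omni$q <- bh_adjust(omni$p)
  intervals <- do.call(rbind, ints)
  rownames(intervals) <- NULL
  list(omnibus = omni, intervals = intervals)
}

#' Interval-level change summary
#'
#' Counts and lists, per time-point interval, the features whose Nemenyi
#' q-value (Benjamini-Hochberg across the feature family within each
#' interval) falls below \code{alpha}, and the highlighted subset whose
#' cohort-median percent change is at least \code{magnitude} in absolute
#' value.
#'
#' @param table a filtered, imputed \code{\link{feature_table}}.
#' @param cohort \code{"all"}, \code{"control"} or \code{"high-stress"}.
#' @param alpha significance level on the interval q-values.
#' @param magnitude minimum absolute fractional change (0.30 = 30 percent)
#'   for the highlighted subset.
#' @return list with \code{detail} (all significant feature x interval rows,
#'   logical \code{highlighted} column) and \code{counts} (per interval:
#'   significant and highlighted feature counts).
#' @export
interval_summary <- function(table,
                             cohort = c("all", "control", "high-stress"),
                             alpha = 0.05, magnitude = 0.30) {
  if (magnitude < 0) stop("'magnitude' must be non-negative")
  cohort <- match.arg(cohort)
  scr <- longitudinal_screen(table, cohort)
  iv <- scr$intervals
  iv$nemenyi_q <- stats::ave(iv$nemenyi_p, iv$interval,
                             FUN = bh_adjust)
  iv$significant <- iv$nemenyi_q < alpha
  iv$highlighted <- iv$significant & abs(iv$pct_change) >= 100 * magnitude
  detail <- iv[iv$significant, , drop = FALSE]
  rownames(detail) <- NULL
  counts <- stats::aggregate(cbind(significant, highlighted) ~ interval,
                             data = iv, FUN = sum)
  list(detail = detail, counts = counts)
}
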