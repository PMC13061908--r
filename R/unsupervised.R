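#' Principal component analysis of a standardised table
#'
#' Eigen decomposition of the feature covariance of a z-scored table (via
#' the singular value decomposition), with a deterministic sign convention:
#' each loading vector is flipped so its largest-magnitude entry is
#' positive.
#'
#' @param table a z-scored \code{\link{feature_table}} (or a plain numeric
#'   matrix, samples in rows).
#' @param n_components number of components to keep (defaults to the rank).
#' @return an object of class \code{pca_result}: \code{scores} (samples x
#'   components), \code{loadings} (features x components, orthonormal) and
#'   \code{explained} (variance fractions, non-increasing).
#' @export
pca <- function(table, n_components = NULL) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-12)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds the matrix rank (",
         rank, ")")
  keep <- seq_len(n_components)
  load <- pr$rotation[, keep, drop = FALSE]
  flip <- vapply(seq_len(ncol(load)), function(j)
    sign(load[which.max(abs(load[, j])), j]), numeric(1))
  load <- sweep(load, 2L, flip, "*")
  scores <- sweep(pr$x[, keep, drop = FALSE], 2L, flip, "*")
  structure(list(scores = scores, loadings = load,
                 explained = pr$sdev[keep]^2 / sum(pr$sdev^2),
                 center = pr$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5L)),
            collapse = ", "),
      if (length(x$explained) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Group confidence ellipses on a 2-D score plot
#'
#' For each group, an ellipse from the group mean and sample covariance
#' scaled by the chi-square(2 df) quantile at the chosen level (the usual
#' large-sample score-plot region; \code{small_sample = TRUE} switches to
#' the F-based Hotelling region). Each point is flagged inside/outside its
#' own group's ellipse by its squared Mahalanobis distance.
#'
#' @param scores two-column matrix of component scores.
#' @param grouping factor-like grouping of the rows.
#' @param level confidence level.
#' @param small_sample use the F-based small-sample region.
#' @return list with \code{ellipses} (per group: center, covariance, radius
#'   scale, axes, \code{degenerate} flag) and \code{inside} (logical per
#'   point).
#' @export
confidence_ellipse <- function(scores, grouping, level = 0.95,
                               small_sample = FALSE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("'scores' must have exactly two columns")
  grouping <- as.factor(grouping)
  inside <- rep(NA, nrow(scores))
  ell <- list()
  for (g in levels(grouping)) {
    i <- which(grouping == g)
    if (length(i) < 3L) stop("group '", g, "' has fewer than 3 points")
    m <- colMeans(scores[i, , drop = FALSE])
    S <- stats::cov(scores[i, , drop = FALSE])
    n <- length(i)
    r2 <- if (small_sample)
      2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
    else stats::qchisq(level, df = 2)
    eg <- eigen(S, symmetric = TRUE)
    degenerate <- any(eg$values <= max(eg$values, 0) * 1e-12)
    d2 <- if (degenerate) {
      # pseudo-inverse Mahalanobis along the non-null directions
      pos <- eg$values > max(eg$values, .Machine$double.eps) * 1e-12
      cent <- sweep(scores[i, , drop = FALSE], 2L, m)
      proj <- cent %*% eg$vectors
      if (any(pos))
        rowSums(sweep(proj[, pos, drop = FALSE]^2, 2L,
                      eg$values[pos], "/"))
      else rep(0, length(i))
    } else {
      stats::mahalanobis(scores[i, , drop = FALSE], m, S)
    }
    inside[i] <- d2 <= r2
    ell[[g]] <- list(center = m, cov = S, radius2 = r2,
                     axes = sqrt(pmax(eg$values, 0) * r2),
                     angle = atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]),
                     degenerate = degenerate, n = n)
  }
  list(ellipses = ell, inside = inside)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the table's rows with Euclidean distances
#' and Ward's minimum-variance linkage (the \code{ward.D2} form, which
#' takes unsquared distances).
#'
#' @param table a z-scored \code{\link{feature_table}} or numeric matrix.
#' @return an \code{hclust} object (merge heights are monotone
#'   non-decreasing; leaf order via \code{$order}).
#' @export
ward_cluster <- function(table) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}
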