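#' Covariate-adjusted logistic fit of a marker
#'
#' Fits logistic regressions of the high-stress indicator on a marker score
#' without (marker only) and with sex and age-group covariates, and reports
#' per-term odds ratios with Wald confidence intervals. With 16 participants
#' per group and a strong marker, (quasi-)complete separation is likely; it
#' is detected from diverging coefficients or boundary fitted probabilities
#' and handled by refitting with Firth's bias-reducing penalised likelihood,
#' surfaced through the \code{separation} flag rather than hidden.
#'
#' @param scores one marker score per participant (e.g. a metabolite ratio;
#'   scale-dependent, so odds-ratio magnitudes depend on the units).
#' @param labels 0/1 high-stress indicator or logical.
#' @param sex,age_group categorical covariates, one value per participant.
#' @param level confidence level of the Wald intervals.
#' @return an object of class \code{adjusted_fit}: \code{adjusted} and
#'   \code{unadjusted} coefficient tables (estimate, odds ratio, CI, p),
#'   plus \code{separation} and \code{converged} flags.
#' @export
logistic_adjust <- function(scores, labels, sex, age_group, level = 0.95) {
  y <- as.integer(labels)
  if (!all(y %in% 0:1)) stop("labels must be binary")
  dat <- data.frame(y = y, score = as.numeric(scores),
                    sex = factor(sex), age_group = factor(age_group))
  drop_const <- vapply(dat[c("sex", "age_group")],
                       function(v) length(unique(v)) < 2L, logical(1))
  const_score <- length(unique(dat$score)) < 2L
  rhs <- c(if (!const_score) "score", names(drop_const)[!drop_const])
  if (!length(rhs)) rhs <- "1"
  form_adj <- stats::reformulate(rhs, response = "y")

  fit_one <- function(formula) {
    fit <- suppressWarnings(stats::glm(formula, family = stats::binomial(),
                                       data = dat))
    p_hat <- stats::fitted(fit)
    sep <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
      any(p_hat < 1e-8 | p_hat > 1 - 1e-8)
    if (sep) {
      ff <- firth_logistic(stats::model.matrix(formula, dat), dat$y)
      list(coef = ff$coef, vcov = ff$vcov, separation = TRUE,
           converged = ff$converged)
    } else {
      list(coef = stats::coef(fit), vcov = stats::vcov(fit),
           separation = FALSE, converged = fit$converged)
    }
  }
  ctable <- function(f) {
    se <- sqrt(diag(f$vcov))
    zq <- stats::qnorm(1 - (1 - level) / 2)
    out <- data.frame(term = names(f$coef), estimate = unname(f$coef),
                      odds_ratio = exp(unname(f$coef)),
                      or_lo = exp(unname(f$coef) - zq * se),
                      or_hi = exp(unname(f$coef) + zq * se),
                      p = 2 * stats::pnorm(-abs(unname(f$coef) / se)),
                      stringsAsFactors = FALSE)
    if (const_score)  # an uninformative marker carries no association
      out <- rbind(out, data.frame(term = "score", estimate = 0,
                                   odds_ratio = 1, or_lo = NA_real_,
                                   or_hi = NA_real_, p = 1))
    out
  }
  fa <- fit_one(form_adj)
  fu <- fit_one(if (const_score) y ~ 1 else y ~ score)
  structure(list(adjusted = ctable(fa), unadjusted = ctable(fu),
                 separation = fa$separation || fu$separation,
                 converged = fa$converged && fu$converged,
                 dropped_constant = names(drop_const)[drop_const]),
            class = "adjusted_fit")
}

#' @export
print.adjusted_fit <- function(x, ...) {
  cat("adjusted_fit (logistic regression of high-stress status)\n")
  if (x$separation)
    cat("  NOTE: separation detected; Firth penalised likelihood used\n")
  if (length(x$dropped_constant))
    cat("  constant covariate(s) dropped:",
        paste(x$dropped_constant, collapse = ", "), "\n")
  cat("unadjusted (marker only):\n")
  print(x$unadjusted, digits = 3)
  cat("adjusted for covariates:\n")
  print(x$adjusted, digits = 3)
  invisible(x)
}

## Firth bias-reduced logistic regression: Fisher scoring on the modified
## score U*(b) = X' (y - p + h (1/2 - p)), h the leverage under W = p(1-p).
firth_logistic <- function(X, y, max_iter = 200L, tol = 1e-8) {
  b <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XW <- X * W
    info <- crossprod(X, XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(inv %*% U)
    # dampen long steps to keep the iteration stable near separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% b)
  W <- stats::plogis(eta) * (1 - stats::plogis(eta))
  vc <- solve(crossprod(X, X * W))
  list(coef = stats::setNames(b, colnames(X)), vcov = vc,
       converged = converged)
}

#' Sex-stratified marker comparison
#'
#' Compares high-stress against control within each sex stratum by the
#' Mann-Whitney U test and reports whether the direction of the median
#' difference is consistent across strata.
#'
#' @param scores one marker score per participant.
#' @param labels 0/1 high-stress indicator or logical.
#' @param sex stratum label per participant.
#' @return list with \code{strata} (data.frame: sex, n, U, p, direction) and
#'   \code{consistent} (TRUE when all testable strata share one direction).
#' @export
stratified_compare <- function(scores, labels, sex) {
  y <- as.integer(labels)
  res <- lapply(unique(as.character(sex)), function(s) {
    i <- as.character(sex) == s
    if (length(unique(y[i])) < 2L) {
      warning("stratum '", s, "' lacks one of the groups; skipped")
      return(NULL)
    }
    mw <- mann_whitney(scores[i & y == 1L], scores[i & y == 0L])
    data.frame(sex = s, n = sum(i), U = mw$statistic, p = mw$p,
               direction = sign(stats::median(scores[i & y == 1L]) -
                                  stats::median(scores[i & y == 0L])),
               stringsAsFactors = FALSE)
  })
  strata <- do.call(rbind, res)
  consistent <- !is.null(strata) && nrow(strata) > 0L &&
    length(unique(strata$direction)) == 1L
  list(strata = strata, consistent = consistent)
}
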