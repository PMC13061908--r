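test_that("AUC matches pair enumeration and equals normalised U", {
  expect_equal(auc(c(3, 1, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(14)
  for (i in 1:300) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    s <- round(rnorm(n1 + n0), 1)  # ties on purpose
    y <- c(rep(1, n1), rep(0, n0))
    u <- mann_whitney(s[y == 1], s[y == 0])$statistic
    expect_equal(auc(s, y), u / (n1 * n0))
  }
})

test_that("Youden fit equals the brute-force threshold maximum", {
  brute_J <- function(s, y) {
    su <- sort(unique(s))
    cuts <- c(-Inf, (su[-1] + su[-length(su)]) / 2, Inf)
    best <- -Inf
    for (cc in cuts) for (o in c(1L, -1L)) {
      pred <- if (o == 1L) s >= cc else s < cc
      J <- mean(pred[y == 1]) + mean(!pred[y == 0]) - 1
      best <- max(best, J)
    }
    best
  }
  f <- youden_fit(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(f$cutoff, 2.5)
  expect_equal(f$J, 1)
  expect_equal(f$orientation, 1L)

  set.seed(15)
  for (i in 1:500) {
    n <- sample(6:24, 1)
    s <- round(rnorm(n), sample(0:1, 1))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    f <- suppressWarnings(youden_fit(s, y))
    expect_equal(f$J, brute_J(s, y))
    # the reported cutoff attains the reported J
    pred <- if (f$orientation == 1L) s >= f$cutoff else s < f$cutoff
    expect_equal(mean(pred[y == 1]) + mean(!pred[y == 0]) - 1, f$J)
  }
})

test_that("degenerate scores yield J = 0 with a warning", {
  expect_warning(f <- youden_fit(rep(2, 6), c(0, 1, 0, 1, 0, 1)),
                 "degenerate")
  expect_equal(f$J, 0)
})

test_that("reciprocal ratios with flipped orientation predict identically", {
  set.seed(16)
  for (i in 1:200) {
    n <- sample(8:20, 1)
    s <- exp(rnorm(n))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    # a fixed model on s versus its reciprocal counterpart on 1/s:
    # cutoff at a midpoint (never equal to a score), orientation flipped
    cut <- mean(sample(s, 2))
    p_high <- s >= cut
    p_recip <- !(1 / s >= 1 / cut)  # low orientation at the inverted cutoff
    expect_identical(p_high, p_recip)
    # refitting on the reciprocal attains the same optimum J
    f1 <- suppressWarnings(youden_fit(s, y))
    f2 <- suppressWarnings(youden_fit(1 / s, y))
    expect_equal(f1$J, f2$J)
  }
})

test_that("DeLong matches pROC's variance and handles degeneracies", {
  skip_if_not_installed("pROC")
  dl <- delong_test(c(1, 2, 3, 4), c(1, 0, 0, 1))
  expect_equal(dl$auc, 0.5)
  expect_equal(dl$z, 0)
  expect_equal(dl$p, 0.5)
  perf <- delong_test(c(1, 2, 10, 11, 12), c(0, 0, 1, 1, 1))
  expect_true(perf$degenerate)
  expect_equal(perf$p, 0)

  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    s <- c(rnorm(n1, 1), rnorm(n0))
    y <- c(rep(1, n1), rep(0, n0))
    r <- pROC::roc(y, s, direction = "<", quiet = TRUE)
    dl <- delong_test(s, y)
    expect_equal(dl$auc, as.numeric(pROC::auc(r)))
    expect_equal(dl$variance, as.numeric(pROC::var(r, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("threshold_model fits, prints, predicts and transfers on itself", {
  tab <- default_imputed()
  m <- threshold_model(tab, "met001", "met002", "Rest")
  expect_s3_class(m, "threshold_model")
  expect_equal(m$direction, "down")  # lower ratio associates with stress
  expect_gt(m$auc, 0.9)
  expect_lt(m$delong$p, 0.01)
  expect_output(print(m), "met001/met002")
  expect_equal(unname(coef(m)["cutoff"]), m$cutoff)

  pred <- predict(m)
  expect_equal(length(pred), 32L)
  # transfer to the training stratum reproduces the full-data confusion
  tr <- transfer_evaluate(m, tab, "Rest")
  acc_full <- (m$sensitivity * m$n1 + m$specificity * (m$n - m$n1)) / m$n
  expect_equal(tr$accuracy, acc_full)
  expect_equal(tr$auc, m$auc)
  expect_error(threshold_model(tab, "nope", NULL, "Rest"), "not found")
  expect_error(threshold_model(tab, "met001", "met001", "Rest"),
               "must differ")
})

test_that("a time-invariant marker transfers; a Rest-only marker does not", {
  tab <- default_imputed()
  m <- threshold_model(tab, "met001", "met002", "Rest")
  tr <- transfer_evaluate(m, tab)
  expect_true(all(tr$f1[tr$stratum != "Rest"] > 0.6))

  k <- 4L
  rest_only <- list(
    list(feature = "met001", group_effect = 0,
         time_offsets = c(-1.5, 0, 0, 0), cohort = "high-stress"))
  cfg <- generator_config(n_per_group = 12L, n_metabolites = 10L,
                          n_steroids = 0L, n_proteins = 0L,
                          planted_effects = rest_only, pair_correlation = 0.9,
                          sex_effect_sd = 0, age_effect_sd = 0,
                          lod_quantile = 0, seed = 23L)
  t2 <- impute_below_lod(generate_study(cfg))
  m2 <- threshold_model(t2, "met001", "met002", "Rest")
  tr2 <- transfer_evaluate(m2, t2)
  f1_train <- tr2$f1[tr2$stratum == "Rest"]
  expect_true(all(tr2$f1[tr2$stratum != "Rest"] < f1_train))
})

test_that("LOOCV is permutation invariant and perfect on separated data", {
  cfg <- small_config(seed = 61L, delta = 3, lod_quantile = 0)
  tab <- impute_below_lod(generate_study(cfg))
  ev <- loocv_evaluate(tab, "met001", "met002", "Rest")
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$f1, 1)
  expect_equal(ev$auc, 1)

  tab2 <- small_imputed()
  ev1 <- loocv_evaluate(tab2, "met001", "met002", "Rest")
  set.seed(99)
  perm <- sample(nrow(tab2$values))
  ev2 <- loocv_evaluate(tab2[perm, ], "met001", "met002", "Rest")
  expect_equal(ev1$accuracy, ev2$accuracy)
  expect_equal(ev1$f1, ev2$f1)
  expect_equal(ev1$auc, ev2$auc)
})

test_that("pooled-stratum LOOCV groups a participant's samples", {
  tab <- small_imputed()
  ev <- loocv_evaluate(tab, "met001", "met002", "All")
  expect_equal(length(ev$score), 16L)  # one held-out score per participant
  expect_true(all(ev$prediction %in% c(0L, 1L)))
})

test_that("bootstrap evaluation is deterministic and internally coherent", {
  tab <- small_imputed()
  a <- bootstrap_loocv(tab, "met003", "met004", "Rest", n_boot = 20,
                       seed = 5)
  b <- bootstrap_loocv(tab, "met003", "met004", "Rest", n_boot = 20,
                       seed = 5)
  expect_identical(a[c("auc", "accuracy", "f1")],
                   b[c("auc", "accuracy", "f1")])
  c <- bootstrap_loocv(tab, "met003", "met004", "Rest", n_boot = 20,
                       seed = 6)
  expect_false(identical(a$auc, c$auc))
  for (v in list(a$auc, a$accuracy, a$f1)) {
    expect_true(v[2] <= v[1] && v[1] <= v[3])
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(bootstrap_loocv(tab, "met001", "met002", "Rest", n_boot = 1),
               "n_boot")
})

test_that("null LOOCV accuracy centres on chance; bootstrap CIs usually cover", {
  accs <- cover <- numeric(40)
  for (s in 1:40) {
    tab <- impute_below_lod(generate_study(
      null_config(seed = s + 9000L, n_per_group = 8L, n_metabolites = 6L,
                  n_steroids = 0L, n_proteins = 0L)))
    accs[s] <- loocv_evaluate(tab, "met001", NULL, "Rest")$accuracy
    b <- bootstrap_loocv(tab, "met001", NULL, "Rest", n_boot = 25L,
                         seed = s)
    cover[s] <- b$auc[2] <= 0.5 && 0.5 <= b$auc[3]
  }
  expect_lt(abs(mean(accs) - 0.5), 0.08)
  # percentile intervals around a cross-validated AUC undercover the
  # population value at these group sizes; they should still bracket 0.5
  # in the majority of null cohorts
  expect_gte(mean(cover), 0.5)
})

test_that("the search enumerates canonical candidates and ranks the marker", {
  tab <- small_imputed()
  singles <- search_models(tab, "Rest", "single", n_boot = 10, seed = 2)
  ratios <- search_models(tab, "Rest", "ratio", n_boot = 10, seed = 2)
  expect_equal(nrow(singles), 20L)
  expect_equal(nrow(ratios), choose(20L, 2L))
  expect_false(any(duplicated(ratios$spec)))
  expect_equal(ratios$spec[1], "met001/met002")
  expect_gt(ratios$auc_mean[1], singles$auc_mean[1])
  # search rows reproduce the single-candidate evaluation
  one <- bootstrap_loocv(tab, "met001", "met002", "Rest", n_boot = 10,
                         seed = 2)
  i <- which(ratios$spec == "met001/met002")
  expect_equal(ratios$auc_mean[i], unname(one$auc["mean"]))
  expect_equal(ratios$f1_lo[i], unname(one$f1[2]))
})

test_that("mean resampled AUC does not beat the full-data AUC materially", {
  tab <- small_imputed()
  rk <- search_models(tab, "Rest", "ratio", n_boot = 20, seed = 4)
  i <- which(rk$spec == "met001/met002")
  expect_lte(rk$auc_mean[i], rk$full_auc[i] + 0.05)
})

test_that("selection applies strict per-stratum CI lower bounds", {
  row <- function(auc_lo, acc_lo = 0.64, f1_lo = 0.667, stratum = "Rest") {
    structure(data.frame(feature = "a", denominator = "b", spec = "a/b",
                         stratum = stratum, auc_mean = 0.85,
                         auc_lo = auc_lo, auc_hi = 0.97,
                         accuracy_mean = 0.8, accuracy_lo = acc_lo,
                         accuracy_hi = 0.94, f1_mean = 0.83, f1_lo = f1_lo,
                         f1_hi = 0.95, full_auc = 0.86, delong_p = 0.04,
                         direction = "down", stringsAsFactors = FALSE),
              stratum = stratum)
  }
  expect_equal(nrow(select_models(row(0.60), "Rest")), 0L)     # strict >
  expect_equal(nrow(select_models(row(0.669), "Rest")), 1L)
  expect_equal(nrow(select_models(row(0.63), "Post-WM")), 0L)  # bar 0.65
  expect_equal(nrow(select_models(row(0.66), "Post-WM")), 1L)
  expect_equal(nrow(select_models(row(0.52), "All")), 1L)      # bar 0.50
  expect_equal(nrow(select_models(row(0.8, acc_lo = 0.5), "Rest")), 0L)
  expect_error(select_models(row(0.8), "Lunch"), "unknown stratum")
})
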