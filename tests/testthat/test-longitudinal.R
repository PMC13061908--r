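test_that("Friedman statistic matches hand-computed ranks", {
  m <- matrix(rep(c(1, 2, 3), each = 3), 3)  # every row ranked 1,2,3
  fr <- friedman(m)
  expect_equal(fr$statistic, 6.0)  # 12/(3*3*4)*(9+36+81) - 3*3*4
  # all rows constant: complete ties
  fr0 <- friedman(matrix(5, 4, 3))
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p, 1)
  expect_error(friedman(matrix(c(1, NA, 2, 3), 2)), "missing cell")
  expect_error(friedman(matrix(1:3, 1)), "at least 2")
})

test_that("Friedman p-values are calibrated under the null", {
  set.seed(500)
  pvals <- replicate(500, friedman(matrix(rnorm(64), 16, 4))$p)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})

test_that("Friedman is invariant to monotone transforms within participants", {
  set.seed(4)
  m <- matrix(rexp(48), 12, 4)
  expect_equal(friedman(m)$statistic, friedman(exp(m))$statistic)
  expect_equal(friedman(m)$statistic, friedman(log(m))$statistic)
})

test_that("Nemenyi post-hoc detects the shifted time point and is symmetric", {
  m <- matrix(5, 10, 4)
  ne0 <- nemenyi_posthoc(m + rnorm(40, 0, 1e-12))
  expect_equal(nrow(ne0), 6L)
  set.seed(8)
  base <- matrix(rnorm(40), 10, 4)
  shifted <- base; shifted[, 3] <- shifted[, 3] + 3
  ne <- nemenyi_posthoc(shifted)
  worst <- ne[which.min(ne$p), ]
  expect_true("t3" %in% c(worst$t1, worst$t2))
  # column permutation permutes the p-values
  perm <- c(2, 1, 4, 3)
  nep <- nemenyi_posthoc(shifted[, perm])
  expect_setequal(round(ne$p, 12), round(nep$p, 12))
  # identical columns: all p = 1
  expect_true(all(nemenyi_posthoc(matrix(rep(1:10, 4), 10))$p == 1))
})

test_that("Nemenyi is conservative against a paired permutation oracle", {
  # same statistic (mean within-row rank difference of one pair), permuted
  # without the familywise studentized-range adjustment
  set.seed(77)
  n_ok <- 0L
  n_draw <- 60L
  for (i in seq_len(n_draw)) {
    m <- matrix(rnorm(64), 16, 4)
    ne <- nemenyi_posthoc(m)
    r <- t(apply(m, 1, rank))
    obs <- abs(mean(r[, 1]) - mean(r[, 2]))
    perm <- replicate(500, {
      rp <- t(apply(r, 1, sample))
      abs(mean(rp[, 1]) - mean(rp[, 2]))
    })
    perm_p <- mean(perm >= obs - 1e-12)
    if (ne$p[ne$t1 == "t1" & ne$t2 == "t2"] >= perm_p) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_draw, 0.95)
})

longitudinal_recovery_table <- function() {
  # a time-course recovery design: the planted 40-percent drop must stand
  # out against within-participant (sampling) noise, so rinse-volume and
  # residual variation are kept small while participant effects stay large
  cached("longitudinal_recovery", {
    cfg <- generator_config(n_metabolites = 30L, n_steroids = 0L,
                            n_proteins = 0L, sigma_dilution = 0.1,
                            sigma_noise = 0.05, seed = 42L)
    impute_below_lod(filter_features(generate_study(cfg))$table)
  })
}

test_that("interval summary recovers exactly the planted high-stress drop", {
  tab <- longitudinal_recovery_table()
  res <- interval_summary(tab, "high-stress")
  planted <- sprintf("met%03d", 10:24)
  hl <- res$detail[res$detail$interval == "Post-UK -> Post-WM" &
                     res$detail$highlighted, ]
  expect_setequal(hl$feature_id, planted)
  expect_true(all(hl$direction == -1))
  # the control cohort carries no planted time course
  res0 <- interval_summary(tab, "control")
  expect_lte(sum(res0$counts$highlighted), 2L)
})

test_that("interval counts shrink with stricter alpha and magnitude", {
  tab <- longitudinal_recovery_table()
  a <- interval_summary(tab, "high-stress", alpha = 0.05, magnitude = 0.30)
  b <- interval_summary(tab, "high-stress", alpha = 0.01, magnitude = 0.30)
  c <- interval_summary(tab, "high-stress", alpha = 0.05, magnitude = 0.45)
  expect_true(all(b$counts$significant <= a$counts$significant))
  expect_true(all(c$counts$highlighted <= a$counts$highlighted))
  expect_error(interval_summary(tab, "all", magnitude = -1), "non-negative")
})

test_that("the 30 percent magnitude gate is a hard boundary", {
  # deterministic drop of exactly 29% (excluded) vs 30% (included)
  build <- function(mult) {
    n <- 16L
    set.seed(1)
    base <- exp(rnorm(n, 2, 0.5))
    vals <- cbind(base, base, base, base * mult)
    jit <- matrix(1 + c(0, 1e-6, 2e-6, -3e-6), n, 4, byrow = TRUE)
    vals <- vals * jit  # break rank ties deterministically
    samples <- data.frame(
      sample_id = paste0("P", rep(1:n, each = 4), "_", rep(1:4, n)),
      participant_id = paste0("P", rep(1:n, each = 4)),
      group = "high-stress",
      time_point = rep(c("Rest", "Post-UK", "Recover", "Post-WM"), n),
      sex = "male", age_group = "20s")
    vmat <- matrix(NA_real_, 4 * n, 1)
    vmat[, 1] <- as.vector(t(vals))
    features <- data.frame(feature_id = "F1", class = "metabolite",
                           recovery = 100, rsd = 5, min_quantifiable = 0.01)
    feature_table(vmat, samples, features)
  }
  res29 <- interval_summary(build(0.71), "high-stress")
  res30 <- interval_summary(build(0.70), "high-stress")
  i29 <- res29$detail[res29$detail$interval == "Post-UK -> Post-WM", ]
  i30 <- res30$detail[res30$detail$interval == "Post-UK -> Post-WM", ]
  expect_true(nrow(i29) == 1L && !i29$highlighted)  # significant, not 30%
  expect_true(nrow(i30) == 1L && i30$highlighted)
})
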