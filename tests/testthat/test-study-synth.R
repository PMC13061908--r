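test_that("default study matches the study design", {
  tab <- default_study()
  expect_equal(nrow(tab$values), 128L)
  expect_equal(ncol(tab$values), 127L)
  expect_equal(length(unique(tab$samples$participant_id)), 32L)
  expect_equal(as.integer(table(tab$samples$group)), c(64L, 64L))
  expect_equal(levels(tab$samples$time_point),
               c("Rest", "Post-UK", "Recover", "Post-WM"))
  expect_equal(as.integer(table(tab$features$class)[c("metabolite", "steroid",
                                                      "protein")]),
               c(100L, 25L, 2L))
  # sex balance within each group
  sx <- unique(tab$samples[, c("participant_id", "group", "sex")])
  expect_equal(as.integer(table(sx$group, sx$sex)["control", ]), c(8L, 8L))
})

test_that("design closure holds for arbitrary configs", {
  for (np in c(2L, 5L)) for (k in c(2L, 3L)) {
    cfg <- generator_config(n_per_group = np,
                            time_points = paste0("T", seq_len(k)),
                            n_metabolites = 6L, n_steroids = 0L,
                            n_proteins = 0L, planted_effects = list(),
                            seed = np * 10L + k)
    tab <- generate_study(cfg)
    expect_equal(nrow(tab$values), 2L * np * k)
  }
})

test_that("generation is deterministic and seed-sensitive", {
  a <- generate_study(generator_config(seed = 11L))
  b <- generate_study(generator_config(seed = 11L))
  expect_identical(a$values, b$values)
  expect_identical(a$below_lod, b$below_lod)
  expect_identical(a$samples, b$samples)
  expect_identical(a$features, b$features)
  c <- generate_study(generator_config(seed = 12L))
  expect_false(identical(a$values, c$values))
})

test_that("config validation names the offending field", {
  expect_error(generator_config(n_per_group = 1), "n_per_group")
  expect_error(generator_config(sigma_noise = -0.1), "sigma_noise")
  expect_error(generator_config(sigma_dilution = -1), "sigma_dilution")
  expect_error(generator_config(time_points = c("a", "a")), "time_points")
  expect_error(generator_config(lod_quantile = 1.5), "lod_quantile")
  expect_error(generator_config(pair_correlation = 2), "pair_correlation")
})

test_that("noise-free degenerate study collapses to exp(mu)", {
  cfg <- generator_config(n_per_group = 2L, n_metabolites = 5L,
                          n_steroids = 0L, n_proteins = 0L,
                          sigma_participant = 0, sigma_participant_shared = 0,
                          sigma_dilution = 0, sigma_noise = 0,
                          planted_effects = list(), pair_correlation = 0,
                          sex_effect_sd = 0, age_effect_sd = 0,
                          lod_quantile = 0, seed = 5L)
  tab <- generate_study(cfg)
  expect_false(any(tab$below_lod))
  for (j in seq_len(ncol(tab$values)))
    expect_equal(unname(tab$values[, j]),
                 rep(exp(unname(tab$truth$mu[j])), nrow(tab$values)))
})

test_that("empirical marker AUC matches the closed-form normal theory", {
  delta <- 0.3; rho <- 0.5
  sigma_u <- 0.3; sigma_n <- 0.1
  cfg <- generator_config(n_per_group = 200L, n_metabolites = 4L,
                          n_steroids = 0L, n_proteins = 0L,
                          sigma_participant = sigma_u, sigma_noise = sigma_n,
                          sigma_dilution = 1.0,
                          planted_effects = marker_only_effects(delta),
                          pair_correlation = rho,
                          sex_effect_sd = 0, age_effect_sd = 0,
                          lod_quantile = 0, seed = 99L)
  sigma_pair <- sqrt(2 * sigma_u^2 * (1 - rho) + 2 * sigma_n^2)
  theory <- pnorm(2 * delta / (sigma_pair * sqrt(2)))

  # independent oracle: simulate the two-class log-ratio model directly
  set.seed(1)
  n_sim <- 10000L
  lr1 <- -2 * delta + rnorm(n_sim, 0, sigma_pair)  # high-stress
  lr0 <- rnorm(n_sim, 0, sigma_pair)               # control
  sim_auc <- mean(lr1 < lr0) + 0.5 * mean(lr1 == lr0)
  expect_lt(abs(sim_auc - theory), 0.015)

  tab <- generate_study(cfg)
  rest <- tab$samples$time_point == "Rest"
  lr <- log(tab$values[rest, "met001"] / tab$values[rest, "met002"])
  y <- as.integer(tab$samples$group[rest] == "high-stress")
  expect_lt(abs(auc(-lr, y) - theory), 0.04)
})

test_that("ratios cancel the shared dilution factor exactly", {
  base <- list(n_per_group = 30L, n_metabolites = 6L, n_steroids = 0L,
               n_proteins = 0L, planted_effects = list(),
               pair_correlation = 0, sex_effect_sd = 0, age_effect_sd = 0,
               lod_quantile = 0, seed = 21L)
  t0 <- generate_study(do.call(generator_config,
                               c(base, sigma_dilution = 0.4)))
  t1 <- generate_study(do.call(generator_config,
                               c(base, sigma_dilution = 1.6)))
  lr0 <- log(t0$values[, 1] / t0$values[, 2])
  lr1 <- log(t1$values[, 1] / t1$values[, 2])
  expect_equal(lr0, lr1, tolerance = 1e-10)
  # while the single features themselves are strongly perturbed
  expect_gt(var(log(t1$values[, 1])) / var(log(t0$values[, 1])), 2)
})

test_that("participant-level variability dominates log concentrations", {
  tab <- default_study()
  tab <- impute_below_lod(tab)
  lv <- log(tab$values)
  pid <- tab$samples$participant_id
  icc <- vapply(seq_len(ncol(lv)), function(j) {
    m <- tapply(lv[, j], pid, mean)
    w <- tapply(lv[, j], pid, var)
    v_within <- mean(w)
    v_between <- max(0, var(m) - v_within / 4)
    v_between / (v_between + v_within)
  }, numeric(1))
  expect_gt(mean(icc), 0.5)
})

test_that("qc metadata is attached per design, decoys violate as configured", {
  cfg <- generator_config(qc_violation_fractions = c(recovery = 0.10,
                                                     rsd = 0.05,
                                                     detection = 0.02),
                          seed = 8L)
  tab <- generate_study(cfg)
  f <- tab$features
  expect_equal(sum(f$decoy), 17L)
  expect_equal(as.integer(table(f$decoy_type)[c("recovery", "rsd",
                                                "detection")]),
               c(10L, 5L, 2L))
  rec_bad <- f$decoy & f$decoy_type == "recovery"
  expect_true(all(f$recovery[rec_bad] > 130 | f$recovery[rec_bad] < 70))
  expect_true(all(f$rsd[f$decoy & f$decoy_type == "rsd"] > 20))
  honest <- !f$decoy & f$class == "metabolite"
  expect_true(all(f$recovery[honest] >= 70 & f$recovery[honest] <= 130))
  expect_true(all(f$rsd[honest] <= 20))
  # adding decoys does not perturb the core draws
  plain <- generate_study(generator_config(seed = 8L))
  expect_identical(tab$values[, !f$decoy], plain$values)
})
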