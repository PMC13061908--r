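#' Configuration for the synthetic study generator
#'
#' Describes a two-group (control vs high-stress), four-collection-point
#' mouth-rinse study on the log-concentration scale. Each concentration is
#' generated as
#' \deqn{\exp(\mu_f + u_{pf} + s_p + d_i + \beta_f g + \tau_{ft} + c_{f} + \epsilon)}
#' where \eqn{u_{pf}} is a feature-specific participant effect, \eqn{s_p} a
#' shared per-participant scalar (global "individuality"), \eqn{d_i} a
#' per-sample shared dilution factor (rinse-volume variation, cancelled by any
#' two-feature ratio), \eqn{\beta_f g} a planted group effect, \eqn{\tau_{ft}}
#' a planted time-course offset, \eqn{c_f} sex/age covariate offsets and
#' \eqn{\epsilon} residual noise. Cells falling below the per-feature limit of
#' detection are censored.
#'
#' @param n_per_group participants per group (>= 2).
#' @param time_points ordered collection-point labels.
#' @param n_metabolites,n_steroids,n_proteins feature counts per class.
#' @param mu optional numeric vector of per-feature baseline log
#'   concentrations; drawn from N(\code{mu_mean}, \code{mu_sd}^2) when NULL.
#' @param mu_mean,mu_sd location/spread of the baseline log concentrations.
#' @param sigma_participant SD of the feature-specific participant effect
#'   (log scale).
#' @param sigma_participant_shared SD of the shared per-participant scalar.
#' @param sigma_dilution SD of the per-sample shared log dilution factor.
#' @param sigma_noise residual log-scale SD.
#' @param planted_effects list of planted effects; each element is a list with
#'   \code{feature} (id), \code{group_effect} (log-fold effect added to the
#'   high-stress group), \code{time_offsets} (per-time-point log offsets) and
#'   \code{cohort} ("all", "control" or "high-stress", scope of the time
#'   offsets). See \code{\link{default_planted_effects}}.
#' @param marker_pair two feature ids forming the planted marker ratio pair.
#' @param pair_correlation correlation (in \code{[0, 1]}) between the two
#'   marker-pair features' participant effects. Co-regulation of the pair is
#'   what makes its ratio cancel individual differences as well as dilution,
#'   so the planted ratio dominates every ratio that pairs one informative
#'   feature with a random partner.
#' @param sex_effect_sd,age_effect_sd SD of small covariate log offsets
#'   planted on a random tenth of the metabolites (0 disables).
#' @param lod_quantile marginal quantile at which the per-feature limit of
#'   detection sits; about this fraction of cells is censored.
#' @param lod optional explicit per-feature LOD vector (overrides
#'   \code{lod_quantile}).
#' @param qc_violation_fractions named numeric vector with elements
#'   \code{recovery}, \code{rsd}, \code{detection}: fractions (of
#'   \code{n_metabolites}) of extra decoy metabolites violating exactly that
#'   inclusion criterion.
#' @param seed integer; fixes the full output bit-for-bit.
#'
#' @return a \code{generator_config} list.
#' @export
generator_config <- function(n_per_group = 16,
                             time_points = c("Rest", "Post-UK",
                                             "Recover", "Post-WM"),
                             n_metabolites = 100,
                             n_steroids = 25,
                             n_proteins = 2,
                             mu = NULL,
                             mu_mean = log(10),
                             mu_sd = 1,
                             sigma_participant = 0.4,
                             sigma_participant_shared = 0.35,
                             sigma_dilution = 0.3,
                             sigma_noise = 0.1,
                             planted_effects = default_planted_effects(
                               time_points),
                             marker_pair = c("met001", "met002"),
                             pair_correlation = 0.9,
                             sex_effect_sd = 0.1,
                             age_effect_sd = 0.1,
                             lod_quantile = 0.01,
                             lod = NULL,
                             qc_violation_fractions = c(recovery = 0,
                                                        rsd = 0,
                                                        detection = 0),
                             seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              time_points = as.character(time_points),
              n_metabolites = as.integer(n_metabolites),
              n_steroids = as.integer(n_steroids),
              n_proteins = as.integer(n_proteins),
              mu = mu, mu_mean = mu_mean, mu_sd = mu_sd,
              sigma_participant = sigma_participant,
              sigma_participant_shared = sigma_participant_shared,
              sigma_dilution = sigma_dilution,
              sigma_noise = sigma_noise,
              planted_effects = planted_effects,
              marker_pair = marker_pair,
              pair_correlation = pair_correlation,
              sex_effect_sd = sex_effect_sd,
              age_effect_sd = age_effect_sd,
              lod_quantile = lod_quantile,
              lod = lod,
              qc_violation_fractions = qc_violation_fractions,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' Default planted effects
#'
#' The default synthetic study plants (i) one marker ratio pair, features
#' \code{met001}/\code{met002}, with opposite group log-fold effects
#' (-0.6, +0.6) so their ratio separates the groups while each single feature
#' is partly masked by dilution and shared-participant variability (the
#' pair's participant effects are additionally correlated, see
#' \code{pair_correlation} in \code{\link{generator_config}}), and (ii)
#' fifteen metabolites (\code{met010}..\code{met024}) that drop 40 percent at
#' the final collection point in the high-stress cohort. The headline marker
#' is oriented so that a LOWER ratio associates with high stress, matching the
#' usual direction of resting-state catabolite markers.
#'
#' @param time_points collection-point labels (time offsets are aligned to
#'   them).
#' @param delta magnitude of the marker-pair group log-fold effect.
#' @return a list of planted-effect descriptors.
#' @export
default_planted_effects <- function(time_points = c("Rest", "Post-UK",
                                                    "Recover", "Post-WM"),
                                    delta = 0.6) {
  k <- length(time_points)
  no_shift <- rep(0, k)
  eff <- list(
    list(feature = "met001", group_effect = -delta, time_offsets = no_shift,
         cohort = "all"),
    list(feature = "met002", group_effect = +delta, time_offsets = no_shift,
         cohort = "all"))
  drop_last <- c(rep(0, k - 1L), log(0.6))
  for (i in 10:24)
    eff[[length(eff) + 1L]] <- list(feature = sprintf("met%03d", i),
                                    group_effect = 0,
                                    time_offsets = drop_last,
                                    cohort = "high-stress")
  eff
}

#' Generator configuration with no planted structure
#'
#' Convenience constructor for null-calibration studies: no planted group or
#' time effects and no covariate offsets, everything else at the defaults.
#'
#' @param ... passed on to \code{\link{generator_config}}.
#' @return a \code{generator_config}.
#' @export
null_config <- function(...) {
  generator_config(planted_effects = list(), pair_correlation = 0,
                   sex_effect_sd = 0, age_effect_sd = 0, ...)
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_per_group) || cfg$n_per_group < 2L)
    stop("invalid generator config: 'n_per_group' must be >= 2")
  if (length(cfg$time_points) == 0L || anyDuplicated(cfg$time_points))
    stop("invalid generator config: 'time_points' must be non-empty and unique")
  for (fld in c("sigma_participant", "sigma_participant_shared",
                "sigma_dilution", "sigma_noise", "sex_effect_sd",
                "age_effect_sd")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("invalid generator config: '", fld, "' must be a single SD >= 0")
  }
  if (!is.numeric(cfg$pair_correlation) || cfg$pair_correlation < 0 ||
      cfg$pair_correlation > 1)
    stop("invalid generator config: 'pair_correlation' must be in [0, 1]")
  if (length(cfg$marker_pair) != 2L ||
      cfg$marker_pair[1L] == cfg$marker_pair[2L])
    stop("invalid generator config: 'marker_pair' must be two distinct ids")
  if (!is.null(cfg$lod) && any(cfg$lod <= 0))
    stop("invalid generator config: 'lod' must be positive")
  if (cfg$lod_quantile < 0 || cfg$lod_quantile >= 1)
    stop("invalid generator config: 'lod_quantile' must be in [0, 1)")
  qv <- cfg$qc_violation_fractions
  if (!all(c("recovery", "rsd", "detection") %in% names(qv)) || any(qv < 0))
    stop("invalid generator config: 'qc_violation_fractions' needs ",
         "non-negative 'recovery', 'rsd', 'detection'")
  k <- length(cfg$time_points)
  for (pe in cfg$planted_effects) {
    if (!all(c("feature", "group_effect", "time_offsets") %in% names(pe)))
      stop("invalid generator config: planted effect missing a field")
    if (length(pe$time_offsets) != k)
      stop("invalid generator config: planted effect on '", pe$feature,
           "' has ", length(pe$time_offsets), " time offsets, expected ", k)
  }
  invisible(cfg)
}

## one master seed -> fixed-purpose sub-seeds, so adding decoy features or QC
## metadata never perturbs the core concentration draws
generator_subseeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("features", "participants", "core", "decoys", "qc", "spare")
  s
}

#' Generate a synthetic mouth-rinse study
#'
#' Draws a complete two-group, multi-time-point concentration table under the
#' log-normal random-effects model described in
#' \code{\link{generator_config}}, attaches QC metadata (recovery, RSD,
#' minimum quantifiable value) and records a truth registry (planted effects,
#' decoy features) used by recovery tests. The same config and seed always
#' reproduce the identical table.
#'
#' @param config a \code{\link{generator_config}}.
#' @param attach_qc attach QC metadata (default TRUE).
#' @return a \code{\link{feature_table}} with a \code{truth} component.
#' @export
generate_study <- function(config = generator_config(), attach_qc = TRUE) {
  validate_generator_config(config)
  ss <- generator_subseeds(config$seed)
  k <- length(config$time_points)
  n_core <- config$n_metabolites + config$n_steroids + config$n_proteins
  n_part <- 2L * config$n_per_group
  n_samp <- n_part * k

  feat_ids <- c(sprintf("met%03d", seq_len(config$n_metabolites)),
                sprintf("ster%02d", seq_len(config$n_steroids)),
                c("sIgA", "CgA")[seq_len(config$n_proteins)])
  feat_class <- rep(c("metabolite", "steroid", "protein"),
                    c(config$n_metabolites, config$n_steroids,
                      config$n_proteins))

  ## feature-level draws
  set.seed(ss["features"])
  mu <- config$mu
  if (is.null(mu)) mu <- stats::rnorm(n_core, config$mu_mean, config$mu_sd)
  if (length(mu) != n_core)
    stop("invalid generator config: 'mu' must have one entry per feature (",
         n_core, ")")
  sex_eff <- age_eff <- numeric(n_core)
  n_cov <- max(1L, round(config$n_metabolites / 10))
  if (config$sex_effect_sd > 0) {
    idx <- sample.int(config$n_metabolites, n_cov)
    sex_eff[idx] <- stats::rnorm(n_cov, 0, config$sex_effect_sd)
  }
  if (config$age_effect_sd > 0) {
    idx <- sample.int(config$n_metabolites, n_cov)
    age_eff[idx] <- stats::rnorm(n_cov, 0, config$age_effect_sd)
  }

  ## participant-level structure: balanced sex and age decades within group
  set.seed(ss["participants"])
  part_ids <- sprintf("P%02d", seq_len(n_part))
  group <- rep(c("control", "high-stress"), each = config$n_per_group)
  sex <- unlist(lapply(seq_len(2L), function(g)
    rep_len(c("male", "female"), config$n_per_group)))
  age_group <- unlist(lapply(seq_len(2L), function(g)
    rep_len(c("20s", "30s", "40s"), config$n_per_group)))
  u <- matrix(stats::rnorm(n_part * n_core, 0, config$sigma_participant),
              n_part, n_core)
  s_shared <- stats::rnorm(n_part, 0, config$sigma_participant_shared)
  # co-regulated marker pair: correlated participant effects, so the pair's
  # ratio cancels individuality on top of dilution
  mp <- match(config$marker_pair, feat_ids)
  rho <- config$pair_correlation
  if (!anyNA(mp) && rho > 0) {
    w <- stats::rnorm(n_part, 0, config$sigma_participant)
    for (j in mp)
      u[, j] <- sqrt(rho) * w + sqrt(1 - rho) * u[, j]
  }

  ## sample-level draws
  set.seed(ss["core"])
  samples <- data.frame(
    sample_id = sprintf("%s_%s", rep(part_ids, each = k),
                        rep(config$time_points, n_part)),
    participant_id = rep(part_ids, each = k),
    group = rep(group, each = k),
    time_point = rep(config$time_points, n_part),
    sex = rep(sex, each = k),
    age_group = rep(age_group, each = k),
    stringsAsFactors = FALSE)
  dilution <- stats::rnorm(n_samp, 0, config$sigma_dilution)
  noise <- matrix(stats::rnorm(n_samp * n_core, 0, config$sigma_noise),
                  n_samp, n_core)

  pi_row <- match(samples$participant_id, part_ids)
  logc <- matrix(mu, n_samp, n_core, byrow = TRUE) +
    u[pi_row, , drop = FALSE] + s_shared[pi_row] + dilution + noise
  is_high <- samples$group == "high-stress"
  is_male <- samples$sex == "male"
  age_code <- match(samples$age_group, c("20s", "30s", "40s")) - 2L
  logc <- logc + outer(as.numeric(is_male), sex_eff) +
    outer(as.numeric(age_code), age_eff)

  tp_idx <- match(samples$time_point, config$time_points)
  for (pe in config$planted_effects) {
    j <- match(pe$feature, feat_ids)
    if (is.na(j))
      stop("planted effect names unknown feature '", pe$feature, "'")
    logc[, j] <- logc[, j] + pe$group_effect * as.numeric(is_high)
    cohort <- if (is.null(pe$cohort)) "all" else pe$cohort
    in_cohort <- switch(cohort,
                        all = rep(TRUE, n_samp),
                        control = !is_high,
                        "high-stress" = is_high,
                        stop("planted effect cohort must be all/control/",
                             "high-stress"))
    logc[in_cohort, j] <- logc[in_cohort, j] + pe$time_offsets[tp_idx[in_cohort]]
  }

  values <- exp(logc)
  sd_marg <- sqrt(config$sigma_participant^2 +
                    config$sigma_participant_shared^2 +
                    config$sigma_dilution^2 + config$sigma_noise^2)
  lod <- config$lod
  if (is.null(lod)) {
    lod <- if (config$lod_quantile > 0)
      exp(mu + stats::qnorm(config$lod_quantile) * sd_marg)
    else rep(.Machine$double.xmin, n_core)
  }
  lod <- rep_len(lod, n_core)

  features <- data.frame(feature_id = feat_ids, class = feat_class,
                         decoy = FALSE, decoy_type = NA_character_,
                         min_quantifiable = lod, stringsAsFactors = FALSE)

  ## decoy metabolites violating exactly one inclusion criterion each
  qv <- config$qc_violation_fractions
  n_dec <- round(unlist(qv[c("recovery", "rsd", "detection")]) *
                   config$n_metabolites)
  if (sum(n_dec) > 0) {
    set.seed(ss["decoys"])
    n_d <- sum(n_dec)
    dec_ids <- sprintf("decoy%03d", seq_len(n_d))
    dec_type <- rep(c("recovery", "rsd", "detection"), n_dec)
    mu_d <- stats::rnorm(n_d, config$mu_mean, config$mu_sd)
    logd <- matrix(mu_d, n_samp, n_d, byrow = TRUE) +
      matrix(stats::rnorm(n_part * n_d, 0, config$sigma_participant),
             n_part, n_d)[pi_row, , drop = FALSE] +
      s_shared[pi_row] + dilution +
      matrix(stats::rnorm(n_samp * n_d, 0, config$sigma_noise), n_samp, n_d)
    vals_d <- exp(logd)
    ## detection decoys: LOD placed so that both groups fall below 50%
    lod_d <- exp(mu_d + stats::qnorm(config$lod_quantile) * sd_marg)
    det <- dec_type == "detection"
    lod_d[det] <- exp(mu_d[det] + stats::qnorm(0.70) * sd_marg)
    values <- cbind(values, vals_d)
    features <- rbind(features,
                      data.frame(feature_id = dec_ids, class = "metabolite",
                                 decoy = TRUE, decoy_type = dec_type,
                                 min_quantifiable = lod_d,
                                 stringsAsFactors = FALSE))
    lod <- c(lod, lod_d)
  }

  below <- sweep(values, 2L, lod, "<")
  values[below] <- NA_real_

  tab <- feature_table(values, samples, features, below_lod = below,
                       time_levels = config$time_points)
  tab$truth <- list(
    config = config,
    planted_pair = c("met001", "met002"),
    planted_effects = config$planted_effects,
    decoys = features[features$decoy,
                      c("feature_id", "decoy_type"), drop = FALSE],
    mu = stats::setNames(mu, feat_ids))
  if (attach_qc) tab <- attach_qc_metadata(tab, config)
  tab
}

#' Attach QC metadata to a synthetic table
#'
#' Draws per-feature recovery and RSD values consistent with the
#' feature-inclusion criteria (recovery within 100 +/- 30 percent, RSD at most
#' 20 percent) for genuine features, and values violating exactly the
#' configured criterion for decoy features. The minimum quantifiable value is
#' the generator's limit of detection. Steroid and protein features, which in
#' the study design are quantified on separate platforms, carry no
#' recovery/RSD entries.
#'
#' @param table a \code{feature_table} from \code{\link{generate_study}}.
#' @param config the \code{\link{generator_config}} used to generate it.
#' @return the table with \code{recovery} and \code{rsd} feature columns.
#' @export
attach_qc_metadata <- function(table, config) {
  ss <- generator_subseeds(config$seed)
  set.seed(ss["qc"])
  f <- table$features
  n <- nrow(f)
  recovery <- rep(NA_real_, n)
  rsd <- rep(NA_real_, n)
  is_met <- f$class == "metabolite"
  recovery[is_met] <- stats::runif(sum(is_met), 85, 115)
  rsd[is_met] <- stats::runif(sum(is_met), 4, 16)
  bad_rec <- is_met & f$decoy & f$decoy_type == "recovery"
  if (any(bad_rec)) {
    side <- stats::runif(sum(bad_rec)) < 0.5
    recovery[bad_rec] <- ifelse(side, stats::runif(sum(bad_rec), 131, 170),
                                stats::runif(sum(bad_rec), 30, 69))
  }
  bad_rsd <- is_met & f$decoy & f$decoy_type == "rsd"
  if (any(bad_rsd)) rsd[bad_rsd] <- stats::runif(sum(bad_rsd), 21, 45)
  f$recovery <- recovery
  f$rsd <- rsd
  table$features <- f
  table
}
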