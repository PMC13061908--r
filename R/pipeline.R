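#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with defaults
#' matching the study protocol: two-sided alpha 0.05, 100 bootstrap
#' iterations, 95 percent percentile CIs, a 30 percent magnitude gate for
#' the highlighted longitudinal subset, and the per-stratum CI-lower-bound
#' selection thresholds.
#'
#' @param input_dir optional directory with a study CSV triplet; when NULL a
#'   synthetic study is generated from \code{generator}.
#' @param generator a \code{\link{generator_config}} (its seed is replaced
#'   by a sub-seed derived from \code{seed}).
#' @param out_dir optional output directory for per-stage CSVs.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("qc", "screen", "longitudinal", "search", "transfer",
#'   "adjust", "pca")} (\code{"qc"} is required by all later stages).
#' @param alpha significance level.
#' @param magnitude longitudinal highlight threshold (fraction).
#' @param n_boot bootstrap iterations for model evaluation.
#' @param ci_level confidence level.
#' @param search_strata strata searched for threshold models.
#' @param families model families to search.
#' @param cohorts cohorts for the longitudinal stage.
#' @param seed global seed; per-stage sub-seeds are derived from it.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            generator = generator_config(),
                            out_dir = NULL,
                            stages = c("qc", "screen", "longitudinal",
                                       "search", "transfer", "adjust",
                                       "pca"),
                            alpha = 0.05,
                            magnitude = 0.30,
                            n_boot = 100L,
                            ci_level = 0.95,
                            search_strata = "Rest",
                            families = c("single", "ratio"),
                            cohorts = c("all", "control", "high-stress"),
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(input_dir = input_dir, generator = generator,
                 out_dir = out_dir, stages = stages, alpha = alpha,
                 magnitude = magnitude, n_boot = as.integer(n_boot),
                 ci_level = ci_level, search_strata = search_strata,
                 families = families, cohorts = cohorts,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path a YAML (\code{.yml}/\code{.yaml}) or JSON file whose keys
#'   mirror the \code{\link{pipeline_config}} arguments; a \code{generator}
#'   sub-map mirrors \code{\link{generator_config}}.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gen <- do.call(generator_config, as.list(lst$generator))
  lst$generator <- NULL
  do.call(pipeline_config, c(lst, list(generator = gen)))
}

## header comment: package version + md5 of the resolved config
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}

write_stage_csv <- function(df, path, hash) {
  if (is.null(path)) return(invisible(NULL))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rinsemet %s config_hash=%s",
                     as.character(utils::packageVersion("rinsemet")), hash),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Executes, deterministically for a given seed: study input (synthetic or
#' read from disk), the QC feature filter with below-LOD substitution,
#' cross-sectional and longitudinal screening, the exhaustive
#' threshold-model search with CI-lower-bound selection, cross-time-point
#' transfer of the best model, the covariate robustness stage, and PCA.
#' Per-stage CSVs (with a version/config-hash header comment) are written
#' when the config names an output directory.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return a named list (report bundle) with each stage's results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config")
  hash <- config_hash(config)
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) if (is.null(out)) NULL else file.path(out, f)
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4L)  # generator, search, ...
  bundle <- list(config = config, config_hash = hash)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  raw <- run_stage("input", {
    if (is.null(config$input_dir)) {
      gen <- config$generator
      gen$seed <- sub[1L]
      generate_study(gen)
    } else read_study(config$input_dir)
  })
  bundle$raw <- raw

  if (!"qc" %in% config$stages) return(invisible(bundle))
  qc <- run_stage("qc", filter_features(raw))
  tab <- run_stage("qc", impute_below_lod(qc$table))
  bundle$qc_report <- qc$report
  bundle$table <- tab
  write_stage_csv(as.data.frame(qc$report), path("qc_report.csv"), hash)

  if ("screen" %in% config$stages) {
    scr <- run_stage("screen", screen_all_strata(tab))
    bundle$screen <- scr
    write_stage_csv(scr, path("screen.csv"), hash)
  }

  if ("longitudinal" %in% config$stages) {
    lng <- run_stage("longitudinal", {
      lapply(stats::setNames(config$cohorts, config$cohorts), function(ch)
        interval_summary(tab, ch, alpha = config$alpha,
                         magnitude = config$magnitude))
    })
    bundle$longitudinal <- lng
    write_stage_csv(do.call(rbind, lapply(lng, `[[`, "counts")),
                    path("longitudinal_counts.csv"), hash)
  }

  best <- NULL
  if ("search" %in% config$stages) {
    searches <- list()
    selected <- list()
    for (st in config$search_strata) {
      for (fam in config$families) {
        key <- paste(st, fam, sep = ".")
        rk <- run_stage("search",
                        search_models(tab, st, fam, n_boot = config$n_boot,
                                      seed = sub[2L],
                                      ci_level = config$ci_level))
        searches[[key]] <- rk
        selected[[key]] <- run_stage("select", select_models(rk, st))
        write_stage_csv(as.data.frame(utils::head(rk, 50L)),
                        path(sprintf("search_%s_%s.csv", st, fam)), hash)
        write_stage_csv(as.data.frame(selected[[key]]),
                        path(sprintf("selected_%s_%s.csv", st, fam)), hash)
      }
    }
    bundle$search <- searches
    bundle$selected <- selected
    ratio_keys <- grep("\\.ratio$", names(searches), value = TRUE)
    if (length(ratio_keys)) {
      top <- searches[[ratio_keys[1L]]][1L, ]
      best <- run_stage("search", threshold_model(
        tab, top$feature,
        if (is.na(top$denominator)) NULL else top$denominator,
        attr(searches[[ratio_keys[1L]]], "stratum")))
      bundle$best_model <- best
    }
  }

  if ("transfer" %in% config$stages && !is.null(best)) {
    tr <- run_stage("transfer", transfer_evaluate(best, tab))
    bundle$transfer <- tr
    write_stage_csv(tr, path("transfer.csv"), hash)
  }

  if ("adjust" %in% config$stages && !is.null(best)) {
    adj <- run_stage("adjust", {
      des <- stratum_design(tab, best$stratum)
      sc <- candidate_scores(tab, best$feature, best$denominator, des$rows)
      s <- tab$samples[des$rows, , drop = FALSE]
      list(logistic = logistic_adjust(sc, des$unit_label, s$sex,
                                      s$age_group),
           stratified = stratified_compare(sc, des$unit_label, s$sex))
    })
    bundle$adjust <- adj
    write_stage_csv(adj$logistic$adjusted, path("adjusted_fit.csv"), hash)
  }

  if ("pca" %in% config$stages) {
    pc <- run_stage("pca", {
      z <- suppressWarnings(zscore(tab))
      p <- pca(z, n_components = min(10L, nrow(z$values) - 1L,
                                     ncol(z$values)))
      ell <- confidence_ellipse(p$scores[, 1:2], tab$samples$group)
      list(pca = p, ellipse = ell)
    })
    bundle$pca <- pc
    write_stage_csv(data.frame(sample_id = tab$samples$sample_id,
                               pc$pca$scores[, 1:2]),
                    path("pca_scores.csv"), hash)
  }

  invisible(bundle)
}
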