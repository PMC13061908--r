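# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_study <- function() {
  cached("default_study", generate_study(generator_config(seed = 42L)))
}

default_imputed <- function() {
  cached("default_imputed",
         impute_below_lod(filter_features(default_study())$table))
}

# marker pair only, no time-course features: usable at any feature count
marker_only_effects <- function(delta = 0.6, k = 4L) {
  list(list(feature = "met001", group_effect = -delta,
            time_offsets = rep(0, k), cohort = "all"),
       list(feature = "met002", group_effect = +delta,
            time_offsets = rep(0, k), cohort = "all"))
}

# small, fast study: 8 per group, 20 metabolites, marker pair planted
small_config <- function(..., delta = 0.6) {
  generator_config(n_per_group = 8L, n_metabolites = 20L, n_steroids = 0L,
                   n_proteins = 0L,
                   planted_effects = marker_only_effects(delta), ...)
}

small_imputed <- function() {
  cached("small_imputed",
         impute_below_lod(filter_features(
           generate_study(small_config(seed = 7L)))$table))
}

# a tiny fully hand-built table: 4 participants, 1 time point, 2 features
manual_table <- function(values, below = NULL,
                         group = c("control", "control", "high-stress",
                                   "high-stress"),
                         recovery = c(100, 100), rsd = c(10, 10),
                         min_quantifiable = c(1, 1),
                         class = c("metabolite", "metabolite")) {
  values <- as.matrix(values)
  n <- nrow(values)
  samples <- data.frame(
    sample_id = paste0("S", seq_len(n)),
    participant_id = paste0("P", seq_len(n)),
    group = rep_len(group, n),
    time_point = "Rest",
    sex = rep_len(c("male", "female"), n),
    age_group = "20s", stringsAsFactors = FALSE)
  features <- data.frame(
    feature_id = paste0("F", seq_len(ncol(values))),
    class = rep_len(class, ncol(values)),
    recovery = rep_len(recovery, ncol(values)),
    rsd = rep_len(rsd, ncol(values)),
    min_quantifiable = rep_len(min_quantifiable, ncol(values)),
    stringsAsFactors = FALSE)
  if (is.null(below)) below <- is.na(values)
  feature_table(values, samples, features, below_lod = below)
}
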