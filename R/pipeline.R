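# End-to-end pipeline: generate -> extract -> filter -> analyze -> report.

# Bonferroni family assignments for the overall ANOVA P values: the two
# window sizes form one family and the seven histogram-shape variables
# another; the remaining variables are corrected only within their pairwise
# post hoc tests.
FEATURE_FAMILIES <- c(
  size_lung_mm = 2, size_mediastinal_mm = 2,
  volume_cm3 = 1, density = 1, mass_g = 1,
  skewness = 7, kurtosis = 7, p2_5_hu = 7, p25_hu = 7, p50_hu = 7,
  p75_hu = 7, p97_5_hu = 7,
  uniformity = 1, entropy_bits = 1
)

FEATURE_COLUMNS <- names(FEATURE_FAMILIES)

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()] (or NULL to build one from the other
#'   arguments).
#' @param out_dir output directory for the report bundle, or NULL to keep
#'   everything in memory.
#' @param master_seed overrides the cohort spec's master seed.
#' @param observer_noise observer boundary noise (voxels); 0 disables the
#'   two-observer simulation and agreement analysis.
#' @param bin_width_hu texture histogram bin width.
#' @param solid_threshold_hu solid-component HU threshold.
#' @param rule the [threshold_rule()] evaluated on the cohort.
#' @param anova_entry_p ANOVA screening level for logistic candidates.
#' @param vif_threshold VIF removal threshold.
#' @param remove_level stepwise likelihood-ratio removal level.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_spec(), out_dir = NULL,
                            master_seed = NULL, observer_noise = NULL,
                            bin_width_hu = 1, solid_threshold_hu = -160,
                            rule = threshold_rule(), anova_entry_p = 0.10,
                            vif_threshold = 10, remove_level = 0.10) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(rule, "threshold_rule"))
  if (!is.null(master_seed)) cohort$master_seed <- as.integer(master_seed)
  if (!is.null(observer_noise)) cohort$observer_noise <- observer_noise
  structure(list(
    cohort = cohort, out_dir = out_dir, bin_width_hu = bin_width_hu,
    solid_threshold_hu = solid_threshold_hu, rule = rule,
    anova_entry_p = anova_entry_p, vif_threshold = vif_threshold,
    remove_level = remove_level
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `cohort` (n_ais, n_mia, n_inv,
#' voxel_spacing_mm, observer_noise, master_seed), `rule` (p75_cutoff_hu,
#' entropy_cutoff_bits), `bin_width_hu`, `solid_threshold_hu`,
#' `anova_entry_p`, `vif_threshold`, `remove_level`, `out_dir`. Missing
#' keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ca <- y$cohort %||% list()
  cs <- cohort_spec(
    n_ais = ca$n_ais %||% 38, n_mia = ca$n_mia %||% 61,
    n_inv = ca$n_inv %||% 92,
    voxel_spacing_mm = unlist(ca$voxel_spacing_mm %||% c(0.7, 0.7, 1.25)),
    observer_noise = ca$observer_noise %||% 1,
    master_seed = ca$master_seed %||% 57290L
  )
  ra <- y$rule %||% list()
  pipeline_config(
    cohort = cs, out_dir = y$out_dir,
    bin_width_hu = y$bin_width_hu %||% 1,
    solid_threshold_hu = y$solid_threshold_hu %||% -160,
    rule = threshold_rule(ra$p75_cutoff_hu %||% -470,
                          ra$entropy_cutoff_bits %||% 7.90),
    anova_entry_p = y$anova_entry_p %||% 0.10,
    vif_threshold = y$vif_threshold %||% 10,
    remove_level = y$remove_level %||% 0.10
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-comparison table for a cohort feature table
#'
#' One-way ANOVA per feature across the three pathologic classes, with
#' family-Bonferroni overall P and pairwise post hoc P values.
#'
#' @param features feature data frame.
#' @param class_labels factor/character of class labels per row.
#' @param feature_cols feature columns to test.
#' @param families named vector of Bonferroni family sizes per feature.
#' @return data frame: feature, group means/SDs, F, p_raw, p_corrected and
#'   the three pairwise post hoc P values.
#' @export
anova_table <- function(features, class_labels,
                        feature_cols = intersect(FEATURE_COLUMNS, names(features)),
                        families = FEATURE_FAMILIES) {
  cls <- factor(class_labels, levels = GGN_CLASSES)
  rows <- lapply(feature_cols, function(f) {
    fam <- if (f %in% names(families)) families[[f]] else 1
    res <- tryCatch(anova_with_posthoc(features[[f]], cls, fam),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    ph <- res$posthoc
    getp <- function(a, b) {
      i <- (ph$group1 == a & ph$group2 == b) | (ph$group1 == b & ph$group2 == a)
      if (any(i)) ph$p[i][1] else NA_real_
    }
    mns <- tapply(features[[f]], cls, mean, na.rm = TRUE)
    sds <- tapply(features[[f]], cls, stats::sd, na.rm = TRUE)
    data.frame(
      feature = f,
      mean_ais = mns[["AIS"]], sd_ais = sds[["AIS"]],
      mean_mia = mns[["MIA"]], sd_mia = sds[["MIA"]],
      mean_inv = mns[["INV"]], sd_inv = sds[["INV"]],
      f_stat = res$f, p_raw = res$p_raw, p_corrected = res$p_family,
      p_ais_mia = getp("AIS", "MIA"),
      p_mia_inv = getp("MIA", "INV"),
      p_ais_inv = getp("AIS", "INV"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation table against invasion extent
#'
#' @param features feature data frame.
#' @param invasion_extent numeric pathologic invasion extent per row.
#' @param feature_cols feature columns to correlate.
#' @return data frame: feature, rho, p.
#' @export
spearman_table <- function(features, invasion_extent,
                           feature_cols = intersect(FEATURE_COLUMNS, names(features))) {
  rows <- lapply(feature_cols, function(f) {
    res <- tryCatch(spearman_vs_invasion(features[[f]], invasion_extent),
                    error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(feature = f, rho = res$rho, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interobserver agreement table
#'
#' Per-feature two-way random absolute-agreement single-measure ICC between
#' the two observers' feature tables.
#'
#' @param obs1,obs2 per-observer feature data frames (same rows).
#' @param feature_cols feature columns.
#' @return data frame: feature, icc, ci_low, ci_high.
#' @export
icc_table <- function(obs1, obs2,
                      feature_cols = intersect(FEATURE_COLUMNS, names(obs1))) {
  rows <- lapply(feature_cols, function(f) {
    res <- tryCatch(icc_two_observers(obs1[[f]], obs2[[f]]),
                    error = function(e) list(icc = NA_real_, ci = c(NA_real_, NA_real_)))
    data.frame(feature = f, icc = res$icc, ci_low = res$ci[1],
               ci_high = res$ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the statistics stage on a feature table
#'
#' Chains the group comparison, Spearman correlations, ANOVA P < 0.10
#' candidate screen, VIF screen, backward-stepwise logistic selection
#' (invasive vs. AIS or MIA), ROC of the fitted probabilities, and the
#' two-threshold rule evaluation (plus the binary-rule ROC).
#'
#' @param features feature data frame (one row per nodule).
#' @param records cohort records with `class_label` and
#'   `invasion_extent_mm` aligned to `features` rows.
#' @param config a [pipeline_config()].
#' @param seed seed for bootstrap CIs.
#' @return list of class `analysis_report`.
#' @export
analyze_cohort <- function(features, records, config = pipeline_config(),
                           seed = config$cohort$master_seed) {
  stopifnot(nrow(features) == nrow(records))
  if (length(unique(records$class_label)) < 2 ||
      !any(records$class_label == "INV") ||
      all(records$class_label == "INV")) {
    stop("single-class outcome: need invasive and non-invasive nodules")
  }
  cls <- records$class_label
  an <- anova_table(features, cls)
  sp <- spearman_table(features, records$invasion_extent_mm)

  candidates <- an$feature[!is.na(an$p_raw) & an$p_raw < config$anova_entry_p]
  vif <- NULL
  if (length(candidates) >= 2) {
    vif <- vif_screen(features, candidates, config$vif_threshold)
    candidates <- vif$retained
  }
  if (length(candidates) == 0) {
    stop("no candidate survived the ANOVA screen; nothing to model")
  }
  dat <- cbind(features, invasive = cls == "INV")
  model <- stepwise_logistic(dat, "invasive", candidates,
                             config$remove_level)
  probs <- stats::fitted(model$fit)
  roc_model <- roc_auc(probs, dat$invasive, seed = derive_seed(seed, 101))
  rule_eval <- evaluate_rule(features, dat$invasive, config$rule,
                             seed = derive_seed(seed, 102))
  structure(list(
    anova = an, spearman = sp, vif = vif, model = model,
    roc_model = roc_model, rule = config$rule, rule_eval = rule_eval,
    n = nrow(features)
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("GGN cohort analysis (n = %d)\n", x$n))
  cat(sprintf("  logistic model retains: %s\n",
              if (length(x$model$retained)) paste(x$model$retained, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  fitted-probability ROC AUC = %.3f (95%% CI %.3f-%.3f)\n",
              x$roc_model$auc, x$roc_model$ci[1], x$roc_model$ci[2]))
  cat(sprintf("  rule (p75 >= %g HU AND entropy >= %g): PPV %.1f%% (%d/%d)\n",
              x$rule$p75_cutoff_hu, x$rule$entropy_cutoff_bits,
              100 * x$rule_eval$ppv, x$rule_eval$n_true_positive,
              x$rule_eval$n_positive))
  invisible(x)
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the cohort, extracts features (optionally via two simulated
#' observers, averaging their measurements and reporting per-feature ICCs),
#' applies the solid-component inclusion filter, runs the statistics stage
#' and, when `out_dir` is set, writes the report bundle: `features.csv`,
#' `cohort.csv`, `anova_table.csv`, `spearman_table.csv`, `icc_table.csv`,
#' `vif_steps.csv`, `logistic_trace.csv`, `logistic_coefficients.csv`,
#' `roc_points.csv`, `rule_evaluation.json`, `exclusions.json` and
#' `manifest.json`. Identical configuration gives identical outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML config file.
#' @return list with `cohort` records, `features`, `icc` (or NULL),
#'   `filter` and `report` (the `analysis_report`), invisibly when writing.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("generate", generate_cohort(config$cohort))
  fx <- stage("extract", cohort_features(
    cohort, observer_noise = config$cohort$observer_noise,
    bin_width_hu = config$bin_width_hu,
    solid_threshold_hu = config$solid_threshold_hu
  ))
  icc <- if (!is.null(fx$obs1)) icc_table(fx$obs1, fx$obs2) else NULL
  flt <- stage("filter", filter_cohort(cohort$records, fx$features))
  keep <- !flt$log$excluded
  features <- fx$features[keep, , drop = FALSE]
  records <- cohort$records[keep, , drop = FALSE]
  report <- stage("analyze", analyze_cohort(features, records, config))

  out <- list(cohort = cohort$records, features = fx$features, icc = icc,
              filter = flt, report = report)
  if (!is.null(config$out_dir)) {
    stage("report", .write_report_bundle(out, records, features, config))
    return(invisible(out))
  }
  out
}

.write_report_bundle <- function(out, records, features, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(out$features, file.path(dir, "features.csv"))
  utils::write.csv(out$cohort[, c("nodule_id", "class_label",
                                  "invasion_extent_mm", "seed")],
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  rep <- out$report
  write_feature_table(rep$anova, file.path(dir, "anova_table.csv"))
  write_feature_table(rep$spearman, file.path(dir, "spearman_table.csv"))
  if (!is.null(out$icc)) {
    write_feature_table(out$icc, file.path(dir, "icc_table.csv"))
  }
  if (!is.null(rep$vif)) {
    write_feature_table(rep$vif$steps, file.path(dir, "vif_steps.csv"))
  }
  write_feature_table(rep$model$trace, file.path(dir, "logistic_trace.csv"))
  write_feature_table(rep$model$coefficients,
                      file.path(dir, "logistic_coefficients.csv"))
  write_feature_table(rep$roc_model$points, file.path(dir, "roc_points.csv"))
  re <- rep$rule_eval
  jsonlite::write_json(list(
    rule = list(p75_cutoff_hu = rep$rule$p75_cutoff_hu,
                entropy_cutoff_bits = rep$rule$entropy_cutoff_bits,
                combination = rep$rule$combination),
    n_positive = re$n_positive, n_true_positive = re$n_true_positive,
    ppv = re$ppv, sensitivity = re$sensitivity,
    specificity = re$specificity, rule_auc = re$roc$auc,
    model_auc = rep$roc_model$auc, model_auc_ci = rep$roc_model$ci
  ), file.path(dir, "rule_evaluation.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  write_exclusion_log(out$filter$log, file.path(dir, "exclusions.json"))
  cs <- config$cohort
  jsonlite::write_json(list(
    package = "ggnquant",
    version = as.character(utils::packageVersion("ggnquant")),
    master_seed = cs$master_seed,
    n_ais = cs$n_ais, n_mia = cs$n_mia, n_inv = cs$n_inv,
    voxel_spacing_mm = cs$voxel_spacing_mm,
    observer_noise = cs$observer_noise,
    bin_width_hu = config$bin_width_hu,
    solid_threshold_hu = config$solid_threshold_hu,
    anova_entry_p = config$anova_entry_p,
    vif_threshold = config$vif_threshold,
    remove_level = config$remove_level,
    rule = list(p75_cutoff_hu = config$rule$p75_cutoff_hu,
                entropy_cutoff_bits = config$rule$entropy_cutoff_bits)
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}
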