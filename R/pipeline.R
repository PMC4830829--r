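# End-to-end orchestration: simulate -> extract -> select -> predict ->
# report, with explicit seeding, per-stage artifacts and a manifest that
# suffices to re-run bit-identically.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Any stochastic
#' step derives its seed from the single `seed` field, so two runs with the
#' same configuration are identical.
#'
#' @param mode `"eeg"` or `"fmri"`.
#' @param seed Master seed.
#' @param n_subjects Subjects to simulate (ignored when `input_dir` points at
#'   an existing cohort).
#' @param input_dir Optional directory with a cohort written by
#'   [write_cohort()]; when `NULL` a synthetic cohort is generated.
#' @param synth Optional list of overrides passed to [synth_config()].
#' @param pre_window,post_window Analysis windows, ms (EEG).
#' @param window_ms,step_ms,freq_range STFT settings (EEG).
#' @param tf_log Use log10 spectrogram power (default `FALSE`).
#' @param peak_lag_scans Peak-scan lag (fMRI, default 4).
#' @param n_components PLSR components per subject.
#' @param point_alpha,n_perm,cluster_alpha Pattern-selection settings.
#' @param svm_cost,svm_epsilon Decoder hyperparameters.
#' @param aggregation `"mean"` or `"pixels"` predictor aggregation.
#' @param selection_mode `"paper-faithful"` (patterns identified once on the
#'   full cohort before per-subject LOOCV) or `"loso"` (patterns re-identified
#'   with the predicted subject left out, avoiding the selection circularity).
#' @param threshold High/low pain class boundary (VAS 5).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("eeg", "fmri"), seed = 1L, n_subjects = 30L,
                       input_dir = NULL, synth = list(),
                       pre_window = c(-500, 0), post_window = c(0, 1000),
                       window_ms = 200, step_ms = 10, freq_range = c(1, 100),
                       tf_log = FALSE, peak_lag_scans = 4L,
                       n_components = 3L, point_alpha = 0.05,
                       n_perm = 1000L, cluster_alpha = 0.05,
                       svm_cost = 1, svm_epsilon = 0.1,
                       aggregation = c("mean", "pixels"),
                       selection_mode = c("paper-faithful", "loso"),
                       threshold = 5) {
  structure(
    list(mode = match.arg(mode), seed = as.integer(seed),
         n_subjects = as.integer(n_subjects), input_dir = input_dir,
         synth = synth, pre_window = pre_window, post_window = post_window,
         window_ms = window_ms, step_ms = step_ms, freq_range = freq_range,
         tf_log = tf_log, peak_lag_scans = as.integer(peak_lag_scans),
         n_components = as.integer(n_components), point_alpha = point_alpha,
         n_perm = as.integer(n_perm), cluster_alpha = cluster_alpha,
         svm_cost = svm_cost, svm_epsilon = svm_epsilon,
         aggregation = match.arg(aggregation),
         selection_mode = match.arg(selection_mode), threshold = threshold),
    class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round trip is lossless for every configuration field.
#'
#' @param path YAML file path.
#' @param cfg A `run_config`.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Per-subject feature extraction (normalized), shared by stages.
extract_cohort_features <- function(cohort, cfg) {
  lapply(cohort$subjects, function(s) {
    fm <- if (cohort$mode == "eeg") {
      specs <- lapply(seq_len(nrow(s$epochs)), function(i)
        compute_spectrogram(
          eeg_epoch(s$epochs[i, ], cohort$fs, cohort$t0_offset_ms),
          window_ms = cfg$window_ms, step_ms = cfg$step_ms,
          freq_range = cfg$freq_range, log_power = cfg$tf_log))
      extract_tf_features(specs, s$meta, cfg$pre_window, cfg$post_window)
    } else {
      extract_bold_features(s$bold, s$mask, s$onsets_s, s$tr_s,
                            cfg$peak_lag_scans, s$meta)
    }
    normalize_by_energy(fm)
  })
}

discover_patterns <- function(fms, cfg, seed) {
  sm <- subject_coefficient_maps(fms, cfg$n_components)
  gpm <- cluster_permutation_test(sm$maps, sm$coords, sm$phase, sm$grid,
                                  point_alpha = cfg$point_alpha,
                                  n_perm = cfg$n_perm, seed = seed)
  list(maps = sm, gpm = gpm,
       patterns = extract_patterns(gpm, cfg$cluster_alpha))
}

decode_cohort <- function(fms, patterns, cfg) {
  post_patterns <- Filter(function(p) p$phase == "post", patterns)
  sets <- list()
  if (length(patterns) > 0L) sets[["Pre+Post"]] <- patterns
  if (length(post_patterns) > 0L) sets[["Post"]] <- post_patterns
  per_subject <- list()
  skipped <- data.frame(subject = character(0), feature_set = character(0),
                        reason = character(0))
  for (set_name in names(sets)) {
    for (sid in names(fms)) {
      fm <- fms[[sid]]
      # classification sees raw-scale features (stimulus-driven amplitude is
      # informative about high/low pain); regression predicts within-energy
      # fluctuation from normalized features and maps back to the VAS scale
      Xp_cls <- aggregate_pattern_features(fm, sets[[set_name]],
                                           cfg$aggregation, scale = "raw")
      Xp_reg <- aggregate_pattern_features(fm, sets[[set_name]],
                                           cfg$aggregation)
      cls <- tryCatch(
        loocv_classify(Xp_cls, fm$meta$rating, cfg$threshold, cfg$svm_cost,
                       set_name),
        error = function(e) e)
      if (inherits(cls, "error")) {
        skipped <- rbind(skipped, data.frame(
          subject = sid, feature_set = set_name,
          reason = conditionMessage(cls)))
        next
      }
      reg <- loocv_regress(Xp_reg, fm$meta$rating, fm$meta$energy, cfg$svm_cost,
                           cfg$svm_epsilon, "raw", set_name)
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject = sid, feature_set = set_name,
        accuracy = cls$metrics$accuracy,
        sensitivity = cls$metrics$sensitivity,
        specificity = cls$metrics$specificity,
        mae = reg$metrics$mae, n_trials = cls$n_trials)
    }
  }
  list(per_subject = do.call(rbind, per_subject) %||% data.frame(),
       skipped = skipped, sets = names(sets))
}

compare_sets_table <- function(per_subject) {
  if (nrow(per_subject) == 0L ||
      !all(c("Pre+Post", "Post") %in% per_subject$feature_set))
    return(data.frame())
  a <- per_subject[per_subject$feature_set == "Pre+Post", ]
  b <- per_subject[per_subject$feature_set == "Post", ]
  common <- intersect(a$subject, b$subject)
  a <- a[match(common, a$subject), ]
  b <- b[match(common, b$subject), ]
  rows <- lapply(c("accuracy", "sensitivity", "specificity", "mae"),
                 function(metric) {
    cmp <- compare_feature_sets(stats::setNames(a[[metric]], common),
                                stats::setNames(b[[metric]], common),
                                metric = metric)
    data.frame(metric = metric, mean_pre_post = mean(a[[metric]]),
               mean_post = mean(b[[metric]]), mean_diff = cmp$mean_diff,
               t = cmp$t, p = cmp$p, n = cmp$n, flag = cmp$flag)
  })
  do.call(rbind, rows)
}

#' Run the full decoding pipeline
#'
#' Simulates (or loads) a cohort, extracts and normalizes features, discovers
#' group-level pain-related patterns, decodes single-trial pain for the
#' "Pre+Post" and "Post" feature sets and for each individual pattern, and
#' writes a report bundle: per-subject metrics, paired feature-set
#' comparisons, the pattern ranking table, serialized patterns, and a
#' manifest with the configuration and seeds. With
#' `selection_mode = "loso"`, each subject's predictors come from patterns
#' re-identified on all other subjects.
#'
#' @param cfg A [run_config()].
#' @param out_dir Directory for the report bundle (created; `NULL` skips
#'   writing).
#' @return Invisibly, a list with `cohort`, `features`, `selection`
#'   (`gpm` + `patterns`), `decoding`, `comparisons`, `ranking`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- if (!is.null(cfg$input_dir)) {
    read_cohort(cfg$input_dir)
  } else {
    sargs <- utils::modifyList(
      list(n_subjects = cfg$n_subjects, seed = derive_seed(cfg$seed, 1L),
           mode = cfg$mode, window_ms = cfg$window_ms, step_ms = cfg$step_ms,
           freq_range = cfg$freq_range, peak_lag_scans = cfg$peak_lag_scans),
      cfg$synth)
    generate_cohort(do.call(synth_config, sargs))
  }
  fms <- extract_cohort_features(cohort, cfg)

  sel <- discover_patterns(fms, cfg, seed = derive_seed(cfg$seed, 2L))
  patterns <- sel$patterns

  if (cfg$selection_mode == "paper-faithful") {
    dec <- decode_cohort(fms, patterns, cfg)
  } else {
    rows <- list(); skipped <- list()
    for (sid in names(fms)) {
      sel_s <- discover_patterns(fms[names(fms) != sid], cfg,
                                 seed = derive_seed(cfg$seed, 2L))
      d <- decode_cohort(fms[sid], sel_s$patterns, cfg)
      rows[[sid]] <- d$per_subject
      skipped[[sid]] <- d$skipped
    }
    dec <- list(per_subject = do.call(rbind, rows),
                skipped = do.call(rbind, skipped),
                sets = c("Pre+Post", "Post"))
  }
  comparisons <- compare_sets_table(dec$per_subject)

  ranking <- if (length(patterns) >= 2L) {
    rank_patterns(fms, patterns, cfg$threshold, cfg$svm_cost, cfg$svm_epsilon,
                  seed = derive_seed(cfg$seed, 3L))
  } else data.frame()

  manifest <- list(
    package_version = as.character(utils::packageVersion("paindecode")),
    config = unclass(cfg),
    seeds = list(simulate = derive_seed(cfg$seed, 1L),
                 permutation = derive_seed(cfg$seed, 2L),
                 ranking = derive_seed(cfg$seed, 3L)),
    selection_mode = cfg$selection_mode,
    n_subjects = length(cohort$subjects),
    n_patterns = length(patterns),
    excluded_subjects = sel$maps$excluded,
    skipped_decoding = dec$skipped)

  result <- list(cohort = cohort, features = fms, selection = sel,
                 decoding = dec, comparisons = comparisons, ranking = ranking,
                 manifest = manifest)
  if (!is.null(out_dir)) write_report(result, out_dir)
  invisible(result)
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$decoding$per_subject,
                   file.path(out_dir, "per_subject_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ranking, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)
  write_group_map(result$selection$gpm, result$selection$patterns,
                  file.path(out_dir, "patterns.json"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
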