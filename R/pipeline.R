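## Night- and cohort-level orchestration: raw recording -> band streams ->
## bouts/events -> refined latencies -> per-case profiles -> LOOCV metrics.

#' Analysis configuration
#'
#' Bundles every tunable of the analysis chain with its default. Detection
#' thresholds not fixed by the published method (bout MAD threshold, merge
#' gaps, pairing radius) are exposed here so they are auditable.
#'
#' @param window_s analysis window length, seconds.
#' @param bout_threshold_mads,bout_merge_s,bout_min_s bout detection rule.
#' @param event_threshold_sds,event_sustain_s,event_merge_s 1-SD event rule.
#' @param pairing_radius_s bout-event pairing radius, seconds.
#' @param refine use model-based sub-sample onset refinement.
#' @param ramp_s,event_duration_s,resp_freq_hz model constants shared with the
#'   generator (rise/fall ramp, total upregulation duration, nominal
#'   respiratory frequency).
#' @param decimate decimation factor for the refinement grid; `NULL` (the
#'   default) selects 9 (6 Hz) for clean recordings and 18 (3 Hz) for noisy
#'   ones, judged by out-of-band energy — under noise the grid resolution is
#'   not the accuracy limit, and the coarser grid halves the runtime.
#' @param bin_ms,range_ms,min_windows profile histogram specification.
#' @param max_latency_rule `"abs"` or `"signed"` window-maximum rule.
#' @return an `smrr_analysis_config`.
#' @export
analysis_config <- function(window_s = 600,
                            bout_threshold_mads = 4, bout_merge_s = 10,
                            bout_min_s = 2,
                            event_threshold_sds = 1, event_sustain_s = 3,
                            event_merge_s = 5,
                            pairing_radius_s = 30,
                            refine = TRUE,
                            ramp_s = 2, event_duration_s = 20,
                            resp_freq_hz = 0.366,
                            decimate = NULL,
                            bin_ms = 20, range_ms = c(-1000, 1000),
                            min_windows = 5,
                            max_latency_rule = "abs") {
  cfg <- as.list(environment())
  pos <- unlist(cfg[c("window_s", "bout_threshold_mads", "bout_merge_s",
                      "bout_min_s", "event_threshold_sds", "event_sustain_s",
                      "event_merge_s", "pairing_radius_s", "ramp_s",
                      "event_duration_s", "resp_freq_hz", "bin_ms",
                      "min_windows")])
  if (!all(is.finite(c(pos, cfg$range_ms))) || any(pos <= 0))
    stop("analysis_config: thresholds must be finite and positive")
  class(cfg) <- "smrr_analysis_config"
  cfg
}

#' Process one night: detection, pairing and refined latencies
#'
#' Runs the full per-night chain: channel aggregation, band separation, bout
#' detection, instantaneous respiratory rate, 10-min windowing, 1-SD event
#' detection, pairing, and (by default) model-based latency refinement.
#'
#' @param rec an `smrr_recording`.
#' @param acfg an [analysis_config()].
#' @return list with `samples` (latency samples across windows), `bouts`,
#'   `windows`, `rate_usable`, `n_events`.
#' @export
process_night <- function(rec, acfg = analysis_config()) {
  stopifnot(inherits(rec, "smrr_recording"))
  fs <- rec$sampling_rate
  comp <- aggregate_channels(rec, keep_channels = acfg$refine)
  sm_stream <- separate_bands(comp$sm, fs)$sm
  rr_stream <- separate_bands(comp$rr, fs)$rr
  bouts <- detect_sm_bouts(sm_stream, fs,
                           threshold_mads = acfg$bout_threshold_mads,
                           merge_gap = acfg$bout_merge_s,
                           min_duration = acfg$bout_min_s)
  rate <- instantaneous_rr(rr_stream, fs)
  windows <- segment_windows(nrow(rec$signal) / fs, acfg$window_s,
                             rec$night_index)
  empty <- data.frame(night = integer(0), window = integer(0),
                      bout_onset_s = numeric(0), event_onset_s = numeric(0),
                      latency_ms = numeric(0))
  if (!rate$usable || nrow(windows) == 0L)
    return(list(samples = empty, bouts = bouts, windows = windows,
                rate_usable = rate$usable, n_events = 0L))
  dec <- acfg$decimate
  if (is.null(dec)) {
    ## out-of-band noise estimate on the raw composite (content is < 1.5 Hz)
    nz <- stats::sd(band_filter(comp$rr, fs, 3, 9, 0.5, 0.5))
    dec <- if (nz < 0.004 * stats::sd(comp$rr)) 9L else 18L
  }
  ctx <- if (acfg$refine)
    refine_context(comp$rr, fs, ramp = acfg$ramp_s,
                   event_duration = acfg$event_duration_s,
                   resp_freq = acfg$resp_freq_hz,
                   decimate = dec,
                   channels_dec = comp$channels_dec, weights = comp$weights)
  else NULL
  samples <- list()
  n_events <- 0L
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    ev <- detect_rr_events(rate, w,
                           threshold_sds = acfg$event_threshold_sds,
                           sustain_s = acfg$event_sustain_s,
                           merge_s = acfg$event_merge_s)
    n_events <- n_events + nrow(ev)
    bw <- bouts[bouts$onset_s >= w$start_s & bouts$onset_s < w$end_s, ,
                drop = FALSE]
    samples[[k]] <- pair_and_latency(bw, ev, w, ctx = ctx,
                                     radius_s = acfg$pairing_radius_s)
  }
  samples <- do.call(rbind, c(list(empty), samples))
  list(samples = samples, bouts = bouts, windows = windows,
       rate_usable = rate$usable, n_events = n_events)
}

#' Latency profile of one cohort case (both nights pooled)
#'
#' @param cohort an `smrr_cohort`.
#' @param case_id case identifier.
#' @param acfg an [analysis_config()].
#' @return list with `profile` (an `smrr_profile`), `samples`, and per-night
#'   diagnostic counts.
#' @export
case_latency_profile <- function(cohort, case_id, acfg = analysis_config()) {
  samples <- list()
  diag <- list()
  for (night in 1:2) {
    rec <- cohort_night(cohort, case_id, night)$recording
    pn <- process_night(rec, acfg)
    samples[[night]] <- pn$samples
    diag[[night]] <- list(n_bouts = nrow(pn$bouts), n_events = pn$n_events,
                          rate_usable = pn$rate_usable)
    rm(rec)
  }
  samples <- do.call(rbind, samples)
  maxima <- c()
  if (nrow(samples) > 0) {
    key <- interaction(samples$night, samples$window, drop = TRUE)
    maxima <- vapply(split(samples$latency_ms, key), window_max_latency,
                     0, rule = acfg$max_latency_rule)
  }
  list(profile = case_profile(maxima, case_id, bin_ms = acfg$bin_ms,
                              range_ms = acfg$range_ms,
                              min_windows = acfg$min_windows),
       samples = samples, diagnostics = diag)
}

#' Profiles and feature matrix for a whole synthetic cohort
#'
#' @param cohort an `smrr_cohort`.
#' @param acfg an [analysis_config()].
#' @param verbose print one line per case.
#' @return list with `profiles` (named list), `features` (matrix), `labels`,
#'   `samples` (pooled latency samples), `diagnostics`.
#' @export
cohort_profiles <- function(cohort, acfg = analysis_config(), verbose = FALSE) {
  ids <- cohort$manifest$case_id
  profiles <- vector("list", length(ids)); names(profiles) <- ids
  samples <- list(); diagnostics <- list()
  for (id in ids) {
    cl <- case_latency_profile(cohort, id, acfg)
    profiles[[id]] <- cl$profile
    samples[[id]] <- if (nrow(cl$samples)) cbind(case_id = id, cl$samples) else NULL
    diagnostics[[id]] <- cl$diagnostics
    if (verbose)
      message(sprintf("%s: %d usable windows, median max %.0f ms", id,
                      cl$profile$n_usable_windows,
                      stats::median(cl$profile$maxima_ms)))
  }
  features <- do.call(rbind, lapply(profiles, features_from_profile))
  rownames(features) <- ids
  list(profiles = profiles, features = features,
       labels = cohort$manifest$label,
       samples = do.call(rbind, samples), diagnostics = diagnostics)
}

#' LOOCV metrics for one or more classifier families
#'
#' @param features case-by-feature matrix (rows named by case).
#' @param labels labels in `{"MCI", "NC"}`.
#' @param families classifier families to evaluate.
#' @param seed seed passed to every [classifier_spec()].
#' @return named list per family: `scores` (data frame) and `roc`
#'   (an `smrr_roc`).
#' @export
evaluate_cohort <- function(features, labels,
                            families = c("neural_network", "gaussian",
                                         "kernel", "latency_threshold"),
                            seed = 1L) {
  out <- list()
  for (fam in families) {
    spec <- classifier_spec(fam, seed = seed)
    sc <- loocv_scores(features, labels, spec)
    out[[fam]] <- list(scores = sc, roc = roc_metrics(sc$score, sc$label))
  }
  out
}

#' Full pipeline configuration
#'
#' A serializable bundle of generator, analysis and classifier settings plus
#' the global seed. `pipeline_config_save()` / `pipeline_config_load()`
#' round-trip it through JSON; unknown keys in a loaded file are rejected.
#'
#' @param generator a [generator_config()] (or list of overrides).
#' @param analysis an [analysis_config()] (or list of overrides).
#' @param n_per_class cohort size per class.
#' @param mci_latency_params,nc_latency_params class latency distributions.
#' @param families classifier families.
#' @param seed global seed (mandatory, never defaulted silently).
#' @param out_dir output directory for persisted artifacts.
#' @param stages stages to run, subset of
#'   `c("simulate", "latency", "classify")`.
#' @return an `smrr_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            analysis = analysis_config(),
                            n_per_class = 20L,
                            mci_latency_params = list(mean = -50, sd = 40),
                            nc_latency_params = list(mean = 150, sd = 40),
                            families = c("neural_network", "gaussian",
                                         "kernel", "latency_threshold"),
                            seed,
                            out_dir = NULL,
                            stages = c("simulate", "latency", "classify")) {
  if (missing(seed) || is.null(seed))
    stop("pipeline_config: seed is mandatory")
  if (is.list(generator) && !inherits(generator, "smrr_generator_config"))
    generator <- do.call(generator_config, generator)
  if (is.list(analysis) && !inherits(analysis, "smrr_analysis_config"))
    analysis <- do.call(analysis_config, analysis)
  bad <- setdiff(stages, c("simulate", "latency", "classify"))
  if (length(bad)) stop("pipeline_config: unknown stages: ", paste(bad, collapse = ", "))
  structure(list(generator = generator, analysis = analysis,
                 n_per_class = as.integer(n_per_class),
                 mci_latency_params = mci_latency_params,
                 nc_latency_params = nc_latency_params,
                 families = families, seed = as.integer(seed),
                 out_dir = out_dir, stages = stages),
            class = "smrr_pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg an `smrr_pipeline_config`.
#' @param path JSON file path.
#' @export
pipeline_config_save <- function(cfg, path) {
  stopifnot(inherits(cfg, "smrr_pipeline_config"))
  x <- unclass(cfg)
  x$generator <- unclass(x$generator)
  x$analysis <- unclass(x$analysis)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
pipeline_config_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("generator", "analysis", "n_per_class", "mci_latency_params",
             "nc_latency_params", "families", "seed", "out_dir", "stages")
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("pipeline_config_load: unknown keys: ",
                        paste(bad, collapse = ", "))
  gk <- setdiff(names(x$generator), names(formals(generator_config)))
  if (length(gk)) stop("pipeline_config_load: unknown generator keys: ",
                       paste(gk, collapse = ", "))
  ak <- setdiff(names(x$analysis), names(formals(analysis_config)))
  if (length(ak)) stop("pipeline_config_load: unknown analysis keys: ",
                       paste(ak, collapse = ", "))
  pipeline_config(generator = as.list(x$generator),
                  analysis = as.list(x$analysis),
                  n_per_class = x$n_per_class,
                  mci_latency_params = as.list(x$mci_latency_params),
                  nc_latency_params = as.list(x$nc_latency_params),
                  families = x$families, seed = x$seed,
                  out_dir = x$out_dir, stages = x$stages)
}

#' Run the full pipeline: simulate, latency profiling, classification
#'
#' Executes the configured stages in order, persisting intermediates to
#' `out_dir` when given (manifest and truths as CSV, profiles as JSON,
#' latency samples as CSV, metrics as JSON). Deterministic given the seed.
#'
#' @param cfg an [pipeline_config()].
#' @param verbose print progress.
#' @return an `smrr_run_report`: cohort manifest, per-case window counts and
#'   flags, metrics per classifier family, parameter echo, seed and package
#'   version.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "smrr_pipeline_config"))
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  cohort <- generate_cohort(cfg$n_per_class, cfg$mci_latency_params,
                            cfg$nc_latency_params, cfg$generator, cfg$seed)
  if (!is.null(out)) {
    write_manifest_csv(cohort$manifest, file.path(out, "manifest.csv"))
    tdir <- file.path(out, "truth"); dir.create(tdir, showWarnings = FALSE)
    for (id in cohort$manifest$case_id)
      for (night in 1:2)
        write_truth_csv(cohort$truth[[id]][[night]],
                        file.path(tdir, sprintf("%s_n%d.csv", id, night)), night)
  }
  report <- list(seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("smrr")),
                 parameters = list(generator = unclass(cfg$generator),
                                   analysis = unclass(cfg$analysis)),
                 manifest = cohort$manifest)
  if (!"latency" %in% cfg$stages) {
    class(report) <- "smrr_run_report"
    return(report)
  }
  cp <- cohort_profiles(cohort, cfg$analysis, verbose = verbose)
  report$case_summary <- data.frame(
    case_id = cohort$manifest$case_id,
    label = cohort$manifest$label,
    n_usable_windows = vapply(cp$profiles, function(p) p$n_usable_windows, 0L),
    low_coverage = vapply(cp$profiles, function(p) p$low_coverage, FALSE),
    median_max_ms = vapply(cp$profiles, function(p)
      if (p$n_usable_windows) stats::median(p$maxima_ms) else NA_real_, 0))
  if (!is.null(out)) {
    utils::write.csv(cp$samples, file.path(out, "latency_samples.csv"),
                     row.names = FALSE)
    pdir <- file.path(out, "profiles"); dir.create(pdir, showWarnings = FALSE)
    for (id in names(cp$profiles))
      write_profile_json(cp$profiles[[id]], file.path(pdir, paste0(id, ".json")))
  }
  if ("classify" %in% cfg$stages) {
    ev <- evaluate_cohort(cp$features, cp$labels, cfg$families, cfg$seed)
    report$metrics <- lapply(ev, function(e) {
      r <- e$roc
      list(auc = r$auc, threshold = r$threshold,
           sensitivity = r$sensitivity, specificity = r$specificity,
           ppv = r$ppv, npv = r$npv,
           confusion = list(tp = r$confusion$tp, tn = r$confusion$tn,
                            fp = r$confusion$fp, fn = r$confusion$fn))
    })
    report$scores <- do.call(rbind, lapply(names(ev), function(f)
      cbind(family = f, ev[[f]]$scores)))
    if (!is.null(out)) {
      jsonlite::write_json(report$metrics, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(report$scores, file.path(out, "scores.csv"),
                       row.names = FALSE)
      for (f in names(ev))
        utils::write.csv(ev[[f]]$roc$curve,
                         file.path(out, paste0("roc_", f, ".csv")),
                         row.names = FALSE)
    }
  }
  class(report) <- "smrr_run_report"
  report
}

#' @export
print.smrr_run_report <- function(x, ...) {
  cat(sprintf("<smrr_run_report> seed %d, %d cases\n", x$seed,
              nrow(x$manifest)))
  if (!is.null(x$metrics)) {
    for (f in names(x$metrics)) {
      m <- x$metrics[[f]]
      cat(sprintf("  %-18s AUC %.3f sens %.2f spec %.2f ppv %s npv %s\n",
                  f, m$auc, m$sensitivity, m$specificity,
                  format(m$ppv, digits = 2), format(m$npv, digits = 2)))
    }
  }
  invisible(x)
}
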