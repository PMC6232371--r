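# End-to-end orchestration: synthetic generation (or manifest input) ->
# artifact masking -> band powers -> coherence -> EMG -> behavior -> stats,
# written as tidy CSV tables with a run log and a resolved config snapshot.

#' Pipeline run configuration
#'
#' Exactly one input source: a [cohort_spec()] (sessions are generated on
#' the fly, one at a time) or a manifest path (sessions are read from
#' disk).
#'
#' @param cohort a [cohort_spec()], or `NULL`.
#' @param manifest path to a manifest JSON, or `NULL`.
#' @param out_dir output directory for tables, log and config snapshot.
#' @param scheme a [band_scheme()].
#' @param params [spectral_params()].
#' @param z_thresh,flat_thresh_uV artifact-rejection thresholds
#'   (see [detect_artifacts()]).
#' @param seed optional override of the cohort seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, manifest = NULL, out_dir,
                       scheme = band_scheme(), params = spectral_params(),
                       z_thresh = 6, flat_thresh_uV = 0.5, seed = NULL) {
  if (is.null(cohort) == is.null(manifest))
    stopf("exactly one of 'cohort' or 'manifest' must be given")
  if (!is.null(cohort) && !is.null(seed)) cohort$seed <- seed
  structure(list(cohort = cohort, manifest = manifest, out_dir = out_dir,
                 scheme = scheme, params = params, z_thresh = z_thresh,
                 flat_thresh_uV = flat_thresh_uV),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized top-level keys: `out_dir`, `seed`, `z_thresh`,
#' `flat_thresh_uV`, `manifest`, and a `cohort` mapping whose entries are
#' passed to [cohort_spec()] (scalar fields only; component/coupling lists
#' keep their programmatic defaults).
#'
#' @param path YAML file path.
#' @param out_dir optional override of the configured output directory.
#' @return A [run_config()].
#' @export
load_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  cohort <- NULL
  if (is.null(cfg$manifest)) {
    args <- cfg$cohort %||% list()
    keep <- intersect(names(args),
                      c("n_animals_per_group", "groups", "days", "fs",
                        "pre_duration_s", "post_duration_s", "seed"))
    cohort <- do.call(cohort_spec, args[keep])
  }
  run_config(cohort = cohort, manifest = cfg$manifest,
             out_dir = out_dir %||% cfg$out_dir %||% stop("out_dir required"),
             z_thresh = cfg$z_thresh %||% 6,
             flat_thresh_uV = cfg$flat_thresh_uV %||% 0.5,
             seed = cfg$seed)
}

coherence_pairs_for <- function(labels) {
  ecog <- setdiff(labels, "EMG")
  if (length(ecog) < 2) return(list())
  utils::combn(ecog, 2, simplify = FALSE)
}

analyze_session <- function(rec, beh, config) {
  mask <- detect_artifacts(rec, config$z_thresh, config$flat_thresh_uV,
                           config$params$win_s, config$params$hop_s)
  ecog <- setdiff(rec$channel_labels, "EMG")
  bp <- recording_band_powers(rec, mask, config$scheme, config$params, ecog)
  coh <- recording_coherence(rec, coherence_pairs_for(rec$channel_labels),
                             mask, config$scheme, config$params)
  emg <- if ("EMG" %in% rec$channel_labels)
    emg_metrics(rec$data["EMG", ], rec$fs, mask, config$params,
                session = rec$session) else NULL
  behav <- NULL
  if (!is.null(beh)) {
    av <- average_reviewers(beh)
    behav <- cbind(session_key_df(rec$session),
                   data.frame(mean_score = mean(av$mean_score),
                              max_epoch_score = max(av$mean_score),
                              aw_percent = aw_percent(beh)))
  }
  list(band_power = bp, coherence = coh, emg = emg, behavior = behav,
       retention = retained_fraction(mask))
}

#' Run the full analysis over a cohort
#'
#' Processes every session of the configured input (generating synthetic
#' sessions one at a time, or reading them from a manifest), applies
#' artifact rejection, computes band powers, coherence summaries, EMG
#' metrics and behavior summaries, normalizes the longitudinal measures to
#' the baseline day, and runs the statistical battery (within-animal
#' Friedman tests of day effects on normalized post-injection measures;
#' Pearson correlations between dystonia score and per-band coherence).
#' All tables are written as CSV under `config$out_dir` together with
#' `run.log` (per-session segment retention) and a resolved config
#' snapshot; the run is fully determined by the cohort seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of the result tables (`band_power`,
#'   `coherence`, `emg`, `behavior`, `stats`, `correlations`,
#'   `retention`) and `truth` (for synthetic input).
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat(sprintf("[%s] pipeline run started\n", format(Sys.time())), file = log_path)
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  bp <- list(); coh <- list(); emg <- list(); behav <- list(); ret <- list()
  truth <- list()
  process <- function(rec, beh, id) {
    res <- tryCatch(analyze_session(rec, beh, config), error = function(e)
      stopf("stage failure in session %s: %s", id, conditionMessage(e)))
    bp[[id]] <<- res$band_power
    coh[[id]] <<- res$coherence
    if (!is.null(res$emg)) emg[[id]] <<- res$emg
    if (!is.null(res$behavior)) behav[[id]] <<- res$behavior
    ret[[id]] <<- cbind(session_key_df(rec$session),
                        data.frame(retained = res$retention))
    logf("session %s: %d x %d samples, retention %.3f", id,
         nrow(rec$data), ncol(rec$data), res$retention)
  }
  if (!is.null(config$cohort)) {
    spec <- config$cohort
    for (gi in seq_along(spec$groups)) for (animal in seq_len(spec$n_animals_per_group))
      for (day in 0:(spec$days - 1)) for (phase in c("pre", "post")) {
        ses <- generate_session(spec, spec$groups[gi], animal, day, phase)
        id <- format(ses$recording$session)
        truth[[id]] <- ses$truth
        process(ses$recording, ses$behavior, id)
      }
  } else {
    man <- load_manifest(config$manifest)
    fs <- attr(man, "fs")
    for (i in seq_len(nrow(man))) {
      key <- session_key(man$animal_id[i], man$group[i], man$day[i], man$phase[i])
      rec <- read_recording(man$signal[i], fs = fs, session = key)
      beh <- NULL
      if ("behavior_scores" %in% names(man) && !is.na(man$behavior_scores[i]) &&
          file.exists(man$behavior_scores[i]))
        beh <- read_behavior(man$behavior_scores[i],
                             if ("behavior_intervals" %in% names(man))
                               man$behavior_intervals[i] else NULL,
                             key, duration_s = recording_duration(rec))
      process(rec, beh, format(key))
    }
  }
  band_power <- baseline_normalize(band_power_table(bp))
  coherence <- coherence_baseline_normalize(do.call(rbind, coh))
  rownames(coherence) <- NULL
  emg_tab <- if (length(emg)) do.call(rbind, emg) else NULL
  behavior_tab <- if (length(behav)) do.call(rbind, behav) else NULL
  retention <- do.call(rbind, ret)
  rownames(retention) <- NULL
  logf("mean retention: %.3f", mean(retention$retained))

  stats_tab <- cohort_day_stats(band_power, coherence)
  corr_tab <- if (!is.null(behavior_tab))
    correlate_behavior_signal(coherence[coherence$phase == "post", ],
                              behavior_tab, value_col = "msc",
                              strata = c("pair", "band")) else NULL

  wr <- function(x, f) if (!is.null(x)) write.csv(x, file.path(config$out_dir, f),
                                                  row.names = FALSE)
  wr(band_power, "band_power.csv")
  wr(coherence, "coherence.csv")
  wr(emg_tab, "emg_metrics.csv")
  wr(behavior_tab, "behavior.csv")
  wr(stats_tab, "stats.csv")
  wr(corr_tab, "correlations.csv")
  wr(retention, "retention.csv")
  snapshot <- list(scheme = unclass_spec(config$scheme),
                   params = unclass_spec(config$params),
                   z_thresh = config$z_thresh,
                   flat_thresh_uV = config$flat_thresh_uV,
                   cohort = if (!is.null(config$cohort)) unclass_spec(config$cohort),
                   manifest = config$manifest)
  jsonlite::write_json(snapshot, file.path(config$out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  logf("[%s] pipeline run finished", format(Sys.time()))
  invisible(list(band_power = band_power, coherence = coherence,
                 emg = emg_tab, behavior = behavior_tab, stats = stats_tab,
                 correlations = corr_tab, retention = retention,
                 truth = truth))
}

# Within-animal Friedman test of the day effect on normalized post-phase
# measures, one row per (group, channel/pair, band). Falls back to one-way
# ANOVA when the within-animal pairing is broken (missing sessions).
cohort_day_stats <- function(band_power, coherence) {
  one <- function(d, label, series_col) {
    d <- d[d$phase == "post", ]
    if (length(unique(d$day)) < 2) return(NULL)
    m <- tryCatch({
      wide <- reshape(d[c("animal_id", "day", "normalized")],
                      idvar = "animal_id", timevar = "day", direction = "wide")
      as.matrix(wide[, -1])
    }, error = function(e) NULL)
    if (!is.null(m) && !anyNA(m) && nrow(m) >= 2) {
      res <- friedman_test(m)
    } else {
      groups <- split(d$normalized, d$day)
      if (any(vapply(groups, length, 1L) < 2)) return(NULL)  # too few animals
      res <- oneway_anova(groups)
      res$note <- "pairing broken; one-way fallback"
    }
    cbind(data.frame(group = d$group[1], series = d[[series_col]][1],
                     band = d$band[1]), res)
  }
  rows <- c(
    lapply(split(band_power, list(band_power$group, band_power$channel,
                                  band_power$band), drop = TRUE),
           one, label = "power", series_col = "channel"),
    lapply(split(coherence, list(coherence$group, coherence$pair,
                                 coherence$band), drop = TRUE),
           one, label = "msc", series_col = "pair"))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
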