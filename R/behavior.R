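# Behavioral scoring: per-epoch dystonia severity (0-4 ordinal scale,
# multiple independent reviewers) and active-wake percentages.

#' Behavior track for one session
#'
#' @param session a [session_key()].
#' @param scores integer matrix, epochs x reviewers, each score in 0..4
#'   (0 = normal motor behavior ... 4 = severe impairment with sustained
#'   dystonic postures). Column names identify reviewers.
#' @param epoch_length_s scoring epoch length in seconds (default 600, i.e.
#'   10-minute epochs).
#' @param aw_intervals data frame with columns `start_s`, `end_s`: intervals
#'   of active-wake (exploratory locomotion) annotation.
#' @param duration_s total recording duration in seconds.
#' @return An object of class `behavior_track`.
#' @export
behavior_track <- function(session, scores, epoch_length_s = 600,
                           aw_intervals = data.frame(start_s = numeric(0), end_s = numeric(0)),
                           duration_s = nrow(scores) * epoch_length_s) {
  scores <- as.matrix(scores)
  if (length(scores) && (any(is.na(scores)) || any(scores < 0 | scores > 4)))
    stopf("dystonia scores must lie in 0..4")
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("reviewer", seq_len(ncol(scores)))
  if (nrow(aw_intervals)) {
    if (any(aw_intervals$end_s <= aw_intervals$start_s))
      stopf("active-wake intervals must have end_s > start_s")
    if (any(aw_intervals$start_s < 0) || any(aw_intervals$end_s > duration_s + 1e-9))
      stopf("active-wake interval outside recording duration")
  }
  structure(list(session = session, scores = scores,
                 epoch_length_s = epoch_length_s,
                 aw_intervals = aw_intervals, duration_s = duration_s),
            class = "behavior_track")
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior> %d epoch(s) x %d reviewer(s), %.0f s, AW%% = %.1f\n",
              nrow(x$scores), ncol(x$scores), x$duration_s,
              aw_percent(x)))
  invisible(x)
}

#' Average reviewer scores per epoch
#'
#' Reviewers score each 10-minute epoch independently; the session-level
#' score is the per-epoch arithmetic mean across reviewers.
#'
#' @param track a [behavior_track()].
#' @return Data frame with `epoch_index` (1-based) and `mean_score` in
#'   \[0, 4\].
#' @export
average_reviewers <- function(track) {
  stopifnot(inherits(track, "behavior_track"))
  sc <- track$scores
  if (ncol(sc) < 1L) stopf("need at least one reviewer")
  bad <- which(sc < 0 | sc > 4 | sc != round(sc), arr.ind = TRUE)
  if (nrow(bad))
    stopf("invalid score %s at epoch %d, reviewer '%s'",
          sc[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(sc)[bad[1, 2]])
  data.frame(epoch_index = seq_len(nrow(sc)), mean_score = rowMeans(sc))
}

# Union length of possibly overlapping/unsorted intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) cur_e <- max(cur_e, end[i])
    else { total <- total + (cur_e - cur_s); cur_s <- start[i]; cur_e <- end[i] }
  }
  total + (cur_e - cur_s)
}

#' Active-wake percentage
#'
#' Percentage of the recording spent in annotated active wake. Overlapping
#' annotations are merged (interval union), so the result does not depend on
#' how intervals were split or ordered.
#'
#' @param track a [behavior_track()].
#' @param total_duration_s total recording duration in seconds; defaults to
#'   the track's own duration.
#' @return AW% in \[0, 100\].
#' @export
aw_percent <- function(track, total_duration_s = track$duration_s) {
  stopifnot(inherits(track, "behavior_track"))
  check_scalar_num(total_duration_s, "total_duration_s", lower = .Machine$double.eps)
  iv <- track$aw_intervals
  if (nrow(iv) && any(iv$end_s > total_duration_s + 1e-9))
    stopf("active-wake interval extends beyond total_duration_s")
  100 * interval_union_length(iv$start_s, iv$end_s) / total_duration_s
}

#' Daily dystonia score profile across a cohort
#'
#' Summarizes per-session reviewer-averaged scores into a per-day mean and
#' standard error, plus the per-epoch time course within each day.
#'
#' @param tracks list of [behavior_track()] objects with session keys.
#' @return List with `per_day` (day, n, mean_score, sem) and `per_epoch`
#'   (day, epoch_index, n, mean_score, sem) data frames.
#' @export
daily_score_profile <- function(tracks) {
  if (!length(tracks)) stopf("need at least one behavior track")
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    av <- average_reviewers(tr)
    cbind(session_key_df(tr$session), av)
  }))
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  per_session <- aggregate(mean_score ~ animal_id + group + day + phase,
                           data = rows, FUN = mean)
  per_day <- do.call(rbind, lapply(split(per_session, per_session$day), function(d) {
    data.frame(day = d$day[1], n = nrow(d), mean_score = mean(d$mean_score),
               sem = sem(d$mean_score))
  }))
  per_epoch <- do.call(rbind, lapply(
    split(rows, list(rows$day, rows$epoch_index), drop = TRUE), function(d) {
      data.frame(day = d$day[1], epoch_index = d$epoch_index[1], n = nrow(d),
                 mean_score = mean(d$mean_score), sem = sem(d$mean_score))
    }))
  per_epoch <- per_epoch[order(per_epoch$day, per_epoch$epoch_index), ]
  rownames(per_day) <- rownames(per_epoch) <- NULL
  list(per_day = per_day, per_epoch = per_epoch)
}

#' Write / read behavior tables
#'
#' Tidy CSV schemas: scores as (animal_id, group, day, phase, epoch_index,
#' reviewer_id, score); intervals as (animal_id, group, day, phase,
#' aw_start_s, aw_end_s).
#'
#' @param track a [behavior_track()].
#' @param scores_path,intervals_path output CSV paths.
#' @return `invisible(NULL)`.
#' @export
write_behavior <- function(track, scores_path, intervals_path) {
  key <- session_key_df(track$session)
  sc <- track$scores
  long <- do.call(rbind, lapply(seq_len(ncol(sc)), function(j) {
    cbind(key, data.frame(epoch_index = seq_len(nrow(sc)),
                          reviewer_id = colnames(sc)[j], score = sc[, j]))
  }))
  write.csv(long, scores_path, row.names = FALSE)
  iv <- cbind(key[rep(1, nrow(track$aw_intervals)), , drop = FALSE],
              data.frame(aw_start_s = track$aw_intervals$start_s,
                         aw_end_s = track$aw_intervals$end_s))
  write.csv(iv, intervals_path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_behavior
#' @param session a [session_key()] for the track being read.
#' @param duration_s recording duration in seconds.
#' @param epoch_length_s scoring epoch length in seconds.
#' @export
read_behavior <- function(scores_path, intervals_path, session, duration_s,
                          epoch_length_s = 600) {
  sc_long <- read.csv(scores_path)
  iv <- if (!is.null(intervals_path) && file.exists(intervals_path))
    read.csv(intervals_path) else data.frame(aw_start_s = numeric(0), aw_end_s = numeric(0))
  reviewers <- sort(unique(sc_long$reviewer_id))
  epochs <- sort(unique(sc_long$epoch_index))
  sc <- matrix(NA_real_, length(epochs), length(reviewers),
               dimnames = list(NULL, reviewers))
  for (i in seq_len(nrow(sc_long)))
    sc[match(sc_long$epoch_index[i], epochs),
       match(sc_long$reviewer_id[i], reviewers)] <- sc_long$score[i]
  behavior_track(session, sc, epoch_length_s = epoch_length_s,
                 aw_intervals = data.frame(start_s = iv$aw_start_s, end_s = iv$aw_end_s),
                 duration_s = duration_s)
}
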