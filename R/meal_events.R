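# Meal-event segmentation: merging staged food logs, density-based
# aggregation of multi-annotator timings, start-time selection by largest
# 3-h incremental AUC, and event qualification by minimum glucose rise.

#' Merge staged food logs into meal logs
#'
#' Participants enter a meal's items in stages (e.g. oatmeal at 10:00,
#' orange juice at 10:15). Item rows at the same minute form one log; logs
#' with the same meal-occasion label within 60 minutes are merged greedily
#' into a single meal log anchored at its first constituent: a log joins the
#' open group if it falls within 60 min of the group's *first* log,
#' otherwise it starts a new group. The merged time is the first log's time.
#'
#' @param food_logs food-log item table (see [read_bundle()]).
#' @param merge_window_min merge window, minutes (default 60).
#' @return data.frame with one row per merged meal log: `participant_id`,
#'   `merged_id`, `occasion`, `merged_time`, `total_calories`, `n_logs`,
#'   `log_keys` (semicolon-joined constituent keys).
#' @export
merge_food_logs <- function(food_logs, merge_window_min = 60) {
  if (!nrow(food_logs)) {
    return(data.frame(participant_id = character(), merged_id = character(),
                      occasion = character(),
                      merged_time = mt_parse(character()),
                      total_calories = numeric(), n_logs = integer(),
                      log_keys = character(), stringsAsFactors = FALSE))
  }
  fl <- food_logs
  fl$log_key <- food_log_key(fl$participant_id, fl$log_time, fl$occasion)
  # collapse item rows -> logs
  agg <- stats::aggregate(calories ~ log_key + participant_id + occasion,
                          data = fl, FUN = sum)
  tm <- fl[!duplicated(fl$log_key), c("log_key", "log_time")]
  logs <- merge(agg, tm, by = "log_key")
  logs <- logs[order(logs$participant_id, logs$occasion, logs$log_time), ]

  out <- list()
  for (key in split(seq_len(nrow(logs)),
                    paste(logs$participant_id, logs$occasion, sep = "\r"))) {
    sub <- logs[key, , drop = FALSE]
    anchor <- sub$log_time[1]
    gid <- cumsum(c(TRUE, rep(FALSE, nrow(sub) - 1)))
    g <- 1L
    for (i in seq_len(nrow(sub))) {
      if (as.numeric(difftime(sub$log_time[i], anchor, units = "mins")) >
          merge_window_min) {
        g <- g + 1L
        anchor <- sub$log_time[i]
      }
      gid[i] <- g
    }
    for (gg in unique(gid)) {
      s2 <- sub[gid == gg, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        participant_id = s2$participant_id[1],
        occasion = s2$occasion[1],
        merged_time = s2$log_time[1],
        total_calories = sum(s2$calories),
        n_logs = nrow(s2),
        log_keys = paste(s2$log_key, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$merged_time), ]
  res$merged_id <- paste0(res$participant_id, ":M",
                          stats::ave(seq_len(nrow(res)), res$participant_id,
                                     FUN = seq_along))
  rownames(res) <- NULL
  res[, c("participant_id", "merged_id", "occasion", "merged_time",
          "total_calories", "n_logs", "log_keys")]
}

#' One-dimensional DBSCAN
#'
#' Density-based clustering on a numeric vector: a point is *core* if at
#' least `min_pts` points (itself included) lie within `eps`; clusters are
#' grown from core points, non-core points within `eps` of a core join as
#' border points, the rest are noise.
#'
#' @param x numeric vector.
#' @param eps neighborhood radius.
#' @param min_pts minimum neighborhood size (self included).
#' @return integer labels, one per point; 0 marks noise.
#' @export
dbscan_1d <- function(x, eps, min_pts = 2) {
  n <- length(x)
  if (!n) return(integer(0))
  d <- abs(outer(x, x, "-"))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Aggregate annotated timings into candidate meal-event groups
#'
#' For each participant-day, clusters the non-unknown annotated timings
#' (hours since midnight) with 1-D DBSCAN, `eps = 1.5` h and
#' `min_samples = 2`, so groups hold at least two timings and sit at least
#' 1.5 h apart; noise points are discarded.
#'
#' @param annotations annotation table (see [read_bundle()]); `unknown`
#'   entries are ignored.
#' @param eps_hours DBSCAN radius in hours.
#' @param min_samples DBSCAN minimum neighborhood size.
#' @return the timing rows that survived clustering, with a `group_id`
#'   column (`participant|date|cluster`).
#' @export
aggregate_annotations <- function(annotations, eps_hours = 1.5,
                                  min_samples = 2) {
  an <- annotations[annotations$source != "unknown" & !is.na(annotations$time), ,
                    drop = FALSE]
  empty <- cbind(an[0, , drop = FALSE],
                 data.frame(group_id = character(), stringsAsFactors = FALSE))
  if (!nrow(an)) return(empty)
  an$.date <- as.character(mt_date(an$time))
  parts <- split(an, paste(an$participant_id, an$.date, sep = "\r"))
  out <- lapply(parts, function(sub) {
    hrs <- mt_minute_of_day(sub$time) / 60
    lab <- dbscan_1d(hrs, eps = eps_hours, min_pts = min_samples)
    sub <- sub[lab != 0L, , drop = FALSE]
    lab <- lab[lab != 0L]
    if (!nrow(sub)) return(NULL)
    sub$group_id <- paste(sub$participant_id, sub$.date, lab, sep = "|")
    sub
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res$.date <- NULL
  rownames(res) <- NULL
  res
}

# Nearest CGM sample to `t` within one nominal interval; NA when absent.
baseline_at <- function(trace, t, interval_min) {
  dt <- abs(as.numeric(difftime(trace$time, t, units = "mins")))
  i <- which.min(dt)
  if (!length(i) || dt[i] > interval_min) return(NA_real_)
  trace$glucose_mgdl[i]
}

# 3-h CGM sub-trace from `t` (inclusive ends), as minutes-from-start.
segment_at <- function(trace, t, window_min = 180) {
  dt <- as.numeric(difftime(trace$time, t, units = "mins"))
  sel <- dt >= 0 & dt <= window_min
  data.frame(minute = dt[sel], glucose_mgdl = trace$glucose_mgdl[sel])
}

# Candidate evaluation shared by select_start_time / qualify_events:
# baseline at the candidate time and iAUC over its 3-h window, or NA when
# CGM coverage is below half the expected sample count.
eval_candidate <- function(trace, t, interval_min) {
  expected <- floor(180 / interval_min) + 1
  base <- baseline_at(trace, t, interval_min)
  seg <- segment_at(trace, t)
  if (is.na(base) || nrow(seg) < max(2, 0.5 * expected))
    return(list(ok = FALSE))
  list(ok = TRUE, baseline = base,
       mgr = mgr_3h(seg$minute, seg$glucose_mgdl, base),
       max_rise = max(seg$glucose_mgdl) - base)
}

#' Select a group's meal-event start time
#'
#' The start time of a candidate group is the member timing with the largest
#' incremental area under the 3-h CGM curve ([mgr_3h()]); ties break to the
#' earliest timing. Candidates whose 3-h window covers less than half the
#' expected CGM samples (or with no baseline sample) are skipped; if no
#' member has coverage the group is discarded (`NULL`).
#'
#' @param times POSIXct member timings of one group.
#' @param trace one participant's glucose trace (`time`, `glucose_mgdl`).
#' @param interval_min nominal CGM interval, minutes.
#' @return list(`start_time`, `baseline`, `mgr`, `max_rise`) or `NULL`.
#' @export
select_start_time <- function(times, trace, interval_min = 15) {
  times <- sort(unique(times))
  best <- NULL
  for (t in seq_along(times)) {
    ev <- eval_candidate(trace, times[t], interval_min)
    if (!ev$ok) next
    if (is.null(best) || ev$mgr > best$mgr + 1e-9)
      best <- list(start_time = times[t], baseline = ev$baseline,
                   mgr = ev$mgr, max_rise = ev$max_rise)
  }
  best
}

#' Qualify candidate groups into meal events
#'
#' A group becomes a meal event when its selected start time lies between
#' 04:00 and 23:59 and the 3-h segment shows a maximum glucose rise of at
#' least `rise_threshold` above the baseline at the start time (inclusive).
#' Each event is linked to the merged meal log that the majority of its
#' corrected timings reference (ties unlinked), and flagged high-agreement
#' when at least `high_agreement_min` distinct annotators' corrected timings
#' for that log fall in the group.
#'
#' @param grouped output of [aggregate_annotations()].
#' @param glucose cohort glucose table.
#' @param merged_logs output of [merge_food_logs()].
#' @param rise_threshold minimum max glucose rise, mg/dL.
#' @param interval_min nominal CGM interval, minutes.
#' @param high_agreement_min corrected-timing quorum for high agreement.
#' @return data.frame of events: `participant_id`, `event_id`, `start_time`,
#'   `baseline_glucose`, `max_rise`, `mgr_3h`, `n_support`, `merged_id`,
#'   `calories`, `high_agreement`.
#' @export
qualify_events <- function(grouped, glucose, merged_logs,
                           rise_threshold = 18.6, interval_min = 15,
                           high_agreement_min = 3) {
  empty <- data.frame(participant_id = character(), event_id = character(),
                      start_time = mt_parse(character()),
                      baseline_glucose = numeric(), max_rise = numeric(),
                      mgr_3h = numeric(), n_support = integer(),
                      merged_id = character(), calories = numeric(),
                      high_agreement = logical(), stringsAsFactors = FALSE)
  if (!nrow(grouped)) return(empty)

  # log_key -> merged_id lookup
  key2merged <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(merged_logs)))
    for (k in strsplit(merged_logs$log_keys[i], ";", fixed = TRUE)[[1]])
      assign(k, merged_logs$merged_id[i], envir = key2merged)
  cal_of <- stats::setNames(merged_logs$total_calories, merged_logs$merged_id)
  traces <- split(glucose, glucose$participant_id)

  rows <- list()
  for (g in split(grouped, grouped$group_id)) {
    pid <- g$participant_id[1]
    trace <- traces[[pid]]
    if (is.null(trace)) next
    sel <- select_start_time(g$time, trace, interval_min)
    if (is.null(sel)) next
    mod <- mt_minute_of_day(sel$start_time)
    if (mod < 240) next                        # events live in 04:00-23:59
    if (sel$max_rise < rise_threshold - 1e-9) next   # inclusive boundary

    corr <- g[g$source == "corrected" & !is.na(g$log_key), , drop = FALSE]
    mids <- vapply(corr$log_key, function(k)
      if (exists(k, envir = key2merged)) get(k, envir = key2merged)
      else NA_character_, "")
    merged_id <- NA_character_
    if (length(mids) && any(!is.na(mids))) {
      tab <- sort(table(mids[!is.na(mids)]), decreasing = TRUE)
      if (length(tab) == 1 || tab[1] > tab[2]) merged_id <- names(tab)[1]
    }
    high <- FALSE
    if (!is.na(merged_id)) {
      n_ann <- length(unique(corr$annotator_id[!is.na(mids) &
                                                 mids == merged_id]))
      high <- n_ann >= high_agreement_min
    }
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = pid, event_id = g$group_id[1],
      start_time = sel$start_time, baseline_glucose = sel$baseline,
      max_rise = sel$max_rise, mgr_3h = sel$mgr, n_support = nrow(g),
      merged_id = merged_id,
      calories = if (is.na(merged_id)) NA_real_ else
        unname(cal_of[merged_id]),
      high_agreement = high, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$participant_id, res$start_time), ]
  rownames(res) <- NULL
  res
}

#' Segment meal events from a study bundle
#'
#' Convenience orchestration: merges food logs, aggregates annotated
#' timings, selects start times and qualifies events.
#'
#' @param bundle a study bundle (see [read_bundle()]).
#' @param eps_hours,min_samples DBSCAN parameters.
#' @param rise_threshold minimum max glucose rise, mg/dL.
#' @param interval_min nominal CGM interval.
#' @return list(`events`, `merged_logs`).
#' @export
segment_meal_events <- function(bundle, eps_hours = 1.5, min_samples = 2,
                                rise_threshold = 18.6, interval_min = 15) {
  merged <- merge_food_logs(bundle$food_logs)
  grouped <- aggregate_annotations(bundle$annotations, eps_hours, min_samples)
  events <- qualify_events(grouped, bundle$glucose, merged,
                           rise_threshold = rise_threshold,
                           interval_min = interval_min)
  list(events = events, merged_logs = merged)
}

#' Intraclass correlation of corrected timings, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC of a
#' complete logs-by-annotators matrix of corrected timings (any common
#' numeric unit).
#'
#' @param mat numeric matrix, rows = logs, columns = annotators; no missing
#'   values.
#' @return ICC estimate in `[-1, 1]`.
#' @export
intraclass_correlation <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("complete cases only: matrix contains NA")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 logs and 2 annotators")
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
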