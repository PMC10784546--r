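# Participant-day records: analysis window, elevated meal count, daily
# steps, baseline glucose, time in range and mean glucose, with the study's
# inclusion rules; plus per-modality adherence summaries.

ELEVATED_LEVELS <- c("0", "1", "2", "3+")

#' Wear mask for one day's step minutes
#'
#' If the step table carries a usable `wear` column it takes precedence.
#' Otherwise non-wear is detected as runs of at least `nonwear_run_min`
#' consecutive zero-step minutes (a simplified surrogate for actigraphy
#' wear-time algorithms; externally computed masks are preferred).
#'
#' @param day_steps step rows of one participant-day, minute order.
#' @param nonwear_run_min minimum zero run length, minutes.
#' @return logical vector, `TRUE` = worn, aligned to `day_steps` rows.
#' @export
wear_mask_of_day <- function(day_steps, nonwear_run_min = 90) {
  if (!nrow(day_steps)) return(logical(0))
  if ("wear" %in% names(day_steps) && any(!is.na(day_steps$wear)))
    return(!is.na(day_steps$wear) & day_steps$wear)
  z <- day_steps$steps == 0
  r <- rle(z)
  nonwear <- rep(r$values & r$lengths >= nonwear_run_min, r$lengths)
  !nonwear
}

#' Analysis window of one participant-day
#'
#' Start = the earlier of the first meal start and the earliest wear minute
#' after 04:00; end = the later of (last meal start + 3 h) and the last wear
#' minute before 23:59. Both are clipped to the 04:00-23:59 bounds.
#'
#' @param meal_minutes meal-event start times, minutes since midnight.
#' @param wear_minutes worn minutes of the day, minutes since midnight.
#' @return `c(start, end)` in minutes since midnight, or `NULL` when the day
#'   has neither meals nor wear (day excluded).
#' @export
day_window <- function(meal_minutes, wear_minutes) {
  wear_minutes <- wear_minutes[wear_minutes >= 240 & wear_minutes <= 1439]
  has_meal <- length(meal_minutes) > 0
  has_wear <- length(wear_minutes) > 0
  if (!has_meal && !has_wear) return(NULL)
  start <- min(c(if (has_meal) min(meal_minutes),
                 if (has_wear) min(wear_minutes)))
  end <- max(c(if (has_meal) max(meal_minutes) + 180,
               if (has_wear) max(wear_minutes)))
  c(start = max(start, 240), end = min(end, 1439))
}

#' Build participant-day records
#'
#' One row per participant-day spanned by the CGM trace, including excluded
#' days with their reasons. Exclusion rules: no meal events identified;
#' accelerometer wear below 10 h (between 04:00 and 23:59; inclusive at
#' exactly 10 h); the first and last study day (incomplete CGM); any CGM
#' sample at or beyond the sensor limits (<= 40 or >= 500 mg/dL). Daily
#' metrics: elevated meal count categorised 0/1/2/>=3; total steps in the
#' window; baseline glucose at the window start (nearest sample within one
#' nominal interval); time in `[tir_lower, 140]` mg/dL as a percentage of
#' observed CGM samples in the window; mean glucose over those samples.
#'
#' @param events labelled event table (needs `start_time` and `label`; see
#'   [compute_meal_biomarkers()]).
#' @param glucose,steps cohort tables.
#' @param tir_lower lower bound of the target range, 54 (default) or 70.
#' @param interval_min nominal CGM interval, minutes.
#' @param min_wear_hours wear-time inclusion threshold.
#' @return data.frame of day records with `included` and `exclusion_reason`.
#' @export
build_day_records <- function(events, glucose, steps, tir_lower = 54,
                              interval_min = 15, min_wear_hours = 10) {
  gl_by_p <- split(glucose, glucose$participant_id)
  st_by_p <- split(steps, steps$participant_id)
  ev_by_p <- if (nrow(events)) split(events, events$participant_id) else list()

  rows <- list()
  for (pid in names(gl_by_p)) {
    gl <- gl_by_p[[pid]]
    st <- st_by_p[[pid]]
    ev <- ev_by_p[[pid]]
    dates <- sort(unique(mt_date(gl$time)))
    first_last <- range(dates)
    gl_date <- mt_date(gl$time)
    st_date <- if (!is.null(st)) mt_date(st$time)
    ev_date <- if (!is.null(ev)) mt_date(ev$start_time)

    for (d in as.list(dates)) {
      g <- gl[gl_date == d, , drop = FALSE]
      s <- if (!is.null(st)) st[st_date == d, , drop = FALSE] else
        data.frame(time = g$time[0], steps = integer(), wear = logical())
      e <- if (!is.null(ev)) ev[ev_date == d, , drop = FALSE] else NULL

      wear <- wear_mask_of_day(s)
      s_min <- mt_minute_of_day(s$time)
      wear_min <- s_min[wear]
      wear_hours <- sum(wear_min >= 240 & wear_min <= 1439) / 60
      meal_min <- if (!is.null(e) && nrow(e)) mt_minute_of_day(e$start_time)

      reasons <- character(0)
      if (is.null(meal_min)) reasons <- c(reasons, "no-meals")
      if (wear_hours < min_wear_hours) reasons <- c(reasons, "wear<10h")
      if (d %in% first_last) reasons <- c(reasons, "cgm-first-last-day")
      if (any(g$glucose_mgdl <= 40 | g$glucose_mgdl >= 500))
        reasons <- c(reasons, "sensor-limit")

      win <- day_window(meal_min, wear_min)
      ws <- we <- NA_real_; dur <- NA_real_
      n_elev <- NA_integer_; dsteps <- NA_real_
      bg <- tir <- mg <- NA_real_
      ws_time <- we_time <- g$time[NA_integer_][1]
      if (!is.null(win)) {
        ws <- win[["start"]]; we <- win[["end"]]; dur <- we - ws
        midn <- mt_midnight(g$time[1])
        ws_time <- midn + ws * 60; we_time <- midn + we * 60
        in_win_ev <- if (is.null(meal_min)) logical(0) else
          meal_min >= ws & meal_min <= we
        n_elev <- if (is.null(e)) 0L else
          sum(e$label[in_win_ev] == "elevated", na.rm = TRUE)
        dsteps <- sum(s$steps[s_min >= ws & s_min <= we])
        gw <- g[mt_minute_of_day(g$time) >= ws &
                  mt_minute_of_day(g$time) <= we, , drop = FALSE]
        if (nrow(gw)) {
          tir <- 100 * mean(gw$glucose_mgdl >= tir_lower &
                              gw$glucose_mgdl <= 140)
          mg <- mean(gw$glucose_mgdl)
        }
        bg <- baseline_at(g, ws_time, interval_min)
      }
      cat_lab <- if (is.na(n_elev)) NA_character_ else
        ELEVATED_LEVELS[pmin(n_elev, 3L) + 1L]
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = pid, date = d,
        window_start = ws_time, window_end = we_time, duration = dur,
        n_meal_events = if (is.null(meal_min)) 0L else length(meal_min),
        elevated_count = n_elev,
        elevated_count_category = cat_lab,
        daily_steps = dsteps, baseline_glucose = bg,
        tir = tir, mean_glucose = mg,
        included = length(reasons) == 0,
        exclusion_reason = paste(reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$elevated_count_category <- factor(res$elevated_count_category,
                                        levels = ELEVATED_LEVELS)
  rownames(res) <- NULL
  res
}

#' Per-participant adherence and cohort feasibility
#'
#' Adherence days per modality: food logging (two or more distinct meal
#' logs in a day), CGM (a day with the full expected sample count at the
#' nominal interval, i.e. no missing values), and accelerometer (>= 10 h of
#' wear between 04:00 and 23:59); plus days simultaneously adherent to all
#' three. Cohort feasibility holds when at least `feasibility_threshold` of
#' participants reach `min_days` simultaneous days.
#'
#' @param bundle a study bundle.
#' @param interval_min nominal CGM interval, minutes.
#' @param min_days adherence-day threshold (default 10).
#' @param min_wear_hours daily wear threshold (default 10, inclusive).
#' @param feasibility_threshold cohort fraction required (default 0.5).
#' @return list(`per_participant` data.frame, `cohort` list with fractions
#'   and the `feasible` flag).
#' @export
adherence_summary <- function(bundle, interval_min = 15, min_days = 10,
                              min_wear_hours = 10,
                              feasibility_threshold = 0.5) {
  pids <- bundle$participants$participant_id
  if (!length(pids)) stop("empty cohort: feasibility undefined")
  expected_cgm <- 1440 %/% interval_min
  merged <- merge_food_logs(bundle$food_logs)

  per <- lapply(pids, function(pid) {
    gl <- bundle$glucose[bundle$glucose$participant_id == pid, , drop = FALSE]
    st <- bundle$steps[bundle$steps$participant_id == pid, , drop = FALSE]
    ml <- merged[merged$participant_id == pid, , drop = FALSE]

    cgm_days <- if (nrow(gl)) {
      tab <- table(mt_date(gl$time))
      names(tab)[tab >= expected_cgm]
    } else character(0)
    mfp_days <- if (nrow(ml)) {
      tab <- table(mt_date(ml$merged_time))
      names(tab)[tab >= 2]
    } else character(0)
    act_days <- character(0)
    if (nrow(st)) {
      for (d in as.list(sort(unique(mt_date(st$time))))) {
        s <- st[mt_date(st$time) == d, , drop = FALSE]
        wear <- wear_mask_of_day(s)
        m <- mt_minute_of_day(s$time)
        if (sum(wear & m >= 240 & m <= 1439) / 60 >= min_wear_hours)
          act_days <- c(act_days, as.character(d))
      }
    }
    sim_days <- Reduce(intersect, list(cgm_days, mfp_days, act_days))
    data.frame(participant_id = pid,
               mfp_days = length(mfp_days), cgm_days = length(cgm_days),
               actigraph_days = length(act_days),
               simultaneous_days = length(sim_days),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  cohort <- list(
    frac_mfp = mean(per$mfp_days >= min_days),
    frac_cgm = mean(per$cgm_days >= min_days),
    frac_actigraph = mean(per$actigraph_days >= min_days),
    frac_simultaneous = mean(per$simultaneous_days >= min_days))
  cohort$feasible <- cohort$frac_simultaneous >= feasibility_threshold
  list(per_participant = per, cohort = cohort)
}
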