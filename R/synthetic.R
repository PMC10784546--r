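# Synthetic multimodal cohort generator.
#
# The generator states a world with the structure the analysis assumes:
# flat-ish participant baseline glucose plus a log-normal-shaped (sharp rise,
# slow decay) excursion superposed for every meal, sampled to the CGM grid;
# minute-level steps with wear/non-wear spans; food logs derived from true
# meals through an explicit logging-error model (delays, omissions,
# end-of-day batch logging); and a linear participant-level map from mean
# 3-h meal glucose response (MGR) to HbA1c. Every planted quantity is
# returned as ground truth so downstream estimators can be validated.

#' Simulation configuration
#'
#' Defaults describe a 36-participant, 14-day free-living study: three main
#' meals (95% each) plus an occasional snack per day, CGM on a 15-min grid
#' with small AR(1) sensor noise, hip-worn accelerometer wear roughly
#' 06:30-22:30, 10% of meals never logged, logging delays averaging 15 min,
#' and 5% of days batch-logged in the evening. The planted effect of
#' post-meal steps on MGR is -0.641 min.mg/dL per step (i.e. -641 per 1000
#' steps); calories add 3 min.mg/dL per kcal. Participant HbA1c is
#' `mapper_intercept + mapper_slope * (true mean MGR) + N(0, hba1c_noise_sd)`.
#'
#' @param n_participants,n_days cohort dimensions.
#' @param cgm_interval_min CGM sampling interval, minutes.
#' @param start_date first study date (ISO).
#' @param meal_prob probability each of breakfast/lunch/dinner occurs.
#' @param snack_prob probability of an afternoon snack.
#' @param base_mgr_mean,base_mgr_sd participant-level baseline MGR
#'   (min.mg/dL) before calorie/step contributions.
#' @param effect_calories_on_mgr min.mg/dL per kcal.
#' @param effect_steps_on_mgr min.mg/dL per post-meal step (negative).
#' @param mgr_noise_sd per-meal MGR noise, min.mg/dL.
#' @param mapper_slope,mapper_intercept,hba1c_noise_sd the planted
#'   MGR -> HbA1c line.
#' @param shape_peak_min,shape_log_sd log-normal excursion shape: minutes to
#'   peak and log-scale width.
#' @param cgm_noise_sd,cgm_ar,cgm_diurnal_amp CGM noise model (mg/dL).
#' @param cgm_dropout probability a scheduled CGM sample is missing.
#' @param cgm_first_day_start_hour,cgm_last_day_end_hour sensor placement /
#'   removal clock hours (first and last study days are incomplete).
#' @param p_walk,walk_steps_mean,walk_steps_sd post-meal walk model.
#' @param activity_prob,activity_lambda background per-minute step process
#'   during wear.
#' @param p_low_wear_day probability of a day with < 10 h wear.
#' @param p_missing_log,log_delay_mean_min,p_batch_day,p_staged_items
#'   logging-error model.
#' @param step_trace set `FALSE` to skip generating the minute-level step
#'   trace (ground-truth post-meal steps are still planted); used to keep
#'   large simulation studies inside their runtime budget.
#' @param food_log_trace set `FALSE` to skip emitting food-log rows (the
#'   logging outcome is still drawn into the ground truth); same purpose.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 36,
                       n_days = 14,
                       cgm_interval_min = 15,
                       start_date = "2024-03-01",
                       meal_prob = 0.95,
                       snack_prob = 0.3,
                       base_mgr_mean = 2500,
                       base_mgr_sd = 1800,
                       effect_calories_on_mgr = 3.0,
                       effect_steps_on_mgr = -0.641,
                       mgr_noise_sd = 400,
                       mapper_slope = 4e-4,
                       mapper_intercept = 4.6,
                       hba1c_noise_sd = 0.3,
                       shape_peak_min = 45,
                       shape_log_sd = 0.5,
                       cgm_noise_sd = 3,
                       cgm_ar = 0.5,
                       cgm_diurnal_amp = 4,
                       cgm_dropout = 5e-4,
                       cgm_first_day_start_hour = 10,
                       cgm_last_day_end_hour = 14,
                       p_walk = 0.55,
                       walk_steps_mean = 1500,
                       walk_steps_sd = 600,
                       activity_prob = 0.3,
                       activity_lambda = 15,
                       p_low_wear_day = 0.05,
                       p_missing_log = 0.10,
                       log_delay_mean_min = 15,
                       p_batch_day = 0.05,
                       p_staged_items = 0.25,
                       step_trace = TRUE,
                       food_log_trace = TRUE) {
  cfg <- as.list(environment())
  probs <- c(meal_prob, snack_prob, cgm_dropout, p_walk, p_low_wear_day,
             p_missing_log, p_batch_day, p_staged_items)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(c(base_mgr_sd, mgr_noise_sd, hba1c_noise_sd, cgm_noise_sd,
            walk_steps_sd) < 0)) stop("standard deviations must be >= 0")
  if (cgm_interval_min < 1) stop("cgm_interval_min must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# Unit-peak log-normal bell: zero at t = 0, peak 1 at t = peak_min.
excursion_shape <- function(u, peak_min, log_sd) {
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- exp(-(log(u[pos] / peak_min))^2 / (2 * log_sd^2))
  out
}

# Integral of the unit shape over [0, 180] min (1-min trapezoid); the
# excursion amplitude is scaled so the continuous-curve incremental area
# equals the planted MGR.
shape_integral <- function(peak_min, log_sd) {
  u <- 0:180
  y <- excursion_shape(u, peak_min, log_sd)
  sum((y[-1] + y[-length(y)]) / 2)
}

rtnorm <- function(n, mean, sd, lower) pmax(stats::rnorm(n, mean, sd), lower)

FOOD_ITEMS <- list(
  breakfast = c("oatmeal", "orange juice", "eggs", "toast", "yogurt"),
  lunch     = c("tacos", "rice and beans", "sandwich", "salad", "soup"),
  dinner    = c("chicken fajitas", "enchiladas", "pasta", "grilled fish",
                "stew"),
  snacks    = c("apple", "chips", "granola bar", "cookies", "nuts"))

#' Simulate a multimodal cohort with planted ground truth
#'
#' Generates participants (HbA1c, diabetes status), CGM traces, minute-level
#' step traces and error-prone food logs according to a [sim_config()];
#' see that help page for the data-generating model. Randomness comes from
#' the current RNG state: call `set.seed()` first for reproducibility.
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (the io collections, annotations empty; see
#'   [read_bundle()]) and `truth` (data.frame of true meals: start time,
#'   occasion, calories, post-meal steps, planted MGR, logging outcome)
#'   carrying per-participant truth as `attr(truth, "participants")`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  if (95 - 6 * cfg$cgm_noise_sd - cfg$cgm_diurnal_amp <= 0)
    stop("CGM noise model implies non-positive glucose floor")
  day0 <- mt_parse(paste0(cfg$start_date, "T00:00"))
  shape_I <- shape_integral(cfg$shape_peak_min, cfg$shape_log_sd)

  pids <- sprintf("P%02d", seq_len(cfg$n_participants))
  occ_spec <- data.frame(
    occasion = c("breakfast", "lunch", "dinner", "snacks"),
    mean_min = c(8, 13, 19, 16) * 60,
    sd_min   = c(45, 45, 45, 60),
    cal_mean = c(450, 650, 700, 250),
    cal_sd   = c(120, 150, 150, 80),
    stringsAsFactors = FALSE)

  truth_rows <- list(); glucose_rows <- list(); step_rows <- list()
  log_rows <- list(); ppl_rows <- list()

  for (p in seq_along(pids)) {
    pid <- pids[p]
    base_mgr <- rtnorm(1, cfg$base_mgr_mean, cfg$base_mgr_sd, 300)
    cal_mult <- rtnorm(1, 1, 0.15, 0.5)

    # --- true meals -------------------------------------------------------
    meals <- list()
    for (d in seq_len(cfg$n_days)) {
      present <- c(stats::runif(3) < cfg$meal_prob,
                   stats::runif(1) < cfg$snack_prob)
      oi <- which(present)
      if (!length(oi)) next
      os <- occ_spec[oi, , drop = FALSE]
      t_min <- round(stats::rnorm(nrow(os), os$mean_min, os$sd_min))
      ord <- order(t_min)
      os <- os[ord, , drop = FALSE]; t_min <- t_min[ord]
      t_min <- pmin(pmax(t_min, 300), 1290)
      if (length(t_min) > 1)                       # keep meals >= 150 min apart
        for (k in 2:length(t_min)) t_min[k] <- max(t_min[k], t_min[k - 1] + 150)
      t_min <- pmin(t_min, 1290)
      cal <- round(rtnorm(nrow(os), os$cal_mean * cal_mult, os$cal_sd, 80))
      walk <- stats::runif(nrow(os)) < cfg$p_walk
      sp <- ifelse(walk,
                   round(rtnorm(nrow(os), cfg$walk_steps_mean,
                                cfg$walk_steps_sd, 100)), 0)
      mgr <- pmax(base_mgr + cfg$effect_calories_on_mgr * cal +
                    cfg$effect_steps_on_mgr * sp +
                    stats::rnorm(nrow(os), 0, cfg$mgr_noise_sd), 50)
      meals[[d]] <- data.frame(day = d, occasion = os$occasion,
                               start_min = t_min, calories = cal,
                               post_meal_steps = sp, mgr_true = mgr,
                               stringsAsFactors = FALSE)
    }
    meals <- if (length(meals)) do.call(rbind, meals) else
      data.frame(day = integer(), occasion = character(),
                 start_min = integer(), calories = numeric(),
                 post_meal_steps = numeric(), mgr_true = numeric())
    meals$start_time <- day0 + ((meals$day - 1) * 1440 + meals$start_min) * 60

    # --- participant-level HbA1c via the planted mapper -------------------
    mean_mgr <- if (nrow(meals)) mean(meals$mgr_true) else 0
    hba1c <- cfg$mapper_intercept + cfg$mapper_slope * mean_mgr +
      stats::rnorm(1, 0, cfg$hba1c_noise_sd)
    hba1c <- min(max(hba1c, 4.2), 14)
    status <- if (hba1c < 5.7) "at_risk" else
      if (hba1c < 6.5) "prediabetes" else "t2d"
    b_p <- rtnorm(1, 95 + 8 * (hba1c - 5.7), 6, 70)
    ppl_rows[[p]] <- data.frame(participant_id = pid, hba1c = hba1c,
                                status = status, base_mgr = base_mgr,
                                mean_mgr_true = mean_mgr,
                                baseline_glucose = b_p,
                                stringsAsFactors = FALSE)

    # --- CGM trace --------------------------------------------------------
    first_min <- round(cfg$cgm_first_day_start_hour * 60)
    last_min <- (cfg$n_days - 1) * 1440 + round(cfg$cgm_last_day_end_hour * 60)
    grid <- seq(from = ceiling(first_min / cfg$cgm_interval_min) *
                  cfg$cgm_interval_min,
                to = last_min, by = cfg$cgm_interval_min)
    vals <- rep(b_p, length(grid))
    mod <- grid %% 1440
    vals <- vals + cfg$cgm_diurnal_amp * sin(2 * pi * (mod - 360) / 1440)
    if (nrow(meals)) {
      gmin <- (meals$day - 1) * 1440 + meals$start_min
      amp <- meals$mgr_true / shape_I
      for (m in seq_len(nrow(meals))) {
        u <- grid - gmin[m]
        sel <- u > 0 & u <= 360       # tail past 3 h kept: excursions decay
        vals[sel] <- vals[sel] +
          amp[m] * excursion_shape(u[sel], cfg$shape_peak_min, cfg$shape_log_sd)
      }
    }
    if (cfg$cgm_noise_sd > 0) {
      e <- stats::rnorm(length(grid), 0, cfg$cgm_noise_sd)
      vals <- vals + as.numeric(stats::filter(e, cfg$cgm_ar,
                                              method = "recursive"))
    }
    keep <- stats::runif(length(grid)) >= cfg$cgm_dropout
    glucose_rows[[p]] <- data.frame(
      participant_id = pid, time = day0 + grid[keep] * 60,
      glucose_mgdl = round(pmax(vals[keep], 40), 1), stringsAsFactors = FALSE)

    # --- step trace -------------------------------------------------------
    if (cfg$step_trace) {
      n_min <- cfg$n_days * 1440
      steps <- integer(n_min)
      wear <- logical(n_min)
      for (d in seq_len(cfg$n_days)) {
        off <- (d - 1) * 1440
        if (stats::runif(1) < cfg$p_low_wear_day) {
          ws <- 540; we <- 840                       # 5 h token wear
        } else {
          ws <- round(stats::rnorm(1, 390, 30)); we <- round(stats::rnorm(1, 1350, 30))
          ws <- max(ws, 240); we <- min(we, 1439)
        }
        wear[off + (ws:we) + 1] <- TRUE
      }
      nw <- sum(wear)
      steps[wear] <- ifelse(stats::runif(nw) < cfg$activity_prob,
                            stats::rpois(nw, cfg$activity_lambda), 0L)
      if (nrow(meals)) {
        gmin <- (meals$day - 1) * 1440 + meals$start_min
        for (m in which(meals$post_meal_steps > 0)) {
          idx <- gmin[m] + (5:44) + 1                # walk 5-45 min post meal
          idx <- idx[idx <= n_min]
          sp <- meals$post_meal_steps[m]
          per <- rep(sp %/% length(idx), length(idx))
          extra <- sp - sum(per)
          if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
          steps[idx] <- steps[idx] + per
          wear[idx] <- TRUE
        }
      }
      step_rows[[p]] <- data.frame(
        participant_id = pid, time = day0 + (seq_len(n_min) - 1) * 60,
        steps = as.integer(steps), wear = wear, stringsAsFactors = FALSE)
    }

    # --- food logs with logging errors ------------------------------------
    meals$logged <- stats::runif(nrow(meals)) >= cfg$p_missing_log
    meals$batch <- rep(FALSE, nrow(meals))
    meals$log_keys <- rep(NA_character_, nrow(meals))
    if (nrow(meals) && cfg$food_log_trace) {
      for (d in unique(meals$day)) {
        di <- which(meals$day == d & meals$logged)
        if (!length(di)) next
        batch <- stats::runif(1) < cfg$p_batch_day
        meals$batch[di] <- batch
        for (m in di) {
          if (batch) {
            lt <- day0 + ((d - 1) * 1440 + 1260) * 60          # 21:00
          } else {
            delay <- min(round(stats::rexp(1, 1 / max(cfg$log_delay_mean_min, 1e-9))), 180)
            lt <- meals$start_time[m] + delay * 60
          }
          occ <- meals$occasion[m]
          n_items <- 1 + stats::rbinom(1, 2, 0.4)
          nm <- sample(FOOD_ITEMS[[occ]], n_items, replace = n_items > 5)
          w <- stats::runif(n_items, 0.5, 1.5)
          cal_i <- round(meals$calories[m] * w / sum(w))
          cal_i[n_items] <- meals$calories[m] - sum(cal_i[-n_items])
          t_i <- rep(lt, n_items)
          if (!batch && n_items >= 2 && stats::runif(1) < cfg$p_staged_items)
            t_i[-1] <- lt + round(stats::runif(n_items - 1, 5, 25)) * 60
          log_rows[[length(log_rows) + 1]] <- data.frame(
            participant_id = pid, log_time = t_i, occasion = occ,
            item_name = nm, calories = cal_i,
            carbs_g = round(cal_i * 0.5 / 4), protein_g = round(cal_i * 0.2 / 4),
            fat_g = round(cal_i * 0.3 / 9), stringsAsFactors = FALSE)
          meals$log_keys[m] <- paste(unique(food_log_key(pid, t_i, occ)),
                                     collapse = ";")
        }
      }
    }
    meals$participant_id <- rep(pid, nrow(meals))
    truth_rows[[p]] <- meals
  }

  ppl <- do.call(rbind, ppl_rows)
  bundle <- list(
    participants = ppl[, c("participant_id", "hba1c", "status")],
    glucose = do.call(rbind, glucose_rows),
    steps = if (length(step_rows)) do.call(rbind, step_rows) else
      data.frame(participant_id = character(), time = day0[0],
                 steps = integer(), wear = logical()),
    food_logs = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(participant_id = character(), log_time = day0[0],
                 occasion = character(), item_name = character(),
                 calories = numeric(), carbs_g = numeric(),
                 protein_g = numeric(), fat_g = numeric()),
    annotations = data.frame(participant_id = character(),
                             annotator_id = character(), source = character(),
                             log_key = character(), time = day0[0],
                             stringsAsFactors = FALSE))
  bundle$food_logs <- bundle$food_logs[order(bundle$food_logs$participant_id,
                                             bundle$food_logs$log_time), ]
  rownames(bundle$food_logs) <- NULL
  class(bundle) <- "cgmeal_bundle"

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  attr(truth, "participants") <- ppl
  attr(truth, "config") <- cfg
  list(bundle = bundle, truth = truth)
}

#' Emulate independent human annotators of meal-log timings
#'
#' For every food log linked to a true meal, each annotator either tags it
#' `unknown` (probability `p_unknown`; always for batch-logged snacks, which
#' cannot be placed) or produces a corrected timing equal to the true meal
#' start plus Normal jitter. True meals with no log are detected with
#' probability `p_detect_added` and receive an `added` timing (no log
#' reference). Annotated times are clamped to 04:00-23:59.
#'
#' @param bundle,truth output of [simulate_cohort()].
#' @param n_annotators number of annotators (>= 1).
#' @param jitter_sd timing jitter standard deviation, minutes.
#' @param p_unknown probability a log is tagged unknown.
#' @param p_detect_added probability an unlogged meal is spotted.
#' @return annotations data.frame (see [read_bundle()]).
#' @export
simulate_annotators <- function(bundle, truth, n_annotators = 4,
                                jitter_sd = 5, p_unknown = 0.05,
                                p_detect_added = 0.8) {
  if (n_annotators < 1) stop("n_annotators must be >= 1")
  rows <- list()
  clamp <- function(t) {
    mod <- mt_minute_of_day(t)
    mt_midnight(t) + pmin(pmax(mod, 240), 1439) * 60
  }
  for (a in seq_len(n_annotators)) {
    aid <- sprintf("A%d", a)
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      if (isTRUE(tr$logged)) {
        keys <- strsplit(tr$log_keys, ";", fixed = TRUE)[[1]]
        for (k in keys) {
          unk <- stats::runif(1) < p_unknown ||
            (isTRUE(tr$batch) && tr$occasion == "snacks")
          if (unk) {
            rows[[length(rows) + 1]] <- data.frame(
              participant_id = tr$participant_id, annotator_id = aid,
              source = "unknown", log_key = k, time = tr$start_time[NA],
              stringsAsFactors = FALSE)
          } else {
            tt <- tr$start_time + round(stats::rnorm(1, 0, jitter_sd)) * 60
            rows[[length(rows) + 1]] <- data.frame(
              participant_id = tr$participant_id, annotator_id = aid,
              source = "corrected", log_key = k, time = clamp(tt),
              stringsAsFactors = FALSE)
          }
        }
      } else if (stats::runif(1) < p_detect_added) {
        tt <- tr$start_time + round(stats::rnorm(1, 0, jitter_sd)) * 60
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = tr$participant_id, annotator_id = aid,
          source = "added", log_key = NA_character_, time = clamp(tt),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(bundle$annotations)
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$annotator_id), ]
  rownames(out) <- NULL
  out
}

#' Simulate a confounded participant-day table with planted causal effects
#'
#' States the world of the daily causal analysis: participant-days with
#' baseline glucose, analysis-window duration, daily step count (1000s) and
#' an elevated-meal-count category, where the treatments depend on the
#' covariates (confounding) and the outcomes (time in range, mean glucose)
#' follow a linear model with participant random intercepts and the given
#' planted coefficients.
#'
#' Generator equations (confounding scaled by `confounding_strength` s):
#' `steps_k = 6 - 0.032 s (bg-95) + (0.32/60) s (dur-900) + u_trt + e`,
#' `P(elevated) drawn Binomial(3, plogis(-0.4 + 0.02 s (bg-95) + 0.5 u_trt))`
#' with the count capped at the ">=3" category, and e.g.
#' `tir = 80 + b_cat[cat] + b_steps*steps_k - 0.5 (bg-95) + 1.0 (dur-900)/60
#'  + u_out + noise`. At s = 1 the unweighted treatment-covariate
#' correlations clearly violate the 0.1 balance heuristic while correct IPW
#' restores balance at this sample size.
#'
#' @param n_participants,days_per_participant table dimensions
#'   (36 x 11 = 396 rows, near the study's 369 daily samples).
#' @param confounding_strength scales treatment-covariate dependence
#'   (0 = randomized).
#' @param b_cat_tir,b_cat_avg planted category effects (reference 0, then 1,
#'   2, >=3) on TIR and mean glucose; defaults follow the magnitudes a
#'   free-living study of this size reports.
#' @param b_steps_tir,b_steps_avg planted per-1000-steps effects.
#' @param sd_tir,sd_avg residual noise; `sd_participant_out`,
#'   `sd_participant_trt` random-intercept scales (0 for the noise-free
#'   limit).
#' @return list with `data` (participant-day table; `elevated_count` is a
#'   factor 0/1/2/3+) and `truth` (named list of planted coefficients).
#' @export
simulate_daily_outcome_cohort <- function(n_participants = 36,
                                          days_per_participant = 11,
                                          confounding_strength = 1,
                                          b_cat_tir = c(0, -1.1, -4.0, -8.1),
                                          b_cat_avg = c(0, 1.7, 5.8, 7.7),
                                          b_steps_tir = 0.07,
                                          b_steps_avg = -0.3,
                                          sd_tir = 5, sd_avg = 4,
                                          sd_participant_out = 3,
                                          sd_participant_trt = 1) {
  s <- confounding_strength
  n <- n_participants * days_per_participant
  pid <- rep(sprintf("P%02d", seq_len(n_participants)),
             each = days_per_participant)
  u_out <- rep(stats::rnorm(n_participants, 0, sd_participant_out),
               each = days_per_participant)
  u_out2 <- rep(stats::rnorm(n_participants, 0, sd_participant_out * 0.8),
                each = days_per_participant)
  u_bg <- rep(stats::rnorm(n_participants, 0, 8), each = days_per_participant)
  u_trt <- rep(stats::rnorm(n_participants, 0, sd_participant_trt),
               each = days_per_participant)

  bg <- 95 + u_bg + stats::rnorm(n, 0, 10)
  dur <- 900 + stats::rnorm(n, 0, 60)
  steps_k <- pmax(6 - 0.032 * s * (bg - 95) + (0.32 / 60) * s * (dur - 900) +
                    u_trt + stats::rnorm(n, 0, 2), 0.2)
  eta <- -0.4 + 0.02 * s * (bg - 95) + 0.5 * u_trt
  cnt <- pmin(stats::rbinom(n, 3, stats::plogis(eta)), 3)
  cat_f <- factor(c("0", "1", "2", "3+")[cnt + 1],
                  levels = c("0", "1", "2", "3+"))

  tir <- 80 + b_cat_tir[cnt + 1] + b_steps_tir * steps_k -
    0.5 * (bg - 95) + 1.0 * (dur - 900) / 60 + u_out +
    stats::rnorm(n, 0, sd_tir)
  avg <- 110 + b_cat_avg[cnt + 1] + b_steps_avg * steps_k +
    0.8 * (bg - 95) - 0.5 * (dur - 900) / 60 + u_out2 +
    stats::rnorm(n, 0, sd_avg)

  data <- data.frame(participant_id = pid,
                     day = rep(seq_len(days_per_participant), n_participants),
                     baseline_glucose = bg, duration = dur,
                     daily_steps_k = steps_k, elevated_count = cat_f,
                     tir = tir, mean_glucose = avg,
                     stringsAsFactors = FALSE)
  truth <- list(b_cat_tir = b_cat_tir, b_cat_avg = b_cat_avg,
                b_steps_tir = b_steps_tir, b_steps_avg = b_steps_avg,
                b_bg_tir = -0.5, b_dur_tir = 1.0 / 60,
                b_bg_avg = 0.8, b_dur_avg = -0.5 / 60,
                confounding_strength = s)
  list(data = data, truth = truth)
}
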