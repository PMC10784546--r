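# Shared fixtures, all built in code.

T0 <- function(s) cgmeal:::mt_parse(s)

# A glucose trace data.frame on an arbitrary minute grid of one day.
mk_glucose <- function(minutes, values, pid = "P01", date = "2024-03-05") {
  data.frame(participant_id = pid,
             time = T0(paste0(date, "T00:00")) + minutes * 60,
             glucose_mgdl = values, stringsAsFactors = FALSE)
}

# Minute-level step trace covering [0, 1439] of one day.
mk_steps <- function(steps, pid = "P01", date = "2024-03-05", wear = NULL) {
  n <- length(steps)
  data.frame(participant_id = pid,
             time = T0(paste0(date, "T00:00")) + (seq_len(n) - 1) * 60,
             steps = as.integer(steps),
             wear = if (is.null(wear)) NA else wear,
             stringsAsFactors = FALSE)
}

# Independent 1-min Riemann (left-sum) iAUC oracle over [0, 180] for a
# continuous curve given as a function of minutes since start.
oracle_iauc_fun <- function(f, baseline) {
  u <- 0:179
  sum(pmax(f(u + 0.5) - baseline, 0))   # midpoint rule, 1-min bins
}

# Independent trapezoid oracle on explicit samples (straight re-derivation,
# kept separate from the package implementation on purpose).
oracle_iauc_samples <- function(minutes, values, baseline) {
  y <- pmax(values - baseline, 0)
  n <- length(y)
  sum(diff(minutes) * (y[-1] + y[-n]) / 2)
}

# A constructed 4-day fixture: day 1 and 4 are first/last (CGM incomplete),
# day 2 is fully clean, day 3 carries the targeted defect.
mk_day_fixture <- function(defect = c("none", "no_meals", "low_wear",
                                      "sensor_low", "sensor_high")) {
  defect <- match.arg(defect)
  dates <- paste0("2024-03-0", 4:7)
  grid <- seq(0, 1439, by = 15)
  glucose <- do.call(rbind, lapply(seq_along(dates), function(i) {
    vals <- 100 + 50 * exp(-((grid - 720) / 60)^2)      # midday excursion
    if (i == 3 && defect == "sensor_low") vals[1] <- 40
    if (i == 3 && defect == "sensor_high") vals[1] <- 500
    mk_glucose(grid, vals, date = dates[i])
  }))
  steps <- do.call(rbind, lapply(seq_along(dates), function(i) {
    wear_len <- if (i == 3 && defect == "low_wear") 594 else 840  # 9.9 / 14 h
    wear <- c(rep(FALSE, 360), rep(TRUE, wear_len),
              rep(FALSE, 1440 - 360 - wear_len))
    mk_steps(ifelse(wear, 10L, 0L), date = dates[i], wear = wear)
  }))
  events <- do.call(rbind, lapply(seq_along(dates), function(i) {
    if (i == 3 && defect == "no_meals") return(NULL)
    data.frame(participant_id = "P01",
               start_time = T0(paste0(dates[i], "T11:30")),
               label = "elevated", stringsAsFactors = FALSE)
  }))
  list(events = events, glucose = glucose, steps = steps)
}

empty_food_logs <- function() {
  data.frame(participant_id = character(), log_time = T0(character(0)),
             occasion = character(), item_name = character(),
             calories = numeric(), carbs_g = numeric(),
             protein_g = numeric(), fat_g = numeric(),
             stringsAsFactors = FALSE)
}

# A small simulated cohort for integration-style tests.
quick_cohort <- function(seed = 1, n_participants = 4, n_days = 4, ...) {
  set.seed(seed)
  sim <- simulate_cohort(sim_config(n_participants = n_participants,
                                    n_days = n_days, ...))
  sim$bundle$annotations <- simulate_annotators(sim$bundle, sim$truth)
  sim
}

# Amplitude (peak rise, mg/dL) of a planted meal given its true MGR -- used
# to decide which true meals have a qualifying (>= 18.6 mg/dL) excursion.
true_amplitude <- function(truth, cfg) {
  truth$mgr_true / cgmeal:::shape_integral(cfg$shape_peak_min, cfg$shape_log_sd)
}
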