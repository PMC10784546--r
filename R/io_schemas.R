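# On-disk tabular schemas shared by every stage of the pipeline.
#
# A "bundle" is a named list of five validated data.frames:
#   participants : participant_id, hba1c, status
#   glucose      : participant_id, time, glucose_mgdl
#   steps        : participant_id, time, steps, wear (logical, may be NA)
#   food_logs    : participant_id, log_time, occasion, item_name,
#                  calories, carbs_g, protein_g, fat_g   (one row per item)
#   annotations  : participant_id, annotator_id, source, log_key, time
#
# A food "log" is the set of item rows sharing (participant, minute, occasion);
# its key is deterministic so annotation files can reference logs without an
# explicit id column in food_logs.csv.

OCCASIONS <- c("breakfast", "lunch", "dinner", "snacks")
STATUSES  <- c("at_risk", "prediabetes", "t2d")
ANNOT_SOURCES <- c("corrected", "added", "unknown")

BUNDLE_FILES <- c(participants = "participants.csv",
                  glucose      = "glucose.csv",
                  steps        = "steps.csv",
                  food_logs    = "food_logs.csv",
                  annotations  = "annotations.csv")

#' Deterministic key identifying one food log
#'
#' Item rows logged at the same minute under the same meal-occasion label
#' belong to one log; the key is `participant|ISO-time|occasion`.
#'
#' @param participant_id,log_time,occasion vectors of equal length.
#' @return character vector of keys.
#' @export
food_log_key <- function(participant_id, log_time, occasion) {
  paste(participant_id, mt_format(log_time), occasion, sep = "|")
}

reject_frame <- function() {
  data.frame(table = character(), row = integer(), reason = character(),
             stringsAsFactors = FALSE)
}

add_reject <- function(rej, table, rows, reason) {
  if (length(rows) == 0) return(rej)
  rbind(rej, data.frame(table = table, row = as.integer(rows),
                        reason = reason, stringsAsFactors = FALSE))
}

# Per-collection validators: return list(data = clean rows, rejects = frame).
# Rejected rows are diagnosed, never silently dropped.

validate_participants <- function(df) {
  rej <- reject_frame()
  bad <- which(!(df$hba1c > 3 & df$hba1c < 20) | is.na(df$hba1c))
  rej <- add_reject(rej, "participants", bad, "hba1c outside (3, 20)")
  bad2 <- which(!(df$status %in% STATUSES))
  rej <- add_reject(rej, "participants", bad2, "unknown diabetes status")
  drop <- union(bad, bad2)
  list(data = if (length(drop)) df[-drop, , drop = FALSE] else df, rejects = rej)
}

validate_glucose <- function(df) {
  rej <- reject_frame()
  bad <- which(is.na(df$time))
  rej <- add_reject(rej, "glucose", bad, "unparsable timestamp")
  bad2 <- which(!(df$glucose_mgdl > 0) | is.na(df$glucose_mgdl))
  rej <- add_reject(rej, "glucose", bad2, "glucose must be > 0 mg/dL")
  drop <- union(bad, bad2)
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  # strictly increasing times per participant: reject ties/backsteps
  df <- df[order(df$participant_id, df$time), , drop = FALSE]
  dup <- which(c(FALSE, diff(as.numeric(df$time)) <= 0 &
                   df$participant_id[-1] == df$participant_id[-nrow(df)]))
  rej <- add_reject(rej, "glucose", dup, "non-increasing timestamp")
  if (length(dup)) df <- df[-dup, , drop = FALSE]
  rownames(df) <- NULL
  list(data = df, rejects = rej)
}

validate_steps <- function(df) {
  rej <- reject_frame()
  bad <- which(is.na(df$time))
  rej <- add_reject(rej, "steps", bad, "unparsable timestamp")
  bad2 <- which(is.na(df$steps) | df$steps < 0)
  rej <- add_reject(rej, "steps", bad2, "steps must be >= 0")
  drop <- union(bad, bad2)
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  df <- df[order(df$participant_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  list(data = df, rejects = rej)
}

validate_food_logs <- function(df) {
  rej <- reject_frame()
  bad <- which(is.na(df$log_time))
  rej <- add_reject(rej, "food_logs", bad, "unparsable timestamp")
  bad2 <- which(!(df$occasion %in% OCCASIONS))
  rej <- add_reject(rej, "food_logs", bad2, "unknown occasion label")
  bad3 <- which(is.na(df$calories) | df$calories < 0)
  rej <- add_reject(rej, "food_logs", bad3, "calories must be >= 0")
  drop <- Reduce(union, list(bad, bad2, bad3))
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  df <- df[order(df$participant_id, df$log_time), , drop = FALSE]
  rownames(df) <- NULL
  list(data = df, rejects = rej)
}

validate_annotations <- function(df) {
  rej <- reject_frame()
  bad <- which(!(df$source %in% ANNOT_SOURCES))
  rej <- add_reject(rej, "annotations", bad, "unknown source")
  # source = unknown  <=>  time absent
  bad2 <- which(df$source == "unknown" & !is.na(df$time))
  rej <- add_reject(rej, "annotations", bad2, "unknown-tagged entry carries a time")
  bad3 <- which(df$source != "unknown" & is.na(df$time))
  rej <- add_reject(rej, "annotations", bad3, "missing or unparsable time")
  # corrected references a log; added references none
  bad4 <- which(df$source == "corrected" & (is.na(df$log_key) | df$log_key == ""))
  rej <- add_reject(rej, "annotations", bad4, "corrected timing without log_key")
  bad5 <- which(df$source == "added" & !(is.na(df$log_key) | df$log_key == ""))
  rej <- add_reject(rej, "annotations", bad5, "added timing must not reference a log")
  drop <- Reduce(union, list(bad, bad2, bad3, bad4, bad5))
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  df$log_key[!is.na(df$log_key) & df$log_key == ""] <- NA_character_
  rownames(df) <- NULL
  list(data = df, rejects = rej)
}

#' Read a multimodal study bundle from a directory of CSV files
#'
#' Expects `participants.csv`, `glucose.csv`, `steps.csv`, `food_logs.csv`
#' and `annotations.csv` (UTF-8, header row, ISO-8601 minute timestamps).
#' Rows violating a schema invariant are rejected with row-level diagnostics
#' attached as the `"rejects"` attribute (and reported via `message()`),
#' never silently dropped.
#'
#' @param path directory containing the five CSV files.
#' @return a named list (`participants`, `glucose`, `steps`, `food_logs`,
#'   `annotations`) of validated data.frames, class `cgmeal_bundle`.
#' @export
read_bundle <- function(path) {
  for (f in BUNDLE_FILES) {
    if (!file.exists(file.path(path, f)))
      stop("missing ", f, " in ", path, call. = FALSE)
  }
  rd <- function(f) utils::read.csv(file.path(path, f),
                                    stringsAsFactors = FALSE,
                                    colClasses = c(participant_id = "character"))

  participants <- rd("participants.csv")
  glucose <- rd("glucose.csv"); glucose$time <- mt_parse(glucose$time)
  steps <- rd("steps.csv"); steps$time <- mt_parse(steps$time)
  if (!"wear" %in% names(steps)) steps$wear <- NA
  steps$wear <- as.logical(steps$wear)
  food_logs <- rd("food_logs.csv"); food_logs$log_time <- mt_parse(food_logs$log_time)
  annotations <- rd("annotations.csv")
  if (!nrow(annotations)) {
    annotations <- data.frame(participant_id = character(),
                              annotator_id = character(), source = character(),
                              log_key = character(), time = character(),
                              stringsAsFactors = FALSE)
  }
  annotations$time <- mt_parse(annotations$time)
  annotations$log_key <- as.character(annotations$log_key)

  vs <- list(participants = validate_participants(participants),
             glucose      = validate_glucose(glucose),
             steps        = validate_steps(steps),
             food_logs    = validate_food_logs(food_logs),
             annotations  = validate_annotations(annotations))
  rejects <- do.call(rbind, lapply(vs, `[[`, "rejects"))
  rownames(rejects) <- NULL
  if (nrow(rejects))
    message(nrow(rejects), " row(s) rejected during validation; ",
            "see attr(bundle, 'rejects')")
  bundle <- lapply(vs, `[[`, "data")
  attr(bundle, "rejects") <- rejects
  class(bundle) <- "cgmeal_bundle"
  bundle
}

#' Write a study bundle to a directory of CSV files
#'
#' Inverse of [read_bundle()]: `read_bundle(write_bundle(b, d))` reproduces
#' `b` up to row order. Timestamps must be carried as naive clock time
#' (POSIXct in UTC); any other timezone is rejected before writing.
#'
#' @param bundle list with the five collections (see [read_bundle()]).
#' @param path output directory, created if needed.
#' @return invisibly, a named character vector of the files written.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  check_tz <- function(t, what) {
    tz <- attr(t, "tzone") %||% ""
    if (!tz %in% c("", "UTC"))
      stop("timestamps in ", what, " must be naive clock time (tz UTC), got ",
           tz, call. = FALSE)
  }
  check_tz(bundle$glucose$time, "glucose")
  check_tz(bundle$steps$time, "steps")
  check_tz(bundle$food_logs$log_time, "food_logs")

  wr <- function(df, f) {
    utils::write.csv(df, file.path(path, f), row.names = FALSE, na = "")
    file.path(path, f)
  }
  g <- bundle$glucose; g$time <- mt_format(g$time)
  s <- bundle$steps;   s$time <- mt_format(s$time)
  fl <- bundle$food_logs; fl$log_time <- mt_format(fl$log_time)
  an <- bundle$annotations
  an$time <- ifelse(is.na(an$time), "", mt_format(an$time))
  files <- c(participants = wr(bundle$participants, "participants.csv"),
             glucose = wr(g, "glucose.csv"),
             steps = wr(s, "steps.csv"),
             food_logs = wr(fl, "food_logs.csv"),
             annotations = wr(an, "annotations.csv"))
  invisible(files)
}

#' @export
print.cgmeal_bundle <- function(x, ...) {
  cat("cgmeal bundle:",
      nrow(x$participants), "participants,",
      nrow(x$glucose), "CGM samples,",
      nrow(x$steps), "step minutes,",
      nrow(x$food_logs), "food-log items,",
      nrow(x$annotations), "annotations\n")
  invisible(x)
}
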