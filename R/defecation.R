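DMP_LABELS <- c("pBoc", "aBoc", "Exp")

default_behavior_aliases <- function() {
  list(pBoc = c("pboc", "posterior body contraction", "p"),
       aBoc = c("aboc", "anterior body contraction", "a"),
       Exp  = c("exp", "expulsion", "emc", "x"))
}

#' Behavioral event log for one animal
#'
#' Time-sorted point events of the defecation motor program: posterior
#' body-wall contractions (`pBoc`), anterior body-wall contractions
#' (`aBoc`) and expulsions (`Exp`). When a pBoc shares a timestamp with
#' another event, the pBoc is ordered first (cycle boundaries take
#' priority).
#'
#' @param time_s Numeric event times in seconds (non-negative).
#' @param label Character labels, each one of `"pBoc"`, `"aBoc"`, `"Exp"`.
#' @param animal Animal identifier.
#' @param condition Genotype/condition label (may be `NA`).
#' @return An object of class `event_log`.
#' @export
event_log <- function(time_s, label, animal = "animal", condition = NA_character_) {
  if (length(time_s) != length(label)) stop("time_s and label lengths differ")
  if (any(!is.finite(time_s)) || any(time_s < 0))
    stop("event times must be finite and non-negative")
  if (!all(label %in% DMP_LABELS))
    stop("labels must be one of: ", paste(DMP_LABELS, collapse = ", "))
  if (!any(label == "pBoc")) stop("event log must contain at least one pBoc")
  ord <- order(time_s, match(label, DMP_LABELS))
  structure(list(animal = as.character(animal),
                 condition = as.character(condition),
                 events = data.frame(time_s = time_s[ord],
                                     label = label[ord],
                                     stringsAsFactors = FALSE)),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  n <- table(factor(x$events$label, levels = DMP_LABELS))
  cat(sprintf("event_log '%s' (%s): %d pBoc, %d aBoc, %d Exp over %.1f s\n",
              x$animal, x$condition, n[["pBoc"]], n[["aBoc"]], n[["Exp"]],
              diff(range(x$events$time_s))))
  invisible(x)
}

#' Specify a synthetic defecation event log
#'
#' Inter-pBoc intervals are drawn from a normal distribution truncated at
#' zero (the rhythm's period distribution); each cycle independently
#' receives an aBoc and/or an expulsion event, placed uniformly within the
#' cycle interval, with the stated probabilities.
#'
#' @param mean_period_s Mean inter-pBoc period, seconds (default 50, the
#'   wild-type cycle length).
#' @param period_sd_s Period standard deviation, seconds (0 for a
#'   perfectly regular rhythm).
#' @param n_cycles Number of cycles (intervals) to generate, at least 1.
#' @param aboc_probability,expulsion_probability Per-cycle occurrence
#'   probabilities in \[0, 1\].
#' @param start_time_s Time of the first pBoc.
#' @param animal,condition Identifiers carried into the log.
#' @param seed Integer seed.
#' @return An object of class `event_log_spec`.
#' @export
event_log_spec <- function(mean_period_s = 50, period_sd_s = 5, n_cycles = 10,
                           aboc_probability = 1, expulsion_probability = 1,
                           start_time_s = 0, animal = "sim_animal",
                           condition = NA_character_, seed = 1) {
  if (mean_period_s <= 0) stop("mean_period_s must be positive")
  if (period_sd_s < 0) stop("period_sd_s must be non-negative")
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (aboc_probability < 0 || aboc_probability > 1 ||
      expulsion_probability < 0 || expulsion_probability > 1)
    stop("event probabilities must lie in [0, 1]")
  structure(list(mean_period_s = mean_period_s, period_sd_s = period_sd_s,
                 n_cycles = as.integer(n_cycles),
                 aboc_probability = aboc_probability,
                 expulsion_probability = expulsion_probability,
                 start_time_s = start_time_s, animal = animal,
                 condition = condition, seed = as.integer(seed)),
            class = "event_log_spec")
}

#' Generate a synthetic defecation event log with known intervals
#'
#' @param spec An [event_log_spec()].
#' @return List with `log` (an [event_log()]) and `true_intervals`
#'   (the realized inter-pBoc intervals, so recovery tests are exact).
#' @export
generate_event_log <- function(spec) {
  stopifnot(inherits(spec, "event_log_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cycles
    intervals <- if (spec$period_sd_s == 0) {
      rep(spec$mean_period_s, n)
    } else {
      draws <- numeric(0)
      while (length(draws) < n) {  # truncate the normal at zero by rejection
        cand <- rnorm(2 * (n - length(draws)), spec$mean_period_s,
                      spec$period_sd_s)
        draws <- c(draws, cand[cand > 0])
      }
      draws[seq_len(n)]
    }
    pboc <- spec$start_time_s + c(0, cumsum(intervals))
    times <- pboc
    labels <- rep("pBoc", length(pboc))
    for (i in seq_len(n)) {
      if (runif(1) < spec$aboc_probability) {
        times <- c(times, pboc[i] + intervals[i] * runif(1, 0.05, 0.5))
        labels <- c(labels, "aBoc")
      }
      if (runif(1) < spec$expulsion_probability) {
        times <- c(times, pboc[i] + intervals[i] * runif(1, 0.5, 0.95))
        labels <- c(labels, "Exp")
      }
    }
    list(log = event_log(times, labels, animal = spec$animal,
                         condition = spec$condition),
         true_intervals = intervals)
  })
}

#' Parse a BORIS-style aggregated-events CSV into event logs
#'
#' Reads the aggregated-export dialect of BORIS (Behavioral Observation
#' Research Interactive Software): one row per scored event with
#' observation-id, time and behavior columns. Behavior labels are mapped
#' through a configurable alias table; unknown labels are skipped with a
#' warning that reports the count. State events (START/STOP rows) are
#' collapsed to their start time with a warning, since DMP steps are
#' scored as point events.
#'
#' @param path CSV file path.
#' @param config Optional list: `col_observation`, `col_time`,
#'   `col_behavior` (required columns; defaults `"Observation id"`,
#'   `"Time"`, `"Behavior"`), `col_type` (behavior-type column, default
#'   `"Behavior type"`, used when present), `col_condition` (optional
#'   condition column), `aliases` (named list mapping canonical labels to
#'   lower-case alias vectors).
#' @return A list of [event_log()] objects, one per observation id.
#' @export
parse_boris_csv <- function(path, config = list()) {
  col_obs <- config$col_observation %||% "Observation id"
  col_time <- config$col_time %||% "Time"
  col_beh <- config$col_behavior %||% "Behavior"
  col_type <- config$col_type %||% "Behavior type"
  col_cond <- config$col_condition
  aliases <- config$aliases %||% default_behavior_aliases()

  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(col_obs, col_time, col_beh), names(df))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))

  times <- suppressWarnings(as.numeric(df[[col_time]]))
  if (any(is.na(times)))
    stop(sprintf("unparseable time value at row %d",
                 which(is.na(times))[1]))

  if (col_type %in% names(df)) {
    type <- toupper(df[[col_type]])
    stop_rows <- grepl("STOP", type)
    state_rows <- grepl("STATE|START", type) & !stop_rows
    if (any(stop_rows) || any(state_rows))
      warning(sprintf("collapsed %d state event(s) to their start time",
                      sum(state_rows)))
    keep <- !stop_rows
    df <- df[keep, , drop = FALSE]
    times <- times[keep]
  }

  lut <- character(0)
  for (canon in names(aliases))
    lut[c(tolower(canon), tolower(aliases[[canon]]))] <- canon
  canon <- unname(lut[tolower(trimws(df[[col_beh]]))])
  unknown <- is.na(canon)
  if (any(unknown))
    warning(sprintf("skipped %d event(s) with unknown behavior label(s): %s",
                    sum(unknown),
                    paste(unique(df[[col_beh]][unknown]), collapse = ", ")))

  # condition label: explicit column if configured, else the Subject
  # column when present (the dialect written by write_boris_csv)
  if (is.null(col_cond) && "Subject" %in% names(df)) col_cond <- "Subject"
  out <- list()
  for (obs in unique(df[[col_obs]])) {
    sel <- df[[col_obs]] == obs & !unknown
    if (!any(sel)) next
    cond <- if (!is.null(col_cond) && col_cond %in% names(df))
      df[[col_cond]][sel][1] else NA_character_
    out[[as.character(obs)]] <-
      event_log(times[sel], canon[sel], animal = obs, condition = cond)
  }
  out
}

#' Write event logs in the BORIS aggregated-events CSV dialect
#'
#' @param logs A single [event_log()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_boris_csv <- function(logs, path) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  rows <- do.call(rbind, lapply(logs, function(lg) {
    data.frame(`Observation id` = lg$animal,
               Subject = lg$condition,
               Behavior = lg$events$label,
               `Behavior type` = "POINT",
               Time = lg$events$time_s,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Inter-pBoc cycle lengths
#'
#' One DMP cycle is the time elapsed between two successive pBoc events;
#' returns the successive differences of the pBoc times, in order.
#'
#' @param log An [event_log()].
#' @return Numeric vector of cycle lengths in seconds.
#' @export
cycle_lengths <- function(log) {
  stopifnot(inherits(log, "event_log"))
  pt <- log$events$time_s[log$events$label == "pBoc"]
  if (length(pt) < 2) stop("at least two pBoc events are required")
  diff(pt)
}

#' Mean cycle length over the first n cycles
#'
#' Arithmetic mean of the first `n_cycles` inter-pBoc intervals (the first
#' 10 consecutive cycles by default). Errors when fewer cycles were scored.
#'
#' @param log An [event_log()].
#' @param n_cycles Number of consecutive cycles to average (default 10).
#' @return Mean cycle length in seconds.
#' @export
mean_cycle_length <- function(log, n_cycles = 10) {
  cl <- cycle_lengths(log)
  if (length(cl) < n_cycles)
    stop(sprintf("only %d cycle(s) available; %d required",
                 length(cl), n_cycles))
  mean(cl[seq_len(n_cycles)])
}

#' aBoc frequency: the ratio of aBoc over pBoc counts
#'
#' @param log An [event_log()].
#' @return Dimensionless ratio.
#' @export
aboc_frequency <- function(log) {
  stopifnot(inherits(log, "event_log"))
  npb <- sum(log$events$label == "pBoc")
  if (npb == 0) stop("no pBoc events")
  sum(log$events$label == "aBoc") / npb
}

#' Expulsion frequency: the ratio of expulsion over pBoc counts
#'
#' Defined analogously to [aboc_frequency()].
#'
#' @param log An [event_log()].
#' @return Dimensionless ratio.
#' @export
expulsion_frequency <- function(log) {
  stopifnot(inherits(log, "event_log"))
  npb <- sum(log$events$label == "pBoc")
  if (npb == 0) stop("no pBoc events")
  sum(log$events$label == "Exp") / npb
}

#' Per-condition summary of defecation statistics
#'
#' Computes the per-animal mean cycle length, aBoc frequency and expulsion
#' frequency, then summarizes each statistic per condition with the
#' boxplot convention: n, mean, minimum, 25th/50th/75th percentiles
#' (linear interpolation between order statistics) and maximum.
#'
#' @param logs List of [event_log()] objects.
#' @param n_cycles Cycles averaged per animal (default 10).
#' @param condition_map Optional named vector mapping animal id to
#'   condition, applied at summary time (supports blinded scoring).
#' @return Data frame with one row per condition x statistic.
#' @export
summarize_group <- function(logs, n_cycles = 10, condition_map = NULL) {
  if (length(logs) == 0) stop("no event logs supplied")
  per_animal <- do.call(rbind, lapply(logs, function(lg) {
    cond <- if (!is.null(condition_map) && lg$animal %in% names(condition_map))
      condition_map[[lg$animal]] else lg$condition
    if (is.na(cond)) cond <- "all"
    data.frame(animal = lg$animal, condition = as.character(cond),
               mean_cycle_length_s = mean_cycle_length(lg, n_cycles),
               aboc_frequency = aboc_frequency(lg),
               expulsion_frequency = expulsion_frequency(lg),
               stringsAsFactors = FALSE)
  }))
  stats_cols <- c("mean_cycle_length_s", "aboc_frequency",
                  "expulsion_frequency")
  out <- do.call(rbind, lapply(split(per_animal, per_animal$condition),
    function(grp) {
      do.call(rbind, lapply(stats_cols, function(sc) {
        v <- grp[[sc]]
        q <- box_quantiles(v)
        data.frame(condition = grp$condition[1], statistic = sc,
                   n = length(v), mean = mean(v), min = min(v),
                   q25 = q[1], median = q[2], q75 = q[3], max = max(v),
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(out) <- NULL
  attr(out, "per_animal") <- per_animal
  out
}
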