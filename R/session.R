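# Multi-task scanner-session simulation: blockwise trials for the three tasks,
# staircase-coupled difficulty, lapses, and BIDS-events-style trial tables.

task_response_labels <- function() {
  list(discrimination = c(low = "anticlockwise", high = "clockwise"),
       detection = c(low = "no", high = "yes"),
       tilt = c(low = "vertical", high = "tilted"))
}

task_class_labels <- function() {
  list(discrimination = c(low = "anticlockwise", high = "clockwise"),
       detection = c(low = "absent", high = "present"),
       tilt = c(low = "vertical", high = "tilted"))
}

#' Session design parameters
#'
#' One scanner run holds one block of each task (random order), each block
#' `trials_per_block` trials with balanced stimulus classes in expectation.
#' Timing follows the study protocol: jittered rest 0.5-4 s, fixation 0.5 s,
#' stimulus 0.5 s, decision window 1 s, rating window 2.5 s; blocks start with
#' an instruction screen. Onsets are stored relative to run start.
#'
#' @param runs Number of runs (study sessions had 5-6).
#' @param trials_per_block Trials per task block (study: 26).
#' @param tasks Task labels; the three-task study design by default.
#' @param run_duration_s Nominal run length in seconds (10 min).
#' @param jitter_range_s Uniform inter-trial jitter range.
#' @param fixation_s,stimulus_s,decision_s,rating_s,instruction_s Phase durations.
#' @return A `session_design` list.
#' @export
session_design <- function(runs = 6, trials_per_block = 26,
                           tasks = c("discrimination", "detection", "tilt"),
                           run_duration_s = 600,
                           jitter_range_s = c(0.5, 4),
                           fixation_s = 0.5, stimulus_s = 0.5,
                           decision_s = 1, rating_s = 2.5,
                           instruction_s = 4) {
  stopifnot(runs >= 1, trials_per_block >= 2, length(tasks) >= 1)
  structure(list(runs = as.integer(runs),
                 trials_per_block = as.integer(trials_per_block),
                 tasks = tasks, run_duration_s = run_duration_s,
                 jitter_range_s = jitter_range_s, fixation_s = fixation_s,
                 stimulus_s = stimulus_s, decision_s = decision_s,
                 rating_s = rating_s, instruction_s = instruction_s),
            class = "session_design")
}

# simulate one block of trials from an observer at a difficulty level;
# level scales the class mean separation (stimulus drive), sds are fixed
simulate_block <- function(n, obs, level, lapse_rate) {
  true_high <- stats::runif(n) < obs$prior_high
  x <- ifelse(true_high,
              stats::rnorm(n, level * obs$mu_high, obs$sigma_high),
              stats::rnorm(n, level * obs$mu_low, obs$sigma_low))
  bin <- findInterval(x, obs$criteria) + 1L
  k <- obs$n_conf_levels
  resp_high <- bin > k
  conf <- ifelse(resp_high, bin - k, k + 1L - bin)
  missed <- stats::runif(n) < lapse_rate
  data.frame(true_high = true_high, resp_high = resp_high, conf = conf,
             missed = missed)
}

#' Simulate one subject's multi-task session
#'
#' Draws trial-level evidence from the per-task unequal-variance observers,
#' maps it through the rating criteria to responses and 6-level confidence,
#' applies independent per-trial lapses (missed trials carry no response or
#' confidence), and couples difficulty to performance: an optional pre-session
#' calibration phase applies the within-block 10-trial staircase, and block
#' accuracy in the session adjusts the next same-task block through the
#' between-block rule ([calibrate_step()]). Difficulty scales the class mean
#' separation; class sds (the variance structure) are unaffected.
#'
#' @param design A [session_design()].
#' @param observers Named list of [uvsdt_params()] per task.
#' @param lapse_rate Per-trial probability of a missed trial.
#' @param seed Optional integer seed; same seed reproduces the table exactly.
#' @param calibrate If `TRUE`, run 2 discarded calibration blocks per task
#'   with the within-block staircase before the session.
#' @return A `trial_table` data frame: onset, duration, task, stim_class,
#'   orientation, visibility, response, correct, confidence, missed, block,
#'   run, trial. Attribute `final_levels` stores the end-of-session
#'   difficulty multipliers.
#' @export
simulate_session <- function(design = session_design(),
                             observers = default_observers(),
                             lapse_rate = 0.03, seed = NULL,
                             calibrate = TRUE) {
  stopifnot(inherits(design, "session_design"))
  if (!all(design$tasks %in% names(observers)))
    stop("observers must be named for every task in the design")
  if (!is.null(seed)) set.seed(seed)
  resp_lab <- task_response_labels()
  cls_lab <- task_class_labels()
  levels <- stats::setNames(rep(1, length(design$tasks)), design$tasks)

  if (calibrate) {
    for (task in design$tasks) {
      for (b in 1:2) {
        tr <- simulate_block(design$trials_per_block, observers[[task]],
                             levels[task], lapse_rate = 0)
        correct <- tr$resp_high == tr$true_high
        for (i in seq(10, design$trials_per_block, by = 10)) {
          acc <- mean(correct[(i - 9):i])
          levels[task] <- calibrate_step(levels[task], acc,
                                         "within_block_10trial")
        }
      }
    }
  }

  rows <- list()
  block_id <- 0L
  for (run in seq_len(design$runs)) {
    task_order <- sample(design$tasks)
    t_cursor <- 0
    for (task in task_order) {
      block_id <- block_id + 1L
      obs <- observers[[task]]
      t_cursor <- t_cursor + design$instruction_s
      tr <- simulate_block(design$trials_per_block, obs, levels[task],
                           lapse_rate)
      n <- design$trials_per_block
      jit <- stats::runif(n, design$jitter_range_s[1], design$jitter_range_s[2])
      onsets <- numeric(n)
      for (i in seq_len(n)) {
        onsets[i] <- t_cursor + jit[i] + design$fixation_s
        t_cursor <- onsets[i] + design$stimulus_s + design$decision_s +
          design$rating_s
      }
      cl <- ifelse(tr$true_high, cls_lab[[task]]["high"], cls_lab[[task]]["low"])
      orientation <- switch(task,
        discrimination = ifelse(tr$true_high, 45, -45),
        detection = ifelse(tr$true_high, stats::rnorm(n, 0, 20 * levels[task]), NA_real_),
        tilt = ifelse(tr$true_high, stats::rnorm(n, 0, 20 * levels[task]), 0),
        ifelse(tr$true_high, 45, -45))
      visibility <- switch(task,
        detection = ifelse(tr$true_high, 0.12 * levels[task], 0),
        tilt = rep(0.2, n),
        rep(0.12 * levels[task], n))
      response <- ifelse(tr$resp_high, resp_lab[[task]]["high"],
                         resp_lab[[task]]["low"])
      correct <- tr$resp_high == tr$true_high
      response[tr$missed] <- NA_character_
      correct[tr$missed] <- NA
      conf <- ifelse(tr$missed, NA_integer_, tr$conf)
      rows[[block_id]] <- data.frame(
        onset = onsets, duration = design$stimulus_s, task = task,
        stim_class = cl, orientation = orientation, visibility = visibility,
        response = response, correct = correct, confidence = conf,
        missed = tr$missed, block = block_id, run = run,
        trial = seq_len(n), stringsAsFactors = FALSE)
      acc_block <- mean(correct, na.rm = TRUE)
      if (is.finite(acc_block))
        levels[task] <- calibrate_step(levels[task], acc_block, "between_block")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "final_levels") <- levels
  class(out) <- c("trial_table", "data.frame")
  out
}
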