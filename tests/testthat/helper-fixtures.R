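# Shared fixtures: all built in code at test time.

# a small included-subject trial table (first trials dropped, excluded column)
small_trials <- function(runs = 3, seed = 11) {
  tab <- simulate_session(session_design(runs = runs), seed = seed)
  ex <- apply_exclusions(list(tab))
  stopifnot(length(ex$tables) == 1)
  ex$tables[[1]]
}

# hand-built 26-trial block for exclusion-rule tests
toy_block <- function(block = 1, task = "detection", n_missed = 0,
                      accuracy = 0.8, same_response = FALSE,
                      same_confidence = FALSE, run = 1) {
  n <- 26
  labs <- task_response_labels()[[task]]
  cls <- task_class_labels()[[task]]
  correct <- rep(c(TRUE, FALSE), c(round(n * accuracy), n - round(n * accuracy)))
  stim <- rep(c(cls["low"], cls["high"]), length.out = n)
  resp <- ifelse(correct,
                 ifelse(stim == cls["high"], labs["high"], labs["low"]),
                 ifelse(stim == cls["high"], labs["low"], labs["high"]))
  if (same_response) resp <- rep(labs["low"], n)
  conf <- if (same_confidence) rep(4L, n) else rep_len(1:6, n)
  missed <- rep(FALSE, n)
  if (n_missed > 0) missed[seq_len(n_missed)] <- TRUE
  resp[missed] <- NA
  conf[missed] <- NA
  correct[missed] <- NA
  data.frame(onset = seq(10, by = 7, length.out = n), duration = 0.5,
             task = task, stim_class = unname(stim), orientation = 0,
             visibility = 0.2, response = unname(resp), correct = correct,
             confidence = conf, missed = missed, block = block, run = run,
             trial = 1:26, stringsAsFactors = FALSE)
}

# subject table: 3 blocks per task, optionally breaking some detection blocks
toy_subject <- function(bad_detection_blocks = 0) {
  blocks <- list(); id <- 0
  for (task in c("discrimination", "detection", "tilt")) {
    for (b in 1:3) {
      id <- id + 1
      bad <- task == "detection" && b <= bad_detection_blocks
      blocks[[id]] <- toy_block(block = id, task = task,
                                accuracy = if (bad) 0.4 else 0.8,
                                run = ceiling(id / 3))
    }
  }
  do.call(rbind, blocks)
}
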