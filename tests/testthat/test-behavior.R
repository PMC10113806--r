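# Exclusion rules, behavioural summaries, and group statistics.

test_that("block exclusion rules fire at their thresholds", {
  # 6/26 missed is over the 20% threshold
  rep6 <- apply_exclusions(list(s = rbind(toy_subject(),
    within(toy_block(block = 10, task = "detection", n_missed = 6),
           run <- 4))))
  blocks <- rep6$report$blocks
  expect_true(blocks$flag_missed[blocks$block == 10])
  expect_true(blocks$excluded[blocks$block == 10])
  # 5/26 missed (19%) stays in
  rep5 <- apply_exclusions(list(s = rbind(toy_subject(),
    within(toy_block(block = 10, task = "detection", n_missed = 5),
           run <- 4))))
  expect_false(rep5$report$blocks$flag_missed[rep5$report$blocks$block == 10])

  bad_acc <- apply_exclusions(list(s = rbind(toy_subject(),
    within(toy_block(block = 10, task = "tilt", accuracy = 0.5), run <- 4))))
  expect_true(bad_acc$report$blocks$flag_accuracy[
    bad_acc$report$blocks$block == 10])

  same_r <- apply_exclusions(list(s = rbind(toy_subject(),
    within(toy_block(block = 10, task = "tilt", same_response = TRUE),
           run <- 4))))
  expect_true(same_r$report$blocks$flag_same_response[
    same_r$report$blocks$block == 10])

  same_c <- apply_exclusions(list(s = rbind(toy_subject(),
    within(toy_block(block = 10, task = "tilt", same_confidence = TRUE),
           run <- 4))))
  expect_true(same_c$report$blocks$flag_same_confidence[
    same_c$report$blocks$block == 10])
})

test_that("a compliant block keeps 25 usable trials and clean subjects stay", {
  res <- apply_exclusions(list(s = toy_subject()))
  expect_true(res$report$subjects$included)
  tab <- res$tables$s
  expect_true(all(tab$trial > 1))
  expect_equal(as.integer(table(tab$block)), rep(25L, 9))
  expect_true(all(!tab$excluded))
})

test_that("subjects lacking 3 included blocks in any task are excluded", {
  res <- apply_exclusions(list(bad = toy_subject(bad_detection_blocks = 1),
                               good = toy_subject()))
  subj <- res$report$subjects
  expect_false(subj$included[subj$subject == "bad"])
  expect_true(subj$included[subj$subject == "good"])
  expect_named(res$tables, "good")
})

test_that("exclusion flags are order-independent", {
  tab <- toy_subject(bad_detection_blocks = 1)
  shuffled <- tab[sample(nrow(tab)), ]
  a <- apply_exclusions(list(s = tab))$report$blocks
  b <- apply_exclusions(list(s = shuffled))$report$blocks
  b <- b[match(a$block, b$block), ]
  expect_equal(a$excluded, b$excluded)
})

test_that("summarize_behavior matches hand counts on a toy table", {
  tab <- toy_block(task = "detection", accuracy = 1)
  tab$excluded <- FALSE
  sm <- summarize_behavior(tab)
  expect_equal(sm$tasks$accuracy, 1.0)
  # hand count of response proportions
  expect_equal(sm$tasks$response_rate_low, mean(tab$response == "no"))
  # constant confidence carries no metacognitive information
  tab2 <- toy_block(task = "tilt", accuracy = 0.6)
  tab2$confidence <- 3L
  sm2 <- summarize_behavior(tab2)
  expect_true(all(abs(sm2$responses$auroc2 - 0.5) < 1e-12))
})

test_that("ttest_with_d obeys d = t / sqrt(n) and the hand formula", {
  v <- c(1.2, 0.7, 1.9, 0.4, 1.1)
  gs <- ttest_with_d(v, null = 0.5)
  # brute-force one-sample t
  t_hand <- (mean(v) - 0.5) / (sd(v) / sqrt(5))
  expect_equal(gs$t, t_hand, tolerance = 1e-12)
  expect_equal(gs$d * sqrt(gs$n), gs$t, tolerance = 1e-10)
  expect_equal(gs$df, 4)

  gs0 <- ttest_with_d(rep(2, 6), null = 2)
  expect_equal(gs0$t, 0)
  expect_equal(gs0$d, 0)
  expect_error(ttest_with_d(rep(2, 6), null = 1), "degenerate")

  for (s in 1:5) {
    set.seed(s)
    g <- ttest_with_d(rnorm(10, 0.4))
    expect_equal(g$d * sqrt(g$n), g$t, tolerance = 1e-10)
  }
})

test_that("rm_anova reproduces hand-computed sums of squares and dfs", {
  m35 <- matrix(rnorm(35 * 3), 35, 3)
  a <- rm_anova(m35)
  expect_equal(c(a$df1, a$df2), c(2, 68))

  same <- matrix(rep(rnorm(10), 3), 10, 3)
  expect_equal(rm_anova(same)$F, 0, tolerance = 1e-20)

  # 4 subjects x 3 conditions, hand SS decomposition
  m <- matrix(c(3, 5, 2, 7, 4, 6, 3, 8, 6, 9, 4, 9), 4, 3)
  n <- 4; k <- 3
  gm <- mean(m)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_hand <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  a2 <- rm_anova(m)
  expect_equal(a2$F, f_hand, tolerance = 1e-10)
  expect_equal(c(a2$df1, a2$df2), c(2, 6))
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("jzs_bf01 matches a fine-grid quadrature oracle and is monotone", {
  grid_bf01 <- function(t, n, r) {
    nu <- n - 1
    g <- exp(seq(log(1e-8), log(1e6), length.out = 2e5))
    w <- diff(c(0, g))
    f <- (1 + n * g)^(-0.5) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
    (1 + t^2 / nu)^(-(nu + 1) / 2) / sum(f * w)
  }
  for (t in c(0, 1.5, 4)) {
    expect_equal(jzs_bf01(t, 35), grid_bf01(t, 35, sqrt(2) / 2),
                 tolerance = 5e-4)
  }
  expect_equal(jzs_bf01(2, 20, scale = 1), grid_bf01(2, 20, 1),
               tolerance = 5e-4)

  bf <- vapply(seq(0, 10, by = 0.25), function(t) jzs_bf01(t, 35), numeric(1))
  expect_true(all(diff(bf) < 0))
  expect_lt(jzs_bf01(50, 35), 1e-10)
  expect_error(jzs_bf01(1, 1), "n must be")
  expect_error(jzs_bf01(Inf, 10), "finite")
})

test_that("group log zROC slopes separate UV tasks from discrimination", {
  # power check: simulated cohorts show negative log-slopes in detection and
  # tilt but not discrimination, and higher AUROC2 for the high-variance
  # response in the UV tasks
  reps <- 10; n_sub <- 20
  det_p <- numeric(reps); tilt_p <- numeric(reps); disc_sig <- logical(reps)
  auroc_sign <- matrix(NA, reps, 2,
                       dimnames = list(NULL, c("detection", "tilt")))
  for (r in seq_len(reps)) {
    tabs <- lapply(seq_len(n_sub), function(s)
      simulate_session(session_design(runs = 5), seed = r * 1000 + s))
    ex <- apply_exclusions(tabs)
    sums <- lapply(ex$tables, summarize_behavior)
    slopes <- sapply(c("discrimination", "detection", "tilt"), function(tk)
      vapply(sums, function(x) x$tasks$zroc_slope[x$tasks$task == tk],
             numeric(1)))
    det_p[r] <- ttest_with_d(log(slopes[, "detection"]))$p
    tilt_p[r] <- ttest_with_d(log(slopes[, "tilt"]))$p
    g_disc <- ttest_with_d(log(slopes[, "discrimination"]))
    disc_sig[r] <- g_disc$p < 0.05
    for (tk in c("detection", "tilt")) {
      labs <- task_response_labels()[[tk]]
      d <- vapply(sums, function(x) {
        r2 <- x$responses[x$responses$task == tk, ]
        r2$auroc2[r2$response == labs["high"]] -
          r2$auroc2[r2$response == labs["low"]]
      }, numeric(1))
      auroc_sign[r, tk] <- mean(d) > 0
    }
  }
  expect_true(all(det_p < 0.05))
  expect_true(all(tilt_p < 0.05))
  expect_lt(mean(disc_sig), 0.5)  # no systematic discrimination asymmetry
  expect_true(all(auroc_sign))    # sign test: high-variance response wins
})
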