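# Exclusion rules, per-task behavioural summaries, and group-level statistics
# (one-sample t with Cohen's d, repeated-measures ANOVA, JZS Bayes factor).

#' Apply block- and subject-level exclusion rules
#'
#' A block is flagged when any of: more than 20% of its trials were missed;
#' accuracy below 60%; the same response on more than 80% of trials; or, for
#' any response given on at least `min_conf_trials` trials, the same
#' confidence level on more than 90% of them. Accuracy/response/confidence
#' rules are evaluated on the usable trials (the first trial of every block is
#' dropped from all analyses); the missed rule uses the full block. Subjects
#' are kept only if every task retains at least 3 included blocks.
#'
#' @param tables A `trial_table` or list of them (one per subject).
#' @param min_conf_trials Minimum trials of a response for the same-confidence
#'   rule (the 90% ratio is only assessed where a response has
#'   enough trials to assess it).
#' @return List with `report` (an `exclusion_report`: `$blocks` per-block
#'   flags, `$subjects` inclusion and per-task included-block counts) and
#'   `tables`: the input tables with trial 1 removed and a logical `excluded`
#'   column marking trials of excluded blocks; excluded subjects are dropped.
#' @export
apply_exclusions <- function(tables, min_conf_trials = 5) {
  single <- is.data.frame(tables)
  if (single) tables <- list(tables)
  if (is.null(names(tables)))
    names(tables) <- sprintf("sub-%02d", seq_along(tables))
  block_rows <- list(); subj_rows <- list(); out_tables <- list()
  for (s in names(tables)) {
    tab <- tables[[s]]
    need <- c("task", "response", "correct", "confidence", "missed", "block",
              "trial")
    if (!all(need %in% names(tab)))
      stop("malformed trial table for ", s, ": missing ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    flags <- lapply(split(tab, tab$block), function(b) {
      usable <- b[b$trial > 1, ]
      ok <- !usable$missed
      same_conf <- FALSE
      for (r in unique(usable$response[ok])) {
        cf <- usable$confidence[ok & usable$response == r]
        if (length(cf) >= min_conf_trials &&
            max(table(cf)) / length(cf) > 0.90) same_conf <- TRUE
      }
      data.frame(
        subject = s, block = b$block[1], task = b$task[1],
        flag_missed = mean(b$missed) > 0.20,
        flag_accuracy = mean(usable$correct[ok]) < 0.60,
        flag_same_response = any(ok) &&
          max(table(usable$response[ok])) / sum(ok) > 0.80,
        flag_same_confidence = same_conf,
        stringsAsFactors = FALSE)
    })
    flags <- do.call(rbind, flags)
    flags$excluded <- flags$flag_missed | flags$flag_accuracy |
      flags$flag_same_response | flags$flag_same_confidence
    block_rows[[s]] <- flags
    kept <- flags$block[!flags$excluded]
    per_task <- vapply(unique(tab$task), function(tk)
      sum(flags$task == tk & !flags$excluded), integer(1))
    included <- all(per_task >= 3)
    subj_rows[[s]] <- data.frame(
      subject = s, included = included,
      t(per_task), check.names = FALSE, stringsAsFactors = FALSE)
    if (included) {
      tab2 <- tab[tab$trial > 1, ]
      tab2$excluded <- !(tab2$block %in% kept)
      out_tables[[s]] <- tab2
    }
  }
  report <- structure(list(blocks = do.call(rbind, block_rows),
                           subjects = do.call(rbind, subj_rows)),
                      class = "exclusion_report")
  rownames(report$blocks) <- rownames(report$subjects) <- NULL
  list(report = report, tables = out_tables)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d/%d blocks excluded; %d/%d subjects included\n",
              sum(x$blocks$excluded), nrow(x$blocks),
              sum(x$subjects$included), nrow(x$subjects)))
  invisible(x)
}

# 2 x 12 rating count table for one task's trials (rows: true low/high class)
rating_table_from_trials <- function(trials, task, n_conf_levels = 6) {
  d <- trials[trials$task == task & !trials$missed & !is.na(trials$response), ]
  if ("excluded" %in% names(d)) d <- d[!d$excluded, ]
  hi_resp <- resp_is_high(d$task, d$response)
  cls_hi <- d$stim_class == task_class_labels()[[task]]["high"]
  bin <- ifelse(hi_resp, n_conf_levels + d$confidence,
                n_conf_levels + 1 - d$confidence)
  counts <- rbind(low = tabulate(bin[!cls_hi], 2 * n_conf_levels),
                  high = tabulate(bin[cls_hi], 2 * n_conf_levels))
  colnames(counts) <- rating_bin_labels(n_conf_levels)
  structure(counts, class = c("rating_count_table", class(counts)),
            n_conf_levels = n_conf_levels)
}

#' Per-task behavioural summary
#'
#' For each task: accuracy, the proportion of low-variance-class responses,
#' mean confidence per response, response-conditional AUROC2 per response, and
#' the type-1 zROC slope estimate (geometric mean over regression directions).
#' Missed trials and excluded blocks are ignored.
#'
#' @param table A `trial_table` that has passed [apply_exclusions()].
#' @return List: `tasks` (one row per task) and `responses` (one row per task
#'   x response with `mean_confidence`, `auroc2`, `prop`). Tasks without
#'   usable blocks are omitted with a message.
#' @export
summarize_behavior <- function(table) {
  stopifnot(is.data.frame(table))
  task_rows <- list(); resp_rows <- list()
  for (task in unique(table$task)) {
    d <- table[table$task == task & !table$missed, ]
    if ("excluded" %in% names(d)) d <- d[!d$excluded, ]
    if (nrow(d) == 0) { message("task '", task, "': no included trials"); next }
    labs <- task_response_labels()[[task]]
    slope <- tryCatch(zroc_slope(rating_table_from_trials(table, task)),
                      error = function(e) NA_real_)
    task_rows[[task]] <- data.frame(
      task = task, n_trials = nrow(d), accuracy = mean(d$correct),
      response_rate_low = mean(d$response == labs["low"]),
      zroc_slope = slope, stringsAsFactors = FALSE)
    for (r in unname(labs)) {
      dr <- d[d$response == r, ]
      if (nrow(dr) == 0) next
      corr_counts <- tabulate(dr$confidence[dr$correct], 6)
      err_counts <- tabulate(dr$confidence[!dr$correct], 6)
      a2 <- if (sum(corr_counts) > 0 && sum(err_counts) > 0)
        auroc2(corr_counts, err_counts) else NA_real_
      resp_rows[[paste(task, r)]] <- data.frame(
        task = task, response = r, n_trials = nrow(dr),
        prop = nrow(dr) / nrow(d),
        mean_confidence = mean(dr$confidence), auroc2 = a2,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(tasks = do.call(rbind, task_rows),
              responses = do.call(rbind, resp_rows))
  rownames(out$tasks) <- rownames(out$responses) <- NULL
  out
}

#' One-sample t-test with Cohen's d
#'
#' Two-sided one-sample (or paired-difference) t-test against `null`, with the
#' standardized effect size `d = t / sqrt(n)`.
#'
#' @param values Per-subject values.
#' @param null Null-hypothesis mean.
#' @return A `group_stats` list: `t`, `df`, `p`, `d`, `n`, `mean`.
#' @export
ttest_with_d <- function(values, null = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    if (mean(values) != null)
      stop("degenerate input: zero variance with nonzero mean difference")
    res <- list(t = 0, df = n - 1, p = 1, d = 0, n = n, mean = mean(values))
    class(res) <- "group_stats"
    return(res)
  }
  tt <- stats::t.test(values, mu = null)
  res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, d = unname(tt$statistic) / sqrt(n), n = n,
              mean = mean(values))
  class(res) <- "group_stats"
  res
}

#' One-way repeated-measures ANOVA
#'
#' Complete subjects x conditions matrix; F with df `(k - 1, (k - 1)(n - 1))`,
#' fitted through `stats::aov` with a subject error stratum.
#'
#' @param mat Numeric matrix or data frame, subjects in rows, conditions in
#'   columns; no missing cells.
#' @return A `group_stats` list: `F`, `df1`, `df2`, `p`, `n`.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need >= 2 subjects and >= 2 conditions")
  if (any(is.na(mat))) stop("missing cells are not supported")
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  if (ss_cond <= 1e-12 * max(ss_tot, 1)) {
    # no condition variation at all: F pinned to 0 rather than 0/0 noise
    res <- list(F = 0, df1 = k - 1, df2 = (k - 1) * (n - 1), p = 1, n = n)
    class(res) <- "group_stats"
    return(res)
  }
  d <- data.frame(y = as.vector(mat),
                  subject = factor(rep(seq_len(n), times = k)),
                  cond = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ cond + Error(subject), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  res <- list(F = s["cond", "F value"], df1 = s["cond", "Df"],
              df2 = s["Residuals", "Df"], p = s["cond", "Pr(>F)"], n = n)
  class(res) <- "group_stats"
  res
}

#' @export
print.group_stats <- function(x, ...) {
  if (!is.null(x$t))
    cat(sprintf("t(%d) = %.3f, p = %.4g, d = %.3f, n = %d%s\n", x$df, x$t,
                x$p, x$d, x$n,
                if (!is.null(x$bf01)) sprintf(", BF01 = %.3g", x$bf01) else ""))
  else
    cat(sprintf("F(%d, %d) = %.3f, p = %.4g, n = %d\n", x$df1, x$df2, x$F,
                x$p, x$n))
  invisible(x)
}

#' JZS Bayes factor for the null (one-sample / paired t design)
#'
#' Default Bayes factor with a Cauchy(0, `scale`) prior on the standardized
#' effect size, computed by numerical integration over the prior's mixing
#' variance (Rouder-style): the marginal likelihood under the alternative is
#' `integral over g of (1 + N g)^(-1/2) (1 + t^2 / ((1 + N g) nu))^(-(nu+1)/2)
#' pi(g) dg` with `g ~ InverseGamma(1/2, scale^2 / 2)`, `nu = n - 1`, divided
#' into the null likelihood `(1 + t^2 / nu)^(-(nu+1)/2)`. BF01 > 1 favours the
#' null; the function is monotone decreasing in `|t|`.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs for a paired design).
#' @param scale Cauchy prior scale (default `sqrt(2) / 2`).
#' @return Positive scalar BF01.
#' @export
jzs_bf01 <- function(t, n, scale = sqrt(2) / 2) {
  if (n < 2) stop("n must be >= 2")
  if (!is.finite(t)) stop("t must be finite")
  if (scale <= 0) stop("scale must be positive")
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(n * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) -
          log_null +                      # stabilise around the null height
          log(scale) - 0.5 * log(2 * pi) - 1.5 * log(g) - scale^2 / (2 * g))
  }
  alt <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e) stop("JZS integration failed: ", conditionMessage(e)))
  if (alt$value <= 0 || !is.finite(alt$value))
    stop("JZS integration failed: non-positive marginal likelihood")
  1 / alt$value
}
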