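# Confidence GLMs: canonical HRF, quadratic-confidence and categorical design
# matrices, OLS fitting, and the bias-controlled two-step polynomial fit.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (shapes 6 and 16, rate 1): a positive
#' peak near 5 s and a negative undershoot near 15 s, on a 32 s support,
#' normalised to unit peak.
#'
#' @param dt Sampling interval in seconds.
#' @param duration Kernel support in seconds.
#' @return Numeric kernel sampled every `dt` seconds.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Build one convolved regressor over concatenated runs.
# onsets are within-run; events in different runs never bleed into each other.
convolve_column <- function(onset, duration, amplitude, run, runs,
                            run_duration, TR, dt, kernel,
                            convolve = TRUE) {
  n_scans <- round(run_duration / TR)
  m <- round(run_duration / dt)
  scan_idx <- round((seq_len(n_scans) - 1) * TR / dt) + 1L
  out <- numeric(0)
  for (r in seq_len(runs)) {
    x <- numeric(m)
    sel <- which(run == r)
    for (i in sel) {
      a <- max(1L, min(m, floor(onset[i] / dt) + 1L))
      b <- max(1L, min(m, ceiling((onset[i] + max(duration[i], dt)) / dt)))
      x[a:b] <- x[a:b] + amplitude[i]
    }
    if (convolve && any(x != 0))
      x <- stats::convolve(x, rev(kernel), type = "open")[seq_len(m)]
    out <- c(out, x[scan_idx])
  }
  out
}

resp_is_high <- function(task, response) {
  labs <- task_response_labels()
  vapply(seq_along(task), function(i) {
    if (is.na(response[i])) NA
    else unname(response[i] == labs[[task[i]]]["high"])
  }, logical(1))
}

canonical_response_order <- function(tasks = c("discrimination", "detection", "tilt")) {
  labs <- task_response_labels()
  unlist(lapply(tasks, function(tk) unname(labs[[tk]][c("high", "low")])),
         use.names = FALSE)
}

included_trials <- function(trials) {
  excl <- if ("excluded" %in% names(trials)) trials$excluded else FALSE
  !trials$missed & trials$trial > 1 & !excl
}

# shared nuisance block: missed / first / excluded-block trials, instruction
# screens, three button-press stick regressors, run constants, extra matrices
nuisance_columns <- function(trials, runs, run_duration, TR, dt, kernel,
                             boxcar = 4, instruction_s = 4, extra = NULL) {
  cols <- list(); meta <- list()
  add <- function(name, x) {
    cols[[length(cols) + 1L]] <<- x
    meta[[length(meta) + 1L]] <<-
      data.frame(name = name, of_interest = FALSE, response = NA_character_,
                 order = NA_integer_, stringsAsFactors = FALSE)
  }
  excl <- if ("excluded" %in% names(trials)) trials$excluded else
    rep(FALSE, nrow(trials))
  groups <- list(missed_trials = trials$missed & !excl,
                 first_trials = trials$trial == 1 & !trials$missed & !excl,
                 excluded_trials = excl)
  for (nm in names(groups)) {
    sel <- groups[[nm]]
    if (any(sel))
      add(nm, convolve_column(trials$onset[sel], rep(boxcar, sum(sel)),
                              rep(1, sum(sel)), trials$run[sel], runs,
                              run_duration, TR, dt, kernel))
  }
  bl <- split(seq_len(nrow(trials)), trials$block)
  instr_on <- vapply(bl, function(i) max(0, min(trials$onset[i]) - instruction_s - 0.5),
                     numeric(1))
  instr_run <- vapply(bl, function(i) trials$run[i][1], numeric(1))
  add("instructions", convolve_column(instr_on, rep(instruction_s, length(instr_on)),
                                      rep(1, length(instr_on)), instr_run, runs,
                                      run_duration, TR, dt, kernel))
  # button presses: decision press per hand-button (2 cols), rating presses (1)
  resp <- !trials$missed
  if (any(resp)) {
    hi <- resp_is_high(trials$task, trials$response)
    press_t <- trials$onset + 0.5 + 0.5  # mid decision window
    for (b in c(FALSE, TRUE)) {
      sel <- resp & !is.na(hi) & hi == b
      if (any(sel))
        add(paste0("button_", if (b) "high" else "low"),
            convolve_column(press_t[sel], rep(dt, sum(sel)), rep(1 / dt, sum(sel)),
                            trials$run[sel], runs, run_duration, TR, dt, kernel))
    }
    add("button_rating",
        convolve_column(trials$onset[resp] + 3, rep(dt, sum(resp)),
                        rep(1 / dt, sum(resp)), trials$run[resp], runs,
                        run_duration, TR, dt, kernel))
  }
  n_scans <- round(run_duration / TR)
  for (r in seq_len(runs)) {
    x <- numeric(runs * n_scans)
    x[((r - 1) * n_scans + 1):(r * n_scans)] <- 1
    add(paste0("run_", r), x)
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (nrow(extra) != runs * n_scans)
      stop("extra nuisance matrix must have one row per scan")
    for (j in seq_len(ncol(extra)))
      add(if (!is.null(colnames(extra))) colnames(extra)[j] else paste0("nuis_", j),
          extra[, j])
  }
  list(cols = cols, meta = do.call(rbind, meta))
}

finish_dm <- function(cols, meta, modulators, trials, runs, run_duration, TR, dt,
                      type) {
  X <- do.call(cbind, cols)
  colnames(X) <- meta$name
  structure(list(X = X, columns = meta, modulators = modulators, TR = TR,
                 dt = dt, run_duration = run_duration, runs = runs,
                 n_scans = nrow(X), type = type,
                 frame_times = rep((seq_len(round(run_duration / TR)) - 1) * TR,
                                   runs) +
                   rep((seq_len(runs) - 1) * run_duration,
                       each = round(run_duration / TR))),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("%s design matrix: %d scans x %d columns (%d of interest)\n",
              x$type, nrow(x$X), ncol(x$X), sum(x$columns$of_interest)))
  invisible(x)
}

#' Quadratic-confidence design matrix (QC-DM)
#'
#' One 4 s boxcar regressor per response plus two parametric modulators: the
#' per-response mean-centred confidence (linear) and its square, mean-centred
#' and then serially orthogonalized against the linear modulator — 18 columns
#' of interest when all six responses occur. Missed trials, first trials of a
#' block and trials of excluded blocks go to separate nuisance regressors,
#' together with instruction screens, three button-press stick regressors and
#' run constants. All event regressors are convolved with the canonical HRF,
#' run by run, on a `dt`-resolution grid and sampled at the scan times.
#'
#' @param trials A `trial_table` (may carry a logical `excluded` column from
#'   [apply_exclusions()]).
#' @param TR Repetition time in seconds.
#' @param run_duration Run length in seconds.
#' @param dt Microtime resolution in seconds.
#' @param boxcar Event boxcar duration in seconds (stimulus onset through the
#'   rating phase).
#' @param nuisance Optional numeric matrix of extra nuisance columns
#'   (one row per scan), e.g. motion or physiological recordings.
#' @return A `design_matrix` object; `$modulators` stores, per response, the
#'   confidence centring constant, the mean of the squared centred confidence
#'   and the orthogonalization coefficient needed to map betas back to raw
#'   polynomial coefficients ([modulation_from_qc()]).
#' @export
build_qc_dm <- function(trials, TR = 2, run_duration = 600, dt = 0.1,
                        boxcar = 4, nuisance = NULL) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  kernel <- canonical_hrf(dt)
  runs <- max(trials$run)
  inc <- included_trials(trials)
  cols <- list(); meta <- list(); modulators <- list()
  add <- function(name, x, of_interest, response, order) {
    cols[[length(cols) + 1L]] <<- x
    meta[[length(meta) + 1L]] <<-
      data.frame(name = name, of_interest = of_interest, response = response,
                 order = order, stringsAsFactors = FALSE)
  }
  for (resp in canonical_response_order(unique(trials$task))) {
    sel <- inc & !is.na(trials$response) & trials$response == resp
    if (!any(sel)) {
      warning("response '", resp, "' absent; its 3 columns are omitted")
      next
    }
    conf <- trials$confidence[sel]
    m1 <- mean(conf)
    cc <- conf - m1
    q <- cc^2
    m2 <- mean(q)
    q <- q - m2
    gamma <- if (sum(cc^2) > 0) sum(q * cc) / sum(cc^2) else 0
    q <- q - gamma * cc
    on <- trials$onset[sel]; rn <- trials$run[sel]
    dur <- rep(boxcar, sum(sel))
    add(resp, convolve_column(on, dur, rep(1, sum(sel)), rn, runs,
                              run_duration, TR, dt, kernel), TRUE, resp, 0L)
    add(paste0(resp, "_conf"),
        convolve_column(on, dur, cc, rn, runs, run_duration, TR, dt, kernel),
        TRUE, resp, 1L)
    add(paste0(resp, "_conf2"),
        convolve_column(on, dur, q, rn, runs, run_duration, TR, dt, kernel),
        TRUE, resp, 2L)
    modulators[[resp]] <- list(centre = m1, m2 = m2, gamma = gamma,
                               n_trials = sum(sel),
                               linear_values = cc, quadratic_values = q)
  }
  nz <- nuisance_columns(trials, runs, run_duration, TR, dt, kernel,
                         boxcar = boxcar, extra = nuisance)
  meta <- rbind(do.call(rbind, meta), nz$meta)
  finish_dm(c(cols, nz$cols), meta, modulators, trials, runs, run_duration,
            TR, dt, "quadratic-confidence")
}

#' Categorical-confidence design matrix for one task
#'
#' One boxcar regressor of interest covering all included trials of the task,
#' modulated by 12 dummy (0/1) parametric modulators — one per response x
#' confidence level. Trials of the other tasks stay in the baseline. Note the
#' base regressor equals the sum of the 12 dummy columns when every level
#' occurs, so the matrix is fitted with the minimum-norm pseudoinverse
#' (`fit_glm(..., method = "pinv")`); the shared null-space offset cancels in
#' the two-step polynomial fit.
#'
#' @inheritParams build_qc_dm
#' @param task Task label to model.
#' @return A `design_matrix`; `$modulators$levels` records the trial count
#'   behind each dummy column.
#' @export
build_categorical_dm <- function(trials, task, TR = 2, run_duration = 600,
                                 dt = 0.1, boxcar = 4, nuisance = NULL) {
  stopifnot(is.data.frame(trials))
  if (!task %in% trials$task) stop("task '", task, "' not present in trials")
  kernel <- canonical_hrf(dt)
  runs <- max(trials$run)
  inc <- included_trials(trials) & trials$task == task
  if (!any(inc)) stop("no included trials for task '", task, "'")
  labs <- task_response_labels()[[task]]
  n_levels <- 6L
  cols <- list(); meta <- list()
  add <- function(name, x, of_interest, response, order) {
    cols[[length(cols) + 1L]] <<- x
    meta[[length(meta) + 1L]] <<-
      data.frame(name = name, of_interest = of_interest, response = response,
                 order = order, stringsAsFactors = FALSE)
  }
  on <- trials$onset[inc]; rn <- trials$run[inc]
  dur <- rep(boxcar, sum(inc))
  add(paste0(task, "_trials"),
      convolve_column(on, dur, rep(1, sum(inc)), rn, runs, run_duration, TR,
                      dt, kernel), TRUE, NA_character_, 0L)
  levels_meta <- list()
  for (resp in unname(labs[c("high", "low")])) {
    for (cf in seq_len(n_levels)) {
      dummy <- as.numeric(!is.na(trials$response[inc]) &
                            trials$response[inc] == resp &
                            trials$confidence[inc] == cf)
      nm <- paste0(resp, "_c", cf)
      add(nm, convolve_column(on, dur, dummy, rn, runs, run_duration, TR, dt,
                              kernel), FALSE, resp, 1L)
      levels_meta[[nm]] <- list(response = resp, conf = cf,
                                n_trials = sum(dummy))
    }
  }
  nz <- nuisance_columns(trials, runs, run_duration, TR, dt, kernel,
                         boxcar = boxcar, extra = nuisance)
  meta <- rbind(do.call(rbind, meta), nz$meta)
  dm <- finish_dm(c(cols, nz$cols), meta, list(levels = levels_meta),
                  trials, runs, run_duration, TR, dt, "categorical")
  dm$task <- task
  dm
}

#' Fit an ordinary least squares GLM to a time series
#'
#' @param y Numeric time series, one value per scan.
#' @param dm A `design_matrix`.
#' @param method `"qr"` (errors on rank deficiency, naming the collinear
#'   columns) or `"pinv"` (minimum-norm solution for deliberately
#'   over-complete designs such as the categorical DM).
#' @return List with named `beta`, `se` (QR method), `sigma2`, `df`, `fitted`,
#'   `cov_unscaled` (QR method).
#' @export
fit_glm <- function(y, dm, method = c("qr", "pinv")) {
  stopifnot(inherits(dm, "design_matrix"))
  method <- match.arg(method)
  X <- dm$X
  if (length(y) != nrow(X))
    stop("length(y) = ", length(y), " but design has ", nrow(X), " scans")
  if (method == "qr") {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("rank-deficient design; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    beta <- qr.coef(qx, y)
    fitted <- drop(X %*% beta)
    df <- nrow(X) - ncol(X)
    sigma2 <- sum((y - fitted)^2) / df
    R <- qr.R(qx)
    cov_unscaled <- chol2inv(R)[order(qx$pivot), order(qx$pivot), drop = FALSE]
    dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
    se <- sqrt(diag(cov_unscaled) * sigma2)
    list(beta = beta, se = se, sigma2 = sigma2, df = df, fitted = fitted,
         cov_unscaled = cov_unscaled, method = method)
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    beta <- drop(sv$v[, pos, drop = FALSE] %*%
                   ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    names(beta) <- colnames(X)
    fitted <- drop(X %*% beta)
    df <- nrow(X) - sum(pos)
    sigma2 <- sum((y - fitted)^2) / df
    list(beta = beta, se = NULL, sigma2 = sigma2, df = df, fitted = fitted,
         cov_unscaled = NULL, method = method)
  }
}

#' Two-step polynomial fit to categorical confidence betas
#'
#' Regresses the per-confidence-level betas of each response on
#' `{1, conf, conf^2}` without orthogonalization: linear and quadratic terms
#' compete for variance, and every confidence level carries equal weight
#' regardless of its trial count, making the estimates indifferent to the
#' confidence distribution.
#'
#' @param betas Data frame with columns `response`, `conf`, `beta`, and
#'   optionally `n_trials` (levels with zero trials are dropped).
#' @return A `modulation_estimate` data frame: one row per response with
#'   `intercept`, `linear`, `quadratic` (raw-confidence polynomial basis) and
#'   standard errors. Responses with fewer than 3 usable levels are skipped
#'   with a warning.
#' @export
two_step_polyfit <- function(betas) {
  stopifnot(is.data.frame(betas),
            all(c("response", "conf", "beta") %in% names(betas)))
  if ("n_trials" %in% names(betas)) betas <- betas[betas$n_trials > 0, ]
  out <- list()
  for (resp in unique(betas$response)) {
    d <- betas[betas$response == resp, ]
    if (length(unique(d$conf)) < 3) {
      warning("response '", resp, "' has < 3 confidence levels; skipped")
      next
    }
    fit <- stats::lm(beta ~ conf + I(conf^2), data = d)
    cf <- stats::coef(fit)
    # zero-residual fits are legitimate here; silence the perfect-fit warning
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    out[[resp]] <- data.frame(
      response = resp, intercept = cf[[1]], linear = cf[[2]], quadratic = cf[[3]],
      se_linear = se[[2]], se_quadratic = se[[3]],
      n_levels = length(unique(d$conf)), stringsAsFactors = FALSE)
  }
  if (is.null(out) || length(out) == 0) {
    res <- data.frame(response = character(), intercept = numeric(),
                      linear = numeric(), quadratic = numeric(),
                      se_linear = numeric(), se_quadratic = numeric(),
                      n_levels = integer(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
  }
  rownames(res) <- NULL
  class(res) <- c("modulation_estimate", "data.frame")
  res
}

#' Collect categorical-DM betas for the two-step fit
#'
#' @param fit Result of [fit_glm()] on a categorical design matrix.
#' @param dm The categorical `design_matrix`.
#' @return Data frame `response`, `conf`, `beta`, `n_trials` suitable for
#'   [two_step_polyfit()].
#' @export
categorical_betas <- function(fit, dm) {
  stopifnot(inherits(dm, "design_matrix"), dm$type == "categorical")
  lv <- dm$modulators$levels
  do.call(rbind, lapply(names(lv), function(nm) {
    data.frame(response = lv[[nm]]$response, conf = lv[[nm]]$conf,
               beta = unname(fit$beta[nm]), n_trials = lv[[nm]]$n_trials,
               stringsAsFactors = FALSE)
  }))
}

#' Convert QC-DM betas to raw-confidence polynomial coefficients
#'
#' The QC-DM codes confidence as a per-response centred linear modulator and a
#' centred, serially orthogonalized quadratic modulator. This re-expresses the
#' fitted (main, linear, quadratic) betas as coefficients of
#' `a(c) = intercept + linear * c + quadratic * c^2` on the raw 1-6 confidence
#' scale, the same basis as [two_step_polyfit()], using the centring constant
#' `m1`, squared-modulator mean `m2` and orthogonalization coefficient `gamma`
#' stored in the design.
#'
#' @param fit Result of [fit_glm()] on a QC design matrix.
#' @param dm The QC `design_matrix`.
#' @return A `modulation_estimate` data frame (one row per response).
#' @export
modulation_from_qc <- function(fit, dm) {
  stopifnot(inherits(dm, "design_matrix"), dm$type == "quadratic-confidence")
  out <- list()
  for (resp in names(dm$modulators)) {
    mm <- dm$modulators[[resp]]
    b0 <- fit$beta[[resp]]
    bL <- fit$beta[[paste0(resp, "_conf")]]
    bQ <- fit$beta[[paste0(resp, "_conf2")]]
    quadratic <- bQ
    linear <- (bL - mm$gamma * bQ) - 2 * mm$centre * bQ
    intercept <- b0 - bQ * mm$m2 - (bL - mm$gamma * bQ) * mm$centre +
      bQ * mm$centre^2
    se_lin <- se_quad <- NA_real_
    if (!is.null(fit$cov_unscaled)) {
      v <- fit$cov_unscaled * fit$sigma2
      nms <- c(paste0(resp, "_conf"), paste0(resp, "_conf2"))
      k <- -(mm$gamma + 2 * mm$centre)
      se_lin <- sqrt(v[nms[1], nms[1]] + k^2 * v[nms[2], nms[2]] +
                       2 * k * v[nms[1], nms[2]])
      se_quad <- sqrt(v[nms[2], nms[2]])
    }
    out[[resp]] <- data.frame(
      response = resp, intercept = intercept, linear = linear,
      quadratic = quadratic, se_linear = se_lin, se_quadratic = se_quad,
      n_levels = NA_integer_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("modulation_estimate", "data.frame")
  res
}

#' Group-level contrast on subject-wise estimates
#'
#' Applies a named linear contrast to each subject's estimates and runs a
#' one-sample t-test (with Cohen's d and, optionally, a JZS Bayes factor), or
#' — when `anova_cols` is given — a one-way repeated-measures ANOVA across
#' those columns.
#'
#' @param estimates Matrix or data frame, subjects x named terms.
#' @param contrast Named numeric vector of contrast weights over columns.
#' @param anova_cols Character vector of >= 2 column names for an RM-ANOVA.
#' @param null Null value for the t-test.
#' @param bf_scale If non-`NULL`, also compute `BF01` with this Cauchy prior
#'   scale.
#' @return A `group_stats` object (see [ttest_with_d()] / [rm_anova()]).
#' @export
group_contrast <- function(estimates, contrast = NULL, anova_cols = NULL,
                           null = 0, bf_scale = NULL) {
  est <- as.matrix(estimates)
  if (nrow(est) < 2) stop("need at least 2 subjects")
  if (!is.null(anova_cols)) {
    if (!all(anova_cols %in% colnames(est)))
      stop("unknown columns: ",
           paste(setdiff(anova_cols, colnames(est)), collapse = ", "))
    return(rm_anova(est[, anova_cols, drop = FALSE]))
  }
  if (is.null(contrast)) stop("give either a contrast or anova_cols")
  if (is.null(names(contrast)) || !all(names(contrast) %in% colnames(est)))
    stop("contrast names must match estimate columns; unknown: ",
         paste(setdiff(names(contrast), colnames(est)), collapse = ", "))
  v <- drop(est[, names(contrast), drop = FALSE] %*% contrast)
  res <- ttest_with_d(v, null = null)
  if (!is.null(bf_scale)) res$bf01 <- jzs_bf01(res$t, res$n, scale = bf_scale)
  res
}
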