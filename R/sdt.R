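# Unequal-variance signal detection core: two Gaussian evidence classes on a
# single decision axis, a set of 2k-1 rating criteria, and the standard
# rating-based estimators (type-1 zROC slope, response-conditional AUROC2).

#' Unequal-variance SDT observer parameters
#'
#' Bundles the two class-conditional Gaussian evidence distributions, the prior
#' on the high-variance class, and the ordered rating criteria that map an
#' evidence sample to one of `2 * n_conf_levels` rating bins
#' (response "low" with confidence `n..1`, then response "high" with
#' confidence `1..n`). The middle criterion is the decision criterion.
#'
#' @param mu_low,sigma_low Mean and sd of the low-variance class evidence.
#' @param mu_high,sigma_high Mean and sd of the high-variance class evidence.
#' @param prior_high Prior probability of the high class, in (0, 1).
#' @param n_conf_levels Number of confidence levels (the study scale is 6).
#' @param criteria Strictly increasing vector of `2 * n_conf_levels - 1`
#'   criteria on the evidence axis. Defaults to the quantiles of the stimulus
#'   mixture at probabilities `(1:(2k-1)) / (2k)`, which populate all rating
#'   bins in expectation.
#' @return An object of class `uvsdt_params`.
#' @export
uvsdt_params <- function(mu_low = 0, sigma_low = 1, mu_high = 1, sigma_high = 1,
                         prior_high = 0.5, n_conf_levels = 6, criteria = NULL) {
  stopifnot(is.numeric(mu_low), is.numeric(mu_high),
            length(mu_low) == 1, length(mu_high) == 1)
  if (!is.finite(sigma_low) || sigma_low <= 0 ||
      !is.finite(sigma_high) || sigma_high <= 0)
    stop("sigma_low and sigma_high must be positive")
  if (prior_high <= 0 || prior_high >= 1) stop("prior_high must be in (0, 1)")
  if (n_conf_levels < 2 || n_conf_levels != round(n_conf_levels))
    stop("n_conf_levels must be an integer >= 2")
  k <- 2L * as.integer(n_conf_levels) - 1L
  if (is.null(criteria)) {
    probs <- seq_len(k) / (k + 1)
    criteria <- vapply(probs, function(p) {
      lo <- min(mu_low - 10 * sigma_low, mu_high - 10 * sigma_high)
      hi <- max(mu_low + 10 * sigma_low, mu_high + 10 * sigma_high)
      stats::uniroot(function(x) {
        (1 - prior_high) * stats::pnorm(x, mu_low, sigma_low) +
          prior_high * stats::pnorm(x, mu_high, sigma_high) - p
      }, c(lo, hi), tol = 1e-10)$root
    }, numeric(1))
  }
  if (length(criteria) != k) stop("criteria must have length 2 * n_conf_levels - 1")
  if (any(diff(criteria) <= 0)) stop("criteria must be strictly increasing")
  structure(list(mu_low = mu_low, sigma_low = sigma_low,
                 mu_high = mu_high, sigma_high = sigma_high,
                 prior_high = prior_high,
                 n_conf_levels = as.integer(n_conf_levels),
                 criteria = as.numeric(criteria)),
            class = "uvsdt_params")
}

#' @export
print.uvsdt_params <- function(x, ...) {
  cat(sprintf("UVSDT observer: low ~ N(%.3g, %.3g), high ~ N(%.3g, %.3g)\n",
              x$mu_low, x$sigma_low, x$mu_high, x$sigma_high))
  cat(sprintf("  prior(high) = %.3g, %d confidence levels, %d criteria\n",
              x$prior_high, x$n_conf_levels, length(x$criteria)))
  invisible(x)
}

#' Log-likelihood ratio of an evidence sample
#'
#' `log N(x; mu_high, sigma_high) - log N(x; mu_low, sigma_low)`. Exactly
#' linear in `x` when the two class sds are equal, and quadratic otherwise
#' (even in `x` when the class means coincide).
#'
#' @param x Evidence value(s); must be finite.
#' @param params A [uvsdt_params()] object.
#' @return Numeric vector of log-likelihood ratios.
#' @export
llr <- function(x, params) {
  stopifnot(inherits(params, "uvsdt_params"))
  if (!is.numeric(x) || any(!is.finite(x))) stop("x must be finite numeric")
  stats::dnorm(x, params$mu_high, params$sigma_high, log = TRUE) -
    stats::dnorm(x, params$mu_low, params$sigma_low, log = TRUE)
}

# polynomial coefficients (c0, c1, c2) with llr(x) = c0 + c1 x + c2 x^2
llr_poly <- function(params) {
  sl2 <- params$sigma_low^2; sh2 <- params$sigma_high^2
  c2 <- 1 / (2 * sl2) - 1 / (2 * sh2)
  c1 <- params$mu_high / sh2 - params$mu_low / sl2
  c0 <- params$mu_low^2 / (2 * sl2) - params$mu_high^2 / (2 * sh2) +
    log(params$sigma_low / params$sigma_high)
  c(c0, c1, c2)
}

#' Simulate a rating count table
#'
#' Draws `n_per_class` evidence samples from each class and bins them by the
#' observer's criteria into the `2 * n_conf_levels`-point response-by-confidence
#' scale (response "low", confidence `n..1`, then response "high", confidence
#' `1..n`).
#'
#' @param params A [uvsdt_params()] object.
#' @param n_per_class Number of trials per true class.
#' @param seed Optional integer seed for reproducibility.
#' @return A `rating_count_table`: 2 x (2n) integer matrix with rows
#'   `low`, `high`; class-wise row sums equal `n_per_class`.
#' @export
simulate_ratings <- function(params, n_per_class, seed = NULL) {
  stopifnot(inherits(params, "uvsdt_params"))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (any(diff(params$criteria) <= 0)) stop("criteria must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  nb <- 2L * params$n_conf_levels
  x_low <- stats::rnorm(n_per_class, params$mu_low, params$sigma_low)
  x_high <- stats::rnorm(n_per_class, params$mu_high, params$sigma_high)
  counts <- rbind(
    low = tabulate(findInterval(x_low, params$criteria) + 1L, nb),
    high = tabulate(findInterval(x_high, params$criteria) + 1L, nb)
  )
  colnames(counts) <- rating_bin_labels(params$n_conf_levels)
  structure(counts, class = c("rating_count_table", class(counts)),
            n_conf_levels = params$n_conf_levels)
}

rating_bin_labels <- function(n_conf_levels) {
  c(paste0("low_conf", n_conf_levels:1), paste0("high_conf", 1:n_conf_levels))
}

#' Type-1 zROC slope from a rating count table
#'
#' Builds cumulative hit (high class) and false-alarm (low class) proportions
#' across the interior criteria, applies the log-linear zero-cell correction
#' (0.5 added to every cumulative cell, 1 to every total), z-transforms, and
#' returns the geometric mean of the two regression-direction slope estimates
#' (z_hit on z_fa, and the reciprocal of z_fa on z_hit). For large Gaussian
#' samples this converges to `sigma_low / sigma_high`.
#'
#' @param table A `rating_count_table` (2 x 2n counts, rows low/high).
#' @return Positive scalar slope estimate.
#' @export
zroc_slope <- function(table) {
  counts <- unclass(table)
  if (!is.matrix(counts) || nrow(counts) != 2) stop("expected a 2-row count table")
  if (any(counts < 0)) stop("counts must be non-negative")
  n_low <- sum(counts[1, ]); n_high <- sum(counts[2, ])
  if (n_low == 0 || n_high == 0) stop("both classes need positive totals")
  if (sum(counts[1, ] > 0) <= 1 && sum(counts[2, ] > 0) <= 1)
    stop("degenerate table: all mass in a single bin")
  nb <- ncol(counts)
  # cumulative counts strictly above each of the nb - 1 criteria
  cum_above <- function(cnt) rev(cumsum(rev(cnt)))[-1]
  fa <- (cum_above(counts[1, ]) + 0.5) / (n_low + 1)
  hit <- (cum_above(counts[2, ]) + 0.5) / (n_high + 1)
  z_fa <- stats::qnorm(fa); z_hit <- stats::qnorm(hit)
  if (stats::var(z_fa) == 0 || stats::var(z_hit) == 0)
    stop("degenerate table: no variation across criteria")
  b_hf <- stats::cov(z_fa, z_hit) / stats::var(z_fa)   # z_hit ~ z_fa
  b_fh <- stats::cov(z_fa, z_hit) / stats::var(z_hit)  # z_fa ~ z_hit
  if (b_hf <= 0 || b_fh <= 0)
    stop("non-positive zROC slope; table inconsistent with an ordered rating scale")
  sqrt(b_hf / b_fh)
}

#' Response-conditional type-2 ROC area (AUROC2)
#'
#' Area under the curve of cumulative `p(conf >= k | correct)` against
#' cumulative `p(conf >= k | error)` across confidence levels, anchored at
#' (0,0) and (1,1), computed by the trapezoid rule. 0.5 means confidence does
#' not distinguish correct from incorrect decisions.
#'
#' @param correct_counts,error_counts Counts of correct/error trials at each
#'   confidence level (low to high), equal lengths, each with a positive total.
#' @return Scalar in `[0, 1]`.
#' @export
auroc2 <- function(correct_counts, error_counts) {
  if (length(correct_counts) != length(error_counts))
    stop("count vectors must have equal length")
  if (any(correct_counts < 0) || any(error_counts < 0)) stop("counts must be >= 0")
  if (sum(correct_counts) == 0 || sum(error_counts) == 0)
    stop("both correct and error counts need a positive total")
  # p(conf >= k), k from the highest level down; anchored at 0 and 1
  p_c <- c(0, cumsum(rev(correct_counts)) / sum(correct_counts))
  p_e <- c(0, cumsum(rev(error_counts)) / sum(error_counts))
  sum(diff(p_e) * (utils::head(p_c, -1) + utils::tail(p_c, -1)) / 2)
}

#' Probability of responding "low" under the posterior decision rule
#'
#' The observer responds "high" when the log-likelihood ratio exceeds the log
#' prior odds against the high class. For unequal variances the LLR is
#' quadratic, so the "respond low" region is an interval on the evidence axis
#' (its complement when the low class has the larger variance); the response
#' probability is computed from the class-conditional normal CDFs at the roots.
#' For equal priors and `sigma_high > sigma_low` the result exceeds 0.5: an
#' optimal observer responds "low" more often than "high".
#'
#' @param params A [uvsdt_params()] object.
#' @return Probability of a "low" response over the stimulus mixture.
#' @export
predicted_low_response_rate <- function(params) {
  stopifnot(inherits(params, "uvsdt_params"))
  thr <- log((1 - params$prior_high) / params$prior_high)
  po <- llr_poly(params)
  # respond low iff c2 x^2 + c1 x + (c0 - thr) <= 0
  a <- po[3]; b <- po[2]; cc <- po[1] - thr
  p_low_region <- function(lo, hi) {
    # P(lo < X <= hi) under each class, mixed by priors
    (1 - params$prior_high) *
      (stats::pnorm(hi, params$mu_low, params$sigma_low) -
         stats::pnorm(lo, params$mu_low, params$sigma_low)) +
      params$prior_high *
      (stats::pnorm(hi, params$mu_high, params$sigma_high) -
         stats::pnorm(lo, params$mu_high, params$sigma_high))
  }
  if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) return(if (cc <= 0) 1 else 0)
    x0 <- -cc / b
    return(if (b > 0) p_low_region(-Inf, x0) else p_low_region(x0, Inf))
  }
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(if (a > 0) 0 else 1)
  r <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  if (a > 0) p_low_region(r[1], r[2]) else 1 - p_low_region(r[1], r[2])
}

#' Default observers for the three study tasks
#'
#' Task-calibrated unequal-variance observers: discrimination has equal class
#' variances; detection and tilt recognition place the high-variance class sd
#' at 1/0.74 and 1/0.55 of the low-variance class. Mean separations are set so
#' that decisions at the default criteria yield approximately 76%, 78% and 77%
#' accuracy respectively, matching the behavioural regime the generator
#' emulates.
#'
#' @return Named list of [uvsdt_params()] for `discrimination`, `detection`
#'   and `tilt` tasks.
#' @export
default_observers <- function() {
  list(
    discrimination = uvsdt_params(mu_low = -0.7063, sigma_low = 1,
                                  mu_high = 0.7063, sigma_high = 1),
    detection = uvsdt_params(mu_low = 0, sigma_low = 1,
                             mu_high = 1.8157, sigma_high = 1 / 0.74),
    tilt = uvsdt_params(mu_low = 0, sigma_low = 1,
                        mu_high = 2.0822, sigma_high = 1 / 0.55)
  )
}
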