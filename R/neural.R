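# Generative counterparts of the imaging analyses: ROI time series with
# linear/quadratic confidence modulations, and run-wise multivoxel condition
# patterns with a controllable generating RDM.

#' Neural generating specification for an ROI
#'
#' Event amplitudes follow `a = mean[response] + linear[response] * cc +
#' quadratic[response] * cc^2`, where `cc` is confidence mean-centred within
#' each response over the included trials — the same coding convention as the
#' quadratic-confidence design matrix, so generated gains and fitted estimates
#' share a scale. Per-task gains are expanded to the task's two responses.
#'
#' @param response_means Named amplitudes per response (defaults to 1 for the
#'   six study responses).
#' @param linear_gain,quadratic_gain Named numeric vectors per response or per
#'   task (task names are expanded to their responses).
#' @param noise_sd White-noise standard deviation added to the series.
#' @param TR Repetition time (s).
#' @param run_duration_s Run length (s).
#' @param boxcar_s Event boxcar duration (s).
#' @param generating_rdm Optional `rdm` used by [simulate_patterns()].
#' @param pattern_noise_sd,voxels Pattern noise sd and voxel count.
#' @return A `neural_spec` list.
#' @export
neural_spec <- function(response_means = NULL, linear_gain = 0.3,
                        quadratic_gain = c(discrimination = 0.1,
                                           detection = 0.2, tilt = 0.3),
                        noise_sd = 1, TR = 2, run_duration_s = 600,
                        boxcar_s = 4, generating_rdm = NULL,
                        pattern_noise_sd = 1, voxels = 80) {
  stopifnot(noise_sd >= 0, TR > 0, pattern_noise_sd >= 0)
  resps <- canonical_response_order()
  expand <- function(x) {
    if (is.null(names(x)) && length(x) == 1)
      return(stats::setNames(rep(x, length(resps)), resps))
    out <- stats::setNames(rep(0, length(resps)), resps)
    labs <- task_response_labels()
    for (nm in names(x)) {
      if (nm %in% resps) out[nm] <- x[[nm]]
      else if (nm %in% names(labs)) out[unname(labs[[nm]])] <- x[[nm]]
      else stop("unknown response/task name: ", nm)
    }
    out
  }
  if (is.null(response_means))
    response_means <- stats::setNames(rep(1, length(resps)), resps)
  structure(list(response_means = expand(response_means),
                 linear_gain = expand(linear_gain),
                 quadratic_gain = expand(quadratic_gain),
                 noise_sd = noise_sd, TR = TR,
                 run_duration_s = run_duration_s, boxcar_s = boxcar_s,
                 generating_rdm = generating_rdm,
                 pattern_noise_sd = pattern_noise_sd, voxels = voxels),
            class = "neural_spec")
}

#' Simulate an ROI time series with confidence modulations
#'
#' Builds per-trial amplitudes from the spec's response means and linear /
#' quadratic confidence gains (confidence mean-centred per response over the
#' included trials), places 4 s boxcars at the trial onsets, convolves with
#' the canonical HRF run by run, samples at the TR, and adds white noise.
#' Missed, first and excluded-block trials contribute a plain response-mean
#' amplitude (they are modelled by nuisance regressors at analysis time).
#'
#' @param trials A `trial_table`.
#' @param spec A [neural_spec()].
#' @param seed Optional integer seed.
#' @return List: `y` (scans), `frame_times`, and `truth` — the generating
#'   gains plus the per-response confidence centres needed to express them in
#'   the raw polynomial basis.
#' @export
simulate_roi_timeseries <- function(trials, spec = neural_spec(), seed = NULL) {
  stopifnot(inherits(spec, "neural_spec"), is.data.frame(trials))
  if (!is.null(seed)) set.seed(seed)
  TR <- spec$TR; dt <- 0.1
  run_duration <- spec$run_duration_s
  runs <- max(trials$run)
  kernel <- canonical_hrf(dt)
  inc <- included_trials(trials)
  amp <- rep(mean(spec$response_means), nrow(trials))
  centres <- list()
  for (resp in unique(trials$response[inc & !is.na(trials$response)])) {
    sel <- inc & !is.na(trials$response) & trials$response == resp
    m1 <- mean(trials$confidence[sel])
    cc <- trials$confidence[sel] - m1
    amp[sel] <- spec$response_means[resp] + spec$linear_gain[resp] * cc +
      spec$quadratic_gain[resp] * cc^2
    centres[[resp]] <- m1
  }
  y <- convolve_column(trials$onset, rep(spec$boxcar_s, nrow(trials)), amp,
                       trials$run, runs, run_duration, TR, dt, kernel)
  if (spec$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
  n_scans <- round(run_duration / TR)
  list(y = y,
       frame_times = rep((seq_len(n_scans) - 1) * TR, runs) +
         rep((seq_len(runs) - 1) * run_duration, each = n_scans),
       TR = TR, runs = runs, run_duration = run_duration,
       truth = list(response_means = spec$response_means,
                    linear_gain = spec$linear_gain,
                    quadratic_gain = spec$quadratic_gain,
                    conf_centres = unlist(centres),
                    noise_sd = spec$noise_sd))
}

#' Expected raw-basis polynomial coefficients from generating gains
#'
#' Expands the centred generating model `m + g1 * (c - m1) + g2 * (c - m1)^2`
#' into raw-confidence coefficients, for comparison with
#' [modulation_from_qc()] / [two_step_polyfit()] output.
#'
#' @param truth `truth` element from [simulate_roi_timeseries()].
#' @return Data frame `response`, `intercept`, `linear`, `quadratic`.
#' @export
expected_modulation <- function(truth) {
  resps <- names(truth$conf_centres)
  do.call(rbind, lapply(resps, function(r) {
    m1 <- truth$conf_centres[[r]]
    g1 <- truth$linear_gain[[r]]; g2 <- truth$quadratic_gain[[r]]
    data.frame(response = r,
               intercept = truth$response_means[[r]] - g1 * m1 + g2 * m1^2,
               linear = g1 - 2 * m1 * g2, quadratic = g2,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate run-wise multivoxel condition patterns
#'
#' Embeds the generating RDM into a low-dimensional configuration by classical
#' multidimensional scaling with the Cailliez additive constant (a strictly
#' monotone transform, so the off-diagonal rank order of the generating RDM is
#' preserved exactly), rotates the configuration into voxel space with a random
#' orthonormal map, and adds independent Gaussian run noise. Masked
#' (no-prediction) entries of a theoretical generating RDM are filled with the
#' mean of its defined off-diagonal entries before embedding.
#'
#' @param conditions Condition labels (default: the 12 task x response x
#'   confidence categories, [rsa_conditions()]).
#' @param runs Number of runs (>= 2; cross-run distances need at least two).
#' @param generating_rdm An `rdm` (theoretical or any symmetric dissimilarity
#'   matrix over the conditions).
#' @param pattern_noise_sd Run-noise standard deviation.
#' @param voxels Number of voxels (>= number of conditions - 1).
#' @param seed Optional integer seed.
#' @param signal_scale Multiplier on the embedded configuration; the default
#'   of 3 (with unit pattern noise over 80 voxels) puts the leave-one-out
#'   noise ceiling around 0.7, a reliably structured ROI.
#' @return `runs x conditions x voxels` array with dimnames.
#' @export
simulate_patterns <- function(conditions = rsa_conditions(), runs,
                              generating_rdm, pattern_noise_sd = 1,
                              voxels = 80, seed = NULL, signal_scale = 3) {
  if (runs < 2) stop("runs must be >= 2 (cross-run distances)")
  D <- rdm_matrix(generating_rdm)
  nc <- length(conditions)
  if (!all(dim(D) == nc)) stop("generating RDM size does not match conditions")
  msk <- rdm_mask(generating_rdm)
  off <- row(D) != col(D)
  if (any(msk & off)) D[msk & off] <- mean(D[off & !msk])
  diag(D) <- 0
  if (voxels < nc - 1) stop("need at least conditions - 1 voxels")
  if (!is.null(seed)) set.seed(seed)
  # near-zero eigenvalues beyond the configuration's true dimensionality
  # trigger a harmless cmdscale warning
  mds <- suppressWarnings(stats::cmdscale(D, k = nc - 1, add = TRUE))
  pts <- mds$points * signal_scale
  q <- qr.Q(qr(matrix(stats::rnorm(voxels * ncol(pts)), voxels)))
  proto <- pts %*% t(q[, seq_len(ncol(pts)), drop = FALSE])
  out <- array(NA_real_, dim = c(runs, nc, voxels),
               dimnames = list(paste0("run", seq_len(runs)), conditions, NULL))
  for (r in seq_len(runs))
    out[r, , ] <- proto +
      matrix(stats::rnorm(nc * voxels, 0, pattern_noise_sd), nc, voxels)
  out
}
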