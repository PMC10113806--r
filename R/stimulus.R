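# Dynamic grating-in-noise stimuli, staircase calibration steps, and the
# protocol-hash seeding scheme.

#' Per-frame grating visibility envelope
#'
#' The 10-frame stimulus embeds the grating with per-frame pixel-replacement
#' probability `p_i = v * exp(-|i - 5| / 2)`, peaking at frame 5 where
#' `p_5 = v`. Target-absent trials use `v = 0`, giving an all-zero envelope.
#'
#' @param v Visibility level in `[0, 1]`.
#' @return Numeric vector of 10 replacement probabilities.
#' @export
visibility_envelope <- function(v) {
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
    stop("v must be a single value in [0, 1]")
  v * exp(-abs(1:10 - 5) / 2)
}

#' Render a sinusoidal grating patch
#'
#' `size` x `size` sinusoid with the given period (pixels), orientation
#' (degrees from vertical) and phase, normalised to luminance `[0, 1]`.
#'
#' @param orientation_deg Grating orientation in degrees (0 = vertical).
#' @param size Patch side in pixels.
#' @param period Pixels per cycle.
#' @param phase Phase in radians.
#' @return `size` x `size` matrix of luminances in `[0, 1]`.
#' @export
make_grating <- function(orientation_deg, size = 142, period = 24, phase = 0) {
  theta <- orientation_deg * pi / 180
  ix <- seq_len(size) - (size + 1) / 2
  # spatial frequency vector perpendicular to the grating stripes
  fx <- sin(theta) * 2 * pi / period
  fy <- cos(theta) * 2 * pi / period
  g <- outer(ix, ix, function(y, x) sin(fx * x + fy * y + phase))
  (g + 1) / 2
}

#' Generate a 10-frame dynamic stimulus
#'
#' Each frame starts as `size^2` independent uniform `[0, 1]` luminance values;
#' each pixel is then replaced by the corresponding grating pixel with the
#' frame's envelope probability [visibility_envelope()]. `v = 0` yields pure
#' noise; a frame with replacement probability 1 equals the grating exactly.
#'
#' @param v Visibility in `[0, 1]`.
#' @param orientation_deg Grating orientation in degrees.
#' @param seed Optional integer seed.
#' @param size,period Patch geometry, see [make_grating()].
#' @param phase Grating phase; drawn uniformly if `NULL`.
#' @return A `stimulus_clip`: list with `frames` (10 x size x size array),
#'   `grating`, `envelope`, `v`, `orientation_deg`.
#' @export
generate_stimulus <- function(v, orientation_deg, seed = NULL,
                              size = 142, period = 24, phase = NULL) {
  if (!is.finite(orientation_deg)) stop("orientation must be finite")
  p <- visibility_envelope(v)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
  g <- make_grating(orientation_deg, size = size, period = period, phase = phase)
  frames <- array(stats::runif(10 * size * size), dim = c(10, size, size))
  for (i in 1:10) {
    if (p[i] > 0) {
      replace <- matrix(stats::runif(size * size) < p[i], size, size)
      fr <- frames[i, , ]
      fr[replace] <- g[replace]
      frames[i, , ] <- fr
    }
  }
  structure(list(frames = frames, grating = g, envelope = p, v = v,
                 orientation_deg = orientation_deg),
            class = "stimulus_clip")
}

#' One staircase calibration step
#'
#' Adjusts a difficulty parameter (visibility `v`, or the orientation sd in
#' tilt recognition; larger = easier) from recent accuracy. Two scopes:
#' `within_block_10trial` (behavioural session, every 10 trials): increase the
#' parameter when accuracy < 60%, decrease when > 80%. `between_block`
#' (scanner session): divide by 0.95 when block accuracy <= 52.5%, multiply by
#' 0.95 when >= 85%. Both scopes use the 0.95 step factor.
#'
#' @param current Current positive parameter value.
#' @param recent_accuracy Accuracy proportion in `[0, 1]`.
#' @param scope `"within_block_10trial"` or `"between_block"`.
#' @param factor Multiplicative step (default 0.95).
#' @return Updated parameter value.
#' @export
calibrate_step <- function(current, recent_accuracy,
                           scope = c("within_block_10trial", "between_block"),
                           factor = 0.95) {
  if (!is.finite(current) || current <= 0) stop("current must be positive")
  scope <- match.arg(scope)
  if (scope == "within_block_10trial") {
    if (recent_accuracy < 0.60) current / factor
    else if (recent_accuracy > 0.80) current * factor
    else current
  } else {
    if (recent_accuracy <= 0.525) current / factor
    else if (recent_accuracy >= 0.85) current * factor
    else current
  }
}

#' Derive an RNG seed from protocol bytes (pre-RNG seeding)
#'
#' Hashes the input with SHA256 and interprets the first 8 digest bytes as a
#' big-endian unsigned integer. Because R seeds are 32-bit, that integer is
#' returned reduced modulo `2^31 - 1` (computed exactly, byte by byte); the
#' full hex digest is also returned so the derivation can be audited.
#'
#' @param x A raw vector, a character string (hashed as UTF-8 bytes), or a
#'   file path with `is_file = TRUE`.
#' @param is_file If `TRUE`, `x` is a path whose bytes are hashed.
#' @return List with `digest` (hex string) and `seed` (integer).
#' @export
seed_from_protocol <- function(x, is_file = FALSE) {
  if (is_file) {
    if (!is.character(x) || length(x) != 1 || !file.exists(x))
      stop("file not found: ", x)
    hex <- digest::digest(x, algo = "sha256", file = TRUE)
  } else {
    if (is.character(x)) x <- charToRaw(paste(x, collapse = ""))
    if (!is.raw(x)) stop("x must be raw bytes, a string, or a file path")
    hex <- digest::digest(x, algo = "sha256", serialize = FALSE, raw = FALSE)
  }
  list(digest = hex, seed = seed_from_digest(hex))
}

#' Convert a SHA256 hex digest to a 32-bit RNG seed
#'
#' @param hex Hex digest string (at least 16 hex characters).
#' @return Integer seed in `[0, 2^31 - 2]`: the first 8 digest bytes read as a
#'   big-endian unsigned integer, modulo `2^31 - 1`.
#' @export
seed_from_digest <- function(hex) {
  if (!is.character(hex) || length(hex) != 1) stop("hex must be a single string")
  hex <- tolower(gsub("\\s", "", hex))
  if (nchar(hex) < 16 || grepl("[^0-9a-f]", hex)) stop("not a valid hex digest")
  bytes <- strtoi(substring(hex, seq(1, 15, 2), seq(2, 16, 2)), base = 16L)
  m <- 2^31 - 1
  acc <- 0
  for (b in bytes) acc <- (acc * 256 + b) %% m
  as.integer(acc)
}
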