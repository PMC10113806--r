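# Representational similarity analysis over the 12 task x response x
# confidence categories: theory-specified RDMs A-H with no-prediction masks,
# cross-run empirical RDMs, reliability diagnostics and noise ceiling, model
# correlations, and the 18 sub-RDM regression.

#' The 12 RSA condition labels
#'
#' 3 tasks x 2 responses x high/low confidence, in a fixed documented order:
#' tasks discrimination, detection, tilt; within each task the high-variance
#' response first (clockwise, anticlockwise; yes, no; tilted, vertical);
#' confidence high before low.
#'
#' @return Character vector of 12 labels like `"detection_yes_high"`.
#' @export
rsa_conditions <- function() {
  info <- condition_info()
  paste(info$task, info$response, info$conf, sep = "_")
}

condition_info <- function() {
  labs <- task_response_labels()
  tasks <- c("discrimination", "detection", "tilt")
  out <- do.call(rbind, lapply(tasks, function(tk) {
    expand.grid(conf = c("high", "low"),
                response = unname(labs[[tk]][c("high", "low")]),
                task = tk, stringsAsFactors = FALSE)[, c("task", "response", "conf")]
  }))
  # variance class of the reported category: equal (discrimination),
  # high-variance (yes/tilted) or low-variance (no/vertical)
  out$varclass <- ifelse(out$task == "discrimination", "eq",
                         ifelse(out$response %in% c("yes", "tilted"), "hv", "lv"))
  out$cell <- paste(out$task, out$response, sep = "_")
  out
}

#' Assign trials to the 12 RSA conditions by a confidence split
#'
#' Labels each usable trial as its task x response x \{high, low\} confidence
#' condition. The default split is the per-response median: within each task x
#' response cell, ratings at or below the cell's median count as low
#' confidence. The alternative `response_invariant` mode uses one fixed cutoff
#' for all cells (ratings <= `cutoff` are low).
#'
#' @param trials A `trial_table`.
#' @param mode `"per_response_median"` or `"response_invariant"`.
#' @param cutoff Rating cutoff for the response-invariant mode.
#' @return Character vector along `trials` with entries from
#'   [rsa_conditions()]; `NA` for missed or excluded trials.
#' @export
confidence_split <- function(trials,
                             mode = c("per_response_median",
                                      "response_invariant"),
                             cutoff = 3) {
  mode <- match.arg(mode)
  usable <- !trials$missed & !is.na(trials$response)
  if ("excluded" %in% names(trials)) usable <- usable & !trials$excluded
  out <- rep(NA_character_, nrow(trials))
  cell <- paste(trials$task, trials$response, sep = "_")
  for (cl in unique(cell[usable])) {
    sel <- usable & cell == cl
    thr <- if (mode == "per_response_median")
      stats::median(trials$confidence[sel]) else cutoff
    out[sel] <- paste(cl, ifelse(trials$confidence[sel] <= thr, "low", "high"),
                      sep = "_")
  }
  out
}

#' Construct an RDM object
#'
#' @param mat Symmetric numeric matrix of dissimilarities.
#' @param mask Logical matrix, `TRUE` where the model makes no prediction
#'   (masked entries never enter correlations or regressions). Defaults to no
#'   mask for empirical RDMs and a masked diagonal for theoretical ones.
#' @param kind `"theoretical"` or `"empirical"`.
#' @param labels Condition labels.
#' @param description Optional free-text description.
#' @return An `rdm` object.
#' @export
rdm <- function(mat, mask = NULL, kind = c("theoretical", "empirical"),
                labels = rownames(mat), description = NULL) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("RDM must be square")
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-9) stop("RDM must be symmetric")
  if (kind == "empirical" && any(mat < 0)) stop("empirical dissimilarities must be >= 0")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(mat), ncol(mat))
    if (kind == "theoretical") diag(mask) <- TRUE
  }
  if (is.null(labels)) labels <- paste0("cond", seq_len(nrow(mat)))
  dimnames(mat) <- dimnames(mask) <- list(labels, labels)
  structure(list(mat = mat, mask = mask, kind = kind, labels = labels,
                 description = description), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("%s RDM over %d conditions (%d masked entries)%s\n", x$kind,
              nrow(x$mat), sum(x$mask),
              if (!is.null(x$description)) paste0(": ", x$description) else ""))
  invisible(x)
}

#' @rdname rdm
#' @param x An `rdm`.
#' @export
rdm_matrix <- function(x) if (inherits(x, "rdm")) x$mat else as.matrix(x)

#' @rdname rdm
#' @export
rdm_mask <- function(x) {
  if (inherits(x, "rdm")) x$mask
  else matrix(FALSE, nrow(as.matrix(x)), ncol(as.matrix(x)))
}

# unique off-diagonal entries (i < j), optionally respecting a mask
offdiag_values <- function(x, respect_mask = TRUE) {
  m <- rdm_matrix(x); msk <- rdm_mask(x)
  idx <- which(upper.tri(m) & (!respect_mask | !msk))
  list(values = m[idx], idx = idx)
}

#' The eight theory-specified RDMs (A-H)
#'
#' Binary (or graded, for F) 12 x 12 dissimilarity models over the task x
#' response x confidence categories, each with a no-prediction mask:
#' \describe{
#'   \item{A task}{different task = 1.}
#'   \item{B variance structure}{groups \{discrimination\},
#'     \{yes, tilted\} (high variance), \{no, vertical\} (low variance);
#'     different group = 1.}
#'   \item{C decision, detection only}{within the detection block, different
#'     response = 1; masked outside.}
#'   \item{D decision, unequal-variance tasks}{within the detection and tilt
#'     blocks, different response = 1; masked elsewhere.}
#'   \item{E task-invariant confidence}{confidence contrast within each task x
#'     response cell and across tasks (confidence-crossed = 1, aligned = 0);
#'     within-task cross-response pairs masked — the 18 sub-RDMs
#'     ([subrdm_set()]) exactly span its unmasked support.}
#'   \item{F confidence x variance structure}{as E, graded: contrast weight
#'     `uv_weight` within/between the unequal-variance tasks and
#'     `disc_conf_weight` within discrimination (pair weights averaged).}
#'   \item{G confidence, detection only}{within the detection block,
#'     same-response confidence contrast = 1, cross-response pairs 0; masked
#'     outside. On the detection off-diagonal `G = 1 - C`, so their Spearman
#'     correlation over mutually defined entries is exactly -1.}
#'   \item{H confidence, unequal-variance tasks}{as G within detection and
#'     tilt; between those two tasks, confidence-crossed = 1, aligned = 0;
#'     pairs involving discrimination masked.}
#' }
#'
#' @param disc_conf_weight Confidence contrast weight inside discrimination
#'   for model F (unequal-variance weight is 1).
#' @return Named list of 8 `rdm` objects.
#' @export
theoretical_rdms <- function(disc_conf_weight = 0.5) {
  info <- condition_info()
  n <- nrow(info)
  labels <- rsa_conditions()
  build <- function(fun, description) {
    m <- matrix(0, n, n); msk <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) { msk[i, j] <- TRUE; next }
      v <- fun(info[i, ], info[j, ])
      if (is.na(v)) msk[i, j] <- TRUE else m[i, j] <- v
    }
    rdm(m, msk, "theoretical", labels, description)
  }
  uv <- c("detection", "tilt")
  wt <- function(task) if (task == "discrimination") disc_conf_weight else 1
  list(
    A = build(function(a, b) as.numeric(a$task != b$task), "task"),
    B = build(function(a, b) as.numeric(a$varclass != b$varclass),
              "variance structure"),
    C = build(function(a, b) {
      if (a$task != "detection" || b$task != "detection") return(NA)
      as.numeric(a$response != b$response)
    }, "decision: detection only"),
    D = build(function(a, b) {
      if (!(a$task %in% uv) || a$task != b$task) return(NA)
      as.numeric(a$response != b$response)
    }, "decision: unequal variance tasks"),
    E = build(function(a, b) {
      if (a$task == b$task && a$response != b$response) return(NA)
      as.numeric(a$conf != b$conf)
    }, "task-invariant confidence"),
    F = build(function(a, b) {
      if (a$task == b$task && a$response != b$response) return(NA)
      (wt(a$task) + wt(b$task)) / 2 * as.numeric(a$conf != b$conf)
    }, "confidence x variance structure"),
    G = build(function(a, b) {
      if (a$task != "detection" || b$task != "detection") return(NA)
      as.numeric(a$response == b$response && a$conf != b$conf)
    }, "confidence: detection only"),
    H = build(function(a, b) {
      if (!(a$task %in% uv) || !(b$task %in% uv)) return(NA)
      if (a$task == b$task)
        as.numeric(a$response == b$response && a$conf != b$conf)
      else as.numeric(a$conf != b$conf)
    }, "confidence: unequal variance tasks")
  )
}

#' Cross-run empirical RDM from multivoxel patterns
#'
#' Entry (i, j) is the mean Euclidean distance between condition i's pattern
#' in run r and condition j's pattern in run s over all ordered run pairs
#' r != s — never within a single run, so run-specific noise cannot masquerade
#' as condition similarity. The diagonal (cross-run self-distance) is retained.
#'
#' @param patterns `runs x conditions x voxels` array
#'   (see [simulate_patterns()]); every condition must be present (non-NA) in
#'   every run.
#' @return An empirical `rdm`.
#' @export
empirical_rdm <- function(patterns) {
  stopifnot(length(dim(patterns)) == 3)
  runs <- dim(patterns)[1]; nc <- dim(patterns)[2]
  if (runs < 2) stop("need >= 2 runs")
  if (any(is.na(patterns))) stop("missing condition pattern in some run")
  m <- matrix(0, nc, nc)
  npairs <- 0L
  for (r in seq_len(runs)) for (s in seq_len(runs)) {
    if (r == s) next
    npairs <- npairs + 1L
    dr <- patterns[r, , , drop = TRUE]
    ds <- patterns[s, , , drop = TRUE]
    cross <- outer(rowSums(dr^2), rowSums(ds^2), "+") - 2 * tcrossprod(dr, ds)
    m <- m + sqrt(pmax(cross, 0))
  }
  m <- m / npairs
  m <- (m + t(m)) / 2  # exact symmetry against floating-point noise
  labels <- dimnames(patterns)[[2]]
  rdm(m, mask = NULL, kind = "empirical",
      labels = if (is.null(labels)) paste0("cond", seq_len(nc)) else labels)
}

#' Spearman correlations between an empirical RDM and candidate models
#'
#' Computed over the off-diagonal entries where the model makes a prediction
#' (mask respected on both sides); average-rank tie handling via
#' `stats::cor(method = "spearman")`.
#'
#' @param empirical An empirical `rdm`.
#' @param models A single `rdm` or named list of them.
#' @return Named numeric vector of Spearman correlations.
#' @export
model_correlations <- function(empirical, models) {
  if (inherits(models, "rdm")) models <- list(model = models)
  emp <- rdm_matrix(empirical); emp_mask <- rdm_mask(empirical)
  vapply(models, function(mod) {
    m <- rdm_matrix(mod)
    if (!all(dim(m) == dim(emp))) stop("model/empirical size mismatch")
    ok <- upper.tri(emp) & !rdm_mask(mod) & !emp_mask
    if (sum(ok) < 3) stop("fewer than 3 usable entries")
    stats::cor(emp[ok], m[ok], method = "spearman")
  }, numeric(1))
}

#' RDM reliability diagnostics and noise ceiling
#'
#' Per subject, all unique entries (diagonal and off-diagonal) are rank
#' transformed and the mean off-diagonal rank is compared with the mean
#' diagonal rank (condition-specific information should make cross-condition
#' distances larger than cross-run self-distances); the per-subject
#' differences go into a group t-test. The noise-ceiling lower bound is the
#' average leave-one-out Spearman correlation between each subject's
#' off-diagonal entries and the average ranked RDM of the other subjects.
#'
#' @param subject_rdms List (>= 2) of empirical `rdm`s on the same conditions.
#' @return List: `diag_stat` per subject (mean off-diagonal minus diagonal
#'   rank), `group` (a `group_stats` t-test), `noise_ceiling_lower`,
#'   `per_subject_ceiling`.
#' @export
rdm_diagnostics <- function(subject_rdms) {
  if (length(subject_rdms) < 2) stop("need >= 2 subjects")
  stat <- vapply(subject_rdms, function(x) {
    m <- rdm_matrix(x)
    idx_all <- which(upper.tri(m, diag = TRUE))
    rk <- rank(m[idx_all])
    on_diag <- (row(m) == col(m))[idx_all]
    mean(rk[!on_diag]) - mean(rk[on_diag])
  }, numeric(1))
  offs <- vapply(subject_rdms, function(x) offdiag_values(x, FALSE)$values,
                 numeric(sum(upper.tri(rdm_matrix(subject_rdms[[1]])))))
  ranked <- apply(offs, 2, rank)
  ceil <- vapply(seq_along(subject_rdms), function(i) {
    others <- rowMeans(ranked[, -i, drop = FALSE])
    stats::cor(offs[, i], others, method = "spearman")
  }, numeric(1))
  group <- if (stats::sd(stat) == 0 && mean(stat) != 0) {
    message("diagnostic statistic identical across subjects; no group t-test")
    NULL
  } else ttest_with_d(stat)
  list(diag_stat = stat, group = group,
       noise_ceiling_lower = mean(ceil), per_subject_ceiling = ceil)
}

#' The 18 constituent sub-RDMs of the confidence model
#'
#' Decomposes the task-invariant confidence model (RDM E) into 6 within-cell
#' sub-RDMs (one per task x response cell, contrasting its high- vs
#' low-confidence conditions) and 12 between-cell sub-RDMs (one per ordered
#' pair of same- or different-response cells from two different tasks;
#' confidence-aligned entries 0, confidence-crossed entries 1). Their supports
#' are disjoint and their sum equals E on its unmasked support.
#'
#' @return List with `predictors` (named list of 18 matrices), `cells`
#'   (data frame describing each sub-RDM), and `domain` (logical matrix of
#'   E's unmasked entries).
#' @export
subrdm_set <- function() {
  info <- condition_info()
  labels <- rsa_conditions()
  n <- nrow(info)
  E <- theoretical_rdms()$E
  preds <- list(); meta <- list()
  cells <- unique(info$cell)
  for (cl in cells) {
    idx <- which(info$cell == cl)
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m[idx[1], idx[2]] <- m[idx[2], idx[1]] <- 1
    nm <- paste0("within_", cl)
    preds[[nm]] <- m
    meta[[nm]] <- data.frame(name = nm, kind = "within", cell_a = cl,
                             cell_b = cl, stringsAsFactors = FALSE)
  }
  cell_task <- info$task[match(cells, info$cell)]
  for (a in seq_along(cells)) for (b in seq_along(cells)) {
    if (b <= a || cell_task[a] == cell_task[b]) next
    ia <- which(info$cell == cells[a]); ib <- which(info$cell == cells[b])
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in ia) for (j in ib) {
      v <- as.numeric(info$conf[i] != info$conf[j])
      m[i, j] <- m[j, i] <- v
    }
    nm <- paste0(cells[a], "__", cells[b])
    preds[[nm]] <- m
    meta[[nm]] <- data.frame(name = nm, kind = "between", cell_a = cells[a],
                             cell_b = cells[b], stringsAsFactors = FALSE)
  }
  list(predictors = preds, cells = do.call(rbind, meta),
       domain = !rdm_mask(E))
}

#' Sub-RDM multiple regression with weighted beta combinations
#'
#' Regresses the empirical RDM's entries, over the unmasked support of the
#' confidence model, on the 18 sub-RDM predictors plus an intercept. Each
#' between-cell predictor marks confidence-crossed entries of its cell pair,
#' so its beta measures confidence-alignment structure shared by the two
#' cells. Two pre-specified combinations summarise the betas:
#' `det_tilt_response_specific` (mean of the 'yes'-'tilted' and
#' 'no'-'vertical' pairings, the unequal-variance prediction) and
#' `tilt_disc_response_invariant` (mean over all four tilt x discrimination
#' pairings, the presence/absence-account prediction).
#'
#' @param empirical An empirical `rdm` over [rsa_conditions()].
#' @param subrdms Result of [subrdm_set()].
#' @return List: `betas` (18 named coefficients), `se`, `combinations` (named
#'   length-2 vector), `intercept`, `fit` (the `lm` object).
#' @export
subrdm_regression <- function(empirical, subrdms = subrdm_set()) {
  emp <- rdm_matrix(empirical)
  dom <- subrdms$domain
  if (!all(dim(emp) == dim(dom))) stop("empirical RDM size mismatch")
  idx <- which(upper.tri(emp) & dom)
  X <- vapply(subrdms$predictors, function(m) m[idx], numeric(length(idx)))
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    cc <- stats::cor(X)
    bad <- unique(colnames(X)[which(abs(cc) > 1 - 1e-8 &
                                      upper.tri(cc), arr.ind = TRUE)])
    stop("collinear sub-RDM predictors: ", paste(bad, collapse = ", "))
  }
  d <- data.frame(y = emp[idx], X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = d)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  betas <- cf[-1]; names(betas) <- colnames(X)
  comb <- c(
    det_tilt_response_specific =
      mean(betas[c("detection_yes__tilt_tilted", "detection_no__tilt_vertical")]),
    tilt_disc_response_invariant =
      mean(betas[grep("^discrimination_.*__tilt_", names(betas))])
  )
  list(betas = betas, se = se[-1], combinations = comb, intercept = cf[[1]],
       fit = fit)
}
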