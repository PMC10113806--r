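# Tab-separated I/O: BIDS-events-style trial tables, rating count tables,
# RDMs with JSON sidecars, and design-matrix export.

events_required_cols <- c("onset", "duration", "task", "stim_class",
                          "response", "confidence", "missed", "block", "run",
                          "trial")

#' Write a trial table as a BIDS-events-style TSV
#'
#' Missing values (missed-trial response/confidence, absent orientations) are
#' written as `n/a` per the BIDS convention.
#'
#' @param table A `trial_table`.
#' @param path Output path.
#' @export
write_events <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    x <- out[[j]]
    x <- as.character(x)
    x[is.na(x)] <- "n/a"
    out[[j]] <- x
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-events-style TSV into a trial table
#'
#' @param path Path to a tab-separated events file with columns onset,
#'   duration, task, stim_class, response, confidence, missed, block, run,
#'   trial (orientation and visibility are optional).
#' @return A validated `trial_table`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         na.strings = c("n/a", "NA"),
                         stringsAsFactors = FALSE)
  missing <- setdiff(events_required_cols, names(d))
  if (length(missing))
    stop("events file is missing required columns: ",
         paste(missing, collapse = ", "))
  num_cols <- c("onset", "duration", "confidence", "block", "run", "trial")
  for (cn in num_cols) {
    if (!is.numeric(d[[cn]]))
      d[[cn]] <- suppressWarnings(as.numeric(d[[cn]]))
    if (cn %in% c("onset", "duration") && any(is.na(d[[cn]])))
      stop("column '", cn, "' contains non-numeric or missing values")
  }
  d$missed <- as.logical(d$missed)
  if (any(is.na(d$missed))) stop("column 'missed' must be logical (TRUE/FALSE)")
  if ("correct" %in% names(d)) d$correct <- as.logical(d$correct)
  if (any(!d$missed & is.na(d$confidence)))
    stop("confidence missing on non-missed trials")
  class(d) <- c("trial_table", "data.frame")
  d
}

#' Serialize a rating count table
#'
#' 2 x (2k) integer table, tab-separated, with a header naming the bin order
#' (response low, confidence k..1, then response high, confidence 1..k).
#'
#' @param table A `rating_count_table`.
#' @param path Output path.
#' @export
write_rating_table <- function(table, path) {
  utils::write.table(cbind(class = rownames(table), as.data.frame(unclass(table))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rating_table
#' @export
read_rating_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  structure(m, class = c("rating_count_table", class(m)),
            n_conf_levels = ncol(m) %/% 2L)
}

#' Write / read an RDM as TSV with a JSON sidecar
#'
#' The matrix goes to `<path>`; labels, kind, description and the
#' no-prediction mask go to `<path>.json`.
#'
#' @param x An `rdm`.
#' @param path Output TSV path.
#' @export
write_rdm <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  utils::write.table(rdm_matrix(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- list(labels = x$labels, kind = x$kind,
               description = x$description,
               mask = apply(x$mask, 1, as.logical, simplify = FALSE))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mask <- do.call(rbind, lapply(side$mask, as.logical))
  rdm(m, mask = mask, kind = side$kind, labels = side$labels,
      description = side$description)
}

#' Export a design matrix as TSV plus JSON column metadata
#'
#' @param dm A `design_matrix`.
#' @param path Output TSV path (columns named; one row per scan). Column
#'   metadata (of-interest flags, parent response, modulator order, TR) goes
#'   to `<path>.json`.
#' @export
write_design_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "design_matrix"))
  utils::write.table(dm$X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(TR = dm$TR, run_duration = dm$run_duration, runs = dm$runs,
               type = dm$type, columns = dm$columns)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
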