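#' @include AllClasses.R accessors.R
NULL

## Default sidecar path for a plate CSV: <stem>.meta.yml
.sidecarPath <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yml")
}

## Scan a YAML sidecar's text for duplicate well keys inside a block, which
## yaml::read_yaml would silently collapse.
.checkDuplicateKeys <- function(lines, block) {
  start <- grep(sprintf("^%s:", block), lines)
  if (!length(start)) return(invisible(NULL))
  keys <- character(0)
  for (ln in lines[seq(from = start[1L] + 1L, length.out = length(lines) - start[1L])]) {
    if (grepl("^\\S", ln)) break            # next top-level block
    m <- regmatches(ln, regexec("^\\s+([^:\\s]+)\\s*:", ln))[[1L]]
    if (length(m) == 2L) keys <- c(keys, m[2L])
  }
  if (anyDuplicated(keys))
    stop("well '", keys[duplicated(keys)][1L],
         "' appears more than once in the metadata", call. = FALSE)
  invisible(NULL)
}

#' Read a plate-format luminescence recording
#'
#' Reads the wide plate CSV dialect (first column `time_h` in hours, one
#' column per well) together with its YAML metadata sidecar, which must map
#' every well to a condition in a `conditions:` block (and optionally a
#' replicate index in a `replicates:` block):
#'
#' ```yaml
#' conditions:
#'   A1: NIH3T3
#' replicates:
#'   A1: 1
#' ```
#'
#' The reader validates rather than repairs: a non-monotone time axis, a
#' non-numeric cell, a duplicated well header, or a well missing from (or
#' duplicated in) the metadata each raise an error identifying the offender.
#'
#' @param path Path to the plate CSV.
#' @param metadata_path Path to the sidecar; defaults to
#'   `<stem>.meta.yml` next to `path`.
#' @return A [PlateRecording-class] whose traces carry empty
#'   `steps_applied` (unless the sidecar records prior steps).
#' @seealso [writePlate()]
#' @export
readPlate <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(metadata_path)) metadata_path <- .sidecarPath(path)
  if (!file.exists(metadata_path))
    stop("metadata sidecar not found: ", metadata_path, call. = FALSE)

  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  hdr <- colnames(raw)
  if (length(hdr) < 2L || hdr[1L] != "time_h")
    stop("first column must be 'time_h'; got '", hdr[1L], "'", call. = FALSE)
  wells <- hdr[-1L]
  if (anyDuplicated(wells))
    stop("duplicate well column '", wells[duplicated(wells)][1L], "'",
         call. = FALSE)

  num <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(NULL, hdr))
  for (j in seq_along(hdr)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]) & nzchar(raw[[j]]))
    if (anyNA(v)) {
      at <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                   at + 1L, hdr[j]), call. = FALSE)   # +1: header row
    }
    num[, j] <- v
  }
  time_h <- num[, 1L]
  if (any(diff(time_h) <= 0))
    stop(sprintf("time_h not strictly increasing at row %d",
                 which(diff(time_h) <= 0)[1L] + 2L), call. = FALSE)

  meta_lines <- readLines(metadata_path, warn = FALSE)
  .checkDuplicateKeys(meta_lines, "conditions")
  meta <- yaml::yaml.load(paste(meta_lines, collapse = "\n"))
  if (is.null(meta$conditions))
    stop("metadata sidecar lacks a 'conditions:' block", call. = FALSE)
  cond <- unlist(meta$conditions)
  missing <- setdiff(wells, names(cond))
  if (length(missing))
    stop("no condition declared for well '", missing[1L], "'", call. = FALSE)
  reps <- if (!is.null(meta$replicates)) unlist(meta$replicates) else NULL
  steps <- if (!is.null(meta$steps_applied))
    as.character(unlist(meta$steps_applied)) else character(0)

  trs <- lapply(wells, function(w)
    luminescenceTrace(w, time_h, num[, w], steps))
  plateRecording(trs, cond, reps)
}

#' Write a plate recording to the wide CSV dialect
#'
#' Writes the plate's luminescence matrix as `time_h,<well>,...` CSV plus a
#' YAML sidecar with the condition and replicate maps (and any preprocessing
#' labels), so that `readPlate(writePlate(x))` reproduces every numeric
#' value to well under 1e-9 relative error and the metadata exactly.
#'
#' @param plate A valid [PlateRecording-class].
#' @param path Output CSV path.
#' @param metadata_path Sidecar path; defaults to `<stem>.meta.yml`.
#' @return Invisibly, `path`.
#' @export
writePlate <- function(plate, path, metadata_path = NULL) {
  validObject(plate)
  if (ncol(plate) == 0L) stop("no traces", call. = FALSE)
  if (is.null(metadata_path)) metadata_path <- .sidecarPath(path)
  mat <- SummarizedExperiment::assay(plate, "luminescence")
  df <- data.frame(time_h = traceTime(plate), check.names = FALSE)
  for (w in colnames(mat)) df[[w]] <- mat[, w]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  meta <- list(
    conditions = as.list(conditions(plate)),
    replicates = lapply(as.list(replicates(plate)), as.integer)
  )
  if (length(stepsApplied(plate)))
    meta$steps_applied <- as.list(stepsApplied(plate))
  yaml::write_yaml(meta, metadata_path)
  invisible(path)
}
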