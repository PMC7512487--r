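#' Read an RR-interval CSV
#'
#' Canonical dialect: a header row, a numeric column `rr_s` (seconds) and an
#' optional `label` column with per-beat rhythm codes. Malformed numeric
#' values are rejected with their line numbers.
#'
#' @param path file path.
#' @return list with `rr` (numeric vector) and `labels` (character vector or
#'   `NULL`).
#' @export
read_rr_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"rr_s" %in% names(df)) {
    stop("missing required column 'rr_s' in ", path)
  }
  rr <- suppressWarnings(as.numeric(df$rr_s))
  bad <- which(!is.finite(rr))
  if (length(bad) > 0) {
    stop("non-numeric or non-finite rr_s at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)  # +1 for header
  }
  labels <- if ("label" %in% names(df)) df$label else NULL
  list(rr = rr, labels = labels)
}

#' Write an RR-interval CSV in the canonical dialect
#'
#' @param rr numeric RR vector, seconds.
#' @param path output path.
#' @param labels optional per-beat labels.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path, labels = NULL) {
  df <- data.frame(rr_s = as.numeric(rr))
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Derive an RR series from a beat-annotation export
#'
#' Reads a PhysioNet-style beat-annotation text export and converts
#' consecutive QRS sample indices to RR intervals:
#' `RR_k = (sample_{k+1} - sample_k) / fs`. Two dialects are accepted: a CSV
#' with columns `sample_index` (and optional `beat_code`), or a
#' whitespace-separated annotation dump whose second column is the sample
#' index (`time sample code ...`).
#'
#' @param path file path.
#' @param fs sampling frequency in Hz (the reference database uses 250 Hz,
#'   i.e. 4 ms resolution).
#' @return numeric RR vector, seconds (empty for fewer than 2 beats).
#' @export
read_beat_annotations <- function(path, fs) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(fs > 0)
  first <- readLines(path, n = 1L)
  if (grepl("sample_index", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    samples <- as.numeric(df$sample_index)
  } else {
    df <- utils::read.table(path, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("cannot parse beat annotations in ", path)
    samples <- suppressWarnings(as.numeric(df[[2]]))
  }
  if (any(!is.finite(samples))) stop("non-numeric sample index in ", path)
  if (length(samples) < 2L) return(numeric(0))
  if (any(diff(samples) <= 0)) {
    stop("sample indices must be strictly increasing in ", path)
  }
  diff(samples) / fs
}

#' Read a rhythm-episode CSV
#'
#' Columns `start_beat`, `end_beat`, `rhythm`.
#'
#' @param path file path.
#' @return data.frame suitable for [segment_episodes()].
#' @export
read_episodes_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_beat", "end_beat", "rhythm")
  if (!all(need %in% names(df))) {
    stop("episode file needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read a signal-quality-index CSV
#'
#' Columns `t_start_s`, `bsqi`, `tsqi`, `isqi`, `psqi`, `ksqi`; one row per
#' 10-s window.
#'
#' @param path file path.
#' @return data.frame suitable for [segment_noise_gate()].
#' @export
read_sqi_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_start_s", "bsqi", "tsqi", "isqi", "psqi", "ksqi")
  if (!all(need %in% names(df))) {
    stop("SQI file needs columns: ", paste(need, collapse = ", "))
  }
  df
}
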