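#' Read an sEMG sample stream from delimited text
#'
#' Reads a plain-text file holding one amplitude sample per row (optionally
#' with a leading time column) into an [emg_record()]. The sampling rate is
#' always user-supplied; a time column, when present, is only validated for
#' approximate uniformity (maximum deviation 1% of `1/fs`) and then
#' discarded.
#'
#' @param path Path to a delimited text file.
#' @param fs Sampling rate in Hz. Defaults to 2000 Hz, the acquisition rate
#'   the classifier's defaults were designed for.
#' @param column Column selector: a name (requires a header row) or index.
#'   Default `NULL` picks the only column of a one-column file, or the
#'   second column of a two-column (time, amplitude) file.
#' @param delimiter Field separator. Default `NULL` means any whitespace;
#'   a `","` is auto-detected for `.csv` files.
#' @param label Optional channel label stored on the record.
#'
#' @return An [emg_record()].
#' @export
read_emg <- function(path, fs = 2000, column = NULL, delimiter = NULL,
                     label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""

  dat <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", comment.char = "",
                           blank.lines.skip = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(dat) == 0L) stop("empty file: ", path, call. = FALSE)

  # header row: first row with any cell that does not parse as a number
  first <- suppressWarnings(as.numeric(unlist(dat[1L, ])))
  has_header <- anyNA(first)
  header <- NULL
  if (has_header) {
    header <- trimws(as.character(unlist(dat[1L, ])))
    dat <- dat[-1L, , drop = FALSE]
    if (nrow(dat) == 0L) stop("file has a header but no data rows: ", path,
                              call. = FALSE)
    names(dat) <- header
  }

  col_idx <- .resolve_column(column, ncol(dat), header)
  vals <- suppressWarnings(as.numeric(dat[[col_idx]]))
  bad <- which(!is.finite(vals))
  if (length(bad) > 0L) {
    row_in_file <- bad[1L] + if (has_header) 1L else 0L
    stop(sprintf("non-numeric value '%s' at row %d of %s",
                 dat[[col_idx]][bad[1L]], row_in_file, path), call. = FALSE)
  }

  # validate (then discard) a time column in two-column files
  if (ncol(dat) == 2L && col_idx == 2L) {
    tcol <- suppressWarnings(as.numeric(dat[[1L]]))
    if (all(is.finite(tcol)) && length(tcol) > 2L) {
      dt <- diff(tcol)
      if (max(abs(dt - stats::median(dt))) > 0.01 / fs)
        stop("time column is not uniformly sampled ",
             "(deviation exceeds 1% of 1/fs)", call. = FALSE)
    }
  }

  emg_record(vals, fs = fs, label = label)
}

.resolve_column <- function(column, ncol, header) {
  if (is.null(column)) {
    if (ncol == 1L) return(1L)
    if (ncol == 2L) return(2L)  # (time, amplitude) convention
    stop("file has ", ncol, " columns; specify `column`", call. = FALSE)
  }
  if (is.character(column)) {
    if (is.null(header))
      stop("column selected by name ('", column,
           "') but the file has no header row", call. = FALSE)
    idx <- match(column, header)
    if (is.na(idx)) stop("no column named '", column, "'", call. = FALSE)
    return(idx)
  }
  idx <- as.integer(column)
  if (is.na(idx) || idx < 1L || idx > ncol)
    stop("column index out of range: ", column, call. = FALSE)
  idx
}

.label_levels <- c("fatigue", "non-fatigue", "not-examined")

.normalize_label <- function(x) {
  y <- tolower(trimws(x))
  y <- gsub("[ _]", "-", y)
  bad <- which(!y %in% .label_levels)
  if (length(bad) > 0L)
    stop("unknown segment label: '", x[bad[1L]], "' (allowed: ",
         paste(.label_levels, collapse = ", "), ")", call. = FALSE)
  y
}

#' Read a per-muscle segment label table
#'
#' Reads a delimited table with one row per muscle: identifier columns
#' (`subject`, `muscle`) followed by ordered per-segment classification
#' labels drawn from the closed vocabulary `fatigue`, `non-fatigue`,
#' `not-examined`. Rows containing any `not-examined` label are retained
#' but flagged as unusable (excluded from downstream tallies).
#'
#' The packaged fixture `session_labels.csv` (see
#' `system.file("extdata", "session_labels.csv", package = "emgfatigue")`)
#' holds the 76-muscle session classification table the evaluation module
#' was validated against: 75 usable muscles plus one not-examined muscle.
#'
#' @param path Path to a CSV file.
#' @return A `label_table`: a data frame with the identifier columns, the
#'   normalized label columns (attribute `label_cols`), and a logical
#'   `usable` column.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(dat) == 0L) stop("empty label table: ", path, call. = FALSE)
  label_cols <- names(dat)[!tolower(names(dat)) %in% c("subject", "muscle")]
  if (length(label_cols) < 2L)
    stop("label table needs at least two segment label columns",
         call. = FALSE)
  for (cl in label_cols) dat[[cl]] <- .normalize_label(dat[[cl]])
  lab <- as.matrix(dat[label_cols])
  dat$usable <- apply(lab, 1L, function(r) all(r != "not-examined"))
  n_lab <- apply(lab, 1L, function(r) sum(r != "not-examined"))
  if (any(dat$usable & n_lab < 2L))
    stop("row ", which(dat$usable & n_lab < 2L)[1L],
         " has fewer than 2 labeled segments", call. = FALSE)
  structure(dat, label_cols = label_cols, class = c("label_table",
                                                    "data.frame"))
}

#' Write a fatigue report to disk
#'
#' Serializes the per-segment classification table of a
#' [detect_fatigue()] report as CSV (segment rows only) or JSON (segment
#' rows plus a summary block with the IEMG baseline and onset time).
#' Numeric fields are written with full precision so a read-back via
#' [read_report()] reproduces them bit-for-bit.
#'
#' @param report A `fatigue_report` from [detect_fatigue()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  stopifnot(inherits(report, "fatigue_report"))
  format <- match.arg(format)
  seg <- report$segments
  if (nrow(seg) == 0L) stop("report is empty", call. = FALSE)
  if (format == "csv") {
    out <- seg
    for (cl in names(out))
      if (is.double(out[[cl]]))
        out[[cl]] <- sprintf("%.17g", out[[cl]])
    ok <- tryCatch({
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  } else {
    obj <- list(
      summary = list(
        n_segments = nrow(seg),
        iemg_initial = report$iemg_initial,
        onset_time_s = if (is.na(report$onset_time)) NULL
                       else report$onset_time,
        fatigue_segments = sum(seg$label == "fatigue")
      ),
      segments = seg
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

#' Read back a fatigue report written by [write_report()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return For CSV, the per-segment data frame. For JSON, a list with
#'   `summary` and `segments` (data frame).
#' @export
read_report <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  fix_types <- function(dat) {
    num_cols <- intersect(c("t_start_s", "iemg", "ima_lfss", "ima_hfss",
                            "fatigue_index"), names(dat))
    for (cl in num_cols) dat[[cl]] <- as.numeric(dat[[cl]])
    if ("gate_passed" %in% names(dat))
      dat$gate_passed <- as.logical(dat$gate_passed)
    if ("label" %in% names(dat)) dat$label <- as.character(dat$label)
    dat
  }
  if (format == "csv") {
    fix_types(utils::read.csv(path, stringsAsFactors = FALSE))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    obj$segments <- fix_types(as.data.frame(obj$segments))
    obj
  }
}
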