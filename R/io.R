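# Shared line-oriented numeric reader: blank lines and lines starting with
# '#' are skipped; anything else must parse as a single leading numeric
# token. Errors name the offending 1-based line number of the file.
read_numeric_lines <- function(path) {
  if (!file.exists(path))
    stop_hrv("file not found: %s", path, class = "hrvkit_io")
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  if (!any(keep))
    stop_hrv("no data lines in %s", path, class = "hrvkit_empty_input")
  tokens <- vapply(strsplit(trimmed[keep], "[[:space:],;]+"), `[`, "", 1)
  values <- suppressWarnings(as.numeric(tokens))
  if (anyNA(values)) {
    bad <- which(keep)[which(is.na(values))[1]]
    stop_hrv("cannot parse '%s' as a number at line %d of %s",
             tokens[which(is.na(values))[1]], bad, path,
             class = "hrvkit_parse")
  }
  values
}

#' Read an RR-interval series from plain text
#'
#' One interval per line; blank lines and `#` comment lines are skipped.
#' Files exported in seconds are converted to ms.
#'
#' @param path Path to a text file.
#' @param units Units of the stored values: `"ms"` (default) or `"s"`.
#' @return An [rri_series] in ms.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("800", "810", "790"), f)
#' read_rri_text(f)
#' @export
read_rri_text <- function(path, units = c("ms", "s")) {
  units <- match.arg(units)
  values <- read_numeric_lines(path)
  if (units == "s") values <- values * 1000
  if (any(values <= 0))
    stop_hrv("non-positive RR interval in %s", path,
             class = "hrvkit_validation")
  rri_series(values, label = basename(path))
}

#' Read a Polar HRM heart-rate-monitor file
#'
#' Parses the INI-style `.hrm` text format: RR intervals (ms) are taken as
#' the first whitespace-separated field of each line in the `[HRData]`
#' section. `[Params]` metadata, when present, is kept as the series label.
#'
#' @param path Path to a `.hrm` file.
#' @return An [rri_series] in ms.
#' @export
read_polar_hrm <- function(path) {
  if (!file.exists(path))
    stop_hrv("file not found: %s", path, class = "hrvkit_io")
  lines <- trimws(readLines(path, warn = FALSE))
  sec_starts <- grep("^\\[.*\\]$", lines)
  hr_at <- which(toupper(lines[sec_starts]) == "[HRDATA]")
  if (!length(hr_at))
    stop_hrv("no [HRData] section in %s", path, class = "hrvkit_format")
  from <- sec_starts[hr_at[1]] + 1
  to <- c(sec_starts, length(lines) + 1)[match(sec_starts[hr_at[1]], sec_starts) + 1] - 1
  body <- lines[seq(from, length.out = max(0, to - from + 1))]
  body <- body[nzchar(body)]
  if (!length(body))
    stop_hrv("[HRData] section of %s is empty", path,
             class = "hrvkit_empty_input")
  tokens <- vapply(strsplit(body, "[[:space:]]+"), `[`, "", 1)
  values <- suppressWarnings(as.numeric(tokens))
  if (anyNA(values)) {
    bad <- from + which(is.na(values))[1] - 1
    stop_hrv("cannot parse RR value at line %d of %s", bad, path,
             class = "hrvkit_parse")
  }
  label <- basename(path)
  par_at <- which(toupper(lines[sec_starts]) == "[PARAMS]")
  if (length(par_at)) {
    pfrom <- sec_starts[par_at[1]] + 1
    pto <- c(sec_starts, length(lines) + 1)[match(sec_starts[par_at[1]], sec_starts) + 1] - 1
    params <- lines[seq(pfrom, length.out = max(0, pto - pfrom + 1))]
    params <- params[nzchar(params)]
    if (length(params))
      label <- paste0(label, " (", paste(params, collapse = "; "), ")")
  }
  rri_series(values, label = label)
}

#' Read an evenly sampled ECG from plain text
#'
#' One voltage sample per line; the sampling frequency is not stored in the
#' file and must be supplied.
#'
#' @param path Path to a text file.
#' @param fs Sampling frequency in Hz.
#' @return An [ecg_record].
#' @export
read_ecg_text <- function(path, fs) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop_hrv("fs must be a single positive number",
             class = "hrvkit_validation")
  ecg_record(read_numeric_lines(path), fs = fs)
}

#' Write an analysis results table to CSV
#'
#' Writes one row per analysed segment (stationary analyses produce a
#' single row spanning the whole record), full numeric precision, RFC-4180
#' quoting with '.' as decimal separator.
#'
#' @param table A data.frame of results.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop_hrv("results table must be a non-empty data.frame",
             class = "hrvkit_validation")
  if (anyDuplicated(names(table)))
    stop_hrv("results table column names must be unique",
             class = "hrvkit_validation")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
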