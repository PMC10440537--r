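#' Construct an EEG recording object
#'
#' An `eeg_recording` holds one subject-week of resting EEG as a
#' lead-by-sample matrix in microvolts, with the 19-lead 10-20 montage and a
#' sampling rate.  Rows are ordered per [montage_1020()].
#'
#' @param data Numeric matrix, 19 rows (leads) by n samples, microvolts.
#'   Row names must be (or normalize to) the montage lead names.
#' @param fs Sampling rate in Hz; must be at least 40 so the 2-20 Hz
#'   analysis band lies below Nyquist.
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `montage`, `duration_s`.
#' @examples
#' m <- matrix(rnorm(19 * 1000), nrow = 19,
#'             dimnames = list(montage_1020()$lead, NULL))
#' rec <- eeg_recording(m, fs = 250)
#' rec$duration_s
#' @export
eeg_recording <- function(data, fs) {
  if (!is.matrix(data) || !is.numeric(data)) abort("`data` must be a numeric matrix.")
  stopifnot_scalar_number(fs, "fs")
  if (fs < 40) abort("`fs` must be >= 40 Hz (the 2-20 Hz band must lie below Nyquist).")
  canon <- canonical_leads(rownames(data))
  montage <- montage_1020()
  missing <- setdiff(montage$lead, canon)
  if (length(missing)) {
    abort(sprintf("Recording is missing montage lead(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  rownames(data) <- canon
  data <- data[montage$lead, , drop = FALSE]
  structure(
    list(data = data, fs = fs, montage = montage,
         duration_s = ncol(data) / fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> 19 leads x %d samples, fs = %g Hz (%.1f s)\n",
              ncol(x$data), x$fs, x$duration_s))
  invisible(x)
}

#' Read a multi-channel EEG recording
#'
#' Reads a 19-lead recording from CSV or EDF into an [eeg_recording()].
#' Lead labels are matched case-insensitively and the modern temporal
#' synonyms (T7/T3, T8/T4, P7/T5, P8/T6) are accepted; rows are reordered
#' onto the montage.  Any montage lead absent from the file is a hard error.
#'
#' The CSV dialect is one metadata line `# fs=<Hz>` followed by one row per
#' lead: the lead label, then the samples.  EDF is the standard 16-bit
#' European Data Format; amplitudes are taken to be microvolts and no
#' re-referencing is applied.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return An [eeg_recording()].
#' @seealso [write_eeg()]
#' @export
read_eeg <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  switch(format, csv = read_eeg_csv(path), edf = read_eeg_edf(path))
}

#' Write an EEG recording
#'
#' Inverse of [read_eeg()].  CSV preserves amplitudes to about 1e-6 relative
#' precision; EDF quantizes to 16 bits over each channel's amplitude range.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param format `"csv"` or `"edf"` (EDF requires an integer sampling rate).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording.")
  switch(format, csv = write_eeg_csv(rec, path), edf = write_eeg_edf(rec, path))
  invisible(path)
}

read_eeg_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  fsm <- regmatches(meta, regexpr("fs\\s*=\\s*[0-9.]+", meta))
  if (!length(fsm)) abort(sprintf("CSV %s lacks the '# fs=<Hz>' metadata line.", path))
  fs <- as.numeric(sub("fs\\s*=\\s*", "", fsm[[1]]))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(body, ",")
  labels <- vapply(rows, `[[`, character(1), 1L)
  vals <- lapply(rows, function(r) as.numeric(r[-1]))
  nlen <- lengths(vals)
  if (length(unique(nlen)) != 1L) abort(sprintf("CSV %s has ragged rows.", path))
  m <- do.call(rbind, vals)
  rownames(m) <- labels
  unknown <- labels[is.na(canonical_leads(labels))]
  if (length(unknown)) m <- m[!labels %in% unknown, , drop = FALSE]
  eeg_recording(m, fs)
}

write_eeg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  for (i in seq_len(nrow(rec$data))) {
    writeLines(paste(c(rownames(rec$data)[i],
                       formatC(rec$data[i, ], format = "g", digits = 9)),
                     collapse = ","), con)
  }
}

# --- minimal EDF (European Data Format) support ------------------------------
# 256-byte fixed header + 256 bytes per signal, then int16 little-endian data
# records.  One-second records; physical range per channel spans its data.

pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n, flag = " ")
}

write_eeg_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF export requires an integer sampling rate.")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  nrec <- floor(ncol(rec$data) / fs)
  if (nrec < 1) abort("Recording shorter than one EDF data record (1 s).")
  x <- rec$data[, seq_len(nrec * fs), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X", 80), pad("X", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44),
    pad(nrec, 8), pad("1", 8), pad(ns, 4),
    paste(vapply(rownames(x), pad, "", n = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.8g", pmin_), pad, "", n = 8), collapse = ""),
    paste(vapply(sprintf("%.8g", pmax_), pad, "", n = 8), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  pmin_r <- as.numeric(sprintf("%.8g", pmin_))  # use the header-encoded range
  pmax_r <- as.numeric(sprintf("%.8g", pmax_))
  gain <- (pmax_r - pmin_r) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    seg <- x[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round((seg - pmin_r) / gain + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  hbytes <- as.numeric(rd(8)); rd(44)
  nrec <- as.numeric(rd(8)); recdur <- as.numeric(rd(8))
  ns <- as.numeric(rd(4))
  if (!is.finite(ns) || ns < 1) abort(sprintf("Unparseable EDF header in %s.", path))
  field <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- field(16); field(80); field(8)
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.numeric(field(8)); field(32)
  if (seek(con) != hbytes) seek(con, hbytes)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- lapply(seq_len(ns), function(i) numeric(0))
  total <- sum(spr)
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = total, size = 2, endian = "little")
    if (length(raw) < total) abort(sprintf("Truncated EDF data in %s.", path))
    off <- 0
    for (i in seq_len(ns)) {
      out[[i]] <- c(out[[i]], (raw[(off + 1):(off + spr[i])] - dmin[i]) * gain[i] + pmin_[i])
      off <- off + spr[i]
    }
  }
  m <- do.call(rbind, out)
  rownames(m) <- labels
  keep <- !is.na(canonical_leads(labels))
  m <- m[keep, , drop = FALSE]
  fs <- spr[which(keep)[1]] / recdur
  eeg_recording(m, fs)
}

#' Read or write weekly psychometric scores
#'
#' The scores table is long-format CSV with columns `subject_id`,
#' `instrument` (`PCL5`, `HAMA`, `HAMD`), `week` (integer, 0 = baseline) and
#' `total`.
#'
#' @param path CSV file path.
#' @return `read_scores()`: a tibble with those columns.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "instrument", "week", "total")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("Scores CSV lacks column(s): %s.", paste(miss, collapse = ", ")))
  df$week <- as.integer(df$week)
  df
}

#' @rdname read_scores
#' @param scores Scores tibble.
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
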