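# WFDB-compatible on-disk interchange: format-16 signal files (.dat,
# 16-bit little-endian two's complement) with a plain-text .hea header,
# plus a text annotation table using the WFDB annotation vocabulary
# (beat codes N/A/V; rhythm-change aux labels "(N", "(AFIB", "(SVTA",
# "(BII", "(NOISE") and a cohort manifest CSV.

BEAT_CODE <- c(N = "N", PAC = "A", PVC = "V")
RHYTHM_AUX <- c(
  SINUS = "(N", AF = "(AFIB", SVT = "(SVTA", AVB = "(BII", ARTIFACT = "(NOISE"
)

#' Write a recording as a WFDB format-16 record plus text annotations
#'
#' Writes `<record_id>.dat` (16-bit little-endian ADC units),
#' `<record_id>.hea` (standard header line: record name, signal count,
#' sampling frequency, sample count; signal line with format, gain and
#' units), and `<record_id>.ann.txt`, a whitespace-delimited annotation
#' table with one row per beat (`sample`, `symbol`) and per rhythm change
#' (`sample`, `+`, aux label).
#'
#' @param record an `af_ecg_recording` (see [simulate_recording()]).
#' @param dir output directory (created if missing).
#' @param gain ADC units per millivolt (default 200).
#' @return invisible vector of the three file paths.
#' @export
write_wfdb <- function(record, dir, gain = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record$record_id
  n <- length(record$signal)
  adc <- as.integer(pmax(pmin(round(record$signal * gain), 32767), -32768))
  dat <- file.path(dir, paste0(id, ".dat"))
  con <- file(dat, "wb")
  writeBin(adc, con, size = 2, endian = "little")
  close(con)
  hea <- file.path(dir, paste0(id, ".hea"))
  writeLines(c(
    sprintf("%s 1 %g %d", id, record$fs, n),
    sprintf("%s.dat 16 %g/mV 16 0 0 0 0 ECG", id, gain),
    sprintf("# age %d sex %s", as.integer(record$age), record$sex)
  ), hea)
  ann <- file.path(dir, paste0(id, ".ann.txt"))
  beat_rows <- sprintf("%d %s .", record$beats$sample_index,
    BEAT_CODE[record$beats$beat_type])
  rhy_rows <- sprintf("%d + %s", record$episodes$start,
    RHYTHM_AUX[record$episodes$rhythm])
  df <- rbind(
    data.frame(s = record$beats$sample_index, line = beat_rows),
    data.frame(s = record$episodes$start, line = rhy_rows)
  )
  writeLines(c("# sample symbol aux", df$line[order(df$s)]), ann)
  invisible(c(dat = dat, hea = hea, ann = ann))
}

#' Read a WFDB format-16 record written by [write_wfdb()]
#'
#' @param dir directory containing the record files.
#' @param record_id record name.
#' @return a list with `record_id`, `signal` (millivolts), `fs`,
#'   `duration`, `age`, `sex`, `beats`, `episodes`.
#' @export
read_wfdb <- function(dir, record_id) {
  hea <- readLines(file.path(dir, paste0(record_id, ".hea")))
  top <- strsplit(hea[1], "\\s+")[[1]]
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sigline <- strsplit(hea[2], "\\s+")[[1]]
  gain <- as.numeric(sub("/mV$", "", sigline[3]))
  meta <- strsplit(hea[3], "\\s+")[[1]]
  con <- file(file.path(dir, paste0(record_id, ".dat")), "rb")
  adc <- readBin(con, "integer", n = n, size = 2, endian = "little", signed = TRUE)
  close(con)
  ann <- utils::read.table(file.path(dir, paste0(record_id, ".ann.txt")),
    col.names = c("sample", "symbol", "aux"), colClasses = c("integer", "character", "character"))
  is_beat <- ann$symbol != "+"
  beats <- data.frame(
    sample_index = ann$sample[is_beat],
    beat_type = names(BEAT_CODE)[match(ann$symbol[is_beat], BEAT_CODE)]
  )
  starts <- ann$sample[!is_beat]
  rhythms <- names(RHYTHM_AUX)[match(ann$aux[!is_beat], RHYTHM_AUX)]
  episodes <- data.frame(
    start = starts, end = c(starts[-1], n), rhythm = rhythms
  )
  list(
    record_id = record_id, signal = adc / gain, fs = fs, duration = n / fs,
    age = as.integer(meta[3]), sex = meta[5],
    beats = beats, episodes = episodes
  )
}

#' Write a cohort manifest CSV
#'
#' @param manifest cohort manifest data.frame.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
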