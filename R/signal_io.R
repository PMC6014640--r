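#' ECG record container
#'
#' A single-channel sampled voltage series with its sampling rate.  All
#' sample positions elsewhere in the package (annotations, detected peaks,
#' max-min points) are 0-based indices into `samples`.
#'
#' @param samples numeric vector of voltages (arbitrary units, typically mV).
#' @param fs sampling rate in Hz (> 0).
#' @param record_id free-text record label.
#' @param channel free-text channel label.
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `record_id`, `channel` and `n` (number of samples).
#' @export
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' rec$n
ecg_record <- function(samples, fs, record_id = "", channel = "") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stopf("'samples' must be a non-empty numeric vector")
  if (any(!is.finite(samples)))
    stopf("'samples' contains non-finite values (NaN/Inf)")
  assert_scalar_num(fs, "fs", positive = TRUE)
  structure(
    list(record_id = as.character(record_id), channel = as.character(channel),
         fs = as.numeric(fs), samples = as.numeric(samples),
         n = length(samples)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> '%s' channel '%s': %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$channel, x$n, x$fs, x$n / x$fs))
  invisible(x)
}

.annotation_kinds <- c("fetal_reference", "fetal_detected",
                       "maternal_reference", "maternal_detected")

#' Beat annotation set
#'
#' Strictly increasing 0-based sample positions of R-peaks.  Duplicates are
#' removed with a warning; input order is irrelevant.
#'
#' @param indices integer-valued vector of 0-based sample positions.
#' @param record_id label of the record the annotations belong to.
#' @param kind one of `"fetal_reference"`, `"fetal_detected"`,
#'   `"maternal_reference"`, `"maternal_detected"`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(indices, record_id = "",
                           kind = "fetal_reference") {
  kind <- match.arg(kind, .annotation_kinds)
  if (length(indices) == 0L) {
    indices <- integer(0)
  } else {
    if (!is.numeric(indices) || any(!is.finite(indices)))
      stopf("annotation indices must be finite numbers")
    if (any(indices != round(indices)))
      stopf("annotation indices must be integers")
    if (any(indices < 0)) stopf("negative annotation index")
    idx <- sort(unique(as.integer(round(indices))))
    if (length(idx) < length(indices))
      warnf("%d duplicate annotation indices removed",
            length(indices) - length(idx))
    indices <- idx
  }
  structure(list(record_id = as.character(record_id), kind = kind,
                 indices = indices),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> '%s' (%s): %d beats\n",
              x$record_id, x$kind, length(x$indices)))
  invisible(x)
}

#' Read a signal from a plain-text/CSV file
#'
#' One numeric value per line, or one column of a delimited file.  Non-numeric
#' rows are an error naming the offending line; nothing is silently coerced.
#'
#' @param path file to read.
#' @param fs sampling rate in Hz of the stored signal.
#' @param record_id record label to attach.
#' @param column 1-based column to read when the file is delimited.
#' @param sep field separator; `NULL` (default) auto-detects `,`, `;`, tab or
#'   whitespace.
#' @param channel channel label to attach.
#' @return An [ecg_record].
#' @export
read_signal_csv <- function(path, fs, record_id = basename(path),
                            column = 1L, sep = NULL, channel = "") {
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (!file.exists(path)) stopf("signal file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stopf("empty signal file: %s", path)
  lineno <- which(keep)
  lines <- lines[keep]
  if (is.null(sep)) {
    probe <- lines[1L]
    sep <- if (grepl(",", probe, fixed = TRUE)) "," else
           if (grepl(";", probe, fixed = TRUE)) ";" else "[ \t]+"
  }
  fields <- strsplit(trimws(lines), sep)
  tok <- vapply(fields, function(f) {
    f <- f[nzchar(f)]
    if (length(f) < column) NA_character_ else f[column]
  }, character(1))
  vals <- suppressWarnings(as.numeric(tok))
  bad <- which(is.na(vals))
  if (length(bad))
    stopf("non-numeric signal value at line %d: '%s'",
          lineno[bad[1L]], lines[bad[1L]])
  ecg_record(vals, fs = fs, record_id = record_id, channel = channel)
}

#' Read beat annotations
#'
#' Plain-text dialect: one integer 0-based sample index per line.  WFDB
#' dialect: a standard MIT-format annotation file; all beat-class annotation
#' codes are returned (times in a WFDB annotation file are already 0-based
#' sample numbers).
#'
#' @param path file to read.
#' @param record_id record label to attach.
#' @param kind annotation kind, see [annotation_set()].
#' @param dialect `"text"` or `"wfdb"`.
#' @return An [annotation_set] with sorted, de-duplicated indices.
#' @export
read_annotations <- function(path, record_id = basename(path),
                             kind = "fetal_reference",
                             dialect = c("text", "wfdb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (dialect == "wfdb") {
    idx <- read_wfdb_annotation_file(path)
    return(annotation_set(idx, record_id = record_id, kind = kind))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(annotation_set(integer(0), record_id = record_id, kind = kind))
  vals <- suppressWarnings(as.numeric(trimws(lines)))
  if (any(is.na(vals)))
    stopf("non-integer annotation at line %d: '%s'",
          which(is.na(vals))[1L], lines[which(is.na(vals))[1L]])
  if (any(vals != round(vals))) stopf("non-integer annotation index")
  if (any(vals < 0)) stopf("negative annotation index")
  annotation_set(vals, record_id = record_id, kind = kind)
}

#' Write beat detections to a plain-text file
#'
#' One 0-based sample index per line; the inverse of [read_annotations()]
#' (text dialect).  With `csv = TRUE` a CSV with columns
#' `index,time_s,label` is written instead.
#'
#' @param ann an [annotation_set].
#' @param path destination file.
#' @param csv write the richer CSV form.
#' @param fs sampling rate in Hz, required for the CSV time column.
#' @return `path`, invisibly.
#' @export
write_detections <- function(ann, path, csv = FALSE, fs = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  if (csv) {
    if (is.null(fs)) stopf("'fs' is required for CSV detection output")
    df <- data.frame(index = ann$indices,
                     time_s = ann$indices / fs,
                     label = rep(ann$kind, length(ann$indices)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(format(ann$indices, scientific = FALSE, trim = TRUE), path)
  }
  invisible(path)
}

## ---- WFDB (PhysioNet) support -------------------------------------------
## Minimal reader for format-16 records (.hea + .dat) and MIT annotation
## files, covering the record layout used by the abdominal fetal ECG
## databases (1 ksps, 16-bit).  A matching writer is provided so round-trip
## fixtures can be generated in code.

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stopf("WFDB header not found: %s", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  name <- sub("/.*$", "", rec[1L])
  nsig <- as.integer(rec[2L])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*$", "", rec[3L])) else 250
  nsamp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  sig <- lapply(lines[1L + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- sub("x.*$|:.*$|\\+.*$", "", f[2L])
    gain_tok <- if (length(f) >= 3L) f[3L] else "200"
    baseline <- if (grepl("\\(", gain_tok))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_tok)) else NA_real_
    gain <- as.numeric(sub("\\(.*$|/.*$", "", gain_tok))
    if (!is.finite(gain) || gain == 0) gain <- 200
    units <- if (grepl("/", gain_tok)) sub("^.*/", "", gain_tok) else "mV"
    adc_zero <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0
    if (!is.finite(adc_zero)) adc_zero <- 0
    if (!is.finite(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1L], format = fmt, gain = gain, baseline = baseline,
         units = units, desc = desc)
  })
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read one channel of a WFDB record
#'
#' Supports format-16 (little-endian 16-bit) single-file records as
#' distributed for the PhysioNet abdominal fetal ECG databases.  Digital
#' values are converted to physical units as `(adc - baseline) / gain`.
#'
#' @param path_stem record path without extension (the `.hea` / `.dat` pair).
#' @param channel channel selector: 1-based integer index or the channel
#'   description string from the header.
#' @return An [ecg_record] for the selected channel.
#' @export
read_wfdb_record <- function(path_stem, channel = 1L) {
  hdr <- parse_wfdb_header(paste0(path_stem, ".hea"))
  descs <- vapply(hdr$signals, `[[`, "", "desc")
  if (is.character(channel)) {
    ch <- match(channel, descs)
    if (is.na(ch))
      stopf("channel '%s' not found; available: %s",
            channel, paste(sprintf("'%s'", descs), collapse = ", "))
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > hdr$nsig)
      stopf("channel index %d out of range (record has %d signals)",
            ch, hdr$nsig)
  }
  fmts <- unique(vapply(hdr$signals, `[[`, "", "format"))
  if (!identical(fmts, "16"))
    stopf("unsupported WFDB signal format '%s' (only format 16 is supported)",
          paste(fmts, collapse = ","))
  dat_files <- vapply(hdr$signals, `[[`, "", "file")
  if (length(unique(dat_files)) != 1L)
    stopf("multi-file WFDB records are not supported")
  dat_path <- file.path(dirname(path_stem), dat_files[1L])
  if (!file.exists(dat_path)) stopf("WFDB signal file not found: %s", dat_path)
  raw_n <- file.size(dat_path) / 2L
  dig <- readBin(dat_path, what = "integer", n = raw_n, size = 2L,
                 signed = TRUE, endian = "little")
  nsamp <- length(dig) %/% hdr$nsig
  mat <- matrix(dig[seq_len(nsamp * hdr$nsig)], nrow = hdr$nsig)
  s <- hdr$signals[[ch]]
  phys <- (mat[ch, ] - s$baseline) / s$gain
  ecg_record(phys, fs = hdr$fs, record_id = hdr$name,
             channel = if (nzchar(s$desc)) s$desc else as.character(ch))
}

#' Write a multi-channel WFDB record (format 16)
#'
#' Companion writer used to build synthetic round-trip fixtures in code;
#' physical values are quantised as `round(x * gain) + baseline`.
#'
#' @param records a single [ecg_record] or list of them (equal length and fs).
#' @param path_stem output path without extension.
#' @param gain ADC gain (units per physical unit).
#' @return `path_stem`, invisibly.
#' @export
write_wfdb_record <- function(records, path_stem, gain = 1000) {
  if (inherits(records, "ecg_record")) records <- list(records)
  ns <- vapply(records, function(r) r$n, 1L)
  if (length(unique(ns)) != 1L) stopf("all channels must have equal length")
  fs <- records[[1L]]$fs
  name <- basename(path_stem)
  dig <- lapply(records, function(r) {
    d <- round(r$samples * gain)
    if (any(abs(d) > 32767))
      stopf("signal exceeds 16-bit range at gain %g", gain)
    as.integer(d)
  })
  mat <- do.call(rbind, dig)
  hea <- c(sprintf("%s %d %g %d", name, length(records), fs, ns[1L]),
           vapply(seq_along(records), function(i)
             sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                     name, gain, dig[[i]][1L],
                     if (nzchar(records[[i]]$channel)) records[[i]]$channel
                     else sprintf("ch%d", i)),
             character(1)))
  writeLines(hea, paste0(path_stem, ".hea"))
  writeBin(as.integer(as.vector(mat)), paste0(path_stem, ".dat"),
           size = 2L, endian = "little")
  invisible(path_stem)
}

# MIT annotation file reader: 2-byte words, low byte first; high 6 bits are
# the annotation code, low 10 bits the sample interval from the previous
# annotation.  Special codes: 59 SKIP (4-byte long interval follows, high
# word first), 60 NUM, 61 SUB, 62 CHN, 63 AUX (aux string follows, padded
# to even length), 0 with interval 0 terminates.  Beat codes (1..49) yield
# sample times.
read_wfdb_annotation_file <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  n2 <- length(raw) %/% 2L
  times <- numeric(0)
  t <- 0
  i <- 1L
  while (i + 1L <= 2L * n2) {
    lo <- as.integer(raw[i]); hi <- as.integer(raw[i + 1L])
    code <- bitwShiftR(hi, 2L)
    interval <- bitwOr(bitwShiftL(bitwAnd(hi, 3L), 8L), lo)
    i <- i + 2L
    if (code == 0L && interval == 0L) break
    if (code == 59L) {          # SKIP: long interval in next 4 bytes
      if (interval == 0L) {
        b <- as.integer(raw[i:(i + 3L)])
        i <- i + 4L
        t <- t + (b[1] + b[2] * 256) * 65536 + (b[3] + b[4] * 256)
      }
    } else if (code == 63L) {   # AUX: skip payload (padded to even)
      i <- i + interval + (interval %% 2L)
    } else if (code >= 60L) {   # NUM/SUB/CHN: no time advance
      next
    } else {
      t <- t + interval
      if (code >= 1L && code <= 49L) times <- c(times, t)
    }
  }
  times
}

# Companion MIT annotation writer (fixture generation only).
write_wfdb_annotation_file <- function(indices, path) {
  indices <- sort(unique(as.integer(indices)))
  out <- raw(0)
  prev <- 0L
  word <- function(code, interval)
    as.raw(c(bitwAnd(interval, 255L),
             bitwOr(bitwShiftL(code, 2L), bitwShiftR(interval, 8L))))
  for (t in indices) {
    d <- t - prev
    if (d > 1023L) {
      hiw <- d %/% 65536L; low <- d %% 65536L
      out <- c(out, word(59L, 0L),
               as.raw(c(hiw %% 256L, hiw %/% 256L, low %% 256L, low %/% 256L)),
               word(1L, 0L))
    } else {
      out <- c(out, word(1L, d))
    }
    prev <- t
  }
  out <- c(out, word(0L, 0L))
  writeBin(out, path)
  invisible(path)
}
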