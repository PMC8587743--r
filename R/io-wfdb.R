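# Minimal WFDB (PhysioBank dialect) support: text headers, format-16
# (16-bit little-endian interleaved) signal files, and MIT-format binary
# annotation files. Covers the subset the pipeline touches; written records
# round-trip bit-exactly.

wfdb_code_symbol <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")")
wfdb_symbol_code <- stats::setNames(as.integer(names(wfdb_code_symbol)),
                                    wfdb_code_symbol)
WFDB_RHYTHM <- 28L
WFDB_SKIP <- 59L
WFDB_AUX <- 63L

wfdb_base <- function(path) sub("\\.(hea|dat|atr)$", "", path)

#' Read a channel of a WFDB record
#'
#' Parses the text header (`<record>.hea`) and the format-16 signal file,
#' applies the per-channel gain/baseline calibration, and returns the
#' selected channel at the record's native sampling rate. WFDB does not
#' encode modality, so it is supplied by the caller.
#'
#' @param path Record path with or without the `.hea` extension.
#' @param channel 0-based channel index.
#' @param modality `"ECG"` or `"PPG"` for the returned signal.
#' @return An [af_signal()].
#' @export
read_wfdb_record <- function(path, channel = 0L, modality = "ECG") {
  base <- wfdb_base(path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop(sprintf("WFDB header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(top[3L]) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (channel < 0L || channel >= nsig) {
    stop(sprintf("channel %d out of range: record has %d channel(s)",
                 channel, nsig))
  }
  sig_lines <- lines[2L:(1L + nsig)]
  specs <- lapply(sig_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- f[2L]
    if (fmt != "16") stop(sprintf("unsupported WFDB signal format '%s'", fmt))
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain_field <- sub("/.*$", "", gain_field)           # strip units
    baseline <- 0
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub("^.*\\((-?[0-9]+)\\).*$", "\\1", gain_field))
      gain_field <- sub("\\(.*$", "", gain_field)
    }
    gain <- as.numeric(gain_field)
    if (!is.finite(gain) || gain == 0) gain <- 200
    list(file = f[1L], gain = gain, baseline = baseline)
  })
  dat <- file.path(dirname(hea), specs[[1L]]$file)
  if (!file.exists(dat)) stop(sprintf("WFDB signal file not found: %s", dat))
  raw_n <- file.info(dat)$size %/% 2L
  con <- file(dat, "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  mat <- matrix(adc, nrow = nsig)                        # interleaved
  if (!is.na(nsamp) && ncol(mat) > nsamp) mat <- mat[, seq_len(nsamp), drop = FALSE]
  sp <- specs[[channel + 1L]]
  af_signal((mat[channel + 1L, ] - sp$baseline) / sp$gain, fs, modality)
}

#' Write a WFDB record (format 16)
#'
#' @param path Record path (with or without `.hea`).
#' @param signals Numeric matrix, one column per channel (or a vector / an
#'   [af_signal()] for single-channel).
#' @param fs Sampling rate in Hz (taken from the signal when one is given).
#' @param gain ADC units per physical unit.
#' @param descriptions Per-channel description strings.
#' @return The record base path, invisibly.
#' @export
write_wfdb_record <- function(path, signals, fs = NULL, gain = 200,
                              descriptions = NULL) {
  if (inherits(signals, "af_signal")) {
    fs <- signals$fs
    signals <- matrix(signals$samples, ncol = 1L)
  }
  if (is.null(fs)) stop("fs required")
  signals <- as.matrix(signals)
  nsig <- ncol(signals)
  n <- nrow(signals)
  base <- wfdb_base(path)
  rec <- basename(base)
  if (is.null(descriptions)) descriptions <- sprintf("ch%d", seq_len(nsig) - 1L)
  adc <- round(signals * gain)
  if (any(abs(adc) > 32767)) stop("signal exceeds 16-bit ADC range at this gain")
  hea <- c(sprintf("%s %d %g %d", rec, nsig, fs, n),
           sprintf("%s.dat 16 %g 16 0 0 0 0 %s", rec, gain, descriptions))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(base)
}

read_u16 <- function(raw2) {
  as.integer(raw2[1L]) + 256L * as.integer(raw2[2L])
}

#' Read a WFDB annotation file
#'
#' Parses the MIT annotation format: beat annotations become a
#' [beat_annotations()] (symbols per the PhysioBank code table; unknown
#' codes are carried through as their numeric code), and rhythm-change
#' markers (`+` with an aux string) become half-open [rhythm_intervals()].
#' Aux strings in `af_aux_strings` map to AF, `"(N"` to NSR, anything else
#' to OTHER.
#'
#' @param path Annotation file path (e.g. `record.atr`).
#' @param fs Sampling rate used to convert annotation sample counts to ms.
#' @param record_end_ms End of the record (closes the last rhythm
#'   interval); defaults to the last annotation time.
#' @param af_aux_strings Aux strings counted as AF.
#' @return List with `beats` and `rhythms`.
#' @export
read_wfdb_annotations <- function(path, fs = 250,
                                  record_end_ms = NULL,
                                  af_aux_strings = "(AFIB") {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) %% 2L == 1L) stop("malformed annotation file (odd length)")
  i <- 1L
  t_samp <- 0
  times <- numeric(0)
  codes <- integer(0)
  auxes <- character(0)
  while (i + 1L <= length(bytes)) {
    w <- read_u16(bytes[i:(i + 1L)])
    i <- i + 2L
    code <- w %/% 1024L
    inc <- w %% 1024L
    if (w == 0L) break
    if (code == WFDB_SKIP) {
      if (i + 3L > length(bytes)) stop("truncated SKIP in annotation stream")
      hi <- read_u16(bytes[i:(i + 1L)])
      lo <- read_u16(bytes[(i + 2L):(i + 3L)])
      i <- i + 4L
      t_samp <- t_samp + hi * 65536 + lo
    } else if (code == WFDB_AUX) {
      if (inc < 1L || i + inc - 1L > length(bytes)) {
        stop("malformed aux field in annotation stream")
      }
      s_raw <- bytes[i:(i + inc - 1L)]
      i <- i + inc + (inc %% 2L)                   # pad byte on odd length
      if (length(auxes)) {
        auxes[length(auxes)] <- rawToChar(s_raw[s_raw != as.raw(0L)])
      }
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: ignored
    } else {
      t_samp <- t_samp + inc
      times <- c(times, t_samp)
      codes <- c(codes, code)
      auxes <- c(auxes, NA_character_)
    }
  }
  times_ms <- 1000 * times / fs

  is_rhythm <- codes == WFDB_RHYTHM
  beat_keep <- !is_rhythm
  sym <- wfdb_code_symbol[as.character(codes[beat_keep])]
  sym[is.na(sym)] <- as.character(codes[beat_keep])[is.na(sym)]
  beats <- beat_annotations(times_ms[beat_keep], unname(sym))

  rt <- times_ms[is_rhythm]
  ra <- auxes[is_rhythm]
  if (length(rt)) {
    if (is.null(record_end_ms)) record_end_ms <- max(times_ms)
    ends <- c(rt[-1L], record_end_ms)
    keep <- ends > rt
    cls <- ifelse(ra %in% af_aux_strings, "AF",
                  ifelse(ra == "(N", "NSR", "OTHER"))
    rhythms <- rhythm_intervals(rt[keep], ends[keep], cls[keep])
  } else {
    rhythms <- rhythm_intervals()
  }
  list(beats = beats, rhythms = rhythms)
}

#' Write a WFDB annotation file
#'
#' @param path Output path.
#' @param beats A [beat_annotations()].
#' @param rhythms Optional [rhythm_intervals()]; written as `+` markers with
#'   `(N` / `(AFIB` / `(X` aux strings at interval starts.
#' @param fs Sampling rate for ms-to-sample conversion.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(path, beats,
                                   rhythms = rhythm_intervals(), fs = 250) {
  stopifnot(inherits(beats, "beat_annotations"))
  events <- data.frame(
    t = as.integer(round(beats$times_ms * fs / 1000)),
    code = unname(wfdb_symbol_code[beats$labels]),
    aux = NA_character_, stringsAsFactors = FALSE)
  if (any(is.na(events$code))) stop("unknown beat symbol(s)")
  if (nrow(rhythms)) {
    aux_of <- c(NSR = "(N", AF = "(AFIB", OTHER = "(X")
    events <- rbind(events, data.frame(
      t = as.integer(round(rhythms$start_ms * fs / 1000)),
      code = WFDB_RHYTHM, aux = unname(aux_of[rhythms$rhythm]),
      stringsAsFactors = FALSE))
  }
  events <- events[order(events$t, events$code), , drop = FALSE]
  out <- raw(0)
  w16 <- function(v) as.raw(c(v %% 256L, v %/% 256L))
  prev <- 0L
  for (r in seq_len(nrow(events))) {
    inc <- events$t[r] - prev
    prev <- events$t[r]
    if (inc >= 1024L) {
      out <- c(out, w16(WFDB_SKIP * 1024L),
               w16(inc %/% 65536L), w16(inc %% 65536L))
      inc <- 0L
    }
    out <- c(out, w16(events$code[r] * 1024L + inc))
    if (!is.na(events$aux[r])) {
      s <- charToRaw(events$aux[r])
      if (length(s) %% 2L == 1L) s <- c(s, as.raw(0L))
      out <- c(out, w16(WFDB_AUX * 1024L + length(s)), s)
    }
  }
  out <- c(out, w16(0L))
  writeBin(out, path)
  invisible(path)
}
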