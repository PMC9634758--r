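#' Three-lead VCG record
#'
#' Container for a vectorcardiogram: three orthogonal leads (X, Y, Z) of
#' equal length, amplitudes in GAIN.mV units (millivolts multiplied by
#' GAIN = 2000, the working amplitude scale of the delineator), and a
#' sampling frequency. The delineation pipeline expects `fs = 1000` Hz;
#' [read_vcg()] resamples on ingestion when needed.
#'
#' @param leads numeric matrix (or data.frame) with N rows and 3 columns,
#'   leads in X, Y, Z order.
#' @param fs sampling frequency in Hz.
#' @param record_id text label.
#' @return object of class `vcg_record`.
#' @export
vcg_record <- function(leads, fs = 1000, record_id = "record") {
  leads <- as.matrix(leads)
  storage.mode(leads) <- "double"
  if (ncol(leads) != 3) stop("a VCG record needs exactly 3 leads (X, Y, Z)")
  if (nrow(leads) < 1) stop("empty record")
  if (any(!is.finite(leads))) stop("non-finite samples in record")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  colnames(leads) <- c("X", "Y", "Z")
  structure(list(leads = leads, fs = fs, record_id = as.character(record_id)),
            class = "vcg_record")
}

#' @export
print.vcg_record <- function(x, ...) {
  cat(sprintf("<vcg_record> '%s': %d samples x 3 leads @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$leads), x$fs, nrow(x$leads) / x$fs))
  invisible(x)
}

#' Number of samples per lead
#' @param record a [vcg_record()].
#' @export
n_samples <- function(record) nrow(record$leads)

#' Read a multichannel record into a VCG record
#'
#' Reads either a plain CSV (header row, one column per lead, comma
#' separated) or a WFDB-style header/signal pair (`.hea` plus a format-16
#' `.dat`, the layout of the PTB database). With more than three channels an
#' explicit `channels` mapping (three column names, X, Y, Z order) is
#' required; PTB's `vx`,`vy`,`vz` Frank leads are picked up automatically
#' when present. Records not sampled at 1000 Hz are polyphase-resampled to
#' 1000 Hz so that all sample-denominated delineation constants apply
#' unchanged. Amplitudes are returned in GAIN.mV (mV times 2000).
#'
#' @param path file path; `.hea` (or a basename with a `.hea` alongside) for
#'   WFDB-style input, anything else is read as CSV.
#' @param format `"auto"`, `"csv"` or `"wfdb"`.
#' @param fs sampling rate of a CSV file (ignored for WFDB input, where the
#'   header states it).
#' @param channels optional character vector of three channel names.
#' @param units units of CSV amplitude columns: already-scaled `"gain_mv"`
#'   (default) or `"mv"` (multiplied by 2000 on read).
#' @param resample_to target rate after ingestion (Hz).
#' @return a [vcg_record()].
#' @export
read_vcg <- function(path, format = c("auto", "csv", "wfdb"), fs = 1000,
                     channels = NULL, units = c("gain_mv", "mv"),
                     resample_to = 1000) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea")))
      "wfdb" else "csv"
  }
  rec <- if (format == "csv") {
    read_vcg_csv(path, fs = fs, channels = channels, units = units)
  } else {
    read_vcg_wfdb(path, channels = channels)
  }
  if (rec$fs != resample_to) rec <- resample_record(rec, resample_to)
  rec
}

read_vcg_csv <- function(path, fs, channels, units) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  d <- pick_channels(d, channels)
  scale <- if (units == "mv") 2000 else 1
  vcg_record(as.matrix(d) * scale, fs = fs,
             record_id = sub("\\.[^.]*$", "", basename(path)))
}

pick_channels <- function(d, channels) {
  nm <- tolower(colnames(d))
  if (!is.null(channels)) {
    idx <- match(tolower(channels), nm)
    if (anyNA(idx)) stop("missing lead: channel(s) ",
                         paste(channels[is.na(idx)], collapse = ", "),
                         " not found")
    return(d[, idx, drop = FALSE])
  }
  if (ncol(d) == 3) return(d)
  if (ncol(d) < 3) stop("missing lead: record has ", ncol(d), " channels")
  frank <- match(c("vx", "vy", "vz"), nm)
  if (!anyNA(frank)) return(d[, frank, drop = FALSE])
  stop("record has ", ncol(d), " channels; supply a 3-name `channels` mapping")
}

# minimal WFDB-style reader: single-segment header, one .dat in format 16
# (little-endian int16, channels interleaved), optional "gain(baseline)/mV"
read_vcg_wfdb <- function(path, channels = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("unreadable header: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 3) stop("unreadable header: malformed record line")
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  nsamp <- if (length(head_tok) >= 4) as.integer(head_tok[4]) else NA_integer_
  if (is.na(nsig) || is.na(fs)) stop("unreadable header: malformed record line")
  sig <- lapply(lines[1 + seq_len(nsig)], parse_wfdb_signal_line)
  dat_files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(dat_files) != 1) {
    stop("unreadable header: multi-file signal layouts are not supported")
  }
  dat <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  raw <- readBin(dat, "integer", n = file.size(dat) / 2L, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) %% nsig != 0) stop("inconsistent channel lengths in ", dat)
  m <- matrix(raw, ncol = nsig, byrow = TRUE)
  if (!is.na(nsamp) && nrow(m) != nsamp) {
    stop("inconsistent channel lengths: header states ", nsamp,
         " samples, file holds ", nrow(m))
  }
  nm <- vapply(sig, `[[`, "", "name")
  colnames(m) <- nm
  d <- pick_channels(as.data.frame(m), channels)
  keep <- match(colnames(d), nm)
  out <- matrix(0, nrow(d), 3)
  for (j in 1:3) {
    s <- sig[[keep[j]]]
    out[, j] <- (d[[j]] - s$baseline) / s$gain * 2000  # -> GAIN.mV
  }
  vcg_record(out, fs = fs,
             record_id = sub("\\.hea$", "", basename(hea)))
}

parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) < 3) stop("unreadable header: malformed signal line")
  if (tok[2] != "16") stop("only format 16 signal files are supported")
  gspec <- tok[3]
  gain <- as.numeric(sub("^([-0-9.eE]+).*$", "\\1", gspec))
  baseline <- if (grepl("\\(", gspec)) {
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec))
  } else if (length(tok) >= 5) as.numeric(tok[5]) else 0
  if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
  if (is.na(baseline)) baseline <- 0
  list(file = tok[1], gain = gain, baseline = baseline,
       name = tolower(tok[length(tok)]))
}

resample_record <- function(record, fs_to) {
  frac <- ratio_approx(fs_to, record$fs)
  leads <- apply(record$leads, 2, function(x) {
    as.numeric(signal::resample(x, p = frac[1], q = frac[2]))
  })
  vcg_record(leads, fs = fs_to, record_id = record$record_id)
}

ratio_approx <- function(p, q) {
  # reduce p/q to smallest integer ratio (rates are rational in practice)
  scale <- 1
  while (any(abs(c(p, q) * scale - round(c(p, q) * scale)) > 1e-9)) {
    scale <- scale * 10
    if (scale > 1e6) stop("cannot express resampling ratio ", p, "/", q)
  }
  p <- round(p * scale); q <- round(q * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write (and read back) a fiducial table with its loop summary
#'
#' One row per (lead, beat) with the QRS peak, onset, end and PQ window
#' bounds as 1-based sample indices, 0-based indices and milliseconds
#' (index times 1000/fs), plus the per-loop isoelectric level and the
#' record-global loop boundaries. `format = "json"` writes the same content
#' as a single JSON object.
#'
#' @param table a `fiducial_table` (see [run_vcg_pipeline()]).
#' @param summary a `loop_summary`, or NULL to omit the summary block.
#' @param path output file.
#' @param fs sampling rate used for the millisecond columns.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(table, summary = NULL, path,
                            fs = 1000, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- fiducials_to_df(table, summary, fs)
  if (nrow(df) == 0) warning("empty fiducial table: writing header only")
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(fs = fs, fiducials = df,
           boundL = if (is.null(summary)) NULL else summary$boundL,
           boundR = if (is.null(summary)) NULL else summary$boundR),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

fiducials_to_df <- function(table, summary, fs) {
  p <- ncol(table$R)
  if (is.null(p) || p == 0) {
    return(data.frame(lead = integer(), beat = integer(), r = integer(),
                      q = integer(), s = integer(), pq_begin = integer(),
                      pq_end = integer(), r0 = integer(), q0 = integer(),
                      s0 = integer(), r_ms = numeric(), q_ms = numeric(),
                      s_ms = numeric(), pq_begin_ms = numeric(),
                      pq_end_ms = numeric(), iso = numeric(),
                      boundL = integer(), boundR = integer()))
  }
  lead <- rep(1:3, times = p)
  beat <- rep(seq_len(p), each = 3)
  ix <- cbind(lead, beat)
  ms <- 1000 / fs
  data.frame(
    lead = lead, beat = beat,
    r = table$R[ix], q = table$Q[ix], s = table$S[ix],
    pq_begin = table$PQ_begin[ix], pq_end = table$PQ_end[ix],
    r0 = table$R[ix] - 1L, q0 = table$Q[ix] - 1L, s0 = table$S[ix] - 1L,
    r_ms = table$R[ix] * ms, q_ms = table$Q[ix] * ms, s_ms = table$S[ix] * ms,
    pq_begin_ms = table$PQ_begin[ix] * ms, pq_end_ms = table$PQ_end[ix] * ms,
    iso = if (is.null(summary)) NA_real_ else summary$ISO[ix],
    boundL = if (is.null(summary)) NA_integer_ else summary$boundL,
    boundR = if (is.null(summary)) NA_integer_ else summary$boundR
  )
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$fiducials)
  }
  p <- if (nrow(df)) max(df$beat) else 0L
  mk <- function(col) {
    m <- matrix(NA_integer_, 3, p)
    if (p) m[cbind(df$lead, df$beat)] <- as.integer(df[[col]])
    m
  }
  table <- structure(
    list(R = mk("r"), Q = mk("q"), S = mk("s"),
         PQ_begin = mk("pq_begin"), PQ_end = mk("pq_end")),
    class = "fiducial_table")
  iso <- matrix(NA_real_, 3, p)
  if (p) iso[cbind(df$lead, df$beat)] <- df$iso
  summary <- structure(
    list(boundL = if (p) df$boundL[1] else NA_integer_,
         boundR = if (p) df$boundR[1] else NA_integer_,
         ISO = iso),
    class = "loop_summary")
  list(table = table, summary = summary)
}
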