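# Minimal WFDB reader/writer: header (.hea), format-16 signal (.dat) and the
# MIT annotation byte format (.atr), covering what multi-lead beat-annotated
# records need. Values outside this subset (multi-segment records, other
# signal formats, AUX strings) are not supported.

# Annotation codes (symbol <-> 6-bit code) following the WFDB code table.
wfdb_code_table <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "~" = 14L, "|" = 16L, "\"" = 22L, "B" = 25L, "+" = 28L, "!" = 31L,
  "e" = 34L, "n" = 35L, "f" = 38L, "r" = 41L
)

#' Annotation symbols counted as beats
#'
#' The WFDB beat-class symbols (all QRS-producing annotations regardless of
#' beat type); non-beat symbols such as rhythm changes (`+`), noise (`~`)
#' and artifacts (`|`) are excluded when reading R-peaks.
#'
#' @return Character vector of beat symbols.
#' @export
wfdb_beat_symbols <- function() {
  c("N", "L", "R", "B", "a", "V", "F", "J", "A", "S", "E",
    "j", "n", "e", "/", "f", "Q", "r", "!")
}

#' Write a record in WFDB format
#'
#' Writes `<name>.hea`, `<name>.dat` (format 16: interleaved 16-bit
#' little-endian integers) and, when the record carries R-peaks,
#' `<name>.atr` with one beat annotation (symbol `"N"`) per peak.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param name Record name (file stem).
#' @param gain ADC gain in units per mV (default 200).
#' @return Invisibly, the record path (`file.path(dir, name)`).
#' @export
write_wfdb_record <- function(record, dir, name, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nsig <- nrow(record$signals)
  nsamp <- ncol(record$signals)
  adc <- round(record$signals * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hea <- c(
    sprintf("%s %d %g %d", name, nsig, record$fs, nsamp),
    sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 %s",
            name, gain, as.integer(adc[, 1]), record$lead_names))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  if (length(record$r_peaks))
    write_wfdb_annotation(file.path(dir, name), record$r_peaks,
                          rep("N", length(record$r_peaks)))
  invisible(file.path(dir, name))
}

#' Write a WFDB annotation file
#'
#' @param base Record path without extension.
#' @param samples 0-based annotation sample indices, sorted.
#' @param symbols Annotation symbols, one per sample.
#' @param extension File extension (default `"atr"`).
#' @return Invisibly, the annotation path.
#' @export
write_wfdb_annotation <- function(base, samples, symbols, extension = "atr") {
  stopifnot(length(samples) == length(symbols))
  if (is.unsorted(samples)) stop("annotation samples must be sorted")
  codes <- wfdb_code_table[symbols]
  if (anyNA(codes))
    stop("unsupported annotation symbol(s): ",
         paste(unique(symbols[is.na(codes)]), collapse = " "))
  bytes <- raw(0)
  word <- function(code, time) {
    w <- bitwOr(bitwShiftL(code, 10L), bitwAnd(time, 1023L))
    as.raw(c(bitwAnd(w, 255L), bitwShiftR(w, 8L)))
  }
  prev <- 0L
  for (i in seq_along(samples)) {
    dt <- as.integer(samples[i]) - prev
    if (dt > 1023L || dt < 0L) {
      # SKIP (code 59): 4-byte interval, high 16 bits first
      hi <- dt %/% 65536L
      lo <- dt %% 65536L
      bytes <- c(bytes, word(59L, 0L),
                 as.raw(c(hi %% 256L, hi %/% 256L)),
                 as.raw(c(lo %% 256L, lo %/% 256L)))
      dt <- 0L
    }
    bytes <- c(bytes, word(codes[i], dt))
    prev <- as.integer(samples[i])
  }
  bytes <- c(bytes, as.raw(c(0, 0)))  # EOF
  path <- paste0(base, ".", extension)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(bytes, con)
  invisible(path)
}

#' Read a WFDB annotation file
#'
#' @inheritParams write_wfdb_annotation
#' @return A [tibble::tibble] with columns `sample` (0-based) and `symbol`.
#' @export
read_wfdb_annotation <- function(base, extension = "atr") {
  path <- paste0(base, ".", extension)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  i <- 1L
  t <- 0L
  samples <- integer(0)
  symbols <- character(0)
  code_syms <- names(wfdb_code_table)
  while (i + 1L <= length(bytes)) {
    w <- as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
    i <- i + 2L
    code <- w %/% 1024L
    time <- w %% 1024L
    if (code == 0L && time == 0L) break          # EOF
    if (code == 59L) {                           # SKIP: 4-byte long interval
      hi <- as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
      lo <- as.integer(bytes[i + 2L]) + 256L * as.integer(bytes[i + 3L])
      i <- i + 4L
      t <- t + hi * 65536L + lo
    } else if (code %in% c(60L, 61L, 62L)) {     # NUM/SUB/CHN: ignore
    } else if (code == 63L) {                    # AUX: skip payload (+ pad)
      i <- i + time + (time %% 2L)
    } else {
      t <- t + time
      sym <- code_syms[match(code, wfdb_code_table)]
      if (!is.na(sym)) {
        samples <- c(samples, t)
        symbols <- c(symbols, sym)
      }
    }
  }
  tibble::tibble(sample = samples, symbol = symbols)
}

#' Read a WFDB record with beat annotations
#'
#' Reads the header, the format-16 signal file and the `.atr` annotation
#' file; only beat-class annotation symbols (see [wfdb_beat_symbols()]) are
#' retained as `r_peaks`.
#'
#' @param path Record path without extension (or the `.hea` path).
#' @param lead_subset Optional character vector of lead names to select and
#'   reorder; an absent lead is an error naming the lead.
#' @param require_annotation Error when no `.atr` file exists? When `FALSE`
#'   the record is returned with empty `r_peaks`.
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(path, lead_subset = NULL, require_annotation = TRUE) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) stop("header file not found: ", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sig_lines <- lines[1 + seq_len(nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain <- as.numeric(sub("[(/].*$", "", f[3]))
    if (!grepl("^16", f[2])) stop("only signal format 16 is supported")
    list(file = f[1], gain = gain, name = if (length(f) >= 9) f[9] else NA_character_)
  }
  info <- lapply(sig_lines, parse_sig)
  dat_path <- file.path(dirname(hea_path), info[[1]]$file)
  con <- file(dat_path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "integer", n = nsig * nsamp, size = 2,
                  endian = "little", signed = TRUE)
  m <- matrix(as.numeric(vals), nrow = nsig)     # interleaved by sample
  gains <- vapply(info, `[[`, numeric(1), "gain")
  m <- m / gains
  lead_names <- vapply(info, `[[`, character(1), "name")
  if (anyNA(lead_names)) lead_names <- paste0("L", seq_len(nsig))
  r_peaks <- integer(0)
  if (file.exists(paste0(base, ".atr"))) {
    ann <- read_wfdb_annotation(base)
    keep <- ann$symbol %in% wfdb_beat_symbols()
    r_peaks <- sort(unique(ann$sample[keep]))
  } else if (require_annotation) {
    stop("annotation file not found: ", paste0(base, ".atr"))
  }
  rec <- ecg_record(m, fs, lead_names, r_peaks)
  if (!is.null(lead_subset)) {
    missing <- setdiff(lead_subset, rec$lead_names)
    if (length(missing))
      stop("requested lead(s) absent from record: ",
           paste(missing, collapse = ", "))
    idx <- match(lead_subset, rec$lead_names)
    rec <- ecg_record(rec$signals[idx, , drop = FALSE], rec$fs,
                      lead_subset, rec$r_peaks)
  }
  rec
}
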