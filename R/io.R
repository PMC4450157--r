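# Recording IO: native float32+JSON format and minimal EDF/BDF support.
# No EDF reader exists in the installed R stack, so the (simple, fully
# documented) 16-bit EDF / 24-bit BDF record layout is read and written
# directly. Triggers travel in a BioSemi-style "Status" signal.

# trigger codes are status-channel bits (BioSemi-style), so coincident
# events — e.g. a trial-start marker on the same sample as the first cycle
# minimum — sum without clobbering each other
status_code_map <- c(base = 1L, oddball = 2L, trial_start = 4L)

code_to_int <- function(code) {
  idx <- match(code, names(status_code_map))
  out <- unname(status_code_map[idx])
  extra <- which(is.na(idx))
  if (length(extra)) {
    # unknown codes get stable higher bits
    levels <- unique(code[extra])
    out[extra] <- bitwShiftL(8L, match(code[extra], levels) - 1L)
  }
  as.integer(out)
}

# decode a status value into trigger codes, trial-start first to match the
# order triggers_for() emits coincident events in
decode_status <- function(v) {
  codes <- character()
  if (bitwAnd(v, 4L)) codes <- c(codes, "trial_start")
  if (bitwAnd(v, 1L)) codes <- c(codes, "base")
  if (bitwAnd(v, 2L)) codes <- c(codes, "oddball")
  rest <- bitwAnd(v, bitwNot(7L))
  if (rest != 0L) codes <- c(codes, paste0("code_", rest))
  codes
}

#' Read an EEG recording from disk
#'
#' Supports the package's native format (32-bit float binary matrix plus a
#' JSON sidecar holding labels, sampling rate, triggers, montage and
#' processing provenance) and 16-bit EDF / 24-bit BDF files. For EDF/BDF a
#' signal labelled `Status` is interpreted as the trigger channel (value
#' onsets become triggers); electrode positions are not representable in
#' EDF, so the montage is flagged absent in the metadata.
#'
#' @param path File path.
#' @param format `"native"`, `"edf"` or `"bdf"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("native", "edf", "bdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_invalid(paste0("file not found: ", path))
  }
  switch(format,
    native = read_native(path),
    edf = read_edf_like(path, bits = 16L),
    bdf = read_edf_like(path, bits = 24L)
  )
}

#' Write an EEG recording to disk
#'
#' @param rec An [eeg_recording()].
#' @param path Output path. The native format writes `path` (float32
#'   binary, channels varying fastest) and a `path.json` sidecar.
#' @param format `"native"`, `"edf"` or `"bdf"`. EDF/BDF require the
#'   recording to span a whole number of 1-s data records and quantise the
#'   signal to the channel-wise physical range (16 or 24 bits).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("native", "edf", "bdf")) {
  stopifnot(inherits(rec, "fpvs_recording"))
  format <- match.arg(format)
  switch(format,
    native = write_native(rec, path),
    edf = write_edf_like(rec, path, bits = 16L),
    bdf = write_edf_like(rec, path, bits = 24L)
  )
  invisible(path)
}

# ---- native format -------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

write_native <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  meta <- list(
    format = "fpvs-native-v1",
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    sampling_rate = rec$sampling_rate,
    channel_labels = rec$channel_labels,
    triggers = as.data.frame(rec$triggers),
    montage = if (!is.null(rec$montage)) as.data.frame(rec$montage),
    metadata = rec$metadata
  )
  jsonlite::write_json(meta, sidecar_path(path), digits = NA,
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(path)
}

parse_error <- function(field, path, detail = "") {
  abort_invalid(
    paste0("cannot parse ", path, ": invalid or inconsistent `", field, "` ",
           detail),
    class = "fpvs_parse_error"
  )
}

read_native <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) parse_error("sidecar", path, "(missing .json sidecar)")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("n_channels", "n_samples", "sampling_rate", "channel_labels")) {
    if (is.null(meta[[f]])) parse_error(f, path, "(absent)")
  }
  nch <- as.integer(meta$n_channels)
  ns <- as.integer(meta$n_samples)
  expected <- as.double(nch) * ns
  actual <- file.info(path)$size / 4
  if (actual != expected) {
    parse_error("n_samples", path,
                sprintf("(file holds %g float32 values, sidecar promises %g)",
                        actual, expected))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = expected, size = 4L, endian = "little")
  data <- matrix(vals, nrow = nch)
  triggers <- if (length(meta$triggers)) {
    tibble::as_tibble(meta$triggers)
  } else {
    tibble::tibble(sample = integer(), code = character())
  }
  montage <- if (length(meta$montage)) tibble::as_tibble(meta$montage)
  eeg_recording(
    data, meta$sampling_rate,
    channel_labels = meta$channel_labels,
    montage = montage,
    triggers = triggers,
    metadata = if (length(meta$metadata)) meta$metadata else list()
  )
}

# ---- EDF/BDF -------------------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width)
}

write_edf_like <- function(rec, path, bits) {
  fs <- rec$sampling_rate
  if (!is_integerish(fs)) {
    abort_invalid("EDF/BDF export needs an integer sampling rate")
  }
  fs <- round(fs)
  n_rec <- ncol(rec$data) / fs
  if (!is_integerish(n_rec)) {
    abort_invalid("EDF/BDF export needs a whole number of 1-s data records")
  }
  n_rec <- round(n_rec)
  dig_max <- if (bits == 16L) 32767L else 8388607L
  nch <- nrow(rec$data)
  ns_total <- nch + 1L # plus Status

  # quantise against the value as printed in the header (so reader and
  # writer share exactly the same affine map), rounded *up* at the sixth
  # significant digit so no sample exceeds the declared physical range
  true_max <- apply(rec$data, 1, function(v) max(abs(v), 1e-6))
  phys_max <- signif(true_max, 6)
  bump <- phys_max < true_max
  phys_max[bump] <- phys_max[bump] +
    10^(floor(log10(true_max[bump])) - 5)
  digital <- round(sweep(rec$data, 1, phys_max, "/") * dig_max)
  digital <- pmin(pmax(digital, -dig_max), dig_max)
  status <- integer(ncol(rec$data))
  if (nrow(rec$triggers) > 0) {
    ints <- code_to_int(rec$triggers$code)
    for (i in seq_along(ints)) {
      s <- rec$triggers$sample[i] + 1L
      status[s] <- bitwOr(status[s], ints[i])
    }
  }

  con <- file(path, "wb")
  on.exit(close(con))
  if (bits == 16L) {
    writeBin(charToRaw(pad_field("0", 8L)), con)
  } else {
    writeBin(as.raw(255L), con)
    writeBin(charToRaw(pad_field("BIOSEMI", 7L)), con)
  }
  header_bytes <- 256L + 256L * ns_total
  head <- paste0(
    pad_field("fpvs synthetic subject", 80L),
    pad_field("fpvs recording", 80L),
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    pad_field(header_bytes, 8L),
    pad_field(if (bits == 24L) "24BIT" else "", 44L),
    pad_field(n_rec, 8L), pad_field(1, 8L), pad_field(ns_total, 4L)
  )
  writeBin(charToRaw(head), con)
  labels <- c(rec$channel_labels, "Status")
  field <- function(values, width) {
    writeBin(charToRaw(paste0(vapply(values, pad_field, "", width = width),
                              collapse = "")), con)
  }
  field(labels, 16L)
  field(rep("", ns_total), 80L) # transducer
  field(c(rep("uV", nch), ""), 8L)
  field(c(sprintf("%.6g", -phys_max), -dig_max), 8L)
  field(c(sprintf("%.6g", phys_max), dig_max), 8L)
  field(rep(-dig_max, ns_total), 8L)
  field(rep(dig_max, ns_total), 8L)
  field(rep("", ns_total), 80L) # prefiltering
  field(rep(fs, ns_total), 8L)
  field(rep("", ns_total), 32L)

  write_ints <- function(v) {
    if (bits == 16L) {
      writeBin(as.integer(v), con, size = 2L, endian = "little")
    } else {
      u <- as.integer(v)
      u <- ifelse(u < 0L, u + 16777216L, u)
      b <- rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L)
      writeBin(as.raw(b), con)
    }
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) write_ints(digital[ch, cols])
    write_ints(status[cols])
  }
  invisible(path)
}

read_edf_like <- function(path, bits) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), 8L) # version / magic
  readBin(con, raw(), 160L) # patient + recording ids
  readBin(con, raw(), 16L) # date + time
  as_num <- function(x, field) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) parse_error(field, path)
    v
  }
  header_bytes <- as_num(trimws(rawToChar(readBin(con, raw(), 8L))), "header bytes")
  readBin(con, raw(), 44L) # reserved
  n_rec <- as_num(trimws(rawToChar(readBin(con, raw(), 8L))), "n data records")
  rec_dur <- as_num(trimws(rawToChar(readBin(con, raw(), 8L))), "record duration")
  ns <- as_num(trimws(rawToChar(readBin(con, raw(), 4L))), "n signals")
  if (ns < 1) parse_error("n signals", path)
  labels <- vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, raw(), 16L))), "")
  readBin(con, raw(), 80L * ns) # transducer
  readBin(con, raw(), 8L * ns) # physical dimension
  phys_min <- as_num(vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, raw(), 8L))), ""), "physical minimum")
  phys_max <- as_num(vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, raw(), 8L))), ""), "physical maximum")
  dig_min <- as_num(vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, raw(), 8L))), ""), "digital minimum")
  dig_max <- as_num(vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, raw(), 8L))), ""), "digital maximum")
  readBin(con, raw(), 80L * ns) # prefiltering
  spr <- as_num(vapply(seq_len(ns), function(i)
    trimws(rawToChar(readBin(con, raw(), 8L))), ""), "samples per record")
  readBin(con, raw(), 32L * ns) # reserved
  if (length(unique(spr)) != 1L) {
    parse_error("samples per record", path, "(mixed rates unsupported)")
  }
  fs <- spr[1] / rec_dur
  bytes_per <- bits / 8L
  expected <- n_rec * sum(spr) * bytes_per
  payload <- readBin(con, raw(), expected + 1L)
  if (length(payload) != expected) {
    parse_error("n data records", path,
                sprintf("(expected %d payload bytes, found %d: truncated file)",
                        as.integer(expected), length(payload)))
  }
  decode <- function(raws) {
    if (bits == 16L) {
      readBin(raws, integer(), n = length(raws) / 2L, size = 2L,
              endian = "little", signed = TRUE)
    } else {
      m <- matrix(as.integer(raws), nrow = 3L)
      v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
      ifelse(v >= 8388608L, v - 16777216L, v)
    }
  }
  vals <- decode(payload)
  # records are blocks of [signal1 spr samples, signal2 spr samples, ...]
  arr <- array(vals, dim = c(spr[1], ns, n_rec))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  status_idx <- which(toupper(labels) == "STATUS")
  ch_idx <- setdiff(seq_len(ns), status_idx)
  data <- matrix(0, nrow = length(ch_idx), ncol = spr[1] * n_rec)
  for (i in seq_along(ch_idx)) {
    s <- ch_idx[i]
    raw_s <- as.vector(arr[, s, ])
    data[i, ] <- phys_min[s] + gain[s] * (raw_s - dig_min[s])
  }
  triggers <- tibble::tibble(sample = integer(), code = character())
  if (length(status_idx) == 1L) {
    sv <- as.vector(arr[, status_idx, ])
    onsets <- which(sv != 0 & sv != c(0, sv[-length(sv)]))
    codes <- lapply(sv[onsets], decode_status)
    triggers <- tibble::tibble(
      sample = rep(onsets - 1L, lengths(codes)),
      code = unlist(codes) %||% character()
    )
  }
  eeg_recording(
    data, fs,
    channel_labels = labels[ch_idx],
    montage = NULL,
    triggers = triggers,
    metadata = list(source = path, montage_absent = TRUE,
                    format = if (bits == 16L) "edf" else "bdf")
  )
}
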