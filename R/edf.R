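#' Read and write European Data Format (EDF) recordings
#'
#' Plain EDF (continuous, 16-bit) reader and writer.  Signals are stored
#' per one-second data record with per-channel physical scaling; the
#' round trip `read_edf(write_edf(rec))` reproduces samples to within the
#' 16-bit quantisation step of each channel.  Channel roles are carried in
#' the EDF transducer field and recovered on read (falling back to
#' label-based inference for files written elsewhere).
#'
#' @param rec an [eeg_recording()].  The sampling rate must be a positive
#'   integer (EDF stores an integral number of samples per record).
#' @param path file path.
#' @return `read_edf` returns an [eeg_recording()] in microvolts;
#'   `write_edf` returns `path` invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$srate
  if (fs != round(fs) || fs <= 0) {
    stop("write_edf requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(fs)
  ns <- nrow(rec$signal)
  n_samp <- ncol(rec$signal)
  n_rec <- ceiling(n_samp / fs)
  pad <- n_rec * fs - n_samp

  pmin <- apply(rec$signal, 1L, min)
  pmax <- apply(rec$signal, 1L, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1

  pad_field <- function(x, width) {
    x <- substr(as.character(x), 1L, width)
    formatC(x, width = width, flag = "-")
  }
  num_field <- function(x, width) {
    s <- formatC(x, digits = 7, format = "g", width = 1)
    pad_field(s, width)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field("X X X X", 80L),
    pad_field("Startdate X X X X", 80L),
    "01.01.00", "00.00.00",
    pad_field(256L * (ns + 1L), 8L),
    pad_field("", 44L),
    pad_field(n_rec, 8L),
    pad_field("1", 8L),
    pad_field(ns, 4L)
  )
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- c(
    pad_field(rec$labels, 16L),
    pad_field(unname(rec$roles), 80L),
    pad_field(rep("uV", ns), 8L),
    num_field(pmin, 8L),
    num_field(pmax, 8L),
    pad_field(rep("-32768", ns), 8L),
    pad_field(rep("32767", ns), 8L),
    pad_field(rep("", ns), 80L),
    pad_field(rep(fs, ns), 8L),
    pad_field(rep("", ns), 32L)
  )
  writeChar(paste(fields, collapse = ""), con,
            nchars = sum(nchar(fields)), eos = NULL)

  scale <- (pmax - pmin) / 65535
  x <- if (pad > 0L) {
    cbind(rec$signal, matrix(rec$signal[, n_samp], nrow = ns, ncol = pad))
  } else {
    rec$signal
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(round((x[, cols, drop = FALSE] - pmin) / scale) - 32768)
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.size(path)
  if (sz < 256) stop("format error: EDF header truncated", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < n) {
      stop("format error: EDF header truncated", call. = FALSE)
    }
    trimws(raw)
  }
  rd(8L)                       # version
  rd(80L); rd(80L)             # patient / recording id
  rd(8L); rd(8L)               # date / time
  hdr_bytes <- suppressWarnings(as.integer(rd(8L)))
  rd(44L)
  n_rec <- suppressWarnings(as.integer(rd(8L)))
  rec_dur <- suppressWarnings(as.numeric(rd(8L)))
  ns <- suppressWarnings(as.integer(rd(4L)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns)) || ns < 1L || n_rec < 1L) {
    stop("format error: malformed EDF header", call. = FALSE)
  }
  if (sz < 256L * (ns + 1L)) {
    stop("format error: EDF header truncated", call. = FALSE)
  }
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1L))
  labels <- rdv(16L)
  transducer <- rdv(80L)
  phys_dim <- rdv(8L)
  pmin <- as.numeric(rdv(8L))
  pmax <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L))
  dmax <- as.numeric(rdv(8L))
  rdv(80L)                     # prefiltering
  spr <- as.integer(rdv(8L))
  rdv(32L)

  unit_scale <- vapply(phys_dim, function(u) {
    lu <- tolower(u)
    if (lu %in% c("uv", "µv", "")) return(1)
    if (lu == "mv") return(1e3)
    if (lu == "v") return(1e6)
    stop("unit error: cannot convert '", u, "' to microvolts",
         call. = FALSE)
  }, numeric(1L))

  expected <- 256L * (ns + 1L) + 2 * n_rec * sum(spr)
  if (sz < expected) {
    stop("format error: EDF data truncated (", sz, " of ", expected,
         " bytes)", call. = FALSE)
  }
  if (length(unique(spr)) != 1L) {
    stop("format error: heterogeneous sampling rates are not supported",
         call. = FALSE)
  }
  fs <- spr[1L] / rec_dur
  scale <- (pmax - pmin) / (dmax - dmin)
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1L],
                dimnames = list(labels))
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = spr[1L], ncol = ns)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    sig[, cols] <- t((block - rep(dmin, each = spr[1L])) *
                       rep(scale, each = spr[1L]) +
                       rep(pmin, each = spr[1L]))
  }
  sig <- sig * unit_scale
  known <- c("frontal", "central", "parietal", "occipital", "mastoid",
             "EOG", "EMG", "ECG", "other")
  roles <- ifelse(transducer %in% known, transducer, NA_character_)
  if (anyNA(roles)) {
    inferred <- infer_channel_roles(labels)
    roles[is.na(roles)] <- inferred[is.na(roles)]
  }
  names(roles) <- labels
  eeg_recording(sig, fs, labels = labels, roles = roles)
}
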