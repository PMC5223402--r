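#' @importFrom dplyr .data
NULL

# All file writes go through a temp file in the destination directory plus an
# atomic rename, so a crash can never leave a truncated file behind.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

marker_sidecar_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_markers.csv")
}

# numeric -> full-precision character (17 significant digits round-trips
# doubles exactly)
num17 <- function(x) sprintf("%.17g", x)

write_markers_csv <- function(markers, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(markers, tmp, sep = ",", row.names = FALSE,
                       quote = FALSE, eol = "\n")
  })
}

read_markers_csv <- function(path) {
  if (!file.exists(path)) return(empty_markers())
  mk <- utils::read.csv(path, stringsAsFactors = FALSE)
  mk$sample <- as.integer(mk$sample)
  mk
}

#' Write a recording to CSV or EDF
#'
#' CSV: one column per channel with a header row ('.' decimal, LF line
#' endings, full double precision), markers in a `<name>_markers.csv`
#' sidecar; the round trip is lossless. EDF: 16-bit samples over a fixed
#' physical range of +/-3276.7 uV (0.1 uV resolution), 500-sample (0.5 s)
#' data records; markers go to the same CSV sidecar. The recording length
#' must be a whole number of ticks for EDF.
#'
#' @param recording an `nfb_recording`.
#' @param path output path.
#' @param format `"csv"` or `"edf"`; default inferred from the extension.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path,
                            format = tolower(tools::file_ext(path))) {
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") {
    atomic_write(path, function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines(paste(ALL_CHANNELS, collapse = ","), con)
      chr <- apply(recording$data, 2, num17)
      writeLines(do.call(paste, c(split(chr, col(chr)), sep = ",")), con)
    })
  } else {
    write_edf(recording, path)
  }
  write_markers_csv(recording$markers, marker_sidecar_path(path))
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path path to a `.csv` or `.edf` file (markers are picked up from
#'   the sidecar if present).
#' @param format `"csv"` or `"edf"`.
#' @return an `nfb_recording`.
#' @export
read_recording <- function(path, format = tolower(tools::file_ext(path))) {
  format <- match.arg(format, c("csv", "edf"))
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    missing <- setdiff(ALL_CHANNELS, names(df))
    if (length(missing) > 0L)
      stop("recording file is missing channel(s): ",
           paste(missing, collapse = ", "))
    data <- as.matrix(df[, ALL_CHANNELS])
  } else {
    data <- read_edf(path)
  }
  nfb_recording(data, read_markers_csv(marker_sidecar_path(path)))
}

EDF_PHYS_MAX <- 3276.7
EDF_DIG_MAX <- 32767L
EDF_RECORD_SAMPLES <- 500L

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

write_edf <- function(recording, path) {
  spt <- EDF_RECORD_SAMPLES
  n <- n_samples(recording)
  if (n %% spt != 0L)
    stop("EDF export requires a whole number of 0.5-s records")
  nrec <- n %/% spt
  ns <- length(ALL_CHANNELS)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    hdr <- paste0(
      pad_field("0", 8), pad_field("X X X X", 80),
      pad_field("Startdate X X X X", 80),
      pad_field("01.01.00", 8), pad_field("00.00.00", 8),
      pad_field(256 * (1 + ns), 8), pad_field("", 44),
      pad_field(nrec, 8), pad_field("0.5", 8), pad_field(ns, 4),
      paste(pad_field(ALL_CHANNELS, 16), collapse = ""),
      paste(pad_field(rep("", ns), 80), collapse = ""),
      paste(pad_field(rep("uV", ns), 8), collapse = ""),
      paste(pad_field(rep(-EDF_PHYS_MAX, ns), 8), collapse = ""),
      paste(pad_field(rep(EDF_PHYS_MAX, ns), 8), collapse = ""),
      paste(pad_field(rep(-EDF_DIG_MAX, ns), 8), collapse = ""),
      paste(pad_field(rep(EDF_DIG_MAX, ns), 8), collapse = ""),
      paste(pad_field(rep("", ns), 80), collapse = ""),
      paste(pad_field(rep(spt, ns), 8), collapse = ""),
      paste(pad_field(rep("", ns), 32), collapse = ""))
    writeChar(hdr, con, eos = NULL)
    dig <- round(recording$data / (EDF_PHYS_MAX / EDF_DIG_MAX))
    dig <- pmin(pmax(dig, -EDF_DIG_MAX), EDF_DIG_MAX)
    storage.mode(dig) <- "integer"
    for (r in seq_len(nrec)) {
      rows <- tick_rows(r, spt)
      writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
    }
  })
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16),
                          character(1)))
  rd(80 * ns); rd(8 * ns)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  missing <- setdiff(ALL_CHANNELS, labels)
  if (length(missing) > 0L)
    stop("EDF file is missing channel(s): ", paste(missing, collapse = ", "))
  if (any(abs(spr / recdur - 1000) > 1e-6))
    stop("EDF sample rate is not 1000 Hz")
  data <- matrix(0, nrec * spr[1], ns, dimnames = list(NULL, labels))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                   endian = "little")
      data[((r - 1) * spr[s] + 1):(r * spr[s]), s] <-
        (v - dig_min[s]) * scale[s] + phys_min[s]
    }
  }
  data[, ALL_CHANNELS, drop = FALSE]
}

#' Write a session log (tick log doubles as the yoke file)
#'
#' The tick log is written as `tick,time_s,nfb_score,video_score,level,
#' emg_flag` (comma-separated, '.' decimal, LF endings, full double
#' precision so the round trip is exact); the per-trial titration log goes
#' to a `<name>_trials.csv` sidecar.
#'
#' @param log a `session_log`.
#' @param path output path for the tick CSV.
#' @return the path, invisibly.
#' @export
write_session_log <- function(log, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("tick,time_s,nfb_score,video_score,level,emg_flag", con)
    t <- log$ticks
    writeLines(paste(t$tick, num17(t$time_s), num17(t$nfb_score),
                     t$video_score, t$level, as.integer(t$emg_flag),
                     sep = ","), con)
  })
  atomic_write(trial_sidecar_path(path), function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("trial,block,level_before,level_after,titration_mean", con)
    tr <- log$trials
    writeLines(paste(tr$trial, tr$block, tr$level_before, tr$level_after,
                     num17(tr$titration_mean), sep = ","), con)
  })
  invisible(path)
}

trial_sidecar_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_trials.csv")
}

#' Read a session log / yoke file
#'
#' `read_yoke()` additionally validates the tick count against the session
#' schedule of a config before the log may drive a sham run.
#'
#' @param path path to a tick CSV written by [write_session_log()].
#' @return a `session_log` (without the baseline profile).
#' @export
read_session_log <- function(path) {
  t <- utils::read.csv(path)
  need <- c("tick", "time_s", "nfb_score", "video_score", "level", "emg_flag")
  if (!identical(names(t), need))
    stop("malformed session log: expected columns ",
         paste(need, collapse = ","))
  t$video_score <- as.integer(t$video_score)
  t$level <- as.integer(t$level)
  t$emg_flag <- as.logical(t$emg_flag)
  tp <- trial_sidecar_path(path)
  if (!file.exists(tp)) stop("missing per-trial sidecar ", tp)
  tr <- utils::read.csv(tp)
  structure(list(ticks = t, trials = tr, mode = "real"),
            class = "session_log")
}

#' @rdname read_session_log
#' @param config an [engine_config()] the yoke must match.
#' @export
read_yoke <- function(path, config = engine_config()) {
  log <- read_session_log(path)
  expect <- config$blocks * config$trials_per_block * config$ticks_per_trial
  if (nrow(log$ticks) != expect)
    stop("yoke file has ", nrow(log$ticks), " ticks but the schedule needs ",
         expect)
  if (nrow(log$trials) != config$blocks * config$trials_per_block)
    stop("yoke trial log does not match the schedule")
  log
}

config_to_list <- function(config) {
  config[c("tick", "trial", "rest", "trials_per_block", "blocks",
           "titration_window", "lockout", "baseline", "mi_trials",
           "mi_duration", "mi_rest", "emg_sd_multiplier",
           "smoothing_window")]
}

config_from_list <- function(x) {
  x$mi_rest <- as.numeric(unlist(x$mi_rest))
  do.call(engine_config, x)
}

#' Write / read a run manifest
#'
#' A manifest snapshots everything needed to reproduce a run bit-identically:
#' the subject profile, the engine configuration, the mode, the seed, the
#' package version and (for sham runs) the md5 checksum of the yoke file.
#'
#' @param profile a [subject_profile()].
#' @param config an [engine_config()].
#' @param mode `"real"` or `"sham"`.
#' @param path output JSON path.
#' @param yoke_path optional yoke file referenced by a sham run.
#' @return the path, invisibly.
#' @export
write_manifest <- function(profile, config, mode = "real", path,
                           yoke_path = NULL) {
  m <- list(package = "iinfb",
            version = as.character(utils::packageVersion("iinfb")),
            mode = mode,
            profile = unclass(profile),
            config = config_to_list(config))
  if (!is.null(yoke_path)) {
    m$yoke_path <- yoke_path
    m$yoke_md5 <- unname(tools::md5sum(yoke_path))
  }
  atomic_write(path, function(tmp) {
    jsonlite::write_json(m, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}

#' Re-run a simulation from a manifest
#'
#' @param path manifest JSON path.
#' @return the result of [simulate_closed_loop_session()] under the
#'   manifest's profile and config (bit-identical to the original run).
#' @export
run_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- do.call(subject_profile, m$profile)
  config <- config_from_list(m$config)
  if (!is.null(m$yoke_md5)) {
    if (!file.exists(m$yoke_path) ||
        !identical(unname(tools::md5sum(m$yoke_path)), m$yoke_md5))
      stop("yoke file missing or checksum mismatch")
  }
  simulate_closed_loop_session(profile, config)
}
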