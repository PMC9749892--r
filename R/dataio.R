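# On-disk formats: DAM-style monitor text, TSV trace/ROI/choice tables with
# header + units rows, YAML run configuration, JSON ground-truth sidecars.
# Readers validate strictly and fail with line/field context; writers and
# readers round-trip to identity.

MONTH_ABB <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
               "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
DAM_COLS <- 42L   # index, date, time, status, 6 metadata, 32 channels

dam_datetime_strings <- function(n_minutes, start = "2024-01-01 08:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  tt <- t0 + 60 * (seq_len(n_minutes) - 1)
  lt <- as.POSIXlt(tt, tz = "UTC")
  list(date = sprintf("%02d %s %02d", lt$mday, MONTH_ABB[lt$mon + 1],
                      lt$year %% 100),
       time = sprintf("%02d:%02d:%02d", lt$hour, lt$min, lt$sec))
}

parse_dam_minute <- function(date_str, time_str, line_no) {
  dp <- strsplit(date_str, " ", fixed = TRUE)[[1]]
  mon <- match(dp[2], MONTH_ABB)
  if (length(dp) != 3 || is.na(mon))
    stop(sprintf("line %d: unparseable date '%s'", line_no, date_str),
         call. = FALSE)
  day <- suppressWarnings(as.integer(dp[1]))
  yr <- suppressWarnings(as.integer(dp[3])) + 2000L
  d <- as.Date(sprintf("%04d-%02d-%02d", yr, mon, day))
  tp <- suppressWarnings(as.integer(strsplit(time_str, ":", fixed = TRUE)[[1]]))
  if (is.na(d) || length(tp) != 3 || any(is.na(tp)))
    stop(sprintf("line %d: unparseable timestamp '%s %s'",
                 line_no, date_str, time_str), call. = FALSE)
  as.numeric(d) * 1440 + tp[1] * 60 + tp[2]
}

#' Write activity series as a DAM-style monitor file
#'
#' Tab-delimited TriKinetics dialect: reading index, date, time, a monitor
#' status column (1 = valid data), six metadata columns, then 32 channel
#' counts, one row per minute.  Up to 32 series of equal length occupy
#' channels 1..32 in order; unused channels are written as zeros.
#'
#' @param series_list list of [activity_series()] of equal length.
#' @param path output file.
#' @param start_datetime timestamp of the first row (UTC).
#' @return `path`, invisibly.
#' @export
write_dam <- function(series_list, path, start_datetime = "2024-01-01 08:00:00") {
  stopifnot(length(series_list) >= 1, length(series_list) <= 32)
  n <- length(series_list[[1]]$counts)
  if (!all(vapply(series_list, function(s) length(s$counts), numeric(1)) == n))
    stop("all series must have equal length", call. = FALSE)
  counts <- matrix(0L, nrow = n, ncol = 32)
  for (i in seq_along(series_list)) counts[, i] <- series_list[[i]]$counts
  ts <- dam_datetime_strings(n, start_datetime)
  rows <- cbind(seq_len(n), ts$date, ts$time, 1L,
                matrix(0L, nrow = n, ncol = 6), counts)
  writeLines(apply(rows, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a DAM-style monitor file
#'
#' Parses the 42-column dialect written by [write_dam()].  Rows whose status
#' column is not the valid-data code (1) are skipped with a warning.  Gaps
#' or repeats in the minute timestamps are a hard error unless
#' `zero_fill = TRUE`, in which case missing minutes are zero-filled (a
#' documented relaxation of strictness); non-monotone timestamps and
#' negative or non-integer counts are always errors, reported with their
#' line number.
#'
#' @param path DAM text file.
#' @param channel_map data.frame with columns `channel` (1..32), `fly_id`,
#'   `genotype`; one series is returned per mapped channel.
#' @param schedule a [light_schedule()] attached to every series (monitor
#'   files carry no light metadata).
#' @param zero_fill zero-fill missing minutes instead of failing.
#' @return list of [activity_series()].
#' @export
read_dam <- function(path, channel_map, schedule = light_schedule(),
                     zero_fill = FALSE) {
  stopifnot(all(c("channel", "fly_id", "genotype") %in% names(channel_map)),
            all(channel_map$channel %in% 1:32))
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty DAM file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols != DAM_COLS)
  if (length(bad))
    stop(sprintf("line %d: expected %d columns, got %d",
                 bad[1], DAM_COLS, ncols[bad[1]]), call. = FALSE)
  m <- do.call(rbind, parts)
  status_ok <- m[, 4] == "1"
  if (any(!status_ok))
    warning(sprintf("skipping %d rows with non-valid monitor status",
                    sum(!status_ok)), call. = FALSE)
  keep <- which(status_ok)
  minutes <- vapply(keep, function(i) parse_dam_minute(m[i, 2], m[i, 3], i),
                    numeric(1))
  if (any(diff(minutes) <= 0)) {
    i <- keep[which(diff(minutes) <= 0)[1] + 1]
    stop(sprintf("line %d: non-monotone timestamp", i), call. = FALSE)
  }
  counts <- suppressWarnings(
    matrix(as.numeric(m[keep, 11:42]), nrow = length(keep)))
  badc <- which(rowSums(is.na(counts) | counts < 0 | counts != round(counts)) > 0)
  if (length(badc))
    stop(sprintf("line %d: negative or non-integer count", keep[badc[1]]),
         call. = FALSE)
  rel <- minutes - minutes[1] + 1
  n_total <- rel[length(rel)]
  if (n_total != length(rel)) {
    if (!zero_fill)
      stop(sprintf("missing minutes in the recording (%d rows over %d minutes); use zero_fill = TRUE to pad",
                   length(rel), n_total), call. = FALSE)
    full <- matrix(0, nrow = n_total, ncol = 32)
    full[rel, ] <- counts
    counts <- full
  }
  lapply(seq_len(nrow(channel_map)), function(i) {
    activity_series(fly_id = channel_map$fly_id[i],
                    genotype = channel_map$genotype[i],
                    counts = counts[, channel_map$channel[i]],
                    schedule = schedule)
  })
}

# full-precision number formatting for round-trip TSV output
fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write a voltage recording as a delimited trace table
#'
#' Metadata (`cell_id`, `genotype`, ZT, sampling rate, protocol fields) go
#' in `# key: value` header lines, followed by a column-header row, a units
#' row, and `time_s`/`voltage_mv` data at full precision (round-trip exact).
#'
#' @param rec a [voltage_recording()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_voltage_table <- function(rec, path) {
  p <- rec$protocol
  meta <- c(cell_id = rec$cell_id, genotype = rec$genotype,
            zt_of_recording = rec$zt_of_recording,
            sampling_hz = rec$sampling_hz,
            pre_dark_s = p$pre_dark_s, stim_s = p$stim_s, post_s = p$post_s,
            n_sweeps = p$n_sweeps, wavelength_nm = p$wavelength_nm,
            intensity_uw_cm2 = p$intensity_uw_cm2)
  t_s <- (seq_along(rec$voltage_mv) - 1) / rec$sampling_hz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# %s: %s", names(meta), meta),
               "time_s\tvoltage_mv", "s\tmV",
               paste(fmt_full(t_s), fmt_full(rec$voltage_mv), sep = "\t")),
             con)
  invisible(path)
}

#' Read a voltage trace table
#'
#' Inverse of [write_voltage_table()].  Errors when the units row is absent,
#' required metadata are missing, or the trace length disagrees with the
#' protocol by more than one sample.
#'
#' @param path TSV file.
#' @return a [voltage_recording()].
#' @export
read_voltage_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines)
  meta <- list()
  for (ln in lines[meta_lines]) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  need <- c("cell_id", "genotype", "sampling_hz", "pre_dark_s", "stim_s",
            "post_s", "n_sweeps")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop(sprintf("voltage table missing metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  body <- lines[-meta_lines]
  if (length(body) < 3 || !identical(body[1], "time_s\tvoltage_mv"))
    stop("voltage table header row absent or malformed", call. = FALSE)
  if (!identical(body[2], "s\tmV"))
    stop("voltage table units row absent", call. = FALSE)
  dat <- utils::read.table(text = body[-(1:2)], sep = "\t",
                           col.names = c("time_s", "voltage_mv"))
  zt <- suppressWarnings(as.numeric(meta$zt_of_recording %||% NA))
  protocol <- sweep_protocol(
    pre_dark_s = as.numeric(meta$pre_dark_s), stim_s = as.numeric(meta$stim_s),
    post_s = as.numeric(meta$post_s), n_sweeps = as.integer(meta$n_sweeps),
    wavelength_nm = as.numeric(meta$wavelength_nm %||% NA),
    intensity_uw_cm2 = as.numeric(meta$intensity_uw_cm2 %||% NA))
  voltage_recording(cell_id = meta$cell_id, genotype = meta$genotype,
                    voltage_mv = dat$voltage_mv,
                    sampling_hz = as.numeric(meta$sampling_hz),
                    protocol = protocol, zt_of_recording = zt)
}

#' Write / read an ROI fluorescence table
#'
#' TSV with a header row and a units row (`au` for intensities, `h` for ZT).
#' The reader validates the full ROI contract (see [validate_roi_table()])
#' and rejects, e.g., nonpositive backgrounds or ZT points outside the
#' measured set.
#'
#' @param table a validated ROI data.frame.
#' @param path TSV file.
#' @return `path` (writer, invisibly); validated data.frame (reader).
#' @export
write_roi_table <- function(table, path) {
  table <- validate_roi_table(table)
  cols <- c("brain_id", "neuron_id", "channel", "mean_intensity",
            "background_intensity", "zt", "genotype")
  units <- c("-", "-", "-", "au", "au", "h", "-")
  body <- table[, cols]
  body$mean_intensity <- fmt_full(body$mean_intensity)
  body$background_intensity <- fmt_full(body$background_intensity)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), paste(units, collapse = "\t"),
               do.call(paste, c(body, sep = "\t"))), con)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("ROI table too short", call. = FALSE)
  header <- strsplit(lines[1], "\t")[[1]]
  if (!"mean_intensity" %in% header)
    stop("ROI table header row absent", call. = FALSE)
  units <- strsplit(lines[2], "\t")[[1]]
  if (length(units) != length(header) || !"au" %in% units)
    stop("ROI table units row absent", call. = FALSE)
  dat <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                           col.names = header, stringsAsFactors = FALSE)
  validate_roi_table(dat)
}

#' Write / read a two-environment choice table
#'
#' TSV (header + units row) with one row per fly per minute: lit and dark
#' counts plus wavelength/intensity metadata.
#'
#' @param cohort list of [choice_series()].
#' @param path TSV file.
#' @return `path` (writer, invisibly); list of [choice_series()] (reader).
#' @export
write_choice_table <- function(cohort, path) {
  cols <- c("fly_id", "genotype", "minute", "lit", "dark",
            "wavelength_nm", "intensity_uw_cm2")
  units <- c("-", "-", "min", "counts", "counts", "nm", "uW/cm2")
  rows <- do.call(rbind, lapply(cohort, function(cs) {
    data.frame(fly_id = cs$fly_id, genotype = cs$genotype,
               minute = seq_along(cs$lit_counts) - 1,
               lit = cs$lit_counts, dark = cs$dark_counts,
               wavelength_nm = cs$wavelength_nm,
               intensity_uw_cm2 = cs$intensity_uw_cm2)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), paste(units, collapse = "\t"),
               do.call(paste, c(rows, sep = "\t"))), con)
  invisible(path)
}

#' @rdname write_choice_table
#' @export
read_choice_table <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t")[[1]]
  if (!"lit" %in% header) stop("choice table header row absent", call. = FALSE)
  if (length(strsplit(lines[2], "\t")[[1]]) != length(header))
    stop("choice table units row absent", call. = FALSE)
  dat <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                           col.names = header, stringsAsFactors = FALSE)
  lapply(split(dat, dat$fly_id), function(d) {
    d <- d[order(d$minute), ]
    choice_series(fly_id = d$fly_id[1], genotype = d$genotype[1],
                  lit_counts = d$lit, dark_counts = d$dark,
                  wavelength_nm = d$wavelength_nm[1],
                  intensity_uw_cm2 = d$intensity_uw_cm2[1])
  })
}

#' Write a ground-truth sidecar
#'
#' JSON companion file recording the latent parameters a synthetic fixture
#' was generated from, so analyses on the fixture can be checked by
#' parameter recovery.
#'
#' @param ground_truth list (e.g. the `ground_truth` attribute of a
#'   generator's output).
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
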