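# On-disk session layout: one directory per insertion, columnar tables for
# units / spikes / trials / channels / LFP PSD (CSV or Parquet), metadata
# and trajectories as JSON. One object, one file.

# format numerics so that read-back is bit-exact (%.17g round-trips doubles)
fmt_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

write_table_file <- function(df, path, format) {
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_invalid("parquet support requires the 'arrow' package")
    arrow::write_parquet(df, paste0(path, ".parquet"))
  } else {
    write.csv(fmt_num_df(df), paste0(path, ".csv"), row.names = FALSE)
  }
}

read_table_file <- function(path, required_cols) {
  csv <- paste0(path, ".csv")
  pq <- paste0(path, ".parquet")
  df <- if (file.exists(csv)) {
    read.csv(csv, stringsAsFactors = FALSE)
  } else if (file.exists(pq)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop_invalid("parquet support requires the 'arrow' package")
    as.data.frame(arrow::read_parquet(pq))
  } else {
    stop_invalid("format-error: missing table file %s(.csv|.parquet)", path)
  }
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop_invalid("format-error in %s: missing columns %s", basename(path),
                 paste(miss, collapse = ", "))
  df
}

#' Write a session record to a directory
#'
#' @param session a [session_record()].
#' @param path directory to create/populate.
#' @param format `"csv"` (default) or `"parquet"` for the columnar tables.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(session, "session_record"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  units_df <- do.call(rbind, lapply(session$units, function(u) {
    data.frame(unit_id = u$unit_id, x = u$position[1], y = u$position[2],
               z = u$position[3], ptt_duration = u$ptt_duration,
               region = u$region, stringsAsFactors = FALSE)
  }))
  if (is.null(units_df))
    units_df <- data.frame(unit_id = character(), x = double(), y = double(),
                           z = double(), ptt_duration = double(),
                           region = character())
  spikes_df <- do.call(rbind, lapply(session$units, function(u) {
    data.frame(unit_id = rep(u$unit_id, length(u$spike_times)),
               time = u$spike_times, amplitude = u$amplitudes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(spikes_df))
    spikes_df <- data.frame(unit_id = character(), time = double(),
                            amplitude = double())
  write_table_file(units_df, file.path(path, "units"), format)
  write_table_file(spikes_df, file.path(path, "spikes"), format)
  write_table_file(session$trial_table, file.path(path, "trials"), format)
  write_table_file(
    data.frame(depth = session$channel_depths,
               ap_rms = session$ap_rms_per_channel),
    file.path(path, "channels"), format)
  if (!is.null(session$lfp_psd)) {
    psd <- as.data.frame(session$lfp_psd$psd_db)
    names(psd) <- sprintf("f_%g", session$lfp_psd$freqs)
    write_table_file(psd, file.path(path, "lfp_psd"), format)
  }

  traj_json <- function(tr) if (is.null(tr)) NULL else
    list(entry = tr$entry, direction = tr$direction, source = tr$source)
  meta <- list(
    lab_id = session$lab_id, subject_id = session$subject_id,
    session_id = session$session_id,
    n_channels_per_region = as.list(session$n_channels_per_region),
    exclusion_ledger = as.list(session$exclusion_ledger),
    planned_traj = traj_json(session$planned_traj),
    micro_traj = traj_json(session$micro_traj),
    histology_traj = traj_json(session$histology_traj)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session record from a directory
#'
#' Inverse of [write_session()]: the round trip is lossless on all fields.
#' Missing or malformed files raise a format error naming the offending
#' file.
#'
#' @param path session directory.
#' @return a [session_record()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop_invalid("session directory not found: %s", path)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop_invalid("format-error: missing file meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)

  units_df <- read_table_file(file.path(path, "units"),
                              c("unit_id", "x", "y", "z", "ptt_duration",
                                "region"))
  spikes_df <- read_table_file(file.path(path, "spikes"),
                               c("unit_id", "time", "amplitude"))
  trials <- read_table_file(file.path(path, "trials"),
                            c("trial", "stim_on", "contrast", "side",
                              "block_p_left", "first_move", "choice",
                              "feedback_type", "feedback_time",
                              "reaction_time"))
  if (nrow(trials) &&
      !all(trials$stim_on < trials$first_move &
           trials$first_move < trials$feedback_time))
    stop_invalid("format-error in trials: event times out of order")
  channels <- read_table_file(file.path(path, "channels"),
                              c("depth", "ap_rms"))

  lfp <- NULL
  if (file.exists(file.path(path, "lfp_psd.csv")) ||
      file.exists(file.path(path, "lfp_psd.parquet"))) {
    psd <- read_table_file(file.path(path, "lfp_psd"), character())
    freqs <- as.numeric(sub("^f_", "", names(psd)))
    if (anyNA(freqs))
      stop_invalid("format-error in lfp_psd: bad frequency columns")
    lfp <- list(freqs = freqs, psd_db = unname(as.matrix(psd)))
  }

  spl <- split(spikes_df, factor(spikes_df$unit_id, levels = units_df$unit_id))
  units <- lapply(seq_len(nrow(units_df)), function(i) {
    row <- units_df[i, ]
    sp <- spl[[row$unit_id]]
    unit_record(unit_id = row$unit_id, spike_times = sp$time,
                amplitudes = sp$amplitude,
                position = c(row$x, row$y, row$z),
                ptt_duration = row$ptt_duration, region = row$region)
  })

  traj_from <- function(x) if (is.null(x)) NULL else
    trajectory(unlist(x$entry), unlist(x$direction), x$source)
  session_record(
    lab_id = meta$lab_id, subject_id = meta$subject_id,
    session_id = meta$session_id, units = units,
    n_channels_per_region = unlist(meta$n_channels_per_region),
    channel_depths = channels$depth, ap_rms_per_channel = channels$ap_rms,
    lfp_psd = lfp, trial_table = trials,
    planned_traj = traj_from(meta$planned_traj),
    micro_traj = traj_from(meta$micro_traj),
    histology_traj = traj_from(meta$histology_traj),
    exclusion_ledger = unlist(meta$exclusion_ledger)
  )
}

#' Ordered session exclusion cascade
#'
#' Removes sessions in a fixed criterion order — data-acquisition failures
#' (hardware, histology), visually assessed recording criteria (drift,
#' noisy channels, artefacts, epileptiform activity), computed recording
#' criteria (yield, noise), the behaviour criterion (at least `min_trials`
#' completed trials), and finally the lab-session-count rule for across-lab
#' comparisons. A session counts against exactly one criterion: the first
#' one it fails, so the tallies are disjoint and
#' `survivors + sum(tally) = input`.
#'
#' @param sessions list of [session_record()] objects.
#' @param min_trials behaviour criterion threshold (default 400 trials).
#' @param min_sessions_per_lab across-lab inclusion rule (default 3).
#' @return list with `survivors` (the retained sessions), `tally` (named
#'   integer, sessions removed per criterion) and `n_input`.
#' @export
exclusion_cascade <- function(sessions, min_trials = 400L,
                              min_sessions_per_lab = 3L) {
  stages <- c(ledger_criteria(), "behavior", "lab_count")
  tally <- setNames(integer(length(stages)), stages)
  surviving <- list()
  for (s in sessions) {
    failed <- NA_character_
    for (crit in ledger_criteria()) {
      if (!isTRUE(s$exclusion_ledger[[crit]])) { failed <- crit; break }
    }
    if (is.na(failed)) {
      n_tr <- if (is.null(s$trial_table)) 0L else nrow(s$trial_table)
      if (n_tr < min_trials) failed <- "behavior"
    }
    if (is.na(failed)) surviving[[length(surviving) + 1L]] <- s
    else tally[[failed]] <- tally[[failed]] + 1L
  }
  labs <- vapply(surviving, function(s) s$lab_id, character(1))
  keep <- labs %in% names(which(table(labs) >= min_sessions_per_lab))
  tally[["lab_count"]] <- sum(!keep)
  list(survivors = surviving[keep], tally = tally,
       n_input = length(sessions))
}
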