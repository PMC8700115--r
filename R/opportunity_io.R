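# Loader for the UCI OPPORTUNITY Activity Recognition challenge files
# (https://archive.ics.uci.edu/ml/datasets/OPPORTUNITY+Activity+Recognition).
# The dataset is an opt-in download and is never fetched by this package;
# tests exercise the loader on small synthetic files in the same format.

#' Default column specification for Opportunity challenge .dat files
#'
#' The native files are whitespace-delimited with 250 columns: a millisecond
#' timestamp, 242 sensor columns, and 7 label columns. The challenge's
#' standard 113-channel subset (on-body accelerometers, the five XSense IMUs
#' and the two shoe-mounted sensors, dropping the quaternion and
#' environmental columns) is used by default; the Modes-of-Locomotion (ML)
#' task reads the Locomotion label column and the gesture task (GR) the
#' ML_Both_Arms column. Both maps put the Null class at id 0. All of this is
#' overridable for non-standard extracts — the column roles below follow the
#' dataset's own column documentation.
#'
#' @param gesture_column 1-based column index of the gesture label; the
#'   default (250) is the ML_Both_Arms column.
#' @return a colspec list as accepted by [read_recording()] /
#'   [load_opportunity()].
#' @export
opportunity_colspec <- function(gesture_column = 250L) {
  channel_cols <- c(2:46, 51:59, 64:72, 77:85, 90:98, 103:134)
  gestures <- c(
    "0" = "Null",
    "406516" = "Open_Door1", "406517" = "Open_Door2",
    "404516" = "Close_Door1", "404517" = "Close_Door2",
    "406520" = "Open_Fridge", "404520" = "Close_Fridge",
    "406505" = "Open_Dishwasher", "404505" = "Close_Dishwasher",
    "406519" = "Open_Drawer1", "404519" = "Close_Drawer1",
    "406511" = "Open_Drawer2", "404511" = "Close_Drawer2",
    "406508" = "Open_Drawer3", "404508" = "Close_Drawer3",
    "408512" = "Clean_Table", "407521" = "Drink_Cup",
    "405506" = "Toggle_Switch"
  )
  locomotion <- c("0" = "Null", "1" = "Stand", "2" = "Walk",
                  "4" = "Sit", "5" = "Lie")
  list(
    channel_cols = channel_cols,
    label_cols = list(ML = 244L, GR = as.integer(gesture_column)),
    label_maps = list(ML = as.list(locomotion), GR = as.list(gestures)),
    channel_names = paste0("ch", seq_along(channel_cols)),
    sample_rate = 30
  )
}

#' Sensor layout of the 113-channel Opportunity subset
#'
#' The 19 body-worn sensor nodes and the channel block each owns within the
#' 113-channel matrix: twelve 3-channel accelerometers (RKN^, HIP, LUA^,
#' RUA_, LH, BACK acc, RKN_, RWR, RUA^, LUA_, LWR, RH), five 9-channel IMUs
#' (BACK, RUA, RLA, LUA, LLA) and two 16-channel shoe sensors (L-SHOE,
#' R-SHOE).
#'
#' @return a [sensor_layout()] over 113 channels.
#' @export
opportunity_layout <- function() {
  blocks <- list(
    "RKN^" = 1:3, "HIP" = 4:6, "LUA^" = 7:9, "RUA_" = 10:12,
    "LH" = 13:15, "BACK (Acc)" = 16:18, "RKN_" = 19:21, "RWR" = 22:24,
    "RUA^" = 25:27, "LUA_" = 28:30, "LWR" = 31:33, "RH" = 34:36,
    "BACK (IMU)" = 37:45, "RUA" = 46:54, "RLA" = 55:63, "LUA" = 64:72,
    "LLA" = 73:81, "L-SHOE" = 82:97, "R-SHOE" = 98:113
  )
  sensor_layout(blocks, total_channels = 113L)
}

#' Load one Opportunity challenge recording
#'
#' Reads a whitespace-delimited `.dat` file (one sample per row), keeps the
#' configured channel columns, maps the raw label codes of both tasks to
#' contiguous 0-based class ids (Null = 0) and marks non-finite channel
#' entries as missing. Rows with the wrong column count and unknown label
#' codes are errors.
#'
#' @param path path to e.g. `S2-ADL4.dat`.
#' @param colspec column specification; default [opportunity_colspec()].
#' @param source_id recording identity; defaults to the file name without
#'   extension (e.g. `S2-ADL4`), which [challenge_split()] parses.
#' @return an [activity_recording()] with `D = 113` channels (under the
#'   default spec) and label sequences for tasks `ML` and `GR`.
#' @export
load_opportunity <- function(path, colspec = opportunity_colspec(),
                             source_id = sub("\\.dat$", "", basename(path))) {
  first <- utils::read.table(path, header = FALSE, nrows = 1)
  need <- max(unlist(colspec$channel_cols), unlist(colspec$label_cols))
  if (ncol(first) < need) {
    stop(sprintf("%s line 1: expected at least %d columns, found %d",
                 path, need, ncol(first)))
  }
  read_recording(path, colspec, source_id = source_id, sep = "")
}

#' Opportunity challenge train/test split
#'
#' The challenge protocol: sessions `ADL4` and `ADL5` of subjects 2 and 3
#' form the test set; every other Drill/ADL session of subjects 1-3 is
#' training data. Subject 4 is excluded entirely (its signals carry injected
#' noise for a different challenge task). A warning lists any expected
#' session that is absent.
#'
#' @param recordings list of [activity_recording()]s whose `source_id`s look
#'   like `S<subject>-<session>` with subject in 1..4 and session one of
#'   `Drill`, `ADL1`..`ADL5`.
#' @return list with elements `train` and `test`, each a named list of
#'   recordings.
#' @export
challenge_split <- function(recordings) {
  ids <- vapply(recordings, function(r) r$source_id, "")
  names(recordings) <- ids
  m <- regmatches(ids, regexec("^S([0-9]+)-(Drill|ADL[1-5])$", ids))
  parsed <- do.call(rbind, lapply(seq_along(m), function(i) {
    if (length(m[[i]]) == 0) {
      stop(sprintf("cannot parse subject/session from source_id '%s'",
                   ids[i]))
    }
    data.frame(id = ids[i], subject = as.integer(m[[i]][2]),
               session = m[[i]][3], stringsAsFactors = FALSE)
  }))
  test_ids <- c("S2-ADL4", "S2-ADL5", "S3-ADL4", "S3-ADL5")
  keep <- parsed$subject %in% 1:3
  expected <- c(outer(paste0("S", 1:3), c("Drill", paste0("ADL", 1:5)),
                      paste, sep = "-"))
  absent <- setdiff(expected, parsed$id[keep])
  if (length(absent) > 0) {
    warning(sprintf("missing expected session(s): %s",
                    paste(sort(absent), collapse = ", ")))
  }
  test <- recordings[parsed$id[keep & parsed$id %in% test_ids]]
  train <- recordings[parsed$id[keep & !(parsed$id %in% test_ids)]]
  list(train = train, test = test)
}

#' Segment a set of recordings and pool the windows
#'
#' Applies [interpolate_missing()] and [segment_windows()] to each recording
#' separately (windows never span recording boundaries) and concatenates the
#' results.
#'
#' @param recordings list of [activity_recording()]s.
#' @param task task name.
#' @param window_length,step see [segment_windows()].
#' @return a [windowed_dataset()].
#' @export
segment_recordings <- function(recordings, task, window_length = 24L,
                               step = 12L) {
  parts <- lapply(recordings, function(r) {
    segment_windows(interpolate_missing(r), task,
                    window_length = window_length, step = step)
  })
  bind_windowed(parts)
}
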