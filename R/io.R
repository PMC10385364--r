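# Trial interchange: one CSV per trial with columns
# time_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z (SI units), plus an
# optional JSON sidecar (same path with extension .json) carrying the
# participant metadata and, for synthetic trials, the ground truth.

TRIAL_COLUMNS <- c("time_s", "acc_x", "acc_y", "acc_z",
                   "gyr_x", "gyr_y", "gyr_z")

#' Write a trial to CSV (+ JSON sidecar)
#'
#' @param trial An `imu_trial`.
#' @param path CSV file path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  df <- data.frame(time_s = trial$time,
                   acc_x = trial$acc[, 1], acc_y = trial$acc[, 2],
                   acc_z = trial$acc[, 3],
                   gyr_x = trial$gyr[, 1], gyr_y = trial$gyr[, 2],
                   gyr_z = trial$gyr[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(meta = unclass(trial$meta))
  if (!is.null(trial$truth)) {
    side$truth <- trial$truth
    if (!is.null(side$truth$features)) {
      side$truth$features <- as.list(side$truth$features)
    }
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial from CSV (+ JSON sidecar)
#'
#' @param path CSV file path as written by [write_trial()].
#' @return An `imu_trial`; when the sidecar is missing the metadata is
#'   empty and a warning is issued.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("trial file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  side_path <- paste0(path, ".json")
  meta <- NULL; truth <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    m <- side$meta
    meta <- participant_meta(m$id, m$mass, m$height, m$repetition, m$label6)
    truth <- side$truth
    if (!is.null(truth$features)) truth$features <- unlist(truth$features)
  } else {
    warning("no sidecar for ", path, "; trial loaded without metadata")
  }
  structure(list(time = df$time_s,
                 acc = as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
                 gyr = as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")]),
                 meta = meta, truth = truth),
            class = "imu_trial")
}

#' Write a cohort of trials and its manifest
#'
#' @param trials List of `imu_trial` objects.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV (columns `trial_path, participant_id,
#'   repetition, label2, label6`).
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    fn <- sprintf("%s_rep%d.csv", tr$meta$id, tr$meta$repetition)
    write_trial(tr, file.path(dir, fn))
    data.frame(trial_path = fn, participant_id = tr$meta$id,
               repetition = tr$meta$repetition, label2 = tr$meta$label2,
               label6 = tr$meta$label6, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

#' Read a cohort from its manifest
#'
#' @param manifest Path to a manifest CSV from [write_cohort()].
#' @return List of `imu_trial` objects.
#' @export
read_cohort <- function(manifest) {
  mf <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  lapply(mf$trial_path, function(p) read_trial(file.path(dir, p)))
}
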