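#' Calm/stress labeling from arousal and valence ratings
#'
#' Applies the affect-rating rule used with the DEAP benchmark: a trial is
#' *calm* when arousal < 4 and 4 < valence < 6, *stress* when arousal > 5 and
#' valence < 3, and *unlabeled* otherwise. The inequalities are strict, so
#' ratings exactly on a boundary (arousal 4 or 5; valence 3, 4 or 6) are
#' unlabeled.
#'
#' @param arousal,valence ratings in `[0, 9]`.
#' @return one of `"calm"`, `"stress"`, `"unlabeled"`.
#' @examples
#' label_trial(3, 5)   # calm
#' label_trial(6, 2)   # stress
#' label_trial(4.5, 7) # unlabeled
#' @export
label_trial <- function(arousal, valence) {
  if (!is.numeric(arousal) || !is.numeric(valence) ||
      length(arousal) != 1L || length(valence) != 1L)
    stop("`arousal` and `valence` must be numeric scalars")
  if (is.na(arousal) || is.na(valence) ||
      arousal < 0 || arousal > 9 || valence < 0 || valence > 9)
    stop("ratings must lie in [0, 9]")
  if (arousal < 4 && valence > 4 && valence < 6) return("calm")
  if (arousal > 5 && valence < 3) return("stress")
  "unlabeled"
}

#' Write a trial set (or single recording) as delimited text
#'
#' Each trial is stored as a headerless CSV with one row per channel, plus a
#' YAML sidecar `meta.yaml` holding the sampling rate, channel names and any
#' ratings, so a directory round-trips through [read_recording()].
#'
#' @param x a `trial_set` or `eeg_recording`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(x, dir) {
  if (inherits(x, "eeg_recording")) x <- trial_set(list(x))
  if (!inherits(x, "trial_set")) stop("`x` must be a trial_set or recording")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(x$trials)) {
    utils::write.table(format(x$trials[[i]]$data, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       file.path(dir, sprintf("trial%03d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  meta <- list(fs = x$trials[[1]]$fs,
               channel_names = x$trials[[1]]$channel_names,
               n_trials = length(x$trials),
               arousal = x$arousal, valence = x$valence, label = x$label)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"), precision = 17L)
  invisible(dir)
}

#' Read EEG recordings from delimited text
#'
#' Two on-disk layouts are supported:
#'
#' * `format = "csv"`: a single channels-by-samples CSV (one trial), or a
#'   directory written by [write_recording()] (`trialNNN.csv` files plus a
#'   `meta.yaml` sidecar with `fs`, `channel_names` and optional ratings).
#' * `format = "deap_container"`: a plain-text export of a DEAP preprocessed
#'   per-subject container — a directory with `data_trialNN.csv` files of 40
#'   rows each (the 32 EEG channels followed by 8 peripheral rows, which are
#'   dropped) and a `ratings.csv` whose first two columns are valence and
#'   arousal. Ratings are mapped to labels with [label_trial()].
#'
#' @param path file or directory to read.
#' @param format `"csv"` or `"deap_container"`.
#' @param fs sampling rate in Hz, used when no sidecar provides it
#'   (default 128, the DEAP preprocessed rate).
#' @return a `trial_set`.
#' @export
read_recording <- function(path, format = c("csv", "deap_container"),
                           fs = 128) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (format == "csv") read_csv_recording(path, fs) else read_deap_export(path)
}

read_data_csv <- function(file) {
  mat <- tryCatch(
    as.matrix(utils::read.table(file, sep = ",", header = FALSE,
                                colClasses = "numeric")),
    error = function(e) stop("failed to parse '", file, "': ",
                             conditionMessage(e)))
  dimnames(mat) <- NULL
  mat
}

read_csv_recording <- function(path, fs) {
  if (dir.exists(path)) {
    meta_file <- file.path(path, "meta.yaml")
    meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
    files <- sort(list.files(path, pattern = "^trial[0-9]+\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop("no trialNNN.csv files found in ", path)
    fs <- if (!is.null(meta$fs)) meta$fs else fs
    trials <- lapply(files, function(f)
      recording(read_data_csv(f), fs,
                channel_names = unlist(meta$channel_names)))
    trial_set(trials,
              arousal = unlist(meta$arousal), valence = unlist(meta$valence),
              label = unlist(meta$label))
  } else {
    trial_set(list(recording(read_data_csv(path), fs)))
  }
}

read_deap_export <- function(path) {
  if (!dir.exists(path))
    stop("a DEAP container export must be a directory, got file: ", path)
  files <- sort(list.files(path, pattern = "^data_trial[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no data_trialNN.csv files found in ", path)
  trials <- lapply(files, function(f) {
    mat <- read_data_csv(f)
    if (nrow(mat) != 40L)
      stop("DEAP trial '", f, "' must have 40 channel rows, found ",
           nrow(mat))
    # rows 33-40 are EOG/EMG/peripheral signals, not EEG
    recording(mat[1:32, , drop = FALSE], fs = 128,
              channel_names = deap_eeg_channels())
  })
  rfile <- file.path(path, "ratings.csv")
  if (file.exists(rfile)) {
    ratings <- read_data_csv(rfile)
    if (nrow(ratings) != length(trials) || ncol(ratings) < 2L)
      stop("ratings.csv must have one row per trial and >= 2 columns ",
           "(valence, arousal)")
    trial_set(trials, arousal = ratings[, 2], valence = ratings[, 1])
  } else {
    trial_set(trials, label = rep("unlabeled", length(trials)))
  }
}

#' The 32 EEG channel labels of the DEAP preprocessed layout
#' @return character vector of 10-20 system labels, in container order.
#' @export
deap_eeg_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
    "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}
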