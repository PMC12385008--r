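#' Multi-channel EEG recording
#'
#' The basic unit every stage of the pipeline consumes and produces: a
#' channels-by-samples numeric matrix (microvolts) together with its sampling
#' rate and channel names.
#'
#' @param data numeric matrix, rows are channels, columns are samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector of channel identifiers
#'   (10-20 system labels when known); defaults to `"ch01"`, `"ch02"`, ...
#' @return an object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 256), nrow = 2), fs = 128)
#' n_samples(rec)
#' @export
recording <- function(data, fs, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (ncol(data) < 2L)
    stop("`data` must have at least 2 samples per channel")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` length must equal the number of channels")
  rownames(data) <- channel_names
  structure(list(data = data, fs = as.numeric(fs),
                 channel_names = as.character(channel_names)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec an `eeg_recording`.
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Collection of EEG trials with affect ratings and class labels
#'
#' @param trials list of [recording()] objects sharing channel geometry.
#' @param arousal,valence per-trial self-assessment ratings on the 0-9 scale,
#'   or `NA` when unknown.
#' @param label per-trial class, one of `"calm"`, `"stress"`, `"unlabeled"`.
#'   When omitted it is derived from the ratings with [label_trial()].
#' @return an object of class `trial_set`.
#' @seealso [generate_synthetic_dataset()], [split_trials()]
#' @export
trial_set <- function(trials, arousal = NULL, valence = NULL, label = NULL) {
  if (!is.list(trials) || length(trials) == 0L)
    stop("`trials` must be a non-empty list of recordings")
  ok <- vapply(trials, inherits, logical(1), "eeg_recording")
  if (!all(ok)) stop("every element of `trials` must be an `eeg_recording`")
  n <- length(trials)
  if (is.null(arousal)) arousal <- rep(NA_real_, n)
  if (is.null(valence)) valence <- rep(NA_real_, n)
  if (length(arousal) != n || length(valence) != n)
    stop("`arousal` and `valence` must have one entry per trial")
  if (is.null(label)) {
    label <- ifelse(is.na(arousal) | is.na(valence), "unlabeled",
                    mapply(label_trial, arousal, valence))
  }
  label <- as.character(label)
  if (length(label) != n) stop("`label` must have one entry per trial")
  bad <- setdiff(unique(label), c("calm", "stress", "unlabeled"))
  if (length(bad))
    stop("labels must be 'calm', 'stress' or 'unlabeled'; got: ",
         paste(bad, collapse = ", "))
  structure(list(trials = trials, arousal = as.numeric(arousal),
                 valence = as.numeric(valence), label = label),
            class = "trial_set")
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' @export
`[.trial_set` <- function(x, i) {
  trial_set(x$trials[i], x$arousal[i], x$valence[i], x$label[i])
}

#' @export
print.trial_set <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("calm", "stress", "unlabeled")))
  cat(sprintf("<trial_set> %d trials (%d calm, %d stress, %d unlabeled)\n",
              length(x$trials), tab[["calm"]], tab[["stress"]],
              tab[["unlabeled"]]))
  if (length(x$trials))
    cat(sprintf("  %d channels x %d samples @ %g Hz\n",
                n_channels(x$trials[[1]]), n_samples(x$trials[[1]]),
                x$trials[[1]]$fs))
  invisible(x)
}

#' Numeric class codes used by the classifier (calm = 0, stress = 1)
#' @param label character vector of `"calm"`/`"stress"` labels.
#' @return integer vector of 0/1 codes.
#' @export
class_code <- function(label) {
  if (any(!label %in% c("calm", "stress")))
    stop("class_code() is defined for 'calm'/'stress' labels only")
  as.integer(label == "stress")
}
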