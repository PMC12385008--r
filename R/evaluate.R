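#' Confusion counts for a binary stress/calm prediction
#'
#' Stress is the positive class: TP = stress predicted stress,
#' TN = calm predicted calm, FP = calm predicted stress, FN = stress
#' predicted calm.
#'
#' @param truth true labels (`"calm"`/`"stress"` or 0/1 codes).
#' @param predicted predicted labels in the same encoding.
#' @return named integer vector `c(tp, fn, fp, tn)`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (is.character(truth)) truth <- class_code(truth)
  if (is.character(predicted)) predicted <- class_code(predicted)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!all(c(truth, predicted) %in% c(0L, 1L)))
    stop("labels must be calm/stress (codes 0/1)")
  c(tp = sum(truth == 1 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0))
}

#' Classification metrics from confusion counts
#'
#' Computes recall (sensitivity) `TP/(TP+FN)`, selectivity (specificity)
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, negative predictive value
#' `TN/(TN+FN)`, accuracy `(TP+TN)/(TP+TN+FP+FN)` and
#' F1 `2*precision*recall/(precision+recall)`. A zero denominator yields
#' `NaN` with a warning naming the metric; all-zero counts are an error.
#'
#' @param counts named vector with `tp`, `fn`, `fp`, `tn` (order-free), or
#'   four numbers in that order.
#' @return named numeric vector of the six metrics.
#' @export
compute_metrics <- function(counts) {
  if (!is.null(names(counts)) && all(c("tp", "fn", "fp", "tn") %in%
                                     names(counts))) {
    tp <- counts[["tp"]]; fn <- counts[["fn"]]
    fp <- counts[["fp"]]; tn <- counts[["tn"]]
  } else if (length(counts) == 4) {
    tp <- counts[[1]]; fn <- counts[[2]]; fp <- counts[[3]]; tn <- counts[[4]]
  } else stop("counts must supply tp, fn, fp, tn")
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  if (tp + fn + fp + tn == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; returning NaN")
      return(NaN)
    }
    num / den
  }
  recall <- safe_div(tp, tp + fn, "recall")
  selectivity <- safe_div(tn, tn + fp, "selectivity")
  precision <- safe_div(tp, tp + fp, "precision")
  npv <- safe_div(tn, tn + fn, "negative predictive value")
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- if (is.nan(precision) || is.nan(recall) ||
            precision + recall == 0) {
    warning("zero denominator for F1; returning NaN")
    NaN
  } else 2 * precision * recall / (precision + recall)
  c(recall = recall, selectivity = selectivity, precision = precision,
    npv = npv, accuracy = accuracy, f1 = f1)
}

stratified_indices <- function(y, test_frac) {
  if (test_frac <= 0 || test_frac >= 1)
    stop("test_frac must lie in (0, 1)")
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("both classes must be present for a stratified split")
  test <- integer(0)
  for (cl in classes) {
    idx <- which(y == cl)
    n_test <- max(1L, floor(test_frac * length(idx)))
    if (n_test >= length(idx))
      stop("class ", cl, " has too few members for the requested split")
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Stratified train/test split of a trial set
#'
#' Draws `floor(test_frac * n_class)` (at least 1) test trials per class;
#' the default 0.3 gives the usual 70:30 train/test split. Errors if a
#' class would lose all its members or is absent. Deterministic given
#' `seed`.
#'
#' @param trials a `trial_set` with labels.
#' @param test_frac test fraction per class.
#' @param seed RNG seed.
#' @return list with `train` and `test` trial sets plus the index vectors.
#' @export
split_trials <- function(trials, test_frac = 0.3, seed = 1L) {
  stopifnot(inherits(trials, "trial_set"))
  y <- class_code(trials$label)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sp <- stratified_indices(y, test_frac)
  list(train = trials[sp$train], test = trials[sp$test],
       train_idx = sp$train, test_idx = sp$test)
}

#' Run the full stress-detection experiment on a trial set
#'
#' Pipeline: preprocessing (band-pass + wavelet-packet denoising), channel
#' selection by improved crow search, feature extraction on the selected
#' channels, stratified train/test split, optional hyperparameter tuning,
#' classifier training, prediction and metric computation. Each stage
#' failure is reported with the stage name. Deterministic given `seed`.
#'
#' @param trials labeled `trial_set`.
#' @param k number of channels to select.
#' @param test_frac test fraction per class.
#' @param config optional [bddnet_config()]; defaults to one sized for
#'   `k` selected channels with the given `epochs`.
#' @param epochs training epochs when `config` is not supplied.
#' @param denoise a [denoise_config()].
#' @param icsa an [icsa_params()] (field `k` is overwritten with `k`).
#' @param tune `FALSE`, or an [eoa_params()] to tune learning rate, decay
#'   and momentum before the final fit.
#' @param seed master seed; stage seeds are derived from it.
#' @return list with `channels`, `params` (fitted classifier), `counts`,
#'   `metrics`, `predictions`, `truth`, `split`, and `tuning` (when
#'   enabled).
#' @export
run_experiment <- function(trials, k = 4, test_frac = 0.3, config = NULL,
                           epochs = 30, denoise = denoise_config(),
                           icsa = icsa_params(k = k), tune = FALSE,
                           seed = 1L) {
  stopifnot(inherits(trials, "trial_set"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  clean <- stage("preprocess", preprocess_trials(trials, denoise))
  icsa$k <- as.integer(k)
  icsa$seed <- as.integer(seed)
  sel <- stage("channel selection", select_channels(clean, icsa))
  feats <- stage("feature extraction",
                 extract_features(clean, channels = sel$channels))
  y <- class_code(attr(feats, "label"))
  sp <- stage("split", {
    idx <- {
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed + 1L)
      stratified_indices(y, test_frac)
    }
    idx
  })
  if (is.null(config)) {
    config <- bddnet_config(n_features = ncol(feats), epochs = epochs,
                            seed = seed + 2L)
  }
  if (config$n_features != ncol(feats))
    stop("stage 'configuration' failed: config$n_features does not match ",
         "the extracted feature dimension ", ncol(feats))
  tuning <- NULL
  if (!isFALSE(tune)) {
    stopifnot(inherits(tune, "eoa_params"))
    tuning <- stage("tuning",
                    tune_hyperparameters(feats[sp$train, , drop = FALSE],
                                         y[sp$train], config, tune))
    config <- tuning$config
  }
  fit <- stage("training",
               bddnet_train(feats[sp$train, , drop = FALSE], y[sp$train],
                            config))
  pred <- stage("prediction",
                bddnet_predict(fit, feats[sp$test, , drop = FALSE]))
  counts <- confusion_counts(y[sp$test], pred$code)
  metrics <- compute_metrics(counts)
  list(channels = sel$channels, selection = sel, params = fit,
       counts = counts, metrics = metrics,
       predictions = pred$code, truth = y[sp$test],
       split = sp, tuning = tuning, config = config)
}
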