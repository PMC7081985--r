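# Band-power decoding of call type. Features: per randomization trial, the
# band-mean log10 power at each spectrogram time point within the pre-
# (or post-) vocalization window. Classifier: binary soft-margin SVM with
# Gaussian (RBF) kernel, no feature standardization, trained once (no
# hyperparameter search); box constraint 1, kernel scale sqrt(n_features)
# (gamma = 1 / n_features).

#' Band-power feature set from randomization-trial spectrograms
#'
#' @param rand_set a [build_randomization_trials()] output.
#' @param band band name or `c(low, high)` Hz.
#' @param window `"pre"` (`[-0.5, 0)` s) or `"post"` (`(0, 0.5]` s), or a
#'   numeric `c(lo, hi)` window (s rel. onset) applied to spectrogram bin
#'   centers.
#' @param channel channel index within the randomization set.
#' @param win_s,step_s,tw,k multitaper parameters.
#' @param log_power use log10 power features (default; linear with FALSE).
#' @return list of class `feature_set`: `x` (trials x features matrix),
#'   `y` (condition label, one per trial), `band`, `window`, `time`
#'   (feature time points).
#' @export
band_power_features <- function(rand_set, band, window = "pre", channel = 1,
                                win_s = 0.25, step_s = 0.01, tw = 2, k = 3,
                                log_power = TRUE) {
  stopifnot(inherits(rand_set, "randomization_set"))
  sp <- randomization_log_spectrograms(rand_set, channel, win_s, step_s,
                                       tw, k)
  fidx <- band_bins(sp$freq, band)
  if (is.character(window)) {
    window <- switch(match.arg(window, c("pre", "post")),
                     pre = c(-0.5, 0), post = c(0, 0.5))
  }
  tidx <- which(sp$time >= window[1] & sp$time < window[2])
  if (length(tidx) == 0L) stop("window contains no spectrogram time bins")
  lp <- sp$logp
  if (!log_power) lp <- 10^lp
  # mean over band frequencies at each kept time point
  x <- vapply(tidx, function(ti) {
    rowMeans(lp[, ti, fidx, drop = FALSE], dims = 1)
  }, numeric(dim(lp)[1]))
  structure(list(x = as.matrix(x),
                 y = factor(rep(rand_set$condition, dim(lp)[1])),
                 band = band, window = window, time = sp$time[tidx],
                 log_power = log_power),
            class = "feature_set")
}

#' Combine feature sets of the two conditions
#'
#' @param fa,fb `feature_set` objects for the two conditions (equal
#'   feature grids).
#' @return a `feature_set` with stacked rows and a two-level label factor.
#' @export
combine_features <- function(fa, fb) {
  stopifnot(inherits(fa, "feature_set"), inherits(fb, "feature_set"),
            ncol(fa$x) == ncol(fb$x))
  structure(list(x = rbind(fa$x, fb$x),
                 y = factor(c(as.character(fa$y), as.character(fb$y))),
                 band = fa$band, window = fa$window, time = fa$time,
                 log_power = fa$log_power),
            class = "feature_set")
}

#' Train the RBF-kernel SVM decoder
#'
#' Single training, no standardization, cost 1, `gamma = 1 / n_features`
#' (kernel scale `sqrt(n_features)`).
#'
#' @param train a `feature_set` containing both classes.
#' @param cost box constraint.
#' @param gamma RBF kernel coefficient (default `1 / ncol(x)`).
#' @return fitted `e1071::svm` model.
#' @export
train_decoder <- function(train, cost = 1, gamma = NULL) {
  stopifnot(inherits(train, "feature_set"))
  if (nlevels(droplevels(train$y)) != 2) {
    stop("training set must contain exactly two classes")
  }
  e1071::svm(x = train$x, y = droplevels(train$y), kernel = "radial",
             cost = cost, gamma = gamma %||% (1 / ncol(train$x)),
             scale = FALSE)
}

#' Held-out decoding accuracy (percent)
#'
#' @param model a fitted decoder.
#' @param test a `feature_set` disjoint from training.
#' @return percent correct in \[0, 100\].
#' @export
evaluate_decoder <- function(model, test) {
  stopifnot(inherits(test, "feature_set"))
  pred <- stats::predict(model, test$x)
  mean(as.character(pred) == as.character(test$y)) * 100
}

#' Stratified 10-fold cross-validation error
#'
#' @param train a `feature_set` with both classes, at least `folds` trials
#'   per class.
#' @param folds number of folds.
#' @param rng_seed integer seed for the fold assignment.
#' @param cost,gamma passed to [train_decoder()].
#' @return misclassification rate in \[0, 1\].
#' @export
crossvalidate_decoder <- function(train, folds = 10, rng_seed = 1,
                                  cost = 1, gamma = NULL) {
  stopifnot(inherits(train, "feature_set"))
  y <- droplevels(train$y)
  if (min(table(y)) < folds) stop("need at least `folds` trials per class")
  fold_id <- integer(length(y))
  with_seed(rng_seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  errs <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    m <- e1071::svm(x = train$x[tr, , drop = FALSE], y = y[tr],
                    kernel = "radial", cost = cost,
                    gamma = gamma %||% (1 / ncol(train$x)), scale = FALSE)
    pred <- stats::predict(m, train$x[!tr, , drop = FALSE])
    mean(as.character(pred) != as.character(y[!tr]))
  }, numeric(1))
  mean(errs)
}

#' Shuffled-label control
#'
#' Training labels are permuted uniformly at random (training set only);
#' the model is trained and evaluated exactly as the true decoder. With
#' unfaithful training information, accuracy drops to chance (about 50%).
#'
#' @param train,test `feature_set` objects.
#' @param rng_seed integer seed for the permutation.
#' @param permutation optional explicit permutation of the training rows
#'   (for the identity-permutation contract).
#' @param cost,gamma passed to [train_decoder()].
#' @return held-out accuracy (percent) of the shuffled-label model.
#' @export
shuffled_label_control <- function(train, test, rng_seed = 1,
                                   permutation = NULL, cost = 1,
                                   gamma = NULL) {
  stopifnot(inherits(train, "feature_set"))
  perm <- permutation %||%
    with_seed(rng_seed, sample.int(length(train$y)))
  shuffled <- train
  shuffled$y <- train$y[perm]
  model <- train_decoder(shuffled, cost = cost, gamma = gamma)
  evaluate_decoder(model, test)
}

#' Accuracy on contaminated-post trials
#'
#' Applies a decoder trained on clean pre-vocalization features to features
#' from trials whose post-vocalization window contained other sounds.
#'
#' @param model decoder trained on clean trials.
#' @param contaminated `feature_set` built from contaminated_post trials
#'   (may have zero rows: skipped with a warning, returns `NA`).
#' @return percent correct, or `NA` when the set is empty.
#' @export
predict_contaminated <- function(model, contaminated) {
  stopifnot(inherits(contaminated, "feature_set"))
  if (nrow(contaminated$x) == 0L) {
    warning("empty contaminated set: skipped")
    return(NA_real_)
  }
  evaluate_decoder(model, contaminated)
}
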