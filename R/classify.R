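#' Classifier specification
#'
#' Describes one of the four score-based classifiers evaluated by the
#' replicated split protocol, with its hyperparameters.
#'
#' Defaults: SVM uses a radial (RBF) kernel `k(x1, x2) = exp(-gamma
#' ||x1 - x2||^2)` with cost `C = 1` and `gamma = 1/K` scaled by the
#' feature variance (set `gamma` explicitly to use the `1/(2 sigma^2)`
#' form); RF grows 500 bagged trees with `floor(sqrt(K))` candidate
#' features per split; the elastic-net multinomial GLM uses mixing
#' `alpha = 0.5` with penalty strength chosen by stratified 5-fold
#' cross-validation on the training set only; Gaussian naive Bayes has no
#' tuning parameters (a variance floor of `1e-9` guards constant features).
#'
#' @param name One of `"NB"`, `"SVM"`, `"RF"`, `"GLM"`.
#' @param ... Hyperparameter overrides: `cost`, `gamma` (SVM); `n_trees`,
#'   `mtry` (RF); `alpha`, `n_folds` (GLM).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name = c("NB", "SVM", "RF", "GLM"), ...) {
  name <- match.arg(name)
  hp <- list(...)
  defaults <- switch(name,
    NB = list(var_floor = 1e-9),
    SVM = list(cost = 1, gamma = NULL),
    RF = list(n_trees = 500, mtry = NULL),
    GLM = list(alpha = 0.5, n_folds = 5)
  )
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown) > 0) {
    fm_abort(paste0("Unknown hyperparameters for ", name, ": ",
                    paste(unknown, collapse = ", ")), "fm_usage_error")
  }
  hp <- utils::modifyList(defaults, hp)
  if (name == "SVM" && (hp$cost <= 0 || (!is.null(hp$gamma) && hp$gamma <= 0))) {
    fm_abort("SVM cost and gamma must be positive.", "fm_validation_error")
  }
  if (name == "RF" && hp$n_trees < 1) fm_abort("RF needs at least 1 tree.", "fm_validation_error")
  if (name == "GLM" && (hp$alpha < 0 || hp$alpha > 1)) {
    fm_abort("GLM mixing alpha must lie in [0, 1].", "fm_validation_error")
  }
  structure(list(name = name, hyperparameters = hp), class = "classifier_spec")
}

#' The four classifiers of the evaluation protocol
#'
#' @return List of [classifier_spec()] objects: NB, SVM, RF, GLM.
#' @export
default_classifiers <- function() {
  lapply(c("NB", "SVM", "RF", "GLM"), classifier_spec)
}

#' Stratified train/test split
#'
#' Per class `c` with `n_c` members the training count is
#' `round(train_fraction * n_c)` (round-half-to-even), clamped to
#' `[1, n_c - 1]` so both sides always see every class; members are drawn
#' uniformly at random from the seeded generator.
#'
#' @param labels Class labels of all observations.
#' @param train_fraction Training fraction in `(0, 1)` (default 0.7).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_stratified <- function(labels, train_fraction = 0.7, seed) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    fm_abort("train_fraction must lie strictly between 0 and 1.", "fm_usage_error")
  }
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    fm_abort(paste0("Classes too small to split (need >= 2 members): ",
                    paste(names(sizes)[sizes < 2], collapse = ", ")), "fm_validation_error")
  }
  train <- integer(0)
  withr::local_seed(seed)
  for (cl in names(sizes)) {
    idx <- which(labels == cl)
    n_train <- min(max(round(train_fraction * length(idx)), 1L), length(idx) - 1L)
    train <- c(train, sort(sample(idx, n_train)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# ---- Gaussian naive Bayes (posterior by Bayes' theorem with independent
# Gaussian class-conditional densities) ------------------------------------

nb_train <- function(features, labels, var_floor = 1e-9) {
  classes <- sort(unique(labels))
  stats_by_class <- lapply(classes, function(cl) {
    f <- features[labels == cl, , drop = FALSE]
    v <- apply(f, 2, stats::var)
    if (any(v < var_floor)) {
      inform("Constant feature in a class: applying naive Bayes variance floor.")
      v <- pmax(v, var_floor)
    }
    list(mean = colMeans(f), var = v, prior = nrow(f) / nrow(features))
  })
  names(stats_by_class) <- classes
  structure(list(classes = classes, stats = stats_by_class), class = "fm_nb")
}

# posterior P(c | x) = P(c) prod_j N(x_j; mu_cj, s2_cj) / evidence
nb_posterior <- function(model, features) {
  features <- as.matrix(features)
  logp <- vapply(model$classes, function(cl) {
    s <- model$stats[[cl]]
    lp <- rowSums(stats::dnorm(features,
                               mean = matrix(s$mean, nrow(features), ncol(features), byrow = TRUE),
                               sd = matrix(sqrt(s$var), nrow(features), ncol(features), byrow = TRUE),
                               log = TRUE))
    lp + log(s$prior)
  }, numeric(nrow(features)))
  logp <- matrix(logp, nrow = nrow(features))
  colnames(logp) <- model$classes
  mx <- apply(logp, 1, max)
  post <- exp(logp - mx)
  post / rowSums(post)
}

# ---- fitting and prediction ------------------------------------------------

#' Train one classifier on a score table
#'
#' Dispatches on the [classifier_spec()]: Gaussian naive Bayes is computed
#' in-package from the Bayes posterior formula; the radial-kernel SVM
#' (one-vs-one voting), the bagged random forest and the elastic-net
#' multinomial GLM are delegated to e1071, randomForest and glmnet. The GLM
#' penalty strength is selected by stratified cross-validation on the
#' training data only.
#'
#' @param spec A [classifier_spec()].
#' @param data Tibble with a `label` column and numeric feature columns
#'   (typically the first three component scores).
#' @return A fitted `shape_classifier` usable with [predict()].
#' @export
train_classifier <- function(spec, data) {
  if (!inherits(spec, "classifier_spec")) fm_abort("spec must be a classifier_spec.", "fm_usage_error")
  feats <- as.matrix(data[, vapply(data, is.numeric, logical(1)), drop = FALSE])
  labels <- as.character(data$label)
  if (length(unique(labels)) < 2) {
    fm_abort("Training data contains a single class.", "fm_validation_error")
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    NB = nb_train(feats, labels, var_floor = hp$var_floor),
    SVM = {
      gamma <- hp$gamma %||% (1 / (ncol(feats) * mean(apply(feats, 2, stats::var))))
      e1071::svm(x = feats, y = factor(labels), kernel = "radial",
                 cost = hp$cost, gamma = gamma, scale = FALSE)
    },
    RF = {
      mtry <- hp$mtry %||% max(1, floor(sqrt(ncol(feats))))
      randomForest::randomForest(x = feats, y = factor(labels),
                                 ntree = hp$n_trees, mtry = mtry)
    },
    GLM = {
      foldid <- stratified_folds(labels, hp$n_folds)
      # glmnet warns about per-fold class counts at the sample sizes this
      # protocol routinely uses; the CV-selected penalty is still valid
      withCallingHandlers(
        glmnet::cv.glmnet(feats, factor(labels), family = "multinomial",
                          alpha = hp$alpha, foldid = foldid),
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
        }
      )
    }
  )
  structure(list(name = spec$name, fit = fit, feature_names = colnames(feats)),
            class = "shape_classifier")
}

# deterministic stratified fold assignment from the current RNG stream
stratified_folds <- function(labels, n_folds) {
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' @export
predict.shape_classifier <- function(object, newdata, ...) {
  feats <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, vapply(newdata, is.numeric, logical(1)), drop = FALSE])
  } else {
    as.matrix(newdata)
  }
  switch(object$name,
    NB = {
      post <- nb_posterior(object$fit, feats)
      object$fit$classes[max.col(post, ties.method = "first")]
    },
    SVM = as.character(stats::predict(object$fit, feats)),
    RF = as.character(stats::predict(object$fit, feats)),
    GLM = as.character(stats::predict(object$fit, feats, s = "lambda.min", type = "class"))
  )
}

#' Replicated stratified split evaluation
#'
#' The accuracy protocol: the score table is split into stratified
#' training and test samples (default 70:30); every classifier is fitted on
#' the same training sample and scored by plain proportion correct on the
#' test sample; the split is redrawn `reps` times (default 20) with seeds
#' `seed0 + 1, ..., seed0 + reps`, and per-classifier mean accuracy and
#' sample standard deviation (divisor `reps - 1`) are reported. All
#' randomness (splits, forest bootstraps, CV folds) flows from the per-rep
#' seed, so a fixed `seed0` reproduces the report bit-for-bit.
#'
#' @param data Tibble with `label` and numeric score columns.
#' @param specs List of [classifier_spec()] (default all four).
#' @param reps Number of split replicates (default 20, minimum 2).
#' @param train_fraction Training fraction (default 0.7).
#' @param seed0 Master seed for the protocol.
#' @return A `protocol_eval` object; `tidy()` gives per-classifier
#'   `mean_accuracy` and `sd_accuracy`, `$replicates` the per-rep
#'   accuracies and seeds.
#' @export
evaluate_protocol <- function(data, specs = default_classifiers(), reps = 20,
                              train_fraction = 0.7, seed0 = 1) {
  if (reps < 2) fm_abort("reps must be at least 2.", "fm_usage_error")
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  labels <- as.character(data$label)
  rows <- purrr::map_dfr(seq_len(reps), function(r) {
    seed_r <- child_seed(seed0, r)
    split <- split_stratified(labels, train_fraction, seed = seed_r)
    if (length(unique(labels[split$train])) < length(unique(labels))) {
      fm_abort(paste0("Training split lost a class at seed ", seed_r, "."),
               "fm_validation_error")
    }
    train <- data[split$train, ]
    test <- data[split$test, ]
    purrr::map_dfr(specs, function(spec) {
      withr::local_seed(child_seed(seed_r, match(spec$name, c("NB", "SVM", "RF", "GLM"))))
      model <- train_classifier(spec, train)
      pred <- predict(model, test)
      tibble(classifier = spec$name, rep = r, seed = seed_r,
             accuracy = mean(pred == test$label))
    })
  })
  structure(
    list(replicates = rows, reps = reps, train_fraction = train_fraction, seed0 = seed0),
    class = "protocol_eval"
  )
}

#' @describeIn evaluate_protocol Per-classifier mean and standard deviation
#'   of test accuracy over the replicates.
#' @param x,object A `protocol_eval`.
#' @param ... Unused.
#' @export
tidy.protocol_eval <- function(x, ...) {
  x$replicates %>%
    dplyr::group_by(classifier = factor(.data$classifier, levels = unique(.data$classifier))) %>%
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     .groups = "drop")
}

#' @describeIn evaluate_protocol One-row summary of the protocol settings.
#' @export
glance.protocol_eval <- function(x, ...) {
  tibble(reps = x$reps, train_fraction = x$train_fraction, seed0 = x$seed0,
         n_classifiers = length(unique(x$replicates$classifier)))
}

#' @export
print.protocol_eval <- function(x, ...) {
  cat("Replicated split protocol (", x$reps, " x ",
      round(100 * x$train_fraction), ":", round(100 * (1 - x$train_fraction)), ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn evaluate_protocol Box plot of replicate accuracies per
#'   classifier.
#' @export
autoplot.protocol_eval <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = .data$classifier, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "test accuracy")
}
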