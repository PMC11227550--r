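test_that("stratified splits follow the rounding rule and are deterministic", {
  labels <- rep(c("a", "b", "c"), each = 30)
  sp <- split_stratified(labels, 0.7, seed = 151)
  train_counts <- table(labels[sp$train])
  expect_true(all(train_counts == 21))
  expect_true(all(table(labels[sp$test]) == 9))
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)

  # the study's class sizes: round(0.7 * c(29, 30, 30)) clamped
  labels2 <- rep(c("a", "b", "c"), times = c(29, 30, 30))
  sp2 <- split_stratified(labels2, 0.7, seed = 152)
  expect_equal(as.integer(table(labels2[sp2$train])), c(20, 21, 21))

  expect_identical(split_stratified(labels, 0.7, seed = 7),
                   split_stratified(labels, 0.7, seed = 7))
  expect_error(split_stratified(c("a", "a", "b"), 0.7, seed = 1),
               class = "fm_validation_error")
  expect_error(split_stratified(labels, 1.2, seed = 1), class = "fm_usage_error")
})

test_that("naive Bayes posteriors are normalised and symmetric", {
  train <- tibble::tibble(
    label = rep(c("a", "b"), each = 4),
    PC1 = c(-1.2, -0.8, -1.1, -0.9, 0.8, 1.2, 0.9, 1.1),
    PC2 = rep(c(0.5, -0.5), 4),
    PC3 = rep(c(0.1, -0.1), 4)
  )
  model <- train_classifier(classifier_spec("NB"), train)
  nb <- model$fit
  # symmetric construction: equal priors, equal variances, query midway
  post <- funmorph:::nb_posterior(nb, matrix(c(0, 0, 0), 1))
  expect_equal(as.numeric(post), c(0.5, 0.5), tolerance = 1e-12)
  # normalisation on arbitrary points
  pts <- withr::with_seed(153, matrix(stats::rnorm(30), 10, 3))
  posts <- funmorph:::nb_posterior(nb, pts)
  expect_equal(rowSums(posts), rep(1, 10), tolerance = 1e-12)
})

test_that("the two-class 1D posterior matches the hand-evaluated Bayes formula", {
  feats <- matrix(c(-0.5, 0.5, -0.1, 0.1, 1.5, 2.5, 1.9, 2.1), ncol = 1)
  labels <- rep(c("a", "b"), each = 4)
  model <- funmorph:::nb_train(feats, labels)
  # force the textbook setting: priors 1/2, unit variances, means 0 and 2
  model$stats$a$mean <- 0; model$stats$b$mean <- 2
  model$stats$a$var <- 1; model$stats$b$var <- 1
  model$stats$a$prior <- 0.5; model$stats$b$prior <- 0.5
  post <- funmorph:::nb_posterior(model, matrix(0))
  oracle <- 0.5 * stats::dnorm(0, 0, 1) /
    (0.5 * stats::dnorm(0, 0, 1) + 0.5 * stats::dnorm(0, 2, 1))
  expect_equal(post[1, "a"], c(a = oracle), tolerance = 1e-12)
})

test_that("in-package naive Bayes agrees with an independent implementation", {
  df <- score_clusters(list(a = c(0, 0, 0), b = c(2, 1, 0), c = c(-1, 2, 1)),
                       n_per_class = 15, seed = 154)
  feats <- as.matrix(df[, c("PC1", "PC2", "PC3")])
  ours <- funmorph:::nb_train(feats, df$label)
  theirs <- e1071::naiveBayes(feats, factor(df$label))
  pts <- withr::with_seed(155, matrix(stats::rnorm(24), 8, 3,
                                      dimnames = list(NULL, colnames(feats))))
  p1 <- funmorph:::nb_posterior(ours, pts)
  p2 <- stats::predict(theirs, as.data.frame(pts), type = "raw")
  expect_equal(unname(p1), unname(p2), tolerance = 1e-6)
})

test_that("well-separated clusters are classified nearly perfectly by all four models", {
  df <- score_clusters(list(a = c(0, 0, 0), b = c(20, 0, 0), c = c(0, 20, 0)),
                       n_per_class = 30, sd = 1, seed = 156)
  res <- evaluate_protocol(df, reps = 5, seed0 = 157)
  acc <- tidy(res)
  expect_equal(nrow(acc), 4)
  expect_true(all(acc$mean_accuracy >= 0.95))
})

test_that("permuted labels drop every classifier to chance level", {
  df <- score_clusters(list(a = c(0, 0, 0), b = c(20, 0, 0), c = c(0, 20, 0)),
                       n_per_class = 30, sd = 1, seed = 158)
  df$label <- withr::with_seed(159, sample(df$label))
  res <- evaluate_protocol(df, reps = 10, seed0 = 160)
  acc <- tidy(res)
  expect_true(all(abs(acc$mean_accuracy - 1 / 3) <= 0.20))
})

test_that("the protocol report is reproducible and internally consistent", {
  df <- score_clusters(list(a = c(0, 0, 0), b = c(3, 0, 0), c = c(0, 3, 0)),
                       n_per_class = 12, seed = 161)
  r1 <- evaluate_protocol(df, reps = 3, seed0 = 162)
  r2 <- evaluate_protocol(df, reps = 3, seed0 = 162)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(tidy(r1), tidy(r2))

  acc <- tidy(r1)
  expect_true(all(acc$mean_accuracy >= 0 & acc$mean_accuracy <= 1))
  for (cl in acc$classifier) {
    reps <- r1$replicates$accuracy[r1$replicates$classifier == cl]
    expect_equal(acc$sd_accuracy[acc$classifier == cl], stats::sd(reps), tolerance = 1e-12)
    expect_gte(acc$mean_accuracy[acc$classifier == cl], min(reps))
    expect_lte(acc$mean_accuracy[acc$classifier == cl], max(reps))
  }
  expect_error(evaluate_protocol(df, reps = 1, seed0 = 1), class = "fm_usage_error")
})

test_that("classifier specifications validate their hyperparameters", {
  expect_error(classifier_spec("SVM", cost = -1), class = "fm_validation_error")
  expect_error(classifier_spec("GLM", alpha = 2), class = "fm_validation_error")
  expect_error(classifier_spec("RF", n_trees = 0), class = "fm_validation_error")
  expect_error(classifier_spec("NB", gamma = 1), class = "fm_usage_error")
  single <- tibble::tibble(label = rep("a", 5), PC1 = rnorm(5), PC2 = rnorm(5), PC3 = rnorm(5))
  expect_error(train_classifier(classifier_spec("NB"), single), class = "fm_validation_error")
})
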