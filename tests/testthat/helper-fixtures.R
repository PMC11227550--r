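# Fixture builders shared across the test files. Everything is generated in
# code under explicit seeds; no data files are read.

# a landmark tibble of n random configurations with N landmarks
random_landmarks <- function(n, n_lm, seed = 1, labels = NULL) {
  withr::with_seed(seed, {
    tibble::tibble(
      specimen_id = rep(sprintf("s%02d", seq_len(n)), each = n_lm),
      label = rep(labels %||% rep("a", n), each = n_lm),
      view = "test",
      landmark = rep(seq_len(n_lm), times = n),
      type = "I",
      x = stats::rnorm(n * n_lm),
      y = stats::rnorm(n * n_lm),
      scale = NA_real_
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply a similarity transform to every specimen of a landmark tibble
apply_similarity <- function(data, angle, scale, translation) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- as.matrix(data[, c("x", "y")]) %*% t(rot) * scale
  data$x <- xy[, 1] + translation[1]
  data$y <- xy[, 2] + translation[2]
  data
}

# one triangle as a landmark tibble
triangle_tbl <- function(id = "t1", coords = rbind(c(0, 0), c(1, 0), c(0.3, 0.8))) {
  tibble::tibble(
    specimen_id = id, label = "a", view = "test",
    landmark = seq_len(nrow(coords)), type = "I",
    x = coords[, 1], y = coords[, 2], scale = NA_real_
  )
}

# centre a configuration matrix and scale to unit centroid size
normalise_mat <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# closed-form pairwise Procrustes distance oracle for centred unit-size 2D
# configurations: the optimal proper rotation maximises
# (M11 + M22) cos(theta) + (M21 - M12) sin(theta) with M = b' a
pairwise_pd_oracle <- function(a, b) {
  m <- crossprod(b, a)
  best <- sqrt((m[1, 1] + m[2, 2])^2 + (m[2, 1] - m[1, 2])^2)
  sqrt(max(sum(a^2) + sum(b^2) - 2 * best, 0))
}

# quadrature-weighted PCA of concatenated element matrices: independent
# oracle for the multivariate functional decomposition under full retention
concat_weighted_pca <- function(elements, weights) {
  blocks <- purrr::map2(elements, weights, function(v, w) {
    xc <- sweep(v, 2, colMeans(v))
    sweep(xc, 2, sqrt(w), `*`)
  })
  y <- do.call(cbind, blocks)
  sv <- svd(y)
  list(eigenvalues = sv$d^2 / (nrow(y) - 1), scores = y %*% sv$v)
}

# tiny fd_set built by hand (bypasses to_functional)
manual_fd <- function(elements, grid, labels = NULL) {
  w <- funmorph:::trapezoid_weights(grid)
  n <- nrow(elements[[1]])
  funmorph:::new_fd_set(
    values = elements,
    grids = stats::setNames(rep(list(grid), length(elements)), names(elements)),
    weights = stats::setNames(rep(list(w), length(elements)), names(elements)),
    specimen_ids = sprintf("s%02d", seq_len(n)),
    labels = labels %||% rep("a", n),
    views = "test"
  )
}

# labelled Gaussian score clusters around given class means (n x K)
score_clusters <- function(means, n_per_class, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    purrr::imap_dfr(means, function(mu, cl) {
      k <- length(mu)
      m <- matrix(stats::rnorm(n_per_class * k, mean = rep(mu, each = n_per_class), sd = sd),
                  n_per_class, k)
      colnames(m) <- paste0("PC", seq_len(k))
      dplyr::bind_cols(tibble::tibble(label = cl), tibble::as_tibble(m))
    })
  })
}
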