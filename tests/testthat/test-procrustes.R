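test_that("centroid size has the closed form, scales linearly, and matches a two-pass oracle", {
  sq <- triangle_tbl("sq", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(centroid_size(sq)$centroid_size, sqrt(2), tolerance = 1e-12)

  d <- random_landmarks(1, 9, seed = 5)
  base <- centroid_size(d)$centroid_size
  d3 <- d; d3$x <- d3$x * 3.7; d3$y <- d3$y * 3.7
  expect_equal(centroid_size(d3)$centroid_size / base, 3.7, tolerance = 1e-12)

  many <- random_landmarks(20, 8, seed = 6)
  got <- centroid_size(many)$centroid_size
  oracle <- vapply(unique(many$specimen_id), function(id) {
    m <- as.matrix(many[many$specimen_id == id, c("x", "y")])
    ctr <- c(mean(m[, 1]), mean(m[, 2]))
    sqrt(sum((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(got, oracle, tolerance = 1e-12)

  degen <- triangle_tbl("d", rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_error(centroid_size(degen), class = "fm_degenerate_error")
})

test_that("GPA removes similarity transforms exactly", {
  tri <- triangle_tbl("a")
  copy <- apply_similarity(triangle_tbl("b"), angle = 37 * pi / 180,
                           scale = 2.5, translation = c(10, -4))
  fit <- gpa(dplyr::bind_rows(tri, copy))
  d <- procrustes_distance(fit$array[1, , ], fit$array[2, , ])
  expect_lt(d, 1e-8)
  expect_true(fit$converged)
})

test_that("pairwise Procrustes distances are invariant to extra similarity transforms of the input", {
  d <- random_landmarks(6, 10, seed = 71)
  fit1 <- gpa(d)
  withr::with_seed(72, {
    d2 <- purrr::map_dfr(unique(d$specimen_id), function(id) {
      apply_similarity(d[d$specimen_id == id, ],
                       angle = stats::runif(1, -pi, pi),
                       scale = stats::runif(1, 0.5, 2),
                       translation = stats::rnorm(2, 0, 20))
    })
  })
  fit2 <- gpa(d2)
  pd <- function(fit) {
    n <- dim(fit$array)[1]
    pairs <- utils::combn(n, 2)
    apply(pairs, 2, function(p) procrustes_distance(fit$array[p[1], , ], fit$array[p[2], , ]))
  }
  expect_equal(pd(fit1), pd(fit2), tolerance = 1e-8)
})

test_that("pairwise superimposition matches the closed-form cross-covariance oracle", {
  a <- normalise_mat(rbind(c(0, 0), c(1, 0), c(0.3, 0.8)))
  b <- normalise_mat(rbind(c(0.1, -0.2), c(1.2, 0.1), c(0.5, 1.1)))
  expect_equal(procrustes_distance(a, b), pairwise_pd_oracle(a, b), tolerance = 1e-10)

  withr::with_seed(81, {
    for (i in 1:10) {
      a <- normalise_mat(matrix(stats::rnorm(16), 8, 2))
      b <- normalise_mat(matrix(stats::rnorm(16), 8, 2))
      expect_equal(procrustes_distance(a, b), pairwise_pd_oracle(a, b), tolerance = 1e-10)
    }
  })
})

test_that("pairwise superimposition agrees with an installed Procrustes routine", {
  skip_if_not_installed("vegan")
  withr::with_seed(82, {
    a <- normalise_mat(matrix(stats::rnorm(20), 10, 2))
    b <- normalise_mat(matrix(stats::rnorm(20), 10, 2))
  })
  v <- vegan::procrustes(a, b, scale = FALSE, symmetric = FALSE)
  # vegan allows reflections; compare only when its optimum is a proper
  # rotation, where the two solutions must coincide
  if (det(v$rotation) > 0) {
    expect_equal(procrustes_distance(a, b), sqrt(v$ss), tolerance = 1e-8)
  } else {
    expect_lte(sqrt(v$ss), procrustes_distance(a, b))
  }
})

test_that("procrustes distance is zero for identical and rotated copies and matches a grid search", {
  a <- normalise_mat(matrix(stats::rnorm(12, sd = 2), 6, 2))
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  th <- 1.234
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_lt(procrustes_distance(a, a %*% t(rot)), 1e-10)

  b <- normalise_mat(matrix(stats::rnorm(12), 6, 2))
  angles <- seq(0, 2 * pi, by = 1e-4)
  dists <- vapply(angles, function(t) {
    r <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
    sqrt(sum((a - b %*% r)^2))
  }, numeric(1))
  expect_equal(procrustes_distance(a, b), min(dists), tolerance = 1e-6)

  expect_error(procrustes_distance(a * 2, b), class = "fm_validation_error")
})

test_that("the consensus is rotation-optimal for every configuration", {
  d <- random_landmarks(8, 7, seed = 91)
  fit <- gpa(d)
  base_obj <- sum(vapply(seq_len(8), function(i) sum((fit$array[i, , ] - fit$consensus)^2),
                         numeric(1)))
  withr::with_seed(92, {
    for (rep in 1:100) {
      i <- sample(8, 1)
      th <- stats::runif(1, -pi, pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      perturbed <- fit$array[i, , ] %*% t(rot)
      obj <- base_obj - sum((fit$array[i, , ] - fit$consensus)^2) +
        sum((perturbed - fit$consensus)^2)
      expect_gte(obj, base_obj - 1e-10)
    }
  })
})

test_that("GPA is idempotent up to a global rotation and its objective is monotone", {
  d <- random_landmarks(6, 9, seed = 93)
  fit <- gpa(d)
  expect_true(all(diff(fit$objective) <= 1e-12))

  refit <- gpa(fit$coords)
  pd <- function(arr) {
    pairs <- utils::combn(dim(arr)[1], 2)
    apply(pairs, 2, function(p) procrustes_distance(arr[p[1], , ], arr[p[2], , ]))
  }
  expect_equal(pd(fit$array), pd(refit$array), tolerance = 1e-9)
})

test_that("aligned configurations satisfy the centring and unit-size invariants", {
  d <- random_landmarks(5, 8, seed = 94)
  fit <- gpa(d)
  for (i in 1:5) {
    m <- fit$array[i, , ]
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_lt(abs(sqrt(sum(m^2)) - 1), 1e-9)
  }
  expect_equal(sqrt(sum(fit$consensus^2)), 1, tolerance = 1e-9)
  expect_error(gpa(d[d$specimen_id == "s01", ]), class = "fm_usage_error")
})
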