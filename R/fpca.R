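#' Univariate functional principal component analysis
#'
#' FPCA of one element (one set of curves sampled on a common grid): rows
#' are centred by the mean function, the quadrature-weighted sample
#' covariance (divisor `n - 1`) is eigen-decomposed via the symmetrised
#' `W^{1/2} K W^{1/2}` route, and the eigenvectors are mapped back by
#' `W^{-1/2}` so the eigenfunctions are orthonormal under the quadrature
#' inner product. Scores are the weighted inner products of the centred
#' curves with the eigenfunctions. The smallest number of components whose
#' cumulative eigenvalue fraction reaches `pve_threshold` is retained.
#'
#' @param values n x N matrix of curve values (rows = specimens).
#' @param grid Strictly increasing sampling points in `[0, 1]`.
#' @param weights Quadrature weights (default: trapezoidal on `grid`).
#' @param pve_threshold Proportion of variance to retain, in `(0, 1]`
#'   (default 0.99).
#' @return An object of class `ufpca`: `mean_function`, `eigenfunctions`
#'   (N x J, columns orthonormal under quadrature), `eigenvalues`
#'   (non-increasing), `scores` (n x J, sample means zero), `n_retained`.
#' @export
ufpca <- function(values, grid, weights = trapezoid_weights(grid), pve_threshold = 0.99) {
  if (pve_threshold <= 0 || pve_threshold > 1) {
    fm_abort("pve_threshold must lie in (0, 1].", "fm_usage_error")
  }
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3) fm_abort("FPCA needs at least 3 curves.", "fm_usage_error")
  if (length(grid) != ncol(values) || length(weights) != ncol(values)) {
    fm_abort("grid/weights length must match the number of sampling points.",
             "fm_validation_error")
  }
  mu <- colMeans(values)
  xc <- sweep(values, 2, mu)
  k_hat <- crossprod(xc) / (n - 1)
  sw <- sqrt(weights)
  m <- t(k_hat * sw) * sw            # W^{1/2} K W^{1/2}, symmetric
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  phi <- eig$vectors / sw            # back-transform: orthonormal under quadrature

  total <- sum(lambda)
  if (total <= .Machine$double.eps * length(lambda)) {
    # zero-variance element: keep a single flagged component
    inform("Zero-variance element: retaining a single component with eigenvalue 0.")
    j <- 1L
  } else {
    frac <- cumsum(lambda) / total
    j <- which(frac >= pve_threshold - 1e-12)[1]
  }
  lambda <- lambda[seq_len(j)]
  phi <- phi[, seq_len(j), drop = FALSE]
  s <- col_signs(phi)
  phi <- sweep(phi, 2, s, `*`)
  scores <- xc %*% (weights * phi)
  structure(
    list(mean_function = mu, eigenfunctions = phi, eigenvalues = lambda,
         scores = scores, n_retained = j, grid = grid, weights = weights,
         all_eigenvalues = pmax(eig$values, 0)),
    class = "ufpca"
  )
}

#' Multivariate functional principal component analysis
#'
#' The score-based MFPCA estimator: (1) a univariate FPCA per element;
#' (2) the univariate scores are collected row-wise per specimen into
#' `Xi` (n x J, J the total retained count) and the block score-covariance
#' `Z = Xi' Xi / (n - 1)` is formed; (3) `Z` is eigen-decomposed into
#' eigenvalues `lambda_j` and orthonormal eigenvectors `v_j`; (4) element
#' `p` of multivariate eigenfunction `j` is the linear combination of the
#' univariate eigenfunctions of element `p` with the corresponding block of
#' `v_j`, and the multivariate scores are `Xi v_j`. With full univariate
#' retention (`pve_threshold = 1`) the estimator is exact: eigenvalues and
#' scores coincide with a quadrature-weighted PCA of the concatenated
#' elements.
#'
#' @param fd An [`fd_set`][to_functional()].
#' @param pve_threshold Proportion-of-variance threshold used for each
#'   univariate FPCA and for the multivariate truncation (default 0.99).
#' @param n_components Optional hard truncation of the multivariate
#'   components (overrides the threshold at the multivariate stage).
#' @return An object of class `mfpca_fit`: `score_matrix` (`Xi`),
#'   `block_cov` (`Z`), `eigenvalues`, `eigenvectors`, per-element
#'   `eigenfunctions`, multivariate `scores` (tibble with `specimen_id`,
#'   `label`, `PC1...`), cumulative `pve`, the per-element `ufpca` fits, and
#'   bookkeeping of block offsets.
#' @export
#' @examples
#' spec <- simulation_spec(n_landmarks = 12, n_per_class = c(6, 6), seed = 2)
#' lm <- average_replicates(simulate_dataset(spec)$replicates)
#' fit <- gpa(lm) |> to_functional() |> mfpca()
#' glance(fit)
mfpca <- function(fd, pve_threshold = 0.99, n_components = NULL) {
  if (!inherits(fd, "fd_set")) fm_abort("mfpca expects an fd_set.", "fm_usage_error")
  n <- length(fd$specimen_ids)
  uni <- purrr::imap(fd$values, function(v, nm) {
    ufpca(v, fd$grids[[nm]], fd$weights[[nm]], pve_threshold = pve_threshold)
  })
  j_p <- vapply(uni, `[[`, integer(1), "n_retained")
  xi <- do.call(cbind, lapply(uni, `[[`, "scores"))
  j_tot <- ncol(xi)
  z_hat <- crossprod(xi) / (n - 1)
  eig <- eigen((z_hat + t(z_hat)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  v <- eig$vectors
  s <- col_signs(v)
  v <- sweep(v, 2, s, `*`)

  keep <- if (!is.null(n_components)) {
    if (n_components > j_tot) {
      fm_abort(paste0("Requested ", n_components, " components but only ", j_tot,
                      " are available."), "fm_usage_error")
    }
    n_components
  } else {
    total <- sum(lambda)
    if (total <= 0) 1L else which(cumsum(lambda) / total >= pve_threshold - 1e-12)[1]
  }

  offsets <- c(0, cumsum(j_p))
  eigenfunctions <- purrr::imap(uni, function(u, nm) {
    p <- match(nm, names(uni))
    block <- offsets[p] + seq_len(j_p[p])
    u$eigenfunctions %*% v[block, seq_len(keep), drop = FALSE]
  })
  scores_mat <- xi %*% v[, seq_len(keep), drop = FALSE]
  colnames(scores_mat) <- paste0("PC", seq_len(keep))
  scores <- dplyr::bind_cols(
    tibble(specimen_id = fd$specimen_ids, label = fd$labels),
    as_tibble(scores_mat)
  )
  nz <- lambda[lambda > 1e-10 * max(lambda, .Machine$double.eps)]
  structure(
    list(score_matrix = xi, block_cov = z_hat,
         eigenvalues = lambda[seq_len(keep)], all_eigenvalues = lambda,
         eigenvectors = v[, seq_len(keep), drop = FALSE],
         eigenfunctions = eigenfunctions,
         scores = scores, scores_matrix = scores_mat,
         pve = cumsum(lambda[seq_len(keep)]) / sum(nz),
         uni = uni, block_sizes = j_p, n = n,
         specimen_ids = fd$specimen_ids, labels = fd$labels),
    class = "mfpca_fit"
  )
}

#' @export
print.mfpca_fit <- function(x, ...) {
  cat("Multivariate functional PCA\n")
  cat("  specimens:  ", x$n, "\n")
  cat("  components: ", length(x$eigenvalues),
      sprintf(" (%.2f%% of variance)", 100 * x$pve[length(x$pve)]), "\n")
  invisible(x)
}

#' @describeIn mfpca Specimen scores, one row per specimen.
#' @param x,object An `mfpca_fit`.
#' @param ... Unused.
#' @export
tidy.mfpca_fit <- function(x, ...) x$scores

#' @describeIn mfpca One-row summary: n, total and retained component
#'   counts, variance explained by the first two components.
#' @export
glance.mfpca_fit <- function(x, ...) {
  tot <- sum(x$all_eigenvalues[x$all_eigenvalues > 1e-10 * max(x$all_eigenvalues, .Machine$double.eps)])
  tibble(
    n = x$n,
    n_components = length(x$eigenvalues),
    n_eigenvalues = sum(x$all_eigenvalues > 1e-10 * max(x$all_eigenvalues, .Machine$double.eps)),
    pve_first2 = sum(x$all_eigenvalues[1:min(2, length(x$all_eigenvalues))]) / tot
  )
}

#' @describeIn mfpca Ordination of the first two component scores.
#' @export
autoplot.mfpca_fit <- function(object, ...) plot_scores(tidy(object), glance(object)$pve_first2)

plot_scores <- function(scores, pve2 = NA) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "class",
                  title = if (is.na(pve2)) "Component scores" else
                    sprintf("Component scores (first two: %.1f%% of variance)", 100 * pve2))
}

#' Classical PCA of Procrustes coordinates
#'
#' The geometric-morphometrics baseline: covariance-form PCA (divisor
#' `n - 1`) of the n x 2N matrix of flattened Procrustes coordinates
#' (`x1, y1, x2, y2, ...`). At most `min(n - 1, 2N)` components are
#' retainable; trailing components with eigenvalues below `1e-10` times the
#' largest are dropped as numerically zero.
#'
#' @param aligned A [gpa()] fit, a landmark tibble of aligned coordinates,
#'   or an n x 2N numeric matrix.
#' @param n_components Optional truncation of the retained components.
#' @return An object of class `shape_pca`: `center`, `loadings`,
#'   `eigenvalues`, `scores` tibble, cumulative `pve`.
#' @export
classical_pca <- function(aligned, n_components = NULL) {
  if (inherits(aligned, "gpa_fit")) {
    arr <- aligned$array
    meta <- aligned$meta
    flat <- cbind_interleave(arr)
  } else if (is.matrix(aligned)) {
    flat <- aligned
    meta <- tibble(specimen_id = rownames(aligned) %||% paste0("spec_", seq_len(nrow(aligned))),
                   label = NA_character_)
  } else {
    arr <- lm_array(aligned)
    meta <- lm_meta(aligned)
    flat <- cbind_interleave(arr)
  }
  n <- nrow(flat)
  if (n < 3) fm_abort("PCA needs at least 3 specimens.", "fm_usage_error")
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  nz <- which(ev > 1e-10 * ev[1])
  keep <- length(nz)
  if (!is.null(n_components)) keep <- min(keep, n_components)
  signs <- col_signs(pc$rotation[, seq_len(keep), drop = FALSE])
  loadings <- sweep(pc$rotation[, seq_len(keep), drop = FALSE], 2, signs, `*`)
  scores_mat <- sweep(pc$x[, seq_len(keep), drop = FALSE], 2, signs, `*`)
  colnames(scores_mat) <- paste0("PC", seq_len(keep))
  scores <- dplyr::bind_cols(
    tibble(specimen_id = meta$specimen_id, label = meta$label),
    as_tibble(scores_mat)
  )
  structure(
    list(center = pc$center, loadings = loadings,
         eigenvalues = ev[seq_len(keep)], all_eigenvalues = ev[nz],
         scores = scores, scores_matrix = scores_mat,
         pve = cumsum(ev[seq_len(keep)]) / sum(ev[nz]),
         n = n, labels = meta$label),
    class = "shape_pca"
  )
}

# n x N x 2 -> n x 2N, columns x1, y1, x2, y2, ...
cbind_interleave <- function(arr) {
  n <- dim(arr)[1]; n_lm <- dim(arr)[2]
  flat <- matrix(NA_real_, n, 2 * n_lm)
  flat[, seq(1, 2 * n_lm, by = 2)] <- array(arr[, , 1], dim = c(n, n_lm))
  flat[, seq(2, 2 * n_lm, by = 2)] <- array(arr[, , 2], dim = c(n, n_lm))
  rownames(flat) <- dimnames(arr)[[1]]
  flat
}

#' @describeIn classical_pca Specimen scores, one row per specimen.
#' @param x,object A `shape_pca`.
#' @param ... Unused.
#' @export
tidy.shape_pca <- function(x, ...) x$scores

#' @describeIn classical_pca One-row summary.
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(
    n = x$n,
    n_components = length(x$eigenvalues),
    n_eigenvalues = length(x$all_eigenvalues),
    pve_first2 = sum(x$all_eigenvalues[1:min(2, length(x$all_eigenvalues))]) / sum(x$all_eigenvalues)
  )
}

#' @describeIn classical_pca Ordination of the first two component scores.
#' @export
autoplot.shape_pca <- function(object, ...) plot_scores(tidy(object), glance(object)$pve_first2)

#' Proportion of variance explained
#'
#' Cumulative eigenvalue share: the sum of the first `k` eigenvalues over
#' the sum of all numerically nonzero eigenvalues.
#'
#' @param eigenvalues Non-increasing, non-negative eigenvalue vector.
#' @param k Number of leading components.
#' @return A proportion in `[0, 1]`.
#' @export
pve <- function(eigenvalues, k) {
  if (k < 1 || k > length(eigenvalues)) fm_abort("k out of range.", "fm_usage_error")
  nz <- eigenvalues[eigenvalues > 1e-10 * max(eigenvalues, 0)]
  if (length(nz) == 0) fm_abort("All eigenvalues are zero: variance undefined.", "fm_undefined_error")
  sum(eigenvalues[seq_len(k)]) / sum(nz)
}

#' Extract the leading score columns of a fitted decomposition
#'
#' Convenience accessor shared by the discriminant and classification
#' stages: the first `k` component scores with specimen ids and labels.
#'
#' @param fit An `mfpca_fit` or `shape_pca`.
#' @param k Number of leading components (default 3).
#' @return A tibble `specimen_id`, `label`, `PC1..PCk`.
#' @export
shape_scores <- function(fit, k = 3) {
  scores <- tidy(fit)
  pcs <- paste0("PC", seq_len(k))
  if (!all(pcs %in% names(scores))) {
    fm_abort(paste0("Fit has fewer than ", k, " components."), "fm_usage_error")
  }
  scores[, c("specimen_id", "label", pcs)]
}
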