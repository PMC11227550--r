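#' Linear discriminant analysis on component scores
#'
#' Fits LDA from explicit scatter matrices on a score table. With `rho` the
#' n x K score matrix, `G` the n x M one-hot class-indicator matrix and `H`
#' the M x K matrix of class mean scores, the within-class and between-class
#' scatters are
#' \deqn{W = (\rho - GH)^T (\rho - GH) / (n - M), \quad
#'       B = (GH - 1\bar\rho^T)^T (GH - 1\bar\rho^T) / (M - 1),}
#' and the discriminant axes `a` maximise the ratio
#' \eqn{a^T B a / a^T W a}, i.e. solve the generalised eigenproblem
#' `B a = lambda W a`. At most `min(K, M - 1)` axes carry discrimination.
#' Axes are normalised to unit Euclidean length with a deterministic sign
#' convention; each axis's eigenvalue share (its separation percentage) sums
#' to 100 over the retained axes.
#'
#' If `W` is singular a small ridge (`1e-8 * trace(W)/K`) is added with a
#' warning.
#'
#' @param scores A tibble with a `label` column and numeric score columns
#'   (e.g. from [shape_scores()]), or an n x K matrix plus `labels`.
#' @param labels Class labels (needed only when `scores` is a matrix).
#' @return An object of class `lda_fit`: scatters `W` and `B`, class means
#'   `H`, axes `a` (K x n_axes), `axis_eigenvalues`,
#'   `separation_percentages`, the grand mean, and `projected` discriminant
#'   coordinates (tibble).
#' @export
#' @examples
#' set.seed(1)
#' df <- tibble::tibble(
#'   label = rep(c("a", "b", "c"), each = 20),
#'   PC1 = rnorm(60, rep(c(0, 3, 6), each = 20)),
#'   PC2 = rnorm(60), PC3 = rnorm(60)
#' )
#' fit <- lda_fit(df)
#' separation_percentages(fit)
lda_fit <- function(scores, labels = NULL) {
  parts <- score_parts(scores, labels)
  rho <- parts$rho
  labels <- parts$labels
  ids <- parts$ids
  n <- nrow(rho)
  k <- ncol(rho)
  classes <- sort(unique(labels))
  m <- length(classes)
  if (m < 2) fm_abort("LDA needs at least 2 classes.", "fm_validation_error")
  if (n <= m) fm_abort("LDA needs n > number of classes.", "fm_usage_error")
  sizes <- table(factor(labels, levels = classes))
  if (any(sizes < 2)) {
    fm_abort(paste0("Every class needs at least 2 members; too small: ",
                    paste(classes[sizes < 2], collapse = ", ")), "fm_validation_error")
  }

  g <- outer(labels, classes, `==`) * 1            # n x M indicators
  h <- diag(1 / as.numeric(sizes)) %*% crossprod(g, rho)   # M x K class means
  rho_bar <- colMeans(rho)
  w <- crossprod(rho - g %*% h) / (n - m)
  centred_means <- g %*% h - matrix(rho_bar, n, k, byrow = TRUE)
  b <- crossprod(centred_means) / (m - 1)

  ridge_used <- FALSE
  lw <- tryCatch(chol(w), error = function(e) NULL)
  if (is.null(lw) || min(diag(lw)) < sqrt(.Machine$double.eps) * max(diag(lw))) {
    ridge_used <- TRUE
    warn("Within-class scatter is (near-)singular; adding ridge 1e-8 * trace(W)/K.",
         class = "fm_ridge_warning")
    w_r <- w + diag(1e-8 * sum(diag(w)) / k, k)
    lw <- chol(w_r)
  }
  # generalised eigenproblem via the Cholesky whitening of W
  linv <- backsolve(lw, diag(k))                   # L^{-1} with W = L'L (chol gives upper)
  mstar <- t(linv) %*% b %*% linv
  eig <- eigen((mstar + t(mstar)) / 2, symmetric = TRUE)
  n_axes <- min(k, m - 1)
  lambda <- pmax(eig$values[seq_len(n_axes)], 0)
  a <- linv %*% eig$vectors[, seq_len(n_axes), drop = FALSE]
  a <- sweep(a, 2, sqrt(colSums(a^2)), `/`)        # unit Euclidean length
  a <- sign_fix_cols(a)
  rownames(a) <- colnames(rho)

  if (sum(lambda) <= 0) {
    fm_abort("All discriminant eigenvalues are zero: separation undefined.",
             "fm_undefined_error")
  }
  sep <- 100 * lambda / sum(lambda)
  proj <- sweep(rho, 2, rho_bar) %*% a
  colnames(proj) <- paste0("LD", seq_len(n_axes))
  projected <- dplyr::bind_cols(
    tibble(specimen_id = ids, label = labels),
    as_tibble(proj)
  )
  structure(
    list(W = w, B = b, H = h, classes = classes, G = g,
         axes = a, axis_eigenvalues = lambda,
         separation_percentages = sep, grand_mean = rho_bar,
         projected = projected, ridge_used = ridge_used, n = n, K = k, M = m),
    class = "lda_fit"
  )
}

score_parts <- function(scores, labels) {
  if (is.data.frame(scores)) {
    num_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
    rho <- as.matrix(scores[, num_cols, drop = FALSE])
    labels <- as.character(scores$label)
    ids <- if ("specimen_id" %in% names(scores)) scores$specimen_id else
      paste0("spec_", seq_len(nrow(scores)))
  } else {
    rho <- as.matrix(scores)
    if (is.null(labels)) fm_abort("labels required with matrix input.", "fm_usage_error")
    labels <- as.character(labels)
    ids <- rownames(rho) %||% paste0("spec_", seq_len(nrow(rho)))
    if (is.null(colnames(rho))) colnames(rho) <- paste0("PC", seq_len(ncol(rho)))
  }
  if (length(labels) != nrow(rho) || anyNA(labels)) {
    fm_abort("Every score row needs a non-missing class label.", "fm_validation_error")
  }
  list(rho = rho, labels = labels, ids = ids)
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("Linear discriminant analysis (", x$M, " classes, ", x$K, " scores)\n", sep = "")
  cat("  separation: ", paste(sprintf("%.2f%%", x$separation_percentages), collapse = ", "), "\n")
  invisible(x)
}

#' Separation percentages of a discriminant fit
#'
#' Each discriminant axis's eigenvalue as a percentage of the eigenvalue
#' total — the share of between-class discrimination the axis carries.
#'
#' @param fit An [lda_fit()] object.
#' @return Numeric vector summing to 100.
#' @export
separation_percentages <- function(fit) {
  if (!inherits(fit, "lda_fit")) fm_abort("Expected an lda_fit.", "fm_usage_error")
  fit$separation_percentages
}

#' Project score rows onto fitted discriminant axes
#'
#' Centres new scores by the training grand mean and projects them onto the
#' discriminant axes; the training rows project exactly to
#' `fit$projected`.
#'
#' @param fit An [lda_fit()] object.
#' @param scores Score tibble (numeric columns used) or m x K matrix.
#' @return A tibble of discriminant coordinates `LD1..`.
#' @export
lda_project <- function(fit, scores) {
  if (is.data.frame(scores)) {
    rho <- as.matrix(scores[, vapply(scores, is.numeric, logical(1)), drop = FALSE])
  } else {
    rho <- as.matrix(scores)
  }
  if (ncol(rho) != fit$K) {
    fm_abort(paste0("Expected ", fit$K, " score columns, got ", ncol(rho), "."),
             "fm_usage_error")
  }
  proj <- sweep(rho, 2, fit$grand_mean) %*% fit$axes
  colnames(proj) <- paste0("LD", seq_len(ncol(proj)))
  as_tibble(proj)
}

#' @describeIn lda_fit Discriminant coordinates of the training specimens.
#' @param x,object An `lda_fit`.
#' @param ... Unused.
#' @export
tidy.lda_fit <- function(x, ...) x$projected

#' @describeIn lda_fit One-row summary: class count, axis count, leading
#'   separation percentage, ridge flag.
#' @export
glance.lda_fit <- function(x, ...) {
  tibble(
    n = x$n, n_classes = x$M, n_axes = length(x$axis_eigenvalues),
    separation_1 = x$separation_percentages[1],
    ridge_used = x$ridge_used
  )
}

#' @describeIn lda_fit Discriminant-plane scatter (first two axes, or a
#'   strip plot when only one axis exists).
#' @export
autoplot.lda_fit <- function(object, ...) {
  d <- tidy(object)
  if ("LD2" %in% names(d)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$LD1, y = .data$LD2, colour = .data$label)) +
      ggplot2::geom_point() +
      ggplot2::labs(colour = "class", title = "Discriminant coordinates")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$LD1, y = .data$label, colour = .data$label)) +
      ggplot2::geom_jitter(height = 0.1) +
      ggplot2::labs(colour = "class", title = "Discriminant coordinates")
  }
}
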