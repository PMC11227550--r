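# trapezoidal quadrature weights for a strictly increasing grid on [0, 1];
# weights sum to the domain length
trapezoid_weights <- function(grid) {
  n <- length(grid)
  if (n < 2 || any(diff(grid) <= 0)) {
    fm_abort("Grid must be strictly increasing with at least 2 points.", "fm_validation_error")
  }
  h <- diff(grid)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

new_fd_set <- function(values, grids, weights, specimen_ids, labels, views) {
  structure(
    list(values = values, grids = grids, weights = weights,
         specimen_ids = specimen_ids, labels = labels, views = views),
    class = "fd_set"
  )
}

#' Functional representation of aligned landmark configurations
#'
#' Treats each specimen's aligned x- and y-coordinate sequences as two
#' discretised curves over the landmark-index continuum: landmark `j` of `N`
#' maps to grid point `(j - 1)/(N - 1)` on `[0, 1]` (the digitisation order
#' is the only ordering the landmark scheme defines). With smoothing
#' disabled (the default) the representation is lossless — curve values are
#' exactly the aligned coordinates. Trapezoidal quadrature weights on the
#' grid define the inner product used by all downstream functional
#' operations.
#'
#' @param aligned A [gpa()] fit, or a landmark tibble of aligned coordinates.
#' @param smoothing Optional B-spline least-squares smoothing spec:
#'   `list(n_basis =, order =)` (order defaults to 4, i.e. cubic). With
#'   `n_basis` equal to the number of landmarks the fit interpolates and the
#'   raw values are reproduced. `n_basis` greater than `N` is an error.
#' @param parameterisation `"index"` (default) for the uniform landmark-index
#'   grid, or `"arclength"` to space grid points by cumulative consensus
#'   arc length.
#' @return An `fd_set`: per-element (`x`, `y`) n-by-N value matrices, shared
#'   grid, quadrature weights, specimen ids and class labels.
#' @export
to_functional <- function(aligned, smoothing = NULL,
                          parameterisation = c("index", "arclength")) {
  parameterisation <- match.arg(parameterisation)
  if (inherits(aligned, "gpa_fit")) {
    arr <- aligned$array
    meta <- aligned$meta
    consensus <- aligned$consensus
  } else {
    arr <- lm_array(aligned)
    meta <- lm_meta(aligned)
    consensus <- apply(arr, c(2, 3), mean)
  }
  n_lm <- dim(arr)[2]
  if (n_lm < 4) fm_abort("Functional representation needs at least 4 landmarks.", "fm_validation_error")
  if (!all(is.finite(arr))) fm_abort("Non-finite coordinates in aligned data.", "fm_validation_error")
  grid <- if (parameterisation == "index") {
    seq(0, 1, length.out = n_lm)
  } else {
    seg <- sqrt(rowSums(diff(consensus)^2))
    c(0, cumsum(seg)) / sum(seg)
  }
  w <- trapezoid_weights(grid)
  vals_x <- array(arr[, , 1], dim = dim(arr)[1:2])
  vals_y <- array(arr[, , 2], dim = dim(arr)[1:2])
  if (!is.null(smoothing)) {
    vals_x <- smooth_rows(vals_x, grid, smoothing)
    vals_y <- smooth_rows(vals_y, grid, smoothing)
  }
  view <- meta$view[1]
  if (is.na(view)) view <- "view"
  values <- list(vals_x, vals_y)
  names(values) <- paste0(view, c("_x", "_y"))
  new_fd_set(
    values = values,
    grids = stats::setNames(list(grid, grid), names(values)),
    weights = stats::setNames(list(w, w), names(values)),
    specimen_ids = meta$specimen_id,
    labels = meta$label,
    views = view
  )
}

# least-squares B-spline smoothing of each row of a value matrix
smooth_rows <- function(values, grid, smoothing) {
  n_basis <- smoothing$n_basis
  order <- smoothing$order %||% 4
  if (is.null(n_basis)) fm_abort("smoothing spec needs n_basis.", "fm_usage_error")
  if (n_basis > length(grid)) {
    fm_abort("Smoothing basis count cannot exceed the number of landmarks.",
             "fm_config_error")
  }
  basis <- splines::bs(grid, df = n_basis, degree = order - 1, intercept = TRUE)
  coef <- solve(crossprod(basis), crossprod(basis, t(values)))
  t(basis %*% coef)
}

#' Combine the functional data of several views
#'
#' Stacks the elements of `V` per-view functional datasets into one
#' multivariate functional datum with `2V` elements (x and y curves per
#' view), matching specimens by id across views. The specimen order of the
#' first view is used throughout.
#'
#' @param views A list of `fd_set` objects sharing the same specimen ids.
#' @return An `fd_set` with the concatenated elements.
#' @export
combine_views <- function(views) {
  if (!is.list(views) || length(views) < 2 || !all(vapply(views, inherits, logical(1), "fd_set"))) {
    fm_abort("combine_views expects a list of at least two fd_set objects.", "fm_usage_error")
  }
  ids <- views[[1]]$specimen_ids
  for (v in views[-1]) {
    diff_ids <- union(setdiff(ids, v$specimen_ids), setdiff(v$specimen_ids, ids))
    if (length(diff_ids) > 0) {
      fm_abort(paste0("Specimen ids differ across views: ", paste(diff_ids, collapse = ", ")),
               "fm_validation_error")
    }
  }
  values <- list(); grids <- list(); weights <- list()
  for (v in views) {
    idx <- match(ids, v$specimen_ids)
    nm <- names(v$values)
    nm <- make.unique(c(names(values), nm))[length(values) + seq_along(nm)]
    for (k in seq_along(v$values)) {
      values[[nm[k]]] <- v$values[[k]][idx, , drop = FALSE]
      grids[[nm[k]]] <- v$grids[[k]]
      weights[[nm[k]]] <- v$weights[[k]]
    }
  }
  new_fd_set(values, grids, weights, ids, views[[1]]$labels,
             unlist(lapply(views, `[[`, "views")))
}

#' @export
print.fd_set <- function(x, ...) {
  cat("Multivariate functional dataset\n")
  cat("  specimens: ", length(x$specimen_ids), "\n")
  cat("  elements:  ", paste(names(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a functional dataset
#'
#' @param x An `fd_set`.
#' @param ... Unused.
#' @return A tibble with columns `specimen_id`, `label`, `element`, `t`,
#'   `value` — one row per specimen, element and grid point.
#' @export
as_tibble.fd_set <- function(x, ...) {
  purrr::imap_dfr(x$values, function(m, nm) {
    tibble(
      specimen_id = rep(x$specimen_ids, each = ncol(m)),
      label = rep(x$labels, each = ncol(m)),
      element = nm,
      t = rep(x$grids[[nm]], times = nrow(m)),
      value = as.vector(t(m))
    )
  })
}

# quadrature inner product of two curves sampled on the same grid
quad_inner <- function(f, g, w) sum(w * f * g)

#' Export functional data as long CSV
#'
#' @param fd An `fd_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_functional <- function(fd, path) {
  readr::write_csv(as_tibble(fd), path)
  invisible(path)
}
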