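# ---- matrix-level primitives ----------------------------------------------

# centroid size of an N x 2 coordinate matrix
cs_matrix <- function(m) {
  ctr <- colMeans(m)
  sqrt(sum(sweep(m, 2, ctr)^2))
}

# centre at origin and scale to unit centroid size
normalise_config <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  s <- sqrt(sum(m^2))
  if (s < .Machine$double.eps * nrow(m)) {
    fm_abort("Degenerate configuration: all landmarks coincident.", "fm_degenerate_error")
  }
  m / s
}

# proper rotation (det +1) of b onto a, both centred; reflections excluded
# because anatomical views must not be mirrored
optimal_rotation <- function(a, b) {
  s <- svd(crossprod(a, b))
  r <- s$v %*% t(s$u)
  if (det(r) < 0) {
    v <- s$v
    v[, ncol(v)] <- -v[, ncol(v)]
    r <- v %*% t(s$u)
  }
  r
}

pd_matrix <- function(a, b) {
  r <- optimal_rotation(a, b)
  sqrt(sum((a - b %*% r)^2))
}

# ---- user-facing operations ------------------------------------------------

#' Centroid size of each configuration
#'
#' Centroid size — the square root of the summed squared distances of the
#' landmarks from their centroid — is the size measure removed by Procrustes
#' scaling. It scales exactly linearly with the configuration: multiplying
#' all coordinates by `c > 0` multiplies centroid size by `c`.
#'
#' @param data Landmark tibble ([read_tps()] format).
#' @return A tibble with columns `specimen_id` and `centroid_size`.
#' @export
centroid_size <- function(data) {
  arr <- lm_array(data)
  sizes <- vapply(seq_len(dim(arr)[1]), function(i) {
    m <- arr[i, , ]
    if (max(stats::dist(m)) < .Machine$double.eps * nrow(m)) {
      fm_abort(paste0("Degenerate configuration (all landmarks coincident): ",
                      dimnames(arr)[[1]][i]), "fm_degenerate_error")
    }
    cs_matrix(m)
  }, numeric(1))
  tibble(specimen_id = dimnames(arr)[[1]], centroid_size = sizes)
}

#' Generalised Procrustes analysis
#'
#' Iterative superimposition of all configurations: each is centred at the
#' origin, scaled to unit centroid size, and rotated (proper rotation only,
#' no reflection) onto the current consensus; the consensus is then
#' recomputed as the mean shape, renormalised to unit centroid size, and the
#' cycle repeats until the consensus changes by less than `tol`
#' root-mean-square or `max_iter` is reached. The consensus is initialised
#' from the first configuration after centring and scaling. After
#' convergence a final rotation pass aligns every configuration exactly onto
#' the stored consensus.
#'
#' The least-squares objective (summed squared distances of aligned
#' configurations to their mean) is non-increasing across iterations and is
#' recorded per iteration in `objective`.
#'
#' @param data Landmark tibble with one configuration per specimen.
#' @param tol Convergence tolerance on the RMS change of the consensus
#'   (default `1e-8`).
#' @param max_iter Maximum number of superimposition sweeps (default 100).
#' @return An object of class `gpa_fit`: aligned coordinates (`coords`
#'   tibble), `consensus` (N x 2 matrix, unit centroid size),
#'   `centroid_sizes` tibble (sizes of the raw configurations), per-iteration
#'   `objective`, `iterations`, and a `converged` flag.
#' @export
#' @examples
#' spec <- simulation_spec(n_landmarks = 12, n_per_class = c(5, 5), seed = 1)
#' lm <- average_replicates(simulate_dataset(spec)$replicates)
#' fit <- gpa(lm)
#' glance(fit)
gpa <- function(data, tol = 1e-8, max_iter = 100) {
  arr <- lm_array(data)
  meta <- lm_meta(data)
  n <- dim(arr)[1]
  if (n < 2) fm_abort("GPA needs at least 2 configurations.", "fm_usage_error")
  sizes <- centroid_size(data)

  configs <- lapply(seq_len(n), function(i) normalise_config(arr[i, , ]))
  consensus <- configs[[1]]
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    configs <- lapply(configs, function(m) m %*% optimal_rotation(consensus, m))
    mean_shape <- Reduce(`+`, configs) / n
    objective <- c(objective, sum(vapply(configs, function(m) sum((m - mean_shape)^2),
                                         numeric(1))))
    new_consensus <- mean_shape / sqrt(sum(mean_shape^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("GPA did not converge in ", max_iter, " iterations."),
         class = "fm_convergence_warning")
  }
  # final pass: every configuration exactly optimally rotated onto the
  # stored consensus (makes per-configuration rotation optimality exact)
  configs <- lapply(configs, function(m) m %*% optimal_rotation(consensus, m))

  aligned <- array(NA_real_, dim = dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) aligned[i, , ] <- configs[[i]]
  types <- validate_landmarks(data)
  types <- types$type[types$specimen_id == types$specimen_id[1]]
  structure(
    list(
      coords = lm_tibble(aligned, meta = meta, types = types),
      array = aligned,
      consensus = consensus,
      centroid_sizes = sizes,
      meta = meta,
      objective = objective,
      iterations = iter,
      converged = converged,
      tol = tol
    ),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalised Procrustes analysis\n")
  cat("  specimens:  ", dim(x$array)[1], "\n")
  cat("  landmarks:  ", dim(x$array)[2], "\n")
  cat("  iterations: ", x$iterations, if (x$converged) " (converged)" else " (NOT converged)", "\n")
  invisible(x)
}

#' @describeIn gpa Aligned Procrustes coordinates, one row per landmark,
#'   joined with centroid size.
#' @param x A `gpa_fit` object.
#' @param ... Unused.
#' @export
tidy.gpa_fit <- function(x, ...) {
  dplyr::left_join(x$coords, x$centroid_sizes, by = "specimen_id")
}

#' @describeIn gpa One-row summary: sample size, landmark count, iterations,
#'   convergence, final objective.
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble(
    n = dim(x$array)[1],
    n_landmarks = dim(x$array)[2],
    iterations = x$iterations,
    converged = x$converged,
    objective = x$objective[length(x$objective)]
  )
}

#' @describeIn gpa Scatter of aligned landmarks with the consensus overlaid.
#' @param object A `gpa_fit` object.
#' @export
autoplot.gpa_fit <- function(object, ...) {
  cons <- tibble(x = object$consensus[, 1], y = object$consensus[, 2])
  ggplot2::ggplot(object$coords, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = cons, colour = "black", size = 2, shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned landmarks", colour = "class")
}

#' Procrustes distance between two aligned configurations
#'
#' Root summed squared coordinate differences after the optimal proper
#' rotation of `b` onto `a`. Both configurations must already be centred and
#' of unit centroid size (as produced by [gpa()]); violations beyond `1e-6`
#' are an error.
#'
#' @param a,b N x 2 coordinate matrices, or single-specimen landmark tibbles.
#' @return Non-negative scalar distance.
#' @export
procrustes_distance <- function(a, b) {
  a <- as_config_matrix(a)
  b <- as_config_matrix(b)
  for (m in list(a, b)) {
    if (max(abs(colMeans(m))) > 1e-6 || abs(sqrt(sum(sweep(m, 2, colMeans(m))^2)) - 1) > 1e-6) {
      fm_abort("Configurations must be centred with unit centroid size; run gpa() or normalise first.",
               "fm_validation_error")
    }
  }
  pd_matrix(a, b)
}

as_config_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 2) fm_abort("Configuration matrices must have 2 columns.", "fm_usage_error")
    return(x)
  }
  if (is.data.frame(x)) {
    if (length(unique(x$specimen_id %||% "one")) > 1) {
      fm_abort("Expected a single-specimen configuration.", "fm_usage_error")
    }
    return(cbind(x$x, x$y))
  }
  fm_abort("Cannot interpret input as a landmark configuration.", "fm_usage_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export aligned coordinates
#'
#' Writes Procrustes coordinates either as a long CSV (`specimen_id`,
#' `landmark`, `x`, `y`, ...) or as a TPS file of aligned shapes.
#'
#' @param fit A `gpa_fit`.
#' @param path Output path.
#' @param format `"csv"` or `"tps"`.
#' @return `path`, invisibly.
#' @export
write_aligned <- function(fit, path, format = c("csv", "tps")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(tidy(fit), path)
  } else {
    write_tps(fit$coords, path)
  }
  invisible(path)
}
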