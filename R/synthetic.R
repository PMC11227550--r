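#' Simulation specification for synthetic landmark data
#'
#' Describes a synthetic study: class-specific mean (template) shapes on a
#' closed curve, per-specimen landmark noise, a random similarity transform
#' per specimen (emulating arbitrary image placement and magnification),
#' and repeated digitisation rounds with independent digitisation noise.
#' The defaults mirror a three-species craniodental study design: three
#' classes of 29/30/30 specimens, 25 landmarks, three digitisation
#' replicates.
#'
#' Noise levels are expressed in consensus (unit-centroid-size shape)
#' units: `class_separation` is the pairwise full-Procrustes distance
#' between class templates, `landmark_sd` the isotropic per-landmark sd of
#' individual shape variation, and `digitisation_sd` the per-round observer
#' error, added in shape space before the similarity transform so replicate
#' error scales with the specimen.
#'
#' @param n_landmarks Number of landmarks `N` (>= 4).
#' @param n_classes Number of classes `M` (ignored when `n_per_class` is
#'   given with names or length > 1).
#' @param n_per_class Specimen counts per class.
#' @param class_separation Pairwise Procrustes distance `delta` between
#'   class templates (default 0.10).
#' @param landmark_sd Individual shape sd `sigma_L` (default 0.025).
#' @param digitisation_sd Per-replicate digitisation sd `sigma_D`
#'   (default 0.005).
#' @param rotation_range Rotations drawn uniformly from
#'   `[-rotation_range, rotation_range]` radians (default `pi`).
#' @param scale_range Scales drawn uniformly from this interval
#'   (default `c(0.75, 1.25)`).
#' @param translation_range Translations drawn uniformly from
#'   `[-translation_range, translation_range]` per axis (default 50).
#' @param n_replicates Digitisation rounds `R` (default 3).
#' @param view View name stamped on the generated data.
#' @param seed Master seed.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_landmarks = 25, n_classes = 3,
                            n_per_class = c(29, 30, 30),
                            class_separation = 0.10, landmark_sd = 0.025,
                            digitisation_sd = 0.005, rotation_range = pi,
                            scale_range = c(0.75, 1.25), translation_range = 50,
                            n_replicates = 3, view = "dorsal", seed = 1) {
  if (n_landmarks < 4) fm_abort("Need at least 4 landmarks.", "fm_validation_error")
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, n_classes)
  n_classes <- length(n_per_class)
  if (class_separation < 0 || landmark_sd < 0 || digitisation_sd < 0) {
    fm_abort("Noise and separation parameters must be non-negative.", "fm_validation_error")
  }
  if (length(scale_range) != 2 || any(scale_range <= 0) || diff(scale_range) < 0) {
    fm_abort("scale_range must be a positive increasing interval.", "fm_validation_error")
  }
  if (n_replicates < 1) fm_abort("Need at least one replicate round.", "fm_validation_error")
  structure(
    list(n_landmarks = n_landmarks, n_classes = n_classes,
         n_per_class = n_per_class,
         class_names = paste0("class_", letters[seq_len(n_classes)]),
         class_separation = class_separation, landmark_sd = landmark_sd,
         digitisation_sd = digitisation_sd, rotation_range = rotation_range,
         scale_range = scale_range, translation_range = translation_range,
         n_replicates = n_replicates, view = view, seed = seed),
    class = "simulation_spec"
  )
}

# smooth (low-order Fourier) random displacement field over the closed curve
smooth_field <- function(theta, n_harmonics = 4) {
  f <- matrix(0, length(theta), 2)
  for (h in seq_len(n_harmonics) + 1) {
    f[, 1] <- f[, 1] + stats::rnorm(1, 0, 1 / h) * cos(h * theta) +
      stats::rnorm(1, 0, 1 / h) * sin(h * theta)
    f[, 2] <- f[, 2] + stats::rnorm(1, 0, 1 / h) * cos(h * theta) +
      stats::rnorm(1, 0, 1 / h) * sin(h * theta)
  }
  f
}

#' Class template shapes
#'
#' Builds `M` template configurations: a base shape of `N` landmarks on a
#' closed curve (an ellipse perturbed by seeded smooth noise, so that the
#' landmark-index ordering is geometrically meaningful), plus class-specific
#' smooth displacement fields projected into the tangent space of the base
#' shape, orthogonalised, and scaled so every pairwise full-Procrustes
#' distance between templates equals `class_separation` within 2%.
#'
#' @param spec A [simulation_spec()].
#' @return A named list of `N x 2` template matrices (unit centroid size,
#'   centred), one per class.
#' @export
make_templates <- function(spec) {
  withr::local_seed(child_seed(spec$seed, 101))
  n_lm <- spec$n_landmarks
  m <- spec$n_classes
  theta <- seq(0, 2 * pi, length.out = n_lm + 1)[seq_len(n_lm)]
  base <- cbind(cos(theta), 0.6 * sin(theta)) + 0.05 * smooth_field(theta)
  base <- normalise_config(base)
  if (m == 1 || spec$class_separation == 0) {
    return(stats::setNames(rep(list(base), m), spec$class_names))
  }

  # tangent-space basis at the base shape: remove translation, scale, rotation
  flat <- function(x) as.vector(x)
  rot90 <- cbind(-base[, 2], base[, 1])
  nuisance <- cbind(
    flat(cbind(rep(1, n_lm), 0)), flat(cbind(0, rep(1, n_lm))),
    flat(base), flat(rot90)
  )
  nuisance <- qr.Q(qr(nuisance))
  project_tangent <- function(f) {
    v <- flat(f)
    v <- v - nuisance %*% crossprod(nuisance, v)
    matrix(v, n_lm, 2)
  }
  fields <- lapply(seq_len(m), function(c) project_tangent(smooth_field(theta)))
  # Gram-Schmidt so pairwise template distances come out symmetric
  for (c in seq_len(m)) {
    v <- flat(fields[[c]])
    if (c > 1) for (b in seq_len(c - 1)) {
      u <- flat(fields[[b]])
      v <- v - sum(u * v) * u
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) {
      fm_abort(paste0("Cannot build ", m, " separated templates from ", n_lm,
                      " landmarks; increase n_landmarks or reduce n_classes."),
               "fm_degenerate_error")
    }
    fields[[c]] <- matrix(v / nv, n_lm, 2)
  }

  build <- function(s) lapply(fields, function(f) normalise_config(base + s * f))
  mean_pd <- function(s) {
    tpl <- build(s)
    pairs <- utils::combn(m, 2)
    mean(apply(pairs, 2, function(p) pd_matrix(tpl[[p[1]]], tpl[[p[2]]])))
  }
  delta <- spec$class_separation
  upper <- 2
  if (mean_pd(upper) < delta) {
    fm_abort(paste0("Requested class_separation ", delta,
                    " is unreachable (max attainable ~", round(mean_pd(upper), 3),
                    "); reduce class_separation."), "fm_validation_error")
  }
  s_star <- stats::uniroot(function(s) mean_pd(s) - delta,
                           interval = c(1e-9, upper), tol = 1e-12)$root
  templates <- build(s_star)
  pairs <- utils::combn(m, 2)
  pds <- apply(pairs, 2, function(p) pd_matrix(templates[[p[1]]], templates[[p[2]]]))
  if (any(abs(pds - delta) > 0.02 * delta)) {
    fm_abort("Template separation calibration failed to reach 2% accuracy.",
             "fm_degenerate_error")
  }
  stats::setNames(templates, spec$class_names)
}

#' Simulate a replicated landmark study
#'
#' Draws one true shape per specimen (its class template plus isotropic
#' landmark noise), applies a random similarity transform per specimen, and
#' digitises it `R` times, each round adding independent digitisation noise
#' in shape space before the (fixed) transform is applied. The output flows
#' through the identical entry points as real data.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `replicates` — landmark tibble with a `replicate` column
#'   (feed to [average_replicates()]); `truth` — class labels, per-specimen
#'   transform parameters, and the noiseless (pre-transform) shapes.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_spec(n_landmarks = 12, n_per_class = c(5, 5), seed = 3))
#' dplyr::count(sim$truth$labels, label)
simulate_dataset <- function(spec) {
  templates <- make_templates(spec)
  withr::local_seed(child_seed(spec$seed, 202))
  n_lm <- spec$n_landmarks
  ids <- character(0); labels <- character(0)
  shapes <- list(); transforms <- list()
  for (c in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$n_per_class[c])) {
      id <- sprintf("%s_%02d", spec$class_names[c], i)
      ids <- c(ids, id)
      labels <- c(labels, spec$class_names[c])
      shapes[[id]] <- templates[[c]] +
        matrix(stats::rnorm(2 * n_lm, 0, spec$landmark_sd), n_lm, 2)
      transforms[[id]] <- list(
        angle = stats::runif(1, -spec$rotation_range, spec$rotation_range),
        scale = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
        translation = stats::runif(2, -spec$translation_range, spec$translation_range)
      )
    }
  }
  reps <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
    purrr::map_dfr(seq_along(ids), function(k) {
      id <- ids[k]
      shape <- shapes[[id]] +
        matrix(stats::rnorm(2 * n_lm, 0, spec$digitisation_sd), n_lm, 2)
      tr <- transforms[[id]]
      rot <- matrix(c(cos(tr$angle), sin(tr$angle), -sin(tr$angle), cos(tr$angle)), 2, 2)
      coords <- tr$scale * shape %*% t(rot)
      coords <- sweep(coords, 2, -tr$translation)
      tibble(
        specimen_id = id, label = labels[k], view = spec$view,
        replicate = r, landmark = seq_len(n_lm), type = "I",
        x = coords[, 1], y = coords[, 2], scale = NA_real_
      )
    })
  })
  truth <- list(
    labels = tibble(specimen_id = ids, label = labels),
    templates = templates,
    shapes = shapes,
    transforms = transforms,
    spec = spec
  )
  list(replicates = reps, truth = truth)
}

#' Write a simulated study to disk
#'
#' Emits one TPS file per digitisation round plus a manifest CSV
#' (`specimen_id`, `species_label`, `view`, `tps_path`, `replicate_index`)
#' and the truth record as JSON, so synthetic data enters the pipeline
#' through the same files as real data.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- sim$truth$spec
  manifest <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
    path <- file.path(dir, sprintf("%s_rep%d.tps", spec$view, r))
    d <- sim$replicates[sim$replicates$replicate == r, ]
    write_tps(d, path)
    dplyr::distinct(d, .data$specimen_id, .data$label) %>%
      dplyr::transmute(.data$specimen_id, species_label = .data$label,
                       view = spec$view, tps_path = path, replicate_index = r)
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  truth <- list(
    labels = sim$truth$labels,
    transforms = sim$truth$transforms,
    spec = unclass(spec)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}
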