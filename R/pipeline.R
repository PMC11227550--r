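#' Pipeline run configuration
#'
#' Bundles everything one end-to-end comparison needs: the per-view input
#' data (or simulation specs), the decomposition threshold, the number of
#' leading scores used by the discriminant and classification stages, the
#' classifier roster, the split protocol settings, and the master seed from
#' which every stochastic stage derives its own seed.
#'
#' @param input Per-view input: a named list of landmark tibbles (each with
#'   a `replicate` column when digitisation rounds are present), a named
#'   list of [simulation_spec()] objects, or the path of a manifest CSV with
#'   columns `specimen_id`, `species_label`, `view`, `tps_path`,
#'   `replicate_index`.
#' @param combine Also analyse all views jointly (default: yes when more
#'   than one view is given).
#' @param pve_threshold Variance threshold for the functional decomposition
#'   (default 0.99).
#' @param k Number of leading component scores fed to LDA and the
#'   classifiers (default 3).
#' @param specs Classifier roster (default all four).
#' @param reps,train_fraction Split-protocol settings (defaults 20, 0.7).
#' @param seed Master seed.
#' @param output_dir Optional directory for CSV/JSON artefacts.
#' @return A `run_config` list.
#' @export
run_config <- function(input, combine = NULL, pve_threshold = 0.99, k = 3,
                       specs = default_classifiers(), reps = 20,
                       train_fraction = 0.7, seed = 1, output_dir = NULL) {
  structure(
    list(input = input, combine = combine, pve_threshold = pve_threshold,
         k = k, specs = specs, reps = reps, train_fraction = train_fraction,
         seed = seed, output_dir = output_dir),
    class = "run_config"
  )
}

resolve_input <- function(input) {
  if (is.character(input) && length(input) == 1) {
    manifest <- readr::read_csv(input, show_col_types = FALSE)
    req <- c("specimen_id", "species_label", "view", "tps_path", "replicate_index")
    if (!all(req %in% names(manifest))) {
      fm_abort(paste0("Manifest must have columns: ", paste(req, collapse = ", ")),
               "fm_validation_error")
    }
    files <- dplyr::distinct(manifest, .data$view, .data$tps_path, .data$replicate_index)
    out <- list()
    for (v in unique(files$view)) {
      fv <- files[files$view == v, ]
      out[[v]] <- purrr::map_dfr(seq_len(nrow(fv)), function(i) {
        d <- read_tps(fv$tps_path[i], view = v)
        d$replicate <- fv$replicate_index[i]
        lab <- manifest[manifest$view == v, c("specimen_id", "species_label")]
        lab <- dplyr::distinct(lab)
        d$label <- lab$species_label[match(d$specimen_id, lab$specimen_id)]
        d
      })
    }
    return(out)
  }
  if (is.list(input) && all(vapply(input, inherits, logical(1), "simulation_spec"))) {
    return(lapply(input, function(s) simulate_dataset(s)$replicates))
  }
  if (inherits(input, "simulation_spec")) {
    return(stats::setNames(list(simulate_dataset(input)$replicates), input$view))
  }
  if (is.list(input) && all(vapply(input, is.data.frame, logical(1)))) {
    return(input)
  }
  fm_abort("Unrecognised pipeline input.", "fm_usage_error")
}

#' Run the end-to-end comparison pipeline
#'
#' For every requested view set (each view on its own, plus all views
#' combined) the pipeline averages digitisation replicates, Procrustes-aligns
#' the configurations once, and runs two branches off the identical aligned
#' dataset: the classical branch (PCA of the flattened Procrustes
#' coordinates; for the combined set, of the column-concatenated per-view
#' coordinates) and the functional branch (curves over the landmark-index
#' continuum, decomposed by multivariate functional PCA; for the combined
#' set, one decomposition of the 2V-element functional datum). The first
#' `k` scores of each branch feed the discriminant analysis and the
#' replicated classification protocol.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result`: per view set and branch, the fitted
#'   decomposition, discriminant fit and protocol evaluation; `tidy()`
#'   gives the accuracy report (rows = classifiers, one block per view set
#'   and method).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) fm_abort("config must be a run_config.", "fm_usage_error")
  views <- resolve_input(config$input)
  if (is.null(names(views)) || any(!nzchar(names(views)))) {
    names(views) <- paste0("view", seq_along(views))
  }
  combine <- config$combine %||% (length(views) > 1)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }

  stage <- function(what, view_set, expr) {
    tryCatch(expr, error = function(e) {
      fm_abort(paste0("Stage '", what, "' failed for view set '", view_set, "': ",
                      conditionMessage(e)), "fm_pipeline_error")
    })
  }

  aligned <- list(); fds <- list()
  for (v in names(views)) {
    say("averaging replicates: ", v)
    avg <- stage("average", v, average_replicates(views[[v]]))
    say("GPA: ", v)
    aligned[[v]] <- stage("gpa", v, gpa(avg))
    fds[[v]] <- stage("functional", v, to_functional(aligned[[v]]))
  }

  sets <- as.list(names(views))
  names(sets) <- names(views)
  if (combine) sets$combined <- names(views)

  results <- list()
  for (s in names(sets)) {
    members <- sets[[s]]
    say("decomposition: ", s)
    gm <- stage("classical_pca", s, {
      if (length(members) == 1) classical_pca(aligned[[members]])
      else classical_pca_multi(aligned[members])
    })
    fd <- if (length(members) == 1) fds[[members]] else
      stage("combine_views", s, combine_views(fds[members]))
    mf <- stage("mfpca", s, {
      fit <- mfpca(fd, pve_threshold = config$pve_threshold)
      # the threshold may retain fewer multivariate components than the k
      # scores the discriminant/classification stages consume; keep >= k
      if (length(fit$eigenvalues) < config$k) {
        fit <- mfpca(fd, pve_threshold = config$pve_threshold, n_components = config$k)
      }
      fit
    })
    branch <- function(fit, offset) {
      scores <- shape_scores(fit, k = config$k)
      ld <- stage("lda", s, lda_fit(scores))
      proto <- stage("classify", s, evaluate_protocol(
        scores[, c("label", paste0("PC", seq_len(config$k)))],
        specs = config$specs, reps = config$reps,
        train_fraction = config$train_fraction,
        seed0 = child_seed(config$seed, offset + match(s, names(sets)))
      ))
      list(scores = scores, lda = ld, protocol = proto)
    }
    say("GM branch: ", s)
    gm_branch <- c(list(fit = gm), branch(gm, 0))
    say("FDGM branch: ", s)
    fd_branch <- c(list(fit = mf), branch(mf, 100))
    results[[s]] <- list(GM = gm_branch, FDGM = fd_branch)
  }

  out <- structure(
    list(results = results, aligned = aligned, config = config, log = log_lines),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_pipeline(out, config$output_dir)
  out
}

# combined-view GM baseline: PCA of the column-concatenated Procrustes
# coordinates of the per-view alignments (rows matched by specimen id)
classical_pca_multi <- function(fits) {
  ids <- fits[[1]]$meta$specimen_id
  flats <- lapply(fits, function(f) {
    flat <- cbind_interleave(f$array)
    idx <- match(ids, f$meta$specimen_id)
    if (anyNA(idx)) fm_abort("Specimen ids differ across views.", "fm_validation_error")
    flat[idx, , drop = FALSE]
  })
  flat <- do.call(cbind, flats)
  rownames(flat) <- ids
  res <- classical_pca(flat)
  res$scores$label <- fits[[1]]$meta$label[match(res$scores$specimen_id, fits[[1]]$meta$specimen_id)]
  res$labels <- res$scores$label
  res
}

#' @describeIn run_pipeline Accuracy report: one row per view set, method
#'   and classifier, with mean and sd of test accuracy.
#' @param x,object A `pipeline_result`.
#' @param ... Unused.
#' @export
tidy.pipeline_result <- function(x, ...) {
  purrr::imap_dfr(x$results, function(res, s) {
    purrr::imap_dfr(res, function(br, method) {
      dplyr::mutate(tidy(br$protocol), view_set = s, method = method,
                    .before = 1)
    })
  })
}

#' @describeIn run_pipeline Per view set and method: component count,
#'   variance explained by the first two components, and the leading
#'   discriminant separation percentage.
#' @export
glance.pipeline_result <- function(x, ...) {
  purrr::imap_dfr(x$results, function(res, s) {
    purrr::imap_dfr(res, function(br, method) {
      g <- glance(br$fit)
      tibble(view_set = s, method = method,
             n_components = g$n_eigenvalues,
             pve_first2 = g$pve_first2,
             separation_1 = br$lda$separation_percentages[1])
    })
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Shape classification pipeline (", length(x$results), " view sets)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Accuracy report in the two-branch table layout
#'
#' Rows are classifiers, columns the view sets of each method, cells
#' `"mean (sd)"`.
#'
#' @param result A `pipeline_result`.
#' @return A tibble.
#' @export
report_table <- function(result) {
  tidy(result) %>%
    dplyr::mutate(cell = sprintf("%.3f (%.3f)", .data$mean_accuracy, .data$sd_accuracy),
                  col = paste(.data$method, .data$view_set, sep = "_")) %>%
    dplyr::select("classifier", "col", "cell") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
}

write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(result$results)) {
    for (method in names(result$results[[s]])) {
      br <- result$results[[s]][[method]]
      base <- file.path(dir, paste0(s, "_", method))
      readr::write_csv(br$scores, paste0(base, "_scores.csv"))
      readr::write_csv(
        tibble(component = seq_along(br$fit$all_eigenvalues),
               eigenvalue = br$fit$all_eigenvalues,
               pve = cumsum(br$fit$all_eigenvalues) / sum(br$fit$all_eigenvalues)),
        paste0(base, "_eigenvalues.csv"))
      readr::write_csv(tidy(br$lda), paste0(base, "_discriminant.csv"))
      readr::write_csv(br$protocol$replicates, paste0(base, "_accuracy_replicates.csv"))
    }
  }
  readr::write_csv(tidy(result), file.path(dir, "accuracy_report.csv"))
  readr::write_csv(report_table(result), file.path(dir, "accuracy_table.csv"))
  jsonlite::write_json(
    list(report = tidy(result), summary = glance(result),
         seed = result$config$seed,
         pve_threshold = result$config$pve_threshold,
         k = result$config$k, reps = result$config$reps,
         train_fraction = result$config$train_fraction),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(result$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' Build a run configuration from a YAML or JSON file
#'
#' The file may describe either a manifest-based run (`manifest:` path) or a
#' simulated run (`simulate:` block with [simulation_spec()] fields, or a
#' named list of such blocks under `views:`). Remaining top-level keys map
#' to [run_config()] arguments.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @param seed Optional master-seed override.
#' @param output_dir Optional output-directory override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL, output_dir = NULL) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  input <- if (!is.null(cfg$manifest)) {
    cfg$manifest
  } else if (!is.null(cfg$views)) {
    lapply(cfg$views, function(block) do.call(simulation_spec, block))
  } else if (!is.null(cfg$simulate)) {
    do.call(simulation_spec, cfg$simulate)
  } else {
    fm_abort("Config needs a 'manifest', 'views' or 'simulate' entry.", "fm_config_error")
  }
  run_config(
    input = input,
    combine = cfg$combine,
    pve_threshold = cfg$pve_threshold %||% 0.99,
    k = cfg$k %||% 3,
    reps = cfg$reps %||% 20,
    train_fraction = cfg$train_fraction %||% 0.7,
    seed = seed %||% cfg$seed %||% 1,
    output_dir = output_dir %||% cfg$output_dir
  )
}
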