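#' Read a TPS landmark file
#'
#' Parses the plain-text TPS interchange format used by the tps software
#' family: records begin with `LM=<N>`, followed by `N` lines of
#' whitespace-separated x/y coordinates and optional `IMAGE=`, `ID=` and
#' `SCALE=` fields. Only 2D records are accepted; `LM3=` (3D) records and
#' `CURVES=`/`POINTS=` outline blocks are rejected. Coordinates are ingested
#' exactly as stored (image convention, no axis flip); downstream Procrustes
#' alignment is invariant to any consistent global reflection convention.
#'
#' @param path Path to a TPS file.
#' @param species_label Optional class label attached to every specimen in
#'   the file (column `label`).
#' @param view View name recorded in the `view` column, e.g. `"dorsal"`,
#'   `"jaw"`, `"lateral"`; default `"other"`.
#' @param apply_scale If `TRUE`, multiply coordinates by the record's
#'   `SCALE=` value when present. Default `FALSE`: the pipeline standardises
#'   size by Procrustes scaling, so physical units are irrelevant downstream.
#' @param landmark_types Optional character vector of length `N` with entries
#'   `"I"` (homologous landmark) or `"III"` (semilandmark), carried as
#'   annotation only — no differential treatment (no semilandmark sliding).
#'
#' @return A tibble with one row per landmark: columns `specimen_id`,
#'   `label`, `view`, `landmark` (digitisation order, never permuted),
#'   `type`, `x`, `y`, `scale`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=s1"), f)
#' read_tps(f)
read_tps <- function(path, species_label = NA_character_, view = "other",
                     apply_scale = FALSE, landmark_types = NULL) {
  if (!file.exists(path)) fm_abort(paste0("TPS file not found: ", path), "fm_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_lm3 <- grepl("^LM3=", lines, ignore.case = TRUE)
  if (any(is_lm3)) {
    fm_abort("TPS file contains LM3= (3D) records; only 2D LM= records are supported.",
             "fm_parse_error")
  }
  if (any(grepl("^(CURVES|POINTS)=", lines, ignore.case = TRUE))) {
    fm_abort("TPS file contains CURVES=/POINTS= outline blocks, which are not supported; store semilandmarks as ordinary landmarks.",
             "fm_parse_error")
  }
  starts <- grep("^LM=", lines, ignore.case = TRUE)
  if (length(starts) == 0) fm_abort("No LM= records found in TPS file.", "fm_parse_error")
  ends <- c(starts[-1] - 1L, length(lines))

  recs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    n_lm <- suppressWarnings(as.integer(sub("^LM=", "", block[1], ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 1) {
      fm_abort(paste0("Record ", r, ": malformed LM= count."), "fm_parse_error")
    }
    body <- block[-1]
    is_kv <- grepl("^[A-Za-z][A-Za-z0-9_]*=", body)
    coord_lines <- body[!is_kv]
    kv_lines <- body[is_kv]
    if (length(coord_lines) != n_lm) {
      fm_abort(paste0("Record ", r, ": LM=", n_lm, " but ", length(coord_lines),
                      " coordinate lines present."), "fm_parse_error")
    }
    xy <- t(vapply(coord_lines, function(l) {
      parts <- strsplit(l, "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || anyNA(vals)) {
        fm_abort(paste0("Record ", r, ": non-numeric or non-2D coordinate line: '", l, "'"),
                 "fm_parse_error")
      }
      vals
    }, numeric(2), USE.NAMES = FALSE))
    kv <- stats::setNames(
      sub("^[A-Za-z][A-Za-z0-9_]*=", "", kv_lines),
      toupper(sub("=.*$", "", kv_lines))
    )
    id <- if ("ID" %in% names(kv)) kv[["ID"]] else
      if ("IMAGE" %in% names(kv)) sub("\\.[A-Za-z]+$", "", basename(kv[["IMAGE"]])) else
        paste0("record_", r)
    scl <- if ("SCALE" %in% names(kv)) as.numeric(kv[["SCALE"]]) else NA_real_
    if (isTRUE(apply_scale) && !is.na(scl)) xy <- xy * scl
    recs[[r]] <- list(id = id, xy = xy, scale = scl, n = n_lm)
  }

  ns <- vapply(recs, `[[`, integer(1), "n")
  if (length(unique(ns)) > 1) {
    fm_abort(paste0("Inconsistent landmark counts across records: ",
                    paste(unique(ns), collapse = ", ")), "fm_validation_error")
  }
  n_lm <- ns[1]
  types <- resolve_types(landmark_types, n_lm)

  purrr::map_dfr(recs, function(rec) {
    tibble(
      specimen_id = rec$id,
      label = species_label,
      view = view,
      landmark = seq_len(n_lm),
      type = types,
      x = rec$xy[, 1],
      y = rec$xy[, 2],
      scale = rec$scale
    )
  })
}

resolve_types <- function(landmark_types, n_lm) {
  if (is.null(landmark_types)) return(rep("I", n_lm))
  if (length(landmark_types) != n_lm || !all(landmark_types %in% c("I", "III"))) {
    fm_abort("landmark_types must be length N with entries 'I' or 'III'.",
             "fm_validation_error")
  }
  as.character(landmark_types)
}

#' Write landmarks to a TPS file
#'
#' Emits the same dialect [read_tps()] accepts (`LM=`, coordinate lines,
#' `ID=`, optional `SCALE=`), preserving specimen order and six decimal
#' places of coordinate precision.
#'
#' @param data Landmark tibble as produced by [read_tps()].
#' @param path Output file path.
#' @param digits Coordinate decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_tps <- function(data, path, digits = 6) {
  data <- validate_landmarks(data)
  ids <- unique(data$specimen_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f")
  for (id in ids) {
    d <- data[data$specimen_id == id, ]
    writeLines(paste0("LM=", nrow(d)), con)
    writeLines(paste(sprintf(fmt, d$x), sprintf(fmt, d$y)), con)
    writeLines(paste0("ID=", id), con)
    scl <- d$scale[1]
    if (!is.null(scl) && !is.na(scl)) writeLines(paste0("SCALE=", scl), con)
  }
  invisible(path)
}

#' Validate a landmark tibble
#'
#' Checks the invariants every landmark dataset must satisfy: required
#' columns present, at least three landmarks, finite coordinates, identical
#' landmark count and ordering across specimens, unique specimen ids.
#'
#' @param data Landmark tibble (`specimen_id`, `landmark`, `x`, `y`, and
#'   optionally `label`, `view`, `type`, `scale`, `replicate`).
#' @return The validated tibble (missing optional columns filled), invisibly
#'   usable in a pipe.
#' @export
validate_landmarks <- function(data) {
  req <- c("specimen_id", "landmark", "x", "y")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    fm_abort(paste0("Landmark data lacks columns: ", paste(missing_cols, collapse = ", ")),
             "fm_validation_error")
  }
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    fm_abort("Non-finite coordinates in landmark data.", "fm_validation_error")
  }
  for (col in c("label", "view")) if (!col %in% names(data)) data[[col]] <- NA_character_
  if (!"type" %in% names(data)) data$type <- "I"
  if (!"scale" %in% names(data)) data$scale <- NA_real_
  key <- if ("replicate" %in% names(data)) {
    paste(data$specimen_id, data$replicate)
  } else {
    data$specimen_id
  }
  counts <- table(key)
  if (length(unique(as.integer(counts))) > 1) {
    fm_abort("All specimens must share the same number of landmarks.", "fm_validation_error")
  }
  n_lm <- as.integer(counts[1])
  if (n_lm < 3) fm_abort("At least 3 landmarks are required.", "fm_validation_error")
  ord <- unlist(tapply(data$landmark, key, identity, simplify = FALSE), use.names = FALSE)
  if (!all(unlist(tapply(data$landmark, key, function(l) identical(sort(l), seq_len(n_lm)), simplify = FALSE)))) {
    fm_abort("Each specimen must carry landmarks 1..N exactly once.", "fm_validation_error")
  }
  tibble::as_tibble(data)
}

# landmark tibble -> n x N x 2 array (specimens in first-appearance order)
lm_array <- function(data) {
  data <- validate_landmarks(data)
  data <- dplyr::arrange(data, match(.data$specimen_id, unique(data$specimen_id)), .data$landmark)
  ids <- unique(data$specimen_id)
  n_lm <- nrow(data) / length(ids)
  arr <- array(NA_real_, dim = c(length(ids), n_lm, 2),
               dimnames = list(ids, NULL, c("x", "y")))
  arr[, , 1] <- matrix(data$x, nrow = length(ids), byrow = TRUE)
  arr[, , 2] <- matrix(data$y, nrow = length(ids), byrow = TRUE)
  arr
}

# per-specimen metadata (label, view) in specimen first-appearance order
lm_meta <- function(data) {
  data <- validate_landmarks(data)
  dplyr::distinct(data, .data$specimen_id, .keep_all = TRUE)[, c("specimen_id", "label", "view")]
}

# n x N x 2 array (+ metadata tibble) -> landmark tibble
lm_tibble <- function(arr, meta = NULL, types = NULL) {
  n <- dim(arr)[1]; n_lm <- dim(arr)[2]
  ids <- dimnames(arr)[[1]]
  if (is.null(ids)) ids <- paste0("spec_", seq_len(n))
  out <- tibble(
    specimen_id = rep(ids, each = n_lm),
    landmark = rep(seq_len(n_lm), times = n),
    type = rep(if (is.null(types)) rep("I", n_lm) else types, times = n),
    x = as.vector(t(array(arr[, , 1], dim = dim(arr)[1:2]))),
    y = as.vector(t(array(arr[, , 2], dim = dim(arr)[1:2])))
  )
  if (!is.null(meta)) {
    out <- dplyr::left_join(out, meta, by = "specimen_id")
    out <- out[, c("specimen_id", "label", "view", "landmark", "type", "x", "y")]
  }
  out
}

#' Average digitisation replicates
#'
#' Repeated digitisation of the same specimens quantifies observer error;
#' the arithmetic per-landmark mean over replicates is the configuration
#' carried forward into alignment. Averaging happens on raw coordinates,
#' before any Procrustes standardisation.
#'
#' @param replicates Either a single landmark tibble with a `replicate`
#'   column, or a list of landmark tibbles (one per replicate round).
#' @return A landmark tibble with one configuration per specimen (the
#'   coordinate-wise mean), metadata taken from the first replicate.
#' @export
average_replicates <- function(replicates) {
  data <- bind_replicates(replicates)
  reps <- unique(data$replicate)
  sets <- lapply(reps, function(r) validate_landmarks(data[data$replicate == r, ]))
  ids <- sort(unique(sets[[1]]$specimen_id))
  n_lm <- sum(sets[[1]]$specimen_id == ids[1])
  for (s in seq_along(sets)) {
    ids_s <- sort(unique(sets[[s]]$specimen_id))
    missing_ids <- union(setdiff(ids, ids_s), setdiff(ids_s, ids))
    if (length(missing_ids) > 0) {
      fm_abort(paste0("Specimen ids differ across replicates: ",
                      paste(missing_ids, collapse = ", ")), "fm_validation_error")
    }
    if (sum(sets[[s]]$specimen_id == ids[1]) != n_lm) {
      fm_abort("Landmark count differs across replicates.", "fm_validation_error")
    }
  }
  out <- data %>%
    dplyr::group_by(.data$specimen_id, .data$landmark) %>%
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  meta <- dplyr::distinct(sets[[1]], .data$specimen_id,
                          .data$label, .data$view, .data$type, .data$landmark, .data$scale)
  out <- dplyr::left_join(out, meta, by = c("specimen_id", "landmark"))
  out <- dplyr::arrange(out, match(.data$specimen_id, unique(sets[[1]]$specimen_id)), .data$landmark)
  out[, c("specimen_id", "label", "view", "landmark", "type", "x", "y", "scale")]
}

bind_replicates <- function(replicates) {
  if (is.data.frame(replicates)) {
    if (!"replicate" %in% names(replicates)) replicates$replicate <- 1L
    return(replicates)
  }
  if (!is.list(replicates) || length(replicates) < 1) {
    fm_abort("replicates must be a landmark tibble or a non-empty list of them.",
             "fm_usage_error")
  }
  purrr::imap_dfr(replicates, function(d, i) {
    d$replicate <- as.integer(i)
    d
  })
}

#' Per-replicate digitisation error
#'
#' Measures, for each replicate round, the root-mean-square per-landmark
#' deviation from the replicate average; zero for every round iff all
#' rounds digitised identical coordinates.
#'
#' @inheritParams average_replicates
#' @return A tibble with columns `replicate` and `rms_deviation`.
#' @export
replicate_error <- function(replicates) {
  data <- bind_replicates(replicates)
  avg <- average_replicates(data)
  joined <- dplyr::left_join(
    data, avg[, c("specimen_id", "landmark", "x", "y")],
    by = c("specimen_id", "landmark"), suffix = c("", "_mean")
  )
  joined %>%
    dplyr::group_by(.data$replicate) %>%
    dplyr::summarise(
      rms_deviation = sqrt(mean((.data$x - .data$x_mean)^2 + (.data$y - .data$y_mean)^2)),
      .groups = "drop"
    )
}
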