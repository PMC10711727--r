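# Pattern-set handling: validation of the long-format beta table, CSV
# round-tripping, and per-subject RDM computation.

pattern_columns <- function() {
  c("subject", "roi", "phase", "condition_id", "voxel", "beta")
}

#' Validate a long-format pattern table
#'
#' Checks column presence, numeric betas, duplicate index rows, and that the
#' `subject x roi x phase x condition x voxel` crossing is complete.
#'
#' @param patterns Data frame with the columns of [pattern_columns()].
#' @return The validated tibble (invisibly classed as `pattern_set`).
#' @export
validate_patterns <- function(patterns) {
  missing <- setdiff(pattern_columns(), names(patterns))
  if (length(missing) > 0) {
    abort(paste0("pattern table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.numeric(patterns$beta)) abort("column 'beta' must be numeric")
  if (anyNA(patterns$beta) || any(!is.finite(patterns$beta))) {
    abort("column 'beta' must be finite and non-missing")
  }
  idx <- paste(patterns$subject, patterns$roi, patterns$phase,
               patterns$condition_id, patterns$voxel, sep = "\r")
  if (anyDuplicated(idx) > 0) {
    d <- patterns[duplicated(idx), ][1, ]
    abort(paste0("duplicate pattern rows, e.g. subject=", d$subject,
                 " roi=", d$roi, " phase=", d$phase,
                 " condition=", d$condition_id, " voxel=", d$voxel))
  }
  counts <- dplyr::count(patterns, .data$subject, .data$roi, .data$phase,
                         .data$condition_id)
  expected <- length(unique(patterns$voxel))
  full <- tidyr::expand_grid(
    subject = unique(patterns$subject), roi = unique(patterns$roi),
    phase = unique(patterns$phase),
    condition_id = unique(patterns$condition_id)
  )
  counts <- dplyr::left_join(full, counts,
                             by = c("subject", "roi", "phase", "condition_id"))
  bad <- counts[is.na(counts$n) | counts$n != expected, ]
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(paste0("incomplete pattern crossing: subject=", b$subject,
                 " roi=", b$roi, " phase=", b$phase,
                 " condition=", b$condition_id, " has ",
                 ifelse(is.na(b$n), 0L, b$n), " of ", expected, " voxels"))
  }
  if (!inherits(patterns, "pattern_set")) {
    class(patterns) <- c("pattern_set", class(patterns))
  }
  invisible(patterns)
}

#' Write / read a pattern set as CSV
#'
#' Long format with columns `subject, roi, phase, condition_id, voxel, beta`;
#' the canonical interchange format of the pipeline.
#'
#' @param patterns A pattern tibble.
#' @param path File path.
#' @return `read_patterns()` returns a validated `pattern_set` tibble sorted
#'   in a stable index order.
#' @export
write_patterns <- function(patterns, path) {
  validate_patterns(patterns)
  readr::write_csv(patterns[pattern_columns()], path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_double(), roi = readr::col_character(),
    phase = readr::col_character(), condition_id = readr::col_double(),
    voxel = readr::col_double(), beta = readr::col_double()
  ))
  out <- dplyr::arrange(out, .data$subject, .data$roi, .data$phase,
                        .data$condition_id, .data$voxel)
  validate_patterns(out)
  out
}

#' Per-subject neural RDMs from a pattern set
#'
#' Computes one correlation-distance RDM per `subject x roi x phase` cell
#' via [compute_rdm()].
#'
#' @param patterns A validated pattern tibble.
#' @param design A design tibble supplying condition labels.
#' @param zscore_voxels Passed to [compute_rdm()].
#' @return Nested tibble with columns `subject`, `roi`, `phase`, `rdm`
#'   (list of [rdm] objects).
#' @export
subject_rdms <- function(patterns, design = build_design(),
                         zscore_voxels = FALSE) {
  validate_patterns(patterns)
  validate_design(design)
  labels <- design$label[order(design$condition_id)]
  cond_ids <- sort(design$condition_id)
  patterns |>
    dplyr::group_by(.data$subject, .data$roi, .data$phase) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(rdm = purrr::map(.data$data, function(d) {
      wide <- tidyr::pivot_wider(d, id_cols = "condition_id",
                                 names_from = "voxel", values_from = "beta")
      wide <- dplyr::arrange(wide, .data$condition_id)
      if (!identical(as.integer(wide$condition_id), as.integer(cond_ids))) {
        abort("pattern conditions do not match the design")
      }
      mat <- as.matrix(wide[, -1])
      rownames(mat) <- labels
      compute_rdm(mat, zscore_voxels = zscore_voxels)
    })) |>
    dplyr::select("subject", "roi", "phase", "rdm")
}

#' Group-average RDM per region and phase
#'
#' @param patterns A validated pattern tibble (or the output of
#'   [subject_rdms()]).
#' @param design A design tibble.
#' @param zscore_voxels Passed to [compute_rdm()].
#' @return Tibble with columns `roi`, `phase`, `rdm` (list of subject-mean
#'   [rdm] objects).
#' @export
average_subject_rdms <- function(patterns, design = build_design(),
                                 zscore_voxels = FALSE) {
  per_subject <- if (is.data.frame(patterns) && "rdm" %in% names(patterns)) {
    patterns
  } else {
    subject_rdms(patterns, design, zscore_voxels)
  }
  per_subject |>
    dplyr::group_by(.data$roi, .data$phase) |>
    dplyr::summarise(rdm = list(average_rdms(.data$rdm)), .groups = "drop")
}
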