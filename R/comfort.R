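# Grasp-comfort analysis: paired factor contrasts on ratings, per-subject
# comfort RDMs, and correlation of comfort geometry with model RDMs and
# with neural RDMs.

validate_ratings <- function(ratings, design) {
  missing <- setdiff(c("subject", "condition_id", "rating"), names(ratings))
  if (length(missing) > 0) {
    abort(paste0("ratings are missing columns: ", paste(missing, collapse = ", ")))
  }
  counts <- dplyr::count(ratings, .data$subject)
  if (any(counts$n != nrow(design))) {
    abort("every subject must rate every condition exactly once")
  }
  if (anyNA(ratings$rating)) abort("ratings must not be missing")
  invisible(ratings)
}

#' Paired t test on ratings between the two levels of a factor
#'
#' Averages each subject's ratings within each level of the factor, then
#' runs a two-tailed paired t test on the per-subject level differences
#' (level 2 minus level 1; df = n - 1).
#'
#' @param ratings Tibble with columns `subject`, `condition_id`, `rating`.
#' @param design A design tibble.
#' @param factor_name One of the three grasp factors.
#' @return Tibble with one row: `factor`, `level_1`, `level_2`,
#'   `mean_difference`, `t`, `df`, `p_value`.
#' @export
level_contrast_ttest <- function(ratings, design = build_design(),
                                 factor_name) {
  validate_design(design)
  validate_ratings(ratings, design)
  fac <- grasp_factors()
  if (!factor_name %in% names(fac)) {
    abort(paste0("unknown factor name: ", factor_name))
  }
  levels <- fac[[factor_name]]
  joined <- dplyr::left_join(ratings,
                             design[, c("condition_id", factor_name)],
                             by = "condition_id")
  per_level <- joined |>
    dplyr::group_by(.data$subject, level = .data[[factor_name]]) |>
    dplyr::summarise(rating = mean(.data$rating), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "level", values_from = "rating")
  diffs <- per_level[[levels[2]]] - per_level[[levels[1]]]
  if (sd(diffs) == 0) {
    abort("zero variance of paired differences: t statistic is undefined")
  }
  tt <- t.test(diffs)
  tibble::tibble(
    factor = factor_name, level_1 = levels[1], level_2 = levels[2],
    mean_difference = mean(diffs),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Comfort RDM for one subject
#'
#' Entry (i, j) is the absolute difference between the subject's ratings of
#' conditions i and j: a symmetric, zero-diagonal, non-negative
#' dissimilarity, invariant to shifting all ratings by a constant.
#'
#' @param ratings Tibble with columns `condition_id`, `rating` for one
#'   subject (all nine conditions present).
#' @param design A design tibble supplying labels.
#' @return An [rdm].
#' @export
comfort_rdm <- function(ratings, design = build_design()) {
  validate_design(design)
  design <- dplyr::arrange(design, .data$condition_id)
  miss <- setdiff(design$condition_id, ratings$condition_id)
  if (length(miss) > 0) {
    abort(paste0("missing rating for condition(s): ", paste(miss, collapse = ", ")))
  }
  r <- ratings$rating[match(design$condition_id, ratings$condition_id)]
  rdm(abs(outer(r, r, `-`)), labels = design$label)
}

#' Per-subject and average comfort RDMs
#'
#' @param ratings Tibble with columns `subject`, `condition_id`, `rating`.
#' @param design A design tibble.
#' @return List with `per_subject` (named list of [rdm]) and `average`.
#' @export
comfort_rdms <- function(ratings, design = build_design()) {
  validate_ratings(ratings, design)
  subs <- sort(unique(ratings$subject))
  per_subject <- lapply(subs, function(s) {
    comfort_rdm(ratings[ratings$subject == s, ], design)
  })
  names(per_subject) <- subs
  list(per_subject = per_subject, average = average_rdms(per_subject))
}

#' Correlations between comfort geometry and the model RDMs
#'
#' For each grasp factor, correlates every subject's comfort RDM with the
#' binary model RDM and tests the per-subject correlations against zero with
#' the one-tailed Wilcoxon signed-rank test (as in the neural analysis).
#' The correlation of the group-average comfort RDM with each model is
#' reported descriptively alongside.
#'
#' @param ratings Tibble with columns `subject`, `condition_id`, `rating`.
#' @param design A design tibble.
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble with one row per model: `model`, `mean_r`, `avg_rdm_r`,
#'   `statistic`, `p_value`, `n`.
#' @export
comfort_model_correlations <- function(ratings, design = build_design(),
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  crdms <- comfort_rdms(ratings, design)
  mods <- model_rdms(design)
  purrr::map(names(mods), function(m) {
    r <- model_data_correlations(crdms$per_subject, mods[[m]], method)
    wt <- if (all(r == 0)) {
      # comfort geometry exactly orthogonal to this model for every subject:
      # no evidence in either direction
      list(statistic = NA_real_, p_value = NA_real_)
    } else {
      wilcoxon_greater(r)
    }
    tibble::tibble(
      model = m, mean_r = mean(r),
      avg_rdm_r = correlate_rdms(crdms$average, mods[[m]], method),
      statistic = wt$statistic, p_value = wt$p_value, n = length(r)
    )
  }) |> dplyr::bind_rows()
}

#' Search for neural encoding of grasp comfort
#'
#' Correlates each subject's neural RDM in every region and phase with the
#' group-average comfort RDM, then applies the same group inference as the
#' first-order analysis: one-tailed Wilcoxon signed-rank test per region and
#' phase, Benjamini-Hochberg FDR across regions within each phase, and
#' noise ceilings.
#'
#' @param avg_comfort_rdm The group-average comfort [rdm] (see
#'   [comfort_rdms()]).
#' @param patterns Long pattern tibble.
#' @param design A design tibble.
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha FDR level.
#' @param zero_method Wilcoxon zero handling.
#' @return Tibble with one row per `roi x phase`: `n`, `mean_r`,
#'   `statistic`, `p_raw`, `p_fdr`, `significant`, `ceiling_lower`,
#'   `ceiling_upper`, `subject_r` list-column.
#' @export
comfort_neural_rsa <- function(avg_comfort_rdm, patterns,
                               design = build_design(),
                               method = c("pearson", "spearman"),
                               alpha = 0.05,
                               zero_method = c("wilcox", "pratt")) {
  method <- match.arg(method)
  zero_method <- match.arg(zero_method)
  if (sd(vectorize_upper(avg_comfort_rdm)$value) == 0) {
    abort("constant comfort RDM: correlations are undefined")
  }
  per_subject <- subject_rdms(patterns, design)
  cells <- per_subject |>
    dplyr::group_by(.data$roi, .data$phase) |>
    dplyr::summarise(rdms = list(.data$rdm[order(.data$subject)]),
                     .groups = "drop")
  out <- purrr::pmap(cells, function(roi, phase, rdms) {
    r <- model_data_correlations(rdms, avg_comfort_rdm, method)
    wt <- wilcoxon_greater(r, zero_method = zero_method)
    ceiling <- if (length(rdms) >= 2) noise_ceiling(rdms, method)
               else list(lower = NA_real_, upper = NA_real_)
    tibble::tibble(
      roi = roi, phase = phase, n = length(r), mean_r = mean(r),
      statistic = wt$statistic, p_raw = wt$p_value,
      ceiling_lower = ceiling$lower, ceiling_upper = ceiling$upper,
      subject_r = list(r)
    )
  }) |> dplyr::bind_rows()
  out$p_fdr <- NA_real_
  for (ph in unique(out$phase)) {
    sel <- out$phase == ph
    out$p_fdr[sel] <- fdr_bh(out$p_raw[sel], q = alpha)$p_adjusted
  }
  out$significant <- out$p_fdr < alpha
  out[, c("roi", "phase", "n", "mean_r", "statistic", "p_raw", "p_fdr",
          "significant", "ceiling_lower", "ceiling_upper", "subject_r")]
}

#' Full comfort-rating analysis
#'
#' Runs the three factor contrasts, builds comfort RDMs, correlates comfort
#' geometry with the model RDMs, and (when patterns are supplied) with
#' neural RDMs in every region and phase.
#'
#' @param ratings Tibble with columns `subject`, `condition_id`, `rating`.
#' @param design A design tibble.
#' @param patterns Optional long pattern tibble for the neural comparison.
#' @param method,alpha Passed through to the component analyses.
#' @return A `comfort_result` list with elements `contrasts`,
#'   `model_correlations`, `average_rdm`, and `neural` (or `NULL`).
#' @export
run_comfort_analysis <- function(ratings, design = build_design(),
                                 patterns = NULL,
                                 method = c("pearson", "spearman"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  contrasts <- dplyr::bind_rows(lapply(names(grasp_factors()), function(f) {
    level_contrast_ttest(ratings, design, f)
  }))
  crdms <- comfort_rdms(ratings, design)
  model_cor <- comfort_model_correlations(ratings, design, method)
  neural <- if (!is.null(patterns)) {
    comfort_neural_rsa(crdms$average, patterns, design, method, alpha)
  }
  structure(list(contrasts = contrasts, model_correlations = model_cor,
                 average_rdm = crdms$average, per_subject_rdms = crdms$per_subject,
                 neural = neural, alpha = alpha, method = method),
            class = "comfort_result")
}

#' @export
print.comfort_result <- function(x, ...) {
  cat("<comfort_result>\nFactor contrasts:\n")
  print(x$contrasts)
  cat("\nModel correlations:\n")
  print(x$model_correlations)
  if (!is.null(x$neural)) {
    cat("\nNeural correlations: ", nrow(x$neural), " region x phase cells, ",
        sum(x$neural$significant), " significant\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.comfort_result <- function(x, ...) x$contrasts

#' @export
glance.comfort_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$model_correlations$n[1],
    mass_model_r = x$model_correlations$mean_r[
      x$model_correlations$model == "object_mass"],
    n_neural_significant = if (is.null(x$neural)) NA_integer_
                           else sum(x$neural$significant),
    alpha = x$alpha, method = x$method
  )
}
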