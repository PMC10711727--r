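# First-order RSA: per-subject model-RDM correlations per region and phase,
# noise ceilings, one-tailed Wilcoxon signed-rank group inference, and
# Benjamini-Hochberg FDR control.

#' One-tailed Wilcoxon signed-rank test (greater)
#'
#' Tests H0: the distribution of `x` is symmetric about zero against H1: it
#' is shifted upward. The p-value is exact whenever that is tractable: up to
#' `enum_max` non-zero values the full null distribution of the
#' positive-rank sum is enumerated over all 2^n sign patterns (correct even
#' with tied absolute values); with no ties it is exact up to `exact_max`
#' values via the closed-form signed-rank distribution. Beyond that a
#' normal approximation with tie and continuity corrections is used.
#'
#' @param x Numeric vector.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"` (rank
#'   with zeros included, then drop their ranks; always uses the normal
#'   approximation).
#' @param exact_max Largest n for which the closed-form exact distribution
#'   is used (no ties).
#' @param enum_max Largest n for which full sign-pattern enumeration is used
#'   when ties are present.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `n` (values used) and `exact` (logical).
#' @export
wilcoxon_greater <- function(x, zero_method = c("wilcox", "pratt"),
                             exact_max = 25L, enum_max = 14L) {
  zero_method <- match.arg(zero_method)
  if (anyNA(x)) abort("x must not contain NA")
  if (all(x == 0)) abort("all values are zero: no information for a signed-rank test")
  n_zero <- sum(x == 0)
  if (zero_method == "wilcox") {
    x_use <- x[x != 0]
    r <- rank(abs(x_use))
    n <- length(x_use)
    W <- sum(r[x_use > 0])
    ties <- any(duplicated(abs(x_use)))
    if (!ties && n <= exact_max) {
      # exact: P(W+ >= W) under the uniform distribution over sign patterns
      p <- psignrank(W - 1, n, lower.tail = FALSE)
      return(list(statistic = W, p_value = p, n = n, exact = TRUE))
    }
    if (ties && n <= enum_max) {
      # exact even with ties: enumerate all sign patterns of the ranks
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      w_all <- as.vector(signs %*% r)
      p <- mean(w_all >= W - 1e-9)
      return(list(statistic = W, p_value = p, n = n, exact = TRUE))
    }
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
  } else {
    r_all <- rank(abs(x))
    n <- length(x)
    n0 <- n_zero
    W <- sum(r_all[x > 0])
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    tie_tab <- table(r_all[x != 0])
    sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    n <- n - n0
  }
  if (sig2 <= 0) abort("degenerate signed-rank distribution (no variance)")
  z <- (W - mu - 0.5) / sqrt(sig2)
  list(statistic = W, p_value = pnorm(z, lower.tail = FALSE), n = n,
       exact = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control. Adjusted p-values are the standard
#' monotone BH values (`p * m / rank`, with a running minimum enforced from
#' the largest rank downward); the rejection mask is `p_adjusted < q`.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = adj < q)
}

#' Per-subject correlations between neural RDMs and one model RDM
#'
#' @param rdms List of subject [rdm] objects (matching labels).
#' @param model An [rdm] (e.g. from [model_rdm()]).
#' @param method `"pearson"` or `"spearman"`.
#' @return Numeric vector, one correlation per subject.
#' @export
model_data_correlations <- function(rdms, model,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(rdms) < 1) abort("need at least one subject RDM")
  vapply(rdms, correlate_rdms, numeric(1), b = model, method = method)
}

#' Noise ceiling for a set of subject RDMs
#'
#' Bounds on the group-mean model correlation attainable given
#' between-subject variability. The upper bound is the mean correlation of
#' each subject's RDM with the grand-mean RDM (which includes that subject);
#' the lower bound is the mean correlation of each subject's RDM with the
#' mean RDM of the remaining subjects. All correlations use upper-triangle
#' vectors only.
#'
#' @param rdms List of at least two subject [rdm] objects.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `lower` and `upper`.
#' @export
noise_ceiling <- function(rdms, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(rdms)
  if (n < 2) abort("noise ceiling needs at least two subjects")
  vecs <- vapply(rdms, function(r) vectorize_upper(r)$value,
                 numeric(nrow(pair_index(nrow(rdms[[1]])))))
  grand <- rowMeans(vecs)
  if (sd(grand) == 0) abort("constant mean RDM: noise ceiling is undefined")
  upper <- mean(vapply(seq_len(n), function(i) {
    cor(vecs[, i], grand, method = method)
  }, numeric(1)))
  lower <- mean(vapply(seq_len(n), function(i) {
    loo <- rowMeans(vecs[, -i, drop = FALSE])
    cor(vecs[, i], loo, method = method)
  }, numeric(1)))
  list(lower = lower, upper = upper)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Utility for error bars on group-mean correlations.
#'
#' @param x Numeric vector.
#' @param level Confidence level.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for resampling.
#' @return List with `lower`, `upper`.
#' @export
bootstrap_mean_ci <- function(x, level = 0.95, n_boot = 2000L, seed = 1L) {
  withr::with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i) {
      mean(sample(x, replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - level) / 2
  list(lower = unname(quantile(means, a)), upper = unname(quantile(means, 1 - a)))
}

#' First-order RSA across regions, phases and models
#'
#' For every region x phase cell, computes each subject's neural RDM once,
#' correlates it with each binary model RDM, tests the group of per-subject
#' correlations against zero with a one-tailed Wilcoxon signed-rank test,
#' estimates the noise ceiling, and controls the false discovery rate with
#' Benjamini-Hochberg within the configured family of tests.
#'
#' @param patterns Long pattern tibble (see [generate_patterns()] /
#'   [read_patterns()]).
#' @param design A design tibble.
#' @param models Character vector of factors to test.
#' @param method `"pearson"` or `"spearman"` for all RDM-to-RDM correlations
#'   (model correlations and noise ceilings alike).
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @param fdr_family Family within which BH correction is applied:
#'   `"per_model_phase"` (default: across regions, separately per model and
#'   phase, matching per-panel presentation), `"per_phase"`, or `"global"`.
#' @param zero_method Zero handling for the Wilcoxon test.
#' @param fisher_z If `TRUE`, the reported `mean_r` is the inverse-transformed
#'   mean Fisher z; default is the plain mean correlation.
#' @param zscore_voxels Passed to [compute_rdm()].
#' @return An `rsa_first_order` tibble: one row per `roi x phase x model`
#'   with columns `n`, `mean_r`, `statistic`, `p_raw`, `p_fdr`,
#'   `significant`, `ceiling_lower`, `ceiling_upper` and a `subject_r`
#'   list-column.
#' @export
run_first_order <- function(patterns, design = build_design(),
                            models = names(grasp_factors()),
                            method = c("pearson", "spearman"),
                            alpha = 0.05,
                            fdr_family = c("per_model_phase", "per_phase",
                                           "global"),
                            zero_method = c("wilcox", "pratt"),
                            fisher_z = FALSE,
                            zscore_voxels = FALSE) {
  method <- match.arg(method)
  fdr_family <- match.arg(fdr_family)
  zero_method <- match.arg(zero_method)
  validate_design(design)
  per_subject <- subject_rdms(patterns, design, zscore_voxels)
  mods <- model_rdms(design)
  bad <- setdiff(models, names(mods))
  if (length(bad) > 0) abort(paste0("unknown model(s): ", paste(bad, collapse = ", ")))
  cells <- per_subject |>
    dplyr::group_by(.data$roi, .data$phase) |>
    dplyr::summarise(rdms = list(.data$rdm[order(.data$subject)]),
                     .groups = "drop")
  rows <- purrr::pmap(cells, function(roi, phase, rdms) {
    ceiling <- if (length(rdms) >= 2) {
      noise_ceiling(rdms, method)
    } else {
      list(lower = NA_real_, upper = NA_real_)
    }
    purrr::map(models, function(m) {
      r <- model_data_correlations(rdms, mods[[m]], method)
      wt <- wilcoxon_greater(r, zero_method = zero_method)
      mean_r <- if (fisher_z) tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))))
                else mean(r)
      tibble::tibble(
        roi = roi, phase = phase, model = m, n = length(r),
        mean_r = mean_r, statistic = wt$statistic, p_raw = wt$p_value,
        ceiling_lower = ceiling$lower, ceiling_upper = ceiling$upper,
        subject_r = list(r)
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(match(.data$model, models), .data$phase, .data$roi)
  fam <- switch(fdr_family,
    per_model_phase = paste(out$model, out$phase),
    per_phase = out$phase,
    global = rep("all", nrow(out))
  )
  out$p_fdr <- NA_real_
  for (f in unique(fam)) {
    sel <- fam == f
    out$p_fdr[sel] <- fdr_bh(out$p_raw[sel], q = alpha)$p_adjusted
  }
  out$significant <- out$p_fdr < alpha
  out <- out[, c("roi", "phase", "model", "n", "mean_r", "statistic",
                 "p_raw", "p_fdr", "significant", "ceiling_lower",
                 "ceiling_upper", "subject_r")]
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  attr(out, "fdr_family") <- fdr_family
  class(out) <- c("rsa_first_order", class(out))
  out
}

#' @export
tidy.rsa_first_order <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$subject_r <- NULL
  out
}

#' @export
glance.rsa_first_order <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    method = attr(x, "method"),
    fdr_family = attr(x, "fdr_family")
  )
}

#' Bar plot of first-order RSA results with noise ceilings
#'
#' One panel per model x phase; bars are group-mean correlations, the grey
#' band is the noise ceiling, bright bars are FDR-significant.
#'
#' @param object An `rsa_first_order` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsa_first_order <- function(object, ...) {
  df <- tidy(object)
  df$roi <- factor(df$roi, levels = unique(df$roi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data$mean_r)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.numeric(.data$roi) - 0.45, xmax = as.numeric(.data$roi) + 0.45,
      ymin = .data$ceiling_lower, ymax = .data$ceiling_upper),
      fill = "grey80", alpha = 0.6) +
    ggplot2::geom_col(ggplot2::aes(alpha = .data$significant), fill = "#2166ac") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                name = "FDR significant") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$phase),
                        cols = ggplot2::vars(.data$model)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "mean model-RDM correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
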