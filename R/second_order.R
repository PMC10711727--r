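# Second-order RSA: correlations between group-average RDMs of different
# regions, within one task phase or across planning and execution, with
# Bonferroni-thresholded significance, hierarchical clustering and classical
# multidimensional scaling of the inter-region similarity structure.

rdm_vec_list <- function(rdms) {
  if (is.null(names(rdms))) abort("RDM list must be named by region")
  vecs <- lapply(rdms, function(r) vectorize_upper(r)$value)
  if (length(unique(lengths(vecs))) != 1) abort("RDMs differ in size")
  for (nm in names(vecs)) {
    if (sd(vecs[[nm]]) == 0) {
      abort(paste0("RDM for region '", nm, "' has a constant vector"))
    }
  }
  vecs
}

#' Parametric p-value for an RDM-to-RDM correlation
#'
#' Two-tailed t-transform with `n - 2` degrees of freedom, where n is the
#' number of upper-triangle entries (36 for nine conditions). The entries of
#' an RDM vector are not strictly independent, so this test is approximate;
#' [inter_roi_similarity()] offers a condition-label permutation test as the
#' safer alternative.
#'
#' @param r Correlation value.
#' @param n_pairs Number of vector entries.
#' @return Two-tailed p-value.
#' @export
rdm_cor_pvalue <- function(r, n_pairs) {
  if (n_pairs < 3) abort("need at least three vector entries")
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n_pairs - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t_stat), df = n_pairs - 2)
}

# Permutations of condition labels induce permutations of the upper-triangle
# pair order; rows of the returned matrix index the permuted vector.
permuted_pair_orders <- function(n_conditions, n_perm, seed) {
  pr <- pair_index(n_conditions)
  key <- matrix(0L, n_conditions, n_conditions)
  key[cbind(pr$i, pr$j)] <- seq_len(nrow(pr))
  key <- key + t(key)
  withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(k) {
      perm <- sample.int(n_conditions)
      key[cbind(perm[pr$i], perm[pr$j])]
    }, integer(nrow(pr))))
  })
}

perm_pvalues <- function(va, vb_mat, r_obs) {
  # va: numeric vector; vb_mat: n_perm x n_pairs matrix of permuted b vectors
  r_perm <- suppressWarnings(cor(va, t(vb_mat)))
  mean_ge <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (ncol(r_perm) + 1)
  mean_ge
}

second_order_result <- function(matrix, p_matrix, m, alpha, phase_pair,
                                method, test, linkage = NULL,
                                embedding = NULL) {
  mask <- p_matrix < alpha / m
  edges <- which(!is.na(p_matrix), arr.ind = TRUE)
  labs_row <- rownames(matrix); labs_col <- colnames(matrix)
  within_phase <- identical(phase_pair[1], phase_pair[2])
  if (within_phase) edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  edge_tbl <- tibble::tibble(
    roi_a = labs_row[edges[, 1]], roi_b = labs_col[edges[, 2]],
    r = matrix[edges], p = p_matrix[edges],
    significant = mask[edges]
  )
  structure(list(
    phase_pair = phase_pair, matrix = matrix, p_matrix = p_matrix,
    significant_mask = mask, m = m, alpha = alpha, method = method,
    test = test, linkage = linkage, embedding = embedding, edges = edge_tbl
  ), class = "second_order")
}

#' @export
print.second_order <- function(x, ...) {
  cat("<second_order: ", x$phase_pair[1], " vs ", x$phase_pair[2],
      ", ", nrow(x$matrix), " regions, ", x$m, " tests, ",
      sum(x$significant_mask[!is.na(x$significant_mask)]),
      " significant at alpha/m>\n", sep = "")
  invisible(x)
}

#' Inter-region similarity within one phase
#'
#' Correlates the group-average RDMs of every pair of regions (upper-triangle
#' vectors), tests each correlation against zero, and Bonferroni-thresholds
#' over the `R(R-1)/2` unique pairs. Also returns average-linkage
#' hierarchical clustering and a 2D classical MDS embedding of the
#' inter-region structure (both on distance `1 - r`).
#'
#' @param rdms Named list (region -> [rdm]) of group-average RDMs, all with
#'   identical condition labels.
#' @param method `"pearson"` or `"spearman"`.
#' @param test `"parametric"` (t-transform, default) or `"permutation"`
#'   (condition-label permutations).
#' @param n_perm Number of permutations when `test = "permutation"`.
#' @param alpha Significance level before Bonferroni division.
#' @param bonferroni_m Number of tests to correct over; defaults to the
#'   number of unique pairs.
#' @param linkage Linkage for hierarchical clustering.
#' @param seed Seed for the permutation test.
#' @param phase Phase label recorded in the result.
#' @return A `second_order` object: correlation matrix, p-value matrix,
#'   Bonferroni mask, `m`, linkage tree, embedding and an edge table.
#' @export
inter_roi_similarity <- function(rdms, method = c("pearson", "spearman"),
                                 test = c("parametric", "permutation"),
                                 n_perm = 10000L, alpha = 0.05,
                                 bonferroni_m = NULL,
                                 linkage = c("average", "single", "complete"),
                                 seed = 1L, phase = "phase") {
  method <- match.arg(method)
  test <- match.arg(test)
  linkage <- match.arg(linkage)
  if (length(rdms) < 2) abort("need at least two regions")
  vecs <- rdm_vec_list(rdms)
  R <- length(vecs)
  labs <- names(vecs)
  V <- do.call(cbind, vecs)
  cmat <- cor(V, method = method)
  n_pairs <- nrow(V)
  m <- bonferroni_m %||% (R * (R - 1) / 2)
  pmat <- matrix(NA_real_, R, R, dimnames = list(labs, labs))
  if (test == "parametric") {
    pv <- rdm_cor_pvalue(cmat, n_pairs)
    pmat[] <- pv
  } else {
    n_cond <- nrow(rdms[[1]])
    ranked <- if (method == "spearman") apply(V, 2, rank) else V
    orders <- permuted_pair_orders(n_cond, n_perm, seed)
    for (a in seq_len(R)) {
      for (b in seq_len(R)) {
        if (a == b) { pmat[a, b] <- 0; next }
        if (b < a) { pmat[a, b] <- pmat[b, a]; next }
        vb_perm <- matrix(ranked[, b][orders], nrow = n_perm)
        pmat[a, b] <- perm_pvalues(ranked[, a], vb_perm, cmat[a, b])
      }
    }
  }
  diag(pmat) <- NA_real_
  tree <- hierarchical_cluster(cmat, linkage = linkage)
  emb <- if (R >= 3) mds_embed(cmat) else NULL
  second_order_result(cmat, pmat, m, alpha, c(phase, phase), method, test,
                      linkage = tree, embedding = emb)
}

#' Inter-region similarity across planning and execution
#'
#' Correlates every planning-phase region's average RDM with every
#' execution-phase region's average RDM (full R x R matrix, rows = planning,
#' columns = execution, diagonal self-pairs included) and Bonferroni-corrects
#' over all `R^2` tests.
#'
#' @param rdms_planning,rdms_execution Named lists (region -> [rdm]) with
#'   the same region set and condition labels.
#' @inheritParams inter_roi_similarity
#' @return A `second_order` object (no clustering/embedding: the matrix is
#'   not symmetric).
#' @export
cross_phase_similarity <- function(rdms_planning, rdms_execution,
                                   method = c("pearson", "spearman"),
                                   test = c("parametric", "permutation"),
                                   n_perm = 10000L, alpha = 0.05,
                                   bonferroni_m = NULL, seed = 1L) {
  method <- match.arg(method)
  test <- match.arg(test)
  if (!setequal(names(rdms_planning), names(rdms_execution))) {
    abort("planning and execution region sets differ")
  }
  rdms_execution <- rdms_execution[names(rdms_planning)]
  va <- rdm_vec_list(rdms_planning)
  vb <- rdm_vec_list(rdms_execution)
  labs <- names(va)
  A <- do.call(cbind, va); B <- do.call(cbind, vb)
  R <- ncol(A)
  cmat <- cor(A, B, method = method)
  dimnames(cmat) <- list(labs, labs)
  m <- bonferroni_m %||% (R * R)
  pmat <- matrix(NA_real_, R, R, dimnames = list(labs, labs))
  if (test == "parametric") {
    pmat[] <- rdm_cor_pvalue(cmat, nrow(A))
  } else {
    n_cond <- nrow(rdms_planning[[1]])
    rankfun <- function(M) if (method == "spearman") apply(M, 2, rank) else M
    A2 <- rankfun(A); B2 <- rankfun(B)
    orders <- permuted_pair_orders(n_cond, n_perm, seed)
    for (b in seq_len(R)) {
      vb_perm <- matrix(B2[, b][orders], nrow = n_perm)
      for (a in seq_len(R)) {
        pmat[a, b] <- perm_pvalues(A2[, a], vb_perm, cmat[a, b])
      }
    }
  }
  second_order_result(cmat, pmat, m, alpha,
                      c("planning", "execution"), method, test)
}

#' Average-linkage clustering of an inter-region correlation matrix
#'
#' Agglomerative clustering on distance `1 - r`. Regions are ordered
#' alphabetically before clustering so that merge order does not depend on
#' the input ordering (ties broken by label).
#'
#' @param cmat Symmetric correlation matrix with unit diagonal.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(cmat,
                                 linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!isTRUE(all.equal(cmat, t(cmat), tolerance = 1e-10))) {
    abort("correlation matrix must be symmetric")
  }
  ord <- order(rownames(cmat))
  cmat <- cmat[ord, ord]
  d <- as.dist(1 - cmat)
  hclust(d, method = linkage)
}

#' Classical multidimensional scaling of an inter-region matrix
#'
#' Torgerson double-centering MDS on distance `1 - r`, two dimensions,
#' negative eigenvalues clipped. Coordinates are centered at the origin and
#' each axis's sign is fixed so that the coordinate of largest magnitude on
#' that axis is positive.
#'
#' @param cmat Symmetric correlation (or similarity) matrix; distances are
#'   `1 - cmat`. A matrix that is already a distance matrix (zero diagonal)
#'   is used as-is.
#' @param k Embedding dimension.
#' @return Tibble with columns `roi`, `x`, `y` (more columns if `k > 2`).
#' @export
mds_embed <- function(cmat, k = 2L) {
  if (nrow(cmat) < 3) abort("MDS embedding needs at least three regions")
  if (!isTRUE(all.equal(cmat, t(cmat), tolerance = 1e-10))) {
    abort("matrix must be symmetric")
  }
  d <- if (all(abs(diag(cmat)) < 1e-12)) cmat else 1 - cmat
  # degenerate geometries (fewer positive eigenvalues than k) come back with
  # fewer columns and a warning; the missing dimensions are identically zero
  xy <- suppressWarnings(cmdscale(as.dist(d), k = k, eig = FALSE))
  if (is.null(dim(xy)) || ncol(xy) < k) {
    # degenerate geometry: pad trailing zero dimensions
    pad <- matrix(0, nrow(cmat), k - NCOL(xy))
    xy <- cbind(xy, pad)
  }
  xy <- scale(xy, center = TRUE, scale = FALSE)
  for (dd in seq_len(ncol(xy))) {
    i_max <- which.max(abs(xy[, dd]))
    if (xy[i_max, dd] < 0) xy[, dd] <- -xy[, dd]
  }
  out <- tibble::tibble(roi = rownames(cmat), x = xy[, 1], y = xy[, 2])
  if (k > 2) for (dd in 3:k) out[[paste0("dim", dd)]] <- xy[, dd]
  out
}

#' @export
tidy.second_order <- function(x, ...) x$edges

#' @export
glance.second_order <- function(x, ...) {
  tibble::tibble(
    phase_a = x$phase_pair[1], phase_b = x$phase_pair[2],
    n_regions = nrow(x$matrix), m = x$m, alpha = x$alpha,
    test = x$test, n_significant = sum(x$edges$significant)
  )
}

#' Heatmap of a second-order similarity matrix
#'
#' Significant cells (Bonferroni) are marked with an asterisk.
#'
#' @param object A `second_order` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.second_order <- function(object, ...) {
  labs_r <- rownames(object$matrix); labs_c <- colnames(object$matrix)
  df <- tidyr::expand_grid(row = labs_r, col = labs_c)
  df$r <- as.vector(t(object$matrix))
  df$sig <- as.vector(t(object$significant_mask))
  df$row <- factor(df$row, levels = rev(labs_r))
  df$col <- factor(df$col, levels = labs_c)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(!is.na(df$sig) & df$sig,
                                                   "*", "")),
                       color = "white", size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = object$phase_pair[2], y = object$phase_pair[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of the 2D region embedding
#'
#' @param embedding Tibble from [mds_embed()].
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding) {
  ggplot2::ggplot(embedding, ggplot2::aes(x = .data$x, y = .data$y,
                                          label = .data$roi)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2") +
    ggplot2::theme_minimal()
}
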