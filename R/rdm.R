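# Representational dissimilarity matrices: construction, vectorization,
# comparison and averaging. These operations are the mathematical core that
# every later analysis stage builds on.

#' Construct an RDM
#'
#' An `rdm` is a symmetric, zero-diagonal dissimilarity matrix over labelled
#' conditions.
#'
#' @param matrix Square numeric matrix.
#' @param labels Condition labels (defaults to existing rownames or
#'   `"c1".."cn"`).
#' @param tol Symmetry tolerance.
#' @return An object of class `rdm` (a labelled matrix).
#' @export
rdm <- function(matrix, labels = NULL, tol = 1e-12) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    abort("an RDM must be a square matrix")
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    abort("an RDM must contain finite values only")
  }
  if (max(abs(matrix - t(matrix))) > tol) {
    abort("an RDM must be symmetric")
  }
  if (max(abs(diag(matrix))) > tol) {
    abort("an RDM must have a zero diagonal")
  }
  labels <- labels %||% rownames(matrix) %||% paste0("c", seq_len(nrow(matrix)))
  if (length(labels) != nrow(matrix)) {
    abort("labels must match the matrix dimension")
  }
  matrix <- (matrix + t(matrix)) / 2
  diag(matrix) <- 0
  dimnames(matrix) <- list(labels, labels)
  structure(matrix, class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm: ", nrow(x), " x ", ncol(x), " conditions>\n", sep = "")
  print(unclass(round(x, 3)))
  invisible(x)
}

rdm_labels <- function(x) rownames(x)

#' Upper-triangle pair order for n conditions
#'
#' Row-major order (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This fixed
#' order is used everywhere an RDM is vectorized, so vectors from different
#' RDMs of the same size are always comparable entry by entry.
#'
#' @param n Number of conditions.
#' @return Tibble with columns `i`, `j` (`i < j`), `n(n-1)/2` rows.
#' @export
pair_index <- function(n) {
  stopifnot(n >= 2)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ord <- order(pr[, "row"], pr[, "col"])
  tibble::tibble(i = as.integer(pr[ord, "row"]), j = as.integer(pr[ord, "col"]))
}

#' Vectorize the upper triangle of an RDM
#'
#' @param x An [rdm] (or square symmetric matrix).
#' @return Tibble with columns `i`, `j`, `label_i`, `label_j`, `value`, in
#'   the fixed [pair_index()] order; length `n(n-1)/2`.
#' @export
vectorize_upper <- function(x) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) abort("input must be a square matrix")
  labs <- rdm_labels(x) %||% paste0("c", seq_len(nrow(x)))
  pr <- pair_index(nrow(x))
  tibble::tibble(
    i = pr$i, j = pr$j,
    label_i = labs[pr$i], label_j = labs[pr$j],
    value = x[cbind(pr$i, pr$j)]
  )
}

#' Rebuild an RDM from an upper-triangle vector
#'
#' Inverse of [vectorize_upper()].
#'
#' @param values Numeric vector of length `n(n-1)/2`.
#' @param labels Optional condition labels of length n.
#' @return An [rdm].
#' @export
devectorize_upper <- function(values, labels = NULL) {
  m <- length(values)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (n != round(n)) abort("length is not a triangular number n(n-1)/2")
  n <- as.integer(n)
  pr <- pair_index(n)
  mat <- matrix(0, n, n)
  mat[cbind(pr$i, pr$j)] <- values
  mat <- mat + t(mat)
  rdm(mat, labels = labels)
}

#' Correlation-distance RDM from condition-wise voxel patterns
#'
#' Computes the neural RDM for one subject, region and phase: entry (i, j)
#' is `1 - r` where `r` is the Pearson correlation between the voxel beta
#' patterns of conditions i and j. Entries therefore lie in [0, 2].
#'
#' @param patterns Numeric matrix, conditions x voxels; rownames are used as
#'   condition labels.
#' @param zscore_voxels If `TRUE`, each voxel (column) is z-scored across
#'   conditions before the correlation distance is computed. Off by default:
#'   inputs are taken to be normalized beta estimates already.
#' @return An [rdm].
#' @export
compute_rdm <- function(patterns, zscore_voxels = FALSE) {
  if (!is.matrix(patterns)) patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2) abort("need at least two condition patterns")
  if (ncol(patterns) < 3) abort("need at least three voxels")
  labs <- rownames(patterns) %||% paste0("c", seq_len(nrow(patterns)))
  if (zscore_voxels) {
    patterns <- scale(patterns)
    keep <- !is.nan(colSums(patterns))
    patterns <- patterns[, keep, drop = FALSE]
    if (ncol(patterns) < 3) abort("fewer than three voxels vary across conditions")
  }
  sds <- apply(patterns, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance pattern for condition(s): ",
                 paste(labs[sds == 0], collapse = ", ")))
  }
  cmat <- cor(t(patterns))
  rdm(1 - cmat, labels = labs, tol = 1e-8)
}

#' Correlate two RDMs
#'
#' Correlation between the upper-triangle vectors (diagonal excluded) of two
#' RDMs with identical condition labels.
#'
#' @param a,b [rdm] objects of the same size and label order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A single correlation value; never `NaN` (constant vectors raise an
#'   error instead).
#' @export
correlate_rdms <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(dim(a), dim(b))) abort("RDMs differ in size")
  la <- rdm_labels(a); lb <- rdm_labels(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    abort("RDM condition labels do not match")
  }
  va <- vectorize_upper(a)$value
  vb <- vectorize_upper(b)$value
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("constant RDM vector: correlation is undefined")
  }
  cor(va, vb, method = method)
}

#' Average a list of RDMs entrywise
#'
#' @param rdms Non-empty list of [rdm] objects with identical labels.
#' @return The entrywise mean [rdm].
#' @export
average_rdms <- function(rdms) {
  if (!is.list(rdms) || length(rdms) == 0) abort("need a non-empty list of RDMs")
  labs <- rdm_labels(rdms[[1]])
  for (r in rdms) {
    if (!identical(dim(r), dim(rdms[[1]]))) abort("RDMs differ in size")
    if (!identical(rdm_labels(r), labs)) abort("RDM condition labels do not match")
  }
  mat <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  rdm(mat, labels = labs)
}

#' @export
tidy.rdm <- function(x, ...) vectorize_upper(x)

#' Heatmap of an RDM
#'
#' @param object An [rdm].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  labs <- rdm_labels(object)
  df <- tidyr::expand_grid(row = labs, col = labs)
  df$value <- as.vector(t(unclass(object)))
  df$row <- factor(df$row, levels = rev(labs))
  df$col <- factor(df$col, levels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "dissimilarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
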