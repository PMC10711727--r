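# Experimental design: nine grasp conditions (3 objects x 3 grasps) crossed
# with three binary grasp factors whose model RDMs are mutually uncorrelated.

grasp_factors <- function() {
  list(
    grasp_axis  = c("cw45", "ccw45"),
    grasp_size  = c("small_2.5cm", "large_7.5cm"),
    object_mass = c("light_67g", "heavy_557g")
  )
}

design_objects <- function() c("Wood", "BrassUp", "BrassDown")

# Mass is fixed by object: the wooden object is light, the two brass-bearing
# objects are heavy (3 light / 6 heavy conditions).
mass_bits <- function() c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L)

# Default axis/size level assignments. These are the first joint assignment,
# in the deterministic enumeration order of search_orthogonal_assignment()
# (condition 1 = least-significant bit, axis key before size key), for which
# all three pairwise model-RDM Pearson correlations are exactly zero given
# the fixed 3/6 mass split. The published condition chart shows one such
# assignment only graphically, so any relabeling-equivalent solution carries
# the same information; the choice is pinned here for stable indexing.
default_axis_key <- function() 9L
default_size_key <- function() 56L

#' Convert an assignment key to per-condition level bits
#'
#' Assignment keys enumerate binary level assignments over the nine
#' conditions: condition 1 is the least-significant bit of the key.
#'
#' @param key Integer in `0:511`.
#' @param n_conditions Number of conditions (default 9).
#' @return Integer vector of 0/1 bits, one per condition.
#' @export
assignment_bits <- function(key, n_conditions = 9L) {
  stopifnot(length(key) == 1L, key >= 0, key < 2^n_conditions)
  as.integer(floor(key / 2^(seq_len(n_conditions) - 1L)) %% 2L)
}

#' Build the default nine-condition grasping design
#'
#' Returns the study design as a tibble of nine conditions: three objects
#' (`Wood`, light; `BrassUp` and `BrassDown`, heavy) times three grasp slots.
#' Each condition carries a level of each of the three grasp factors:
#' `grasp_axis` (hand rotated 45 degrees clockwise or counterclockwise about
#' vertical), `grasp_size` (2.5 cm or 7.5 cm grip aperture) and `object_mass`
#' (67 g wood vs 557 g brass-loaded objects). Axis and size levels follow the
#' stored orthogonal assignment, so the three binary model RDMs derived from
#' the design are pairwise uncorrelated (Pearson r = 0 on upper-triangle
#' vectors).
#'
#' @param axis_key,size_key Assignment keys for the axis and size factors
#'   (see [assignment_bits()]). Defaults are the stored orthogonal solution.
#' @return A `grasp_design` tibble with columns `condition_id`, `object`,
#'   `grasp_slot`, `label`, `grasp_axis`, `grasp_size`, `object_mass`.
#' @examples
#' design <- build_design()
#' model_rdm(design, "object_mass")
#' @export
build_design <- function(axis_key = default_axis_key(),
                         size_key = default_size_key()) {
  fac <- grasp_factors()
  axis_b <- assignment_bits(axis_key)
  size_b <- assignment_bits(size_key)
  mass_b <- mass_bits()
  objects <- rep(design_objects(), each = 3L)
  slots <- rep(1:3, times = 3L)
  out <- tibble::tibble(
    condition_id = 1:9,
    object = objects,
    grasp_slot = slots,
    label = paste0(objects, "-", slots),
    grasp_axis = fac$grasp_axis[axis_b + 1L],
    grasp_size = fac$grasp_size[size_b + 1L],
    object_mass = fac$object_mass[mass_b + 1L]
  )
  class(out) <- c("grasp_design", class(out))
  out
}

validate_design <- function(design) {
  needed <- c("condition_id", "object", "grasp_slot", "label",
              names(grasp_factors()))
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    abort(paste0("design is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!identical(sort(design$condition_id), 1:9)) {
    abort("design must have condition_id 1..9, each exactly once")
  }
  fac <- grasp_factors()
  for (f in names(fac)) {
    bad <- setdiff(unique(design[[f]]), fac[[f]])
    if (length(bad) > 0) {
      abort(paste0("unknown level(s) for ", f, ": ", paste(bad, collapse = ", ")))
    }
  }
  invisible(design)
}

#' Binary model RDM for one grasp factor
#'
#' The model RDM for a factor is the 9 x 9 matrix with entry (i, j) equal to
#' 0 when conditions i and j share the factor level and 1 when they differ;
#' the diagonal is zero.
#'
#' @param design A design tibble from [build_design()].
#' @param factor_name One of `"grasp_axis"`, `"grasp_size"`, `"object_mass"`.
#' @return An [rdm] object (9 x 9, binary).
#' @export
model_rdm <- function(design, factor_name) {
  validate_design(design)
  if (!factor_name %in% names(grasp_factors())) {
    abort(paste0("unknown factor name: ", factor_name))
  }
  design <- dplyr::arrange(design, .data$condition_id)
  lev <- design[[factor_name]]
  mat <- outer(lev, lev, FUN = function(a, b) as.numeric(a != b))
  rdm(mat, labels = design$label)
}

#' All three model RDMs of a design
#'
#' @inheritParams model_rdm
#' @return Named list of [rdm] objects (`grasp_axis`, `grasp_size`,
#'   `object_mass`).
#' @export
model_rdms <- function(design) {
  fac <- names(grasp_factors())
  stats::setNames(lapply(fac, function(f) model_rdm(design, f)), fac)
}

#' Pairwise correlations between RDMs
#'
#' Pearson (or Spearman) correlations between the upper-triangle vectors of
#' every pair of RDMs. Used to verify that model RDMs are mutually
#' uncorrelated, hence linearly independent predictors of neural geometry.
#'
#' @param rdms Named list of [rdm] objects of equal size.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A symmetric correlation matrix with unit diagonal, one row/column
#'   per RDM.
#' @export
check_orthogonality <- function(rdms, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.list(rdms) || length(rdms) < 2) {
    abort("check_orthogonality() needs a list of at least two RDMs")
  }
  nm <- names(rdms) %||% paste0("rdm", seq_along(rdms))
  vecs <- lapply(rdms, function(r) vectorize_upper(r)$value)
  n <- lengths(vecs)
  if (length(unique(n)) != 1) abort("RDMs must all have the same size")
  for (i in seq_along(vecs)) {
    if (sd(vecs[[i]]) == 0) {
      abort(paste0("RDM '", nm[i], "' has a constant upper-triangle vector; ",
                   "correlation is undefined"))
    }
  }
  V <- do.call(cbind, vecs)
  colnames(V) <- nm
  cor(V, method = method)
}

#' Exhaustive search for mutually uncorrelated axis/size assignments
#'
#' With the object-mass split fixed at 3 light / 6 heavy, enumerates all
#' 2^9 x 2^9 joint binary assignments of grasp axis and grasp size over the
#' nine conditions and reports those whose three pairwise model-RDM Pearson
#' correlations are all within `tolerance` of zero. Assignments whose RDM
#' upper-triangle vector is constant (all conditions share one level) cannot
#' be declared uncorrelated; their maximum absolute correlation is recorded
#' as 1.
#'
#' @param tolerance Maximum allowed absolute pairwise correlation.
#' @param max_results Keep at most this many assignments (after sorting).
#' @return Tibble with columns `axis_key`, `size_key`, `max_abs_r`, sorted by
#'   `max_abs_r`, then `axis_key`, then `size_key`. Empty (zero rows) when no
#'   assignment meets the tolerance.
#' @export
search_orthogonal_assignment <- function(tolerance = 1e-12,
                                         max_results = Inf) {
  stopifnot(tolerance >= 0)
  keys <- 0:511
  bits_mat <- sapply(keys, assignment_bits)            # 9 x 512
  pr <- pair_index(9)
  V <- (bits_mat[pr$i, ] != bits_mat[pr$j, ]) * 1      # 36 x 512
  mass_v <- as.numeric(mass_bits()[pr$i] != mass_bits()[pr$j])
  const <- apply(V, 2, sd) == 0
  # correlation of every assignment's RDM vector with the mass RDM vector
  r_mass <- rep(1, length(keys))
  r_mass[!const] <- drop(suppressWarnings(cor(V[, !const, drop = FALSE], mass_v)))
  # pairwise correlations among all non-constant assignment vectors
  r_pair <- matrix(1, length(keys), length(keys))
  r_pair[!const, !const] <- suppressWarnings(cor(V[, !const, drop = FALSE]))
  axis_key <- rep(keys, times = length(keys))
  size_key <- rep(keys, each = length(keys))
  max_abs_r <- pmax(abs(r_pair[axis_key + 1L + 512L * size_key]),
                    abs(r_mass)[axis_key + 1L],
                    abs(r_mass)[size_key + 1L])
  keep <- max_abs_r <= tolerance
  out <- tibble::tibble(
    axis_key = axis_key[keep],
    size_key = size_key[keep],
    max_abs_r = max_abs_r[keep]
  )
  out <- dplyr::arrange(out, .data$max_abs_r, .data$axis_key, .data$size_key)
  if (is.finite(max_results)) out <- head(out, max_results)
  out
}
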