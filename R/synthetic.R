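# Synthetic data: subject-level voxel beta patterns and comfort ratings with
# known planted representational structure. The generator stands in for the
# study's deposited fMRI data so that every analysis stage can be verified
# against a known ground truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions: 21 subjects, the nine left-
#' hemisphere regions of interest, planning and execution phases, and 65
#' voxels per region (a 15-mm-diameter spherical ROI at 3-mm isotropic
#' resolution covers about 65 voxels). Planted effect weights default to the
#' qualitative significance map reported for the real data (grasp axis in
#' dorsal and motor regions during planning, grasp size in ventral then
#' premotor regions, object mass only during execution); comfort ratings are
#' dominated by object mass with a small grasp-axis effect and no size
#' effect.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param rois Character vector of region labels.
#' @param phases Character vector of task phases.
#' @param n_voxels Voxels per region (>= 3).
#' @param planted_weights Tibble with columns `roi`, `phase`, `factor`,
#'   `weight` (non-negative); missing combinations mean weight 0. See
#'   [default_planted_weights()] and [uniform_planted_weights()].
#' @param subject_sd SD of the subject-specific perturbation applied to each
#'   factor-level prototype pattern (between-subject geometry noise).
#' @param voxel_sd SD of the per-voxel measurement noise added to every
#'   condition pattern.
#' @param rating_baseline Comfort baseline on the 1-10 scale.
#' @param rating_weights Named vector (`grasp_axis`, `grasp_size`,
#'   `object_mass`): how much the costly level of each factor lowers comfort.
#' @param rating_sd SD of rating noise.
#' @param integer_ratings Round ratings to integers (default: real-valued,
#'   clipped to [1, 10]).
#' @param seed Integer seed for all randomness.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 21L,
                             rois = default_rois(),
                             phases = c("planning", "execution"),
                             n_voxels = 65L,
                             planted_weights = default_planted_weights(),
                             subject_sd = 0.3,
                             voxel_sd = 1.2,
                             rating_baseline = 8,
                             rating_weights = c(grasp_axis = 0.5,
                                                grasp_size = 0,
                                                object_mass = 3),
                             rating_sd = 0.75,
                             integer_ratings = FALSE,
                             seed = 1L) {
  if (n_subjects < 2) abort("n_subjects must be at least 2")
  if (n_voxels < 3) abort("n_voxels must be at least 3")
  if (subject_sd < 0 || voxel_sd < 0 || rating_sd < 0) {
    abort("noise standard deviations must be non-negative")
  }
  stopifnot(is.data.frame(planted_weights),
            all(c("roi", "phase", "factor", "weight") %in% names(planted_weights)))
  if (any(planted_weights$weight < 0)) abort("planted weights must be non-negative")
  fac <- names(grasp_factors())
  rating_weights <- rating_weights[fac]
  names(rating_weights) <- fac
  rating_weights[is.na(rating_weights)] <- 0
  structure(list(
    n_subjects = as.integer(n_subjects), rois = rois, phases = phases,
    n_voxels = as.integer(n_voxels), planted_weights = planted_weights,
    subject_sd = subject_sd, voxel_sd = voxel_sd,
    rating_baseline = rating_baseline, rating_weights = rating_weights,
    rating_sd = rating_sd, integer_ratings = integer_ratings,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default region-of-interest labels
#'
#' The nine left-hemisphere regions analysed in the study: early visual
#' cortex, three ventral-stream areas, four dorsal/premotor areas, and
#' primary sensorimotor cortex.
#'
#' @return Character vector of nine labels.
#' @export
default_rois <- function() {
  c("V1", "LOC", "pFS", "PPA", "SPOC", "aIPS", "PMv", "PMd", "M1/S1")
}

#' Uniform planted-weight table
#'
#' Convenience builder: the same weight per factor in every listed region
#' and phase.
#'
#' @param grasp_axis,grasp_size,object_mass Non-negative weights.
#' @param rois,phases Regions and phases to cover.
#' @return Tibble with columns `roi`, `phase`, `factor`, `weight`.
#' @export
uniform_planted_weights <- function(grasp_axis = 0, grasp_size = 0,
                                    object_mass = 0,
                                    rois = default_rois(),
                                    phases = c("planning", "execution")) {
  w <- c(grasp_axis = grasp_axis, grasp_size = grasp_size,
         object_mass = object_mass)
  if (any(w < 0)) abort("planted weights must be non-negative")
  tidyr::expand_grid(roi = rois, phase = phases, factor = names(w)) |>
    dplyr::mutate(weight = unname(w[.data$factor]))
}

#' Default planted-weight table
#'
#' Encodes, with unit weights, the qualitative pattern of significant
#' model-RDM correlations reported for the real data: grasp axis in V1, LOC
#' and all dorsal/motor regions during planning and in V1/LOC during
#' execution; grasp size in ventral regions plus aIPS and PMd during
#' planning, shifting to V1, LOC, PPA, PMv and PMd during execution; object
#' mass in pFS, PPA, aIPS, PMd and M1/S1 during execution only.
#'
#' @param weight Effect weight for every planted cell.
#' @return Tibble with columns `roi`, `phase`, `factor`, `weight`.
#' @export
default_planted_weights <- function(weight = 1) {
  cells <- dplyr::bind_rows(
    tibble::tibble(roi = c("V1", "LOC", "SPOC", "aIPS", "PMv", "PMd", "M1/S1"),
                   phase = "planning", factor = "grasp_axis"),
    tibble::tibble(roi = c("V1", "LOC"),
                   phase = "execution", factor = "grasp_axis"),
    tibble::tibble(roi = c("LOC", "pFS", "PPA", "aIPS", "PMd"),
                   phase = "planning", factor = "grasp_size"),
    tibble::tibble(roi = c("V1", "LOC", "PPA", "PMv", "PMd"),
                   phase = "execution", factor = "grasp_size"),
    tibble::tibble(roi = c("pFS", "PPA", "aIPS", "PMd", "M1/S1"),
                   phase = "execution", factor = "object_mass")
  )
  cells$weight <- weight
  cells
}

#' Planted target geometry for a weight setting
#'
#' The weighted sum of the three binary model RDMs, rescaled so the largest
#' entry is 1 whenever any weight is positive. This is the condition
#' geometry the pattern generator embeds, and the ground truth that
#' recovery tests compare against.
#'
#' @param weights Named non-negative vector (`grasp_axis`, `grasp_size`,
#'   `object_mass`); missing names mean 0.
#' @param design A design tibble from [build_design()].
#' @return An [rdm].
#' @export
planted_geometry <- function(weights, design = build_design()) {
  fac <- names(grasp_factors())
  w <- stats::setNames(rep(0, length(fac)), fac)
  bad <- setdiff(names(weights), fac)
  if (length(bad) > 0) abort(paste0("unknown factor(s): ", paste(bad, collapse = ", ")))
  w[names(weights)] <- as.numeric(weights)
  if (any(w < 0)) abort("planted weights must be non-negative")
  mods <- model_rdms(design)
  mat <- Reduce(`+`, Map(function(wf, m) wf * unclass(m), w, mods))
  if (max(mat) > 0) mat <- mat / max(mat)
  rdm(mat, labels = design$label)
}

weight_lookup <- function(planted_weights, roi, phase) {
  fac <- names(grasp_factors())
  w <- stats::setNames(rep(0, length(fac)), fac)
  sel <- planted_weights$roi == roi & planted_weights$phase == phase
  hit <- planted_weights[sel, ]
  if (nrow(hit) > 0) w[hit$factor] <- hit$weight
  w
}

#' Generate synthetic voxel beta patterns
#'
#' For each region and phase, draws one unit-norm prototype voxel pattern
#' per level of each factor. A condition's group-mean pattern is the
#' weighted sum of the prototypes of its levels (weights from
#' `config$planted_weights`). Each subject perturbs every prototype with
#' Gaussian noise of SD `subject_sd` (between-subject geometry variation),
#' and independent Gaussian measurement noise of SD `voxel_sd` is added to
#' every condition pattern. The expected neural RDM therefore correlates
#' positively with each planted factor's model RDM, increasingly so as its
#' weight grows.
#'
#' @param config A [generator_config()].
#' @param design A design tibble from [build_design()].
#' @return A `pattern_set`: long tibble with columns `subject`, `roi`,
#'   `phase`, `condition_id`, `voxel`, `beta`, fully crossed; the generator
#'   configuration is attached as attribute `config`.
#' @export
generate_patterns <- function(config, design = build_design()) {
  stopifnot(inherits(config, "generator_config"))
  validate_design(design)
  design <- dplyr::arrange(design, .data$condition_id)
  fac <- grasp_factors()
  nv <- config$n_voxels
  ns <- config$n_subjects
  nc <- nrow(design)
  unit <- function(v) v / sqrt(sum(v^2))
  blocks <- list()
  withr::with_seed(config$seed, {
    for (roi in config$rois) {
      for (phase in config$phases) {
        w <- weight_lookup(config$planted_weights, roi, phase)
        proto <- lapply(fac, function(levels) {
          vs <- lapply(levels, function(l) unit(rnorm(nv)))
          names(vs) <- levels
          vs
        })
        for (s in seq_len(ns)) {
          subj_proto <- lapply(names(proto), function(f) {
            lapply(proto[[f]], function(v) v + rnorm(nv, sd = config$subject_sd))
          })
          names(subj_proto) <- names(proto)
          beta <- matrix(0, nc, nv)
          for (ci in seq_len(nc)) {
            mu <- rep(0, nv)
            for (f in names(fac)) {
              lev <- design[[f]][ci]
              mu <- mu + w[[f]] * subj_proto[[f]][[lev]]
            }
            beta[ci, ] <- mu + rnorm(nv, sd = config$voxel_sd)
          }
          blocks[[length(blocks) + 1L]] <- tibble::tibble(
            subject = s, roi = roi, phase = phase,
            condition_id = rep(design$condition_id, each = nv),
            voxel = rep(seq_len(nv), times = nc),
            beta = as.vector(t(beta))
          )
        }
      }
    }
  })
  out <- dplyr::bind_rows(blocks)
  attr(out, "config") <- config
  class(out) <- c("pattern_set", class(out))
  out
}

#' Generate synthetic grasp-comfort ratings
#'
#' A subject's rating of a condition is a baseline minus a penalty for each
#' costly factor level (heavy mass, counterclockwise axis, large grip by
#' default weights 3 / 0.5 / 0), plus Gaussian noise, clipped to the 1-10
#' scale. Default weights emulate the reported rating structure: a large
#' mass effect, a weak axis effect, and no size effect.
#'
#' @param config A [generator_config()].
#' @param design A design tibble from [build_design()].
#' @return Tibble with columns `subject`, `condition_id`, `rating`.
#' @export
generate_comfort_ratings <- function(config, design = build_design()) {
  stopifnot(inherits(config, "generator_config"))
  validate_design(design)
  design <- dplyr::arrange(design, .data$condition_id)
  fac <- grasp_factors()
  costly <- vapply(fac, function(l) l[2], character(1))  # second level of each
  penalty <- rep(0, nrow(design))
  for (f in names(fac)) {
    penalty <- penalty + config$rating_weights[[f]] * (design[[f]] == costly[[f]])
  }
  withr::with_seed(config$seed + 1L, {
    out <- tidyr::expand_grid(subject = seq_len(config$n_subjects),
                              condition_id = design$condition_id)
    out$rating <- config$rating_baseline -
      penalty[match(out$condition_id, design$condition_id)] +
      rnorm(nrow(out), sd = config$rating_sd)
    if (config$integer_ratings) out$rating <- round(out$rating)
    out$rating <- pmin(10, pmax(1, out$rating))
    out
  })
}
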