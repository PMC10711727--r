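make_ratings <- function(design, fun, n_subjects = 3) {
  tidyr::expand_grid(subject = seq_len(n_subjects),
                     condition_id = design$condition_id) |>
    dplyr::mutate(rating = fun(.data$subject, .data$condition_id))
}

test_that("level_contrast_ttest computes the paired t on per-subject differences", {
  d <- build_design()
  # craft ratings whose per-subject heavy-minus-light differences are 1, 2, 3
  diffs <- c(1, 2, 3)
  r <- make_ratings(d, function(s, c) {
    heavy <- d$object_mass[match(c, d$condition_id)] == "heavy_557g"
    5 + ifelse(heavy, diffs[s], 0)
  })
  res <- level_contrast_ttest(r, d, "object_mass")
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean_difference, 2)
  # definitional check: t = mean / (sd / sqrt(n))
  expect_equal(res$t, mean(diffs) / (sd(diffs) / sqrt(3)), tolerance = 1e-12)
  # all differences identical: zero variance is an error
  r0 <- make_ratings(d, function(s, c) {
    heavy <- d$object_mass[match(c, d$condition_id)] == "heavy_557g"
    5 + ifelse(heavy, 1, 0)
  })
  expect_error(level_contrast_ttest(r0, d, "object_mass"), "zero variance")
  expect_error(level_contrast_ttest(r, d, "comfort"), "unknown factor")
})

test_that("level_contrast_ttest matches the definitional t on random ratings", {
  d <- build_design()
  set.seed(3)
  for (rep in 1:10) {
    r <- make_ratings(d, function(s, c) runif(length(c), 1, 10), n_subjects = 8)
    res <- level_contrast_ttest(r, d, "grasp_axis")
    per <- merge(r, as.data.frame(d[, c("condition_id", "grasp_axis")]))
    agg <- tapply(per$rating, list(per$subject, per$grasp_axis), mean)
    dd <- agg[, "ccw45"] - agg[, "cw45"]
    expect_equal(res$t, mean(dd) / (sd(dd) / sqrt(length(dd))),
                 tolerance = 1e-12)
  }
})

test_that("comfort_rdm is the absolute-difference dissimilarity", {
  d <- build_design()
  r <- tibble::tibble(condition_id = 1:9, rating = 1:9)
  m <- comfort_rdm(r, d)
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 9], 8)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(m) == 0))
  # shift invariance
  r2 <- dplyr::mutate(r, rating = .data$rating + 3)
  expect_equal(unclass(comfort_rdm(r2, d)), unclass(m))
  flat <- tibble::tibble(condition_id = 1:9, rating = rep(4, 9))
  expect_true(all(comfort_rdm(flat, d) == 0))
  expect_error(comfort_rdm(r[-3, ], d), "condition")
})

test_that("comfort RDMs satisfy the triangle inequality", {
  d <- build_design()
  set.seed(5)
  for (rep in 1:20) {
    m <- unclass(comfort_rdm(tibble::tibble(condition_id = 1:9,
                                            rating = runif(9, 1, 10)), d))
    for (i in 1:9) for (j in 1:9) for (k in 1:9) {
      expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
    }
  }
})

test_that("comfort geometry matching a model yields r = 1 and a minimal exact p", {
  d <- build_design()
  # ratings that differ only by mass make the comfort RDM proportional to
  # the mass model RDM
  r <- make_ratings(d, function(s, c) {
    heavy <- d$object_mass[match(c, d$condition_id)] == "heavy_557g"
    ifelse(heavy, 4, 8)
  }, n_subjects = 6)
  res <- comfort_model_correlations(r, d)
  mass <- res[res$model == "object_mass", ]
  expect_equal(mass$mean_r, 1)
  expect_equal(mass$avg_rdm_r, 1)
  expect_equal(mass$p_value, 1 / 2^6, tolerance = 1e-12)
})

test_that("synthetic default ratings are dominated by object mass", {
  d <- build_design()
  hits_mass <- 0
  for (seed in 1:20) {
    cfg <- generator_config(seed = seed)
    r <- generate_comfort_ratings(cfg, d)
    tt_mass <- level_contrast_ttest(r, d, "object_mass")
    tt_axis <- level_contrast_ttest(r, d, "grasp_axis")
    if (tt_mass$p_value < 0.001) hits_mass <- hits_mass + 1
    expect_gt(abs(tt_mass$t), abs(tt_axis$t))
    mc <- comfort_model_correlations(r, d)
    expect_gt(mc$mean_r[mc$model == "object_mass"],
              mc$mean_r[mc$model == "grasp_size"])
  }
  expect_gte(hits_mass, 19)
})

test_that("comfort-model inference flags mass and not size on default ratings", {
  # the size rating weight is zero and the size model RDM is orthogonal to
  # the mass model RDM, so the comfort-to-size-model correlation is a null
  # test while the mass test carries a large planted effect
  d <- build_design()
  sig_mass <- 0; nonsig_size <- 0
  for (seed in 1:20) {
    r <- generate_comfort_ratings(generator_config(seed = 100 + seed), d)
    mc <- comfort_model_correlations(r, d)
    if (mc$p_value[mc$model == "object_mass"] < 0.05) sig_mass <- sig_mass + 1
    if (mc$p_value[mc$model == "grasp_size"] > 0.05) nonsig_size <- nonsig_size + 1
  }
  expect_gte(sig_mass, 19)
  expect_gte(nonsig_size, 17)
})

test_that("comfort_neural_rsa finds the region that embodies comfort geometry", {
  d <- build_design()
  cfg <- generator_config(
    n_subjects = 12, rois = c("PPA", "ctrl"), phases = "execution",
    n_voxels = 40,
    planted_weights = uniform_planted_weights(object_mass = 1, rois = "PPA",
                                              phases = "execution"),
    subject_sd = 0.02, voxel_sd = 0.05, seed = 13
  )
  pats <- generate_patterns(cfg, d)
  ratings <- generate_comfort_ratings(generator_config(seed = 13, rating_sd = 0.2), d)
  avg_rdm <- comfort_rdms(ratings, d)$average
  res <- comfort_neural_rsa(avg_rdm, pats, d)
  expect_true(res$significant[res$roi == "PPA"])
  expect_false(res$significant[res$roi == "ctrl"])
  const <- rdm(matrix(0, 9, 9), labels = d$label)
  expect_error(comfort_neural_rsa(const, pats, d), "constant")
})

test_that("run_comfort_analysis assembles contrasts, models and neural results", {
  d <- build_design()
  cfg <- generator_config(n_subjects = 8, rois = "PMv", n_voxels = 20,
                          seed = 17)
  ratings <- generate_comfort_ratings(cfg, d)
  pats <- generate_patterns(cfg, d)
  res <- run_comfort_analysis(ratings, d, patterns = pats)
  expect_s3_class(res, "comfort_result")
  expect_equal(nrow(res$contrasts), 3)
  expect_equal(res$contrasts$df, rep(7, 3))
  expect_equal(nrow(res$model_correlations), 3)
  expect_equal(nrow(res$neural), 2)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_subjects, 8)
})
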