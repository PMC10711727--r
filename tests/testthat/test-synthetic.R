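test_that("planted_geometry mixes model RDMs and rescales to unit maximum", {
  d <- build_design()
  axis <- model_rdm(d, "grasp_axis")
  g1 <- planted_geometry(c(grasp_axis = 1), d)
  expect_equal(unclass(g1), unclass(axis))
  g0 <- planted_geometry(c(grasp_axis = 0, grasp_size = 0, object_mass = 0), d)
  expect_true(all(g0 == 0))
  g11 <- planted_geometry(c(grasp_axis = 1, grasp_size = 1), d)
  expect_equal(max(g11), 1)
  # equal-weight mixture of two equal-split factors correlates identically
  # with both components (size and mass both split the conditions 3/6)
  g_sm <- planted_geometry(c(grasp_size = 1, object_mass = 1), d)
  r_size <- correlate_rdms(g_sm, model_rdm(d, "grasp_size"))
  r_mass <- correlate_rdms(g_sm, model_rdm(d, "object_mass"))
  expect_equal(r_size, r_mass, tolerance = 1e-12)
  expect_error(planted_geometry(c(grasp_axis = -1), d), "non-negative")
  expect_error(planted_geometry(c(torque = 1), d), "unknown factor")
})

test_that("noiseless single-factor patterns recover the planted model almost perfectly", {
  d <- build_design()
  cfg <- generator_config(
    n_subjects = 4, rois = "ROI1", phases = "planning", n_voxels = 65,
    planted_weights = uniform_planted_weights(grasp_axis = 1, rois = "ROI1",
                                              phases = "planning"),
    subject_sd = 0, voxel_sd = 0, seed = 3
  )
  pats <- generate_patterns(cfg, d)
  rdms <- subject_rdms(pats, d)
  axis <- model_rdm(d, "grasp_axis")
  r <- model_data_correlations(rdms$rdm, axis)
  expect_true(all(r > 0.99))
})

test_that("pattern generation is bit-identical under a fixed seed", {
  cfg <- generator_config(n_subjects = 3, rois = c("A", "B"),
                          n_voxels = 10, seed = 7,
                          planted_weights = uniform_planted_weights(
                            grasp_axis = 0.5, rois = c("A", "B")))
  p1 <- generate_patterns(cfg)
  p2 <- generate_patterns(cfg)
  expect_identical(p1$beta, p2$beta)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(generate_patterns(cfg2)$beta, p1$beta))
})

test_that("null patterns give model correlations centered on zero", {
  d <- build_design()
  rs <- c()
  for (seed in 1:10) {
    cfg <- generator_config(
      n_subjects = 20, rois = "ROI1", phases = "planning", n_voxels = 30,
      planted_weights = uniform_planted_weights(rois = "ROI1"),
      subject_sd = 0, voxel_sd = 1, seed = seed
    )
    rdms <- subject_rdms(generate_patterns(cfg, d), d)
    rs <- c(rs, model_data_correlations(rdms$rdm, model_rdm(d, "grasp_axis")))
  }
  expect_length(rs, 200)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("mean model-data correlation rises with the planted weight and is selective", {
  d <- build_design()
  mods <- model_rdms(d)
  grid <- c(0, 0.25, 0.5, 1)
  mean_r <- sapply(grid, function(w) {
    per_seed <- sapply(1:20, function(seed) {
      cfg <- generator_config(
        n_subjects = 8, rois = "ROI1", phases = "planning", n_voxels = 40,
        planted_weights = uniform_planted_weights(grasp_size = w,
                                                  rois = "ROI1",
                                                  phases = "planning"),
        subject_sd = 0.06, voxel_sd = 0.12, seed = 1000 + seed
      )
      rdms <- subject_rdms(generate_patterns(cfg, d), d)
      mean(model_data_correlations(rdms$rdm, mods$grasp_size))
    })
    mean(per_seed)
  })
  expect_true(all(diff(mean_r) > 0))
  # selectivity: planting only size must favour the size model over the others
  per_seed <- t(sapply(1:20, function(seed) {
    cfg <- generator_config(
      n_subjects = 8, rois = "ROI1", phases = "planning", n_voxels = 40,
      planted_weights = uniform_planted_weights(grasp_size = 1, rois = "ROI1",
                                                phases = "planning"),
      subject_sd = 0.06, voxel_sd = 0.12, seed = 2000 + seed
    )
    rdms <- subject_rdms(generate_patterns(cfg, d), d)
    sapply(mods, function(m) mean(model_data_correlations(rdms$rdm, m)))
  }))
  expect_true(all(per_seed[, "grasp_size"] > per_seed[, "grasp_axis"]))
  expect_true(all(per_seed[, "grasp_size"] > per_seed[, "object_mass"]))
})

test_that("comfort ratings embody the planted factor structure", {
  d <- build_design()
  cfg <- generator_config(n_subjects = 5, rating_sd = 0,
                          rating_weights = c(object_mass = 3), seed = 2)
  r <- generate_comfort_ratings(cfg, d)
  joined <- merge(r, as.data.frame(d[, c("condition_id", "object_mass")]))
  light <- joined$rating[joined$object_mass == "light_67g"]
  heavy <- joined$rating[joined$object_mass == "heavy_557g"]
  expect_true(all(abs(outer(light, heavy, `-`) - 3) < 1e-12))
  expect_true(all(r$rating >= 1 & r$rating <= 10))
  # null weights: comfort-RDM vs mass-RDM correlation centred on zero
  rs <- sapply(1:30, function(seed) {
    cfg0 <- generator_config(n_subjects = 2, rating_sd = 1,
                             rating_weights = c(object_mass = 0), seed = seed)
    rr <- generate_comfort_ratings(cfg0, d)
    correlate_rdms(comfort_rdm(rr[rr$subject == 1, ], d),
                   model_rdm(d, "object_mass"))
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("comfort rating generation is reproducible and clippable to integers", {
  cfg <- generator_config(n_subjects = 4, seed = 9, integer_ratings = TRUE)
  r1 <- generate_comfort_ratings(cfg)
  r2 <- generate_comfort_ratings(cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$rating == round(r1$rating)))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_subjects = 1), "at least 2")
  expect_error(generator_config(n_voxels = 2), "at least 3")
  expect_error(generator_config(subject_sd = -1), "non-negative")
  expect_error(generator_config(
    planted_weights = tibble::tibble(roi = "A", phase = "planning",
                                     factor = "grasp_axis", weight = -2)),
    "non-negative")
})
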