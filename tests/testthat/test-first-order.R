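test_that("wilcoxon_greater reproduces hand-computable exact cases", {
  res <- wilcoxon_greater(c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 1 / 32)
  expect_true(res$exact)
  res_neg <- wilcoxon_greater(c(-1, -2, -3))
  expect_equal(res_neg$statistic, 0)
  expect_equal(res_neg$p_value, 1)
  expect_error(wilcoxon_greater(c(0, 0, 0)), "zero")
})

test_that("exact wilcoxon p equals the 2^n sign-pattern enumeration oracle", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n), 6)
    while (any(x == 0) || any(duplicated(abs(x)))) x <- round(rnorm(n), 6)
    res <- wilcoxon_greater(x)
    expect_true(res$exact)
    expect_equal(res$p_value, wilcoxon_enum_oracle(x), tolerance = 1e-12)
  }
})

test_that("wilcoxon_greater agrees with wilcox.test across modes", {
  set.seed(29)
  x <- rnorm(15)
  ref <- wilcox.test(x, alternative = "greater", exact = TRUE)
  res <- wilcoxon_greater(x)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(res$statistic, unname(ref$statistic))
  # small tied samples are enumerated exactly over all sign patterns
  xt <- c(1, 1, 2, 2, 3, 3, -1, -2)
  res_t <- wilcoxon_greater(xt)
  expect_true(res_t$exact)
  r <- rank(abs(xt))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  w_all <- as.vector(signs %*% r)
  expect_equal(res_t$p_value, mean(w_all >= sum(r[xt > 0]) - 1e-9))
  # large tied samples use the tie-corrected normal approximation
  xl <- rep(c(1, 1, 2, 2, 3, 3, -1, -2, 4, 4, 5, -3), 2)
  ref_l <- suppressWarnings(wilcox.test(xl, alternative = "greater",
                                        correct = TRUE))
  res_l <- wilcoxon_greater(xl)
  expect_false(res_l$exact)
  expect_equal(res_l$p_value, ref_l$p.value, tolerance = 1e-10)
})

test_that("pratt zero handling keeps zeros in the ranking", {
  x <- c(0, 0, 1, 2, 3, -1, 4, 5)
  res <- wilcoxon_greater(x, zero_method = "pratt")
  expect_false(res$exact)
  expect_equal(res$n, 6)
  expect_gt(res$statistic, 0)
  expect_true(res$p_value > 0 && res$p_value < 1)
})

test_that("fdr_bh reproduces the definitional step-up", {
  res <- fdr_bh(c(0.001, 0.013, 0.04, 0.1), q = 0.05)
  expect_equal(res$p_adjusted, c(0.004, 0.026, 0.04 * 4 / 3, 0.1),
               tolerance = 1e-12)
  expect_equal(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_bh(0.5)$p_adjusted, 0.5)
  expect_equal(fdr_bh(rep(0.03, 5))$p_adjusted, rep(0.03, 5))
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(2:30, 1))
    expect_equal(fdr_bh(p)$p_adjusted, bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(fdr_bh(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("noise ceiling bounds behave as defined", {
  set.seed(37)
  base <- compute_rdm(matrix(rnorm(9 * 20), 9, 20))
  same <- replicate(5, base, simplify = FALSE)
  nc <- noise_ceiling(same)
  expect_equal(nc$lower, 1)
  expect_equal(nc$upper, 1)
  # two negatively correlated subjects: lower < upper
  a <- devectorize_upper(c(0.1, 0.5, 0.9))
  b <- devectorize_upper(c(0.9, 0.1, 0.5))
  expect_lt(correlate_rdms(a, b), 0)
  nc2 <- noise_ceiling(list(a, b))
  expect_lt(nc2$lower, nc2$upper)
  expect_error(noise_ceiling(list(base)), "two subjects")
})

test_that("noise ceiling bounds approach one as generator noise vanishes", {
  d <- build_design()
  bounds <- sapply(c(0.3, 0.1, 0.01), function(sdv) {
    cfg <- generator_config(
      n_subjects = 8, rois = "ROI1", phases = "planning", n_voxels = 40,
      planted_weights = uniform_planted_weights(grasp_axis = 1, rois = "ROI1",
                                                phases = "planning"),
      subject_sd = sdv / 2, voxel_sd = sdv, seed = 11
    )
    rdms <- subject_rdms(generate_patterns(cfg, d), d)
    unlist(noise_ceiling(rdms$rdm))
  })
  expect_true(all(diff(bounds["lower", ]) > 0))
  expect_true(all(diff(bounds["upper", ]) > 0))
  expect_gt(bounds["lower", 3], 0.99)
  expect_gt(bounds["upper", 3], 0.99)
})

test_that("model_data_correlations handles perfect and orthogonal cases", {
  d <- build_design()
  axis <- model_rdm(d, "grasp_axis")
  size <- model_rdm(d, "grasp_size")
  expect_equal(model_data_correlations(list(axis, axis, axis), axis),
               rep(1, 3))
  # subject RDMs built from an orthogonal model correlate exactly zero
  expect_equal(model_data_correlations(list(size, size), axis), rep(0, 2),
               tolerance = 1e-12)
})

test_that("run_first_order recovers a planted factor and controls the family", {
  d <- build_design()
  pw <- uniform_planted_weights(grasp_axis = 1, rois = c("dorsal1", "dorsal2"),
                                phases = "planning")
  cfg <- generator_config(
    n_subjects = 12, rois = c("dorsal1", "dorsal2", "ctrl"),
    phases = c("planning", "execution"), n_voxels = 40,
    planted_weights = pw, subject_sd = 0.02, voxel_sd = 0.05, seed = 21
  )
  res <- run_first_order(generate_patterns(cfg, d), d)
  expect_s3_class(res, "rsa_first_order")
  expect_equal(nrow(res), 3 * 2 * 3)
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
  axis_rows <- res[res$model == "grasp_axis", ]
  sig <- axis_rows[axis_rows$significant, ]
  expect_setequal(paste(sig$roi, sig$phase),
                  c("dorsal1 planning", "dorsal2 planning"))
  got <- tidy(res)
  expect_false("subject_r" %in% names(got))
  g <- glance(res)
  expect_equal(g$n_tests, 18L)
})

test_that("first-order results are invariant to subject and region ordering", {
  d <- build_design()
  cfg <- generator_config(
    n_subjects = 5, rois = c("B", "A"), phases = "planning", n_voxels = 20,
    planted_weights = uniform_planted_weights(grasp_axis = 0.8,
                                              rois = c("B", "A"),
                                              phases = "planning"),
    subject_sd = 0.05, voxel_sd = 0.1, seed = 31
  )
  pats <- generate_patterns(cfg, d)
  shuffled <- pats[sample(nrow(pats)), ]
  r1 <- tidy(run_first_order(pats, d))
  r2 <- tidy(run_first_order(shuffled, d))
  key <- function(x) x[order(x$roi, x$phase, x$model), ]
  expect_equal(key(as.data.frame(r1)), key(as.data.frame(r2)),
               ignore_attr = TRUE)
})

test_that("a single-subject pattern set still yields results without ceilings", {
  d <- build_design()
  cfg <- generator_config(
    n_subjects = 2, rois = "ROI1", phases = "planning", n_voxels = 20,
    planted_weights = uniform_planted_weights(grasp_axis = 1, rois = "ROI1",
                                              phases = "planning"),
    subject_sd = 0, voxel_sd = 0.1, seed = 41
  )
  pats <- generate_patterns(cfg, d)
  solo <- pats[pats$subject == 1, ]
  res <- run_first_order(solo, d)
  expect_equal(nrow(res), 3)
  expect_true(all(is.na(res$ceiling_lower)))
  expect_true(all(is.na(res$ceiling_upper)))
  expect_true(all(is.finite(res$p_raw)))
})

test_that("rejections shrink as the FDR level decreases", {
  set.seed(43)
  p <- runif(20)^2
  r1 <- fdr_bh(p, q = 0.10)$reject
  r2 <- fdr_bh(p, q = 0.05)$reject
  r3 <- fdr_bh(p, q = 0.01)$reject
  expect_true(all(r2 <= r1))
  expect_true(all(r3 <= r2))
})
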