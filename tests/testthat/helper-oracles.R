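# Independent oracles used to cross-check the package's statistics against
# brute-force or definitional computations.

# Pearson correlation by the definitional centered-sum formula
pearson_oracle <- function(x, y) {
  xc <- x - sum(x) / length(x)
  yc <- y - sum(y) / length(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Exact one-tailed (greater) signed-rank p by enumerating all 2^n sign
# patterns; assumes no zeros and no ties among |x|
wilcoxon_enum_oracle <- function(x) {
  stopifnot(all(x != 0), !any(duplicated(abs(x))))
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all >= w_obs)
}

# Benjamini-Hochberg adjusted p by the definitional step-up
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  }
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# RMSE between two point sets after optimal rigid alignment (translation +
# rotation/reflection), used to compare an MDS embedding with a known
# configuration
procrustes_rmse <- function(X, Y) {
  X <- scale(as.matrix(X), scale = FALSE)
  Y <- scale(as.matrix(Y), scale = FALSE)
  s <- svd(crossprod(X, Y))
  R <- s$v %*% t(s$u)
  sqrt(mean((X - Y %*% R)^2))
}

# Small high-signal generator settings used by recovery tests
high_snr_config <- function(weights, seed = 1L, rois = "ROI1",
                            phases = "planning", n_subjects = 21L) {
  generator_config(
    n_subjects = n_subjects, rois = rois, phases = phases,
    planted_weights = weights, subject_sd = 0.02, voxel_sd = 0.05,
    seed = seed
  )
}
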