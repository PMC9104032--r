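# Independent oracles and shared fixtures, built in code at test time.

# Brute-force two-sided signed-rank p-value: enumerate all 2^n sign
# assignments of the ranked absolute differences and count assignments at
# least as extreme (in |T+ - E[T+]|) as observed.
brute_force_signed_rank_p <- function(values, mu) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  ranks <- rank(abs(d))
  t_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- drop(signs %*% ranks)
  mu0 <- sum(ranks) / 2
  mean(abs(t_all - mu0) >= abs(t_obs - mu0) - 1e-9)
}

# Brute-force distance between the convex hulls of two 2-D point sets:
# minimum over all point-to-segment distances in both directions. For
# linearly separable sets the hard-margin SVM satisfies
# 2 / ||w|| = hull distance.
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

hull_distance_2d <- function(x1, x2) {
  seg_dists <- function(pts, others) {
    d <- Inf
    n <- nrow(others)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j && n > 1) next
        for (k in seq_len(nrow(pts))) {
          d <- min(d, point_segment_dist(pts[k, ], others[i, ], others[j, ]))
        }
      }
    }
    d
  }
  min(seg_dists(x1, x2), seg_dists(x2, x1))
}

# short synthetic session for pipeline tests (3 task blocks keeps tests fast;
# acceptance tests use the full default session)
quick_config <- function(seed = 1, ...) {
  sim_config(n_nback_blocks = 3L, seed = seed, ...)
}

quick_session <- function(seed = 1, ...) {
  simulate_session(quick_config(seed = seed, ...))
}

# a small feature matrix with planted class structure
toy_features <- function(n_per_class = 10, n_feat = 6, sep = 2, seed = 1,
                         noise_sd = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(stats::rnorm(n_per_class * n_feat, 0, noise_sd), n_per_class),
    matrix(stats::rnorm(n_per_class * n_feat, sep, noise_sd), n_per_class)
  )
  colnames(x) <- paste0("f", seq_len(n_feat))
  structure(
    list(x = x, labels = rep(c("relax", "nback"), each = n_per_class)),
    class = "feature_matrix"
  )
}
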