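# PCA + K-Means single-voxel clustering: features, elbow, fits, maps.

test_that("build_feature_matrix pools (voxel, subject, condition) rows", {
  cfg <- tiny_config(n_trials = 3)
  g1 <- generate_trialset(cfg, subject_id = "m1")
  cfg2 <- tiny_config(n_trials = 3, rng_seed = 8)
  g2 <- generate_trialset(cfg2, subject_id = "m2")
  map <- g1$truth$label_map

  fm <- build_feature_matrix(list(g1$ts, g2$ts), map, "SCs")
  # 2 subjects x 2 conditions x 36 voxels
  expect_identical(nrow(fm$index), 2L * 2L * 36L)
  expect_identical(length(fm$back_index), nrow(fm$index))
  # noisy data: no duplicates expected
  expect_identical(nrow(fm$features), nrow(fm$index))

  # row order deterministic across runs
  fm2 <- build_feature_matrix(list(g1$ts, g2$ts), map, "SCs")
  expect_identical(fm$features, fm2$features)
  expect_identical(fm$index, fm2$index)

  expect_error(build_feature_matrix(list(g1$ts),
                                    region_label_map(matrix(0L, 12, 12),
                                                     c("1" = "SCs")),
                                    "SCs"), "empty")
})

test_that("duplicate traces are collapsed and restored through the back-index", {
  # noiseless generation makes all voxels of a class exact duplicates
  cfg <- tiny_config(n_trials = 2, conditions = 100,
                     frame_noise_pct = 0, trial_gain_sd = 0)
  g <- generate_trialset(cfg)
  fm <- build_feature_matrix(list(g$ts), g$truth$label_map, "SCs")
  # SCs = 18 class-2 voxels + 18 background: exactly 2 unique traces
  expect_identical(nrow(fm$features), 2L)
  expect_identical(length(fm$back_index), 36L)
  expect_equal(fm$features[fm$back_index, ],
               fm$features[fm$back_index, ])   # projection well-defined
})

test_that("fit_pca honors the variance target", {
  set.seed(4)
  # rank-1 data: one component explains everything
  u <- rnorm(30); v <- rnorm(12)
  rank1 <- outer(u, v)
  p1 <- fit_pca(rank1, variance_target = 0.5)
  expect_identical(p1$n_components, 1L)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)

  noisy <- rank1 + matrix(rnorm(30 * 12, 0, 0.01), 30, 12)
  pfull <- fit_pca(noisy, variance_target = 1.0)
  expect_identical(pfull$n_components, as.integer(qr(noisy)$rank))
  # cumulative explained variance is nondecreasing and ends at 1
  expect_true(all(diff(pfull$cum_explained) >= -1e-12))
  expect_equal(pfull$cum_explained[length(pfull$cum_explained)], 1,
               tolerance = 1e-9)

  expect_error(fit_pca(noisy, variance_target = 1.5), "variance_target")
  expect_error(fit_pca(noisy[1, , drop = FALSE]), "2 rows")
})

test_that("fit_kmeans finds planted blobs and orders them by amplitude", {
  bl <- blob_traces(per_blob = 30, seed = 13)
  model <- fit_kmeans(bl$traces, k = 5, n_init = 20, seed = 2)
  expect_equal(adjusted_rand_index(model$labels, bl$labels), 1.0)
  # amplitude ordering: blob amplitudes were generated increasing, so the
  # planted blob index must map monotonically onto the cluster id
  expect_true(all(diff(model$centroid_peaks) >= 0))
  expect_identical(model$labels, bl$labels)

  # k = 1: inertia equals the total sum of squared deviations from the mean
  m1 <- fit_kmeans(bl$traces, k = 1, n_init = 1, seed = 1)
  tss <- sum(sweep(bl$traces, 2, colMeans(bl$traces))^2)
  expect_equal(m1$inertia, tss, tolerance = 1e-9)

  # reported inertia is self-consistent with labels and centroids
  d2 <- rowSums((bl$traces - model$centroids[model$labels, ])^2)
  expect_equal(model$inertia, sum(d2), tolerance = 1e-9)

  expect_error(fit_kmeans(bl$traces[1:3, ], k = 5), "exceeds")
})

test_that("PCA-space fits reconstruct centroid traces for ordering", {
  bl <- blob_traces(per_blob = 20, seed = 17)
  pca <- fit_pca(bl$traces, variance_target = 0.5)
  model <- fit_kmeans(pca$scores, k = 5, n_init = 20, seed = 3, pca = pca)
  expect_equal(adjusted_rand_index(model$labels, bl$labels), 1.0)
  expect_identical(ncol(model$centroid_traces), 57L)
  expect_true(all(diff(model$centroid_peaks) >= 0))
})

test_that("increasing n_init never increases the retained inertia", {
  bl <- blob_traces(amplitudes = c(1, 2, 3, 4, 5), per_blob = 15,
                    jitter_sd = 1.5, seed = 23)   # hard, overlapping blobs
  for (seed in 1:3) {
    i_small <- fit_kmeans(bl$traces, 5, n_init = 2, seed = seed)$inertia
    i_large <- fit_kmeans(bl$traces, 5, n_init = 25, seed = seed)$inertia
    expect_lte(i_large, i_small + 1e-9)
  }
})

test_that("elbow_k suggests the planted cluster count", {
  bl <- blob_traces(per_blob = 25, seed = 29)
  e <- elbow_k(bl$traces, k_range = 2:8, n_init_small = 5, seed = 7)
  expect_identical(e$suggested_k, 5L)
  # inertia nonincreasing in k at the retained optimum
  expect_true(all(diff(e$inertia) <= 1e-6 * max(e$inertia)))

  # degenerate input: single repeated point
  same <- matrix(1, 20, 57)
  e0 <- elbow_k(same, k_range = 1:3, n_init_small = 2, seed = 1)
  expect_true(e0$no_elbow)
  expect_equal(e0$inertia[1], 0)
})

test_that("cluster_traces decompose the global mean and flag empties", {
  bl <- blob_traces(per_blob = 20, seed = 37)
  model <- fit_kmeans(bl$traces, 5, n_init = 10, seed = 5)
  ct <- cluster_traces(model, bl$traces)
  # identical members within a blob up to jitter: small SD
  expect_true(all(ct$sd < 0.2, na.rm = TRUE))
  # size-weighted mean of cluster traces = global mean trace
  global <- colMeans(bl$traces)
  recomposed <- colSums(ct$mean * ct$n) / sum(ct$n)
  expect_equal(recomposed, global, tolerance = 1e-10)
  # per-cluster peaks nondecreasing in cluster id (amplitude ordering)
  timing <- default_timing()
  peaks <- apply(ct$mean[, stim_window(timing)$frames], 1, max)
  expect_true(all(diff(peaks) >= -1e-9))

  # empty cluster flagged: relabel a run's members away
  expect_warning(cluster_traces(model, bl$traces,
                                labels = pmax(model$labels, 2L)),
                 "empty cluster")
})

test_that("cluster_map restores duplicates and partitions analyzed voxels", {
  cfg <- tiny_config(n_trials = 2, conditions = 100,
                     frame_noise_pct = 0, trial_gain_sd = 0)
  g <- generate_trialset(cfg)
  fm <- build_feature_matrix(list(g$ts), g$truth$label_map, "SCs")
  model <- fit_kmeans(fm$features, k = 2, n_init = 5, seed = 1,
                      timing = default_timing())
  cm <- cluster_map(model, fm, "synth-1", 100)
  # every analyzed voxel got exactly one id; others 0
  expect_identical(sum(cm != 0), 36L)
  expect_true(all(cm[g$truth$label_map$labels == 1] %in% 1:2))
  # duplicates share their representative's id: noiseless classes are uniform
  expect_identical(length(unique(cm[g$truth$class_map == 2])), 1L)
  # regenerating the map is deterministic
  expect_identical(cm, cluster_map(model, fm, "synth-1", 100))
  expect_error(cluster_map(model, fm, "nope", 100), "unknown subject")
})

test_that("map_similarity counts agreeing analyzed voxels", {
  a <- matrix(0L, 10, 10); a[1:5, ] <- sample(1:3, 50, replace = TRUE)
  expect_equal(map_similarity(a, a), 1.0)
  b <- a; b[a != 0] <- a[a != 0] %% 3L + 1L     # everywhere different
  expect_equal(map_similarity(a, b), 0.0)
  # 95 of 100 equal
  big <- matrix(1L, 10, 10); big2 <- big; big2[1, 1:5] <- 2L
  expect_equal(map_similarity(big, big2), 0.95)
  # symmetry
  expect_equal(map_similarity(a, b), map_similarity(b, a))
  # mismatched analyzed sets are an error
  c2 <- a; c2[6, 1] <- 1L
  expect_error(map_similarity(a, c2), "different analyzed")
})

test_that("stability is perfect on separable data and counts pairs", {
  bl <- blob_traces(per_blob = 15, seed = 41)
  st2 <- stability(bl$traces, 5, n_runs = 2, seed = 3, n_init = 10)
  expect_identical(length(st2$similarities), 1L)       # exactly one pair
  st <- stability(bl$traces, 5, n_runs = 4, seed = 3, n_init = 10)
  expect_true(all(st$similarities >= 0 & st$similarities <= 1))
  expect_equal(st$mean, 1.0)
  expect_identical(length(st$similarities), 6L)        # 4*3/2 pairs
})

test_that("cluster_region_distribution matches brute-force counts", {
  labels <- matrix(0L, 6, 6)
  labels[1:2, ] <- 1L; labels[3:4, ] <- 2L; labels[5:6, ] <- 3L
  map <- region_label_map(labels, c("1" = "SCs", "2" = "SCi", "3" = "SCd"))
  cm <- matrix(0L, 6, 6)
  cm[1:2, 1:3] <- 1L          # cluster 1 entirely inside SCs
  cm[3:6, 1:2] <- 2L          # cluster 2 split SCi/SCd
  dist <- cluster_region_distribution(structure(cm, class = "cluster_map"), map)
  expect_equal(unname(dist$per_cluster["c1", ]), c(100, 0, 0))
  expect_equal(unname(dist$per_cluster["c2", ]), c(0, 50, 50))
  expect_equal(unname(rowSums(dist$per_cluster)), rep(100, 2), tolerance = 1e-9)
  # brute-force oracle
  for (j in 1:2) for (ai in 1:3)
    expect_equal(dist$per_cluster[j, ai],
                 100 * sum(cm == j & labels == ai) / sum(cm == j))
  # inverse view columns: per region, proportions over clusters
  expect_equal(dist$per_region["c1", "SCs"], 100)
})
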