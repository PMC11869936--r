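#' Feature matrix for single-voxel clustering
#'
#' Pools recording sessions: one row per (voxel, subject, condition)
#' trial-averaged ΔI trace within the region, in deterministic order
#' (subject, then condition, then voxel row-major). Exact duplicate rows
#' (e.g. from nearest-neighbour grid resampling) are removed via
#' [dedup_traces()] with the back-index retained so labels can be
#' propagated to every voxel.
#'
#' @param ts_list list of `trial_set`s (one per subject).
#' @param map a `region_label_map` shared by all subjects.
#' @param acronym region acronym to analyze (e.g. `"SC"` layers pooled via
#'   repeated calls, or a single layer).
#' @param conditions subset of contrasts to include (default: all of the
#'   first subject's conditions).
#' @return list with `features` (unique rows x frames), `index`
#'   (data.frame `subject`, `condition`, `z`, `x`, one row per original
#'   sample), `back_index` (original row -> unique row), and `grid_shape`.
#' @export
build_feature_matrix <- function(ts_list, map, acronym, conditions = NULL) {
  stopifnot(length(ts_list) >= 1)
  vox <- select_region(map, acronym)
  if (nrow(vox) == 0) stop("region is empty: ", acronym)
  if (is.null(conditions)) conditions <- ts_list[[1]]$conditions
  rows <- list(); meta <- list()
  for (si in seq_along(ts_list)) {
    ts <- ts_list[[si]]
    timing <- timing_of(ts)
    for (cond in conditions) {
      avg <- trial_average(ts, cond)
      tr <- matrix(NA_real_, nrow(vox), dim(avg)[3])
      for (i in seq_len(nrow(vox))) {
        rt <- to_relative(avg[vox[i, "z"], vox[i, "x"], ], timing)
        if (!rt$degenerate) tr[i, ] <- rt$values
      }
      tr[is.na(tr)] <- 0
      rows[[length(rows) + 1L]] <- tr
      meta[[length(meta) + 1L]] <- data.frame(
        subject = ts$subject_id, condition = cond,
        z = vox[, "z"], x = vox[, "x"])
    }
  }
  full <- do.call(rbind, rows)
  index <- do.call(rbind, meta)
  dd <- dedup_traces(full)
  list(features = dd$unique, index = index, back_index = dd$index,
       grid_shape = dim(map$labels))
}

#' PCA feature reduction
#'
#' Mean-centered PCA; the number of retained components is either fixed or
#' the smallest count whose cumulative explained variance reaches
#' `variance_target` (default 0.5, the 50%-of-variance rule).
#'
#' @param mat samples x frames matrix.
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @param n_components fixed component count overriding the target.
#' @return list with `scores` (samples x m), `basis` (m x frames), `center`
#'   (per-frame mean), `n_components`, `explained` (per-component ratios),
#'   `cum_explained`.
#' @export
fit_pca <- function(mat, variance_target = 0.50, n_components = NULL) {
  if (nrow(mat) < 2) stop("PCA needs at least 2 rows")
  if (is.null(n_components) &&
      (variance_target <= 0 || variance_target > 1))
    stop("variance_target must be in (0, 1]")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(expl)
  m <- if (!is.null(n_components)) n_components
       else which(cum >= variance_target - 1e-12)[1]
  m <- min(m, length(expl))
  list(scores = pc$x[, seq_len(m), drop = FALSE],
       basis = t(pc$rotation[, seq_len(m), drop = FALSE]),
       center = pc$center,
       n_components = m,
       explained = expl,
       cum_explained = cum)
}

# centroid (k x m) back to trace space (k x frames)
reconstruct_centroids <- function(pca, centroids) {
  sweep(centroids %*% pca$basis, 2, pca$center, `+`)
}

squared_dists <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- squared_dists(X, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1)) {
    probs <- pmax(d2, 0)
    pick <- if (sum(probs) <= 0) sample.int(n, 1)
            else sample.int(n, 1, prob = probs)
    centers[j + 1, ] <- X[pick, ]
    d2 <- pmin(d2, squared_dists(X, centers[j + 1, , drop = FALSE])[, 1])
  }
  centers
}

# Lloyd iterations (the fixed point targeted by the Elkan acceleration);
# empty clusters are reseeded on the farthest sample.
lloyd <- function(X, centers, max_iter = 100L, tol = 1e-10) {
  k <- nrow(centers)
  labels <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- squared_dists(X, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    nearest <- d2[cbind(seq_len(nrow(X)), new_labels)]
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(nearest)
        new_labels[far] <- j
        nearest[far] <- -Inf   # keep later empties from stealing it back
      }
    }
    new_centers <- matrix(0, k, ncol(X))
    for (j in seq_len(k))
      new_centers[j, ] <- colMeans(X[new_labels == j, , drop = FALSE])
    shift <- sum((new_centers - centers)^2)
    centers <- new_centers
    if (identical(new_labels, labels) || shift < tol) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  d2 <- squared_dists(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), labels)])
  list(centers = centers, labels = labels, inertia = inertia)
}

#' K-Means with multiple initializations and amplitude-ordered labels
#'
#' Runs k-means++-seeded Lloyd iterations `n_init` times and keeps the
#' lowest-inertia model (the same optimum the Elkan acceleration targets),
#' then relabels clusters so the stimulus-window peak amplitude of the
#' centroid trace is nondecreasing in cluster id (c1 lowest ... cK
#' highest). When a `pca` is supplied the centroid trace is reconstructed
#' through the PCA basis; otherwise the features themselves are taken as
#' traces.
#'
#' @param features samples x m matrix (PCA scores or raw traces).
#' @param k number of clusters (<= number of samples).
#' @param n_init number of random initializations (default 100).
#' @param seed integer RNG seed.
#' @param pca result of [fit_pca()] used to reconstruct centroid traces.
#' @param timing timing list for the stimulus window; defaults to the
#'   canonical 0.6 s / 10-4-20 s trial when omitted.
#' @return object of class `cluster_model`: `centroids` (k x m), `labels`
#'   (amplitude-ordered, per sample), `inertia`, `k`, `centroid_traces`
#'   (k x frames), `centroid_peaks`, plus the `pca` and `seed` used.
#' @export
fit_kmeans <- function(features, k, n_init = 100L, seed = 1L,
                       pca = NULL, timing = NULL) {
  features <- as.matrix(features)
  if (k > nrow(features)) stop("k exceeds the number of samples")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- lloyd(features, kmeanspp_init(features, k))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  if (is.null(timing))
    timing <- list(frame_interval_s = 0.6, baseline_s = 10,
                   stimulus_s = 4, post_s = 20)
  traces <- if (is.null(pca)) best$centers
            else reconstruct_centroids(pca, best$centers)
  win <- stim_window(timing)
  frames <- win$frames[win$frames <= ncol(traces)]
  if (length(frames) == 0) frames <- seq_len(ncol(traces))
  peaks <- apply(traces[, frames, drop = FALSE], 1, max)
  ord <- order(peaks)
  relabel <- match(seq_len(k), ord)
  structure(list(centroids = best$centers[ord, , drop = FALSE],
                 labels = relabel[best$labels],
                 inertia = best$inertia,
                 k = k,
                 centroid_traces = traces[ord, , drop = FALSE],
                 centroid_peaks = peaks[ord],
                 pca = pca, timing = timing, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, inertia = %.4g, centroid peaks: %s\n",
              x$k, x$inertia,
              paste(sprintf("%.2f", x$centroid_peaks), collapse = ", ")))
  invisible(x)
}

#' Elbow-based cluster-count suggestion
#'
#' Fits K-Means over `k_range` (best of `n_init_small` initializations
#' each), min-max normalizes the inertia curve on both axes and suggests
#' the interior k with maximum discrete curvature. The full curve is always
#' returned for manual override; a flat curve sets the `no_elbow` flag.
#'
#' @param features samples x m matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param n_init_small initializations per k (default 10).
#' @param seed integer RNG seed.
#' @return list with `k_range`, `inertia`, `suggested_k`, `no_elbow`.
#' @export
elbow_k <- function(features, k_range = 2:10, n_init_small = 10L, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(all(k_range >= 1), all(k_range <= nrow(features)))
  inertia <- vapply(seq_along(k_range), function(i) {
    fit_kmeans(features, k_range[i], n_init = n_init_small,
               seed = seed + i)$inertia
  }, numeric(1))
  rng <- diff(range(inertia))
  if (rng <= 0)
    return(list(k_range = k_range, inertia = inertia,
                suggested_k = NA_integer_, no_elbow = TRUE))
  xs <- (k_range - min(k_range)) / diff(range(k_range))
  ys <- (inertia - min(inertia)) / rng
  n <- length(xs)
  h <- xs[2] - xs[1]
  curv <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    d1 <- (ys[i + 1] - ys[i - 1]) / (2 * h)
    d2 <- (ys[i + 1] - 2 * ys[i] + ys[i - 1]) / h^2
    curv[i] <- d2 / (1 + d1^2)^1.5
  }
  list(k_range = k_range, inertia = inertia,
       suggested_k = k_range[which.max(curv)], no_elbow = FALSE)
}

#' Per-cluster mean and SD traces
#'
#' @param model a `cluster_model`.
#' @param traces matrix of ΔI traces aligned with `labels` (one row per
#'   sample; pass the deduplicated feature-matrix traces, or the
#'   back-projected full set with `labels = model$labels[back_index]`).
#' @param labels per-row cluster ids (default the model's).
#' @return list with `mean` (k x frames), `sd` (k x frames), `n` (members
#'   per cluster); empty clusters yield NA rows and a warning.
#' @export
cluster_traces <- function(model, traces, labels = model$labels) {
  traces <- as.matrix(traces)
  stopifnot(length(labels) == nrow(traces))
  k <- model$k
  mu <- matrix(NA_real_, k, ncol(traces))
  sdv <- matrix(NA_real_, k, ncol(traces))
  n <- integer(k)
  for (j in seq_len(k)) {
    member <- traces[labels == j, , drop = FALSE]
    n[j] <- nrow(member)
    if (n[j] > 0) {
      mu[j, ] <- colMeans(member)
      sdv[j, ] <- apply(member, 2, stats::sd)
    }
  }
  if (any(n == 0))
    warning("empty cluster id(s): ", paste(which(n == 0), collapse = ", "),
            call. = FALSE)
  list(mean = mu, sd = sdv, n = n)
}

#' Cluster map for one subject and condition
#'
#' Projects the model labels back onto the voxel grid through the sample
#' index and duplicate back-index; voxels outside the analyzed set get 0.
#'
#' @param model a `cluster_model`.
#' @param fm result of [build_feature_matrix()] the model was fitted on.
#' @param subject subject id present in the index.
#' @param condition contrast present in the index.
#' @return object of class `cluster_map`: integer matrix of cluster ids.
#' @export
cluster_map <- function(model, fm, subject, condition) {
  sel <- fm$index$subject == subject & fm$index$condition == condition
  if (!any(sel)) stop("unknown subject/condition: ", subject, "/", condition)
  full_labels <- model$labels[fm$back_index]
  m <- matrix(0L, fm$grid_shape[1], fm$grid_shape[2])
  m[cbind(fm$index$z[sel], fm$index$x[sel])] <- full_labels[sel]
  structure(m, class = c("cluster_map", "matrix", "array"))
}

#' Similarity of two cluster maps
#'
#' Fraction of analyzed voxels (nonzero in both maps) assigned the same
#' cluster id; both maps must already carry amplitude-ordered labels (as
#' produced by [fit_kmeans()]) and cover the same analyzed set.
#'
#' @param map_a,map_b integer matrices (0 = outside analyzed set).
#' @return fraction in [0, 1].
#' @export
map_similarity <- function(map_a, map_b) {
  a <- unclass(map_a); b <- unclass(map_b)
  if (!identical(dim(a), dim(b))) stop("maps have different grids")
  in_a <- a != 0L; in_b <- b != 0L
  if (!identical(in_a, in_b)) stop("maps cover different analyzed voxel sets")
  if (!any(in_a)) stop("maps contain no analyzed voxels")
  mean(a[in_a] == b[in_a])
}

#' Clustering stability across repeated fits
#'
#' Fits `n_runs` independent models (each best-of-`n_init`
#' initializations), amplitude-orders each, and returns the mean and SD of
#' the label agreement over all run pairs. Agreement is computed on the
#' full per-sample label vectors, i.e. pooled over every (subject,
#' condition) map at once.
#'
#' @param features samples x m matrix.
#' @param k number of clusters.
#' @param n_runs number of repeated fits (default 10).
#' @param seed base RNG seed; run i uses `seed + i`.
#' @param n_init initializations per run (default 100).
#' @inheritParams fit_kmeans
#' @return list with `mean`, `sd`, `similarities` (all pairs), `n_runs`.
#' @export
stability <- function(features, k, n_runs = 10L, seed = 1L, n_init = 100L,
                      pca = NULL, timing = NULL) {
  stopifnot(n_runs >= 2)
  runs <- lapply(seq_len(n_runs), function(i)
    fit_kmeans(features, k, n_init = n_init, seed = seed + i,
               pca = pca, timing = timing))
  pairs <- utils::combn(n_runs, 2)
  sims <- apply(pairs, 2, function(p)
    mean(runs[[p[1]]]$labels == runs[[p[2]]]$labels))
  list(mean = mean(sims), sd = stats::sd(sims), similarities = sims,
       n_runs = n_runs)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples
#' (1 = identical partitions up to relabeling, ~0 = random agreement).
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Layer-wise composition of each cluster
#'
#' For every cluster id, the percentage of its voxels falling in each
#' region (rows sum to 100), pooled over the supplied maps; plus the
#' inverse view (per region, percentage of voxels per cluster).
#'
#' @param maps a `cluster_map` or list of them.
#' @param map a `region_label_map` on the same grid.
#' @return list with `per_cluster` and `per_region` percentage matrices.
#' @export
cluster_region_distribution <- function(maps, map) {
  if (!is.list(maps)) maps <- list(maps)
  acronyms <- unname(map$lookup)
  k <- max(vapply(maps, max, numeric(1)))
  counts <- matrix(0, k, length(acronyms),
                   dimnames = list(paste0("c", seq_len(k)), acronyms))
  for (cm in maps) {
    m <- unclass(cm)
    for (j in seq_len(k)) for (ai in seq_along(acronyms)) {
      lab <- label_for_acronym(map, acronyms[ai])
      counts[j, ai] <- counts[j, ai] + sum(m == j & map$labels == lab)
    }
  }
  rs <- rowSums(counts)
  per_cluster <- 100 * counts / ifelse(rs == 0, NA, rs)
  cs <- colSums(counts)
  per_region <- t(100 * t(counts) / ifelse(cs == 0, NA, cs))
  list(per_cluster = per_cluster, per_region = per_region)
}
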