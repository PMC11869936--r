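#' Run configuration defaults
#'
#' Assembles a full pipeline configuration; defaults follow the canonical
#' acquisition and analysis parameters (0.6 s frames, 10/4/20 s trial,
#' alpha 0.01 for the correlation threshold, 1% active-area exclusion, 50%
#' PCA variance target, 100 K-Means initializations, 10 stability runs).
#'
#' @param input directory of a saved trial set ([save_trialset()]), or NULL
#'   when `ts` is passed to [run_pipeline()] directly.
#' @param labels directory of a saved label map, or NULL.
#' @param regions region acronyms to analyze.
#' @param condition contrast used for the correlation and map stages;
#'   NULL = highest available.
#' @param alpha,threshold,min_fraction correlation-stage parameters.
#' @param variance_target,k,n_init,n_runs clustering-stage parameters
#'   (`k = NULL` lets the elbow rule choose over `k_range`).
#' @param k_range candidate k values for the elbow stage.
#' @param seed integer RNG seed.
#' @param out output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, labels = NULL,
                       regions = c("SCs", "SCi", "SCd"),
                       condition = NULL,
                       alpha = 0.01, threshold = NULL, min_fraction = 0.01,
                       variance_target = 0.50, k = NULL, k_range = 2:8,
                       n_init = 100L, n_runs = 10L,
                       seed = 1L, out = tempfile("voxelus-run-")) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the three analysis strategies end-to-end
#'
#' Region averaging, stimulus-correlation mapping and single-voxel
#' clustering on one trial set, writing CSV artifacts plus a JSON manifest
#' (config echo, seed, file hashes). Deterministic for a fixed config and
#' seed. Stage failures propagate as errors after a failure marker is
#' written.
#'
#' @param config a [run_config()].
#' @param ts optional in-memory `trial_set` overriding `config$input`.
#' @param map optional in-memory `region_label_map` overriding
#'   `config$labels`.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, ts = NULL, map = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(ts)) ts <- load_trialset(config$input)
  if (is.null(map)) map <- load_label_map(config$labels)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(out, "FAILED")
  ok <- FALSE
  on.exit(if (!ok) writeLines("pipeline failed; partial outputs retained",
                              fail_marker))
  timing <- timing_of(ts)
  cond <- if (is.null(config$condition)) max(ts$conditions) else config$condition
  for (reg in config$regions)
    if (!reg %in% map$lookup) stop("unknown region acronym: ", reg)

  # --- region averaging --------------------------------------------------
  traces_rows <- list()
  for (reg in config$regions) for (cc in ts$conditions) {
    rt <- suppressWarnings(region_trace(ts, map, reg, cc))
    traces_rows[[length(traces_rows) + 1L]] <- data.frame(
      region = reg, condition = cc, frame = seq_along(rt$values),
      time_s = rt$time_s, dI_percent = rt$values)
  }
  region_traces <- do.call(rbind, traces_rows)
  utils::write.csv(region_traces, file.path(out, "region_traces.csv"),
                   row.names = FALSE)

  # --- correlation -------------------------------------------------------
  res <- suppressWarnings(
    correlate_stimulus(ts, cond, alpha = config$alpha,
                       threshold = config$threshold))
  utils::write.table(round(res$r_map, 6), file.path(out, "rmap.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(res$active_mask * 1L, file.path(out, "active_mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  fractions <- data.frame(
    region = config$regions,
    active_fraction = vapply(config$regions, function(r)
      active_fraction(res, map, r), numeric(1)))
  utils::write.csv(fractions, file.path(out, "active_fractions.csv"),
                   row.names = FALSE)

  # --- clustering --------------------------------------------------------
  fm <- build_feature_matrix(list(ts), map, config$regions[1],
                             conditions = ts$conditions)
  pca <- fit_pca(fm$features, variance_target = config$variance_target)
  kk <- config$k
  elbow <- NULL
  if (is.null(kk)) {
    elbow <- elbow_k(pca$scores, config$k_range, seed = config$seed)
    kk <- elbow$suggested_k
    if (is.na(kk)) stop("elbow rule found no usable k; set config$k")
  }
  model <- fit_kmeans(pca$scores, kk, n_init = config$n_init,
                      seed = config$seed, pca = pca, timing = timing)
  cm <- cluster_map(model, fm, ts$subject_id, cond)
  utils::write.table(unclass(cm), file.path(out, "cluster_map.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  ct <- suppressWarnings(cluster_traces(model, fm$features))
  trace_df <- do.call(rbind, lapply(seq_len(model$k), function(j)
    data.frame(cluster = j, frame = seq_len(ncol(ct$mean)),
               mean_dI = ct$mean[j, ], sd_dI = ct$sd[j, ])))
  utils::write.csv(trace_df, file.path(out, "cluster_traces.csv"),
                   row.names = FALSE)

  files <- list.files(out, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("voxelus")),
    seed = config$seed,
    condition = cond,
    k = kk,
    n_components = pca$n_components,
    elbow = if (is.null(elbow)) NULL else elbow[c("k_range", "inertia",
                                                  "suggested_k")],
    threshold = res$threshold,
    hashes = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher backing the `inst/cli/voxelus` script:
#' `simulate` writes a synthetic dataset, `run` executes the full pipeline
#' on a saved dataset.
#'
#' @param args character vector, e.g. `c("simulate", "--seed", "3",
#'   "--out", "dir")`.
#' @return exit status (0 on success), invisibly.
#' @export
voxelus_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: voxelus simulate --out DIR [--seed N]",
    "       voxelus run --in DIR --labels DIR --out DIR [--seed N] [--k K]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0) default else args[i[1] + 1]
  }
  cmd <- args[1]
  status <- tryCatch({
    if (cmd == "simulate") {
      out <- opt("--out"); if (is.null(out)) stop("--out is required")
      seed <- as.integer(opt("--seed", "1"))
      cfg <- synth_config(rng_seed = seed)
      save_synth(generate_trialset(cfg), cfg, out)
      message("wrote synthetic dataset to ", out)
      0L
    } else if (cmd == "run") {
      input <- opt("--in"); labels <- opt("--labels"); out <- opt("--out")
      if (is.null(input) || is.null(labels) || is.null(out))
        stop("--in, --labels and --out are required")
      k <- opt("--k"); k <- if (is.null(k)) NULL else as.integer(k)
      cfg <- run_config(input = file.path(input, "trialset"),
                        labels = file.path(input, "labels"),
                        seed = as.integer(opt("--seed", "1")),
                        k = k, out = out)
      if (!is.null(opt("--labels"))) cfg$labels <- labels
      run_pipeline(cfg)
      message("pipeline complete; manifest in ", out)
      0L
    } else {
      message(usage)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
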