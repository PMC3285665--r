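#' Configuration for an end-to-end synthetic screen run
#'
#' Bundles every tunable of the generate - quantify - features - cluster -
#' discriminate pipeline into one serializable object. Defaults are the
#' reference demonstration conditions of [demo_screen()].
#'
#' @param n_probes,n_informative,time_points_h,noise_cv,batch_sd,batch_aligned
#'   Passed to [demo_screen()].
#' @param seed Master seed for every random draw of the run.
#' @param store `"memory"` renders images lazily during quantification;
#'   `"disk"` writes every TIFF under `out_dir`.
#' @param collapse,baseline_floor Passed to [build_feature_matrix()].
#' @param log2 Log2-transform folds for clustering and discriminant
#'   analysis.
#' @param cluster_metric,cluster_linkage,purity_k Clustering options.
#' @param alpha_enter,alpha_remove,max_features,priors,ridge Stepwise/LDA
#'   options. The default `max_features = 35` keeps the leave-one-out
#'   pooled covariance comfortably inside its degrees of freedom
#'   (p well below n - g) for the 60-line panel.
#' @param n_bins Histogram bins for Otsu quantification.
#' @param out_dir Optional directory for the report bundle.
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_probes = 100, n_informative = 30,
                          seed = 7L,
                          time_points_h = c(1, 48),
                          noise_cv = 0.2, batch_sd = 0.3,
                          batch_aligned = TRUE,
                          store = c("memory", "disk"),
                          collapse = "per_condition", baseline_floor = 1,
                          log2 = TRUE,
                          cluster_metric = "euclidean",
                          cluster_linkage = "average", purity_k = 9,
                          alpha_enter = 0.150, alpha_remove = 0.150,
                          max_features = 35, priors = "equal", ridge = 0,
                          n_bins = 256L, out_dir = NULL) {
  cfg <- list(
    n_probes = n_probes, n_informative = n_informative, seed = seed,
    time_points_h = time_points_h, noise_cv = noise_cv,
    batch_sd = batch_sd, batch_aligned = batch_aligned,
    store = match.arg(store), collapse = collapse,
    baseline_floor = baseline_floor, log2 = log2,
    cluster_metric = cluster_metric, cluster_linkage = cluster_linkage,
    purity_k = purity_k, alpha_enter = alpha_enter,
    alpha_remove = alpha_remove, max_features = max_features,
    priors = priors, ridge = ridge, n_bins = n_bins, out_dir = out_dir
  )
  structure(cfg, class = "screen_config")
}

#' Validate a run configuration
#'
#' @param config A `screen_config`.
#' @param design Optional `screen_design` the run will use (for checks
#'   that need the realized panel, e.g. single-member origin classes).
#' @return A tibble of findings `(level, field, message)`; empty when the
#'   configuration is clean. `level` is `"error"` or `"warning"`.
#' @export
validate_config <- function(config, design = NULL) {
  f <- list()
  note <- function(level, field, message) {
    f[[length(f) + 1L]] <<- tibble(level = level, field = field,
                                   message = message)
  }
  for (a in c("alpha_enter", "alpha_remove")) {
    if (!is.numeric(config[[a]]) || config[[a]] <= 0 || config[[a]] >= 1) {
      note("error", a, "alpha must lie in (0, 1)")
    }
  }
  if (config$n_probes < 2 || config$n_probes %% 2 != 0) {
    note("error", "n_probes", "need an even probe count >= 2")
  }
  if (config$n_informative > config$n_probes) {
    note("error", "n_informative", "more informative probes than probes")
  }
  if (is.unsorted(config$time_points_h, strictly = TRUE) ||
      !all(c(1, 48) %in% config$time_points_h)) {
    note("error", "time_points_h",
         "time points must be strictly increasing and contain 1 and 48")
  }
  if (config$noise_cv < 0 || config$batch_sd < 0) {
    note("error", "noise", "noise scales must be >= 0")
  }
  if (is.character(config$priors) &&
      !config$priors %in% c("equal", "proportional")) {
    note("error", "priors", "priors must be equal/proportional or numeric")
  }
  if (!is.null(design)) {
    sizes <- table(design$lines$origin)
    n <- nrow(design$lines); g <- length(sizes)
    if (any(sizes == 1)) {
      note("warning", "design",
           sprintf("single-member origin class (%s): its sample is necessarily misclassified under leave-one-out",
                   paste(names(sizes)[sizes == 1], collapse = ", ")))
    }
    if (g < 2) note("error", "design", "need >= 2 origin classes")
    if (is.finite(config$max_features) &&
        config$max_features > n - g - 1) {
      note("warning", "max_features",
           "max_features exceeds the residual-df guard n - g - 1 and will be capped")
    }
  }
  if (length(f) == 0) {
    tibble(level = character(), field = character(), message = character())
  } else {
    dplyr::bind_rows(f)
  }
}

#' Log2-transform the feature columns of a feature matrix
#'
#' @param data Feature matrix from [build_feature_matrix()].
#' @return The same tibble with each feature column log2-transformed.
#' @export
log2_features <- function(data) {
  assert_feature_table(data)
  dplyr::mutate(data, dplyr::across(tidyselect::all_of(feature_columns(data)),
                                    base::log2))
}

#' Run the full phenomic profiling pipeline on a synthetic screen
#'
#' Generates the screen, quantifies foreground intensities, builds the
#' kinetic fold-change feature matrix, clusters both axes, and runs
#' stepwise discriminant analysis with jackknifed cross-validation and
#' the probe-family comparison. Every stage is the same function a user
#' would call on a real manifest; the synthetic generator only supplies
#' the images. Fully reproducible from `(config, seed)`.
#'
#' @param config A `screen_config`.
#' @param design,model Optional explicit `screen_design`/`effect_model`
#'   overriding the [demo_screen()] pair built from the config.
#' @return A `screen_report` list: `intensity`, `features`,
#'   `line_dendro`, `probe_dendro`, `purity`, `stepwise`, `model`,
#'   `jackknife`, `scores`, `family_comparison`, `informative`,
#'   `ground_truth`, `meta` (seed, config, config hash, stage timings,
#'   flagged-record counts).
#' @export
run_screen_pipeline <- function(config = screen_config(), design = NULL,
                                model = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(design) != is.null(model)) {
    abort("supply both `design` and `model`, or neither")
  }
  informative <- NULL
  if (is.null(design)) {
    demo <- demo_screen(n_probes = config$n_probes,
                        n_informative = config$n_informative,
                        seed = config$seed,
                        time_points_h = config$time_points_h,
                        noise_cv = config$noise_cv,
                        batch_sd = config$batch_sd,
                        batch_aligned = config$batch_aligned)
    design <- demo$design; model <- demo$model
    informative <- demo$informative
  }
  findings <- validate_config(config, design)
  if (any(findings$level == "error")) {
    abort(paste0("invalid configuration:\n  ",
                 paste(findings$message[findings$level == "error"],
                       collapse = "\n  ")))
  }
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  out_dir <- config$out_dir
  screen <- generate_screen(
    design, model, seed = config$seed,
    out_dir = if (identical(config$store, "disk")) {
      if (is.null(out_dir)) abort("store = 'disk' needs an `out_dir`")
      file.path(out_dir, "screen")
    } else NULL)
  timings["generate"] <- lap(t0)

  t0 <- tic()
  intensity <- quantify_screen(screen, n_bins = config$n_bins)
  timings["quantify"] <- lap(t0)

  t0 <- tic()
  features <- build_feature_matrix(
    intensity, collapse = config$collapse,
    baseline_floor = config$baseline_floor,
    expected_lines = design$lines$line_id)
  feats_lda <- if (config$log2) log2_features(features) else features
  timings["features"] <- lap(t0)

  t0 <- tic()
  line_dendro <- hierarchical_cluster(features, "lines",
                                      metric = config$cluster_metric,
                                      linkage = config$cluster_linkage,
                                      log2 = config$log2)
  probe_dendro <- hierarchical_cluster(features, "probes",
                                       metric = config$cluster_metric,
                                       linkage = config$cluster_linkage,
                                       log2 = config$log2)
  purity <- origin_purity(line_dendro, k = config$purity_k)
  timings["cluster"] <- lap(t0)

  t0 <- tic()
  n <- nrow(feats_lda); g <- dplyr::n_distinct(feats_lda$origin)
  max_feat <- min(config$max_features, n - g - 1)
  stepwise <- forward_stepwise_select(feats_lda,
                                      alpha_enter = config$alpha_enter,
                                      alpha_remove = config$alpha_remove,
                                      max_features = max_feat)
  if (length(stepwise$selected) == 0) {
    abort("discriminant stage: stepwise selection retained no features")
  }
  lda_fit <- fit_lda(feats_lda, features = stepwise$selected,
                     priors = config$priors, ridge = config$ridge)
  jack <- jackknife_classification(feats_lda, features = stepwise$selected,
                                   priors = config$priors,
                                   ridge = config$ridge)
  scores <- score_plot(lda_fit, feats_lda)
  family_comparison <- subset_comparison(feats_lda,
                                         alpha_enter = config$alpha_enter,
                                         alpha_remove = config$alpha_remove,
                                         max_features = max_feat,
                                         priors = config$priors,
                                         ridge = config$ridge)
  timings["discriminate"] <- lap(t0)

  report <- structure(
    list(intensity = intensity, features = features,
         line_dendro = line_dendro, probe_dendro = probe_dendro,
         purity = purity, stepwise = stepwise, model = lda_fit,
         jackknife = jack, scores = scores,
         family_comparison = family_comparison,
         informative = informative,
         ground_truth = screen$ground_truth,
         design = design, effect_model = model,
         meta = list(seed = config$seed, config = unclass(config),
                     config_hash = rlang::hash(unclass(config)),
                     n_records = nrow(screen$manifest),
                     n_flagged = sum(intensity$flag != "ok"),
                     dropped_features = attr(features, "dropped_features"),
                     timings = timings,
                     package_version =
                       as.character(utils::packageVersion("phenoscreen")))),
    class = "screen_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat(sprintf("  %s condition records, %d flagged\n",
              format(x$meta$n_records, big.mark = ","), x$meta$n_flagged))
  cat(sprintf("  %d lines x %d features (%d dropped)\n",
              nrow(x$features), length(feature_columns(x$features)),
              length(x$meta$dropped_features)))
  cat(sprintf("  origin purity at k = %d: %.3f\n",
              x$purity$k, x$purity$purity))
  cat(sprintf("  stepwise selected %d features; jackknifed %.1f%% correct\n",
              length(x$stepwise$selected), x$jackknife$overall_correct))
  cat("  family comparison:\n")
  fc <- x$family_comparison
  for (i in seq_len(nrow(fc))) {
    cat(sprintf("    %-9s %2d/%3d selected, %5.1f%% correct\n",
                fc$pool[i], fc$n_selected[i], fc$pool_size[i],
                fc$pct_correct[i]))
  }
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' Persists every table as CSV, the dendrograms as Newick, the model as
#' JSON (per-class score-function coefficient vectors and constants), the
#' score plot and confusion matrix as PNG, and the effective
#' configuration as YAML, under `dir`.
#'
#' @param report A `screen_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$intensity, file.path(dir, "intensity_table.csv"))
  write_feature_matrix(report$features,
                       file.path(dir, "feature_matrix.csv"),
                       file.path(dir, "line_origins.csv"))
  readr::write_csv(leaf_orders(report$line_dendro, report$probe_dendro),
                   file.path(dir, "leaf_orders.csv"))
  if (requireNamespace("ape", quietly = TRUE)) {
    write_newick(report$line_dendro, file.path(dir, "lines.nwk"))
    write_newick(report$probe_dendro, file.path(dir, "probes.nwk"))
  }
  readr::write_csv(tidy(report$stepwise),
                   file.path(dir, "stepwise_trace.csv"))
  model_json <- list(
    classes = report$model$classes,
    features = report$model$features,
    coefficients = setNames(
      lapply(seq_along(report$model$classes),
             function(k) unname(report$model$coef[, k])),
      report$model$classes),
    constants = as.list(report$model$const),
    priors = as.list(report$model$priors))
  jsonlite::write_json(model_json, file.path(dir, "lda_model.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(tidy(report$jackknife),
                   file.path(dir, "classification_matrix.csv"))
  readr::write_csv(as_tibble(report$scores),
                   file.path(dir, "score_plot.csv"))
  readr::write_csv(dplyr::select(report$family_comparison, -"selected"),
                   file.path(dir, "family_comparison.csv"))
  yaml::write_yaml(report$meta$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(report$meta[c("seed", "config_hash", "n_records",
                                     "n_flagged", "package_version")],
                       file.path(dir, "run_meta.json"), auto_unbox = TRUE)
  try({
    ggplot2::ggsave(file.path(dir, "score_plot.png"),
                    autoplot(report$scores), width = 6, height = 5,
                    dpi = 150)
    ggplot2::ggsave(file.path(dir, "classification_matrix.png"),
                    autoplot(report$jackknife), width = 6, height = 5,
                    dpi = 150)
    ggplot2::ggsave(
      file.path(dir, "profile_heatmap.png"),
      plot_profile_heatmap(report$features, report$line_dendro,
                           report$probe_dendro),
      width = 8, height = 6, dpi = 150)
  }, silent = TRUE)
  invisible(dir)
}

#' Read / write a screen configuration as YAML
#'
#' @param path File path.
#' @param config A `screen_config`.
#' @return `read_screen_config()` returns a `screen_config`;
#'   `write_screen_config()` returns `path` invisibly.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  do.call(screen_config, raw)
}

#' @rdname read_screen_config
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
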