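#' Kinetic fold change
#'
#' Fold = (foreground intensity at the endpoint, 48 h) / (foreground
#' intensity at baseline, 1 h). The ratio of two measurements of the same
#' well cancels any plate-constant multiplicative batch factor, which is
#' what makes it the batch-robust phenotype for screens acquired over long
#' periods. Baselines below `baseline_floor` give unstable ratios and are
#' an error; [build_feature_matrix()] maps that error to a flagged record.
#'
#' @param intensity_baseline,intensity_endpoint Non-negative intensities
#'   (vectorized).
#' @param baseline_floor Smallest admissible baseline intensity.
#' @return `intensity_endpoint / intensity_baseline`.
#' @export
#' @examples
#' fold_change(50, 250)  # 5
fold_change <- function(intensity_baseline, intensity_endpoint,
                        baseline_floor = 1) {
  if (any(intensity_baseline < 0, na.rm = TRUE) ||
      any(intensity_endpoint < 0, na.rm = TRUE)) {
    abort("intensities must be >= 0")
  }
  if (any(intensity_baseline < baseline_floor, na.rm = TRUE)) {
    abort("baseline below floor")
  }
  intensity_endpoint / intensity_baseline
}

#' Build the line x feature fold-change matrix
#'
#' Turns a per-condition intensity table into the kinetic feature matrix:
#' one row per cell line, one column per retained feature. Under the
#' default `"per_condition"` policy every (probe, concentration, channel)
#' is its own feature; `"brightest"` keeps, per probe, only the highest
#' concentration and the channel with the larger mean baseline intensity
#' across lines (the single-trace view used in per-probe figures).
#' Features with any flagged, missing or below-floor line are dropped and
#' reported, so the retained matrix has no missing values.
#'
#' @param intensity Intensity table from [quantify_screen()] or
#'   [simulate_intensity_table()].
#' @param collapse `"per_condition"` or `"brightest"`.
#' @param baseline_floor Passed to [fold_change()].
#' @param baseline_h,endpoint_h Time points defining the fold.
#' @param expected_lines Optional character vector of line ids that must
#'   all appear in the intensity table; a line absent entirely is an
#'   error (a flagged line only drops the affected features).
#' @return A tibble with columns `line_id`, `origin` and one numeric
#'   column per feature, plus attributes `feature_info` (tibble mapping
#'   feature to probe, family, concentration, channel) and
#'   `dropped_features`.
#' @export
build_feature_matrix <- function(intensity,
                                 collapse = c("per_condition", "brightest"),
                                 baseline_floor = 1,
                                 baseline_h = 1, endpoint_h = 48,
                                 expected_lines = NULL) {
  collapse <- match.arg(collapse)
  intensity <- as_tibble(intensity)
  need <- c("probe_id", "line_id", "concentration_nM", "channel", "time_h",
            "mean_fg", "flag")
  if (!all(need %in% names(intensity))) {
    abort(paste("intensity table lacks columns:",
                paste(setdiff(need, names(intensity)), collapse = ", ")))
  }
  if (!"origin" %in% names(intensity)) intensity$origin <- NA_character_
  if (!"family" %in% names(intensity)) intensity$family <- NA_character_
  lines <- dplyr::distinct(intensity, .data$line_id, .data$origin)
  if (nrow(lines) < 1) abort("no lines in intensity table")
  if (anyDuplicated(lines$line_id) > 0) {
    abort("a line maps to more than one origin")
  }
  if (!is.null(expected_lines) &&
      !all(expected_lines %in% lines$line_id)) {
    abort(paste("line(s) missing from the intensity table entirely:",
                paste(setdiff(expected_lines, lines$line_id),
                      collapse = ", ")))
  }

  wide <- intensity |>
    dplyr::filter(.data$time_h %in% c(baseline_h, endpoint_h)) |>
    dplyr::mutate(when = ifelse(.data$time_h == baseline_h,
                                "baseline", "endpoint")) |>
    dplyr::select("probe_id", family = "family", "line_id",
                  "concentration_nM", "channel", "when", "mean_fg",
                  "flag") |>
    tidyr::pivot_wider(names_from = "when",
                       values_from = c("mean_fg", "flag"))
  if (!all(c("mean_fg_baseline", "mean_fg_endpoint") %in% names(wide))) {
    abort("intensity table must contain both baseline and endpoint records")
  }
  wide <- wide |>
    dplyr::mutate(
      bad = .data$flag_baseline %in% c("missing", "degenerate") |
        .data$flag_endpoint %in% c("missing", "degenerate") |
        is.na(.data$mean_fg_baseline) | is.na(.data$mean_fg_endpoint) |
        .data$mean_fg_baseline < baseline_floor,
      fold = ifelse(.data$bad, NA_real_,
                    .data$mean_fg_endpoint / .data$mean_fg_baseline))

  if (collapse == "brightest") {
    top_conc <- max(wide$concentration_nM)
    pick <- wide |>
      dplyr::filter(.data$concentration_nM == top_conc) |>
      dplyr::group_by(.data$probe_id, .data$channel) |>
      dplyr::summarise(bright = mean(.data$mean_fg_baseline, na.rm = TRUE),
                       .groups = "drop_last") |>
      dplyr::slice_max(.data$bright, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("probe_id", "channel")
    wide <- wide |>
      dplyr::filter(.data$concentration_nM == top_conc) |>
      dplyr::inner_join(pick, by = c("probe_id", "channel"))
    wide$feature <- wide$probe_id
  } else {
    one_cell <- dplyr::n_distinct(wide$concentration_nM) == 1 &&
      dplyr::n_distinct(wide$channel) == 1
    wide$feature <- if (one_cell) wide$probe_id else {
      sprintf("%s_%gnM_%s", wide$probe_id, wide$concentration_nM,
              wide$channel)
    }
  }

  n_lines <- nrow(lines)
  status <- wide |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n_ok = sum(!.data$bad),
                     n = dplyr::n(), .groups = "drop")
  complete <- status$feature[status$n_ok == n_lines & status$n == n_lines]
  dropped <- setdiff(status$feature, complete)
  if (length(dropped) > 0) {
    inform(sprintf(
      "build_feature_matrix: dropping %d feature(s) with flagged or incomplete lines: %s",
      length(dropped),
      paste(utils::head(dropped, 5), collapse = ", ")))
  }
  if (length(complete) == 0) abort("no complete features retained")

  info <- wide |>
    dplyr::filter(.data$feature %in% complete) |>
    dplyr::distinct(.data$feature, .data$probe_id, .data$family,
                    .data$concentration_nM, .data$channel)
  out <- wide |>
    dplyr::filter(.data$feature %in% complete) |>
    dplyr::select("line_id", "feature", "fold") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "fold") |>
    dplyr::left_join(lines, by = "line_id") |>
    dplyr::relocate("line_id", "origin")
  attr(out, "feature_info") <- info
  attr(out, "dropped_features") <- dropped
  attr(out, "collapse_policy") <- collapse
  out
}

#' Read and write feature matrices as CSV
#'
#' The matrix travels as one CSV of lines x features with a sidecar CSV
#' of origin labels (`line_id`, `origin`); reading joins the two back
#' into the tibble layout [build_feature_matrix()] produces. Feature
#' metadata attributes are not round-tripped.
#'
#' @param data A feature matrix tibble.
#' @param path CSV path for the matrix; the sidecar defaults to
#'   `<path-sans-ext>_origins.csv`.
#' @param origins_path Path of the origin-label sidecar CSV.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the feature matrix tibble.
#' @export
write_feature_matrix <- function(data, path,
                                 origins_path = sub("\\.csv$",
                                                    "_origins.csv", path)) {
  assert_feature_table(data)
  readr::write_csv(dplyr::select(data, -"origin"), path)
  readr::write_csv(dplyr::select(data, "line_id", "origin"), origins_path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path,
                                origins_path = sub("\\.csv$",
                                                   "_origins.csv", path)) {
  mat <- readr::read_csv(path, show_col_types = FALSE)
  origins <- readr::read_csv(origins_path, show_col_types = FALSE)
  if (!all(c("line_id", "origin") %in% names(origins))) {
    abort("origin sidecar needs `line_id` and `origin` columns")
  }
  out <- dplyr::inner_join(mat, origins, by = "line_id") |>
    dplyr::relocate("line_id", "origin")
  if (nrow(out) != nrow(mat)) {
    abort("origin sidecar does not cover every line in the matrix")
  }
  assert_feature_table(out)
  out
}

#' Per-line selectivity index of a feature
#'
#' For a response vector across lines, each line's index is its value
#' divided by the mean value of all other lines. A probe that turns on in
#' a single line stands out with an index equal to its fold advantage —
#' the canonical published example being a 5.64 index of one rosamine
#' probe in the KM12 colon line.
#'
#' @param x Positive numeric vector (one value per line).
#' @return Numeric vector of indices, same length and names as `x`.
#' @export
#' @examples
#' selectivity_index(c(KM12 = 5.64, rep(1, 59)))[1]
selectivity_index <- function(x) {
  if (length(x) < 2) abort("need >= 2 lines")
  if (any(!is.finite(x)) || any(x <= 0)) abort("values must be positive")
  n <- length(x)
  x / ((sum(x) - x) / (n - 1))
}

#' Selectivity indices for every feature of a feature matrix
#'
#' @param data A feature matrix from [build_feature_matrix()].
#' @return A tibble `(feature, line_id, origin, fold, selectivity)` in
#'   long form.
#' @export
probe_selectivity <- function(data) {
  assert_feature_table(data)
  feats <- feature_columns(data)
  purrr::map_dfr(feats, function(f) {
    tibble(feature = f, line_id = data$line_id, origin = data$origin,
           fold = data[[f]], selectivity = selectivity_index(data[[f]]))
  })
}
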