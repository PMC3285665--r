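#' Define the generative effect model for a synthetic screen
#'
#' The generator draws, for every condition record, a foreground mean
#' intensity from a hierarchical multiplicative model:
#' \deqn{I(t) = B_{pl} \cdot f_{pl}(t) \cdot b \cdot e}
#' where \eqn{B_{pl}} is a per-(probe, line) lognormal baseline (the 1 h
#' intensity), \eqn{f_{pl}(t)} is the turn-on fold at time \eqn{t}
#' (geometric interpolation from 1 at baseline to the full fold at the
#' endpoint), \eqn{b} a per-(plate, replicate) lognormal batch factor, and
#' \eqn{e} a per-(condition, time, replicate) lognormal noise term.
#' The full fold for (probe, line) is the product of the probe-series x
#' origin turn-on effect and any line-specific effect; 1 everywhere by
#' default.
#'
#' @param baseline_log_mean,baseline_log_sd Mean and sd of the log 1 h
#'   foreground intensity across (probe, line) pairs.
#' @param turnon_effects Data frame `(series, origin, fold)`: multiplicative
#'   endpoint fold for probes of a series in lines of an origin.
#' @param line_effects Data frame `(probe_id, line_id, fold)`:
#'   line-specific multiplicative endpoint folds.
#' @param noise_cv Coefficient of variation of the condition-level
#'   multiplicative noise (per probe, line, concentration, channel,
#'   replicate and time; shared by sites of the same well).
#' @param batch_sd Lognormal sigma of the per-(plate, replicate) batch
#'   factor. 0 disables batch effects.
#' @param batch_aligned If `TRUE` (default) one batch factor applies to all
#'   time points of a well, so kinetic fold changes cancel it; if `FALSE`
#'   batch factors are drawn independently per time point, which breaks
#'   that cancellation (for robustness testing).
#' @param pixel_noise_cv Coefficient of variation of per-pixel lognormal
#'   noise around the foreground mean.
#' @param background_mean,background_cv Background level (counts) and its
#'   per-pixel lognormal noise.
#' @param area_fraction Fraction of the image covered by cell blobs.
#' @return An `effect_model` object.
#' @export
effect_model <- function(baseline_log_mean = log(800),
                         baseline_log_sd = 0.3,
                         turnon_effects = NULL,
                         line_effects = NULL,
                         noise_cv = 0.2,
                         batch_sd = 0.3,
                         batch_aligned = TRUE,
                         pixel_noise_cv = 0.3,
                         background_mean = 60,
                         background_cv = 0.25,
                         area_fraction = 0.7) {
  empty_turnon <- tibble(series = character(), origin = character(),
                         fold = numeric())
  empty_line <- tibble(probe_id = character(), line_id = character(),
                       fold = numeric())
  turnon_effects <- as_tibble(turnon_effects %||% empty_turnon)
  line_effects <- as_tibble(line_effects %||% empty_line)
  stopifnot(all(c("series", "origin", "fold") %in% names(turnon_effects)),
            all(c("probe_id", "line_id", "fold") %in% names(line_effects)))
  if (any(turnon_effects$fold <= 0) || any(line_effects$fold <= 0)) {
    abort("multiplicative effects must be > 0")
  }
  if (noise_cv < 0 || batch_sd < 0 || pixel_noise_cv < 0 || background_cv < 0) {
    abort("noise scales must be >= 0")
  }
  if (area_fraction <= 0 || area_fraction >= 1) {
    abort("`area_fraction` must be in (0, 1)")
  }
  structure(
    list(baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         turnon_effects = turnon_effects,
         line_effects = line_effects,
         noise_cv = noise_cv,
         batch_sd = batch_sd,
         batch_aligned = isTRUE(batch_aligned),
         pixel_noise_cv = pixel_noise_cv,
         background_mean = background_mean,
         background_cv = background_cv,
         area_fraction = area_fraction),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model>\n")
  cat(sprintf("  baseline ~ lognormal(meanlog %.2f, sdlog %.2f)\n",
              x$baseline_log_mean, x$baseline_log_sd))
  cat(sprintf("  %d turn-on effects, %d line-specific effects\n",
              nrow(x$turnon_effects), nrow(x$line_effects)))
  cat(sprintf(
    "  noise CV %.2f, batch sigma %.2f (%s), pixel CV %.2f\n",
    x$noise_cv, x$batch_sd,
    if (x$batch_aligned) "aligned across time" else "independent per time",
    x$pixel_noise_cv))
  invisible(x)
}

#' Expected endpoint fold changes under an effect model
#'
#' The ground-truth expected fold for every design cell: the product of the
#' probe-series x origin turn-on effect and the line-specific effect
#' (default 1 for both). Effects do not depend on concentration or channel,
#' but one row is emitted per (probe, line, concentration, channel) design
#' cell so the table matches the measured feature layout.
#'
#' @param design A `screen_design`.
#' @param model An `effect_model`.
#' @return A tibble `(probe_id, family, line_id, origin, concentration_nM,
#'   channel, expected_fold)`.
#' @export
expected_fold_table <- function(design, model) {
  stopifnot(inherits(design, "screen_design"), inherits(model, "effect_model"))
  cells <- tidyr::expand_grid(
    probe_id = design$probes$probe_id,
    line_id = design$lines$line_id,
    concentration_nM = design$concentrations_nM,
    channel = design$channels
  )
  pr <- design$probes[match(cells$probe_id, design$probes$probe_id), ]
  cells$family <- pr$family
  cells$series <- pr$series
  cells$origin <- design$lines$origin[match(cells$line_id,
                                            design$lines$line_id)]
  cells <- cells |>
    dplyr::left_join(
      dplyr::rename(model$turnon_effects, turnon = "fold"),
      by = c("series", "origin")) |>
    dplyr::left_join(
      dplyr::rename(model$line_effects, line_fold = "fold"),
      by = c("probe_id", "line_id")) |>
    dplyr::mutate(
      expected_fold = dplyr::coalesce(.data$turnon, 1) *
        dplyr::coalesce(.data$line_fold, 1))
  dplyr::select(cells, "probe_id", "family", "line_id", "origin",
                "concentration_nM", "channel", "expected_fold")
}

#' Ground truth tables for a synthetic screen
#'
#' @inheritParams expected_fold_table
#' @param informative_log2_min Smallest |log2 expected fold| that counts a
#'   probe as informative for an origin.
#' @return A list with `fold_table` (see [expected_fold_table()]),
#'   `line_origins` and `informative_probes` (`probe_id`, `origin`, the
#'   origins a probe responds to).
#' @export
ground_truth <- function(design, model, informative_log2_min = 0.5) {
  ft <- expected_fold_table(design, model)
  info <- ft |>
    dplyr::group_by(.data$probe_id, .data$origin) |>
    dplyr::summarise(
      max_abs_log2 = max(abs(log2(.data$expected_fold))), .groups = "drop") |>
    dplyr::filter(.data$max_abs_log2 >= informative_log2_min) |>
    dplyr::select("probe_id", "origin")
  list(fold_table = ft,
       line_origins = design$lines,
       informative_probes = info)
}

# geometric interpolation of the turn-on fold between baseline and endpoint
fold_at_time <- function(fold, time_h, baseline_h, endpoint_h) {
  if (endpoint_h == baseline_h) return(rep(1, length(fold)))
  frac <- (time_h - baseline_h) / (endpoint_h - baseline_h)
  fold^pmax(0, pmin(1, frac))
}

#' Reference demonstration screen: design and effect model
#'
#' A desk-scale analog of the published screen used throughout the package
#' examples and validation suite: 100 probes (50 BD + 50 RS) against the
#' real NCI-60 panel (9 origins, prostate class of size 2), 500 nM, one
#' channel, 2 sites, time points 1 h and 48 h, 2 replicates, 128 x 128
#' 16-bit images. 30 probes (15 per family) are informative: each targets
#' one origin with an endpoint fold drawn uniformly in [2, 4] and carries
#' its own lognormal off-target fold signature (sdlog 0.3) across the
#' remaining origins — probes respond to multiple origins with distinct
#' patterns rather than acting as single-line switches.
#' BD informative probes cover origins 1-6 and RS probes origins 4-9, so
#' the two families carry complementary signal and only their combination
#' covers all nine origins. Noise: condition CV 0.20, batch sigma 0.30
#' (aligned across time), pixel CV 0.30.
#'
#' @param n_probes Total probe count (split evenly between BD and RS).
#' @param n_informative Number of informative probes (split evenly).
#' @param seed Seed for drawing the effect folds.
#' @param time_points_h Imaging times; the default omits an unused
#'   intermediate time point to keep rendered screens small.
#' @param noise_cv,batch_sd,batch_aligned Passed to [effect_model()].
#' @return A list with elements `design` (a `screen_design`) and `model`
#'   (an `effect_model`).
#' @export
#' @examples
#' demo <- demo_screen(seed = 1)
#' design_size(demo$design)
demo_screen <- function(n_probes = 100, n_informative = 30, seed = 20120223,
                        time_points_h = c(1, 48),
                        noise_cv = 0.2, batch_sd = 0.3,
                        batch_aligned = TRUE) {
  stopifnot(n_probes %% 2 == 0, n_informative %% 2 == 0,
            n_informative <= n_probes)
  half <- n_probes / 2
  probes <- probe_library(n_bd = half, n_rs = half)
  lines <- nci60_lines()
  design <- screen_design(
    probes, lines,
    concentrations_nM = 500, channels = "TRITC", sites = 2L,
    time_points_h = time_points_h, replicates = 2L,
    image_shape = c(128L, 128L), bit_depth = 16L
  )
  origins <- unique(lines$origin)  # 9, in panel order
  k <- n_informative / 2
  informative <- c(probes$probe_id[seq_len(k)],
                   probes$probe_id[half + seq_len(k)])
  # complementary coverage: BD -> origins 1..6, RS -> origins 4..9
  targets <- c(origins[1:6][(seq_len(k) - 1L) %% 6L + 1L],
               origins[4:9][(seq_len(k) - 1L) %% 6L + 1L])
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  turnon <- purrr::map2_dfr(informative, targets, function(p, tgt) {
    fold <- stats::runif(1, 2, 4)
    off <- stats::rlnorm(length(origins) - 1, 0, 0.3)
    tibble(series = p, origin = c(tgt, setdiff(origins, tgt)),
           fold = c(fold, off))
  })
  model <- effect_model(
    turnon_effects = turnon,
    noise_cv = noise_cv, batch_sd = batch_sd, batch_aligned = batch_aligned
  )
  list(design = design, model = model,
       informative = tibble(probe_id = informative, target_origin = targets))
}

# save/restore .Random.seed without assuming it exists
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", value, envir = globalenv())
  }
}

#' Single-line spike-in effect model
#'
#' A neutral effect model except that one probe turns on in one line with
#' the given fold: the canonical validation case is a 5.64-fold effect of
#' probe RS-C3 in the colon line KM12, the most line-selective signature
#' reported for the original screen. Condition-level noise is off so the
#' recovered selectivity isolates the rendering-and-quantification error.
#'
#' @param probe_id,line_id The spiked (probe, line) cell.
#' @param fold The spiked endpoint fold.
#' @param ... Passed to [effect_model()].
#' @return An `effect_model`.
#' @export
spike_in_model <- function(probe_id, line_id, fold = 5.64, ...) {
  args <- list(...)
  if (is.null(args$noise_cv)) args$noise_cv <- 0
  args$line_effects <- tibble(probe_id = probe_id, line_id = line_id,
                              fold = fold)
  do.call(effect_model, args)
}
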