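#' Render one synthetic fluorescence image
#'
#' Draws cell "blobs" as random ellipses until a target area fraction is
#' covered, fills them with lognormal pixel noise around the requested
#' foreground mean, and puts them over a low constant-plus-noise
#' background. Morphological realism is not a goal: downstream analysis
#' uses intensity statistics only. Deterministic given `seed`.
#'
#' @param fg_mean Target mean foreground intensity (counts).
#' @param shape Integer pair: image rows, columns.
#' @param bit_depth Camera bit depth; pixels are rounded and clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param area_fraction Fraction of pixels covered by cells, in (0, 1).
#' @param pixel_noise_cv Coefficient of variation of per-pixel lognormal
#'   noise around `fg_mean` (0 gives a flat foreground).
#' @param background_mean,background_cv Background level and noise.
#' @return An integer matrix with attribute `bit_depth`.
#' @export
#' @examples
#' img <- render_image(800, shape = c(64, 64), seed = 1)
#' mean(img[img > 200])
render_image <- function(fg_mean, shape = c(128L, 128L), bit_depth = 16L,
                         seed = NULL, area_fraction = 0.7,
                         pixel_noise_cv = 0, background_mean = 60,
                         background_cv = 0) {
  if (area_fraction <= 0 || area_fraction >= 1) {
    abort("`area_fraction` must be in (0, 1)")
  }
  stopifnot(fg_mean >= 0, length(shape) == 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- .render_image_cpp(fg_mean, as.integer(shape[1]),
                           as.integer(shape[2]), area_fraction,
                           cv_to_sdlog(pixel_noise_cv), background_mean,
                           cv_to_sdlog(background_cv), 2^bit_depth - 1)
  attr(out, "bit_depth") <- as.integer(bit_depth)
  out
}

# Draw the per-record expected foreground mean for every condition record:
# baseline x fold(t) x batch x condition noise. Separate deterministic seed
# streams per component, so e.g. toggling the batch scale leaves every other
# draw untouched.
compute_target_means <- function(design, model, seed) {
  rec <- enumerate_design(design)

  # per-(probe, line) lognormal baseline (the 1 h intensity)
  pl <- tidyr::expand_grid(probe_id = design$probes$probe_id,
                           line_id = design$lines$line_id)
  set.seed(derive_seed(seed, "baseline"))
  pl$baseline <- exp(stats::rnorm(nrow(pl), model$baseline_log_mean,
                                  model$baseline_log_sd))

  # expected endpoint fold per (probe, line)
  folds <- expected_fold_table(design, model) |>
    dplyr::distinct(.data$probe_id, .data$line_id, .data$expected_fold)
  pl <- dplyr::left_join(pl, folds, by = c("probe_id", "line_id"))

  # condition-level noise, shared by the sites of a well
  cond <- dplyr::distinct(rec, .data$probe_id, .data$line_id,
                          .data$concentration_nM, .data$channel,
                          .data$time_h, .data$replicate)
  set.seed(derive_seed(seed, "condition"))
  cond$cond_noise <- rlnorm1(nrow(cond), model$noise_cv)

  # one batch factor per plate (aligned) or per (plate, time point);
  # all images pooled into one condition share a plate, so an aligned
  # factor cancels exactly in the kinetic fold change
  batch_key <- if (model$batch_aligned) {
    dplyr::distinct(rec, .data$plate)
  } else {
    dplyr::distinct(rec, .data$plate, .data$time_h)
  }
  set.seed(derive_seed(seed, "batch"))
  batch_key$batch <- if (model$batch_sd > 0) {
    stats::rlnorm(nrow(batch_key), 0, model$batch_sd)
  } else rep(1, nrow(batch_key))

  rec <- rec |>
    dplyr::left_join(pl, by = c("probe_id", "line_id")) |>
    dplyr::left_join(cond, by = c("probe_id", "line_id", "concentration_nM",
                                  "channel", "time_h", "replicate")) |>
    dplyr::left_join(batch_key,
                     by = intersect(names(batch_key), names(rec)))
  rec$.target_mean <- rec$baseline *
    fold_at_time(rec$expected_fold, rec$time_h,
                 design$baseline_h, design$endpoint_h) *
    rec$batch * rec$cond_noise
  # batch emulates acquisition gain, so it scales the background too
  rec$.bg_mean <- model$background_mean * rec$batch
  rec$.pixel_seed <- derive_seed(seed, "pixel", rec$record)
  dplyr::select(rec, -"baseline", -"expected_fold", -"cond_noise", -"batch")
}

#' Generate a synthetic plate screen
#'
#' Enumerates the design, draws per-record expected foreground intensities
#' from the effect model, and (optionally) renders and writes one 16-bit
#' grayscale TIFF per condition record, named
#' `{probe}_{line}_{conc}_{channel}_{site}_{time}_{rep}.tif`, together
#' with a manifest CSV and ground-truth tables. Re-running with the same
#' seed reproduces identical files. With `out_dir = NULL` no pixels are
#' written: the returned manifest carries the per-record generative state
#' and [screen_reader()] renders images lazily, which keeps large screens
#' inside desk-scale memory.
#'
#' @param design A `screen_design`.
#' @param model An `effect_model`.
#' @param seed Integer master seed.
#' @param out_dir Output directory, or `NULL` for a virtual (lazy) screen.
#' @return A `synthetic_screen`: list with `manifest`, `ground_truth`
#'   (see [ground_truth()]), `design`, `model`, `seed`, `image_dir`.
#' @export
generate_screen <- function(design, model, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(design, "screen_design"), inherits(model, "effect_model"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  manifest <- compute_target_means(design, model, seed)
  manifest$path <- sprintf("%s_%s_%g_%s_%d_%g_%d.tif",
                           manifest$probe_id, manifest$line_id,
                           manifest$concentration_nM, manifest$channel,
                           manifest$site, manifest$time_h,
                           manifest$replicate)
  gt <- ground_truth(design, model)
  image_dir <- NULL
  if (!is.null(out_dir)) {
    if (design$bit_depth != 16L) {
      abort("disk output supports 16-bit designs only")
    }
    image_dir <- file.path(out_dir, "images")
    dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
    scale <- 2^design$bit_depth - 1
    for (i in seq_len(nrow(manifest))) {
      img <- render_image(
        manifest$.target_mean[i], shape = design$image_shape,
        bit_depth = design$bit_depth, seed = manifest$.pixel_seed[i],
        area_fraction = model$area_fraction,
        pixel_noise_cv = model$pixel_noise_cv,
        background_mean = manifest$.bg_mean[i],
        background_cv = model$background_cv)
      ok <- try(tiff::writeTIFF(img / scale,
                                file.path(image_dir, manifest$path[i]),
                                bits.per.sample = 16L), silent = TRUE)
      if (inherits(ok, "try-error")) {
        abort(sprintf("failed writing image for record %d (%s)",
                      manifest$record[i], manifest$path[i]))
      }
    }
    readr::write_csv(
      dplyr::select(manifest, "probe_id", "family", "line_id", "origin",
                    "concentration_nM", "channel", "site", "time_h",
                    "replicate", "plate", "well", "path"),
      file.path(out_dir, "manifest.csv"))
    readr::write_csv(gt$fold_table, file.path(out_dir, "ground_truth_fold.csv"))
    readr::write_csv(gt$line_origins, file.path(out_dir, "line_origins.csv"))
    readr::write_csv(gt$informative_probes,
                     file.path(out_dir, "informative_probes.csv"))
  }
  structure(
    list(manifest = manifest, ground_truth = gt, design = design,
         model = model, seed = seed, image_dir = image_dir),
    class = "synthetic_screen"
  )
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("<synthetic_screen>\n")
  cat(sprintf("  %s condition records (%s)\n",
              format(nrow(x$manifest), big.mark = ","),
              if (is.null(x$image_dir)) "virtual, rendered on demand"
              else paste("images in", x$image_dir)))
  cat(sprintf("  seed %s\n", format(x$seed)))
  invisible(x)
}

#' Image readers for screen manifests
#'
#' A reader maps one manifest row to an integer pixel matrix (or `NULL`
#' for a missing image). [tiff_reader()] reads 16-bit grayscale TIFFs from
#' the manifest `path` column resolved against `dir`; [screen_reader()]
#' returns the right reader for a [generate_screen()] result, re-rendering
#' virtual screens deterministically from the stored per-record state.
#' Quantification accepts any reader, so real and synthetic screens follow
#' the same code path.
#'
#' @param dir Directory against which manifest paths are resolved.
#' @param bit_depth Bit depth of the stored images.
#' @return A function `(row) -> matrix or NULL`.
#' @export
tiff_reader <- function(dir = ".", bit_depth = 16L) {
  force(dir); force(bit_depth)
  function(row) {
    f <- file.path(dir, row$path)
    if (!file.exists(f)) return(NULL)
    px <- tiff::readTIFF(f)
    out <- matrix(as.integer(round(px * (2^bit_depth - 1))),
                  nrow = nrow(px), ncol = ncol(px))
    attr(out, "bit_depth") <- as.integer(bit_depth)
    out
  }
}

#' @rdname tiff_reader
#' @param screen A `synthetic_screen`.
#' @export
screen_reader <- function(screen) {
  stopifnot(inherits(screen, "synthetic_screen"))
  if (!is.null(screen$image_dir)) {
    return(tiff_reader(screen$image_dir, screen$design$bit_depth))
  }
  design <- screen$design; model <- screen$model
  function(row) {
    render_image(row$.target_mean, shape = design$image_shape,
                 bit_depth = design$bit_depth, seed = row$.pixel_seed,
                 area_fraction = model$area_fraction,
                 pixel_noise_cv = model$pixel_noise_cv,
                 background_mean = row$.bg_mean %||% model$background_mean,
                 background_cv = model$background_cv)
  }
}

#' Simulate an intensity table without rendering pixels
#'
#' Samples the same hierarchical intensity model as [generate_screen()]
#' (identical seed streams, so a rendered screen with the same seed agrees
#' up to pixel-sampling error) and aggregates the per-record expected
#' foreground means directly into a per-condition intensity table. Useful
#' for statistical property checks at many replicates, where rendering
#' every image would only add the sampling error of a mean over ~10^4
#' foreground pixels.
#'
#' @inheritParams generate_screen
#' @return An intensity table as from [quantify_screen()] with
#'   `flag = "simulated"` and `NA` threshold/pixel-count columns.
#' @export
simulate_intensity_table <- function(design, model, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  rec <- compute_target_means(design, model, seed)
  rec |>
    dplyr::group_by(.data$probe_id, .data$family, .data$line_id,
                    .data$origin, .data$concentration_nM, .data$channel,
                    .data$time_h) |>
    dplyr::summarise(mean_fg = mean(.data$.target_mean), .groups = "drop") |>
    dplyr::mutate(n_fg_pixels = NA_integer_, threshold = NA_real_,
                  flag = "simulated")
}
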