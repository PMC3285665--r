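#' Construct an image record
#'
#' One grayscale image plus its condition metadata. Pixel values must be
#' non-negative and fit the stated bit depth.
#'
#' @param pixels Non-negative integer matrix.
#' @param bit_depth Integer bit depth.
#' @param condition Named list (or one-row data frame) of condition
#'   metadata; the keys `probe_id`, `line_id`, `concentration_nM`,
#'   `channel`, `time_h` identify the condition, `site` and `replicate`
#'   distinguish the images pooled within it.
#' @return An `image_record`.
#' @export
image_record <- function(pixels, bit_depth = attr(pixels, "bit_depth") %||% 16L,
                         condition = list()) {
  if (!is.matrix(pixels) || length(pixels) == 0) {
    abort("`pixels` must be a non-empty matrix")
  }
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1)) {
    abort(sprintf("pixel values must lie in [0, 2^%d - 1]", bit_depth))
  }
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 condition = as.list(condition)),
            class = "image_record")
}

#' Pool the images of one experimental condition
#'
#' Concatenates the pixels of all images belonging to one condition
#' (typically 2 sites x 2 replicates = 4 images per well condition) into a
#' single pixel pool; all downstream statistics of the pool are invariant
#' to image order. Images must share the condition key (everything except
#' site and replicate) and bit depth.
#'
#' @param images List of [image_record()]s (bare matrices are accepted and
#'   treated as metadata-free records).
#' @return Numeric vector of pooled pixel values with attribute
#'   `bit_depth`.
#' @export
pool_condition_images <- function(images) {
  if (length(images) < 1) abort("need at least one image to pool")
  images <- lapply(images, function(im) {
    if (is.matrix(im)) image_record(im) else im
  })
  if (!all(vapply(images, inherits, logical(1), "image_record"))) {
    abort("`images` must be image_record objects or matrices")
  }
  depths <- vapply(images, function(im) im$bit_depth, integer(1))
  if (length(unique(depths)) != 1) abort("mixed bit depths in one pool")
  keys <- lapply(images, function(im) {
    k <- im$condition
    k[setdiff(names(k), c("site", "replicate", "path", "record",
                          "plate", "well"))]
  })
  if (length(unique(keys)) != 1) {
    abort("mismatched condition keys in one pool")
  }
  out <- as.numeric(unlist(lapply(images, function(im) im$pixels),
                           use.names = FALSE))
  attr(out, "bit_depth") <- depths[1]
  out
}

#' Otsu's threshold of a histogram
#'
#' Exhaustively maximizes the between-class variance of the two-class
#' split (bins `<= t` versus `> t`) over all candidate splits; ties are
#' broken towards the smallest threshold. A histogram whose mass sits in a
#' single bin is degenerate (there is nothing to split) and raises an
#' error so that the caller decides the fallback.
#'
#' @param counts Non-negative bin counts.
#' @param levels Intensity value of each bin (default `0, 1, ...`).
#' @return The threshold: the level of the last bin of the lower class.
#' @export
#' @examples
#' otsu_threshold(c(50, 0, 0, 50))  # splits after bin 1 -> level 0
otsu_threshold <- function(counts, levels = seq_along(counts) - 1) {
  if (length(counts) < 1 || any(counts < 0) || any(!is.finite(counts))) {
    abort("`counts` must be finite and non-negative")
  }
  stopifnot(length(levels) == length(counts))
  if (sum(counts > 0) < 2) abort("degenerate histogram")
  n <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * levels)
  k <- length(counts)
  w0 <- w0[-k]; m0 <- m0[-k]          # splits after bins 1 .. k-1
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (m0[length(m0)] + counts[k] * levels[k] - m0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf   # not a two-class split
  levels[which.max(sigma_b)]
}

#' Otsu's threshold of a pixel pool
#'
#' Bins the pooled pixels into `n_bins` equal-width bins spanning the
#' observed range (mirroring 8-bit `graythresh`-style behaviour on
#' arbitrary-range data), applies [otsu_threshold()], and returns the
#' upper edge of the selected bin on the intensity scale, so that
#' "foreground" is every pixel strictly above the returned value.
#'
#' @param pixels Numeric vector of pooled pixel values.
#' @param n_bins Number of histogram bins.
#' @return The threshold on the intensity scale.
#' @export
otsu_threshold_pixels <- function(pixels, n_bins = 256L) {
  if (length(pixels) < 1) abort("empty pixel pool")
  rng <- range(pixels)
  if (!all(is.finite(rng))) abort("non-finite pixel values")
  if (rng[1] == rng[2]) abort("degenerate histogram")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  # equal-width binning by arithmetic (equivalent to a left-closed
  # interval search, with the maximum folded into the last bin)
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(floor((pixels - rng[1]) / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  t_level <- otsu_threshold(counts, levels = centers)
  breaks[match(t_level, centers) + 1L]
}

#' Mean intensity over the threshold-positive area
#'
#' The mean of the pixels strictly greater than the threshold — the
#' "cell area" average that suppresses background contribution. An empty
#' foreground is an error, never a silent zero.
#'
#' @param pixels Numeric vector of pooled pixel values.
#' @param threshold Intensity threshold.
#' @return List with `mean` and `count`.
#' @export
mean_foreground_intensity <- function(pixels, threshold) {
  if (length(pixels) < 1) abort("empty pixel pool")
  stopifnot(is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  fg <- pixels[pixels > threshold]
  if (length(fg) == 0) abort("empty foreground")
  list(mean = mean(fg), count = length(fg))
}

#' Quantify a screen manifest into an intensity table
#'
#' For every condition (probe, line, concentration, channel, time point)
#' the images across sites and replicates (4 per condition in the
#' reference design) are pooled, Otsu's threshold is computed on the
#' pooled histogram, and the mean intensity over the threshold-positive
#' area is recorded. Conditions whose images cannot be read are flagged
#' `"missing"` and constant-image conditions `"degenerate"`; neither is
#' silently dropped.
#'
#' @param manifest Tibble with one row per image: columns `probe_id`,
#'   `line_id`, `concentration_nM`, `channel`, `site`, `time_h`,
#'   `replicate` plus whatever the reader needs (`path`, or the generative
#'   state of a virtual screen). A `synthetic_screen` may be given
#'   directly.
#' @param reader A reader function as from [tiff_reader()] or
#'   [screen_reader()]; defaults to [screen_reader()] when `manifest` is a
#'   `synthetic_screen`.
#' @param n_bins Histogram bins for Otsu's method.
#' @return A tibble with one row per condition: `probe_id`, `family`,
#'   `line_id`, `origin`, `concentration_nM`, `channel`, `time_h`,
#'   `mean_fg`, `n_fg_pixels`, `threshold`, `flag` (`"ok"`, `"missing"`
#'   or `"degenerate"`).
#' @export
quantify_screen <- function(manifest, reader = NULL, n_bins = 256L) {
  if (inherits(manifest, "synthetic_screen")) {
    reader <- reader %||% screen_reader(manifest)
    manifest <- manifest$manifest
  }
  if (is.null(reader)) abort("a `reader` is required for a bare manifest")
  manifest <- as_tibble(manifest)
  need <- c("probe_id", "line_id", "concentration_nM", "channel",
            "site", "time_h", "replicate")
  if (!all(need %in% names(manifest))) {
    abort(paste("manifest lacks columns:",
                paste(setdiff(need, names(manifest)), collapse = ", ")))
  }
  key <- paste(manifest$probe_id, manifest$line_id,
               manifest$concentration_nM, manifest$channel,
               manifest$time_h, sep = "\r")
  groups <- split(seq_len(nrow(manifest)), factor(key, levels = unique(key)))
  ng <- length(groups)
  cols <- as.list(manifest)
  first <- vapply(groups, `[`, integer(1), 1L)
  out <- tibble(
    probe_id = cols$probe_id[first],
    family = (cols$family %||% rep(NA_character_, nrow(manifest)))[first],
    line_id = cols$line_id[first],
    origin = (cols$origin %||% rep(NA_character_, nrow(manifest)))[first],
    concentration_nM = cols$concentration_nM[first],
    channel = cols$channel[first],
    time_h = cols$time_h[first],
    mean_fg = NA_real_, n_fg_pixels = NA_integer_,
    threshold = NA_real_, flag = "ok"
  )
  nm <- names(cols)
  for (g in seq_len(ng)) {
    idx <- groups[[g]]
    pools <- vector("list", length(idx))
    missing <- FALSE
    for (j in seq_along(idx)) {
      row <- lapply(cols, `[[`, idx[j])
      names(row) <- nm
      img <- reader(row)
      if (is.null(img)) { missing <- TRUE; break }
      pools[[j]] <- as.numeric(img)
    }
    if (missing) {
      out$flag[g] <- "missing"
      next
    }
    px <- unlist(pools, use.names = FALSE)
    thr <- try(otsu_threshold_pixels(px, n_bins = n_bins), silent = TRUE)
    if (inherits(thr, "try-error")) {
      out$flag[g] <- "degenerate"
      next
    }
    fg <- mean_foreground_intensity(px, thr)
    out$mean_fg[g] <- fg$mean
    out$n_fg_pixels[g] <- fg$count
    out$threshold[g] <- thr
  }
  n_bad <- sum(out$flag != "ok")
  if (n_bad > 0) {
    inform(sprintf("quantify_screen: %d of %d conditions flagged (%s)",
                   n_bad, ng,
                   paste(unique(out$flag[out$flag != "ok"]),
                         collapse = ", ")))
  }
  out
}
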