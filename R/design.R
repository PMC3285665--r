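#' The NCI-60 cell-line panel
#'
#' The 60 human cancer cell lines of the National Cancer Institute's
#' Developmental Therapeutics Program panel, with their 9 tissues of origin
#' (leukemia, lung, colon, CNS, melanoma, ovarian, renal, prostate, breast).
#' The prostate class has only two members, which makes it the stress case
#' for leave-one-out classification.
#'
#' @return A tibble with columns `line_id` and `origin`.
#' @export
#' @examples
#' dplyr::count(nci60_lines(), origin)
nci60_lines <- function() {
  tibble(
    line_id = c(
      "CCRF-CEM", "HL-60", "K-562", "MOLT-4", "RPMI-8226", "SR",
      "A549", "EKVX", "HOP-62", "HOP-92", "NCI-H226", "NCI-H23",
      "NCI-H322M", "NCI-H460", "NCI-H522",
      "COLO205", "HCC-2998", "HCT-116", "HCT-15", "HT29", "KM12", "SW-620",
      "SF-268", "SF-295", "SF-539", "SNB-19", "SNB-75", "U251",
      "LOX-IMVI", "MALME-3M", "M14", "MDA-MB-435", "SK-MEL-2", "SK-MEL-28",
      "SK-MEL-5", "UACC-257", "UACC-62",
      "IGROV1", "OVCAR-3", "OVCAR-4", "OVCAR-5", "OVCAR-8", "NCI-ADR-RES",
      "SK-OV-3",
      "786-0", "A498", "ACHN", "CAKI-1", "RXF-393", "SN12C", "TK-10", "UO-31",
      "PC-3", "DU-145",
      "MCF7", "MDA-MB-231", "HS-578T", "BT-549", "T-47D", "MDA-MB-468"
    ),
    origin = rep(
      c("leukemia", "lung", "colon", "CNS", "melanoma", "ovarian",
        "renal", "prostate", "breast"),
      times = c(6, 9, 7, 6, 9, 7, 8, 2, 6)
    )
  )
}

#' Probe library table
#'
#' Enumerates a diversity-oriented fluorescence library of two scaffold
#' families: rosamine (`RS`) and BODIPY (`BD`). The full library has 240 RS
#' and 317 BD compounds (557 in total). A `series` tag groups probes that
#' share a response signature; by default every probe is its own series.
#'
#' @param n_bd,n_rs Number of BODIPY and rosamine probes.
#' @return A tibble with columns `probe_id`, `family`, `series`.
#' @export
#' @examples
#' nrow(probe_library())  # 557
probe_library <- function(n_bd = 317, n_rs = 240) {
  stopifnot(n_bd >= 0, n_rs >= 0, n_bd + n_rs >= 1)
  tibble(
    probe_id = c(sprintf("BD-%03d", seq_len(n_bd)),
                 sprintf("RS-%03d", seq_len(n_rs))),
    family = rep(c("BD", "RS"), times = c(n_bd, n_rs))
  ) |>
    dplyr::mutate(series = .data$probe_id)
}

#' Define a plate-screen factorial design
#'
#' A screen design is the full factorial layout of a fluorescence
#' phenotyping screen: every probe is applied to every cell line at each
#' concentration, imaged in each channel at several sites per well, at a
#' series of time points, in replicate.
#'
#' @param probes Data frame with columns `probe_id`, `family` and optionally
#'   `series` (defaults to `probe_id`).
#' @param lines Data frame with columns `line_id`, `origin`.
#' @param concentrations_nM Numeric vector of probe concentrations (nM).
#' @param channels Character vector of imaging channels.
#' @param sites Integer, imaging sites per well.
#' @param time_points_h Strictly increasing numeric vector of imaging times
#'   (hours). Must contain the fold-change baseline and endpoint used
#'   downstream (1 h and 48 h by default).
#' @param replicates Integer, biological replicates.
#' @param image_shape Integer pair, image rows and columns in pixels.
#' @param bit_depth Integer, camera bit depth.
#' @param baseline_h,endpoint_h Hours used for the kinetic fold change.
#' @return A `screen_design` object.
#' @export
#' @examples
#' d <- screen_design(probe_library(2, 1), nci60_lines()[1:4, ],
#'                    concentrations_nM = 500, channels = "TRITC",
#'                    sites = 1, time_points_h = c(1, 48), replicates = 1)
#' nrow(enumerate_design(d))
screen_design <- function(probes, lines,
                          concentrations_nM = c(250, 500),
                          channels = c("FITC", "TRITC"),
                          sites = 2L,
                          time_points_h = c(1, 24, 48),
                          replicates = 2L,
                          image_shape = c(128L, 128L),
                          bit_depth = 16L,
                          baseline_h = 1, endpoint_h = 48) {
  probes <- as_tibble(probes)
  lines <- as_tibble(lines)
  if (!all(c("probe_id", "family") %in% names(probes)) || nrow(probes) < 1) {
    abort("`probes` needs >= 1 row with columns `probe_id`, `family`.")
  }
  if (!"series" %in% names(probes)) probes$series <- probes$probe_id
  if (!all(c("line_id", "origin") %in% names(lines)) || nrow(lines) < 1) {
    abort("`lines` needs >= 1 row with columns `line_id`, `origin`.")
  }
  if (anyDuplicated(probes$probe_id) > 0) abort("`probe_id` must be unique.")
  if (anyDuplicated(lines$line_id) > 0) abort("`line_id` must be unique.")
  if (length(concentrations_nM) < 1 || length(channels) < 1 ||
      sites < 1 || replicates < 1 || length(time_points_h) < 1) {
    abort("degenerate design: every factor needs at least one level")
  }
  if (is.unsorted(time_points_h, strictly = TRUE)) {
    abort("`time_points_h` must be strictly increasing.")
  }
  if (!all(c(baseline_h, endpoint_h) %in% time_points_h)) {
    abort("`time_points_h` must contain `baseline_h` and `endpoint_h`.")
  }
  stopifnot(length(image_shape) == 2, all(image_shape >= 8), bit_depth >= 8)
  structure(
    list(
      probes = probes, lines = lines,
      concentrations_nM = as.numeric(concentrations_nM),
      channels = as.character(channels),
      sites = as.integer(sites),
      time_points_h = as.numeric(time_points_h),
      replicates = as.integer(replicates),
      image_shape = as.integer(image_shape),
      bit_depth = as.integer(bit_depth),
      baseline_h = baseline_h, endpoint_h = endpoint_h
    ),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design>\n")
  cat(sprintf("  %d probes (%s) x %d lines (%d origins)\n",
              nrow(x$probes),
              paste(sprintf("%s:%d", names(table(x$probes$family)),
                            table(x$probes$family)), collapse = ", "),
              nrow(x$lines), dplyr::n_distinct(x$lines$origin)))
  cat(sprintf("  %d conc x %d channels x %d sites x %d times x %d reps\n",
              length(x$concentrations_nM), length(x$channels), x$sites,
              length(x$time_points_h), x$replicates))
  cat(sprintf("  %s condition records\n",
              format(design_size(x), big.mark = ",")))
  invisible(x)
}

#' @rdname screen_design
#' @param x A `screen_design`.
#' @export
design_size <- function(x) {
  stopifnot(inherits(x, "screen_design"))
  prod(nrow(x$probes), nrow(x$lines), length(x$concentrations_nM),
       length(x$channels), x$sites, length(x$time_points_h), x$replicates)
}

#' The full published-scale screen design
#'
#' The paper-scale layout: 557 probes (317 BD + 240 RS) x the NCI-60 panel
#' x 2 concentrations (250/500 nM) x 2 channels (FITC/TRITC) x 2 sites x
#' 3 time points (1/24/48 h) x 2 replicates = 1,604,160 condition records.
#' Intended for metadata-level enumeration; rendering images at this scale
#' is not the point of the generator.
#'
#' @return A `screen_design`.
#' @export
full_screen_design <- function() {
  screen_design(probe_library(), nci60_lines())
}

#' Enumerate all condition records of a design
#'
#' Expands the factorial design into one record per
#' (probe, line, concentration, channel, site, time point, replicate).
#' Records carry plate and well assignments: probes are plated in pairs and
#' lines in subsets of at most five per plate, and the two edge columns on
#' each side of a 384-well plate are never used (evaporation guard).
#'
#' @param design A `screen_design`.
#' @return A tibble with one row per condition record, columns `record`,
#'   `probe_id`, `family`, `series`, `line_id`, `origin`,
#'   `concentration_nM`, `channel`, `site`, `time_h`, `replicate`,
#'   `plate`, `well`.
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  rec <- tidyr::expand_grid(
    probe_id = design$probes$probe_id,
    line_id = design$lines$line_id,
    concentration_nM = design$concentrations_nM,
    channel = design$channels,
    site = seq_len(design$sites),
    time_h = design$time_points_h,
    replicate = seq_len(design$replicates)
  )
  probe_idx <- match(rec$probe_id, design$probes$probe_id)
  line_idx <- match(rec$line_id, design$lines$line_id)
  rec$family <- design$probes$family[probe_idx]
  rec$series <- design$probes$series[probe_idx]
  rec$origin <- design$lines$origin[line_idx]
  # plate map: 2 probes and <= 5 lines per plate (Fig-S1-style layout);
  # usable well columns are 3..22 of a 24-column plate
  probe_block <- (probe_idx - 1L) %/% 2L
  line_block <- (line_idx - 1L) %/% 5L
  rec$plate <- sprintf("P%04d-%02d", probe_block + 1L, line_block + 1L)
  within_probe <- (probe_idx - 1L) %% 2L
  within_line <- (line_idx - 1L) %% 5L
  conc_idx <- match(rec$concentration_nM, design$concentrations_nM) - 1L
  col_slot <- within_line * 4L + conc_idx * 2L + rec$replicate - 1L
  rec$well <- sprintf("%s%02d", LETTERS[within_probe + 1L], 3L + col_slot)
  rec$record <- seq_len(nrow(rec))
  dplyr::select(
    rec, "record", "probe_id", "family", "series", "line_id", "origin",
    "concentration_nM", "channel", "site", "time_h", "replicate",
    "plate", "well"
  )
}
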