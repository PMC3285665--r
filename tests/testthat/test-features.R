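test_that("fold change is the guarded endpoint/baseline ratio", {
  expect_equal(fold_change(100, 100), 1)
  expect_equal(fold_change(50, 250), 5)
  expect_error(fold_change(0, 500, baseline_floor = 1), "baseline below floor")
  expect_error(fold_change(-1, 5), ">= 0")
  # identity property over a range of baselines
  a <- c(1, 2.5, 10, 1e4)
  expect_equal(fold_change(a, a), rep(1, 4))
})

test_that("feature matrix layout follows the collapse policy", {
  # 2 probes x 2 concentrations x 2 channels, synthetic intensity rows
  grid <- tidyr::expand_grid(
    probe_id = c("BD-001", "RS-001"),
    line_id = c("L1", "L2", "L3"),
    concentration_nM = c(250, 500),
    channel = c("FITC", "TRITC"),
    time_h = c(1, 48))
  grid$origin <- "x"
  grid$family <- substr(grid$probe_id, 1, 2)
  set.seed(10)
  grid$mean_fg <- ifelse(grid$time_h == 1, 100, 100 * runif(nrow(grid), 1, 3))
  # make channel brightness differ per probe at 500 nM
  grid$mean_fg[grid$time_h == 1 & grid$channel == "TRITC"] <- 150
  grid$flag <- "ok"

  fm <- build_feature_matrix(grid)
  expect_equal(length(feature_columns(fm)), 8)
  expect_equal(nrow(fm), 3)
  expect_true(all(as.matrix(fm[feature_columns(fm)]) > 0))

  fb <- build_feature_matrix(grid, collapse = "brightest")
  expect_equal(sort(feature_columns(fb)), c("BD-001", "RS-001"))
  # chosen channel is the one with larger mean baseline at 500 nM,
  # checked against an exhaustive per-probe comparison
  info <- attr(fb, "feature_info")
  for (p in c("BD-001", "RS-001")) {
    sub <- grid[grid$probe_id == p & grid$concentration_nM == 500 &
                  grid$time_h == 1, ]
    bright <- tapply(sub$mean_fg, sub$channel, mean)
    expect_equal(info$channel[info$feature == p],
                 names(bright)[which.max(bright)])
  }
})

test_that("flagged lines drop the affected feature; absent lines error", {
  grid <- tidyr::expand_grid(probe_id = c("P-1", "P-2"),
                             line_id = c("L1", "L2"),
                             concentration_nM = 500, channel = "TRITC",
                             time_h = c(1, 48))
  grid$origin <- "x"; grid$family <- "P"
  grid$mean_fg <- 100
  grid$flag <- "ok"
  grid$flag[grid$probe_id == "P-1" & grid$line_id == "L2" &
              grid$time_h == 48] <- "missing"
  expect_message(fm <- build_feature_matrix(grid), "dropping 1 feature")
  expect_equal(feature_columns(fm), "P-2")
  expect_error(
    build_feature_matrix(grid, expected_lines = c("L1", "L2", "L9")),
    "missing from the intensity table")
  # a baseline below the floor behaves like a flag
  grid$flag <- "ok"
  grid$mean_fg[grid$probe_id == "P-1" & grid$time_h == 1 &
                 grid$line_id == "L1"] <- 0.5
  expect_message(fm2 <- build_feature_matrix(grid), "dropping")
  expect_equal(feature_columns(fm2), "P-2")
})

test_that("aligned batch factors cancel in the feature matrix", {
  demo <- tiny_screen(n_probes = 4, n_informative = 2, seed = 6)
  base <- demo$model
  no_batch <- effect_model(
    turnon_effects = base$turnon_effects, noise_cv = base$noise_cv,
    batch_sd = 0, pixel_noise_cv = base$pixel_noise_cv,
    background_cv = base$background_cv)
  with_batch <- effect_model(
    turnon_effects = base$turnon_effects, noise_cv = base$noise_cv,
    batch_sd = 0.3, batch_aligned = TRUE,
    pixel_noise_cv = base$pixel_noise_cv,
    background_cv = base$background_cv)
  broken <- effect_model(
    turnon_effects = base$turnon_effects, noise_cv = base$noise_cv,
    batch_sd = 0.3, batch_aligned = FALSE,
    pixel_noise_cv = base$pixel_noise_cv,
    background_cv = base$background_cv)
  f0 <- build_feature_matrix(quantify_screen(
    generate_screen(demo$design, no_batch, seed = 55)))
  f1 <- build_feature_matrix(quantify_screen(
    generate_screen(demo$design, with_batch, seed = 55)))
  f2 <- build_feature_matrix(quantify_screen(
    generate_screen(demo$design, broken, seed = 55)))
  cols <- feature_columns(f0)
  expect_identical(f0$line_id, f1$line_id)
  rel_aligned <- abs(as.matrix(f1[cols]) / as.matrix(f0[cols]) - 1)
  expect_lt(max(rel_aligned), 0.01)
  rel_broken <- abs(as.matrix(f2[cols]) / as.matrix(f0[cols]) - 1)
  expect_gt(max(rel_broken), 0.05)
})

test_that("selectivity index matches the leave-one-out mean loop", {
  x <- c(5.64, rep(1, 59))
  si <- selectivity_index(x)
  expect_equal(si[1], 5.64)
  expect_true(all(si[-1] < 1))
  expect_equal(selectivity_index(rep(2.5, 10)), rep(1, 10))
  expect_error(selectivity_index(c(1, -1)), "positive")
  expect_error(selectivity_index(3), ">= 2")
  set.seed(19)
  v <- rlnorm(40, 0, 0.5)
  si <- selectivity_index(v)
  oracle <- vapply(seq_along(v), function(i) v[i] / mean(v[-i]), numeric(1))
  expect_equal(si, oracle)
  # permutation equivariance
  p <- sample(seq_along(v))
  expect_equal(selectivity_index(v[p]), si[p])
})

test_that("feature matrices round-trip through CSV with their sidecar", {
  demo <- tiny_screen(seed = 14)
  sim <- simulate_intensity_table(demo$design, demo$model, seed = 4)
  fm <- build_feature_matrix(sim)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(as.data.frame(back), as.data.frame(fm),
               ignore_attr = TRUE, tolerance = 1e-12)
  # sidecar must cover every line
  orig <- readr::read_csv(sub("\\.csv$", "_origins.csv", f),
                          show_col_types = FALSE)
  readr::write_csv(orig[-1, ], sub("\\.csv$", "_origins.csv", f))
  expect_error(read_feature_matrix(f), "cover every line")
})

test_that("probe_selectivity tidies every feature column", {
  demo <- tiny_screen(seed = 9)
  sim <- simulate_intensity_table(demo$design, demo$model, seed = 2)
  fm <- build_feature_matrix(sim)
  ps <- probe_selectivity(fm)
  expect_equal(nrow(ps), length(feature_columns(fm)) * nrow(fm))
  one <- ps[ps$feature == feature_columns(fm)[1], ]
  expect_equal(one$selectivity, selectivity_index(fm[[one$feature[1]]]))
})
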