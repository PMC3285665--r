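test_that("wilks lambda reproduces hand-computed scatter decompositions", {
  # zero within-class scatter -> exactly 0
  expect_equal(wilks_lambda(matrix(c(1, 1, 3, 3), ncol = 1),
                            y = c("a", "a", "b", "b")), 0)
  # equal class means -> no between-class signal -> 1
  expect_equal(wilks_lambda(matrix(c(0, 2, 0, 2), ncol = 1),
                            y = c("a", "a", "b", "b")), 1)
  # hand ANOVA decomposition: W = 1, T = 5 -> 0.2
  expect_equal(wilks_lambda(matrix(c(0, 1, 2, 3), ncol = 1),
                            y = c("a", "a", "b", "b")), 0.2)
  # collinear features make the total scatter singular
  x <- cbind(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_error(wilks_lambda(x, y = c("a", "a", "b", "b")),
               "degenerate feature subset")
})

test_that("lambda equals the eigenvalue route 1/prod(1 + lambda_i)", {
  set.seed(51)
  for (i in 1:20) {
    n <- 30; p <- sample(2:4, 1); g <- 3
    y <- rep(letters[1:g], length.out = n)
    x <- matrix(rnorm(n * p), n, p) +
      outer(as.integer(factor(y)), seq_len(p) / 2)
    lam <- wilks_lambda(x, y = y)
    sc <- phenoscreen:::scatter_matrices(x, y)
    ev <- Re(eigen(solve(sc$W, sc$B), only.values = TRUE)$values)
    expect_equal(lam, 1 / prod(1 + ev), tolerance = 1e-8)
  }
})

test_that("first-variable F-to-enter is the one-way ANOVA F", {
  # hand case: lambda 1 -> 0.2 with n = 4, g = 2, q = 1 gives F = 8
  ft <- partial_f(1, 0.2, n = 4, g = 2, q = 1)
  expect_equal(ft$statistic, 8)
  # no improvement -> F = 0, p = 1
  ft0 <- partial_f(0.5, 0.5, n = 20, g = 3, q = 2)
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p_value, 1)
  expect_error(partial_f(1, 0.5, n = 5, g = 3, q = 4),
               "degrees of freedom")
  # random 3-class data: agree with base R's ANOVA to 1e-10
  set.seed(52)
  for (i in 1:20) {
    y <- rep(c("a", "b", "c"), times = c(7, 9, 8))
    x <- rnorm(24) + as.integer(factor(y)) * runif(1, 0, 2)
    lam <- wilks_lambda(matrix(x, ncol = 1), y = y)
    ft <- partial_f(1, lam, n = 24, g = 3, q = 1)
    ref <- anova_f(x, y)
    expect_equal(ft$statistic, unname(ref["F"]), tolerance = 1e-10)
    expect_equal(ft$p_value, unname(ref["p"]), tolerance = 1e-10)
  }
})

test_that("F-tail p-values agree with direct numerical integration", {
  cases <- expand.grid(f = c(0.5, 2.3, 7.7), df1 = c(4, 8),
                       df2 = c(17, 200))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      p <- partial_f(1, 1 / (1 + f * df1 / df2), n = df2 + df1 + 1,
                     g = df1 + 1, q = 1)
      ref <- stats::integrate(function(x) stats::df(x, df1, df2),
                              f, Inf, rel.tol = 1e-12)$value
      expect_equal(p$p_value, ref, tolerance = 1e-10)
    })
  }
})

test_that("stepwise enters the separating feature first and respects alpha", {
  set.seed(53)
  n <- 60
  y <- rep(letters[1:3], each = 20)
  x <- matrix(rnorm(n * 20), n, 20)
  x[, 1] <- x[, 1] + 4 * as.integer(factor(y))
  colnames(x) <- paste0("f", 1:20)
  st <- forward_stepwise_select(x, y = y)
  expect_equal(st$trace$feature[1], "f1")
  # verified against exhaustive single-feature F ranking
  f_each <- vapply(1:20, function(j) {
    lam <- wilks_lambda(x[, j, drop = FALSE], y = y)
    partial_f(1, lam, n, 3, 1)$statistic
  }, numeric(1))
  expect_equal(which.max(f_each), 1L)
  # pure noise with a tiny alpha: empty selection, not an error
  xn <- matrix(rnorm(n * 10), n, 10)
  expect_message(
    st0 <- forward_stepwise_select(xn, y = y, alpha_enter = 1e-6,
                                   alpha_remove = 1e-5),
    "empty selection")
  expect_length(st0$selected, 0)
  expect_error(forward_stepwise_select(x, y = y, alpha_enter = 0),
               "alphas")
})

test_that("lambda is non-increasing over enter steps and kept features stay significant", {
  set.seed(54)
  y <- rep(letters[1:3], each = 15)
  x <- matrix(rnorm(45 * 8), 45, 8)
  x[, 1:3] <- x[, 1:3] + outer(as.integer(factor(y)), c(1.5, 1, 0.8))
  st <- forward_stepwise_select(x, y = y)
  enters <- st$trace[st$trace$action == "enter", ]
  expect_true(all(diff(enters$lambda) <= 1e-12))
  # termination condition: every kept feature's removal p < alpha_remove
  sel <- match(st$selected, colnames(x) %||% paste0("V", 1:8))
  for (f in sel) {
    lam_wo <- if (length(sel) > 1) {
      wilks_lambda(x[, setdiff(sel, f), drop = FALSE], y = y)
    } else 1
    ft <- partial_f(lam_wo, st$lambda, 45, 3, length(sel))
    expect_lt(ft$p_value, st$alpha_remove)
  }
})

test_that("stepwise never exceeds the residual-df guard", {
  set.seed(55)
  n <- 20; g <- 4
  y <- rep(letters[1:g], each = 5)
  x <- matrix(rnorm(n * 40), n, 40) + as.integer(factor(y))
  st <- forward_stepwise_select(x, y = y, alpha_enter = 0.99,
                                alpha_remove = 0.995)
  expect_lte(length(st$selected), n - g - 1)
})

test_that("stepwise matches exhaustive best-subset-by-lambda on small pools", {
  # 6 features, 3 informative: the greedy selection should find the
  # best subset of its own size in nearly every replicate
  set.seed(56)
  hits <- 0
  n_rep <- 50
  for (r in 1:n_rep) {
    n <- 60
    y <- rep(letters[1:3], each = 20)
    x <- matrix(rnorm(n * 6), n, 6)
    x[, 1:3] <- x[, 1:3] + outer(as.integer(factor(y)),
                                 runif(3, 0.8, 1.5))
    colnames(x) <- paste0("f", 1:6)
    st <- forward_stepwise_select(x, y = y, max_features = 3)
    k <- length(st$selected)
    if (k == 0) next
    combos <- utils::combn(6, k)
    lams <- apply(combos, 2, function(idx) {
      wilks_lambda(x[, idx, drop = FALSE], y = y)
    })
    best <- sort(colnames(x)[combos[, which.min(lams)]])
    if (identical(sort(st$selected), best)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("classification functions match the Gaussian-density oracle", {
  # two 1-D classes at -1/+1: a point at 0.9 goes to the + class
  x <- matrix(c(-1.2, -0.8, -1, 0.8, 1.2, 1), ncol = 1)
  y <- rep(c("neg", "pos"), each = 3)
  fit <- fit_lda(x, y = y)
  pr <- predict(fit, matrix(0.9, 1, 1, dimnames = list(NULL, "V1")))
  expect_equal(pr$.pred, "pos")
  # equal class means: scores differ only by the prior terms
  xe <- matrix(c(0, 1, 2, 0, 1, 2), ncol = 1)
  fit_e <- fit_lda(xe, y = y, priors = c(0.3, 0.7))
  sc <- predict(fit_e, matrix(c(0, 5), 2, 1,
                              dimnames = list(NULL, "V1")))
  gap <- sc$score_pos - sc$score_neg
  expect_equal(gap, rep(log(0.7) - log(0.3), 2), tolerance = 1e-10)
  # 3-class 2-feature toy against density x prior evaluation
  set.seed(57)
  y3 <- rep(c("a", "b", "c"), each = 10)
  x3 <- matrix(rnorm(60), 30, 2) +
    cbind(as.integer(factor(y3)), -as.integer(factor(y3)))
  fit3 <- fit_lda(x3, y = y3)
  test_pts <- matrix(rnorm(20), 10, 2)
  colnames(test_pts) <- colnames(x3) <- fit3$features
  got <- predict(fit3, test_pts)$.pred
  S <- phenoscreen:::scatter_matrices(x3, y3)$W / (30 - 3)
  oracle <- apply(test_pts, 1, function(pt) {
    dens <- vapply(c("a", "b", "c"), function(cl) {
      mu <- colMeans(x3[y3 == cl, ])
      -0.5 * stats::mahalanobis(pt, mu, S) + log(1 / 3)
    }, numeric(1))
    names(which.max(dens))
  })
  expect_equal(got, unname(oracle))
})

test_that("fit_lda enforces estimability and valid priors", {
  x <- matrix(rnorm(12), 6, 2)
  y <- rep(c("a", "b"), 3)
  expect_error(fit_lda(cbind(x, x), y = y), "singular|n - g")
  expect_error(fit_lda(x, y = y, priors = c(0.5, 0.2)), "sum to 1")
  # ridge rescues a collinear pool
  fit <- fit_lda(cbind(x, x + rnorm(12, 0, 1e-12)), y = y, ridge = 1e-3)
  expect_s3_class(fit, "pheno_lda")
})

test_that("classify returns sorted scores with documented tie-breaking", {
  x <- matrix(c(-1.1, -0.9, 0.9, 1.1), ncol = 1)
  y <- c("a", "a", "b", "b")
  fit <- fit_lda(x, y = y)
  at_mean <- predict(fit, matrix(-1, 1, 1, dimnames = list(NULL, "V1")))
  expect_equal(at_mean$.pred, "a")
  expect_equal(at_mean$top_score, at_mean$score_a)
  # equidistant point: scores tie, first class label wins, tie reported
  expect_message(
    mid <- predict(fit, matrix(0, 1, 1, dimnames = list(NULL, "V1"))),
    "tie")
  expect_equal(mid$score_a, mid$score_b)
  expect_equal(mid$.pred, "a")
  expect_error(predict(fit, matrix(0, 1, 1, dimnames = list(NULL, "Z"))),
               "features")
  # random models: argmax agrees with explicit evaluation of c_k
  set.seed(58)
  y3 <- rep(c("a", "b", "c"), each = 8)
  x3 <- matrix(rnorm(48), 24, 2) + as.integer(factor(y3))
  fit3 <- fit_lda(x3, y = y3)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, fit3$features))
  pr <- predict(fit3, pts)
  manual <- pts %*% fit3$coef + matrix(fit3$const, 5, 3, byrow = TRUE)
  expect_equal(pr$.pred, fit3$classes[apply(manual, 1, which.max)])
  expect_true(all(pr$top_score >= pr$second_score))
})

test_that("jackknife equals an independent leave-one-out refit loop", {
  set.seed(59)
  n <- 30
  y <- rep(c("a", "b", "c"), each = 10)
  x <- matrix(rnorm(n * 4), n, 4) +
    outer(as.integer(factor(y)), c(1, 0.5, -0.5, 0.2))
  jk <- jackknife_classification(x, y = y)
  oracle <- naive_loo_predictions(x, y)
  expect_equal(jk$predictions$predicted, oracle)
  expect_equal(unname(rowSums(jk$counts)), unname(as.integer(table(y))))
  expect_equal(jk$overall_correct,
               100 * mean(oracle == y))
  # far-separated classes classify perfectly
  xs <- matrix(rnorm(20), 20, 1) + rep(c(0, 100), each = 10)
  ys <- rep(c("lo", "hi"), each = 10)
  expect_equal(jackknife_classification(xs, y = ys)$overall_correct, 100)
})

test_that("overlapping classes approach chance under the jackknife", {
  set.seed(60)
  n <- 900
  y <- rep(c("a", "b", "c"), each = 300)
  x <- matrix(rnorm(n * 2), n, 2)
  jk <- jackknife_classification(x, y = y)
  expect_lt(abs(jk$overall_correct - 100 / 3), 5)
})

test_that("single-member classes are refitted absent and misclassified", {
  x <- matrix(c(rnorm(8), 50), ncol = 1)
  y <- c(rep(c("a", "b"), 4), "solo")
  expect_message(jk <- jackknife_classification(x, y = y),
                 "single-member")
  solo_row <- jk$counts["solo", ]
  expect_equal(unname(solo_row["solo"]), 0L)
  expect_equal(sum(solo_row), 1)
})

test_that("jackknifed accuracy is optimistic-free relative to resubstitution", {
  set.seed(61)
  diffs <- replicate(20, {
    n <- 36
    y <- rep(c("a", "b", "c"), each = 12)
    x <- matrix(rnorm(n * 5), n, 5) +
      outer(as.integer(factor(y)), runif(5, 0, 0.6))
    fit <- fit_lda(x, y = y)
    resub <- 100 * mean(predict(fit, x)$.pred == y)
    jack <- jackknife_classification(x, y = y)$overall_correct
    resub - jack
  })
  expect_gte(mean(diffs), 0)
})

test_that("score plot coordinates are classify()'s top two scores", {
  set.seed(62)
  y <- rep(c("a", "b", "c"), each = 10)
  x <- matrix(rnorm(60), 30, 2) + 10 * as.integer(factor(y))
  fm <- tibble::as_tibble(as.data.frame(x)) |>
    dplyr::rename(F1 = "V1", F2 = "V2") |>
    dplyr::mutate(line_id = paste0("L", 1:30), origin = y, .before = 1)
  fit <- fit_lda(fm)
  sp <- score_plot(fit, fm)
  expect_true(all(sp$top_score >= sp$second_score))
  pr <- predict(fit, fm)
  expect_equal(sp$top_score, pr$top_score)
  expect_equal(sp$second_score, pr$second_score)
  expect_equal(sp$predicted, pr$.pred)
  # cleanly separated data: all predictions correct
  expect_equal(sp$predicted, sp$origin)
})

test_that("family comparison covers each pool and the redundancy limit", {
  set.seed(63)
  y <- rep(letters[1:3], each = 10)
  base <- matrix(rnorm(90), 30, 3) + outer(as.integer(factor(y)),
                                           c(1.2, 0.9, 1.1))
  # family B duplicates family A's features (plus microscopic noise so
  # the pools are distinct columns): combined cannot beat one family
  x <- cbind(base, base + rnorm(90, 0, 1e-8))
  colnames(x) <- c(paste0("AA-", 1:3), paste0("BB-", 1:3))
  fm <- dplyr::bind_cols(
    tibble::tibble(line_id = paste0("L", 1:30), origin = y),
    tibble::as_tibble(as.data.frame(x)))
  cmp <- subset_comparison(fm)
  expect_setequal(cmp$pool, c("AA", "BB", "combined"))
  expect_equal(cmp$pct_correct[cmp$pool == "combined"],
               max(cmp$pct_correct[cmp$pool != "combined"]))
  # a pool of one feature selects at most that feature
  fm1 <- fm[, c("line_id", "origin", "AA-1", "BB-1", "BB-2", "BB-3")]
  cmp1 <- subset_comparison(fm1)
  expect_lte(cmp1$n_selected[cmp1$pool == "AA"], 1)
})

test_that("predictions agree with MASS::lda as an independent reference", {
  skip_if_not_installed("MASS")
  set.seed(64)
  y <- rep(c("a", "b", "c"), each = 12)
  x <- matrix(rnorm(36 * 3), 36, 3) + as.integer(factor(y))
  colnames(x) <- paste0("f", 1:3)
  fit <- fit_lda(x, y = y)
  ref <- MASS::lda(x, grouping = y, prior = rep(1 / 3, 3))
  pts <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_equal(predict(fit, pts)$.pred,
               as.character(predict(ref, pts)$class))
})

test_that("recovery: stepwise finds the informative probes and the jackknife stays accurate", {
  # five fixed-seed synthetic screens at the reference conditions
  # (60 lines / 9 origins, 100 probes of which 30 informative, >= 2-fold
  # origin effects, 20% condition noise); sampled at the condition level
  entered <- integer(0)
  total <- integer(0)
  for (s in 1:5) {
    demo <- demo_screen(seed = s)
    sim <- simulate_intensity_table(demo$design, demo$model,
                                    seed = s + 1000)
    fm <- log2_features(build_feature_matrix(sim))
    st <- forward_stepwise_select(fm)
    jk <- jackknife_classification(fm, features = st$selected)
    expect_gte(jk$overall_correct, 95)
    entered <- c(entered, sum(st$selected %in% demo$informative$probe_id))
    total <- c(total, nrow(demo$informative))
  }
  expect_gte(sum(entered) / sum(total), 0.8)
})
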