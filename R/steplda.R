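# Stepwise linear discriminant analysis, written from scratch:
# Wilks' lambda as the selection criterion, partial-F enter/remove tests,
# per-class linear classification score functions, and jackknifed
# (leave-one-out) cross-validation. Only the F-distribution tail comes
# from stats::pf.

# resolve (data, class, features) into an x matrix and factor y
.resolve_xy <- function(data, y = NULL, features = NULL) {
  if (is.matrix(data)) {
    if (is.null(y)) abort("`y` labels are required with a matrix input")
    x <- data
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    if (!is.null(features)) x <- x[, features, drop = FALSE]
  } else {
    assert_feature_table(data)
    y <- y %||% data$origin
    x <- feature_matrix_of(data, features)
  }
  storage.mode(x) <- "double"
  list(x = x, y = factor(y))
}

# pooled within-class (W) and total (T) scatter matrices
scatter_matrices <- function(x, y) {
  y <- factor(y)
  grand <- colMeans(x)
  Tm <- crossprod(sweep(x, 2, grand))
  W <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(y)) {
    xi <- x[y == lev, , drop = FALSE]
    if (nrow(xi) > 0) {
      W <- W + crossprod(sweep(xi, 2, colMeans(xi)))
    }
  }
  dimnames(W) <- dimnames(Tm) <- list(colnames(x), colnames(x))
  list(W = W, T = Tm, B = Tm - W)
}

# Lambda = det(W)/det(T) on a feature subset, from precomputed scatters.
# Singular W -> exactly 0 (perfect within-class fit); singular T -> error.
.lambda_subset <- function(W, Tm, idx) {
  if (length(idx) == 0) return(1)
  dT <- determinant(Tm[idx, idx, drop = FALSE], logarithm = TRUE)
  if (dT$sign <= 0 || !is.finite(dT$modulus)) {
    abort("degenerate feature subset")
  }
  dW <- determinant(W[idx, idx, drop = FALSE], logarithm = TRUE)
  if (dW$sign <= 0 || !is.finite(dW$modulus)) return(0)
  min(1, exp(as.numeric(dW$modulus) - as.numeric(dT$modulus)))
}

#' Wilks' lambda of a feature subset
#'
#' \eqn{\Lambda = \det(W)/\det(T)} with \eqn{W} the pooled within-class
#' scatter and \eqn{T} the total scatter on the chosen features. Values
#' near 0 indicate strong class separation; 1 means the class means carry
#' no signal. Zero within-class scatter returns exactly 0; a singular
#' total scatter (collinear or constant features) is an error.
#'
#' @param data Feature table (with `origin` labels) or numeric matrix.
#' @param y Class labels (required for matrix input).
#' @param features Feature subset; default all numeric features.
#' @return Lambda in `[0, 1]`.
#' @export
#' @examples
#' wilks_lambda(matrix(c(0, 1, 2, 3), ncol = 1), y = c("a", "a", "b", "b"))
wilks_lambda <- function(data, y = NULL, features = NULL) {
  xy <- .resolve_xy(data, y, features)
  if (nlevels(xy$y) < 2) abort("need >= 2 classes")
  sc <- scatter_matrices(xy$x, xy$y)
  .lambda_subset(sc$W, sc$T, seq_len(ncol(xy$x)))
}

#' Partial F statistic for a change in Wilks' lambda
#'
#' The enter/remove test of stepwise discriminant analysis: for a model
#' growing from a subset with \eqn{\Lambda_{before}} to one of size `q`
#' with \eqn{\Lambda_{after}},
#' \deqn{F = \frac{n - g - q + 1}{g - 1}
#'            \left(\frac{\Lambda_{before}}{\Lambda_{after}} - 1\right)}
#' on \eqn{(g - 1, n - g - q + 1)} degrees of freedom. For a single first
#' variable this reduces to the one-way ANOVA F. A zero
#' \eqn{\Lambda_{after}} (perfect separation) gives `F = Inf`, `p = 0`.
#'
#' @param lambda_before,lambda_after Wilks' lambda before/after adding the
#'   `q`-th variable.
#' @param n,g Sample and class counts.
#' @param q Subset size after the addition.
#' @return List with `statistic`, `p_value`, `df1`, `df2`.
#' @export
partial_f <- function(lambda_before, lambda_after, n, g, q) {
  if (lambda_after > lambda_before + 1e-12 || lambda_before > 1 + 1e-12 ||
      lambda_after < 0) {
    abort("need 0 <= lambda_after <= lambda_before <= 1")
  }
  df1 <- g - 1
  df2 <- n - g - q + 1
  if (df1 < 1 || df2 < 1) abort("insufficient residual degrees of freedom")
  if (lambda_after <= 0) {
    return(list(statistic = Inf, p_value = 0, df1 = df1, df2 = df2))
  }
  f <- (df2 / df1) * (lambda_before / lambda_after - 1)
  list(statistic = f,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Forward stepwise variable selection by Wilks' lambda
#'
#' Iterates the classical SYSTAT-style loop: among the candidates, enter
#' the feature with the smallest F-to-enter p-value if it beats
#' `alpha_enter`; then remove any included feature whose F-to-remove
#' p-value exceeds `alpha_remove` (never the one just entered); stop when
#' neither fires, `max_features` is reached, or the residual degrees of
#' freedom are exhausted (never more than `n - g - 1` features). Ties are
#' broken by smallest p, then largest F, then lowest feature index, so the
#' procedure is deterministic. Candidates whose addition leaves the
#' within-class scatter with a 2-norm condition number above `cond_max`
#' are skipped (singularity guard).
#'
#' @inheritParams wilks_lambda
#' @param alpha_enter,alpha_remove Significance gates for entry/removal
#'   (both 0.150 by convention for this screen design).
#' @param max_features Hard cap on the number of entered features.
#' @param cond_max Condition-number guard for the within-class scatter.
#' @return A `pheno_stepwise`: `selected` (character), `trace` tibble
#'   (`step`, `action`, `feature`, `lambda`, `statistic`, `p_value`),
#'   `lambda` (final), `alphas`, `n`, `g`.
#' @export
forward_stepwise_select <- function(data, y = NULL, features = NULL,
                                    alpha_enter = 0.150,
                                    alpha_remove = 0.150,
                                    max_features = Inf,
                                    cond_max = 1e10) {
  if (alpha_enter <= 0 || alpha_enter >= 1 ||
      alpha_remove <= 0 || alpha_remove >= 1) {
    abort("alphas must lie in (0, 1)")
  }
  xy <- .resolve_xy(data, y, features)
  x <- xy$x; yy <- xy$y
  n <- nrow(x); g <- nlevels(yy); p <- ncol(x)
  if (n <= g + 1) abort("need n > g + 1 samples")
  sc <- scatter_matrices(x, yy)
  W <- sc$W; Tm <- sc$T

  selected <- integer(0)
  lambda_now <- 1
  trace <- list()
  step <- 0L
  repeat {
    acted <- FALSE
    just_entered <- NA_integer_
    # --- entry ---
    q_new <- length(selected) + 1L
    if (q_new <= min(max_features, n - g - 1L)) {
      cands <- setdiff(seq_len(p), selected)
      best <- NULL
      for (cand in cands) {
        idx <- c(selected, cand)
        if (kappa(W[idx, idx, drop = FALSE], exact = FALSE) > cond_max) next
        lam <- tryCatch(.lambda_subset(W, Tm, idx), error = function(e) NA)
        if (is.na(lam) || lam > lambda_now + 1e-12) next
        ft <- partial_f(lambda_now, lam, n, g, q_new)
        key <- c(ft$p_value, -ft$statistic, cand)
        if (is.null(best) ||
            key[1] < best$key[1] - 0 ||
            (key[1] == best$key[1] &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(cand = cand, lambda = lam, f = ft, key = key)
        }
      }
      if (!is.null(best) && best$f$p_value < alpha_enter) {
        selected <- c(selected, best$cand)
        lambda_now <- best$lambda
        step <- step + 1L
        trace[[length(trace) + 1L]] <- tibble(
          step = step, action = "enter",
          feature = colnames(x)[best$cand], lambda = lambda_now,
          statistic = best$f$statistic, p_value = best$f$p_value)
        acted <- TRUE
        just_entered <- best$cand
      }
    }
    # --- removal ---
    repeat {
      if (length(selected) < 1) break
      removable <- setdiff(selected, just_entered)
      if (length(removable) == 0) break
      worst <- NULL
      q <- length(selected)
      for (f in removable) {
        idx_without <- setdiff(selected, f)
        lam_without <- tryCatch(.lambda_subset(W, Tm, idx_without),
                                error = function(e) NA)
        if (is.na(lam_without)) next
        ft <- partial_f(lam_without, lambda_now, n, g, q)
        if (is.null(worst) || ft$p_value > worst$f$p_value ||
            (ft$p_value == worst$f$p_value && f < worst$feature)) {
          worst <- list(feature = f, lambda = lam_without, f = ft)
        }
      }
      if (is.null(worst) || worst$f$p_value <= alpha_remove) break
      selected <- setdiff(selected, worst$feature)
      lambda_now <- worst$lambda
      step <- step + 1L
      trace[[length(trace) + 1L]] <- tibble(
        step = step, action = "remove",
        feature = colnames(x)[worst$feature], lambda = lambda_now,
        statistic = worst$f$statistic, p_value = worst$f$p_value)
      acted <- TRUE
    }
    if (!acted || step > 10L * p) break
  }
  if (length(selected) == 0) {
    inform("forward_stepwise_select: no feature passed alpha-to-enter; empty selection")
  }
  structure(
    list(selected = colnames(x)[selected],
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble(step = integer(), action = character(),
                  feature = character(), lambda = double(),
                  statistic = double(), p_value = double()),
         lambda = lambda_now,
         alpha_enter = alpha_enter, alpha_remove = alpha_remove,
         n = n, g = g, pool_size = p, classes = levels(yy)),
    class = "pheno_stepwise"
  )
}

#' @export
print.pheno_stepwise <- function(x, ...) {
  cat(sprintf(
    "<pheno_stepwise> %d of %d features selected (alpha enter/remove %.3g/%.3g)\n",
    length(x$selected), x$pool_size, x$alpha_enter, x$alpha_remove))
  cat(sprintf("  final Wilks' lambda %.4g over %d classes, n = %d\n",
              x$lambda, x$g, x$n))
  invisible(x)
}

.resolve_priors <- function(priors, y) {
  g <- nlevels(y)
  if (is.character(priors)) {
    priors <- match.arg(priors, c("equal", "proportional"))
    pr <- if (priors == "equal") rep(1 / g, g) else
      as.numeric(table(y)) / length(y)
  } else {
    pr <- as.numeric(priors)
    if (length(pr) != g || any(pr <= 0) || abs(sum(pr) - 1) > 1e-8) {
      abort("numeric priors must be positive and sum to 1 over the classes")
    }
  }
  setNames(pr, levels(y))
}

#' Fit linear discriminant classification score functions
#'
#' Per-class linear classification functions on the selected features:
#' \deqn{c_k(x) = \mu_k^\top S^{-1} x - \tfrac12 \mu_k^\top S^{-1} \mu_k
#'       + \ln \pi_k}
#' with \eqn{S = W / (n - g)} the pooled within-class covariance. The
#' predicted class maximizes \eqn{c_k}. Equal priors are the default:
#' panel class sizes reflect how the panel was assembled, not prevalence.
#'
#' @inheritParams wilks_lambda
#' @param priors `"equal"`, `"proportional"`, or a numeric vector summing
#'   to 1 over the classes.
#' @param ridge Optional ridge added to `S` as
#'   `ridge * mean(diag(S)) * I`; 0 (off) by default.
#' @return A `pheno_lda`: classes, features, per-class means,
#'   pooled covariance, coefficient matrix (features x classes), constants
#'   and priors.
#' @export
fit_lda <- function(data, y = NULL, features = NULL, priors = "equal",
                    ridge = 0) {
  xy <- .resolve_xy(data, y, features)
  x <- xy$x; yy <- xy$y
  n <- nrow(x); g <- nlevels(yy); p <- ncol(x)
  if (g < 2) abort("need >= 2 classes")
  if (n - g < p) abort("need n - g >= number of features")
  pr <- .resolve_priors(priors, yy)
  means <- t(vapply(levels(yy), function(lev) {
    colMeans(x[yy == lev, , drop = FALSE])
  }, numeric(p)))
  if (p == 1) {
    means <- matrix(means, ncol = 1,
                    dimnames = list(levels(yy), colnames(x)))
  }
  W <- scatter_matrices(x, yy)$W
  S <- W / (n - g)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), p)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    abort("pooled within-class covariance is singular: select fewer features or set `ridge` > 0")
  }
  Sinv <- chol2inv(ch)
  coef <- Sinv %*% t(means)                       # p x g
  const <- -0.5 * colSums(t(means) * coef) + log(pr)
  dimnames(coef) <- list(colnames(x), levels(yy))
  structure(
    list(classes = levels(yy), features = colnames(x), means = means,
         cov = S, coef = coef, const = setNames(const, levels(yy)),
         priors = pr, counts = table(yy), n = n, ridge = ridge),
    class = "pheno_lda"
  )
}

#' @export
print.pheno_lda <- function(x, ...) {
  cat(sprintf("<pheno_lda> %d classes, %d features, n = %d\n",
              length(x$classes), length(x$features), x$n))
  invisible(x)
}

# score matrix for new observations (n x g)
.lda_scores <- function(object, x) {
  if (is.null(colnames(x)) && ncol(x) == length(object$features)) {
    colnames(x) <- object$features   # positional match for bare matrices
  }
  if (!all(object$features %in% colnames(x))) {
    abort("new data lacks the model's features")
  }
  x <- x[, object$features, drop = FALSE]
  sweep(x %*% object$coef, 2, object$const, `+`)
}

#' Classify observations with fitted score functions
#'
#' Evaluates every class's classification score function and predicts the
#' argmax; exact score ties are broken by class label order and reported.
#'
#' @param object A `pheno_lda`.
#' @param newdata Feature table or matrix with the model's features.
#' @param ... Unused.
#' @return A tibble with `line_id` (when available), `.pred`, one
#'   `score_<class>` column per class, and `top_score`, `second_score`.
#' @export
predict.pheno_lda <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix_of(newdata)
  sc <- .lda_scores(object, x)
  pred_i <- max.col(sc, ties.method = "first")
  ties <- apply(sc, 1, function(s) sum(s == max(s)) > 1)
  if (any(ties)) {
    inform(sprintf("predict.pheno_lda: %d tie(s) broken by class order",
                   sum(ties)))
  }
  sorted <- t(apply(unname(sc), 1, sort, decreasing = TRUE))
  out <- tibble(.pred = object$classes[pred_i],
                top_score = unname(sorted[, 1]),
                second_score = if (ncol(sorted) > 1) unname(sorted[, 2])
                else NA_real_)
  if (!is.null(rownames(x))) out <- dplyr::bind_cols(
    tibble(line_id = rownames(x)), out)
  scores <- as_tibble(sc, .name_repair = "minimal")
  names(scores) <- paste0("score_", object$classes)
  dplyr::bind_cols(out, scores)
}

#' Jackknifed (leave-one-out) classification matrix
#'
#' Classifies every sample with score functions refitted without it
#' (means and pooled covariance re-estimated; the feature set is fixed —
#' variable selection is not rerun inside the loop, matching the classical
#' jackknifed classification matrix; see [jackknife_selected()] for the
#' double-loop variant). When removing a sample empties its class, the
#' refit proceeds without that class and the sample is necessarily
#' misclassified; this is counted, reported and never hidden.
#'
#' @inheritParams fit_lda
#' @return A `pheno_jackknife`: `counts` (true x predicted matrix),
#'   `per_class` tibble with `% correct`, `overall_correct` (percent),
#'   `predictions` tibble, `n`.
#' @export
jackknife_classification <- function(data, y = NULL, features = NULL,
                                     priors = "equal", ridge = 0) {
  xy <- .resolve_xy(data, y, features)
  x <- xy$x; yy <- xy$y
  n <- nrow(x)
  classes <- levels(yy)
  if (any(table(yy) < 1) || length(classes) < 2) abort("need >= 2 classes")
  pred <- character(n)
  orphan <- 0L
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    yi <- droplevels(yy[-i])
    if (nlevels(yi) < nlevels(yy)) orphan <- orphan + 1L
    fit <- fit_lda(xi, y = yi, priors = priors, ridge = ridge)
    sc <- .lda_scores(fit, x[i, , drop = FALSE])
    pred[i] <- fit$classes[max.col(sc, ties.method = "first")]
  }
  if (orphan > 0) {
    inform(sprintf(
      "jackknife_classification: %d sample(s) from single-member classes were fitted with their class absent (necessarily misclassified)",
      orphan))
  }
  counts <- table(factor(yy, levels = classes),
                  factor(pred, levels = classes))
  names(dimnames(counts)) <- c("true", "predicted")
  per_class <- tibble(
    origin = classes,
    n = as.integer(rowSums(counts)),
    n_correct = as.integer(diag(counts))
  ) |>
    dplyr::mutate(pct_correct = 100 * .data$n_correct / .data$n)
  structure(
    list(counts = counts, per_class = per_class,
         overall_correct = 100 * sum(diag(counts)) / n,
         predictions = tibble(line_id = rownames(x) %||%
                                as.character(seq_len(n)),
                              true = as.character(yy), predicted = pred),
         n = n, priors = priors),
    class = "pheno_jackknife"
  )
}

#' @export
print.pheno_jackknife <- function(x, ...) {
  cat(sprintf("<pheno_jackknife> %.1f%% correct over %d samples\n",
              x$overall_correct, x$n))
  print(x$counts)
  invisible(x)
}

#' Double-loop jackknife: selection rerun inside each fold
#'
#' The more conservative leave-one-out estimate in which the stepwise
#' selection itself is repeated without the held-out sample. Slower and
#' not the classical jackknifed-matrix convention, but free of
#' selection bias.
#'
#' @inheritParams forward_stepwise_select
#' @param priors,ridge Passed to [fit_lda()].
#' @return A `pheno_jackknife` (with an extra `selected_per_fold` list).
#' @export
jackknife_selected <- function(data, y = NULL, features = NULL,
                               alpha_enter = 0.150, alpha_remove = 0.150,
                               max_features = Inf, priors = "equal",
                               ridge = 0) {
  xy <- .resolve_xy(data, y, features)
  x <- xy$x; yy <- xy$y
  n <- nrow(x)
  classes <- levels(yy)
  pred <- character(n)
  sel_list <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    yi <- droplevels(yy[-i])
    st <- forward_stepwise_select(xi, y = yi, alpha_enter = alpha_enter,
                                  alpha_remove = alpha_remove,
                                  max_features = max_features)
    sel_list[[i]] <- st$selected
    if (length(st$selected) == 0) {
      pred[i] <- NA_character_
      next
    }
    fit <- fit_lda(xi, y = yi, features = st$selected, priors = priors,
                   ridge = ridge)
    sc <- .lda_scores(fit, x[i, st$selected, drop = FALSE])
    pred[i] <- fit$classes[max.col(sc, ties.method = "first")]
  }
  counts <- table(factor(yy, levels = classes),
                  factor(pred, levels = classes))
  names(dimnames(counts)) <- c("true", "predicted")
  per_class <- tibble(origin = classes,
                      n = as.integer(rowSums(counts)),
                      n_correct = as.integer(diag(counts))) |>
    dplyr::mutate(pct_correct = 100 * .data$n_correct / .data$n)
  structure(
    list(counts = counts, per_class = per_class,
         overall_correct = 100 * sum(diag(counts)) / n,
         predictions = tibble(line_id = rownames(x) %||%
                                as.character(seq_len(n)),
                              true = as.character(yy), predicted = pred),
         selected_per_fold = sel_list, n = n, priors = priors),
    class = "pheno_jackknife"
  )
}

#' Top-two-score coordinates for every sample
#'
#' The score-plot view: each sample's highest and second-highest
#' classification scores, with its true and predicted class. Samples of
#' one origin cluster together and misassignments sit near the diagonal.
#'
#' @param model A `pheno_lda`.
#' @param data Feature table with `line_id`/`origin` columns.
#' @return A `pheno_scores` tibble: `line_id`, `origin`, `predicted`,
#'   `top_score`, `second_score`.
#' @export
score_plot <- function(model, data) {
  assert_feature_table(data)
  pr <- predict(model, data)
  out <- tibble(line_id = data$line_id, origin = data$origin,
                predicted = pr$.pred,
                top_score = pr$top_score, second_score = pr$second_score)
  class(out) <- c("pheno_scores", class(out))
  out
}

#' Compare probe-family feature pools
#'
#' Runs stepwise selection followed by jackknifed cross-validation on
#' each family's features alone and on the combined pool, the comparison
#' that shows whether scaffold diversity buys classification accuracy
#' (in the published screen: BD alone 90%, RS alone 80%, combined 98%).
#'
#' @inheritParams forward_stepwise_select
#' @param families Named character vector mapping feature name to family;
#'   defaults to the `feature_info` attribute of `data`, else the prefix
#'   of the feature name before the first `-`.
#' @param priors,ridge Passed to [fit_lda()]/[jackknife_classification()].
#' @return A tibble `(pool, pool_size, n_selected, pct_correct, selected)`
#'   with one row per family and one for the combined pool.
#' @export
subset_comparison <- function(data, families = NULL,
                              alpha_enter = 0.150, alpha_remove = 0.150,
                              max_features = Inf, priors = "equal",
                              ridge = 0) {
  assert_feature_table(data)
  feats <- feature_columns(data)
  if (is.null(families)) {
    info <- attr(data, "feature_info")
    families <- if (!is.null(info) && all(feats %in% info$feature)) {
      setNames(info$family[match(feats, info$feature)], feats)
    } else {
      setNames(sub("-.*$", "", feats), feats)
    }
  }
  if (!all(feats %in% names(families)) ||
      any(is.na(families[feats]))) {
    abort("every feature needs a family label")
  }
  fams <- sort(unique(as.character(families[feats])))
  pools <- c(as.list(setNames(fams, fams)), list(combined = fams))
  purrr::imap_dfr(pools, function(members, pool_name) {
    pool_feats <- feats[families[feats] %in% members]
    st <- forward_stepwise_select(data, features = pool_feats,
                                  alpha_enter = alpha_enter,
                                  alpha_remove = alpha_remove,
                                  max_features = max_features)
    pct <- NA_real_
    if (length(st$selected) > 0) {
      jk <- jackknife_classification(data, features = st$selected,
                                     priors = priors, ridge = ridge)
      pct <- jk$overall_correct
    }
    tibble(pool = pool_name, pool_size = length(pool_feats),
           n_selected = length(st$selected), pct_correct = pct,
           selected = list(st$selected))
  })
}
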