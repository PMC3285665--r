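# Independent oracles used across the suite. Each is a deliberately naive
# implementation (explicit loops, closed forms) kept separate from the
# package's own code paths.

# exhaustive Otsu: try every split and score between-class variance by loop
naive_otsu <- function(counts, levels = seq_along(counts) - 1) {
  n <- sum(counts)
  best_t <- NA
  best_v <- -Inf
  for (t in seq_len(length(counts) - 1)) {
    lo <- 1:t
    hi <- (t + 1):length(counts)
    w0 <- sum(counts[lo]); w1 <- sum(counts[hi])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lo] * levels[lo]) / w0
    mu1 <- sum(counts[hi] * levels[hi]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-9) {
      best_v <- v
      best_t <- levels[t]
    }
  }
  best_t
}

# naive O(n^3) UPGMA agglomeration, returns sorted merge heights
naive_average_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  sizes <- rep(1, nrow(d))
  active <- seq_len(nrow(d))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i < j && d[active[i], active[j]] < best_d) {
          best_d <- d[active[i], active[j]]
          best <- c(active[i], active[j])
        }
      }
    }
    heights <- c(heights, best_d)
    a <- best[1]; b <- best[2]
    for (k in setdiff(active, best)) {
      d[a, k] <- d[k, a] <-
        (sizes[a] * d[a, k] + sizes[b] * d[b, k]) / (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  sort(heights)
}

# one-way ANOVA F through base R's linear-model machinery
anova_f <- function(x, y) {
  fit <- stats::anova(stats::lm(x ~ factor(y)))
  c(F = fit$`F value`[1], p = fit$`Pr(>F)`[1])
}

# leave-one-out classification by the Gaussian-density route:
# argmax_k pi_k * N(x; mu_k, S_pooled), an algebraically different
# formulation than the package's linear score functions
naive_loo_predictions <- function(x, y, priors = NULL) {
  y <- factor(y)
  n <- nrow(x)
  preds <- character(n)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    yi <- droplevels(y[-i])
    levs <- levels(yi)
    pr <- if (is.null(priors)) rep(1 / length(levs), length(levs)) else priors
    mus <- lapply(levs, function(l) colMeans(xi[yi == l, , drop = FALSE]))
    Wp <- Reduce(`+`, lapply(levs, function(l) {
      xs <- xi[yi == l, , drop = FALSE]
      crossprod(sweep(xs, 2, colMeans(xs)))
    }))
    S <- Wp / (nrow(xi) - length(levs))
    logd <- vapply(seq_along(levs), function(k) {
      m <- stats::mahalanobis(x[i, , drop = FALSE], mus[[k]], S)
      log(pr[k]) - 0.5 * m
    }, numeric(1))
    preds[i] <- levs[which.max(logd)]
  }
  preds
}

# small random factorial design for property tests
random_small_design <- function() {
  np <- sample(1:4, 1); nl <- sample(2:5, 1)
  tp <- sort(sample(c(1, 6, 24, 48), sample(2:3, 1)))
  if (!1 %in% tp) tp <- c(1, tp)
  if (!48 %in% tp) tp <- c(tp, 48)
  screen_design(
    probe_library(np, sample(0:2, 1)),
    nci60_lines()[seq_len(nl), ],
    concentrations_nM = sample(c(250, 500), sample(1:2, 1)),
    channels = c("FITC", "TRITC")[seq_len(sample(1:2, 1))],
    sites = sample(1:2, 1),
    time_points_h = sort(unique(tp)),
    replicates = sample(1:2, 1)
  )
}

# tiny screen pair used by several image-level tests
tiny_screen <- function(n_probes = 4, n_informative = 2, seed = 11,
                        ...) {
  demo_screen(n_probes = n_probes, n_informative = n_informative,
              seed = seed, ...)
}
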