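#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted LDA model into its score-function coefficients
#'
#' One row per (class, term): the linear coefficient of each selected
#' feature in that class's classification score function, with the
#' constant as term `"(constant)"` — the tabular analog of a published
#' score-function table.
#'
#' @param x A `pheno_lda`.
#' @param ... Unused.
#' @return A tibble `(class, term, estimate)`.
#' @method tidy pheno_lda
#' @export
tidy.pheno_lda <- function(x, ...) {
  coefs <- purrr::map_dfr(seq_along(x$classes), function(k) {
    tibble(class = x$classes[k],
           term = c(x$features, "(constant)"),
           estimate = c(x$coef[, k], x$const[k]))
  })
  coefs
}

#' @rdname tidy.pheno_lda
#' @method glance pheno_lda
#' @export
glance.pheno_lda <- function(x, ...) {
  tibble(n = x$n, n_classes = length(x$classes),
         n_features = length(x$features), ridge = x$ridge)
}

#' Tidy the stepwise selection trace
#'
#' @param x A `pheno_stepwise`.
#' @param ... Unused.
#' @return The per-step trace tibble (`step`, `action`, `feature`,
#'   `lambda`, `statistic`, `p_value`).
#' @method tidy pheno_stepwise
#' @export
tidy.pheno_stepwise <- function(x, ...) x$trace

#' @rdname tidy.pheno_stepwise
#' @method glance pheno_stepwise
#' @export
glance.pheno_stepwise <- function(x, ...) {
  tibble(n_selected = length(x$selected), pool_size = x$pool_size,
         lambda = x$lambda, n = x$n, n_classes = x$g,
         alpha_enter = x$alpha_enter, alpha_remove = x$alpha_remove)
}

#' Tidy a jackknifed classification matrix
#'
#' @param x A `pheno_jackknife`.
#' @param ... Unused.
#' @return Long tibble `(true, predicted, n)` of the confusion counts.
#' @method tidy pheno_jackknife
#' @export
tidy.pheno_jackknife <- function(x, ...) {
  as_tibble(as.data.frame(x$counts, stringsAsFactors = FALSE)) |>
    dplyr::rename(n = "Freq") |>
    dplyr::mutate(dplyr::across(c("true", "predicted"), as.character))
}

#' @rdname tidy.pheno_jackknife
#' @method glance pheno_jackknife
#' @export
glance.pheno_jackknife <- function(x, ...) {
  tibble(overall_correct = x$overall_correct, n = x$n,
         n_classes = nrow(x$counts))
}
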