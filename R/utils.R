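# Internal helpers shared across modules.

# Deterministic sub-seed streams derived from one master seed. Offsets keep
# streams disjoint; record-indexed pixel seeds stay below .Machine$integer.max
# for any screen enumerable at desk scale.
.seed_offsets <- c(baseline = 1e6L, condition = 2e6L, batch = 3e6L,
                   pixel = 4e6L, design = 5e6L)

derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  off <- .seed_offsets[[stream]]
  s <- as.double(seed) + as.double(off) + as.double(index)
  as.integer(s %% 2147483647)
}

# lognormal sdlog for a given coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

# draw multiplicative lognormal factors with mean exactly 1
rlnorm1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- cv_to_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Feature columns of a line-by-feature table
#'
#' The names of the numeric probe-feature columns of a feature matrix —
#' everything except the `line_id`/`origin` metadata.
#'
#' @param data A feature matrix from [build_feature_matrix()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(data) {
  meta <- c("line_id", "origin")
  nm <- setdiff(names(data), meta)
  nm[vapply(data[nm], is.numeric, logical(1))]
}

assert_feature_table <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of lines x features.", call = call)
  }
  if (!all(c("line_id", "origin") %in% names(data))) {
    abort("`data` must have `line_id` and `origin` columns.", call = call)
  }
  if (anyDuplicated(data$line_id) > 0) {
    abort("`line_id` values must be unique.", call = call)
  }
  invisible(data)
}

# feature table -> numeric matrix with line_id rownames
feature_matrix_of <- function(data, features = NULL) {
  assert_feature_table(data)
  features <- features %||% feature_columns(data)
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("Features not present in `data`: ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[features])
  storage.mode(x) <- "double"
  rownames(x) <- data$line_id
  x
}
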