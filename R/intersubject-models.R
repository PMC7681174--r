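#' @title Intersubject dissimilarity models
#' @description
#' An `isrsa_model` holds an n x n symmetric trait-based dissimilarity matrix
#' `d_ij` predicting how dissimilar two subjects' neural response patterns
#' should be, given their trait scores. Four kinds are supported:
#'
#' * `low_alike`  (Anna Karenina): `d_ij = max(s_i, s_j)` -- all low scorers
#'   are alike, each high scorer is different in their own way.
#' * `high_alike` (Anna Karenina): `d_ij = 1 - min(s_i, s_j)` -- the mirror
#'   image.
#' * `nn_abs` (nearest neighbours): `d_ij = |s_i - s_j|` -- similarity is
#'   relative, not absolute.
#' * `nn_euclid`: Euclidean distance between subjects' raw item-wise response
#'   vectors.
#'
#' The scalar kinds operate on scores normalized to the in-sample maximum
#' (see [normalize_scores()]).
#' @name isrsa_model
NULL

new_isrsa_model <- function(matrix, kind, subjects, norm_max = NA_real_) {
  dimnames(matrix) <- NULL
  structure(
    list(matrix = matrix, kind = kind, subjects = subjects,
         norm_max = norm_max),
    class = "isrsa_model"
  )
}

model_kinds <- function() c("low_alike", "high_alike", "nn_abs", "nn_euclid")

#' Build an intersubject dissimilarity model
#'
#' @param x A scored cohort data frame (from [score_cohort()]), a numeric
#'   vector of already-normalized scores in `[0, 1]`, or a subjects x items
#'   numeric matrix of raw item responses (for `kind = "nn_euclid"`).
#' @param kind One of `"low_alike"`, `"high_alike"`, `"nn_abs"`,
#'   `"nn_euclid"`.
#' @param ... Passed to methods.
#' @return An `isrsa_model` (see [isrsa_model]).
#' @examples
#' build_model(c(a = 0.2, b = 0.9), "low_alike")
#' @export
build_model <- function(x, kind, ...) {
  kind <- match.arg(kind, model_kinds())
  UseMethod("build_model")
}

#' @describeIn build_model Scores are taken from column `score_col`
#'   (default `total`) and normalized to the in-sample maximum first;
#'   `nn_euclid` instead uses the raw item vectors in list-column `items`.
#' @param score_col Column holding the summary score (data-frame method).
#' @export
build_model.data.frame <- function(x, kind, score_col = "total", ...) {
  kind <- match.arg(kind, model_kinds())
  subjects <- as.character(x$subject_id)
  if (kind == "nn_euclid") {
    if (!"items" %in% names(x)) {
      stop("nn_euclid needs an `items` list-column of raw responses.",
           call. = FALSE)
    }
    items <- do.call(rbind, x$items)
    rownames(items) <- subjects
    return(build_model(items, kind, ...))
  }
  s <- normalize_scores(x[[score_col]])
  names(s) <- subjects
  build_model.numeric(s, kind)
}

#' @describeIn build_model `x` is a vector of normalized scores (values in
#'   `[0, 1]`); no re-normalization is applied.
#' @export
build_model.numeric <- function(x, kind, ...) {
  kind <- match.arg(kind, model_kinds())
  if (kind == "nn_euclid") {
    stop("nn_euclid needs an item matrix, not scalar scores.", call. = FALSE)
  }
  if (any(is.na(x))) stop("Scores must be complete.", call. = FALSE)
  if (any(x < 0 | x > 1)) {
    stop("Scalar model kinds expect normalized scores in [0, 1]; see ",
         "normalize_scores().", call. = FALSE)
  }
  subjects <- if (is.null(names(x))) paste0("s", seq_along(x)) else names(x)
  d <- switch(kind,
    low_alike = outer(x, x, pmax),
    high_alike = 1 - outer(x, x, pmin),
    nn_abs = abs(outer(x, x, `-`))
  )
  new_isrsa_model(unname(d), kind, subjects,
                  norm_max = attr(x, "norm_max") %||% NA_real_)
}

#' @describeIn build_model `x` is a subjects x items matrix of raw responses
#'   (`nn_euclid` only). Set `normalize_items = TRUE` to rescale each item to
#'   `[0, 1]` before computing distances (sensitivity analysis; off by
#'   default, matching the use of raw responses).
#' @param normalize_items Rescale items by their in-sample maxima first
#'   (matrix method only).
#' @export
build_model.matrix <- function(x, kind, normalize_items = FALSE, ...) {
  kind <- match.arg(kind, model_kinds())
  if (kind != "nn_euclid") {
    stop("Item matrices are only used by kind = 'nn_euclid'.", call. = FALSE)
  }
  if (any(is.na(x))) {
    stop("nn_euclid requires complete item responses (impute first).",
         call. = FALSE)
  }
  if (normalize_items) {
    mx <- apply(x, 2, max)
    mx[mx == 0] <- 1
    x <- sweep(x, 2, mx, `/`)
  }
  subjects <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  new_isrsa_model(unname(d), kind, subjects)
}

#' @export
print.isrsa_model <- function(x, ...) {
  cat("<isrsa_model> kind =", x$kind, "| n =", length(x$subjects),
      "subjects (", n_pairs(length(x$subjects)), "pairs )\n")
  if (!is.na(x$norm_max)) cat("  normalization max:", x$norm_max, "\n")
  invisible(x)
}

#' Strictly-lower-triangle vector of a symmetric matrix
#'
#' Extracts the below-diagonal entries in a fixed column-major order (pair
#' (2,1), (3,1), ..., (n,1), (3,2), ...), identical for every matrix of the
#' same size, so vectors from different matrices align pair-by-pair.
#'
#' @param m Symmetric numeric matrix, or an [isrsa_model] / `neural_rdm`.
#' @param tol Symmetry tolerance (absolute), default `1e-8`.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
lower_triangle <- function(m, tol = 1e-8) {
  m <- as_square_matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop("Matrix is not symmetric within tolerance ", tol, ".", call. = FALSE)
  }
  m[lower.tri(m)]
}

as_square_matrix <- function(m) {
  if (inherits(m, "isrsa_model")) return(m$matrix)
  if (inherits(m, "neural_rdm")) return(m$matrix)
  if (!is.matrix(m)) stop("Expected a matrix.", call. = FALSE)
  m
}

model_subjects <- function(m) {
  if (inherits(m, c("isrsa_model", "neural_rdm"))) m$subjects else
    rownames(as_square_matrix(m))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intersubject model into pairwise long form
#'
#' @param x An [isrsa_model].
#' @param ... Unused.
#' @return Tibble with one row per unordered subject pair: `subject_i`,
#'   `subject_j`, `dissimilarity`, `kind`.
#' @exportS3Method generics::tidy
tidy.isrsa_model <- function(x, ...) {
  n <- length(x$subjects)
  idx <- which(lower.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(
    subject_i = x$subjects[idx[, 1]],
    subject_j = x$subjects[idx[, 2]],
    dissimilarity = x$matrix[idx],
    kind = x$kind
  )
}

#' Write / read an intersubject model matrix
#'
#' The matrix is stored as TSV with subject ids as header row and first
#' column; a JSON sidecar (`<path>.json`) records the model kind, the
#' normalization maximum and a content hash.
#'
#' @param model An [isrsa_model].
#' @param path Output TSV path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the reconstructed [isrsa_model].
#' @export
write_model <- function(model, path) {
  df <- as.data.frame(model$matrix)
  names(df) <- model$subjects
  df <- cbind(subject_id = model$subjects, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    kind = model$kind,
    norm_max = model$norm_max,
    n_subjects = length(model$subjects),
    hash = rlang::hash(model$matrix)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  subjects <- as.character(df$subject_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_isrsa_model(unname(m), sidecar$kind, subjects,
                  norm_max = sidecar$norm_max %||% NA_real_)
}
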