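#' Spearman correspondence between model and neural dissimilarity
#'
#' Spearman rank correlation (average ranks for ties) between the
#' strictly-lower triangles of a trait-based intersubject model and a neural
#' RDM, taken pair-by-pair in the shared subject order.
#'
#' @param model An [isrsa_model] or symmetric matrix.
#' @param neural A `neural_rdm` or symmetric matrix, same subjects in the
#'   same order.
#' @return Spearman rho in `[-1, 1]`.
#' @export
isrsa_correlation <- function(model, neural) {
  check_subject_alignment(model, neural)
  a <- lower_triangle(model)
  b <- lower_triangle(neural)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("Zero variance in a lower-triangle vector; correlation undefined.",
         call. = FALSE)
  }
  stats::cor(a, b, method = "spearman")
}

check_subject_alignment <- function(model, neural) {
  sa <- model_subjects(model)
  sb <- model_subjects(neural)
  if (!is.null(sa) && !is.null(sb)) {
    if (length(sa) != length(sb)) {
      stop("Model and neural matrices have different subject counts (",
           length(sa), " vs ", length(sb), ").", call. = FALSE)
    }
    if (!identical(as.character(sa), as.character(sb))) {
      stop("Model and neural subject orders differ; reorder one first.",
           call. = FALSE)
    }
  } else {
    ma <- as_square_matrix(model); mb <- as_square_matrix(neural)
    if (nrow(ma) != nrow(mb)) {
      stop("Matrices have different sizes.", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Ranks of the lower-triangle entries of a symmetric matrix, written back
# into full symmetric form so that simultaneous row/column permutation of the
# original matrix corresponds to permuting this rank matrix. Valid because a
# joint row/column permutation only re-selects which unordered pairs land in
# the lower triangle -- the multiset of values (hence their ranks) is fixed.
lt_rank_matrix <- function(m) {
  m <- as_square_matrix(m)
  r <- matrix(0, nrow(m), ncol(m))
  r[lower.tri(r)] <- rank(m[lower.tri(m)])
  r + t(r)
}

# m-pairs x B matrix whose column b is the lower triangle of the rank matrix
# under permutation perms[, b].
perm_lt_columns <- function(rank_mat, perms) {
  lt <- lower.tri(rank_mat)
  apply(perms, 2, function(p) rank_mat[p, p][lt])
}

draw_permutations <- function(n, B, seed = NULL) {
  draw <- function() vapply(seq_len(B), function(b) sample.int(n), integer(n))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

all_permutations <- function(n) {
  if (n > 8) stop("Exhaustive enumeration limited to n <= 8.", call. = FALSE)
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]))
    }))
  }
  t(rec(seq_len(n)))  # n x n! matrix, one permutation per column
}

#' Mantel permutation test for model-neural correspondence
#'
#' Tests the Spearman correspondence between an intersubject model and a
#' neural RDM by jointly shuffling the rows and columns (subject labels) of
#' the model matrix and recomputing the correlation `B` times. The p-value is
#' the proportion of permuted statistics strictly exceeding the observed one
#' (for positive observed rho); for negative observed rho the one-sided
#' p-value in the negative direction is reported and the sign flagged
#' (`alternative = "observed_sign"`, the default).
#'
#' @param model,neural As in [isrsa_correlation()].
#' @param B Number of permutations, default 1000. Ignored when
#'   `exhaustive = TRUE`.
#' @param seed RNG seed for the permutation schedule (optional but
#'   recommended; required for reproducibility).
#' @param alternative `"observed_sign"` (default), `"greater"` (strict
#'   exceedances of the observed statistic) or `"less"`.
#' @param exhaustive Enumerate all `n!` label permutations (n <= 8) instead
#'   of sampling.
#' @param add_one Use the smoothed estimator `(r + 1) / (B + 1)` instead of
#'   `r / B`. Off by default: the plain proportion with strict inequality can
#'   attain p = 0.
#' @param perms Optional pre-drawn n x B permutation matrix (one permutation
#'   per column), e.g. to share one schedule across many tests.
#' @return An `isrsa_mantel` object: `rho`, `p`, `B`, `sign`, `seed`,
#'   `alternative`, and the permutation null `null_rho`.
#' @export
mantel_test <- function(model, neural, B = 1000, seed = NULL,
                        alternative = c("observed_sign", "greater", "less"),
                        exhaustive = FALSE, add_one = FALSE, perms = NULL) {
  alternative <- match.arg(alternative)
  check_subject_alignment(model, neural)
  mm <- as_square_matrix(model)
  nm <- as_square_matrix(neural)
  n <- nrow(mm)
  if (n < 4) stop("Mantel test needs n >= 4 subjects.", call. = FALSE)

  a <- lower_triangle(nm)
  b <- lower_triangle(mm)
  ra <- rank(a); rb <- rank(b)
  sa <- stats::sd(ra); sb <- stats::sd(rb)
  if (sa == 0 || sb == 0) {
    stop("Zero variance in a lower-triangle vector; Mantel test undefined.",
         call. = FALSE)
  }
  m <- length(a)
  ac <- ra - mean(ra)
  rho_obs <- sum(ac * rb) / ((m - 1) * sa * sb)

  if (exhaustive) {
    perms <- all_permutations(n)
    B <- ncol(perms)
  } else if (is.null(perms)) {
    if (B < 1) stop("B must be >= 1.", call. = FALSE)
    perms <- draw_permutations(n, B, seed)
  } else {
    stopifnot(nrow(perms) == n)
    B <- ncol(perms)
  }

  rank_mat <- lt_rank_matrix(mm)
  cols <- perm_lt_columns(rank_mat, perms)
  null_rho <- as.vector(crossprod(cols, ac)) / ((m - 1) * sa * sb)

  sign_obs <- if (rho_obs < 0) -1L else 1L
  count <- switch(alternative,
    greater = sum(null_rho > rho_obs),
    less = sum(null_rho < rho_obs),
    observed_sign = if (sign_obs < 0) sum(null_rho < rho_obs)
                    else sum(null_rho > rho_obs)
  )
  p <- if (add_one) (count + 1) / (B + 1) else count / B

  structure(
    list(rho = rho_obs, p = p, B = B, sign = sign_obs, seed = seed,
         alternative = alternative, exhaustive = exhaustive,
         add_one = add_one, null_rho = null_rho),
    class = "isrsa_mantel"
  )
}

#' @export
print.isrsa_mantel <- function(x, ...) {
  cat(sprintf("<isrsa_mantel> rho = %.4f, p = %.4g (%s, B = %d%s)\n",
              x$rho, x$p, x$alternative, x$B,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' @rdname mantel_test
#' @param x An `isrsa_mantel` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.isrsa_mantel <- function(x, ...) {
  tibble::tibble(estimate = x$rho, p.value = x$p, sign = x$sign,
                 B = x$B, alternative = x$alternative)
}

#' @rdname mantel_test
#' @exportS3Method generics::glance
glance.isrsa_mantel <- function(x, ...) {
  tibble::tibble(B = x$B, exhaustive = x$exhaustive, add_one = x$add_one,
                 null_mean = mean(x$null_rho), null_sd = stats::sd(x$null_rho))
}

#' Partial Spearman correlation controlling for covariates
#'
#' Rank-transforms `x`, `y` and each covariate (average ranks), residualizes
#' the ranked `x` and `y` on the ranked covariates plus an intercept by least
#' squares, and correlates the residuals. The two-sided p-value uses the
#' t approximation with `n - 2 - k` degrees of freedom (`k` covariates), the
#' usual ROI-analysis statistic for trait-activation associations.
#'
#' @param data A data frame (data-frame method) or numeric vector of `x`
#'   values (default method).
#' @param ... Passed to methods.
#' @return One-row tibble: `estimate` (partial rho), `statistic` (t), `df`,
#'   `p.value`, `n`.
#' @examples
#' d <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20))
#' partial_spearman(d, x, y, c(z))
#' @export
partial_spearman <- function(data, ...) UseMethod("partial_spearman")

#' @describeIn partial_spearman Columns are selected with tidy evaluation:
#'   `partial_spearman(df, callousness, amygdala, c(age, gender, iq))`.
#' @param x,y Column names (unquoted) of the two variables to correlate.
#' @param covariates Columns (unquoted, wrapped in `c()`) to control for.
#' @export
partial_spearman.data.frame <- function(data, x, y, covariates, ...) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  cv <- as.matrix(dplyr::select(data, {{ covariates }}))
  partial_spearman.default(xv, yv, cv)
}

#' @describeIn partial_spearman `data` and `y` are numeric vectors,
#'   `covariates` a numeric matrix with one column per covariate.
#' @export
partial_spearman.default <- function(data, y, covariates, ...) {
  x <- as.numeric(data)
  y <- as.numeric(y)
  covariates <- as.matrix(covariates)
  n <- length(x)
  k <- ncol(covariates)
  stopifnot(length(y) == n, nrow(covariates) == n)
  if (anyNA(x) || anyNA(y) || anyNA(covariates)) {
    stop("Missing values are not supported.", call. = FALSE)
  }
  if (n <= k + 2) {
    stop("Need n > number of covariates + 2 (have n = ", n, ", k = ", k, ").",
         call. = FALSE)
  }
  Q <- cbind(1, apply(covariates, 2, rank))
  if (qr(Q)$rank < ncol(Q)) {
    stop("Rank-deficient covariate matrix.", call. = FALSE)
  }
  rx <- stats::lm.fit(Q, rank(x))$residuals
  ry <- stats::lm.fit(Q, rank(y))$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("Residual variance is zero; partial correlation undefined.",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    estimate = r,
    statistic = tstat,
    df = df,
    p.value = 2 * stats::pt(-abs(tstat), df),
    n = n
  )
}
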