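# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: ranks by explicit sorting, correlations from first
# principles, permutations by recursive enumeration.

rank_oracle <- function(x) {
  # average ranks via explicit tie groups
  out <- numeric(length(x))
  ord <- order(x)
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    out[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  out
}

pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

spearman_oracle <- function(a, b) pearson_oracle(rank_oracle(a), rank_oracle(b))

lower_triangle_oracle <- function(m) {
  n <- nrow(m)
  out <- numeric(0)
  for (j in seq_len(n - 1)) {
    for (i in (j + 1):n) out <- c(out, m[i, j])
  }
  out
}

perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  sub <- perms_oracle(n - 1)
  out <- list()
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (p in sub) out[[length(out) + 1]] <- c(k, rest[p])
  }
  out
}

mantel_exhaustive_oracle <- function(model_mat, neural_mat) {
  obs <- spearman_oracle(lower_triangle_oracle(model_mat),
                         lower_triangle_oracle(neural_mat))
  ps <- perms_oracle(nrow(model_mat))
  null <- vapply(ps, function(p) {
    spearman_oracle(lower_triangle_oracle(model_mat[p, p]),
                    lower_triangle_oracle(neural_mat))
  }, numeric(1))
  list(rho = obs, null = null,
       p_greater = sum(null > obs) / length(null),
       p_less = sum(null < obs) / length(null))
}

bh_oracle <- function(p, q) {
  # step-up: largest k with p_(k) <= k/m * q; reject the k smallest
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

knn_oracle <- function(coords, pixdim, center_row, V) {
  # exhaustive distance sort with (x, y, z) tie-break
  mm <- sweep(coords - 1, 2, pixdim, `*`)
  d <- sqrt(colSums((t(mm) - mm[center_row, ])^2))
  ord <- order(d, coords[, 1], coords[, 2], coords[, 3])
  ord[seq_len(V)]
}

partial_spearman_oracle <- function(x, y, covs) {
  # residualize ranked x and y on ranked covariates via normal equations
  n <- length(x)
  Q <- cbind(rep(1, n), apply(covs, 2, rank_oracle))
  beta_x <- solve(t(Q) %*% Q, t(Q) %*% rank_oracle(x))
  beta_y <- solve(t(Q) %*% Q, t(Q) %*% rank_oracle(y))
  rx <- rank_oracle(x) - Q %*% beta_x
  ry <- rank_oracle(y) - Q %*% beta_y
  pearson_oracle(as.numeric(rx), as.numeric(ry))
}

random_symmetric <- function(n, zero_diag = TRUE) {
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- m + t(m)
  if (zero_diag) diag(m) <- 0
  m
}

# small random RDM from random patterns (always a valid dissimilarity)
random_rdm <- function(n, n_vox = 20) {
  X <- matrix(stats::rnorm(n_vox * n), n_vox, n)
  d <- 1 - stats::cor(apply(X, 2, rank))
  diag(d) <- 0
  d
}

tiny_subscales <- function() {
  list(callous = c(1L, 2L), uncaring = 3L, unemotional = 4L)
}

tiny_scored <- function() {
  score_cohort(tiny_cohort_table(), subscale_map = tiny_subscales())
}

tiny_cohort_table <- function() {
  # three subjects, 4 items, hand-constructed to exercise the rules
  tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    informant = rep(c("child", "parent"), 3),
    item_1 = c("2", "1", "", "3", "0", "0"),
    item_2 = c("1", "1", "2", "", "0|1", "0"),
    item_3 = c("0", "2", "", "", "3", "3"),
    item_4 = c("3", "0", "1", "1", "2", "2"),
    age = rep(c(12, 14, 16), each = 2),
    gender = rep(c(0L, 1L, 0L), each = 2),
    iq = rep(c(100, 110, 95), each = 2)
  )
}
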