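test_that("model-neural correspondence is a rank correlation of triangles", {
  set.seed(2)
  m <- random_rdm(8)
  expect_equal(isrsa_correlation(m, m), 1)

  # rank reversal of an all-distinct symmetric matrix
  m2 <- abs(random_symmetric(8))
  v <- lower_triangle(m2)
  expect_equal(length(unique(v)), length(v))
  rev_m <- matrix(0, 8, 8)
  rev_m[lower.tri(rev_m)] <- max(v) - v
  rev_m <- rev_m + t(rev_m)
  expect_equal(isrsa_correlation(m2, rev_m), -1)

  a <- random_rdm(10, 30); b <- random_rdm(10, 30)
  expect_equal(isrsa_correlation(a, b),
               spearman_oracle(lower_triangle_oracle(a),
                               lower_triangle_oracle(b)))

  expect_error(isrsa_correlation(matrix(1, 5, 5), random_rdm(5)),
               "Zero variance")
})

test_that("subject order mismatches are refused", {
  sc <- tiny_scored()
  model <- build_model(sc, "low_alike")
  betas <- beta_set(array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3)),
                    subjects = c("b", "a", "c"))
  rdm <- pattern_rdm(betas, cbind(1:4, 1, 1))
  expect_error(isrsa_correlation(model, rdm), "subject order")
  expect_error(mantel_test(model, rdm), "subject order")
})

test_that("perfect correspondence yields p = 0 under strict exceedance", {
  set.seed(7)
  m <- random_rdm(10, 50)
  expect_equal(length(unique(lower_triangle(m))), 45)
  res <- mantel_test(m, m, B = 1000, seed = 1)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 0)   # no permutation can strictly exceed rho = 1
  expect_equal(res$sign, 1L)
  # p lives on the grid {0, 1/B, ..., 1}
  expect_true(res$p * res$B == round(res$p * res$B))
})

test_that("fast permutation path equals direct recomputation", {
  set.seed(19)
  model <- random_rdm(9, 25)
  neural <- random_rdm(9, 25)
  perms <- matrix(replicate(50, sample.int(9)), nrow = 9)
  res <- mantel_test(model, neural, perms = perms)
  direct <- apply(perms, 2, function(p) {
    spearman_oracle(lower_triangle_oracle(model[p, p]),
                    lower_triangle_oracle(neural))
  })
  expect_equal(res$null_rho, direct, tolerance = 1e-12)
})

test_that("exhaustive mode matches the enumeration oracle at n = 5", {
  set.seed(23)
  model <- random_rdm(5, 12)
  neural <- random_rdm(5, 12)
  res <- mantel_test(model, neural, exhaustive = TRUE,
                     alternative = "greater")
  oracle <- mantel_exhaustive_oracle(model, neural)
  expect_equal(res$B, 120)
  expect_equal(res$rho, oracle$rho)
  expect_equal(sort(res$null_rho), sort(oracle$null), tolerance = 1e-12)
  expect_equal(res$p, oracle$p_greater)
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  set.seed(29)
  model <- random_rdm(5, 15)
  neural <- random_rdm(5, 15)
  exact <- mantel_test(model, neural, exhaustive = TRUE,
                       alternative = "greater")$p
  mc <- mantel_test(model, neural, B = 10000, seed = 101,
                    alternative = "greater")$p
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc - exact), max(3 * se, 1e-6))
})

test_that("Mantel p is invariant to a shared subject relabeling", {
  set.seed(41)
  model <- random_rdm(6, 30)
  neural <- random_rdm(6, 30)
  p <- sample(6)
  # exhaustive mode: the null is the full permutation multiset, which is
  # exactly invariant under a joint relabeling of both matrices
  r1 <- mantel_test(model, neural, exhaustive = TRUE)
  r2 <- mantel_test(model[p, p], neural[p, p], exhaustive = TRUE)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(sort(r1$null_rho), sort(r2$null_rho), tolerance = 1e-10)
  expect_equal(r1$p, r2$p)
  # determinism
  expect_identical(mantel_test(model, neural, B = 200, seed = 9)$null_rho,
                   mantel_test(model, neural, B = 200, seed = 9)$null_rho)
})

test_that("negative correspondence reports a one-sided p with its sign", {
  set.seed(43)
  m <- random_rdm(10, 40)
  v <- lower_triangle(m)
  rev_m <- matrix(0, 10, 10)
  rev_m[lower.tri(rev_m)] <- max(v) - v
  rev_m <- rev_m + t(rev_m)
  res <- mantel_test(m, rev_m, B = 500, seed = 2)
  expect_equal(res$rho, -1)
  expect_equal(res$sign, -1L)
  expect_equal(res$p, 0)   # nothing is strictly below rho = -1
  # add-one smoothing shifts the grid
  res2 <- mantel_test(m, rev_m, B = 500, seed = 2, add_one = TRUE)
  expect_equal(res2$p, 1 / 501)
})

test_that("tidiers expose the statistic and the null summary", {
  set.seed(3)
  res <- mantel_test(random_rdm(6), random_rdm(6), B = 50, seed = 1)
  td <- generics::tidy(res)
  expect_named(td, c("estimate", "p.value", "sign", "B", "alternative"))
  gl <- generics::glance(res)
  expect_equal(gl$B, 50)
})

test_that("partial Spearman matches the residualize-then-correlate oracle", {
  set.seed(57)
  n <- 25
  covs <- cbind(age = runif(n, 10, 17), gender = rbinom(n, 1, 0.5),
                iq = rnorm(n, 100, 15))
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  res <- partial_spearman(x, y, covs)
  expect_equal(res$estimate, partial_spearman_oracle(x, y, covs),
               tolerance = 1e-12)
  expect_equal(res$df, n - 2 - 3)
  # t-based two-sided p recomputed directly
  tt <- res$estimate * sqrt(res$df / (1 - res$estimate^2))
  expect_equal(res$p.value, 2 * pt(-abs(tt), res$df))

  # y = x with independent covariates: near-perfect partial correlation
  r2 <- partial_spearman(x, x + 1e-9 * rnorm(n), covs)
  expect_gt(r2$estimate, 0.99)

  # the data-frame interface selects columns tidily
  df <- tibble::tibble(x = x, y = y, age = covs[, 1], gender = covs[, 2],
                       iq = covs[, 3])
  res_df <- partial_spearman(df, x, y, c(age, gender, iq))
  expect_equal(res_df, res)

  expect_error(partial_spearman(x, y, cbind(covs[, 1], covs[, 1])),
               "Rank-deficient")
  expect_error(partial_spearman(x[1:4], y[1:4], covs[1:4, ]), "covariates")
})

test_that("a covariate-driven response has near-zero partial correlation", {
  set.seed(71)
  reps <- 200
  est <- replicate(reps, {
    z <- rnorm(20)
    x <- rnorm(20)
    y <- z  # entirely determined by the covariate
    partial_spearman(x, y, cbind(z, rnorm(20)))$estimate
  })
  expect_lt(abs(mean(est)), 0.05)
})
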