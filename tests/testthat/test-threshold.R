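make_map <- function(dims = c(12, 12, 10), rho = NULL, p = NULL,
                     condition = "baseline", kind = "low_alike") {
  structure(
    list(rho = rho %||% array(NA_real_, dims),
         p = p %||% array(NA_real_, dims),
         dim = dims, pixdim = c(3, 3, 3), origin = c(0, 0, 0),
         condition = condition, model_kind = kind, B = 1000, seed = 1,
         alternative = "observed_sign",
         failures = tibble::tibble()),
    class = "searchlight_map"
  )
}

test_that("only the contiguous blob survives the extent threshold", {
  dims <- c(12, 12, 10)
  rho <- array(NA_real_, dims)
  p <- array(NA_real_, dims)
  # background of defined but null centers
  rho[2:11, 2:11, 2:9] <- 0.01
  p[2:11, 2:11, 2:9] <- 0.8
  # one 15-voxel contiguous blob at p = .001 ...
  blob <- as.matrix(expand.grid(x = 3:5, y = 3:7, z = 3))
  for (r in seq_len(nrow(blob))) {
    rho[blob[r, 1], blob[r, 2], blob[r, 3]] <- 0.4
    p[blob[r, 1], blob[r, 2], blob[r, 3]] <- 0.001
  }
  # ... plus 5 isolated significant voxels
  iso <- cbind(c(9, 9, 9, 10, 10), c(9, 2, 5, 7, 3), c(8, 2, 6, 2, 8))
  for (r in 1:5) {
    rho[iso[r, 1], iso[r, 2], iso[r, 3]] <- 0.5
    p[iso[r, 1], iso[r, 2], iso[r, 3]] <- 0.001
  }
  m <- make_map(dims, rho, p)
  ct <- threshold_map(m, p_cluster_forming = 0.005, k_min = 10)
  expect_equal(sum(ct$survives_extent), 1)
  big <- ct[ct$survives_extent, ]
  expect_equal(big$k, 15)
  expect_equal(big$sign, "positive")
  expect_equal(big$peak_rho, 0.4)
  # peak mm coordinate is (index - 1) * 3mm
  expect_true(big$peak_mm_x %in% ((3:5 - 1) * 3))
})

test_that("an all-null map yields an empty cluster table", {
  dims <- c(6, 6, 6)
  rho <- array(0.1, dims)
  p <- array(1, dims)
  ct <- threshold_map(make_map(dims, rho, p))
  expect_equal(nrow(ct), 0)
  expect_error(threshold_map(make_map(dims)), "no defined centers")
})

test_that("positive and negative clusters are split by sign", {
  dims <- c(10, 10, 6)
  rho <- array(NA_real_, dims); p <- array(NA_real_, dims)
  rho[2:9, 2:9, 2:5] <- 0; p[2:9, 2:9, 2:5] <- 0.9
  rho[2:4, 2:4, 3] <- 0.3; p[2:4, 2:4, 3] <- 0.001
  rho[6:8, 6:8, 3] <- -0.3; p[6:8, 6:8, 3] <- 0.002
  ct <- threshold_map(make_map(dims, rho, p), k_min = 5)
  expect_setequal(ct$sign, c("positive", "negative"))
  expect_equal(ct$k, c(9, 9))
  # a bridging voxel joins its own sign's cluster but never the other's
  rho[5, 5, 3] <- 0.3; p[5, 5, 3] <- 0.001
  ct2 <- threshold_map(make_map(dims, rho, p), k_min = 5)
  expect_equal(nrow(ct2), 2)
  expect_equal(ct2$k[ct2$sign == "positive"], 10)
  expect_equal(ct2$k[ct2$sign == "negative"], 9)
})

test_that("FDR survival matches the independent step-up oracle", {
  set.seed(77)
  for (rep in 1:5) {
    dims <- c(8, 8, 6)
    p <- array(NA_real_, dims)
    rho <- array(NA_real_, dims)
    defined <- runif(prod(dims)) < 0.6
    p[defined] <- rbeta(sum(defined), 0.3, 1)  # enriched small p
    rho[defined] <- rnorm(sum(defined))
    m <- make_map(dims, rho, p)
    ct <- threshold_map(m, p_cluster_forming = 0.05, k_min = 1, q = 0.05,
                        connectivity = 6)
    rej <- bh_oracle(p[!is.na(p)], 0.05)
    p_rej <- sort(p[!is.na(p)][rej])
    for (r in seq_len(nrow(ct))) {
      vx <- ct$voxels[[r]]
      member_p <- p[cbind(vx[, 1], vx[, 2], vx[, 3])]
      expect_equal(ct$survives_fdr[r], any(member_p %in% p_rej))
    }
  }
})

test_that("cluster extents are stable under connectivity conventions", {
  dims <- c(8, 8, 4)
  rho <- array(NA_real_, dims); p <- array(NA_real_, dims)
  rho[, , ] <- 0; p[, , ] <- 0.9
  # two voxels touching only at an edge (dx = dy = 1)
  for (v in list(c(3, 3, 2), c(4, 4, 2))) {
    rho[v[1], v[2], v[3]] <- 0.3; p[v[1], v[2], v[3]] <- 0.001
  }
  m <- make_map(dims, rho, p)
  expect_equal(nrow(threshold_map(m, connectivity = 6, k_min = 1)), 2)
  expect_equal(nrow(threshold_map(m, connectivity = 18, k_min = 1)), 1)
  # corner-touching voxels merge only at 26
  rho[3, 3, 2] <- 0.3
  rho2 <- array(NA_real_, dims); p2 <- array(NA_real_, dims)
  rho2[, , ] <- 0; p2[, , ] <- 0.9
  for (v in list(c(3, 3, 2), c(4, 4, 3))) {
    rho2[v[1], v[2], v[3]] <- 0.3; p2[v[1], v[2], v[3]] <- 0.001
  }
  m2 <- make_map(dims, rho2, p2)
  expect_equal(nrow(threshold_map(m2, connectivity = 18, k_min = 1)), 2)
  expect_equal(nrow(threshold_map(m2, connectivity = 26, k_min = 1)), 1)
})

test_that("component labeling is invariant to voxel ordering", {
  set.seed(5)
  dims <- c(10, 10, 8)
  coords <- unique(cbind(sample(1:10, 60, TRUE), sample(1:10, 60, TRUE),
                         sample(1:8, 60, TRUE)))
  l1 <- isrsa:::label_components(coords, dims, 18)
  shuf <- sample(nrow(coords))
  l2 <- isrsa:::label_components(coords[shuf, ], dims, 18)
  # same partition regardless of labeling order
  expect_equal(outer(l1[shuf], l1[shuf], `==`), outer(l2, l2, `==`))
})

test_that("map comparison uses the common defined centers only", {
  dims <- c(6, 6, 4)
  rho_a <- array(NA_real_, dims)
  set.seed(8)
  rho_a[2:5, 2:5, 2:3] <- rnorm(32)
  a <- make_map(dims, rho_a, rho_a * 0 + 0.5)
  expect_equal(compare_maps(a, a), 1)
  # partially overlapping defined sets
  rho_b <- array(NA_real_, dims)
  rho_b[3:6, 2:5, 2:3] <- rnorm(32)
  b <- make_map(dims, rho_b, rho_b * 0 + 0.5)
  both <- !is.na(rho_a) & !is.na(rho_b)
  expect_equal(compare_maps(a, b),
               spearman_oracle(rho_a[both], rho_b[both]))
  expect_equal(compare_maps(a, b), compare_maps(b, a))
  # disjoint defined sets
  rho_c <- array(NA_real_, dims)
  rho_c[1, 1, 1] <- 1
  expect_error(compare_maps(a, make_map(dims, rho_c, rho_c)), "Fewer than 3")
})
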