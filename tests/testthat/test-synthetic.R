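test_that("cohort generation is deterministic and respects its config", {
  a <- simulate_cohort(seed = 5)
  b <- simulate_cohort(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(seed = 6)))

  expect_equal(nrow(a), 2 * 37)
  expect_setequal(unique(a$informant), c("child", "parent"))
  expect_true(all(a$age >= 10 & a$age <= 17))
  expect_true(all(a$gender %in% 0:1))
  expect_equal(sum(a$motion_excluded) / 2, 4)
  expect_equal(sum(a$attention_excluded) / 2, 3)

  sc <- score_cohort(a)
  expect_equal(nrow(sc), 30)
  expect_equal(n_pairs(nrow(sc)), 435L)
  man <- cohort_manifest(sc)
  expect_equal(man$n_enrolled - man$n_motion_excluded -
                 man$n_attention_excluded, 30)

  expect_error(simulate_cohort(n_enrolled = 6, n_motion_excluded = 4,
                               n_attention_excluded = 3), "no analyzable")
  expect_error(simulate_cohort(missing_rate = 0.9), "Infeasible")
})

test_that("perfectly correlated informants give identical responses", {
  coh <- simulate_cohort(informant_r = 1, missing_rate = 0,
                         both_missing_rate = 0, multimark_rate = 0, seed = 8)
  items <- grep("^item_", names(coh), value = TRUE)
  child <- coh[coh$informant == "child", items]
  parent <- coh[coh$informant == "parent", items]
  expect_identical(child, parent)
})

test_that("wider latent traits spread the score distribution", {
  tot_var <- function(sd_t) {
    v <- vapply(1:6, function(s) {
      var(score_cohort(simulate_cohort(trait_sd = sd_t, seed = s))$total)
    }, numeric(1))
    mean(v)
  }
  expect_gt(tot_var(2), tot_var(0.3))
})

test_that("task metadata reproduces run-level volume and block counts", {
  meta <- task_metadata()
  base <- meta$runs[meta$runs$type == "baseline", ]
  expect_equal(unique(base$n_volumes), 72L)  # 3 min at TR 2.5 s
  expect_equal(nrow(base), 2)
  ctx <- meta$runs[meta$runs$type == "context", ]
  expect_equal(unique(ctx$n_volumes), 102L)
  expect_equal(nrow(ctx), 4)
  expect_equal(meta$contextualized_blocks_per_run, 6L)  # 3 contexts x 2
  expect_equal(unique(ctx$n_face_blocks), 6L)

  path <- file.path(withr::local_tempdir(), "task.json")
  write_task_manifest(meta, path)
  rt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rt$runs$n_volumes[rt$runs$type == "baseline"], c(72L, 72L))
  expect_equal(rt$contextualized_blocks_per_run, 6L)
})

test_that("the default mask and planted regions are consistent", {
  mask <- simulate_mask()
  expect_gt(sum(mask), 1500)
  expect_lt(sum(mask), 2500)
  pl <- default_planted_regions(mask)
  expect_equal(nrow(pl), 3)
  expect_setequal(pl$kind, c("low_alike", "high_alike", "nn"))
  for (vx in pl$voxels) {
    expect_equal(nrow(vx), 64)
    expect_true(all(mask[vx]))
  }
  # pairwise disjoint
  lins <- lapply(pl$voxels, isrsa:::coords_to_linear, dims = dim(mask))
  expect_equal(length(unique(unlist(lins))), 3 * 64)
  # a region outside the mask is refused
  bad <- tibble::tibble(kind = "nn",
                        voxels = list(cbind(1L, 1L, 1L)))
  expect_error(isrsa:::check_planted_regions(bad, mask), "outside the mask")
})

test_that("beta generation is deterministic and masks non-finite voxels", {
  sc <- score_cohort(simulate_cohort(seed = 3))
  mask <- simulate_mask(c(9, 9, 8))
  pl <- tibble::tibble(kind = "high_alike",
                       voxels = list(as.matrix(expand.grid(3:5, 3:5, 3:5))))
  b1 <- simulate_betas(sc, mask, pl, conditions = "baseline", seed = 4)
  b2 <- simulate_betas(sc, mask, pl, conditions = "baseline", seed = 4)
  expect_identical(b1$baseline$data, b2$baseline$data)

  dat <- b1$baseline$data
  for (k in seq_len(dim(dat)[4])) {
    vol <- dat[, , , k]
    expect_true(all(is.finite(vol[mask])))
    expect_true(all(is.na(vol[!mask])))
  }
  expect_identical(b1$baseline$subjects, sc$subject_id)
  expect_error(simulate_betas(sc, mask, pl, w = 1.5), "\\[0, 1\\]")
})

test_that("planted structure appears in its region and nowhere else", {
  sc <- score_cohort(simulate_cohort(seed = 21))
  mask <- simulate_mask(c(11, 11, 9))
  region <- as.matrix(expand.grid(4:7, 4:7, 4:6))
  pl <- tibble::tibble(kind = "low_alike", voxels = list(region))
  betas <- simulate_betas(sc, mask, pl, w = 0.9,
                          conditions = "afraid_for_you", seed = 22)[[1]]
  model <- build_model(sc, "low_alike")
  rdm_in <- pattern_rdm(betas, region)
  rho_in <- isrsa_correlation(model, rdm_in)
  # a matched-size voxel set away from the plant
  outside <- as.matrix(expand.grid(8:11, 1:4, 1:3))
  outside <- outside[mask[outside], , drop = FALSE]
  rdm_out <- pattern_rdm(betas, outside)
  rho_out <- isrsa_correlation(model, rdm_out)
  expect_gt(rho_in, 0.25)
  expect_lt(abs(rho_out), 0.25)
})

test_that("effect weight monotonically strengthens recovered correspondence", {
  sc <- score_cohort(simulate_cohort(seed = 31))
  mask <- simulate_mask(c(9, 9, 8))
  region <- as.matrix(expand.grid(3:6, 3:6, 3:5))
  model <- build_model(sc, "high_alike")
  mean_rho <- vapply(c(0, 0.5, 1), function(w) {
    rhos <- vapply(1:4, function(s) {
      pl <- tibble::tibble(kind = "high_alike", voxels = list(region), w = w)
      b <- simulate_betas(sc, mask, pl, conditions = "baseline",
                          seed = 100 + s)[[1]]
      isrsa_correlation(model, pattern_rdm(b, region))
    }, numeric(1))
    mean(rhos)
  }, numeric(1))
  expect_true(all(diff(mean_rho) > 0))
  expect_lt(abs(mean_rho[1]), 0.2)  # w = 0 is null
})

test_that("degenerate planting with identical loadings breaks correlation", {
  # all subjects share the same loading -> expected RDM constant at high w
  sc <- score_cohort(simulate_cohort(seed = 41))
  sc$total <- rep(60, nrow(sc))  # constant scores
  expect_error(build_model(sc, "nn_abs") |> isrsa_correlation(random_rdm(30)),
               "Zero variance|constant")
})

test_that("smoothed noise keeps unit scale and stays deterministic", {
  sc <- score_cohort(simulate_cohort(seed = 51))
  mask <- simulate_mask(c(9, 9, 8))
  b <- simulate_betas(sc, mask, planted = NULL, smooth_fwhm_vox = 2,
                      conditions = "baseline", seed = 52)[[1]]
  vals <- matrix(b$data[rep(mask, dim(b$data)[4])], ncol = dim(b$data)[4])
  expect_equal(apply(vals, 2, sd), rep(1, ncol(vals)), tolerance = 1e-8)
  b2 <- simulate_betas(sc, mask, planted = NULL, smooth_fwhm_vox = 2,
                       conditions = "baseline", seed = 52)[[1]]
  expect_identical(b$data, b2$data)
})
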