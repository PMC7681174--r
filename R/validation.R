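#' Null calibration of the Mantel test
#'
#' Repeatedly tests a fixed trait model against independent pure-noise
#' neural RDMs and records the permutation p-value, to verify that the
#' test's rejection rate at a nominal level matches that level.
#'
#' @param n_reps Number of null replicates, default 500.
#' @param n Subjects per replicate, default 30.
#' @param n_vox Voxels per simulated pattern, default 100.
#' @param B Permutations per test, default 200.
#' @param kind Model kind for the fixed trait model.
#' @param seed RNG seed.
#' @return Tibble with one row per replicate: `rep`, `rho`, `p`.
#' @export
validate_mantel_null <- function(n_reps = 500, n = 30, n_vox = 100, B = 200,
                                 kind = "high_alike", seed = 1) {
  withr::with_seed(seed, {
    scored <- score_cohort(simulate_cohort(
      n_enrolled = n + 7, seed = sample.int(1e6, 1)))
    stopifnot(nrow(scored) == n)
    model <- build_model(scored, kind)
    rows <- lapply(seq_len(n_reps), function(r) {
      X <- matrix(stats::rnorm(n_vox * n), n_vox, n)
      rdm <- 1 - stats::cor(apply(X, 2, rank))
      diag(rdm) <- 0
      res <- mantel_test(model, rdm, B = B, alternative = "greater")
      tibble::tibble(rep = r, rho = res$rho, p = res$p)
    })
    dplyr::bind_rows(rows)
  })
}

#' Planted-region recovery experiment
#'
#' Simulates a cohort and beta maps with one region planted per model kind
#' (`low_alike`, `high_alike`, `nn`), runs the searchlight analysis for the
#' three corresponding trait models, thresholds each map, and scores whether
#' each planted region is recovered by each model's map. A region counts as
#' recovered when some positive-sign cluster covers at least
#' `overlap_frac` of its voxels.
#'
#' Correct behaviour is selective recovery: each model recovers its own
#' region and not the other models' regions.
#'
#' @param n_seeds Number of independent replicates, default 20.
#' @param w Planted effect weight, default 0.8.
#' @param B Permutations per searchlight, default 200.
#' @param V Searchlight size, default 100.
#' @param mask Analysis mask, default [simulate_mask()] (~1900 voxels).
#' @param p_cluster_forming,k_min,q Thresholding parameters (defaults .005,
#'   10, .05).
#' @param overlap_frac Required fractional overlap, default 0.5.
#' @param seed Base RNG seed; replicate r uses `seed + r` offsets.
#' @return Tibble with one row per replicate x map-model x planted region:
#'   `seed_rep`, `model`, `region`, `overlap` (voxel fraction), `recovered`.
#' @export
validate_recovery <- function(n_seeds = 20, w = 0.8, B = 200, V = 100,
                              mask = simulate_mask(),
                              p_cluster_forming = 0.005, k_min = 10,
                              q = 0.05, overlap_frac = 0.5, seed = 1) {
  planted <- default_planted_regions(mask)
  planted$w <- w
  searchlights <- build_searchlights(mask, V = V)
  map_models <- c(low_alike = "low_alike", high_alike = "high_alike",
                  nn = "nn_abs")
  region_lin <- lapply(planted$voxels, coords_to_linear, dims = dim(mask))
  names(region_lin) <- planted$kind

  rows <- list()
  for (r in seq_len(n_seeds)) {
    scored <- score_cohort(simulate_cohort(seed = seed + 1000L * r))
    betas <- simulate_betas(scored, mask, planted, w = w,
                            conditions = "afraid_for_you",
                            seed = seed + 1000L * r + 1L)[[1]]
    models <- lapply(map_models, function(k) build_model(scored, k))
    maps <- searchlight_isrsa(betas, models, searchlights, B = B,
                              seed = seed + 1000L * r + 2L)
    for (mk in names(map_models)) {
      clusters <- threshold_map(maps[[mk]], p_cluster_forming, k_min, q)
      pos <- clusters[clusters$sign == "positive" & clusters$survives_extent,
                      , drop = FALSE]
      cluster_lin <- lapply(pos$voxels, coords_to_linear, dims = dim(mask))
      for (rg in names(region_lin)) {
        target <- region_lin[[rg]]
        overlap <- if (length(cluster_lin) == 0) 0 else
          max(vapply(cluster_lin, function(cl) {
            length(intersect(cl, target)) / length(target)
          }, numeric(1)))
        rows[[length(rows) + 1]] <- tibble::tibble(
          seed_rep = r, model = mk, region = rg, overlap = overlap,
          recovered = overlap >= overlap_frac
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarize a recovery experiment into per-pair recovery rates
#'
#' @param recovery Output of [validate_recovery()].
#' @return Tibble `model` x `region` with `rate`, the fraction of replicates
#'   in which the model's thresholded map recovered the region.
#' @export
recovery_rates <- function(recovery) {
  dplyr::summarise(
    dplyr::group_by(recovery, .data$model, .data$region),
    rate = mean(.data$recovered), .groups = "drop"
  )
}
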