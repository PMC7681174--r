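#' Simulate a two-informant trait cohort
#'
#' Generates a subject table in the pipeline's input format: one row per
#' subject x informant with ordinal item responses on a `0..L-1` scale,
#' covariates, and exclusion flags. Responses come from a correlated ordinal
#' model: each subject has a latent trait, each item an offset, and the two
#' informants observe the shared subject-item propensity plus informant-
#' specific noise whose variance is set so the informant correlation equals
#' `informant_r` (at `informant_r = 1` child and parent responses are
#' identical). Missing cells, items missing from both informants, and
#' multi-marked cells (`"v|v+1"`) are injected at configurable rates to
#' exercise the combination and imputation rules. Ages are uniform on 10-17,
#' gender is a balanced 0/1 indicator, IQ is N(100, 15) and independent of
#' the trait unless `confounded = TRUE`.
#'
#' @param n_enrolled Enrolled subjects, default 37.
#' @param n_motion_excluded Subjects flagged for excessive motion, default 4.
#' @param n_attention_excluded Subjects flagged for failed attention checks,
#'   default 3. The analyzed sample is `n_enrolled - 4 - 3 = 30` under the
#'   defaults.
#' @param n_items,n_levels Questionnaire size (default 24 items, 4 levels).
#' @param informant_r Child-parent correlation of the latent propensity,
#'   default 0.9.
#' @param trait_sd Latent trait standard deviation, default 1.
#' @param missing_rate Per-cell single-informant missingness, default 0.01.
#' @param both_missing_rate Per-item probability that both informants are
#'   missing (exercises imputation), default 0.005.
#' @param multimark_rate Per-cell probability of a two-box response, default
#'   0.005.
#' @param confounded Couple IQ and age to the latent trait (default `FALSE`,
#'   keeping covariates clean for partial-correlation recovery tests).
#' @param seed RNG seed; identical seed and configuration give identical
#'   output.
#' @return Long tibble with columns `subject_id`, `informant`, `item_1..K`
#'   (character; `""` missing, `"a|b"` multi-marked), `age`, `gender`, `iq`,
#'   `motion_excluded`, `attention_excluded`. The latent traits are attached
#'   as attribute `"latent"`.
#' @export
simulate_cohort <- function(n_enrolled = 37, n_motion_excluded = 4,
                            n_attention_excluded = 3, n_items = 24,
                            n_levels = 4, informant_r = 0.9, trait_sd = 1,
                            missing_rate = 0.01, both_missing_rate = 0.005,
                            multimark_rate = 0.005, confounded = FALSE,
                            seed = NULL) {
  if (n_motion_excluded + n_attention_excluded >= n_enrolled) {
    stop("Exclusions leave no analyzable subjects.", call. = FALSE)
  }
  if (missing_rate + both_missing_rate > 0.5) {
    stop("Infeasible missingness fraction.", call. = FALSE)
  }
  if (informant_r <= 0 || informant_r > 1) {
    stop("`informant_r` must be in (0, 1].", call. = FALSE)
  }
  run <- function() {
    n <- n_enrolled
    trait <- stats::rnorm(n, 0, trait_sd)
    item_offset <- stats::rnorm(n_items, 0, 0.5)
    sd_itemnoise <- 0.5
    propensity <- outer(trait, item_offset, `+`) +
      matrix(stats::rnorm(n * n_items, 0, sd_itemnoise), n, n_items)
    var_u <- trait_sd^2 + 0.25 + sd_itemnoise^2
    sd_e <- sqrt(var_u * (1 - informant_r) / informant_r)
    cuts <- stats::qnorm(c(0.25, 0.60, 0.85), sd = sqrt(var_u + sd_e^2))
    to_ordinal <- function(u) findInterval(u, cuts)  # 0..3

    obs <- list(
      child = to_ordinal(propensity +
        matrix(stats::rnorm(n * n_items, 0, sd_e), n, n_items)),
      parent = to_ordinal(propensity +
        matrix(stats::rnorm(n * n_items, 0, sd_e), n, n_items))
    )

    cells <- lapply(obs, function(m) {
      ch <- matrix(as.character(m), n, n_items)
      # two adjacent boxes marked
      mm <- matrix(stats::runif(n * n_items) < multimark_rate, n, n_items) &
        m < (n_levels - 1)
      ch[mm] <- paste0(m[mm], "|", m[mm] + 1)
      # single-informant missingness
      drop <- matrix(stats::runif(n * n_items) < missing_rate, n, n_items)
      ch[drop] <- ""
      ch
    })
    # both-informant missingness (flagged for imputation downstream)
    both <- matrix(stats::runif(n * n_items) < both_missing_rate, n, n_items)
    cells$child[both] <- ""
    cells$parent[both] <- ""
    # never leave a subject with no responses at all
    for (i in seq_len(n)) {
      if (all(cells$child[i, ] == "" & cells$parent[i, ] == "")) {
        cells$child[i, 1] <- as.character(obs$child[i, 1])
      }
    }

    age <- round(stats::runif(n, 10, 17), 1)
    gender <- stats::rbinom(n, 1, 0.5)
    iq <- if (confounded) {
      round(100 - 5 * trait + stats::rnorm(n, 0, 12))
    } else {
      round(stats::rnorm(n, 100, 15))
    }
    if (confounded) age <- round(pmin(17, pmax(10, age + trait)), 1)

    excl <- sample.int(n, n_motion_excluded + n_attention_excluded)
    motion <- seq_len(n) %in% excl[seq_len(n_motion_excluded)]
    attention <- seq_len(n) %in%
      excl[n_motion_excluded + seq_len(n_attention_excluded)]

    ids <- sprintf("sub-%02d", seq_len(n))
    one_informant <- function(who) {
      df <- tibble::as_tibble(cells[[who]], .name_repair = "minimal")
      names(df) <- paste0("item_", seq_len(n_items))
      dplyr::bind_cols(
        tibble::tibble(subject_id = ids, informant = who),
        df,
        tibble::tibble(age = age, gender = gender, iq = iq,
                       motion_excluded = motion,
                       attention_excluded = attention)
      )
    }
    out <- dplyr::bind_rows(one_informant("child"), one_informant("parent"))
    out <- dplyr::arrange(out, .data$subject_id, .data$informant)
    attr(out, "latent") <- tibble::tibble(subject_id = ids, trait = trait)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Task timing metadata
#'
#' Records the block-design timing of the fearful-face task the beta maps
#' come from: two 3-minute baseline runs of noncontextualized faces, then
#' four context runs in which each of the three interpretative contexts
#' ("afraid for you", "afraid of you", "afraid for self") is presented twice
#' per run as an 18-s block. Volume counts are derived from run duration and
#' TR (`ceiling(duration / tr)`).
#'
#' @param tr_s Repetition time in seconds, default 2.5.
#' @param baseline_run_s Baseline run duration, default 180 (3 min).
#' @param context_run_s Context run duration, default 253 (4 min 13 s).
#' @param n_baseline_runs,n_context_runs Run counts, defaults 2 and 4.
#' @param n_contexts Interpretative contexts, default 3.
#' @param presentations_per_context Blocks per context per run, default 2.
#' @return List with per-run tibble `runs` (`run`, `type`, `duration_s`,
#'   `n_volumes`, `n_face_blocks`) and scalar timing fields.
#' @export
task_metadata <- function(tr_s = 2.5, baseline_run_s = 180,
                          context_run_s = 253, n_baseline_runs = 2,
                          n_context_runs = 4, n_contexts = 3,
                          presentations_per_context = 2) {
  blocks_context <- n_contexts * presentations_per_context
  runs <- dplyr::bind_rows(
    tibble::tibble(
      run = seq_len(n_baseline_runs), type = "baseline",
      duration_s = baseline_run_s,
      n_volumes = as.integer(ceiling(baseline_run_s / tr_s)),
      n_face_blocks = 4L
    ),
    tibble::tibble(
      run = n_baseline_runs + seq_len(n_context_runs), type = "context",
      duration_s = context_run_s,
      n_volumes = as.integer(ceiling(context_run_s / tr_s)),
      n_face_blocks = as.integer(blocks_context)
    )
  )
  list(
    runs = runs,
    tr_s = tr_s,
    block_s = 18,
    face_ms = 200, fixation_ms = 300,
    contexts = c("afraid_for_you", "afraid_of_you", "afraid_for_self"),
    contextualized_blocks_per_run = as.integer(blocks_context)
  )
}

#' Write the task metadata manifest
#'
#' @param meta Output of [task_metadata()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_task_manifest <- function(meta, path) {
  meta$runs <- as.data.frame(meta$runs)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Ellipsoidal analysis mask
#'
#' A brain-stand-in: the ellipsoid inscribed in the given grid (semi-axes
#' `(shape - 1) / 2`), roughly 1900 voxels at the default 17 x 17 x 15 grid
#' of 3 mm voxels.
#'
#' @param shape Grid dimensions, default `c(17, 17, 15)`.
#' @param type `"ellipsoid"` (default) or `"box"` (all voxels in mask).
#' @return 3D logical array.
#' @export
simulate_mask <- function(shape = c(17, 17, 15),
                          type = c("ellipsoid", "box")) {
  type <- match.arg(type)
  if (type == "box") return(array(TRUE, shape))
  ctr <- (shape + 1) / 2
  ax <- pmax((shape - 1) / 2, 0.5)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  array(inside, shape)
}

#' Default planted regions for recovery simulations
#'
#' Three pairwise-disjoint cubes of `size^3` voxels inside the mask, one per
#' planted model kind (`low_alike`, `high_alike`, `nn`), placed around the
#' mask center.
#'
#' @param mask 3D mask array.
#' @param size Cube edge length in voxels, default 4.
#' @return Tibble with columns `kind` and `voxels` (list of m x 3 index
#'   matrices).
#' @export
default_planted_regions <- function(mask, size = 4) {
  shape <- dim(mask)
  ctr <- round((shape + 1) / 2)
  half <- floor(size / 2)
  cube <- function(center) {
    rng <- lapply(center, function(c0) (c0 - half):(c0 + half - 1 + size %% 2))
    as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  }
  offsets <- list(c(-size - 1, 0, 0), c(size + 1, 0, 0), c(0, size + 1, 0))
  regions <- lapply(offsets, function(o) cube(ctr + o))
  out <- tibble::tibble(
    kind = c("low_alike", "high_alike", "nn"),
    voxels = regions
  )
  check_planted_regions(out, mask)
  out
}

check_planted_regions <- function(planted, mask) {
  shape <- dim(mask)
  seen <- integer(0)
  for (i in seq_len(nrow(planted))) {
    vx <- planted$voxels[[i]]
    if (any(vx < 1) || any(vx[, 1] > shape[1]) || any(vx[, 2] > shape[2]) ||
        any(vx[, 3] > shape[3]) || !all(mask[vx])) {
      stop("Planted region ", i, " (", planted$kind[i],
           ") falls outside the mask.", call. = FALSE)
    }
    lin <- coords_to_linear(vx, shape)
    if (any(lin %in% seen)) {
      stop("Planted regions overlap.", call. = FALSE)
    }
    seen <- c(seen, lin)
  }
  invisible(planted)
}

#' Simulate beta maps with planted intersubject structure
#'
#' Emits one [beta_set()] per condition on the given mask. Outside planted
#' regions every in-mask voxel is independent Gaussian noise; inside a
#' planted region each subject's pattern is a loading on a shared latent
#' pattern plus noise, with the loading chosen so the expected neural RDM
#' matches the planted model:
#'
#' * `low_alike`: loading `1 - s_i` (low scorers share the pattern),
#' * `high_alike`: loading `s_i`,
#' * `nn`: loadings `cos(pi s_i / 2)` and `sin(pi s_i / 2)` on two orthogonal
#'   shared patterns, so pattern similarity decays smoothly with
#'   `|s_i - s_j|`.
#'
#' The effect weight `w` in `[0, 1]` scales the signal amplitude against
#' unit-scale noise: voxel value `= w * loading * pattern + noise_sd * eps`.
#' Voxels outside the mask are `NA`. Identical configuration and seed give
#' bit-identical output.
#'
#' @param scored Scored cohort (from [score_cohort()]); normalized scores are
#'   derived from its `total` column.
#' @param mask 3D mask array, default [simulate_mask()].
#' @param planted Tibble of planted regions (`kind`, `voxels`, optionally
#'   `w` and `condition`); default [default_planted_regions()] applied to all
#'   conditions. Use `planted = NULL` for pure noise.
#' @param w Default effect weight for regions without their own, default 0.8.
#' @param noise_sd Noise standard deviation, default 1.
#' @param pixdim Voxel size (mm), default `c(3, 3, 3)`.
#' @param conditions Conditions to emit.
#' @param smooth_fwhm_vox Optional Gaussian smoothing FWHM (in voxels)
#'   applied to the noise field to mimic spatial autocorrelation; 0 (default)
#'   disables it.
#' @param seed RNG seed.
#' @return Named list of `beta_set`s, with the ground-truth planting recorded
#'   in attribute `"ground_truth"`.
#' @export
simulate_betas <- function(scored, mask = simulate_mask(),
                           planted = default_planted_regions(mask),
                           w = 0.8, noise_sd = 1, pixdim = c(3, 3, 3),
                           conditions = c("baseline", "afraid_for_you",
                                          "afraid_of_you", "afraid_for_self"),
                           smooth_fwhm_vox = 0, seed = NULL) {
  s <- normalize_scores(scored$total)
  n <- length(s)
  shape <- dim(mask)
  lin_mask <- coords_to_linear(mask_coords(mask), shape)
  if (!is.null(planted)) {
    if (!"w" %in% names(planted)) planted$w <- w
    if (!"condition" %in% names(planted)) planted$condition <- NA_character_
    check_planted_regions(planted, mask)
    if (any(planted$w < 0 | planted$w > 1)) {
      stop("Effect weights must lie in [0, 1].", call. = FALSE)
    }
  }

  run <- function() {
    out <- lapply(conditions, function(cond) {
      arr <- array(NA_real_, c(shape, n))
      flat <- matrix(NA_real_, prod(shape), n)
      noise <- matrix(stats::rnorm(length(lin_mask) * n, 0, noise_sd),
                      length(lin_mask), n)
      if (smooth_fwhm_vox > 0) {
        noise <- smooth_in_mask(noise, mask, smooth_fwhm_vox)
      }
      flat[lin_mask, ] <- noise
      if (!is.null(planted)) {
        for (r in seq_len(nrow(planted))) {
          if (!is.na(planted$condition[r]) && planted$condition[r] != cond) {
            next
          }
          vx <- planted$voxels[[r]]
          lin <- coords_to_linear(vx, shape)
          nv <- length(lin)
          wr <- planted$w[r]
          load <- switch(planted$kind[r],
            low_alike = 1 - s,
            high_alike = s,
            nn = NULL,
            stop("Unknown planted kind '", planted$kind[r], "'.",
                 call. = FALSE)
          )
          eps <- matrix(stats::rnorm(nv * n, 0, noise_sd), nv, n)
          if (planted$kind[r] == "nn") {
            g1 <- stats::rnorm(nv)
            g2 <- stats::rnorm(nv)
            signal <- outer(g1, cos(pi * s / 2)) + outer(g2, sin(pi * s / 2))
          } else {
            g <- stats::rnorm(nv)
            signal <- outer(g, load)
          }
          flat[lin, ] <- wr * signal + eps
        }
      }
      arr[] <- flat
      beta_set(arr, pixdim = pixdim, condition = cond,
               subjects = as.character(scored$subject_id))
    })
    names(out) <- conditions
    attr(out, "ground_truth") <- list(
      planted = planted, w = w, noise_sd = noise_sd,
      normalized_scores = as.numeric(s), seed = seed
    )
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Separable Gaussian smoothing of per-subject noise restricted to the mask
# (voxels outside stay untouched); used to stress cluster inference with
# spatially autocorrelated noise.
smooth_in_mask <- function(noise, mask, fwhm_vox) {
  shape <- dim(mask)
  sigma <- fwhm_vox / 2.3548
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  lin_mask <- coords_to_linear(mask_coords(mask), shape)
  out <- noise
  for (j in seq_len(ncol(noise))) {
    vol <- array(0, shape)
    vol[lin_mask] <- noise[, j]
    for (axis in 1:3) {
      vol <- convolve_axis(vol, kern, axis)
    }
    out[, j] <- vol[lin_mask]
  }
  # restore unit scale inside the mask
  sweep(out, 2, apply(out, 2, stats::sd), `/`)
}

convolve_axis <- function(vol, kern, axis) {
  shape <- dim(vol)
  half <- (length(kern) - 1) / 2
  res <- array(0, shape)
  for (o in -half:half) {
    src <- shift_array(vol, o, axis)
    res <- res + kern[o + half + 1] * src
  }
  res
}

shift_array <- function(vol, o, axis) {
  if (o == 0) return(vol)
  shape <- dim(vol)
  idx <- lapply(shape, seq_len)
  src <- idx
  src[[axis]] <- pmin(pmax(idx[[axis]] + o, 1), shape[axis])
  do.call(`[`, c(list(vol), src))
}
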