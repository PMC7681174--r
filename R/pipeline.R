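#' Analysis configuration
#'
#' Bundles the tunable parameters of the searchlight IS-RSA workflow. The
#' defaults are the standard settings of this analysis: 1000 permutations,
#' cluster-forming p < .005, cluster extent k = 10, FDR q = .05, 100-voxel
#' searchlights.
#'
#' @param B Mantel permutations, default 1000.
#' @param p_cluster_forming Cluster-forming p threshold, default 0.005.
#' @param k_min Cluster-extent threshold in voxels, default 10.
#' @param q FDR level, default 0.05.
#' @param V Searchlight size in voxels, default 100.
#' @param connectivity Cluster connectivity (6/18/26), default 18.
#' @param models Model kinds to fit.
#' @param seed RNG seed for the permutation schedule.
#' @return Named list of class `isrsa_config`.
#' @export
isrsa_config <- function(B = 1000, p_cluster_forming = 0.005, k_min = 10,
                         q = 0.05, V = 100, connectivity = 18,
                         models = c("low_alike", "high_alike", "nn_abs",
                                    "nn_euclid"),
                         seed = 1L) {
  models <- match.arg(models, model_kinds(), several.ok = TRUE)
  structure(
    list(B = B, p_cluster_forming = p_cluster_forming, k_min = k_min, q = q,
         V = V, connectivity = connectivity, models = models, seed = seed),
    class = "isrsa_config"
  )
}

#' Run the full searchlight IS-RSA workflow
#'
#' For each condition and each requested model kind: build the intersubject
#' model from the scored cohort, compute searchlight Mantel maps, and
#' threshold them into cluster tables. When both nearest-neighbours variants
#' (`nn_abs` on summary scores, `nn_euclid` on item-wise responses) are
#' fitted, their maps are compared voxel-wise per condition.
#'
#' @param betas_by_condition Named list of [beta_set()]s, one per condition.
#' @param mask 3D mask array on the shared grid.
#' @param scored Scored cohort from [score_cohort()], subject order matching
#'   the beta sets.
#' @param config An [isrsa_config()].
#' @return List of class `isrsa_run`:
#'   * `maps`: nested list `condition -> model -> searchlight_map`,
#'   * `clusters`: one bound `isrsa_clusters` tibble,
#'   * `nn_comparison`: tibble of per-condition Spearman rho between the two
#'     nearest-neighbours maps (empty if not both fitted),
#'   * `provenance`: config, config hash, seed, package version.
#' @export
run_isrsa <- function(betas_by_condition, mask, scored,
                      config = isrsa_config()) {
  stopifnot(inherits(config, "isrsa_config"))
  if (is.null(names(betas_by_condition))) {
    names(betas_by_condition) <-
      vapply(betas_by_condition, function(b) b$condition, character(1))
  }
  models <- lapply(config$models, function(kind) build_model(scored, kind))
  names(models) <- config$models
  first <- betas_by_condition[[1]]
  searchlights <- build_searchlights(mask, V = config$V,
                                     pixdim = first$pixdim)

  maps <- list()
  cluster_list <- list()
  nn_rows <- list()
  for (cond in names(betas_by_condition)) {
    betas <- betas_by_condition[[cond]]
    cond_maps <- searchlight_isrsa(betas, models, searchlights,
                                   B = config$B, seed = config$seed)
    maps[[cond]] <- cond_maps
    for (kind in names(cond_maps)) {
      cluster_list[[paste(cond, kind)]] <- threshold_map(
        cond_maps[[kind]],
        p_cluster_forming = config$p_cluster_forming,
        k_min = config$k_min, q = config$q,
        connectivity = config$connectivity
      )
    }
    if (all(c("nn_abs", "nn_euclid") %in% names(cond_maps))) {
      nn_rows[[cond]] <- tibble::tibble(
        condition = cond,
        rho = compare_maps(cond_maps$nn_abs, cond_maps$nn_euclid)
      )
    }
  }
  clusters <- dplyr::bind_rows(cluster_list)
  structure(
    list(
      maps = maps,
      clusters = clusters,
      nn_comparison = dplyr::bind_rows(nn_rows),
      provenance = list(
        config = unclass(config),
        config_hash = rlang::hash(unclass(config)),
        seed = config$seed,
        n_subjects = nrow(scored),
        package_version = as.character(utils::packageVersion("isrsa"))
      )
    ),
    class = "isrsa_run"
  )
}

#' @export
print.isrsa_run <- function(x, ...) {
  cat("<isrsa_run>", length(x$maps), "condition(s) x",
      length(x$maps[[1]]), "model(s);", nrow(x$clusters),
      "clusters above the forming threshold\n")
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Writes per-condition, per-model rho/p NIfTI maps, the cluster table, the
#' nearest-neighbours map comparison and a provenance record.
#'
#' @param run An `isrsa_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "isrsa_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(run$maps)) {
    for (kind in names(run$maps[[cond]])) {
      write_map(run$maps[[cond]][[kind]],
                file.path(dir, paste0(cond, "_", kind)))
    }
  }
  write_cluster_table(run$clusters, file.path(dir, "clusters.tsv"))
  if (nrow(run$nn_comparison) > 0) {
    utils::write.table(as.data.frame(run$nn_comparison),
                       file.path(dir, "nn_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname run_isrsa
#' @param x An `isrsa_run`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.isrsa_run <- function(x, ...) {
  tibble::tibble(
    n_conditions = length(x$maps),
    n_models = length(x$maps[[1]]),
    n_clusters = nrow(x$clusters),
    n_surviving_extent = sum(x$clusters$survives_extent),
    n_surviving_fdr = sum(x$clusters$survives_fdr)
  )
}
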