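#' Searchlight intersubject RSA
#'
#' Runs the full searchlight analysis for one condition: at every searchlight
#' center, the subjects' multivoxel beta patterns give a neural RDM
#' (`1 - Spearman rho`, see [pattern_rdm()]); its lower triangle is rank-
#' correlated with the intersubject model's lower triangle; and a Mantel
#' permutation test (joint row/column shuffles of the model matrix) yields a
#' p-value. The statistic rho is assigned to the center voxel.
#'
#' One permutation schedule, derived from `seed`, is drawn up front and
#' reused at every searchlight (and for every model when several are given),
#' so p-values are comparable across the map; set
#' `shared_schedule = FALSE` to draw a fresh schedule per center.
#'
#' Searchlights whose patterns violate the RDM preconditions (too few finite
#' voxels, a constant pattern) are recorded as undefined with the reason, not
#' fatal.
#'
#' @param betas A [beta_set()].
#' @param models A single [isrsa_model] or a (optionally named) list of them,
#'   all on the beta set's subject order.
#' @param searchlights A `searchlight_set` from [build_searchlights()].
#' @param B Permutations per test, default 1000.
#' @param seed Seed for the permutation schedule.
#' @param alternative Passed to the Mantel test; default `"observed_sign"`.
#' @param shared_schedule Reuse one permutation schedule across centers
#'   (default `TRUE`).
#' @return A `searchlight_map` (single model) or named list of them: 3D
#'   arrays `rho` and `p` (`NA` at undefined voxels), grid metadata,
#'   condition, model kind, `B`, `seed`, and a tibble `failures`.
#' @export
searchlight_isrsa <- function(betas, models, searchlights, B = 1000,
                              seed = NULL,
                              alternative = c("observed_sign", "greater",
                                              "less"),
                              shared_schedule = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(betas, "beta_set"),
            inherits(searchlights, "searchlight_set"))
  single <- inherits(models, "isrsa_model")
  if (single) models <- list(models)
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$kind, character(1))
  }
  dims <- dim(betas$data)
  if (!identical(searchlights$dim, dims[1:3])) {
    stop("Searchlight grid does not match beta grid.", call. = FALSE)
  }
  n <- dims[4]
  for (mod in models) {
    if (length(mod$subjects) != n) {
      stop("Model subject count differs from beta set.", call. = FALSE)
    }
    if (!identical(as.character(mod$subjects), as.character(betas$subjects))) {
      stop("Model '", mod$kind, "' subject order differs from beta set.",
           call. = FALSE)
    }
  }
  m_pairs <- n_pairs(n)
  perms <- draw_permutations(n, B, seed)

  # per model: lower-triangle ranks, their permuted columns, sd
  prep <- lapply(models, function(mod) {
    b <- lower_triangle(mod$matrix)
    rb <- rank(b)
    sb <- stats::sd(rb)
    if (sb == 0) {
      stop("Model '", mod$kind, "' has a constant lower triangle.",
           call. = FALSE)
    }
    cols <- perm_lt_columns(lt_rank_matrix(mod$matrix), perms)
    list(rb = rb, sb = sb, cols = cols)
  })

  flat <- matrix(betas$data, prod(dims[1:3]), n)
  n_centers <- nrow(searchlights$centers)
  center_lin <- coords_to_linear(searchlights$centers, dims[1:3])
  rho_mat <- matrix(NA_real_, n_centers, length(models))
  p_mat <- matrix(NA_real_, n_centers, length(models))
  fail_idx <- integer(0)
  fail_msg <- character(0)

  for (i in seq_len(n_centers)) {
    lin <- searchlights$voxel_linear[searchlights$members[[i]]]
    X <- flat[lin, , drop = FALSE]
    ok <- rowSums(!is.finite(X)) == 0
    X <- X[ok, , drop = FALSE]
    if (nrow(X) < 3) {
      fail_idx <- c(fail_idx, i)
      fail_msg <- c(fail_msg, "fewer than 3 finite voxels")
      next
    }
    R <- apply(X, 2, rank)
    sds <- sqrt(colSums(sweep(R, 2, colMeans(R))^2))
    if (any(sds == 0)) {
      fail_idx <- c(fail_idx, i)
      fail_msg <- c(fail_msg, "constant subject pattern")
      next
    }
    rdm <- 1 - stats::cor(R)
    a <- rdm[lower.tri(rdm)]
    ra <- rank(a)
    sa <- stats::sd(ra)
    if (sa == 0) {
      fail_idx <- c(fail_idx, i)
      fail_msg <- c(fail_msg, "constant neural RDM")
      next
    }
    ac <- ra - mean(ra)
    if (!shared_schedule) {
      perms_i <- draw_permutations(n, B, NULL)
    }
    for (j in seq_along(models)) {
      pr <- prep[[j]]
      rho_obs <- sum(ac * pr$rb) / ((m_pairs - 1) * sa * pr$sb)
      cols <- if (shared_schedule) pr$cols else
        perm_lt_columns(lt_rank_matrix(models[[j]]$matrix), perms_i)
      null_rho <- as.vector(crossprod(cols, ac)) / ((m_pairs - 1) * sa * pr$sb)
      count <- switch(alternative,
        greater = sum(null_rho > rho_obs),
        less = sum(null_rho < rho_obs),
        observed_sign = if (rho_obs < 0) sum(null_rho < rho_obs)
                        else sum(null_rho > rho_obs)
      )
      rho_mat[i, j] <- rho_obs
      p_mat[i, j] <- count / B
    }
  }

  failures <- tibble::tibble(
    center_x = searchlights$centers[fail_idx, 1],
    center_y = searchlights$centers[fail_idx, 2],
    center_z = searchlights$centers[fail_idx, 3],
    reason = fail_msg
  )

  maps <- lapply(seq_along(models), function(j) {
    rho_vol <- array(NA_real_, dims[1:3])
    p_vol <- array(NA_real_, dims[1:3])
    rho_vol[center_lin] <- rho_mat[, j]
    p_vol[center_lin] <- p_mat[, j]
    structure(
      list(rho = rho_vol, p = p_vol, dim = dims[1:3],
           pixdim = searchlights$pixdim, origin = betas$origin,
           condition = betas$condition, model_kind = models[[j]]$kind,
           B = B, seed = seed, alternative = alternative,
           failures = failures),
      class = "searchlight_map"
    )
  })
  names(maps) <- names(models)
  if (single) maps[[1]] else maps
}

#' @export
print.searchlight_map <- function(x, ...) {
  nd <- sum(!is.na(x$rho))
  cat("<searchlight_map>", x$condition, "x", x$model_kind, "|", nd,
      "defined centers | B =", x$B, "\n")
  invisible(x)
}

#' Tidy a searchlight map
#'
#' @param x A `searchlight_map`.
#' @param ... Unused.
#' @return Tibble with one row per defined center: voxel indices, mm
#'   coordinates, `rho`, `p`.
#' @exportS3Method generics::tidy
tidy.searchlight_map <- function(x, ...) {
  map <- x
  idx <- which(!is.na(map$rho), arr.ind = TRUE)
  mm <- sweep(idx - 1, 2, map$pixdim, `*`)
  mm <- sweep(mm, 2, map$origin, `+`)
  tibble::tibble(
    x = idx[, 1], y = idx[, 2], z = idx[, 3],
    mm_x = mm[, 1], mm_y = mm[, 2], mm_z = mm[, 3],
    rho = map$rho[idx], p = map$p[idx],
    condition = map$condition, model = map$model_kind
  )
}

neighbor_offsets <- function(connectivity = 18) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1,
    "18" = nz >= 1 & nz <= 2,
    "26" = nz >= 1,
    stop("connectivity must be 6, 18 or 26.", call. = FALSE)
  )
  g[keep, , drop = FALSE]
}

# Connected-component labels for a set of voxel coordinates (m x 3) on a
# grid, under 6/18/26 connectivity. Returns an integer label per voxel;
# labels are assigned in first-encounter order over ascending linear index.
label_components <- function(coords, dims, connectivity = 18) {
  m <- nrow(coords)
  if (m == 0) return(integer(0))
  lin <- coords_to_linear(coords, dims)
  ord <- order(lin)
  lin_sorted <- lin[ord]
  offs <- neighbor_offsets(connectivity)
  labels <- integer(m)
  next_label <- 0L
  for (start in seq_len(m)) {
    v <- ord[start]
    if (labels[v] > 0L) next
    next_label <- next_label + 1L
    queue <- v
    labels[v] <- next_label
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(coords[cur, ]), `+`)
      inside <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[inside, , drop = FALSE]
      if (nrow(nb) == 0) next
      nb_lin <- coords_to_linear(nb, dims)
      pos <- findInterval(nb_lin, lin_sorted)
      valid <- pos > 0
      pos <- pos[valid]
      hit <- ord[pos[lin_sorted[pos] == nb_lin[valid]]]
      new <- hit[labels[hit] == 0L]
      labels[new] <- next_label
      queue <- c(queue, new)
    }
  }
  labels
}

#' Threshold a searchlight map into a cluster table
#'
#' Binarizes the map at the cluster-forming threshold (`p <
#' p_cluster_forming`), splits supra-threshold centers by the sign of rho,
#' labels connected components within each sign, and applies two survival
#' rules: cluster extent (`extent >= k_min`) and voxel-level
#' Benjamini-Hochberg FDR over all defined centers' p-values at level `q`
#' (a cluster survives FDR if any member voxel passes).
#'
#' @param map A `searchlight_map`.
#' @param p_cluster_forming Cluster-forming p threshold, default 0.005.
#' @param k_min Minimum cluster extent in voxels, default 10.
#' @param q FDR level, default 0.05.
#' @param connectivity Component connectivity: 6 (face), 18 (face+edge,
#'   default) or 26 (face+edge+corner).
#' @return An `isrsa_clusters` tibble, one row per cluster: `condition`,
#'   `model`, `sign`, peak mm coordinates, `k` (extent), `peak_rho`,
#'   `peak_p`, `survives_extent`, `survives_fdr`; thresholds attached as
#'   attribute `"thresholds"`.
#' @export
threshold_map <- function(map, p_cluster_forming = 0.005, k_min = 10,
                          q = 0.05, connectivity = 18) {
  stopifnot(inherits(map, "searchlight_map"))
  defined <- which(!is.na(map$p), arr.ind = TRUE)
  if (nrow(defined) == 0) {
    stop("Map has no defined centers.", call. = FALSE)
  }
  p_def <- map$p[defined]
  rho_def <- map$rho[defined]
  p_adj <- stats::p.adjust(p_def, method = "BH")
  fdr_pass <- p_adj <= q

  out <- list()
  for (sgn in c(1, -1)) {
    sel <- p_def < p_cluster_forming &
      (if (sgn > 0) rho_def >= 0 else rho_def < 0)
    if (!any(sel)) next
    coords <- defined[sel, , drop = FALSE]
    labels <- label_components(coords, map$dim, connectivity)
    for (lb in sort(unique(labels))) {
      in_cl <- labels == lb
      cl_coords <- coords[in_cl, , drop = FALSE]
      cl_rho <- rho_def[sel][in_cl]
      cl_p <- p_def[sel][in_cl]
      cl_fdr <- fdr_pass[sel][in_cl]
      peak <- which.max(abs(cl_rho))
      mm <- (cl_coords[peak, ] - 1) * map$pixdim + map$origin
      out[[length(out) + 1]] <- tibble::tibble(
        condition = map$condition,
        model = map$model_kind,
        sign = if (sgn > 0) "positive" else "negative",
        peak_mm_x = mm[1], peak_mm_y = mm[2], peak_mm_z = mm[3],
        k = sum(in_cl),
        peak_rho = cl_rho[peak],
        peak_p = cl_p[peak],
        survives_extent = sum(in_cl) >= k_min,
        survives_fdr = any(cl_fdr),
        voxels = list(cl_coords)
      )
    }
  }
  res <- if (length(out) == 0) empty_cluster_table() else dplyr::bind_rows(out)
  res <- dplyr::arrange(res, dplyr::desc(.data$sign), dplyr::desc(.data$k))
  attr(res, "thresholds") <- list(
    p_cluster_forming = p_cluster_forming, k_min = k_min, q = q,
    connectivity = connectivity
  )
  class(res) <- c("isrsa_clusters", class(res))
  res
}

empty_cluster_table <- function() {
  tibble::tibble(
    condition = character(0), model = character(0), sign = character(0),
    peak_mm_x = numeric(0), peak_mm_y = numeric(0), peak_mm_z = numeric(0),
    k = integer(0), peak_rho = numeric(0), peak_p = numeric(0),
    survives_extent = logical(0), survives_fdr = logical(0),
    voxels = list()
  )
}

#' Voxel-wise similarity of two searchlight maps
#'
#' Spearman rank correlation between the rho values of two maps over the
#' centers defined in both, list-wise excluding centers undefined in either.
#'
#' @param map_a,map_b `searchlight_map`s on the same grid.
#' @return Spearman rho.
#' @export
compare_maps <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "searchlight_map"),
            inherits(map_b, "searchlight_map"))
  if (!identical(map_a$dim, map_b$dim)) {
    stop("Maps are on different grids.", call. = FALSE)
  }
  both <- !is.na(map_a$rho) & !is.na(map_b$rho)
  if (sum(both) < 3) {
    stop("Fewer than 3 centers defined in both maps.", call. = FALSE)
  }
  stats::cor(map_a$rho[both], map_b$rho[both], method = "spearman")
}
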