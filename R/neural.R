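#' Construct a beta-volume set
#'
#' A `beta_set` bundles one condition's subject-level beta coefficient maps on
#' a shared voxel grid: a 4D array (x, y, z, subject), the grid spacing in
#' millimeters, the condition label and the subject order (which must match
#' the trait table's order for all downstream intersubject analyses).
#'
#' @param data 4D numeric array, dimensions x, y, z, subject.
#' @param pixdim Voxel size in mm per axis, default `c(3, 3, 3)`.
#' @param condition Condition label, e.g. `"baseline"`, `"afraid_for_you"`.
#' @param subjects Character vector of subject ids, length `dim(data)[4]`.
#' @param origin mm coordinate of voxel index (1,1,1); default `c(0, 0, 0)`.
#' @return A `beta_set`.
#' @export
beta_set <- function(data, pixdim = c(3, 3, 3), condition = "unknown",
                     subjects = NULL, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  n <- dim(data)[4]
  if (is.null(subjects)) subjects <- sprintf("sub-%02d", seq_len(n))
  if (length(subjects) != n) {
    stop("`subjects` must have one id per 4th-dimension slice.", call. = FALSE)
  }
  structure(
    list(data = data, pixdim = as.numeric(pixdim), condition = condition,
         subjects = as.character(subjects), origin = as.numeric(origin)),
    class = "beta_set"
  )
}

#' @export
print.beta_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<beta_set>", x$condition, "|", d[4], "subjects | grid",
      paste(d[1:3], collapse = "x"), "@",
      paste(x$pixdim, collapse = "x"), "mm\n")
  invisible(x)
}

grid_of <- function(x) {
  list(dim = dim(x$data)[1:3], pixdim = x$pixdim, origin = x$origin)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    max(abs(a$pixdim - b$pixdim)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

mask_coords <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  which(mask != 0 & !is.na(mask), arr.ind = TRUE)
}

coords_to_linear <- function(coords, dims) {
  (coords[, 3] - 1) * dims[1] * dims[2] + (coords[, 2] - 1) * dims[1] +
    coords[, 1]
}

#' Build spherical searchlights over a mask
#'
#' For every in-mask voxel (the center), selects the `V` in-mask voxels
#' nearest to it by Euclidean millimeter distance (so anisotropic grids are
#' handled correctly). Distance ties at the cutoff are broken by ascending
#' (x, y, z) voxel index. Because membership is defined by nearest in-mask
#' voxels rather than a fixed radius, every searchlight has exactly `V`
#' members, including near mask edges where the enclosing sphere grows;
#' set `radius_cap_mm` to instead drop centers whose enclosing radius
#' exceeds a bound.
#'
#' @param mask 3D array, nonzero = in mask.
#' @param V Searchlight size in voxels, default 100.
#' @param pixdim Voxel size (mm), default `c(3, 3, 3)`.
#' @param radius_cap_mm Optional maximum enclosing radius; centers exceeding
#'   it are omitted.
#' @return A `searchlight_set`: centers (voxel indices), member lists
#'   (indices into the in-mask voxel table), and grid metadata.
#' @export
build_searchlights <- function(mask, V = 100, pixdim = c(3, 3, 3),
                               radius_cap_mm = NULL) {
  coords <- mask_coords(mask)
  m <- nrow(coords)
  if (m < V) {
    stop("Mask has ", m, " voxels but searchlights need V = ", V, ".",
         call. = FALSE)
  }
  mm <- sweep(coords - 1, 2, as.numeric(pixdim), `*`)
  sq <- rowSums(mm^2)
  members <- vector("list", m)
  radii <- numeric(m)
  # chunked (center block) x (all voxels) distance computation
  chunk <- max(1L, as.integer(2e7 / m))
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    d2 <- outer(sq[idx], sq, `+`) - 2 * mm[idx, , drop = FALSE] %*% t(mm)
    for (k in seq_along(idx)) {
      ord <- order(d2[k, ], coords[, 1], coords[, 2], coords[, 3])[seq_len(V)]
      members[[idx[k]]] <- ord
      radii[idx[k]] <- sqrt(max(0, d2[k, ord[V]]))
    }
  }
  keep <- if (is.null(radius_cap_mm)) rep(TRUE, m) else radii <= radius_cap_mm
  structure(
    list(
      centers = coords[keep, , drop = FALSE],
      members = members[keep],
      radius_mm = radii[keep],
      voxel_coords = coords,
      voxel_linear = coords_to_linear(coords, dim(mask)),
      dim = dim(mask), pixdim = as.numeric(pixdim), V = as.integer(V)
    ),
    class = "searchlight_set"
  )
}

#' @export
print.searchlight_set <- function(x, ...) {
  cat("<searchlight_set>", nrow(x$centers), "centers | V =", x$V,
      "| grid", paste(x$dim, collapse = "x"), "\n")
  invisible(x)
}

#' Neural representational dissimilarity matrix over a voxel set
#'
#' Computes, for every unordered subject pair, `1 - Spearman rho` between the
#' two subjects' beta values over the given voxels (average ranks for ties).
#' Voxels with a non-finite value in any subject are excluded listwise; at
#' least 3 usable voxels are required.
#'
#' @param betas A [beta_set()].
#' @param voxels Voxel selection: linear indices into the volume, or an
#'   m x 3 matrix of voxel indices.
#' @param voxel_set_id Label stored with the RDM (searchlight center or ROI
#'   name).
#' @return A `neural_rdm`: symmetric n x n matrix in `[0, 2]` with exact zero
#'   diagonal, plus condition and subject order.
#' @export
pattern_rdm <- function(betas, voxels, voxel_set_id = NA_character_) {
  stopifnot(inherits(betas, "beta_set"))
  dims <- dim(betas$data)
  lin <- if (is.matrix(voxels)) coords_to_linear(voxels, dims[1:3])
         else as.integer(voxels)
  n <- dims[4]
  if (n < 2) stop("Need at least 2 subjects.", call. = FALSE)
  flat <- matrix(betas$data, prod(dims[1:3]), n)
  X <- flat[lin, , drop = FALSE]
  ok <- rowSums(!is.finite(X)) == 0
  X <- X[ok, , drop = FALSE]
  if (nrow(X) < 3) {
    stop("Only ", nrow(X), " voxels with finite values for all subjects; ",
         "need >= 3.", call. = FALSE)
  }
  R <- apply(X, 2, rank)
  sds <- apply(R, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- betas$subjects[which(sds == 0)]
    stop("Constant pattern (zero rank variance) for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rdm <- 1 - stats::cor(R)
  diag(rdm) <- 0
  structure(
    list(matrix = unname(rdm), condition = betas$condition,
         subjects = betas$subjects, voxel_set_id = voxel_set_id,
         n_voxels = nrow(X)),
    class = "neural_rdm"
  )
}

#' @export
print.neural_rdm <- function(x, ...) {
  cat("<neural_rdm>", x$condition, "|", length(x$subjects), "subjects |",
      x$n_voxels, "voxels\n")
  invisible(x)
}

#' Mean activation within a region of interest
#'
#' @param betas A [beta_set()].
#' @param roi_mask 3D array on the same grid; nonzero = in ROI.
#' @param roi_name Label for the output.
#' @return Tibble with `subject_id`, `condition`, `roi`, `mean_beta` (the
#'   arithmetic mean over finite in-ROI voxels per subject).
#' @export
roi_mean <- function(betas, roi_mask, roi_name = "roi") {
  stopifnot(inherits(betas, "beta_set"))
  dims <- dim(betas$data)
  if (!identical(dim(roi_mask), dims[1:3])) {
    stop("ROI mask grid ", paste(dim(roi_mask), collapse = "x"),
         " does not match beta grid ", paste(dims[1:3], collapse = "x"), ".",
         call. = FALSE)
  }
  lin <- coords_to_linear(mask_coords(roi_mask), dims[1:3])
  if (length(lin) == 0) stop("ROI mask is empty.", call. = FALSE)
  flat <- matrix(betas$data, prod(dims[1:3]), dims[4])
  X <- flat[lin, , drop = FALSE]
  means <- apply(X, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  if (any(is.na(means))) {
    stop("ROI contains no finite voxels for subject(s): ",
         paste(betas$subjects[is.na(means)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    subject_id = betas$subjects,
    condition = betas$condition,
    roi = roi_name,
    mean_beta = unname(means)
  )
}
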