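#' Write / read a beta-volume set as NIfTI
#'
#' The 4D stack (x, y, z, subject) is written as one NIfTI file with a JSON
#' manifest (`<path>.json`) recording the subject order, condition and grid.
#' Subject order is always taken from the manifest, never from filesystem
#' order.
#'
#' @param betas A [beta_set()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_beta_set()` returns `path` invisibly.
#' @export
write_beta_set <- function(betas, path) {
  stopifnot(inherits(betas, "beta_set"))
  img <- RNifti::asNifti(betas$data)
  RNifti::pixdim(img) <- c(betas$pixdim, 1)  # 4th dim carries subjects
  RNifti::writeNifti(img, path, datatype = "double")
  manifest <- list(
    subjects = betas$subjects,
    condition = betas$condition,
    dim = dim(betas$data)[1:3],
    pixdim = betas$pixdim,
    origin = betas$origin
  )
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

manifest_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' @rdname write_beta_set
#' @param path4d Path to a 4D NIfTI stack whose sidecar JSON lists the
#'   subject order, or a character vector of per-subject 3D NIfTI paths (in
#'   which case `subjects` and `condition` must be given).
#' @param subjects Subject ids matching `path4d` when it is a vector of 3D
#'   files.
#' @param condition Condition label for the 3D-files form.
#' @export
read_beta_set <- function(path4d, subjects = NULL, condition = NULL) {
  if (length(path4d) == 1 && is.null(subjects)) {
    manifest <- jsonlite::read_json(manifest_path(path4d),
                                    simplifyVector = TRUE)
    img <- RNifti::readNifti(path4d)
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) != 4) {
      stop("Expected a 4D volume in ", path4d, ".", call. = FALSE)
    }
    if (dim(arr)[4] != length(manifest$subjects)) {
      stop("Subject count in ", path4d, " (", dim(arr)[4],
           ") does not match its manifest (", length(manifest$subjects), ").",
           call. = FALSE)
    }
    return(beta_set(arr, pixdim = RNifti::pixdim(img)[1:3],
                    condition = manifest$condition,
                    subjects = manifest$subjects,
                    origin = manifest$origin %||% c(0, 0, 0)))
  }
  if (is.null(subjects) || length(subjects) != length(path4d)) {
    stop("When reading per-subject 3D files, supply one subject id per file.",
         call. = FALSE)
  }
  vols <- vector("list", length(path4d))
  ref <- NULL
  for (i in seq_along(path4d)) {
    img <- RNifti::readNifti(path4d[i])
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) != 3) {
      stop("Expected a 3D volume in ", path4d[i], ".", call. = FALSE)
    }
    grid <- list(dim = dim(arr), pixdim = RNifti::pixdim(img)[1:3],
                 origin = c(0, 0, 0))
    if (is.null(ref)) {
      ref <- grid
    } else if (!same_grid(ref, grid, tol = 1e-4)) {
      stop("Grid mismatch: ", path4d[i], " is ",
           paste(grid$dim, collapse = "x"), " @ ",
           paste(signif(grid$pixdim, 4), collapse = "x"),
           " mm, expected ", paste(ref$dim, collapse = "x"), " @ ",
           paste(signif(ref$pixdim, 4), collapse = "x"), " mm.",
           call. = FALSE)
    }
    vols[[i]] <- arr
  }
  data <- array(unlist(vols), c(ref$dim, length(vols)))
  beta_set(data, pixdim = ref$pixdim,
           condition = condition %||% "unknown", subjects = subjects)
}

#' Read a binary mask volume
#'
#' Any nonzero voxel is in-mask (so a probabilistic map thresholded at zero
#' keeps every nonzero voxel).
#'
#' @param path NIfTI path.
#' @param grid Optional reference grid (list with `dim`, `pixdim`) that the
#'   mask must match exactly.
#' @return 3D logical array with attribute `"pixdim"`.
#' @export
read_mask <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 3) {
    stop("Mask in ", path, " is not a 3D volume.", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)[1:3]
  if (!is.null(grid)) {
    this <- list(dim = dim(arr), pixdim = pd, origin = grid$origin %||% c(0, 0, 0))
    ref <- list(dim = grid$dim, pixdim = grid$pixdim,
                origin = grid$origin %||% c(0, 0, 0))
    if (!same_grid(ref, this, tol = 1e-4)) {
      stop("Mask grid in ", path, " does not match the analysis grid.",
           call. = FALSE)
    }
  }
  m <- arr != 0 & !is.na(arr)
  if (!any(m)) stop("Mask in ", path, " is empty.", call. = FALSE)
  out <- array(m, dim(arr))
  attr(out, "pixdim") <- pd
  out
}

#' Write a mask volume
#' @param mask 3D logical/numeric array.
#' @param path Output path.
#' @param pixdim Voxel size (mm).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, pixdim = c(3, 3, 3)) {
  img <- RNifti::asNifti(array(as.numeric(mask != 0), dim(mask)))
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a searchlight map as NIfTI volumes
#'
#' Writes `<prefix>_rho.nii.gz` and `<prefix>_p.nii.gz`; undefined centers
#' are NaN. A JSON sidecar records condition, model, B and seed.
#'
#' @param map A `searchlight_map`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_map <- function(map, prefix) {
  stopifnot(inherits(map, "searchlight_map"))
  paths <- paste0(prefix, c("_rho.nii.gz", "_p.nii.gz"))
  for (i in 1:2) {
    vol <- if (i == 1) map$rho else map$p
    vol[is.na(vol)] <- NaN
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- map$pixdim
    RNifti::writeNifti(img, paths[i], datatype = "double")
  }
  jsonlite::write_json(
    list(condition = map$condition, model = map$model_kind, B = map$B,
         seed = map$seed, alternative = map$alternative),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Write / read a subject table
#'
#' Tab-separated text in the pipeline's input layout: one row per subject x
#' informant, `item_*` columns as text (blank = missing, `"a|b"` =
#' multi-marked).
#'
#' @param data Subject table (e.g. from [simulate_cohort()]).
#' @param path TSV path.
#' @return `write_subject_table()` returns `path` invisibly;
#'   `read_subject_table()` returns a tibble with item columns as character.
#' @export
write_subject_table <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  out <- tibble::as_tibble(df)
  for (col in intersect(c("age", "iq"), names(out))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  for (col in intersect(c("gender"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in intersect(c("motion_excluded", "attention_excluded"),
                        names(out))) {
    out[[col]] <- as.logical(out[[col]])
  }
  out
}

#' Write a cluster table as delimited text
#'
#' Columns mirror the usual results-table conventions: condition, model,
#' sign, peak mm coordinates, extent k, peak rho and the FDR flag.
#'
#' @param clusters An `isrsa_clusters` tibble from [threshold_map()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- as.data.frame(clusters[, setdiff(names(clusters), "voxels")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
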