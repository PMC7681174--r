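#' Combine two informants' item responses
#'
#' Applies the highest-response rule used when a trait questionnaire is
#' completed separately by a child and a parent: for every item the combined
#' response is the maximum over all responses actually given. When only one
#' informant answered, that answer is used; when an informant marked more than
#' one box on an item, all marked values enter the maximum. Items answered by
#' neither informant are flagged for imputation rather than dropped.
#'
#' @param child,parent Item responses for each informant. Either numeric
#'   vectors (with `NA` for missing) or lists of numeric vectors, where a
#'   length-0 element is missing and a longer element is a multi-marked
#'   response such as `c(0, 1)`.
#' @param n_levels Number of ordinal response levels `L`; valid responses are
#'   integers in `0..L-1`. Default 4 (a 0-3 scale).
#'
#' @return A tibble with one row per item and columns `item`, `combined`
#'   (numeric, `NA` where both informants are missing) and `flagged`
#'   (logical, `TRUE` where imputation is required).
#' @examples
#' combine_informant_items(c(2, NA, 0), c(1, 3, 0))
#' combine_informant_items(list(0, 2), list(c(0, 1), 2))
#' @export
combine_informant_items <- function(child, parent, n_levels = 4) {
  child <- as_response_list(child, "child")
  parent <- as_response_list(parent, "parent")
  if (length(child) != length(parent)) {
    stop("`child` and `parent` must have the same number of items (",
         length(child), " vs ", length(parent), ").", call. = FALSE)
  }
  validate_responses(child, n_levels, "child")
  validate_responses(parent, n_levels, "parent")

  marks <- unname(purrr::map2(child, parent, c))
  combined <- purrr::map_dbl(marks, function(m) {
    m <- m[!is.na(m)]
    if (length(m) == 0) NA_real_ else max(m)
  })
  tibble::tibble(
    item = seq_along(combined),
    combined = combined,
    flagged = is.na(combined)
  )
}

as_response_list <- function(x, what) {
  if (is.list(x)) {
    lapply(x, function(v) as.numeric(v[!is.na(v)]))
  } else if (is.numeric(x) || is.logical(x)) {
    lapply(as.numeric(x), function(v) if (is.na(v)) numeric(0) else v)
  } else {
    stop("`", what, "` must be a numeric vector or a list of numeric vectors.",
         call. = FALSE)
  }
}

validate_responses <- function(x, n_levels, what) {
  vals <- unlist(x)
  bad <- vals[!(vals %in% 0:(n_levels - 1))]
  if (length(bad) > 0) {
    stop("`", what, "` contains responses outside 0..", n_levels - 1, ": ",
         paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Impute flagged questionnaire items
#'
#' Replaces each item flagged as missing-by-both-informants with the
#' arithmetic mean of the subject's remaining combined responses. The imputed
#' value is real-valued and not re-rounded to the ordinal scale.
#'
#' @param combined Numeric vector of combined responses, `NA` at flagged items.
#' @param flagged Logical vector marking items to impute; defaults to
#'   `is.na(combined)`.
#' @return Numeric vector with no missing values.
#' @export
impute_flagged_items <- function(combined, flagged = is.na(combined)) {
  stopifnot(length(flagged) == length(combined))
  if (all(flagged)) {
    stop("All items are flagged; nothing to impute from.", call. = FALSE)
  }
  if (any(is.na(combined[!flagged]))) {
    stop("Non-flagged items must be complete.", call. = FALSE)
  }
  combined[flagged] <- mean(combined[!flagged])
  combined
}

#' Standard ICU subscale item assignment
#'
#' Default mapping of the 24 items of the Inventory of Callous-Unemotional
#' Traits to its callous, uncaring and unemotional subscales. Supply your own
#' named list of item indices to [score_items()] / [score_cohort()] to use a
#' different instrument or assignment.
#'
#' @return Named list of integer item indices.
#' @export
icu_subscales <- function() {
  list(
    callous = c(2L, 4L, 7L, 8L, 9L, 10L, 11L, 12L, 18L, 20L, 21L),
    uncaring = c(3L, 5L, 13L, 15L, 16L, 17L, 23L, 24L),
    unemotional = c(1L, 6L, 14L, 19L, 22L)
  )
}

#' Total and subscale scores for one item vector
#'
#' @param items Complete numeric vector of (possibly imputed) item responses.
#' @param subscale_map Named list of integer item indices; subsets need not
#'   partition the items. Default [icu_subscales()].
#' @return One-row tibble with `total` and one column per subscale.
#' @export
score_items <- function(items, subscale_map = icu_subscales()) {
  if (any(is.na(items))) {
    stop("Items must be complete (impute first).", call. = FALSE)
  }
  check_subscale_map(subscale_map, length(items))
  out <- tibble::tibble(total = sum(items))
  for (nm in names(subscale_map)) {
    out[[nm]] <- sum(items[subscale_map[[nm]]])
  }
  out
}

check_subscale_map <- function(subscale_map, n_items) {
  if (length(subscale_map) > 0 &&
      (is.null(names(subscale_map)) || any(names(subscale_map) == ""))) {
    stop("`subscale_map` must be a named list.", call. = FALSE)
  }
  for (nm in names(subscale_map)) {
    idx <- subscale_map[[nm]]
    if (any(idx < 1 | idx > n_items | idx != as.integer(idx))) {
      stop("Subscale '", nm, "' references item indices outside 1..", n_items,
           ".", call. = FALSE)
    }
  }
  invisible(subscale_map)
}

#' Score a two-informant cohort table
#'
#' Takes a long subject table (one row per subject x informant, item columns
#' `item_1..item_K` as text where blank is missing and `"a|b"` is a
#' multi-marked response), applies the highest-response combination rule,
#' imputes items missing from both informants, and computes total and subscale
#' scores. Subjects carrying exclusion flags (`motion_excluded`,
#' `attention_excluded`) are dropped from the scored output and counted in the
#' attached manifest, mirroring the usual cohort accounting
#' (enrolled - motion - attention = analyzed).
#'
#' @param data Data frame with columns `subject_id`, `informant` (`"child"` /
#'   `"parent"`), `item_*` columns, and optionally `age`, `gender`, `iq` and
#'   logical exclusion flags.
#' @param subscale_map Named list of item indices, default [icu_subscales()].
#' @param n_levels Ordinal levels `L`, default 4.
#' @param apply_exclusions Drop flagged subjects from the output (default
#'   `TRUE`); the manifest records the accounting either way.
#'
#' @return A tibble with one row per analyzed subject: `subject_id`,
#'   covariates, `n_imputed`, `total`, subscale columns, and a list-column
#'   `items` holding the combined (post-imputation) item vector. The cohort
#'   manifest is attached as attribute `"manifest"`; see [cohort_manifest()].
#' @export
score_cohort <- function(data, subscale_map = icu_subscales(), n_levels = 4,
                         apply_exclusions = TRUE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("Empty subject table.", call. = FALSE)
  need <- c("subject_id", "informant")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("Subject table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  item_cols <- grep("^item_[0-9]+$", names(data), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("^item_", "", item_cols)))]
  if (length(item_cols) == 0) stop("No item_* columns found.", call. = FALSE)
  bad_inf <- setdiff(unique(data$informant), c("child", "parent"))
  if (length(bad_inf) > 0) {
    stop("Unknown informant label(s): ", paste(bad_inf, collapse = ", "),
         call. = FALSE)
  }

  covar_cols <- intersect(c("age", "gender", "iq"), names(data))
  flag_cols <- intersect(c("motion_excluded", "attention_excluded"),
                         names(data))

  subjects <- unique(data$subject_id)
  rows <- lapply(subjects, function(sid) {
    sub <- data[data$subject_id == sid, , drop = FALSE]
    child <- informant_items(sub, "child", item_cols)
    parent <- informant_items(sub, "parent", item_cols)
    comb <- combine_informant_items(child, parent, n_levels = n_levels)
    items <- impute_flagged_items(comb$combined, comb$flagged)
    scores <- score_items(items, subscale_map)
    meta <- sub[1, c(covar_cols, flag_cols), drop = FALSE]
    dplyr::bind_cols(
      tibble::tibble(subject_id = sid),
      tibble::as_tibble(meta),
      tibble::tibble(n_imputed = sum(comb$flagged)),
      scores,
      tibble::tibble(items = list(items))
    )
  })
  scored <- dplyr::bind_rows(rows)

  excl_motion <- if ("motion_excluded" %in% flag_cols) {
    isTRUE_vec(scored$motion_excluded)
  } else rep(FALSE, nrow(scored))
  excl_att <- if ("attention_excluded" %in% flag_cols) {
    isTRUE_vec(scored$attention_excluded) & !excl_motion
  } else rep(FALSE, nrow(scored))

  manifest <- list(
    n_enrolled = nrow(scored),
    n_motion_excluded = sum(excl_motion),
    n_attention_excluded = sum(excl_att),
    n_analyzed = nrow(scored) - sum(excl_motion) - sum(excl_att),
    n_items = length(item_cols),
    n_imputed_items = sum(scored$n_imputed),
    subscales = names(subscale_map)
  )
  if (apply_exclusions) {
    scored <- scored[!(excl_motion | excl_att), , drop = FALSE]
  }
  attr(scored, "manifest") <- manifest
  scored
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

informant_items <- function(sub, who, item_cols) {
  row <- sub[sub$informant == who, item_cols, drop = FALSE]
  if (nrow(row) == 0) {
    return(rep(list(numeric(0)), length(item_cols)))
  }
  if (nrow(row) > 1) {
    stop("Subject '", sub$subject_id[1], "' has multiple '", who, "' rows.",
         call. = FALSE)
  }
  lapply(as.list(row[1, ]), parse_item_response)
}

#' Parse one item cell of a subject table
#'
#' `""`/`NA` is missing, `"2"` a single response, `"0|1"` a multi-marked
#' response.
#' @param x Scalar cell value (character or numeric).
#' @return Numeric vector of marked values (length 0 when missing).
#' @keywords internal
parse_item_response <- function(x) {
  if (length(x) != 1) stop("Expected a scalar cell.", call. = FALSE)
  if (is.na(x)) return(numeric(0))
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(x)
  if (x == "") return(numeric(0))
  vals <- suppressWarnings(as.numeric(strsplit(x, "|", fixed = TRUE)[[1]]))
  if (any(is.na(vals))) {
    stop("Cannot parse item response '", x, "'.", call. = FALSE)
  }
  vals
}

#' Cohort accounting manifest of a scored table
#'
#' @param scored Output of [score_cohort()].
#' @return Named list: `n_enrolled`, `n_motion_excluded`,
#'   `n_attention_excluded`, `n_analyzed`, `n_items`, `n_imputed_items`.
#' @export
cohort_manifest <- function(scored) {
  m <- attr(scored, "manifest")
  if (is.null(m)) stop("Not a scored cohort (no manifest).", call. = FALSE)
  m
}

#' Normalize scores relative to the in-sample maximum
#'
#' Divides each subject's score by the largest score in the sample, so the
#' highest scorer maps to exactly 1. This is the normalization applied to
#' summary trait scores before constructing intersubject models.
#'
#' @param x Non-negative numeric scores, one per subject, `n >= 2`.
#' @return Numeric vector in `[0, 1]` with attribute `"norm_max"` recording
#'   the divisor; names are preserved.
#' @examples normalize_scores(c(10, 20, 40))
#' @export
normalize_scores <- function(x) {
  if (!is.numeric(x)) stop("Scores must be numeric.", call. = FALSE)
  if (length(x) < 2) stop("Need at least two subjects.", call. = FALSE)
  if (any(is.na(x))) stop("Scores must be complete.", call. = FALSE)
  if (any(x < 0)) stop("Scores must be non-negative.", call. = FALSE)
  mx <- max(x)
  if (mx == 0) {
    stop("All scores are zero; normalized models would be degenerate.",
         call. = FALSE)
  }
  out <- x / mx
  attr(out, "norm_max") <- mx
  out
}

#' Number of unordered subject pairs
#'
#' @param n Subject count, `n >= 2`.
#' @return `n * (n - 1) / 2`, e.g. 435 for `n = 30`.
#' @export
n_pairs <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 2 || n != as.integer(n)) {
    stop("`n` must be a single integer >= 2.", call. = FALSE)
  }
  as.integer(n * (n - 1) / 2)
}
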