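#' Validate an ROI legend
#'
#' @param legend Data frame with columns `label_id`, `region`, `hemisphere`
#'   (and optionally `section`).
#' @return The legend, with canonicalised types, invisibly checked.
#' @export
roi_legend <- function(legend) {
  need <- c("label_id", "region", "hemisphere")
  miss <- setdiff(need, names(legend))
  if (length(miss))
    stop("legend missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(legend$label_id))
    stop("legend label ids must be unique")
  bad <- !legend$region %in% REGIONS
  if (any(bad))
    stop("unknown region(s) in legend: ",
         paste(unique(legend$region[bad]), collapse = ", "))
  bad <- !tolower(legend$hemisphere) %in% HEMISPHERES
  if (any(bad))
    stop("unknown hemisphere(s) in legend: ",
         paste(unique(legend$hemisphere[bad]), collapse = ", "))
  legend$label_id <- as.integer(legend$label_id)
  legend$hemisphere <- tolower(legend$hemisphere)
  legend
}

#' Pooled ROI mean T1 for one region and hemisphere
#'
#' Unweighted arithmetic mean of fitted T1 over all converged voxels
#' carrying any of the (region, hemisphere) section labels, pooled across
#' sections.
#'
#' @param map A `t1_map` from [fit_t1_volume()].
#' @param labels 3D integer label volume on the same grid.
#' @param legend ROI legend (see [roi_legend()]).
#' @param region,hemisphere ROI selector.
#' @return List with `mean_t1_ms` and `n_voxels` (converged voxels used).
#' @export
roi_mean_t1 <- function(map, labels, legend, region, hemisphere) {
  stopifnot(inherits(map, "t1_map"))
  region <- match.arg(region, REGIONS)
  hemisphere <- match.arg(hemisphere, HEMISPHERES)
  if (!identical(as.integer(dim(labels)), as.integer(dim(map$t1_ms))))
    stop("label volume grid does not match the T1 map grid")
  legend <- roi_legend(legend)
  ids <- legend$label_id[legend$region == region &
                           legend$hemisphere == hemisphere]
  if (!length(ids))
    stop("legend has no entries for (", region, ", ", hemisphere, ")")
  sel <- labels %in% ids & map$converged
  n <- sum(sel)
  if (n == 0)
    stop("empty ROI: no converged voxels for (", region, ", ", hemisphere, ")")
  list(mean_t1_ms = mean(map$t1_ms[sel]), n_voxels = n)
}

#' Convert mean T1 to a longitudinal relaxation rate
#'
#' The study's rate transform `t1 = (1/T1) * 1000`: T1 in ms maps to a rate
#' in s^-1, strictly decreasing in T1.
#'
#' @param mean_t1_ms Positive T1 value(s) in ms.
#' @return Rate(s) in s^-1.
#' @export
rate_transform <- function(mean_t1_ms) {
  if (any(mean_t1_ms <= 0))
    stop("T1 must be strictly positive")
  1000 / mean_t1_ms
}

#' Hemispheric lateralization index
#'
#' `(L - R) / (L + R)` on the hemispheric relaxation rates: +1 means
#' activity only in the left hemisphere, -1 only in the right; the index
#' lies in (-1, 1) for positive rates.
#'
#' @param left_rate,right_rate Positive relaxation rates, s^-1 (vectorised).
#' @return Dimensionless index in (-1, 1).
#' @export
lateralization_index <- function(left_rate, right_rate) {
  if (any(left_rate <= 0) || any(right_rate <= 0))
    stop("rates must be strictly positive")
  (left_rate - right_rate) / (left_rate + right_rate)
}

#' Per-subject regional lateralization record
#'
#' For each of the three visual regions: pooled hemispheric mean T1
#' ([roi_mean_t1()]), then the rate transform, then the lateralization
#' index. Averaging T1 across voxels precedes the rate transform (the means
#' are computed on the T1 scale, not on voxelwise rates).
#'
#' @param map A `t1_map`.
#' @param labels 3D integer label volume.
#' @param legend ROI legend.
#' @param subject_id Subject identifier.
#' @param condition `"light"` or `"dark"` (case-insensitive).
#' @return Data frame, one row per region, with columns `subject_id`,
#'   `condition`, `region`, `left_mean_t1_ms`, `right_mean_t1_ms`,
#'   `left_rate`, `right_rate`, `lateralization_index`, `n_left`, `n_right`.
#' @export
build_subject_record <- function(map, labels, legend, subject_id, condition) {
  condition <- tolower(condition)
  if (!condition %in% c("light", "dark"))
    stop("condition must be 'light' or 'dark' (subject ", subject_id, ")")
  rows <- lapply(REGIONS, function(reg) {
    sides <- lapply(HEMISPHERES, function(h) {
      tryCatch(roi_mean_t1(map, labels, legend, reg, h),
               error = function(e) stop("subject ", subject_id, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
    names(sides) <- HEMISPHERES
    lr <- rate_transform(sides$left$mean_t1_ms)
    rr <- rate_transform(sides$right$mean_t1_ms)
    data.frame(subject_id = subject_id, condition = condition, region = reg,
               left_mean_t1_ms = sides$left$mean_t1_ms,
               right_mean_t1_ms = sides$right$mean_t1_ms,
               left_rate = lr, right_rate = rr,
               lateralization_index = lateralization_index(lr, rr),
               n_left = sides$left$n_voxels, n_right = sides$right$n_voxels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a cohort lateralization table
#'
#' @param records Data frame of subject records (rows of
#'   [build_subject_record()] output, or any long table holding
#'   `subject_id`, `condition`, `region`, `lateralization_index`).
#' @return Validated long-format cohort table (one row per subject x
#'   region), class `cohort_table`.
#' @export
cohort_table <- function(records) {
  need <- c("subject_id", "condition", "region", "lateralization_index")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  tab <- records[, need]
  tab$subject_id <- as.character(tab$subject_id)
  tab$region <- as.character(tab$region)
  tab$condition <- tolower(as.character(tab$condition))
  if (!all(tab$condition %in% c("light", "dark")))
    stop("conditions must be 'light' or 'dark'")
  if (!all(tab$region %in% REGIONS))
    stop("regions must be in {", paste(REGIONS, collapse = ", "), "}")
  counts <- table(tab$subject_id, tab$region)
  if (any(counts != 1)) {
    bad <- rownames(counts)[apply(counts != 1, 1, any)]
    stop("each subject needs exactly one row per region; offending ",
         "subject(s): ", paste(bad, collapse = ", "))
  }
  per_cond <- table(unique(tab[, c("subject_id", "condition")])$condition)
  if (any(per_cond < 2) || length(per_cond) < 2)
    stop("need >= 2 subjects in each of the two conditions")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
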