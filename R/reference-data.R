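#' Printed group summaries of the lateralization index
#'
#' Group mean and SEM of the lateralization index per region x condition as
#' reported for the 8 dark- and 10 light-incubated subjects.
#'
#' @return Data frame with columns `region`, `condition`, `n`, `mean`,
#'   `sem`.
#' @export
reported_group_summaries <- function() {
  data.frame(
    region = rep(REGIONS, each = 2),
    condition = rep(c("dark", "light"), 3),
    n = rep(c(8L, 10L), 3),
    mean = c(-0.007, -0.020, -0.038, -0.015, -0.010, -0.009),
    sem = c(0.005, 0.009, 0.006, 0.006, 0.009, 0.006),
    stringsAsFactors = FALSE
  )
}

# Deterministic zero-mean unit-SD pattern of length n (normal scores,
# standardised exactly). Used to impose exact cell moments.
unit_pattern <- function(n) {
  z <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  (z - mean(z)) / stats::sd(z)
}

#' Synthetic stand-in cohort table matching the printed summaries
#'
#' Constructs an 18-subject lateralization table whose per-(region,
#' condition) cell means and SEMs equal the printed group summaries
#' exactly. This is a synthetic surrogate for the deposited per-subject
#' table (which requires an external download): statistics that depend only
#' on cell means and SDs (between-condition pooled t and d, one-sample t
#' and d, cell summaries) are fully determined by it, whereas the mixed
#' ANOVA additionally depends on the unpublished within-subject covariance
#' and is therefore not reproduced exactly by this surrogate.
#'
#' Within each cell the subject values are the standardised normal scores
#' of the cell size, cyclically shifted by one subject per region so the
#' three regional values of a subject are not artificially collinear. Fully
#' deterministic; no RNG.
#'
#' @return A [cohort_table()] with 18 subjects x 3 regions.
#' @export
synthetic_reference_table <- function() {
  summ <- reported_group_summaries()
  rows <- list()
  for (cc in c("dark", "light")) {
    n <- summ$n[summ$condition == cc][1]
    ids <- sprintf("synthetic_%s_%02d", cc, seq_len(n))
    base <- unit_pattern(n)
    for (k in seq_along(REGIONS)) {
      reg <- REGIONS[k]
      s <- summ[summ$region == reg & summ$condition == cc, ]
      pattern <- base[((seq_len(n) - 1 + (k - 1)) %% n) + 1]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ids, condition = cc, region = reg,
        lateralization_index = s$mean + s$sem * sqrt(n) * pattern,
        stringsAsFactors = FALSE
      )
    }
  }
  cohort_table(do.call(rbind, rows))
}
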