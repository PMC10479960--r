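#' Mixed-design ANOVA on the cohort lateralization table
#'
#' 2 (condition: light, dark; between subjects) x 3 (region; within
#' subjects) univariate mixed-model decomposition: condition is tested
#' against the subjects-within-condition mean square, region and the
#' region x condition interaction against the region x subject-within-
#' condition mean square. No sphericity correction is applied, so the
#' degrees of freedom are integers — (1, N-2) and (2, 2(N-2)).
#'
#' @param table A [cohort_table()] (or coercible data frame).
#' @return Data frame with one row per effect and error stratum: `effect`,
#'   `stratum`, `ss`, `df`, `ms`, `F`, `p`.
#' @export
mixed_anova <- function(table) {
  tab <- cohort_table(table)
  d <- data.frame(
    subject = factor(tab$subject_id),
    condition = factor(tab$condition, levels = c("dark", "light")),
    region = factor(tab$region, levels = REGIONS),
    li = tab$lateralization_index
  )
  fit <- stats::aov(li ~ condition * region + Error(subject / region),
                    data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: subject:region"]][[1]])
  row_of <- function(df, name, effect, stratum) {
    i <- which(trimws(rownames(df)) == name)
    data.frame(effect = effect, stratum = stratum,
               ss = df[i, "Sum Sq"], df = df[i, "Df"],
               ms = df[i, "Mean Sq"],
               F = if ("F value" %in% names(df)) df[i, "F value"] else NA_real_,
               p = if ("Pr(>F)" %in% names(df)) df[i, "Pr(>F)"] else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_of(between, "condition", "condition", "between"),
    row_of(between, "Residuals", "subjects_within_condition", "between"),
    row_of(within, "region", "region", "within"),
    row_of(within, "condition:region", "region_x_condition", "within"),
    row_of(within, "Residuals", "region_x_subjects_within_condition",
           "within")
  )
  rownames(out) <- NULL
  out
}

# Independent brute-force SS decomposition used as the test oracle: explicit
# mean decomposition over subjects, conditions and regions. Exported so the
# acceptance checks can compare both routes.

#' Brute-force mixed-ANOVA sums of squares (oracle)
#'
#' Explicit cell-mean decomposition of the mixed design: between-subject SS
#' split into condition and subjects-within-condition, within-subject SS
#' into region, region x condition, and the residual
#' region x subjects-within-condition stratum. Intended as an independent
#' cross-check of [mixed_anova()].
#'
#' @param table A [cohort_table()] (or coercible data frame).
#' @return Same layout as [mixed_anova()].
#' @export
mixed_anova_bruteforce <- function(table) {
  tab <- cohort_table(table)
  r <- length(REGIONS)
  subj <- unique(tab[, c("subject_id", "condition")])
  n_by_cond <- table(subj$condition)
  grand <- mean(tab$lateralization_index)
  subj_mean <- tapply(tab$lateralization_index, tab$subject_id, mean)
  cond_of <- stats::setNames(subj$condition, subj$subject_id)
  cond_mean <- tapply(tab$lateralization_index, tab$condition, mean)
  reg_mean <- tapply(tab$lateralization_index, tab$region, mean)
  cell_mean <- tapply(tab$lateralization_index,
                      list(tab$condition, tab$region), mean)

  ss_cond <- r * sum(n_by_cond * (cond_mean[names(n_by_cond)] - grand)^2)
  ss_subj <- r * sum((subj_mean - cond_mean[cond_of[names(subj_mean)]])^2)
  ss_reg <- nrow(subj) * sum((reg_mean - grand)^2)
  ss_int <- 0
  for (cc in names(n_by_cond)) for (rr in REGIONS)
    ss_int <- ss_int + n_by_cond[[cc]] *
      (cell_mean[cc, rr] - cond_mean[[cc]] - reg_mean[[rr]] + grand)^2
  resid <- tab$lateralization_index -
    subj_mean[tab$subject_id] -
    cell_mean[cbind(as.character(tab$condition), tab$region)] +
    cond_mean[tab$condition]
  ss_res <- sum(resid^2)

  n_tot <- nrow(subj)
  df_cond <- length(n_by_cond) - 1
  df_subj <- n_tot - length(n_by_cond)
  df_reg <- r - 1
  df_int <- df_cond * df_reg
  df_res <- df_subj * df_reg
  ms <- c(ss_cond / df_cond, ss_subj / df_subj, ss_reg / df_reg,
          ss_int / df_int, ss_res / df_res)
  F_cond <- ms[1] / ms[2]
  F_reg <- ms[3] / ms[5]
  F_int <- ms[4] / ms[5]
  data.frame(
    effect = c("condition", "subjects_within_condition", "region",
               "region_x_condition", "region_x_subjects_within_condition"),
    stratum = c("between", "between", "within", "within", "within"),
    ss = c(ss_cond, ss_subj, ss_reg, ss_int, ss_res),
    df = c(df_cond, df_subj, df_reg, df_int, df_res),
    ms = ms,
    F = c(F_cond, NA, F_reg, F_int, NA),
    p = c(stats::pf(F_cond, df_cond, df_subj, lower.tail = FALSE), NA,
          stats::pf(F_reg, df_reg, df_res, lower.tail = FALSE),
          stats::pf(F_int, df_int, df_res, lower.tail = FALSE), NA),
    stringsAsFactors = FALSE
  )
}

#' Two-tailed independent-samples t-test (pooled variance)
#'
#' Student's t with pooled variance, df = n_x + n_y - 2.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
independent_t_pooled <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0)
    stop("pooled variance is zero; t statistic undefined")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-tailed one-sample t-test
#'
#' @param x Numeric sample of length >= 2 with nonzero SD.
#' @param mu0 Null value (default 0, the chance level of the index).
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
one_sample_t <- function(x, mu0 = 0) {
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0)
    stop("sample standard deviation is zero; t statistic undefined")
  ht <- stats::t.test(x, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1) || any(!is.finite(p_values)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' One-sample Cohen's d
#'
#' `d = (mean(x) - mu0) / sd(x)`; equals `t / sqrt(n)`.
#'
#' @param x Numeric sample of length >= 2 with nonzero SD.
#' @param mu0 Null value (default 0).
#' @return Effect size d.
#' @export
cohens_d_one_sample <- function(x, mu0 = 0) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  if (s == 0) stop("sample standard deviation is zero; d undefined")
  (mean(x) - mu0) / s
}

#' Pooled-SD Cohen's d for two independent samples
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled^2 = ((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2)`;
#' satisfies `d = t * sqrt(1/n_x + 1/n_y)` for the pooled t.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return Effect size d.
#' @export
cohens_d_pooled <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero; d undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Run the full group statistical battery
#'
#' (a) the mixed ANOVA; (b) per-region between-condition pooled t-tests with
#' Benjamini-Hochberg FDR applied across exactly those three p-values, plus
#' pooled Cohen's d; (c) six one-sample tests of the index against chance
#' (0), one per region x condition, uncorrected, with one-sample d; (d)
#' group mean and SEM per region x condition cell.
#'
#' @param table A [cohort_table()] (or coercible data frame).
#' @return List with elements `anova`, `between_condition` (data frame:
#'   region, t, df, p, p_fdr, cohens_d, dark/light mean and SEM),
#'   `one_sample` (data frame: region, condition, n, mean, sem, t, df, p,
#'   cohens_d), and `cells` (region x condition summary).
#' @export
run_full_analysis <- function(table) {
  tab <- cohort_table(table)
  anova_tab <- mixed_anova(tab)

  sem <- function(v) stats::sd(v) / sqrt(length(v))
  cells <- do.call(rbind, lapply(REGIONS, function(reg) {
    do.call(rbind, lapply(c("dark", "light"), function(cc) {
      v <- tab$lateralization_index[tab$region == reg & tab$condition == cc]
      data.frame(region = reg, condition = cc, n = length(v),
                 mean = mean(v), sem = sem(v), stringsAsFactors = FALSE)
    }))
  }))

  between <- do.call(rbind, lapply(REGIONS, function(reg) {
    dk <- tab$lateralization_index[tab$region == reg & tab$condition == "dark"]
    lt <- tab$lateralization_index[tab$region == reg & tab$condition == "light"]
    tt <- independent_t_pooled(dk, lt)
    data.frame(region = reg, t = tt$t, df = tt$df, p = tt$p,
               cohens_d = cohens_d_pooled(dk, lt),
               mean_dark = mean(dk), sem_dark = sem(dk),
               mean_light = mean(lt), sem_light = sem(lt),
               stringsAsFactors = FALSE)
  }))
  between$p_fdr <- bh_fdr(between$p)
  between <- between[, c("region", "t", "df", "p", "p_fdr", "cohens_d",
                         "mean_dark", "sem_dark", "mean_light", "sem_light")]

  one_sample <- do.call(rbind, lapply(REGIONS, function(reg) {
    do.call(rbind, lapply(c("dark", "light"), function(cc) {
      v <- tab$lateralization_index[tab$region == reg & tab$condition == cc]
      tt <- one_sample_t(v, 0)
      data.frame(region = reg, condition = cc, n = length(v),
                 mean = mean(v), sem = sem(v), t = tt$t, df = tt$df,
                 p = tt$p, cohens_d = cohens_d_one_sample(v, 0),
                 stringsAsFactors = FALSE)
    }))
  }))

  list(anova = anova_tab, between_condition = between,
       one_sample = one_sample, cells = cells)
}
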