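#' Myocardial flow reserve
#'
#' Ratio of stress to rest flow, computed per subject/region before any
#' averaging (the cohort mean of per-subject ratios is not the ratio of the
#' cohort means).
#'
#' @param rest_F Rest MBF, mL/g/min (> 0); vectorised.
#' @param stress_F Stress MBF, mL/g/min; vectorised.
#' @return Dimensionless MFR.
#' @export
mfr <- function(rest_F, stress_F) {
  if (any(!is.finite(rest_F)) || any(rest_F <= 0))
    stop("`rest_F` must be finite and > 0", call. = FALSE)
  stress_F / rest_F
}

#' Bland-Altman agreement statistics
#'
#' Mean difference (bias) and 1.96-SD limits of agreement of `x - y`, with
#' the n-1 SD denominator and no small-sample t correction.
#'
#' @param x,y Paired measurement vectors (equal length >= 2, no NAs —
#'   excluded pairs are removed beforehand).
#' @return List: `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite (drop excluded pairs first)", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(n = length(d), bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Ranks with average ties, Pearson correlation of the ranks, and a
#' two-sided p value from `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of
#' freedom (p = 0 at |r| = 1).
#'
#' @param x,y Paired vectors (length >= 3, non-constant).
#' @return List: `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(r) >= 1) 0
       else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  list(r = r, p = p, n = n)
}

#' Paired t test
#'
#' Two-sided paired t statistic `t = mean(d) / (sd(d)/sqrt(n))`, d = x - y.
#' A zero-variance difference yields t = 0, p = 1 when the mean difference is
#' also zero, and an infinite-statistic flag otherwise.
#'
#' @param x,y Paired vectors (length >= 2).
#' @return List: `t`, `p`, `df`, `infinite` (logical flag).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1,
                                  infinite = FALSE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                infinite = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), infinite = FALSE)
}

region_set <- function(level) {
  switch(level,
         global = "global",
         territory = c("LAD", "RCA", "LCx"),
         segment = sprintf("seg%02d", 1:17),
         stop("unknown level", call. = FALSE))
}

#' Dual-modality agreement report
#'
#' Joins a PET and an MRI fit table on subject x condition x region at the
#' requested aggregation level, drops pairs with missing values or MRI
#' exclusion markers (`reliable == FALSE`), and reports bias, limits of
#' agreement, Spearman correlation and the paired t test on the remaining
#' pairs. The MRI value compared is `F` when present (extraction-corrected
#' and direct routes) and `K1` otherwise (plain route).
#'
#' @param pet_table Output of [fit_cohort_pet()].
#' @param mri_table Output of [fit_cohort_mri()].
#' @param level `"global"`, `"territory"` or `"segment"`.
#' @param condition `"rest"`, `"stress"` or `"pooled"` (rest and stress
#'   entered as independent pairs).
#' @return List of class `agreement_report`: `level`, `condition`, `n`,
#'   `bias`, `loa_low`, `loa_high`, `spearman_r`, `spearman_p`, `t_stat`,
#'   `t_p`, `excluded_count`, and `pairs` (the underlying data.frame with
#'   columns subject, condition, region, mri, pet).
#' @export
compare_modalities <- function(pet_table, mri_table,
                               level = c("global", "territory", "segment"),
                               condition = c("pooled", "rest", "stress")) {
  level <- match.arg(level)
  condition <- match.arg(condition)
  regions <- region_set(level)
  conds <- if (condition == "pooled") c("rest", "stress") else condition
  pet <- pet_table[pet_table$region %in% regions &
                     pet_table$condition %in% conds, ]
  mri <- mri_table[mri_table$region %in% regions &
                     mri_table$condition %in% conds, ]
  mri$value <- if (all(is.na(mri$F))) mri$K1 else mri$F
  m <- merge(pet[, c("subject", "condition", "region", "F")],
             mri[, c("subject", "condition", "region", "value", "reliable")],
             by = c("subject", "condition", "region"),
             suffixes = c("_pet", "_mri"))
  if (nrow(m) == 0)
    stop(sprintf("empty join at level '%s', condition '%s'", level, condition),
         call. = FALSE)
  keep <- is.finite(m$F) & is.finite(m$value) & m$reliable
  excluded <- sum(!keep)
  m <- m[keep, ]
  if (nrow(m) < 3)
    stop("fewer than 3 usable pairs after exclusions", call. = FALSE)
  ba <- bland_altman(m$value, m$F)
  sp <- spearman_cor(m$value, m$F)
  tt <- paired_t(m$value, m$F)
  structure(list(level = level, condition = condition, n = nrow(m),
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 spearman_r = sp$r, spearman_p = sp$p,
                 t_stat = tt$t, t_p = tt$p,
                 excluded_count = excluded,
                 pairs = data.frame(subject = m$subject,
                                    condition = m$condition,
                                    region = m$region,
                                    mri = m$value, pet = m$F)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement %s/%s> n=%d bias=%.3f LoA [%.3f, %.3f] rho=%.3f (p=%.3g) excl=%d\n",
    x$level, x$condition, x$n, x$bias, x$loa_low, x$loa_high,
    x$spearman_r, x$spearman_p, x$excluded_count))
  invisible(x)
}

#' Per-subject/region MFR table from a rest/stress fit table
#'
#' Pivots a fit table (PET `F`, or MRI `F`/`K1` as in
#' [compare_modalities()]) to one MFR per subject x region. Rows missing
#' either condition, with a non-positive rest value, or flagged unreliable
#' in either condition are dropped.
#'
#' @param table A fit table with subject, condition, region and F (or K1).
#' @return data.frame: subject, region, rest, stress, mfr.
#' @export
mfr_table <- function(table) {
  value <- if (!is.null(table$F) && !all(is.na(table$F))) table$F else table$K1
  reliable <- if (!is.null(table$reliable)) table$reliable else TRUE
  df <- data.frame(subject = table$subject, condition = table$condition,
                   region = table$region, value = value, reliable = reliable)
  rest <- df[df$condition == "rest", ]
  stress <- df[df$condition == "stress", ]
  m <- merge(rest, stress, by = c("subject", "region"),
             suffixes = c("_rest", "_stress"))
  keep <- is.finite(m$value_rest) & is.finite(m$value_stress) &
    m$value_rest > 0 & m$reliable_rest & m$reliable_stress
  m <- m[keep, ]
  data.frame(subject = m$subject, region = m$region,
             rest = m$value_rest, stress = m$value_stress,
             mfr = mfr(m$value_rest, m$value_stress))
}
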