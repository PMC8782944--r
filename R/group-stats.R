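#' Shapiro-Wilk normality classification
#'
#' @param values numeric sample, at least 3 non-missing values, not all
#'   identical.
#' @param alpha significance level; the sample is classified "normal" iff
#'   p > alpha.
#' @return list(classification = "normal"|"non_normal", statistic, p).
#' @export
test_normality <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop("normality test undefined for fewer than 3 values")
  if (diff(range(values)) == 0)
    stop("normality test undefined for a constant sample")
  sw <- stats::shapiro.test(values)
  list(classification = if (sw$p.value > alpha) "normal" else "non_normal",
       statistic = unname(sw$statistic), p = sw$p.value)
}

## normality routing for one group; constant samples (Shapiro-Wilk
## undefined) route to the non-parametric branch by convention
.route_group <- function(values, alpha) {
  if (diff(range(values)) == 0) return("non_normal")
  test_normality(values, alpha)$classification
}

#' Two-group comparison with normality-based test routing
#'
#' Each group is screened with Shapiro-Wilk at `alpha`; the unpaired
#' Student t-test (pooled variance) is used only when BOTH groups classify
#' normal, otherwise the two-sided Mann-Whitney U test (exact when the
#' smaller group has n <= 8 and there are no ties, normal approximation
#' with tie correction otherwise). Constant groups route non-parametric.
#'
#' @param table a concentration table (see
#'   [generate_concentration_table()]).
#' @param metabolite column name to compare.
#' @param tissue tissue to subset to (NULL = use all rows).
#' @param alpha significance level (default 0.05), used both for routing
#'   and for the significance flag.
#' @param welch logical; use the Welch t-test instead of the pooled
#'   Student variant on the parametric route.
#' @return one-row data.frame: metabolite, tissue, test_used, statistic,
#'   p, group means/SEMs/n, significant.
#' @export
compare_groups <- function(table, metabolite, tissue = NULL, alpha = 0.05,
                           welch = FALSE) {
  stopifnot(is.data.frame(table), metabolite %in% names(table))
  dat <- if (is.null(tissue)) table else table[table$tissue == tissue, ]
  groups <- unique(dat$group)
  if (length(groups) != 2L)
    stop("exactly two groups required; found: ",
         paste(groups, collapse = ", "))
  x <- dat[[metabolite]][dat$group == groups[1]]
  y <- dat[[metabolite]][dat$group == groups[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop(sprintf("need >= 3 non-missing values per group for '%s'",
                 metabolite))
  if (diff(range(c(x, y))) == 0) {
    ## degenerate: every observation identical -- no evidence of any
    ## difference; reported under the non-parametric route by convention
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    return(data.frame(metabolite = metabolite,
                      tissue = if (is.null(tissue)) NA_character_ else tissue,
                      test_used = "mannwhitney",
                      statistic = length(x) * length(y) / 2, p = 1,
                      mean_control = mean(x), sem_control = sem(x),
                      mean_treated = mean(y), sem_treated = sem(y),
                      n_control = length(x), n_treated = length(y),
                      significant = FALSE, row.names = NULL))
  }
  normal <- .route_group(x, alpha) == "normal" &&
    .route_group(y, alpha) == "normal"
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = !welch)
    test_used <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = min(length(x), length(y)) <= 8 &&
                           !ties, correct = TRUE))
    test_used <- "mannwhitney"; statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  data.frame(metabolite = metabolite,
             tissue = if (is.null(tissue)) NA_character_ else tissue,
             test_used = test_used, statistic = statistic, p = p,
             mean_control = mean(x), sem_control = sem(x),
             mean_treated = mean(y), sem_treated = sem(y),
             n_control = length(x), n_treated = length(y),
             significant = p <= alpha, row.names = NULL)
}

#' Compare every metabolite column of a table within one tissue
#'
#' @inheritParams compare_groups
#' @param metabolites columns to test (default: every numeric column
#'   after the metadata columns).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   "none" (the default) mirrors per-metabolite testing at alpha.
#' @return data.frame with one row per metabolite, plus `p_adj`.
#' @export
compare_all <- function(table, tissue = NULL, metabolites = NULL,
                        alpha = 0.05, welch = FALSE, adjust = "none") {
  meta_cols <- c("sample_id", "tissue", "group", "wet_weight_g")
  if (is.null(metabolites))
    metabolites <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                           meta_cols)
  res <- do.call(rbind, lapply(metabolites, function(m)
    compare_groups(table, m, tissue, alpha, welch)))
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res$significant <- res$p_adj <= alpha
  res
}

#' Derived energetic indices
#'
#' Adds the total adenine nucleotide pool TAN = AMP + ADP + ATP, the
#' energy-reserve ratio PCr/ATP, the redox ratio NAD/NADH and the
#' succinate/fumarate ratio to a concentration table. Ratios with a
#' non-positive denominator are set missing and logged.
#'
#' @param table concentration table with the component columns present.
#' @return the table with columns TAN, PCr_ATP, NAD_NADH,
#'   succinate_fumarate appended.
#' @export
derived_indices <- function(table) {
  need <- c("AMP", "ADP", "ATP", "PCr", "NAD", "NADH",
            "succinate", "fumarate")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing component column(s): ",
         paste(missing_cols, collapse = ", "))
  guarded_ratio <- function(num, den, name) {
    bad <- !is.na(den) & den <= 0
    if (any(bad))
      cm_log("group_stats", "warn",
             sprintf("%s undefined for %d sample(s): denominator <= 0",
                     name, sum(bad)))
    out <- num / den
    out[bad] <- NA_real_
    out
  }
  table$TAN <- table$AMP + table$ADP + table$ATP
  table$PCr_ATP <- guarded_ratio(table$PCr, table$ATP, "PCr/ATP")
  table$NAD_NADH <- guarded_ratio(table$NAD, table$NADH, "NAD/NADH")
  table$succinate_fumarate <-
    guarded_ratio(table$succinate, table$fumarate, "succinate/fumarate")
  table
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample: dCt = Ct_target - Ct_reference; ddCt = dCt minus the mean
#' dCt of the control group; fold = 2^(-ddCt).
#'
#' @param ct data.frame with columns sample_id, group, ct_target,
#'   ct_reference (finite values).
#' @param control_group label of the control group.
#' @return list(per_sample = data.frame with dct, ddct, fold;
#'   per_group = data.frame with group mean and SEM of fold).
#' @export
fold_change_ddct <- function(ct, control_group) {
  stopifnot(is.data.frame(ct),
            all(c("group", "ct_target", "ct_reference") %in% names(ct)))
  if (!all(is.finite(ct$ct_target)) || !all(is.finite(ct$ct_reference)))
    stop("Ct values must be finite")
  if (!control_group %in% ct$group)
    stop("control group '", control_group, "' absent from Ct table")
  dct <- ct$ct_target - ct$ct_reference
  ddct <- dct - mean(dct[ct$group == control_group])
  per_sample <- cbind(ct, dct = dct, ddct = ddct, fold = 2^(-ddct))
  agg <- lapply(split(per_sample$fold, per_sample$group), function(v)
    c(mean_fold = mean(v), sem_fold = stats::sd(v) / sqrt(length(v)),
      n = length(v)))
  per_group <- data.frame(group = names(agg),
                          do.call(rbind, agg), row.names = NULL)
  list(per_sample = per_sample, per_group = per_group)
}
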