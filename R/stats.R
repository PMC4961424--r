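# Study-level statistics: temporal coefficient of variation of regional
# high-DF proportions, the Friedman test of spatial consistency across
# analysis windows, Kruskal-Wallis across sections, the grouped Welch
# t-test (PV/appendage/peri-mitral vs other walls), and the chi-square on
# ablation outcomes. Test engines are the standard stats:: routines.

#' Temporal coefficient of variation (%)
#'
#' 100 x sample standard deviation / mean of a series (e.g. a region's
#' % High DF Area across windows). Undefined (NA) when the mean is not
#' positive.
#'
#' @param series numeric, length >= 2.
#' @export
temporal_cov <- function(series) {
  stopifnot(length(series) >= 2)
  m <- mean(series)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  100 * stats::sd(series) / m
}

#' Friedman test of spatial consistency
#'
#' Tests whether the ranking of the ten LA sections by % High DF Area is
#' consistent across the analysis windows (windows as blocks, sections as
#' treatments). A small p-value indicates a spatially consistent high-DF
#' distribution.
#'
#' @param table windows x regions matrix (e.g. 9 x 10).
#' @return list with `statistic` and `p`.
#' @export
friedman_consistency <- function(table) {
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop("incomplete table", call. = FALSE)
  ft <- stats::friedman.test(table)
  s <- unname(ft$statistic); p <- ft$p.value
  if (!is.finite(s)) { s <- 0; p <- 1 }   # fully tied (constant rows)
  list(statistic = s, p = p)
}

#' Kruskal-Wallis test across sections
#'
#' @param covs list of numeric vectors (one per region) or a data frame
#'   with columns `value` and `group`.
#' @return list with `statistic` and `p`.
#' @export
kruskal_regions <- function(covs) {
  if (is.data.frame(covs)) {
    values <- covs$value; groups <- covs$group
  } else {
    values <- unlist(covs, use.names = FALSE)
    groups <- rep(seq_along(covs), lengths(covs))
  }
  if (length(unique(values)) == 1) return(list(statistic = 0, p = 1))
  kt <- stats::kruskal.test(values, factor(groups))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Grouped comparison of temporal CoVs (Welch t-test)
#'
#' Compares pooled per-geometry-per-region CoVs between the temporally
#' unstable group (four PVs R7-R10, appendage R3, peri-mitral R4) and the
#' remaining wall sections (R1, R2, R5, R6).
#'
#' @param covs geometries x regions matrix of temporal CoVs (%), columns
#'   R1..R10.
#' @param group_a,group_b region indices of the two groups.
#' @return list with group means, sds and `p`.
#' @export
grouped_cov_ttest <- function(covs, group_a = c(3, 4, 7, 8, 9, 10),
                              group_b = c(1, 2, 5, 6)) {
  covs <- as.matrix(covs)
  a <- as.numeric(covs[, group_a]); a <- a[!is.na(a)]
  b <- as.numeric(covs[, group_b]); b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  if (isTRUE(all.equal(c(a, b), rep(mean(c(a, b)), length(a) + length(b)))))
    return(list(mean_a = mean(a), sd_a = 0, mean_b = mean(b), sd_b = 0,
                p = 1))
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b),
       statistic = unname(tt$statistic), p = tt$p.value)
}

#' Chi-square test on ablation outcomes
#'
#' Pearson chi-square (no continuity correction) on the fractions x
#' {maintained, changed-or-terminated} contingency table.
#'
#' @param table a 3 x 2 matrix of counts, or a [tabulate_outcomes()] result
#'   (collapsed automatically).
#' @return list with `statistic`, `df` and `p`.
#' @export
chi_square_outcomes <- function(table) {
  if (is.data.frame(table) && "defrag_or_term_rate" %in% names(table)) {
    tab <- cbind(maintained = table$AF_maintained,
                 changed = table$AT_conversion + table$AF_terminated)
  } else {
    tab <- as.matrix(table)
  }
  if (any(tab < 0) || any(rowSums(tab) == 0))
    stop("invalid contingency table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
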