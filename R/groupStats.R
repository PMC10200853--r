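#' Welch's two-sample t-test
#'
#' Two-sided Welch (unequal-variance) t-test of the difference in means,
#' with Welch-Satterthwaite degrees of freedom:
#' \deqn{t = \frac{\bar a - \bar b}{\sqrt{s_a^2/n_a + s_b^2/n_b}}}
#' Thin wrapper around \code{stats::t.test(var.equal = FALSE)} returning
#' the statistic, degrees of freedom and two-sided p-value.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return data.frame with \code{t_statistic, degrees_of_freedom, p_value,
#'   two_sided}.
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both groups have zero variance; Welch test is degenerate")
  fit <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  data.frame(t_statistic = unname(fit$statistic),
             degrees_of_freedom = unname(fit$parameter),
             p_value = fit$p.value, two_sided = TRUE)
}

#' Per-sample summary of classified mtDNA variants
#'
#' Counts and mean VAFs over the sample's classified (somatic +
#' tumour-specific dysplastic) variants, alongside its mtDNA copy number.
#' Mean VAF over the pathogenic stratum is \code{NA} when the sample has
#' no pathogenic variant; the mean VAF overall is \code{NA} at zero
#' variants.
#'
#' @param classified classified-variant data.frame for one sample (from
#'   \code{\link{classifyVariants}}), with a logical
#'   \code{pathogenic_flag} column (absent treated as all-FALSE).
#' @param cn one-row copy-number result for the sample (or NULL).
#' @param group group label from the sample sheet.
#' @param sampleIdValue sample identifier (required when \code{classified}
#'   is empty).
#' @return one-row data.frame with \code{sample_id, group,
#'   n_total_variants, n_somatic, n_dysplastic, n_pathogenic,
#'   mean_vaf_total, mean_vaf_pathogenic, mtCN}.
#' @export
summarizeSample <- function(classified, cn = NULL, group = NA_character_,
                            sampleIdValue = NULL) {
  n <- nrow(classified)
  if (is.null(sampleIdValue))
    sampleIdValue <- if (n) classified$sample_id[1] else
      stop("sampleIdValue required for an empty classified set")
  path <- if (n && !is.null(classified$pathogenic_flag))
    classified$pathogenic_flag else rep(FALSE, n)
  data.frame(
    sample_id = sampleIdValue, group = group,
    n_total_variants = n,
    n_somatic = if (n) sum(classified$label == "somatic") else 0L,
    n_dysplastic = if (n)
      sum(classified$label == "tumour_specific_dysplastic") else 0L,
    n_pathogenic = sum(path),
    mean_vaf_total = if (n) mean(classified$tumour_vaf) else NA_real_,
    mean_vaf_pathogenic = if (sum(path))
      mean(classified$tumour_vaf[path]) else NA_real_,
    mtCN = if (!is.null(cn)) cn$mtCN else NA_real_,
    stringsAsFactors = FALSE)
}

#' Pairwise group comparisons of summary quantities
#'
#' Welch-tests each quantity between every pair of groups with at least
#' two non-missing values on both sides. Per-sample means are compared
#' across samples (per-variant VAFs are averaged within sample first).
#'
#' @param summaries data.frame of per-sample summaries (rows from
#'   \code{\link{summarizeSample}}).
#' @param quantities columns of \code{summaries} to compare.
#' @return data.frame with \code{quantity, group_a, group_b, n_a, n_b,
#'   t_statistic, degrees_of_freedom, p_value}.
#' @export
compareGroups <- function(summaries,
                          quantities = c("n_total_variants",
                                         "mean_vaf_total",
                                         "mean_vaf_pathogenic", "mtCN")) {
  groups <- sort(unique(summaries$group[!is.na(summaries$group)]))
  rows <- list()
  for (q in intersect(quantities, names(summaries))) {
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      a <- summaries[[q]][summaries$group == groups[i]]
      b <- summaries[[q]][summaries$group == groups[j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) next
      if (stats::var(a) == 0 && stats::var(b) == 0) next
      w <- welchTTest(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = q, group_a = groups[i], group_b = groups[j],
        n_a = length(a), n_b = length(b),
        t_statistic = w$t_statistic,
        degrees_of_freedom = w$degrees_of_freedom,
        p_value = w$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(quantity = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0),
                      n_b = integer(0), t_statistic = numeric(0),
                      degrees_of_freedom = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
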