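#' Estimate mtDNA copy number per cell
#'
#' Estimates the number of mitochondrial genome copies per cell from the
#' ratio of mean chrM read depth to mean autosomal read depth, corrected for
#' tumour purity and ploidy:
#' \deqn{mtCN = \frac{mean.DP_{chrM}}{mean.DP_{auto}} \times
#'       (f \times ploidy + (1 - f) \times 2)}
#' where \eqn{f} is tumour purity (1 for normal tissues) and ploidy the mean
#' autosomal ploidy of the tumour cell population (2 in normal tissues).
#' For a normal tissue this reduces to twice the depth ratio.
#'
#' @param depth one-row data.frame (or row) with \code{sample_id,
#'   mean_dp_auto, mean_dp_chrm}.
#' @param pp one-row data.frame with \code{sample_id, f, ploidy} for the
#'   same sample.
#' @return data.frame with \code{sample_id, depth_ratio, f, ploidy, mtCN}.
#' @examples
#' estimateMtCopyNumber(
#'   data.frame(sample_id = "N1", mean_dp_auto = 30, mean_dp_chrm = 30),
#'   data.frame(sample_id = "N1", f = 1, ploidy = 2))  # mtCN = 2
#' @export
estimateMtCopyNumber <- function(depth, pp) {
  depth <- as.data.frame(depth); pp <- as.data.frame(pp)
  stopifnot(nrow(depth) == 1L, nrow(pp) == 1L)
  if (!identical(depth$sample_id, pp$sample_id))
    stop("sample mismatch: depth is for '", depth$sample_id,
         "', purity/ploidy for '", pp$sample_id, "'")
  if (!is.finite(depth$mean_dp_auto) || depth$mean_dp_auto <= 0 ||
      !is.finite(depth$mean_dp_chrm) || depth$mean_dp_chrm <= 0)
    stop("depths must be positive for sample '", depth$sample_id, "'")
  if (is.na(pp$f) || pp$f < 0 || pp$f > 1)
    stop("purity f out of [0, 1] for sample '", pp$sample_id, "'")
  if (is.na(pp$ploidy) || pp$ploidy <= 0)
    stop("ploidy must be positive for sample '", pp$sample_id, "'")
  ratio <- depth$mean_dp_chrm / depth$mean_dp_auto
  data.frame(sample_id = depth$sample_id, depth_ratio = ratio,
             f = pp$f, ploidy = pp$ploidy,
             mtCN = ratio * (pp$f * pp$ploidy + (1 - pp$f) * 2),
             stringsAsFactors = FALSE)
}

#' Estimate mtDNA copy number for a cohort
#'
#' Vectorized wrapper over \code{\link{estimateMtCopyNumber}} joining the
#' depth and purity/ploidy tables on \code{sample_id}. Samples missing a
#' purity/ploidy row are treated as diploid with purity 1 (with a warning),
#' matching the normal-tissue convention.
#'
#' @param depthTable data.frame from \code{\link{readDepthTable}}.
#' @param purityTable data.frame from \code{\link{readPurityPloidy}}.
#' @return data.frame, one row per sample in \code{depthTable}.
#' @export
estimateCohortCopyNumber <- function(depthTable, purityTable) {
  hit <- match(depthTable$sample_id, purityTable$sample_id)
  if (anyNA(hit))
    warning("no purity/ploidy for sample(s) ",
            paste(depthTable$sample_id[is.na(hit)], collapse = ", "),
            "; assuming f = 1, ploidy = 2", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(depthTable)), function(i) {
    pp <- if (is.na(hit[i])) {
      data.frame(sample_id = depthTable$sample_id[i], f = 1, ploidy = 2)
    } else purityTable[hit[i], ]
    estimateMtCopyNumber(depthTable[i, ], pp)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize mtDNA copy number by group
#'
#' @param results data.frame of per-sample copy-number results
#'   (\code{sample_id, mtCN}).
#' @param grouping named character vector mapping \code{sample_id} to a
#'   group label; every sample in \code{results} must be mapped.
#' @return data.frame with \code{group, n, mean_mtCN, median_mtCN}; groups
#'   with no samples are omitted.
#' @export
summarizeCopyNumberByGroup <- function(results, grouping) {
  unmapped <- setdiff(results$sample_id, names(grouping))
  if (length(unmapped))
    stop("sample(s) missing from grouping: ", paste(unmapped, collapse = ", "))
  g <- grouping[results$sample_id]
  out <- do.call(rbind, lapply(split(results$mtCN, g), function(v) {
    data.frame(n = length(v), mean_mtCN = mean(v), median_mtCN = stats::median(v))
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out$group <- as.character(out$group)
  out[order(out$group), ]
}
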