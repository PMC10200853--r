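#' Classify a passing tumour variant as somatic or tumour-specific
#' dysplastic
#'
#' A filtered tumour variant is labelled \code{somatic} when the matched
#' normal shows essentially no signal (normal VAF < 1\%), and
#' \code{tumour_specific_dysplastic} when it is present at low level in the
#' normal (1\% <= normal VAF <= 95\%) but expanded in the tumour
#' (tumour VAF - normal VAF >= 5\%). Calls meeting neither rule (e.g.
#' comparable VAF in tumour and normal) are dropped from the classified
#' output with label \code{NA}. Thresholds are configurable interpretive
#' defaults.
#'
#' @param tumourCall one-row call data.frame of a variant that passed all
#'   filters.
#' @param normalVaf matched-normal VAF of the same allele (0 when absent).
#' @param config a \code{\link{FilterConfig}}.
#' @return data.frame with \code{sample_id, pos, ref, alt, label,
#'   tumour_vaf, normal_vaf}; \code{label} is \code{NA} for dropped calls.
#' @export
classifySomaticStatus <- function(tumourCall, normalVaf,
                                  config = filterConfig()) {
  tumourCall <- as.data.frame(tumourCall)
  stopifnot(nrow(tumourCall) == length(normalVaf))
  if (any(is.na(normalVaf) | normalVaf < 0 | normalVaf > 1))
    stop("normal VAF must lie in [0, 1]")
  tv <- tumourCall$vaf
  label <- rep(NA_character_, length(normalVaf))
  label[normalVaf < config@somaticNormalVafMax] <- "somatic"
  dys <- is.na(label) & normalVaf <= config@dysplasticNormalVafMax &
    (tv - normalVaf) >= config@dysplasticMinVafDiff
  label[dys] <- "tumour_specific_dysplastic"
  data.frame(sample_id = tumourCall$sample_id, pos = tumourCall$pos,
             ref = tumourCall$ref, alt = tumourCall$alt,
             label = label, tumour_vaf = tv, normal_vaf = normalVaf,
             stringsAsFactors = FALSE)
}

#' Classify every passing variant of a filtered call set
#'
#' Looks up each passing call's allele in the matched normal and applies
#' \code{\link{classifySomaticStatus}}. Dropped calls (label NA) are
#' reported with a message and excluded from the returned table.
#'
#' @param verdicts audit data.frame from \code{\link{filterVariants}}.
#' @param normalCalls matched-normal \code{MtCallSet} or call data.frame.
#' @param config a \code{\link{FilterConfig}}.
#' @return classified-variant data.frame (passing, labelled calls only),
#'   with an attribute \code{"dropped"} holding the unlabelled ones.
#' @export
classifyVariants <- function(verdicts, normalCalls = NULL,
                             config = filterConfig()) {
  pass <- verdicts[verdicts$passed, , drop = FALSE]
  if (!nrow(pass)) {
    out <- data.frame(sample_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      label = character(0), tumour_vaf = numeric(0),
                      normal_vaf = numeric(0), stringsAsFactors = FALSE)
    attr(out, "dropped") <- out
    return(out)
  }
  nv <- normalVafAt(normalCalls, pass$pos, pass$alt)
  cls <- classifySomaticStatus(pass, nv, config)
  dropped <- cls[is.na(cls$label), , drop = FALSE]
  if (nrow(dropped))
    message(nrow(dropped),
            " passing call(s) dropped from classification (VAF difference below thresholds)")
  out <- cls[!is.na(cls$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
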