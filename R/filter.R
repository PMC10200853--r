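#' Union-merge the call sets of two callers
#'
#' Merges two callers' call sets for the same sample into one record per
#' (position, ref, alt). Records reported by both callers carry both caller
#' ids; their annotations are taken from caller_a's record (caller_b's kept
#' as provenance in the \code{"secondary"} attribute), so the merge is
#' deterministic and commutative on keys and caller sets.
#'
#' @param callsA,callsB \code{MtCallSet}s from the same sample (each
#'   typically from one caller).
#' @return an \code{MtCallSet} of the union.
#' @export
unionCalls <- function(callsA, callsB) {
  stopifnot(is(callsA, "MtCallSet"), is(callsB, "MtCallSet"))
  if (!identical(sampleId(callsA), sampleId(callsB)))
    stop("cannot union call sets from different samples ('",
         sampleId(callsA), "' vs '", sampleId(callsB), "')")
  df <- rbind(mtCalls(callsA), mtCalls(callsB))
  if (!nrow(df)) return(MtCallSet(df, sampleId = sampleId(callsA)))
  key <- paste(df$pos, df$ref, df$alt, sep = ":")
  ind <- vapply(split(df$is_indel, key), function(x) length(unique(x)),
                integer(1))
  if (any(ind > 1L))
    stop("inconsistent is_indel between callers at: ",
         paste(names(ind)[ind > 1L], collapse = ", "))
  callers_by_key <- vapply(split(df$callers, key), function(x)
    paste(sort(unique(unlist(strsplit(x, ",")))), collapse = ","),
    character(1))
  ## representative row per key: prefer the lexicographically first caller id
  pref <- order(key, df$callers)
  df <- df[pref, , drop = FALSE]
  dup <- duplicated(key[pref])
  secondary <- df[dup, , drop = FALSE]
  out <- df[!dup, , drop = FALSE]
  out$callers <- unname(callers_by_key[key[pref][!dup]])
  out <- out[order(out$pos, out$ref, out$alt), , drop = FALSE]
  res <- MtCallSet(out, sampleId = sampleId(callsA))
  attr(res, "secondary") <- secondary
  res
}

#' Check a call against the position blacklist
#'
#' A variant inside an \code{all_variants} region fails regardless of type;
#' a variant inside an \code{indel_only} region fails only when it is an
#' indel. Region boundaries are inclusive.
#'
#' @param call one-row call data.frame (needs \code{pos, is_indel}).
#' @param regions blacklist data.frame (\code{start, end, applies_to}).
#' @return \code{"BLACKLIST"} or \code{character(0)}.
#' @export
checkPositionBlacklist <- function(call, regions) {
  if (length(checkBlacklistVec(call$pos, call$is_indel, regions)[[1]]))
    "BLACKLIST" else character(0)
}

checkBlacklistVec <- function(pos, is_indel, regions) {
  if (!nrow(regions)) return(rep(list(character(0)), length(pos)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(pos, width = 1L),
    IRanges::IRanges(regions$start, regions$end))
  bad <- rep(FALSE, length(pos))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  applies <- regions$applies_to[s]
  bad[q[applies == "all_variants"]] <- TRUE
  bad[q[applies == "indel_only"][is_indel[q[applies == "indel_only"]]]] <- TRUE
  lapply(bad, function(b) if (b) "BLACKLIST" else character(0))
}

#' Evaluate the read-evidence filter criteria
#'
#' Applies the seven per-read evidence criteria independently and returns
#' every violated one:
#' variant reads >= 10; mean variant base quality >= 20; forward/total
#' variant-read ratio strictly inside (0.1, 0.9); mean read position
#' strictly inside (0.15, 0.85) (measured from both read ends); reference
#' minus variant read length < 25; reference minus variant mapping quality
#' < 10; > 80\% of variant reads with reference-matching context (waived
#' for calls adjacent to a germline variant); variant minus reference NM
#' <= 3. A record missing any required annotation additionally gets
#' \code{MISSING_ANNOTATION}; criteria whose inputs are present are still
#' evaluated. With zero variant reads the ratio criteria are skipped.
#'
#' @param call one-row call data.frame.
#' @param config a \code{\link{FilterConfig}}.
#' @return character vector of violated reason codes (possibly empty).
#' @export
checkReadEvidence <- function(call, config = filterConfig()) {
  checkReadEvidenceVec(as.data.frame(call), config)[[1]]
}

checkReadEvidenceVec <- function(df, config) {
  n <- nrow(df)
  fail <- function(cond) !is.na(cond) & cond
  reasons <- vector("list", n)
  add <- function(reasons, cond, code) {
    idx <- which(fail(cond))
    for (i in idx) reasons[[i]] <- c(reasons[[i]], code)
    reasons
  }
  vr <- df$variant_reads
  reasons <- add(reasons, vr < config@minVariantReads, "SUPPORT")
  reasons <- add(reasons, df$variant_base_quality < config@minBaseQuality,
                 "BASE_QUALITY")
  ratio <- ifelse(!is.na(vr) & vr > 0, df$forward_variant_reads / vr, NA)
  sb <- config@strandFractionBounds
  reasons <- add(reasons, ratio <= sb[1] | ratio >= sb[2], "STRAND")
  rb <- config@readPositionBounds
  reasons <- add(reasons,
                 df$mean_read_position <= rb[1] | df$mean_read_position >= rb[2],
                 "READ_POSITION")
  reasons <- add(reasons,
                 df$ref_read_length - df$var_read_length >= config@maxLenDiff,
                 "LENGTH_DIFF")
  reasons <- add(reasons, df$ref_mapq - df$var_mapq >= config@maxMapqDiff,
                 "MAPQ_DIFF")
  ncf_bad <- df$normal_context_fraction <= config@minNormalContext &
    !df$adjacent_to_germline
  reasons <- add(reasons, ncf_bad, "NORMAL_CONTEXT")
  reasons <- add(reasons, df$var_nm - df$ref_nm > config@maxNmDiff, "NM_DIFF")
  ## fail-closed: any missing required annotation flags the record
  req <- setdiff(ANNOTATION_COLS, "adjacent_to_germline")
  miss <- Reduce(`|`, lapply(req, function(col) is.na(df[[col]])))
  for (i in which(miss)) reasons[[i]] <- c(reasons[[i]], "MISSING_ANNOTATION")
  reasons
}

#' Run the full filter chain on one call
#'
#' Composes the blacklist, read-evidence, germline and noise-level checks.
#' Every stage is evaluated (no short-circuiting), so \code{failed_reasons}
#' lists every violated criterion and the pass set is invariant to stage
#' order.
#'
#' @param call one-row call data.frame.
#' @param config a \code{\link{FilterConfig}}.
#' @param regions blacklist data.frame (default: packaged blacklist).
#' @param resource germline resource data.frame (may be NULL).
#' @param normalCalls matched-normal \code{MtCallSet} or call data.frame
#'   (may be NULL).
#' @param model a \code{\link{NoiseModel}} (may be NULL to skip the noise
#'   filter).
#' @return list with \code{passed} (logical) and \code{failed_reasons}
#'   (character vector in canonical reason order).
#' @export
filterVariant <- function(call, config = filterConfig(),
                          regions = defaultBlacklist(), resource = NULL,
                          normalCalls = NULL, model = NULL) {
  v <- filterVariants(MtCallSet(as.data.frame(call)), config = config,
                      regions = regions, resource = resource,
                      normalCalls = normalCalls, model = model)
  list(passed = v$passed[1],
       failed_reasons = strsplit(v$reasons[1], ",")[[1]])
}

#' Run the full filter chain on a call set
#'
#' @param callset an \code{MtCallSet} (typically the caller union).
#' @inheritParams filterVariant
#' @return the call data.frame with columns \code{passed} (logical) and
#'   \code{reasons} (comma-joined reason codes in canonical order, ""
#'   when passing) appended — the per-variant audit table.
#' @export
filterVariants <- function(callset, config = filterConfig(),
                           regions = defaultBlacklist(), resource = NULL,
                           normalCalls = NULL, model = NULL) {
  stopifnot(is(callset, "MtCallSet"))
  df <- mtCalls(callset)
  if (!nrow(df)) {
    df$passed <- logical(0); df$reasons <- character(0)
    return(df)
  }
  if (is(normalCalls, "MtCallSet")) normalCalls <- mtCalls(normalCalls)
  stages <- list(
    checkBlacklistVec(df$pos, df$is_indel, regions),
    checkReadEvidenceVec(df, config),
    germlineReasonVec(df, resource, normalCalls, config),
    noiseReasonVec(df, model))
  reasons <- lapply(seq_len(nrow(df)), function(i) {
    r <- unlist(lapply(stages, `[[`, i))
    REASON_CODES[REASON_CODES %in% r]   # canonical order, order-invariant
  })
  df$passed <- lengths(reasons) == 0L
  df$reasons <- vapply(reasons, paste, character(1), collapse = ",")
  df
}
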