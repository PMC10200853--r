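#' Build a cohort-normals germline resource from normal call sets
#'
#' Collects (position, allele) pairs seen in any panel normal together with
#' the maximum VAF observed, as \code{source = "cohort_normals"} entries.
#' Combined with external-panel and population-database entries this forms
#' the germline-removal resource.
#'
#' @param normalCallsBySample named list of \code{MtCallSet} (or call
#'   data.frames), one per normal sample.
#' @return data.frame with \code{position, allele, source,
#'   frequency_or_vaf}.
#' @export
buildGermlineResource <- function(normalCallsBySample) {
  dfs <- lapply(normalCallsBySample, function(x)
    if (is(x, "MtCallSet")) mtCalls(x) else x)
  all <- do.call(rbind, dfs)
  if (is.null(all) || !nrow(all))
    return(data.frame(position = integer(0), allele = character(0),
                      source = character(0), frequency_or_vaf = numeric(0),
                      stringsAsFactors = FALSE))
  key <- paste(all$pos, all$alt, sep = ":")
  vaf <- vapply(split(all$vaf, key), function(v) max(v, na.rm = TRUE),
                numeric(1))
  parts <- strsplit(names(vaf), ":", fixed = TRUE)
  data.frame(
    position = as.integer(vapply(parts, `[[`, character(1), 1L)),
    allele = vapply(parts, `[[`, character(1), 2L),
    source = "cohort_normals",
    frequency_or_vaf = unname(vaf),
    stringsAsFactors = FALSE)
}

.normalVafAt <- function(normalCalls, pos, alt) {
  if (is.null(normalCalls) || !nrow(normalCalls)) return(rep(0, length(pos)))
  hit <- match(paste(pos, alt, sep = ":"),
               paste(normalCalls$pos, normalCalls$alt, sep = ":"))
  v <- normalCalls$vaf[hit]
  v[is.na(v)] <- 0
  v
}

#' Matched-normal VAF lookup
#'
#' @param normalCalls matched-normal \code{MtCallSet} or call data.frame
#'   (NULL treated as no signal).
#' @param pos,alt vectors identifying the alleles to look up.
#' @return numeric VAF vector, 0 where the normal has no matching record.
#' @export
normalVafAt <- function(normalCalls, pos, alt) {
  if (is(normalCalls, "MtCallSet")) normalCalls <- mtCalls(normalCalls)
  .normalVafAt(normalCalls, pos, alt)
}

germlineReasonVec <- function(df, resource, normalCalls, config) {
  n <- nrow(df)
  if (is.null(resource) && is.null(normalCalls))
    return(rep(list(character(0)), n))
  bad <- rep(FALSE, n)
  if (!is.null(resource) && nrow(resource)) {
    key <- paste(df$pos, df$alt, sep = ":")
    rkey <- paste(resource$position, resource$allele, sep = ":")
    panel <- resource$source %in% c("cohort_normals", "external_panel") &
      resource$frequency_or_vaf > config@germlineVafThreshold
    popdb <- resource$source == "population_db" &
      resource$frequency_or_vaf > config@germlinePopfreqThreshold
    bad <- bad | key %in% rkey[panel] | key %in% rkey[popdb]
  }
  if (!is.null(normalCalls) && nrow(normalCalls)) {
    nv <- .normalVafAt(normalCalls, df$pos, df$alt)
    bad <- bad | nv > config@germlineVafThreshold
  }
  lapply(bad, function(b) if (b) "GERMLINE" else character(0))
}

#' Remove germline polymorphisms from a call set
#'
#' A call is marked \code{GERMLINE} when its (position, allele) matches a
#' cohort-normals or external-panel resource entry with VAF > 95\%, a
#' population-database entry with frequency > 1\%, or is present in the
#' sample's matched normal at VAF > 95\% (thresholds from \code{config}).
#'
#' @param calls an \code{MtCallSet} or call data.frame.
#' @param resource germline resource data.frame
#'   (\code{\link{readGermlineResource}} /
#'   \code{\link{buildGermlineResource}}); may be NULL.
#' @param normalCalls matched-normal calls; may be NULL.
#' @param config a \code{\link{FilterConfig}}.
#' @return the call data.frame with logical column \code{germline}
#'   appended.
#' @export
removeGermline <- function(calls, resource = NULL, normalCalls = NULL,
                           config = filterConfig()) {
  df <- if (is(calls, "MtCallSet")) mtCalls(calls) else calls
  if (is(normalCalls, "MtCallSet")) normalCalls <- mtCalls(normalCalls)
  r <- germlineReasonVec(df, resource, normalCalls, config)
  df$germline <- lengths(r) > 0L
  df
}

#' Flag calls adjacent to a germline variant
#'
#' Sets \code{adjacent_to_germline} where a germline variant (a panel
#' resource entry above the germline VAF threshold, or a matched-normal
#' call at VAF above it) lies within \code{config@adjacencyWindow} bp of
#' the call. Such calls are exempted from the read-context criterion only
#' (a phased germline allele legitimately breaks the read context of a
#' neighbouring somatic variant).
#'
#' @inheritParams removeGermline
#' @return an \code{MtCallSet} with updated \code{adjacent_to_germline}.
#' @export
flagGermlineAdjacency <- function(calls, resource = NULL, normalCalls = NULL,
                                  config = filterConfig()) {
  cs <- if (is(calls, "MtCallSet")) calls else MtCallSet(calls)
  df <- mtCalls(cs)
  if (is(normalCalls, "MtCallSet")) normalCalls <- mtCalls(normalCalls)
  gpos <- integer(0)
  if (!is.null(resource) && nrow(resource))
    gpos <- c(gpos, resource$position[
      resource$source %in% c("cohort_normals", "external_panel") &
        resource$frequency_or_vaf > config@germlineVafThreshold])
  if (!is.null(normalCalls) && nrow(normalCalls))
    gpos <- c(gpos, normalCalls$pos[
      !is.na(normalCalls$vaf) &
        normalCalls$vaf > config@germlineVafThreshold])
  gpos <- unique(gpos)
  if (length(gpos) && nrow(df)) {
    w <- config@adjacencyWindow
    near <- IRanges::overlapsAny(
      IRanges::IRanges(df$pos, width = 1L),
      IRanges::IRanges(gpos - w, gpos + w))
    ## a germline variant is not adjacent to itself
    self <- paste(df$pos, df$alt, sep = ":") %in%
      c(if (!is.null(normalCalls) && nrow(normalCalls))
          paste(normalCalls$pos, normalCalls$alt, sep = ":")[
            !is.na(normalCalls$vaf) &
              normalCalls$vaf > config@germlineVafThreshold]
        else character(0))
    df$adjacent_to_germline <- df$adjacent_to_germline | (near & !self)
  }
  MtCallSet(df, sampleId = sampleId(cs))
}
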