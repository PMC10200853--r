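#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAString
NULL

## Length of the circular human mitochondrial reference (rCRS, NC_012920.1).
MT_LENGTH <- 16569L

## Canonical contig name used internally and on output; "MT", "M" and
## "chrMT" are normalized to this on input.
MT_CONTIG <- "chrM"

## Reason codes emitted by the filter chain, in canonical (reporting) order.
REASON_CODES <- c(
  "BLACKLIST", "SUPPORT", "BASE_QUALITY", "STRAND", "READ_POSITION",
  "LENGTH_DIFF", "MAPQ_DIFF", "NORMAL_CONTEXT", "NM_DIFF",
  "GERMLINE", "BELOW_NOISE", "MISSING_ANNOTATION"
)

## Per-read summary annotations every filter criterion consumes.
ANNOTATION_COLS <- c(
  "total_depth", "variant_reads", "forward_variant_reads",
  "variant_base_quality", "mean_read_position",
  "ref_read_length", "var_read_length", "ref_mapq", "var_mapq",
  "normal_context_fraction", "ref_nm", "var_nm", "adjacent_to_germline"
)

CALL_COLS <- c("sample_id", "pos", "ref", "alt", "is_indel",
               ANNOTATION_COLS, "callers", "vaf")

#' MtCallSet: candidate chrM variant calls for one sample
#'
#' Container for the candidate mitochondrial variant calls of a single
#' sample, one row per (position, ref, alt, caller-provenance), carrying the
#' per-read summary statistics that the filter criteria evaluate. Annotation
#' fields may be \code{NA} (records flagged as missing an annotation fail
#' filtering with reason \code{MISSING_ANNOTATION}, never pass by default).
#'
#' @slot calls data.frame with columns \code{sample_id, pos, ref, alt,
#'   is_indel, total_depth, variant_reads, forward_variant_reads,
#'   variant_base_quality, mean_read_position, ref_read_length,
#'   var_read_length, ref_mapq, var_mapq, normal_context_fraction, ref_nm,
#'   var_nm, adjacent_to_germline, callers, vaf}.
#' @slot sampleId single sample identifier.
#' @export
setClass("MtCallSet",
  representation(calls = "data.frame", sampleId = "character"))

setValidity("MtCallSet", function(object) {
  df <- object@calls
  msg <- character(0)
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  missing_cols <- setdiff(CALL_COLS, names(df))
  if (length(missing_cols))
    return(paste("missing call columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$pos < 1L | df$pos > MT_LENGTH))
      msg <- c(msg, sprintf("positions must lie in [1, %d]", MT_LENGTH))
    if (any(!nzchar(df$ref) | !nzchar(df$alt)))
      msg <- c(msg, "ref and alt alleles must be non-empty")
    if (any(df$ref == df$alt))
      msg <- c(msg, "ref allele must differ from alt allele")
    ok <- !is.na(df$variant_reads) & !is.na(df$total_depth) &
      !is.na(df$forward_variant_reads)
    if (any(ok & (df$forward_variant_reads > df$variant_reads |
                  df$variant_reads > df$total_depth |
                  df$forward_variant_reads < 0L)))
      msg <- c(msg, "need 0 <= forward_variant_reads <= variant_reads <= total_depth")
    okv <- ok & df$total_depth > 0L & !is.na(df$vaf)
    if (any(okv & abs(df$vaf - df$variant_reads / df$total_depth) > 1e-6))
      msg <- c(msg, "vaf inconsistent with variant_reads/total_depth")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an MtCallSet
#'
#' @param calls data.frame of calls; \code{vaf} is (re)computed from
#'   \code{variant_reads / total_depth} where depths are available.
#' @param sampleId sample identifier; defaults to the unique
#'   \code{calls$sample_id}.
#' @return an \code{MtCallSet}.
#' @export
MtCallSet <- function(calls, sampleId = NULL) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (is.null(sampleId)) {
    sampleId <- unique(calls$sample_id)
    if (length(sampleId) != 1L)
      stop("calls must come from exactly one sample, or pass sampleId")
  }
  if (nrow(calls)) {
    calls$sample_id <- sampleId
    if (is.null(calls$is_indel))
      calls$is_indel <- nchar(calls$ref) != nchar(calls$alt)
    for (col in ANNOTATION_COLS)
      if (is.null(calls[[col]])) calls[[col]] <- NA
    if (is.null(calls$callers)) calls$callers <- NA_character_
    calls$adjacent_to_germline[is.na(calls$adjacent_to_germline)] <- FALSE
    calls$vaf <- ifelse(!is.na(calls$total_depth) & calls$total_depth > 0 &
                          !is.na(calls$variant_reads),
                        calls$variant_reads / calls$total_depth, NA_real_)
    calls$pos <- as.integer(calls$pos)
  } else {
    calls <- emptyCalls(sampleId)
  }
  rownames(calls) <- NULL
  new("MtCallSet", calls = calls, sampleId = sampleId)
}

emptyCalls <- function(sampleId = character(0)) {
  df <- data.frame(sample_id = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   is_indel = logical(0), stringsAsFactors = FALSE)
  for (col in ANNOTATION_COLS) df[[col]] <- numeric(0)
  df$adjacent_to_germline <- logical(0)
  df$callers <- character(0)
  df$vaf <- numeric(0)
  df
}

#' FilterConfig: thresholds of the variant filter chain
#'
#' Holds every tunable threshold of the filter stack, the germline-removal
#' rules and the somatic/dysplastic classification. Defaults reproduce the
#' published recipe; inequality strictness follows the printed criteria
#' exactly (see the methods vignette).
#'
#' @slot minVariantReads minimum variant-supporting reads (pass at >= value).
#' @slot minBaseQuality minimum mean Phred base quality of variant bases
#'   (pass at >= value).
#' @slot strandFractionBounds open interval for forward/total variant-read
#'   ratio; pass strictly inside.
#' @slot readPositionBounds open interval for mean relative read position
#'   (measured from both read ends); pass strictly inside.
#' @slot maxLenDiff pass when ref read length minus variant read length is
#'   strictly below this.
#' @slot maxMapqDiff pass when ref MAPQ minus variant MAPQ is strictly below
#'   this.
#' @slot minNormalContext pass when the fraction of variant reads whose
#'   remaining bases match the reference is strictly above this (waived for
#'   calls adjacent to a germline variant).
#' @slot maxNmDiff pass when variant-read NM minus ref-read NM is <= this.
#' @slot germlineVafThreshold a cohort-normal/external-panel allele (or the
#'   matched normal) marks a call germline when its VAF is strictly above
#'   this.
#' @slot germlinePopfreqThreshold a population-database allele marks a call
#'   germline when its frequency is strictly above this.
#' @slot noiseFloor global minimum of the panel-of-normals VAF noise level.
#' @slot somaticNormalVafMax matched-normal VAF strictly below this labels a
#'   passing call somatic.
#' @slot dysplasticNormalVafMax upper matched-normal VAF bound (inclusive)
#'   for the tumour-specific dysplastic label.
#' @slot dysplasticMinVafDiff minimum tumour-minus-normal VAF difference
#'   (inclusive) for the dysplastic label.
#' @slot adjacencyWindow distance in bp within which a germline variant
#'   marks a call as adjacent_to_germline.
#' @export
setClass("FilterConfig",
  representation(
    minVariantReads = "integer", minBaseQuality = "numeric",
    strandFractionBounds = "numeric", readPositionBounds = "numeric",
    maxLenDiff = "numeric", maxMapqDiff = "numeric",
    minNormalContext = "numeric", maxNmDiff = "numeric",
    germlineVafThreshold = "numeric", germlinePopfreqThreshold = "numeric",
    noiseFloor = "numeric", somaticNormalVafMax = "numeric",
    dysplasticNormalVafMax = "numeric", dysplasticMinVafDiff = "numeric",
    adjacencyWindow = "integer"),
  prototype(
    minVariantReads = 10L, minBaseQuality = 20,
    strandFractionBounds = c(0.1, 0.9), readPositionBounds = c(0.15, 0.85),
    maxLenDiff = 25, maxMapqDiff = 10,
    minNormalContext = 0.80, maxNmDiff = 3,
    germlineVafThreshold = 0.95, germlinePopfreqThreshold = 0.01,
    noiseFloor = 0.005, somaticNormalVafMax = 0.01,
    dysplasticNormalVafMax = 0.95, dysplasticMinVafDiff = 0.05,
    adjacencyWindow = 2L))

setValidity("FilterConfig", function(object) {
  msg <- character(0)
  chkInterval <- function(x, nm, lo, hi) {
    if (length(x) != 2L || x[1] >= x[2] || x[1] < lo || x[2] > hi)
      sprintf("%s must be an interval with lower < upper inside [%g, %g]",
              nm, lo, hi)
    else character(0)
  }
  msg <- c(msg,
    chkInterval(object@strandFractionBounds, "strandFractionBounds", 0, 1),
    chkInterval(object@readPositionBounds, "readPositionBounds", 0, 1))
  if (object@minVariantReads < 0L) msg <- c(msg, "minVariantReads must be >= 0")
  for (nm in c("germlineVafThreshold", "germlinePopfreqThreshold",
               "somaticNormalVafMax", "dysplasticNormalVafMax"))
    if (slot(object, nm) < 0 || slot(object, nm) > 1)
      msg <- c(msg, paste(nm, "must lie in [0, 1]"))
  if (object@noiseFloor < 0) msg <- c(msg, "noiseFloor must be >= 0")
  if (object@adjacencyWindow < 0L) msg <- c(msg, "adjacencyWindow must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a FilterConfig
#'
#' @param ... named overrides of any \code{FilterConfig} slot.
#' @return a validated \code{FilterConfig}.
#' @examples
#' filterConfig()                       # published defaults
#' filterConfig(minVariantReads = 5L)   # relaxed support threshold
#' @export
filterConfig <- function(...) {
  args <- list(...)
  obj <- new("FilterConfig")
  for (nm in names(args)) {
    if (!nm %in% slotNames(obj))
      stop("unknown FilterConfig field: ", nm)
    value <- args[[nm]]
    if (is(slot(obj, nm), "integer")) value <- as.integer(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

#' NoiseModel: panel-of-normals VAF noise floor
#'
#' Per-position background non-reference allele fraction estimated from
#' normal samples, with a global floor. Positions absent from the map carry
#' the floor.
#'
#' @slot perPositionNoise numeric vector of noise levels named by chrM
#'   position (only positions with signal are stored).
#' @slot floor global minimum noise level.
#' @slot nNormals number of normal samples the model was estimated from.
#' @export
setClass("NoiseModel",
  representation(perPositionNoise = "numeric", floor = "numeric",
                 nNormals = "integer"),
  prototype(perPositionNoise = numeric(0), floor = 0.005, nNormals = 0L))

setValidity("NoiseModel", function(object) {
  if (length(object@floor) != 1L || object@floor < 0)
    return("floor must be a single value >= 0")
  if (length(object@perPositionNoise) &&
      any(object@perPositionNoise < object@floor - 1e-12))
    return("all per-position noise values must be >= floor")
  TRUE
})

#' MtGeneModel: mitochondrial gene model plus reference sequence
#'
#' The 37-gene mitochondrial gene model (rCRS coordinates by default) and
#' the reference sequence consequences are computed against.
#'
#' @slot genes data.frame with columns \code{name, start, end, strand}
#'   ("heavy"/"light"), \code{type} ("protein"/"tRNA"/"rRNA"/"control") and
#'   \code{incomplete_stop} (protein gene length not divisible by 3; the
#'   terminal codon is completed by polyadenylation and is A-padded before
#'   translation).
#' @slot refSeq \code{DNAString} of the reference (length 16569), or a
#'   zero-length \code{DNAString} when no sequence was supplied.
#' @export
setClass("MtGeneModel",
  representation(genes = "data.frame", refSeq = "DNAString"))

setValidity("MtGeneModel", function(object) {
  g <- object@genes
  need <- c("name", "start", "end", "strand", "type")
  if (!all(need %in% names(g)))
    return(paste("gene table needs columns:", paste(need, collapse = ", ")))
  if (any(g$start > g$end) || any(g$start < 1L) || any(g$end > MT_LENGTH))
    return(sprintf("gene intervals must lie within [1, %d]", MT_LENGTH))
  if (!all(g$strand %in% c("heavy", "light")))
    return("strand must be 'heavy' or 'light'")
  if (!all(g$type %in% c("protein", "tRNA", "rRNA", "control")))
    return("type must be protein/tRNA/rRNA/control")
  if (length(object@refSeq) && length(object@refSeq) != MT_LENGTH)
    return(sprintf("refSeq must have length %d (or 0)", MT_LENGTH))
  TRUE
})

#' SimulatedCohort: synthetic paired tumour/normal chrM cohort
#'
#' Output of \code{\link{simulateCohort}}: per-sample per-caller call sets,
#' depth and purity tables, the synthetic reference, the germline resource,
#' and a ground-truth ledger labelling every emitted record.
#'
#' @slot tumourCalls named list (tumour sample) of named lists
#'   (\code{caller_a}, \code{caller_b}) of \code{MtCallSet}.
#' @slot normalCalls named list (normal sample) of \code{MtCallSet}.
#' @slot depthTable data.frame \code{sample_id, mean_dp_auto, mean_dp_chrm}.
#' @slot purityTable data.frame \code{sample_id, f, ploidy}.
#' @slot sampleTable data.frame \code{sample_id, kind, group,
#'   matched_normal, true_mtCN, f, ploidy}.
#' @slot truth data.frame labelling every emitted tumour record
#'   (\code{sample_id, pos, ref, alt, label, designed_reason, true_vaf}).
#' @slot germlineResource data.frame of population-database entries
#'   (\code{position, allele, source, frequency_or_vaf}).
#' @slot refSeq synthetic chrM reference (\code{DNAString}).
#' @slot spec the \code{SimulationSpec} list used, including the seed.
#' @export
setClass("SimulatedCohort",
  representation(tumourCalls = "list", normalCalls = "list",
                 depthTable = "data.frame", purityTable = "data.frame",
                 sampleTable = "data.frame", truth = "data.frame",
                 germlineResource = "data.frame", refSeq = "DNAString",
                 spec = "list"))

setMethod("show", "MtCallSet", function(object) {
  cat(sprintf("MtCallSet for sample '%s': %d call(s)\n",
              object@sampleId, nrow(object@calls)))
  if (nrow(object@calls)) {
    n_ind <- sum(object@calls$is_indel)
    cat(sprintf("  %d SNV, %d indel; positions %d..%d\n",
                nrow(object@calls) - n_ind, n_ind,
                min(object@calls$pos), max(object@calls$pos)))
  }
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig (published defaults unless overridden)\n")
  for (nm in slotNames(object))
    cat(sprintf("  %-26s %s\n", nm,
                paste(format(slot(object, nm)), collapse = " .. ")))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: %d position(s) above floor %.4g (from %d normal sample(s))\n",
    length(object@perPositionNoise), object@floor, object@nNormals))
})

setMethod("show", "MtGeneModel", function(object) {
  cat(sprintf("MtGeneModel: %d feature(s), reference %s\n",
              nrow(object@genes),
              if (length(object@refSeq)) "attached" else "not attached"))
})

setMethod("show", "SimulatedCohort", function(object) {
  cat(sprintf(
    "SimulatedCohort: %d tumour(s), %d normal(s), %d emitted truth record(s) (seed %d)\n",
    length(object@tumourCalls), length(object@normalCalls),
    nrow(object@truth), object@spec$seed))
})

#' @describeIn MtCallSet number of calls
#' @param x an \code{MtCallSet}
#' @export
setMethod("length", "MtCallSet", function(x) nrow(x@calls))

#' Accessors for mtSomatic containers
#'
#' @param x an object with calls or a sample identifier.
#' @return \code{mtCalls}: the call data.frame; \code{sampleId}: the sample
#'   identifier.
#' @export
setGeneric("mtCalls", function(x) standardGeneric("mtCalls"))

#' @rdname mtCalls
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname mtCalls
#' @export
setMethod("mtCalls", "MtCallSet", function(x) x@calls)

#' @rdname mtCalls
#' @export
setMethod("sampleId", "MtCallSet", function(x) x@sampleId)

#' Noise level at chrM positions
#'
#' @param model a \code{NoiseModel}.
#' @param pos integer vector of chrM positions.
#' @return numeric vector of VAF noise levels (the floor where no normal had
#'   signal).
#' @export
noiseAt <- function(model, pos) {
  stopifnot(is(model, "NoiseModel"))
  out <- rep(model@floor, length(pos))
  hit <- match(as.character(pos), names(model@perPositionNoise))
  out[!is.na(hit)] <- model@perPositionNoise[hit[!is.na(hit)]]
  out
}
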