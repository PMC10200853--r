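## VCF INFO key <-> internal annotation column mapping. The two callers'
## native keys differ; both are normalized to these keys by the sidecar /
## simulator, and these are the keys written on output.
INFO_MAP <- c(
  DP  = "total_depth",            # Integer
  VD  = "variant_reads",          # Integer
  VDF = "forward_variant_reads",  # Integer
  VBQ = "variant_base_quality",   # Float, mean Phred over variant bases
  MRP = "mean_read_position",     # Float in [0,1], min distance to either read end
  RRL = "ref_read_length",        # Float, mean over reference reads
  VRL = "var_read_length",        # Float, mean over variant reads
  RMQ = "ref_mapq",               # Float
  VMQ = "var_mapq",               # Float
  NCF = "normal_context_fraction",# Float in [0,1]
  RNM = "ref_nm",                 # Float, mean edit distance, reference reads
  VNM = "var_nm")                 # Float, variant reads
INFO_INT <- c("DP", "VD", "VDF")

.mitoNames <- c("chrM", "MT", "M", "chrMT")

normalizeContig <- function(x) ifelse(x %in% .mitoNames, MT_CONTIG, x)

vcfInfoHeader <- function() {
  desc <- c(
    DP = "Total read depth at the site",
    VD = "Variant-supporting reads",
    VDF = "Forward-strand variant-supporting reads",
    VBQ = "Mean Phred base quality of variant-supporting bases",
    MRP = "Mean relative position of the variant within supporting reads (min distance to either end / read length)",
    RRL = "Mean read length, reference-supporting reads",
    VRL = "Mean read length, variant-supporting reads",
    RMQ = "Mean mapping quality, reference-supporting reads",
    VMQ = "Mean mapping quality, variant-supporting reads",
    NCF = "Fraction of variant reads whose remaining bases match the reference",
    RNM = "Mean edit distance (NM), reference-supporting reads",
    VNM = "Mean edit distance (NM), variant-supporting reads")
  S4Vectors::DataFrame(
    Number = c(rep("1", length(INFO_MAP)), "0"),
    Type = c(ifelse(names(INFO_MAP) %in% INFO_INT, "Integer", "Float"), "Flag"),
    Description = c(unname(desc[names(INFO_MAP)]),
                    "Variant lies within 2 bp of a germline variant"),
    row.names = c(names(INFO_MAP), "AGL"))
}

#' Read a caller's chrM VCF into an MtCallSet
#'
#' Reads a VCF v4.x file, keeps mitochondrial records (contig \code{chrM},
#' \code{MT}, \code{M} or \code{chrMT}, normalized to \code{chrM}), splits
#' multi-allelic sites into one record per alt allele, and maps the
#' per-read summary INFO keys (\code{DP, VD, VDF, VBQ, MRP, RRL, VRL, RMQ,
#' VMQ, NCF, RNM, VNM, AGL}) onto the \code{MtCallSet} annotation columns.
#' Records missing a required annotation are kept with \code{NA} in that
#' field (they later fail filtering with \code{MISSING_ANNOTATION}).
#'
#' @param path VCF file path.
#' @param callerId one of \code{"caller_a"}, \code{"caller_b"}.
#' @param sampleId sample identifier; default: the \code{##sample_id} header
#'   meta line if present, else the file base name.
#' @return an \code{MtCallSet} with \code{callers == callerId} on every
#'   record.
#' @export
readVariantVcf <- function(path, callerId = c("caller_a", "caller_b"),
                           sampleId = NULL) {
  callerId <- match.arg(callerId)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "rCRS"),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(sampleId)) {
    hdr_lines <- grep("^##sample_id=", readLines(path, n = 100L),
                      value = TRUE)
    sampleId <- if (length(hdr_lines)) {
      sub("^##sample_id=", "", hdr_lines[1])
    } else sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  on_mt <- contig %in% .mitoNames
  if (any(!on_mt))
    message(sum(!on_mt), " record(s) on non-mitochondrial contigs ignored")
  if (!any(on_mt)) return(MtCallSet(emptyCalls(), sampleId = sampleId))
  vcf <- vcf[on_mt]
  rr <- rr[on_mt]
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  df <- data.frame(
    sample_id = rep(sampleId, n),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    stringsAsFactors = FALSE)
  for (key in names(INFO_MAP)) {
    col <- INFO_MAP[[key]]
    df[[col]] <- if (key %in% names(info)) {
      v <- info[[key]]
      if (key %in% INFO_INT) as.integer(v) else as.numeric(v)
    } else rep(NA, n)
  }
  df$adjacent_to_germline <- if ("AGL" %in% names(info))
    as.logical(info$AGL) else rep(FALSE, n)
  df$is_indel <- nchar(df$ref) != nchar(df$alt)
  df$callers <- callerId
  MtCallSet(df, sampleId = sampleId)
}

#' Write an MtCallSet as VCF 4.2
#'
#' Writes one biallelic record per call on contig \code{chrM}, with the
#' annotation columns as INFO keys (see \code{\link{readVariantVcf}}) and
#' the sample identifier as a \code{##sample_id} header line. Reading the
#' file back reproduces (position, ref, alt, annotations) exactly.
#'
#' @param callset an \code{MtCallSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVariantVcf <- function(callset, path) {
  stopifnot(is(callset, "MtCallSet"))
  df <- mtCalls(callset)
  ord <- order(df$pos, df$ref, df$alt)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  gr <- GenomicRanges::GRanges(
    rep(MT_CONTIG, n),
    IRanges::IRanges(if (n) df$pos else integer(0), width = 1L))
  fx <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(df$ref),
    ALT = Biostrings::DNAStringSetList(as.list(df$alt)),
    QUAL = rep(NA_real_, n), FILTER = rep(".", n))
  info <- S4Vectors::DataFrame(row.names = seq_len(max(n, 0L)))
  for (key in names(INFO_MAP)) {
    v <- df[[INFO_MAP[[key]]]]
    info[[key]] <- if (key %in% INFO_INT) as.integer(v) else as.numeric(v)
  }
  info$AGL <- as.logical(df$adjacent_to_germline)
  hdr <- VariantAnnotation::VCFHeader(samples = character(0))
  VariantAnnotation::meta(hdr)$fileformat <-
    S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat")
  VariantAnnotation::meta(hdr)$sample_id <-
    S4Vectors::DataFrame(Value = sampleId(callset), row.names = "sample_id")
  VariantAnnotation::info(hdr) <- vcfInfoHeader()
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fx, info = info,
                                collapsed = TRUE)
  S4Vectors::metadata(vcf)$header <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Merge a sidecar annotation table into a call set
#'
#' Fills annotation fields a caller's VCF did not provide from a TSV keyed
#' on (sample_id, pos, ref, alt). Existing non-NA values are kept.
#'
#' @param callset an \code{MtCallSet}.
#' @param sidecar data.frame (or TSV path) with key columns plus any subset
#'   of the annotation columns.
#' @return the completed \code{MtCallSet}.
#' @export
mergeAnnotationSidecar <- function(callset, sidecar) {
  if (is.character(sidecar))
    sidecar <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  df <- mtCalls(callset)
  key <- function(d) paste(d$sample_id, d$pos, d$ref, d$alt, sep = ":")
  hit <- match(key(df), key(sidecar))
  for (col in intersect(ANNOTATION_COLS, names(sidecar))) {
    fill <- is.na(df[[col]]) & !is.na(hit)
    df[[col]][fill] <- sidecar[[col]][hit[fill]]
  }
  MtCallSet(df, sampleId = sampleId(callset))
}

.readTsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE,
                                             comment.char = "#")

#' Read the per-sample depth summary table
#'
#' @param path TSV with header \code{sample_id, mean_dp_auto, mean_dp_chrm}
#'   (mean coverage at autosomal germline-variant sites and at chrM sites).
#' @return data.frame, one row per sample.
#' @export
readDepthTable <- function(path) {
  df <- .readTsv(path)
  need <- c("sample_id", "mean_dp_auto", "mean_dp_chrm")
  if (!all(need %in% names(df)))
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in depth table: ", paste(unique(dup), collapse = ", "))
  bad <- !is.finite(df$mean_dp_auto) | !is.finite(df$mean_dp_chrm) |
    df$mean_dp_auto <= 0 | df$mean_dp_chrm <= 0
  if (any(bad))
    stop("non-positive depth for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  df[need]
}

#' Read the per-sample purity/ploidy table
#'
#' @param path TSV with header \code{sample_id, f, ploidy}; \code{f} is
#'   tumour purity in [0,1] (1 for normal tissues), \code{ploidy} the mean
#'   autosomal ploidy (2 in normal tissues).
#' @return data.frame, one row per sample.
#' @export
readPurityPloidy <- function(path) {
  df <- .readTsv(path)
  need <- c("sample_id", "f", "ploidy")
  if (!all(need %in% names(df)))
    stop("purity/ploidy table must have columns: ", paste(need, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in purity table: ", paste(unique(dup), collapse = ", "))
  bad <- is.na(df$f) | df$f < 0 | df$f > 1 | is.na(df$ploidy) | df$ploidy <= 0
  if (any(bad))
    stop("invalid purity/ploidy for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  df[need]
}

#' Read the germline polymorphism resource
#'
#' @param path TSV with header \code{position, allele, source,
#'   frequency_or_vaf}; \code{source} is one of \code{cohort_normals},
#'   \code{external_panel}, \code{population_db}.
#' @return data.frame of resource entries.
#' @export
readGermlineResource <- function(path) {
  df <- .readTsv(path)
  need <- c("position", "allele", "source", "frequency_or_vaf")
  if (!all(need %in% names(df)))
    stop("germline resource must have columns: ", paste(need, collapse = ", "))
  if (!all(df$source %in% c("cohort_normals", "external_panel", "population_db")))
    stop("unknown germline resource source value")
  if (any(is.na(df$frequency_or_vaf) | df$frequency_or_vaf < 0 |
          df$frequency_or_vaf > 1))
    stop("frequency_or_vaf must lie in [0, 1]")
  df$position <- as.integer(df$position)
  df[need]
}

#' The published chrM position blacklist
#'
#' The eight mitochondrial regions excluded from variant calling
#' (poly-C/homopolymer tracts and NUMT-prone segments); the last region
#' (16180-16195) applies to indels only. Coordinates 1-based inclusive.
#'
#' @return data.frame with columns \code{start, end, applies_to}.
#' @export
defaultBlacklist <- function() {
  data.frame(
    start = c(302L, 513L, 568L, 956L, 3105L, 5895L, 8270L, 16180L),
    end   = c(315L, 525L, 573L, 965L, 3109L, 5899L, 8289L, 16195L),
    applies_to = c(rep("all_variants", 7L), "indel_only"),
    stringsAsFactors = FALSE)
}

#' Read a position blacklist
#'
#' BED-like TSV with columns \code{start, end} and an optional
#' \code{applies_to} column (\code{all_variants}/\code{indel_only};
#' default \code{all_variants}). On-disk coordinate convention is declared
#' either via \code{coords} or a \code{#coords=0-based-half-open} comment
#' line; regions are stored 1-based inclusive. Overlapping regions of the
#' same class are merged with a warning.
#'
#' @param path TSV path.
#' @param coords \code{"1-based-inclusive"} (default) or
#'   \code{"0-based-half-open"}.
#' @return data.frame with columns \code{start, end, applies_to}.
#' @export
readBlacklist <- function(path, coords = NULL) {
  hdr <- readLines(path, n = 5L)
  declared <- grep("^#\\s*coords\\s*=", hdr, value = TRUE)
  if (is.null(coords))
    coords <- if (length(declared))
      trimws(sub("^#\\s*coords\\s*=", "", declared[1])) else "1-based-inclusive"
  coords <- match.arg(coords, c("1-based-inclusive", "0-based-half-open"))
  df <- .readTsv(path)
  if (!nrow(df))
    return(data.frame(start = integer(0), end = integer(0),
                      applies_to = character(0), stringsAsFactors = FALSE))
  if (!all(c("start", "end") %in% names(df)))
    stop("blacklist must have columns start, end")
  if (is.null(df$applies_to)) df$applies_to <- "all_variants"
  df$applies_to[is.na(df$applies_to) | df$applies_to == ""] <- "all_variants"
  if (coords == "0-based-half-open") {
    df$start <- df$start + 1L   # end is already the last covered 1-based position
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end) || any(df$start < 1L) || any(df$end > MT_LENGTH))
    stop(sprintf("blacklist coordinates out of range [1, %d]", MT_LENGTH))
  out <- do.call(rbind, lapply(split(df, df$applies_to), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    if (length(ir) < nrow(d))
      warning("overlapping blacklist regions merged", call. = FALSE)
    data.frame(start = IRanges::start(ir), end = IRanges::end(ir),
               applies_to = d$applies_to[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$start), ]
}

#' Write a blacklist table
#'
#' @param blacklist data.frame from \code{\link{defaultBlacklist}} or
#'   \code{\link{readBlacklist}}.
#' @param path output TSV path (written 1-based inclusive).
#' @return \code{path}, invisibly.
#' @export
writeBlacklist <- function(blacklist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords=1-based-inclusive", con)
  utils::write.table(blacklist, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
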