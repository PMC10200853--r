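## Consequence severity, worst-first, used when a variant falls in
## overlapping genes (ATP8/ATP6, ND4L/ND4).
.SEVERITY <- c(frameshift = 7, nonsense = 6, missense = 5, tRNA = 4,
               rRNA = 3, synonymous = 2, noncoding = 1)

#' Load the mitochondrial gene model
#'
#' Loads the packaged 37-gene mitochondrial gene model (rCRS coordinates,
#' NC_012920.1) or a user-supplied table, optionally attaching the
#' reference sequence used for codon lookup. Protein genes whose length is
#' not divisible by 3 (incomplete stop codons, completed by polyadenylation
#' in vivo) are flagged; their terminal codon is A-padded at translation.
#'
#' @param refSeq reference sequence: a \code{DNAString}, a single character
#'   string of length 16569, or a FASTA path; NULL leaves the model without
#'   sequence (protein-gene SNV consequences then error).
#' @param genesPath TSV with columns \code{name, start, end, strand, type};
#'   default: the packaged rCRS table.
#' @return an \code{\link{MtGeneModel}}.
#' @export
mtGeneModel <- function(refSeq = NULL,
                        genesPath = system.file("extdata", "mt_gene_model.tsv",
                                                package = "mtSomatic")) {
  genes <- utils::read.delim(genesPath, stringsAsFactors = FALSE)
  genes$incomplete_stop <- genes$type == "protein" &
    (genes$end - genes$start + 1L) %% 3L != 0L
  seq <- if (is.null(refSeq)) {
    Biostrings::DNAString("")
  } else if (is(refSeq, "DNAString")) {
    refSeq
  } else if (is.character(refSeq) && length(refSeq) == 1L &&
             file.exists(refSeq)) {
    Biostrings::readDNAStringSet(refSeq)[[1]]
  } else {
    Biostrings::DNAString(refSeq)
  }
  new("MtGeneModel", genes = genes, refSeq = seq)
}

.translateCodon <- function(codon) {
  code <- Biostrings::getGeneticCode("SGC1")  # vertebrate mitochondrial
  unname(code[codon])
}

.consequenceInGene <- function(pos, ref, alt, gene, refSeq) {
  if (gene$type == "control") return("noncoding")
  if (gene$type == "tRNA") return("tRNA")
  if (gene$type == "rRNA") return("rRNA")
  ## protein gene
  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt))
    return(if (shift %% 3L != 0L) "frameshift" else "missense")
  }
  if (nchar(ref) != 1L) return("missense")   # MNV: conservative
  if (length(refSeq) == 0L)
    stop("protein-gene SNV consequence requires a reference sequence; ",
         "build the model with mtGeneModel(refSeq = ...)")
  cds <- refSeq[gene$start:gene$end]
  if (gene$strand == "light") {
    cds <- Biostrings::reverseComplement(cds)
    off <- gene$end - pos + 1L
    alt_b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
  } else {
    off <- pos - gene$start + 1L
    alt_b <- alt
  }
  cidx <- (off - 1L) %/% 3L
  cstart <- cidx * 3L + 1L
  codon <- as.character(cds[cstart:min(cstart + 2L, length(cds))])
  pad <- 3L - nchar(codon)
  if (pad > 0L) codon <- paste0(codon, strrep("A", pad))  # poly-A completion
  within <- off - cstart + 1L
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_b
  aa_ref <- .translateCodon(codon)
  aa_alt <- .translateCodon(alt_codon)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}

#' Annotate variant consequences on the mitochondrial gene model
#'
#' Classifies each variant as synonymous / missense / nonsense /
#' frameshift / tRNA / rRNA / noncoding. Protein-gene SNVs are translated
#' with the vertebrate mitochondrial genetic code (AGA/AGG stop, ATA Met,
#' TGA Trp); light-strand genes (e.g. ND6) are reverse-complemented before
#' codon lookup; protein-gene indels whose length change is not divisible
#' by 3 are frameshifts (in-frame indels are reported protein-altering,
#' i.e. missense). Variants in overlapping genes are annotated against
#' both, worst consequence reported; variants outside every gene (or in
#' the control region) are noncoding. A variant spanning a gene boundary
#' is annotated against the gene containing its start, with a warning.
#'
#' @param calls call data.frame or \code{MtCallSet} (needs \code{pos, ref,
#'   alt}).
#' @param model an \code{\link{MtGeneModel}} with reference attached.
#' @param pathogenicList optional data.frame with columns \code{position,
#'   allele}: alleles to flag as pathogenic.
#' @param trnaRrnaNonsilent count tRNA/rRNA variants as non-silent
#'   (default TRUE).
#' @return data.frame with \code{pos, ref, alt, gene, category,
#'   is_nonsilent, pathogenic_flag}.
#' @export
annotateConsequence <- function(calls, model, pathogenicList = NULL,
                                trnaRrnaNonsilent = TRUE) {
  df <- if (is(calls, "MtCallSet")) mtCalls(calls) else as.data.frame(calls)
  genes <- model@genes
  n <- nrow(df)
  out <- data.frame(pos = df$pos, ref = df$ref, alt = df$alt,
                    gene = rep(NA_character_, n),
                    category = rep("noncoding", n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    pos <- df$pos[i]; ref <- df$ref[i]; alt <- df$alt[i]
    span_end <- pos + max(nchar(ref), 1L) - 1L
    hit <- which(genes$start <= pos & genes$end >= pos)
    if (!length(hit)) next
    if (any(span_end > genes$end[hit]))
      warning("variant at ", pos, " spans a gene boundary; annotated ",
              "against the gene containing its start", call. = FALSE)
    cats <- vapply(hit, function(j)
      .consequenceInGene(pos, ref, alt, genes[j, ], model@refSeq),
      character(1))
    worst <- which.max(.SEVERITY[cats])
    out$category[i] <- cats[worst]
    out$gene[i] <- genes$name[hit[worst]]
  }
  silent_cats <- c("synonymous", "noncoding",
                   if (!trnaRrnaNonsilent) c("tRNA", "rRNA"))
  out$is_nonsilent <- !(out$category %in% silent_cats)
  out$pathogenic_flag <- if (is.null(pathogenicList) || !nrow(pathogenicList)) {
    rep(FALSE, n)
  } else {
    paste(out$pos, out$alt, sep = ":") %in%
      paste(pathogenicList$position, pathogenicList$allele, sep = ":")
  }
  out
}
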