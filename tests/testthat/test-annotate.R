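# reference with known codons planted in two synthetic genes:
#   heavy-strand protein gene 10..18   = CTA CTA CTA (Leu Leu Leu)
#   light-strand protein gene 30..38   = revcomp CTA CTA CTA
testModel <- function() {
  set.seed(4)
  base <- sample(c("A", "C", "G", "T"), 16569, replace = TRUE)
  base[10:18] <- strsplit("CTACTACTA", "")[[1]]
  base[30:38] <- strsplit("TAGTAGTAG", "")[[1]]  # revcomp is CTACTACTA
  base[50:58] <- strsplit("TCATCATCA", "")[[1]]  # Ser Ser Ser
  genesPath <- tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend\tstrand\ttype",
               "GH\t10\t18\theavy\tprotein",
               "GL\t30\t38\tlight\tprotein",
               "GS\t50\t58\theavy\tprotein",
               "TR1\t100\t160\theavy\ttRNA",
               "RR1\t200\t400\theavy\trRNA",
               "INC\t500\t506\theavy\tprotein"),   # length 7: incomplete stop
             genesPath)
  mtGeneModel(refSeq = paste(base, collapse = ""), genesPath = genesPath)
}

annOne <- function(model, pos, ref, alt, ...) {
  annotateConsequence(data.frame(pos = pos, ref = ref, alt = alt),
                      model, ...)
}

test_that("noncoding, synonymous, missense, nonsense, frameshift", {
  m <- testModel()
  # intergenic position
  a <- annOne(m, 5000L, as.character(m@refSeq[5000]), "A")
  if (a$ref == a$alt) a <- annOne(m, 5000L, a$ref, "C")
  expect_equal(a$category, "noncoding")
  expect_false(a$is_nonsilent)
  # third codon position CTA -> CTG: Leu -> Leu, synonymous
  s <- annOne(m, 12L, "A", "G")
  expect_equal(s$category, "synonymous")
  expect_false(s$is_nonsilent)
  # first codon position CTA -> GTA: Leu -> Val, missense
  expect_equal(annOne(m, 10L, "C", "G")$category, "missense")
  # TCA -> TAA: Ser -> stop, nonsense
  n <- annOne(m, 51L, "C", "A")
  expect_equal(n$category, "nonsense")
  expect_true(n$is_nonsilent)
  # 1-bp insertion in a protein gene -> frameshift
  fs <- annOne(m, 11L, "T", "TA")
  expect_equal(fs$category, "frameshift")
  expect_true(fs$is_nonsilent)
  # tRNA and rRNA categories, non-silent by default, silent when configured
  expect_equal(annOne(m, 120L, as.character(m@refSeq[120]), "N")$category,
               "tRNA")
  expect_true(annOne(m, 250L, as.character(m@refSeq[250]), "N")$is_nonsilent)
  expect_false(annOne(m, 250L, as.character(m@refSeq[250]), "N",
                      trnaRrnaNonsilent = FALSE)$is_nonsilent)
})

test_that("light-strand genes are annotated on the reverse complement", {
  m <- testModel()
  # ref[36] = T; CDS codon 1 = CTA (Leu). alt G reads as C on the coding
  # strand: CTA -> CTC, synonymous
  expect_equal(annOne(m, 36L, "T", "G")$category, "synonymous")
  # independent oracle: translate the reverse-complemented CDS directly
  cds <- Biostrings::reverseComplement(m@refSeq[30:38])
  expect_equal(as.character(Biostrings::translate(
    cds, genetic.code = Biostrings::getGeneticCode("SGC1"))), "LLL")
  # alt A reads as T: CTA -> CTT, still Leu
  expect_equal(annOne(m, 36L, "T", "A")$category, "synonymous")
  # ref[38] = G maps to codon 1 position 1: CTA -> TTA keeps Leu;
  # but -> ATA (alt T on heavy strand) is Met: missense
  expect_equal(annOne(m, 38L, "G", "A")$category, "synonymous")
  expect_equal(annOne(m, 38L, "G", "T")$category, "missense")
})

test_that("the reference allele annotated against itself is silent", {
  m <- testModel()
  for (pos in c(10L, 14L, 33L, 120L, 5000L)) {
    rb <- as.character(m@refSeq[pos])
    a <- annotateConsequence(data.frame(pos = pos, ref = rb, alt = rb), m)
    expect_false(a$category %in% c("missense", "nonsense", "frameshift"))
  }
})

test_that("packaged rCRS gene model is valid and flags incomplete stops", {
  m <- mtGeneModel()
  expect_equal(nrow(m@genes), 39L)   # 37 features + split control region
  expect_equal(sum(m@genes$type == "protein"), 13L)
  expect_setequal(m@genes$name[m@genes$incomplete_stop],
                  c("ND1", "ND2", "CO3", "ND3", "ND4", "CYB"))
  # overlapping gene pairs are present (ATP8/ATP6, ND4L/ND4)
  atp <- m@genes[m@genes$name %in% c("ATP8", "ATP6"), ]
  expect_true(max(atp$start) <= min(atp$end))
  # every chrM position resolves to exactly one category without error
  set.seed(8)
  ref <- paste(sample(c("A", "C", "G", "T"), 16569, replace = TRUE),
               collapse = "")
  m2 <- mtGeneModel(refSeq = ref)
  pos <- as.integer(sample(16569, 80))
  rb <- vapply(pos, function(p) as.character(m2@refSeq[p]), character(1))
  alt <- ifelse(rb == "A", "C", "A")
  ann <- annotateConsequence(data.frame(pos = pos, ref = rb, alt = alt), m2)
  expect_true(all(ann$category %in% c("synonymous", "missense", "nonsense",
                                      "frameshift", "tRNA", "rRNA",
                                      "noncoding")))
})

test_that("incomplete terminal codons are A-padded before translation", {
  m <- testModel()
  expect_true(m@genes$incomplete_stop[m@genes$name == "INC"])
  # SNV in the 7th base (partial codon 3, padded with AA) must not error
  rb <- as.character(m@refSeq[506])
  a <- annOne(m, 506L, rb, setdiff(c("A", "C", "G", "T"), rb)[1])
  expect_true(a$category %in% c("synonymous", "missense", "nonsense"))
})

test_that("pathogenic alleles are flagged by list membership", {
  m <- testModel()
  plist <- data.frame(position = 51L, allele = "A")
  a <- annOne(m, 51L, "C", "A", pathogenicList = plist)
  expect_true(a$pathogenic_flag)
  b <- annOne(m, 51L, "C", "G", pathogenicList = plist)
  expect_false(b$pathogenic_flag)
})

test_that("variants in overlapping genes report the worst consequence", {
  genesPath <- tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend\tstrand\ttype",
               "P1\t10\t18\theavy\tprotein",
               "R1\t10\t30\theavy\trRNA"), genesPath)
  set.seed(4)
  ref <- sample(c("A", "C", "G", "T"), 16569, replace = TRUE)
  ref[10:18] <- strsplit("TCATCATCA", "")[[1]]
  m <- mtGeneModel(paste(ref, collapse = ""), genesPath = genesPath)
  # TCA -> TAA nonsense in P1 beats rRNA
  expect_equal(annOne(m, 11L, "C", "A")$category, "nonsense")
  # synonymous in P1: rRNA (more severe than synonymous) is reported
  expect_equal(annOne(m, 12L, "A", "G")$category, "rRNA")
})
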