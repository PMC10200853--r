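test_that("the same spec and seed reproduce the cohort exactly", {
  c1 <- simulateCohort(smallSpec(seed = 9L))
  c2 <- simulateCohort(smallSpec(seed = 9L))
  expect_equal(c1@truth, c2@truth)
  expect_equal(c1@depthTable, c2@depthTable)
  expect_equal(mtCalls(c1@tumourCalls[[1]]$caller_a),
               mtCalls(c2@tumourCalls[[1]]$caller_a))
  expect_equal(as.character(c1@refSeq), as.character(c2@refSeq))
  c3 <- simulateCohort(smallSpec(seed = 10L))
  expect_false(identical(c1@truth, c3@truth))
})

test_that("per-sample substreams keep earlier samples fixed as the cohort
          grows", {
  # fixed normal panel: the germline exclusion zone, hence every tumour
  # substream, is then independent of the tumour count
  a <- simulateCohort(simulationSpec(seed = 5L, groupSizes = c(g = 3L),
                                     nNormals = 3L, nNoisyPositions = 10L))
  b <- simulateCohort(simulationSpec(seed = 5L, groupSizes = c(g = 5L),
                                     nNormals = 3L, nNoisyPositions = 10L))
  for (i in 1:3)
    expect_equal(mtCalls(a@tumourCalls[[i]]$caller_a),
                 mtCalls(b@tumourCalls[[i]]$caller_a))
})

test_that("every emitted record carries exactly one ground-truth label", {
  cohort <- simulateCohort(smallSpec(seed = 17L))
  for (sid in names(cohort@tumourCalls)) {
    u <- unionCalls(cohort@tumourCalls[[sid]]$caller_a,
                    cohort@tumourCalls[[sid]]$caller_b)
    tr <- cohort@truth[cohort@truth$sample_id == sid, ]
    expect_equal(length(u), nrow(tr))
    key <- function(d) sort(paste(d$pos, d$ref, d$alt))
    expect_equal(key(mtCalls(u)), key(tr))
  }
})

test_that("with no somatic and no artifact injections the pass set is empty", {
  spec <- smallSpec(seed = 23L,
                    artifactRates = c(BLACKLIST = 0),
                    nTrueSomaticMean = 0,
                    groupProfiles = list(
                      "BHD" = list(nSomaticMean = 0),
                      "sporadic-ChRCC" = list(nSomaticMean = 0)))
  cohort <- simulateCohort(spec)
  expect_false(any(cohort@truth$label %in%
                     c("true_somatic", paste0("artifact:", "STRAND"))))
  model <- estimateNoise(cohort@normalCalls)
  resource <- rbind(buildGermlineResource(cohort@normalCalls),
                    cohort@germlineResource)
  for (sid in names(cohort@tumourCalls)) {
    u <- unionCalls(cohort@tumourCalls[[sid]]$caller_a,
                    cohort@tumourCalls[[sid]]$caller_b)
    nrm <- cohort@normalCalls[[
      cohort@sampleTable$matched_normal[cohort@sampleTable$sample_id == sid]]]
    v <- filterVariants(u, resource = resource, normalCalls = nrm,
                        model = model)
    expect_equal(sum(v$passed), 0L)
  }
})

test_that("high-depth somatic injections at VAF ~ 0.3 are recovered", {
  # Beta(50, 130) rescaled concentrates VAF tightly around 0.30; chrM
  # depth is in the thousands, so >= 48/50 recovered is the expectation
  spec <- simulationSpec(seed = 31L, groupSizes = c(g = 16L),
                         nTrueSomaticMean = 5,
                         somaticVafShape = c(50, 130),
                         groupProfiles = list(),
                         nNoisyPositions = 10L)
  cohort <- simulateCohort(spec)
  model <- estimateNoise(cohort@normalCalls)
  resource <- rbind(buildGermlineResource(cohort@normalCalls),
                    cohort@germlineResource)
  recovered <- 0L; total <- 0L
  for (sid in names(cohort@tumourCalls)) {
    tr <- cohort@truth[cohort@truth$sample_id == sid &
                         cohort@truth$label == "true_somatic", ]
    if (!nrow(tr)) next
    u <- unionCalls(cohort@tumourCalls[[sid]]$caller_a,
                    cohort@tumourCalls[[sid]]$caller_b)
    nrm <- cohort@normalCalls[[
      cohort@sampleTable$matched_normal[cohort@sampleTable$sample_id == sid]]]
    v <- filterVariants(u, resource = resource, normalCalls = nrm,
                        model = model)
    hit <- paste(v$pos, v$ref, v$alt) %in% paste(tr$pos, tr$ref, tr$alt)
    total <- total + nrow(tr)
    recovered <- recovered + sum(v$passed & hit)
    if (total >= 50L) break
  }
  expect_gte(total, 50L)
  expect_gte(recovered / total, 48 / 50)
})

test_that("fixture bundle writes a manifest and round-trips records", {
  cohort <- simulateCohort(simulationSpec(
    seed = 13L, groupSizes = c(g = 2L), nNormals = 2L,
    nGermlineHaplogroup = 8L, nNoisyPositions = 5L, groupProfiles = list()))
  dir <- tempfile("bundle-")
  manifest <- writeFixtureBundle(cohort, dir)
  expect_equal(manifest$seed, 13L)
  # one VCF per caller per tumour plus one per normal
  kinds <- vapply(manifest$vcfs, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "tumour"), 2L * 2L)
  expect_equal(sum(kinds == "normal"), 2L)
  json <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(json$seed, 13L)
  # records reread from disk equal the in-memory call set
  sid <- names(cohort@tumourCalls)[1]
  back <- readVariantVcf(
    file.path(dir, "vcf", sprintf("%s.caller_a.vcf", sid)), "caller_a")
  expect_equal(sampleId(back), sid)
  orig <- mtCalls(cohort@tumourCalls[[sid]]$caller_a)
  orig <- orig[order(orig$pos, orig$ref, orig$alt), ]
  got <- mtCalls(back)
  expect_equal(got$pos, orig$pos)
  expect_equal(got$variant_reads, orig$variant_reads, ignore_attr = TRUE)
  expect_equal(got$variant_base_quality, orig$variant_base_quality,
               ignore_attr = TRUE)
  # depth and purity tables reread through the package readers
  expect_equal(readDepthTable(file.path(dir, "depth.tsv")),
               cohort@depthTable, tolerance = 1e-9)
  expect_equal(readPurityPloidy(file.path(dir, "purity.tsv"))$f,
               cohort@purityTable$f, tolerance = 1e-9)
})
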