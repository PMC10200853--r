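test_that("germline removal applies the printed frequency rules", {
  cfg <- filterConfig()
  res <- data.frame(
    position = c(100L, 200L, 300L, 400L),
    allele = c("G", "G", "G", "G"),
    source = c("population_db", "population_db", "cohort_normals",
               "cohort_normals"),
    frequency_or_vaf = c(0.02, 0.009, 0.96, 0.95))
  isG <- function(pos) removeGermline(makeCall(pos = pos), resource = res,
                                      config = cfg)$germline
  expect_true(isG(100L))    # population frequency 2% > 1%
  expect_false(isG(200L))   # 0.9% is not > 1%
  expect_true(isG(300L))    # cohort VAF 96% > 95%
  expect_false(isG(400L))   # 95% is not > 95% (strict)
  expect_false(isG(999L))   # absent everywhere
})

test_that("a matched-normal allele above 95% VAF is germline", {
  nrm <- makeCall(pos = 500L, sample_id = "N1",
                  variant_reads = 960L, forward_variant_reads = 480L)
  expect_true(removeGermline(makeCall(pos = 500L),
                             normalCalls = nrm)$germline)
  nrm2 <- makeCall(pos = 500L, sample_id = "N1",
                   variant_reads = 940L, forward_variant_reads = 470L)
  expect_false(removeGermline(makeCall(pos = 500L),
                              normalCalls = nrm2)$germline)
  # allele-specific: a different alt at the same position does not match
  tum <- makeCall(pos = 500L); tum$alt <- "T"
  expect_false(removeGermline(tum, normalCalls = nrm)$germline)
})

test_that("noise level is mean + 3 SD across normals, clamped by the floor", {
  mkN <- function(id, pos, vr, depth = 1000L)
    makeCall(sample_id = id, pos = pos, variant_reads = as.integer(vr),
             forward_variant_reads = as.integer(vr %/% 2),
             total_depth = as.integer(depth))
  # three normals all at VAF 0.01: SD 0, noise = 0.01 >= floor
  panel <- list(N1 = mkN("N1", 700L, 10L), N2 = mkN("N2", 700L, 10L),
                N3 = mkN("N3", 700L, 10L))
  m <- estimateNoise(panel, floor = 0.005)
  expect_equal(noiseAt(m, 700L), 0.01)
  # position without signal in any normal carries the floor
  expect_equal(noiseAt(m, 701L), 0.005)
  # single-normal panel: SD undefined -> 0; noise = max(vaf, floor)
  m1 <- estimateNoise(list(N1 = mkN("N1", 800L, 40L)), floor = 0.005)
  expect_equal(noiseAt(m1, 800L), 0.04)
  # hand-check mean + 3 SD with unequal VAFs {0.01, 0.02, 0.03}
  panel2 <- list(N1 = mkN("N1", 900L, 10L), N2 = mkN("N2", 900L, 20L),
                 N3 = mkN("N3", 900L, 30L))
  m2 <- estimateNoise(panel2, floor = 0.005)
  expect_equal(noiseAt(m2, 900L), mean(c(0.01, 0.02, 0.03)) +
                 3 * sd(c(0.01, 0.02, 0.03)))
  # a normal without a record at the position contributes 0
  panel3 <- list(N1 = mkN("N1", 950L, 20L), N2 = mkN("N2", 951L, 20L))
  m3 <- estimateNoise(panel3, floor = 0)
  expect_equal(noiseAt(m3, 950L), mean(c(0.02, 0)) + 3 * sd(c(0.02, 0)))
})

test_that("near-fixed germline alleles are excluded from noise estimation", {
  g <- makeCall(sample_id = "N1", pos = 600L, variant_reads = 990L,
                forward_variant_reads = 495L)
  m <- estimateNoise(list(N1 = g), floor = 0.005)
  expect_equal(noiseAt(m, 600L), 0.005)   # VAF 0.99 ignored as germline
})

test_that("the noise filter is a strict comparison", {
  m <- new("NoiseModel", perPositionNoise = c("1000" = 0.005), floor = 0.005,
           nNormals = 3L)
  vafCall <- function(vaf) {
    d <- makeCall(total_depth = 100000L,
                  variant_reads = as.integer(vaf * 100000),
                  forward_variant_reads = as.integer(vaf * 50000))
    d
  }
  expect_length(applyNoiseFilter(vafCall(0.30), m), 0L)
  expect_equal(applyNoiseFilter(vafCall(0.004), m), "BELOW_NOISE")
  expect_length(applyNoiseFilter(vafCall(0.005), m), 0L)  # equal passes
})

test_that("an empty normal panel is a hard error", {
  expect_error(estimateNoise(list()), "empty normal panel")
})

test_that("calls near a germline variant are flagged adjacent, not the
          germline call itself", {
  cfg <- filterConfig()
  nrm <- makeCall(pos = 500L, sample_id = "N1", variant_reads = 990L,
                  forward_variant_reads = 495L)
  cs <- makeCallSet(c(498, 502, 504, 500))
  out <- mtCalls(flagGermlineAdjacency(cs, normalCalls = nrm, config = cfg))
  expect_true(out$adjacent_to_germline[out$pos == 498])   # within 2 bp
  expect_true(out$adjacent_to_germline[out$pos == 502])
  expect_false(out$adjacent_to_germline[out$pos == 504])  # 4 bp away
  expect_false(out$adjacent_to_germline[out$pos == 500])  # the allele itself
})
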