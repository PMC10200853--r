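test_that("union of disjoint, identical and overlapping call sets", {
  a <- makeCallSet(c(100, 200), caller = "caller_a")
  b <- makeCallSet(c(300, 400, 500), caller = "caller_b")
  expect_equal(length(unionCalls(a, b)), 5L)

  a4 <- makeCallSet(c(10, 20, 30, 40), caller = "caller_a")
  b4 <- makeCallSet(c(10, 20, 30, 40), caller = "caller_b")
  u <- unionCalls(a4, b4)
  expect_equal(length(u), 4L)
  expect_true(all(mtCalls(u)$callers == "caller_a,caller_b"))

  # |A| = 3, |B| = 3, overlap 1 -> 5 by inclusion-exclusion
  a3 <- makeCallSet(c(1, 2, 3), caller = "caller_a")
  b3 <- makeCallSet(c(3, 4, 5), caller = "caller_b")
  expect_equal(length(unionCalls(a3, b3)), 5L)
})

test_that("union is commutative on keys, caller sets and annotations", {
  a <- makeCallSet(c(100, 200), caller = "caller_a",
                   variant_base_quality = 31)
  b <- makeCallSet(c(200, 300), caller = "caller_b",
                   variant_base_quality = 25)
  u1 <- mtCalls(unionCalls(a, b))
  u2 <- mtCalls(unionCalls(b, a))
  expect_equal(u1[c("pos", "ref", "alt", "callers")],
               u2[c("pos", "ref", "alt", "callers")])
  # caller_a's annotations win for the shared record regardless of order
  expect_equal(u1$variant_base_quality[u1$pos == 200], 31)
  expect_equal(u2$variant_base_quality[u2$pos == 200], 31)
})

test_that("union errors on conflicting variant type and mixed samples", {
  a <- makeCallSet(100, caller = "caller_a")
  bdf <- makeCall(pos = 100L, ref = "A", alt = "AG", is_indel = TRUE,
                  callers = "caller_b")
  bdf$alt <- "G"; bdf$is_indel <- TRUE
  b <- MtCallSet(bdf, sampleId = "T1")
  expect_error(unionCalls(a, b), "is_indel")
  expect_error(unionCalls(a, makeCallSet(5, sampleId = "OTHER")),
               "different samples")
})

test_that("position blacklist honours inclusive bounds and indel-only regions", {
  bl <- defaultBlacklist()
  expect_equal(checkPositionBlacklist(makeCall(pos = 302L), bl), "BLACKLIST")
  expect_equal(checkPositionBlacklist(makeCall(pos = 315L), bl), "BLACKLIST")
  expect_length(checkPositionBlacklist(makeCall(pos = 301L), bl), 0L)
  expect_length(checkPositionBlacklist(makeCall(pos = 316L), bl), 0L)
  # 16180-16195 applies to indels only
  expect_length(checkPositionBlacklist(makeCall(pos = 16185L), bl), 0L)
  ind <- makeCall(pos = 16185L, ref = "A", alt = "AT", is_indel = TRUE)
  expect_equal(checkPositionBlacklist(ind, bl), "BLACKLIST")
})

test_that("each read-evidence criterion is a sharp boundary", {
  cfg <- filterConfig()
  run <- function(...) checkReadEvidence(makeCall(...), cfg)
  expect_length(run(), 0L)
  # support: >= 10
  expect_equal(run(variant_reads = 9L, forward_variant_reads = 5L), "SUPPORT")
  expect_length(run(variant_reads = 10L, forward_variant_reads = 5L), 0L)
  # base quality: >= 20
  expect_equal(run(variant_base_quality = 19.99), "BASE_QUALITY")
  expect_length(run(variant_base_quality = 20), 0L)
  # strand fraction strictly inside (0.1, 0.9): 0.9 is not < 0.9
  expect_equal(run(variant_reads = 100L, forward_variant_reads = 90L),
               "STRAND")
  expect_equal(run(variant_reads = 100L, forward_variant_reads = 10L),
               "STRAND")
  expect_length(run(variant_reads = 100L, forward_variant_reads = 89L), 0L)
  expect_length(run(variant_reads = 100L, forward_variant_reads = 11L), 0L)
  # read position strictly inside (0.15, 0.85)
  expect_equal(run(mean_read_position = 0.15), "READ_POSITION")
  expect_equal(run(mean_read_position = 0.85), "READ_POSITION")
  expect_length(run(mean_read_position = 0.1501), 0L)
  # read length difference < 25
  expect_equal(run(ref_read_length = 150, var_read_length = 125),
               "LENGTH_DIFF")
  expect_length(run(ref_read_length = 150, var_read_length = 125.01), 0L)
  # mapping quality difference < 10
  expect_equal(run(ref_mapq = 60, var_mapq = 50), "MAPQ_DIFF")
  expect_length(run(ref_mapq = 60, var_mapq = 50.01), 0L)
  # normal context > 0.80, waived next to a germline variant
  expect_equal(run(normal_context_fraction = 0.80), "NORMAL_CONTEXT")
  expect_length(run(normal_context_fraction = 0.8001), 0L)
  expect_length(run(normal_context_fraction = 0.5,
                    adjacent_to_germline = TRUE), 0L)
  # NM difference <= 3 (inclusive)
  expect_length(run(ref_nm = 1, var_nm = 4), 0L)
  expect_equal(run(ref_nm = 1, var_nm = 4.01), "NM_DIFF")
})

test_that("zero variant reads fails SUPPORT without dividing by zero", {
  r <- checkReadEvidence(makeCall(variant_reads = 0L,
                                  forward_variant_reads = 0L))
  expect_true("SUPPORT" %in% r)
  expect_false("STRAND" %in% r)
})

test_that("missing annotations fail closed with MISSING_ANNOTATION", {
  r <- checkReadEvidence(makeCall(normal_context_fraction = NA))
  expect_equal(r, "MISSING_ANNOTATION")
  # present criteria are still evaluated alongside the flag
  r2 <- checkReadEvidence(makeCall(normal_context_fraction = NA,
                                   variant_reads = 5L,
                                   forward_variant_reads = 3L))
  expect_setequal(r2, c("SUPPORT", "MISSING_ANNOTATION"))
})

test_that("criteria are evaluated independently, no short-circuit", {
  v <- filterVariant(makeCall(variant_reads = 9L, forward_variant_reads = 9L))
  expect_setequal(v$failed_reasons, c("SUPPORT", "STRAND"))
  v2 <- filterVariant(makeCall(pos = 302L, variant_reads = 9L,
                               forward_variant_reads = 5L))
  expect_setequal(v2$failed_reasons, c("BLACKLIST", "SUPPORT"))
  v3 <- filterVariant(makeCall())
  expect_true(v3$passed)
  expect_length(v3$failed_reasons, 0L)
})

test_that("the reason set is invariant to stage evaluation order", {
  cfg <- filterConfig()
  bl <- defaultBlacklist()
  resource <- data.frame(position = 302L, allele = "G",
                         source = "population_db", frequency_or_vaf = 0.2)
  model <- new("NoiseModel", perPositionNoise = c("302" = 0.9), floor = 0.005,
               nNormals = 1L)
  call <- makeCall(pos = 302L, variant_reads = 9L,
                   forward_variant_reads = 5L)
  call$vaf <- call$variant_reads / call$total_depth
  stages <- list(
    blacklist = function() checkPositionBlacklist(call, bl),
    evidence = function() checkReadEvidence(call, cfg),
    germline = function() {
      d <- removeGermline(call, resource = resource, config = cfg)
      if (d$germline[1]) "GERMLINE" else character(0)
    },
    noise = function() applyNoiseFilter(call, model))
  set.seed(5)
  combined <- filterVariant(call, cfg, bl, resource, NULL, model)$failed_reasons
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    manual <- unlist(lapply(stages[perm], function(f) f()))
    expect_setequal(unname(manual), combined)
  }
})

test_that("filtering is idempotent: the pass set passes again unchanged", {
  set.seed(11)
  n <- 60
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    makeCall(pos = as.integer(sample(16569, 1)),
             variant_reads = as.integer(sample(c(5L, 50L, 300L), 1)),
             forward_variant_reads = 0L,
             mean_read_position = round(runif(1, 0.05, 0.95), 3))))
  df$forward_variant_reads <- vapply(df$variant_reads, function(v)
    rbinom(1, v, 0.5), integer(1))
  cs <- MtCallSet(df, sampleId = "T1")
  v1 <- filterVariants(cs)
  pass1 <- v1[v1$passed, setdiff(names(v1), c("passed", "reasons"))]
  expect_lte(nrow(pass1), nrow(df))        # pass set is a subset
  v2 <- filterVariants(MtCallSet(pass1, sampleId = "T1"))
  expect_true(all(v2$passed))
  expect_equal(v2[, names(pass1)], pass1, ignore_attr = TRUE)
})
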