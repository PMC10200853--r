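# A single call whose read evidence sits at interior (safely passing)
# points of every filter criterion; tests perturb one field at a time.
makeCall <- function(...) {
  base <- list(
    sample_id = "T1", pos = 1000L, ref = "A", alt = "G", is_indel = FALSE,
    total_depth = 1000L, variant_reads = 300L, forward_variant_reads = 150L,
    variant_base_quality = 30, mean_read_position = 0.5,
    ref_read_length = 150, var_read_length = 150,
    ref_mapq = 60, var_mapq = 60, normal_context_fraction = 0.95,
    ref_nm = 1, var_nm = 1.5, adjacent_to_germline = FALSE,
    callers = "caller_a")
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  df <- as.data.frame(base, stringsAsFactors = FALSE)
  df$vaf <- ifelse(df$total_depth > 0, df$variant_reads / df$total_depth, NA)
  df
}

makeCallSet <- function(positions, sampleId = "T1", caller = "caller_a",
                        ...) {
  df <- do.call(rbind, lapply(positions, function(p)
    makeCall(pos = as.integer(p), sample_id = sampleId,
             callers = caller, ...)))
  MtCallSet(df, sampleId = sampleId)
}

reasonsOf <- function(verdicts, i = 1L) {
  r <- strsplit(verdicts$reasons[i], ",")[[1]]
  r[nzchar(r)]
}

# small, fast cohort spec for pipeline-level tests
smallSpec <- function(seed = 42L, ...) {
  simulationSpec(seed = seed,
                 groupSizes = c("BHD" = 4L, "sporadic-ChRCC" = 4L),
                 nNormals = 4L, nGermlineHaplogroup = 15L,
                 nNoisyPositions = 15L, ...)
}
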