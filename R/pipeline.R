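.stageStop <- function(stage, ...)
  stop(stage, " stage: ", ..., call. = FALSE)

.log <- function(verbose, ...) if (verbose) message(...)

#' Run the full mtDNA analysis pipeline on a fixture bundle
#'
#' End-to-end orchestration over a bundle directory (the layout written by
#' \code{\link{writeFixtureBundle}}, described by its
#' \code{manifest.json}): copy-number estimation; per-sample caller union;
#' blacklist and read-evidence filters; germline removal (cohort-normals
#' panel built from the bundle's normals, the bundle's population-database
#' resource, and the matched normal); noise-level estimation from the
#' normal panel; noise filter; somatic/dysplastic classification;
#' consequence annotation; per-sample summaries and pairwise Welch tests.
#' Every stage logs record counts in/out, and the resolved configuration
#' is embedded in the returned report.
#'
#' @param inputDir bundle directory containing \code{manifest.json}.
#' @param outDir output directory for the result tables and
#'   \code{report.json} (default \code{<inputDir>/results}).
#' @param config a \code{\link{FilterConfig}}.
#' @param pathogenicList optional data.frame (\code{position, allele}) of
#'   pathogenic alleles to flag.
#' @param trnaRrnaNonsilent count tRNA/rRNA variants as non-silent.
#' @param verbose log per-stage counts via \code{message()}.
#' @return the run report (list), invisibly; also written as
#'   \code{report.json}.
#' @export
runPipeline <- function(inputDir, outDir = file.path(inputDir, "results"),
                        config = filterConfig(), pathogenicList = NULL,
                        trnaRrnaNonsilent = TRUE, verbose = TRUE) {
  mpath <- file.path(inputDir, "manifest.json")
  if (!file.exists(mpath)) .stageStop("ingest", "no manifest.json in ", inputDir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  fp <- function(rel) file.path(inputDir, rel)
  need <- function(stage, rel) {
    if (is.null(rel) || !file.exists(fp(rel)))
      .stageStop(stage, "required input missing: ",
                 if (is.null(rel)) "(not in manifest)" else rel)
    fp(rel)
  }

  ## -- copy number ----------------------------------------------------
  depth <- readDepthTable(need("copy_number", manifest$files$depth))
  purity <- readPurityPloidy(need("copy_number", manifest$files$purity))
  cn <- estimateCohortCopyNumber(depth, purity)
  .log(verbose, "copy_number: ", nrow(cn), " sample(s)")

  samples <- .readTsv(need("ingest", manifest$files$samples))
  blacklist <- readBlacklist(need("ingest", manifest$files$blacklist))
  popResource <- readGermlineResource(
    need("ingest", manifest$files$germline_resource))
  geneModel <- mtGeneModel(refSeq = need("annotation",
                                         manifest$files$reference))

  vcfs <- manifest$vcfs
  kindOf <- vapply(vcfs, `[[`, character(1), "kind")
  sidOf <- vapply(vcfs, `[[`, character(1), "sample_id")
  callerOf <- vapply(vcfs, `[[`, character(1), "caller")

  ## -- normal panel ----------------------------------------------------
  normal_ids <- unique(sidOf[kindOf == "normal"])
  if (!length(normal_ids)) .stageStop("noise", "no normal samples in bundle")
  normalCalls <- lapply(normal_ids, function(sid) {
    idx <- which(sidOf == sid & kindOf == "normal")[1]
    readVariantVcf(need("ingest", vcfs[[idx]]$path),
                   callerId = callerOf[idx], sampleId = sid)
  })
  names(normalCalls) <- normal_ids
  resource <- rbind(buildGermlineResource(normalCalls), popResource)
  model <- estimateNoise(normalCalls, floor = config@noiseFloor,
                         germlineVafThreshold = config@germlineVafThreshold)
  .log(verbose, "noise model: ", length(model@perPositionNoise),
       " position(s) above floor from ", length(normal_ids), " normal(s)")

  ## -- per-tumour filter chain -----------------------------------------
  tumour_rows <- samples[samples$kind == "tumour", , drop = FALSE]
  audits <- list(); classifieds <- list(); summaries <- list()
  stage_counts <- list()
  for (i in seq_len(nrow(tumour_rows))) {
    sid <- tumour_rows$sample_id[i]
    nrm <- normalCalls[[tumour_rows$matched_normal[i]]]
    idxA <- which(sidOf == sid & callerOf == "caller_a" & kindOf == "tumour")
    idxB <- which(sidOf == sid & callerOf == "caller_b" & kindOf == "tumour")
    if (!length(idxA) || !length(idxB))
      .stageStop("union", "missing caller VCF(s) for ", sid)
    u <- unionCalls(
      readVariantVcf(need("union", vcfs[[idxA[1]]]$path), "caller_a", sid),
      readVariantVcf(need("union", vcfs[[idxB[1]]]$path), "caller_b", sid))
    u <- flagGermlineAdjacency(u, resource = resource, normalCalls = nrm,
                               config = config)
    audit <- filterVariants(u, config = config, regions = blacklist,
                            resource = resource, normalCalls = nrm,
                            model = model)
    has <- function(code) grepl(code, audit$reasons, fixed = TRUE)
    n_union <- nrow(audit)
    n_after_evidence <- sum(!(has("BLACKLIST") | has("SUPPORT") |
      has("BASE_QUALITY") | has("STRAND") | has("READ_POSITION") |
      has("LENGTH_DIFF") | has("MAPQ_DIFF") | has("NORMAL_CONTEXT") |
      has("NM_DIFF") | has("MISSING_ANNOTATION")))
    n_after_germline <- sum(audit$reasons == "" |
                              audit$reasons == "BELOW_NOISE")
    n_pass <- sum(audit$passed)
    cls <- classifyVariants(audit, normalCalls = nrm, config = config)
    n_dropped <- nrow(attr(cls, "dropped"))
    ann <- annotateConsequence(cls, geneModel,
                               pathogenicList = pathogenicList,
                               trnaRrnaNonsilent = trnaRrnaNonsilent)
    cls <- cbind(cls, ann[, c("gene", "category", "is_nonsilent",
                              "pathogenic_flag")])
    cn_row <- cn[cn$sample_id == sid, , drop = FALSE]
    summaries[[sid]] <- summarizeSample(
      cls, cn = if (nrow(cn_row)) cn_row else NULL,
      group = tumour_rows$group[i], sampleIdValue = sid)
    stage_counts[[sid]] <- list(
      union = n_union, after_read_evidence = n_after_evidence,
      after_germline = n_after_germline, passed = n_pass,
      rejected = n_union - n_pass, classified = nrow(cls),
      dropped_unclassified = n_dropped)
    audits[[sid]] <- audit
    classifieds[[sid]] <- cls
    .log(verbose, sid, ": union ", n_union, " -> evidence ",
         n_after_evidence, " -> germline ", n_after_germline,
         " -> pass ", n_pass, " -> classified ", nrow(cls))
  }
  audit_all <- do.call(rbind, audits)
  classified_all <- do.call(rbind, classifieds)
  summary_all <- do.call(rbind, summaries)
  rownames(audit_all) <- rownames(classified_all) <-
    rownames(summary_all) <- NULL

  comparisons <- compareGroups(summary_all)
  cn_groups <- summarizeCopyNumberByGroup(
    cn[cn$sample_id %in% tumour_rows$sample_id, , drop = FALSE],
    stats::setNames(tumour_rows$group, tumour_rows$sample_id))

  ## -- outputs ----------------------------------------------------------
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(cn, "mt_copy_number.tsv")
  wtsv(cn_groups, "mt_copy_number_by_group.tsv")
  wtsv(audit_all, "filter_audit.tsv")
  wtsv(classified_all, "classified_variants.tsv")
  wtsv(summary_all, "sample_summaries.tsv")
  wtsv(comparisons, "group_comparisons.tsv")
  cfg <- lapply(stats::setNames(slotNames(config), slotNames(config)),
                function(nm) slot(config, nm))
  report <- list(
    config = cfg,
    n_tumours = nrow(tumour_rows), n_normals = length(normal_ids),
    stage_counts = stage_counts,
    noise_positions_above_floor = length(model@perPositionNoise),
    copy_number_by_group = cn_groups,
    comparisons = comparisons,
    outputs = list(dir = outDir,
                   tables = c("mt_copy_number.tsv",
                              "mt_copy_number_by_group.tsv",
                              "filter_audit.tsv", "classified_variants.tsv",
                              "sample_summaries.tsv",
                              "group_comparisons.tsv")))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the demo pipeline on a freshly simulated cohort
#'
#' Simulates a small paired cohort (two groups of six tumours), writes the
#' fixture bundle, runs \code{\link{runPipeline}} on it, and returns the
#' cohort, report and directories — a one-command end-to-end check with
#' known ground truth.
#'
#' @param seed master seed for the simulated cohort.
#' @param dir bundle directory (default: a fresh temporary directory).
#' @param verbose log per-stage counts.
#' @return list with \code{cohort}, \code{report}, \code{dir}.
#' @export
runDemo <- function(seed = 1L, dir = tempfile("mtSomatic-demo-"),
                    verbose = TRUE) {
  spec <- simulationSpec(
    seed = seed,
    groupSizes = c("BHD" = 6L, "sporadic-ChRCC" = 6L),
    nNormals = 6L, nGermlineHaplogroup = 20L, nNoisyPositions = 20L)
  cohort <- simulateCohort(spec)
  writeFixtureBundle(cohort, dir)
  report <- runPipeline(dir, verbose = verbose)
  list(cohort = cohort, report = report, dir = dir)
}
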