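#' Specification of a synthetic paired tumour/normal chrM cohort
#'
#' Builds the parameter list that \code{\link{simulateCohort}} consumes.
#' Defaults emulate the study conditions of a whole-genome renal-tumour
#' cohort: 16 BHD-associated tumours versus 49 sporadic ChRCCs, 30x
#' autosomal coverage, mtDNA copy numbers of hundreds to thousands per
#' cell, near-fixed germline haplogroup variants, strand-/position-biased
#' and blacklist-region artifacts, and a low per-position sequencing-error
#' baseline. The BHD profile carries fewer, lower-VAF somatic variants and
#' higher copy number than the sporadic profile. One master seed fixes the
#' whole cohort; per-sample substreams are derived by counter so earlier
#' samples are unchanged when the cohort grows.
#'
#' @param seed master seed (integer).
#' @param groupSizes named integer vector of tumours per group.
#' @param nNormals number of distinct normal samples; tumours are matched
#'   cyclically (default: one matched normal per tumour).
#' @param trueMtCNRange,purityRange,ploidyChoices sampling ranges for true
#'   copies/cell, tumour purity and tumour ploidy.
#' @param normalMtCNRange copies/cell range for normal tissues.
#' @param nTrueSomaticMean Poisson mean of injected somatic variants per
#'   tumour (per-group override via \code{groupProfiles}).
#' @param somaticVafShape Beta shape parameters; somatic VAFs are
#'   \code{0.05 + 0.9 * Beta(shape1, shape2)}.
#' @param nGermlineHaplogroup near-fixed germline variants per patient.
#' @param artifactRates named Poisson means per tumour for injected
#'   artifacts, keyed by the criterion each is designed to violate.
#' @param sequencingErrorVaf per-position error-call VAF baseline.
#' @param errorCallRate Poisson mean of stray error calls per tumour.
#' @param nNoisyPositions,noisyVafRange recurrently noisy (NUMT-like)
#'   positions shared across samples and their VAF level range.
#' @param meanDepthAuto mean autosomal depth.
#' @param depthOverdispersion negative-binomial size of per-site depths.
#' @param callerConcordance probability with which each caller reports a
#'   record (conditioned on at least one caller reporting it).
#' @param indelFraction fraction of injected germline/somatic variants
#'   that are 1-bp indels.
#' @param nAutoSites autosomal germline-variant sites averaged for
#'   mean depth.
#' @param groupProfiles named list of per-group overrides, each a list
#'   with any of \code{mtCNRange, nSomaticMean, somaticVafShape}.
#' @return a list of class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(
    seed = 1L,
    groupSizes = c("BHD" = 16L, "sporadic-ChRCC" = 49L),
    nNormals = NULL,
    trueMtCNRange = c(100, 2000),
    purityRange = c(0.3, 0.9),
    ploidyChoices = c(1.8, 2, 2.2, 3),
    normalMtCNRange = c(200, 1500),
    nTrueSomaticMean = 2,
    somaticVafShape = c(2, 2),
    nGermlineHaplogroup = 30L,
    artifactRates = c(BLACKLIST = 0.5, SUPPORT = 0.5, BASE_QUALITY = 0.5,
                      STRAND = 0.5, READ_POSITION = 0.5, LENGTH_DIFF = 0.5,
                      MAPQ_DIFF = 0.5, NORMAL_CONTEXT = 0.5, NM_DIFF = 0.5),
    sequencingErrorVaf = 0.002,
    errorCallRate = 2,
    nNoisyPositions = 40L,
    noisyVafRange = c(0.01, 0.05),
    meanDepthAuto = 30,
    depthOverdispersion = 30,
    callerConcordance = 0.9,
    indelFraction = 0.15,
    nAutoSites = 200L,
    groupProfiles = list(
      "BHD" = list(mtCNRange = c(500, 2000), nSomaticMean = 1,
                   somaticVafShape = c(2, 5)),
      "sporadic-ChRCC" = list(mtCNRange = c(100, 800), nSomaticMean = 3,
                              somaticVafShape = c(3, 3)))) {
  spec <- as.list(environment())
  stopifnot(length(groupSizes) >= 1L, all(groupSizes >= 0L),
            seed == as.integer(seed),
            purityRange[1] >= 0, purityRange[2] <= 1,
            purityRange[1] <= purityRange[2],
            all(ploidyChoices > 0), trueMtCNRange[1] > 0,
            callerConcordance > 0, callerConcordance <= 1,
            sequencingErrorVaf >= 0, sequencingErrorVaf < noisyVafRange[1],
            meanDepthAuto > 0, depthOverdispersion > 0)
  if (!all(names(artifactRates) %in% REASON_CODES))
    stop("artifactRates keys must be filter reason codes")
  spec$seed <- as.integer(seed)
  spec$nTumours <- sum(groupSizes)
  if (is.null(nNormals)) spec$nNormals <- spec$nTumours
  class(spec) <- "SimulationSpec"
  spec
}

## counter-derived substream seed, kept inside 32-bit integer range
.substreamSeed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483629 * 7919 +
                counter * 104729) %% 2147483629)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## per-read summaries centred at non-violating values (truncated normals)
.genuineStats <- function(vr, depth) {
  rrl <- round(stats::rnorm(1, 150, 5), 4)
  rmq <- round(.clamp(stats::rnorm(1, 60, 1), 50, 60), 4)
  rnm <- round(stats::runif(1, 0.5, 1.5), 4)
  list(
    total_depth = depth, variant_reads = vr,
    forward_variant_reads = stats::rbinom(1, vr, 0.5),
    variant_base_quality = round(.clamp(stats::rnorm(1, 32, 2.5), 25, 40), 4),
    mean_read_position = round(.clamp(stats::rnorm(1, 0.5, 0.07), 0.2, 0.8), 4),
    ref_read_length = rrl,
    var_read_length = round(rrl - .clamp(stats::rnorm(1, 0, 5), -20, 20), 4),
    ref_mapq = rmq,
    var_mapq = round(rmq - .clamp(stats::rnorm(1, 0, 1.5), -5, 8), 4),
    normal_context_fraction = round(stats::runif(1, 0.88, 1), 4),
    ref_nm = rnm,
    var_nm = round(rnm + .clamp(stats::rnorm(1, 0.5, 0.7), -1, 2.5), 4),
    adjacent_to_germline = FALSE)
}

## overwrite exactly one summary so that the named criterion is violated
.violate <- function(stats, reason) {
  switch(reason,
    SUPPORT = {
      stats$variant_reads <- sample(3:9, 1)
      stats$forward_variant_reads <-
        stats::rbinom(1, stats$variant_reads, 0.5)
    },
    BASE_QUALITY = stats$variant_base_quality <-
      round(stats::runif(1, 10, 19.5), 4),
    STRAND = stats$forward_variant_reads <-
      if (stats::runif(1) < 0.5) 0L else stats$variant_reads,
    READ_POSITION = stats$mean_read_position <-
      round(if (stats::runif(1) < 0.5) stats::runif(1, 0.01, 0.14)
            else stats::runif(1, 0.86, 0.99), 4),
    LENGTH_DIFF = stats$var_read_length <-
      round(stats$ref_read_length - stats::runif(1, 26, 60), 4),
    MAPQ_DIFF = stats$var_mapq <-
      round(stats$ref_mapq - stats::runif(1, 11, 30), 4),
    NORMAL_CONTEXT = stats$normal_context_fraction <-
      round(stats::runif(1, 0.3, 0.79), 4),
    NM_DIFF = stats$var_nm <-
      round(stats$ref_nm + stats::runif(1, 3.5, 8), 4),
    BLACKLIST = NULL)   # violation is positional, handled by the caller
  stats
}

.refBase <- function(refSeq, pos) as.character(refSeq[pos])

## draw ref/alt for a SNV or a 1-bp indel at pos on the given reference
.drawAlleles <- function(refSeq, pos, indel) {
  rb <- .refBase(refSeq, pos)
  if (!indel) {
    list(ref = rb, alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1),
         is_indel = FALSE)
  } else if (stats::runif(1) < 0.5 || pos >= MT_LENGTH) {
    list(ref = rb, alt = paste0(rb, sample(c("A", "C", "G", "T"), 1)),
         is_indel = TRUE)                        # insertion
  } else {
    list(ref = paste0(rb, .refBase(refSeq, pos + 1L)), alt = rb,
         is_indel = TRUE)                        # deletion
  }
}

.siteDepth <- function(n, mu, size)
  pmax(1L, stats::rnbinom(n, mu = mu, size = size))

#' Simulate a paired tumour/normal synthetic chrM cohort
#'
#' Generates, deterministically from the spec's seed: a synthetic chrM
#' reference; per-patient germline haplogroup variants emitted near VAF 1
#' in tumour and matched normal; tumour-only somatic heteroplasmies at the
#' spec'd VAF distribution; artifact records each designed to violate
#' exactly one filter criterion; recurrently noisy positions and stray
#' error calls; per-site depths (negative binomial) from which the depth
#' table is computed so that the copy-number estimator recovers the true
#' copies/cell in expectation; and a population-database germline
#' resource. Both "callers" emit overlapping but non-identical record
#' subsets; every emitted record carries exactly one ground-truth label.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return a \code{\link{SimulatedCohort}}.
#' @export
simulateCohort <- function(spec = simulationSpec()) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  refSeq <- Biostrings::DNAString(
    paste(sample(c("A", "C", "G", "T"), MT_LENGTH, replace = TRUE),
          collapse = ""))
  bl <- defaultBlacklist()
  bl_pos <- unlist(mapply(seq, bl$start, bl$end, SIMPLIFY = FALSE))
  bl_all <- unlist(mapply(seq, bl$start[bl$applies_to == "all_variants"],
                          bl$end[bl$applies_to == "all_variants"],
                          SIMPLIFY = FALSE))
  bl_indel <- setdiff(bl_pos, bl_all)
  noisy <- sort(sample(setdiff(seq_len(MT_LENGTH), bl_pos),
                       spec$nNoisyPositions))
  noisy_level <- stats::runif(spec$nNoisyPositions, spec$noisyVafRange[1],
                              spec$noisyVafRange[2])
  names(noisy_level) <- noisy
  open_pos <- setdiff(seq_len(MT_LENGTH), c(bl_pos, noisy))

  groups <- rep(names(spec$groupSizes), spec$groupSizes)
  tumour_ids <- sprintf("T%03d", seq_len(spec$nTumours))
  normal_ids <- sprintf("N%03d", seq_len(spec$nNormals))
  matched <- normal_ids[((seq_len(spec$nTumours) - 1L) %% spec$nNormals) + 1L]

  pattern_probs <- local({
    cc <- spec$callerConcordance
    p <- c(a = cc * (1 - cc), b = (1 - cc) * cc, both = cc * cc)
    p / sum(p)
  })

  callRow <- function(sid, pos, al, vaf_true, st) {
    c(list(sample_id = sid, pos = pos, ref = al$ref, alt = al$alt,
           is_indel = al$is_indel), st,
      list(callers = NA_character_, true_vaf = vaf_true))
  }

  simNormal <- function(j) {
    set.seed(.substreamSeed(spec$seed, j))
    sid <- normal_ids[j]
    mtCN <- stats::runif(1, spec$normalMtCNRange[1], spec$normalMtCNRange[2])
    dm <- spec$meanDepthAuto * mtCN / 2
    gpos <- sort(sample(open_pos, spec$nGermlineHaplogroup))
    gdef <- lapply(gpos, function(p)
      .drawAlleles(refSeq, p, stats::runif(1) < spec$indelFraction))
    rows <- list()
    site_depths <- integer(0)
    for (k in seq_along(gpos)) {
      depth <- .siteDepth(1, dm, spec$depthOverdispersion)
      site_depths <- c(site_depths, depth)
      vaf <- .clamp(stats::rnorm(1, 0.995, 0.003), 0.97, 1)
      vr <- stats::rbinom(1, depth, vaf)
      st <- .genuineStats(vr, depth)
      rows[[length(rows) + 1L]] <- callRow(sid, gpos[k], gdef[[k]], vaf, st)
    }
    for (k in seq_along(noisy)) {
      if (stats::runif(1) > 0.9) next
      depth <- .siteDepth(1, dm, spec$depthOverdispersion)
      vaf <- max(5e-4, stats::rnorm(1, noisy_level[k], 0.25 * noisy_level[k]))
      vr <- stats::rbinom(1, depth, vaf)
      if (vr == 0L) next
      al <- list(ref = .refBase(refSeq, noisy[k]),
                 alt = sample(setdiff(c("A", "C", "G", "T"),
                                      .refBase(refSeq, noisy[k])), 1),
                 is_indel = FALSE)
      st <- .genuineStats(vr, depth)
      rows[[length(rows) + 1L]] <- callRow(sid, noisy[k], al, vaf, st)
    }
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    df$callers <- "caller_a"
    list(sid = sid, mtCN = mtCN,
         germline = data.frame(
           pos = gpos,
           ref = vapply(gdef, `[[`, character(1), "ref"),
           alt = vapply(gdef, `[[`, character(1), "alt"),
           is_indel = vapply(gdef, `[[`, logical(1), "is_indel"),
           stringsAsFactors = FALSE),
         calls = df,
         mean_dp_chrm = mean(site_depths),
         mean_dp_auto = mean(.siteDepth(spec$nAutoSites, spec$meanDepthAuto,
                                        spec$depthOverdispersion)))
  }

  normals <- lapply(seq_len(spec$nNormals), simNormal)
  names(normals) <- normal_ids

  ## somatic/artifact injections stay clear of every patient's germline
  ## positions (+/- 2 bp): a context-violating artifact adjacent to a
  ## germline variant would legitimately earn the read-context waiver and
  ## no longer be a designed artifact
  all_gpos <- unique(unlist(lapply(normals, function(n) n$germline$pos)))
  germ_zone <- unique(as.vector(outer(all_gpos, -2:2, "+")))

  simTumour <- function(i) {
    set.seed(.substreamSeed(spec$seed, 100000L + i))
    sid <- tumour_ids[i]
    grp <- groups[i]
    prof <- spec$groupProfiles[[grp]]
    mtCNRange <- if (!is.null(prof$mtCNRange)) prof$mtCNRange else
      spec$trueMtCNRange
    nSomMean <- if (!is.null(prof$nSomaticMean)) prof$nSomaticMean else
      spec$nTrueSomaticMean
    vafShape <- if (!is.null(prof$somaticVafShape)) prof$somaticVafShape else
      spec$somaticVafShape
    mtCN <- stats::runif(1, mtCNRange[1], mtCNRange[2])
    f <- stats::runif(1, spec$purityRange[1], spec$purityRange[2])
    ploidy <- sample(spec$ploidyChoices, 1)
    factor <- f * ploidy + (1 - f) * 2
    dm <- spec$meanDepthAuto * mtCN / factor
    nrm <- normals[[matched[i]]]
    used <- c(germ_zone, noisy)
    pick <- function(n, from = open_pos) {
      p <- sample(setdiff(from, used), n)
      used <<- c(used, p)
      p
    }
    rows <- list(); labels <- character(0); designed <- character(0)
    emit <- function(row, label, reason = NA_character_) {
      rows[[length(rows) + 1L]] <<- row
      labels <<- c(labels, label)
      designed <<- c(designed, reason)
    }
    ## germline haplogroup variants of the matched patient, VAF ~ 1
    gdepths <- integer(0)
    for (k in seq_len(nrow(nrm$germline))) {
      depth <- .siteDepth(1, dm, spec$depthOverdispersion)
      gdepths <- c(gdepths, depth)
      vaf <- .clamp(stats::rnorm(1, 0.995, 0.003), 0.97, 1)
      vr <- stats::rbinom(1, depth, vaf)
      al <- as.list(nrm$germline[k, c("ref", "alt", "is_indel")])
      emit(callRow(sid, nrm$germline$pos[k], al, vaf,
                   .genuineStats(vr, depth)), "germline")
    }
    ## true somatic heteroplasmies, tumour only
    n_som <- stats::rpois(1, nSomMean)
    if (n_som > 0) for (p in pick(n_som)) {
      vaf <- 0.05 + 0.9 * stats::rbeta(1, vafShape[1], vafShape[2])
      depth <- .siteDepth(1, dm, spec$depthOverdispersion)
      vr <- stats::rbinom(1, depth, vaf)
      al <- .drawAlleles(refSeq, p, stats::runif(1) < spec$indelFraction)
      emit(callRow(sid, p, al, vaf, .genuineStats(vr, depth)),
           "true_somatic")
    }
    ## artifacts, each designed to violate exactly one criterion
    for (reason in names(spec$artifactRates)) {
      n_art <- stats::rpois(1, spec$artifactRates[[reason]])
      if (n_art == 0) next
      for (dummy in seq_len(n_art)) {
        indel <- FALSE
        if (reason == "BLACKLIST") {
          indel <- stats::runif(1) < 0.2
          from <- if (indel) bl_indel else bl_all
          p <- sample(setdiff(from, used), 1)
          used <- c(used, p)
        } else {
          p <- pick(1)
        }
        vaf <- stats::runif(1, 0.1, 0.4)
        depth <- .siteDepth(1, dm, spec$depthOverdispersion)
        vr <- max(10L, stats::rbinom(1, depth, vaf))
        st <- .violate(.genuineStats(vr, depth), reason)
        al <- .drawAlleles(refSeq, p, indel)
        emit(callRow(sid, p, al, if (reason == "SUPPORT")
          st$variant_reads / depth else vaf, st),
          paste0("artifact:", reason), reason)
      }
    }
    ## recurrent noisy positions, below the panel noise level
    for (k in seq_along(noisy)) {
      if (stats::runif(1) > 0.7) next
      depth <- .siteDepth(1, dm, spec$depthOverdispersion)
      vaf <- stats::runif(1, 0.2, 0.5) * noisy_level[k]
      vr <- stats::rbinom(1, depth, vaf)
      if (vr == 0L) next
      al <- list(ref = .refBase(refSeq, noisy[k]),
                 alt = sample(setdiff(c("A", "C", "G", "T"),
                                      .refBase(refSeq, noisy[k])), 1),
                 is_indel = FALSE)
      emit(callRow(sid, noisy[k], al, vaf, .genuineStats(vr, depth)),
           "noise")
    }
    ## stray sequencing-error calls at the baseline VAF
    n_err <- stats::rpois(1, spec$errorCallRate)
    if (n_err > 0) for (p in pick(n_err)) {
      depth <- .siteDepth(1, dm, spec$depthOverdispersion)
      vr <- stats::rbinom(1, depth, spec$sequencingErrorVaf)
      if (vr == 0L) next
      al <- .drawAlleles(refSeq, p, FALSE)
      emit(callRow(sid, p, al, spec$sequencingErrorVaf,
                   .genuineStats(vr, depth)), "noise")
    }
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    pattern <- sample(names(pattern_probs), nrow(df), replace = TRUE,
                      prob = pattern_probs)
    dfA <- df[pattern %in% c("a", "both"), , drop = FALSE]
    dfB <- df[pattern %in% c("b", "both"), , drop = FALSE]
    dfA$callers <- "caller_a"; dfB$callers <- "caller_b"
    truth <- data.frame(sample_id = sid, pos = df$pos, ref = df$ref,
                        alt = df$alt, label = labels,
                        designed_reason = designed,
                        true_vaf = df$true_vaf,
                        stringsAsFactors = FALSE)
    list(sid = sid, group = grp, mtCN = mtCN, f = f, ploidy = ploidy,
         callsA = dfA, callsB = dfB, truth = truth,
         mean_dp_chrm = mean(gdepths),
         mean_dp_auto = mean(.siteDepth(spec$nAutoSites, spec$meanDepthAuto,
                                        spec$depthOverdispersion)))
  }

  tumours <- lapply(seq_len(spec$nTumours), simTumour)
  names(tumours) <- tumour_ids

  dropTrueVaf <- function(df) df[, setdiff(names(df), "true_vaf")]
  tumourCalls <- lapply(tumours, function(t) list(
    caller_a = MtCallSet(dropTrueVaf(t$callsA), sampleId = t$sid),
    caller_b = MtCallSet(dropTrueVaf(t$callsB), sampleId = t$sid)))
  normalCalls <- lapply(normals, function(n)
    MtCallSet(dropTrueVaf(n$calls), sampleId = n$sid))

  depthTable <- rbind(
    data.frame(sample_id = tumour_ids,
               mean_dp_auto = vapply(tumours, `[[`, numeric(1), "mean_dp_auto"),
               mean_dp_chrm = vapply(tumours, `[[`, numeric(1), "mean_dp_chrm"),
               stringsAsFactors = FALSE),
    data.frame(sample_id = normal_ids,
               mean_dp_auto = vapply(normals, `[[`, numeric(1), "mean_dp_auto"),
               mean_dp_chrm = vapply(normals, `[[`, numeric(1), "mean_dp_chrm"),
               stringsAsFactors = FALSE))
  rownames(depthTable) <- NULL
  purityTable <- rbind(
    data.frame(sample_id = tumour_ids,
               f = vapply(tumours, `[[`, numeric(1), "f"),
               ploidy = vapply(tumours, `[[`, numeric(1), "ploidy"),
               stringsAsFactors = FALSE),
    data.frame(sample_id = normal_ids, f = 1, ploidy = 2,
               stringsAsFactors = FALSE))
  rownames(purityTable) <- NULL
  sampleTable <- rbind(
    data.frame(sample_id = tumour_ids, kind = "tumour", group = groups,
               matched_normal = matched,
               true_mtCN = vapply(tumours, `[[`, numeric(1), "mtCN"),
               f = vapply(tumours, `[[`, numeric(1), "f"),
               ploidy = vapply(tumours, `[[`, numeric(1), "ploidy"),
               stringsAsFactors = FALSE),
    data.frame(sample_id = normal_ids, kind = "normal", group = "normal",
               matched_normal = NA_character_,
               true_mtCN = vapply(normals, `[[`, numeric(1), "mtCN"),
               f = 1, ploidy = 2, stringsAsFactors = FALSE))
  rownames(sampleTable) <- NULL
  truth <- do.call(rbind, lapply(tumours, `[[`, "truth"))
  rownames(truth) <- NULL

  ## population-database slice of the cohort's germline alleles
  set.seed(.substreamSeed(spec$seed, 999999L))
  gall <- unique(do.call(rbind, lapply(normals, function(n)
    n$germline[, c("pos", "alt")])))
  keep <- stats::runif(nrow(gall)) < 0.5
  germlineResource <- data.frame(
    position = gall$pos[keep], allele = gall$alt[keep],
    source = "population_db",
    frequency_or_vaf = round(stats::runif(sum(keep), 0.02, 0.5), 4),
    stringsAsFactors = FALSE)

  new("SimulatedCohort", tumourCalls = tumourCalls,
      normalCalls = normalCalls, depthTable = depthTable,
      purityTable = purityTable, sampleTable = sampleTable, truth = truth,
      germlineResource = germlineResource, refSeq = refSeq,
      spec = unclass(spec))
}

#' Write a simulated cohort as a loadable fixture bundle
#'
#' Writes one VCF per caller per tumour (and one per normal), the depth,
#' purity/ploidy, sample and germline-resource TSVs, the blacklist, the
#' synthetic reference FASTA, the ground-truth table and a JSON manifest
#' recording the seed. The bundle round-trips through the package readers
#' and is the input format of \code{\link{runPipeline}}.
#'
#' @param cohort a \code{\link{SimulatedCohort}}.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly (a list; also written as
#'   \code{manifest.json}).
#' @export
writeFixtureBundle <- function(cohort, dir) {
  stopifnot(is(cohort, "SimulatedCohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  vcfdir <- file.path(dir, "vcf")
  dir.create(vcfdir, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    name
  }
  vcfs <- list()
  for (sid in names(cohort@tumourCalls)) {
    for (caller in names(cohort@tumourCalls[[sid]])) {
      f <- file.path("vcf", sprintf("%s.%s.vcf", sid, caller))
      writeVariantVcf(cohort@tumourCalls[[sid]][[caller]],
                      file.path(dir, f))
      vcfs[[length(vcfs) + 1L]] <-
        list(sample_id = sid, caller = caller, path = f, kind = "tumour")
    }
  }
  for (sid in names(cohort@normalCalls)) {
    f <- file.path("vcf", sprintf("%s.caller_a.vcf", sid))
    writeVariantVcf(cohort@normalCalls[[sid]], file.path(dir, f))
    vcfs[[length(vcfs) + 1L]] <-
      list(sample_id = sid, caller = "caller_a", path = f, kind = "normal")
  }
  files <- list(
    depth = wtsv(cohort@depthTable, "depth.tsv"),
    purity = wtsv(cohort@purityTable, "purity.tsv"),
    samples = wtsv(cohort@sampleTable, "samples.tsv"),
    germline_resource = wtsv(cohort@germlineResource,
                             "germline_resource.tsv"),
    truth = wtsv(cohort@truth, "truth.tsv"),
    blacklist = "blacklist.tsv",
    reference = "synthetic_chrM_reference.fa")
  writeBlacklist(defaultBlacklist(), file.path(dir, "blacklist.tsv"))
  ref <- Biostrings::DNAStringSet(cohort@refSeq)
  names(ref) <- "chrM synthetic"
  Biostrings::writeXStringSet(ref, file.path(dir, files$reference))
  manifest <- list(seed = cohort@spec$seed,
                   spec = cohort@spec[setdiff(names(cohort@spec),
                                              "groupProfiles")],
                   files = files, vcfs = vcfs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
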