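#' Estimate the panel-of-normals VAF noise model
#'
#' For each chrM position, the noise level is the mean plus three standard
#' deviations of the non-reference allele fraction across the panel's
#' normal samples (a sample without signal at a position contributes 0; a
#' single-sample panel has SD 0), clamped from below by a global floor.
#' Per-sample fractions above the germline VAF threshold are excluded
#' before estimation — near-fixed haplogroup alleles are polymorphism, not
#' noise, and would otherwise saturate their positions.
#'
#' @param normalCallsBySample named list of \code{MtCallSet} (or call
#'   data.frames), one per normal sample; must be non-empty. An empty panel
#'   is an error — construct a floor-only model with
#'   \code{new("NoiseModel", floor = ...)} instead.
#' @param normalDepths optional named numeric vector of mean chrM depths
#'   (used only for validation/reporting).
#' @param floor global minimum noise level (default 0.005).
#' @param germlineVafThreshold per-sample fractions above this are excluded
#'   (default 0.95).
#' @return a \code{\link{NoiseModel}}.
#' @export
estimateNoise <- function(normalCallsBySample, normalDepths = NULL,
                          floor = 0.005, germlineVafThreshold = 0.95) {
  if (length(normalCallsBySample) == 0L)
    stop("empty normal panel: no noise model can be estimated; ",
         "use a floor-only model (new(\"NoiseModel\", floor = floor))")
  dfs <- lapply(normalCallsBySample, function(x) {
    d <- if (is(x, "MtCallSet")) mtCalls(x) else x
    d[!is.na(d$vaf) & d$vaf <= germlineVafThreshold, c("pos", "vaf")]
  })
  n_normals <- length(dfs)
  ## per sample, total non-reference fraction per position
  per_sample <- lapply(seq_along(dfs), function(i) {
    d <- dfs[[i]]
    if (!nrow(d)) return(data.frame(pos = integer(0), frac = numeric(0),
                                    sample = integer(0)))
    frac <- vapply(split(d$vaf, d$pos), sum, numeric(1))
    data.frame(pos = as.integer(names(frac)), frac = unname(frac),
               sample = i)
  })
  all <- do.call(rbind, per_sample)
  noise <- numeric(0)
  if (nrow(all)) {
    stats_by_pos <- vapply(split(all$frac, all$pos), function(v) {
      v <- c(v, rep(0, n_normals - length(v)))  # absent samples contribute 0
      s <- if (length(v) > 1L) stats::sd(v) else 0
      mean(v) + 3 * s
    }, numeric(1))
    noise <- pmax(stats_by_pos, floor)
  }
  new("NoiseModel", perPositionNoise = noise, floor = floor,
      nNormals = as.integer(n_normals))
}

#' Apply the noise-level filter to a call
#'
#' A call fails with \code{BELOW_NOISE} when its VAF is strictly lower than
#' the panel-of-normals noise level at its position.
#'
#' @param call one-row call data.frame (needs \code{pos, vaf}).
#' @param model a \code{\link{NoiseModel}}.
#' @return \code{"BELOW_NOISE"} or \code{character(0)}.
#' @export
applyNoiseFilter <- function(call, model) {
  noiseReasonVec(as.data.frame(call), model)[[1]]
}

noiseReasonVec <- function(df, model) {
  if (is.null(model)) return(rep(list(character(0)), nrow(df)))
  stopifnot(is(model, "NoiseModel"))
  lvl <- noiseAt(model, df$pos)
  bad <- !is.na(df$vaf) & df$vaf < lvl
  lapply(bad, function(b) if (b) "BELOW_NOISE" else character(0))
}
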