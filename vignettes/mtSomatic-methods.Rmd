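---
title: "Somatic mtDNA variants and copy number from tumour/normal pairs: methods"
author: "mtSomatic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mtDNA variants and copy number from tumour/normal pairs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtSomatic)
```

# Scope

mtSomatic analyses the mitochondrial genome in paired tumour/normal
sequencing data. It answers two questions per sample: *how many mtDNA
copies per cell does the tissue carry*, and *which chrM variant calls are
genuine somatic heteroplasmies* rather than germline haplogroup alleles,
alignment artifacts, or sequencing noise. Downstream it compares groups of
samples (variant burden, heteroplasmy level, copy number) with Welch
t-tests. The package operates on caller output (VCF plus per-read summary
annotations); it performs no alignment, realignment, or caller
re-implementation.

# mtDNA copy number

Mitochondria are polyploid organelles: a diploid cell carries two copies
of each autosome but hundreds to thousands of mtDNA molecules, so the
ratio of chrM to autosomal read depth estimates the per-cell copy number.
In a tumour sample of purity $f$ (fraction of tumour cells) whose tumour
cell population has mean autosomal ploidy $p$, the autosomal depth
corresponds to $f \cdot p + (1 - f) \cdot 2$ genome copies per cell, giving

$$\mathrm{mtCN} \;=\; \frac{\overline{\mathrm{DP}}_\mathrm{chrM}}
{\overline{\mathrm{DP}}_\mathrm{auto}}\,\bigl(f \cdot p + (1-f)\cdot 2\bigr).$$

For a normal tissue ($f = 1$, $p = 2$) this reduces to twice the depth
ratio. Both mean depths are taken over *variant sites* — autosomal
germline-variant sites and chrM sites — rather than every base, which
matches how callers summarize depth and avoids weighting by callability.
When fewer than a handful of chrM variant sites exist, the mean over all
chrM positions is an acceptable substitute and should be flagged in the
input provenance. Purity and ploidy are inputs (estimated by a nuclear
copy-number pipeline, out of scope here); samples without an entry are
treated as diploid with purity 1 — the normal-tissue convention — with a
warning.

Assumptions worth keeping in mind: the correction presumes a single
dominant tumour clone with a well-defined mean ploidy; strong subclonal
aneuploidy or normal-cell mtDNA content differing systematically from
tumour-cell content biases the estimate in ways the formula cannot see.

# The variant filter chain

Candidate calls from two independent callers are union-merged per sample —
one record per (position, ref, alt); records reported by both callers
carry both caller ids. Annotations of a doubly-called record are taken
deterministically from `caller_a` (the other caller's record is retained as
provenance) because the two callers summarize reads differently and an
element-wise mixture would describe no real read population.

Each union record then faces four independent stages; every violated
criterion is recorded, with no short-circuiting, so the audit table lists
the complete reason set and the pass set is invariant to stage order.

1. **Position blacklist.** Eight rCRS regions (`302–315`, `513–525`,
   `568–573`, `956–965`, `3105–3109`, `5895–5899`, `8270–8289`, and
   `16180–16195` for indels only) covering homopolymer/poly-C tracts and
   NUMT-prone segments where short-read alignment is unreliable.
   Boundaries are inclusive.
2. **Read evidence.** Seven criteria, each with its printed threshold and
   strictness: variant reads $\ge 10$; mean variant base quality
   $\ge 20$; forward/total variant-read ratio strictly inside
   $(0.1, 0.9)$; mean relative read position strictly inside
   $(0.15, 0.85)$, measured as the distance to the *nearer* read end so
   one scalar covers both the 5′ and 3′ windows; reference minus variant
   mean read length $< 25$ bases; reference minus variant mean mapping
   quality $< 10$; fraction of variant reads whose remaining bases match
   the reference $> 0.80$; variant minus reference mean edit distance
   (NM) $\le 3$. The read-context criterion is waived for calls within
   2 bp of a germline variant, because a phased germline allele
   legitimately breaks the context of every supporting read; the 2 bp
   window is a deliberately conservative reading of "next to" and is
   configurable (`adjacencyWindow`).
3. **Germline removal.** A call is germline when its allele appears in
   the cohort-normals panel or an external panel at VAF $> 0.95$, in a
   population database at frequency $> 0.01$, or in the sample's own
   matched normal at VAF $> 0.95$.
4. **Noise level.** Low-frequency artifacts recur at characteristic
   positions across unrelated samples. From the panel of normals the
   per-position noise level is estimated as mean $+\,3$ SD of the
   non-reference allele fraction across normals (a normal without signal
   contributes 0; a single-normal panel has SD 0), clamped below by a
   global floor of 0.005. A call fails when its VAF is strictly below the
   level at its position. Near-fixed alleles (VAF $> 0.95$) are excluded
   from estimation first: haplogroup polymorphism is not noise, and a
   patient-private haplogroup position would otherwise saturate to a
   noise level near 1 and swallow genuine signal there. The mean+3SD form
   is the minimal parametric upper bound on background; both it and the
   floor are exposed in the configuration.

All inequality directions and strictness follow the printed recipe
exactly — the boundaries are part of the contract and are exercised one
grid step on either side in the test suite. Records missing any required
annotation fail closed with `MISSING_ANNOTATION` rather than passing by
default; a sidecar TSV can supply fields a caller's VCF lacks.

## Somatic versus tumour-specific dysplastic

A passing tumour variant is labelled by the matched normal's VAF of the
same allele: **somatic** when the normal VAF is below 0.01 (essentially no
signal), **tumour-specific dysplastic** when the allele is present at low
level in the normal ($0.01 \le \mathrm{VAF_N} \le 0.95$) but expanded in
the tumour ($\mathrm{VAF_T} - \mathrm{VAF_N} \ge 0.05$) — the signature of
a variant present in a dysplastic field that clonally expanded. Calls
meeting neither rule (comparable VAF in both tissues) are dropped from the
classified output with a logged count. The 0.01 / 0.05 cutoffs are
interpretive defaults — the underlying recipe specifies only that the
labels derive from VAF differences in normal tissue — and are exposed as
`somaticNormalVafMax` and `dysplasticMinVafDiff`.

# Consequence annotation

Passing variants are classified on the 37-gene mitochondrial gene model
(rCRS coordinates, shipped as a package table). Protein-gene SNVs are
translated with the vertebrate mitochondrial genetic code (AGA/AGG stop,
ATA Met, TGA Trp); light-strand genes (ND6 and several tRNAs) are
reverse-complemented before codon lookup. Indels whose length change is
not divisible by 3 are frameshifts; in-frame indels are reported as
protein-altering (missense) since the category set has no separate
in-frame class. Variants in the overlapping gene pairs (ATP8/ATP6,
ND4L/ND4) are annotated against both genes and the worst consequence is
reported. Genes with incomplete terminal stop codons (ND1, ND2, CO3, ND3,
ND4, CYB — completed by polyadenylation in vivo) are flagged, and their
terminal codon is A-padded before translation. tRNA/rRNA variants count
as non-silent by default (they disrupt structural RNAs), switchable via
`trnaRrnaNonsilent`. Pathogenicity is membership in a user-supplied
allele list; the package does no in-house scoring. The reference sequence
is an input (supply the rCRS FASTA for real data); the packaged table
carries coordinates only.

# Group statistics

Per sample, the classified variants yield the variant count, the mean VAF
over all classified variants and over the pathogenic stratum, alongside
the sample's mtCN. Group differences are tested with Welch's two-sample
t-test (unequal variances, Welch–Satterthwaite degrees of freedom),
two-sided, with no multiple-testing correction — matching the original
analysis, which reports nominal p-values for a handful of planned
comparisons. "Average VAF" is computed per-sample-first (variants averaged
within a sample, samples then compared across groups), so samples with
many variants do not dominate the group mean.

# The synthetic cohort generator

Because the motivating data are access-controlled, the package ships a
generator that emulates the *statistical structure* of paired
tumour/normal chrM call sets with full ground truth:

* **Cohort**: by default 16 "BHD" tumours and 49 "sporadic-ChRCC" tumours
  (the published cohort sizes), each with a matched normal; the BHD
  profile draws fewer, lower-VAF somatic variants and higher copy numbers
  (500–2000 vs 100–800 copies/cell), reproducing the direction of the
  published contrast without encoding its effect sizes.
* **Depths**: per-site depths are negative binomial (size 30) around the
  sample's expected chrM depth, which is derived by inverting the
  copy-number formula from the sample's true copies/cell (100–2000),
  purity (0.3–0.9), ploidy (drawn from {1.8, 2, 2.2, 3}) and 30×
  autosomal coverage — so the estimator recovers truth in expectation and
  the residual error measures sampling noise only.
* **Variants**: ~30 near-fixed germline haplogroup variants per patient
  (VAF ≈ 0.995 in tumour and normal); somatic heteroplasmies only in
  tumour with Beta-distributed VAF rescaled into [0.05, 0.95] and
  binomial read support; artifacts each constructed to violate exactly
  one named criterion (all other summaries drawn from passing
  distributions); recurrently noisy NUMT-like positions shared across
  samples at VAF 1–5%, with tumour-side echoes placed below the panel's
  mean+3SD level; and stray error calls at the 0.002 baseline.
  Somatic and artifact positions avoid a ±2 bp zone around every cohort
  germline position, since a context-violating artifact next to a
  germline allele would legitimately earn the adjacency waiver and stop
  being a designed artifact.
* **Callers**: each record is emitted by caller A only, caller B only, or
  both, with probabilities proportional to $c(1-c) : (1-c)c : c^2$ at
  concordance $c = 0.9$ — conditioning on at least one caller so that
  every ground-truth label corresponds to exactly one emitted union
  record and measured sensitivity reflects the filter chain, not caller
  dropout.
* **Determinism**: one master seed; per-sample substreams are derived by
  counter, so a cohort can grow without perturbing earlier samples (for a
  fixed normal panel, which defines the germline exclusion zone). Float
  annotations are rounded to 4 decimals so VCF round trips are exact.

What the simulator does **not** model: read-level errors (no FASTQ/BAM),
alignment context, NUMT mis-mapping mechanics beyond recurrent noisy
positions, haplogroup phylogeny (germline positions are random, not
tree-structured), contamination between samples, and tumour-in-normal
contamination (somatic variants have true normal VAF 0). Passing the
recovery suites therefore demonstrates that the *decision rules* behave
as specified under realistic count statistics — not that the thresholds
are optimal for any particular instrument or aligner.

# Validation problem sizes

The shipped checks use: copy-number recovery on 100 simulated tumours at
30× autosomal depth (median relative error required below 5%); somatic
sensitivity and artifact rejection on a 30-tumour cohort with boosted
injection rates giving well over 200 somatic and 200 artifact injections
(sensitivity at least 0.95 for variants with ≥ 10 supporting reads and
VAF at least twice the local noise level; designed-reason rejection of
every artifact); Welch null calibration on 10,000 Gaussian replicates at
n = 20 per group (empirical type-I error within 0.05 ± 0.01); and a
12-sample demo cohort whose per-stage counts are reconciled record by
record against ground truth.

# Numerical and degenerate-input choices

* Zero variant reads fails the support criterion and skips the ratio
  criteria (no division by zero).
* A VAF exactly equal to the noise level passes ("lower than" is strict);
  all other printed comparisons keep their printed strictness.
* Welch's test refuses both-groups-constant input (zero pooled variance)
  and groups of size below 2, rather than returning NaN.
* Blacklist inputs in 0-based half-open convention are converted at the
  boundary; internally everything is 1-based inclusive. Overlapping
  blacklist regions of the same class are merged with a warning.
* Indels are represented minimally with `is_indel` defined by allele
  length difference; the blacklist's indel-only region applies to them
  regardless of representation anchor.

# Limitations

The pipeline inherits every limitation of its inputs: purity/ploidy
errors propagate linearly into mtCN; per-read summaries are trusted as
computed by the callers; and the germline/noise resources determine how
aggressively low-frequency variants are removed — with a small normal
panel the mean+3SD level is itself noisy, and the 0.005 floor is the only
guard at positions without panel signal. Classification thresholds
(0.01 normal VAF, 0.05 expansion) are interpretive defaults, not
published constants, and should be revisited when matched-normal purity
is in doubt.
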