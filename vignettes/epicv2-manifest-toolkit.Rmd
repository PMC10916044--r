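---
title: "EPICv2 manifest engineering: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPICv2 manifest engineering: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epickit)
```

This vignette records the scientific conventions, tunable parameters and
design decisions behind epickit, in the spirit of a methods supplement.
It states no empirical result that the package's tests and acceptance
script do not themselves compute.

## Coordinates and manifest dialects

The internal convention is the 1-based plus-strand position of the
interrogated cytosine (`mapinfo`), matching the Illumina `MAPINFO`
column. SeSAMe-style manifests give each target as a 0-based half-open
two-nucleotide BED interval; `read_sesame_manifest()` derives
`mapinfo = beg + 1` at the boundary. `compare_manifests()` tests
agreement by *interval intersection* — the Illumina point widened to the
CpG dinucleotide against the SeSAMe range — so the comparison is
invariant to whether a point was reported at the C or at the paired G.
Probes with `CHR = chr0` / `MAPINFO = 0` are retained in tables but
excluded from every location-keyed operation; they can still join
sequence-keyed replicate sets. Control probes are a separate partition
and never counted among assay probes.

## The bisulphite design engine

Sodium bisulphite converts unmethylated cytosines to uracil (read as T)
and leaves methylated cytosines unchanged. The engine models a probe as
a 50-nt window of the bisulphite-converted design strand:

* **T/B**: T designs use the `Forward_Sequence` strand as the design
  strand; B designs use its reverse complement (the CpG reappears as CG).
  Illumina assigns TOP/BOT by a sequence-walking rule; re-deriving that
  rule is out of scope, so T-is-the-forward-strand is this package's own
  convention, which is exactly invertible against its own designer.
* **C/O**: probes against the Converted strand are the reverse
  complement of the converted window; Opposite-strand probes anneal to
  the strand synthesised complementary to the converted strand, so the
  probe sequence equals the converted window read 5′→3′.
* **Window placement** (t = 0-based target-C index on the design
  strand): Type I C-strand `[t, t+49]` (target at the probe 3′
  terminus, extension reads the adjacent base — the manifest
  `Next_Base`); Type II C-strand `[t+1, t+50]` (3′ terminus abuts the
  target; single-base extension reads the target itself); Type I
  O-strand `[t−49, t]`; Type II O-strand `[t−50, t−1]`. For Type I
  O-strand designs the extension site is the C of the target CpG on the
  opposite strand, and a G is always incorporated (green channel).
* **Modes**: Type I allele A is built from the fully unmethylated
  template (every C→T), allele B from the methylated template (CpG and
  target cytosines retained); Type II uses a single degenerate template
  (body CpG C→Y, rendered R after reverse complementation). The
  interrogated cytosine is converted per-mode regardless of its own
  dinucleotide context, which also covers CpH (`ch`) targets.
* A window-terminal C whose successor lies outside the window is
  resolved from the full `Forward_Sequence` context (conversion depends
  on the genome, not on where the window was cut). The parser locates
  the brackets rather than assuming 60-nt flanks, so other flank
  lengths work; anything too short for a 50-nt window plus one base of
  context is an explicit "undesignable" error.

`verify_manifest_sequences()` reports per-probe exact-match flags and
the overall fraction. Discrepant probes are reported, never "fixed".

## Replicates and cross-version matching

Replicate classes: *exact* (same Name and allele-sequence pair),
*location* (same reconciled coordinate, ≥ 2 distinct sequences, with
name agreement recorded so both published phrasings of
"location-replicate" are covered), *sequence-only* (same sequence pair,
≥ 2 distinct names). Location keying ignores strand: the C and G
coordinates of a CpG are reconciled to the C before grouping, and a
`names_agree` flag records strand-discordant sets rather than deciding
their status.

Cross-version matching treats every EPICv2 replicate independently and
emits one row per (v2 probe, other probe) pair — older-array internal
replicates duplicate the other probe id rather than being collapsed.
Sequence matches require both allele A and allele B to match.
Provenance partitions unique EPICv2 locations (rs/nv and chr0 removed,
locations deduplicated first): *retained* (∩ EPICv1), *reinstated*
(∩ 450K∪27K, ∉ EPICv1), *new* (EPICv2 only); *excluded* = EPICv1 \ v2.

## Genomic annotation

TSS windows are not pinned down by convention, so they are parameters:
default `[−1500, +500]` around each transcript start, strand-aware.
Precedence is TSS > gene body > intergenic. CpG shores are the regions
2,000 bp either side of an island (a point k bp beyond an island edge is
shore for k ≤ 2000), islands taking precedence; everything farther is
open sea. Feature overlap (enhancers, super-enhancers — the same
operation with a different BED) uses merged intervals for
"unique features covered" counts and reports a probes-per-feature
histogram.

## The cross-hybridisation scan

Four genome variants are built: forward, forward-bisulphite (every C→T,
the fully unmethylated limit — the unconverted genome serves as the
fully methylated proxy), reverse complement, and reverse-complement
bisulphite. Like BLAT, the aligner searches both query orientations;
because the unconverted genome is reverse-complement symmetric, hits of
the reversed query on the forward store are labelled as the reverse
genome, while each converted store genuinely needs both orientations.

Candidate loci are found exhaustively with `Biostrings::matchPattern`
(`with.indels`, degenerate probe bases R/Y matching either alternative
and never counted as mismatches), then refined by a gapped
global-in-query / local-in-window alignment that maximises the BLAT
PSL-style score `matches − mismatches − query gap openings − target gap
openings` with the match count as tie-break. This score formula
reproduces the published threshold pair: 47 matches on an ungapped
50-mer is a score of exactly 44, and for ungapped alignments
`score = 2·matches − 50`. The candidate search uses an edit budget of
`50 − min_matches` (default 3) — alignments requiring larger indels are
the domain of genome-scale external BLAT runs, ingested via
`read_psl()` (minus-strand records are remapped so block walking is
orientation-free). The built-in aligner is for toy genomes and tests:
correctness over speed, verified in the test suite against an
independent sliding-window edit-distance oracle.

Off-target mapping transposes the target cytosine's query offset from
the on-target alignment through each off-target's blocks. Type II and
opposite-strand designs interrogate a base at or just beyond the probe
3′ terminus, outside the aligned footprint, so the walkers extrapolate
along the terminal block diagonal (bounded to offsets −2…51 for the
on-target test); offsets falling in an internal gap are skipped and
counted. Off-target bases are read from the unconverted genome in the
orientation that reproduces the interrogated cytosine at the on-target
(flipped when the off-target aligns on the other strand), then
classified CpG / CpH / non-C; a cytosine at a contig end is flagged
undecidable. Every scanned probe lands in exactly one of: unmapped
(chr0), no homology, no homology at MAPINFO, cross-hybridising, not
cross-hybridising.

## Cross-platform consensus and verdicts

All cross-platform and RMSE computations are done in M/logit space;
beta-space inputs are transformed at the boundary (clip 10⁻⁶ for exact
0/1). The matched block keeps only sites with a full complement: any
array detection p > 0.05 in any sample drops the site on that platform,
as does any zero-coverage WGBS sample; duplicate-location EPICv2 probes
resolve to the earliest manifest row; every exclusion is logged with a
reason. The row-linear fit regresses each platform on the per-sample
across-platform mean; precision uses denominator n − 2 (two fitted
parameters). A centred (Mandel) parameterisation is exposed; it changes
only the intercept. When every platform contributes to the consensus,
the per-site platform slopes average to 1.

For replicate adjudication one consensus is built per set — from the
set-mean EPICv2 series, EPICv1, and WGBS when available — and every
member is fitted against that same consensus. This makes the set-mean
sensitivity exactly the mean of member sensitivities, hence by
definition intermediate of the member extremes (the package asserts
this on every simulated set); the same does not hold for precision,
which motivates the `best_precision_by_group_mean` label. "Best
sensitivity" means the largest slope (more positive slope = more
sensitive); ties break by better precision, then manifest order. The
dropout rule — at least 12 of 18 matched values — is parameterised
(`min_pairs`, `n_samples`) so synthetic designs with other sample
counts scale proportionally. Without matched EPICv1 data, members are
ranked by RMSE against on-target WGBS; if the set-mean series
outperforms every member, all members are relabelled
`superior_group_mean_WGBS` (the published wording — "probes were
relabelled" — is read as applying to the whole set). Sets below the
dropout rule are `insufficient`. WGBS-based cross-hybridisation
evidence requires at least one CpG off-target and the same dropout
rule; the flag is `Y` when some off-target RMSE beats the on-target
RMSE, the minimiser being the suggested alternative. Whether RMSE is
computed on M-values or betas is not fixed by convention; M space is
used for consistency with the consensus analysis.

RLM (relative log methylation) deviations subtract the per-site median
M-value across samples; widening per-sample deviation distributions
indicate degraded data quality. A helper picks, among technical
replicates, the sample with the fewest probes failing the detection-p
threshold.

## The synthetic-data generator

The generator defines the study conditions for all tests:

* **Toy genomes**: random sequence with all accidental CGs broken, then
  the requested number of CG sites planted at non-overlapping positions
  — the realised CpG count matches the request by construction.
  Defaults: 20 kb, density 0.02.
* **Manifests**: probes cycle through all eight (T/B × C/O × I/II)
  combinations at well-separated CpGs; replicate plantings per class are
  parameters. Designed manifests verify at fraction 1.0 by
  construction (the designer and the recomputation share one engine).
* **Off-target plants**: the on-target footprint (plus two bases of
  conversion context) is copied elsewhere with interior substitutions
  (complement swaps, which never collapse under C→T conversion on
  either strand) and optional deletions. Converted genomes are
  three-letter and repetitive, so a given layout can admit a
  better-scoring gapped alignment than intended; the generator
  therefore samples layouts until realignment confirms the planted
  truth is the unique optimum at the locus.
* **Methylation data**: per-site latent levels from a beta mixture
  (near-0 / intermediate / near-1, weights 0.4/0.2/0.4) emulating the
  bimodal-plus-intermediate distributions of array data, with
  N(0, 1.5²) per-sample variation in M space; arrays observe
  `α_p + β_p·latent + N(0, σ_p)` (default σ = 0.3, a typical technical
  M-value noise level) with detection-p companions; WGBS is purely
  binomial at Poisson(20) coverage through the half-count logit — no
  conversion-error term, the simplest model consistent with the
  transform. Dropouts (detection-p failures, zero coverage) are planted
  as indicator masks at 1% rates, not modelled chemically.

What the generator does *not* emulate: dye bias and raw IDAT
intensities, batch effects, genuine TOP/BOT sequence-walking strand
assignment, polymorphisms under probes, and genome-scale repeat
structure. Passing tests therefore demonstrate the correctness of the
algorithms under the stated model, not array-specific chemistry
artefacts; the published full-array counts (probe totals, genome-wide
cross-hybridisation totals, real-data effect sizes) require the real
manifests, external BLAT runs and the deposited datasets, and are
deliberately not asserted.

## Numerical choices and problem sizes

Degenerate fits (fewer than 3 complete samples, zero consensus
variance) raise errors rather than returning silent NAs; verdict
routes fall back to `insufficient`. Exact-0/1 betas require an explicit
clipping policy. The test suite and acceptance script run at desk
scale: 30 kb genomes and 504 probes for the design round trip, 12 kb
genomes with three planted probes for aligner-oracle equivalence and
transposition, 200 sites × 18 samples for slope recovery, and 200
seeded repetitions for verdict recovery — sizes chosen so the whole
suite completes in about a minute while keeping every estimate's
sampling error far below the tested tolerances.
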