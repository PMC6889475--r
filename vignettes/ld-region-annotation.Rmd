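---
title: "Delineating and annotating the genomic regions genetically linked to candidate SNPs"
author: "ldregion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and annotating the genomic regions genetically linked to candidate SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genotyping-by-sequencing and SNP arrays interrogate only a fraction of a
genome. A SNP that an association or co-segregation analysis flags as a
candidate is therefore rarely the causal polymorphism; it tags a surrounding
stretch of the chromosome that travels with it through meiosis. Annotating
such a candidate with only the gene it falls in — or the nearest gene — is
misleading in both directions: a remote gene may be in strong linkage
disequilibrium (LD) with the candidate while the physically closest gene is
not linked to it at all. The appropriate neighborhood is
*experiment-specific*: LD extent depends on the population's demography,
inbreeding, allele frequencies and sample size, so it must be estimated from
the study's own genotypes rather than borrowed from a reference panel.

`ldregion` implements this reasoning as a pipeline:

1. estimate pairwise r² between all genotyped SNPs on the same chromosome,
2. for each candidate SNP, delineate the interval spanned by the foremost
   upstream and downstream SNPs linked to it at a user-chosen r² threshold,
3. report **every** annotated feature overlapping that interval, one output
   row per (candidate, feature) pair.

## The r² estimators

For biallelic loci LD is summarised by the squared correlation r² between
allelic states. With unphased diploid genotypes two estimators are in common
use, and both are provided:

* **Dosage correlation** (default, `r2_dosage()`): the squared Pearson
  correlation of the alternate-allele dosage vectors (values 0/1/2) over
  pairwise-complete samples. Deterministic, fast, and the common default of
  standard LD software.
* **EM haplotype frequencies** (`r2_em()`): gametic r² computed as
  D²/(pA·pa·pB·pb) from the four haplotype frequencies estimated by
  expectation–maximization under Hardy–Weinberg equilibrium. All genotype
  pairs except the double heterozygote determine their two gametes; double
  heterozygotes are split fractionally between the AB/ab and Ab/aB phases
  according to the current frequency estimates. Iteration starts from
  linkage equilibrium and stops when every haplotype frequency changes by
  less than 1e-10, or after 1000 iterations (then the last iterate is used
  and a warning emitted). Because the EM update conserves allele
  frequencies, the likelihood is effectively one-dimensional in pAB; the
  test suite checks the EM fixed point against an exhaustive grid over that
  parameter and against direct haplotype counting whenever no double
  heterozygote is present.

Both estimators are symmetric in their arguments and invariant to relabeling
either locus's alleles (dosage d → 2−d), which is what licenses the
SNP-array reader's arbitrary ("first seen") reference-orientation choice.

## Parameters that matter

* `base_threshold` (default **0.4**): pairs below this r² are never retained.
  It is the lowest threshold a user may later select, which is exactly what
  makes the checkpoint reusable (see below). Retention is inclusive (`>=`):
  a pair sitting exactly at a threshold is kept, the conservative choice for
  region delineation.
* `threshold` (user, `>= 0.4`): the r² level defining "genetically linked"
  for region delineation. Typical analyses compare several values
  (e.g. 0.7, 0.8, 0.9); higher thresholds give smaller regions.
* `window_bp` (default 1 Mb, `0` = unlimited): maximum inter-variant
  distance considered. LD beyond a megabase is negligible in most outbred
  populations, and the cap bounds the otherwise quadratic pair count on
  dense whole-genome data; pedigree or strongly selected populations with
  very long-range LD should raise or disable it.
* `min_informative` (default 4): minimum samples non-missing at both loci.
  Below this, r² is numerically meaningless; such pairs are skipped and
  counted, never reported as zero.
* `maf_min` (default 0): minor-allele-frequency floor at parsing time. Rare
  alleles inflate the variance of r²; filtering at 5% is a common choice and
  markedly increases the average linked distance.
* Monomorphic pairs are likewise skipped with a count: correlation is
  undefined there, and reporting 0 would deflate the average linked
  distance.

## Regions, "alone" candidates, and the average distance

For each candidate, every variant linked at `>= threshold` is collected and
the region is `[min(linked positions), max(linked positions)]`, always
including the candidate's own position (a region is never empty). When no
variant is linked, the dataset-wide **average linked distance** — the mean
bp separation of *all* retained pairs at the user threshold, across the
whole dataset — is used instead: the region becomes the candidate position
± that average (clamped at 1), the region carries `alone = TRUE`, and the
candidate's identifier is suffixed `_alone` in the output. That average is a
broad summary (r² varies along the genome and distance distributions are
skewed), so alone regions should be interpreted with caution; the same
caveat applies to the genome-coverage estimate below.

Candidates whose position is not itself a genotyped variant are an error by
default; `on_missing = "nearest"` substitutes the closest genotyped variant
within the window for the linkage lookup, with a logged substitution.

**Genome coverage.** Each genotyped variant is extended by ± the average
linked distance, intervals are clipped to the chromosome and merged, and
coverage is the merged length over the summed chromosome lengths. All
coordinates in the package are 1-based inclusive (the native convention of
both VCF and GFF), so interval lengths are `end − start + 1`; the merge is
overlap-aware rather than the cruder `n_SNPs × 2d / genome` product, which
overcounts as soon as intervals overlap.

## Overlap semantics

A feature is reported for a region when their closed intervals share at
least one base pair; adjacency is not overlap, and containment is not
required. "Nearest feature" is never substituted — the entire point of the
method is that proximity without linkage is not evidence. Feature-type
selection (`gene`, `mRNA`, `CDS`, ...) is an exact, case-sensitive match on
the third GFF column, avoiding the redundancy of hierarchical annotation
levels; exact duplicate records are dropped with a count. The attributes
column is passed through verbatim (an optional `feature_id` column can be
extracted from `ID=` for convenience).

## The checkpoint

The expensive stage — genotype parsing plus the pairwise scan — depends only
on the genotype input and the LD parameters, not on the user threshold or
the annotation inputs. `ld_annotate(..., checkpoint_dir =)` therefore stores
the pair table at the base threshold, the kept variant positions and a
fingerprint (MD5 of the genotype file contents plus the LD parameters) as a
versioned TSV + JSON sidecar. A rerun with matching fingerprint and a
threshold at or above the stored base reuses the table; r² values are
serialized at full double precision (`%.17g`), so checkpointed reruns are
byte-identical to cold runs. Any change to the genotype files or parameters
invalidates the fingerprint and forces recomputation.

## What the synthetic generator emulates — and what it does not

`simulate_genotypes()` produces diploid dosage matrices with block-wise LD by
founder-gamete copying:

* **hard blocks**: every variant carries an exact copy of the block's two
  founder gametes, some variants allele-flipped — pairwise r² is exactly 1
  before missingness, so the true region around any in-block candidate is
  known by construction;
* **decay blocks**: a Markov chain along the block — each variant's gametes
  copy the previous variant's, with each gamete independently resampled from
  the founder allele frequency with probability `rate`, giving haplotype
  correlation (1 − rate)^(steps apart), i.e. genuine distance-decaying LD;
* variants outside blocks are drawn independently; founder minor-allele
  frequencies are uniform on `maf_range`; missingness is uniform at
  `missing_rate`; everything is reproducible from one seed.

The defaults (50 diploid individuals, 2 chromosomes × 1 Mb × 60 evenly
spaced variants, one hard and one decay block per chromosome, MAF 0.1–0.5,
no missingness) are sized like a small breeding-population or pedigree
genotyping experiment while keeping the full test suite and the acceptance
script inside seconds of compute; that scale is a deliberate package choice
and is what all end-to-end numbers in the README were produced at.
`write_fixture_bundle()` renders one simulated matrix as every input format
the pipeline accepts, places genes inside blocks, across block edges and
between blocks, places candidates inside blocks and in no-LD gaps, and
records the expected regions and hits in a JSON manifest.

This generator is a test substrate, not population genetics: there is no
recombination map, demography, selection, genotyping-error model, or allele
frequency spectrum from a real ascertainment scheme. Passing tests therefore
demonstrate the *algorithmic* contracts (estimator correctness, exact block
recovery, threshold monotonicity, checkpoint transparency, cross-format
equivalence) — not that any particular biological dataset will show LD of a
given extent.

## Numerical choices and degenerate inputs

* r² is clamped to [0, 1]; values within 1e-12 of 1 are snapped to exactly 1
  so that complete LD (identical or allele-flipped dosage vectors) survives
  an inclusive cut at threshold 1 despite floating-point rounding in the
  sums.
* Ties at a threshold are retained (inclusive comparison) at both the base
  and the user threshold.
* The EM split weight for double heterozygotes falls back to 1/2 when both
  phase products are zero.
* Zero qualifying pairs make the average distance undefined: alone regions
  then degenerate to the candidate position itself, with a prominent
  warning.
* Chromosome-name normalization strips a single leading `chr`/`Chr`/`CHR`
  prefix and nothing else; broader aliasing (e.g. `MT` vs `M`) risks silent
  mis-joins and is deliberately not attempted. A candidate chromosome with
  no genotyped counterpart is an error naming the file and the probable
  cause; an annotation chromosome without variants is only a warning.
* Variant ordering uses a radix sort on (chromosome, position), so record
  order in the input files never leaks into the output; two runs on
  identical inputs are byte-identical.
* Output files are written to a temporary name and atomically renamed, so a
  failed run never leaves a partial output behind.

## Design decisions that were genuinely open

* **Which r² definition?** Standard LD tooling computes either the dosage
  correlation or the EM gametic r² depending on flags, and pipelines built
  on such tools rarely record which was used. Both are exposed here, with
  dosage correlation as the deterministic default; no silent choice is made
  for the user.
* **SNP-array reference orientation.** Array exports carry allele calls but
  no REF/ALT. The first allele seen per SNP (scanning files in lexicographic
  name order) fixes the orientation; r²'s relabeling invariance makes the
  choice immaterial, and a test asserts as much.
* **SNP map layout.** Array vendors vary; the reader fixes (name,
  chromosome, position) columns with an auto-detected header line, which
  covers the common exports and fails loudly otherwise.
* **Per-individual header length.** Array exports are read after skipping 12
  comment/header lines by default, the usual layout of such files;
  `skip_lines` overrides it.
* **Average distance weighting.** The mean is taken over all retained pairs
  globally, not per chromosome; with very uneven SNP densities a
  per-chromosome average could differ, but a single global figure matches
  the quantity's role as a dataset-wide fallback radius.
* **Output contents.** The output table includes both the candidate
  identifier and its position alongside the region, feature coordinates and
  attributes — the identifier is where the `_alone` flag lives, and the
  position makes rows self-contained.

## Known limitations

* No haplotype-block detection (confidence-interval or four-gamete methods);
  regions are defined purely by thresholded pairwise r² with the candidate.
* No D or D′ statistics, no inbreeding-corrected composite LD, and no use of
  phase information even when genotypes are phased (`|` separators are
  treated as unphased).
* The genome-coverage figure inherits all caveats of the average linked
  distance; treat it as an order-of-magnitude statement.
* The pairwise scan is quadratic per chromosome within the window; for
  whole-genome SNP sets in the tens of millions, run with a finite
  `window_bp` and expect the LD stage to dominate, mitigated on reruns by
  the checkpoint.
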