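---
title: "Curating SSR fingerprint collections: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating SSR fingerprint collections: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrcurate)
```

## The problem

Germplasm collections of clonally propagated crops (the motivating system is
apple, *Malus* × *domestica*) hold thousands of accessions whose labels are
historically unreliable: the same cultivar is planted under synonyms at
several sites, mislabelled trees abound, and grafted rootstocks or wild
seedlings masquerade as cultivars. SSR fingerprinting at a standard marker
panel identifies which trees are genetically the same cultivar — but the raw
fragment data are noisy (±1 bp sizing variation, allelic dropout, occasional
sample swaps, systematic offsets between genotyping campaigns), and each
cultivar is represented by anything from 1 to ~73 replicate samples. This
package turns that raw table into a curated cultivar-level table: molecular
groups, one consensus genotype per group, an aggregated trueness-to-type code,
and a validation of which consensus genotypes correspond to a real tree.

## Data model

An allele call at one marker is a *set* of distinct allele fragment lengths
(AFLs, integers in bp), not a multiset: fragment sizing cannot observe copy
number, and the encodings `x:x` and `x:0` for a homozygote are
indistinguishable in intent, so both normalise to `{x}`. A `0` cell is a null
call (no amplification). AFLs outside 50–600 bp — the range covered by
standard capillary sizing ladders — are rejected as errors rather than
warnings, because they indicate upstream scoring problems that silent
tolerance would hide.

The default panel is the 17-marker apple set (CH01h01 … GD147). Hi02c07 and
CH04e05 are flagged multi-locus (supernumerary alleles there are genuine),
GD12 unknown, the rest single-locus. The panel is data
(`inst/extdata/marker_panel.yaml`), so other crops or panels are a YAML file
away.

## Distance and clustering

The pairwise distance between profiles is one minus the Dice–Sørensen
similarity, summed over all panel markers, with tolerance-aware allele
matching:

$$ d = 1 - \frac{2\sum \text{common alleles}}{\sum \text{alleles}_1 + \sum \text{alleles}_2} $$

Three choices here were genuinely open and are worth recording:

* **Matching, not binning.** "Common alleles" is the size of a maximum
  bipartite matching under $|x-y| \le$ `tolerance_bp` (default 1). Matching
  is computed by a greedy two-pointer sweep over the sorted sets, which is
  optimal for an interval tolerance on a line; the test suite verifies it
  against brute-force enumeration on 1,000+ random pairs. Transitive binning
  would let a 1 bp chain (100, 101, 102) count as more shared material than
  the data support.
* **Null handling.** Markers null in both profiles contribute nothing to
  either sum — otherwise two profiles sharing a failed marker would look more
  similar — while a marker null in only one profile contributes its alleles
  to the denominator only, so dropout is penalised. This keeps $d(p,p)=0$
  exactly. A pair in which *both* profiles are entirely null has no defined
  distance; the matrix routine records the pair, warns, and sets 1.0 rather
  than aborting a whole run for one empty record.
* **Single linkage, inclusive cutoff.** Groups are connected components of
  the graph joining pairs with $d \le 0.25$. The merging behaviour observed
  when datasets are pooled (previously separate groups joining through
  intermediate profiles) is characteristic of single linkage, and the
  inclusive threshold matches the reading that profiles 75–100% identical
  belong together. The cutoff is a parameter; the distance histogram
  (`autoplot()` on an `ssr_dist`) shows the replicate mode near 0 and the
  between-cultivar mode near 0.85, and the wide valley between them is what
  makes the method robust to the exact value.

Group identifiers `MD_####` are assigned in order of first appearance of each
group's earliest member, so they are deterministic for a given input file.
Reproducing any historical numbering is out of scope; splits performed by
directives allocate fresh numbers after the current maximum.

The full matrix is computed in compiled code (Rcpp); an $n=2{,}000$ campaign
(2 million pairs × 17 markers) takes seconds, which the test suite exercises.

## Harmonization

**Inter-cohort shift correction.** Capillary sizing can drift systematically
between campaigns; the default panel carries a rule for CH02g09: values of
the 2009–2014 cohort sit 2 bp below the 2017–2021 cohort, predominantly at
122–140 bp. Correction is evidence-based, per molecular group: an
affected-cohort AFL $a$ in the window is raised to $a+2$ only if some
same-group sample from the other cohort shows $a+2$ at that marker *and* $a$
itself is not seen in the other cohort. The second condition is not in the
original narrative but is forced by coherence: without it a value could be
re-shifted on a second pass (130 → 132 → 134 when the reference cohort shows
both 132 and 134), and values already consistent across cohorts would be
"corrected" away. With it, the operation is idempotent, which the tests
assert. The window is configurable because the drift is only *predominantly*
in 122–140 bp.

Some simulated offsets are unrecoverable in principle: if the offset makes
two alleles of one call collide ({128, 130} observed as {128}), or shifts a
chain ({136, 138} observed as {134, 136}), no within-group evidence can
reconstruct the original. The tests therefore assert exact repair only for
unambiguous single-allele offsets, plus strict overall improvement.

**Directives.** Manual curation — removing rootstocks/crab/wild apples and
mislabelled samples, reassigning swapped samples, splitting groups that lump
closely related di-/triploid cultivars — is expressed as a YAML file of
`{verb, target, args}` entries replayed on every run. This converts ad hoc
spreadsheet edits into a reproducible, auditable artefact; the audit log
records each mutation in order, and the pipeline manifest records a hash of
the directive set.

## Consensus rules

Per group and marker the calls are tallied (`tally_calls()`), and the
consensus starts from the modal call. Three refinements, in this order:

1. **Missing-value fill**: a null modal call yields to the most frequent
   amplified call (flag `missing-filled`).
2. **Heterozygous preference**: a call that is a strict superset of the
   current consensus, whose extra alleles all differ from every consensus
   allele by *more than* the tolerance, replaces it (flag
   `heterozygous-preference`), iterated to a fixed point. The superset
   requirement means a conflicting disjoint minority can never overwrite the
   majority; the tolerance condition stops a 1 bp sizing artefact from being
   promoted to a real allele. The rationale: dropout of one allele is far
   likelier than spurious amplification of a clearly distinct one.
   Fill-before-preference is our resolution of the (unstated) precedence
   between the two rules; both flags are kept when both fire.
3. **Ties** between equally frequent calls: if all tied calls are pairwise
   within tolerance (same size, allele-for-allele match), they are sizing
   variants of one call and collapse to the smallest AFLs; otherwise the
   first-seen call is kept. Either way the marker is flagged `unresolved` —
   the deterministic fallback replaces a human judgement call and must stay
   visible for review.

**Ploidy-aware artefact removal** (`ploidy_adjust()`): where a known-diploid
genotype carries more than two alleles at a single-locus marker, each allele
is checked against a dataset-wide census over *consensus genotypes* (not
samples — replicate counts would otherwise let one heavily sampled cultivar
dominate the evidence). An allele unique to this genotype lying within
`window_bp` (default 1; directive override up to 2) of a widespread allele in
the same call is removed as a chromatogram-processing artefact. Multi-locus
markers are exempt, ploidy is never inferred from allele counts (a triploid's
3-allele call is genuine), and if removals cannot bring the call down to two
alleles the call is left intact and flagged rather than mutilated.

Every deviation from the plain modal call carries a flag; the flag table
(`consensus_flags()`) is the curator's work list.

**Naming.** A group's cultivar name falls back through: modal pomological
determination → modal holder-provided name → the group id itself.

## Trueness-to-type aggregation

Codes: `1` true-to-type, `2` true-to-type (group/mutant), `5` true-to-type
with reservations, `R` reference (substituted by `1`), `3` not determined,
`4` not assessed, `0` deceased. Aggregation per cultivar: any true-to-type
code wins by preference `1 > 5 > 2`; otherwise the more common of `3`/`4`
(our tie-break: `3`, the weaker claim); `0` survives only alone, since any
actual assessment supersedes a dead tree. The operation is order-invariant
and idempotent, so it can be re-run on mixed sample/cultivar inputs safely.

## Reciprocal validation

A consensus genotype is *assignable* if it equals — exact set equality at
every marker, zero tolerance — at least one individual profile. Tolerance is
deliberately absent here: the question is whether a physical tree exists
whose recorded fingerprint *is* the consensus, not whether one is close.
Consensus genotypes failing this are synthetic compilations; they are valid
reference profiles but cannot be tied to a specific accession for, e.g.,
budwood collection.

## The synthetic generator

The generator emulates the structure of a two-campaign genebank inventory so
the pipeline can be tested against known truth without any external data:

* per-marker allele pools of 8–25 distinct AFLs in 90–260 bp (the shift-rule
  marker draws its pool around its 122–140 bp window so the offset process
  has material to act on);
* cultivars diploid (90%) or triploid (10%); multi-locus markers carry a
  supernumerary allele 30% of the time; mutants/sports (default 3%) share a
  parent's genotype under a distinct name and are scored as one molecular
  class with it, since SSRs cannot separate them;
* 1–73 replicate samples per cultivar (uniform), cohort split 37%/63%
  matching a 2,939/4,951 two-campaign split;
* noise: per-allele ±1 bp jitter (default 1%), per-marker dropout (default
  2%), per-sample label swaps (default 0.2%), and the systematic 2 bp
  cohort offset.

Distinctness of true genotypes is enforced by rejection sampling: every
accepted genotype must exceed the clustering cutoff from all previous ones,
evaluated with the matching tolerance widened by 2 bp so that ±1 bp jitter on
both sides can never pull two cultivars under the cutoff — this is what makes
perfect recovery (adjusted Rand index 1.0) *achievable* at zero noise, and
hence a meaningful control. Every injected error is a ledger row recording
the affected sample, marker, and the call before/after; replaying the ledger
backwards reproduces the noise-free dataset exactly, which the tests assert
byte-for-byte.

What the generator does **not** emulate: realistic allele-frequency spectra,
pedigree relatedness between cultivars (all non-mutant genotypes are drawn
independently, so between-cultivar distances are larger and cleaner than in a
real collection of related varieties), multi-tested trees, and stutter or
split peaks beyond ±1 bp. Passing recovery tests therefore shows the
machinery is correct under the stated noise model, not that a real inventory
with closely related cultivars would cluster as cleanly — that is exactly
why the group-splitting directives exist.

## Numerical and degenerate-case choices

* All allele arithmetic is integer; randomness flows through R's generator
  from a single seed, so runs are bit-reproducible across platforms.
* Adjusted Rand index (via mclust) with the convention that two identical
  partitions — including the degenerate single-cluster case, where the index
  is 0/0 — score 1.0.
* Recovery metrics attribute a swapped sample to its profile donor's class:
  the pipeline sees only the profile, so penalising it for the label would
  measure the simulator, not the method. Swap detection is scored separately
  as the fraction of swapped samples landing in their donor's group.
* Problem sizes in the shipped tests: oracle equivalence on 1,000+ random
  pairs, recovery runs at 50 cultivars × 1–10 replicates, and a
  2,000-sample × 17-marker scale run — sizes chosen to exercise the
  quadratic distance stage meaningfully while keeping the default suite
  quick on a laptop.

## Known limitations

* Exact consensus recovery degrades sharply for cultivars represented by
  very few noisy replicates: a single sample carrying any jitter or dropout
  *is* its group's consensus, so no rule can recover the true genotype. The
  recovery metrics quantify this; in practice such cultivars are exactly the
  ones flagged for resampling.
* Mutants/sports are molecularly invisible; the package follows the field in
  masking them under the parent's profile rather than pretending to separate
  them.
* The shift-correction rule repairs only what within-group cross-cohort
  evidence supports; collided or chained offsets remain (flagged by
  disagreement, not silently guessed).
* Trueness code `5` carries multi-accession sub-conditions that are not
  computable from fingerprint data; the code is carried and aggregated as an
  opaque label.
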