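---
title: "Designing MMEJ-driven gene edits: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing MMEJ-driven gene edits: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmejdesign)
```

## The repair model

When a programmable nuclease (Cas9, Cas12a, a TALEN pair) cuts genomic DNA,
the cell can repair the double-strand break (DSB) by microhomology-mediated
end joining (MMEJ): 5'→3' end resection exposes single-stranded DNA on both
sides of the break, short identical sequences (*microhomology arms*, roughly
2–25 bp) anneal across the break, the unpaired flaps are clipped, and the
result is a clean deletion of everything between the two arm copies. Unlike
non-homologous end joining, which produces heterogeneous indels, MMEJ
outcomes are dictated by the sequence itself and are therefore predictable —
and exploitable, both for making reproducible deletion alleles and for
knocking cargo in via homology-mediated end joining (HMEJ).

This package models that process with three connected components:

1. **A deletion-pattern kernel.** Every pair of identical k-mers
   (2 ≤ k ≤ 25) in which the left copy starts before the cut, the right copy
   ends after it, and the copies do not overlap, is one candidate MMEJ
   deletion. Each pattern is scored by

   *score = 100 · round(exp(−D / 20), 3) · Σ w(b)*,

   where *D* is the deletion length (distance between the arm-copy starts),
   the sum runs over the arm bases, and *w(A) = w(T) = 1*,
   *w(G) = w(C) = 2*. Long, GC-rich arms anneal more stably (higher score);
   long deletions require more resection (exponential penalty with a 20-bp
   decay constant). The decay constant, the ×100 scale, the 3-decimal
   rounding of the decay factor and the arm-length bounds are all exposed in
   `gss_config()`; the defaults follow the established pattern-score
   formulation that this score family comes from.

2. **A competition score for target selection** (`menthu_scan()`). Patterns
   describing the same repaired junction are collapsed to the maximal arm
   (`deduplicate_patterns()`), and the site's score is the quotient of the
   two highest pattern scores in an 80-bp window centred on the cut. A large
   quotient means one deletion has no serious competitor, so a single
   *predominant MMEJ allele* (PreMA) is expected to dominate repair. A site
   enters the report only if its top pattern has ≤ 5 bases between the arm
   copies in the wild type, and is *recommended* when the quotient is
   ≥ 1.5. Exact ties give a quotient of 1.0 and are never recommended —
   equal competition means no predominant allele. Sites with fewer than two
   deduplicated patterns have no defined quotient and are excluded (the
   report needs both a winner and a runner-up); they are logged as warnings.

3. **A repair-fraction regressor** (`medjed_*`). Not every site channels its
   deletions through MMEJ. Six summary statistics of the pattern set at a
   centrally-cut 20–200-nt sequence — minimum deletion length; maximum, mean
   and standard deviation of arm lengths; maximum and standard deviation of
   pattern scores — feed a random-forest regression of the fraction of
   deletion outcomes attributable to MMEJ. The forest averages training
   targets, so predictions always lie within the training range.

## Nuclease geometry

`nuclease_spec()` describes where a cutter cuts. For Cas9-like enzymes the
blunt cut sits 3 bp from the PAM-proximal end of the protospacer (between
positions 17 and 18 of a 20-nt guide). Staggered cutters such as Cas12a
leave a 5' overhang; because resection proceeds 5'→3', the overhang bases
are lost before annealing can use them. `make_context()` therefore builds a
*pseudostring* — the sequence 5' of the cut concatenated to the sequence
past the overhang — and recentres the 80-bp window on that junction, so
staggered cuts reduce to the blunt case. We recentre rather than truncate
asymmetrically so both sides contribute equally to the pattern search; sites
too close to a sequence end to fill the window are skipped with a warning
rather than padded with invented sequence. For complement-strand sites the
cut index is normalised to the leftmost strand cut in forward coordinates,
which makes forward and reverse-complement scans exact mirror images —
a property the test suite checks on dozens of random loci.

TALEN support uses a conventional geometry the source material leaves open:
binding arms of 15–18 nt, spacers of 14–16 nt, cut at the spacer midpoint
(left-biased for odd spacers), and the canonical T immediately 5' of the
left arm with the complementary A 3' of the right arm. All of it is
configurable.

## Knock-in oligo design

`gtaghd_design()` supports HMEJ knock-in: the 20-nt guide is located in the
locus (it must occur exactly once across both strands — a hard error
otherwise), the cut is placed 17 nt into the protospacer, and the requested
number of bases on each side becomes the 5' and 3' homology arms. No PAM
check is made at the hit, so any Cas9-like nuclease works. When the locus
carries CDS annotation and the cut falls at codon phase 1 or 2, `3 − phase`
bases duplicated from immediately downstream of the cut are appended to the
5' arm (configurably the 3' arm instead), so the cargo junction lands on a
codon boundary while the genomic sequence remains intact — deliberately
*not* the alternative of inserting filler C's or deleting a codon, which
alters the locus. Without CDS annotation, frame repair is disabled with a
warning.

Each arm becomes an annealing forward/reverse oligo pair; plasmid-series
adapters (sticky ends, restriction sites) are prepended/appended verbatim
from an editable configuration (`gtaghd_series()`). The shipped series are
synthetic documented examples, not real vector sequences; the `custom`
series shows guide templating, where `{guide}` / `{guide_rc}` placeholders
are filled with the cargo-freeing gRNA. When a series defines a plasmid
template, a GenBank-format map with the arms annotated is written alongside
the oligo text file.

## What the synthetic generator emulates

Training data pairing sequences with observed MMEJ deletion fractions are
experimental and external, so the package ships a seeded generator
(`medjed_dataset()`) that emulates that table's *structure*: random
60–120-nt sequences of varying GC content whose latent MMEJ propensity is a
logistic function of the strength of the best microhomology —
`plogis(-6 + 0.007·score_max + 0.6·arm_length_max)` — plus Gaussian noise
(sd 0.05 by default), clipped to [0, 1]. The constants were chosen once so
noiseless targets span roughly 0.1–0.9, similar to the spread of MMEJ
fractions reported for real Cas9 sites.

What a passing recovery test shows: the feature extraction and forest can
recover a smooth monotone signal carried by the features at realistic noise.
What it does not show: that real repair fractions follow a logistic in these
two features, that the features are sufficient in real chromatin contexts,
or that any particular cell type behaves like the generator. A model trained
on synthetic data is a demonstration; for real predictions, retrain on an
experimental table via `medjed_train()` (the CLI accepts a
`sequence, observed_fraction` CSV).

Likewise, `implant_microhomology()` writes two copies of a chosen arm into
random background and rejection-samples the background until the implant is
the strict top-scoring pattern at the cut; generator and kernel
cross-validate each other, and the returned ground truth is used throughout
the tests.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; the report's `DSB_Location`
  column is the 1-based position of the nucleotide directly left of the cut,
  which numerically equals the 0-based cut index.
* The recommendation threshold is applied as ≥ 1.5 (inclusive).
* Score ties are ordered by intervening distance before position, so
  eligibility and the score multiset are invariant under reverse
  complement; the reported arm sequence for an exactly tied pair may still
  legitimately differ between strands.
* Standard deviations in the six features use the sample (n − 1) definition
  and are 0 for a single pattern.
* Odd-length inputs to `medjed_features()` are rejected with advice to trim
  one terminal base: "the exact middle" of an odd-length sequence would
  silently shift the cut by half a base, and we refuse to guess.
* An N in the genome never satisfies a non-N PAM code (`iupac_match()`):
  ambiguous sequence is not claimed as a targetable site.
* The forest uses 500 trees and default feature subsampling, seeded;
  training is deterministic given the seed.
* T7-compatibility filtering keeps guides beginning `GG` as written 5'→3'
  (the T7 polymerase initiation preference).
* Report CSVs render scores with two decimals; all writers are
  deterministic, so identical seeds give byte-identical outputs.

Problem sizes used in the shipped validation: the enumeration oracle runs on
200 random contexts of ≤ 60 nt; strand symmetry on 50 loci of 250 nt; the
recovery experiment trains on 200 and tests on 100 synthetic sites. These
sizes give stable results at interactive runtimes.

## Known limitations

* Only deletion-by-annealing outcomes are modelled: no insertion or NHEJ
  indel profiles, no single-strand annealing (arms > 25 bp), and no
  per-outcome probability distribution.
* The pattern score is a heuristic for annealing strength; its constants
  come from an established formulation rather than being refit here.
* Staggered-cutter (Cas12a-type) handling follows the resection logic above
  but has no experimental validation behind it in this package.
* The GenBank reader covers simple forward-strand `a..b` features (exon,
  CDS with `/codon_start`, labelled misc_features) — adequate for
  package-generated annotation and plasmid maps, not for arbitrary records;
  joins and complement locations are not parsed.
* Accession-based sequence retrieval is not performed; inputs are local
  files or pasted text.
* Off-target scanning is out of scope; dedicated genome-wide tools exist
  for that purpose.
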