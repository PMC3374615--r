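---
title: "Methods: CRISPR detection, targeted assembly and spacer analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR detection, targeted assembly and spacer analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrispr)
```

This vignette documents the models, procedures and numerical choices behind
`mcrispr`, in the spirit of a methods section: what each stage assumes, which
parameters matter and why their defaults are what they are, and what the
synthetic-data validation does and does not demonstrate.

## Sequence primitives

All sequences live over `{A,C,G,T,N}`; lowercase input is uppercased on read
and IUPAC ambiguity codes other than N are rejected, which keeps every
downstream mismatch count well defined. **N matches nothing, including
another N** — in mismatch counting, in the edit distance, and in k-mer
extraction (k-mers containing N are discarded). This is the conservative
choice: an uncalled base can never *support* a repeat match, only cost one.
Quality strings are carried through FASTQ I/O but never used: recruitment
and assembly are sequence-only, and the substitution-noise regime the
package targets does not benefit from quality weighting.

The edit distance is plain unit-cost Levenshtein (computed via `adist`).
Because the orientation of a CRISPR repeat is generally not determinable
without cas-gene context, all repeat-to-repeat comparisons use the
*oriented* distance: the minimum of the forward distance and the distance to
the reverse complement (`orientedDist`). Repeats of unequal length receive
no special treatment — end gaps cost like any other indel. Column consensus
is per-column majority over `A,C,G,T` with N excluded from voting, ties
broken alphabetically, and an all-N column yielding N; the alphabetical
tie-break is arbitrary but total, which makes every consensus deterministic.

## De novo array detection

Detection follows the classic seed-and-validate design:

1. **Seeding** (`findSeedChains`): exact `seedLen`-mers (default 8) that
   recur with consecutive gaps inside the window
   `[minRepeatLen + minSpacerLen, maxRepeatLen + maxSpacerLen]` form
   candidate chains with at least `minCopies` (default 3) occurrences. An
   8-mer seed is long enough that a 10 kb random contig yields essentially
   no persistent chains, and short enough that a repeat whose copies carry
   scattered substitutions still shares some exact 8-mer across copies.
2. **Boundary extension** (`extendAndRefine`): repeat edges are pushed
   outward from the seed one column at a time while at least
   `columnAgreement` (default 0.75) of the copies agree with the column
   majority. The 0.75 rule tolerates one divergent copy in four — matched
   to the catalog filter's one-mismatch-per-copy average — while random
   spacer columns agree at ~0.4 in expectation.
3. **Consensus re-scan**: the candidate consensus is scanned back against
   the contig with the 3-mismatch full-repeat budget and re-chained, so
   copies whose seed k-mer was mutated away are still recovered. The full
   copy set then drives a second boundary refinement. Two asymmetries are
   handled here deliberately:
   * With few copies, a random spacer column passes 3-of-4 agreement about
     20% of the time, so *trimming* terminal columns demands more than
     *extending* does: the trim threshold is
     `columnAgreement + 0.75/n` (unanimity for n = 4, relaxing toward
     0.75 as copies accumulate). On error-free arrays this gives exact
     boundary recovery; under per-copy substitution at rate 0.02 the
     boundary error stays within 1 bp at each end in ≥ 95% of simulated
     arrays.
   * Terminal copies more than 3 mismatches from the consensus are pruned —
     they are almost always coincidental seed matches in flanking sequence,
     not repeat copies.
4. **Validation** (`validateArray`): an array is accepted iff it has enough
   copies, the consensus length is within bounds, every spacer length is in
   `[18, 72]`, the longest spacer is at most 2.5× the shortest, no spacer
   pair reaches 0.80 identity (identity = 1 − edit distance / longer
   length), and no spacer reaches 0.80 identity with the repeat consensus.
   These enumerated checks are this package's explicit replacements for the
   unpublished internals of earlier structural detectors; each produces a
   distinct machine-readable reject reason.
5. **Truncated ends** (`attachTruncatedEnds`): if the flank beyond a
   terminal repeat is shorter than one spacer-plus-repeat period, the
   contig end is searched for a fragment of the consensus of at least 5 bp
   whose mismatches stay within `ceil(3·m/L)` — the 3-mismatch full-repeat
   budget prorated to the fragment length m. The 5 bp floor keeps the
   expected number of spurious flags low (a random 5-mer matches a given
   consensus suffix with probability ~10⁻³ per end). A complementary case
   is handled first: when the truncated fragment itself joined the seed
   chain (a cut that keeps most of the repeat), it caps boundary extension,
   so detection tries dropping the edge copy and keeps that variant iff the
   consensus grows.

Overlapping accepted candidates (many seeds per locus) are resolved by most
copies, then longest span, then leftmost — a deterministic total order, so
repeated runs produce byte-identical GFF3.

Coordinates are 1-based inclusive throughout the R API (the native
convention of `IRanges`), and GFF3 output is 1-based inclusive as the format
requires.

## Similarity-search detection and novelty

`scanRepeat` reports every window of the target, on both strands, within
`maxMm` mismatches of the query — by construction equal to a brute-force
sliding scan, which is exactly how the tests check it. Matching is gapless:
at repeat lengths of 24–47 bp with small mismatch budgets, an alignment
with an indel cannot also stay within budget, so Hamming windows lose
nothing. Overlapping same-strand hits with starts closer than half a query
length are reduced to the lowest-mismatch one (ties leftmost); genuine
adjacent repeat copies are always separated by at least `minSpacerLen`, so
the reduction can never merge them. `hitsToArrays` chains same-strand hits
across spacer-sized gaps; chains of ≥ 2 elements become arrays and inherit
the spacer validation rules.

A repeat is *novel* with respect to a reference collection if no reference
contains a chained array (≥ 2 elements) of it within 4 mismatches. The
array requirement, rather than any single hit, is deliberate: a lone repeat
copy in a genome is not a CRISPR instance, and treating it as one would
misclassify repeats that happen to have a single cross-reactive copy
elsewhere.

## Targeted assembly

Recruitment keeps a read iff some full-length window on either strand
matches the query repeat with ≤ 3 mismatches — tolerant to sequencing error
and natural inter-copy variation, strict enough that random 100-mers are
essentially never recruited at repeat lengths ≥ 24. Mates of recruited
reads are *not* pulled in; recruitment is purely sequence-driven and
single-end.

The assembler is an internal node-centric de Bruijn graph over canonical
k-mers (lexicographic minimum of k-mer and reverse complement; recruitment
captures both strands, so strands must be merged). Defaults: `k = 45` —
long enough that a 45-mer spans a repeat–spacer junction uniquely, which is
the entire point of targeted assembly; `minCount = 2` — singleton k-mers
are overwhelmingly sequencing errors at ≥ 30× coverage (documented override
to 1 for very low coverage). Contigs are maximal non-branching paths; tips
(dead-ended unitigs) shorter than 2k are clipped; contigs are emitted in
canonical orientation ordered by length then sequence, making assembly
deterministic for a fixed read multiset. After assembly, each contig is
re-oriented so the query matches the forward strand, arrays are located by
the similarity-search machinery (which defines the exact repeat/spacer
boundaries), and contigs with no repeat hit are suppressed and counted.
The per-sample summary (reads recruited, contigs, max spacers per contig,
total spacers) is the toolchain's comparison schema.

## Catalog and spacer analytics

The **selection filter** promotes an array into the trusted catalog iff its
consensus is 24–40 bp, it has ≥ 4 *complete* (non-truncated) copies, and
complete copies average ≤ 1 mismatch to the consensus — all bounds
inclusive, all checked at exactly the boundary in the tests. Truncated
copies are excluded from both the copy count and the average: a fragment's
mismatch count is not comparable to a full copy's.

**Clustering** is greedy in decreasing length (ties alphabetical), joining
the first representative at or above the identity threshold, with identity
`1 − orientedDist/longer length`. Using the longer sequence as denominator
is a deliberate, testable divergence from CD-HIT's short-sequence
convention. Because joining is orientation-aware, a sequence and its
reverse complement always co-cluster; a final representative-level
reverse-complement sweep (dropping the lexicographically larger of any
rc-duplicate pair) is retained as a guarantee rather than an expected code
path.

The **repeat network** connects repeats at oriented edit distance ≤ 10.
The threshold is inclusive ("at most 10 operations"); a strict variant is
one flag away (`maxDist = 9`). **Body-site classification** labels a
repeat rare below 5 total samples, otherwise assigns every site where it
appears in > 10% of that site's samples.

**Proto-spacer search** implements "≥ 90% identity over ≥ 30 bp" as a
gapless full-spacer window scan on both strands, computed exactly (a
vectorized all-window mismatch count) rather than through a lossy seed
filter — at 90%/30 bp a 3-mismatch hit can lack any 11 bp exact stretch,
so exact scanning is both simpler and provably complete; at these problem
sizes it is also fast. Gapped alignments are deliberately out of scope
(documented limitation): gapless windows are what make the brute-force
oracle equivalence exact. Flanks (default 10 bp) are reported in
proto-spacer orientation and N-padded at genome ends. The **PAM profile**
gives per-position base frequencies over the flanks (N mass excluded and
reported) and the top dinucleotide — the dinucleotide with the highest
frequency at any single adjacent position pair, which is the statistic that
returns frequency 1.0 when a motif is planted at a fixed offset and stays
below ~0.09 on uniform flanks.

Spacer **uniqueness** is defined on the canonical orientation
(lexicographic minimum of sequence and reverse complement), since the
strand of an assembled spacer is arbitrary; deduplication preserves total
multiplicity by construction.

## The synthetic-data generator

`simLocus`/`simGenome` plant repeat–spacer arrays (spacers i.i.d. uniform,
pairwise identity < 0.8 enforced by rejection, per-copy substitutions at a
configurable rate) into i.i.d. uniform backgrounds; `simReads` draws
uniform single-end reads with substitution-only errors; `simCommunity`
builds multi-subject, multi-site, multi-visit inventories with strictly
ordered sharing tiers (defaults 0.8 same-site resample, 0.2 same-subject
cross-site, 0.0 cross-subject); `simPhage` embeds (optionally mutated)
spacers with a PAM immediately downstream on a random strand. Every
generator returns exact truth (coordinates, consensus, inventories), so
recovery can be scored without external data.

Default study conditions used by the validation suite: 100 bp reads, 50×
coverage, error rate 0 for the six-genome/ten-array perfect-recovery
check (the published-style validation regime leaves these unstated; these
are declared defaults, with 30× used for the community fixture where
coverage is not the quantity under test). Problem sizes in the tests —
genomes of 1.5–9 kb, 200-case oracle sweeps, 1000-pair DP comparisons, a
6-subject × 2-site × 2-visit community — were chosen as the smallest sizes
at which each claim is meaningfully exercised.

What the simulations do **not** emulate: indel sequencing errors (the
matchers are gapless by design, so indel noise would need a different
recruitment model), GC bias and non-uniform coverage, strain mixtures
within a sample, and realistic phage genome composition. Passing on
synthetic data therefore demonstrates algorithmic correctness under the
stated noise model, not field performance on real survey-scale microbiome
data.

## Degenerate inputs and tie-breaks, collected

* Contig shorter than two repeats plus a spacer: empty result with a
  message, not an error.
* Empty recruitment: empty contig/array/spacer outputs and a zero-filled
  summary row.
* All reads shorter than k: an error advising a smaller k (the assembler
  cannot proceed, and silently returning nothing would mask a
  misconfiguration).
* Identity comparisons at thresholds use a 1e-9 slack so that exact
  boundary cases (e.g. 27/30 = 0.90) are decided by arithmetic, not by
  floating-point representation.
* Every ordering the package emits (hits, contigs, clusters, network
  edges, sharing summaries) has a documented total order, so identical
  inputs give byte-identical outputs.

## Known limitations

* Detection reports arrays in contig orientation; without cas context the
  biological direction of an array (hence spacer acquisition order) is not
  inferred.
* The novelty test and proto-spacer search are exact-scan based and scale
  linearly in target size; they are meant for repeat catalogs and phage
  genomes, not for all-vs-all genome sweeps.
* Boundary recovery at 3–4 copies has an irreducible ±1 bp ambiguity when a
  random spacer column is unanimous across all copies; with ≥ 5 copies the
  probability of that event drops below 0.4% per end.
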