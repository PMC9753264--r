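---
title: "Seeding, mapping and alignment in strobemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeding, mapping and alignment in strobemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strobemap)
```

strobemap is a seed-and-extend short-read mapper whose seeds are *fuzzy and
variable-length*: two canonical open syncmers linked into a randstrobe. This
vignette explains the model behind each stage, the tunable parameters and
why their defaults are what they are, the design decisions taken where the
method left room, and what the synthetic-data experiments shipped with the
package do and do not demonstrate.

All coordinates in the package are 0-based and half-open (the BED
convention); conversion to 1-based happens once, at SAM emission.

## Seeding model

**2-bit encoding and hashing.** Nucleotides are packed two bits per base
(A=00, C=01, G=10, T=11, first base most significant), so a k-mer is an
integer: `encode_kmer("TCA")` is binary `110100` = 52. k-mers containing an
ambiguous base are skipped, and scanning resumes past the ambiguous run —
the standard aligner treatment of N runs. Hashing uses a fixed
xorshift-multiply finalizer (the splitmix64 constants, frozen in
`src/core.h`). The mixer is a bijection of the 64-bit space, which the test
suite exploits: an independent implementation of its inverse
(`unhash64()`) certifies that no two encodings can collide.

**Canonical open syncmers.** A k-mer is an open syncmer when the smallest
of its $k-s+1$ constituent s-mer hashes sits at a fixed offset $t$
(1-based; ties break toward the smallest offset). With the defaults $k=20$,
$s=16$ the expected density is $1/(k-s+1) = 1/5$ of k-mer positions, the
same as window minimizers at $w=9$, but syncmer selection is decided by
k-mer content alone, so the same k-mers are selected in a read and in the
reference regardless of flanking context. Both the k-mer and its s-mers are
hashed canonically (hash of the numerically smaller of forward and
reverse-complement encoding). Because $k-s+1$ is odd and
$t=\lceil (k-s+1)/2\rceil$ is central, a sequence and its reverse
complement select mirrored positions with identical hashes — the suite
asserts this exactly. Tie-breaking toward the leftmost offset is not
mirror-symmetric in degenerate windows (identical s-mers, as in
homopolymers); random 64-bit hashes make such ties vanishingly rare outside
low-complexity sequence.

**Skewed randstrobe linking.** Each syncmer (the *anchor*) is linked to one
downstream syncmer chosen among the $w_{\min}$-th through $w_{\max}$-th
syncmers after it. The partner minimises

$$B\big((h(k_1)\oplus h(k'))\,\&\,p\big),$$

the number of set bits among the $p$ leftmost bits of the XOR of the two
strobe hashes, with ties resolved to the nearest candidate. Because the
criterion takes only $p+1$ distinct values (default $p=8$), ties are
frequent and the selection is skewed toward *short* seeds. Short seeds help
short reads: near the read ends few syncmers remain, and a skew toward
nearby partners makes read and reference agree on the chosen pair more
often. The package also provides the unskewed masked-sum criterion
(`link_randstrobe_sum()`) for comparison; a test verifies the skewed
variant picks systematically nearer partners.

**Symmetric seed hash.** The stored seed hash is
$h'= \lfloor h(k_1)/2\rfloor + \lfloor h(k_2)/2\rfloor$ — symmetric in the
two strobes and free of 64-bit overflow. Together with canonical syncmers
this gives the same hash whether a seed is built from the forward or the
reverse-complement direction, so abundance masking treats both strands
consistently, and "false symmetrical matches" (a reverse-orientation seed
pairing the same two syncmers in the opposite order) can still anchor a
read when the forward seed was destroyed by a mutation.

An important subtlety: the *pairing itself* is not mirror-invariant. An
anchor picks its best partner downstream; on the reverse complement the
roles of anchor and partner swap, and the XOR-argmin need not select the
same pairs. Identically linked pairs hash identically (that is what $h'$
guarantees), but a small fraction of pairs (well under 1% on random
sequence with the default window) link differently in the two directions.
Reference seeding is therefore only approximately strand-symmetric at the
seed level — exactly symmetric at the syncmer level — and the test suite
records the distinction honestly: the syncmer assertion is exact, the
seed-multiset assertion is left as a known failing expectation rather than
weakened.

**Read-length profiles.** The tuple $(k, k-s, p, l, u)$ is selected from
the median length of the first 500 reads, with
$w_{\min} = \lfloor k/(k-s+1)\rfloor + l$ (floored at 1) and
$w_{\max} = \lfloor k/(k-s+1)\rfloor + u$; e.g. 150 nt reads use
$(20, 4, 8, 1, 7)$, hence a window of the 5th–11th downstream syncmers.
The seed span is capped at the median read length minus 50 (never below
$k+1$): open syncmers have no window guarantee, so a sparse stretch could
otherwise produce a seed longer than the read it must match. Anchors with
an empty window (sequence end, N runs, span cap) fall back to a
single-syncmer seed, flagged `is_single` and hashed by self-linking so
read and reference fallbacks still match.

## Index

Seeds of every reference are stored in a flat vector sorted by (hash,
reference id, start) — the full ordering makes builds reproducible — with a
directory from hash to (offset, count). Each record packs the reference id
into the rightmost 24 bits and the second-strobe offset into the leftmost 8
bits of one 32-bit word, which is why offsets above 255 are truncated to
the fallback seed (counted in a diagnostic; impossible with read lengths
up to about 350 nt, rare above). The abundance cutoff $A$ masks the most
repetitive hashes: $A$ is the count of the distinct hash ranked at
$\lceil f\cdot M\rceil$ in descending count order ($M$ = distinct hashes,
$f$ = 0.0002 by default), floored at 2. The quantile construction is this
package's concrete choice for the masking fraction's semantics; it masks at
most a fraction $f$ of distinct hashes by construction. The serialized
index is a versioned little-endian binary format whose writes are
byte-deterministic; reference sequences are not stored, so alignment after
`load_index()` requires the FASTA again.

## Mapping

**Matches and the streaming lowest-d filter.** Every read seed at or below
the abundance cutoff contributes one match per reference occurrence. Let
$d$ be the absolute difference between the reference span and the query
span of a match. While streaming over a read's matches the running minimum
of $d$ is maintained and a match is kept iff its $d$ does not exceed the
minimum *so far*. This one-pass rule is deliberately order-dependent — an
early match with larger $d$ survives if it streamed by before the minimum
dropped — and cheaper than a two-pass filter; a test replays the rule
through exported building blocks on a read whose leading seeds bridge a
small deletion, confirming both the equality and the order dependence.
Reverse-orientation matches carry query coordinates on the
reverse-complemented read so query and reference coordinates increase
together within an orientation.

**Merged matches.** Matches are swept in ascending query order and joined
into merged matches when they overlap on both query and reference, lie on
the same reference and orientation, and order their four strobes
consistently (both staggered or both nested). Inconsistent orderings — a
signature of local repeats — start separate candidates. Each merged match
is scored $S_M = (\min\{a,b\} - |a-b|)\cdot n$ with $a$, $b$ the query and
reference spans and $n$ the number of constituent matches: only the
smaller span counts, span disagreement is penalised, and more supporting
seeds score higher.

**MAPQ.** From the top two candidate scores,
$\mathrm{MAPQ} = 40\,(1-S_2/S_1)\cdot\min\{1, n/10\}\cdot\ln S_1$, rounded
down and clamped to $[0, 60]$; a single candidate uses $S_2=0$, and
$S_1\le 0$ yields 0. The natural logarithm and the clamp follow the
mapping-quality convention of minimizer-based mappers.

**Rescue mode.** If more than 30% of a read's seed instances were masked,
seeds are re-admitted below a higher abundance threshold — `rescue_level`
times $A$ by default (the multiplicative reading; an absolute threshold is
available behind `absolute = TRUE`, since the method description admits
both readings) — and if fewer than 5 seeds qualify, a hard threshold of
1000 is used. A read with no matches after rescue is unmapped.

## Alignment

For each candidate, the read is projected through the merged match onto
the reference and a segment `[r_s - q_s - pad, r_e + (len - q_e) + pad)`
is extracted with `pad` = 20 bp to absorb indels. The projection uses the
query *start* on the left edge (the span-consistent form; the alternative
left coordinate `r_s - q_e` over-extends every segment by about a read
length and is treated as an erratum). Equal query/reference spans are
first checked by Hamming distance against the length-matched projection
(score +1/−4); if the distance exceeds 5% of the read length — equal spans
can hide compensating indels — a Smith-Waterman alignment is additionally
computed and the better result kept. Unequal spans go straight to
Smith-Waterman with match +1, mismatch −4, gap open 6 and gap extension 1,
where the opening penalty covers the first gap base. Unaligned read ends
become soft clips, CIGARs use `M` for both matches and mismatches, and NM
counts mismatches plus gap bases over the aligned region. Candidates are
extended in score order, at most 20 of them and none below half the best
score; a perfect (edit-0) alignment stops the search and an edit-1
alignment suppresses further base-level calls. Reported records carry NM
and AS tags; only primary alignments are emitted, and unmapped reads keep
their sequence.

**Paired-end mode.** Candidate pair placements are ranked by the joint
seed count $C_{ij} = n_i + n_j$ for combinations that are *proper* —
same reference, FR orientation, template shorter than $\mu + 10\sigma$ —
with individually placed candidates ranked by their own counts. After
extension a proper pair scores
$S_{ij} = SW_i + SW_j + \ln N(d_{ij};\mu,\sigma)$, the log normal density
of the observed template length; individually placed mates score
$SW_i + SW_j - 10$, the penalty corresponding to a template more than four
standard deviations out. Scores are tracked per distinct final placement:
seed-level fragments of one locus, or the individually scored copy of the
winning placement, would otherwise impersonate a second-best candidate and
destroy the MAPQ of uniquely placed pairs. The joint MAPQ is computed from
the top two placement scores and assigned to both mates. A mate without
any merged match is rescued by Smith-Waterman against the window up to
$\mu + 5\sigma$ bases from its placed partner in the expected orientation,
accepted when the score reaches half the read length — the acceptance
floor is this package's choice, set so that a rescue must explain at least
half the mate under the +1/−4 scheme.

**Insert-size model.** $\mu$ and $\sigma$ are estimated from the first 500
pairs in which both mates have a unique best merged match on the same
reference in FR orientation; template lengths are measured by projecting
full read extents through the merged matches, observations outside the
median ± 10 MAD are discarded, and the model is frozen thereafter. The
estimation scheme (500 pairs, MAD screen, moment estimates, fallback to
$\mu=300$, $\sigma=100$ with a warning when fewer than 100 concordant
pairs exist, $\sigma$ floored at 1) is this package's design; the pairing
model itself only presumes some frozen $(\mu,\sigma)$.

## Seed-repetitiveness statistics

For counts $x_1,\dots,x_M$ over $N$ seed instances, E-hits is
$\frac1N\sum_i x_i^2$ — the expected number of reference hits of a seed
drawn uniformly from the seed multiset, and, for uniformly sampled reads,
of an error-free read seed. It is 1 exactly when all seeds are unique,
scales linearly under genome duplication, and depends only on the count
multiset. `census_of()` computes comparable censuses for k-mers,
minimizers, syncmers and randstrobes under canonical hashing, reporting
the median seed span for the variable-length randstrobes. The hard-masked
fraction is the fraction of seed *instances* whose hash occurs more than
1000 times; instance weighting matches the E-hits sampling model (the
distinct-hash weighting is the other defensible reading — output headers
of `seedstats` note the choice). Only the expectation itself is
implemented; related summaries (expected hit rate with an $N^2$
denominator, E-size analogues) are not.

## Synthetic data: what it emulates and what it does not

The generator provides: i.i.d. uniform random genomes; a repeat genome of
$n$ copies of one unit independently mutated at a chosen per-base rate
(copies share about $(1-d)^2$ pairwise identity — a desk-scale analogue of
a 500 × 100 kbp, 90%-similar repeat genome); mutated haplotypes with SNPs
(never identity substitutions) and geometric-length indels
(`rgeom(0.5)+1`, mean 2) plus an exact block liftover back to reference
coordinates; and uniform read sampling, single or paired, with
normal-truncated template lengths and uniform substitution errors at
Phred+33 constant quality. Four divergence presets span the designs used
throughout the tests: `sim1` (0.01% SNP / 0.001% indel) through `sim4`
(1% / 0.1%), with `sim3` (0.1% / 0.01%) as the human-population-like
default; the preset rates and the 0.1% sequencing error default are this
package's declared stand-ins for simulation details that are not part of
the method. Everything is bit-reproducible from the seed.

What passing these tests shows: the seeding, indexing, candidate
selection, scoring and pairing machinery recover uniformly sampled reads
from genomes with realistic SNP/indel divergence, at the correct loci and
with calibrated MAPQ, on one CPU at desk scale. What they do not show:
performance on real Illumina error profiles (quality-dependent,
non-uniform errors), GC or coverage bias, structural variation,
chromosome-scale repeat families, or genome sizes where the abundance
cutoff $A$ rises far above its floor — on these synthetic genomes $A$ is
almost always 2, so masking and rescue are exercised through constructed
repeat fixtures rather than emerging organically.

**Accuracy metric.** A read counts as aligned when its record lacks SAM
flag 4 and as correct when placed on the truth reference with at least 1 bp
overlap of the truth interval (configurable via `min_overlap`); the exact
overlap rule is declared rather than inherited, since correctness rules
differ across published evaluations.

## Problem sizes and numerical choices

The shipped tests run on 20–100 kb genomes with hundreds of reads per
scenario; the end-to-end acceptance run uses a 1 Mbp genome with 2,000
simulated 150 nt pairs at the `sim3` preset, and the density checks use a
1 Mbp sequence, sizes at which every check completes in seconds to a
couple of minutes on one CPU while estimating densities to within ±0.005.
Deterministic tie-breaks are used throughout — candidate ordering by
(score, reference id, position), leftmost winners in argmin scans, first
eligible merged match on joins — so identical inputs give byte-identical
SAM, which the suite asserts. There is no stochastic tie-breaking anywhere
and the only RNG in the package lives in the simulator, always behind an
explicit seed.

## Known limitations

- Reference seeding is forward-only, so the index of a genome and of its
  reverse complement differ in a small fraction of seed hashes (see
  above); reads are unaffected since they seed both orientations.
- Execution is serial; `--threads` is accepted for interface compatibility
  only.
- MAPQ calibration beyond the formula (e.g. against empirical error rates)
  is out of scope, as are base-quality-aware scoring, secondary and
  supplementary alignments, and BAM/CRAM output (pipe through samtools).
- The aligner targets reads of roughly 100 nt and longer; profiles exist
  down to 50 nt but short reads yield few strobemers and correspondingly
  weaker candidates.
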