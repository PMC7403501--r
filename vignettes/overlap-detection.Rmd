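---
title: "Detecting overlaps among noisy long reads from the k-mer spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting overlaps among noisy long reads from the k-mer spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koverlap)
```

## The problem

Third-generation sequencing (PacBio SMRT, Oxford Nanopore) produces reads of
roughly 5--100 kb with per-base error rates of 10--20%, dominated by random
insertions and deletions. Overlap--layout--consensus assembly of such reads
begins by deciding, for every pair of reads, whether they were sampled from
overlapping positions of the genome, and if so which interval of each read is
shared. Two things make this hard: sequencing errors destroy most exact seed
matches, and genomic repeats create seed matches between reads that do not
overlap at all.

`koverlap` detects overlaps with exact k-mer seeds filtered by the
*dataset-wide k-mer frequency spectrum*, followed by collinear chaining with
a two-stage consistency test and a geometric revision/acceptance step. Input
is FASTA/FASTQ; output is 12-column PAF.

## The model

### Solid k-mers

Let $F(x)$ be the number of distinct (canonical) k-mers whose frequency in
the whole read set is exactly $x$, and $h$ the largest observed frequency.
A k-mer seen once cannot witness an overlap (it occurs in a single read), and
with high error rates frequency-1 k-mers are overwhelmingly error artifacts,
so the lower solid bound is $f_{\min} = 2$. Very frequent k-mers are
repeat-derived; the upper bound $f_{\max}$ is the smallest $f$ with

$$S(f) = \sum_{x=f_{\min}}^{f} F(x) \;>\; \theta \cdot S(h),$$

i.e. the frequency below which a fraction $\theta$ (default 0.9) of the
usable k-mer mass lies. Only k-mers with frequency in
$[f_{\min}, f_{\max}]$ are indexed, as postings
(read, 0-based start, orientation) under their canonical form. Counting is
canonical (a k-mer and its reverse complement are one key) so that reads
sequenced from opposite strands still share seeds; this is the convention of
every k-mer counting tool in this space, and opposite-orientation anchors
would be meaningless without it.

Note a perhaps counter-intuitive fact: raising $f_{\min}$ cannot lower
$f_{\max}$ -- dropping $F(f_{\min})$ from both the cumulative sum and the
total moves the $\theta$-crossing right. The package implements the literal
interval filter and documents this direction (the property suite asserts it).

### Anchors and the strand vote

For a read pair $(R_1, R_2)$, k-mers are sampled from $R_1$ every $s$
positions (default every position) and matched through the index against
their occurrences in $R_2$. Each match is an anchor, a four-tuple
$(P_1, O_1, P_2, O_2)$ of start positions and orientations. A k-mer value
matching at more than one position in either read is a within-pair repeat and
all its anchors are removed (symmetric reading: a repeat on either side
creates the positional contradiction). Anchors whose orientations agree are
*positive*, the others *opposite*; with $M$ positive and $N$ opposite
anchors, the pair is kept on the forward strand when $M > N$ and
$M > \textit{count}$, on the reverse strand when $N > M$ and
$N > \textit{count}$, and discarded otherwise. Ties $M = N$ fall through to
"no overlap" -- neither strict condition fires, and a pair whose anchors
split evenly between strands is not credible evidence. Repeat removal runs
before the vote, matching the pipeline order in which the anchor set is
constructed and then filtered.

### Two-stage chaining

A candidate overlap is a chain of anchors, consecutive in $P_1$ order, each
consecutive pair *consistent*. With $D_1 = |P_{1j} - P_{1i}|$ and
$D_2 = |P_{2j} - P_{2i}|$, stage 1 requires:

* C1/C2 (ordering): $P_2$ strictly advances in the direction dictated by the
  strand;
* C3 (proximity): $D_1 < \alpha$ and $D_2 < \alpha$;
* C4 (collinearity): $(\max(D_1,D_2) - \min(D_1,D_2)) / \max(D_1,D_2) < \gamma$.

When stage 1 fails but both distances are below a larger bound $\beta$, the
pair may still be consistent -- the gap may simply contain too many errors
for any full-length k-mer to survive. Stage 2 extracts the two inter-anchor
gap sequences (start-to-start distances, gap from anchor start $+k$ to the
next anchor start; the $R_2$ gap is reverse-complemented into the forward
frame for reverse-strand pairs), collects shared small $k_s$-mers that are
unique within both gaps, links two of them when they satisfy C3/C4, and
declares the anchors consistent when a monotone path of linked $k_s$-mers
leads from one anchor to the other. The anchor endpoints join the path graph
as virtual nodes under the same edge test; monotonicity of the path in both
gap coordinates is enforced (it is what C1/C2 imply at the $k_s$ scale).
Requiring gap-uniqueness of the $k_s$-mers mirrors the anchor-level repeat
filter: tandem content inside a gap would otherwise fabricate paths. No
dataset-wide frequency filter applies at the $k_s$ scale -- the gaps are at
most $\beta$ long and frequency is meaningless there.

Chaining itself is greedy: starting from a chosen anchor, scan the remaining
anchors in $P_1$ order and append the first one consistent with the current
tail. The start anchor is a genuinely open choice; `koverlap` runs the greedy
pass from *every* start and keeps the largest chain (first found wins ties).
Because the greedy extension depends only on the current tail, a start inside
an earlier chain reproduces a strict suffix of it, so such starts are skipped
-- an exact optimization, not an approximation. Chains need more than 2
anchors to proceed: one or two collinear matches arise too easily by chance.

### Revision and acceptance

The chain spans draft intervals $[P_1, P_n + k]$ and $[Q_1, Q_n + k]$ (first
and last anchor starts, 1-based; for reverse-strand chains $Q$ is taken in
the reverse-complement frame of $R_2$ so it increases with $P$). Sequencing
errors pull chain ends inside the true overlap, so the draft is extended to
the read boundaries: on the left, the read with the earlier anchor start is
entered at position 1 and the other at the start difference; on the right,
the read with less sequence after its last anchor is exited at its end and
the remainder projected onto the other. The four combinations cover dovetail
and containment geometries. Exact equality $P_1 = Q_1$ (not covered by the
four strict cases) folds into the clamped-to-1 branch.

The revised overlap $[SP_1, EP_1] \times [SP_2, EP_2]$ is accepted iff

1. the chain covers it to within $\alpha$ on both reads:
   $(EP - SP) - (\text{last} + k - \text{first}) < \alpha$ (the same
   $\alpha$ as chaining -- both bound how much unanchored sequence is
   tolerated);
2. the shorter overlap length exceeds $\varepsilon$;
3. the two per-read lengths are balanced:
   $(\text{MaxLen} - \text{MinLen})/\text{MaxLen} < \gamma$.

Reverse-strand coordinates are mapped back to the original $R_2$ strand for
output, with the PAF strand column set to `-` (PAF convention: coordinates
always on the original sequence).

## Parameters

| name | default | unit | role |
|------|---------|------|------|
| `k` | 15 | bases | seed length; larger = repeat-robust, fewer seeds |
| `ks` | 9 | bases | small seed for the stage-2 gap rescue |
| `s` | 1 | bases | seed sampling step on the first read |
| `f_min` | 2 | count | lower solid frequency bound |
| `theta` | 0.9 | fraction | cumulative-mass quantile defining `f_max` |
| `alpha` | 400 | bases | stage-1 anchor distance bound; also condition 1 |
| `beta` | 1500 | bases | stage-2 rescue distance bound |
| `gamma` | 0.3 | ratio | collinearity and length-balance bound |
| `epsilon` | 500 | bases | minimum accepted overlap length |
| `count` | 5 | count | strand-vote threshold (strict) |
| `min_read_len` | 2000 | bases | read length cutoff at load time |

Lowering `alpha`/`beta`/`gamma` tightens the geometry and suits low-error
data; `epsilon` trades sensitivity to short overlaps against false joins.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; the revision formulas run in
  the 1-based inclusive convention in which they are stated, and PAF output
  converts back to 0-based half-open. Conversions happen only at module
  boundaries.
* k-mers are packed 2 bits/base into doubles (exact below $2^{53}$, so
  $k \le 26$); windows covering an `N` are skipped; any character beyond
  A/C/G/T/N is rejected as a parse error.
* Palindromic k-mers (possible only for even k) count as forward-oriented;
  with the odd defaults the case cannot arise.
* A spectrum with no k-mer at frequency $\ge f_{\min}$ is "degenerate":
  `derive_fmax()` raises an error, but the end-to-end driver treats it as
  "no solid seeds, hence no overlaps" and returns an empty result -- two
  unrelated reads must not crash the pipeline.
* Anchors tied on $P_1$ are ordered by $P_2$ ascending for determinism; the
  strict ordering conditions make such ties unchainable pairs anyway.
* A repeated identical anchor ($D_1 = D_2 = 0$) fails the strict ordering
  before the C4 division; the ratio is evaluated in product form
  ($\max - \min < \gamma \max$) so no 0/0 is ever computed.
* Detection uses no random numbers: results are byte-identical across runs.

## What the simulator emulates -- and what it does not

`simulate_reads()` draws a uniform-random genome, samples read positions
uniformly and strands by a coin flip, and applies independent per-base
errors (default total 15%, split 20% substitution / 50% insertion /
30% deletion, an SMRT-like, insertion-heavy profile). Read lengths are
normal (mean 7 kb, sd 1.5 kb, matching published long-read dataset
averages), truncated below at 2.5 kb so simulated sets survive the default
load-time cutoff. The ground truth records every read pair whose genome
intervals intersect, with the shared interval projected into each read's
*error-free* coordinate frame; indel drift between that frame and the
errored read is absorbed by the scoring criterion (a detected pair matches a
truth pair when ids and strand agree and the intervals intersect reciprocally
by at least 50% of the shorter on both reads -- the matching rule is a
package decision, configurable via `min_frac`).

The simulator does **not** model homopolymer-biased errors, chimeric reads,
adapter artifacts, non-uniform coverage, or genomic repeat structure (the
genome is random, so almost no k-mer repeats at 200 kb scale). A green
end-to-end test therefore establishes that the pipeline recovers overlaps
under heavy random indel noise -- it says nothing about repeat resolution on
real genomes, which is exactly the regime the $f_{\max}$ filter is designed
for but the random-genome world cannot exercise. Error-free simulation is a
stress case in the opposite direction: k-mer frequencies concentrate at the
coverage depth, so the fixed $\theta$ cut can discard seeds in the deepest
regions; with realistic error rates the frequency spectrum spreads out and
the filter behaves as intended.

## Known limitations

* One chain per pair: chimeric reads and split overlaps are out of scope.
* Greedy chaining is not score-optimal (no dynamic programming); the
  multi-start policy recovers from a bad first anchor but not from an
  adversarial interleaving of two equally long chains.
* All-pairs detection is in-memory and single-threaded; the design target is
  desk-scale experiments, not production assembly runs.
* The residue-match PAF column is a proxy (chain support $\times k$), not an
  alignment statistic.
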