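---
title: "Methods: editing-outcome and AAV-integration analysis in crispaav"
author: "crispaav maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: editing-outcome and AAV-integration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions
behind `crispaav`: what each stage computes, which parameters matter,
what the simulator does and does not emulate, and where the numerical
edge cases live.

## Coordinates and references

All coordinates are 0-based and half-open. Cut and nick sites are
*between-base* integers in `[0, len]`: a nick at `p` falls between
bases `p-1` and `p`, so deleting `[p1, p2)` removes exactly the
inter-nick segment and no ±1 bookkeeping is ever needed. References
are curated and may not contain `N`; reads may (an `N` never counts as
a match anywhere in the package).

A guide's nick position is derived from its protospacer placement:
`nick_offset` bases from the PAM-proximal protospacer end, measured
into the protospacer on the protospacer strand. The default offset is
3 nt (the conventional Cas9 scissile position 3 nt 5′ of the PAM).
This is a *parameter*, not an assertion — different enzymes and
annotation conventions place the expected cut differently, so the
offset is configurable per guide and recorded in the output.

Pair orientation is always derived from the strands and PAM placements
(PAM-out, PAM-in, or tandem), never taken on trust from the input
file. The inter-nick distance is the absolute difference of the two
nick positions; for the package's default synthetic design it is 64 bp
in PAM-out orientation, which for a paired D10A nickase predicts 5′
overhangs spanning the inter-nick interval and a "perfect" deletion of
the same length.

## Alignment model

Amplicon-only reads are aligned with an affine-gap aligner under
`score = 5·matches − 4·mismatches − Σ_gaps (25 + length)`. The gap
cost convention is `cost(k) = gap_open + k · gap_extend` — conventions
differ between tools, so this is stated explicitly and the independent
cross-check in the test suite uses an implementation with the same
convention. The heavy gap-open keeps sequencing noise from fragmenting
real indels; the mild extension keeps long (inter-nick sized, or
vector-sized) indels affordable.

The alignment is *glocal*: global in the read, local in the reference,
because reads are subfragments of the amplicon. Tie-breaking is
deterministic (diagonal over deletion over insertion, smallest
reference coordinate on equal end scores), and every indel is then
left-aligned to its minimal reference start among sequence-equivalent
placements. Left-normalization makes variant keys stable: all
equivalent placements of the same indel collapse onto one signature.
Normalization only shifts indels through matching columns, so
alignments around substitutions are preserved, and it is idempotent.

Two provably-safe fast paths bypass the dynamic program: exact
substring reads, and ungapped placements with at most two mismatches
(a gap costs at least 26 while converting a mismatch into a match
regains only 9 per base, so for ≤ 2 mismatches the ungapped placement
is optimal).

## Read classification

Classification is two-pass, amplicon first and vector second, matching
how such data are filtered in practice (map to the genome, remove
unmapped pairs, then map the remainder to the vector). At amplicon
scale the genome-filtering step reduces to an amplicon-anchor
requirement; we note, without asserting equivalence, that a
genome-wide filter could additionally remove reads matching other
loci.

A read is **locus-anchored** if its glocal alignment contains a
gapless block of at least `anchor_min = 25` nt at ≥ 90% identity.
Candidate vector segments of an anchored read are (i) insertion ops of
length ≥ `vector_min_len = 15` and (ii) terminal segments outside the
outermost clean match runs. The terminal rule matters: an internal
foreign fragment must surface as an insertion op (smearing it against
the reference would cost more than the gap), but a fragment at a read
end can be absorbed against the free reference overhang as scattered
mismatches — walking in from each read end to the first ≥ 15 nt clean
match run recovers such segments, and the stored amplicon alignment of
a terminal-chimeric read is truncated at the junction so the smeared
tail cannot leak into coverage profiles.

Candidate segments are prescreened against a 12-mer index of the
vector (both strands) and, on a seed hit, aligned locally to the
vector in both orientations. A hit qualifies at ≥ 15 aligned nt and
≥ 90% identity; with these defaults the probability of a spurious
qualifying hit per read against a kb-scale vector is negligible, which
is why the thresholds default where they do (all are configurable).
The decision rule is then: anchored + qualifying hit → `chimeric`;
anchored only → `amplicon_only`; hit only → `vector_only`; neither →
`unaligned`. Every read receives exactly one class, so class counts
always sum to the input — a conservation property the test suite
checks on every fixture.

## Palindromic ITRs and ambiguity

AAV ITRs are palindromes, and the 3′ ITR is the reverse complement of
the 5′ ITR. Consequently a vector hit can match two locations (or two
orientations) with *exactly* equal score; such hits are assigned to
the best-scoring location under a deterministic preference (forward
orientation, then smallest vector start), flagged `ambiguous`, and
contribute half weight at each tied location in vector coverage — two
identical ambiguous events on the two ITRs therefore reconstruct full
weight at both. Ambiguity is detected by masking the primary interval
and realigning; an equal masked score means a genuine alternative
location.

## Integration events and breakpoint statistics

One chimeric read is one integration event — the unit matching a
"% of reads" integration frequency. Events carry the amplicon
breakpoints flanking the vector segment (single-sided when the segment
sits at a read end, since short reads truncate long insertions), the
vector interval and orientation, and the ITR arms overlapped. A
vector-side breakpoint is an interval endpoint that is not a vector
terminus; it scores an arm-boundary hit when it falls within
`boundary_tol = 3` bp of an annotated A′–A or B′–B junction. The
tolerance reflects junction microtrimming: the biological signal is a
regional preference at the arm boundary, not a base-exact site.
Coverage is read-weighted (each event adds its weight along its vector
interval); whether one should count fragments instead is not
determinable from short reads, so the definition is fixed and
documented.

A junction subtlety: when the terminal base of an inserted fragment
equals the amplicon base immediately left of the insertion point,
left-normalization rotates the insertion and the resolved vector
interval shortens by the junction-microhomology length `r`
(`P(r ≥ 1) = 1/4` per event for random sequence). This is genuine
placement ambiguity, not an error; truth-recovery tests assert exact
interval equality when `r = 0` and equality up to `r` otherwise, and
the ±3 bp boundary tolerance absorbs it in breakpoint statistics.

## Variant aggregation and the two denominators

A read is *edited* iff at least one indel op overlaps the
quantification window; substitutions never count. The window defaults
to `[min(cut) − 5, max(cut) + 5)` — wide enough for both nicks plus
end-joining jitter — and is configurable and recorded in the output,
since no standard width exists. Reads whose only indels fall outside
the window are counted unedited but flagged. Chimeric reads are added
to the variant table as `vector_insertion` records and counted as
edited, which yields the two headline denominators:
`integration_frequency_reads` (chimeric / all locus reads) and
`integration_frequency_indels` (chimeric / edited reads); their ratio
identity with `indel_frequency` is asserted in tests. No minimum
per-variant support is imposed — paired-nickase outcomes are too
heterogeneous for frequency floors, which discard exactly the signal
of interest — so every variant is reported with its count.

The per-position deletion profile divides, at each amplicon position,
the number of reads whose alignment deletes that position by the
number of reads covering it; zero-coverage positions are emitted as
missing rather than zero.

## Microhomology

The microhomology length of a left-aligned deletion `[s, e)` is the
largest `m` with `ref[s : s+m] == ref[e : e+m]` — equivalently the
number of equivalent placements minus one, which is how the
independent test oracle computes it. It is evaluated on the reference
only, after normalization, so it is a property of the deletion itself
and robust to read errors; insertions are excluded (locus-templated
insertions are handled by origin classification instead, which matches
an insertion against the inter-nick region, then the vector, with
exact matching required under 10 bp and ≥ 90% identity above). The
headline "MH > 2 bp" fraction uses a strictly-greater threshold,
support-weighted over pure-deletion variants; complex variants are
excluded from MH scoring but decomposed into their component ops for
size histograms.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` draws class counts multinomially from a
configured mix over seven read classes and builds each read by
applying class-specific ops to the amplicon. Defaults describe a
paired-nickase experiment: 60% edited reads of heterogeneous type
(small nick-site indels, the perfect inter-nick deletion, MMEJ
deletions, locus-templated insertions, complex events), 10% of reads
carrying a vector insertion, substitution error at 0.001/base,
breakpoint bias 0.8 at the A′–A arm boundary. MMEJ deletions are
generated only at reference positions where the requested flanking
microhomology genuinely exists; the synthetic locus plants two such
sites inside the inter-nick region (a 23 bp deletion with a 4 bp MH
and a 10 bp deletion with a 5 bp MH, the recurrent signature of such
designs) and the builder verifies them with `scan_mh` after
construction. Truth ops are emitted in canonical form (deletions
left-aligned, insertions rotated leftmost) so truth coordinates
coincide with the pipeline's normalized keys; vector-op intervals are
left physical. Every read's truth record reproduces the emitted read
exactly when ops and recorded errors are re-applied.

Deliberate simplifications: substitution-only error (amplicon
platforms are substitution-dominated, and indel errors would blur the
truth labels; an indel-error mode exists but is off by default);
a single contiguous vector fragment per chimeric read (short-read
junction resolution cannot see concatemers anyway); constant base
qualities (trimming is exercised by dedicated low-quality fixtures);
forward-only fragment insertion by default, because the palindromic
ITRs make orientation non-identifiable and forward insertion keeps
truth comparisons exact — reverse-complement insertion is a flag.
Consequently, passing tests demonstrate correct resolution of the
modelled event spectrum, not robustness to PCR chimeras, platform
error profiles, or full-length insert structure.

## Problem sizes and determinism

The test suite runs the pipeline on bundles of 300–2,000 reads and one
10,000-read recovery bundle; the acceptance script uses 10,000
(nickase) and 4,000 (nuclease) reads — sizes at which binomial
3-standard-deviation bands on the recovered fractions are a few tenths
of a percent to a percent, tight enough to be informative while
keeping a full run in minutes on one core. Everything downstream of
the simulator is deterministic; the run seed is recorded, and the full
configuration is serialized verbatim into the summary JSON so any
output bundle is reproducible from its own provenance. Stage-boundary
read counts are logged so the conservation invariants can be audited
from the log alone.

## Known limitations

- Junction-rotation ambiguity (above) can shorten resolved vector
  intervals by a few bases; statistics that depend on exact junctions
  use the boundary tolerance.
- Off-amplicon integration and genome-wide off-target discovery are
  out of scope; off-target support is limited to identity scoring of
  candidate sites against a guide with IUPAC-degenerate PAM matching.
- Group comparison stops at descriptive means ± SD; inferential
  statistics are left to general-purpose tools.
- Pair merging is overlap-based with a fixed 10% mismatch allowance;
  non-overlapping pairs are dropped and counted rather than analysed
  as split reads.
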