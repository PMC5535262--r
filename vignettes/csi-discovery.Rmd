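---
title: "Discovering conserved signature indels with csiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved signature indels with csiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conserved signature indels (CSIs) are insertions or deletions in a protein
family that are shared by all members of a taxonomic clade and absent from
taxa outside it. Because an indel of a fixed length at a fixed position is
an essentially irreversible, vertically inherited event, a CSI flanked by
conserved sequence is strong evidence of common descent and a practical
molecular marker for the clade — for example, indels in the large subunits
of the class Ib and class III ribonucleotide reductases that distinguish
the order *Bifidobacteriales* (probiotic bifidobacteria and relatives)
from all other bacteria, ranging from single residues up to a 43–44 aa
insertion.

`csiscan` implements that discovery procedure as a reusable pipeline.
Given (i) a pre-aligned protein FASTA, (ii) a partition of the sequence
ids into an in-group (the clade of interest) and an out-group (the
reference taxa), and (iii) a scan configuration, it reports every indel
region that discriminates the two groups, survives a flanking-conservation
filter, and is classified as either exclusive to the in-group or shared
with an enumerated list of out-group exceptions.

```{r, eval = FALSE}
library(csiscan)

aln <- read_alignment("nrdd.fasta")
part <- read_partition("partition.tsv", aln)
calls <- scan_csi(aln, part)
tidy(calls)
glance(calls)
```

## The scanning model

**Coordinates.** Alignment columns are 1-based and spans are inclusive on
both ends, throughout the package and in every report. (Half-open 0-based
coordinates are common in genomics toolchains, but a single convention
that matches both R indexing and the human-readable reports removes a
whole class of off-by-one errors.) Positions *on a sequence* are 1-based
ungapped residue counts; a call is anchored at the reference residue
immediately preceding its span ([ungapped_index()]).

**Conservation.** A column is *conserved* when its majority amino acid is
carried by at least `conservation_fraction` (default 0.8) of all partition
rows. Gaps and the unknown residue `X` stay in the denominator and never
match, so a column that is mostly gap can never be conserved. The
published criterion never quantifies "conserved"; the figures of
signature alignments show near-identity flanks, so 0.8 is a deliberately
permissive default and 1.0 recovers strict identity. Ties between equally
frequent residues break alphabetically, making the profile deterministic.

**Candidate detection.** A column is an *insert-candidate* column when at
least `outgroup_absence_fraction` (default 1.0) of out-group rows are
gapped there and at least one in-group row carries a residue; a
*deletion-candidate* column is the exact mirror image, which is what makes
the scan symmetric: relabelling the groups maps every insert onto a
deletion with the identical span. Maximal runs of same-type candidate
columns (optionally bridging up to `merge_gap_cols` interrupting columns)
become candidate regions, and a region is kept only when at least
`ingroup_presence_fraction` (default 1.0) of the carrier group's rows
hold at least one residue anywhere in it. Applying the presence test to
the *region* rather than to each column is a deliberate design choice:
real CSIs can be length-variable (some in-group homologs carry 43
residues, others 44), so the final block column is necessarily absent from
some carriers, and a per-column presence test at fraction 1.0 would
truncate the span and split the reported length. The region-level test
keeps such indels whole — they are reported with a min–max length range
over carrier rows ("43 or 44 aa insertion") — while still rejecting
insertions private to a few rows.

**Flank filter.** From each side of a candidate, the scanner walks outward
column by column until it has passed `flank_window_aa` (default 40)
residues *of the reference sequence* — the neighborhood is measured in
amino acids of a real sequence, not in raw alignment columns, because
that is how the criterion is stated in practice; 30 is the other
conventional window. Within each side's walked window, at least
`min_flank_conserved` (default 5) conserved columns are required, the
bound being inclusive. Candidates failing on either side are recorded
(and logged by the pipeline) but never emitted as calls: an indel in a
poorly aligned region cannot be positioned reliably. Conservation in the
flanks is assessed over *both* groups jointly — the most conservative
reading, since a flank conserved in only one group is weaker evidence —
and the window applies per side, matching "flanked on both sides".

**Specificity.** An insert is `exclusive` when every out-group row is
fully gapped over the span; any out-group row carrying a residue there is
an *exception*, and the call becomes `shared_with_exceptions` with the
exceptions enumerated — never silently passed. Deletions mirror this
(out-group rows that are also gapped share the deletion). This replaces a
database-wide homology search for confirming specificity: the scan can
only vouch for the out-group rows actually supplied, so widening the
out-group is the user's responsibility.

**Length reporting.** `length_min`/`length_max` give the indel length
over the rows that *carry* it: in-group rows for an insert, out-group
rows for a deletion (a "1 aa deletion" is one residue of out-group
material missing from the in-group; the in-group rows themselves contain
0 residues there, which would be a vacuous length).

## What cannot happen, and ties

With the default fractions (1.0) a column cannot satisfy both the insert
and the deletion predicate; for relaxed fractions summing above 1 this
remains impossible, and below that the two candidate sets are simply
computed independently. Overlapping candidates of one type cannot arise
because runs are maximal. Raising `min_flank_conserved` or
`conservation_fraction` can only remove calls (both are property-tested);
note that *lowering* `outgroup_absence_fraction` grows the set of
candidate columns monotonically but can **merge** two adjacent regions
into one, so the call *count* is not monotone in that parameter — the
candidate-column set is, and that is the invariant tested.

## The synthetic-alignment generator

No machine-readable accession list ships with the motivating study, so
the package carries a first-class, seeded generator
([synthetic_spec()], [simulate_msa()]) emulating the statistical
structure of those alignments:

* a uniform-random ancestor of `core_length_aa` (default 600 aa, the
  scale of the ribonucleotide-reductase large subunits), copied to
  `n_ingroup` = 12 and `n_outgroup` = 10 rows — the homolog counts used
  per group in the study's signature alignments;
* i.i.d. per-site substitutions per row at `substitution_rate` (default
  0.05, a modest divergence consistent with well-alignable flanks across
  phyla), uniform over the 19 alternative residues;
* planted indels, by default spanning the study's spectrum — 1, 2 and
  4 aa inserts, 1 aa deletions, and a length-variable 43–44 aa insert —
  realized as in-group residue blocks (inserts; per-row length drawn
  uniformly from the range, left-aligned) or in-group gap blocks
  (deletions), with optional out-group *exception* rows sharing the
  full-length indel;
* `frozen_flank_aa` (default 10) residues on each side of every indel
  exempt from substitution, so flank conservation is guaranteed by
  construction and can then be degraded *controllably* with
  [degrade_flanks()] to any exact conserved-column count — the fixture
  family behind the flank-threshold tests.

Per-row length ranges apply to inserts only; deletions take a fixed
length (all deletions in the motivating spectrum are single residues, and
a per-row-variable deletion has no clean counterpart there).

The generator is deliberately simple where realism would not change what
is being tested: substitutions are i.i.d. uniform rather than drawn from
an empirical substitution matrix, there is no phylogeny-aware evolution,
no indel birth–death process, and insert content is random. The scanner
is a thresholded conservation test on gap patterns, so none of those
refinements would alter its decisions; what the passing recovery tests
demonstrate is that the *decision logic* is exact under the stated
conditions, not that the generator reproduces real evolutionary data.
On real alignments the binding issues are alignment quality and out-group
breadth, neither of which a simulation can certify.

[evaluate_recovery()] scores a scan against the generator's ground truth:
a call matches a planted indel only when span *and* type agree exactly;
precision is 1.0 by convention when there are no calls, recall 1.0 when
there is no truth.

## Rendering and exports

[render_signature()] reproduces the signature-figure convention: top
sequence verbatim, dash = identity with the top line, the indel block
highlighted, flanking context defaulting to the 40-residue scan window so
the evidence for the flank filter is visible. Because `-` is reserved for
identity, alignment gaps display as `␣` (configurable, e.g. to `.`);
overloading the dash would make the figure ambiguous, whereas this
rendering is information-preserving and [signature_reconstruct()]
inverts it exactly. Exports ([export_calls()], [run_pipeline()]) are
byte-deterministic: fixed column order, stable JSON, no timestamps in the
manifest, and no pipeline stage consumes randomness (only the simulator
does, through its explicit seed).

## Problem sizes and runtime

The bundled tests run the scanner against a brute-force oracle that
enumerates every column interval and tests the full predicate directly,
on 100 seeded alignments of up to 12 columns and 8 rows with randomized
thresholds, and score recovery on 100 seeded synthetic alignments at the
default scale (22 rows × ~650 columns, six planted indels each). Both
complete in well under a minute on a single core; the scan itself is a
few vectorized passes over the character matrix, so desk-scale alignments
(hundreds of rows, thousands of columns) pose no difficulty.

## Limitations

* Input must be pre-aligned; the package neither builds nor refines
  alignments, and misalignment around an indel will distort or hide it.
* Specificity is relative to the supplied out-group only; it is not a
  database search.
* No statistical significance is attached to a CSI — none is defined in
  the underlying methodology; the flank filter is the only evidence
  gate.
* Protein alignments only; no nucleotide support.
* Duplicate strains of one species are treated as independent rows.
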