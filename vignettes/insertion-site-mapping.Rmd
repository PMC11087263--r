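---
title: "Mapping piggyBac integration sites from splinkerette-PCR reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping piggyBac integration sites from splinkerette-PCR reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinmap)
```

## The biological signal

piggyBac is a cut-and-paste DNA transposon that integrates exclusively at
TTAA tetranucleotides and duplicates the target site on insertion, so in
the engineered genome the identical genomic TTAA abuts the transposon's
5' and 3' inverted terminal repeats (ITRs). Splinkerette PCR amplifies the
genomic sequence flanking each ITR: a hairpin adapter is ligated to
fragmented genomic DNA, a primary PCR pairs an ITR primer with an adapter
primer, and a nested PCR sharpens specificity. A sequencing read from this
library therefore has the structure

```
[nested ITR primer] [TTAA] [genomic flank ...]
```

and after primer trimming its genome-derived portion begins with the
duplicated TTAA. Reads from the two flanks of one insertion, aligned to the
reference, overlap in exactly that tetranucleotide. These two facts — the
terminal TTAA and the 4-bp shared overlap — are the whole basis of the
caller.

## The calling model

`spinmap` formalizes the site-calling procedure as three deterministic
steps over ungapped, uniquely aligned reads:

1. **Junction detection.** A side-tagged read is a junction read when the
   reference sequence under its 5'-terminus (the end that carried the
   primer) is `TTAA`. For a `+`-strand alignment that terminus is the
   interval start; for a `-`-strand alignment, the interval end. Both the
   read and the reference must agree on the motif; a read whose aligned
   sequence contains a TTAA at any *other* position is flagged
   `internal_ttaa`. Reads without a side tag cannot be assigned to a flank
   and are counted and dropped.
2. **Candidate assembly.** Junction reads are grouped by the genomic
   coordinate of their terminal TTAA: two reads support the same site if
   and only if their terminal TTAAs are the identical genomic
   tetranucleotide. Within a site, reads with identical
   `(start, end, strand)` are collapsed as PCR duplicates — splinkerette
   libraries are heavily amplified and fragment-end identity is the
   standard duplicate proxy in the absence of UMIs. A collapsed group
   counts as "clean" when *any* member lacks an internal TTAA: duplicates
   represent one molecule, and an internal TTAA introduced by a sequencing
   error is a read-level artifact.
3. **Two-stage validation.** A candidate becomes a validated insertion
   call when (a) deduplicated junction support is present on both flanks
   (`min_support` per flank, default 1 — the literal reading of "reads
   present on both sides"), and (b) the internal-TTAA rule holds.

### Interpreting "no TTAA in the middle of the read"

The filter that removes candidates whose supporting reads contain an
internal TTAA can be read three ways, and the package implements all three
behind `internal_ttaa_mode`:

* **`per-read`** (default): at least one clean supporting read per flank.
  In random sequence TTAA recurs about every 256 bp, so roughly a quarter
  of 70-bp genomic flanks contain a second TTAA by chance; demanding that
  *every* read be clean would discard many true sites, while demanding one
  clean read per flank keeps the filter's intent (the junction TTAA is the
  outermost TTAA of the fragment) without that penalty.
* **`all-reads`**: every supporting read on both flanks must be clean; the
  strictest reading.
* **`between-reads`**: no TTAA other than the site's own may occur in the
  genomic span between the flanks' innermost read termini. Because junction
  reads abut the duplicated TTAA by definition, that span *is* the site's
  TTAA, so in practice this mode reduces the filter to rule (a); it is the
  most permissive reading.

The choice matters for real libraries where fragment structure is messier
than the simulator's; the default is `per-read`.

Candidate sites failing rule (a) are reported with
`rejection_reason = "single_flank"`, those failing only rule (b) with
`"internal_ttaa"`, and all rejected candidates are persisted to a
reviewable `rejected.tsv` — the package's substitute for manual browser
inspection of candidate pileups, which is not reproducible and therefore
not implemented.

## The aligner

Junction logic depends on exact read termini, so the built-in aligner is
strictly end-to-end and ungapped: a read placement is scored by Hamming
distance over its full length, both strands are searched, and placements
with more than `max_mismatch` (default 2) substitutions are discarded. An
indel or clipped alignment would move the terminus that carries the TTAA,
so such records are also excluded when importing external SAM. Candidate
placements come from `max_mismatch + 1` disjoint 15-mer seeds: by
pigeonhole, any placement within the budget matches at least one seed
exactly, so the seeded search provably equals an exhaustive scan. Reads
shorter than `k × (max_mismatch + 1)` = 45 bp fall back to an explicit
exhaustive scan to preserve that guarantee. Reads with more than one
equally best placement are marked non-unique and never reach the caller —
dropping multimappers costs sensitivity in repeats but cannot create
phantom sites, which is the right trade-off for an insertion screen.

Coordinates are 0-based half-open everywhere internally and in BED output;
1-based coordinates appear only where an interchange format (SAM, GFF3)
requires them.

## The simulator: what it emulates, and what it does not

`generate_genome()` draws i.i.d. uniform A/C/G/T contigs, so TTAA occurs
at the Bernoulli rate 1/256 per position. `place_insertions()` chooses
ground-truth sites among TTAA occurrences that are at least
`2 × read_length` away from **every other TTAA occurrence** and
`insert_size + read_length` from contig ends. This isolation requirement is
deliberate: it makes each truth site unambiguous and its junction reads
clean by construction, so that exact-recovery tests measure caller
correctness rather than motif-collision handling. A `hard_mode` flag drops
the isolation requirement for stress testing. `simulate_reads()` emits, per
event and flank, `junction_depth` pairs: read 1 is the nested ITR primer
plus the TTAA-leading genomic flank (left-flank reads reverse-complemented
so both orientations are exercised), read 2 a purely genomic mate at a
fixed `insert_size`; background pairs are plain genomic fragments with no
primer and no junction, modelling genomic carry-over, the simplest
contaminant class the protocol admits.

Defaults state a realistic-but-benign sequencing world: 2×100 bp reads
(the real study's layout is unpublished; this is a choice, not a
reconstruction), fixed 300 bp insert, constant Q37 qualities, 1%
substitution error, 20% background. Substitutions are never placed inside
the terminal TTAA of read 1 unless `protect_junction = FALSE`: with
protection on, exact-recovery runs are deterministic; switching it off
tests robustness of the junction filter itself.

The simulator does **not** emulate: indels or instrument-specific quality
profiles; variable fragment sizes; chimeric or adapter-dimer artifacts;
local duplications or repeats around insertion sites; multiple insertions
closer than the spacing bound (except in `hard_mode`). A green truth-
recovery test therefore establishes that the pipeline's logic is correct on
well-separated insertions under moderate noise — not that it is robust to
every pathology of real libraries, and not that any particular real-data
candidate count will be reproduced. For the same reason, category counts
against a real annotation depend on the annotation release and are outside
what the tests claim.

## Annotation semantics

Sites are classified against per-transcript gene models from GFF3.
`five_prime_UTR`/`three_prime_UTR` features are used when present;
otherwise UTRs are derived as exon-minus-CDS, with the 5' side determined
by strand. Precedence when a 4-bp site interval overlaps several features
or transcripts is CDS-exon > 5'UTR > 3'UTR > intron > intergenic, with
≥ 1 shared base counting as overlap — a 4-bp interval straddling a boundary
takes the more consequential category, the only stable rule at this width.
"Exon" in reports means *coding* exon; UTR hits are reported separately.
Ties at equal precedence resolve to the lexicographically smallest gene
name so that results are invariant to GFF3 record order. A site inside a
non-coding transcript's exon classifies as intron under this precedence
(there is no CDS or UTR to hit); a dedicated ncRNA category was judged out
of scope.

## Numerical and degenerate-input choices

* Primer matching is anchored Hamming scanning (no indels), leftmost match,
  tolerance `ceil(0.1 × primer length)` mismatches; nested-PCR chemistry
  puts the primer at a fixed offset, and an indel-free search keeps
  downstream coordinates exact. A read matching both nested primers is
  ambiguous and discarded (counted).
* Reads shorter than 20 bp after trimming are discarded — below that,
  placements on a megabase-scale toy genome stop being reliably unique.
* Deterministic ordering everywhere: alignments sort by
  (contig, start, read id, mate), candidate sites by (contig, ttaa_start);
  reruns with one config and seed are byte-identical.
* Empty inputs: an empty read set or empty genome is an error at
  alignment; an empty GFF3 yields an empty model list with a warning; zero
  requested insertions yield an empty truth table.
* All randomness flows from explicit integer seeds (`withr::with_seed`),
  so no global RNG state leaks between stages.

## Limitations

Only the TTAA motif is supported end to end (TA-site transposons such as
Sleeping Beauty would need the duplicated motif parameterized through the
junction and validation stages). The caller does not estimate clonality or
abundance from read counts, and does not test common-insertion-site
enrichment across samples. The built-in aligner is for desk-scale genomes;
for real genomes, align externally in end-to-end mode and import the SAM.
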