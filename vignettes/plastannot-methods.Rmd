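---
title: "plastannot: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastannot: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `plastannot`,
the parameters that matter, what the synthetic fixture generator does and
does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The annotation model

A plastome is treated as a single circular contig over {A,C,G,T,N}. All
coordinates are 1-based inclusive on the forward strand; features on the
minus strand keep forward coordinates with `strand == "-"`, and features
crossing the origin carry `wraps_origin` and are split into two location
segments only at the writer layer (GFF3/GenBank/feature table) — a single
documented conversion point.

### Quadripartite layout

`detect_inverted_repeats()` finds the maximal pair of disjoint, exactly
reverse-complementary segments of at least `min_ir_len` (default 1000
bp), scanning the doubled sequence so an IR copy may wrap the origin.
The longer single-copy gap is labelled LSC. Exact matching is a stated
restriction: near-identical IRs with internal mismatches are not
detected, and IR-lacking plastomes return `NULL` with a warning rather
than an error. `N` never matches.

### Similarity search

The search engine is deliberately self-contained so the test suite needs
no external aligner binary. Exact k-mer seeds (11 nt, or 4 aa against
the six-frame translation) are clustered by diagonal, and each candidate
window is scored with an affine-gap local alignment
(`Biostrings::pairwiseAlignment`; match/mismatch +2/−3, gap open/extend
5/2 for DNA; BLOSUM62, 11/1 for protein). Significance uses a
Karlin–Altschul-style scaling, E = K·m·n·e^{−λS}, with the documented
constants λ = 0.625, K = 0.41 (DNA) and λ = 0.267, K = 0.041 (protein).
These constants are the standard published gapped values for the chosen
scoring schemes; the E-values are comparable to, but not numerically
identical with, any particular BLAST build.

### Chaining and refinement

HSPs of one gene are chained by weighted dynamic programming under
colinearity in query and target, one strand, target gaps at most
`max_intron` (default 2000 bp — the same bound used when curating
reference exon structures from RNA-seq), and query overlaps at most 50%
of the shorter HSP. Chains are extracted iteratively so genes present in
both inverted repeats yield one chain per copy.

Refinement projects the reference exon structure through each exon's own
alignment diagonal: exon lengths (hence splice phase) always follow the
reference. This is exact under substitution-only divergence, which is
what the fixture world models; divergence with indels would shift the
projection and is outside the tested envelope (a documented limitation —
on real data a chain with indel-bearing alignments still yields a model,
but boundary accuracy degrades to the alignment's accuracy). After
projection, a complete CDS must start at ATG — otherwise the nearest
in-frame ATG within ±90 bp is used — and end at the first in-frame stop
within +90 bp; failure sets the corresponding partial flag instead of
discarding the model. The ±90 bp window covers the start-ambiguity scale
seen in curated plastome sets (tens of codons). Internal stops never
discard a model; they attach a warning note.

### Anchored micro-exon detection

For *petB*, *petD* and *rpl16* the anchor is the 50 bp of 5′ UTR
immediately upstream of the start codon in each reference; for *rps12*
it is the 50 bp downstream of the stop codon. The query is the
concatenation anchor+exon (or exon+anchor on the 3′ side): concatenation
was chosen because the extraction rule — cut the exon from the hit
footprint by the reference exon length — presumes one contiguous hit.
The genome is scanned at E ≤ 1e-20; the hit footprint is first extended
to the full query extent (gapless projection) so that alignment trimming
at a mutated anchor end cannot shift the exon cut. Admissibility checks
are deliberate additions: a 5′ micro-exon must begin with ATG, a 3′ one
must end with a stop codon, and when a partner exon is supplied the
micro-exon must lie on the same strand, on the correct side in
transcription orientation, within `max_intron`. Equal-scoring hits break
ties toward the partner exon, then toward the smaller start coordinate,
making the search deterministic. With the constants above, the 1e-20
cutoff tolerates roughly 3 anchor mismatches at genome scale (34 kb) and
about 4 on kilobase-scale test genomes — which is why the suite's
robustness check (100 fixtures, 4% per-base anchor mutation, ≥95%
recovery) holds with margin rather than by luck.

### Trans-splicing assembly

*rps12* exons 1 and 2 are located by independent nucleotide searches
(all genomic copies retained; distinct loci are deduplicated at 50%
overlap of the projected full-length footprint). The micro last exon is
found per exon-2 copy with the 3′-anchored search constrained downstream
within `max_intron`. Each (exon 2, exon 3) cassette joins the single
exon 1 into one transcript, so two IRs give two transcripts sharing exon
1; a single IR or an IR-less genome gives one (the single-transcript
fallback is this package's choice; two-exon references assemble the same
way without the exon-3 step). Mixed-strand models are legal only for
trans-spliced genes. A missing exon 3 demotes the transcript to a 2-exon
partial with a warning, never an error.

### tRNA reconciliation

The predictors themselves are not reimplemented — covariance-model tRNA
prediction is a solved problem and out of scope. The module parses a
tRNAscan-SE v2 tabular file and an ARAGORN-style batch file (plus a
neutral TSV), then applies the rule: keep intron-less predictions from
the first scanner and intron-bearing predictions from the second; at a
shared locus (≥50% reciprocal overlap, this package's threshold) the
prediction matching its intron status wins. Intron-bearing predictions
from the first scanner with no counterpart are dropped with a warning
record — the rule never saves them, and silence would hide a locus.
Predicted names are validated by aligning each model against the
reference tRNAs; a best hit under a different normalized name produces a
warning row (`warnings.tsv`), mirroring the expert-inspection file the
pipeline is meant to feed. Note the ARAGORN intron token `i(start,len)`
is this package's documented dialect; files from other sources may need
the neutral TSV.

## Repeat discovery

The three finders share exact, test-oracle-checked definitions:

* **SSR** (unit 1–6 bp): every maximal perfect run of a primitive unit
  reaching its copy threshold — defaults 10/6/5/5/5/5 copies for units
  1–6, the MISA tradition — trimmed to whole copies, motif canonicalized
  to the minimal rotation. Runs within 100 bp share a `compound_id`.
* **Tandem** (unit > 6 bp): arrays of ≥2 (fractional) copies whose
  per-copy identity to the column-majority consensus is ≥0.9 and whose
  match score (+2 per match, −7 per mismatch) reaches 50 — TRF's default
  weights and minimum score. The score floor is essential: without it a
  random 34-kb genome is expected to contain about two exact adjacent
  7-mer duplicates, which would qualify under identity/copies alone.
  TRF's Bernoulli-model statistics are not reproduced. Candidate arrays
  ≥90% dominated by a ≤6-bp periodicity belong to the SSR finder and are
  suppressed here; overlapping explanations resolve smallest-unit-first.
* **Dispersed**: maximal-scoring diagonal segments (+1 match, −3
  mismatch, x-drop) with ends on matches, at most `max_mismatch`
  substitutions (default 3), length ≥ `min_len` (default 30), in forward
  or palindromic orientation, intervals non-overlapping, contained
  duplicates dropped. This concretization makes a planted exact pair
  come back at exactly its planted length, where "maximal under ≤k
  mismatches" would absorb flanking mismatches. Candidate diagonals come
  from shared exact 7-mers — a 30/3 segment always contains one, and for
  the default parameters always contains two within 30 bp (pigeonhole),
  which is used to discard isolated chance seeds. With `exclude_ir` the
  IRa/IRb pair itself (and anything wholly inside the IRs, i.e. the
  duplicated gene copies) is suppressed: the IR pair is the layout, not
  a dispersed repeat.

All three are verified against independent brute-force enumerators; the
equivalence fixtures are ~2 kb (and a ~700 bp window for the tandem
oracle) because the pure-R oracles are quadratic — the finders
themselves run at genome scale against planted truth elsewhere in the
suite.

## Diversity analyses

Mapping is out of scope; the module consumes SAM with true coordinates
(the simulator emits exactly that). Pileups are built with Rsamtools
(CIGAR-aware; MAPQ < 20, base quality < 20, unmapped/secondary/duplicate
reads excluded; deletions contribute no base count). The callers are
transparent threshold rules, replacing likelihood machinery whose
parameters the pipeline never specified:

* **SNPs**: an alternate allele needs ≥3 reads and ≥5% of the column;
  depth < 10 flags `low_depth`, ≥10 alternate reads on a single strand
  flag `strand_bias`. These defaults suit heteroplasmy screening, where
  sub-unit allele fractions are the signal, not diploid genotypes.
* **RNA editing**: only the C→U class is called — a site inside a CDS
  whose sense-strand base is C with sense-strand T reads (C→T on plus
  genes, G→A mirrored on minus genes), depth ≥ 10 and level ≥ 0.1, is
  annotated with its codon and amino-acid change from the model's frame.
  The detector cannot, by construction, report a site whose sense base
  is not C. U→C editing is excluded by design.
* **Prefilter**: a read passes at ≥0.9 identity over ≥50% of its length
  against any gene sequence, either strand; a pair passes if either
  mate does.

## The synthetic fixture world

`generate_plastome(seed)` builds a 34-kb quadripartite genome (LSC 18 kb,
IR 6 kb each, SSC 4 kb — a faithful architectural scale-down of a 120–170
kb plastome, sized so brute-force oracles stay fast): 12 CDS genes with
valid ORFs (two multi-exon, two overlapping on opposite strands), the
three micro-exon genes carrying the consensus first exons (6/8/9 bp)
behind fixed 50-bp anchors, *rps12* with exon 1 (114 bp) on the LSC minus
strand and the exon2(232)+exon3(26) cassette in both IRs behind a 3′
anchor, four rRNA and six tRNA loci (two intron-bearing, in the IR), four
SSRs, one 30-bp × 4 tandem array and two dispersed pairs. Filler sequence
is rejection-sampled to stay free of threshold-level SSRs so the planted
repeat roster is the complete truth; tandem copies carry three private
substitutions each so no copy pair doubles as a dispersed repeat.
Reference-vs-query divergence (substitutions only) can be switched on;
anchors, micro-exons and the IRs are never mutated — mutating the IRs
would break the exact inverted-repeat premise, and anchored-scan
robustness has its own dedicated mutation tests.

What a green test does **not** establish: tolerance to indel divergence,
assembly errors, realistic gene order/synteny, sequencing-error models
beyond uniform substitution, IR boundary shifts between reference and
query, or performance of the predictors whose outputs the tRNA module
consumes.

`simulate_reads()` emits uniform gapless reads (CIGAR `<len>M`) with
their true coordinates; `dna` mode injects planted heteroplasmic
variants at their fractions, `rna` mode samples exonic windows (exons
shorter than the read length are skipped — micro-exons are therefore
uncovered by simulated RNA reads) and injects C→U editing at planted
levels. Acceptance tests run the simulator at 60× because "100% recovery
of sites at twice the caller thresholds" is a statement about
expectation that only becomes deterministic when the binomial tail under
the threshold is negligible (< 1e-8 per site at 60×; at 30× it is about
1%, i.e. several expected misses over 20 seeds × 15 sites).

## Numerical and encoding choices

* Identity comparisons against the 0.9 tandem floor use a 1e-9 tolerance
  (27/30 is exactly 0.9 and must not fall under it by floating error).
* GFF3 encodes a trans-spliced gene as one `gene` with two `mRNA`
  children; the shared exon is a single `exon` feature with both
  transcript IDs in `Parent` (Apollo-compatible multi-parent).
* GenBank encodes each transcript as a CDS with a mixed
  `join(complement(...),...)` and `/exception="trans-splicing"`;
  origin-wrapping features split into two join segments at the origin.
* The submission output is the modern `.tbl`/`.fsa` pair (the Sequin
  tool this role descends from is retired); minus strand is encoded by
  descending interval coordinates, partial ends by `<`/`>`.
* IR-duplicated loci keep one gene name with a `copy` index assigned in
  ascending genomic start order (`rrn16`, `rrn16_2` in feature IDs).
* The circular map is plain SVG 1.1 text with fixed 2-decimal geometry,
  so identical inputs produce byte-identical files.

## Known limitations

Ab-initio prediction, pseudogene calling, indel-aware boundary
refinement, near-identical (mismatched) IR detection, repeat-based
marker design, genotype likelihoods and indel calling are all out of
scope. The ARAGORN dialect caveat above applies. The package annotates
one circular contig at a time.
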