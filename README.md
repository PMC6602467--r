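# plastannot

Reference-guided annotation and analysis of plastid genomes in R.

Plastomes (chloroplast genomes) are circular DNAs of typically 120–170 kb
with a quadripartite architecture: a large and a small single-copy region
(LSC, SSC) separated by two exact inverted repeats (IRa, IRb). Annotating
them by similarity against an annotated reference works well for
single-exon genes but fails systematically in three places:

* **micro-exons** — the first exons of *petB*, *petD* and *rpl16* are
  only 6, 8 and 9 bp long, far below what local similarity search can
  detect;
* **the trans-spliced *rps12* gene** — exon 1 lies in the LSC while
  exons 2(+3) sit inside the inverted repeats, so a two-IR genome
  produces two transcripts sharing exon 1, and the 26-bp last exon is
  again invisible to similarity search;
* **tRNA genes** — the two standard predictors disagree, one being more
  reliable for intron-less and the other for intron-bearing genes.

`plastannot` implements the full pipeline for these cases:

* a self-contained seeded local aligner (exact k-mer seeds, affine-gap
  window alignment, Karlin–Altschul-style E-values), HSP chaining and
  reference-projection refinement for protein-coding and rRNA genes;
* **anchored micro-exon detection**: the 50 bp of UTR immediately
  flanking a micro-exon are highly conserved, so the anchor+exon
  concatenation is scanned at E ≤ 1e-20 and the exon is cut from the hit
  footprint by the reference exon length (5′ anchors for
  *petB*/*petD*/*rpl16*, a 3′ anchor for the *rps12* last exon);
* **trans-splicing assembly**: *rps12* exons are located independently
  (all genomic copies kept) and joined per IR copy, yielding one
  transcript per IR sharing exon 1;
* tRNA prediction **reconciliation** (intron-less loci from a
  tRNAscan-SE-style file, intron-bearing loci from an ARAGORN-style
  file) with name validation against reference tRNAs, written to a
  warnings table;
* repeat discovery: SSRs (unit 1–6 bp, MISA-style copy thresholds),
  longer tandem repeats (unit > 6 bp, consensus by column majority) and
  dispersed forward/palindromic repeat pairs;
* exploratory diversity: SAM pileups (Rsamtools), threshold-based
  heteroplasmic SNP calling, C→U RNA-editing site detection with codon
  effects, and a read prefilter;
* writers for GFF3, GenBank flat files, NCBI 5-column feature tables
  (+FASTA) and a deterministic SVG circular map;
* a deterministic synthetic-plastome and read simulator
  (`generate_plastome()`, `simulate_reads()`) that provides ground truth
  for every test in the package.

## Worked example

```r
library(plastannot)

truth <- generate_plastome(7)            # 34-kb quadripartite fixture
files <- fixture_write(truth, tempfile())

genome <- read_plastome_fasta(files$fasta)
db     <- load_reference(files$reference)
ann    <- annotate_genome(genome, db)
ann
#> <annotation_set> fixture: 21 models (CDS=13, rRNA=8), 0 warnings

## the micro-exons and the trans-spliced gene:
for (nm in c("petB", "petD", "rpl16")) {
  m <- Filter(function(x) x$name == nm, ann$models)[[1]]
  cat(nm, "exon 1:", interval_span(m$exons[[1]]$interval), "bp\n")
}
#> petB exon 1: 6 bp
#> petD exon 1: 8 bp
#> rpl16 exon 1: 9 bp
r12 <- Filter(function(m) m$name == "rps12", ann$models)
length(r12)                                     # two transcripts (two IRs)
#> [1] 2
interval_span(r12[[1]]$exons[[3]]$interval)     # 26-bp last exon
#> [1] 26
```

The printed exon lengths are the structure reported for *Arabidopsis*-type
plastomes: 6, 8, 9 bp micro-exons and a 26-bp trans-spliced last exon.

Repeats and diversity:

```r
find_ssrs(genome)                 # 4 planted SSRs (A12, AT7, AAG6, AAAT5)
find_tandem_repeats(genome, max_unit = 60)   # 30-bp unit x 4 copies
find_dispersed_repeats(genome, layout = ann$layout)  # 1 forward + 1 palindromic

sim <- simulate_reads(truth, "rna", depth = 40, seed = 5)
pu  <- build_pileup(sim$sam, genome)
call_editing_sites(pu, ann, genome)   # 12 planted C->U sites, all TCA->TTA (S->L)
```

## Command line

```sh
inst/cli/plastannot annotate genome.fasta --ref reference.gb --out outdir \
    --trna-a trnascan.out --trna-b aragorn.txt
inst/cli/plastannot repeats genome.fasta --out outdir
inst/cli/plastannot diversity genome.fasta --sam reads.sam \
    --gff outdir/plastome.gff3 --mode both --out outdir
```

`annotate` writes `plastome.gff3`, `plastome.gb`, `plastome.tbl`,
`plastome.fsa`, `map.svg`, `warnings.tsv` and `run.log`; exit status is 0
on success, 2 for an empty annotation, 1 on a hard error.

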