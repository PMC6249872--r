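# qpcrdesign

Splice-variant-aware design of quantitative PCR (qPCR) assays in R, with
transcriptome-wide specificity screening, SNP-aware primer placement and
secondary-structure (minimum-free-energy, MFE) ranking.

## Who this is for

Anyone who needs ready-to-run qPCR assays for gene-expression targets —
primer pairs that amplify a known subset of a gene's splice variants, avoid
off-target amplification of similar genes, sit outside known polymorphic
sites, and are unlikely to fold into hairpins or primer dimers under the
assay's annealing conditions. The package takes the four standard reference
inputs (genome FASTA, GFF3 gene annotation, transcriptome FASTA, variant
VCF) plus a list of target transcript ids, and produces one assay per
splice-variant category per gene, together with full run statistics.

## The method

For each target transcript the pipeline:

1. **Generates up to 200 candidate primer pairs** inside the 3′-most
   1500 bases of the target: primers of 18–27 nt with 40–60 % GC and
   melting temperature (Tm) 58–62 °C, products of 80–150 bp (optimum
   115 bp), or 50–70 bp (optimum 60 bp) for targets too short to admit a
   standard product; targets under 50 bp are excluded. Tm is
   nearest-neighbour (SantaLucia unified parameters) with the Owczarzy
   monovalent-salt correction at 200 mM:
   1/Tm([Na⁺]) = 1/Tm(1 M) + (4.29·f(GC) − 3.95)·10⁻⁵·ln[Na⁺] +
   9.40·10⁻⁶·ln²[Na⁺].
2. **Screens for cross-hybridisation** against the whole transcriptome: a
   primer "matches" a transcript wherever an ungapped full-length placement
   exceeds 0.7 identity (primer length as reference, strict inequality).
   Forward/reverse matches on opposite strands that imply an amplicon
   smaller than 20× the intended product are candidate off-target
   amplifications. Hits to other genes are fatal; hits to sibling splice
   variants of the same gene define the set of variants the pair amplifies.
3. **Screens for SNP contamination**: for every variant inside the gene's
   genomic span a "corona" sequence of 26 bases on each side of the locus
   is extracted from the genome; a primer is flagged when it (or its
   reverse complement) occurs exactly in the corona with the occurrence
   covering the variant.
4. **Scores secondary structure** with ViennaRNA (`RNAfold` hairpins,
   `RNAcofold` primer dimers) using the `dna_mathews2004` DNA parameters at
   the 60 °C annealing temperature.
5. **Selects assays**: pairs failing any screen are dropped; survivors are
   partitioned by the exact subset of splice variants they amplify; within
   each subset the pair with the *maximum* dimer MFE (least dimer-prone)
   becomes the assay.

A seeded synthetic-reference generator (multi-exon genes, exon-skipping
isoforms, near-identical decoy paralogs, SNVs planted at known coordinates)
provides ground truth for testing every stage.

## Worked example

```r
library(qpcrdesign)

# a small self-consistent reference set with known ground truth:
# 3 genes, splice variants, one 95%-identity decoy paralog, 10 planted SNVs
tr <- generate_fixture(fixture_spec(seed = 7, n_genes = 3, n_planted_snvs = 10,
                                    snv_placement = "primer_window"))
tr$bundle
#> ReferenceBundle: 4 chromosome(s) (12,769 bp), 4 gene(s), 5 transcript(s), 10 variant(s)

res <- run_pipeline(run_config(targets = tr$targets,
                               generation = generation_config(n_pairs_requested = 50),
                               seed = 1),
                    bundle = tr$bundle)
res$outcomes
#>   gene_id           status n_categories
#> 1     G01    no_valid_pair            0
#> 2     G02 assays_generated            2
#> 3     G03 assays_generated            1
```

G01 is the gene the decoy paralog was copied from: every candidate pair
also amplifies the decoy, so no specific pair exists — the intended
behaviour of the specificity screen. The run statistics and the first
selected assay:

```r
s <- res$stats
sprintf("n_p = %d, n_X = %d, n_SNP = %d, assays = %d", s$n_p, s$n_X, s$n_SNP, s$n_assays)
#> "n_p = 150, n_X = 50, n_SNP = 6, assays = 3"

res$assays[[1]]
#> G02|G02T1.A1
#>   fwd CCGCCATTATATTCGTATGACG (Tm 59.9 C)
#>   rev GGTCCCAGTACAGCTTGAT (Tm 59.9 C)
#>   product 115 bp, dimer MFE -1.21 kcal/mol, amplifies: G02T1
```

`n_p` is the number of candidate pairs considered, `n_X` the pairs flagged
for cross-hybridisation (all 50 of G01's), `n_SNP` the pairs overlapping a
planted SNP. With an output directory set, `run_pipeline()` also writes
`assays.json`/`assays.tsv`, `primers.fa`, `amplicons.fa`, `primers.bed`,
the per-pair table and the statistics report (ΔTm histogram, MFE
distributions before/after selection, failed-vs-successful target-length
CDFs).

A thin command-line wrapper with `make-fixtures`, `check-refs`, `design`
and `stats` subcommands is installed under `inst/cli/qpcrdesign`.

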