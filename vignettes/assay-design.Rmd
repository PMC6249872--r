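---
title: "Designing splice-variant-aware qPCR assays: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing splice-variant-aware qPCR assays: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrdesign)
```

# The problem

A qPCR assay for gene-expression analysis is more than a primer pair. The
pair must amplify a *known* subset of the gene's splice variants and
nothing else in the transcriptome; neither primer may sit on a common
polymorphism, which can abolish binding in some individuals; and the pair
must behave under a universal reaction protocol, which constrains product
size, melting temperatures and secondary-structure propensity. This
package implements that whole filtering cascade around a simple candidate
generator, together with a synthetic-reference generator that gives every
screen a known ground truth.

# Pipeline model and assumptions

The pipeline treats each target transcript independently (and can process
targets in parallel; outputs are merged in sorted target order so the
worker count never changes a byte of output). Per target:

candidate generation → cross-hybridisation screen → SNP screen →
structure scoring → quality filter → variant categorisation → per-category
selection.

Key modelling assumptions:

* **Specificity is a transcriptome property.** Off-target screening runs
  against the transcriptome only; intronic or intergenic binding sites are
  not considered (a primer pair cannot amplify what is not transcribed in
  the assayed material).
* **Primer binding is ungapped.** For 18–27-mers, indel-containing duplexes
  are marginal binders; matches are scored as full-length ungapped
  placements, and "similarity" is identities divided by primer length.
  This makes the 0.7 threshold exact and the screen deterministic.
* **A single overlapping SNP is a hard flag.** No attempt is made to model
  the quantitative effect of a mismatch on Tm; a primer whose genomic
  binding site covers a known variant is discarded.
* **Structure at annealing temperature.** Hairpin and dimer minimum free
  energies are computed with DNA parameters at the annealing temperature
  (60 °C), not at 37 °C, since that is the temperature at which the
  competing structures would interfere with priming.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `n_pairs_requested` | 200 | pairs | candidate pool per target; large enough that screens can discard heavily |
| `product_range_standard` / opt | 80–150 / 115 | bp | efficient qPCR amplicon size under universal cycling |
| `product_range_short` / opt | 50–70 / 60 | bp | fallback for targets too short for a standard product |
| `min_target_length` | 50 | bp | below this no sensible primer pair exists; target excluded |
| `three_prime_window` | 1500 | bp | primers restricted to the 3′-most window, matching oligo-dT-primed RT coverage |
| `monovalent_salt` | 200 | mM | reproduces measured Tm under the intended master mix |
| `annealing_temp` | 60 | °C | assay annealing temperature; also the folding temperature |
| `primer_length` | 18–27 | nt | enumeration range of the internal generator |
| `gc_range`, `tm_range` | 40–60 %, 58–62 °C | | per-primer admissibility window |
| `min_similarity` | 0.7 (strict >) | fraction | cross-hybridisation match threshold, primer length as reference |
| `max_product_factor` | 20 (strict <) | × | an off-target "amplicon" larger than 20× the intended product will not amplify efficiently |
| `seed_length` | 6 | bp | word size for the optional external blastn backend |
| `flank` | 26 | bp | corona half-width; accommodates any full primer up to 27 nt over the locus |
| `min_freq` | 0.01 (inclusive ≥) | fraction | variants rarer than 1 % are ignored |

Melting temperature is nearest-neighbour thermodynamics (SantaLucia
unified parameter set, 25 nM strand concentrations) with the Owczarzy
reciprocal monovalent-salt correction; the test suite pins the
implementation to an independent reference implementation to within
0.1 °C.

# Candidate generation

Candidate pairs are produced by an internal enumeration engine: every
primer window of length 18–27 nt within the 3′ window is scored once
(an O(n) cumulative-sum computation per window width), windows passing the
GC and Tm filters are paired per product size, and pairs are ranked by
mean |Tm − 60 °C| of the two primers plus |product − optimum|. The engine
is deliberately simple — the package's contribution is the screening
cascade around generation, and the generator is a pluggable stage. Two
semantics were fixed here that a black-box generator leaves open:

* **Mode switch.** "Long enough for standard mode" means the effective
  (3′-window-truncated) target admits a standard product at all, i.e.
  length ≥ 80 bp; shorter targets use the 50–70 bp window; below 50 bp the
  target is excluded with a typed `target_too_short` condition.
* **3′ restriction.** Implemented by truncating the input to its 3′-most
  1500 bases before enumeration and shifting coordinates back — the
  simplest semantics under which "no primer base lies 5′ of
  length − 1500" holds exactly.

# Cross-hybridisation screen

The scanner reports *every* full-length placement of a primer (and its
reverse complement) on every transcript whose identity exceeds
`min_similarity` strictly. It is complete — equivalent to exhaustive
alignment over every offset and strand — implemented as bit-parallel
Hamming-distance matching (Wu–Manber) in compiled code over an encoded,
concatenated transcriptome. A word-seed heuristic was deliberately *not*
used for the default backend: with a 0.7 threshold a 20-mer may match with
5 mismatches, which need not leave a 6-bp exact word, so a seeded scan
cannot guarantee completeness. The seed length and e-value parameters
apply to the optional external `blastn -task blastn-short` backend, whose
results pass through the same strict similarity rule.

Matched forward/reverse placements on one transcript become an off-target
amplification event when they lie on opposite strands in amplifiable
orientation and the implied product — measured from the 5′-most base of
the upstream placement to the 3′-most base of the downstream placement,
inclusive — is at least the combined primer length (shorter products are
physically impossible) and strictly smaller than `max_product_factor` ×
the intended product.

Classification distinguishes three situations: hits confined to the
intended transcript (`clean`; the pair's own design site is recorded but
never counts as off-target), hits to sibling splice variants
(`variants_only`, or `all_variants` when every variant of the gene is
amplified), and any hit to a different gene (`other_gene`, or `mixed` when
sibling hits coexist) — the last two set the fatal `crosshyb_fail` flag. A
transcript absent from the annotation is conservatively treated as a
different gene. Pairs amplifying *all* variants are kept as their own
category rather than discarded: an all-variant assay is a legitimate
gene-level expression assay, and per-category variant counts are part of
the reported statistics.

# SNP screen

For each variant inside the gene's genomic span, a corona — the reference
genome from 26 bases before the variant's first base to 26 bases after its
last — is extracted; an SNV corona is 53 bp unless clipped at a chromosome
end. A primer is flagged when the full primer (or its reverse complement;
the binding strand depends on gene orientation) occurs *exactly* in a
corona with the occurrence interval covering the whole variant locus.
"Full-length exact and covering" is the declared interpretation of
match filtering by length and location: a partial match cannot place the
complete binding site over the variant, and the 26-base flank guarantees
that any full primer up to 27 nt overlapping the locus lies entirely
inside the corona. Coronas are built from the reference allele only; ALT
substitution is not searched. Coronas containing N are emitted but marked
unusable, so no primer can match them.

One structural blind spot is documented rather than patched: a primer
spanning an exon–exon junction has no contiguous genomic binding site, so
the corona method cannot see variants under it. The planted-SNP recovery
tests therefore assert exact sensitivity and specificity over primers with
a contiguous genomic footprint and treat junction-spanning primers as
out of scope for this screen.

# Structure scoring and selection

Hairpin MFEs come from `RNAfold`, dimer MFEs from `RNAcofold`, both with
the `dna_mathews2004` DNA parameter set at 60 °C, batched over all
distinct sequences of a target in a single process invocation. "No
structure below 0 kcal/mol" is encoded as exactly 0.0 with an empty
structure string, which under max-MFE selection naturally sorts as the
least dimer-prone value. Dimer calls canonicalise the argument order, so
symmetry holds exactly. If the engine or parameter file is missing the
backend raises a typed `backend_missing` error — never a silent default —
and a deterministic rule-based stub backend (longest Watson–Crick
complementary run, with an optional lookup-table override) allows ranking
logic to be exercised without the thermodynamics engine.

Selection applies the three quality criteria (no other-gene
cross-hybridisation, no SNP overlap, generation criteria passed), groups
survivors by the exact amplified-variant subset, and takes the member with
the maximum dimer MFE per category. MFE ties — common at the 0.0 sentinel
— are broken by lower generator penalty rank, then lexicographic pair id,
giving a deterministic total order. Hairpin MFEs are stored and reported;
a configurable hairpin cutoff exists but is off by default, since the
selection rule operates on dimer MFE alone. One assay is emitted per
category with no additional per-gene cap, and the amplicon sequence is
taken from the intended target transcript (per-variant amplicons of a
multi-variant category may differ and are not enumerated).

# Coordinates and formats

Internally every interval is 1-based inclusive — the Biostrings/IRanges
convention this package is built on — applied uniformly across modules so
no boundary crossing ever reinterprets a coordinate. Conversions happen
only at serialisation: GFF3 and VCF are read and written 1-based, BED
output is 0-based half-open, and exported candidate TSVs carry 0-based
starts. VCF frequencies are read from a configurable INFO key (default
`AF`, one value per ALT allele; `CAF`-style lists whose first entry is the
reference-allele frequency are also understood), and multi-allelic rows
are split into one record per ALT before screening. Variants without any
frequency annotation pass the 1 % filter by default — the cut is only
meaningful where frequencies exist, and whole catalogues (e.g. for less
annotated species) may lack them — with a strict mode to drop them.

# What the synthetic fixtures emulate — and what they do not

`generate_fixture()` builds a self-consistent reference set: multi-exon
genes on their own chromosomes, splice variants produced by skipping
subsets of internal exons from a master chain (guaranteeing shared and
unique regions, so both all-variant and variant-specific categories are
reachable), decoy paralogs as point-mutated full-length copies of a master
transcript annotated as distinct genes on separate chromosomes (making
"other gene" classification well-defined), and SNVs planted in exonic
sequence — optionally concentrated within 30 bp of exon 3′ ends, where
primers preferentially land, to maximise the power of the SNP-screen
tests. Every emitted variant's REF allele matches the genome by
construction, and identical seeds reproduce byte-identical files.

The fixtures are uniform-composition random sequence: they have no repeat
families, no GC skew, no homopolymer runs, no gene families beyond the
planted decoys, and no indel variants. Passing tests on fixtures therefore
demonstrates the *correctness of the screening logic* (thresholds,
geometry, classification, selection, bookkeeping), not the discard rates
to expect on a real genome, where repeats and paralog families make
cross-hybridisation far more common.

# Numerical choices and degenerate inputs

* Strict thresholds are evaluated on integer identity counts
  (`identities ≥ ⌊0.7·L⌋ + 1`), so floating-point noise cannot flip a
  boundary case; 14/20 is never reported, 15/20 always is.
* The candidate enumerator keeps a bounded running top-K during pairing,
  so memory stays flat on primer-dense targets; final ranking ties are
  broken by position, product size and primer widths, making ranks a
  reproducible strict total order.
* Targets shorter than 50 bp raise a typed condition that the pipeline
  converts into the `too_short` outcome; a gene whose 200 candidates are
  all flagged becomes `no_valid_pair`; any unexpected stage error
  quarantines the affected target without aborting the run.
* Empty inputs (no variants, no matches, no survivors) flow through every
  stage as zero-row tables, not errors.
* All randomness derives from a single run seed, with per-target
  sub-seeds assigned by sorted target id, so results are independent of
  worker count and processing order.

# Problem sizes used by the checks

The test-suite runs use 3–5-gene fixtures for unit-level properties and a
50-gene fixture (1–3 variants per gene, 5 decoys, 120 planted SNVs,
30 requested pairs per target) for run-level properties such as selection
optimality and tally conservation. The reproduction script uses a 20-gene
fixture with the full 200-pair request. These sizes were chosen as the
smallest at which every behaviour of interest (multi-variant categories,
decoy-driven failures, SNP flags, MFE-tail compression) occurs robustly
across seeds.

# Known limitations

* Template (amplicon) secondary structure in the primer-binding regions is
  not analysed; only primer hairpins and primer–primer dimers are scored.
* Junction-spanning primers escape the SNP screen (see above).
* The internal candidate generator does not reproduce the full penalty
  model of dedicated primer-design engines; it enforces the documented
  GC/Tm/product constraints and a simple optimality score. The generation
  stage is pluggable for users who want an external engine.
* Off-target search is transcriptome-only by design; genomic DNA
  contamination amplifying intronic sites is outside the model.
* No probe (hydrolysis/TaqMan) design and no multiplex compatibility
  checking.
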