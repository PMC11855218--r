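---
title: "Detecting and classifying cryptic insertion elements in phage genes"
author: "cryptorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying cryptic insertion elements in phage genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptorf)
```

## The problem

Phage coding genes -- DNA methylases, capsid proteins, tail proteins --
are frequent targets of mobile genetic elements. The familiar kinds
announce themselves: a self-splicing **intron** interrupts the reading
frame (translating straight through it usually hits a stop codon within
a few codons), and an **intein** reads through seamlessly but carries a
recognisable splicing apparatus: a nucleophilic Cys/Ser/Thr at its
N-terminus, a terminal Asn, conserved interior blocks, and a
splicing-compatible (+1) Thr/Ser/Cys as the first host residue after
the insertion site.

A third, cryptic arrangement exists: an in-phase, stop-free insertion
that carries **no** detectable splicing machinery in its own frame, but
conceals a complete protein -- typically an HNH homing endonuclease --
in an *alternate* reading frame, starting at a non-canonical GTG and
ending at a stop placed in the element's final bases. Read in the host
frame the element is an unremarkable seamless peptide; read in the
hidden frame it is an endonuclease with a central His-Asn-His catalytic
triad and flanking CXX(X)C zinc fingers. The canonical layout this
package reproduces as its fixture: a 606-nt insertion, GTG at 1-based
positions 18--20 (third frame relative to the host), TAA at 603--605,
last four bases `TAAC`, a seamless 202-aa host-frame reading, and a
195-aa hidden product.

`cryptorf` turns the manual workflow that uncovers such elements into a
tested pipeline:

1. **map** insertion blocks from a protein alignment of invaded and
   uninvaded homologs (runs of columns where every uninvaded member is
   gapped);
2. **test continuity** of each insertion in the host frame;
3. **scan all six frames** of the insertion for hidden ORFs, with
   start-codon set {ATG, GTG, TTG};
4. **collect signatures**: intein residue/motif tests, group I/II
   intron end motifs, the 5'-insertion/3'-flank similarity statistic,
   HNH and zinc-finger motif scans;
5. **classify** with a transparent rule cascade and emit GFF3 / JSON /
   TSV plus query FASTA for downstream database searches.

## The classification rules

Classification mirrors the elimination order used in element
characterisation, and every rule demands a conjunction -- single motifs
arise too easily by chance:

| priority | label | requires |
|---|---|---|
| 1 | `intein_candidate` | seamless AND +1 ∈ {T,S,C} AND terminal Asn (or Ser variant) AND ≥1 splicing-block hit |
| 2 | `group1_intron_candidate` | terminal G, OR interrupted + flank identity ≥ threshold |
| 3 | `group2_intron_candidate` | 5' `GTGCG` |
| 4 | `hidden_orf_element` | alternate-frame ORF ≥ `min_orf_len_aa` |
| 5 | `unclassified` | none of the above |

All labels are *candidate* classes: no rule asserts actual splicing or
cutting activity. Satisfied lower-priority rules are kept as co-labels
in the notes, never discarded.

The **flank-similarity threshold** defaults to 70%. Published group I
introns can mimic their 3' exon flank at their 5' end (both interact
with the intron's internal guide sequence); reported identities for
real elements of this kind sit in the 65--76% band, so 70% splits that
band. It is a configured choice, not a derived constant, and the raw
statistic is always reported next to the decision.

The **intein splicing blocks** (A/B/F/G) ship as deliberately loose
regex sketches (`^[CST]`, `T..H`, `[LIVM]H[NQ]`, `[HN][NS]$`) in
`inst/extdata/intein_blocks.tsv`; the motif literature describes these
blocks as positional preferences rather than strict consensus, so the
file is user-overridable and a hit only ever counts inside rule 1's
conjunction.

**HNH spacing** defaults to 10--60 residues between H and N and between
N and H, bracketing the compact cores of solved phage HNH structures;
**zinc-finger pairing** accepts two CXX(X)C motifs within 40 residues.
Both are exposed as parameters.

## Coordinates and conventions

All coordinates, everywhere, are 1-based inclusive -- the
R/Bioconductor convention. (The design alternative, 0-based half-open
internals with 1-based output, buys nothing in R and doubles the
conversion surface.) Hence "GTG at positions 18--20" is exactly
`substr(x, 18, 20)`. Frame index is `((start - 1) %% 3) + 1` relative
to the host frame; minus-strand ORFs are reported in coordinates of the
reverse complement with `orig_start`/`orig_end` locating them on the
input. GTG/TTG-initiated products keep their literal Val/Leu first
residue (a `genetic_code(initiator_to_met = TRUE)` flag remaps it).
Codons containing N translate to X and are never starts or stops. Stop
offsets follow the "reached N bp into the insertion" convention: the
offset of the *last* base of the stop codon, always a multiple of 3.

Within one stop-anchored ORF the most upstream start is primary
(ties in the global ranking: longest product, then forward strand, then
smallest start) -- matching the choice of the most upstream plausible
start for the canonical element.

## The synthetic world

Real sequences of this family live in public phage databases without
printed accessions, so the package carries a generator that emulates
them, and every test runs against generated data with exact ground
truth.

`plant_hidden_orf()` builds an insertion by **constrained codon-wise
construction**: the hidden ORF's codons are laid down first (synonymous
choices free, planted H/N/H and CXX(X)C residues fixed), then a
randomized sweep-repair loop mutates free bases and resamples
synonymous codons until the host frame is stop-free, no in-frame start
codon precedes the planted one, the 5' end is not `GTGCG`, the 3' base
is not G, and the host-frame translation is free of the shipped intein
block patterns. Naive whole-sequence rejection cannot do this job: a
~590-nt stop-free run in a *shifted* frame has probability around
$(61/64)^{196} \approx 10^{-4}$ per attempt in one frame, and jointly
with the host-frame and motif constraints the acceptance probability is
effectively zero. One repair move goes beyond synonymous resampling:
background product residues (never planted motif residues) may be
swapped outright, because a fixed start codon followed by a residue
whose codons all begin with A locks the overlapping host codon at TGA.
The truth record carries the final product, and a test asserts that
rescanning the emitted insertion recovers the planted layout exactly.

By default the generated product's background composition excludes H,
N and C so that motif-scan ground truth is unambiguous (planted motifs
are provably the only ones), and excludes the single-codon residues
M and W so every background codon has a synonymous alternative for
repair. This is a deliberate unrealism: real products contain those
residues, and a green motif test here establishes correctness of the
scan, not realistic specificity.

`make_host_family()` emulates the homolog family: a stop-free ancestral
CDS, per-codon substitution noise (synonymous-biased,
site-independent, no indels outside planted insertions -- so boundary
recovery can be asserted exactly), an insertion planted between the
same two codons of every invaded member, and the alignment emitted
alongside. Invaded members receive a Thr at the +1 flank position (the
"conversion track" such elements carry along), uninvaded members a Pro.
Fixture lengths not printed anywhere were chosen once: 402 nt for the
intron-interrupted fixture, 507 nt for the frame-2 fixture carrying the
483-nt hidden coding span.

Flank mimicry (the group I signature) is controlled per position: with
probability *p* the insertion's head residue copies the C-flank
residue, otherwise it is drawn from the other background residues, so
each window position is exactly Bernoulli(*p*) and the group mean
recovers 100 *p*. Because the canonical hidden-ORF layout's first 11
host-frame residues overlap the planted frame-3 ORF, arbitrary mimicry
levels are generated on inert-class (stop-free, ORF-free) insertions;
the acceptance run uses *p* = 0.7, inside the band reported for real
invaded families.

The `group_flank_similarity()` aggregation is the arithmetic mean of
(insertion head vs each member's own C-flank) comparisons within a
group -- one of several aggregations consistent with published
percent-identity pairs; the choice is recorded here and in the
function's documentation. The nucleotide window is 3 x the residue
window (33 nt for the default 11).

## What the tests establish -- and what they do not

The suite verifies: translation and six-frame enumeration against an
independent Biostrings oracle; the ORF scanner against exhaustive
brute-force enumeration on 1000+ random sequences; exact recovery of
planted insertion boundaries and ORF layouts; binomial recovery of the
mimicry parameter; and 100% label accuracy on the noiseless four-class
benchmark. Because the benchmark classes are generated to satisfy their
own definitions, that accuracy measures the internal consistency of
generator + pipeline, not performance on diverged natural sequences.
Mutational noise, indel noise in alignments, GC-content realism,
recombination and homing dynamics are all outside the generated world.
Database searches (BLASTP/HHpred/Foldseek), RNA secondary structure and
protein structure prediction are out of scope by design -- the pipeline
*prepares* query FASTA for them and stops there.

## Degenerate inputs and edge policies

* Insertions not a multiple of 3 nt, or not between codons, are
  reported with a `phase_warning` rather than dropped.
* An insertion at the very end of a gene yields an empty C-flank; the
  +1 test is skipped with a flag rather than failed.
* Flank windows running off the gene are clipped and flagged.
* An empty finding set is a successful run, not an error.
* Open-ended ORFs (no stop inside the insertion) are a non-default,
  flagged mode (`require_stop = FALSE`).

## Reproducibility

Every generator takes a seed; the same seed gives byte-identical
output. Fixture builders re-derive attempt seeds from the master seed
and verify the printed layout post hoc, so any small integer seed
yields a valid canonical fixture. `scripts/acceptance.R --seed N --out
f.json` regenerates all fixtures from scratch and reports the measured
quantities.
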