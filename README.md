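# cryptorf

Detection and classification of cryptic insertion elements — and the
out-of-frame ORFs they can hide — in phage coding genes.

## The problem

Some insertion elements in phage genes are neither introns nor inteins.
They sit in-phase between two codons, add no internal stop codon when
the host gene is read straight through, yet carry none of the residues
or motifs that self-splicing requires. The resolution can hide in
plain sight, one reading frame over: an HNH homing endonuclease encoded
in an alternate frame of the insertion, starting at a non-canonical GTG
a few codons in and ending at a stop tucked into the element's last
bases. Finding such elements means (a) locating insertions by
comparing invaded and uninvaded homologs, (b) testing in-frame
continuity, (c) scanning all six reading frames with an extended
start-codon set, and (d) weighing intein, intron, and hidden-ORF
evidence against each other. `cryptorf` implements that workflow as a
tested R package, for phage genomicists and mobile-element researchers.

The canonical element layout (built into the package as a synthetic
fixture with exact ground truth): a 606-nt insertion in a DNA methylase
gene; host-frame reading seamless, 202 aa; GTG at 1-based positions
18–20 — the third frame relative to the host — and TAA at 603–605 with
terminal `TAAC`, yielding a 195-aa hidden product with a central
His-Asn-His triad and flanking CXX(X)C zinc fingers.

## Core statistics and rules

* **Continuity**: first in-frame stop offset (bp, last base of the stop
  codon), or seamless.
* **Hidden-ORF scan**: every stop-anchored ORF in all six frames,
  starts {ATG, GTG, TTG}, most upstream start primary, ranked by
  product length.
* **Flank similarity**: ungapped percent identity between the first 11
  residues of the insertion (host frame) and the 11 residues
  C-terminal of the insertion site — the group I intron mimicry
  statistic.
* **Intein tests**: +1 ∈ {T,S,C} (Pro flagged as splicing-inhibiting),
  terminal Asn (Ser variant tracked), splicing-block motif scan.
* **Intron end motifs**: terminal G (group I), 5′ `GTGCG` (group II).
* **Motif scans**: H-N-H triads at 10–60 residue spacings; paired
  CXX(X)C zinc-finger motifs within 40 residues.
* **Classifier**: priority cascade intein > group I > group II >
  hidden ORF, each rule a conjunction, co-labels retained.

## Worked example

```r
library(cryptorf)

fx <- make_shilan_fixture(seed = 1)   # canonical 606-nt element + truth
fx$insertion
#> <nuc_seq planted_hidden_orf: 606 nt>

continuity_test(fx$insertion)
#> seamless in-frame reading (no internal stop), 202 aa

orfs <- scan_hidden_orfs(fx$insertion)  # six frames, starts ATG/GTG/TTG
orfs[[1]]
#> <hidden_orf primary strand + frame +3: start 18 (GTG), stop 605, 195 aa>

str(intron_signature(fx$insertion))
#> List of 2
#>  $ g_3prime    : logi FALSE
#>  $ gtgcg_5prime: logi FALSE

hnh_motif_scan(orfs[[1]]$product)$hits
#>   h1  n  h2
#> 1 67 97 127
```

The insertion reads through seamlessly in the host frame (202 aa, no
internal stop), so it is not intron-interrupted; it lacks both intron
end motifs; and the six-frame scan surfaces a primary frame-3 ORF with
a GTG start 18 bp in and a 195-aa product whose H-N-H triad sits at
product positions 67/97/127. The rule cascade draws the same
conclusion end to end:

```r
call <- characterize_locus(cryptorf:::standalone_locus(
  fx$insertion, c_flank_aa = fx$c_flank_aa))
call
#> <element_call planted_hidden_orf: hidden_orf_element / hnh_endonuclease>
```

For a whole gene family, `make_host_family()` simulates invaded and
uninvaded homologs with an alignment and truth records,
`find_insertion_blocks()` maps the insertions, and `run_pipeline()`
drives everything from FASTA to GFF3/JSON/TSV reports plus query FASTA
for external database searches. A command-line front end is exported:

```sh
Rscript -e 'cryptorf::cryptorf_cli()' simulate --out fam/ --seed 3
Rscript -e 'cryptorf::cryptorf_cli()' run --cds fam/cds.fna \
    --groups fam/groups.tsv --alignment fam/alignment.faa --out results/
```

## Scope

No database searches, structure prediction, RNA folding, or phylogeny:
the pipeline prepares query FASTA for those tools and stops. See
`vignettes/cryptic-elements.Rmd` for the model, parameter rationale,
generator design, and limitations.
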